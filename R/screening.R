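#' Reaction profiles and viability screening
#'
#' The generalized serine-hydrolase degradation mechanism runs
#' RC -> TS1 -> TI1 -> TS2 -> EAM (acylation: nucleophilic attack of the
#' catalytic serine and release of the drug) and
#' EAM -> TS3 -> TI2 -> TS4 -> PC (deacylation: hydrolysis of the
#' acyl-enzyme and release of the polymeric carrier). A `reaction_profile`
#' stores the per-transition-state free-energy barriers of one conjugate in
#' one phase; screening compares the rate-limiting (largest) barrier
#' against a kinetic viability threshold, 25.0 kcal/mol by default.
#'
#' @name mechanism
NULL

.phase_ts <- list(acylation = c("TS1", "TS2"), deacylation = c("TS3", "TS4"))
.state_labels <- c("RC", "TS1", "TI1", "TS2", "EAM", "TS3", "TI2", "TS4", "PC")

#' Assemble a validated reaction profile
#'
#' @param id conjugate identifier, digits plus an optional letter (the
#'   screening set's naming grammar, e.g. `"2a"`, `"4b"`, `"11c"`).
#' @param phase `"acylation"` (TS1, TS2) or `"deacylation"` (TS3, TS4).
#' @param barriers named numeric vector of per-TS barriers, kcal/mol,
#'   non-negative; every TS of the phase must be present unless
#'   `partial = TRUE` (e.g. a scan resolving only one step).
#' @param provenance `"PES"` (potential-energy scan) or `"FEL"`
#'   (free-energy landscape).
#' @param states optional named per-state relative energies, kcal/mol.
#' @param partial allow a subset of the phase's transition states.
#' @return a `reaction_profile` list.
#' @examples
#' assemble_profile("2a", "acylation", c(TS1 = 22.0, TS2 = 22.2), "FEL")
#' @export
assemble_profile <- function(id, phase = c("acylation", "deacylation"),
                             barriers, provenance = c("FEL", "PES"),
                             states = NULL, partial = FALSE) {
  phase <- match.arg(phase)
  provenance <- match.arg(provenance)
  if (!grepl("^[0-9]+[a-z]?$", id))
    stop("id '", id, "' does not match the conjugate naming grammar (digits + optional letter)")
  need <- .phase_ts[[phase]]
  if (is.null(names(barriers)) || !all(names(barriers) %in% need))
    stop("barriers must be named with the ", phase, " transition states: ",
         paste(need, collapse = ", "))
  if (!partial && !all(need %in% names(barriers)))
    stop("missing transition state(s): ",
         paste(setdiff(need, names(barriers)), collapse = ", "))
  if (any(barriers < 0)) stop("barriers must be non-negative")
  if (!is.null(states) && !all(names(states) %in% .state_labels))
    stop("unknown state label(s): ",
         paste(setdiff(names(states), .state_labels), collapse = ", "))
  barriers <- barriers[order(match(names(barriers), need))]
  structure(list(id = id, phase = phase, barriers = barriers,
                 states = states, provenance = provenance),
            class = "reaction_profile")
}

#' @export
print.reaction_profile <- function(x, ...) {
  cat(sprintf("reaction_profile %s (%s, %s): %s kcal/mol\n", x$id, x$phase,
              x$provenance,
              paste(names(x$barriers), sprintf("%.1f", x$barriers),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Rate-limiting step of a profile
#'
#' The transition state with the largest barrier; exact ties are broken
#' towards the later step, so the reported step is the one nearest product.
#'
#' @param profile a [assemble_profile()] object.
#' @return named length-1 numeric: the rate-limiting barrier, named by its
#'   transition state.
#' @examples
#' rate_limiting(assemble_profile("4b", "acylation",
#'                                c(TS1 = 20.2, TS2 = 19.1), "FEL"))
#' @export
rate_limiting <- function(profile) {
  stopifnot(inherits(profile, "reaction_profile"))
  b <- profile$barriers
  i <- max(which(b == max(b)))  # tie towards the later step
  b[i]
}

#' Screen reaction profiles against a viability threshold
#'
#' A conjugate is viable when its rate-limiting barrier is strictly below
#' the threshold (a barrier exactly at the threshold is too slow). Viable
#' conjugates are ranked 1..n ascending in rate-limiting barrier.
#'
#' @param profiles list of [assemble_profile()] objects with unique
#'   id/phase combinations.
#' @param threshold viability threshold, kcal/mol (default 25.0).
#' @param temperature K, for the reported Eyring rate constant.
#' @return a `screening_result` data frame: `id`, `phase`, `provenance`,
#'   one column per TS barrier, `rate_limiting_step`, `rate_limiting_dg`,
#'   `eyring_rate`, `viable`, `rank` (NA for non-viable).
#' @export
screen <- function(profiles, threshold = 25.0,
                   temperature = fel_constants$T_default) {
  if (threshold <= 0) stop("threshold must be positive")
  if (!length(profiles)) {
    out <- data.frame(id = character(0), phase = character(0),
                      provenance = character(0),
                      rate_limiting_step = character(0),
                      rate_limiting_dg = numeric(0), eyring_rate = numeric(0),
                      viable = logical(0), rank = integer(0))
    class(out) <- c("screening_result", "data.frame")
    return(out)
  }
  keys <- vapply(profiles, function(p) paste(p$id, p$phase), character(1))
  if (anyDuplicated(keys))
    stop("duplicate conjugate id(s): ", paste(unique(keys[duplicated(keys)]), collapse = ", "))
  all_ts <- unique(unlist(lapply(profiles, function(p) names(p$barriers))))
  all_ts <- all_ts[order(match(all_ts, .state_labels))]
  rows <- lapply(profiles, function(p) {
    rl <- rate_limiting(p)
    bs <- stats::setNames(rep(NA_real_, length(all_ts)), all_ts)
    bs[names(p$barriers)] <- p$barriers
    cbind(data.frame(id = p$id, phase = p$phase, provenance = p$provenance),
          as.data.frame(as.list(bs)),
          data.frame(rate_limiting_step = names(rl), rate_limiting_dg = unname(rl),
                     eyring_rate = dg_to_rate(unname(rl), temperature),
                     viable = unname(rl) < threshold))
  })
  out <- do.call(rbind, rows)
  out$rank <- NA_integer_
  out$rank[out$viable] <- rank(out$rate_limiting_dg[out$viable],
                               ties.method = "first")
  attr(out, "threshold") <- threshold
  attr(out, "temperature") <- temperature
  class(out) <- c("screening_result", "data.frame")
  out
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("screening_result: %d profile(s), threshold %.1f kcal/mol at %.2f K\n",
              nrow(x), attr(x, "threshold"), attr(x, "temperature")))
  NextMethod()
}

#' Transition-state-theory barrier/rate interconversion
#'
#' Eyring equation with unit transmission coefficient:
#' k = (kB T / h) exp(-dG / (R T)), with R expressed in kcal/mol/K so dG is
#' a molar free-energy barrier in kcal/mol. `rate_to_dg` is the exact
#' inverse.
#'
#' @param dg activation free energy, kcal/mol.
#' @param rate first-order rate constant, 1/s (> 0).
#' @param temperature K (> 0), default 310.15.
#' @return `dg_to_rate`: rate constant in 1/s. `rate_to_dg`: barrier in
#'   kcal/mol.
#' @examples
#' dg_to_rate(0)                   # kB*T/h ~ 6.46e12 /s at 310.15 K
#' rate_to_dg(dg_to_rate(19.7))    # 19.7
#' @export
dg_to_rate <- function(dg, temperature = fel_constants$T_default) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  pre <- fel_constants$kB_SI * temperature / fel_constants$h_SI
  pre * exp(-dg / (fel_constants$kB * temperature))
}

#' @rdname dg_to_rate
#' @export
rate_to_dg <- function(rate, temperature = fel_constants$T_default) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  if (any(rate <= 0)) stop("rate must be positive")
  pre <- fel_constants$kB_SI * temperature / fel_constants$h_SI
  -fel_constants$kB * temperature * log(rate / pre)
}

#' Reference per-TS barriers of the hCE2 conjugate screening set
#'
#' The published per-transition-state free-energy barriers (kcal/mol) for
#' the best-ranked polymer-drug conjugates hydrolysed by human
#' carboxylesterase 2: the acylation set (conjugates 2a, 4a, 4b, 6a-c;
#' TS1 and TS2, FEL-derived) and the deacylation set for the polymeric
#' carriers (11a-c; TS3 and TS4; 11a FEL-derived, 11b-c PES-derived).
#' Shipped as plain text under `inst/extdata/pdc_barriers.tsv`.
#'
#' @param phase optional filter, `"acylation"` or `"deacylation"`.
#' @return data frame: `id`, `phase`, `ts`, `dg`, `provenance`.
#' @export
pdc_reference_barriers <- function(phase = NULL) {
  path <- system.file("extdata", "pdc_barriers.tsv", package = "felscreen")
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(phase)) df <- df[df$phase == phase, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build reaction profiles from a long-format barrier table
#'
#' @param df data frame with columns `id`, `phase`, `ts`, `dg`,
#'   `provenance` (as returned by [pdc_reference_barriers()]).
#' @param partial passed to [assemble_profile()].
#' @return list of `reaction_profile` objects, one per id/phase.
#' @export
profiles_from_table <- function(df, partial = FALSE) {
  stopifnot(all(c("id", "phase", "ts", "dg") %in% names(df)))
  keys <- unique(df[, c("id", "phase")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$id == keys$id[i] & df$phase == keys$phase[i], , drop = FALSE]
    prov <- if ("provenance" %in% names(sub)) sub$provenance[1] else "FEL"
    assemble_profile(as.character(keys$id[i]), keys$phase[i],
                     stats::setNames(sub$dg, sub$ts), prov,
                     partial = partial)
  })
}
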