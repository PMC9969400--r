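#' Read and validate a pipeline run configuration
#'
#' YAML configuration with one block per stage. Unknown keys are rejected
#' with the offending key named, so typos never silently fall back to a
#' default. The configuration round-trips losslessly through
#' [yaml::write_yaml()].
#'
#' @param config a file path to a YAML file, or an equivalent nested list.
#' @return validated config list with defaults filled in.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1L,
    temperature = fel_constants$T_default,
    threshold = 25.0,
    out_dir = NULL,
    simulate = list(n_samples = 5000L, force_constant_kj = 200,
                    coarse_step = 0.1, fine_step = 0.02, thin = 1L),
    wham = list(bin_width = 0.02, tolerance = 1e-6, max_iterations = 1e5,
                n_boot = 0L),
    mep = list(connectivity = 8L, min_prominence = 1.0),
    candidates = list()
  )
  .check_keys(config, names(defaults), "top level")
  for (blk in c("simulate", "wham", "mep"))
    if (!is.null(config[[blk]]))
      .check_keys(config[[blk]], names(defaults[[blk]]), blk)
  cand_keys <- c("id", "phase", "pes", "fel", "correct")
  # per-stage overrides of the simulate block: steep surfaces need the
  # escalated restraint (up to 1000 kJ/mol/A^2) to keep windows overlapping
  stage_keys <- c("preset", "parameters", "fine_regions",
                  "force_constant_kj", "n_samples")
  for (cand in config$candidates) {
    .check_keys(cand, cand_keys, paste0("candidate '", cand$id, "'"))
    if (is.null(cand$id) || is.null(cand$pes))
      stop("every candidate needs an 'id' and a 'pes' block")
    for (blk in c("pes", "fel"))
      if (!is.null(cand[[blk]]))
        .check_keys(cand[[blk]], stage_keys,
                    paste0("candidate '", cand$id, "' ", blk))
    if (!is.null(cand$correct))
      .check_keys(cand$correct, c("high_preset", "high_parameters", "n_anchors"),
                  paste0("candidate '", cand$id, "' correct"))
  }
  cfg <- utils::modifyList(defaults, config)
  # modifyList merges by name and would drop the (unnamed) candidate entries
  if (!is.null(config$candidates)) cfg$candidates <- config$candidates
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown key '", unknown[1], "' in ", where,
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  invisible(NULL)
}

#' Run the full screening pipeline
#'
#' Executes simulate -> WHAM -> MEP (-> dual-level correction) -> screen
#' for every candidate, mirroring the two-stage triage of the screening
#' protocol: a 1D potential-of-mean-force pass over all candidates first,
#' then the 2D free-energy-landscape pass only for candidates whose 1D
#' rate-limiting barrier already clears the viability threshold (a 2D map
#' costs two orders of magnitude more windows, so hopeless candidates are
#' never promoted). All randomness flows from the single config seed via
#' per-candidate, per-stage substreams, so a rerun with the same config is
#' byte-identical; when `out_dir` is set every intermediate artifact
#' (window tables, PMF grids, paths, profiles, reports) is written there as
#' plain text together with a run-metadata YAML.
#'
#' Per-candidate barriers are extracted by ordering the landscape minima
#' along the first (reaction) coordinate and tracing the bottleneck path
#' between each consecutive pair; each step's barrier is the path peak
#' minus the step's starting minimum. Steps are labelled with the phase's
#' transition states in order (TS1, TS2 for acylation). When a `correct`
#' block names a high-level surrogate surface, anchor energies are taken
#' at evenly spaced nodes of the full reactant-to-product path, a natural
#' spline of the high-minus-low differences is built, and the corrected
#' profile replaces the low-level one before screening.
#'
#' @param config a [read_run_config()] config, YAML path, or nested list.
#' @param out_dir optional output directory (overrides the config's).
#' @return a `screening_report` list: `report` (the combined
#'   `screening_result`), `pes`, `fel` (stage results), `profiles`,
#'   `grids`, `paths`, `config`.
#' @export
run_screening_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!length(cfg$candidates)) stop("config lists no candidates")
  ncand <- length(cfg$candidates)
  seeds <- matrix(derive_seeds(cfg$seed, 2L * ncand), ncol = 2)

  grids <- list(); paths <- list(); profiles <- list()
  pes_profiles <- vector("list", ncand)
  for (i in seq_len(ncand)) {
    cand <- cfg$candidates[[i]]
    res <- tryCatch(
      .run_candidate_stage(cand, cand$pes, cfg, seeds[i, 1]),
      error = function(e) stop("candidate '", cand$id, "', PES stage: ",
                               conditionMessage(e), call. = FALSE))
    grids[[paste0(cand$id, ".pes")]] <- res$grid
    paths[[paste0(cand$id, ".pes")]] <- res$path
    pes_profiles[[i]] <- .stage_profile(cand, res, "PES")
  }
  pes_screen <- screen(pes_profiles, cfg$threshold, cfg$temperature)

  fel_profiles <- list()
  for (i in seq_len(ncand)) {
    cand <- cfg$candidates[[i]]
    if (!isTRUE(pes_screen$viable[i]) || is.null(cand$fel)) next
    res <- tryCatch(
      .run_candidate_stage(cand, cand$fel, cfg, seeds[i, 2]),
      error = function(e) stop("candidate '", cand$id, "', FEL stage: ",
                               conditionMessage(e), call. = FALSE))
    grids[[paste0(cand$id, ".fel")]] <- res$grid
    paths[[paste0(cand$id, ".fel")]] <- res$path
    fel_profiles[[length(fel_profiles) + 1L]] <- .stage_profile(cand, res, "FEL")
  }
  fel_screen <- screen(fel_profiles, cfg$threshold, cfg$temperature)

  final <- if (length(fel_profiles)) {
    c(fel_profiles,
      pes_profiles[!vapply(pes_profiles, function(p)
        any(vapply(fel_profiles, function(q) q$id == p$id, logical(1))),
        logical(1))])
  } else pes_profiles
  report <- screen(final, cfg$threshold, cfg$temperature)

  out <- structure(list(report = report, pes = pes_screen, fel = fel_screen,
                        profiles = final, grids = grids, paths = paths,
                        config = cfg),
                   class = "screening_report")
  if (!is.null(cfg$out_dir)) .write_pipeline_outputs(out, cfg$out_dir)
  out
}

# one simulate -> wham -> mep pass on one candidate surface; returns the
# grid, the full reactant-to-product path, and the per-step barrier vector
.run_candidate_stage <- function(cand, stage, cfg, seed) {
  landscape <- make_surface(stage$preset, if (is.null(stage$parameters)) list()
                            else stage$parameters)
  sim <- cfg$simulate
  kj <- if (is.null(stage$force_constant_kj)) sim$force_constant_kj
        else stage$force_constant_kj
  ns <- if (is.null(stage$n_samples)) sim$n_samples else stage$n_samples
  windows <- generate_window_grid(
    landscape$domain, coarse_step = sim$coarse_step, fine_step = sim$fine_step,
    fine_regions = stage$fine_regions,
    force_constant = kj_to_kcal(kj),
    n_samples = ns, temperature = cfg$temperature)
  series <- sample_windows(landscape, windows, seed, thin = sim$thin)
  hist <- histogram_windows(windows, series, bin_width = cfg$wham$bin_width)
  grid <- solve_wham(hist, windows, tolerance = cfg$wham$tolerance,
                     max_iterations = cfg$wham$max_iterations)
  if (cfg$wham$n_boot >= 2)
    grid <- bootstrap_errors(hist, windows, n_boot = cfg$wham$n_boot,
                             seed = seed, tolerance = cfg$wham$tolerance,
                             max_iterations = cfg$wham$max_iterations,
                             base = grid)
  sp <- find_stationary_points(grid, cfg$mep$connectivity,
                               min_prominence = cfg$mep$min_prominence)
  mins <- sp$minima[order(sp$minima$x1), , drop = FALSE]
  # a reaction path needs one connected sampled region: drop basins cut off
  # from the global minimum by masked (never-sampled) bins, e.g. stray
  # pockets past the sampled range
  gm <- mins$node[which.min(mins$energy)]
  comp <- .component_of(grid, gm, cfg$mep$connectivity)
  mins <- mins[comp[mins$node], , drop = FALSE]
  if (nrow(mins) < 2) stop("found ", nrow(mins), " minimum; need at least 2 basins")
  # per-step barriers between consecutive basins along the reaction coordinate
  energies <- grid$free_energy
  barriers <- numeric(nrow(mins) - 1L)
  for (s in seq_len(nrow(mins) - 1L)) {
    p <- trace_mep(grid, mins$node[s], mins$node[s + 1L], cfg$mep$connectivity)
    barriers[s] <- extract_barrier(p, reference = energies[mins$node[s]])
  }
  full_path <- trace_mep(grid, mins$node[1], mins$node[nrow(mins)],
                         cfg$mep$connectivity)
  if (!is.null(cand$correct))
    barriers <- .corrected_barriers(cand, grid, mins, full_path, cfg)
  list(grid = grid, path = full_path, barriers = barriers,
       stationary = sp)
}

# dual-level correction along the full path: anchors at evenly spaced path
# nodes, high-level energies from the surrogate high-level surface, both
# levels referenced to the path start. Corrected barriers are read off the
# anchor set itself: at an anchor E_corr = E_low + (E_high - E_low) =
# E_high exactly, so the low-level statistical noise cancels there, while
# between anchors it would leak through the spline unchanged.
.corrected_barriers <- function(cand, grid, mins, full_path, cfg) {
  high <- make_surface(cand$correct$high_preset,
                       if (is.null(cand$correct$high_parameters)) list()
                       else cand$correct$high_parameters)
  n_anchor <- if (is.null(cand$correct$n_anchors)) 11L
              else as.integer(cand$correct$n_anchors)
  prog <- path_progress(full_path)
  if (prog[1] > prog[length(prog)]) {  # anchor positions must increase
    full_path$nodes <- rev(full_path$nodes)
    full_path$coords <- full_path$coords[rev(seq_len(nrow(full_path$coords))), , drop = FALSE]
    full_path$energy <- rev(full_path$energy)
    prog <- rev(prog)
  }
  low <- full_path$energy - full_path$energy[1]
  high_e <- landscape_energy(high, full_path$coords)
  high_e <- high_e - high_e[1]
  ai <- unique(round(seq(1, length(prog), length.out = n_anchor)))
  spline <- build_correction(correction_anchors(prog[ai], low[ai], high_e[ai]))
  corrected <- apply_correction(low[ai], prog[ai], spline, offset = FALSE)
  # step boundaries: anchors nearest each basin minimum's path node
  bi <- vapply(seq_len(nrow(mins)), function(m) {
    j <- match(mins$node[m], full_path$nodes)
    if (is.na(j)) {
      cen <- as.numeric(mins[m, grep("^x[0-9]", names(mins)), drop = TRUE])
      j <- which.min(colSums((t(full_path$coords) - cen)^2))
    }
    which.min(abs(ai - j))
  }, integer(1))
  bi <- sort(bi)
  vapply(seq_len(length(bi) - 1L), function(s) {
    seg <- corrected[bi[s]:bi[s + 1L]]
    max(seg) - corrected[bi[s]]
  }, numeric(1))
}

.stage_profile <- function(cand, res, provenance) {
  phase <- if (is.null(cand$phase)) "acylation" else cand$phase
  labels <- .phase_ts[[phase]]
  nb <- length(res$barriers)
  if (nb > length(labels))
    stop("candidate '", cand$id, "': ", nb, " reaction steps but phase '",
         phase, "' has only ", length(labels), " transition states")
  assemble_profile(cand$id, phase,
                   stats::setNames(pmax(res$barriers, 0), labels[seq_len(nb)]),
                   provenance, partial = nb < length(labels))
}

.write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(out$grids))
    write_pmf(out$grids[[nm]], file.path(dir, paste0("pmf_", nm, ".tsv")))
  for (nm in names(out$paths))
    write_path(out$paths[[nm]], file.path(dir, paste0("path_", nm, ".tsv")))
  write_profiles(out$profiles, file.path(dir, "profiles.tsv"))
  write_report(out$report, file.path(dir, "report.tsv"))
  meta <- out$config
  meta$package_version <- as.character(utils::packageVersion("felscreen"))
  yaml::write_yaml(meta, file.path(dir, "run_metadata.yaml"))
  invisible(dir)
}

#' @export
print.screening_report <- function(x, ...) {
  cat("screening_report\n")
  print(x$report)
  invisible(x)
}
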