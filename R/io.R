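#' Plain-text artifact files
#'
#' Every pipeline artifact is a diff-friendly delimited text file with
#' `#`-prefixed header lines carrying units, temperature, provenance and
#' format version. Each writer has a matching reader and round-trips
#' losslessly at the declared precision (energies to 1e-6 kcal/mol;
#' coordinates at full double precision). A file written, read back and
#' rewritten is byte-identical.
#'
#' @name fel_io
NULL

.hdr <- function(con, ...) writeLines(paste0("# ", sprintf(...)), con)

.read_headers <- function(lines) {
  h <- grep("^#", lines, value = TRUE)
  kv <- regmatches(h, regexec("^#\\s*([A-Za-z_0-9]+):\\s*(.*)$", h))
  kv <- kv[vapply(kv, length, integer(1)) == 3]
  stats::setNames(lapply(kv, `[[`, 3), vapply(kv, `[[`, 2, FUN.VALUE = character(1)))
}

.check_format <- function(headers, what, path) {
  if (is.null(headers$format) || headers$format != paste0("felscreen_", what, "_v1"))
    stop(path, ": not a felscreen ", what,
         " file (format header missing or mismatched)")
}

.fmt_num <- function(x) {
  out <- sprintf("%.10g", x)
  out[is.na(x)] <- "NA"
  out
}
.fmt_energy <- function(x) {
  out <- sprintf("%.6f", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write / read an umbrella-window metadata table
#'
#' @param windows a `bias_windows` table.
#' @param path file path.
#' @return `read_windows` returns a `bias_windows` data frame.
#' @export
write_windows <- function(windows, path) {
  con <- file(path, "w"); on.exit(close(con))
  .hdr(con, "format: felscreen_windows_v1")
  .hdr(con, "units: centre A, force_constant kcal/mol/A^2, temperature K")
  d <- .window_dim(windows)
  cols <- c("id", paste0("centre_", seq_len(d)), "force_constant",
            "n_samples", "temperature")
  writeLines(paste(cols, collapse = "\t"), con)
  for (i in seq_len(nrow(windows))) {
    writeLines(paste(c(windows$id[i],
                       .fmt_num(as.numeric(windows[i, paste0("centre_", seq_len(d))])),
                       .fmt_num(windows$force_constant[i]),
                       windows$n_samples[i],
                       .fmt_num(windows$temperature[i])), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  lines <- readLines(path)
  .check_format(.read_headers(lines), "windows", path)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  df$id <- as.integer(df$id); df$n_samples <- as.integer(df$n_samples)
  class(df) <- c("bias_windows", "data.frame")
  df
}

#' Write / read one window's biased time series
#'
#' One sample per line, whitespace-delimited coordinate values in Angstrom;
#' header lines carry the window id, seed and burn-in count.
#'
#' @param ts a `window_timeseries`.
#' @param path file path.
#' @return `read_series` returns a `window_timeseries`. Malformed sample
#'   lines raise an error naming the line number.
#' @export
write_series <- function(ts, path) {
  stopifnot(inherits(ts, "window_timeseries"))
  con <- file(path, "w"); on.exit(close(con))
  .hdr(con, "format: felscreen_series_v1")
  .hdr(con, "window_id: %d", ts$window_id)
  .hdr(con, "seed: %d", ts$seed)
  .hdr(con, "burn_in_discarded: %d", ts$burn_in_discarded)
  .hdr(con, "units: A")
  writeLines(apply(ts$samples, 1, function(r) paste(.fmt_num(r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  lines <- readLines(path)
  h <- .read_headers(lines)
  .check_format(h, "series", path)
  for (f in c("window_id", "seed", "burn_in_discarded"))
    if (is.null(h[[f]])) stop(path, ": missing header field '", f, "'")
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  rows <- strsplit(trimws(lines[body_idx]), "\\s+")
  d <- length(rows[[1]])
  vals <- suppressWarnings(lapply(rows, as.numeric))
  bad <- which(vapply(vals, function(v) anyNA(v) || length(v) != d, logical(1)))
  if (length(bad))
    stop(path, ": malformed sample on line ", body_idx[bad[1]],
         ": '", lines[body_idx[bad[1]]], "'")
  structure(list(
    window_id = as.integer(h$window_id),
    samples = matrix(unlist(vals), ncol = d, byrow = TRUE),
    seed = as.integer(h$seed),
    burn_in_discarded = as.integer(h$burn_in_discarded),
    acceptance_rate = NA_real_, proposal_scale = NA_real_
  ), class = "window_timeseries")
}

#' @rdname write_series
#' @export
read_window_series <- read_series

#' Write / read a free-energy grid
#'
#' One row per unmasked bin (coordinate centres, free energy, bootstrap
#' error); the header records the bin-edge layout, temperature and WHAM
#' convergence, so the mask is reconstructed on read.
#'
#' @param grid an `fe_grid`.
#' @param path file path.
#' @return `read_pmf` returns an `fe_grid` (without the `prob`/`shifts`
#'   fields, which are solver internals).
#' @export
write_pmf <- function(grid, path) {
  stopifnot(inherits(grid, "fe_grid"))
  con <- file(path, "w"); on.exit(close(con))
  .hdr(con, "format: felscreen_pmf_v1")
  .hdr(con, "temperature_K: %s", .fmt_num(grid$temperature))
  .hdr(con, "dim: %d", grid$dim)
  # full double precision so the reconstructed edges (and hence bin centres)
  # are bit-identical on read, keeping re-serialisation byte-stable
  for (d in seq_len(grid$dim))
    .hdr(con, "edges_%d: %.17g %.17g %d", d, grid$edges[[d]][1],
         grid$edges[[d]][2] - grid$edges[[d]][1], grid$nbin[d])
  .hdr(con, "iterations: %d", grid$iterations)
  .hdr(con, "residual: %s", .fmt_num(grid$residual))
  .hdr(con, "units: centres A, free_energy kcal/mol (offset: min over sampled bins = 0)")
  cols <- c("bin", paste0("centre_", seq_len(grid$dim)), "free_energy", "error")
  writeLines(paste(cols, collapse = "\t"), con)
  cen <- as.matrix(do.call(expand.grid, grid$centres))
  for (b in which(!grid$mask)) {
    writeLines(paste(c(b, .fmt_num(cen[b, ]),
                       .fmt_energy(grid$free_energy[b]),
                       .fmt_energy(grid$error[b])), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  lines <- readLines(path)
  h <- .read_headers(lines)
  .check_format(h, "pmf", path)
  dim <- as.integer(h$dim)
  edges <- vector("list", dim)
  for (d in seq_len(dim)) {
    es <- as.numeric(strsplit(trimws(h[[paste0("edges_", d)]]), "\\s+")[[1]])
    edges[[d]] <- es[1] + es[2] * (0:es[3])
  }
  nbin <- vapply(edges, function(e) length(e) - 1L, integer(1))
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  nb <- prod(nbin)
  fe <- rep(NA_real_, nb); err <- rep(NA_real_, nb)
  fe[df$bin] <- df$free_energy
  err[df$bin] <- df$error
  mask <- rep(TRUE, nb); mask[df$bin] <- FALSE
  structure(list(
    centres = lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2),
    edges = edges, free_energy = fe, error = err, mask = mask,
    prob = NULL, shifts = NULL,
    iterations = as.integer(h$iterations), residual = as.numeric(h$residual),
    temperature = as.numeric(h$temperature_K), dim = dim, nbin = nbin
  ), class = "fe_grid")
}

#' Write / read a traced reaction path
#'
#' @param rpath a `reaction_path`.
#' @param path file path.
#' @return `read_path` returns a `reaction_path`.
#' @export
write_path <- function(rpath, path) {
  stopifnot(inherits(rpath, "reaction_path"))
  con <- file(path, "w"); on.exit(close(con))
  .hdr(con, "format: felscreen_path_v1")
  .hdr(con, "start_node: %d", rpath$nodes[1])
  .hdr(con, "end_node: %d", rpath$nodes[length(rpath$nodes)])
  .hdr(con, "peak_index: %d", rpath$peak_index)
  .hdr(con, "units: coords A, energy kcal/mol")
  d <- ncol(rpath$coords)
  writeLines(paste(c("node", paste0("x", seq_len(d)), "energy"), collapse = "\t"), con)
  for (i in seq_along(rpath$nodes))
    writeLines(paste(c(rpath$nodes[i], .fmt_num(rpath$coords[i, ]),
                       .fmt_energy(rpath$energy[i])), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_path
#' @export
read_path <- function(path) {
  lines <- readLines(path)
  h <- .read_headers(lines)
  .check_format(h, "path", path)
  df <- utils::read.delim(text = lines[!grepl("^#", lines)], stringsAsFactors = FALSE)
  en <- df$energy
  structure(list(
    nodes = as.integer(df$node),
    coords = as.matrix(df[, grep("^x", names(df)), drop = FALSE]),
    energy = en, peak_index = as.integer(h$peak_index),
    peak_energy = en[as.integer(h$peak_index)]
  ), class = "reaction_path")
}

#' Write / read a correction anchor table
#'
#' @param anchors a [correction_anchors()] object.
#' @param path file path.
#' @return `read_anchors` returns a `correction_anchors` object (the
#'   `delta` column is recomputed from `low` and `high`, never trusted).
#' @export
write_anchors <- function(anchors, path) {
  stopifnot(inherits(anchors, "correction_anchors"))
  con <- file(path, "w"); on.exit(close(con))
  .hdr(con, "format: felscreen_anchors_v1")
  .hdr(con, "units: position path-progress (A for 1D profiles), energies kcal/mol")
  writeLines("position\tlow\thigh", con)
  for (i in seq_len(nrow(anchors)))
    writeLines(paste(.fmt_num(c(anchors$position[i], anchors$low[i],
                                anchors$high[i])), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_anchors
#' @export
read_anchors <- function(path) {
  lines <- readLines(path)
  .check_format(.read_headers(lines), "anchors", path)
  df <- utils::read.delim(text = lines[!grepl("^#", lines)], stringsAsFactors = FALSE)
  correction_anchors(df$position, df$low, df$high)
}

#' Write / read reaction profiles (long format)
#'
#' @param profiles list of `reaction_profile` objects.
#' @param path file path.
#' @return `read_profiles` returns a list of `reaction_profile` objects.
#' @export
write_profiles <- function(profiles, path) {
  con <- file(path, "w"); on.exit(close(con))
  .hdr(con, "format: felscreen_profiles_v1")
  .hdr(con, "units: dg kcal/mol")
  writeLines("id\tphase\tts\tdg\tprovenance", con)
  for (p in profiles)
    for (ts in names(p$barriers))
      writeLines(paste(p$id, p$phase, ts, .fmt_num(p$barriers[[ts]]),
                       p$provenance, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  lines <- readLines(path)
  .check_format(.read_headers(lines), "profiles", path)
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
  profiles_from_table(df, partial = TRUE)
}

#' Write / read a screening report
#'
#' @param result a [screen()] `screening_result`.
#' @param path file path.
#' @return `read_report` returns a `screening_result` with the same
#'   ranking.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "screening_result"))
  con <- file(path, "w"); on.exit(close(con))
  .hdr(con, "format: felscreen_report_v1")
  .hdr(con, "threshold_kcal: %s", .fmt_num(attr(result, "threshold")))
  .hdr(con, "temperature_K: %s", .fmt_num(attr(result, "temperature")))
  .hdr(con, "units: barriers kcal/mol, eyring_rate 1/s")
  writeLines(paste(names(result), collapse = "\t"), con)
  num <- vapply(result, is.numeric, logical(1)) & !vapply(result, is.integer, logical(1))
  for (i in seq_len(nrow(result))) {
    row <- vapply(seq_along(result), function(j) {
      v <- result[i, j]
      if (num[j]) .fmt_num(v) else as.character(v)
    }, character(1))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  h <- .read_headers(lines)
  .check_format(h, "report", path)
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
  df$rank <- as.integer(df$rank)
  attr(df, "threshold") <- as.numeric(h$threshold_kcal)
  attr(df, "temperature") <- as.numeric(h$temperature_K)
  class(df) <- c("screening_result", "data.frame")
  df
}
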