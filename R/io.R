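## Snapshot and trajectory file formats.
##
## Snapshot CSV: one row per lattice row, comma-separated integer species
## codes (0 = coral, 1 = turf, 2 = macroalgae), with an optional leading
## comment line `# t=<time>`.  Presence/absence CSV: codes {0, 1} with
## 1 = coral; everything else is read as turf.

#' Write a snapshot as CSV
#'
#' @param snap a `reef_snapshot`.
#' @param path output file.
#' @param time_comment write a `# t=<time>` header line (default TRUE).
#' @export
write_snapshot <- function(snap, path, time_comment = TRUE) {
  stopifnot(inherits(snap, "reef_snapshot"))
  lines <- apply(snap$state, 1L, paste, collapse = ",")
  if (time_comment) lines <- c(sprintf("# t=%g", snap$time), lines)
  writeLines(lines, path)
  invisible(path)
}

parse_grid <- function(path, allowed) {
  lines <- readLines(path)
  tline <- grep("^#", lines, value = TRUE)
  time <- 0
  if (length(tline)) {
    m <- regmatches(tline[[1L]], regexec("t\\s*=\\s*([0-9.eE+-]+)", tline[[1L]]))[[1L]]
    if (length(m) == 2L) time <- as.numeric(m[[2L]])
  }
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("%s: no grid rows found", path))
  rows <- strsplit(lines, ",")
  wid <- length(rows[[1L]])
  out <- matrix(NA_integer_, nrow = length(rows), ncol = wid)
  for (r in seq_along(rows)) {
    if (length(rows[[r]]) != wid)
      stop(sprintf("%s: row %d has %d cells, expected %d", path, r,
                   length(rows[[r]]), wid))
    v <- suppressWarnings(as.integer(trimws(rows[[r]])))
    bad <- which(is.na(v) | !(v %in% allowed))
    if (length(bad))
      stop(sprintf("%s: invalid cell value '%s' at row %d, col %d", path,
                   trimws(rows[[r]][[bad[[1L]]]]), r, bad[[1L]]))
    out[r, ] <- v
  }
  list(state = out, time = time)
}

#' Read a snapshot from CSV
#'
#' @param path CSV file of species codes \{0, 1, 2\} (see
#'   [write_snapshot()] for the format).
#' @return A `reef_snapshot`; malformed cells raise an error naming the
#'   offending row and column.
#' @export
read_snapshot <- function(path) {
  g <- parse_grid(path, allowed = 0:2)
  snapshot(g$state, time = g$time)
}

#' Read an empirical coral presence/absence grid
#'
#' Reads the quadrat-photograph style format: a CSV grid of \{0, 1\} with
#' 1 where coral is seen.  All non-coral cells become turf (the empirical
#' analysis only uses coral presence, so macroalgae and other cover are
#' collapsed).
#'
#' @param path CSV file of \{0, 1\}.
#' @param time model time to stamp on the snapshot (default from the
#'   `# t=` header, else 0).
#' @return A `reef_snapshot`.
#' @export
read_presence_grid <- function(path, time = NULL) {
  g <- parse_grid(path, allowed = 0:1)
  st <- ifelse(g$state == 1L, 0L, 1L)
  snapshot(st, time = if (is.null(time)) g$time else time)
}

#' Write a trajectory to a directory
#'
#' Lays out a manifest (`manifest.json`: parameters, seed, recorded
#' times), one snapshot CSV per recorded time (`snapshot_<i>.csv`), and a
#' covers table (`covers.csv`).
#'
#' @param traj a `reef_trajectory`.
#' @param dir output directory (created if needed).
#' @export
write_trajectory <- function(traj, dir) {
  stopifnot(inherits(traj, "reef_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- traj$params
  manifest <- list(
    package_version = as.character(utils::packageVersion("reeftda")),
    width = traj$width, height = traj$height, seed = traj$seed,
    times = traj$times,
    params = p[c("r", "d", "a", "gamma", "g", "ell", "dt", "scheme",
                 "pair_scaling")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(traj$covers, file.path(dir, "covers.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  for (i in seq_along(traj$snapshots))
    write_snapshot(traj$snapshots[[i]],
                   file.path(dir, sprintf("snapshot_%04d.csv", i)))
  invisible(dir)
}

#' Read a trajectory directory written by [write_trajectory()]
#'
#' @param dir trajectory directory.
#' @return A `reef_trajectory` (parameters restored from the manifest).
#' @export
read_trajectory <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  covers <- read.table(file.path(dir, "covers.csv"), sep = ",", header = TRUE)
  files <- sort(list.files(dir, pattern = "^snapshot_\\d+\\.csv$",
                           full.names = TRUE))
  snaps <- lapply(files, read_snapshot)
  pm <- manifest$params
  params <- smhe_params(r = pm$r, d = pm$d, a = pm$a, gamma = pm$gamma,
                        g = pm$g, ell = pm$ell, dt = pm$dt,
                        scheme = pm$scheme, pair_scaling = pm$pair_scaling)
  structure(list(snapshots = snaps, covers = covers,
                 times = vapply(snaps, `[[`, numeric(1), "time"),
                 params = params, width = manifest$width,
                 height = manifest$height,
                 seed = if (is.null(manifest$seed)) NA_integer_ else manifest$seed),
            class = "reef_trajectory")
}

#' Read a multi-year stack of presence grids
#'
#' @param paths character vector of presence-grid CSV files, in time
#'   order.
#' @param times numeric vector of observation times (defaults to
#'   `0, 1, ...`).
#' @return A list of `reef_snapshot`s, suitable for [build_zigzag()].
#' @export
read_presence_stack <- function(paths, times = seq_along(paths) - 1) {
  stopifnot(length(paths) == length(times))
  mapply(function(p, t) read_presence_grid(p, time = t), paths, times,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write a barcode as TSV
#'
#' Columns `dim`, `birth_level`, `death_level`; essential bars serialize
#' their death as `inf`.
#'
#' @param bc a `reef_barcode`.
#' @param path output file.
#' @export
write_barcode <- function(bc, path) {
  df <- data.frame(dim = bc$dim, birth_level = bc$birth,
                   death_level = ifelse(bc$essential, "inf", bc$death))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
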