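#' Assemble a cotyledon map
#'
#' Bundles one cotyledon's outline, its sector outlines and its stomatal
#' coordinates (all in um) with a free-text label (e.g. genotype or sector
#' type). Validation enforces that every stoma lies inside the cotyledon
#' outline; a sector that grazes or crosses the cotyledon boundary raises a
#' warning but is kept.
#'
#' @param cotyledon Cotyledon [outline()].
#' @param sectors List of sector [outline()]s (possibly empty).
#' @param stomata Data frame / list with numeric `x` and `y` (um).
#' @param label Free-text label.
#' @return An object of class `cotyledon_map`.
#' @export
cotyledon_map <- function(cotyledon, sectors = list(), stomata = list(x = numeric(), y = numeric()),
                          label = "") {
  cotyledon <- as_outline(cotyledon)
  sectors <- lapply(sectors, as_outline)
  sx <- as.numeric(stomata$x); sy <- as.numeric(stomata$y)
  if (length(sx) != length(sy)) stop("stomata x and y must have equal length")
  if (length(sx) && !all(is.finite(sx) & is.finite(sy)))
    stop("stomatal coordinates must be finite numbers")
  if (length(sx)) {
    ok <- point_in_polygon(sx, sy, cotyledon)
    if (!all(ok))
      stop(sprintf("stoma outside the cotyledon outline (first offending row: %d)",
                   which(!ok)[1]))
  }
  for (k in seq_along(sectors)) {
    s <- sectors[[k]]
    if (!all(point_in_polygon(s$x, s$y, cotyledon)))
      warning(sprintf("sector %d extends beyond the cotyledon outline", k))
  }
  structure(list(cotyledon = cotyledon, sectors = sectors,
                 stomata = data.frame(x = sx, y = sy), label = label),
            class = "cotyledon_map")
}

#' @export
print.cotyledon_map <- function(x, ...) {
  cat(sprintf("<cotyledon map '%s': %d stomata, %d sector(s), cotyledon area %.4g um^2>\n",
              x$label, nrow(x$stomata), length(x$sectors), polygon_area(x$cotyledon)))
  invisible(x)
}

read_xy_csv <- function(path, min_rows = 1L) {
  if (!file.exists(path)) stop(sprintf("missing file: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x_um", "y_um") %in% names(d)))
    stop(sprintf("%s: expected columns x_um,y_um", path))
  for (col in c("x_um", "y_um")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(!is.finite(v) & !is.na(d[[col]]) | is.na(v))
    if (length(bad))
      stop(sprintf("%s: non-numeric coordinate in column %s, row %d", path, col, bad[1]))
    d[[col]] <- v
  }
  if ("z_um" %in% names(d))
    message(sprintf("%s: dropping z_um column (analysis is two dimensional)", path))
  if (nrow(d) < min_rows)
    stop(sprintf("%s: expected at least %d rows, found %d", path, min_rows, nrow(d)))
  d[c("x_um", "y_um")]
}

#' Read a cotyledon map from its interchange directory
#'
#' The on-disk schema is one directory per cotyledon holding `cotyledon.csv`,
#' `stomata.csv`, zero or more `sector_<k>.csv`, each with header `x_um,y_um`
#' (row order is vertex order for outlines), plus an optional `manifest.json`
#' carrying `label` and free-form provenance. A `z_um` column, if present, is
#' dropped with a message.
#'
#' @param path Directory containing the files.
#' @param label Label override; defaults to the manifest's label or the
#'   directory name.
#' @return A [cotyledon_map()].
#' @export
read_cotyledon_map <- function(path, label = NULL) {
  if (!dir.exists(path)) stop(sprintf("missing directory: %s", path))
  cot <- read_xy_csv(file.path(path, "cotyledon.csv"), min_rows = 3L)
  sto_path <- file.path(path, "stomata.csv")
  sto <- read_xy_csv(sto_path, min_rows = 0L)
  sec_files <- sort(list.files(path, pattern = "^sector_[0-9]+\\.csv$", full.names = TRUE))
  sectors <- lapply(sec_files, function(f) {
    d <- read_xy_csv(f, min_rows = 3L)
    tryCatch(outline(d$x_um, d$y_um),
             error = function(e) stop(sprintf("%s: %s", f, conditionMessage(e))))
  })
  if (is.null(label)) {
    mf <- file.path(path, "manifest.json")
    label <- if (file.exists(mf)) {
      m <- jsonlite::read_json(mf)
      if (!is.null(m$label)) as.character(m$label) else basename(path)
    } else basename(path)
  }
  cot_out <- tryCatch(outline(cot$x_um, cot$y_um),
                      error = function(e) stop(sprintf("%s: %s",
                        file.path(path, "cotyledon.csv"), conditionMessage(e))))
  cotyledon_map(cot_out, sectors,
                stomata = list(x = sto$x_um, y = sto$y_um), label = label)
}

#' Write a cotyledon map to its interchange directory
#'
#' Inverse of [read_cotyledon_map()]; coordinates round-trip losslessly
#' (written with full precision).
#'
#' @param map A [cotyledon_map()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_cotyledon_map <- function(map, path) {
  stopifnot(inherits(map, "cotyledon_map"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, y, f)
    utils::write.csv(data.frame(x_um = x, y_um = y),
                     file.path(path, f), row.names = FALSE, quote = FALSE)
  wr(map$cotyledon$x, map$cotyledon$y, "cotyledon.csv")
  wr(map$stomata$x, map$stomata$y, "stomata.csv")
  for (k in seq_along(map$sectors))
    wr(map$sectors[[k]]$x, map$sectors[[k]]$y, sprintf("sector_%d.csv", k))
  jsonlite::write_json(list(label = map$label, generator = "stomaspace",
                            n_stomata = nrow(map$stomata),
                            n_sectors = length(map$sectors)),
                       file.path(path, "manifest.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write result tables to CSV
#'
#' Density tables are written as-is; correlation functions are written with
#' columns `r_lo, r_hi, r_mid, S_count, R_expected, zeta, ci_lo, ci_hi`.
#' Undefined bins (expected random count zero) are serialized as empty
#' fields.
#'
#' @param x A density `data.frame` or a `space_corr` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (inherits(x, "space_corr")) x <- as.data.frame(x)
  stopifnot(is.data.frame(x))
  utils::write.csv(x, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
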