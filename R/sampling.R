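#' Uniform random points inside a cotyledon outline
#'
#' Complete-spatial-randomness null points confined to the cotyledon window.
#' Following the original sampling scheme, candidate points are drawn in the
#' bounding rectangle at five times the requested count, points outside the
#' outline are discarded, and the first `n` interior points are kept; if the
#' oversampling falls short the draw is repeated until `n` interior points
#' exist.
#'
#' @param n Number of points (>= 1).
#' @param cotyledon Cotyledon [outline()].
#' @param seed Integer seed (optional); the point set is deterministic given
#'   the seed.
#' @param oversample Oversampling factor for the rejection draw (default 5).
#' @return Data frame with columns `x`, `y` and exactly `n` rows.
#' @export
generate_uniform_points <- function(n, cotyledon, seed = NULL, oversample = 5) {
  cotyledon <- as_outline(cotyledon)
  if (n < 1) stop("n must be >= 1")
  if (polygon_area(cotyledon) <= 0) stop("invalid geometry: outline has zero area")
  bx <- range(cotyledon$x); by <- range(cotyledon$y)
  with_seed(seed, {
    keep_x <- numeric(0); keep_y <- numeric(0)
    while (length(keep_x) < n) {
      m <- ceiling(oversample * max(n - length(keep_x), 1))
      px <- stats::runif(m, bx[1], bx[2])
      py <- stats::runif(m, by[1], by[2])
      ok <- point_in_polygon(px, py, cotyledon)
      keep_x <- c(keep_x, px[ok]); keep_y <- c(keep_y, py[ok])
    }
    data.frame(x = keep_x[seq_len(n)], y = keep_y[seq_len(n)])
  })
}

#' Ensemble of random null point sets
#'
#' Generates `n_sets` independent uniform point sets of size `n` inside the
#' cotyledon outline (size matched to the observed stoma count). One master
#' seed deterministically spawns per-set child seeds, so individual sets are
#' reproducible and independent.
#'
#' @inheritParams generate_uniform_points
#' @param n_sets Number of sets (reference analyses use 1000).
#' @return An object of class `random_ensemble`: list with `sets` (list of
#'   data frames), `n`, `n_sets`, `seed`.
#' @export
generate_ensemble <- function(n, cotyledon, n_sets = 1000, seed = NULL) {
  cotyledon <- as_outline(cotyledon)
  if (n_sets < 1) stop("n_sets must be >= 1")
  child <- with_seed(seed, sample.int(.Machine$integer.max, n_sets))
  sets <- lapply(child, function(s) generate_uniform_points(n, cotyledon, seed = s))
  structure(list(sets = sets, n = n, n_sets = n_sets, seed = seed),
            class = "random_ensemble")
}

#' @export
print.random_ensemble <- function(x, ...) {
  cat(sprintf("<random ensemble: %d sets of %d points>\n", x$n_sets, x$n))
  invisible(x)
}
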