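#' Reference pattern specification
#'
#' Parameters of the synthetic stomatal pattern generators used to validate
#' the correlation estimators against patterns of known structure.
#'
#' @param kind One of `"uniform"` (complete spatial randomness over the
#'   cotyledon), `"clustered"` (intensity decaying exponentially with
#'   distance from the sector boundary), `"ringed"` (points confined to
#'   annuli at successive multiples of `ring_spacing` from the sector
#'   boundary) or `"spaced"` (sequential-inhibition hard-core pattern
#'   emulating the one-cell spacing rule).
#' @param n Point count (reference 500).
#' @param ring_spacing Ring center spacing (um, reference 200).
#' @param ring_width Ring annulus width (um, default 40).
#' @param n_rings Number of rings (default 3).
#' @param decay_scale Exponential decay scale of the clustered intensity
#'   (um, default 50).
#' @param hardcore_distance Minimum pairwise distance of the spaced pattern
#'   (um; default 40.9, the measured mean one-cell spacing).
#' @param seed Integer seed.
#' @return A `pattern_spec` object.
#' @export
pattern_spec <- function(kind = c("uniform", "clustered", "ringed", "spaced"),
                         n = 500, ring_spacing = 200, ring_width = 40,
                         n_rings = 3, decay_scale = 50,
                         hardcore_distance = 40.9, seed = 1) {
  kind <- match.arg(kind)
  if (n < 1) stop("n must be >= 1")
  if (any(c(ring_spacing, ring_width, decay_scale, hardcore_distance) <= 0))
    stop("length parameters must be positive")
  structure(list(kind = kind, n = as.integer(n), ring_spacing = ring_spacing,
                 ring_width = ring_width, n_rings = as.integer(n_rings),
                 decay_scale = decay_scale, hardcore_distance = hardcore_distance,
                 seed = seed), class = "pattern_spec")
}

#' Synthetic cotyledon outline
#'
#' Smooth convex ellipse-like blade with a slight egg-shaped taper, sized in
#' um. Deterministic given the seed (the seed jitters the taper and
#' orientation slightly so replicate cotyledons differ).
#'
#' @param width,height Bounding dimensions (um); defaults emulate a
#'   7-day-old cotyledon blade (~2 mm x 1.2 mm).
#' @param n_vertices Polygon resolution (>= 8).
#' @param seed Integer seed.
#' @return An [outline()].
#' @export
synth_cotyledon <- function(width = 2000, height = 1200, n_vertices = 64, seed = 1) {
  if (width <= 0 || height <= 0) stop("dimensions must be positive")
  if (n_vertices < 8) stop("n_vertices must be >= 8")
  with_seed(seed, {
    taper <- stats::runif(1, 0.05, 0.15)
    phase <- stats::runif(1, 0, 2 * pi)
    th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)] + phase
    a <- width / 2; b <- height / 2
    x <- a * cos(th)
    y <- b * sin(th) * (1 - taper * cos(th))
    y <- y * b / max(abs(y))   # keep the taper within the stated height
    outline(x, y)
  })
}

#' Synthetic mosaic sector outline
#'
#' Irregular cell-cluster-like blob placed fully inside the cotyledon, with
#' area within 10% of `area_target` (the low-order radial harmonics that
#' roughen the boundary are rescaled to the exact target, so typically much
#' closer).
#'
#' @param area_target Target area (um^2); defaults to 20,000, inside the
#'   15,000-40,000 um^2 analysis window.
#' @param cotyledon Cotyledon [outline()].
#' @param seed Integer seed.
#' @param n_vertices Blob resolution.
#' @param center Optional `c(x, y)` placement; random inside the cotyledon
#'   when `NULL`.
#' @param max_attempts Placement retries before failing.
#' @return An [outline()].
#' @export
synth_sector <- function(area_target = 20000, cotyledon, seed = 1,
                         n_vertices = 32, center = NULL, max_attempts = 100) {
  if (area_target <= 0) stop("area_target must be positive")
  cotyledon <- as_outline(cotyledon)
  if (area_target >= 0.5 * polygon_area(cotyledon))
    stop("area_target too large relative to the cotyledon")
  with_seed(seed, {
    bx <- range(cotyledon$x); by <- range(cotyledon$y)
    th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
    for (i in seq_len(max_attempts)) {
      amp <- stats::runif(3, 0.03, 0.12)
      ph <- stats::runif(3, 0, 2 * pi)
      r <- 1 + amp[1] * cos(2 * th + ph[1]) + amp[2] * cos(3 * th + ph[2]) +
        amp[3] * cos(4 * th + ph[3])
      x0 <- r * cos(th); y0 <- r * sin(th)
      sc <- sqrt(area_target / abs(signed_area(x0, y0)))
      x0 <- x0 * sc; y0 <- y0 * sc
      cx <- if (is.null(center)) stats::runif(1, bx[1], bx[2]) else center[1]
      cy <- if (is.null(center)) stats::runif(1, by[1], by[2]) else center[2]
      cand <- tryCatch(outline(x0 + cx, y0 + cy), error = function(e) NULL)
      if (is.null(cand)) next
      if (all(point_in_polygon(cand$x, cand$y, cotyledon)) &&
          point_in_polygon(cx, cy, cotyledon))
        return(cand)
      if (!is.null(center))
        stop("placement failure: sector at requested center leaves the cotyledon")
    }
    stop(sprintf("placement failure: no interior placement in %d attempts", max_attempts))
  })
}

#' Generate a reference stomatal pattern
#'
#' Draws exactly `spec$n` points inside the cotyledon according to the
#' pattern kind (see [pattern_spec()]). `clustered` and `ringed` require a
#' sector outline; distances are measured to the sector boundary (points
#' inside the sector count as distance 0 for the clustered intensity).
#'
#' @param spec A [pattern_spec()].
#' @param cotyledon Cotyledon [outline()].
#' @param sector Sector [outline()] (required for clustered/ringed).
#' @return Data frame with columns `x`, `y` (`spec$n` rows).
#' @export
generate_pattern <- function(spec, cotyledon, sector = NULL) {
  stopifnot(inherits(spec, "pattern_spec"))
  cotyledon <- as_outline(cotyledon)
  if (spec$kind %in% c("clustered", "ringed") && is.null(sector))
    stop(sprintf("'%s' pattern requires a sector outline", spec$kind))
  switch(spec$kind,
    uniform = generate_uniform_points(spec$n, cotyledon, seed = spec$seed),
    clustered = with_seed(spec$seed, pattern_clustered(spec, cotyledon, as_outline(sector))),
    ringed = with_seed(spec$seed, pattern_ringed(spec, cotyledon, as_outline(sector))),
    spaced = with_seed(spec$seed, pattern_spaced(spec, cotyledon))
  )
}

sector_distance0 <- function(x, y, sector) {
  d <- nearest_boundary_distance(x, y, sector)
  d[point_in_polygon(x, y, sector)] <- 0
  d
}

# thinning of CSR proposals with retention prob exp(-d / decay_scale)
pattern_clustered <- function(spec, cotyledon, sector) {
  bx <- range(cotyledon$x); by <- range(cotyledon$y)
  kx <- numeric(0); ky <- numeric(0)
  guard <- 0L
  while (length(kx) < spec$n) {
    m <- 10L * max(spec$n - length(kx), 50L)
    px <- stats::runif(m, bx[1], bx[2]); py <- stats::runif(m, by[1], by[2])
    ok <- point_in_polygon(px, py, cotyledon)
    px <- px[ok]; py <- py[ok]
    keep <- stats::runif(length(px)) < exp(-sector_distance0(px, py, sector) / spec$decay_scale)
    kx <- c(kx, px[keep]); ky <- c(ky, py[keep])
    guard <- guard + 1L
    if (guard > 1000L) stop("clustered pattern: acceptance rate too low")
  }
  data.frame(x = kx[seq_len(spec$n)], y = ky[seq_len(spec$n)])
}

# equal allocation over annuli centered at k * ring_spacing from the boundary
pattern_ringed <- function(spec, cotyledon, sector) {
  k <- spec$n_rings
  alloc <- rep(spec$n %/% k, k)
  if (spec$n %% k) alloc[seq_len(spec$n %% k)] <- alloc[seq_len(spec$n %% k)] + 1L
  bx <- range(cotyledon$x); by <- range(cotyledon$y)
  out_x <- numeric(0); out_y <- numeric(0)
  for (ring in seq_len(k)) {
    cen <- ring * spec$ring_spacing
    lo <- cen - spec$ring_width / 2; hi <- cen + spec$ring_width / 2
    kx <- numeric(0); ky <- numeric(0)
    guard <- 0L
    while (length(kx) < alloc[ring]) {
      m <- 50L * max(alloc[ring] - length(kx), 20L)
      px <- stats::runif(m, bx[1], bx[2]); py <- stats::runif(m, by[1], by[2])
      ok <- point_in_polygon(px, py, cotyledon)
      px <- px[ok]; py <- py[ok]
      d <- sector_distance0(px, py, sector)
      keep <- d >= lo & d <= hi
      kx <- c(kx, px[keep]); ky <- c(ky, py[keep])
      guard <- guard + 1L
      if (guard > 2000L)
        stop(sprintf("ringed pattern: annulus at %g um has no usable area", cen))
    }
    out_x <- c(out_x, kx[seq_len(alloc[ring])])
    out_y <- c(out_y, ky[seq_len(alloc[ring])])
  }
  data.frame(x = out_x, y = out_y)
}

# simple sequential inhibition (dart throwing)
pattern_spaced <- function(spec, cotyledon) {
  bx <- range(cotyledon$x); by <- range(cotyledon$y)
  h2 <- spec$hardcore_distance^2
  kx <- numeric(spec$n); ky <- numeric(spec$n)
  placed <- 0L; attempts <- 0L
  max_attempts <- 1000L * spec$n
  while (placed < spec$n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf("packing error: placed %d of %d points at hard-core %g um",
                   placed, spec$n, spec$hardcore_distance))
    px <- stats::runif(1, bx[1], bx[2]); py <- stats::runif(1, by[1], by[2])
    if (!point_in_polygon(px, py, cotyledon)) next
    if (placed > 0 &&
        min((kx[seq_len(placed)] - px)^2 + (ky[seq_len(placed)] - py)^2) < h2) next
    placed <- placed + 1L
    kx[placed] <- px; ky[placed] <- py
  }
  data.frame(x = kx, y = ky)
}

#' Build a complete synthetic cotyledon map
#'
#' Convenience fixture generator: synthetic cotyledon, one synthetic sector
#' and a reference pattern, bundled as a [cotyledon_map()].
#'
#' @param spec A [pattern_spec()].
#' @param width,height Cotyledon dimensions (um).
#' @param sector_area Sector target area (um^2).
#' @param label Map label.
#' @return A [cotyledon_map()] (the sector is included for all kinds).
#' @export
synth_map <- function(spec, width = 2000, height = 1200, sector_area = 20000,
                      label = spec$kind) {
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max, 2))
  cot <- synth_cotyledon(width, height, seed = seeds[1])
  sec <- synth_sector(sector_area, cot, seed = seeds[2], center = c(0, 0))
  pts <- generate_pattern(spec, cot, sec)
  cotyledon_map(cot, list(sec), stomata = pts, label = label)
}
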