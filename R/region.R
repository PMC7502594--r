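#' Planar regions with exact area accounting
#'
#' A `space_region` is a possibly multi-part planar set (parts may carry
#' holes), the result of dilation, clipping and union operations on outlines.
#' Internally it is a list of rings as used by the Clipper polygon engine;
#' hole rings are detected by even-odd nesting so the cached area is the sum
#' of part areas minus holes.
#'
#' @param rings List of `list(x, y)` rings (may be empty).
#' @return A `space_region` with cached `$area` (um^2).
#' @export
region <- function(rings = list()) {
  rings <- lapply(rings, function(p) list(x = as.numeric(p$x), y = as.numeric(p$y)))
  structure(list(rings = rings, area = rings_area(rings)), class = "space_region")
}

#' @export
print.space_region <- function(x, ...) {
  cat(sprintf("<region: %d ring(s), area %.6g um^2>\n", length(x$rings), x$area))
  invisible(x)
}

#' Convert an outline to a single-part region
#' @param x An [outline()] object (or a region, returned unchanged).
#' @return A `space_region`.
#' @export
as_region <- function(x) {
  if (inherits(x, "space_region")) return(x)
  x <- as_outline(x)
  region(list(list(x = x$x, y = x$y)))
}

#' @export
region_area <- function(region) {
  stopifnot(inherits(region, "space_region"))
  region$area
}

# area with hole signs assigned by even-odd nesting depth (robust to ring
# orientation conventions of the clipping backend)
rings_area <- function(rings) {
  if (length(rings) == 0) return(0)
  n <- length(rings)
  a <- vapply(rings, function(p) abs(signed_area(p$x, p$y)), 0)
  depth <- integer(n)
  for (i in seq_len(n)) {
    px <- rings[[i]]$x[1]; py <- rings[[i]]$y[1]
    for (k in seq_len(n)) {
      if (k != i && ray_cast(px, py, rings[[k]]$x, rings[[k]]$y)) {
        depth[i] <- depth[i] + 1L
      }
    }
  }
  sum(a * ifelse(depth %% 2 == 0, 1, -1))
}

#' Membership test for a region
#'
#' Boundary-inclusive: a point on any ring boundary (within `tol`) is inside.
#' Interior membership uses even-odd parity over the rings, so holes are
#' excluded and multiple parts behave as their union.
#'
#' @param region A `space_region`.
#' @param x,y Query coordinates (vectorized).
#' @param tol Boundary tolerance (um).
#' @return Logical vector.
#' @export
region_contains <- function(region, x, y, tol = 1e-9) {
  stopifnot(inherits(region, "space_region"))
  if (length(region$rings) == 0) return(rep(FALSE, length(x)))
  inside <- rep(FALSE, length(x))
  mind2 <- rep(Inf, length(x))
  for (p in region$rings) {
    inside <- xor(inside, ray_cast(x, y, p$x, p$y))
    n <- length(p$x); j <- c(2:n, 1L)
    for (i in seq_len(n))
      mind2 <- pmin(mind2, dist2_point_segment(x, y, p$x[i], p$y[i], p$x[j[i]], p$y[j[i]]))
  }
  inside | (sqrt(mind2) <= tol)
}

#' Euclidean dilation of an outline
#'
#' Minkowski sum of the closed polygon with a disk of radius `d`: every point
#' of the result lies within `d` of the original region and vice versa, up to
#' arc polygonization. This grows the sector outline while preserving its
#' geometry, as used to build the offset "nearby" analysis bands.
#'
#' @param outline An [outline()] object.
#' @param d Dilation radius (um), `>= 0`. `d = 0` returns the outline as a
#'   region unchanged.
#' @param segments Number of chords used per full circle when polygonizing
#'   arcs (default 64).
#' @return A `space_region`.
#' @export
dilate_outline <- function(outline, d, segments = 64) {
  outline <- as_outline(outline)
  if (!is.finite(d) || d < 0) stop("dilation distance must be >= 0")
  if (d == 0) return(as_region(outline))
  dilate_rings(list(list(x = outline$x, y = outline$y)), d, segments)
}

#' Euclidean dilation of a region
#' @param region A `space_region`.
#' @inheritParams dilate_outline
#' @return A `space_region`.
#' @export
dilate_region <- function(region, d, segments = 64) {
  stopifnot(inherits(region, "space_region"))
  if (!is.finite(d) || d < 0) stop("dilation distance must be >= 0")
  if (d == 0 || length(region$rings) == 0) return(region)
  dilate_rings(region$rings, d, segments)
}

dilate_rings <- function(rings, d, segments) {
  arctol <- d * (1 - cos(pi / segments))
  region(polyclip::polyoffset(rings, d, jointype = "round", arctol = arctol,
                              eps = clip_eps(rings, d)))
}

# finer integer-scaling resolution than polyclip's default (range / 2^31),
# so boolean area accounting is exact to ~1e-12 of the coordinate range
clip_eps <- function(..., pad = 0) {
  rng <- 1
  for (rings in list(...)) {
    if (is.numeric(rings)) { pad <- pad + rings; next }
    for (p in rings) rng <- max(rng, abs(p$x), abs(p$y))
  }
  (rng + pad) / 2^40
}

#' Clip a region to a window and subtract regions
#'
#' Intersects `x` with the `keep_within` outline (typically the cotyledon)
#' and removes the union of the `remove` regions (typically sector
#' interiors and inner offset bands). An empty result is a valid region of
#' area 0.
#'
#' @param x A `space_region` (or outline).
#' @param keep_within An [outline()] window, or `NULL` to skip clipping.
#' @param remove List of regions/outlines to subtract (may be empty).
#' @return A `space_region`.
#' @export
clip_subtract <- function(x, keep_within = NULL, remove = list()) {
  rings <- as_region(x)$rings
  if (!is.null(keep_within)) {
    w <- as_outline(keep_within)
    wl <- list(list(x = w$x, y = w$y))
    rings <- polyclip::polyclip(rings, wl, op = "intersection",
                                eps = clip_eps(rings, wl))
  }
  for (r in remove) {
    rr <- as_region(r)$rings
    if (length(rings) == 0) break
    if (length(rr) > 0)
      rings <- polyclip::polyclip(rings, rr, op = "minus", eps = clip_eps(rings, rr))
  }
  region(rings)
}

#' Union of regions
#'
#' Overlapping parts are merged so that area is never double counted:
#' `area(union) <= sum(area)`, with equality iff the inputs are pairwise
#' disjoint.
#'
#' @param regions List of `space_region`s / outlines (possibly empty).
#' @return A `space_region`.
#' @export
union_regions <- function(regions) {
  if (length(regions) == 0) return(region())
  rings <- as_region(regions[[1]])$rings
  for (r in regions[-1]) {
    rr <- as_region(r)$rings
    if (length(rr) == 0) next
    rings <- if (length(rings) == 0) rr else
      polyclip::polyclip(rings, rr, op = "union", eps = clip_eps(rings, rr))
  }
  region(rings)
}
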