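#' Construct a closed polygon outline
#'
#' An outline is a simple (non-self-intersecting) closed polygon given by its
#' vertices in order, with the closing vertex stored only once. Coordinates are
#' in micrometres, matching the units of segmented confocal exports. Vertex
#' order is normalized to counter-clockwise on construction.
#'
#' @param x,y Numeric vectors of vertex coordinates (equal length, >= 3).
#' @return An object of class `space_outline` with elements `x` and `y`.
#' @examples
#' sq <- outline(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' polygon_area(sq)
#' @export
outline <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("outline coordinates must be finite")
  # drop a duplicated closing vertex if present
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
  if (n < 3) stop("an outline needs at least 3 distinct vertices")
  if (self_intersects(x, y)) stop("outline is self-intersecting")
  a <- signed_area(x, y)
  if (abs(a) <= 0) stop("degenerate outline: zero area")
  if (a < 0) { x <- rev(x); y <- rev(y) }   # normalize counter-clockwise
  structure(list(x = x, y = y), class = "space_outline")
}

#' @export
print.space_outline <- function(x, ...) {
  cat(sprintf("<outline: %d vertices, area %.6g um^2>\n",
              length(x$x), polygon_area(x)))
  invisible(x)
}

as_outline <- function(o) {
  if (inherits(o, "space_outline")) return(o)
  if (is.list(o) && !is.null(o$x) && !is.null(o$y)) return(outline(o$x, o$y))
  stop("cannot interpret object as an outline")
}

signed_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# O(n^2) segment pairwise check; outlines are a few hundred vertices at most
self_intersects <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  for (i in seq_len(n - 2L)) {
    ks <- (i + 2L):n
    # the closing edge (n,1) is adjacent to edge 1
    if (i == 1L) ks <- ks[ks != n]
    for (k in ks) {
      if (segments_cross(x[i], y[i], x[j[i]], y[j[i]], x[k], y[k], x[j[k]], y[j[k]]))
        return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Area enclosed by an outline
#'
#' Shoelace area, independent of vertex orientation.
#'
#' @param outline A [outline()] object.
#' @return Area in square micrometres (> 0).
#' @export
polygon_area <- function(outline) {
  outline <- as_outline(outline)
  abs(signed_area(outline$x, outline$y))
}

#' Point-in-polygon test
#'
#' Even-odd ray casting with a boundary-inclusive convention: a point lying on
#' an outline edge (within `tol`) counts as inside. Vectorized over points.
#'
#' @param x,y Numeric vectors of query coordinates.
#' @param outline A [outline()] object.
#' @param tol Absolute distance (um) within which a point is treated as on the
#'   boundary.
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, outline, tol = 1e-9) {
  outline <- as_outline(outline)
  inside <- ray_cast(x, y, outline$x, outline$y)
  onb <- nearest_boundary_distance(x, y, outline) <= tol
  inside | onb
}

# strict even-odd crossing count, vectorized over query points
ray_cast <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j[i]]; yj <- vy[j[i]]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

#' Nearest distance from points to an outline boundary
#'
#' Minimum Euclidean distance from each query point to any boundary segment
#' (not vertex-only). Zero iff the point lies on the boundary; points inside
#' and outside both get positive distances.
#'
#' @inheritParams point_in_polygon
#' @return Numeric vector of distances (um).
#' @export
nearest_boundary_distance <- function(x, y, outline) {
  outline <- as_outline(outline)
  vx <- outline$x; vy <- outline$y
  n <- length(vx)
  j <- c(2:n, 1L)
  d2 <- rep(Inf, length(x))
  for (i in seq_len(n)) {
    d2 <- pmin(d2, dist2_point_segment(x, y, vx[i], vy[i], vx[j[i]], vy[j[i]]))
  }
  sqrt(d2)
}

# squared distance from (px,py) vectors to segment (ax,ay)-(bx,by)
dist2_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return((px - ax)^2 + (py - ay)^2)
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / l2))
  (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
}

#' Minimum boundary-to-boundary distance between two outlines
#'
#' Zero if the outlines touch, cross, or one contains a vertex of the other.
#' Used by the sector-separation filter.
#'
#' @param a,b [outline()] objects.
#' @return Distance in um.
#' @export
outline_separation <- function(a, b) {
  a <- as_outline(a); b <- as_outline(b)
  if (any(point_in_polygon(b$x, b$y, a)) || any(point_in_polygon(a$x, a$y, b)))
    return(0)
  min(nearest_boundary_distance(a$x, a$y, b),
      nearest_boundary_distance(b$x, b$y, a))
}

#' Randomly transpose an outline within a cotyledon
#'
#' Rigid translation (no rotation or scaling) of a sector outline to a
#' uniformly random position such that it lies entirely within the cotyledon
#' outline — the "geometric sector" control used to overlay real sector shapes
#' onto wild-type cotyledons. Placements that stick out of the cotyledon are
#' rejected and redrawn.
#'
#' @param outline Sector [outline()] to transpose.
#' @param cotyledon Cotyledon [outline()].
#' @param seed Integer seed; the placement is deterministic given the seed.
#' @param max_attempts Rejections allowed before giving up.
#' @return The translated outline.
#' @export
transpose_outline <- function(outline, cotyledon, seed, max_attempts = 1000) {
  outline <- as_outline(outline); cotyledon <- as_outline(cotyledon)
  a_sector <- polygon_area(outline)
  cx <- mean(range(outline$x)); cy <- mean(range(outline$y))
  hw <- diff(range(outline$x)) / 2; hh <- diff(range(outline$y)) / 2
  bx <- range(cotyledon$x); by <- range(cotyledon$y)
  lox <- bx[1] + hw; hix <- bx[2] - hw
  loy <- by[1] + hh; hiy <- by[2] - hh
  if (lox > hix || loy > hiy)
    stop("placement failure: sector does not fit inside the cotyledon bounding box")
  with_seed(seed, {
    for (i in seq_len(max_attempts)) {
      nx <- stats::runif(1, lox, hix)
      ny <- stats::runif(1, loy, hiy)
      cand <- list(list(x = outline$x + (nx - cx), y = outline$y + (ny - cy)))
      cotl <- list(list(x = cotyledon$x, y = cotyledon$y))
      inter <- polyclip::polyclip(cand, cotl, op = "intersection",
                                  eps = max(abs(unlist(cotl)), 1) / 2^40)
      a_in <- sum(vapply(inter, function(p) abs(signed_area(p$x, p$y)), 0))
      if (abs(a_in - a_sector) <= 1e-7 * a_sector)
        return(structure(list(x = cand[[1]]$x, y = cand[[1]]$y),
                         class = "space_outline"))
    }
    stop(sprintf("placement failure: no interior placement found in %d attempts",
                 max_attempts))
  })
}

# Evaluate expr under a temporary RNG state; the caller's stream is restored.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
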