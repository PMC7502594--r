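# Fixtures and independent oracles used across the suite.

unit_square <- function() outline(c(0, 1, 1, 0), c(0, 0, 1, 1))

# random star-shaped polygon: simple by construction
random_polygon <- function(n = 12, r_mean = 1, jitter = 0.6) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- r_mean * (1 + stats::runif(n, -jitter, jitter) / 2)
  outline(r * cos(th), r * sin(th))
}

# winding-number point-in-polygon oracle (angle summation), scalar
oracle_point_in_polygon <- function(px, py, ol) {
  x <- ol$x - px; y <- ol$y - py
  n <- length(x)
  j <- c(2:n, 1L)
  total <- 0
  for (i in seq_len(n)) {
    a1 <- atan2(y[i], x[i]); a2 <- atan2(y[j[i]], x[j[i]])
    da <- a2 - a1
    if (da > pi) da <- da - 2 * pi
    if (da < -pi) da <- da + 2 * pi
    total <- total + da
  }
  abs(total) > pi # ~2*pi inside, ~0 outside
}

# exhaustive per-segment distance minimization oracle, scalar
oracle_boundary_distance <- function(px, py, ol) {
  n <- length(ol$x)
  j <- c(2:n, 1L)
  best <- Inf
  for (i in seq_len(n)) {
    ax <- ol$x[i]; ay <- ol$y[i]; bx <- ol$x[j[i]]; by <- ol$y[j[i]]
    dx <- bx - ax; dy <- by - ay
    l2 <- dx^2 + dy^2
    t <- if (l2 == 0) 0 else max(0, min(1, ((px - ax) * dx + (py - ay) * dy) / l2))
    best <- min(best, (px - ax - t * dx)^2 + (py - ay - t * dy)^2)
  }
  sqrt(best)
}

# Monte-Carlo area of a dilated outline (>= n uniform points in a padded box)
oracle_dilated_area_mc <- function(ol, d, n = 1e6) {
  bx <- range(ol$x) + c(-d, d) * 1.05
  by <- range(ol$y) + c(-d, d) * 1.05
  px <- stats::runif(n, bx[1], bx[2]); py <- stats::runif(n, by[1], by[2])
  inside <- vapply(seq_len(n), function(i) {
    oracle_point_in_polygon(px[i], py[i], ol) ||
      oracle_boundary_distance(px[i], py[i], ol) <= d
  }, TRUE)
  mean(inside) * diff(bx) * diff(by)
}

# scalar loop bin index matching the [lo, hi) convention, last edge closed
oracle_bin <- function(d, edges) {
  nb <- length(edges) - 1L
  for (i in seq_len(nb)) {
    hi_ok <- if (i == nb) d <= edges[i + 1] else d < edges[i + 1]
    if (d >= edges[i] && hi_ok) return(i)
  }
  0L
}

# naive double-loop stomata-sector correlation: distances via per-segment
# minimization, counts via scalar loops
oracle_sector_zeta <- function(map, sectors, sets, edges) {
  nb <- length(edges) - 1L
  dist_one <- function(px, py) {
    inside <- any(vapply(sectors, function(s) oracle_point_in_polygon(px, py, s) ||
                           oracle_boundary_distance(px, py, s) <= 1e-9, TRUE))
    if (inside) return(NA_real_)
    min(vapply(sectors, function(s) oracle_boundary_distance(px, py, s), 0))
  }
  count_set <- function(pts) {
    cnt <- integer(nb)
    for (i in seq_len(nrow(pts))) {
      d <- dist_one(pts$x[i], pts$y[i])
      if (is.na(d)) next
      b <- oracle_bin(d, edges)
      if (b > 0) cnt[b] <- cnt[b] + 1L
    }
    cnt
  }
  S <- count_set(map$stomata)
  Rm <- rowMeans(vapply(sets, count_set, numeric(nb)))
  list(S = S, R = Rm, zeta = ifelse(Rm > 0, S / Rm - 1, NA_real_))
}

# naive Landy-Szalay autocorrelation with explicit pair loops
oracle_ls_zeta <- function(stomata, sets, edges) {
  nb <- length(edges) - 1L
  pair_counts <- function(ax, ay, bx = NULL, by = NULL) {
    cnt <- integer(nb)
    if (is.null(bx)) {
      n <- length(ax)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        b <- oracle_bin(sqrt((ax[i] - ax[j])^2 + (ay[i] - ay[j])^2), edges)
        if (b > 0) cnt[b] <- cnt[b] + 1L
      }
    } else {
      # coincident (zero-distance) cross pairs are excluded from count and
      # normalization, matching the estimator's degeneracy convention
      denom <- 0L
      for (i in seq_along(ax)) for (j in seq_along(bx)) {
        d <- sqrt((ax[i] - bx[j])^2 + (ay[i] - by[j])^2)
        if (d == 0) next
        denom <- denom + 1L
        b <- oracle_bin(d, edges)
        if (b > 0) cnt[b] <- cnt[b] + 1L
      }
      return(cnt / denom)
    }
    cnt
  }
  n <- length(stomata$x)
  ss <- pair_counts(stomata$x, stomata$y) / choose(n, 2)
  rr <- 0; sr <- 0
  for (p in sets) {
    m <- length(p$x)
    rr <- rr + pair_counts(p$x, p$y) / choose(m, 2)
    sr <- sr + pair_counts(stomata$x, stomata$y, p$x, p$y)
  }
  rr <- rr / length(sets); sr <- sr / length(sets)
  ifelse(rr > 0, (ss - 2 * sr + rr) / rr, NA_real_)
}

# wrap a list of data.frames as a random ensemble without re-drawing
fake_ensemble <- function(sets) {
  structure(list(sets = sets, n = nrow(sets[[1]]), n_sets = length(sets),
                 seed = NULL), class = "random_ensemble")
}

# small synthetic fixture map shared by estimator tests
small_fixture_map <- function(n_stomata = 20, seed = 101) {
  cot <- synth_cotyledon(width = 1200, height = 800, seed = seed)
  sec <- synth_sector(20000, cot, seed = seed + 1, center = c(0, 0))
  pts <- generate_uniform_points(n_stomata, cot, seed = seed + 2)
  cotyledon_map(cot, list(sec), pts, label = "fixture")
}
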