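#' Sector filter settings
#'
#' Sectors are filtered before correlation analysis so that size and
#' cross-talk between nearby sectors do not distort the estimate: only
#' sectors with area inside `[area_min, area_max]` are analyzed (defaults
#' 15,000-40,000 um^2; set `area_max = NULL` to apply the lower bound only),
#' and any pair of retained sectors closer than `min_separation` um
#' (boundary to boundary, default 200) is removed — both members of the
#' pair.
#'
#' @param area_min,area_max Sector area window (um^2).
#' @param min_separation Minimum boundary-to-boundary separation (um).
#' @return A `sector_filter` object.
#' @export
sector_filter <- function(area_min = 15000, area_max = 40000, min_separation = 200) {
  if (!is.null(area_max) && area_min >= area_max)
    stop("area_min must be < area_max")
  structure(list(area_min = area_min, area_max = area_max,
                 min_separation = min_separation), class = "sector_filter")
}

#' Apply a sector filter to a map
#'
#' @param map A [cotyledon_map()].
#' @param filter A [sector_filter()].
#' @return List of retained sector outlines (possibly empty).
#' @export
filter_sectors <- function(map, filter = sector_filter()) {
  stopifnot(inherits(map, "cotyledon_map"))
  secs <- map$sectors
  if (length(secs) == 0) return(list())
  a <- vapply(secs, polygon_area, 0)
  keep <- a >= filter$area_min
  if (!is.null(filter$area_max)) keep <- keep & (a <= filter$area_max)
  secs <- secs[keep]
  if (length(secs) >= 2 && filter$min_separation > 0) {
    n <- length(secs)
    bad <- rep(FALSE, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (outline_separation(secs[[i]], secs[[j]]) < filter$min_separation) {
        bad[i] <- TRUE; bad[j] <- TRUE
      }
    }
    secs <- secs[!bad]
  }
  secs
}

#' Stoma-to-sector boundary distances
#'
#' For each stoma not inside any retained sector, the nearest Euclidean
#' distance to a retained sector boundary (minimum over sectors). Stomata
#' inside a sector are excluded.
#'
#' @param map A [cotyledon_map()].
#' @param sectors Retained sector outlines (non-empty).
#' @param points Optional data frame `x`,`y` to measure instead of the map's
#'   stomata (used internally for random null points).
#' @return Numeric vector of distances (um).
#' @export
stoma_sector_distances <- function(map, sectors, points = NULL) {
  if (length(sectors) == 0) stop("no retained sectors")
  if (is.null(points)) points <- map$stomata
  x <- points$x; y <- points$y
  if (length(x) == 0) return(numeric(0))
  inside <- rep(FALSE, length(x))
  for (s in sectors) inside <- inside | point_in_polygon(x, y, s)
  x <- x[!inside]; y <- y[!inside]
  if (length(x) == 0) return(numeric(0))
  d <- rep(Inf, length(x))
  for (s in sectors) d <- pmin(d, nearest_boundary_distance(x, y, s))
  d
}

#' Logarithmically spaced distance bins
#'
#' @param r_min,r_max Range (um); defaults 5-2000.
#' @param n Number of bins (default 24).
#' @return Numeric vector of `n + 1` bin edges.
#' @export
log_bins <- function(r_min = 5, r_max = 2000, n = 24) {
  if (r_min <= 0 || r_max <= r_min || n < 1) stop("invalid bin specification")
  exp(seq(log(r_min), log(r_max), length.out = n + 1))
}

# counts per bin; bins are [e_i, e_{i+1}) with the last edge closed
bin_counts <- function(d, edges) {
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  idx[idx == length(edges)] <- 0L  # beyond last edge (exact top handled above)
  tabulate(idx[idx > 0], nbins = length(edges) - 1L)
}

corr_skeleton <- function(edges) {
  data.frame(r_lo = edges[-length(edges)], r_hi = edges[-1],
             r_mid = sqrt(edges[-length(edges)] * edges[-1]))
}

#' Stomata-sector spatial correlation function
#'
#' The bivariate two-point correlation of stomatal positions against a
#' sector boundary: per distance bin i,
#' \deqn{\zeta(r_i) = S(r_i) / \langle R(r_i) \rangle - 1,}
#' where `S` counts stomata whose nearest sector-boundary distance falls in
#' the bin and `<R>` is the mean of the same count over an ensemble of
#' uniform random point sets of matched size confined to the cotyledon
#' outline. Positive values mean stomata are more likely at that distance
#' than under spatial randomness; negative values mean depletion. Random
#' points inside sectors are excluded symmetrically with stomata. Bins whose
#' expected random count is zero are reported as undefined (`NA`).
#'
#' @param map A [cotyledon_map()].
#' @param sectors Retained sector outlines (see [filter_sectors()]).
#' @param ensemble A [generate_ensemble()] built on the same cotyledon with
#'   `n` equal to the total stoma count.
#' @param bins Bin edges, see [log_bins()].
#' @return A `space_corr` object; see [as.data.frame.space_corr()].
#' @export
sector_correlation <- function(map, sectors, ensemble, bins = log_bins()) {
  stopifnot(inherits(ensemble, "random_ensemble"))
  d_obs <- stoma_sector_distances(map, sectors)
  S <- bin_counts(d_obs, bins)
  if (sum(S) == 0) warning("bin range excludes all observed distances")
  Rmat <- vapply(ensemble$sets, function(p)
    bin_counts(stoma_sector_distances(map, sectors, points = p), bins),
    numeric(length(bins) - 1L))
  R_expected <- rowMeans(Rmat)
  zeta <- ifelse(R_expected > 1e-12, S / R_expected - 1, NA_real_)
  structure(list(bins = corr_skeleton(bins), edges = bins, S = S,
                 R_expected = R_expected, zeta = zeta,
                 ci_lo = rep(NA_real_, length(S)), ci_hi = rep(NA_real_, length(S)),
                 distances = d_obs, type = "sector",
                 n_stomata = nrow(map$stomata), n_sets = ensemble$n_sets),
            class = "space_corr")
}

cross_dist <- function(ax, ay, bx, by) {
  sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
}

#' Stomata-stomata autocorrelation (Landy-Szalay estimator)
#'
#' Two-point autocorrelation of the stomatal pattern with itself, using the
#' low-bias, low-variance estimator from galaxy clustering statistics:
#' \deqn{\zeta(r_i) = (ss - 2\,sr + rr) / rr,}
#' where `ss`, `rr` and `sr` are per-bin counts of stoma-stoma pairs,
#' random-random pairs (within one null set) and stoma-random cross pairs,
#' each normalized by its total number of pairs, with `rr` and `sr` averaged
#' over the ensemble. All stomata across the cotyledon enter; bins with zero
#' expected random-random count are undefined (`NA`). Degenerate coincident
#' stoma-random pairs (zero distance) are excluded from the cross count and
#' its normalization, so a null set identical to the data yields exactly
#' zero in every defined bin.
#'
#' @inheritParams sector_correlation
#' @return A `space_corr` object with additional normalized `SS`, `RR`, `SR`
#'   components.
#' @export
stomata_autocorrelation <- function(map, ensemble, bins = log_bins()) {
  stopifnot(inherits(ensemble, "random_ensemble"))
  sx <- map$stomata$x; sy <- map$stomata$y
  n <- length(sx)
  if (n < 2) stop("autocorrelation needs at least 2 stomata")
  nb <- length(bins) - 1L
  SS_raw <- bin_counts(as.numeric(stats::dist(cbind(sx, sy))), bins)
  ss <- SS_raw / choose(n, 2)
  rr_acc <- numeric(nb); sr_acc <- numeric(nb)
  for (p in ensemble$sets) {
    m <- nrow(p)
    rr_acc <- rr_acc + bin_counts(as.numeric(stats::dist(cbind(p$x, p$y))), bins) / choose(m, 2)
    # degenerate coincident stoma-random pairs (zero distance) are dropped
    # from the cross count and its normalization, so an ensemble identical
    # to the data gives exactly zero correlation
    cd <- as.numeric(cross_dist(sx, sy, p$x, p$y))
    cd <- cd[cd > 0]
    sr_acc <- sr_acc + bin_counts(cd, bins) / length(cd)
  }
  rr <- rr_acc / ensemble$n_sets
  sr <- sr_acc / ensemble$n_sets
  zeta <- ifelse(rr > 1e-15, (ss - 2 * sr + rr) / rr, NA_real_)
  structure(list(bins = corr_skeleton(bins), edges = bins, S = SS_raw,
                 R_expected = rr * choose(n, 2), zeta = zeta,
                 SS = ss, RR = rr, SR = sr,
                 ci_lo = rep(NA_real_, nb), ci_hi = rep(NA_real_, nb),
                 type = "auto", n_stomata = n, n_sets = ensemble$n_sets),
            class = "space_corr")
}

#' Bootstrap confidence band for the sector correlation
#'
#' Percentile interval from case-resampling the observed stoma distance list
#' (with replacement, same size) and recomputing zeta against the fixed
#' ensemble expectation. Measures the sampling noise of the observed pattern.
#'
#' @param corr A `space_corr` of type `"sector"`.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param level Coverage (default 0.95).
#' @param seed Integer seed for reproducible bands.
#' @return `corr` with `ci_lo`, `ci_hi` filled in.
#' @export
bootstrap_ci <- function(corr, n_boot = 1000, level = 0.95, seed = NULL) {
  stopifnot(inherits(corr, "space_corr"), identical(corr$type, "sector"))
  if (n_boot < 100) stop("n_boot must be >= 100")
  d <- corr$distances
  nb <- length(corr$S)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  zmat <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      S_b <- bin_counts(sample(d, length(d), replace = TRUE), corr$edges)
      ifelse(corr$R_expected > 1e-12, S_b / corr$R_expected - 1, NA_real_)
    }, numeric(nb))
  })
  ok <- corr$R_expected > 1e-12
  corr$ci_lo <- corr$ci_hi <- rep(NA_real_, nb)
  if (any(ok)) {
    ci <- apply(zmat[ok, , drop = FALSE], 1, stats::quantile,
                probs = qs, names = FALSE)
    corr$ci_lo[ok] <- ci[1, ]; corr$ci_hi[ok] <- ci[2, ]
  }
  corr
}

#' Pool per-cotyledon correlation counts
#'
#' Sums the stoma counts `S` and expected random counts `<R>` across
#' cotyledons measured on identical bins before forming zeta, giving a
#' per-genotype curve. Distance lists are concatenated so a pooled bootstrap
#' band can be recomputed.
#'
#' @param corrs List of `space_corr` objects of type `"sector"` with
#'   identical bin edges.
#' @return A pooled `space_corr`.
#' @export
pool_cotyledons <- function(corrs) {
  stopifnot(length(corrs) >= 1)
  e1 <- corrs[[1]]$edges
  for (cc in corrs) {
    stopifnot(inherits(cc, "space_corr"), identical(cc$type, "sector"))
    if (!isTRUE(all.equal(cc$edges, e1))) stop("mismatched bin edges")
  }
  S <- Reduce(`+`, lapply(corrs, `[[`, "S"))
  R <- Reduce(`+`, lapply(corrs, `[[`, "R_expected"))
  zeta <- ifelse(R > 1e-12, S / R - 1, NA_real_)
  structure(list(bins = corrs[[1]]$bins, edges = e1, S = S, R_expected = R,
                 zeta = zeta,
                 ci_lo = rep(NA_real_, length(S)), ci_hi = rep(NA_real_, length(S)),
                 distances = unlist(lapply(corrs, `[[`, "distances")),
                 type = "sector",
                 n_stomata = sum(vapply(corrs, `[[`, 0, "n_stomata")),
                 n_sets = corrs[[1]]$n_sets),
            class = "space_corr")
}

#' @export
as.data.frame.space_corr <- function(x, ...) {
  data.frame(r_lo = x$bins$r_lo, r_hi = x$bins$r_hi, r_mid = x$bins$r_mid,
             S_count = x$S, R_expected = x$R_expected, zeta = x$zeta,
             ci_lo = x$ci_lo, ci_hi = x$ci_hi)
}

#' @export
print.space_corr <- function(x, ...) {
  cat(sprintf("<%s correlation: %d bins, %d stomata, %d random sets>\n",
              if (x$type == "sector") "stomata-sector" else "stomata-stomata",
              length(x$S), x$n_stomata, x$n_sets))
  print(utils::head(as.data.frame(x), 10))
  if (length(x$S) > 10) cat("...\n")
  invisible(x)
}

#' Plot a correlation function
#'
#' zeta against bin mid-distance with the confidence band, on a linear
#' distance axis.
#'
#' @param x A `space_corr`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.space_corr <- function(x, ...) {
  df <- as.data.frame(x)
  ok <- is.finite(df$zeta)
  graphics::plot(df$r_mid[ok], df$zeta[ok], type = "n",
                 xlab = "distance from sector boundary (um)",
                 ylab = expression(zeta(r)), ...)
  if (any(is.finite(df$ci_lo))) {
    okc <- ok & is.finite(df$ci_lo)
    graphics::polygon(c(df$r_mid[okc], rev(df$r_mid[okc])),
                      c(df$ci_lo[okc], rev(df$ci_hi[okc])),
                      col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  }
  graphics::abline(h = 0, lty = 2, col = "grey50")
  graphics::lines(df$r_mid[ok], df$zeta[ok], col = "steelblue")
  graphics::points(df$r_mid[ok], df$zeta[ok], pch = 16, cex = 0.6, col = "steelblue")
  invisible(x)
}

#' Full stomata-sector correlation pipeline for one map
#'
#' Convenience wrapper: filter sectors, generate the null ensemble, compute
#' the sector correlation and its bootstrap band.
#'
#' @param map A [cotyledon_map()].
#' @param filter A [sector_filter()].
#' @param n_sets Ensemble size (reference 1000).
#' @param bins Bin edges.
#' @param n_boot Bootstrap resamples (0 to skip the band).
#' @param seed Integer seed driving both the ensemble and the bootstrap.
#' @return A `space_corr`.
#' @export
space_correlate <- function(map, filter = sector_filter(), n_sets = 1000,
                            bins = log_bins(), n_boot = 1000, seed = NULL) {
  sectors <- filter_sectors(map, filter)
  if (length(sectors) == 0) stop("no sectors pass the filter")
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 2))
  ens <- generate_ensemble(nrow(map$stomata), map$cotyledon, n_sets, seed = seeds[1])
  cf <- sector_correlation(map, sectors, ens, bins)
  if (n_boot > 0) cf <- bootstrap_ci(cf, n_boot = n_boot, seed = seeds[2])
  cf
}
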