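#' Partition a cotyledon into sector, offset-ring and faraway regions
#'
#' Builds the region decomposition used for offset-band density analysis:
#' the union of sector interiors, successive rings between dilation distances
#' (`boundaries`, e.g. `c(100, 200)` um or `seq(50, 400, by = 50)`), and the
#' remaining cotyledon area. Rings exclude sector interiors and anything
#' beyond the cotyledon outline; overlapping dilations of multiple sectors
#' are united so no area is counted twice.
#'
#' Stomata are assigned by exact Euclidean distance to the nearest sector
#' boundary (a stoma inside a sector belongs to the sector region; on a
#' shared boundary the innermost region wins), which makes count conservation
#' exact by construction.
#'
#' @param map A [cotyledon_map()] with at least one sector.
#' @param boundaries Strictly increasing positive distances (um). Empty
#'   vector gives a sector/faraway two-way split.
#' @param sectors Optional subset of sector outlines to use (defaults to all
#'   sectors of the map).
#' @param segments Arc polygonization fineness, see [dilate_outline()].
#' @return A `region_partition`: list with `labels`, `regions` (list of
#'   `space_region`), `areas`, `counts`, `boundaries`.
#' @export
partition_cotyledon <- function(map, boundaries = c(100), sectors = NULL,
                                segments = 64) {
  stopifnot(inherits(map, "cotyledon_map"))
  if (is.null(sectors)) sectors <- map$sectors
  if (length(sectors) == 0) stop("partition requires at least one sector")
  boundaries <- as.numeric(boundaries)
  if (length(boundaries)) {
    if (any(boundaries <= 0) || any(diff(boundaries) <= 0))
      stop("boundaries must be strictly increasing and positive")
  }
  cot <- map$cotyledon
  sector_region <- clip_subtract(union_regions(lapply(sectors, as_region)), cot)

  # cumulative dilations clipped to the cotyledon; rings are their differences
  cum <- list(sector_region)
  for (b in boundaries) {
    dil <- union_regions(lapply(sectors, dilate_outline, d = b, segments = segments))
    cum <- c(cum, list(clip_subtract(dil, cot)))
  }
  k <- length(boundaries)
  regions <- vector("list", k + 2L)
  regions[[1]] <- sector_region
  labels <- "sector"
  prev_b <- 0
  for (i in seq_len(k)) {
    regions[[i + 1L]] <- clip_subtract(cum[[i + 1L]], NULL, remove = list(cum[[i]]))
    labels <- c(labels, sprintf("%g-%g um", prev_b, boundaries[i]))
    prev_b <- boundaries[i]
  }
  regions[[k + 2L]] <- clip_subtract(as_region(cot), NULL, remove = list(cum[[k + 1L]]))
  labels <- c(labels, "rest")

  # distance-based stoma classification: exact, conserving, innermost-wins
  sx <- map$stomata$x; sy <- map$stomata$y
  counts <- integer(k + 2L)
  if (length(sx)) {
    in_sector <- rep(FALSE, length(sx))
    for (s in sectors) in_sector <- in_sector | point_in_polygon(sx, sy, s)
    d <- rep(Inf, length(sx))
    for (s in sectors) d <- pmin(d, nearest_boundary_distance(sx, sy, s))
    # ring k covers (b_{k-1}, b_k]; a stoma exactly on b_k goes to the inner ring
    bin <- findInterval(d, boundaries, left.open = TRUE) + 1L
    bin[bin > k] <- k + 1L                                      # beyond last -> rest
    idx <- ifelse(in_sector, 0L, bin) + 1L
    counts <- tabulate(idx, nbins = k + 2L)
  }
  structure(list(labels = labels, regions = regions,
                 areas = vapply(regions, region_area, 0),
                 counts = counts, boundaries = boundaries),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  print(data.frame(region = x$labels, stoma_count = x$counts,
                   area_um2 = signif(x$areas, 6)))
  invisible(x)
}

#' Count stomata inside a region
#'
#' Boundary-inclusive membership count.
#'
#' @param stomata Data frame / list with `x`, `y` (um).
#' @param region A `space_region`.
#' @return Integer count.
#' @export
count_in_region <- function(stomata, region) {
  x <- as.numeric(stomata$x); y <- as.numeric(stomata$y)
  if (length(x) == 0) return(0L)
  sum(region_contains(region, x, y))
}

#' Per-region stomatal density table
#'
#' One row per (cotyledon, region). Cotyledons with multiple sectors
#' aggregate stoma counts and areas before dividing, so each cotyledon
#' contributes a single density sample per region. Densities are reported
#' both per um^2 and per mm^2.
#'
#' @param maps A [cotyledon_map()] or list of them.
#' @param boundaries As in [partition_cotyledon()].
#' @param ... Passed to [partition_cotyledon()].
#' @return Data frame with columns `cotyledon`, `region`, `stoma_count`,
#'   `area_um2`, `density_per_um2`, `density_per_mm2`.
#' @export
density_table <- function(maps, boundaries = c(100), ...) {
  if (inherits(maps, "cotyledon_map")) maps <- list(maps)
  rows <- lapply(maps, function(m) {
    p <- partition_cotyledon(m, boundaries, ...)
    data.frame(cotyledon = m$label, region = p$labels,
               stoma_count = p$counts, area_um2 = p$areas,
               density_per_um2 = p$counts / p$areas,
               density_per_mm2 = 1e6 * p$counts / p$areas)
  })
  do.call(rbind, rows)
}
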