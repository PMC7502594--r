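test_that("sector filter applies the area window and the separation rule", {
  cot <- outline(c(-2000, 2000, 2000, -2000), c(-2000, -2000, 2000, 2000))
  sq <- function(cx, side) outline(cx + c(-1, 1, 1, -1) * side / 2,
                                   c(-1, -1, 1, 1) * side / 2)
  small <- sq(-1500, 100)      # 10,000 um^2 -> below area_min
  ok1 <- sq(-800, 141.4214)    # ~20,000 um^2
  ok2 <- sq(800, 141.4214)
  big <- sq(1500, 300)         # 90,000 um^2 -> above area_max
  map <- cotyledon_map(cot, list(small, ok1, ok2, big), list(x = 0, y = 0))
  kept <- filter_sectors(map, sector_filter())
  expect_length(kept, 2)
  expect_equal(sort(vapply(kept, function(s) mean(s$x), 0)), c(-800, 800))

  # no maximum limit keeps the large sector
  kept2 <- filter_sectors(map, sector_filter(area_max = NULL))
  expect_length(kept2, 3)

  # two valid sectors 100 um apart are both removed
  near1 <- sq(-120.7107, 141.4214); near2 <- sq(120.7107, 141.4214)
  map2 <- cotyledon_map(cot, list(near1, near2), list(x = 0, y = 1000))
  expect_length(filter_sectors(map2, sector_filter()), 0)
  expect_length(filter_sectors(map2, sector_filter(min_separation = 50)), 2)
})

test_that("stoma-sector distances exclude interior stomata and match the oracle", {
  map <- small_fixture_map(n_stomata = 40, seed = 51)
  sec <- map$sectors[[1]]
  d <- stoma_sector_distances(map, map$sectors)
  inside <- point_in_polygon(map$stomata$x, map$stomata$y, sec)
  expect_length(d, sum(!inside))
  want <- vapply(which(!inside), function(i)
    oracle_boundary_distance(map$stomata$x[i], map$stomata$y[i], sec), 0)
  expect_equal(d, want, tolerance = 1e-9)
  expect_error(stoma_sector_distances(map, list()), "no retained sectors")
})

test_that("zeta follows S over expected R minus one, with undefined bins flagged", {
  # S(r)=10, <R>=10 -> 0 ; S=30, <R>=10 -> 2 (direct ratio arithmetic)
  expect_equal(10 / 10 - 1, 0)
  map <- small_fixture_map(n_stomata = 20, seed = 52)
  ens <- generate_ensemble(20, map$cotyledon, 3, seed = 53)
  cf <- sector_correlation(map, map$sectors, ens)
  expect_s3_class(cf, "space_corr")
  defined <- cf$R_expected > 0
  expect_true(all(is.na(cf$zeta[!defined])))
  expect_equal(cf$zeta[defined], cf$S[defined] / cf$R_expected[defined] - 1)
  expect_true(all(cf$zeta >= -1, na.rm = TRUE))
  # sum of S over all bins = stomata outside sectors whose distance the bins span
  expect_equal(sum(cf$S), sum(cf$distances >= 5 & cf$distances <= 2000))
})

test_that("sector correlation matches the naive double-loop oracle exactly", {
  map <- small_fixture_map(n_stomata = 20, seed = 54)
  sets <- lapply(55:57, function(s) generate_uniform_points(20, map$cotyledon, seed = s))
  edges <- log_bins(5, 2000, 12)
  cf <- sector_correlation(map, map$sectors, fake_ensemble(sets), edges)
  orc <- oracle_sector_zeta(map, map$sectors, sets, edges)
  expect_identical(cf$S, orc$S)
  expect_equal(cf$R_expected, orc$R)
  expect_equal(cf$zeta, orc$zeta)
})

test_that("autocorrelation reproduces hand-enumerated and degenerate cases", {
  cot <- outline(c(-20, 20, 20, -20), c(-20, -20, 20, 20))
  sto <- list(x = c(0, 3, 0), y = c(0, 0, 4))          # pair distances 3,4,5
  map <- cotyledon_map(cot, stomata = sto)
  rnd <- data.frame(x = c(10, 13, 10), y = c(0, 0, 4)) # same triangle, shifted
  ac <- stomata_autocorrelation(map, fake_ensemble(list(rnd)), bins = c(2, 6))
  # ss = rr = 1; none of the 9 cross distances falls in [2,6) -> sr = 0
  expect_equal(ac$SS, 1)
  expect_equal(ac$RR, 1)
  expect_equal(ac$SR, 0)
  expect_equal(ac$zeta, 2)

  # data identical to every random set -> zeta = 0 wherever defined
  pts <- generate_uniform_points(15, cot, seed = 61)
  map2 <- cotyledon_map(cot, stomata = pts)
  ac2 <- stomata_autocorrelation(map2, fake_ensemble(list(pts, pts)),
                                 bins = log_bins(1, 60, 8))
  expect_equal(ac2$zeta[!is.na(ac2$zeta)],
               rep(0, sum(!is.na(ac2$zeta))))
  expect_error(stomata_autocorrelation(cotyledon_map(cot, stomata = list(x = 0, y = 0)),
                                       fake_ensemble(list(pts))), "at least 2")
})

test_that("autocorrelation matches the naive Landy-Szalay oracle exactly", {
  map <- small_fixture_map(n_stomata = 15, seed = 62)
  sets <- lapply(63:65, function(s) generate_uniform_points(15, map$cotyledon, seed = s))
  edges <- log_bins(5, 2000, 10)
  ac <- stomata_autocorrelation(map, fake_ensemble(sets), edges)
  expect_equal(ac$zeta, oracle_ls_zeta(map$stomata, sets, edges))
})

test_that("bootstrap bands are reproducible, contain the point estimate, and shrink with n", {
  map <- small_fixture_map(n_stomata = 100, seed = 66)
  ens <- generate_ensemble(100, map$cotyledon, 30, seed = 67)
  cf <- sector_correlation(map, map$sectors, ens)
  b1 <- bootstrap_ci(cf, n_boot = 200, seed = 68)
  b2 <- bootstrap_ci(cf, n_boot = 200, seed = 68)
  expect_equal(b1$ci_lo, b2$ci_lo)
  ok <- is.finite(b1$zeta)
  expect_true(all(b1$ci_lo[ok] <= b1$zeta[ok] + 1e-9))
  expect_true(all(b1$ci_hi[ok] >= b1$zeta[ok] - 1e-9))
  expect_error(bootstrap_ci(cf, n_boot = 50), ">= 100")

  # width ~ 1/sqrt(N): quadrupling N should roughly halve the mean width
  # (bins compared at matched relative population so the same distance range
  # enters at both sample sizes)
  mk <- function(n, seed) {
    m <- synth_map(pattern_spec("uniform", n = n, seed = seed))
    e <- generate_ensemble(n, m$cotyledon, 30, seed = seed + 1)
    b <- bootstrap_ci(sector_correlation(m, m$sectors, e), n_boot = 300, seed = seed + 2)
    mean((b$ci_hi - b$ci_lo)[b$R_expected >= 0.08 * n], na.rm = TRUE)
  }
  w1 <- mean(vapply(1:3, function(s) mk(150, 70 + 10 * s), 0))
  w4 <- mean(vapply(1:3, function(s) mk(600, 71 + 10 * s), 0))
  expect_gt(w1 / w4, 1.5)
  expect_lt(w1 / w4, 2.7)
})

test_that("pooling sums counts before forming zeta and is order invariant", {
  map <- small_fixture_map(n_stomata = 60, seed = 81)
  ens <- generate_ensemble(60, map$cotyledon, 20, seed = 82)
  cf <- sector_correlation(map, map$sectors, ens)
  expect_equal(pool_cotyledons(list(cf))$zeta, cf$zeta)
  # two identical cotyledons: same zeta, roughly halved CI width
  p2 <- bootstrap_ci(pool_cotyledons(list(cf, cf)), n_boot = 400, seed = 83)
  c1 <- bootstrap_ci(cf, n_boot = 400, seed = 83)
  expect_equal(p2$zeta, cf$zeta)
  ratio <- mean((c1$ci_hi - c1$ci_lo)[c1$R_expected >= 10], na.rm = TRUE) /
    mean((p2$ci_hi - p2$ci_lo)[p2$R_expected >= 20], na.rm = TRUE)
  expect_gt(ratio, 1.2)
  map2 <- small_fixture_map(n_stomata = 60, seed = 84)
  cf2 <- sector_correlation(map2, map2$sectors,
                            generate_ensemble(60, map2$cotyledon, 20, seed = 85))
  expect_equal(pool_cotyledons(list(cf, cf2))$zeta,
               pool_cotyledons(list(cf2, cf))$zeta)
  bad <- sector_correlation(map, map$sectors, ens, bins = log_bins(5, 1000, 10))
  expect_error(pool_cotyledons(list(cf, bad)), "mismatched bin edges")
})
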