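test_that("shoelace area is orientation-independent and rejects degenerate input", {
  expect_equal(polygon_area(unit_square()), 1)
  expect_equal(polygon_area(outline(c(0, 4, 0), c(0, 0, 3))), 6)
  expect_equal(polygon_area(outline(rev(c(0, 1, 1, 0)), rev(c(0, 0, 1, 1)))), 1)
  expect_error(outline(c(0, 1), c(0, 1)), "3")
  expect_error(outline(c(0, 1, 2), c(0, 1, 2)), "zero area")
  expect_error(outline(c(0, 1, 1, 0), c(0, 1, 0, 1)), "self-intersect")
})

test_that("point-in-polygon is boundary-inclusive and matches a winding-number oracle", {
  sq <- unit_square()
  expect_true(point_in_polygon(0.5, 0.5, sq))
  expect_false(point_in_polygon(2, 0.5, sq))
  expect_true(point_in_polygon(1, 0.5, sq))   # on an edge
  expect_true(point_in_polygon(0, 0, sq))     # on a vertex

  set.seed(7)
  for (rep in 1:5) {
    poly <- random_polygon(n = sample(6:20, 1))
    px <- stats::runif(2000, -2, 2); py <- stats::runif(2000, -2, 2)
    # skip points closer than tol to the boundary, where the convention differs
    d <- nearest_boundary_distance(px, py, poly)
    keep <- d > 1e-8
    got <- point_in_polygon(px[keep], py[keep], poly)
    want <- vapply(which(keep), function(i) oracle_point_in_polygon(px[i], py[i], poly), TRUE)
    expect_identical(got, want)
  }
})

test_that("boundary distance matches exhaustive per-segment minimization", {
  sq <- unit_square()
  expect_equal(nearest_boundary_distance(0.5, 0.5, sq), 0.5)
  expect_equal(nearest_boundary_distance(2, 0.5, sq), 1)
  expect_equal(nearest_boundary_distance(2, 2, sq), sqrt(2))
  expect_equal(nearest_boundary_distance(1, 0.5, sq), 0)

  set.seed(11)
  poly <- random_polygon(15)
  px <- stats::runif(500, -2, 2); py <- stats::runif(500, -2, 2)
  got <- nearest_boundary_distance(px, py, poly)
  want <- vapply(seq_along(px), function(i) oracle_boundary_distance(px[i], py[i], poly), 0)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("dilation matches the Minkowski closed form and composes", {
  sq100 <- outline(c(0, 100, 100, 0), c(0, 0, 100, 100))
  expect_equal(region_area(dilate_outline(sq100, 0)), 1e4)
  a50 <- region_area(dilate_outline(sq100, 50))
  closed <- 1e4 + 4 * 100 * 50 + pi * 50^2
  expect_lt(abs(a50 - closed) / closed, 0.005)

  # chained dilation covers at least the single-step dilation
  r1 <- dilate_region(dilate_outline(sq100, 30), 20)
  r2 <- dilate_outline(sq100, 50)
  expect_gte(region_area(r1), region_area(r2) - 1e-6 * region_area(r2))
  expect_lt(abs(region_area(r1) - closed) / closed, 0.005)

  expect_error(dilate_outline(sq100, -1), ">= 0")
})

test_that("dilating a circle-like outline reproduces the disk area", {
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  circ <- outline(100 * cos(th), 100 * sin(th))
  a <- region_area(dilate_outline(circ, 100))
  expect_lt(abs(a - pi * 200^2) / (pi * 200^2), 0.01)
})

test_that("clip and union respect area accounting", {
  sqA <- outline(c(0, 1, 1, 0), c(0, 0, 1, 1))
  sqB <- outline(c(0.5, 1.5, 1.5, 0.5), c(0, 0, 1, 1))
  sqC <- outline(c(5, 6, 6, 5), c(0, 0, 1, 1))
  # inclusion-exclusion
  aU <- region_area(union_regions(list(sqA, sqB)))
  aI <- region_area(clip_subtract(as_region(sqA), sqB))
  expect_equal(aU + aI, polygon_area(sqA) + polygon_area(sqB), tolerance = 1e-9)
  expect_equal(aU, 1.5, tolerance = 1e-9)

  expect_equal(region_area(union_regions(list(sqA, sqC))), 2, tolerance = 1e-9)
  expect_equal(region_area(union_regions(list(sqA, sqA))), 1, tolerance = 1e-9)
  expect_equal(region_area(union_regions(list())), 0)

  big <- outline(c(0, 300, 300, 0), c(0, 0, 300, 300))
  small <- outline(c(0, 200, 200, 0), c(0, 0, 200, 200))
  expect_equal(region_area(clip_subtract(as_region(big), small)), 40000, tolerance = 1e-9)

  # subtracting a region from itself empties it; unclipped region unchanged
  expect_equal(region_area(clip_subtract(as_region(sqA), NULL, list(sqA))), 0)
  expect_equal(region_area(clip_subtract(as_region(sqA), big)), 1, tolerance = 1e-9)
})

test_that("region membership handles holes and multiple parts", {
  donut <- clip_subtract(as_region(outline(c(0, 10, 10, 0), c(0, 0, 10, 10))),
                         NULL, list(outline(c(3, 7, 7, 3), c(3, 3, 7, 7))))
  expect_equal(region_area(donut), 100 - 16, tolerance = 1e-9)
  expect_true(region_contains(donut, 1, 1))
  expect_false(region_contains(donut, 5, 5))     # in the hole
  expect_true(region_contains(donut, 3, 5))      # on the hole boundary
  expect_true(region_contains(donut, 0, 5))      # on the outer boundary
})

test_that("polyclip-backed booleans agree with spatstat.geom on a nontrivial overlap", {
  skip_if_not_installed("spatstat.geom")
  set.seed(21)
  a <- random_polygon(12); b <- random_polygon(12)
  b$x <- b$x + 0.5
  got <- region_area(union_regions(list(a, b)))
  wa <- spatstat.geom::owin(poly = list(x = a$x, y = a$y))
  wb <- spatstat.geom::owin(poly = list(x = b$x, y = b$y))
  want <- spatstat.geom::area.owin(spatstat.geom::union.owin(wa, wb))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("random transposition preserves area, is seeded, stays inside, and fails when impossible", {
  cot <- synth_cotyledon(seed = 1)
  sec <- synth_sector(20000, cot, seed = 2, center = c(0, 0))
  t1 <- transpose_outline(sec, cot, seed = 5)
  t2 <- transpose_outline(sec, cot, seed = 5)
  expect_equal(t1$x, t2$x)
  expect_equal(polygon_area(t1), polygon_area(sec), tolerance = 1e-12)
  expect_true(all(point_in_polygon(t1$x, t1$y, cot)))
  t3 <- transpose_outline(sec, cot, seed = 6)
  expect_false(isTRUE(all.equal(t1$x, t3$x)))

  wide <- outline(c(-3000, 3000, 3000, -3000), c(0, 0, 10, 10))
  expect_error(transpose_outline(wide, cot, seed = 1), "placement failure")
})
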