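test_that("local projection reproduces haversine distances", {
  sites <- data.frame(site_id = c("A", "B", "C"),
                      lon = c(-9.10, -9.10, -9.06),
                      lat = c(38.600, 38.609, 38.604),
                      role = c("background", "exposure", "exposure"))
  xy <- project_local(sites)
  d_ab <- sqrt(sum((xy["A", ] - xy["B", ])^2))
  d_ac <- sqrt(sum((xy["A", ] - xy["C", ])^2))
  hav_ab <- geosphere::distHaversine(c(-9.10, 38.600), c(-9.10, 38.609),
                                     r = 6371000)
  hav_ac <- geosphere::distHaversine(c(-9.10, 38.600), c(-9.06, 38.604),
                                     r = 6371000)
  expect_equal(d_ab, hav_ab, tolerance = 1e-4)
  expect_equal(d_ac, hav_ac, tolerance = 1e-4)
  # 0.009 degrees of latitude is about a kilometre
  expect_equal(d_ab, 1000.6, tolerance = 1e-3)
  expect_equal(d_ab, sqrt(sum((xy["B", ] - xy["A", ])^2))) # symmetry
  expect_equal(unname(xy["A", ] - xy["A", ]), c(0, 0))
})

test_that("IDW reproduces the hand-computed weighting and its bounds", {
  # query cell at origin; samples 1 m and 2 m away with values 0 and 3:
  # (0 * 1 + 3 * 1/4) / (1 + 1/4) = 0.6
  xy <- rbind(c(0, 1), c(2, 0))
  surf <- idw_interpolate(xy, c(0, 3), bbox = c(-0.5, 0.5, -0.5, 0.5),
                          cell = 1, k = 2)
  expect_equal(dim(surf$values), c(1, 1))
  expect_equal(surf$values[1, 1], 0.6)

  # single sample: constant surface at its value
  s1 <- idw_interpolate(rbind(c(10, 10)), 7,
                        bbox = c(0, 100, 0, 100), cell = 20)
  expect_equal(max(abs(s1$values - 7)), 0, tolerance = 1e-12)

  # equidistant query: arithmetic mean
  s2 <- idw_interpolate(rbind(c(-3, 0), c(3, 0)), c(2, 8),
                        bbox = c(-0.5, 0.5, -0.5, 0.5), cell = 1)
  expect_equal(s2$values[1, 1], 5)

  # exact at sample locations, bounded by the sample range
  set.seed(5)
  pts <- cbind(runif(12, 0, 1000), runif(12, 0, 1000))
  v <- runif(12, 10, 50)
  surf3 <- idw_interpolate(pts, v, bbox = c(0, 1000, 0, 1000),
                           cell = c(1000 / 3, 1000 / 3))
  expect_true(all(surf3$values >= min(v) & surf3$values <= max(v)))
  exact <- idw_interpolate(pts, v,
                           bbox = c(pts[1, 1] - 1, pts[1, 1] + 1,
                                    pts[1, 2] - 1, pts[1, 2] + 1),
                           cell = 2)
  expect_equal(exact$values[1, 1], v[1])

  # adding a constant shifts the whole surface by that constant
  surf4 <- idw_interpolate(pts, v + 11, bbox = c(0, 1000, 0, 1000),
                           cell = c(1000 / 3, 1000 / 3))
  expect_equal(surf4$values, surf3$values + 11, tolerance = 1e-12)
  expect_error(idw_interpolate(pts[0, , drop = FALSE], numeric(0)),
               "no samples")
})

test_that("percentile classes cut at linear-interpolation quintiles", {
  pc <- percentile_classes(1:10)
  expect_equal(unname(pc$edges), c(2.8, 4.6, 6.4, 8.2))
  # right-closed intervals
  expect_equal(pc$classes[c(1, 3, 5, 7, 9, 10)], c(0, 1, 2, 3, 4, 4))
  expect_warning(percentile_classes(rep(2, 6)), "distinct")
  counts <- table(percentile_classes(1:100)$classes)
  expect_true(all(counts == 20))
  # grid classified at edges from station values, not grid values
  pc2 <- percentile_classes(matrix(c(0, 100), 1), sample_values = 1:10)
  expect_equal(unname(pc2$edges), c(2.8, 4.6, 6.4, 8.2))
  expect_equal(unname(pc2$classes[1, ]), c(0, 4))
})

test_that("ASCII raster export writes a parseable grid", {
  surf <- idw_interpolate(rbind(c(0, 0), c(90, 90)), c(1, 9),
                          bbox = c(0, 100, 0, 100), cell = 50)
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(surf, path)
  lines <- readLines(path)
  expect_match(lines[1], "^ncols 2$")
  expect_match(lines[2], "^nrows 2$")
  body <- do.call(rbind, lapply(lines[8:9], function(l) {
    as.numeric(strsplit(l, " ")[[1]])
  }))
  # last line = southern row; values serialized at 7 significant digits
  expect_equal(body[2, ], surf$values[1, ], tolerance = 1e-6)
})

test_that("crown profiles recover an exact exponential decay", {
  # sites exactly at ring midpoints east of the source, one per ring
  a <- 10; b <- 0.5
  d_km <- c(0.5, 1.5, 2.5, 3.5, 4.5)
  xy <- cbind(d_km * 1000, 0)
  fe <- a * exp(-b * d_km) * 1000 # mg/kg scale
  conc <- cbind(Al = rep(300, 5), Fe = fe)
  s <- make_survey(conc, bg = c(Al = 300, Fe = 500), xy = xy)
  center_ll <- xy_to_lonlat(matrix(c(0, 0), 1))
  cp <- crown_profile(s, "Fe", unname(center_ll[1, ]))
  expect_equal(cp$ring_n, rep(1, 5))
  expect_equal(cp$fit_b, b, tolerance = 1e-9)
  expect_equal(cp$fit_a, a * 1000, tolerance = 1e-6)
  expect_equal(cp$r2, 1, tolerance = 1e-9)

  # all sites in one ring: means reported, no fit
  xy1 <- cbind(c(400, 500, 600), 0)
  s1 <- make_survey(cbind(Al = rep(300, 3), Fe = c(4, 5, 6) * 1000),
                    bg = c(Al = 300, Fe = 500), xy = xy1)
  expect_warning(cp1 <- crown_profile(s1, "Fe", unname(center_ll[1, ])),
                 "empty ring")
  expect_true(is.na(cp1$fit_b))
  expect_equal(cp1$ring_mean[1], 5000)
})

test_that("quadrant labels partition and rotate cyclically; H matches ranks", {
  # 9 sites, 3 in each of NE, SE, SW
  xy <- rbind(c(100, 200), c(300, 400), c(200, 100),    # NE
              c(100, -200), c(300, -100), c(200, -300), # SE
              c(-100, -200), c(-300, -100), c(-200, -300)) # SW
  v <- c(1, 2, 3, 10, 11, 12, 5, 6, 7) * 100
  conc <- cbind(Al = rep(300, 9), Fe = v)
  s <- make_survey(conc, bg = c(Al = 300, Fe = 500), xy = xy)
  center <- unname(xy_to_lonlat(matrix(c(0, 0), 1))[1, ])
  qs <- quadrant_compare(s, "Fe", center)
  expect_equal(unname(qs$labels),
               c("NE", "NE", "NE", "SE", "SE", "SE", "SW", "SW", "SW"))
  # brute-force Kruskal-Wallis H from rank sums (no ties)
  r <- rank(v)
  groups <- split(r, qs$labels)
  H <- 12 / (9 * 10) * sum(vapply(groups, function(g) {
    length(g) * mean(g)^2
  }, numeric(1))) - 3 * 10
  expect_equal(qs$H, H)
  expect_equal(nrow(qs$pairwise), 3)

  # rotating all sites +90 degrees about the center shifts each label
  xy_rot <- cbind(xy[, 2], -xy[, 1])
  s_rot <- make_survey(conc, bg = c(Al = 300, Fe = 500), xy = xy_rot)
  q_rot <- quadrant_compare(s_rot, "Fe", center)
  cyc <- c(NE = "SE", SE = "SW", SW = "NW", NW = "NE")
  expect_equal(unname(q_rot$labels), unname(cyc[qs$labels]))

  # degenerate geometry rejected
  xy_one <- cbind(abs(xy[, 1]), abs(xy[, 2]))
  s_one <- make_survey(conc, bg = c(Al = 300, Fe = 500), xy = xy_one)
  expect_error(quadrant_compare(s_one, "Fe", center), "quadrant")
})
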