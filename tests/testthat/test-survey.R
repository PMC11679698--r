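test_that("survey CSV round trip preserves values and censoring mask", {
  conc <- rand_conc(5, c("Al", "Fe", "Cr", "Pb"), seed = 3)
  cens <- matrix(FALSE, 5, 4, dimnames = list(NULL, colnames(conc)))
  cens[2, "Cr"] <- TRUE
  cens[c(1, 4), "Pb"] <- TRUE
  conc[cens] <- NA
  s <- make_survey(conc, bg = c(Al = 300, Fe = 800, Cr = 9, Pb = 6),
                   censored = cens, detection_limits = c(Cr = 2, Pb = 1.6))
  path <- tempfile(fileext = ".csv")
  write_survey(s, path)
  s2 <- read_survey(path, detection_limits = c(Cr = 2, Pb = 1.6))
  expect_identical(unname(s2$censored), unname(s$censored))
  keep <- !s$censored
  expect_equal(s2$concentrations[keep], s$concentrations[keep],
               tolerance = 1e-6)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$units, "mg/kg dry weight")
})

test_that("below-DL encodings and malformed files are handled", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("site_id,lon,lat,role,Al,Cr",
               "A,-9.1,38.6,exposure,300,<DL",
               "B,-9.11,38.61,exposure,310,5",
               "C,-9.12,38.62,exposure,305,",
               "BG,-9.2,38.5,background,290,4"), tmp)
  s <- read_survey(tmp, detection_limits = c(Cr = 2))
  expect_true(s$censored["A", "Cr"])
  expect_true(s$censored["C", "Cr"])  # empty cell = censored by default
  expect_false(s$censored["B", "Cr"])
  expect_false(any(s$censored[, "Al"]))
  expect_error(read_survey(tmp, detection_limits = c(Cr = 2), strict = TRUE),
               "empty")

  # missing background row
  writeLines(c("site_id,lon,lat,role,Al",
               "A,-9.1,38.6,exposure,300",
               "B,-9.11,38.61,exposure,310"), tmp)
  expect_error(read_survey(tmp), "background")

  # duplicate ids and unknown element
  writeLines(c("site_id,lon,lat,role,Al",
               "A,-9.1,38.6,exposure,300",
               "A,-9.11,38.61,background,310"), tmp)
  expect_error(read_survey(tmp), "duplicate")
  writeLines(c("site_id,lon,lat,role,Xx",
               "A,-9.1,38.6,exposure,300",
               "BG,-9.2,38.5,background,290"), tmp)
  expect_error(read_survey(tmp), "unknown element")
})

test_that("DL/2 imputation fills censored cells only and is idempotent", {
  conc <- rand_conc(4, c("Al", "Cr", "Pb"), seed = 5)
  cens <- matrix(FALSE, 4, 3, dimnames = list(NULL, colnames(conc)))
  cens[1, "Cr"] <- TRUE
  cens[c(2, 3), "Pb"] <- TRUE
  conc[cens] <- NA
  s <- make_survey(conc, bg = c(Al = 300, Cr = 9, Pb = 6), censored = cens,
                   detection_limits = c(Cr = 2.0, Pb = 1.6))
  s1 <- impute_censored(s)
  expect_equal(unname(s1$concentrations[1, "Cr"]), 1.0)
  expect_equal(unname(s1$concentrations[2, "Pb"]), 0.8)
  expect_equal(unname(s1$concentrations[3, "Pb"]), 0.8)
  keep <- !s$censored & !is.na(s$concentrations)
  expect_identical(s1$concentrations[keep], s$concentrations[keep])
  expect_identical(impute_censored(s1)$concentrations, s1$concentrations)
  # input not modified
  expect_true(anyNA(s$concentrations))
  # censored cell without a DL errors with the element named
  s_bad <- make_survey(conc, bg = c(Al = 300, Cr = 9, Pb = 6),
                       censored = cens, detection_limits = c(Cr = 2.0))
  expect_error(impute_censored(s_bad), "Pb")
})

test_that("summaries count uncensored cells and respect concatenation", {
  conc <- rand_conc(6, c("Al", "Cr"), seed = 7)
  cens <- matrix(FALSE, 6, 2, dimnames = list(NULL, colnames(conc)))
  cens[c(1, 3, 5), "Cr"] <- TRUE
  conc[cens] <- NA
  s <- impute_censored(make_survey(conc, bg = c(Al = 300, Cr = 9),
                                   censored = cens,
                                   detection_limits = c(Cr = 2)))
  tab <- summarize_survey(s)
  expect_equal(tab$n_above_dl[tab$element == "Al"], 6)
  expect_equal(tab$n_above_dl[tab$element == "Cr"], 3)

  # constant element: mean = median = min = max, sd = 0
  cc <- cbind(Al = rep(5, 4), Fe = c(1, 2, 3, 4))
  sc <- make_survey(cc, bg = c(Al = 5, Fe = 2))
  tc <- summarize_survey(sc)
  al <- tc[tc$element == "Al", ]
  expect_equal(unlist(al[c("mean", "median", "min", "max")]),
               c(mean = 5, median = 5, min = 5, max = 5))
  expect_equal(al$sd, 0)

  # doubling the exposure sites doubles n, preserves location statistics
  conc2 <- rbind(conc, conc)
  cens2 <- rbind(cens, cens)
  s2 <- impute_censored(make_survey(conc2, bg = c(Al = 300, Cr = 9),
                                    censored = cens2,
                                    detection_limits = c(Cr = 2)))
  t2 <- summarize_survey(s2)
  expect_equal(t2$n_above_dl, 2 * tab$n_above_dl)
  expect_equal(t2$mean, tab$mean)
  expect_equal(t2$median, tab$median)
  expect_equal(t2$min, tab$min)
  expect_equal(t2$max, tab$max)
})

test_that("survey construction enforces its invariants", {
  conc <- rand_conc(3)
  expect_error(make_survey(-conc), "non-positive")
  sites <- data.frame(site_id = c("A", "B"), lon = c(0, 0), lat = c(0, 0),
                      role = c("exposure", "exposure"))
  expect_error(elemental_survey(sites, conc[1:2, ]), "background")
  sites$role <- c("background", "background")
  expect_error(elemental_survey(sites, conc[1:2, ]), "background")
  sites2 <- data.frame(site_id = "A", lon = 200, lat = 0,
                       role = "background")
  expect_error(elemental_survey(sites2, conc[1, , drop = FALSE]),
               "WGS84")
})
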