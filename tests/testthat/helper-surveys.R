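# Fixture builders used across the suite. All fixtures are constructed in
# code; coordinates are synthesized around a nominal survey origin.

FIX_LON0 <- -9.1
FIX_LAT0 <- 38.6

# planar metres -> lon/lat, independent re-derivation for fixture building
xy_to_lonlat <- function(xy) {
  R <- 6371000
  lat <- FIX_LAT0 + xy[, 2] / R * 180 / pi
  lon <- FIX_LON0 + xy[, 1] / (R * cos(FIX_LAT0 * pi / 180)) * 180 / pi
  cbind(lon = lon, lat = lat)
}

# survey from a concentration matrix; background row appended from bg
make_survey <- function(conc, bg = NULL, xy = NULL, censored = NULL,
                        detection_limits = numeric(0)) {
  conc <- as.matrix(conc)
  n <- nrow(conc)
  if (is.null(bg)) bg <- conc[1, ]
  if (is.null(xy)) {
    xy <- cbind(runif(n, 0, 4000), runif(n, 0, 6000))
  }
  full <- rbind(conc, bg)
  ll <- xy_to_lonlat(rbind(xy, c(-3000, -8000)))
  ids <- c(sprintf("S%02d", seq_len(n)), "BG")
  rownames(full) <- ids
  sites <- data.frame(site_id = ids, lon = ll[, "lon"], lat = ll[, "lat"],
                      role = c(rep("exposure", n), "background"),
                      stringsAsFactors = FALSE)
  if (!is.null(censored)) censored <- rbind(censored, FALSE)
  elemental_survey(sites, full, censored, detection_limits)
}

# small random positive concentration matrix over a subset panel
rand_conc <- function(n, elements = c("Al", "Fe", "Zn", "Pb"), seed = 1) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n * length(elements), 3, 0.5)), n,
              dimnames = list(NULL, elements))
  m
}
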