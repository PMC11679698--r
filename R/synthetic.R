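#' Default configuration for the synthetic paired survey generator
#'
#' Encodes the study design the package emulates: 49 exposure sites
#' placed in distinct cells of a 7 x 11 grid of 650 m x 620 m cells
#' (4.55 km x 6.82 km), one background site well outside the grid, a
#' 22-element panel, and four latent concentration components --
#' geogenic dust (Al, Si, K, Cl, Mg), a steelworks point source
#' (Cr, Fe, Mn, Ti) with exponential distance decay, a traffic line
#' source (Zn, Pb, Ti) along a southern corridor, and root-uptake plant
#' nutrients (P, S, Mg). Concentrations are lognormal: multiplicative
#' component contributions on a background profile, plus lognormal
#' noise. Cr and Pb carry detection limits that left-censor the low tail.
#' The paired lichen survey is the leaf survey scaled by element-specific
#' accumulation ratios with independent lognormal noise.
#'
#' @param n_sites Number of exposure sites (default 49).
#' @param seed Integer seed driving all randomness.
#' @param noise_sigma_log SD of lognormal measurement/site noise (0.2).
#' @param lichen_sigma_log SD of the extra lichen noise (0.25).
#' @return A list of class `synthetic_config`; fields may be overridden
#'   before passing to [generate_survey()].
#' @export
synthetic_config <- function(n_sites = 49, seed = 1,
                             noise_sigma_log = 0.15,
                             lichen_sigma_log = 0.25) {
  grid <- grid_spec(4550, 6820, 650, 620)
  background_profile <- c(
    K = 18000, Ca = 18200, Mg = 3320, Si = 1450, P = 940, S = 1290,
    Cl = 2650, Fe = 780, Al = 291, Mn = 132, Zn = 26, Cu = 4,
    Sr = 96, Ba = 50, As = 15, Ti = 15, Br = 29, Rb = 17, Zr = 4,
    Se = 11, Cr = 1.5, Pb = 6)
  lichen_ratio <- c(
    K = 0.32, Ca = 10, Mg = 0.25, Si = 2.6, P = 1, S = 1.39, Cl = 1,
    Fe = 4.88, Al = 7.46, Mn = 3.17, Zn = 12.9, Cu = 29.1, Sr = 5.23,
    Ba = 1, As = 0.43, Ti = 36.4, Br = 8.41, Rb = 3.27, Zr = 4.41,
    Se = 8.06, Cr = 5.65, Pb = 21.7)
  components <- list(
    geogenic = list(
      spatial_kind = "uniform",
      loadings = c(Al = 0.25, Si = 0.45, K = 0.25, Cl = 0.6, Mg = 0.12)),
    steelworks = list(
      spatial_kind = "point_source",
      center_frac = c(0.55, 0.62), # position as fraction of grid extent
      decay_b = 0.5,               # /km
      log_amp = log(10),           # source strength at d = 0
      intensity_sd = 0.15,         # site-level emission/exposure variability
      loadings = c(Fe = 1.0, Cr = 1.4, Mn = 0.5, Ti = 0.3)),
    traffic = list(
      spatial_kind = "line_source",
      y_frac = 0.12,               # corridor crosses the south of the grid
      width_m = 600,
      intensity_sd = 0.25,
      loadings = c(Zn = 1.2, Pb = 1.4, Ti = 0.8)),
    nutrients = list(
      spatial_kind = "uniform",
      loadings = c(P = 0.45, S = 0.3, Mg = 0.4)))
  structure(list(
    n_sites = n_sites, seed = seed, grid = grid,
    origin = c(lon = -9.105, lat = 38.586), # grid lower-left corner
    background_offset_m = c(-4000, -8000),  # background site, outside grid
    components = components,
    noise_sigma_log = noise_sigma_log,
    lichen_sigma_log = lichen_sigma_log,
    detection_limits = c(Cr = 8, Pb = 5.5),
    background_profile = background_profile,
    lichen_ratio = lichen_ratio),
    class = "synthetic_config")
}

# metres -> lon/lat about the configured origin
local_to_lonlat <- function(xy, origin) {
  lat <- origin[["lat"]] + xy[, 2] / EARTH_RADIUS_M * 180 / pi
  lat_ref <- origin[["lat"]] + 3410 / EARTH_RADIUS_M * 180 / pi # mid-grid
  lon <- origin[["lon"]] +
    xy[, 1] / (EARTH_RADIUS_M * cos(lat_ref * pi / 180)) * 180 / pi
  cbind(lon = lon, lat = lat)
}

#' Generate a synthetic paired biomonitoring survey
#'
#' Draws a paired strawberry-leaf/lichen survey from a
#' [synthetic_config()]. Exposure sites occupy distinct, uniformly
#' chosen grid cells (at cell centres). Each element's log concentration
#' is the log background profile plus the sum over latent components of
#' loading times component score plus Normal(0, sigma) noise; point
#' sources score `log_amp - decay_b * distance_km`, line sources
#' `exp(-distance_to_corridor / width)`, and uniform components are
#' standard-normal site effects. Values below an element's detection
#' limit are censored (mask set, value withheld); the uncensored truth is
#' returned for validation. The lichen survey is the leaf survey times
#' element-wise accumulation ratios with independent lognormal noise.
#'
#' @param config A [synthetic_config()].
#' @return List with `survey_a` (leaves), `survey_b` (lichens) -- both
#'   `elemental_survey` objects with censoring masks set but not yet
#'   imputed -- and `truth` (class `ground_truth`): component site
#'   scores, planted decay and source location, uncensored
#'   concentrations, per-element censored counts, planted component
#'   element groups.
#' @export
generate_survey <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  g <- config$grid
  if (config$n_sites > g$n_cells) {
    stop("n_sites exceeds grid capacity (", g$n_cells, " cells)")
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  elements <- names(config$background_profile)
  n <- config$n_sites
  cells <- sample.int(g$n_cells, n)
  ix <- (cells - 1) %% g$nx
  iy <- (cells - 1) %/% g$nx
  xy <- cbind(x = (ix + 0.5) * g$cell[1], y = (iy + 0.5) * g$cell[2])

  # component site scores
  scores <- matrix(0, n, length(config$components),
                   dimnames = list(NULL, names(config$components)))
  src_xy <- NULL
  decay_b <- NA_real_
  for (cn in names(config$components)) {
    cmp <- config$components[[cn]]
    scores[, cn] <- switch(cmp$spatial_kind,
      uniform = stats::rnorm(n),
      point_source = {
        src_xy <- c(cmp$center_frac[1] * g$extent[1],
                    cmp$center_frac[2] * g$extent[2])
        d_km <- sqrt((xy[, 1] - src_xy[1])^2 + (xy[, 2] - src_xy[2])^2) / 1000
        decay_b <- cmp$decay_b
        cmp$log_amp - cmp$decay_b * d_km +
          (cmp$intensity_sd %||% 0) * stats::rnorm(n)
      },
      line_source = {
        d_m <- abs(xy[, 2] - cmp$y_frac * g$extent[2])
        exp(-d_m / cmp$width_m) +
          (cmp$intensity_sd %||% 0) * stats::rnorm(n)
      },
      stop("unknown spatial_kind: ", cmp$spatial_kind))
  }

  # loading matrix element x component
  L <- matrix(0, length(elements), length(config$components),
              dimnames = list(elements, names(config$components)))
  for (cn in names(config$components)) {
    ld <- config$components[[cn]]$loadings
    L[names(ld), cn] <- ld
  }

  sigma <- config$noise_sigma_log
  logc <- matrix(log(config$background_profile), n, length(elements),
                 byrow = TRUE, dimnames = list(NULL, elements)) +
    scores %*% t(L) +
    matrix(stats::rnorm(n * length(elements), 0, sigma), n)
  conc_a <- exp(logc)

  # background site: profile with its own noise, no component signal
  bg_a <- config$background_profile *
    exp(stats::rnorm(length(elements), 0, sigma))

  # lichen survey: element-wise ratio plus independent noise
  ratio <- config$lichen_ratio[elements]
  sig_b <- config$lichen_sigma_log
  conc_b <- sweep(conc_a, 2, ratio, "*") *
    exp(matrix(stats::rnorm(n * length(elements), 0, sig_b), n))
  bg_b <- bg_a * ratio * exp(stats::rnorm(length(elements), 0, sig_b))

  site_ids <- sprintf("S%02d", seq_len(n))
  ll <- local_to_lonlat(xy, config$origin)
  bg_ll <- local_to_lonlat(
    matrix(config$background_offset_m, 1), config$origin)
  sites <- data.frame(
    site_id = c(site_ids, "BG"),
    lon = c(ll[, "lon"], bg_ll[, "lon"]),
    lat = c(ll[, "lat"], bg_ll[, "lat"]),
    role = c(rep("exposure", n), "background"),
    stringsAsFactors = FALSE)

  mk_survey <- function(conc, bg, label) {
    full <- rbind(conc, bg)
    rownames(full) <- sites$site_id
    cens <- censor_mask(full, config$detection_limits)
    shown <- full
    shown[cens] <- NA_real_
    elemental_survey(sites, shown, cens, config$detection_limits,
                     biomonitor_label = label)
  }
  survey_a <- mk_survey(conc_a, bg_a, "strawberry_leaf")
  survey_b <- mk_survey(conc_b, bg_b, "lichen")

  groups <- lapply(config$components, function(cmp) names(cmp$loadings))
  shared <- names(which(table(unlist(groups)) > 1))
  core_groups <- lapply(groups, setdiff, y = shared)
  structured <- elements[elements %in% unlist(groups)]

  truth <- structure(list(
    component_site_scores = scores,
    site_xy_m = xy,
    decay_b = decay_b,
    source_xy_m = src_xy,
    source_lonlat = if (!is.null(src_xy)) {
      drop(local_to_lonlat(matrix(src_xy, 1), config$origin))
    },
    concentrations_a = rbind(conc_a, BG = bg_a),
    concentrations_b = rbind(conc_b, BG = bg_b),
    censored_count_a = colSums(survey_a$censored),
    censored_count_b = colSums(survey_b$censored),
    component_elements = groups,
    component_core_elements = core_groups,
    structured_elements = structured,
    lichen_ratio = ratio,
    seed = config$seed), class = "ground_truth")

  list(survey_a = survey_a, survey_b = survey_b, truth = truth)
}

# mask of cells below their element's detection limit
censor_mask <- function(conc, dl_table) {
  cens <- matrix(FALSE, nrow(conc), ncol(conc), dimnames = dimnames(conc))
  for (e in intersect(names(dl_table), colnames(conc))) {
    cens[, e] <- conc[, e] < dl_table[[e]]
  }
  cens
}

#' Apply detection-limit censoring to a survey
#'
#' Masks every cell whose concentration is below the element's detection
#' limit. Values are withheld (NA) in the returned survey;
#' [impute_censored()] substitutes DL/2.
#'
#' @param survey An `elemental_survey` with observed values.
#' @param dl_table Named numeric vector of positive detection limits.
#' @return The survey with the censoring mask extended and censored
#'   values removed.
#' @export
apply_censoring <- function(survey, dl_table) {
  if (any(dl_table < 0)) stop("detection limits must be non-negative")
  newmask <- censor_mask(survey$concentrations, dl_table)
  newmask[is.na(survey$concentrations)] <- FALSE
  survey$censored <- survey$censored | newmask
  survey$concentrations[survey$censored] <- NA_real_
  dl <- survey$detection_limits
  dl[names(dl_table)] <- dl_table
  survey$detection_limits <- dl
  survey$imputed <- FALSE
  survey
}
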