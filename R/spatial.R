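EARTH_RADIUS_M <- 6371000

#' Project WGS84 coordinates to a local metric plane
#'
#' Equirectangular projection about the mean latitude:
#' x = R * dlon * cos(mean lat), y = R * dlat (radians,
#' R = 6,371,000 m). Adequate for survey extents of a few tens of km;
#' distances thereafter are Euclidean.
#'
#' @param sites Data frame with `lon`, `lat` (decimal degrees), or an
#'   `elemental_survey` (all sites projected).
#' @return Matrix with columns `x`, `y` in metres, rownames = site ids
#'   when available.
#' @export
project_local <- function(sites) {
  if (inherits(sites, "elemental_survey")) sites <- sites$sites
  lon <- sites$lon * pi / 180
  lat <- sites$lat * pi / 180
  lat0 <- mean(lat)
  x <- EARTH_RADIUS_M * (lon - mean(lon)) * cos(lat0)
  y <- EARTH_RADIUS_M * (lat - lat0)
  if (max(dist(cbind(x, y))) > 100000) {
    warning("extent exceeds 100 km; equirectangular approximation degrades")
  }
  out <- cbind(x = x, y = y)
  rownames(out) <- if (!is.null(sites$site_id)) sites$site_id
  out
}

#' Inverse distance weighted interpolation
#'
#' Every grid cell takes the weighted mean of ALL sample values with
#' weights d^-k (global IDW, no neighbourhood truncation). A cell lying
#' within `eps` metres of a sample takes that sample's value exactly.
#' The surface is a convex combination of the samples, hence bounded by
#' their range. Quintile classes are cut at the 20/40/60/80th percentiles
#' of the sample values.
#'
#' @param xy Sample coordinates, matrix with columns `x`, `y` (metres).
#' @param values Sample values (finite).
#' @param bbox Extent `c(xmin, xmax, ymin, ymax)`; default the sample
#'   bounding box.
#' @param cell Cell size in metres, length-1 or `c(dx, dy)`. Default 65.
#' @param k Power exponent (default 2).
#' @param eps Snap distance to a sample, metres (default 1e-6).
#' @return Object of class `idw_surface`: list with `values` (ny x nx
#'   matrix, row 1 = southernmost), `xs`, `ys` (cell-centre coordinates),
#'   `classes` (quintile indices 0-4), `class_edges`, `k`, `S`, `bbox`,
#'   `cell`.
#' @export
idw_interpolate <- function(xy, values, bbox = NULL, cell = 65, k = 2,
                            eps = 1e-6) {
  xy <- as.matrix(xy)
  values <- as.numeric(values)
  if (length(values) < 1) stop("no samples")
  if (any(!is.finite(values))) stop("samples must be finite")
  stopifnot(nrow(xy) == length(values))
  if (length(cell) == 1) cell <- c(cell, cell)
  if (is.null(bbox)) {
    bbox <- c(min(xy[, 1]), max(xy[, 1]), min(xy[, 2]), max(xy[, 2]))
  }
  xs <- seq(bbox[1] + cell[1] / 2, bbox[2], by = cell[1])
  ys <- seq(bbox[3] + cell[2] / 2, bbox[4], by = cell[2])
  if (!length(xs)) xs <- mean(bbox[1:2])
  if (!length(ys)) ys <- mean(bbox[3:4])
  grid <- matrix(NA_real_, length(ys), length(xs))
  for (iy in seq_along(ys)) {
    dx <- outer(xs, xy[, 1], "-")
    dy <- ys[iy] - xy[, 2]
    d <- sqrt(sweep(dx^2, 2, dy^2, "+"))
    w <- d^(-k)
    hit <- d < eps
    v <- as.vector((w %*% values) / rowSums(w))
    if (any(hit)) {
      for (r in which(rowSums(hit) > 0)) v[r] <- values[which(hit[r, ])[1]]
    }
    grid[iy, ] <- v
  }
  if (length(values) >= 5) {
    pc <- percentile_classes(grid, sample_values = values)
  } else {
    pc <- list(classes = NULL, edges = NULL) # too few samples for quintiles
  }
  structure(list(values = grid, xs = xs, ys = ys,
                 classes = pc$classes, class_edges = pc$edges,
                 k = k, S = length(values), bbox = bbox, cell = cell),
            class = "idw_surface")
}

#' Quintile classes at sample-derived percentile edges
#'
#' Classifies values into the five classes bounded by the 20/40/60/80th
#' percentiles (linear-interpolation quantile convention; intervals
#' right-closed). By default edges come from the values themselves; for
#' an interpolated surface pass the measured station values as
#' `sample_values` so the class edges reflect the measurements, not the
#' smoothing.
#'
#' @param values Numeric vector, matrix or grid to classify.
#' @param sample_values Values from which the percentile edges are
#'   computed (default `values`).
#' @return List with `classes` (integer 0-4, same shape as `values`) and
#'   `edges` (the four cut points).
#' @export
percentile_classes <- function(values, sample_values = values) {
  sv <- as.numeric(sample_values)
  sv <- sv[is.finite(sv)]
  if (length(sv) < 5) stop("need at least 5 finite values for quintiles")
  edges <- stats::quantile(sv, probs = c(0.2, 0.4, 0.6, 0.8),
                           type = 7, names = FALSE)
  if (length(unique(sv)) < 5 || any(diff(edges) == 0)) {
    warning("fewer than 5 distinct values; degenerate class edges")
  }
  cls <- findInterval(values, edges, left.open = TRUE) # right-closed bins
  cls[!is.finite(values)] <- NA_integer_
  if (is.matrix(values)) cls <- matrix(cls, nrow(values), ncol(values))
  list(classes = cls, edges = edges)
}

#' Write an IDW surface as an ESRI ASCII raster
#'
#' @param surface An `idw_surface`.
#' @param path Output `.asc` path.
#' @param what `"values"` or `"classes"`.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(surface, path, what = c("values", "classes")) {
  what <- match.arg(what)
  g <- surface[[what]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(g)),
    paste("nrows", nrow(g)),
    paste("xllcorner", surface$bbox[1]),
    paste("yllcorner", surface$bbox[3]),
    paste("dx", surface$cell[1]),
    paste("dy", surface$cell[2]),
    "NODATA_value -9999"), con)
  # ASCII rasters list rows north to south
  for (iy in rev(seq_len(nrow(g)))) {
    row <- g[iy, ]
    row[!is.finite(row)] <- -9999
    writeLines(paste(format(row, trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}

#' Concentric-crown distance profile with exponential decay fit
#'
#' Sites are grouped into annuli around a putative point source; ring
#' means of an element's concentration are fitted by log-linear least
#' squares to c = a * exp(-b * d) with d the ring midpoint distance (km).
#' r^2 is reported on the fitted (log) scale. Empty rings are skipped
#' with a warning; with fewer than 2 non-empty rings the profile reports
#' means only and no fit.
#'
#' @param survey An imputed `elemental_survey`.
#' @param element Element symbol.
#' @param center `c(lon, lat)` of the source, or a site id present in the
#'   survey.
#' @param ring_edges Outer ring radii in km (default `1:5`); rings are
#'   `(edge[i-1], edge[i]]` with the first ring starting at 0.
#' @param ring_distance Abscissa used in the fit: `"midpoint"` (default,
#'   the geometric ring midpoint) or `"mean"` (mean distance of the
#'   sites actually in the ring, which removes the flattening bias when
#'   the survey extent truncates the outer rings).
#' @return Object of class `crown_profile`: list with `ring_edges`,
#'   `ring_mid`, `ring_dist`, `ring_mean`, `ring_n`, `fit_a`, `fit_b`,
#'   `r2`, `element`.
#' @export
crown_profile <- function(survey, element, center, ring_edges = 1:5,
                          ring_distance = c("midpoint", "mean")) {
  ring_distance <- match.arg(ring_distance)
  stopifnot(element %in% colnames(survey$concentrations))
  keep <- survey$sites$role == "exposure"
  xy <- project_local(survey)[keep, , drop = FALSE]
  cxy <- resolve_center(survey, center)
  d_km <- sqrt((xy[, 1] - cxy[1])^2 + (xy[, 2] - cxy[2])^2) / 1000
  v <- exposure_matrix(survey)[, element]
  if (anyNA(v)) stop("unimputed censored cells; run impute_censored() first")
  edges <- sort(ring_edges)
  lower <- c(0, edges[-length(edges)])
  # right-closed rings: (lower, edge]
  ring <- rep(NA_integer_, length(d_km))
  for (i in seq_along(edges)) {
    ring[d_km > lower[i] & d_km <= edges[i]] <- i
  }
  mids <- (lower + edges) / 2
  ring_mean <- vapply(seq_along(edges),
                      function(i) mean(v[which(ring == i)]), numeric(1))
  ring_n <- vapply(seq_along(edges),
                   function(i) sum(ring == i, na.rm = TRUE), numeric(1))
  ring_d <- if (ring_distance == "mean") {
    vapply(seq_along(edges),
           function(i) mean(d_km[which(ring == i)]), numeric(1))
  } else {
    mids
  }
  empty <- ring_n == 0
  if (any(empty)) {
    warning("empty ring(s) skipped: ",
            paste(edges[empty], collapse = ", "), " km")
  }
  use <- !empty
  fit_a <- fit_b <- r2 <- NA_real_
  if (sum(use) >= 2) {
    if (any(ring_mean[use] <= 0)) stop("non-positive ring mean")
    yy <- log(ring_mean[use])
    fit <- stats::lm(yy ~ ring_d[use])
    fit_a <- exp(unname(stats::coef(fit)[1]))
    fit_b <- -unname(stats::coef(fit)[2])
    sst <- sum((yy - mean(yy))^2)
    r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  }
  structure(list(ring_edges = edges, ring_mid = mids, ring_dist = ring_d,
                 ring_mean = ring_mean, ring_n = ring_n,
                 fit_a = fit_a, fit_b = fit_b, r2 = r2,
                 element = element, center = cxy),
            class = "crown_profile")
}

resolve_center <- function(survey, center) {
  xy_all <- project_local(survey)
  if (is.character(center)) {
    if (!center %in% survey$sites$site_id) {
      stop("center site id not found: ", center)
    }
    xy_all[center, ]
  } else {
    # lon/lat pair: project with the same reference as the survey sites
    lon0 <- mean(survey$sites$lon) * pi / 180
    lat0 <- mean(survey$sites$lat) * pi / 180
    c(EARTH_RADIUS_M * (center[1] * pi / 180 - lon0) * cos(lat0),
      EARTH_RADIUS_M * (center[2] * pi / 180 - lat0))
  }
}

#' Quadrant comparison of concentrations around a point source
#'
#' Labels exposure sites by compass quadrant of their bearing from the
#' center (NE = [0, 90) degrees, SE = [90, 180), SW = [180, 270),
#' NW = [270, 360)) and compares the element's concentrations across
#' quadrants with a Kruskal-Wallis test (tie-corrected), followed by
#' pairwise Wilcoxon rank-sum follow-ups (unadjusted by default).
#'
#' @param survey An imputed `elemental_survey`.
#' @param element Element symbol.
#' @param center `c(lon, lat)` or a site id.
#' @param p_adjust `"none"` (default) or `"bonferroni"` for the pairwise
#'   follow-ups.
#' @return Object of class `quadrant_split`: list with `labels` (named by
#'   site), `H`, `df`, `p`, `pairwise` (data frame `group1, group2, p`),
#'   `element`.
#' @export
quadrant_compare <- function(survey, element, center,
                             p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(element %in% colnames(survey$concentrations))
  keep <- survey$sites$role == "exposure"
  xy <- project_local(survey)[keep, , drop = FALSE]
  cxy <- resolve_center(survey, center)
  dx <- xy[, 1] - cxy[1]
  dy <- xy[, 2] - cxy[2]
  bearing <- (atan2(dx, dy) * 180 / pi) %% 360 # 0 = N, 90 = E
  quad <- c("NE", "SE", "SW", "NW")[findInterval(bearing, c(0, 90, 180, 270))]
  names(quad) <- rownames(xy)
  v <- exposure_matrix(survey)[, element]
  tab <- table(quad)
  if (length(tab) < 2 || sum(tab >= 2) < 2) {
    stop("need at least 2 quadrants with at least 2 sites")
  }
  kw <- stats::kruskal.test(v, factor(quad))
  qs <- names(tab)
  pw <- do.call(rbind, lapply(utils::combn(qs, 2, simplify = FALSE),
    function(pr) {
      p <- suppressWarnings(
        stats::wilcox.test(v[quad == pr[1]], v[quad == pr[2]])$p.value)
      data.frame(group1 = pr[1], group2 = pr[2], p = p,
                 stringsAsFactors = FALSE)
    }))
  if (p_adjust == "bonferroni") pw$p <- pmin(1, pw$p * nrow(pw))
  structure(list(labels = quad, H = unname(kw$statistic),
                 df = unname(kw$parameter), p = kw$p.value,
                 pairwise = pw, element = element),
            class = "quadrant_split")
}
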