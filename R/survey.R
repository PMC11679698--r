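#' Default 22-element analyte panel
#'
#' The standard panel of a leaf/lichen XRF biomonitoring survey: six macro
#' elements, six micro elements and ten trace elements, each reported in
#' mg per kg dry weight.
#'
#' @return A data frame with columns `element` and `category`
#'   (`"macro"`, `"micro"` or `"trace"`).
#' @export
#' @examples
#' nrow(default_panel())  # 22
default_panel <- function() {
  data.frame(
    element = c("K", "Ca", "Mg", "Si", "P", "S",
                "Cl", "Fe", "Al", "Mn", "Zn", "Cu",
                "Sr", "Ba", "As", "Ti", "Br", "Rb", "Zr", "Se", "Cr", "Pb"),
    category = rep(c("macro", "micro", "trace"), times = c(6, 6, 10)),
    stringsAsFactors = FALSE
  )
}

#' Upper-continental-crust reference composition
#'
#' Average upper-continental-crust abundances (Rudnick & Gao 2003
#' compilation; oxide weight percentages converted to elemental mg/kg),
#' used as the denominator of enrichment factors.
#'
#' @param normalizing_element Reference element for crustal double ratios,
#'   by convention a purely geogenic element. Default `"Al"`.
#' @param path Optional path to a CSV with columns `element, mg_per_kg` to
#'   use instead of the packaged table.
#' @param provenance_label Free-text label recorded in outputs.
#' @return An object of class `crustal_reference`: a list with `abundances`
#'   (named numeric, mg/kg), `normalizing_element`, `provenance_label`.
#' @export
crustal_reference <- function(normalizing_element = "Al", path = NULL,
                              provenance_label = "UCC (Rudnick & Gao 2003)") {
  if (is.null(path)) {
    path <- system.file("extdata", "ucc_composition.csv", package = "metalmon")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  ab <- stats::setNames(as.numeric(tab$mg_per_kg), tab$element)
  if (any(!is.finite(ab)) || any(ab <= 0)) {
    stop("crustal abundances must be positive and finite")
  }
  if (!normalizing_element %in% names(ab)) {
    stop("normalizing element '", normalizing_element,
         "' absent from crustal reference")
  }
  structure(list(abundances = ab,
                 normalizing_element = normalizing_element,
                 provenance_label = provenance_label),
            class = "crustal_reference")
}

#' Construct an elemental biomonitoring survey
#'
#' Bundles site metadata, a site-by-element concentration matrix
#' (mg/kg dry weight), a left-censoring mask and per-element detection
#' limits into a validated survey object. Exactly one site must carry the
#' `background` role; it anchors accumulation factors and background tests
#' and is excluded from descriptive and multivariate statistics.
#'
#' @param sites Data frame with columns `site_id`, `lon`, `lat`, `role`
#'   (one of `"exposure"`, `"background"`, `"source"`, `"control"`).
#' @param concentrations Numeric matrix, one row per site (rownames =
#'   `site_id`), one column per element, mg/kg dry weight.
#' @param censored Logical matrix of the same shape; `TRUE` marks a value
#'   below the detection limit. Default: nothing censored.
#' @param detection_limits Named numeric vector of per-element detection
#'   limits (mg/kg) for elements that can be censored.
#' @param panel Analyte panel data frame as from [default_panel()]; columns
#'   of `concentrations` must be a subset of it.
#' @param biomonitor_label Label such as `"strawberry_leaf"` or `"lichen"`.
#' @return An object of class `elemental_survey`.
#' @export
elemental_survey <- function(sites, concentrations, censored = NULL,
                             detection_limits = numeric(0),
                             panel = default_panel(),
                             biomonitor_label = "strawberry_leaf") {
  stopifnot(is.data.frame(sites))
  need <- c("site_id", "lon", "lat", "role")
  if (!all(need %in% names(sites))) {
    stop("sites must have columns: ", paste(need, collapse = ", "))
  }
  sites$site_id <- as.character(sites$site_id)
  if (anyDuplicated(sites$site_id)) stop("duplicate site ids")
  ok_role <- c("exposure", "background", "source", "control")
  if (!all(sites$role %in% ok_role)) {
    stop("role must be one of: ", paste(ok_role, collapse = ", "))
  }
  if (sum(sites$role == "background") != 1) {
    stop("no background site (exactly one site must have role 'background')")
  }
  if (any(sites$lon < -180 | sites$lon > 180) ||
      any(sites$lat < -90 | sites$lat > 90)) {
    stop("coordinates outside WGS84 bounds")
  }
  concentrations <- as.matrix(concentrations)
  storage.mode(concentrations) <- "double"
  if (nrow(concentrations) != nrow(sites)) {
    stop("concentration rows do not match sites")
  }
  rownames(concentrations) <- sites$site_id
  elems <- colnames(concentrations)
  if (is.null(elems)) stop("concentration matrix must have element colnames")
  unknown <- setdiff(elems, panel$element)
  if (length(unknown)) {
    stop("unknown element column: ", paste(unknown, collapse = ", "))
  }
  if (is.null(censored)) {
    censored <- matrix(FALSE, nrow(concentrations), ncol(concentrations),
                       dimnames = dimnames(concentrations))
  }
  censored <- as.matrix(censored)
  stopifnot(identical(dim(censored), dim(concentrations)))
  dimnames(censored) <- dimnames(concentrations)
  bad <- !censored & (!is.finite(concentrations) | concentrations <= 0)
  if (any(bad)) {
    stop("non-positive or missing concentration at uncensored cells: ",
         paste(utils::head(colnames(concentrations)[col(bad)[bad]]),
               collapse = ", "))
  }
  structure(list(sites = sites,
                 panel = panel[panel$element %in% elems, , drop = FALSE],
                 concentrations = concentrations,
                 censored = censored,
                 detection_limits = detection_limits,
                 biomonitor_label = biomonitor_label,
                 imputed = FALSE),
            class = "elemental_survey")
}

#' @export
print.elemental_survey <- function(x, ...) {
  cat("<elemental_survey> ", x$biomonitor_label, "\n",
      "  sites: ", nrow(x$sites), " (", sum(x$sites$role == "exposure"),
      " exposure + 1 background)\n",
      "  elements: ", ncol(x$concentrations), "\n",
      "  censored cells: ", sum(x$censored),
      if (x$imputed) " (imputed at DL/2)" else "", "\n", sep = "")
  invisible(x)
}

#' Exposure-site concentration matrix
#'
#' @param survey An `elemental_survey`.
#' @return The concentration matrix restricted to `role == "exposure"` sites.
#' @export
exposure_matrix <- function(survey) {
  survey$concentrations[survey$sites$role == "exposure", , drop = FALSE]
}

#' Background-site concentration vector
#' @param survey An `elemental_survey`.
#' @return Named numeric vector of the single background site.
#' @export
background_vector <- function(survey) {
  m <- survey$concentrations[survey$sites$role == "background", ,
                             drop = FALSE]
  stats::setNames(as.vector(m), colnames(m))
}

#' Read a survey from CSV
#'
#' Expects a header `site_id, lon, lat, role` followed by one column per
#' element. Cells below the detection limit may be encoded as `"<DL"`
#' (case-insensitive, optionally `"<2"` style with the limit) or left
#' empty; in `strict` mode empty cells are an error instead.
#'
#' @param path CSV file path.
#' @param detection_limits Named numeric vector of DLs (mg/kg).
#' @param panel Analyte panel; unknown element columns are rejected.
#' @param biomonitor_label Stored on the returned survey.
#' @param strict If `TRUE`, empty concentration cells raise an error rather
#'   than being read as censored.
#' @return An `elemental_survey` with the censoring mask set; censored
#'   cells hold `NA` until [impute_censored()] is applied.
#' @export
read_survey <- function(path, detection_limits = numeric(0),
                        panel = default_panel(),
                        biomonitor_label = "strawberry_leaf",
                        strict = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  need <- c("site_id", "lon", "lat", "role")
  if (!all(need %in% names(raw))) {
    stop("survey file must have columns: ", paste(need, collapse = ", "))
  }
  elems <- setdiff(names(raw), need)
  unknown <- setdiff(elems, panel$element)
  if (length(unknown)) {
    stop("unknown element column: ", paste(unknown, collapse = ", "))
  }
  sites <- data.frame(site_id = raw$site_id,
                      lon = as.numeric(raw$lon),
                      lat = as.numeric(raw$lat),
                      role = raw$role, stringsAsFactors = FALSE)
  conc <- matrix(NA_real_, nrow(raw), length(elems),
                 dimnames = list(raw$site_id, elems))
  cens <- matrix(FALSE, nrow(raw), length(elems),
                 dimnames = list(raw$site_id, elems))
  for (e in elems) {
    cell <- trimws(raw[[e]])
    below <- grepl("^<", cell)
    empty <- !nzchar(cell)
    if (strict && any(empty)) {
      stop("empty concentration cell for element ", e, " (strict mode)")
    }
    cens[, e] <- below | empty
    conc[, e] <- suppressWarnings(as.numeric(cell))
    conc[cens[, e], e] <- NA_real_
  }
  elemental_survey(sites, conc, cens, detection_limits, panel,
                   biomonitor_label)
}

#' Write a survey to CSV with a JSON metadata sidecar
#'
#' Censored cells are written as `"<DL"`. A sidecar `<path>.json` records
#' units, detection limits, the imputation rule and labels.
#'
#' @param survey An `elemental_survey`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  conc <- survey$concentrations
  out <- cbind(survey$sites,
               as.data.frame(matrix(format(conc, digits = 7, trim = TRUE),
                                    nrow(conc), ncol(conc),
                                    dimnames = dimnames(conc)),
                             stringsAsFactors = FALSE))
  for (e in colnames(conc)) out[[e]][survey$censored[, e]] <- "<DL"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- list(units = "mg/kg dry weight",
               biomonitor = survey$biomonitor_label,
               detection_limits = as.list(survey$detection_limits),
               imputation = if (survey$imputed) "DL/2" else "none",
               n_sites = nrow(survey$sites))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Substitute censored values by half the detection limit
#'
#' Left-censored (below-DL) concentrations are replaced by DL/2, the
#' conventional substitution for mapping and ratio statistics. Uncensored
#' cells are untouched; the operation is idempotent and returns a new
#' survey.
#'
#' @param survey An `elemental_survey`.
#' @return A new `elemental_survey` with every censored cell equal to DL/2.
#' @export
impute_censored <- function(survey) {
  cens_elem <- colnames(survey$censored)[colSums(survey$censored) > 0]
  missing_dl <- setdiff(cens_elem, names(survey$detection_limits))
  if (length(missing_dl)) {
    stop("censored cells but no detection limit for element: ",
         paste(missing_dl, collapse = ", "))
  }
  for (e in cens_elem) {
    survey$concentrations[survey$censored[, e], e] <-
      survey$detection_limits[[e]] / 2
  }
  survey$imputed <- TRUE
  survey
}

#' Per-element descriptive statistics over exposure sites
#'
#' Mirrors the descriptive table of a biomonitoring report: `n_above_dl`
#' counts uncensored exposure-site values; mean, sd, median, min and max
#' are computed over uncensored exposure-site values only, so that
#' detection-limit substitution does not distort location statistics. The
#' background site is excluded throughout.
#'
#' @param survey An `elemental_survey`.
#' @return Data frame with one row per element: `element, n_above_dl,
#'   mean, sd, median, min, max`.
#' @export
summarize_survey <- function(survey) {
  keep <- survey$sites$role == "exposure"
  if (!any(keep)) stop("survey has no exposure sites")
  conc <- survey$concentrations[keep, , drop = FALSE]
  cens <- survey$censored[keep, , drop = FALSE]
  rows <- lapply(colnames(conc), function(e) {
    v <- conc[!cens[, e], e]
    v <- v[is.finite(v)]
    data.frame(element = e, n_above_dl = length(v),
               mean = mean(v), sd = stats::sd(v),
               median = stats::median(v), min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sampling-grid geometry
#'
#' Number and layout of whole cells in a rectangular sampling grid.
#'
#' @param width_m,height_m Grid extent in metres.
#' @param cell_w_m,cell_h_m Cell dimensions in metres.
#' @return List with `nx`, `ny` (whole cells per side) and `n_cells`.
#' @export
#' @examples
#' grid_spec(4550, 6820, 650, 620)$n_cells  # 77
grid_spec <- function(width_m, height_m, cell_w_m, cell_h_m) {
  stopifnot(width_m > 0, height_m > 0, cell_w_m > 0, cell_h_m > 0)
  nx <- floor(width_m / cell_w_m)
  ny <- floor(height_m / cell_h_m)
  list(nx = nx, ny = ny, n_cells = nx * ny,
       cell = c(cell_w_m, cell_h_m), extent = c(width_m, height_m))
}

#' Sample retrieval rate
#'
#' @param n_retrieved Samples recovered at the end of exposure.
#' @param n_deployed Samples deployed.
#' @return Percentage retrieved.
#' @export
retrieval_rate <- function(n_retrieved, n_deployed) {
  stopifnot(n_deployed > 0, n_retrieved >= 0, n_retrieved <= n_deployed)
  100 * n_retrieved / n_deployed
}

#' Exposure duration in days
#'
#' Counts both the deployment and the collection day, the convention used
#' when reporting biomonitor exposure periods.
#'
#' @param start,end Dates (or strings coercible via [as.Date()]).
#' @return Integer number of days, endpoints inclusive.
#' @export
#' @examples
#' exposure_days("2020-02-01", "2020-06-17")  # 138
exposure_days <- function(start, end) {
  d <- as.integer(as.Date(end) - as.Date(start)) + 1L
  if (d <= 0) stop("end date precedes start date")
  d
}

#' Published reference rotated loadings
#'
#' Packaged varimax-rotated loading tables and per-component explained
#' variance percentages from a published strawberry-leaf/lichen survey of
#' the study design this package emulates, for bookkeeping checks and as
#' plausible planted structure.
#'
#' @param biomonitor `"strawberry_leaf"` or `"lichen"`.
#' @return List with `loadings` (element x component matrix),
#'   `published_communality` (named numeric) and `pct_variance`
#'   (named numeric per component).
#' @export
reference_loadings <- function(biomonitor = c("strawberry_leaf", "lichen")) {
  biomonitor <- match.arg(biomonitor)
  file <- if (biomonitor == "strawberry_leaf") {
    "reference_loadings_leaves.csv"
  } else {
    "reference_loadings_lichens.csv"
  }
  tab <- utils::read.csv(system.file("extdata", file, package = "metalmon"),
                         stringsAsFactors = FALSE)
  pcs <- grep("^PC", names(tab), value = TRUE)
  L <- as.matrix(tab[, pcs])
  rownames(L) <- tab$element
  vtab <- utils::read.csv(system.file("extdata", "reference_variance.csv",
                                      package = "metalmon"),
                          stringsAsFactors = FALSE)
  vtab <- vtab[vtab$biomonitor == biomonitor, ]
  list(loadings = L,
       published_communality = stats::setNames(tab$communality, tab$element),
       pct_variance = stats::setNames(vtab$pct_variance, vtab$component))
}
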