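#' Classify accumulation factors
#'
#' Maps AF values onto the conventional contamination categories:
#' AF <= 1 none; 1 < AF < 2 minimal; 2 <= AF <= 5 moderate;
#' 5 < AF <= 20 significant; 20 < AF <= 40 very high; AF > 40 extremely
#' high. Boundaries are resolved deterministically (AF = 2 is moderate,
#' AF = 5 moderate, AF = 20 significant, AF = 40 very high).
#'
#' @param af Numeric vector of accumulation factors (> 0).
#' @return Ordered factor with levels `none < minimal < moderate <
#'   significant < very_high < extremely_high`.
#' @export
classify_af <- function(af) {
  if (any(!is.finite(af) | af <= 0)) stop("AF values must be positive")
  lev <- c("none", "minimal", "moderate", "significant",
           "very_high", "extremely_high")
  idx <- ifelse(af <= 1, 1L,
         ifelse(af < 2, 2L,
         ifelse(af <= 5, 3L,
         ifelse(af <= 20, 4L,
         ifelse(af <= 40, 5L, 6L)))))
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Accumulation factors relative to the background site
#'
#' For each exposure site and element, the ratio of the element's
#' reference-normalized concentration to the same ratio at the background
#' site:
#' \deqn{AF_X = (C_X / C_{ref})_{site} / (C_X / C_{ref})_{background}}
#' The reference element (Al by default, taken as purely geogenic) has
#' AF identically 1.
#'
#' @param survey An imputed `elemental_survey` with a background site.
#' @param reference_element Normalizing element, default `"Al"`.
#' @return Object of class `af_result`: list with `af` (site x element
#'   matrix over exposure sites), `category` (same shape, see
#'   [classify_af()]), `mean_af`, `sd_af` (per element),
#'   `from_imputed` (logical matrix flagging AFs touched by a DL/2 cell),
#'   `reference_element`.
#' @export
accumulation_factor <- function(survey, reference_element = "Al") {
  conc <- survey$concentrations
  if (!reference_element %in% colnames(conc)) {
    stop("reference element '", reference_element, "' not in panel")
  }
  if (any(survey$censored[, reference_element])) {
    stop("reference element '", reference_element,
         "' is censored at some sites")
  }
  if (anyNA(conc)) {
    stop("survey has unimputed censored cells; run impute_censored() first")
  }
  bg <- background_vector(survey)
  if (any(bg <= 0)) {
    stop("zero background concentration for element: ",
         paste(names(bg)[bg <= 0], collapse = ", "))
  }
  keep <- survey$sites$role == "exposure"
  ex <- conc[keep, , drop = FALSE]
  ratio_site <- ex / ex[, reference_element]
  ratio_bg <- bg / bg[[reference_element]]
  af <- sweep(ratio_site, 2, ratio_bg, "/")
  af[, reference_element] <- 1
  cat_m <- matrix(as.character(classify_af(af)), nrow(af), ncol(af),
                  dimnames = dimnames(af))
  bg_cens <- survey$censored[survey$sites$role == "background", ]
  from_imp <- survey$censored[keep, , drop = FALSE] |
    matrix(bg_cens, nrow(af), ncol(af), byrow = TRUE)
  structure(list(af = af, category = cat_m,
                 mean_af = colMeans(af),
                 sd_af = apply(af, 2, stats::sd),
                 from_imputed = from_imp,
                 reference_element = reference_element),
            class = "af_result")
}

#' Enrichment factors relative to upper continental crust
#'
#' For each exposure-site sample, the crustal double ratio
#' \deqn{EF_X = (C_X / C_{Al})_{sample} / (C_X / C_{Al})_{crust}.}
#' Per-element summaries follow the usual screening rules: a mean EF
#' below 10 is read as predominantly crustal origin; an element is
#' flagged as enriched when its mean EF exceeds 3 and at least 30% of
#' samples have EF > 3.
#'
#' @param survey An imputed `elemental_survey`.
#' @param crust A [crustal_reference()].
#' @return Object of class `ef_result`: list with `ef` (site x element
#'   matrix over exposure sites), `mean_ef`, `sd_ef`, `frac_above_3`,
#'   `origin` (`"crustal"`/`"anthropogenic"`), `enriched_flag`,
#'   `from_imputed`, `normalizing_element`, `provenance_label`.
#' @export
enrichment_factor <- function(survey, crust = crustal_reference()) {
  ref <- crust$normalizing_element
  conc <- survey$concentrations
  if (!ref %in% colnames(conc)) stop("normalizing element not in panel")
  if (any(survey$censored[, ref])) {
    stop("normalizing element '", ref, "' is censored at some sites")
  }
  if (anyNA(conc)) {
    stop("survey has unimputed censored cells; run impute_censored() first")
  }
  absent <- setdiff(colnames(conc), names(crust$abundances))
  if (length(absent)) {
    stop("element absent from crustal reference: ",
         paste(absent, collapse = ", "))
  }
  keep <- survey$sites$role == "exposure"
  ex <- conc[keep, , drop = FALSE]
  ratio_sample <- ex / ex[, ref]
  crust_ab <- crust$abundances[colnames(ex)]
  ratio_crust <- crust_ab / crust_ab[[ref]]
  ef <- sweep(ratio_sample, 2, ratio_crust, "/")
  ef[, ref] <- 1
  mean_ef <- colMeans(ef)
  frac3 <- colMeans(ef > 3)
  structure(list(ef = ef, mean_ef = mean_ef,
                 sd_ef = apply(ef, 2, stats::sd),
                 frac_above_3 = frac3,
                 origin = ifelse(mean_ef < 10, "crustal", "anthropogenic"),
                 enriched_flag = mean_ef > 3 & frac3 >= 0.30,
                 from_imputed = survey$censored[keep, , drop = FALSE],
                 normalizing_element = ref,
                 provenance_label = crust$provenance_label),
            class = "ef_result")
}

#' Modified coefficient of variation
#'
#' Standard deviation divided by the median, per element over exposure
#' sites. More robust to a few extreme sites than the ordinary CV; large
#' values flag elements whose spatial dispersion suggests anthropogenic
#' influence rather than physiological regulation.
#'
#' @param survey An imputed `elemental_survey`.
#' @return Named numeric vector, one value per element.
#' @export
modified_cv <- function(survey) {
  ex <- exposure_matrix(survey)
  if (anyNA(ex)) {
    stop("survey has unimputed censored cells; run impute_censored() first")
  }
  med <- apply(ex, 2, stats::median)
  if (any(med <= 0)) {
    stop("zero median for element: ",
         paste(colnames(ex)[med <= 0], collapse = ", "))
  }
  apply(ex, 2, stats::sd) / med
}

#' Export AF results as a tidy table
#' @param x An `af_result`.
#' @return Data frame `(site_id, element, af, af_category, from_imputed)`.
#' @export
af_table <- function(x) {
  data.frame(site_id = rep(rownames(x$af), times = ncol(x$af)),
             element = rep(colnames(x$af), each = nrow(x$af)),
             af = as.vector(x$af),
             af_category = as.vector(x$category),
             from_imputed = as.vector(x$from_imputed),
             stringsAsFactors = FALSE)
}

#' Export EF summaries as a tidy table
#' @param x An `ef_result`.
#' @return Data frame `(element, mean_ef, sd_ef, frac_above_3, origin,
#'   enriched)`.
#' @export
ef_table <- function(x) {
  data.frame(element = names(x$mean_ef),
             mean_ef = unname(x$mean_ef),
             sd_ef = unname(x$sd_ef),
             frac_above_3 = unname(x$frac_above_3),
             origin = unname(x$origin),
             enriched = unname(x$enriched_flag),
             stringsAsFactors = FALSE)
}
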