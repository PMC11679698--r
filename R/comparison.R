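# closed-form MA slope only (no CI), for permutation loops
ma_slope <- function(x, y) {
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxy == 0) {
    if (sxx == syy) return(NA_real_)
    return(if (sxx > syy) 0 else Inf)
  }
  (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
}

# Wilcoxon signed-rank with Pratt handling of zero differences: zeros are
# ranked together with the non-zero |d|, then discarded from the rank
# sums. Normal approximation with tie and zero corrections.
wilcoxon_signed_pratt <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  pos <- sum(r[d > 0])
  nz <- sum(d == 0)
  if (all(d == 0)) return(list(statistic = 0, p = 1))
  # moments of the positive rank sum under H0, zeros excluded (Pratt 1959)
  mu <- (n * (n + 1) / 4) - (nz * (nz + 1) / 4)
  ties <- table(r[d != 0])
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    nz * (nz + 1) * (2 * nz + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- (pos - mu) / sqrt(sig2)
  list(statistic = pos, p = 2 * stats::pnorm(-abs(z)))
}

#' Paired comparison of enrichment factors between two biomonitors
#'
#' For one element, compares per-site EF values of two co-located
#' biomonitors. The Shapiro-Wilk test on the paired differences routes
#' to a paired t-test (normal) or a Wilcoxon signed-rank test with Pratt
#' zero handling (non-normal). Direction is called from the median
#' difference when the test is significant at `alpha`.
#'
#' @param ef_a,ef_b Numeric vectors of per-site EFs (same sites, same
#'   order), biomonitor A and B.
#' @param alpha Significance level for the direction call (0.05).
#' @return Object of class `paired_ef_test`: list with `n_pairs`,
#'   `route` (`"t_test"`/`"wilcoxon"`), `statistic`, `p_two_sided`,
#'   `shapiro_p`, `direction` (`"biomonitor_a_higher"`,
#'   `"biomonitor_b_higher"` or `"none"`).
#' @export
paired_ef_test <- function(ef_a, ef_b, alpha = 0.05) {
  ok <- is.finite(ef_a) & is.finite(ef_b)
  ef_a <- ef_a[ok]; ef_b <- ef_b[ok]
  n <- length(ef_a)
  if (n < 6) stop("need at least 6 complete pairs")
  d <- ef_a - ef_b
  if (all(d == 0)) {
    return(structure(list(n_pairs = n, route = "none", statistic = 0,
                          p_two_sided = 1, shapiro_p = NA_real_,
                          direction = "none"),
                     class = "paired_ef_test"))
  }
  sw <- stats::shapiro.test(d)$p.value
  if (sw >= alpha) {
    tt <- stats::t.test(ef_a, ef_b, paired = TRUE)
    route <- "t_test"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- wilcoxon_signed_pratt(d)
    route <- "wilcoxon"; statistic <- wt$statistic; p <- wt$p
  }
  direction <- if (p >= alpha || stats::median(d) == 0) {
    "none"
  } else if (stats::median(d) > 0) {
    "biomonitor_a_higher"
  } else {
    "biomonitor_b_higher"
  }
  structure(list(n_pairs = n, route = route, statistic = statistic,
                 p_two_sided = p, shapiro_p = sw, direction = direction),
            class = "paired_ef_test")
}

#' Major-axis (Model II) regression
#'
#' Symmetric regression minimizing perpendicular distances, appropriate
#' when neither variable can be designated an error-free predictor. The
#' slope is the direction of the first principal axis of the 2x2
#' covariance matrix:
#' \deqn{b = (s_{yy} - s_{xx} + \sqrt{(s_{yy} - s_{xx})^2 + 4 s_{xy}^2})
#'   / (2 s_{xy})}
#' The 95% CI is obtained by the angular method: an axis direction
#' belongs to the CI when rotating the data to that direction leaves the
#' two rotated coordinates uncorrelated at the 5% level.
#'
#' @param x,y Numeric vectors, n >= 3.
#' @param alpha CI level is `1 - alpha` (default 0.05).
#' @return Object of class `ma_regression`: list with `n`, `slope`,
#'   `intercept`, `slope_ci95`, `angle`, `r`.
#' @export
major_axis_regression <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx + syy == 0) stop("degenerate data: no variance")
  if (sxy == 0 && sxx == syy) {
    stop("isotropic point cloud: major axis undefined")
  }
  slope <- if (sxy == 0) {
    if (sxx > syy) 0 else Inf
  } else {
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  intercept <- if (is.finite(slope)) mean(y) - slope * mean(x) else NA_real_
  theta <- atan2(if (is.finite(slope)) slope else 1,
                 if (is.finite(slope)) 1 else 0)
  ci <- ma_angle_ci(x, y, theta, alpha)
  structure(list(n = n, slope = slope, intercept = intercept,
                 slope_ci95 = ci, angle = theta,
                 r = stats::cor(x, y)),
            class = "ma_regression")
}

# CI of the major-axis direction by inverting the rotated-coordinates
# correlation test: direction theta0 is compatible with the data iff the
# correlation between (x cos + y sin) and (-x sin + y cos) is not
# significant at alpha (F test on 1 and n-2 df).
ma_angle_ci <- function(x, y, theta_hat, alpha = 0.05) {
  n <- length(x)
  fcrit <- stats::qf(1 - alpha, 1, n - 2)
  tstat2 <- function(theta0) {
    u <- x * cos(theta0) + y * sin(theta0)
    v <- -x * sin(theta0) + y * cos(theta0)
    if (stats::sd(u) == 0 || stats::sd(v) == 0) return(0)
    r <- stats::cor(u, v)
    (n - 2) * r^2 / (1 - r^2)
  }
  f <- function(theta0) tstat2(theta0) - fcrit
  # search outward from the estimate on both sides, within +/- pi/2
  lo <- hi <- NA_real_
  if (f(theta_hat) >= 0) {
    # estimate itself at the boundary (pathological); CI undefined
    return(c(NA_real_, NA_real_))
  }
  step <- pi / 720
  th <- theta_hat
  while (th > theta_hat - pi / 2 && f(th) < 0) th <- th - step
  if (f(th) >= 0) {
    lo <- stats::uniroot(f, c(th, th + step))$root
  }
  th <- theta_hat
  while (th < theta_hat + pi / 2 && f(th) < 0) th <- th + step
  if (f(th) >= 0) {
    hi <- stats::uniroot(f, c(th - step, th))$root
  }
  out <- tan(c(lo, hi))
  # angles past vertical wrap the slope sign; report as unbounded side
  if (!is.na(lo) && abs(lo) > pi / 2) out[1] <- -Inf
  if (!is.na(hi) && abs(hi) > pi / 2) out[2] <- Inf
  out
}

#' Permutation tests for a major-axis regression
#'
#' Two permutation tests on paired biomonitor data: (1) association --
#' y is permuted against x and the null distribution of |r| is compared
#' with the observed absolute correlation; (2) slope different from 1 --
#' under the null of a symmetric (slope-1) relation the mean-centered
#' coordinates of each pair are exchangeable, so each centered pair
#' (x_i - mean x, y_i - mean y) may be swapped at random; the test
#' statistic is |ln slope| of the re-estimated major axis (centering is
#' required: the raw coordinates are not exchangeable when the two
#' biomonitors differ in overall level, which is the usual case). Both
#' p-values use the (count + 1) / (n_perm + 1) construction and are
#' bit-reproducible for a fixed seed.
#'
#' @param x,y Numeric vectors, n >= 6.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed (required for reproducibility).
#' @return List with `p_association`, `p_slope_ne_1`, `n_perm`, `seed`,
#'   `slope`.
#' @export
ma_permutation_tests <- function(x, y, n_perm = 999, seed = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 6) stop("need at least 6 pairs")
  obs_r <- abs(stats::cor(x, y))
  obs_slope <- ma_slope(x, y)
  if (is.na(obs_slope)) stop("isotropic point cloud: major axis undefined")
  obs_stat <- if (is.finite(obs_slope) && obs_slope > 0) {
    abs(log(obs_slope))
  } else {
    Inf # a non-positive or vertical MA slope is maximally far from 1
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  cnt_assoc <- 0L
  cnt_slope <- 0L
  for (b in seq_len(n_perm)) {
    yp <- y[sample.int(n)]
    if (abs(stats::cor(x, yp)) >= obs_r) cnt_assoc <- cnt_assoc + 1L
    sw <- stats::runif(n) < 0.5
    xs <- ifelse(sw, yc, xc)
    ys <- ifelse(sw, xc, yc)
    bs <- ma_slope(xs, ys)
    stat <- if (!is.na(bs) && is.finite(bs) && bs > 0) {
      abs(log(bs))
    } else {
      Inf
    }
    if (stat >= obs_stat) cnt_slope <- cnt_slope + 1L
  }
  list(p_association = (cnt_assoc + 1) / (n_perm + 1),
       p_slope_ne_1 = (cnt_slope + 1) / (n_perm + 1),
       n_perm = n_perm, seed = seed, slope = obs_slope)
}

#' Element-wise comparison of two co-located biomonitor surveys
#'
#' Computes per-site EFs for both surveys (same crustal reference),
#' then for each element runs the paired routed test and the major-axis
#' regression with permutation tests.
#'
#' @param survey_a,survey_b Imputed surveys on the same sites.
#' @param crust A [crustal_reference()].
#' @param elements Elements to compare (default: panel intersection,
#'   excluding the normalizing element).
#' @param n_perm,seed Passed to [ma_permutation_tests()].
#' @param alpha Significance level.
#' @return Data frame, one row per element: `element, n, slope, ci_lo,
#'   ci_hi, p_association, p_slope_ne_1, route, p_paired, direction`.
#' @export
compare_biomonitors <- function(survey_a, survey_b,
                                crust = crustal_reference(),
                                elements = NULL, n_perm = 999, seed = 1,
                                alpha = 0.05) {
  ef_a <- enrichment_factor(survey_a, crust)
  ef_b <- enrichment_factor(survey_b, crust)
  common_sites <- intersect(rownames(ef_a$ef), rownames(ef_b$ef))
  if (is.null(elements)) {
    elements <- setdiff(intersect(colnames(ef_a$ef), colnames(ef_b$ef)),
                        crust$normalizing_element)
  }
  rows <- lapply(seq_along(elements), function(i) {
    e <- elements[i]
    a <- ef_a$ef[common_sites, e]
    b <- ef_b$ef[common_sites, e]
    pt <- paired_ef_test(a, b, alpha = alpha)
    ma <- major_axis_regression(a, b)
    pm <- ma_permutation_tests(a, b, n_perm = n_perm, seed = seed + i)
    data.frame(element = e, n = ma$n, slope = ma$slope,
               ci_lo = ma$slope_ci95[1], ci_hi = ma$slope_ci95[2],
               p_association = pm$p_association,
               p_slope_ne_1 = pm$p_slope_ne_1,
               route = pt$route, p_paired = pt$p_two_sided,
               direction = pt$direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
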