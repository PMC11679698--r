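#' Pairwise Spearman correlation screen
#'
#' Rank correlations between element concentrations over exposure sites,
#' with two-sided p-values (t approximation for n >= 10, exact below).
#' Ties are handled by average ranks. Constant elements yield `NA` with a
#' warning.
#'
#' @param survey An imputed `elemental_survey`, or a numeric sites x
#'   elements matrix.
#' @param alpha Significance level stored with the screen (default 0.05).
#' @return Object of class `correlation_screen`: list with `method`,
#'   `rho` and `p` (element x element matrices) and `alpha`.
#' @export
spearman_screen <- function(survey, alpha = 0.05) {
  x <- if (inherits(survey, "elemental_survey")) {
    exposure_matrix(survey)
  } else {
    as.matrix(survey)
  }
  if (nrow(x) < 3) stop("need at least 3 sites")
  p_ <- ncol(x)
  rho <- p <- matrix(NA_real_, p_, p_,
                     dimnames = list(colnames(x), colnames(x)))
  diag(rho) <- 1
  diag(p) <- 0
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("constant element(s), correlations undefined: ",
            paste(colnames(x)[const], collapse = ", "))
  }
  exact <- nrow(x) < 10
  for (i in seq_len(p_ - 1)) {
    for (j in (i + 1):p_) {
      if (const[i] || const[j]) next
      ct <- suppressWarnings(
        stats::cor.test(x[, i], x[, j], method = "spearman", exact = exact)
      )
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(method = "spearman", rho = rho, p = p, alpha = alpha),
            class = "correlation_screen")
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity (no common
#' structure), a precondition check before PCA:
#' chi^2 = -(n - 1 - (2p + 5)/6) * ln|R| on p(p-1)/2 degrees of freedom.
#'
#' @param corr Correlation matrix.
#' @param n Number of observations behind `corr`.
#' @return List `chi2`, `df`, `p`.
#' @export
bartlett_sphericity <- function(corr, n) {
  corr <- as.matrix(corr)
  p_ <- ncol(corr)
  stopifnot(n > p_)
  ld <- determinant(corr, logarithm = TRUE)
  logdet <- as.numeric(ld$modulus) * as.numeric(ld$sign)
  if (!is.finite(logdet) || as.numeric(ld$sign) <= 0) {
    warning("singular correlation matrix; sphericity p-value reported as 0")
    return(list(chi2 = Inf, df = p_ * (p_ - 1) / 2, p = 0))
  }
  chi2 <- -(n - 1 - (2 * p_ + 5) / 6) * logdet
  df <- p_ * (p_ - 1) / 2
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# Anti-image machinery: partial correlations from the inverse correlation
# matrix. a_ij = -Q_ij / sqrt(Q_ii Q_jj) with Q = R^{-1}.
partial_correlations <- function(corr) {
  Q <- tryCatch(solve(corr), error = function(e) {
    stop("correlation matrix is singular")
  })
  d <- 1 / sqrt(diag(Q))
  A <- -Q * tcrossprod(d)
  diag(A) <- 1
  dimnames(A) <- dimnames(corr)
  A
}

#' Per-variable measure of sampling adequacy (anti-image diagonal)
#'
#' MSA_i = sum_j r_ij^2 / (sum_j r_ij^2 + sum_j a_ij^2) over j != i,
#' where a_ij are partial correlations. Low values identify variables
#' that share too little common variance to enter a PCA.
#'
#' @param corr Correlation matrix (invertible).
#' @return Named numeric vector of MSA values in `[0, 1]`.
#' @export
msa <- function(corr) {
  corr <- as.matrix(corr)
  A <- partial_correlations(corr)
  r2 <- corr^2; diag(r2) <- 0
  a2 <- A^2; diag(a2) <- 0
  stats::setNames(rowSums(r2) / (rowSums(r2) + rowSums(a2)),
                  colnames(corr))
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' KMO = sum of squared off-diagonal correlations over the same sum plus
#' the squared off-diagonal partial correlations. Values near 1 indicate
#' data well-suited to factor-analytic methods; any 2-variable matrix
#' gives exactly 0.5.
#'
#' @param corr Correlation matrix (invertible, >= 2 variables).
#' @return KMO statistic in `[0, 1]`.
#' @export
kmo <- function(corr) {
  corr <- as.matrix(corr)
  if (ncol(corr) < 2) stop("need at least 2 variables")
  A <- partial_correlations(corr)
  r2 <- corr^2; diag(r2) <- 0
  a2 <- A^2; diag(a2) <- 0
  sum(r2) / (sum(r2) + sum(a2))
}

#' Iterative anti-image elimination of inadequate variables
#'
#' Repeatedly drops the variable with the lowest MSA (recomputing after
#' each removal) until all remaining variables have MSA at or above the
#' threshold. Variables in `keep` are never dropped, accommodating a
#' deliberate retention of a low-MSA variable.
#'
#' @param corr Correlation matrix.
#' @param msa_threshold Minimum acceptable MSA (default 0.5).
#' @param keep Character vector of variables exempt from elimination.
#' @return List with `retained` (character) and `dropped` (data frame
#'   `variable, msa_at_drop` in drop order).
#' @export
msa_eliminate <- function(corr, msa_threshold = 0.5, keep = character(0)) {
  corr <- as.matrix(corr)
  dropped <- data.frame(variable = character(0), msa_at_drop = numeric(0),
                        stringsAsFactors = FALSE)
  repeat {
    m <- msa(corr)
    cand <- m[!(names(m) %in% keep)]
    if (!length(cand) || min(m) >= msa_threshold ||
        min(cand) >= msa_threshold) break
    worst <- names(cand)[which.min(cand)]
    dropped <- rbind(dropped,
                     data.frame(variable = worst,
                                msa_at_drop = unname(cand[worst]),
                                stringsAsFactors = FALSE))
    sel <- setdiff(colnames(corr), worst)
    if (length(sel) < 3) stop("insufficient variables for PCA")
    corr <- corr[sel, sel, drop = FALSE]
  }
  list(retained = colnames(corr), dropped = dropped)
}

#' Varimax simplicity criterion
#'
#' Mean of column variances of squared loadings:
#' sum_k ( mean(L_k^4) - mean(L_k^2)^2 ). The quantity pairwise varimax
#' sweeps maximize (computed on Kaiser-normalized loadings when
#' normalization is in use).
#'
#' @param L Loading matrix.
#' @return The criterion value.
#' @export
varimax_criterion <- function(L) {
  L <- as.matrix(L)
  sum(colMeans(L^4) - colMeans(L^2)^2)
}

# Pairwise (Kaiser 1958) varimax sweeps. Rows are optionally normalized
# to unit communality before rotation and rescaled after. Deterministic
# stopping: criterion increase < tol or max_sweeps reached.
varimax_rotate <- function(L, normalize = TRUE, tol = 1e-9,
                           max_sweeps = 1000) {
  L <- as.matrix(L)
  p_ <- nrow(L); k <- ncol(L)
  if (k < 2) return(list(loadings = L, rotmat = diag(k), sweeps = 0L,
                         converged = TRUE))
  h <- sqrt(rowSums(L^2))
  W <- if (normalize) L / h else L
  Rtot <- diag(k)
  crit_old <- varimax_criterion(W)
  sweeps <- 0L
  converged <- FALSE
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        xi <- W[, i]; xj <- W[, j]
        u <- xi^2 - xj^2
        v <- 2 * xi * xj
        A <- sum(u); B <- sum(v)
        C <- sum(u^2 - v^2); D <- sum(2 * u * v)
        num <- D - 2 * A * B / p_
        den <- C - (A^2 - B^2) / p_
        phi <- atan2(num, den) / 4
        if (abs(phi) < 1e-14) next
        cs <- cos(phi); sn <- sin(phi)
        W[, i] <- cs * xi + sn * xj
        W[, j] <- -sn * xi + cs * xj
        Ri <- Rtot[, i]; Rj <- Rtot[, j]
        Rtot[, i] <- cs * Ri + sn * Rj
        Rtot[, j] <- -sn * Ri + cs * Rj
      }
    }
    crit_new <- varimax_criterion(W)
    if (crit_new - crit_old < tol) {
      converged <- TRUE
      break
    }
    crit_old <- crit_new
  }
  if (!converged) {
    warning("varimax did not converge in ", max_sweeps,
            " sweeps; returning last iterate")
  }
  out <- if (normalize) W * h else W
  dimnames(out) <- dimnames(L)
  list(loadings = out, rotmat = Rtot, sweeps = sweeps,
       converged = converged)
}

#' Principal component extraction with varimax rotation
#'
#' The correlation-matrix PCA used for source apportionment: variables
#' are z-scored implicitly by working on the correlation matrix; unrotated
#' loadings are eigenvector * sqrt(eigenvalue) for components with
#' eigenvalue above `eigen_cut`; varimax rotation with Kaiser (row)
#' normalization is applied; per-component explained variance is
#' recomputed after rotation as the column sum of squared loadings over
#' the number of variables; elements are assigned to the component on
#' which their absolute loading exceeds `loading_threshold`. Each rotated
#' component is sign-flipped so its largest-magnitude loading is positive,
#' and components are ordered by explained variance.
#'
#' @param x Numeric sites x variables matrix (already screened), or an
#'   `elemental_survey` (exposure sites used).
#' @param eigen_cut Retain components with eigenvalue above this (1.0).
#' @param loading_threshold Assignment threshold on |loading| (0.5).
#' @param max_sweeps,tol Varimax stopping parameters.
#' @return Object of class `pca_solution`; see Details.
#' @details Fields: `retained_variables`, `eigenvalues`, `n_components`,
#'   `rotated_loadings`, `unrotated_loadings`, `communalities`,
#'   `explained_variance_pct`, `total_variance_pct`, `assignments`,
#'   `n_obs`.
#' @export
pca_varimax <- function(x, eigen_cut = 1.0, loading_threshold = 0.5,
                        max_sweeps = 1000, tol = 1e-9) {
  if (inherits(x, "elemental_survey")) x <- exposure_matrix(x)
  x <- as.matrix(x)
  if (nrow(x) < ncol(x)) {
    warning("fewer sites than variables; PCA solution may be unstable")
  }
  R <- stats::cor(x)
  eig <- eigen(R, symmetric = TRUE)
  ev <- eig$values
  nc <- sum(ev > eigen_cut)
  if (nc < 1) stop("no eigenvalue above the retention cut")
  L <- eig$vectors[, seq_len(nc), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(nc)]), nc)
  rownames(L) <- colnames(x)
  rot <- varimax_rotate(L, normalize = TRUE, tol = tol,
                        max_sweeps = max_sweeps)
  Lr <- rot$loadings
  # sign convention: dominant loading of each component positive
  for (k in seq_len(ncol(Lr))) {
    if (Lr[which.max(abs(Lr[, k])), k] < 0) Lr[, k] <- -Lr[, k]
  }
  expl <- colSums(Lr^2) / nrow(Lr) * 100
  ord <- order(expl, decreasing = TRUE)
  Lr <- Lr[, ord, drop = FALSE]
  expl <- expl[ord]
  colnames(Lr) <- paste0("PC", seq_len(ncol(Lr)))
  names(expl) <- colnames(Lr)
  assignments <- lapply(colnames(Lr), function(k) {
    rownames(Lr)[abs(Lr[, k]) > loading_threshold]
  })
  names(assignments) <- colnames(Lr)
  structure(list(retained_variables = colnames(x),
                 eigenvalues = ev,
                 n_components = nc,
                 rotated_loadings = Lr,
                 unrotated_loadings = L,
                 communalities = rowSums(Lr^2),
                 explained_variance_pct = expl,
                 total_variance_pct = sum(expl),
                 assignments = assignments,
                 loading_threshold = loading_threshold,
                 n_obs = nrow(x)),
            class = "pca_solution")
}

#' @export
print.pca_solution <- function(x, ...) {
  cat("<pca_solution> ", x$n_components, " components, ",
      length(x$retained_variables), " variables, total variance ",
      sprintf("%.1f%%", x$total_variance_pct), "\n", sep = "")
  for (k in names(x$assignments)) {
    cat("  ", k, sprintf(" (%.1f%%): ", x$explained_variance_pct[[k]]),
        paste(x$assignments[[k]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Total explained variance of a solution or loading table
#'
#' For a `pca_solution`, the sum of the per-component explained-variance
#' percentages. A numeric vector of per-component percentages is summed
#' directly, so published per-component values can be book-kept the same
#' way.
#'
#' @param x A `pca_solution` or numeric vector of percentages.
#' @return Total percentage of variance explained.
#' @export
total_variance <- function(x) {
  if (inherits(x, "pca_solution")) {
    return(sum(x$explained_variance_pct))
  }
  sum(as.numeric(x))
}

#' Communalities from a loading matrix
#'
#' Row sums of squared loadings: the fraction of each variable's variance
#' captured by the retained components.
#'
#' @param L Variable x component loading matrix, or a `pca_solution`.
#' @return Named numeric vector of communalities.
#' @export
communality <- function(L) {
  if (inherits(L, "pca_solution")) return(L$communalities)
  rowSums(as.matrix(L)^2)
}

#' Full source-apportionment procedure for a survey
#'
#' Runs the screening-and-rotation chain on exposure-site concentrations:
#' Spearman screen, anti-image MSA elimination (with optional keep-list),
#' Bartlett sphericity and KMO on the retained set, then correlation PCA
#' with varimax rotation and threshold-based source assignment.
#'
#' @param survey An imputed `elemental_survey`.
#' @param msa_threshold Minimum MSA for retention (0.5).
#' @param keep Variables never eliminated (e.g. a deliberately retained
#'   low-MSA element).
#' @param eigen_cut,loading_threshold,max_sweeps See [pca_varimax()].
#' @return A `pca_solution` with additional fields `kmo`,
#'   `bartlett_chi2`, `bartlett_df`, `bartlett_p`, `dropped_variables`
#'   and `screen` (the [spearman_screen()]).
#' @export
apportion_sources <- function(survey, msa_threshold = 0.5,
                              keep = character(0), eigen_cut = 1.0,
                              loading_threshold = 0.5, max_sweeps = 1000) {
  x <- exposure_matrix(survey)
  screen <- spearman_screen(survey)
  R <- stats::cor(x)
  elim <- msa_eliminate(R, msa_threshold = msa_threshold, keep = keep)
  xs <- x[, elim$retained, drop = FALSE]
  Rs <- stats::cor(xs)
  bart <- bartlett_sphericity(Rs, nrow(xs))
  sol <- pca_varimax(xs, eigen_cut = eigen_cut,
                     loading_threshold = loading_threshold,
                     max_sweeps = max_sweeps)
  sol$kmo <- kmo(Rs)
  sol$bartlett_chi2 <- bart$chi2
  sol$bartlett_df <- bart$df
  sol$bartlett_p <- bart$p
  sol$dropped_variables <- elim$dropped
  sol$screen <- screen
  sol
}

#' Export a PCA solution in a publication-style layout
#' @param sol A `pca_solution`.
#' @return Data frame: element, one column per component, communality.
#' @export
loadings_table <- function(sol) {
  L <- sol$rotated_loadings
  out <- data.frame(element = rownames(L), as.data.frame(unclass(L)),
                    communality = unname(sol$communalities),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
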