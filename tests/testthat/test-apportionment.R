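# independent anti-image oracle used by several tests
oracle_msa <- function(R) {
  Q <- solve(R)
  d <- 1 / sqrt(diag(Q))
  A <- -Q * outer(d, d)
  diag(A) <- 1
  r2 <- R^2; diag(r2) <- 0
  a2 <- A^2; diag(a2) <- 0
  rowSums(r2) / (rowSums(r2) + rowSums(a2))
}

test_that("Spearman screen matches rank arithmetic including ties", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 2, 3, 5, 4)  # one tie
  m <- cbind(A = x, B = y, C = -x)
  sc <- spearman_screen(m)
  # oracle: Pearson correlation of average ranks
  expect_equal(sc$rho["A", "B"], cor(rank(x), rank(y)))
  expect_equal(sc$rho["A", "C"], -1)
  # monotone transform leaves rho at 1
  m2 <- cbind(A = x, B = exp(x))
  expect_equal(spearman_screen(m2)$rho["A", "B"], 1)
  # constant column flagged
  expect_warning(sc3 <- spearman_screen(cbind(A = x, B = rep(2, 5))),
                 "constant")
  expect_true(is.na(sc3$rho["A", "B"]))
  expect_error(spearman_screen(m[1:2, ]), "3 sites")
})

test_that("Bartlett sphericity follows the chi-square formula", {
  p <- 4
  expect_equal(bartlett_sphericity(diag(p), 50),
               list(chi2 = 0, df = 6, p = 1))
  # direct formula oracle, 2 variables, r = 0.9, n = 50
  R <- matrix(c(1, 0.9, 0.9, 1), 2)
  got <- bartlett_sphericity(R, 50)
  chi_oracle <- -(50 - 1 - (2 * 2 + 5) / 6) * log(det(R))
  expect_equal(got$chi2, chi_oracle)
  expect_equal(got$df, 1)
  expect_equal(got$p, pchisq(chi_oracle, 1, lower.tail = FALSE))
  # df for 13 variables
  expect_equal(bartlett_sphericity(diag(13), 47)$df, 78)
})

test_that("KMO and MSA reproduce the partial-correlation identities", {
  # any 2-variable correlation matrix gives exactly 0.5
  for (r in c(-0.7, 0.1, 0.9)) {
    expect_equal(kmo(matrix(c(1, r, r, 1), 2)), 0.5)
  }
  # constructed 4x4 oracle
  set.seed(11)
  X <- matrix(rnorm(200), 50)
  X <- cbind(X[, 1], X[, 1] + 0.3 * X[, 2], X[, 3], X[, 1] - 0.5 * X[, 4])
  R <- cor(X)
  A <- solve(R)
  dA <- 1 / sqrt(diag(A))
  partial <- -A * outer(dA, dA)
  r2 <- sum(R^2) - 4
  a2 <- sum(partial^2) - 4
  expect_equal(kmo(R), r2 / (r2 + a2))
  expect_equal(unname(msa(R)), unname(oracle_msa(R)))
  # permutation invariance
  perm <- c(3, 1, 4, 2)
  expect_equal(kmo(R[perm, perm]), kmo(R))
  expect_equal(bartlett_sphericity(R[perm, perm], 50)$chi2,
               bartlett_sphericity(R, 50)$chi2)
})

test_that("anti-image elimination drops the unshared variable first", {
  set.seed(21)
  f <- rnorm(60)
  X <- cbind(A = f + rnorm(60, 0, 0.4),
             B = f + rnorm(60, 0, 0.4),
             C = f + rnorm(60, 0, 0.4),
             D = rnorm(60))          # independent noise
  R <- cor(X)
  expect_equal(names(which.min(oracle_msa(R))), "D") # brute-force check
  expect_equal(unname(msa(R)), unname(oracle_msa(R)))

  # with a sizeable coherent block, the lone noise variable falls well
  # below the 0.5 default and is eliminated first
  set.seed(22)
  f2 <- rnorm(40)
  X2 <- sapply(1:12, function(i) f2 + rnorm(40, 0, 0.5))
  colnames(X2) <- LETTERS[1:12]
  X2 <- cbind(X2, Z = rnorm(40))
  R2 <- cor(X2)
  out <- msa_eliminate(R2)
  expect_equal(out$dropped$variable[1], "Z")
  expect_setequal(out$retained, LETTERS[1:12])
  expect_equal(unname(out$dropped$msa_at_drop[1]),
               unname(oracle_msa(R2)[["Z"]]))
  # a coherent block loses nothing; threshold 0 is vacuous
  expect_equal(msa_eliminate(R2[1:12, 1:12])$retained, LETTERS[1:12])
  expect_equal(nrow(msa_eliminate(R2, msa_threshold = 0)$dropped), 0)
  # keep-list overrides elimination
  out_keep <- msa_eliminate(R2, keep = "Z")
  expect_true("Z" %in% out_keep$retained)
})

test_that("varimax conserves communalities and maximizes the criterion", {
  set.seed(31)
  L <- matrix(rnorm(8 * 3), 8, 3)
  rot <- metalmon:::varimax_rotate(L, normalize = TRUE)
  expect_equal(rowSums(rot$loadings^2), rowSums(L^2), tolerance = 1e-9)
  # rotation matrix orthogonal
  expect_equal(crossprod(rot$rotmat), diag(3), tolerance = 1e-9)
  expect_true(rot$converged)

  # 2-component case: exhaustive angle search oracle within 1e-6
  L2 <- matrix(rnorm(12 * 2), 12, 2)
  h <- sqrt(rowSums(L2^2))
  W <- L2 / h
  crit_at <- function(phi) {
    Rm <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2)
    varimax_criterion(W %*% Rm)
  }
  grid <- seq(-pi / 4, pi / 4, length.out = 4001)
  vals <- vapply(grid, crit_at, numeric(1))
  best <- optimize(crit_at, interval = grid[which.max(vals)] + c(-1, 1) *
                     diff(grid)[1], maximum = TRUE)$objective
  rot2 <- metalmon:::varimax_rotate(L2, normalize = TRUE)
  expect_equal(varimax_criterion(rot2$loadings / h), best,
               tolerance = 1e-6)

  # independent cross-check against the reference varimax implementation
  sv <- stats::varimax(L2, normalize = TRUE, eps = 1e-10)
  expect_equal(varimax_criterion(rot2$loadings / h),
               varimax_criterion(unclass(sv$loadings) / h),
               tolerance = 1e-6)
})

test_that("PCA extraction books eigenvalues, variance and assignments", {
  set.seed(41)
  n <- 120
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(a = f1 + rnorm(n, 0, 0.3), b = f1 + rnorm(n, 0, 0.3),
             c = f1 + rnorm(n, 0, 0.3),
             d = f2 + rnorm(n, 0, 0.3), e = f2 + rnorm(n, 0, 0.3),
             f = f2 + rnorm(n, 0, 0.3))
  sol <- pca_varimax(X)
  expect_equal(sol$n_components, 2)
  expect_setequal(sol$assignments$PC1, c("a", "b", "c"))
  expect_setequal(sol$assignments$PC2, c("d", "e", "f"))
  # trace identity and communality conservation
  expect_equal(sum(sol$eigenvalues), 6, tolerance = 1e-9)
  expect_equal(sol$communalities, rowSums(sol$unrotated_loadings^2),
               tolerance = 1e-9)
  # explained variance recomputed from rotated loadings
  expect_equal(unname(sol$explained_variance_pct),
               unname(colSums(sol$rotated_loadings^2) / 6 * 100))
  expect_equal(sol$total_variance_pct, sum(sol$explained_variance_pct))
  # sign convention: dominant loading positive
  for (k in seq_len(ncol(sol$rotated_loadings))) {
    lk <- sol$rotated_loadings[, k]
    expect_gt(lk[which.max(abs(lk))], 0)
  }
  expect_warning(pca_varimax(X[1:4, ]), "fewer sites")
})

test_that("communality and variance accessors match their definitions", {
  L <- rbind(c(1, 0), c(0.6, 0.5))
  expect_equal(unname(communality(L)), c(1, 0.61))
  expect_equal(total_variance(c(29.2, 18.8, 14.3, 9.4)), 71.7)
})

test_that("full apportionment chain wires screening into the solution", {
  gen <- generate_survey(synthetic_config(seed = 3))
  s <- impute_censored(gen$survey_a)
  sol <- apportion_sources(s)
  expect_true(sol$kmo > 0.5) # planted blocks are factorable
  expect_lt(sol$bartlett_p, 0.001)
  expect_true(all(msa(cor(
    exposure_matrix(s)[, sol$retained_variables])) >= 0.5))
  expect_true(all(c("element", "communality") %in%
                  names(loadings_table(sol))))
})
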