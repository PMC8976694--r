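test_that("kernel bundle arithmetic matches the closed forms", {
  # pre-standardized rows (1,1) and (-1,-1): G = MM'/m, D, K = exp(-hD)
  M <- rbind(a = c(1, 1), b = c(-1, -1))
  kb <- build_kernels(M, bandwidths = 0.5, standardize = FALSE)
  expect_equal(unname(kb$G), rbind(c(1, -1), c(-1, 1)))
  expect_equal(unname(kb$D), rbind(c(0, 4), c(4, 0)))
  expect_equal(kb$K[[1]][1, 2], exp(-2), tolerance = 1e-12)
  expect_true(all(kb$K[[1]] > 0 & kb$K[[1]] <= 1))
  expect_equal(diag(kb$D), c(a = 0, b = 0))
})

test_that("kernel bundle standardizes, drops monomorphic markers and is PSD", {
  p <- small_panel()
  X <- cbind(p$geno$dosage[, 1:200], mono = rep(1L, 250))
  expect_message(kb <- build_kernels(X), "monomorphic")
  expect_equal(kb$n_dropped, 1)
  expect_equal(ncol(kb$M), 200)
  expect_equal(unname(colMeans(kb$M)), rep(0, 200), tolerance = 1e-12)
  ev <- eigen(kb$G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  for (K in kb$K) {
    expect_equal(K, t(K))
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-6)
  }
  expect_error(build_kernels(X[1, , drop = FALSE]), "two genotypes")
})

test_that("gibbs_config validates its chain settings", {
  expect_error(gibbs_config(burn_in = 12000), "burn_in")
  expect_error(gibbs_config(thinning = 0), "thinning")
})

test_that("G-BLUP matches the closed-form mixed-model BLUP", {
  p <- small_panel()
  tr <- gblup_trait(p$kb$G, 0.5, seed = 71)
  fit <- fit_gblup(tr$y, p$kb$G, quick_gibbs(seed = 1))
  su <- fit$variance[["sigma_u2"]]; se <- fit$variance[["sigma_e2"]]
  n <- length(tr$y)
  ustar <- drop(su * p$kb$G %*% solve(su * p$kb$G + se * diag(n),
                                      tr$y - mean(tr$y)))
  expect_gt(cor(fit$u, ustar), 0.99)
})

test_that("G-BLUP recovers a noise-free genetic signal", {
  p <- small_panel()
  tr <- gblup_trait(p$kb$G, 0.5, seed = 73)
  y <- tr$u + rnorm(length(tr$u), sd = 0.02)
  names(y) <- names(tr$y)
  fit <- fit_gblup(y, p$kb$G, quick_gibbs(seed = 2))
  expect_gt(cor(fit$u, tr$u), 0.95)
})

test_that("on a structure-free trait the sampler matches the analytic
          posterior and the genetic values collapse", {
  p <- small_panel()
  eg <- eigen(p$kb$G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  # independent oracle: v integrates out, so the (sigma_u2, sigma_e2)
  # posterior is a cheap 2-D quadrature over the eigen-variances
  analytic_share <- function(yt, vy, nu = 5) {
    Se <- vy * 0.5 * (nu + 2) / nu
    Su <- Se / mean(d[d > 1e-8])
    lp <- function(su2, se2) {
      sum(dnorm(yt, 0, sqrt(d * su2 + se2), log = TRUE)) -
        (nu / 2 + 1) * log(su2) - nu * Su / (2 * su2) -
        (nu / 2 + 1) * log(se2) - nu * Se / (2 * se2)
    }
    su <- exp(seq(log(0.005), log(2), length.out = 80))
    se <- seq(0.3, 2, length.out = 80)
    Lp <- outer(su, se, Vectorize(lp))
    w <- exp(Lp - max(Lp)); w <- w / sum(w)
    Esu <- sum(rowSums(w) * su); Ese <- sum(colSums(w) * se)
    Esu / (Esu + Ese)
  }
  for (s in 1:2) {
    set.seed(100 + s)
    y <- rnorm(250)
    names(y) <- rownames(p$kb$G)
    fit <- fit_gblup(y, p$kb$G, quick_gibbs(seed = s, iterations = 3000))
    gibbs_share <- fit$variance[["sigma_u2"]] /
      (fit$variance[["sigma_u2"]] + fit$variance[["sigma_e2"]])
    oracle <- analytic_share(drop(crossprod(eg$vectors, y - mean(y))), var(y))
    expect_lt(abs(gibbs_share - oracle), 0.05)
    # the posterior-mean genetic values themselves carry almost no variance
    expect_lt(var(fit$u) / var(y), 0.15)
  }
})

test_that("G-BLUP genetic values are invariant to genotype order", {
  p <- small_panel()
  tr <- gblup_trait(p$kb$G, 0.5, seed = 79)
  f1 <- fit_gblup(tr$y, p$kb$G, quick_gibbs(seed = 3, iterations = 3000))
  set.seed(12)
  perm <- sample(length(tr$y))
  f2 <- fit_gblup(tr$y[perm], p$kb$G[perm, perm],
                  quick_gibbs(seed = 4, iterations = 3000))
  expect_gt(cor(f1$u[perm], f2$u), 0.995)
})

test_that("multi-kernel RKHS reduces to G-BLUP with a single G kernel", {
  p <- small_panel()
  tr <- gblup_trait(p$kb$G, 0.5, seed = 83)
  fg <- fit_gblup(tr$y, p$kb$G, quick_gibbs(seed = 5))
  fr <- fit_rkhs_multikernel(tr$y, list(p$kb$G), quick_gibbs(seed = 6))
  expect_gt(cor(fg$u, fr$u), 0.99)
  # the standard three bandwidths are accepted and fitted jointly
  fr3 <- fit_rkhs_multikernel(tr$y, p$kb$K, quick_gibbs(seed = 7))
  expect_equal(ncol(fr3$u_l), 3)
  expect_gt(cor(fr3$u, tr$u), 0.5)
  # identity kernel: no covariance structure, u shrinks toward zero
  fid <- fit_rkhs_multikernel(tr$y, list(diag(length(tr$y))),
                              quick_gibbs(seed = 8))
  expect_lt(sqrt(sum(fid$u^2)), sqrt(sum((tr$y - mean(tr$y))^2)))
  expect_error(fit_rkhs_multikernel(tr$y, list(diag(5)), quick_gibbs()),
               "dimensions")
})

test_that("BayesC-pi handles degenerate, sparse and dense architectures", {
  p <- small_panel()
  M <- p$kb$M
  # constant response: no marker effects, negligible genomic heritability
  yc <- rep(3, nrow(M)); names(yc) <- rownames(M)
  fc <- fit_bayescpi(yc, M, quick_gibbs(seed = 9))
  expect_lt(genomic_heritability(fc), 0.05)
  expect_lt(max(abs(fc$effects)), 0.05)

  # sparse architecture: the expected number of nonzero effects lands within
  # a factor of 3 of the planted count (average over seeds; markers drawn
  # independently so LD does not smear the causal set)
  n_in <- vapply(1:3, function(s) {
    set.seed(200 + s)
    Mi <- matrix(rnorm(500 * 2000), 500)
    causal <- sample(2000, 20)
    g <- drop(Mi[, causal] %*% rnorm(20))
    g <- g / sd(g) * sqrt(0.5)
    y <- g + rnorm(500, sd = sqrt(0.5))
    fit <- fit_bayescpi(y, Mi, quick_gibbs(seed = s, iterations = 2500))
    mean((1 - fit$samples$pi) * 2000)
  }, numeric(1))
  expect_gt(mean(n_in), 20 / 3)
  expect_lt(mean(n_in), 20 * 3)
  expect_error(fit_bayescpi(yc, M[, 0]), "no markers")
})

test_that("BayesC-pi and G-BLUP agree under a dense architecture", {
  p <- small_panel()
  tr <- gblup_trait(p$kb$G, 0.5, seed = 89)
  mask <- seq(1, 250, by = 5)
  ym <- tr$y; ym[mask] <- NA
  fb <- fit_bayescpi(ym, p$kb$M, quick_gibbs(seed = 10, iterations = 2500))
  fg <- fit_gblup(ym, p$kb$G, quick_gibbs(seed = 11, iterations = 2500))
  ab <- cor(tr$y[mask], fb$yhat[mask])
  ag <- cor(tr$y[mask], fg$yhat[mask])
  expect_lt(abs(ab - ag), 0.1)
})

test_that("genomic heritability averages the per-iteration ratio", {
  fake <- structure(list(samples = data.frame(h2 = rep(0.5, 10))),
                    class = "gx_fit")
  expect_equal(genomic_heritability(fake), 0.5)
  expect_error(genomic_heritability(structure(list(samples = NULL),
                                              class = "gx_fit")), "samples")
})

test_that("random forest uses the prescribed configuration and is seeded", {
  p <- small_panel()
  tr <- gblup_trait(p$kb$G, 0.5, seed = 97)
  M10 <- p$kb$M[, 1:10]
  f1 <- fit_rf(tr$y, M10, n_trees = 50, seed = 42)
  expect_equal(f1$forest$mtry, 3)  # floor(10/3)
  expect_equal(f1$forest$num.trees, 50)
  f2 <- fit_rf(tr$y, M10, n_trees = 50, seed = 42)
  expect_identical(f1$yhat, f2$yhat)
  expect_warning(fit_rf(tr$y, p$kb$M[, 1:2], n_trees = 10), "mtry")
})

test_that("random forest predicts a strong oligogenic trait out of sample", {
  p <- small_panel()
  X <- p$geno$dosage
  maf <- pmin(colMeans(X) / 2, 1 - colMeans(X) / 2)
  k <- which(maf > 0.3)[1]
  set.seed(101)
  z <- (X[, k] - mean(X[, k])) / sd(X[, k])
  y <- z * sqrt(0.6) + rnorm(nrow(X), sd = sqrt(0.4))
  names(y) <- rownames(X)
  ym <- y; ym[1:50] <- NA
  fit <- fit_rf(ym, p$kb$M, seed = 7)
  expect_gt(cor(y[1:50], fit$yhat[1:50]), 0.6)
})

test_that("the bivariate model detects shared and absent genetic correlation", {
  p <- small_panel()
  tr <- gblup_trait(p$kb$G, 0.5, seed = 103)
  # a duplicated response (tiny jitter keeps the residual covariance proper)
  Y <- cbind(a = tr$y, b = tr$y + rnorm(250, sd = 0.02))
  rownames(Y) <- rownames(p$kb$G)
  fm <- fit_mtm_un(Y, p$kb$G, quick_gibbs(seed = 12))
  expect_gt(fm$genetic_cor[1, 2], 0.95)
  expect_error(fit_mtm_un(cbind(Y, Y[, 1]), p$kb$G), "two traits")

  # genetically independent traits
  cors <- vapply(1:2, function(s) {
    t1 <- gblup_trait(p$kb$G, 0.5, seed = 300 + s)
    t2 <- gblup_trait(p$kb$G, 0.5, seed = 400 + s)
    Yi <- cbind(a = t1$y, b = t2$y)
    fit_mtm_un(Yi, p$kb$G, quick_gibbs(seed = s))$genetic_cor[1, 2]
  }, numeric(1))
  expect_lt(mean(abs(cors)), 0.3)
})

test_that("a correlated trait lends strength to a partially masked trait", {
  p <- small_panel()
  diffs <- vapply(1:2, function(s) {
    set.seed(500 + s)
    L <- t(chol(p$kb$G + diag(1e-6, 250)))
    g1 <- drop(L %*% rnorm(250))
    g2 <- 0.8 * g1 + sqrt(1 - 0.64) * drop(L %*% rnorm(250))
    sc <- function(g) (g - mean(g)) / sd(g) * sqrt(0.6)
    yA <- sc(g1) + rnorm(250, sd = sqrt(0.4))
    yB <- sc(g2) + rnorm(250, sd = sqrt(0.4))
    mask <- sample(250, 50)
    Y <- cbind(A = yA, B = yB)
    rownames(Y) <- rownames(p$kb$G)
    Ym <- Y; Ym[mask, "B"] <- NA
    fm <- fit_mtm_un(Ym, p$kb$G, quick_gibbs(seed = s))
    yBm <- yB; yBm[mask] <- NA; names(yBm) <- rownames(p$kb$G)
    fu <- fit_gblup(yBm, p$kb$G, quick_gibbs(seed = s))
    cor(yB[mask], fm$u[mask, "B"]) - cor(yB[mask], fu$u[mask])
  }, numeric(1))
  expect_gt(mean(diffs), -0.02)
})

test_that("trait pairing selects pairs above the GEBV correlation threshold", {
  p <- small_panel()
  tr <- gblup_trait(p$kb$G, 0.7, seed = 107)
  t2 <- gblup_trait(p$kb$G, 0.7, seed = 108)
  Y <- cbind(a = tr$u + rnorm(250, sd = 0.2),
             b = tr$u + rnorm(250, sd = 0.2),
             c = t2$u + rnorm(250, sd = 0.2))
  rownames(Y) <- rownames(p$kb$G)
  pairs <- select_trait_pairs(Y, p$kb$G, quick_gibbs(seed = 13))
  expect_true(any(pairs$trait1 == "a" & pairs$trait2 == "b"))
  expect_true(all(pairs$gebv_cor > 0.3))
})
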