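#' Gibbs sampler settings
#'
#' Defaults follow the standard long-chain configuration used for the full
#' analysis (12 000 iterations, thinning 5, burn-in 2000). Simulated test
#' problems mix much faster and can use shorter chains.
#'
#' @param iterations total Gibbs iterations.
#' @param thinning keep every `thinning`-th post-burn-in sample.
#' @param burn_in discarded initial iterations.
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   before sampling.
#' @return list of class `gibbs_config`.
#' @export
gibbs_config <- function(iterations = 12000L, thinning = 5L, burn_in = 2000L,
                         seed = NULL) {
  if (burn_in >= iterations) stop("gibbs_config: burn_in must be < iterations")
  if (thinning < 1) stop("gibbs_config: thinning must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 thinning = as.integer(thinning),
                 burn_in = as.integer(burn_in), seed = seed),
            class = "gibbs_config")
}

#' Build the marker-derived kernel bundle
#'
#' Standardizes the dosage matrix (column mean 0, SD 1; monomorphic markers
#' dropped), and computes the genomic relationship matrix G = MM'/m, the
#' average squared-Euclidean distance matrix D between genotypes, and the
#' Gaussian kernels K_l = exp(-h_l D) for the requested bandwidths.
#'
#' @param genotypes a `gx_geno` or an n x m dosage matrix with rownames.
#' @param bandwidths Gaussian-kernel bandwidths h.
#' @param standardize center and scale the columns (set to `FALSE` when the
#'   matrix is already standardized).
#' @return list of class `kernel_bundle`: `M` (standardized), `G`, `D`,
#'   `K` (named list per bandwidth), `bandwidths`, `n_dropped`.
#' @export
build_kernels <- function(genotypes, bandwidths = c(0.1, 0.5, 2.5),
                          standardize = TRUE) {
  X <- if (inherits(genotypes, "gx_geno")) genotypes$dosage else as.matrix(genotypes)
  if (nrow(X) < 2) stop("build_kernels: need at least two genotypes")
  drop <- logical(ncol(X))
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    drop <- sds == 0
    if (any(drop)) {
      message(sprintf("build_kernels: dropping %d monomorphic marker(s)", sum(drop)))
      X <- X[, !drop, drop = FALSE]
      sds <- sds[!drop]
    }
    M <- scale(X, center = TRUE, scale = sds)
    attr(M, "scaled:center") <- NULL; attr(M, "scaled:scale") <- NULL
  } else M <- X
  m <- ncol(M)
  G <- tcrossprod(M) / m
  sq <- diag(G)
  D <- outer(sq, sq, "+") - 2 * G
  D[D < 0] <- 0
  diag(D) <- 0
  K <- lapply(bandwidths, function(h) exp(-h * D))
  names(K) <- paste0("h=", bandwidths)
  structure(list(M = M, G = G, D = D, K = K, bandwidths = bandwidths,
                 n_dropped = sum(drop)), class = "kernel_bundle")
}

# Shared eigen machinery: decompose a PSD kernel once, flag usable components.
gx_eigen <- function(K, tol = 1e-8) {
  K <- as.matrix(K)
  if (max(abs(K - t(K))) > 1e-6 * max(1, max(abs(K))))
    stop("kernel/relationship matrix is not symmetric")
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("kernel/relationship matrix is not positive semi-definite")
  pos <- eg$values > tol * max(eg$values, 1)
  list(U = eg$vectors, d = pmax(eg$values, 0), pos = pos)
}

# scaled-inverse-chi-square draw: (ss + nu*S) / rchisq(nu + df)
riscaled <- function(ss, df, nu, S) (ss + nu * S) / stats::rchisq(1, nu + df)

# prior scales: mode of scaled-inv-chisq(nu, S) = nu*S/(nu+2); aim the mode
# at `frac` of the observed response variance
gx_prior_scale <- function(vy, nu, frac = 0.5) vy * frac * (nu + 2) / nu

#' G-BLUP by Gibbs sampling
#'
#' Fits y = 1 mu + u + e with u ~ N(0, G sigma_u^2) in the eigenbasis of G.
#' Missing responses are imputed by data augmentation, so masked genotypes
#' get predictions from their relationship to the training set.
#'
#' @param y response (length n, NA = masked).
#' @param G n x n genomic relationship matrix (PSD).
#' @param config a [gibbs_config()].
#' @param nu prior degrees of freedom for the variance components.
#' @return list of class `gx_fit`: `u` (posterior-mean genetic values), `mu`,
#'   `yhat` = mu + u, `samples` (sigma_u2, sigma_e2, h2 per retained
#'   iteration), `variance` (posterior means).
#' @export
fit_gblup <- function(y, G, config = gibbs_config(), nu = 5) {
  n <- length(y)
  stopifnot(nrow(G) == n, ncol(G) == n)
  if (!is.null(config$seed)) set.seed(config$seed)
  eg <- gx_eigen(G)
  U <- eg$U; d <- eg$d; pos <- eg$pos
  miss <- which(is.na(y))
  vy <- stats::var(y, na.rm = TRUE)
  if (!is.finite(vy) || vy <= 0) vy <- 1e-8
  Se <- gx_prior_scale(vy, nu)
  Su <- gx_prior_scale(vy, nu) / mean(d[pos])
  ycur <- y
  ycur[miss] <- mean(y, na.rm = TRUE)
  mu <- mean(ycur); sigma_e2 <- vy / 2; sigma_u2 <- vy / 2 / mean(d[pos])
  v <- numeric(n)
  Ut1 <- drop(crossprod(U, rep(1, n)))
  yt <- drop(crossprod(U, ycur))

  it <- config$iterations; keep_from <- config$burn_in
  u_sum <- numeric(n); mu_sum <- 0
  s_u2 <- s_e2 <- s_h2 <- numeric(0)
  for (t in seq_len(it)) {
    et <- yt - mu * Ut1 - v
    mu_new <- mu + sum(Ut1 * et) / n + stats::rnorm(1, 0, sqrt(sigma_e2 / n))
    et <- et - (mu_new - mu) * Ut1
    mu <- mu_new
    prec <- 1 / sigma_e2 + ifelse(pos, 1 / (d * sigma_u2), Inf)
    mean_v <- (et + v) / sigma_e2 / prec
    v <- ifelse(pos, mean_v + stats::rnorm(n) / sqrt(prec), 0)
    sigma_u2 <- riscaled(sum(v[pos]^2 / d[pos]), sum(pos), nu, Su)
    resid <- yt - mu * Ut1 - v
    sigma_e2 <- riscaled(sum(resid^2), n, nu, Se)
    if (length(miss)) {
      u_full <- drop(U %*% v)
      ycur[miss] <- mu + u_full[miss] +
        stats::rnorm(length(miss), 0, sqrt(sigma_e2))
      yt <- drop(crossprod(U, ycur))
    }
    if (t > keep_from && (t - keep_from) %% config$thinning == 0) {
      u_full <- drop(U %*% v)
      u_sum <- u_sum + u_full; mu_sum <- mu_sum + mu
      vg <- mean((u_full - mean(u_full))^2)
      s_u2 <- c(s_u2, sigma_u2); s_e2 <- c(s_e2, sigma_e2)
      s_h2 <- c(s_h2, vg / (vg + sigma_e2))
    }
  }
  kept <- length(s_u2)
  u_hat <- u_sum / kept
  names(u_hat) <- names(y)
  structure(list(model = "gblup", u = u_hat, mu = mu_sum / kept,
                 yhat = mu_sum / kept + u_hat,
                 samples = data.frame(sigma_u2 = s_u2, sigma_e2 = s_e2, h2 = s_h2),
                 variance = c(sigma_u2 = mean(s_u2), sigma_e2 = mean(s_e2)),
                 kept = kept), class = "gx_fit")
}

#' @export
print.gx_fit <- function(x, ...) {
  cat(sprintf("gx_fit [%s]: %d genetic values, %d retained samples\n",
              x$model, length(x$u), x$kept))
  if (!is.null(x$variance)) print(round(unlist(x$variance), 4))
  invisible(x)
}

#' Multi-kernel RKHS regression by Gibbs sampling
#'
#' y = 1 mu + sum_l u_l + e with u_l ~ N(0, K_l sigma_ul^2); each kernel gets
#' its own variance, sampled in its own eigenbasis.
#'
#' @param y response (NA = masked).
#' @param kernels list of n x n PSD kernels (e.g. `build_kernels()$K`).
#' @param config a [gibbs_config()].
#' @param nu prior degrees of freedom.
#' @return A `gx_fit`; `u` is the posterior mean of the summed kernel
#'   effects, `u_l` the per-kernel posterior means.
#' @export
fit_rkhs_multikernel <- function(y, kernels, config = gibbs_config(), nu = 5) {
  n <- length(y)
  if (!is.list(kernels)) kernels <- list(kernels)
  L <- length(kernels)
  if (any(vapply(kernels, function(K) nrow(K) != n || ncol(K) != n, TRUE)))
    stop("fit_rkhs_multikernel: kernel dimensions do not match response")
  if (!is.null(config$seed)) set.seed(config$seed)
  egs <- lapply(kernels, gx_eigen)
  miss <- which(is.na(y))
  vy <- stats::var(y, na.rm = TRUE); if (!is.finite(vy) || vy <= 0) vy <- 1e-8
  Se <- gx_prior_scale(vy, nu)
  Sl <- vapply(egs, function(e) gx_prior_scale(vy, nu, 0.5 / L) / mean(e$d[e$pos]),
               numeric(1))
  ycur <- y; ycur[miss] <- mean(y, na.rm = TRUE)
  mu <- mean(ycur)
  u <- matrix(0, n, L)
  s2 <- rep(vy / (2 * L), L); sigma_e2 <- vy / 2

  it <- config$iterations
  u_sum <- numeric(n); ul_sum <- matrix(0, n, L); mu_sum <- 0
  s_e2 <- s_h2 <- numeric(0); s_ul <- NULL
  for (t in seq_len(it)) {
    utot <- rowSums(u)
    mu <- mean(ycur - utot) + stats::rnorm(1, 0, sqrt(sigma_e2 / n))
    for (l in seq_len(L)) {
      r_l <- ycur - mu - rowSums(u[, -l, drop = FALSE])
      rt <- drop(crossprod(egs[[l]]$U, r_l))
      d <- egs[[l]]$d; pos <- egs[[l]]$pos
      prec <- 1 / sigma_e2 + ifelse(pos, 1 / (d * s2[l]), Inf)
      vmean <- rt / sigma_e2 / prec
      v <- ifelse(pos, vmean + stats::rnorm(n) / sqrt(prec), 0)
      u[, l] <- drop(egs[[l]]$U %*% v)
      s2[l] <- riscaled(sum(v[pos]^2 / d[pos]), sum(pos), nu, Sl[l])
    }
    utot <- rowSums(u)
    resid <- ycur - mu - utot
    sigma_e2 <- riscaled(sum(resid^2), n, nu, Se)
    if (length(miss))
      ycur[miss] <- mu + utot[miss] + stats::rnorm(length(miss), 0, sqrt(sigma_e2))
    if (t > config$burn_in && (t - config$burn_in) %% config$thinning == 0) {
      u_sum <- u_sum + utot; ul_sum <- ul_sum + u; mu_sum <- mu_sum + mu
      vg <- mean((utot - mean(utot))^2)
      s_e2 <- c(s_e2, sigma_e2); s_h2 <- c(s_h2, vg / (vg + sigma_e2))
      s_ul <- rbind(s_ul, s2)
    }
  }
  kept <- length(s_e2)
  u_hat <- u_sum / kept; names(u_hat) <- names(y)
  colnames(ul_sum) <- names(kernels)
  structure(list(model = "rkhs", u = u_hat, u_l = ul_sum / kept,
                 mu = mu_sum / kept, yhat = mu_sum / kept + u_hat,
                 samples = data.frame(sigma_e2 = s_e2, h2 = s_h2),
                 variance = c(colMeans(s_ul), sigma_e2 = mean(s_e2)),
                 kept = kept), class = "gx_fit")
}

#' BayesC-pi whole-genome regression
#'
#' Spike-and-slab Gibbs sampler over marker effects: each marker has zero
#' effect with probability pi (uniform prior, Beta full conditional) and
#' otherwise a normal effect with common variance. Inner loop in C++.
#'
#' @param y response (NA = masked).
#' @param M n x m marker matrix (standardized dosages recommended; see
#'   [build_kernels()]).
#' @param config a [gibbs_config()].
#' @param nu prior degrees of freedom for the variance components.
#' @return A `gx_fit` with `u` (posterior-mean genetic values M a), marker
#'   `effects`, `inclusion` probabilities, and per-iteration `samples`
#'   (h2, pi, variances, number of included markers).
#' @export
fit_bayescpi <- function(y, M, config = gibbs_config(), nu = 5) {
  M <- as.matrix(M)
  n <- length(y)
  if (nrow(M) != n) stop("fit_bayescpi: dimensions of y and M differ")
  if (ncol(M) == 0) stop("fit_bayescpi: no markers")
  if (!is.null(config$seed)) set.seed(config$seed)
  miss <- which(is.na(y))
  vy <- stats::var(y, na.rm = TRUE); if (!is.finite(vy) || vy <= 0) vy <- 1e-8
  Se <- gx_prior_scale(vy, nu)
  msx <- sum(apply(M, 2, stats::var))
  Sa <- gx_prior_scale(vy, nu) / (0.5 * max(msx, 1e-8))
  res <- bayescpi_gibbs(ifelse(is.na(y), 0, y), M, miss - 1L,
                        config$iterations, config$burn_in, config$thinning,
                        nu, Se, Sa)
  u <- drop(res$u); names(u) <- names(y)
  structure(list(model = "bayescpi", u = u, mu = mean(res$samples$mu),
                 yhat = mean(res$samples$mu) + u,
                 effects = drop(res$effects), inclusion = drop(res$inclusion),
                 samples = res$samples,
                 variance = c(sigma_a2 = mean(res$samples$sigma_a2),
                              sigma_e2 = mean(res$samples$sigma_e2),
                              pi = mean(res$samples$pi)),
                 kept = res$kept), class = "gx_fit")
}

#' Genomic heritability from a Bayesian whole-genome fit
#'
#' h2 = Vg / (Vg + Ve) computed per retained Gibbs iteration (Vg = variance
#' of the marker-explained genetic values across genotypes, Ve = current
#' residual variance) and averaged over iterations.
#'
#' @param fit a `gx_fit` with an `h2` column in `samples`
#'   (from [fit_bayescpi()], [fit_gblup()] or [fit_rkhs_multikernel()]).
#' @return posterior-mean genomic heritability in \[0, 1\].
#' @export
genomic_heritability <- function(fit) {
  if (is.null(fit$samples) || is.null(fit$samples$h2) || nrow(fit$samples) == 0)
    stop("genomic_heritability: fit carries no retained samples")
  mean(fit$samples$h2)
}

#' Random-forest genomic prediction
#'
#' Thin wrapper around `ranger` configured for genomic data: 500 trees and
#' mtry = floor(m/3). Trains on the non-missing responses and predicts all
#' genotypes.
#'
#' @param y response (NA = masked).
#' @param M marker matrix.
#' @param n_trees number of trees.
#' @param mtry candidate variables per split; default floor(m/3), clamped to
#'   1 (with a warning) when m < 3.
#' @param seed integer seed for the forest.
#' @return A `gx_fit` with `u` = predictions centered on the training mean
#'   and `yhat` = raw predictions.
#' @export
fit_rf <- function(y, M, n_trees = 500L, mtry = NULL, seed = 1L) {
  M <- as.matrix(M)
  m <- ncol(M)
  if (is.null(mtry)) mtry <- floor(m / 3)
  if (mtry < 1) {
    warning("fit_rf: m < 3; mtry clamped to 1")
    mtry <- 1L
  }
  obs <- which(!is.na(y))
  df <- data.frame(y = y[obs])
  rf <- ranger::ranger(x = M[obs, , drop = FALSE], y = y[obs],
                       num.trees = n_trees, mtry = mtry, seed = seed)
  pred <- stats::predict(rf, data = M)$predictions
  names(pred) <- names(y)
  mu <- mean(y[obs])
  structure(list(model = "rf", u = pred - mu, mu = mu, yhat = pred,
                 samples = NULL, variance = NULL, kept = 0L,
                 forest = rf), class = "gx_fit")
}

#' Select trait pairs for the bivariate model by breeding-value correlation
#'
#' Runs single-trait G-BLUP per trait and returns the pairs whose genomic
#' breeding-value correlation exceeds the threshold.
#'
#' @param Y genotype x trait matrix of responses.
#' @param G genomic relationship matrix.
#' @param config a [gibbs_config()].
#' @param threshold minimum absolute GEBV correlation (default 0.3 on the
#'   positive side, matching the pairing rule).
#' @return data.frame trait1, trait2, gebv_cor for retained pairs.
#' @export
select_trait_pairs <- function(Y, G, config = gibbs_config(), threshold = 0.3) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 2) stop("select_trait_pairs: need >= 2 traits")
  gebv <- sapply(colnames(Y), function(tn) fit_gblup(Y[, tn], G, config)$u)
  cc <- stats::cor(gebv)
  pairs <- which(upper.tri(cc) & cc > threshold, arr.ind = TRUE)
  data.frame(trait1 = colnames(Y)[pairs[, 1]], trait2 = colnames(Y)[pairs[, 2]],
             gebv_cor = cc[pairs])
}

#' Bivariate genomic prediction with an unstructured covariance
#'
#' Two-trait model y = mu + u + e with u ~ N(0, U x G) (U an unstructured
#' 2 x 2 genetic covariance) and e ~ N(0, R x I); inverse-Wishart updates for
#' U and R, genotype effects sampled in the eigenbasis of G. Intended for
#' trait pairs with genomic breeding-value correlation > 0.3
#' (see [select_trait_pairs()]).
#'
#' @param Y n x 2 matrix of the two traits (NA = masked cells).
#' @param G genomic relationship matrix.
#' @param config a [gibbs_config()].
#' @return A `gx_mtm` fit: `u` (n x 2 posterior-mean breeding values), `mu`,
#'   `Sigma_t` (posterior-mean U), `R`, `genetic_cor`.
#' @export
fit_mtm_un <- function(Y, G, config = gibbs_config()) {
  Y <- as.matrix(Y)
  if (ncol(Y) != 2) stop("fit_mtm_un: exactly two traits are required")
  mtm_gibbs(Y, G, structure = "UN", config = config)
}
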