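# Multivariate Gaussian Gibbs sampler behind fit_mtm_un (unstructured
# genetic covariance, 2 traits) and fit_mtm_fa (factor-analytic covariance
# across environments).
#
# Model: Y (n x t), row i: y_i = mu + u_i + e_i with
#   u ~ N(0, Sigma_t (x) G),  e_i ~ N(0, R).
# Genotype effects are sampled in the eigenbasis of G; within an iteration
# the trait dimension is whitened by the generalized eigendecomposition of
# (Sigma_t, R), which makes all n x t effect draws elementwise. Kronecker
# matrices are never formed. Missing cells are imputed from the conditional
# normal of R given the observed cells of the same genotype.
mtm_gibbs <- function(Y, G, structure = c("UN", "FA"), n_factors = 1L,
                      config = gibbs_config(), nu = 5,
                      loading_prior_var = 100) {
  structure <- match.arg(structure)
  Y <- as.matrix(Y)
  n <- nrow(Y); t <- ncol(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("t", seq_len(t))
  stopifnot(nrow(G) == n, ncol(G) == n)
  if (!is.null(config$seed)) set.seed(config$seed)

  eg <- gx_eigen(G)
  U <- eg$U; d <- eg$d; pos <- eg$pos
  npos <- sum(pos)
  Ut1 <- drop(crossprod(U, rep(1, n)))
  vy <- apply(Y, 2, stats::var, na.rm = TRUE)
  vy[!is.finite(vy) | vy <= 0] <- 1e-8

  miss <- is.na(Y)
  Ycur <- Y
  for (j in seq_len(t)) Ycur[miss[, j], j] <- mean(Y[, j], na.rm = TRUE)
  pat <- apply(miss, 1, function(z) paste(as.integer(z), collapse = ""))
  pat_groups <- split(seq_len(n), pat)
  pat_groups <- pat_groups[vapply(names(pat_groups),
                                  function(k) grepl("1", k), TRUE)]

  mu <- colMeans(Ycur)
  Sigma_t <- diag(vy / 2, t)
  R <- diag(vy / 2, t)
  nf <- as.integer(n_factors)
  B <- matrix(0.1, t, nf)
  psi <- vy / 4
  if (structure == "FA") Sigma_t <- tcrossprod(B) + diag(psi, t)
  Vt <- matrix(0, n, t)
  mean_d <- mean(d[pos])
  Spsi <- gx_prior_scale(vy, nu, 0.25) / mean_d
  nu0 <- t + 2
  S0 <- diag(t)

  riwish <- function(df, S) {
    W <- stats::rWishart(1, df, solve(S))[, , 1]
    solve(W)
  }

  it <- config$iterations
  U_sum <- matrix(0, n, t); mu_sum <- numeric(t)
  St_sum <- matrix(0, t, t); R_sum <- matrix(0, t, t)
  B_sum <- matrix(0, t, nf); psi_sum <- numeric(t)
  kept <- 0L
  for (iter in seq_len(it)) {
    Ytc <- crossprod(U, Ycur) - tcrossprod(Ut1, mu)

    # whiten the trait dimension: W'RW = I, W'Sigma_t W = Lambda
    Lr <- chol(R)
    T0 <- backsolve(Lr, diag(t))
    Sw <- crossprod(T0, Sigma_t %*% T0)
    ew <- eigen((Sw + t(Sw)) / 2, symmetric = TRUE)
    lam <- pmax(ew$values, 1e-10)
    W <- T0 %*% ew$vectors

    Ystar <- Ytc %*% W
    Pmat <- 1 + 1 / outer(d, lam)
    Vstar <- Ystar / Pmat + matrix(stats::rnorm(n * t), n, t) / sqrt(Pmat)
    Vstar[!pos, ] <- 0
    Vt <- Vstar %*% solve(W)

    Ug <- U %*% Vt
    E <- Ycur - Ug
    mu <- colMeans(E) + drop(crossprod(chol(R), stats::rnorm(t))) / sqrt(n)

    if (structure == "UN") {
      Sv <- crossprod(Vt[pos, , drop = FALSE], Vt[pos, , drop = FALSE] / d[pos])
      Sigma_t <- riwish(nu0 + npos, S0 + Sv)
    } else {
      Aq <- diag(nf) + crossprod(B, B / psi)
      Aq_inv <- solve(Aq)
      Fmean <- Vt %*% t(Aq_inv %*% t(B / psi))
      Fm <- Fmean + (matrix(stats::rnorm(n * nf), n, nf) %*%
                       chol(Aq_inv)) * sqrt(d)
      Fm[!pos, ] <- 0
      FtF <- crossprod(Fm[pos, , drop = FALSE], Fm[pos, , drop = FALSE] / d[pos])
      for (j in seq_len(t)) {
        precB <- FtF / psi[j] + diag(nf) / loading_prior_var
        rhsB <- crossprod(Fm[pos, , drop = FALSE],
                          Vt[pos, j] / d[pos]) / psi[j]
        cB <- chol(precB)
        B[j, ] <- backsolve(cB, forwardsolve(t(cB), rhsB) +
                              stats::rnorm(nf))
        resid <- Vt[pos, j] - Fm[pos, , drop = FALSE] %*% B[j, ]
        psi[j] <- riscaled(sum(resid^2 / d[pos]), npos, nu, Spsi[j])
      }
      for (q in seq_len(nf)) if (B[1, q] < 0) {
        B[, q] <- -B[, q]; Fm[, q] <- -Fm[, q]
      }
      Sigma_t <- tcrossprod(B) + diag(psi, t)
    }

    Et <- Ytc - Vt
    R <- riwish(nu0 + n, S0 + crossprod(Et))

    for (idx in pat_groups) {
      mzz <- miss[idx[1], ]
      obs <- which(!mzz); ms <- which(mzz)
      mean_m <- sweep(Ug[idx, ms, drop = FALSE], 2, mu[ms], "+")
      if (length(obs)) {
        Eobs <- Ycur[idx, obs, drop = FALSE] -
          sweep(Ug[idx, obs, drop = FALSE], 2, mu[obs], "+")
        Roo_i <- solve(R[obs, obs, drop = FALSE])
        mean_m <- mean_m + Eobs %*% t(R[ms, obs, drop = FALSE] %*% Roo_i)
        Cv <- R[ms, ms, drop = FALSE] -
          R[ms, obs, drop = FALSE] %*% Roo_i %*% R[obs, ms, drop = FALSE]
      } else Cv <- R[ms, ms, drop = FALSE]
      Cv <- (Cv + t(Cv)) / 2
      draw <- matrix(stats::rnorm(length(idx) * length(ms)),
                     length(idx)) %*% chol(Cv + diag(1e-10, length(ms)))
      Ycur[idx, ms] <- mean_m + draw
    }

    if (iter > config$burn_in &&
        (iter - config$burn_in) %% config$thinning == 0) {
      kept <- kept + 1L
      U_sum <- U_sum + Ug; mu_sum <- mu_sum + mu
      St_sum <- St_sum + Sigma_t; R_sum <- R_sum + R
      if (structure == "FA") { B_sum <- B_sum + B; psi_sum <- psi_sum + psi }
    }
  }
  u <- U_sum / kept
  dimnames(u) <- dimnames(Y)
  St <- St_sum / kept
  dimnames(St) <- list(colnames(Y), colnames(Y))
  gcor <- stats::cov2cor(St)
  out <- list(model = if (structure == "UN") "mtm_un" else "mtm_fa",
              u = u, mu = mu_sum / kept,
              yhat = sweep(u, 2, mu_sum / kept, "+"),
              Sigma_t = St, R = R_sum / kept, genetic_cor = gcor,
              kept = kept)
  if (structure == "FA") {
    out$loadings <- B_sum / kept
    out$psi <- psi_sum / kept
    out$C <- St
  }
  structure(out, class = c("gx_mtm", "gx_fit"))
}
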