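#' Stack a genotype-by-environment response table
#'
#' Converts a genotype x environment matrix of adjusted phenotypic values to
#' the stacked vector form used by the multi-environment models, flagging
#' missing cells explicitly.
#'
#' @param Y genotype x environment matrix (dimnames required).
#' @return data.frame genotype, environment, value with attribute `dim_info`.
#' @export
stack_environments <- function(Y) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y)) || is.null(colnames(Y)))
    stop("stack_environments: Y needs genotype rownames and environment colnames")
  out <- data.frame(genotype = rep(rownames(Y), ncol(Y)),
                    environment = rep(colnames(Y), each = nrow(Y)),
                    value = as.vector(Y), stringsAsFactors = FALSE)
  attr(out, "dim_info") <- dim(Y)
  out
}

#' Across-environment covariance structures (explicit form)
#'
#' Materializes G0 = J (x) G (shared genetic effects) and the block-diagonal
#' G1 = diag(sigma_uj^2 G) of the marker-by-environment interaction model.
#' Intended for inspection and testing on small problems; the samplers never
#' build these matrices.
#'
#' @param G n x n relationship matrix.
#' @param r number of environments.
#' @param sigma_u02 shared-effect variance multiplying G0.
#' @param sigma_uj2 vector (length r) of environment-specific variances.
#' @return list with `G0` and `G1`, both nr x nr.
#' @export
env_covariance <- function(G, r, sigma_u02 = 1, sigma_uj2 = rep(1, r)) {
  J <- matrix(1, r, r)
  G0 <- sigma_u02 * kronecker(J, G)
  G1 <- matrix(0, r * nrow(G), r * nrow(G))
  for (j in seq_len(r)) {
    idx <- (j - 1) * nrow(G) + seq_len(nrow(G))
    G1[idx, idx] <- sigma_uj2[j] * G
  }
  list(G0 = G0, G1 = G1)
}

# Shared sampler for the across-environment G-BLUP (shared effects only)
# and the marker-by-environment interaction extension (shared + deviation
# effects). Everything runs in the eigenbasis of G; per-environment
# intercepts; iid residuals; masked cells imputed by augmentation.
gblup_env_gibbs <- function(Y, G, interaction, config, nu = 5) {
  Y <- as.matrix(Y)
  n <- nrow(Y); r <- ncol(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("env", seq_len(r))
  stopifnot(nrow(G) == n, ncol(G) == n)
  empty <- colSums(!is.na(Y)) == 0
  if (any(empty)) {
    warning("dropping environment(s) with no data: ",
            paste(colnames(Y)[empty], collapse = ", "))
    Y <- Y[, !empty, drop = FALSE]
    r <- ncol(Y)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  eg <- gx_eigen(G)
  U <- eg$U; d <- eg$d; pos <- eg$pos
  npos <- sum(pos)
  Ut1 <- drop(crossprod(U, rep(1, n)))
  miss <- is.na(Y)
  vy <- mean(apply(Y, 2, stats::var, na.rm = TRUE), na.rm = TRUE)
  if (!is.finite(vy) || vy <= 0) vy <- 1e-8
  mean_d <- mean(d[pos])
  Se <- gx_prior_scale(vy, nu)
  S0p <- gx_prior_scale(vy, nu, 0.25) / mean_d
  Sjp <- gx_prior_scale(vy, nu, 0.25) / mean_d

  Ycur <- Y
  for (j in seq_len(r)) Ycur[miss[, j], j] <- mean(Y[, j], na.rm = TRUE)
  mu <- colMeans(Ycur)
  v0 <- numeric(n)
  V1 <- matrix(0, n, r)
  s0 <- vy / 4 / mean_d
  sj <- rep(vy / 8 / mean_d, r)
  sigma_e2 <- vy / 2
  any_miss <- any(miss)

  it <- config$iterations
  u_sum <- matrix(0, n, r); mu_sum <- numeric(r)
  s_s0 <- s_e2 <- numeric(0); s_sj <- NULL
  kept <- 0L
  for (iter in seq_len(it)) {
    Yt <- crossprod(U, Ycur)
    Ytc <- Yt - tcrossprod(Ut1, mu)

    # shared genetic component
    res0 <- Ytc - V1
    prec0 <- r / sigma_e2 + ifelse(pos, 1 / (d * s0), Inf)
    m0 <- rowSums(res0) / sigma_e2 / prec0
    v0 <- ifelse(pos, m0 + stats::rnorm(n) / sqrt(prec0), 0)
    s0 <- riscaled(sum(v0[pos]^2 / d[pos]), npos, nu, S0p)

    # environment-specific deviations
    if (interaction) {
      res1 <- Ytc - v0
      prec1 <- 1 / sigma_e2 + 1 / outer(d, sj)
      prec1[!pos, ] <- Inf
      m1 <- (res1 / sigma_e2) / prec1
      V1 <- m1 + matrix(stats::rnorm(n * r), n, r) / sqrt(prec1)
      V1[!pos, ] <- 0
      for (j in seq_len(r))
        sj[j] <- riscaled(sum(V1[pos, j]^2 / d[pos]), npos, nu, Sjp)
    }

    resid <- Ytc - v0 - V1
    sigma_e2 <- riscaled(sum(resid^2), n * r, nu, Se)

    # intercepts
    for (j in seq_len(r)) {
      mj <- sum(Ut1 * (Yt[, j] - v0 - V1[, j])) / n
      mu[j] <- mj + stats::rnorm(1, 0, sqrt(sigma_e2 / n))
    }

    Ug <- U %*% (v0 + V1)
    if (any_miss) {
      for (j in seq_len(r)) {
        mi <- miss[, j]
        if (any(mi))
          Ycur[mi, j] <- mu[j] + Ug[mi, j] +
            stats::rnorm(sum(mi), 0, sqrt(sigma_e2))
      }
    }

    if (iter > config$burn_in &&
        (iter - config$burn_in) %% config$thinning == 0) {
      kept <- kept + 1L
      u_sum <- u_sum + Ug; mu_sum <- mu_sum + mu
      s_s0 <- c(s_s0, s0 * mean_d); s_e2 <- c(s_e2, sigma_e2)
      if (interaction) s_sj <- rbind(s_sj, sj * mean_d)
    }
  }
  u <- u_sum / kept
  dimnames(u) <- dimnames(Y)
  vout <- c(sigma_u02 = mean(s_s0), sigma_e2 = mean(s_e2))
  if (interaction) {
    sjm <- colMeans(s_sj)
    names(sjm) <- paste0("sigma_u2.", colnames(Y))
    vout <- c(vout, sjm)
  }
  structure(list(model = if (interaction) "gblup_e_gxe" else "gblup_e",
                 u = u, mu = mu_sum / kept,
                 yhat = sweep(u, 2, mu_sum / kept, "+"),
                 samples = data.frame(sigma_u02 = s_s0, sigma_e2 = s_e2),
                 variance = vout, kept = kept), class = "gx_fit")
}

#' Across-environment G-BLUP (shared marker effects)
#'
#' Multi-environment model with genetic effects common to all environments:
#' u ~ N(0, G0 sigma_u0^2) with G0 = J (x) G, plus per-environment
#' intercepts and iid residuals. Equivalent to one shared genetic value per
#' genotype replicated across environments; the J (x) G Kronecker structure
#' is exploited, never materialized.
#'
#' @param Y genotype x environment matrix of adjusted phenotypic values
#'   (NA = masked/unobserved cells).
#' @param G genomic relationship matrix.
#' @param config a [gibbs_config()].
#' @return A `gx_fit` with `u` (n x r genetic values, identical columns up
#'   to Monte-Carlo error), `mu` (per-environment intercepts), `yhat`.
#' @export
fit_gblup_e <- function(Y, G, config = gibbs_config()) {
  gblup_env_gibbs(Y, G, interaction = FALSE, config = config)
}

#' Marker-by-environment interaction G-BLUP
#'
#' Extends [fit_gblup_e()] with environment-specific genetic deviations:
#' u = u0 + u1, u1 ~ N(0, G1) with block-diagonal G1 = diag(sigma_uj^2 G),
#' allowing marker effects to change across environments while assuming
#' positive cross-environment correlation.
#'
#' @inheritParams fit_gblup_e
#' @return A `gx_fit`; `variance` reports the shared component and the
#'   per-environment deviation variances.
#' @export
fit_gblup_e_gxe <- function(Y, G, config = gibbs_config()) {
  if (ncol(as.matrix(Y)) < 2)
    stop("fit_gblup_e_gxe: interaction model needs >= 2 environments")
  gblup_env_gibbs(Y, G, interaction = TRUE, config = config)
}

#' Factor-analytic multivariate multi-environment model
#'
#' Treats environments as traits: u ~ N(0, C (x) G) with
#' C = BB' + Psi (loadings B, environment-specific variances Psi), Gaussian
#' prior variance 100 on the loadings, unstructured residual covariance
#' across environments. Requires at least three environments; the first
#' loading of each factor is constrained positive for identifiability.
#'
#' @param Y genotype x environment matrix (NA = masked).
#' @param G genomic relationship matrix.
#' @param n_factors number of common factors (default 1).
#' @param config a [gibbs_config()].
#' @param loading_prior_var prior variance of the loadings.
#' @return A `gx_mtm` fit with `loadings`, `psi`, implied covariance `C` and
#'   per-environment breeding values `u`.
#' @export
fit_mtm_fa <- function(Y, G, n_factors = 1L, config = gibbs_config(),
                       loading_prior_var = 100) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 3)
    stop("fit_mtm_fa: the factor-analytic model requires at least three environments")
  mtm_gibbs(Y, G, structure = "FA", n_factors = n_factors, config = config,
            loading_prior_var = loading_prior_var)
}
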