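#' Fit a linear mixed model by REML
#'
#' Generic engine for models of the form \eqn{y = X\beta + \sum_j Z_j u_j +
#' \epsilon}, with \eqn{u_j \sim N(0, \sigma_j^2 K_j)} and \eqn{\epsilon \sim
#' N(0, \sigma_\epsilon^2 I)}. Each random term is either a grouping factor
#' (identity covariance over its levels) or a factor paired with a symmetric
#' positive semi-definite covariance/kernel matrix over its levels.
#'
#' Variance components are estimated by direct maximization of the profiled
#' restricted log-likelihood over the log variance ratios
#' \eqn{\gamma_j = \sigma_j^2/\sigma_\epsilon^2}; every evaluation is one
#' sparse Cholesky factorization of the mixed-model coefficient matrix.
#' Components whose ratio is driven to the lower boundary are reported as 0.
#' BLUPs solve the mixed-model equations at the estimated components.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (defaults to an intercept). Must have
#'   full column rank.
#' @param random named list of random terms. Each element is either a factor
#'   (or something coercible to one) of length `length(y)`, or a list with
#'   elements `factor` and `K`, where `K` is a covariance matrix whose
#'   rows/columns are named by (or aligned with) the factor levels.
#' @param tol relative convergence tolerance passed to the optimizer.
#' @param max_iter maximum number of optimizer iterations.
#' @return An object of class `gx_lmm`: list with `sigma2` (named vector of
#'   variance components, residual last as `"residual"`), `beta`, `blups`
#'   (named list per term, on the original level scale), `fitted_fixed`,
#'   `fitted`, `loglik` (restricted, up to a constant), and `convergence`.
#' @examples
#' y <- c(1, 3, 5, 7)
#' g <- factor(c("a", "a", "b", "b"))
#' fit <- fit_lmm(y, random = list(genotype = g))
#' fit$sigma2  # genotype 7, residual 2 on this balanced toy
#' @export
fit_lmm <- function(y, X = NULL, random, tol = 1e-10, max_iter = 500L) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("fit_lmm: response contains NA; subset before fitting")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("fit_lmm: X and y row counts differ")
  if (qr(X)$rank < ncol(X)) stop("fit_lmm: fixed-effect design is rank deficient")
  if (!is.list(random) || length(random) == 0L)
    stop("fit_lmm: at least one random term is required")
  if (is.null(names(random)) || any(names(random) == ""))
    names(random) <- paste0("term", seq_along(random))

  terms <- lapply(random, gx_random_term, n = n)
  J <- length(terms)
  Z <- do.call(cbind, lapply(terms, `[[`, "Z"))
  qj <- vapply(terms, function(t) ncol(t$Z), integer(1))
  idx <- split(seq_len(sum(qj)), rep(seq_len(J), qj))

  # degenerate response: no variance anywhere
  if (stats::var(y) < 1e-24 * (1 + mean(y)^2)) {
    beta <- qr.coef(qr(X), y)
    blups <- lapply(terms, function(t)
      stats::setNames(numeric(t$nlev), t$levels))
    s2 <- stats::setNames(numeric(J + 1), c(names(random), "residual"))
    return(structure(list(
      sigma2 = s2, beta = beta, blups = blups,
      fitted_fixed = drop(X %*% beta), fitted = drop(X %*% beta),
      loglik = NA_real_,
      convergence = list(code = 0L, iterations = 0L, message = "constant response")),
      class = "gx_lmm"))
  }

  # sparse symmetric form so the Cholesky analysis can be reused across
  # optimizer steps (kernel-rotated terms would otherwise come back dense)
  ZtZ <- methods::as(methods::as(Matrix::forceSymmetric(Matrix::crossprod(Z)),
                                 "generalMatrix"), "CsparseMatrix")
  ZtZ <- Matrix::forceSymmetric(ZtZ)
  ZtX <- Matrix::crossprod(Z, X)
  Zty <- Matrix::crossprod(Z, y)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  p <- ncol(X)

  # -2 * profiled restricted log-likelihood at log-ratios lg
  # H = I + sum_j gamma_j Z_j Z_j'; |H| = |A| * prod gamma_j^qj,
  # A = Z'Z + diag(1/gamma); H^-1 = I - Z A^-1 Z'.
  ch <- NULL
  dev <- function(lg) {
    gamma <- exp(lg)
    dinv <- rep(1 / gamma, qj)
    A <- ZtZ + Matrix::Diagonal(x = dinv)
    if (is.null(ch)) ch <<- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
    else ch <<- Matrix::update(ch, A)
    ldA <- 2 * Matrix::determinant(ch, sqrt = TRUE)$modulus
    S <- Matrix::solve(ch, cbind(ZtX, Zty))
    XtHiX <- XtX - as.matrix(Matrix::crossprod(ZtX, S[, seq_len(p), drop = FALSE]))
    XtHiy <- Xty - as.matrix(Matrix::crossprod(ZtX, S[, p + 1, drop = FALSE]))
    ytHiy <- yty - sum(Zty * S[, p + 1])
    cXtHiX <- tryCatch(chol(XtHiX), error = function(e) NULL)
    if (is.null(cXtHiX)) return(1e10)
    beta <- backsolve(cXtHiX, forwardsolve(t(cXtHiX), XtHiy))
    yPy <- max(ytHiy - sum(XtHiy * beta), 1e-12)
    as.numeric((n - p) * log(yPy) + ldA + sum(qj * lg) +
                 2 * sum(log(diag(cXtHiX))))
  }

  lg0 <- rep(0, J)
  lower <- rep(log(1e-9), J)
  upper <- rep(log(1e7), J)
  opt <- stats::optim(lg0, dev, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(maxit = max_iter, factr = tol / .Machine$double.eps))
  gamma <- exp(opt$par)
  at_zero <- opt$par <= lower + 1e-6

  # final solve at the optimum for estimates and BLUPs
  dinv <- rep(1 / gamma, qj)
  A <- ZtZ + Matrix::Diagonal(x = dinv)
  ch <- Matrix::update(ch, A)
  S <- Matrix::solve(ch, cbind(ZtX, Zty))
  XtHiX <- XtX - as.matrix(Matrix::crossprod(ZtX, S[, seq_len(p), drop = FALSE]))
  XtHiy <- Xty - as.matrix(Matrix::crossprod(ZtX, S[, p + 1, drop = FALSE]))
  ytHiy <- yty - sum(Zty * S[, p + 1])
  beta <- drop(solve(XtHiX, XtHiy))
  names(beta) <- colnames(X)
  yPy <- max(ytHiy - sum(XtHiy * drop(beta)), 0)
  sigma_e2 <- yPy / (n - p)
  sigma2 <- gamma * sigma_e2
  sigma2[at_zero] <- 0

  r <- y - drop(X %*% beta)
  ustar <- as.numeric(Matrix::solve(ch, Matrix::crossprod(Z, r)))
  blups <- vector("list", J)
  fitted_rand <- numeric(n)
  for (j in seq_len(J)) {
    uj <- ustar[idx[[j]]]
    if (at_zero[j]) uj <- uj * 0
    fitted_rand <- fitted_rand + as.numeric(terms[[j]]$Z %*% uj)
    blups[[j]] <- terms[[j]]$to_levels(uj)
  }
  names(blups) <- names(random)

  structure(list(
    sigma2 = stats::setNames(c(sigma2, sigma_e2), c(names(random), "residual")),
    beta = beta,
    blups = blups,
    fitted_fixed = drop(X %*% beta),
    fitted = drop(X %*% beta) + fitted_rand,
    loglik = -opt$value / 2,
    convergence = list(code = opt$convergence, iterations = opt$counts[["function"]],
                       message = if (is.null(opt$message)) "" else opt$message)),
    class = "gx_lmm")
}

#' @export
print.gx_lmm <- function(x, ...) {
  cat("Linear mixed model (REML)\n  variance components:\n")
  print(round(x$sigma2, 6))
  invisible(x)
}

# Normalize one random-term specification into Z (sparse), level names and a
# mapping from the working (possibly kernel-rotated) effects back to levels.
gx_random_term <- function(term, n) {
  K <- NULL
  if (is.list(term) && !is.factor(term)) {
    K <- term$K
    term <- term$factor
  }
  f <- factor(term)
  if (length(f) != n) stop("fit_lmm: random term length differs from response")
  Zf <- Matrix::sparse.model.matrix(~ 0 + f)
  colnames(Zf) <- levels(f)
  if (is.null(K)) {
    return(list(Z = Zf, nlev = nlevels(f), levels = levels(f),
                to_levels = function(u) stats::setNames(u, levels(f))))
  }
  K <- as.matrix(K)
  if (!is.null(rownames(K))) {
    miss <- setdiff(levels(f), rownames(K))
    if (length(miss))
      stop("fit_lmm: covariance matrix lacks levels: ", paste(miss, collapse = ", "))
    K <- K[levels(f), levels(f)]
  } else if (nrow(K) != nlevels(f)) {
    stop("fit_lmm: covariance dimension does not match factor levels")
  }
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stop("fit_lmm: covariance matrix is not symmetric")
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  keep <- eg$values > 1e-8 * max(eg$values, 1)
  if (!any(keep)) stop("fit_lmm: covariance matrix is numerically zero")
  B <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(eg$values[keep]),
                                                 sum(keep))
  Z <- Zf %*% B
  list(Z = Z, nlev = nlevels(f), levels = levels(f),
       to_levels = function(u) stats::setNames(drop(B %*% u), levels(f)))
}
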