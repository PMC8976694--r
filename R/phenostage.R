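#' Adjust tree-level phenotypes for spatial heterogeneity in one environment
#'
#' Fits a low-rank tensor-product P-spline surface over the field plan
#' (second-order difference penalty, smoothing selected by REML) together
#' with a random genotype effect, then removes the estimated surface from
#' each observation. The genotype effect is in the model only so the surface
#' is not contaminated by genetic signal; it is not removed from the values.
#'
#' @param records data.frame with columns genotype, row, col, value
#'   (one environment; filter first, or use the `location`/`year` columns via
#'   `environment_key`).
#' @param environment_key optional c(location, year) pair used to subset
#'   `records`.
#' @param k basis dimension per margin of the tensor product (capped by the
#'   number of distinct rows/columns).
#' @return list of class `gx_adjusted`: `tree` (the input records plus an
#'   `adjusted` column), `genotype` (data.frame genotype, value = mean
#'   adjusted value over its trees), `surface` (fitted spatial component per
#'   record) and `spatial_model` ("psplines" or "none").
#' @export
adjust_spatial <- function(records, environment_key = NULL, k = 8) {
  records <- as.data.frame(records)
  if (!is.null(environment_key)) {
    records <- records[records$location == environment_key[1] &
                         records$year == environment_key[2], , drop = FALSE]
  }
  if (!is.null(records$location)) {
    ek <- unique(paste(records$location, records$year))
    if (length(ek) > 1)
      stop("adjust_spatial: records span several environments; adjust one at a time")
  }
  if (nrow(records) == 0) stop("adjust_spatial: no records")
  records$genotype <- factor(records$genotype)

  no_coords <- is.null(records$row) || is.null(records$col) ||
    anyNA(records$row) || anyNA(records$col)
  if (no_coords) {
    warning("adjust_spatial: missing row/column coordinates; no spatial adjustment applied")
    records$adjusted <- records$value
    surface <- rep(0, nrow(records))
    model <- "none"
  } else {
    kr <- max(3, min(k, length(unique(records$row))))
    kc <- max(3, min(k, length(unique(records$col))))
    fit <- mgcv::gam(value ~ te(row, col, k = c(kr, kc), bs = "ps", m = 2) +
                       s(genotype, bs = "re"),
                     data = records, method = "REML", select = TRUE)
    tt <- stats::predict(fit, type = "terms")
    surface <- tt[, grep("^te\\(row", colnames(tt)), drop = TRUE]
    records$adjusted <- records$value - surface
    model <- "psplines"
  }
  gmean <- tapply(records$adjusted, records$genotype, mean)
  structure(list(
    tree = records,
    genotype = data.frame(genotype = names(gmean), value = as.numeric(gmean),
                          stringsAsFactors = FALSE),
    surface = as.numeric(surface), spatial_model = model),
    class = "gx_adjusted")
}

#' Environment-specific clonal-mean heritability
#'
#' Fits a random-genotype-intercept model to the adjusted tree-level values
#' of one environment and computes \eqn{H^2 = \sigma_g^2 / \sigma_p^2} with
#' \eqn{\sigma_p^2 = \sigma_g^2 + \sigma_\epsilon^2 / \bar{n}_r}, where
#' \eqn{\bar{n}_r} is the mean number of replicate trees per genotype.
#'
#' @param adjusted a `gx_adjusted` from [adjust_spatial()], or a data.frame
#'   with columns genotype and adjusted.
#' @return list of class `gx_h2`: H2, sigma_g2, sigma_e2, sigma_ge2 (NA
#'   here), nbar_r, ne = 1, scope = "environment-specific", flagged.
#' @export
env_clonal_heritability <- function(adjusted) {
  d <- if (inherits(adjusted, "gx_adjusted")) adjusted$tree else as.data.frame(adjusted)
  g <- factor(d$genotype)
  if (nlevels(g) < 2) stop("env_clonal_heritability: need >= 2 genotypes")
  nbar <- length(g) / nlevels(g)
  fit <- fit_lmm(d$adjusted, random = list(genotype = g))
  sg2 <- fit$sigma2[["genotype"]]; se2 <- fit$sigma2[["residual"]]
  flagged <- nbar <= 1 + 1e-12
  if (flagged) warning("env_clonal_heritability: all genotypes single-replicated; residual variance inestimable")
  h2 <- heritability_eq(sg2, se2, sigma_ge2 = 0, ne = 1, nbar_r = nbar)
  structure(list(H2 = h2, sigma_g2 = sg2, sigma_e2 = se2, sigma_ge2 = NA_real_,
                 nbar_r = nbar, ne = 1L, scope = "environment-specific",
                 flagged = flagged, fit = fit), class = "gx_h2")
}

#' Clonal-mean heritability from variance components
#'
#' Direct arithmetic of the heritability formula:
#' \eqn{H^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_{ge}^2/n_e +
#' \sigma_\epsilon^2/(n_e \bar{n}_r))}. With `ne = 1` and no interaction
#' variance this is the environment-specific form.
#'
#' @param sigma_g2,sigma_e2,sigma_ge2 variance components (trait units^2).
#' @param ne number of environments.
#' @param nbar_r mean number of replicates per genotype within environment.
#' @return H2 in \[0, 1\].
#' @export
heritability_eq <- function(sigma_g2, sigma_e2, sigma_ge2 = 0, ne = 1,
                            nbar_r = 1) {
  sp2 <- sigma_g2 + sigma_ge2 / ne + sigma_e2 / (ne * nbar_r)
  if (sp2 <= 0) return(0)
  min(max(sigma_g2 / sp2, 0), 1)
}

#' Across-environment clonal-mean heritability
#'
#' Fits environment (location.year) as fixed and genotype plus
#' genotype-by-environment as random effects on adjusted tree-level values
#' pooled over the retained environments, then applies the across-environment
#' phenotypic-variance formula (see [heritability_eq()]).
#'
#' @param adjusted_tree data.frame with columns genotype, location, year,
#'   adjusted (tree-level adjusted values across >= 2 environments).
#' @return A `gx_h2` with scope "across-environment".
#' @export
across_env_heritability <- function(adjusted_tree) {
  d <- as.data.frame(adjusted_tree)
  d$env <- factor(paste(d$location, d$year, sep = "."))
  ne <- nlevels(d$env)
  if (ne < 2)
    stop("across_env_heritability: needs >= 2 environments; use env_clonal_heritability")
  g <- factor(d$genotype)
  ge <- factor(paste(g, d$env, sep = ":"))
  X <- stats::model.matrix(~ env, d)
  fit <- fit_lmm(d$adjusted, X = X, random = list(genotype = g, gxe = ge))
  sg2 <- fit$sigma2[["genotype"]]; sge2 <- fit$sigma2[["gxe"]]
  se2 <- fit$sigma2[["residual"]]
  nbar <- nrow(d) / nlevels(ge)
  h2 <- heritability_eq(sg2, se2, sge2, ne, nbar)
  structure(list(H2 = h2, sigma_g2 = sg2, sigma_e2 = se2, sigma_ge2 = sge2,
                 nbar_r = nbar, ne = ne, scope = "across-environment",
                 flagged = FALSE, fit = fit), class = "gx_h2")
}

#' @export
print.gx_h2 <- function(x, ...) {
  cat(sprintf("%s clonal-mean heritability: H2 = %.3f (sigma_g2 = %.3g, sigma_ge2 = %s, sigma_e2 = %.3g, ne = %d, nbar_r = %.2f)\n",
              x$scope, x$H2, x$sigma_g2,
              ifelse(is.na(x$sigma_ge2), "-", sprintf("%.3g", x$sigma_ge2)),
              x$sigma_e2, x$ne, x$nbar_r))
  invisible(x)
}

#' Retain environment-trait combinations by heritability
#'
#' A combination is kept iff its heritability is at or above the threshold
#' (strictly-below combinations are eliminated).
#'
#' @param estimates data.frame with columns location, year, trait, H2 (or any
#'   data.frame with an `H2` column).
#' @param threshold heritability threshold (default 0.1).
#' @return The retained rows of `estimates`.
#' @export
filter_low_heritability <- function(estimates, threshold = 0.1) {
  estimates <- as.data.frame(estimates)
  if (nrow(estimates) == 0) return(estimates)
  estimates[estimates$H2 >= threshold, , drop = FALSE]
}

#' Clonal values (genotype BLUPs) from adjusted tree-level data
#'
#' Across-location scope fits location, year and their interaction as fixed
#' effects with random genotype effects; location-specific scope subsets one
#' location and fits year as fixed. Traits flagged for transformation are
#' fitted on the natural log of their values (values <= 0 raise an error).
#' Fixed-effect columns that are constant in the data are dropped.
#'
#' @param adjusted_tree data.frame with columns genotype, location, year,
#'   adjusted (from [adjust_spatial()] per environment, row-bound).
#' @param scope "across-location" or "location-specific".
#' @param location required when scope = "location-specific".
#' @param log_transform apply natural log to the adjusted values first.
#' @return data.frame of class `gx_clonal` with columns genotype, value and
#'   attributes `scope`, `transform`.
#' @export
compute_clonal_values <- function(adjusted_tree,
                                  scope = c("across-location", "location-specific"),
                                  location = NULL, log_transform = FALSE) {
  scope <- match.arg(scope)
  d <- as.data.frame(adjusted_tree)
  if (scope == "location-specific") {
    if (is.null(location)) {
      location <- unique(d$location)
      if (length(location) > 1)
        stop("compute_clonal_values: give `location` for location-specific scope")
    }
    d <- d[d$location == location, , drop = FALSE]
  }
  if (nrow(d) == 0) stop("compute_clonal_values: no data in scope")
  y <- d$adjusted
  if (log_transform) {
    if (any(y <= 0))
      stop("compute_clonal_values: log transform requested but values <= 0 present")
    y <- log(y)
  }
  # fixed effects: location, year and their interaction (across-location) or
  # year (location-specific); single-level factors drop to the intercept
  dd <- data.frame(location = factor(d$location), year = factor(d$year))
  terms <- if (scope == "across-location") {
    c(if (nlevels(dd$location) > 1) "location",
      if (nlevels(dd$year) > 1) "year",
      if (nlevels(dd$location) > 1 && nlevels(dd$year) > 1) "location:year")
  } else {
    if (nlevels(dd$year) > 1) "year"
  }
  fml <- stats::reformulate(if (length(terms)) terms else "1")
  X <- stats::model.matrix(fml, dd)
  if (ncol(X) > 1)
    X <- X[, c(TRUE, apply(X[, -1, drop = FALSE], 2,
                           function(cc) stats::var(cc) > 0)), drop = FALSE]
  if (qr(X)$rank < ncol(X)) X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
  fit <- fit_lmm(y, X = X, random = list(genotype = factor(d$genotype)))
  out <- data.frame(genotype = names(fit$blups$genotype),
                    value = as.numeric(fit$blups$genotype),
                    stringsAsFactors = FALSE)
  structure(out, scope = scope, transform = if (log_transform) "log" else "none",
            location = if (scope == "location-specific") location else NA_character_,
            class = c("gx_clonal", "data.frame"))
}

#' Assemble global clonal values across traits
#'
#' Across-location clonal values, with the addition of location-specific
#' clonal values for traits measured at a single location. Because the two
#' scopes use different fixed effects, elements from different scopes are
#' not strictly comparable; the per-trait scope is recorded in the
#' `"scopes"` attribute.
#'
#' @param clonal_list named list (per trait) of `gx_clonal` data.frames.
#' @return genotype x trait matrix of clonal values (NA where a genotype has
#'   no data for a trait), with attribute `scopes`.
#' @export
global_clonal_values <- function(clonal_list) {
  ids <- sort(unique(unlist(lapply(clonal_list, function(d) d$genotype))))
  out <- matrix(NA_real_, length(ids), length(clonal_list),
                dimnames = list(ids, names(clonal_list)))
  for (tn in names(clonal_list)) {
    d <- clonal_list[[tn]]
    out[d$genotype, tn] <- d$value
  }
  attr(out, "scopes") <- vapply(clonal_list, function(d) attr(d, "scope"), "")
  out
}

#' Trait and environment correlation summaries with PCA
#'
#' Pearson correlations between traits on the clonal-value table
#' (pairwise-complete), Pearson correlations between environments within a
#' trait on genotype-level adjusted values, and PCA scores of the centered,
#' scaled, mean-imputed clonal-value table.
#'
#' @param clonal_table genotype x trait matrix (e.g. from
#'   [global_clonal_values()]).
#' @param env_values optional named list per trait of genotype x environment
#'   matrices of adjusted genotype values.
#' @return list with `trait_cor`, `env_cor` (list per trait or NULL), `pca`
#'   (a `prcomp`) and `scores`.
#' @export
correlation_analysis <- function(clonal_table, env_values = NULL) {
  ct <- as.matrix(clonal_table)
  if (ncol(ct) < 2 && is.null(env_values))
    stop("correlation_analysis: need >= 2 traits or environment-level values")
  sds <- apply(ct, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("correlation_analysis: zero-variance trait(s); correlations reported as NA")
  trait_cor <- suppressWarnings(stats::cor(ct, use = "pairwise.complete.obs"))
  env_cor <- NULL
  if (!is.null(env_values)) {
    env_cor <- lapply(env_values, function(m)
      suppressWarnings(stats::cor(as.matrix(m), use = "pairwise.complete.obs")))
  }
  imp <- apply(ct, 2, function(x) { x[is.na(x)] <- mean(x, na.rm = TRUE); x })
  keep <- apply(imp, 2, stats::sd) > 0
  pca <- stats::prcomp(imp[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  list(trait_cor = trait_cor, env_cor = env_cor, pca = pca, scores = pca$x)
}
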