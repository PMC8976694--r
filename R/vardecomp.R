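#' Decompose phenotypic variance into SNP, genotype, environment, G-by-E and
#' residual parts
#'
#' Fits a mixed model to adjusted tree-level values with environment as a
#' fixed effect and, as random effects, a 3-level dosage-class factor per
#' significantly associated SNP, the remaining genotype effect, and the
#' genotype-by-environment interaction. The environment share is the
#' variance of the fixed-effect fitted values (all random effects zeroed);
#' random shares are their variance components; the residual is the
#' remainder; everything is relative to the total response variance. The sum
#' of the SNP shares and the genotype share is the genotypic variance.
#'
#' @param adjusted_tree data.frame genotype, location, year, adjusted.
#' @param snp_dosages optional genotype x SNP matrix (or data.frame) of
#'   dosage classes for the associated SNPs; omit (NULL) when the trait has
#'   no associations. Constant SNPs are dropped with a warning. With few
#'   dosage levels these variance estimates are uncertain; a warning notes
#'   terms estimated at 0.
#' @return list of class `gx_vardecomp`: `proportions` (named: SNP1..SNPk
#'   sorted descending, genotype, env, gxe, residual), `genotypic`
#'   (SNP sum + genotype), `fit` (the `gx_lmm`), `snp_names`.
#' @export
decompose_variance <- function(adjusted_tree, snp_dosages = NULL) {
  d <- as.data.frame(adjusted_tree)
  d$env <- factor(paste(d$location, d$year, sep = "."))
  g <- factor(d$genotype)
  ge <- factor(paste(g, d$env, sep = ":"))
  X <- stats::model.matrix(~ env, d)

  random <- list()
  snp_names <- character(0)
  if (!is.null(snp_dosages)) {
    snp_dosages <- as.matrix(snp_dosages)
    for (j in seq_len(ncol(snp_dosages))) {
      snp_f <- factor(snp_dosages[as.character(d$genotype), j])
      if (nlevels(snp_f) < 2) {
        warning("decompose_variance: SNP ", colnames(snp_dosages)[j],
                " is constant in the data; term dropped")
        next
      }
      nm <- colnames(snp_dosages)[j]
      if (is.null(nm)) nm <- paste0("SNP", j)
      random[[nm]] <- snp_f
      snp_names <- c(snp_names, nm)
    }
  }
  random$genotype <- g
  random$gxe <- ge

  fit <- fit_lmm(d$adjusted, X = X, random = random)
  vtot <- mean((d$adjusted - mean(d$adjusted))^2)
  env_prop <- mean((fit$fitted_fixed - mean(fit$fitted_fixed))^2) / vtot
  # a 3-level factor's REML component is a superpopulation variance, which
  # over-weights rare dosage classes; the record-level share of each SNP is
  # therefore the realized variance of its fitted class effects
  snp_prop <- vapply(snp_names, function(nm) {
    eff <- fit$blups[[nm]][as.character(random[[nm]])]
    mean((eff - mean(eff))^2) / vtot
  }, numeric(1))
  names(snp_prop) <- snp_names
  if (length(snp_prop)) {
    ord <- order(-snp_prop)
    snp_prop <- snp_prop[ord]
    snp_names <- snp_names[ord]
    if (any(snp_prop == 0))
      warning("decompose_variance: SNP term(s) estimated at zero variance ",
              "(few dosage levels make these estimates uncertain)")
    names(snp_prop) <- paste0("SNP", seq_along(snp_prop))
  }
  g_prop <- fit$sigma2[["genotype"]] / vtot
  ge_prop <- fit$sigma2[["gxe"]] / vtot
  resid_prop <- max(1 - env_prop - sum(snp_prop) - g_prop - ge_prop, 0)
  props <- c(snp_prop, genotype = g_prop, env = env_prop, gxe = ge_prop,
             residual = resid_prop)
  structure(list(proportions = props,
                 genotypic = sum(snp_prop) + g_prop,
                 snp_names = snp_names, fit = fit),
            class = "gx_vardecomp")
}

#' @export
print.gx_vardecomp <- function(x, ...) {
  cat("Phenotypic variance decomposition (proportions of total):\n")
  print(round(x$proportions, 4))
  cat(sprintf("genotypic (SNPs + genotype): %.4f\n", x$genotypic))
  invisible(x)
}

#' Cluster traits by their variance profiles
#'
#' Centers and scales the trait-by-component table (mean 0, SD 1 per
#' column), applies Ward (ward.D2) hierarchical clustering to the Euclidean
#' distance matrix, and cuts the dendrogram where the gap between successive
#' merge heights is largest.
#'
#' @param profiles trait x component numeric table (>= 3 traits); e.g. rows
#'   of `proportions` from [decompose_variance()] restricted to the
#'   genotypic, env, gxe and residual columns.
#' @return list with `labels` (named cluster ids), `k`, `hclust`, `heights`.
#' @export
cluster_traits <- function(profiles) {
  P <- as.matrix(profiles)
  if (nrow(P) < 3)
    stop("cluster_traits: need at least 3 traits (largest-gap cut undefined)")
  sds <- apply(P, 2, stats::sd)
  if (any(sds == 0)) {
    warning("cluster_traits: dropping constant column(s): ",
            paste(colnames(P)[sds == 0], collapse = ", "))
    P <- P[, sds > 0, drop = FALSE]
  }
  Ps <- scale(P)
  hc <- stats::hclust(stats::dist(Ps), method = "ward.D2")
  h <- hc$height
  k <- if (length(h) == 1) 2L else nrow(P) - which.max(diff(h))
  labels <- stats::cutree(hc, k = k)
  list(labels = labels, k = k, hclust = hc, heights = h)
}
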