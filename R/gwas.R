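#' Bonferroni significance threshold on the -log10 scale
#'
#' @param alpha family-wise error rate.
#' @param m number of markers tested.
#' @return -log10(alpha / m).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) -log10(alpha / m)

# Single-marker fixed-effect scan: p-values of each column of M in a
# regression with covariates C, computed from partial correlations after
# projecting C out of both sides. Returns NA for markers constant after
# projection.
fast_assoc <- function(y, M, C) {
  n <- length(y)
  Q <- qr.Q(qr(C))
  yr <- y - Q %*% crossprod(Q, y)
  Mr <- M - Q %*% crossprod(Q, M)
  ssm <- colSums(Mr^2)
  ssy <- sum(yr^2)
  r <- drop(crossprod(Mr, yr)) / sqrt(pmax(ssm * ssy, 1e-300))
  r[ssm < 1e-10] <- NA
  df <- n - ncol(C) - 1
  tt <- r * sqrt(df / pmax(1 - r^2, 1e-12))
  p <- 2 * stats::pt(-abs(tt), df)
  pmin(pmax(p, 1e-300), 1)
}

#' Multi-locus association scan (BLINK-style)
#'
#' Iterative multi-locus GWAS: single-marker fixed-effect tests with
#' principal-component covariates plus the current pseudo-QTNs (any
#' pseudo-QTN in LD with the tested marker is excluded from its test), then
#' reselection of pseudo-QTNs from the p-ranked markers greedily filtered to
#' pairwise LD r-squared below `ld_r2`, with the number of retained
#' pseudo-QTNs chosen by BIC over nested sets. Repeats until the selected
#' set stabilizes or `max_iter` is reached. Markers below the minor allele
#' frequency threshold are excluded; significance is called against the
#' Bonferroni threshold alpha / m over the m tested markers.
#'
#' @param genotypes a `gx_geno` (or dosage matrix; then supply `map`).
#' @param y named numeric vector of clonal values (or a `gx_clonal`
#'   data.frame); names must match genotype ids.
#' @param n_pcs number of principal-component covariates.
#' @param maf_min minor allele frequency threshold.
#' @param alpha family-wise error rate for Bonferroni calling.
#' @param ld_r2 LD r-squared cutoff used both for covariate exclusion and
#'   pseudo-QTN filtering.
#' @param max_iter maximum outer iterations.
#' @param max_qtn cap on candidate pseudo-QTNs (default min(50, n/10)).
#' @param ebic_gamma extended-BIC marker-pool penalty weight in \[0, 1\];
#'   0 recovers the ordinary BIC.
#' @param map marker map (marker, chrom, pos) when `genotypes` is a matrix.
#' @param trait trait label stored on the associations.
#' @param scope scope label ("across-location" or a location).
#' @return An object of class `gx_gwas`: `scan` (all tested markers with p),
#'   `associations` (significant markers with R-squared, effect sign and
#'   chromosome segment), `pseudo_qtns`, `threshold_logp`, `alpha`,
#'   `m_tested`, `iterations`.
#' @export
blink_scan <- function(genotypes, y, n_pcs = 2, maf_min = 0.05, alpha = 0.05,
                       ld_r2 = 0.7, max_iter = 10L, max_qtn = NULL,
                       ebic_gamma = 1, map = NULL, trait = "trait",
                       scope = "across-location") {
  if (inherits(genotypes, "gx_geno")) {
    map <- genotypes$map
    X <- genotypes$dosage
  } else X <- as.matrix(genotypes)
  if (is.null(map)) stop("blink_scan: marker map required")
  if (inherits(y, "gx_clonal") || is.data.frame(y))
    y <- stats::setNames(y$value, y$genotype)
  ids <- intersect(rownames(X), names(y))
  if (length(ids) == 0) stop("blink_scan: no overlap between genotype and phenotype ids")
  X <- X[ids, , drop = FALSE]
  y <- as.numeric(y[ids])
  n <- length(y)

  maf <- colMeans(X) / 2
  maf <- pmin(maf, 1 - maf)
  keep <- maf >= maf_min
  X <- X[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]
  m <- ncol(X)
  if (n <= n_pcs + 2) stop("blink_scan: fewer genotypes than covariates")
  if (is.null(max_qtn)) max_qtn <- max(1L, min(50L, floor(n / 10)))

  Ms <- scale(X)
  Ms[, apply(X, 2, stats::sd) == 0] <- 0
  egG <- eigen(tcrossprod(Ms) / m, symmetric = TRUE)
  PCs <- egG$vectors[, seq_len(n_pcs), drop = FALSE]
  C0 <- cbind(1, PCs)

  S <- integer(0)
  history <- list()
  iter_used <- 0L
  p <- rep(NA_real_, m)
  for (iter in seq_len(max_iter)) {
    iter_used <- iter
    C <- cbind(C0, X[, S, drop = FALSE])
    p <- fast_assoc(y, X, C)
    if (length(S)) {
      ld_with_S <- stats::cor(X[, S, drop = FALSE], X)^2
      affected <- which(apply(ld_with_S >= ld_r2, 2, any))
      for (k in affected) {
        drop_q <- S[ld_with_S[, k] >= ld_r2]
        Ck <- cbind(C0, X[, setdiff(S, drop_q), drop = FALSE])
        p[k] <- fast_assoc(y, X[, k, drop = FALSE], Ck)
      }
    }

    ord <- order(p)
    cand <- integer(0)
    for (k in ord) {
      if (is.na(p[k]) || p[k] > 0.01) break
      if (length(cand) &&
          any(stats::cor(X[, k], X[, cand, drop = FALSE])^2 >= ld_r2)) next
      cand <- c(cand, k)
      if (length(cand) >= max_qtn) break
    }

    # extended BIC over nested candidate sets: the marker-pool term
    # (2 gamma log m per parameter) guards against best-of-m selection bias
    best_k <- 0L; best_bic <- Inf
    for (kk in 0:length(cand)) {
      Ck <- cbind(C0, X[, cand[seq_len(kk)], drop = FALSE])
      rss <- sum(stats::lm.fit(Ck, y)$residuals^2)
      bic <- n * log(rss / n) + ncol(Ck) * (log(n) + 2 * ebic_gamma * log(m))
      if (bic < best_bic) { best_bic <- bic; best_k <- kk }
    }
    S_new <- sort(cand[seq_len(best_k)])
    if (identical(S_new, sort(S))) break
    if (any(vapply(history, identical, TRUE, y = S_new))) { S <- S_new; break }
    history <- c(history, list(sort(S)))
    S <- S_new
  }

  threshold_p <- alpha / m
  scan <- data.frame(marker = map$marker, chrom = map$chrom, pos = map$pos,
                     p_value = p, minus_log10_p = -log10(p),
                     stringsAsFactors = FALSE)
  sig <- which(!is.na(p) & p < threshold_p)
  assoc <- scan[sig, , drop = FALSE]
  if (nrow(assoc)) {
    chrlen <- tapply(map$pos, map$chrom, max)
    assoc$R2 <- vapply(sig, function(k) marker_r2(X[, k], y), numeric(1))
    assoc$effect_sign <- vapply(sig, function(k)
      sign(stats::cov(X[, k], y)), numeric(1))
    assoc$segment <- assign_segment(assoc$pos, chrlen[as.character(assoc$chrom)])
    assoc$trait <- trait
    assoc$scope <- scope
  }
  structure(list(scan = scan, associations = assoc,
                 pseudo_qtns = map$marker[S],
                 threshold_logp = -log10(threshold_p), alpha = alpha,
                 m_tested = m, n = n, iterations = iter_used,
                 trait = trait, scope = scope), class = "gx_gwas")
}

#' @export
print.gx_gwas <- function(x, ...) {
  cat(sprintf("gx_gwas [%s, %s]: %d markers tested, threshold -log10(p) > %.2f, %d significant, %d pseudo-QTN(s)\n",
              x$trait, x$scope, x$m_tested, x$threshold_logp,
              nrow(x$associations), length(x$pseudo_qtns)))
  invisible(x)
}

#' Per-marker coefficient of determination
#'
#' R-squared of the simple linear regression of the response on the marker
#' dosage. Invariant to affine recoding of the dosage (0,1,2 and 1,2,3 give
#' the same value).
#'
#' @param snp numeric dosage vector.
#' @param y response aligned with `snp`.
#' @return R-squared in \[0, 1\].
#' @export
marker_r2 <- function(snp, y) {
  ok <- !is.na(snp) & !is.na(y)
  snp <- snp[ok]; y <- y[ok]
  if (length(y) < 3) stop("marker_r2: need at least 3 genotypes")
  if (stats::sd(snp) == 0) stop("marker_r2: marker is constant")
  if (stats::sd(y) == 0) return(0)
  stats::cor(snp, y)^2
}

#' Assign marker positions to chromosome thirds
#'
#' Chromosomes are divided into three equal segments by physical length
#' (estimated as the position of the last marker): top (<= L/3), center
#' (<= 2L/3) and bottom. Boundary positions go to the lower segment.
#'
#' @param position bp position(s).
#' @param chromosome_length chromosome length(s) in bp (recycled).
#' @return character vector "top"/"center"/"bottom".
#' @export
assign_segment <- function(position, chromosome_length) {
  if (any(position <= 0 | position > chromosome_length))
    stop("assign_segment: position must be in (0, chromosome_length]")
  ifelse(position <= chromosome_length / 3, "top",
         ifelse(position <= 2 * chromosome_length / 3, "center", "bottom"))
}

#' Co-localize associations within a physical window
#'
#' Single-linkage clustering of associations on the same chromosome: two
#' associations join a cluster when their positional gap is strictly below
#' the window. Clusters spanning several traits are flagged.
#'
#' @param assocs data.frame with columns chrom, pos (and optionally trait).
#' @param window window in bp (default 100 kb).
#' @return `assocs` with added `cluster` id, plus attribute `clusters`
#'   summarizing size, span and cross-trait status.
#' @export
colocalize_associations <- function(assocs, window = 1e5) {
  assocs <- as.data.frame(assocs)
  if (nrow(assocs) == 0) {
    assocs$cluster <- integer(0)
    return(assocs)
  }
  ord <- order(assocs$chrom, assocs$pos)
  cl <- integer(nrow(assocs))
  cur <- 0L
  last_chrom <- NULL; last_pos <- -Inf
  for (i in ord) {
    if (is.null(last_chrom) || assocs$chrom[i] != last_chrom ||
        assocs$pos[i] - last_pos >= window) cur <- cur + 1L
    cl[i] <- cur
    last_chrom <- assocs$chrom[i]; last_pos <- assocs$pos[i]
  }
  assocs$cluster <- cl
  summ <- do.call(rbind, lapply(split(seq_len(nrow(assocs)), cl), function(ii) {
    data.frame(cluster = cl[ii[1]], chrom = assocs$chrom[ii[1]],
               n = length(ii), start = min(assocs$pos[ii]),
               end = max(assocs$pos[ii]),
               cross_trait = if (!is.null(assocs$trait))
                 length(unique(assocs$trait[ii])) > 1 else NA)
  }))
  attr(assocs, "clusters") <- summ
  assocs
}

#' Overlap between present and previously published locus catalogs
#'
#' Both sides are reduced to unique (trait_group, chromosome, segment)
#' combinations; the report counts shared, former-only and present-only
#' combinations and the shared/present percentage.
#'
#' @param present data.frame with columns trait_group, chrom, segment.
#' @param former catalog data.frame with the same columns.
#' @return list with `shared`, `former_only`, `present_only` (counts),
#'   `overlap_pct` and the underlying combination tables.
#' @export
catalog_overlap <- function(present, former) {
  norm <- function(d) {
    d <- as.data.frame(d)
    bad <- setdiff(unique(d$segment), c("top", "center", "bottom"))
    if (length(bad))
      stop("catalog_overlap: unknown segment label(s): ", paste(bad, collapse = ", "))
    unique(paste(d$trait_group, d$chrom, d$segment, sep = "|"))
  }
  pres <- norm(present); form <- norm(former)
  shared <- intersect(pres, form)
  list(shared = length(shared), former_only = length(setdiff(form, pres)),
       present_only = length(setdiff(pres, form)),
       overlap_pct = if (length(pres)) 100 * length(shared) / length(pres) else NA_real_,
       shared_combinations = shared, present_combinations = pres,
       former_combinations = form)
}

#' Allele-frequency dynamics over ancestor generations
#'
#' For each association, tracks the frequency of the allele with increasing
#' effect on the phenotype in every recorded ancestor generation and in the
#' progeny group, plus resampled progeny means and standard errors.
#'
#' @param genotypes a `gx_geno` covering the pedigree individuals.
#' @param pedigree data.frame id, parent1, parent2, generation (generation
#'   labels "ancestor_g<k>" and "progeny").
#' @param assocs data.frame with columns marker and effect_sign (e.g. the
#'   `associations` of a [blink_scan()], typically filtered to R2 > 0.1).
#' @param n_resample number of progeny resamples.
#' @param resample_size genotypes per resample.
#' @param seed seed for the resampling.
#' @return data.frame marker, group, frequency, n, plus `resampled_mean` and
#'   `resampled_se` on the progeny rows.
#' @export
allele_frequency_dynamics <- function(genotypes, pedigree, assocs,
                                      n_resample = 10, resample_size = 30,
                                      seed = 1L) {
  stopifnot(inherits(genotypes, "gx_geno"))
  assocs <- as.data.frame(assocs)
  missing_m <- setdiff(assocs$marker, colnames(genotypes$dosage))
  if (length(missing_m))
    stop("allele_frequency_dynamics: marker(s) absent from genotypes: ",
         paste(missing_m, collapse = ", "))
  set.seed(seed)
  gens <- pedigree$generation
  groups <- c(sort(unique(gens[startsWith(gens, "ancestor")]), decreasing = TRUE),
              "progeny")
  out <- list()
  for (i in seq_len(nrow(assocs))) {
    mk <- assocs$marker[i]
    sgn <- assocs$effect_sign[i]
    if (is.na(sgn) || sgn == 0) sgn <- 1
    freq_inc <- function(ids) {
      f_alt <- mean(genotypes$dosage[ids, mk]) / 2
      if (sgn > 0) f_alt else 1 - f_alt
    }
    for (g in groups) {
      ids <- pedigree$id[gens == g]
      ids <- intersect(ids, rownames(genotypes$dosage))
      if (!length(ids)) next
      row <- data.frame(marker = mk, group = g, frequency = freq_inc(ids),
                        n = length(ids), resampled_mean = NA_real_,
                        resampled_se = NA_real_)
      if (g == "progeny") {
        size <- min(resample_size, length(ids))
        fr <- replicate(n_resample, freq_inc(sample(ids, size)))
        row$resampled_mean <- mean(fr)
        row$resampled_se <- stats::sd(fr) / sqrt(n_resample)
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}

#' LD profile around a focal marker
#'
#' Squared Pearson correlation between the focal marker's dosages and every
#' marker in a window of `window` markers centered on it (truncated at the
#' chromosome ends). Monomorphic markers give NA.
#'
#' @param genotypes a `gx_geno`.
#' @param focal_marker marker id.
#' @param window window size in markers.
#' @return data.frame marker, chrom, pos, r2.
#' @export
ld_window <- function(genotypes, focal_marker, window = 3000) {
  stopifnot(inherits(genotypes, "gx_geno"))
  map <- genotypes$map
  k <- match(focal_marker, map$marker)
  if (is.na(k)) stop("ld_window: focal marker not found")
  on_chr <- which(map$chrom == map$chrom[k])
  pos_in <- match(k, on_chr)
  half <- floor(window / 2)
  idx <- on_chr[max(1, pos_in - half):min(length(on_chr), pos_in + half)]
  X <- genotypes$dosage[, idx, drop = FALSE]
  focal <- genotypes$dosage[, k]
  sds <- apply(X, 2, stats::sd)
  r2 <- rep(NA_real_, length(idx))
  ok <- sds > 0 & stats::sd(focal) > 0
  if (any(ok)) r2[ok] <- drop(stats::cor(focal, X[, ok, drop = FALSE]))^2
  data.frame(marker = map$marker[idx], chrom = map$chrom[idx],
             pos = map$pos[idx], r2 = r2, stringsAsFactors = FALSE)
}
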