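#' Configuration for the synthetic-trial generator
#'
#' Defaults mirror the germplasm and trial design the pipeline targets: a
#' diverse accession group plus biparental progeny families bred through a
#' recorded ancestor chain, replicated at two trees per genotype in each
#' (location, year) environment.
#'
#' @param n_accessions number of unrelated founder accessions.
#' @param n_crosses number of biparental parental combinations.
#' @param progeny_per_cross progeny per parental combination.
#' @param n_ancestor_generations depth of the recorded ancestor chain behind
#'   the progeny group.
#' @param m_markers total number of biallelic SNPs.
#' @param n_chromosomes number of chromosomes the markers are spread over.
#' @param chrom_length_bp physical length per chromosome (bp).
#' @param maf_range range (low, high) in (0, 0.5] from which founder minor
#'   allele frequencies are drawn.
#' @param ld_rho latent AR(1) correlation in [0, 1) between adjacent markers;
#'   0 gives linkage equilibrium, values near 1 give long-range LD.
#' @param recomb_rate_per_bp recombination rate in Morgans per bp
#'   (1e-8 = 1 cM/Mb).
#' @param environments data.frame with columns `location` and `year`.
#' @param replicates_per_env trees per genotype per environment (>= 1).
#' @param spatial_field_sd standard deviation of the smooth spatial field
#'   added within each trial, in trait units.
#' @param gxe_env_cor compound-symmetry correlation of G-by-E deviations
#'   across environments (0 = independent; > 0 makes environments
#'   genetically correlated beyond the shared main effect).
#' @param seed integer seed controlling all simulation randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 269L, n_crosses = 27L,
                       progeny_per_cross = 10L, n_ancestor_generations = 5L,
                       m_markers = 5000L, n_chromosomes = 17L,
                       chrom_length_bp = 3e7, maf_range = c(0.05, 0.5),
                       ld_rho = 0.9, recomb_rate_per_bp = 1e-8,
                       environments = default_environments(),
                       replicates_per_env = 2L, spatial_field_sd = 0.3,
                       gxe_env_cor = 0, seed = 1L) {
  counts <- c(n_accessions = n_accessions, n_crosses = n_crosses,
              progeny_per_cross = progeny_per_cross,
              n_ancestor_generations = n_ancestor_generations,
              m_markers = m_markers, n_chromosomes = n_chromosomes)
  if (any(counts <= 0)) stop("sim_config: all counts must be positive")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("sim_config: maf_range must lie within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("sim_config: ld_rho must be in [0, 1)")
  if (replicates_per_env < 1) stop("sim_config: replicates_per_env must be >= 1")
  environments <- as.data.frame(environments)
  stopifnot(all(c("location", "year") %in% names(environments)))
  structure(c(as.list(counts),
              list(chrom_length_bp = chrom_length_bp, maf_range = maf_range,
                   ld_rho = ld_rho, recomb_rate_per_bp = recomb_rate_per_bp,
                   environments = environments,
                   replicates_per_env = as.integer(replicates_per_env),
                   spatial_field_sd = spatial_field_sd,
                   gxe_env_cor = gxe_env_cor, seed = as.integer(seed))),
            class = "sim_config")
}

default_environments <- function() {
  expand.grid(location = c("BEL", "CHE", "ESP", "FRA", "ITA", "POL"),
              year = 2018:2020, stringsAsFactors = FALSE)[, c("location", "year")]
}

#' Specification of one simulated trait
#'
#' The five variance fractions partition the total phenotypic variance (set
#' to 1 in trait units) into planted-QTL, polygenic, environment main effect,
#' genotype-by-environment, and residual parts; they must sum to 1. The
#' smooth spatial field is a nuisance on top of this budget (it is removed by
#' the adjustment stage) and is controlled by `spatial_field_sd` in
#' [sim_config()].
#'
#' @param name trait name.
#' @param n_qtl number of planted QTL.
#' @param qtl_variance_fraction,polygenic_variance_fraction,env_variance_fraction,gxe_variance_fraction,residual_variance_fraction
#'   non-negative fractions summing to 1.
#' @param skewed if `TRUE` the trait is generated on the log scale and
#'   exponentiated, so downstream analysis should log-transform it.
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(name, n_qtl = 10L, qtl_variance_fraction = 0.15,
                       polygenic_variance_fraction = 0.25,
                       env_variance_fraction = 0.35,
                       gxe_variance_fraction = 0.10,
                       residual_variance_fraction = 0.15,
                       skewed = FALSE) {
  fr <- c(qtl = qtl_variance_fraction, polygenic = polygenic_variance_fraction,
          env = env_variance_fraction, gxe = gxe_variance_fraction,
          residual = residual_variance_fraction)
  if (any(fr < 0)) stop("trait_spec: variance fractions must be >= 0")
  if (abs(sum(fr) - 1) > 1e-8) stop("trait_spec: variance fractions must sum to 1")
  structure(list(name = name, n_qtl = as.integer(n_qtl), fractions = fr,
                 skewed = isTRUE(skewed)), class = "trait_spec")
}

#' Simulate founder genotypes with AR(1)-structured linkage disequilibrium
#'
#' Haplotypes are generated per chromosome from a latent Gaussian AR(1)
#' process thresholded at the quantile of each marker's allele frequency, so
#' marginal frequencies land in `maf_range` while adjacent-marker LD decays
#' with `ld_rho`. Dosages are the sum of two independent haplotypes.
#'
#' @param config a [sim_config()].
#' @return A `gx_geno` object: list with `dosage` (n x m matrix in {0,1,2}),
#'   `map` (marker, chrom, pos; sorted by chromosome then position), and
#'   `group` (per-individual label). Founder haplotypes are kept in the
#'   `haplotypes` attribute for gamete sampling.
#' @export
simulate_founder_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_accessions
  m <- config$m_markers
  nchr <- config$n_chromosomes
  chr_sizes <- diff(floor(seq(0, m, length.out = nchr + 1)))
  map <- do.call(rbind, lapply(seq_len(nchr), function(cc) {
    data.frame(chrom = cc,
               pos = sort(sample.int(config$chrom_length_bp, chr_sizes[cc])))
  }))
  map$marker <- sprintf("M%05d", seq_len(m))
  map <- map[, c("marker", "chrom", "pos")]
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  thr <- stats::qnorm(p)

  hap <- function() {
    h <- matrix(0L, n, m)
    off <- 0L
    for (cc in seq_len(nchr)) {
      mc <- chr_sizes[cc]
      z <- matrix(stats::rnorm(n * mc), n, mc)
      if (config$ld_rho > 0 && mc > 1) {
        s <- sqrt(1 - config$ld_rho^2)
        for (k in 2:mc) z[, k] <- config$ld_rho * z[, k - 1] + s * z[, k]
      }
      h[, off + seq_len(mc)] <-
        (z < rep(thr[off + seq_len(mc)], each = n)) * 1L
      off <- off + mc
    }
    h
  }
  h1 <- hap(); h2 <- hap()
  ids <- sprintf("ACC%04d", seq_len(n))
  dimnames(h1) <- dimnames(h2) <- list(ids, map$marker)
  geno <- new_gx_geno(h1 + h2, map, stats::setNames(rep("accession", n), ids))
  attr(geno, "haplotypes") <- list(h1 = h1, h2 = h2)
  geno
}

new_gx_geno <- function(dosage, map, group) {
  structure(list(dosage = dosage, map = map, group = group), class = "gx_geno")
}

#' @export
print.gx_geno <- function(x, ...) {
  cat(sprintf("gx_geno: %d individuals x %d markers on %d chromosomes\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  print(table(x$group))
  invisible(x)
}

# One gamete from an individual's two haplotypes: crossovers are a Poisson
# process along each chromosome (Haldane, no interference).
gx_gamete <- function(h1, h2, map_split, recomb_rate) {
  g <- integer(length(h1))
  for (cc in seq_along(map_split)) {
    idx <- map_split[[cc]]$idx
    pos <- map_split[[cc]]$pos
    len <- map_split[[cc]]$len
    nco <- stats::rpois(1, recomb_rate * len)
    start <- sample(c(TRUE, FALSE), 1)
    if (nco == 0) {
      use1 <- rep(start, length(idx))
    } else {
      co <- sort(stats::runif(nco, 0, len))
      seg <- findInterval(pos, co)
      use1 <- xor(start, seg %% 2 == 1)
    }
    g[idx] <- ifelse(use1, h1[idx], h2[idx])
  }
  g
}

#' Simulate the progeny group and its recorded ancestor chain
#'
#' Builds a breeding history behind the progeny: generation-`g` ancestors are
#' crosses of generation-`g+1` individuals (the deepest generation is crossed
#' from founder accessions), down to the parents used in the biparental
#' crosses that produce the progeny families. All meioses follow Mendelian
#' gamete sampling with Haldane recombination.
#'
#' @param founders founder `gx_geno` from [simulate_founder_genotypes()].
#' @param config the same [sim_config()].
#' @return list with `genotypes` (a `gx_geno` stacking founders, ancestors
#'   and progeny; `group` is "accession", "ancestor" or "progeny") and
#'   `pedigree` (data.frame id, parent1, parent2, generation where generation
#'   is "founder", "ancestor_g<k>" with k = 1 the parents, or "progeny").
#' @export
simulate_pedigree_genotypes <- function(founders, config) {
  stopifnot(inherits(founders, "gx_geno"), inherits(config, "sim_config"))
  haps <- attr(founders, "haplotypes")
  if (is.null(haps)) stop("simulate_pedigree_genotypes: founders lack haplotypes")
  set.seed(config$seed + 1L)
  map <- founders$map
  chr <- unique(map$chrom)
  map_split <- lapply(chr, function(cc) {
    idx <- which(map$chrom == cc)
    list(idx = idx, pos = map$pos[idx] * config$recomb_rate_per_bp,
         len = max(map$pos[idx]) * config$recomb_rate_per_bp)
  })

  pool_h1 <- haps$h1; pool_h2 <- haps$h2
  ped <- data.frame(id = rownames(founders$dosage), parent1 = NA_character_,
                    parent2 = NA_character_, generation = "founder")
  n_par <- max(2L, ceiling(2 * config$n_crosses / 3))
  gens <- config$n_ancestor_generations

  make_generation <- function(parent_ids, n_new, prefix) {
    new_h1 <- matrix(0L, n_new, ncol(pool_h1),
                     dimnames = list(sprintf("%s%03d", prefix, seq_len(n_new)),
                                     colnames(pool_h1)))
    new_h2 <- new_h1
    recs <- vector("list", n_new)
    for (i in seq_len(n_new)) {
      pr <- sample(parent_ids, 2)
      new_h1[i, ] <- gx_gamete(pool_h1[pr[1], ], pool_h2[pr[1], ], map_split, 1)
      new_h2[i, ] <- gx_gamete(pool_h1[pr[2], ], pool_h2[pr[2], ], map_split, 1)
      recs[[i]] <- data.frame(id = rownames(new_h1)[i], parent1 = pr[1],
                              parent2 = pr[2], generation = prefix)
    }
    pool_h1 <<- rbind(pool_h1, new_h1)
    pool_h2 <<- rbind(pool_h2, new_h2)
    do.call(rbind, recs)
  }

  prev_ids <- rownames(founders$dosage)
  anc_ids <- character(0)
  for (g in seq(gens, 1)) {
    prefix <- sprintf("ANC%d_", g)
    rec <- make_generation(prev_ids, n_par, prefix)
    rec$generation <- sprintf("ancestor_g%d", g)
    ped <- rbind(ped, rec)
    prev_ids <- rec$id
    anc_ids <- c(anc_ids, rec$id)
  }
  parents <- prev_ids  # generation 1 = parents of the progeny

  prog_recs <- vector("list", config$n_crosses)
  for (cx in seq_len(config$n_crosses)) {
    pr <- sample(parents, 2)
    rec <- make_generation(pr, config$progeny_per_cross,
                           sprintf("PRG%02d_", cx))
    rec$parent1 <- pr[1]; rec$parent2 <- pr[2]; rec$generation <- "progeny"
    prog_recs[[cx]] <- rec
  }
  ped <- rbind(ped, do.call(rbind, prog_recs))

  dosage <- pool_h1 + pool_h2
  group <- stats::setNames(rep("accession", nrow(dosage)), rownames(dosage))
  group[anc_ids] <- "ancestor"
  group[grep("^PRG", names(group))] <- "progeny"
  out <- new_gx_geno(dosage, map, group)
  attr(out, "haplotypes") <- list(h1 = pool_h1, h2 = pool_h2)
  list(genotypes = out, pedigree = ped)
}

# scale a centered vector/matrix so its population variance is exactly v
scale_to_var <- function(x, v) {
  x <- x - mean(x)
  pv <- mean(x^2)
  if (pv < 1e-300 || v <= 0) return(x * 0)
  x * sqrt(v / pv)
}

# smooth 2D field: 2-4 Gaussian bumps plus linear row/column gradients,
# scaled to the requested SD
gx_spatial_field <- function(nrow, ncol, sd_target) {
  if (sd_target <= 0) return(matrix(0, nrow, ncol))
  r <- matrix(seq_len(nrow), nrow, ncol)
  c <- matrix(rep(seq_len(ncol), each = nrow), nrow, ncol)
  f <- stats::runif(1, -1, 1) * r / nrow + stats::runif(1, -1, 1) * c / ncol
  for (b in seq_len(sample(2:4, 1))) {
    cr <- stats::runif(1, 1, nrow); cc <- stats::runif(1, 1, ncol)
    w <- stats::runif(1, 0.15, 0.4) * max(nrow, ncol)
    f <- f + stats::runif(1, -1, 1) * exp(-((r - cr)^2 + (c - cc)^2) / (2 * w^2))
  }
  scale_to_var(f, sd_target^2)
}

#' Simulate a multi-environment trial for one trait
#'
#' Phenotype of each tree = intercept + environment main effect + genetic
#' value (planted QTL + polygenic tail) + G-by-E deviation + smooth spatial
#' field at the tree's position + residual. Component vectors are rescaled so
#' realized variance fractions match the [trait_spec()] exactly (the spatial
#' field sits outside the fraction budget and is controlled by
#' `spatial_field_sd`).
#'
#' @param genotypes a `gx_geno`; the trial covers all its individuals unless
#'   `individuals` is given.
#' @param spec a [trait_spec()].
#' @param config a [sim_config()].
#' @param individuals optional character vector of ids to include.
#' @return list with `records` (data.frame genotype, location, year, row,
#'   col, trait, value) and `truth` (class `gx_truth`: qtl_indices,
#'   qtl_effects, genetic_values n x r, env_effects, gxe, spatial fields,
#'   variance_components, mu).
#' @export
simulate_multienv_trial <- function(genotypes, spec, config,
                                    individuals = NULL) {
  stopifnot(inherits(genotypes, "gx_geno"), inherits(spec, "trait_spec"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 2L + utf8ToInt(substr(spec$name, 1, 1)))
  M <- genotypes$dosage
  if (!is.null(individuals)) M <- M[individuals, , drop = FALSE]
  n <- nrow(M)
  ids <- rownames(M)
  envs <- config$environments
  r <- nrow(envs)
  env_key <- paste(envs$location, envs$year, sep = ".")
  fr <- spec$fractions

  # genetic values: planted QTL + polygenic tail
  maf <- colMeans(M) / 2
  eligible <- which(pmin(maf, 1 - maf) >= 0.1)
  if (length(eligible) < spec$n_qtl) eligible <- order(-pmin(maf, 1 - maf))[seq_len(spec$n_qtl)]
  qtl_idx <- sort(sample(eligible, spec$n_qtl))
  qtl_eff <- stats::rnorm(spec$n_qtl)
  g_qtl <- scale_to_var(drop(M[, qtl_idx, drop = FALSE] %*% qtl_eff), fr["qtl"])
  # rescale recorded per-QTL effects to the realized scale
  raw <- drop(M[, qtl_idx, drop = FALSE] %*% qtl_eff)
  sc <- if (stats::var(raw) > 0) sqrt(fr["qtl"] / mean((raw - mean(raw))^2)) else 0
  qtl_eff <- qtl_eff * sc
  poly_eff <- stats::rnorm(ncol(M), sd = 1 / sqrt(ncol(M)))
  g_poly <- drop(scale(M, scale = FALSE) %*% poly_eff)
  # orthogonalize against the QTL component so the two variance fractions add
  if (stats::var(g_qtl) > 0 && stats::var(g_poly) > 0)
    g_poly <- g_poly - g_qtl * stats::cov(g_poly, g_qtl) / stats::var(g_qtl)
  g_poly <- scale_to_var(g_poly, fr["polygenic"])
  g <- g_qtl + g_poly

  env_eff <- if (r > 1) scale_to_var(stats::rnorm(r), fr["env"]) else
    rep(0, r)
  if (config$gxe_env_cor > 0) {
    shared <- stats::rnorm(n)
    gxe <- sqrt(config$gxe_env_cor) * matrix(shared, n, r) +
      sqrt(1 - config$gxe_env_cor) * matrix(stats::rnorm(n * r), n, r)
  } else {
    gxe <- matrix(stats::rnorm(n * r), n, r)
  }
  gxe <- if (fr["gxe"] > 0) scale_to_var(gxe, fr["gxe"]) else gxe * 0

  reps <- config$replicates_per_env
  n_trees <- n * reps
  gcols <- ceiling(sqrt(n_trees))
  grows <- ceiling(n_trees / gcols)
  mu <- 10

  fields <- vector("list", r)
  recs <- vector("list", r)
  for (j in seq_len(r)) {
    fields[[j]] <- gx_spatial_field(grows, gcols, config$spatial_field_sd)
    slots <- sample(grows * gcols, n_trees)
    rowp <- (slots - 1) %% grows + 1
    colp <- (slots - 1) %/% grows + 1
    gi <- rep(seq_len(n), reps)
    resid <- scale_to_var(stats::rnorm(n_trees), fr["residual"])
    value <- mu + env_eff[j] + g[gi] + gxe[gi, j] +
      fields[[j]][cbind(rowp, colp)] + resid
    recs[[j]] <- data.frame(genotype = ids[gi], location = envs$location[j],
                            year = envs$year[j], row = rowp, col = colp,
                            trait = spec$name, value = value)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  if (spec$skewed) records$value <- exp(records$value - mu)

  genetic_values <- matrix(g, n, r, dimnames = list(ids, env_key)) + gxe
  truth <- structure(list(
    qtl_indices = qtl_idx, qtl_effects = qtl_eff,
    qtl_markers = colnames(M)[qtl_idx],
    genetic_main = stats::setNames(g, ids),
    genetic_values = genetic_values,
    env_effects = stats::setNames(env_eff, env_key),
    gxe = gxe, spatial_fields = stats::setNames(fields, env_key),
    variance_components = fr, mu = mu, skewed = spec$skewed),
    class = "gx_truth")
  list(records = records, truth = truth)
}

#' Simulate a complete dataset (genotypes, pedigree, phenotypes)
#'
#' Convenience wrapper chaining [simulate_founder_genotypes()],
#' [simulate_pedigree_genotypes()] and one [simulate_multienv_trial()] per
#' trait. The trial population is the union of the accession and progeny
#' groups (recorded ancestors are genotyped but not phenotyped, as in a
#' pedigree study).
#'
#' @param config a [sim_config()].
#' @param traits list of [trait_spec()]s.
#' @return list with `genotypes`, `pedigree`, `phenotypes` (long data.frame
#'   over all traits) and `truth` (named list per trait).
#' @export
simulate_trial <- function(config, traits = list(trait_spec("trait1"))) {
  founders <- simulate_founder_genotypes(config)
  ped <- simulate_pedigree_genotypes(founders, config)
  keep <- names(ped$genotypes$group)[ped$genotypes$group != "ancestor"]
  truth <- list(); phen <- list()
  for (sp in traits) {
    tr <- simulate_multienv_trial(ped$genotypes, sp, config, individuals = keep)
    truth[[sp$name]] <- tr$truth
    phen[[sp$name]] <- tr$records
  }
  list(genotypes = ped$genotypes, pedigree = ped$pedigree,
       phenotypes = do.call(rbind, phen), truth = truth)
}
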