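# Shared fixtures, all generated in code. Expensive objects are memoised per
# session so several test files can reuse one simulation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small panel of accessions plus progeny families (families give G the
# spiked kinship spectrum genomic models rely on), with kernels
small_panel <- function(n = 250, m = 1000, seed = 5, ld_rho = 0.6) {
  memo(sprintf("panel_%d_%d_%d", n, m, seed), {
    n_acc <- round(n * 0.55)
    n_cross <- max(2, round(n * 0.045))
    per <- ceiling((n - n_acc) / n_cross)
    cfg <- sim_config(n_accessions = n_acc, n_crosses = n_cross,
                      progeny_per_cross = per, m_markers = m,
                      n_chromosomes = 5, ld_rho = ld_rho, seed = seed)
    ped <- simulate_pedigree_genotypes(simulate_founder_genotypes(cfg), cfg)
    geno <- ped$genotypes
    keep <- names(geno$group)[geno$group != "ancestor"]
    keep <- keep[seq_len(min(n, length(keep)))]
    geno$dosage <- geno$dosage[keep, , drop = FALSE]
    geno$group <- geno$group[keep]
    attr(geno, "haplotypes") <- NULL
    kb <- build_kernels(geno$dosage)
    list(cfg = cfg, geno = geno, kb = kb, pedigree = ped$pedigree)
  })
}

# draw a trait with genetic values u ~ N(0, G) scaled to heritability h2
gblup_trait <- function(G, h2, seed, mu = 0) {
  set.seed(seed)
  n <- nrow(G)
  L <- t(chol(G + diag(1e-6, n)))
  u <- drop(L %*% stats::rnorm(n))
  u <- (u - mean(u)) / stats::sd(u) * sqrt(h2)
  y <- mu + u + stats::rnorm(n, sd = sqrt(1 - h2))
  names(y) <- rownames(G)
  list(y = y, u = u)
}

# short chains are plenty at these problem sizes
quick_gibbs <- function(seed = NULL, iterations = 1500, burn_in = 300)
  gibbs_config(iterations = iterations, thinning = 5, burn_in = burn_in,
               seed = seed)

# a tiny hand-built genotype object
toy_geno <- function(dosage, chrom = NULL, pos = NULL) {
  m <- ncol(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- sprintf("M%03d", 1:m)
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("G%03d", 1:nrow(dosage))
  map <- data.frame(marker = colnames(dosage),
                    chrom = if (is.null(chrom)) rep(1, m) else chrom,
                    pos = if (is.null(pos)) seq(1e5, by = 1e5, length.out = m) else pos)
  structure(list(dosage = dosage, map = map,
                 group = stats::setNames(rep("accession", nrow(dosage)),
                                         rownames(dosage))),
            class = "gx_geno")
}
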