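test_that("the Bonferroni threshold for a 303k-marker scan clears the printed bound", {
  thr <- bonferroni_threshold(0.05, 303148)
  expect_gte(thr, 6.74)
  expect_equal(thr, 6.7827, tolerance = 1e-4)
})

test_that("chromosome thirds are assigned with left-closed boundaries", {
  L <- 3e7
  expect_equal(assign_segment(c(5e6, 1.5e7, 3e7), L),
               c("top", "center", "bottom"))
  expect_equal(assign_segment(1e7, L), "top")      # exactly L/3
  expect_equal(assign_segment(2e7, L), "center")   # exactly 2L/3
  expect_error(assign_segment(3.1e7, L), "position")
  # every marker of a simulated map gets exactly one segment
  p <- small_panel()
  chrlen <- tapply(p$geno$map$pos, p$geno$map$chrom, max)
  seg <- assign_segment(p$geno$map$pos, chrlen[as.character(p$geno$map$chrom)])
  expect_true(all(seg %in% c("top", "center", "bottom")))
})

test_that("marker R2 matches simple-regression arithmetic and recoding", {
  snp <- c(0, 0, 1, 1, 2, 2)
  expect_equal(marker_r2(snp, 2 * snp + 3), 1)
  y_orth <- c(1, -1, 1, -1, 1, -1)
  expect_equal(marker_r2(snp, y_orth), 0, tolerance = 1e-12)
  set.seed(3)
  y <- rnorm(6)
  expect_equal(marker_r2(snp, y), marker_r2(snp + 1, y))  # 1,2,3 coding
  expect_error(marker_r2(rep(1, 6), y), "constant")
  expect_error(marker_r2(snp[1:2], y[1:2]), "at least 3")
  set.seed(4)
  r2null <- replicate(50, marker_r2(sample(0:2, 1000, TRUE), rnorm(1000)))
  expect_lt(mean(r2null), 0.01)
})

test_that("co-localization clusters by strict 100 kb gaps within chromosomes", {
  a <- data.frame(chrom = c(3, 3, 3, 16, 16, 5),
                  pos = c(30587378, 30590166, 30681581, 9023861, 8985888, 1e6),
                  trait = c("firmness", "firmness", "harvest", "harvest",
                            "firmness", "other"))
  cl <- colocalize_associations(a)
  expect_equal(cl$cluster[1], cl$cluster[3])  # gap 94203 < 100 kb
  expect_equal(cl$cluster[4], cl$cluster[5])
  expect_true(cl$cluster[6] != cl$cluster[1])
  expect_true(attr(cl, "clusters")$cross_trait[
    attr(cl, "clusters")$cluster == cl$cluster[1]])
  # exactly at the window: separate clusters
  b <- data.frame(chrom = 1, pos = c(1e6, 1e6 + 1e5))
  expect_equal(length(unique(colocalize_associations(b)$cluster)), 2)
  # same positions on different chromosomes never cluster
  c2 <- data.frame(chrom = c(1, 2), pos = c(5e5, 5e5))
  expect_equal(length(unique(colocalize_associations(c2)$cluster)), 2)
  expect_equal(nrow(colocalize_associations(a[0, ])), 0)
})

test_that("catalog overlap counts unique trait-group/segment combinations", {
  former <- data.frame(trait_group = "A", chrom = 1, segment = "top")
  present <- data.frame(trait_group = c("A", "B"), chrom = c(1, 2),
                        segment = c("top", "center"))
  ov <- catalog_overlap(present, former)
  expect_equal(ov$shared, 1)
  expect_equal(ov$overlap_pct, 50)
  disjoint <- catalog_overlap(
    data.frame(trait_group = "C", chrom = 3, segment = "bottom"), former)
  expect_equal(disjoint$overlap_pct, 0)
  contained <- catalog_overlap(former, present)
  expect_equal(contained$overlap_pct, 100)
  expect_equal(contained$former_only, 1)
  expect_error(catalog_overlap(
    data.frame(trait_group = "A", chrom = 1, segment = "middle"), former),
    "segment")
})

test_that("allele-frequency dynamics handle fixation, absence and exhaustive resampling", {
  dos <- rbind(matrix(2L, 5, 3), matrix(0L, 4, 3))
  dos[6:9, 2] <- c(0L, 1L, 2L, 1L)
  dimnames(dos) <- list(c(paste0("P", 1:5), paste0("A", 1:4)),
                        c("mA", "mB", "mC"))
  geno <- toy_geno(dos)
  ped <- data.frame(id = rownames(dos),
                    parent1 = NA, parent2 = NA,
                    generation = c(rep("progeny", 5), rep("ancestor_g1", 2),
                                   rep("ancestor_g2", 2)))
  assoc <- data.frame(marker = colnames(dos), effect_sign = c(1, 1, -1))
  af <- allele_frequency_dynamics(geno, ped, assoc, n_resample = 10,
                                  resample_size = 5, seed = 2)
  prog <- af[af$group == "progeny", ]
  # all progeny homozygous for the increasing allele -> fixed at 1
  expect_equal(prog$frequency[prog$marker == colnames(dos)[1]], 1)
  # increasing allele (sign < 0 -> reference allele) also fixed in progeny
  expect_equal(prog$frequency[prog$marker == colnames(dos)[3]], 0)
  # allele absent from ancestors -> frequency 0 there
  anc <- af[af$group == "ancestor_g1" & af$marker == colnames(dos)[1], ]
  expect_equal(anc$frequency, 0)
  # resample size = group size -> resampled mean equals the group frequency
  expect_equal(prog$resampled_mean, prog$frequency)
  expect_error(allele_frequency_dynamics(
    geno, ped, data.frame(marker = "nope", effect_sign = 1)), "absent")
})

test_that("LD windows are centered, truncated and NA on monomorphic markers", {
  p <- small_panel()
  map <- p$geno$map
  mid <- map$marker[which(map$chrom == 2)[100]]
  w <- ld_window(p$geno, mid, window = 50)
  expect_true(all(w$chrom == 2))
  expect_equal(nrow(w), 51)
  expect_equal(w$r2[w$marker == mid], 1)
  # truncation at the chromosome start
  first <- map$marker[which(map$chrom == 2)[1]]
  w2 <- ld_window(p$geno, first, window = 50)
  expect_equal(nrow(w2), 26)
  # duplicated column is in perfect LD; monomorphic is NA
  dos <- cbind(p$geno$dosage[, 1:3], dup = p$geno$dosage[, 2],
               mono = rep(1L, nrow(p$geno$dosage)))
  g2 <- toy_geno(dos)
  w3 <- ld_window(g2, colnames(dos)[2], window = 10)
  expect_equal(w3$r2[w3$marker == "dup"], 1)
  expect_true(is.na(w3$r2[w3$marker == "mono"]))
  set.seed(6)
  indep <- toy_geno(cbind(p$geno$dosage[, 1:50],
                          rnd = sample(0:2, nrow(p$geno$dosage), TRUE)))
  w4 <- ld_window(indep, "rnd", window = 100)
  expect_lt(mean(w4$r2[w4$marker != "rnd"]), 0.02)
  expect_error(ld_window(p$geno, "nope"), "not found")
})

# one planted-QTL simulation reused across the scan tests
planted_scan <- function(seed = 61) {
  memo(paste0("scan_", seed), {
    cfg <- sim_config(n_accessions = 500, m_markers = 3000, n_chromosomes = 5,
                      ld_rho = 0.8, seed = seed)
    geno <- simulate_founder_genotypes(cfg)
    X <- geno$dosage
    set.seed(seed + 1)
    maf <- pmin(colMeans(X) / 2, 1 - colMeans(X) / 2)
    qtl <- sort(sample(which(maf > 0.2), 5))
    gq <- sapply(qtl, function(k) {
      z <- X[, k]; (z - mean(z)) / sd(z) * sqrt(0.08)
    })
    y <- rowSums(gq) + rnorm(500, sd = sqrt(0.6))
    names(y) <- rownames(X)
    list(geno = geno, y = y, qtl = qtl)
  })
}

test_that("the multi-locus scan recovers planted QTL without false clusters", {
  s <- planted_scan()
  gw <- blink_scan(s$geno, s$y, trait = "t")
  expect_s3_class(gw, "gx_gwas")
  hits <- gw$associations
  idx <- match(hits$marker, s$geno$map$marker)
  found <- vapply(s$qtl, function(k)
    any(abs(idx - k) <= 50 & hits$chrom == s$geno$map$chrom[k]), logical(1))
  expect_gte(sum(found), 4)
  near <- vapply(seq_len(nrow(hits)), function(i)
    any(abs(idx[i] - s$qtl) <= 50 &
          s$geno$map$chrom[s$qtl] == hits$chrom[i]), logical(1))
  cl <- colocalize_associations(hits)
  expect_lte(length(unique(cl$cluster[!near])), 1)
  expect_true(all(c("R2", "segment", "effect_sign") %in% names(hits)))
  expect_true(all(hits$R2 > 0 & hits$R2 <= 1))
})

test_that("pseudo-QTN sets respect the pairwise LD cutoff", {
  s <- planted_scan()
  gw <- blink_scan(s$geno, s$y)
  q <- gw$pseudo_qtns
  if (length(q) > 1) {
    r2 <- cor(s$geno$dosage[, q])^2
    expect_lt(max(r2[upper.tri(r2)]), 0.7)
  } else succeed()
})

test_that("null phenotypes yield no significant associations", {
  p <- small_panel(n = 400, m = 1500, seed = 67, ld_rho = 0.8)
  for (sd_seed in 1:2) {
    set.seed(sd_seed)
    y <- rnorm(400)
    names(y) <- rownames(p$geno$dosage)
    gw <- blink_scan(p$geno, y)
    expect_equal(nrow(gw$associations), 0)
  }
})

test_that("Bonferroni calling is monotone in alpha and row order is irrelevant", {
  s <- planted_scan()
  gw05 <- blink_scan(s$geno, s$y, alpha = 0.05)
  gw01 <- blink_scan(s$geno, s$y, alpha = 0.001)
  expect_true(all(gw01$associations$marker %in% gw05$associations$marker))
  # permuting genotype rows (with ids) leaves the result unchanged
  set.seed(8)
  perm <- sample(nrow(s$geno$dosage))
  geno_p <- s$geno
  geno_p$dosage <- s$geno$dosage[perm, ]
  gw_p <- blink_scan(geno_p, s$y)
  expect_setequal(gw_p$associations$marker, gw05$associations$marker)
})

test_that("markers below the MAF threshold are excluded from testing", {
  s <- planted_scan()
  gw <- blink_scan(s$geno, s$y, maf_min = 0.2)
  maf <- colMeans(s$geno$dosage) / 2
  maf <- pmin(maf, 1 - maf)
  expect_equal(gw$m_tested, sum(maf >= 0.2))
  expect_error(blink_scan(s$geno, s$y[1:3]), "covariates")
})
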