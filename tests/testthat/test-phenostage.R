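test_that("heritability formula arithmetic is exact", {
  expect_equal(heritability_eq(3, 2, 0, 1, 2), 0.75)
  expect_equal(heritability_eq(0, 2, 0, 1, 2), 0)
  expect_equal(heritability_eq(3, 2, 2, 2, 2), 3 / 4.5, tolerance = 1e-12)
  # with one environment and no interaction the across-environment form
  # reduces to the environment-specific one
  expect_equal(heritability_eq(3, 2, 0, 1, 2), heritability_eq(3, 2, NULL_ge <- 0, 1, 2))
  expect_equal(heritability_eq(5, 0, 0, 1, 1), 1)
})

test_that("environment-specific heritability chains from the REML fit", {
  d <- data.frame(genotype = c("a", "a", "b", "b"), adjusted = c(1, 3, 5, 7))
  h <- env_clonal_heritability(d)
  # sigma_g2 = 7, sigma_e2 = 2, nbar = 2 -> H2 = 7/8
  expect_equal(h$H2, 0.875, tolerance = 1e-6)
  expect_equal(h$sigma_g2, 7, tolerance = 1e-6)
  expect_equal(h$nbar_r, 2)
  expect_error(env_clonal_heritability(
    data.frame(genotype = "a", adjusted = 1)), ">= 2 genotypes")
  expect_warning(env_clonal_heritability(
    data.frame(genotype = c("a", "b", "c"), adjusted = c(1, 2, 3))),
    "single-replicated")
})

test_that("heritability filtering keeps the boundary and drops below it", {
  est <- data.frame(location = "A", year = 2018, trait = c("t1", "t2", "t3"),
                    H2 = c(0.1, 0.09, 0.8))
  kept <- filter_low_heritability(est)
  expect_setequal(kept$trait, c("t1", "t3"))
  empty <- filter_low_heritability(est[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("spatial adjustment recovers a planted surface and is benign without one", {
  cfg_flat <- sim_config(n_accessions = 300, n_crosses = 2, progeny_per_cross = 2,
                         m_markers = 200, n_chromosomes = 2,
                         environments = data.frame(location = "A", year = 2018),
                         spatial_field_sd = 0, seed = 41)
  geno <- simulate_founder_genotypes(cfg_flat)
  tr <- simulate_multienv_trial(geno, trait_spec("t"), cfg_flat)
  adj <- adjust_spatial(tr$records)
  expect_equal(nrow(adj$tree), nrow(tr$records))
  expect_lt(max(abs(adj$tree$adjusted - tr$records$value)),
            0.05 * sd(tr$records$value))

  cfg_bump <- sim_config(n_accessions = 400, n_crosses = 2, progeny_per_cross = 2,
                         m_markers = 200, n_chromosomes = 2,
                         environments = data.frame(location = "A", year = 2018),
                         spatial_field_sd = 0.5, seed = 43)
  geno2 <- simulate_founder_genotypes(cfg_bump)
  tr2 <- simulate_multienv_trial(geno2, trait_spec("t"), cfg_bump)
  adj2 <- adjust_spatial(tr2$records)
  truth_surface <- tr2$truth$spatial_fields[[1]][cbind(tr2$records$row,
                                                       tr2$records$col)]
  expect_gt(cor(adj2$surface, truth_surface), 0.9)

  # missing coordinates fall back to no adjustment with a warning
  norc <- tr$records[, setdiff(names(tr$records), c("row", "col"))]
  expect_warning(a3 <- adjust_spatial(norc), "coordinates")
  expect_equal(a3$tree$adjusted, norc$value)
  expect_error(adjust_spatial(tr$records[0, ]), "no records")
})

test_that("single tree per genotype on a flat field reduces to the identity", {
  set.seed(5)
  d <- data.frame(genotype = sprintf("g%02d", 1:64), row = rep(1:8, 8),
                  col = rep(1:8, each = 8), value = rnorm(64),
                  location = "A", year = 2018)
  adj <- adjust_spatial(d)
  ord <- match(adj$genotype$genotype, d$genotype)
  expect_equal(adj$genotype$value, adj$tree$adjusted[ord])
})

test_that("clonal values equal the balanced BLUP closed form and center at 0", {
  d <- data.frame(genotype = c("a", "a", "b", "b"), adjusted = c(1, 3, 5, 7),
                  location = "L1", year = 2018)
  cv <- compute_clonal_values(d, scope = "location-specific", location = "L1")
  # genotype means (2, 6), grand mean 4, shrink 7/8 -> +-1.75
  expect_equal(cv$value[order(cv$genotype)], c(-1.75, 1.75), tolerance = 1e-6)
  # all observations identical -> zero clonal values
  d2 <- transform(d, adjusted = 5)
  cv2 <- compute_clonal_values(d2, scope = "location-specific", location = "L1")
  expect_equal(cv2$value, c(0, 0))
})

test_that("clonal-value models use the scope's fixed effects and transforms", {
  cfg <- sim_config(n_accessions = 150, n_crosses = 2, progeny_per_cross = 2,
                    m_markers = 200, n_chromosomes = 2,
                    environments = data.frame(location = c("A", "A", "B", "B"),
                                              year = c(2018, 2019, 2018, 2019)),
                    spatial_field_sd = 0, seed = 47)
  geno <- simulate_founder_genotypes(cfg)
  tr <- simulate_multienv_trial(geno, trait_spec("t"), cfg)
  d <- tr$records
  d$adjusted <- d$value
  cv <- compute_clonal_values(d, scope = "across-location")
  expect_lt(abs(mean(cv$value)), 1e-6 * sd(d$value))
  expect_gt(cor(cv$value, tr$truth$genetic_main[cv$genotype]), 0.85)
  # log transform: fitting exp-scale data with log recovers the same ranking
  d_exp <- transform(d, adjusted = exp(adjusted - mean(adjusted)))
  cv_log <- compute_clonal_values(d_exp, scope = "across-location",
                                  log_transform = TRUE)
  expect_gt(cor(cv_log$value, cv$value), 0.999)
  expect_identical(attr(cv_log, "transform"), "log")
  d_neg <- transform(d, adjusted = adjusted - max(adjusted))
  expect_error(compute_clonal_values(d_neg, scope = "across-location",
                                     log_transform = TRUE), "<= 0")
  expect_error(compute_clonal_values(d[d$trait == "absent", ],
                                     scope = "across-location"), "no data")
})

test_that("correlation analysis behaves on identities, negations and NAs", {
  set.seed(19)
  g <- sprintf("g%03d", 1:120)
  a <- rnorm(120)
  tab <- cbind(t1 = a, t2 = -a, t3 = a + rnorm(120, sd = 0.1))
  rownames(tab) <- g
  res <- correlation_analysis(tab)
  expect_equal(diag(res$trait_cor), c(t1 = 1, t2 = 1, t3 = 1))
  expect_equal(res$trait_cor[1, 2], -1, tolerance = 1e-12)
  expect_equal(res$trait_cor, t(res$trait_cor))
  expect_gt(res$trait_cor["t1", "t3"], 0.9)
  expect_equal(nrow(res$scores), 120)
  # missing values are mean-imputed for the PCA, pairwise-complete for cor
  tab2 <- tab; tab2[1:10, 2] <- NA
  res2 <- correlation_analysis(tab2)
  expect_equal(nrow(res2$scores), 120)
  expect_equal(res2$trait_cor[1, 2], -1, tolerance = 1e-12)
  tab3 <- cbind(tab, t4 = rep(1, 120))
  expect_warning(r3 <- correlation_analysis(tab3), "zero-variance")
  expect_true(is.na(r3$trait_cor["t4", "t1"]))
})

test_that("traits sharing their genetic basis are highly correlated", {
  p <- small_panel()
  tr <- gblup_trait(p$kb$G, 0.8, seed = 53)
  # clonal values share all genetic effects; only a small de-noised residue
  t1 <- tr$u + rnorm(length(tr$u), sd = sqrt(0.05))
  t2 <- tr$u + rnorm(length(tr$u), sd = sqrt(0.05))
  res <- correlation_analysis(cbind(t1 = t1, t2 = t2))
  expect_gt(res$trait_cor[1, 2], 0.9)
})

test_that("global clonal values combine scopes and track provenance", {
  c1 <- structure(data.frame(genotype = c("a", "b"), value = c(1, -1)),
                  scope = "across-location", class = c("gx_clonal", "data.frame"))
  c2 <- structure(data.frame(genotype = c("b", "c"), value = c(2, -2)),
                  scope = "location-specific", class = c("gx_clonal", "data.frame"))
  g <- global_clonal_values(list(t1 = c1, t2 = c2))
  expect_equal(dim(g), c(3, 2))
  expect_true(is.na(g["c", "t1"]) && is.na(g["a", "t2"]))
  expect_equal(unname(attr(g, "scopes")),
               c("across-location", "location-specific"))
})
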