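#' Run the full analysis pipeline
#'
#' Orchestrates the stage order: spatial adjustment per environment ->
#' environment-specific heritability and filtering -> clonal values (across
#' location, plus location-specific for single-location traits) ->
#' across-environment heritability -> multi-locus GWAS -> main-effect
#' genomic prediction under cross-validation -> phenotypic variance
#' decomposition (with trait clustering when >= 3 traits). All stage outputs
#' are written as CSV under `config$out_dir` together with a JSON run
#' manifest (package version, seed, thresholds, output file hashes). A stage
#' failure halts with the stage name; outputs of earlier stages remain on
#' disk.
#'
#' @param config a [pipeline_config()].
#' @param inputs optional pre-loaded [load_inputs()] result (e.g. simulated
#'   data not living on disk).
#' @return list with the in-memory stage results and `manifest`.
#' @export
run_pipeline <- function(config, inputs = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(inputs)) inputs <- load_inputs(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(config$out_dir, name)
  written <- character(0)
  emit <- function(obj, name) {
    utils::write.csv(obj, outfile(name), row.names = FALSE)
    written <<- c(written, name)
  }
  stage <- "setup"
  result <- list()
  tryCatch({
    set.seed(config$seed)
    geno <- inputs$genotypes
    phen <- inputs$phenotypes
    traits <- config$traits
    if (is.null(traits)) traits <- unique(phen$trait)

    stage <- "adjust"
    adjusted <- list()
    for (tn in traits) {
      dt <- phen[phen$trait == tn, , drop = FALSE]
      envs <- unique(dt[, c("location", "year")])
      adj <- lapply(seq_len(nrow(envs)), function(i)
        adjust_spatial(dt, environment_key = c(envs$location[i],
                                               envs$year[i]))$tree)
      adjusted[[tn]] <- do.call(rbind, adj)
    }
    emit(do.call(rbind, adjusted), "adjusted_values.csv")

    stage <- "heritability"
    h2_env <- list()
    for (tn in traits) {
      d <- adjusted[[tn]]
      for (ek in unique(paste(d$location, d$year, sep = "."))) {
        di <- d[paste(d$location, d$year, sep = ".") == ek, ]
        h <- env_clonal_heritability(di)
        h2_env[[length(h2_env) + 1]] <- data.frame(
          trait = tn, location = di$location[1], year = di$year[1],
          H2 = h$H2, sigma_g2 = h$sigma_g2, sigma_e2 = h$sigma_e2,
          nbar_r = h$nbar_r)
      }
    }
    h2_env <- do.call(rbind, h2_env)
    retained <- filter_low_heritability(h2_env, config$h2_threshold)
    emit(h2_env, "heritability_env.csv")
    emit(retained, "heritability_retained.csv")

    stage <- "clonal_values"
    clonal <- list()
    h2_across <- list()
    for (tn in traits) {
      d <- adjusted[[tn]]
      keep_env <- paste(retained$location, retained$year)[retained$trait == tn]
      d <- d[paste(d$location, d$year) %in% keep_env, , drop = FALSE]
      if (nrow(d) == 0) next
      single_loc <- length(unique(d$location)) == 1
      clonal[[tn]] <- compute_clonal_values(
        d, scope = if (single_loc) "location-specific" else "across-location",
        log_transform = tn %in% config$log_traits)
      ne <- length(unique(paste(d$location, d$year)))
      if (ne >= 2) {
        h <- across_env_heritability(d)
        h2_across[[tn]] <- data.frame(trait = tn, H2 = h$H2,
                                      sigma_g2 = h$sigma_g2,
                                      sigma_ge2 = h$sigma_ge2,
                                      sigma_e2 = h$sigma_e2, ne = h$ne,
                                      nbar_r = h$nbar_r)
      }
      adjusted[[tn]] <- d
    }
    global <- global_clonal_values(clonal)
    emit(data.frame(genotype = rownames(global), global, check.names = FALSE),
         "clonal_values.csv")
    if (length(h2_across))
      emit(do.call(rbind, h2_across), "heritability_across.csv")

    stage <- "gwas"
    gwas <- list()
    for (tn in names(clonal)) {
      gwas[[tn]] <- blink_scan(geno, clonal[[tn]], n_pcs = config$n_pcs,
                               maf_min = config$maf_min,
                               alpha = config$alpha, trait = tn)
    }
    assoc <- do.call(rbind, lapply(gwas, function(g) g$associations))
    if (!is.null(assoc) && nrow(assoc))
      assoc <- colocalize_associations(assoc, config$window_bp)
    emit(if (is.null(assoc)) data.frame() else assoc, "associations.csv")

    stage <- "prediction"
    set.seed(config$seed + 1L)
    gc <- gibbs_config(config$gibbs$iterations, config$gibbs$thinning,
                       config$gibbs$burn_in)
    kb <- build_kernels(geno$dosage[rownames(global), , drop = FALSE],
                        config$bandwidths)
    abilities <- list()
    for (tn in names(clonal)) {
      y <- global[, tn]
      names(y) <- rownames(global)
      y <- y[!is.na(y)]
      Gy <- kb$G[names(y), names(y)]
      My <- kb$M[names(y), , drop = FALSE]
      plan <- make_cv_plan(names(y), k = config$cv$k,
                           repeats = config$cv$repeats, scenario = "main",
                           seed = config$seed)
      for (mod in config$models) {
        fit_fun <- switch(mod,
          gblup = function(ym) fit_gblup(ym, Gy, gc),
          bayescpi = function(ym) fit_bayescpi(ym, My, gc),
          rkhs = function(ym) fit_rkhs_multikernel(
            ym, lapply(kb$K, function(K) K[names(y), names(y)]), gc),
          rf = function(ym) fit_rf(ym, My, seed = config$seed),
          stop("run_pipeline: unknown model: ", mod))
        abilities[[paste(tn, mod)]] <-
          run_cv(y, plan, fit_fun, model = mod, trait = tn)
      }
    }
    abilities <- do.call(rbind, abilities)
    emit(abilities, "predictive_ability.csv")
    agg <- aggregate_abilities(abilities)
    emit(agg$per_trait, "predictive_ability_per_trait.csv")

    stage <- "decomposition"
    profiles <- list()
    for (tn in names(clonal)) {
      sig <- gwas[[tn]]$associations
      snps <- if (nrow(sig)) {
        geno$dosage[, sig$marker, drop = FALSE]
      } else NULL
      vd <- decompose_variance(adjusted[[tn]], snps)
      pr <- vd$proportions
      profiles[[tn]] <- c(genotypic = unname(vd$genotypic),
                          env = unname(pr[["env"]]), gxe = unname(pr[["gxe"]]),
                          residual = unname(pr[["residual"]]))
    }
    prof_tab <- do.call(rbind, profiles)
    emit(data.frame(trait = rownames(prof_tab), prof_tab), "variance_profiles.csv")
    clusters <- NULL
    if (nrow(prof_tab) >= 3) {
      clusters <- cluster_traits(prof_tab)
      emit(data.frame(trait = rownames(prof_tab), cluster = clusters$labels),
           "trait_clusters.csv")
    }

    stage <- "manifest"
    manifest <- list(
      package = "orchardgx",
      version = as.character(utils::packageVersion("orchardgx")),
      seed = config$seed,
      h2_threshold = config$h2_threshold, n_pcs = config$n_pcs,
      maf_min = config$maf_min, alpha = config$alpha,
      gibbs = config$gibbs, cv = config$cv,
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(file.path(config$out_dir, written))), written)))
    jsonlite::write_json(manifest, outfile("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    result <- list(adjusted = adjusted, h2_env = h2_env, retained = retained,
                   clonal = clonal, global = global,
                   h2_across = if (length(h2_across)) do.call(rbind, h2_across),
                   gwas = gwas, abilities = abilities, aggregated = agg,
                   profiles = prof_tab, clusters = clusters,
                   manifest = manifest)
  }, error = function(e) {
    stop("run_pipeline: stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  result
}
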