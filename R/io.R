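#' Write genotypes as dosage TSV plus marker-map CSV
#'
#' @param genotypes a `gx_geno`.
#' @param dosage_file TSV path (first column `id`, then one column per
#'   marker).
#' @param map_file CSV path (marker, chrom, pos).
#' @param group_file optional CSV path (id, group).
#' @return invisibly, the file paths.
#' @export
write_dosage_tsv <- function(genotypes, dosage_file, map_file,
                             group_file = NULL) {
  stopifnot(inherits(genotypes, "gx_geno"))
  df <- data.frame(id = rownames(genotypes$dosage), genotypes$dosage,
                   check.names = FALSE)
  utils::write.table(df, dosage_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(genotypes$map, map_file, row.names = FALSE)
  if (!is.null(group_file))
    utils::write.csv(data.frame(id = names(genotypes$group),
                                group = unname(genotypes$group)),
                     group_file, row.names = FALSE)
  invisible(c(dosage_file, map_file, group_file))
}

#' Read genotypes from dosage TSV plus marker-map CSV
#'
#' @param dosage_file,map_file paths written by [write_dosage_tsv()].
#' @param group_file optional group CSV.
#' @return A `gx_geno`.
#' @export
read_dosage_tsv <- function(dosage_file, map_file, group_file = NULL) {
  df <- utils::read.table(dosage_file, sep = "\t", header = TRUE,
                          check.names = FALSE)
  map <- utils::read.csv(map_file)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(map)))
    stop("read_dosage_tsv: map must have columns marker, chrom, pos")
  dosage <- as.matrix(df[, -1, drop = FALSE])
  rownames(dosage) <- df$id
  storage.mode(dosage) <- "integer"
  bad <- !colnames(dosage) %in% map$marker
  if (any(bad))
    stop("read_dosage_tsv: dosage columns missing from map: ",
         paste(utils::head(colnames(dosage)[bad]), collapse = ", "))
  map <- map[match(colnames(dosage), map$marker), ]
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE))
    stop("read_dosage_tsv: dosages outside {0,1,2}")
  group <- stats::setNames(rep("unknown", nrow(dosage)), rownames(dosage))
  if (!is.null(group_file)) {
    gf <- utils::read.csv(group_file)
    group[as.character(gf$id)] <- as.character(gf$group)
  }
  new_gx_geno(dosage, map, group)
}

#' Write genotypes as a minimal VCF (GT field, unphased)
#'
#' @param genotypes a `gx_geno`.
#' @param file output path (plain text).
#' @return invisibly, `file`.
#' @export
write_vcf <- function(genotypes, file) {
  stopifnot(inherits(genotypes, "gx_geno"))
  ids <- rownames(genotypes$dosage)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  gt <- c("0/0", "0/1", "1/1")
  for (k in seq_len(ncol(genotypes$dosage))) {
    row <- c(genotypes$map$chrom[k], genotypes$map$pos[k],
             genotypes$map$marker[k], "A", "T", ".", "PASS", ".", "GT",
             gt[genotypes$dosage[, k] + 1L])
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(file)
}

#' Read dosages from a VCF (GT field; alt-allele counts)
#'
#' Multi-allelic sites and records with malformed GT are skipped with a
#' warning. Uses the vcfR parser.
#'
#' @param file VCF path.
#' @return A `gx_geno`.
#' @export
read_vcf_dosages <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_dosages: the vcfR package is required")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning("read_vcf_dosages: skipping ", sum(multi), " multi-allelic site(s)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1")] <- 2L
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  map <- data.frame(marker = ids, chrom = fix$CHROM,
                    pos = as.numeric(fix$POS), stringsAsFactors = FALSE)
  suppressWarnings({chrn <- as.numeric(map$chrom)})
  if (!anyNA(chrn)) map$chrom <- chrn
  dosage <- t(dos)
  colnames(dosage) <- map$marker
  new_gx_geno(dosage, map,
              stats::setNames(rep("unknown", nrow(dosage)), rownames(dosage)))
}

#' Read/write long-format phenotype records
#'
#' Columns: genotype, location, year, row, col, trait, value.
#' @param records data.frame to write.
#' @param file CSV path.
#' @return the records (read) or invisibly the path (write).
#' @export
write_phenotypes_csv <- function(records, file) {
  utils::write.csv(records, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("genotype", "location", "year", "trait", "value")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_phenotypes_csv: missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(d$value) | is.na(d$genotype) | d$genotype == "")
  if (length(bad))
    stop("read_phenotypes_csv: malformed row(s): ",
         paste(utils::head(bad), collapse = ", "))
  d
}

#' Read/write pedigree tables (id, parent1, parent2, generation)
#' @param pedigree data.frame to write.
#' @param file CSV path.
#' @export
write_pedigree_csv <- function(pedigree, file) {
  utils::write.csv(pedigree, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("id", "parent1", "parent2", "generation")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_pedigree_csv: missing column(s): ", paste(miss, collapse = ", "))
  d
}

#' Read a published-locus catalog (trait_group, chrom, segment, ...)
#' @param file CSV path.
#' @export
read_catalog_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("trait_group", "chrom", "segment")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_catalog_csv: missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(d$segment), c("top", "center", "bottom"))
  if (length(bad))
    stop("read_catalog_csv: unknown segment label(s): ", paste(bad, collapse = ", "))
  d
}

#' Pipeline configuration
#'
#' Bundles paths, trait settings and stage parameters with the standard
#' defaults (heritability threshold 0.1, two GWAS PCs, MAF 0.05, Gaussian
#' kernel bandwidths 0.1/0.5/2.5, Gibbs 12000/5/2000, 500 RF trees, 100 kb
#' co-localization window, 3000-marker LD window, loading prior variance
#' 100). Load from YAML with [read_pipeline_config()].
#'
#' @param genotype_dosage,genotype_map,phenotypes,pedigree,catalog input
#'   paths (`pedigree`/`catalog` optional).
#' @param out_dir output directory.
#' @param traits optional character vector (default: all traits found).
#' @param log_traits traits to log-transform before clonal-value fitting.
#' @param h2_threshold,n_pcs,maf_min,alpha,bandwidths,window_bp,ld_window_markers,loading_prior_var
#'   stage parameters.
#' @param models main-effect models to cross-validate in [run_pipeline()].
#' @param gibbs list(iterations, thinning, burn_in).
#' @param cv list(k, repeats).
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotype_dosage, genotype_map, phenotypes,
                            pedigree = NULL, catalog = NULL,
                            out_dir = "orchardgx_out", traits = NULL,
                            log_traits = character(0), h2_threshold = 0.1,
                            n_pcs = 2, maf_min = 0.05, alpha = 0.05,
                            bandwidths = c(0.1, 0.5, 2.5), window_bp = 1e5,
                            ld_window_markers = 3000,
                            loading_prior_var = 100,
                            models = c("gblup"),
                            gibbs = list(iterations = 12000, thinning = 5,
                                         burn_in = 2000),
                            cv = list(k = 5, repeats = 5), seed = 1L) {
  cfg <- list(genotype_dosage = genotype_dosage, genotype_map = genotype_map,
              phenotypes = phenotypes, pedigree = pedigree, catalog = catalog,
              out_dir = out_dir, traits = traits, log_traits = log_traits,
              h2_threshold = h2_threshold, n_pcs = n_pcs, maf_min = maf_min,
              alpha = alpha, bandwidths = bandwidths, window_bp = window_bp,
              ld_window_markers = ld_window_markers,
              loading_prior_var = loading_prior_var, models = models,
              gibbs = gibbs, cv = cv, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file with fields matching [pipeline_config()]'s
#'   arguments.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Load and cross-validate the pipeline inputs
#'
#' @param config a [pipeline_config()].
#' @return list with `genotypes`, `phenotypes`, `pedigree` (or NULL),
#'   `catalog` (or NULL).
#' @export
load_inputs <- function(config) {
  for (f in c(config$genotype_dosage, config$genotype_map, config$phenotypes,
              config$pedigree, config$catalog))
    if (!file.exists(f)) stop("load_inputs: missing input file: ", f)
  geno <- read_dosage_tsv(config$genotype_dosage, config$genotype_map)
  phen <- read_phenotypes_csv(config$phenotypes)
  shared <- intersect(rownames(geno$dosage), unique(phen$genotype))
  if (length(shared) == 0)
    stop("load_inputs: genotype and phenotype ids do not overlap")
  unknown <- setdiff(unique(phen$genotype), rownames(geno$dosage))
  if (length(unknown))
    warning("load_inputs: dropping phenotype rows for ungenotyped id(s): ",
            paste(utils::head(unknown), collapse = ", "))
  phen <- phen[phen$genotype %in% shared, , drop = FALSE]
  ped <- if (!is.null(config$pedigree)) read_pedigree_csv(config$pedigree)
  cat_ <- if (!is.null(config$catalog)) read_catalog_csv(config$catalog)
  list(genotypes = geno, phenotypes = phen, pedigree = ped, catalog = cat_)
}
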