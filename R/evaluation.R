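#' Build a cross-validation plan
#'
#' Folds partition the genotype set into k nearly equal blocks (sizes differ
#' by at most one); each repeat reshuffles independently, with per-repeat
#' seeds derived from the master seed. Scenarios: `main` masks a genotype's
#' response outright; `CV1` masks a genotype's records in every environment;
#' `CV2` masks them everywhere except the reference environments.
#'
#' @param genotypes character vector of genotype ids.
#' @param k number of folds.
#' @param repeats number of independent repeats.
#' @param scenario "main", "CV1" or "CV2".
#' @param reference_envs environments kept unmasked under CV2.
#' @param seed master seed.
#' @return data.frame of class `gx_cvplan` with columns repeat_i, fold,
#'   genotype (the masked genotypes of that fold); attributes k, repeats,
#'   scenario, reference_envs, seed.
#' @export
make_cv_plan <- function(genotypes, k = 5L, repeats = 5L,
                         scenario = c("main", "CV1", "CV2"),
                         reference_envs = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  n <- length(genotypes)
  if (k > n) stop("make_cv_plan: more folds than genotypes")
  if (scenario == "CV2" && (is.null(reference_envs) || !length(reference_envs)))
    stop("make_cv_plan: CV2 requires reference environments")
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  plans <- lapply(seq_len(repeats), function(rep_i) {
    set.seed(seed * 1000L + rep_i)
    shuffled <- sample(genotypes)
    fold <- rep(seq_len(k), times = sizes)
    data.frame(repeat_i = rep_i, fold = fold, genotype = shuffled,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, plans)
  structure(out, k = k, repeats = repeats, scenario = scenario,
            reference_envs = reference_envs, seed = seed,
            class = c("gx_cvplan", "data.frame"))
}

#' Masked genotypes of one (repeat, fold) cell
#' @param plan a `gx_cvplan`.
#' @param repeat_i,fold indices.
#' @return character vector of genotype ids.
#' @export
cv_masked <- function(plan, repeat_i, fold) {
  plan$genotype[plan$repeat_i == repeat_i & plan$fold == fold]
}

#' Apply a CV mask to a response
#'
#' For a vector response (main scenario), masked genotypes become NA. For a
#' genotype x environment matrix, CV1 masks all environments of the masked
#' genotypes, CV2 all except the plan's reference environments.
#'
#' @param y named vector or genotype x environment matrix.
#' @param masked genotype ids to mask.
#' @param scenario "main", "CV1" or "CV2".
#' @param reference_envs kept environments under CV2.
#' @return `y` with masked entries set to NA.
#' @export
apply_cv_mask <- function(y, masked, scenario = "main",
                          reference_envs = NULL) {
  if (is.matrix(y)) {
    rows <- rownames(y) %in% masked
    if (scenario == "CV2") {
      cols <- !(colnames(y) %in% reference_envs)
      y[rows, cols] <- NA
    } else {
      y[rows, ] <- NA
    }
  } else {
    y[names(y) %in% masked] <- NA
  }
  y
}

#' Predictive ability (Pearson correlation on masked genotypes)
#'
#' @param observed,predicted aligned numeric vectors (same names/order).
#' @param group optional grouping (e.g. environment) for per-group
#'   correlations.
#' @return data.frame group, r, n_pairs; r is NA (with a warning) when a
#'   group has fewer than 3 complete pairs or a constant side.
#' @export
predictive_ability <- function(observed, predicted, group = NULL) {
  if (length(observed) != length(predicted))
    stop("predictive_ability: observed and predicted are misaligned")
  if (!is.null(names(observed)) && !is.null(names(predicted)) &&
      !identical(names(observed), names(predicted)))
    stop("predictive_ability: observed and predicted names disagree")
  if (is.null(group)) group <- rep("global", length(observed))
  out <- lapply(split(seq_along(observed), group), function(ii) {
    o <- observed[ii]; p <- predicted[ii]
    ok <- !is.na(o) & !is.na(p)
    n_ok <- sum(ok)
    if (n_ok < 3 || stats::sd(o[ok]) == 0 || stats::sd(p[ok]) == 0) {
      warning("predictive_ability: degenerate group (", group[ii[1]],
              "); reported as NA")
      r <- NA_real_
    } else r <- stats::cor(o[ok], p[ok])
    data.frame(group = as.character(group[ii[1]]), r = r, n_pairs = n_ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run a main-effect model through a CV plan
#'
#' For every (repeat, fold) cell the masked response is handed to `fit_fun`,
#' which must return predictions for all genotypes (a named vector or a
#' `gx_fit`, whose `yhat` is used); ability is the Pearson correlation
#' between observed and predicted values of the masked genotypes only.
#'
#' @param y named response vector (complete).
#' @param plan a `gx_cvplan` (scenario "main").
#' @param fit_fun function(y_masked) -> predictions.
#' @param model,trait labels stored on the records.
#' @return data.frame of ability records: trait, model, scenario, repeat_i,
#'   fold, environment ("global"), r, n_pairs.
#' @export
run_cv <- function(y, plan, fit_fun, model = "model", trait = "trait") {
  stopifnot(inherits(plan, "gx_cvplan"))
  recs <- list()
  for (rep_i in seq_len(attr(plan, "repeats"))) {
    for (fd in seq_len(attr(plan, "k"))) {
      masked <- cv_masked(plan, rep_i, fd)
      ym <- apply_cv_mask(y, masked, "main")
      fit <- fit_fun(ym)
      pred <- if (inherits(fit, "gx_fit")) fit$yhat else fit
      pa <- predictive_ability(y[masked], pred[masked])
      recs[[length(recs) + 1]] <- data.frame(
        trait = trait, model = model, scenario = "main", repeat_i = rep_i,
        fold = fd, environment = "global", r = pa$r, n_pairs = pa$n_pairs,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, recs)
}

#' Run a multi-environment model through a CV plan
#'
#' Masks the genotype x environment response per the plan's scenario, fits,
#' and computes predictive ability separately for each predicted environment
#' on the masked cells.
#'
#' @param Y genotype x environment matrix (complete cells = observed).
#' @param plan a `gx_cvplan` with scenario "CV1" or "CV2".
#' @param fit_fun function(Y_masked) -> fit with `yhat` matrix (or a matrix).
#' @param model,trait labels.
#' @return ability records as in [run_cv()], one row per (repeat, fold,
#'   environment).
#' @export
run_cv_multienv <- function(Y, plan, fit_fun, model = "model",
                            trait = "trait") {
  stopifnot(inherits(plan, "gx_cvplan"))
  scenario <- attr(plan, "scenario")
  if (!scenario %in% c("CV1", "CV2"))
    stop("run_cv_multienv: plan scenario must be CV1 or CV2")
  ref <- attr(plan, "reference_envs")
  recs <- list()
  for (rep_i in seq_len(attr(plan, "repeats"))) {
    for (fd in seq_len(attr(plan, "k"))) {
      masked <- cv_masked(plan, rep_i, fd)
      Ym <- apply_cv_mask(Y, masked, scenario, ref)
      fit <- fit_fun(Ym)
      pred <- if (inherits(fit, "gx_fit")) fit$yhat else fit
      eval_envs <- if (scenario == "CV2") setdiff(colnames(Y), ref) else colnames(Y)
      for (ev in eval_envs) {
        obs <- Y[masked, ev]
        ok <- !is.na(obs)
        pa <- suppressWarnings(
          predictive_ability(obs[ok], pred[masked, ev][ok]))
        recs[[length(recs) + 1]] <- data.frame(
          trait = trait, model = model, scenario = scenario,
          repeat_i = rep_i, fold = fd, environment = ev, r = pa$r,
          n_pairs = pa$n_pairs, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, recs)
}

#' Aggregate predictive-ability records
#'
#' Arithmetic means excluding missing entries: per-trait averages
#' (trait x model x scenario) and overall per-model averages of the
#' per-trait values.
#'
#' @param records ability records from [run_cv()]/[run_cv_multienv()].
#' @return list with `per_trait` (trait, model, scenario, r_bar, n_used) and
#'   `overall` (model, scenario, r_bar, n_traits).
#' @export
aggregate_abilities <- function(records) {
  records <- as.data.frame(records)
  key <- interaction(records$trait, records$model, records$scenario, drop = TRUE)
  per_trait <- do.call(rbind, lapply(split(records, key), function(d) {
    data.frame(trait = d$trait[1], model = d$model[1], scenario = d$scenario[1],
               r_bar = mean(d$r, na.rm = TRUE), n_used = sum(!is.na(d$r)),
               stringsAsFactors = FALSE)
  }))
  rownames(per_trait) <- NULL
  key2 <- interaction(per_trait$model, per_trait$scenario, drop = TRUE)
  overall <- do.call(rbind, lapply(split(per_trait, key2), function(d) {
    data.frame(model = d$model[1], scenario = d$scenario[1],
               r_bar = mean(d$r_bar, na.rm = TRUE), n_traits = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(overall) <- NULL
  list(per_trait = per_trait, overall = overall)
}
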