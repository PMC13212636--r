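# Internal-external cross-validation (leave-one-study-out), random-effects
# pooling of fold metrics, bootstrap model comparison, and the full
# multiply-imputed analysis run.

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-study variance tau^2; weights
#' `1/(se^2 + tau^2)`; pooled mean with a normal-approximation 95% CI.
#' A single fold returns itself with `tau2 = 0`.
#'
#' @param fold_values per-fold metric values.
#' @param fold_ses per-fold standard errors (all > 0).
#' @return Object of class `pooled_estimate`: `value`, `ci_lo`, `ci_hi`,
#'   `se`, `tau2`, `k`, and the fold inputs.
#' @export
pool_random_effects <- function(fold_values, fold_ses) {
  stopifnot(length(fold_values) == length(fold_ses), length(fold_values) >= 1L)
  if (any(!is.finite(fold_ses)) || any(fold_ses <= 0))
    stop("fold standard errors must be positive", call. = FALSE)
  k <- length(fold_values)
  if (k == 1L) {
    out <- list(value = fold_values, se = fold_ses, tau2 = 0,
                ci_lo = fold_values - 1.959964 * fold_ses,
                ci_hi = fold_values + 1.959964 * fold_ses,
                k = 1L, fold_values = fold_values, fold_ses = fold_ses)
    return(structure(out, class = "pooled_estimate"))
  }
  w <- 1 / fold_ses^2
  ybar <- sum(w * fold_values) / sum(w)
  Q <- sum(w * (fold_values - ybar)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / C)
  ws <- 1 / (fold_ses^2 + tau2)
  pooled <- sum(ws * fold_values) / sum(ws)
  se <- sqrt(1 / sum(ws))
  structure(list(value = pooled, se = se, tau2 = tau2,
                 ci_lo = pooled - 1.959964 * se,
                 ci_hi = pooled + 1.959964 * se, k = k,
                 fold_values = fold_values, fold_ses = fold_ses),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(format(x$value, digits = 4), " (95% CI ", format(x$ci_lo, digits = 4),
      " to ", format(x$ci_hi, digits = 4), "; tau2 = ",
      format(x$tau2, digits = 3), "; k = ", x$k, ")\n", sep = "")
  invisible(x)
}

.default_metrics <- c("c_ordinal", "c_good", "cal_slope", "cal_intercept",
                      "c_for_benefit", "mean_cal_benefit")

# continuous/categorical baseline covariates referenced by a spec,
# used as default matching covariates
.spec_covariates <- function(spec) names(spec$terms)

# metrics with SEs on one held-out cohort given a fitted model
.fold_metrics <- function(model, holdout, metrics, seed, matching,
                          match_covariates) {
  df <- as.data.frame(holdout)
  eta <- linear_predictor(model, holdout)
  p_good <- as.numeric(predict_good_outcome(model, holdout))
  ben <- predict_benefit(model, holdout)
  good <- as.integer(df$mrs90 <= 2L)
  rows <- list()
  add <- function(metric, value, se)
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric, value = value,
                                             se = se, stringsAsFactors = FALSE)
  safe <- function(metric, expr)
    tryCatch(expr, error = function(e) {
      warning("fold metric '", metric, "' undefined: ", conditionMessage(e),
              call. = FALSE)
      add(metric, NA_real_, NA_real_)
    })
  if ("c_ordinal" %in% metrics)
    safe("c_ordinal", { m <- c_ordinal(df$mrs90, eta); add("c_ordinal", m$value, m$se) })
  if ("c_good" %in% metrics)
    safe("c_good", { m <- c_binary(good, p_good); add("c_good", m$value, m$se) })
  if (any(c("cal_slope", "cal_intercept") %in% metrics))
    safe("cal_slope", {
      cal <- calibration_slope_intercept(good, p_good)
      if ("cal_slope" %in% metrics) add("cal_slope", cal$slope, cal$slope_se)
      if ("cal_intercept" %in% metrics)
        add("cal_intercept", cal$intercept, cal$intercept_se)
    })
  pairs <- NULL
  if (any(c("c_for_benefit", "mean_cal_benefit") %in% metrics)) {
    safe("c_for_benefit", {
      pairs <- match_pairs(holdout, match_covariates, ben$benefit,
                           method = matching, within_trial = FALSE,
                           seed = seed)
      if ("c_for_benefit" %in% metrics) {
        m <- c_for_benefit(pairs)
        add("c_for_benefit", m$value, m$se)
      }
      if ("mean_cal_benefit" %in% metrics) {
        mc <- mean_calibration_benefit(pairs)
        # SE of the observed-minus-predicted pair mean
        add("mean_cal_benefit", mc,
            stats::sd(pairs$observed - pairs$predicted) / sqrt(nrow(pairs)))
      }
    })
  }
  list(metrics = do.call(rbind, rows), pairs = pairs,
       predictions = data.frame(patient_id = df$patient_id,
                                trial_id = df$trial_id, mrs90 = df$mrs90,
                                good = good, evt = df$evt, eta = eta,
                                p_good = p_good,
                                p_good_evt = ben$p_good_evt,
                                p_good_control = ben$p_good_control,
                                benefit = ben$benefit,
                                stringsAsFactors = FALSE))
}

#' Leave-one-study-out internal-external cross-validation
#'
#' For each trial, the model specification is re-fit on all other trials
#' (knot placement included, so no information leaks from the held-out
#' study) and evaluated on the held-out trial: ordinal and binary
#' C-statistics, calibration slope and intercept, and, via matched pairs
#' built within the held-out trial, C-for-benefit and mean benefit
#' calibration. Fold estimates are pooled by random-effects
#' meta-analysis. The variable set of `spec` is taken as fixed in
#' advance (run [backward_eliminate()] beforehand).
#'
#' @param cohort a complete `trial_cohort` with at least 2 trials.
#' @param spec a `model_spec`.
#' @param metrics subset of
#'   `c("c_ordinal","c_good","cal_slope","cal_intercept","c_for_benefit","mean_cal_benefit")`.
#' @param seed integer seed (tie-breaking in matching).
#' @param matching matching method for benefit metrics.
#' @param match_covariates covariates for the matching distance (default:
#'   all variables of `spec`).
#' @return Object of class `iecv_result`: per-fold models and metric
#'   tables, pooled estimates, and the out-of-fold prediction table.
#' @export
iecv <- function(cohort, spec, metrics = .default_metrics, seed = 1L,
                 matching = "mahalanobis", match_covariates = NULL) {
  df <- as.data.frame(cohort)
  trials <- attr(cohort, "trial_ids") %||% unique(df$trial_id)
  if (length(trials) < 2L)
    stop("internal-external cross-validation needs at least 2 trials",
         call. = FALSE)
  if (is.null(match_covariates)) match_covariates <- .spec_covariates(spec)
  folds <- list()
  for (i in seq_along(trials)) {
    t_out <- trials[i]
    train <- trial_cohort(df[df$trial_id != t_out, , drop = FALSE],
                          validate = FALSE)
    hold <- trial_cohort(df[df$trial_id == t_out, , drop = FALSE],
                         validate = FALSE)
    model <- fit_outcome_model(train, spec)
    fm <- .fold_metrics(model, hold, metrics, seed = seed + i,
                        matching = matching,
                        match_covariates = match_covariates)
    folds[[t_out]] <- list(trial_id = t_out, model = model,
                           metrics = fm$metrics, pairs = fm$pairs,
                           predictions = fm$predictions)
  }
  per_fold <- do.call(rbind, lapply(folds, function(f) {
    cbind(trial_id = f$trial_id, f$metrics, stringsAsFactors = FALSE)
  }))
  rownames(per_fold) <- NULL
  pooled <- lapply(intersect(metrics, unique(per_fold$metric)), function(m) {
    sel <- per_fold[per_fold$metric == m & is.finite(per_fold$value) &
                      is.finite(per_fold$se) & per_fold$se > 0, , drop = FALSE]
    if (nrow(sel) == 0L) return(NULL)
    pool_random_effects(sel$value, sel$se)
  })
  names(pooled) <- intersect(metrics, unique(per_fold$metric))
  pooled <- pooled[!vapply(pooled, is.null, logical(1))]
  oof <- do.call(rbind, lapply(folds, `[[`, "predictions"))
  rownames(oof) <- NULL
  structure(list(folds = folds, per_fold = per_fold, pooled = pooled,
                 oof = oof, spec = spec),
            class = "iecv_result")
}

#' @export
print.iecv_result <- function(x, ...) {
  cat("Internal-external cross-validation: ", length(x$folds),
      " leave-one-study-out folds\n", sep = "")
  for (m in names(x$pooled)) {
    cat("  ", format(m, width = 18), " ", sep = "")
    print(x$pooled[[m]])
  }
  invisible(x)
}

#' Bootstrap comparison of two models' discrimination
#'
#' Point difference in the chosen concordance between two out-of-fold
#' prediction sets on identical patients, with a percentile 95% CI from
#' resampling patients (or matched pairs, for C-for-benefit) with
#' replacement, stratified by trial; both metrics are recomputed on the
#' same resample.
#'
#' @param preds_a,preds_b out-of-fold prediction tables (from
#'   `iecv()$oof`) for `metric = "c_good"`, or `pair_set`s with identical
#'   pair structure for `metric = "c_for_benefit"`.
#' @param metric `"c_good"` or `"c_for_benefit"`.
#' @param B bootstrap resamples (default 500).
#' @param seed integer seed.
#' @return Object of class `model_comparison`: `delta`, `ci_lo`, `ci_hi`,
#'   `B`, `seed`.
#' @export
compare_models_bootstrap <- function(preds_a, preds_b,
                                     metric = c("c_good", "c_for_benefit"),
                                     B = 500L, seed = 1L) {
  metric <- match.arg(metric)
  if (B < 100L) stop("need at least 100 bootstrap resamples", call. = FALSE)
  if (metric == "c_good") {
    key_a <- preds_a$patient_id; key_b <- preds_b$patient_id
    if (!setequal(key_a, key_b) || length(key_a) != length(key_b))
      stop("prediction sets do not cover identical patients", call. = FALSE)
    preds_b <- preds_b[match(key_a, key_b), , drop = FALSE]
    obs <- preds_a$good; sa <- preds_a$p_good; sb <- preds_b$p_good
    strat <- preds_a$trial_id
  } else {
    if (nrow(preds_a) != nrow(preds_b) ||
        !all(preds_a$treated_id == preds_b$treated_id) ||
        !all(preds_a$control_id == preds_b$control_id))
      stop("pair sets do not cover identical matched pairs", call. = FALSE)
    obs <- preds_a$observed; sa <- preds_a$predicted; sb <- preds_b$predicted
    strat <- preds_a$trial_id
  }
  cstat <- function(o, s) {
    if (length(unique(o)) < 2L) return(NA_real_)
    .concordance_grouped(if (metric == "c_good") as.numeric(o) else as.numeric(o),
                         s)$value
  }
  delta <- cstat(obs, sa) - cstat(obs, sb)
  old_seed <- .save_rng(seed)
  on.exit(.restore_rng(old_seed), add = TRUE)
  by_stratum <- split(seq_along(obs), strat)
  deltas <- vapply(seq_len(B), function(b) {
    idx <- unlist(lapply(by_stratum, function(ix)
      ix[sample.int(length(ix), replace = TRUE)]), use.names = FALSE)
    cstat(obs[idx], sa[idx]) - cstat(obs[idx], sb[idx])
  }, numeric(1))
  deltas <- deltas[is.finite(deltas)]
  ci <- unname(stats::quantile(deltas, c(0.025, 0.975), type = 7))
  structure(list(delta = delta, ci_lo = min(ci[1L], delta),
                 ci_hi = max(ci[2L], delta), B = B, seed = seed,
                 metric = metric, n = length(obs)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("delta ", x$metric, ": ", format(x$delta, digits = 4), " (95% CI ",
      format(x$ci_lo, digits = 4), " to ", format(x$ci_hi, digits = 4),
      "; B = ", x$B, ")\n", sep = "")
  invisible(x)
}

#' Added predictive value of candidate variables
#'
#' Each candidate term is added to the base specification in turn and
#' judged by a full-data likelihood ratio test; when the fit improves
#' (p below `p_threshold`) the extended specification is re-validated by
#' [iecv()] and the change in pooled discrimination is reported.
#'
#' @param cohort a complete `trial_cohort`.
#' @param base_spec the base `model_spec`.
#' @param add_terms named list of term descriptors to add, one at a time.
#' @param p_threshold LRT significance threshold (default 0.05).
#' @param seed integer seed.
#' @param metrics metrics for the re-validation.
#' @return data.frame: `variable`, `lrt_statistic`, `df`, `p`,
#'   `delta_pooled_c_good`, `delta_pooled_c_for_benefit` (NA when the
#'   LRT did not reach the threshold).
#' @export
added_value_analysis <- function(cohort, base_spec, add_terms,
                                 p_threshold = 0.05, seed = 1L,
                                 metrics = c("c_good", "c_for_benefit")) {
  for (nm in names(add_terms))
    if (nm %in% names(base_spec$terms))
      stop("variable already in the base specification: ", nm, call. = FALSE)
  base_fit <- fit_outcome_model(cohort, base_spec)
  base_iecv <- NULL
  rows <- lapply(names(add_terms), function(nm) {
    ext_spec <- base_spec
    ext_spec$terms[[nm]] <- add_terms[[nm]]
    res <- tryCatch({
      ext_fit <- fit_outcome_model(cohort, ext_spec)
      lrt <- likelihood_ratio_test(ext_fit, base_fit)
      d_c <- NA_real_; d_cb <- NA_real_
      if (lrt$p < p_threshold) {
        if (is.null(base_iecv))
          base_iecv <<- iecv(cohort, base_spec, metrics = metrics, seed = seed)
        ext_iecv <- iecv(cohort, ext_spec, metrics = metrics, seed = seed)
        if (!is.null(base_iecv$pooled$c_good) && !is.null(ext_iecv$pooled$c_good))
          d_c <- ext_iecv$pooled$c_good$value - base_iecv$pooled$c_good$value
        if (!is.null(base_iecv$pooled$c_for_benefit) &&
            !is.null(ext_iecv$pooled$c_for_benefit))
          d_cb <- ext_iecv$pooled$c_for_benefit$value -
            base_iecv$pooled$c_for_benefit$value
      }
      data.frame(variable = nm, lrt_statistic = lrt$statistic, df = lrt$df,
                 p = lrt$p, delta_pooled_c_good = d_c,
                 delta_pooled_c_for_benefit = d_cb, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(variable = nm, lrt_statistic = NA_real_, df = NA_integer_,
                 p = NA_real_, delta_pooled_c_good = NA_real_,
                 delta_pooled_c_for_benefit = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE))
    res
  })
  do.call(rbind, rows)
}

# Rubin-style combination of one metric across m imputations, per fold:
# mean of values; total variance = mean within-imputation variance +
# (1 + 1/m) * between-imputation variance
.rubin_combine <- function(values, ses) {
  m <- length(values)
  v <- mean(values)
  within <- mean(ses^2)
  between <- if (m > 1L) stats::var(values) else 0
  list(value = v, se = sqrt(within + (1 + 1 / m) * between))
}

#' Run the full development-and-validation analysis
#'
#' Multiple imputation, per-imputation leave-one-study-out
#' cross-validation of each model specification, Rubin combination of
#' fold metrics across imputations, random-effects pooling across folds,
#' pairwise bootstrap model comparisons on imputation-averaged
#' out-of-fold predictions, and odds-ratio tables from the full-data
#' fits. Deterministic under the configured seed.
#'
#' @param cohort a `trial_cohort` (may contain missing covariates).
#' @param specs named list of `model_spec`s (conventionally `ct`,
#'   `ct_extended`, `reference`).
#' @param config a `run_config` (see [run_config()]).
#' @return Object of class `analysis_report`: `performance` (metric x
#'   model x fold), `pooled` (per model per metric), `comparisons`,
#'   `or_tables`, `forest`, `log`.
#' @export
run_full_analysis <- function(cohort, specs = list(ct = ct_imaging_spec(),
                                                   ct_extended = ct_extended_spec(),
                                                   reference = mr_predicts_spec()),
                              config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  imputed <- impute_missing(cohort, m = config$m, seed = config$seed)
  m <- length(imputed)

  perf_rows <- list(); iecv_store <- list()
  for (model_name in names(specs)) {
    per_imp <- lapply(seq_len(m), function(im)
      iecv(imputed[[im]], specs[[model_name]], metrics = config$metrics,
           seed = config$seed + 1000L * im, matching = config$matching))
    iecv_store[[model_name]] <- per_imp
    # Rubin-combine per fold and metric across imputations
    all_pf <- do.call(rbind, lapply(seq_len(m), function(im)
      cbind(imp = im, per_imp[[im]]$per_fold)))
    for (mt in unique(all_pf$metric)) {
      for (tid in unique(all_pf$trial_id)) {
        sel <- all_pf[all_pf$metric == mt & all_pf$trial_id == tid &
                        is.finite(all_pf$value) & is.finite(all_pf$se), ,
                      drop = FALSE]
        if (nrow(sel) == 0L) next
        rc <- .rubin_combine(sel$value, sel$se)
        perf_rows[[length(perf_rows) + 1L]] <-
          data.frame(model = model_name, metric = mt, fold = tid,
                     value = rc$value, se = rc$se, stringsAsFactors = FALSE)
      }
    }
  }
  performance <- do.call(rbind, perf_rows)

  pooled <- list()
  for (model_name in names(specs)) {
    pooled[[model_name]] <- list()
    for (mt in unique(performance$metric)) {
      sel <- performance[performance$model == model_name &
                           performance$metric == mt & performance$se > 0, ,
                         drop = FALSE]
      if (nrow(sel) == 0L) next
      pooled[[model_name]][[mt]] <- pool_random_effects(sel$value, sel$se)
    }
  }

  # imputation-averaged out-of-fold predictions per model
  oof <- lapply(names(specs), function(model_name) {
    per_imp <- iecv_store[[model_name]]
    base <- per_imp[[1L]]$oof
    base <- base[order(base$patient_id), , drop = FALSE]
    for (cl in c("eta", "p_good", "p_good_evt", "p_good_control", "benefit")) {
      acc <- base[[cl]]
      if (m > 1L) for (im in 2:m) {
        oo <- per_imp[[im]]$oof
        acc <- acc + oo[[cl]][order(oo$patient_id)]
      }
      base[[cl]] <- acc / m
    }
    base
  })
  names(oof) <- names(specs)

  # pairwise comparisons: c_good on out-of-fold predictions; c_for_benefit
  # on a shared pair structure matched on the union of spec covariates
  combos <- utils::combn(names(specs), 2L, simplify = FALSE)
  match_cov <- Reduce(union, lapply(specs, .spec_covariates))
  complete1 <- imputed[[1L]]
  # one shared pair structure; per-model predictions are swapped in
  b1 <- oof[[1L]]
  bb <- b1$benefit[match(as.data.frame(complete1)$patient_id, b1$patient_id)]
  ref_pairs <- match_pairs(complete1, match_cov, bb, method = config$matching,
                           within_trial = TRUE, seed = config$seed)
  pair_sets <- lapply(names(specs), function(model_name) {
    ps <- ref_pairs
    b <- oof[[model_name]]
    ps$predicted <- (b$benefit[match(ps$treated_id, b$patient_id)] +
                       b$benefit[match(ps$control_id, b$patient_id)]) / 2
    ps
  })
  names(pair_sets) <- names(specs)
  comparisons <- list()
  for (cb in combos) {
    nm <- paste(cb[1L], "vs", cb[2L])
    comparisons[[nm]] <- list(
      c_good = compare_models_bootstrap(oof[[cb[1L]]], oof[[cb[2L]]],
                                        metric = "c_good", B = config$B,
                                        seed = config$seed),
      c_for_benefit = compare_models_bootstrap(pair_sets[[cb[1L]]],
                                               pair_sets[[cb[2L]]],
                                               metric = "c_for_benefit",
                                               B = config$B,
                                               seed = config$seed))
  }

  # odds-ratio tables from full-data fits on the first completed cohort
  or_tables <- lapply(specs, function(sp)
    summarize_effects(fit_outcome_model(complete1, sp)))

  forest <- performance[performance$metric %in% c("c_good", "c_ordinal"), ,
                        drop = FALSE]
  log <- list(seed = config$seed, m = m, B = config$B,
              config_hash = config_hash(config),
              package_version = as.character(utils::packageVersion("evtpredict")),
              n_patients = nrow(cohort),
              n_trials = length(attr(cohort, "trial_ids")),
              elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  structure(list(performance = performance, pooled = pooled,
                 comparisons = comparisons, or_tables = or_tables,
                 forest = forest, oof = oof, pairs = pair_sets, log = log),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report (", x$log$n_patients, " patients, ",
      x$log$n_trials, " trials, m = ", x$log$m, ", B = ", x$log$B, ")\n",
      sep = "")
  for (model_name in names(x$pooled)) {
    cat(model_name, ":\n", sep = "")
    for (mt in names(x$pooled[[model_name]])) {
      cat("  ", format(mt, width = 18), " ", sep = "")
      print(x$pooled[[model_name]][[mt]])
    }
  }
  for (nm in names(x$comparisons)) {
    cat(nm, ":\n  ", sep = "")
    print(x$comparisons[[nm]]$c_good)
    cat("  ")
    print(x$comparisons[[nm]]$c_for_benefit)
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `performance.csv`, `pooled.json`, `comparison.json`,
#' `or_table.csv`, `forest.csv` and `run_log.json` under `dir`.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_analysis_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$performance, file.path(dir, "performance.csv"),
                   row.names = FALSE)
  pooled <- lapply(report$pooled, function(per_model)
    lapply(per_model, function(p)
      list(value = p$value, ci_lo = p$ci_lo, ci_hi = p$ci_hi,
           tau2 = p$tau2, k = p$k)))
  jsonlite::write_json(pooled, file.path(dir, "pooled.json"),
                       auto_unbox = TRUE, digits = NA)
  comps <- lapply(report$comparisons, function(pair)
    lapply(pair, function(cmp)
      list(delta = cmp$delta, ci_lo = cmp$ci_lo, ci_hi = cmp$ci_hi,
           B = cmp$B, metric = cmp$metric)))
  jsonlite::write_json(comps, file.path(dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  or_tab <- do.call(rbind, lapply(names(report$or_tables), function(nm)
    cbind(model = nm, report$or_tables[[nm]])))
  utils::write.csv(or_tab, file.path(dir, "or_table.csv"), row.names = FALSE)
  utils::write.csv(report$forest, file.path(dir, "forest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
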