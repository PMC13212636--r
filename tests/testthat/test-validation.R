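test_that("DerSimonian-Laird pooling matches the closed form and metafor", {
  # hand computation for two studies (0.70, se 0.02; 0.76, se 0.02):
  # w = 2500 each; ybar = 0.73; Q = w*(0.03^2)*2 = 4.5; C = 5000 - 2*2500^2/5000
  # = 2500; tau2 = (4.5 - 1)/2500 = 0.0014; w* = 1/(4e-4 + 0.0014) = 555.56;
  # pooled = 0.73; se = sqrt(1/(2*555.56)) = 0.03
  pe <- pool_random_effects(c(0.70, 0.76), c(0.02, 0.02))
  expect_equal(pe$value, 0.73, tolerance = 1e-10)
  expect_equal(pe$tau2, 0.0014, tolerance = 1e-10)
  expect_equal(pe$se, 0.03, tolerance = 1e-10)
  expect_equal(pe$ci_lo, 0.73 - 1.959964 * 0.03, tolerance = 1e-9)

  # identical folds pool to themselves with tau2 = 0
  pe0 <- pool_random_effects(rep(0.7, 5L), rep(0.02, 5L))
  expect_equal(pe0$value, 0.7, tolerance = 1e-12)
  expect_identical(pe0$tau2, 0)

  # single fold: the value itself, normal CI
  pe1 <- pool_random_effects(0.7, 0.02)
  expect_equal(pe1$value, 0.7)
  expect_equal(pe1$ci_hi, 0.7 + 1.959964 * 0.02, tolerance = 1e-9)

  expect_error(pool_random_effects(c(0.7, 0.8), c(0.02, 0)), "positive")

  # independent cross-check on irregular inputs
  skip_if_not_installed("metafor")
  set.seed(31)
  yi <- stats::runif(6L, 0.6, 0.8)
  sei <- stats::runif(6L, 0.01, 0.05)
  pe <- pool_random_effects(yi, sei)
  rma <- metafor::rma(yi = yi, sei = sei, method = "DL")
  expect_equal(pe$value, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(pe$tau2, rma$tau2, tolerance = 1e-10)
  expect_equal(pe$se, rma$se, tolerance = 1e-10)
})

test_that("pooled estimates lie within the fold range", {
  set.seed(32)
  for (rep in 1:20) {
    k <- sample(2:8, 1L)
    v <- stats::runif(k, 0.5, 0.9)
    s <- stats::runif(k, 0.01, 0.08)
    pe <- pool_random_effects(v, s)
    expect_gte(pe$value, min(v))
    expect_lte(pe$value, max(v))
    expect_gte(pe$tau2, 0)
  }
})

test_that("iecv produces one fold per trial with no leakage", {
  co <- gen_cohort(n = 700L, seed = 33L)
  spec <- model_spec(list(aspects = term_linear("aspects"),
                          collateral = term_linear("collateral"),
                          bpf = term_spline("bpf", forced_middle = 80)),
                     treatment = TRUE, interactions = "collateral")
  res <- iecv(co, spec, seed = 4L)
  trials <- attr(co, "trial_ids")
  expect_identical(length(res$folds), length(trials))
  expect_setequal(names(res$folds), trials)
  # each patient predicted exactly once out-of-fold
  expect_setequal(res$oof$patient_id, as.data.frame(co)$patient_id)
  expect_identical(anyDuplicated(res$oof$patient_id), 0L)
  # pooled values inside fold ranges
  for (m in names(res$pooled)) {
    vals <- res$per_fold$value[res$per_fold$metric == m]
    expect_gte(res$pooled[[m]]$value, min(vals, na.rm = TRUE))
    expect_lte(res$pooled[[m]]$value, max(vals, na.rm = TRUE))
  }

  # leakage fingerprint: perturbing held-out outcomes leaves that fold's
  # fitted coefficients unchanged
  df <- as.data.frame(co)
  t1 <- trials[1L]
  df$mrs90[df$trial_id == t1] <- sample(0:6, sum(df$trial_id == t1),
                                        replace = TRUE)
  res2 <- iecv(trial_cohort(df), spec, seed = 4L)
  expect_equal(res2$folds[[t1]]$model$beta, res$folds[[t1]]$model$beta,
               tolerance = 1e-12)

  expect_error(iecv(trial_cohort(df[df$trial_id == t1, ], validate = FALSE),
                    spec), "at least 2 trials")
})

test_that("bootstrap model comparison is deterministic and degenerate on equal inputs", {
  co <- gen_cohort(n = 600L, seed = 34L)
  res <- iecv(co, ct_imaging_spec(), metrics = c("c_good"), seed = 5L)
  oof <- res$oof
  cmp_same <- compare_models_bootstrap(oof, oof, metric = "c_good",
                                       B = 150L, seed = 6L)
  expect_identical(cmp_same$delta, 0)
  expect_identical(c(cmp_same$ci_lo, cmp_same$ci_hi), c(0, 0))

  oof_b <- oof
  set.seed(6)
  oof_b$p_good <- stats::plogis(stats::qlogis(oof_b$p_good) +
                                  stats::rnorm(nrow(oof_b), 0, 0.6))
  c1 <- compare_models_bootstrap(oof, oof_b, metric = "c_good", B = 150L,
                                 seed = 7L)
  c2 <- compare_models_bootstrap(oof, oof_b, metric = "c_good", B = 150L,
                                 seed = 7L)
  expect_identical(c1, c2)
  expect_true(c1$ci_lo <= c1$delta && c1$delta <= c1$ci_hi)
  expect_error(compare_models_bootstrap(oof[-1L, ], oof, metric = "c_good",
                                        B = 150L), "identical patients")
  expect_error(compare_models_bootstrap(oof, oof, metric = "c_good", B = 50L),
               "at least 100")
})

test_that("true predictions dominate noise-corrupted ones in the bootstrap delta", {
  cfg <- small_config(3000L)
  co <- generate_cohort(cfg, seed = 35L)
  df <- as.data.frame(co)
  # truth: the generating probabilities themselves
  spec <- generating_model_spec(cfg)
  X <- build_design_matrix(co, spec)
  truth_eta <- drop(X %*% true_coefficients(cfg))
  p_true <- stats::plogis(cfg$intercepts[3L] + truth_eta)
  oof_a <- data.frame(patient_id = df$patient_id, trial_id = df$trial_id,
                      good = as.integer(df$mrs90 <= 2L), p_good = p_true)
  set.seed(35)
  oof_b <- oof_a
  oof_b$p_good <- stats::plogis(stats::qlogis(p_true) + stats::rnorm(nrow(df), 0, 1.5))
  cmp <- compare_models_bootstrap(oof_a, oof_b, metric = "c_good", B = 200L,
                                  seed = 8L)
  expect_gt(cmp$delta, 0)
  expect_gt(cmp$ci_lo, 0)
})

test_that("added-value analysis flags true omitted predictors and rejects bad input", {
  cfg <- small_config(4000L)
  co <- generate_cohort(cfg, seed = 36L)
  base <- ct_imaging_spec()
  base$terms$wml_volume <- NULL   # omit a true predictor (OR 0.80 per 5 mL)
  out <- added_value_analysis(co, base,
                              list(wml_volume = term_linear("wml_volume", scale = 5)),
                              seed = 9L, metrics = "c_good")
  expect_identical(out$variable, "wml_volume")
  expect_lt(out$p, 0.05)
  expect_false(is.na(out$delta_pooled_c_good))

  expect_error(added_value_analysis(co, ct_imaging_spec(),
                                    list(aspects = term_linear("aspects"))),
               "already in the base")
})

test_that("the full analysis is structurally complete and seed-reproducible", {
  co <- gen_cohort(n = 500L, seed = 37L, missing = TRUE)
  cfgA <- run_config(seed = 10L, m = 2L, B = 100L)
  specs <- list(ct = ct_imaging_spec(), ct_extended = ct_extended_spec())
  repA <- run_full_analysis(co, specs = specs, config = cfgA)
  expect_setequal(names(repA$pooled), names(specs))
  expect_identical(length(repA$comparisons), 1L)
  expect_setequal(unique(repA$performance$metric),
                  c("c_ordinal", "c_good", "cal_slope", "cal_intercept",
                    "c_for_benefit", "mean_cal_benefit"))

  repB <- run_full_analysis(co, specs = specs, config = cfgA)
  expect_equal(repA$performance, repB$performance, tolerance = 1e-12)
  expect_equal(repA$comparisons$`ct vs ct_extended`$c_good$ci_lo,
               repB$comparisons$`ct vs ct_extended`$c_good$ci_lo)

  # report files are written and re-readable
  dir <- withr::local_tempdir()
  write_analysis_report(repA, dir)
  expect_true(all(file.exists(file.path(dir,
    c("performance.csv", "pooled.json", "comparison.json", "or_table.csv",
      "forest.csv", "run_log.json")))))
  pooled <- jsonlite::read_json(file.path(dir, "pooled.json"))
  expect_equal(pooled$ct$c_good$value, repA$pooled$ct$c_good$value,
               tolerance = 1e-12)
})
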