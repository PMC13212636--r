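test_that("intercept-only fit equals empirical cumulative logits", {
  y <- c(rep(0L, 10L), rep(1L, 25L), rep(2L, 15L), rep(3L, 30L), rep(4L, 20L))
  X <- matrix(numeric(0), nrow = length(y), ncol = 0L)
  fit <- fit_proportional_odds(X, y)
  emp <- cumsum(c(10, 25, 15, 30) / 100)
  expect_equal(unname(fit$alpha), stats::qlogis(emp), tolerance = 1e-7)
})

test_that("two-category outcomes reduce exactly to binary logistic regression", {
  for (seed in 1:5) {
    d <- sim_po_data(300L, seed = seed)
    yb <- as.integer(d$y <= 2L)
    # orientation: P(y_dichot <= 0) = P(not good); recode so that the
    # "low" category is the bad outcome and expit(alpha + eta) = P(good)
    fit <- fit_proportional_odds(d$X, 1L - yb)
    glm_fit <- stats::glm(yb ~ d$X, family = stats::binomial())
    expect_equal(unname(fit$beta), unname(stats::coef(glm_fit)[2:3]),
                 tolerance = 1e-6)
    expect_equal(unname(fit$alpha), unname(stats::coef(glm_fit)[1L]),
                 tolerance = 1e-6)
    expect_equal(fit$logLik, as.numeric(stats::logLik(glm_fit)),
                 tolerance = 1e-8)
  }
})

test_that("fit agrees with an independent proportional-odds implementation", {
  d <- sim_po_data(600L, seed = 3L)
  fit <- fit_proportional_odds(d$X, d$y)
  pf <- MASS::polr(factor(y) ~ x1 + x2,
                   data = data.frame(d$X, y = d$y), method = "logistic",
                   Hess = TRUE)
  # orientation differs: logit P(Y<=k) = zeta_k - eta there, alpha_k + eta here
  expect_equal(unname(fit$beta), unname(-stats::coef(pf)), tolerance = 1e-4)
  expect_equal(unname(fit$alpha), unname(pf$zeta), tolerance = 1e-4)
  se <- sqrt(diag(fit$vcov))[length(fit$alpha) + 1:2]
  expect_equal(unname(se), unname(sqrt(diag(stats::vcov(pf)))[1:2]),
               tolerance = 1e-3)
  expect_lt(fit$grad_norm, 1e-6)
})

test_that("equivariance: rescaling a column rescales its coefficient only", {
  d <- sim_po_data(400L, seed = 9L)
  fit1 <- fit_proportional_odds(d$X, d$y)
  X2 <- d$X
  X2[, 1L] <- X2[, 1L] * 10
  fit2 <- fit_proportional_odds(X2, d$y)
  expect_equal(fit2$beta[[1L]], fit1$beta[[1L]] / 10, tolerance = 1e-6)
  expect_equal(fit2$beta[[2L]], fit1$beta[[2L]], tolerance = 1e-6)
  expect_equal(fit2$logLik, fit1$logLik, tolerance = 1e-8)
})

test_that("predicted distributions conserve probability and respect limits", {
  d <- sim_po_data(200L, seed = 5L)
  fit <- fit_proportional_odds(d$X, d$y)
  P <- predict_distribution(fit, d$X)
  expect_true(all(P >= 0))
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
  # flat model: alpha at logit(k/7) and eta = 0 gives uniform 1/7
  fit0 <- list(alpha = stats::qlogis((1:6) / 7), beta = numeric(0),
               levels = 0:6, spec = NULL)
  class(fit0) <- "po_fit"
  P0 <- predict_distribution(fit0, matrix(numeric(0), 3L, 0L))
  expect_equal(unname(P0), matrix(1 / 7, 3L, 7L), tolerance = 1e-12)
  # large positive eta concentrates mass on the best outcome
  fitL <- fit0
  fitL$beta <- c(x = 1)
  PL <- predict_distribution(fitL, matrix(40, 1L, 1L, dimnames = list(NULL, "x")))
  expect_gt(PL[1L, 1L], 1 - 1e-10)
})

test_that("good-outcome probability is the mRS 0-2 mass and expit(alpha_2 + eta)", {
  d <- sim_po_data(150L, seed = 6L)
  fit <- fit_proportional_odds(d$X, d$y)
  pg <- predict_good_outcome(fit, d$X)
  P <- predict_distribution(fit, d$X)
  expect_equal(unname(pg), unname(rowSums(P[, 1:3])), tolerance = 1e-12)
  expect_true(all(pg > 0 & pg < 1))
  # scalar check: alpha_2 = 0, eta = log(1.92) -> expit(0.652) ~ 0.657
  fit0 <- list(alpha = c(-2, -1, 0, 1, 2, 3), beta = c(x = log(1.92)),
               levels = 0:6, spec = NULL)
  class(fit0) <- "po_fit"
  X1 <- matrix(1, 1L, 1L, dimnames = list(NULL, "x"))
  expect_equal(unname(predict_good_outcome(fit0, X1)),
               stats::plogis(log(1.92)), tolerance = 1e-12)
  expect_lt(abs(unname(predict_good_outcome(fit0, X1)) - 0.657), 1e-3)
})

test_that("counterfactual benefit has the closed-form and monotonicity properties", {
  co <- gen_cohort(n = 600L, seed = 12L)
  fit <- fit_outcome_model(co, ct_imaging_spec())
  ben <- predict_benefit(fit, co)
  expect_equal(ben$benefit, ben$p_good_evt - ben$p_good_control,
               tolerance = 1e-12)

  # no treatment effect, no interaction -> zero benefit everywhere
  fit0 <- fit
  fit0$beta[["evt"]] <- 0
  fit0$beta[["evt_x_collateral"]] <- 0
  ben0 <- predict_benefit(fit0, co)
  expect_equal(ben0$benefit, rep(0, nrow(co)), tolerance = 1e-12)

  # beta_evt = log(1.92), no interaction, alpha_2 + eta_control = 0:
  # benefit = expit(log 1.92) - 0.5 ~ 0.157
  expect_lt(abs(stats::plogis(log(1.92)) - 0.5 - 0.157), 1e-3)

  # positive interaction: benefit nondecreasing in collateral, all else fixed
  fitp <- fit
  fitp$beta[["evt"]] <- log(1.5)
  fitp$beta[["evt_x_collateral"]] <- log(1.2)
  df <- as.data.frame(co)[rep(1L, 4L), , drop = FALSE]
  df$collateral <- 0:3
  df$patient_id <- paste0("c", 0:3)
  ben_c <- predict_benefit(fitp, trial_cohort(df, validate = FALSE))
  expect_true(all(diff(ben_c$benefit) > 0))

  # a spec without treatment cannot predict benefit
  fit_nt <- fit_outcome_model(co, model_spec(list(aspects = term_linear("aspects")),
                                             treatment = FALSE))
  expect_error(predict_benefit(fit_nt, co), "treatment term")
})

test_that("likelihood ratio test has the stated degrees of freedom and null behavior", {
  co <- gen_cohort(n = 800L, seed = 13L)
  spec_base <- model_spec(list(aspects = term_linear("aspects"),
                               collateral = term_linear("collateral")),
                          treatment = TRUE)
  fit_base <- fit_outcome_model(co, spec_base)
  expect_identical(likelihood_ratio_test(fit_base, fit_base),
                   list(statistic = 0, df = 0L, p = 1))

  # adding a 3-level categorical adds 2 df
  spec_ext <- spec_base
  spec_ext$terms$icac <- term_categorical("icac", c("NONE", "INTIMAL", "MEDIAL"))
  fit_ext <- fit_outcome_model(co, spec_ext)
  lrt <- likelihood_ratio_test(fit_ext, fit_base)
  expect_identical(lrt$df, 2L)
  expect_gte(lrt$statistic, 0)

  expect_error(likelihood_ratio_test(fit_base, fit_ext), "not nested|fewer")
})

test_that("backward elimination respects protection and the removal threshold", {
  co <- gen_cohort(n = 1200L, seed = 14L)
  spec <- ct_imaging_spec(include_old_infarct = TRUE)
  # nothing is eligible for removal at p_remove = 1 (no p-value exceeds 1)
  res1 <- backward_eliminate(spec, co, p_remove = 1.0)
  expect_identical(names(res1$spec$terms), names(spec$terms))
  expect_identical(nrow(res1$trace), 0L)

  # the zero-effect old-infarct term is dropped at the usual threshold,
  # while EVT and the interacted collateral term are protected
  res <- backward_eliminate(spec, co, p_remove = 0.20)
  expect_true(res$spec$treatment)
  expect_true("collateral" %in% names(res$spec$terms))
  if (nrow(res$trace) > 0L)
    expect_true(all(res$trace$p > 0.20))
})

test_that("effect summaries expose printed-scale odds ratios", {
  co <- gen_cohort(n = 2000L, seed = 15L)
  fit <- fit_outcome_model(co, ct_imaging_spec())
  tab <- summarize_effects(fit)
  # linear term: OR = exp(beta) and CI = exp(beta +/- 1.96 se)
  i <- which(tab$variable == "aspects")
  b <- fit$beta[["aspects"]]
  se <- sqrt(diag(fit$vcov))[["aspects"]]
  expect_equal(tab$or[i], exp(b), tolerance = 1e-12)
  expect_equal(tab$lo[i], exp(b - 1.96 * se), tolerance = 1e-12)
  expect_equal(tab$hi[i], exp(b + 1.96 * se), tolerance = 1e-12)
  # spline term reports chords below and above the inflection
  expect_identical(sum(tab$variable == "bpf"), 2L)

  # a spline fitted to an exactly linear latent effect gives equal chords
  fit_lin <- fit
  fit_lin$beta[["bpf_s1"]] <- 0
  tab_lin <- summarize_effects(fit_lin)
  ors <- tab_lin$or[tab_lin$variable == "bpf"]
  expect_equal(ors[1L], ors[2L], tolerance = 1e-10)
})

test_that("fitted models survive a JSON round-trip exactly", {
  co <- gen_cohort(n = 300L, seed = 16L)
  fit <- fit_outcome_model(co, ct_imaging_spec())
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(back$alpha, fit$alpha)
  expect_equal(back$beta, fit$beta)
  expect_equal(back$vcov, fit$vcov)
  expect_equal(predict_good_outcome(back, co), predict_good_outcome(fit, co))
})
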