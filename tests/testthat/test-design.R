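# independent evaluation of the restricted (natural) cubic truncated-power
# basis, written directly from the formula: for knots t_1..t_K,
# C_j(x) = [ (x-t_j)+^3 - (x-t_{K-1})+^3 (t_K-t_j)/(t_K-t_{K-1})
#            + (x-t_K)+^3 (t_{K-1}-t_j)/(t_K-t_{K-1}) ] / (t_K-t_1)^2
rcs_oracle <- function(x, knots) {
  K <- length(knots)
  pp3 <- function(u) pmax(u, 0)^3
  sapply(seq_len(K - 2L), function(j) {
    (pp3(x - knots[j]) -
       pp3(x - knots[K - 1L]) * (knots[K] - knots[j]) / (knots[K] - knots[K - 1L]) +
       pp3(x - knots[K]) * (knots[K - 1L] - knots[j]) / (knots[K] - knots[K - 1L])) /
      (knots[K] - knots[1L])^2
  })
}

test_that("rcs basis matches direct evaluation of the natural-spline formula", {
  knots <- c(0, 1, 2)
  # left of the first knot the nonlinear term vanishes
  b <- rcs_basis(-0.7, knots)
  expect_equal(unname(b[1, ]), c(-0.7, 0))
  # interior point agrees with the independent oracle
  for (x in c(0.3, 1.0, 1.5, 1.99)) {
    b <- rcs_basis(x, knots)
    expect_equal(unname(b[1, 2]), drop(rcs_oracle(x, knots)), tolerance = 1e-12)
  }
  # arbitrary knots, vectorized
  set.seed(1)
  kn <- sort(stats::runif(5, 0, 100))
  x <- stats::runif(50, -10, 110)
  b <- rcs_basis(x, kn)
  expect_equal(unname(b[, -1]), unname(rcs_oracle(x, kn)), tolerance = 1e-12)

  expect_error(rcs_basis(1, c(0, 1)), "3 knots")
  expect_error(rcs_basis(1, c(0, 1, 1)), "strictly increasing")
})

test_that("rcs basis is linear beyond the boundary knots", {
  knots <- c(10, 50, 90)
  grid <- seq(91, 140, by = 0.5)
  b <- rcs_basis(grid, knots)
  second_diff <- diff(diff(b[, 2]))
  expect_lt(max(abs(second_diff)), 1e-9)
  grid_l <- seq(-40, 9.5, by = 0.5)
  expect_equal(max(abs(rcs_basis(grid_l, knots)[, 2])), 0)
})

test_that("any affine function of x is exactly representable with zero spline weight", {
  set.seed(2)
  x <- stats::rnorm(200, 50, 20)
  b <- rcs_basis(x, c(20, 50, 80))
  f <- 3 - 0.25 * x
  co <- stats::coef(stats::lm(f ~ b))
  expect_equal(unname(co[3]), 0, tolerance = 1e-8)
  expect_equal(unname(co[2]), -0.25, tolerance = 1e-10)
})

test_that("default knots follow the percentile rule with optional forcing", {
  kn <- default_knots(1:100, k = 3)
  expect_equal(kn, unname(stats::quantile(1:100, c(.1, .5, .9))),
               tolerance = 1e-12)
  expect_equal(kn, c(10.9, 50.5, 90.1), tolerance = 1e-9)

  bpf_sample <- seq(70, 90, length.out = 200)
  kn <- default_knots(bpf_sample, k = 3, forced_middle = 80)
  expect_identical(kn[2L], 80)

  expect_error(default_knots(rep(5, 50), k = 3), "degenerate")
})

test_that("design matrices have the documented coding, dimensions and labels", {
  co <- tiny_cohort()
  # spec with only the treatment indicator
  sp <- model_spec(list(aspects = term_linear("aspects")), treatment = TRUE)
  X <- build_design_matrix(co, sp)
  expect_identical(unname(X[, "evt"]), as.numeric(as.data.frame(co)$evt))

  # dummy coding: reference ICA/ICA-T; an M2 row has (M1=0, M2=1)
  sp <- model_spec(list(occlusion = term_categorical("occlusion",
                                                     c("ICA_ICAT", "M1", "M2"))),
                   treatment = FALSE)
  X <- build_design_matrix(co, sp)
  i_m2 <- which(as.data.frame(co)$occlusion == "M2")[1L]
  expect_identical(unname(X[i_m2, ]), c(0, 1))
  expect_identical(colnames(X), c("occlusion_M1", "occlusion_M2"))

  # 3 linear + one 3-knot spline = 5 columns
  sp <- model_spec(list(age = term_linear("age"),
                        nihss = term_linear("nihss"),
                        collateral = term_linear("collateral"),
                        bpf = term_spline("bpf", knots = c(77, 80, 83))),
                   treatment = FALSE)
  X <- build_design_matrix(co, sp)
  expect_identical(dim(X), c(8L, 5L))

  # per-5-mL scaling divides the raw value
  sp <- model_spec(list(wml_volume = term_linear("wml_volume", scale = 5)),
                   treatment = FALSE)
  X <- build_design_matrix(co, sp)
  expect_equal(unname(X[, 1]), as.data.frame(co)$wml_volume / 5)

  # interaction columns are element-wise products
  sp <- model_spec(list(collateral = term_linear("collateral")),
                   treatment = TRUE, interactions = "collateral")
  X <- build_design_matrix(co, sp)
  df <- as.data.frame(co)
  expect_equal(unname(X[, "evt_x_collateral"]), df$evt * df$collateral)

  # determinism
  expect_identical(X, build_design_matrix(co, sp))

  # missing covariate is a design error naming patient and variable
  df$collateral[2L] <- NA
  expect_error(build_design_matrix(trial_cohort(df), sp), "collateral.*p02")
})

test_that("unresolved spline knots are resolved from the training cohort only", {
  co <- gen_cohort(n = 500L, seed = 4L)
  sp <- resolve_spec(ct_imaging_spec(), co)
  expect_identical(sp$terms$bpf$knots[2L], 80)
  df <- as.data.frame(co)
  expect_equal(sp$terms$bpf$knots[c(1L, 3L)],
               unname(stats::quantile(df$bpf, c(.1, .9))), tolerance = 1e-10)
  # spec round-trip through JSON
  path <- withr::local_tempfile(fileext = ".json")
  write_model_spec(sp, path)
  sp2 <- read_model_spec(path)
  expect_equal(build_design_matrix(co, sp2), build_design_matrix(co, sp))
})

test_that("model spec construction validates references", {
  expect_error(model_spec(list(term_linear("not_a_column"))), "unknown variable")
  expect_error(model_spec(list(aspects = term_linear("aspects")),
                          treatment = TRUE, interactions = "collateral"),
               "without a main effect")
  expect_error(model_spec(list(collateral = term_linear("collateral")),
                          treatment = FALSE, interactions = "collateral"),
               "require the treatment term")
})
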