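# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# small handmade two-trial cohort, fully complete
tiny_cohort <- function() {
  df <- data.frame(
    patient_id = sprintf("p%02d", 1:8),
    trial_id = rep(c("A", "B"), each = 4L),
    evt = rep(c(1L, 0L), 4L),
    mrs90 = c(0L, 3L, 2L, 6L, 1L, 4L, 2L, 5L),
    age = c(55, 70, 63, 81, 48, 77, 66, 72),
    nihss = c(10L, 18L, 15L, 22L, 8L, 20L, 17L, 19L),
    sbp = c(130, 150, 145, 160, 125, 155, 148, 152),
    glucose = c(110, 130, 118, 150, 105, 140, 122, 135),
    prestroke_mrs = c(0L, 1L, 0L, 2L, 0L, 0L, 1L, 0L),
    diabetes = c(0L, 1L, 0L, 1L, 0L, 0L, 1L, 0L),
    iv_alteplase = c(1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L),
    onset_to_groin = c(180, 240, 210, 300, 160, 260, 230, 250),
    aspects = c(9L, 7L, 8L, 6L, 10L, 7L, 9L, 8L),
    occlusion = c("M1", "ICA_ICAT", "M1", "M2", "M1", "M1", "ICA_ICAT", "M2"),
    collateral = c(3L, 1L, 2L, 0L, 3L, 2L, 1L, 2L),
    wml_volume = c(0.5, 3.2, 1.1, 6.0, 0.0, 2.4, 1.8, 4.1),
    bpf = c(82.1, 78.5, 80.2, 76.9, 83.0, 79.4, 80.8, 78.0),
    old_infarct_volume = c(0, 2.5, 0, 8.1, 0, 1.2, 0.4, 3.3),
    icac = c("NONE", "MEDIAL", "INTIMAL", "MEDIAL", "NONE", "INTIMAL",
             "MEDIAL", "NONE"),
    stringsAsFactors = FALSE)
  trial_cohort(df)
}

# default generator scaled to roughly n_total patients, missingness off
# unless asked for
small_config <- function(n_total = 1391L, missing = FALSE) {
  cfg <- default_hermes_config()
  if (n_total != sum(cfg$trial_specs$n))
    cfg$trial_specs$n <- pmax(2L, as.integer(round(
      cfg$trial_specs$n * n_total / sum(cfg$trial_specs$n))))
  if (!missing) cfg$missing_rate <- list()
  cfg
}

# complete generated cohort of roughly n patients
gen_cohort <- function(n = 1391L, seed = 1L, missing = FALSE) {
  generate_cohort(small_config(n, missing = missing), seed = seed)
}

# brute-force concordance oracles ------------------------------------------

# exhaustive O(n^2) pair enumeration; group higher = better observed,
# score higher = predicted better
brute_concordance <- function(group, score) {
  num <- 0; den <- 0
  n <- length(group)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (group[i] == group[j]) next
    den <- den + 1
    better <- if (group[i] > group[j]) i else j
    worse <- if (group[i] > group[j]) j else i
    if (score[better] > score[worse]) num <- num + 1
    else if (score[better] == score[worse]) num <- num + 0.5
  }
  num / den
}

# simple compact proportional-odds cohort for model tests: two linear
# covariates, known coefficients
sim_po_data <- function(n, beta = c(0.8, -0.5),
                        alpha = qlogis(c(.10, .25, .40, .55, .70, .85)),
                        seed = 1L) {
  set.seed(seed)
  X <- cbind(x1 = stats::rnorm(n), x2 = stats::rbinom(n, 1L, 0.4))
  eta <- drop(X %*% beta)
  cum <- vapply(alpha, function(a) stats::plogis(a + eta), numeric(n))
  y <- rowSums(stats::runif(n) > cum)
  list(X = X, y = y, beta = beta, alpha = alpha)
}
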