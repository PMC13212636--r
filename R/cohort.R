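# Patient-level cohort container and validated CSV I/O.
#
# A trial cohort is a data.frame with one row per randomized patient, a
# fixed column dictionary, and a "trial_ids" attribute listing the distinct
# trial labels in first-appearance order.

#' Column dictionary of a trial cohort
#'
#' Names, types and closed category sets of the patient-level table used
#' throughout the package. `trial_id`, `evt` and `mrs90` are required on
#' every record; any baseline covariate may be missing (`NA`).
#'
#' @return A data.frame with columns `column`, `type`, `constraint`.
#' @export
cohort_dictionary <- function() {
  data.frame(
    column = c("patient_id", "trial_id", "evt", "mrs90", "age", "nihss",
               "sbp", "glucose", "prestroke_mrs", "diabetes", "iv_alteplase",
               "onset_to_groin", "aspects", "occlusion", "collateral",
               "wml_volume", "bpf", "old_infarct_volume", "icac"),
    type = c("character", "character", "integer", "integer", "numeric",
             "integer", "numeric", "numeric", "integer", "integer",
             "integer", "numeric", "integer", "category", "integer",
             "numeric", "numeric", "numeric", "category"),
    constraint = c("unique, non-missing", "non-missing", "0/1", "0-6",
                   "> 0 years", "0-42", "mmHg > 0", "mg/dL > 0", "0-5",
                   "0/1", "0/1", "minutes > 0", "0-10",
                   "ICA_ICAT | M1 | M2", "0-3", ">= 0 mL", "(0, 100] %",
                   ">= 0 mL", "NONE | INTIMAL | MEDIAL"),
    stringsAsFactors = FALSE
  )
}

.occlusion_levels <- c("ICA_ICAT", "M1", "M2")
.icac_levels <- c("NONE", "INTIMAL", "MEDIAL")

# covariates eligible for missingness / imputation
.covariate_cols <- c("age", "nihss", "sbp", "glucose", "prestroke_mrs",
                     "diabetes", "iv_alteplase", "onset_to_groin", "aspects",
                     "occlusion", "collateral", "wml_volume", "bpf",
                     "old_infarct_volume", "icac")

#' Construct a trial cohort from a patient-level data.frame
#'
#' @param df data.frame holding the columns of [cohort_dictionary()].
#'   Missing covariates are `NA`; `trial_id`, `evt`, `mrs90` must be present
#'   and valid on every row.
#' @param validate stop on any invariant violation (default `TRUE`).
#' @return An object of class `trial_cohort` (a data.frame).
#' @export
trial_cohort <- function(df, validate = TRUE) {
  dict <- cohort_dictionary()
  missing_cols <- setdiff(dict$column, names(df))
  if (length(missing_cols) > 0L)
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[, dict$column]
  df$patient_id <- as.character(df$patient_id)
  df$trial_id <- as.character(df$trial_id)
  for (col in c("evt", "mrs90", "nihss", "prestroke_mrs", "diabetes",
                "iv_alteplase", "aspects", "collateral"))
    df[[col]] <- as.integer(df[[col]])
  for (col in c("age", "sbp", "glucose", "onset_to_groin", "wml_volume",
                "bpf", "old_infarct_volume"))
    df[[col]] <- as.numeric(df[[col]])
  df$occlusion <- as.character(df$occlusion)
  df$icac <- as.character(df$icac)
  rownames(df) <- NULL
  structure(df,
            trial_ids = unique(df$trial_id),
            class = c("trial_cohort", "data.frame")) -> cohort
  if (validate) {
    v <- validate_cohort(cohort)
    if (nrow(v) > 0L)
      stop("invalid cohort (", nrow(v), " violation(s)); first: ",
           v$patient_id[1L], " / ", v$field[1L], ": ", v$rule[1L],
           call. = FALSE)
  }
  cohort
}

#' @export
print.trial_cohort <- function(x, ...) {
  ids <- attr(x, "trial_ids")
  cat("Trial cohort: ", nrow(x), " patients across ", length(ids),
      " trial(s)\n", sep = "")
  cat("  trials: ", paste(ids, collapse = ", "), "\n", sep = "")
  cat("  EVT arm: ", sum(x$evt == 1L), "; control arm: ",
      sum(x$evt == 0L), "\n", sep = "")
  n_miss <- sum(is.na(as.data.frame(x)[, .covariate_cols]))
  cat("  missing covariate cells: ", n_miss, "\n", sep = "")
  invisible(x)
}

#' List invariant violations in a cohort
#'
#' Checks every record against the column dictionary (range and category
#' constraints) and the cohort-level invariants (unique patient ids; at
#' least one treated and one control patient per trial). Reports rather
#' than raises.
#'
#' @param cohort a `trial_cohort` or plain data.frame with the same columns.
#' @return data.frame with columns `patient_id`, `field`, `rule`; zero rows
#'   when the cohort is fully valid.
#' @export
validate_cohort <- function(cohort) {
  df <- as.data.frame(cohort)
  out <- list()
  bad <- function(rows, field, rule) {
    if (any(rows, na.rm = TRUE))
      out[[length(out) + 1L]] <<- data.frame(
        patient_id = df$patient_id[which(rows)], field = field, rule = rule,
        stringsAsFactors = FALSE)
  }
  bad(is.na(df$trial_id) | df$trial_id == "", "trial_id", "must be non-missing")
  bad(is.na(df$evt) | !(df$evt %in% 0:1), "evt", "must be 0 or 1")
  bad(is.na(df$mrs90) | !(df$mrs90 %in% 0:6), "mrs90", "must be in 0..6")
  bad(!is.na(df$age) & df$age <= 0, "age", "must be positive")
  bad(!is.na(df$nihss) & !(df$nihss %in% 0:42), "nihss", "must be in 0..42")
  bad(!is.na(df$sbp) & df$sbp <= 0, "sbp", "must be positive")
  bad(!is.na(df$glucose) & df$glucose <= 0, "glucose", "must be positive")
  bad(!is.na(df$prestroke_mrs) & !(df$prestroke_mrs %in% 0:5),
      "prestroke_mrs", "must be in 0..5")
  bad(!is.na(df$diabetes) & !(df$diabetes %in% 0:1), "diabetes", "must be 0 or 1")
  bad(!is.na(df$iv_alteplase) & !(df$iv_alteplase %in% 0:1),
      "iv_alteplase", "must be 0 or 1")
  bad(!is.na(df$onset_to_groin) & df$onset_to_groin <= 0,
      "onset_to_groin", "must be positive")
  bad(!is.na(df$aspects) & !(df$aspects %in% 0:10), "aspects", "must be in 0..10")
  bad(!is.na(df$occlusion) & !(df$occlusion %in% .occlusion_levels),
      "occlusion", paste("must be one of", paste(.occlusion_levels, collapse = "/")))
  bad(!is.na(df$collateral) & !(df$collateral %in% 0:3),
      "collateral", "must be in 0..3")
  bad(!is.na(df$wml_volume) & df$wml_volume < 0, "wml_volume", "must be >= 0")
  bad(!is.na(df$bpf) & (df$bpf <= 0 | df$bpf > 100), "bpf", "must be in (0, 100]")
  bad(!is.na(df$old_infarct_volume) & df$old_infarct_volume < 0,
      "old_infarct_volume", "must be >= 0")
  bad(!is.na(df$icac) & !(df$icac %in% .icac_levels),
      "icac", paste("must be one of", paste(.icac_levels, collapse = "/")))
  dup <- duplicated(df$patient_id)
  bad(dup, "patient_id", "must be unique within cohort")
  # cohort-level: both arms represented within each trial
  for (tid in unique(df$trial_id)) {
    arms <- df$evt[df$trial_id == tid]
    if (!any(arms == 0L, na.rm = TRUE) || !any(arms == 1L, na.rm = TRUE))
      out[[length(out) + 1L]] <- data.frame(
        patient_id = paste0("<trial ", tid, ">"), field = "evt",
        rule = "trial must contain both treated and control patients",
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(patient_id = character(), field = character(),
                      rule = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Read a patient-level cohort from CSV
#'
#' Expects the header of [cohort_dictionary()]; empty fields are missing
#' values. Category codes are stored as strings (`"M1"`, `"MEDIAL"`, ...),
#' never as integers.
#'
#' @param path CSV file path.
#' @param schema_strict reject files with unknown extra columns (default
#'   `TRUE`).
#' @return A validated `trial_cohort`.
#' @export
read_cohort <- function(path, schema_strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  dict <- cohort_dictionary()
  unknown <- setdiff(names(df), dict$column)
  if (schema_strict && length(unknown) > 0L)
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing_cols <- setdiff(dict$column, names(df))
  if (length(missing_cols) > 0L)
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  mrs <- suppressWarnings(as.integer(df$mrs90))
  bad_mrs <- which(is.na(mrs) | !(mrs %in% 0:6))
  if (length(bad_mrs) > 0L)
    stop("mrs90 missing or outside 0-6 at data row(s): ",
         paste(utils::head(bad_mrs, 5L), collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id: ",
         df$patient_id[which(duplicated(df$patient_id))[1L]], call. = FALSE)
  trial_cohort(df, validate = TRUE)
}

#' Write a cohort to CSV
#'
#' Columns in dictionary order; missing values written as empty fields.
#' `write_cohort()` then [read_cohort()] is the identity on valid cohorts.
#'
#' @param cohort a `trial_cohort`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)[, cohort_dictionary()$column, drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Multiple imputation of missing baseline covariates
#'
#' Fully conditional specification (chained equations) with stochastic
#' regression draws: linear regression with normal residual draws for
#' continuous covariates, logistic draws for binaries, multinomial draws
#' for unordered categoricals, and rounded/clipped linear draws for
#' bounded integer scores. The outcome `mrs90` and the treatment arm are
#' included as predictors in every imputation model. Observed values are
#' never altered.
#'
#' @param cohort a `trial_cohort`, possibly with missing covariates.
#' @param m number of completed cohorts to return (default 5).
#' @param seed integer seed; the run is deterministic given the seed.
#' @param n_cycles chained-equation cycles per imputation (default 10).
#' @return A list of `m` completed `trial_cohort` objects.
#' @export
impute_missing <- function(cohort, m = 5L, seed = 1L, n_cycles = 10L) {
  stopifnot(m >= 1L)
  df <- as.data.frame(cohort)
  miss_cols <- .covariate_cols[vapply(.covariate_cols,
                                      function(cl) anyNA(df[[cl]]), logical(1))]
  entirely <- miss_cols[vapply(miss_cols, function(cl) all(is.na(df[[cl]])),
                               logical(1))]
  if (length(entirely) > 0L)
    stop("covariate(s) entirely missing, cannot impute: ",
         paste(entirely, collapse = ", "), call. = FALSE)
  if (length(miss_cols) == 0L)
    return(replicate(m, cohort, simplify = FALSE))

  old_seed <- .save_rng(seed)
  on.exit(.restore_rng(old_seed), add = TRUE)

  # numeric working frame: categories one-hot for use as predictors
  lapply(seq_len(m), function(im) {
    comp <- .impute_once(df, miss_cols, n_cycles)
    trial_cohort(comp, validate = FALSE)
  })
}

# one chained-equations pass over a data.frame with missing covariates
.impute_once <- function(df, miss_cols, n_cycles) {
  comp <- df
  miss_idx <- lapply(miss_cols, function(cl) which(is.na(df[[cl]])))
  names(miss_idx) <- miss_cols

  # initial fill: random draws from observed values
  for (cl in miss_cols) {
    obs <- comp[[cl]][!is.na(comp[[cl]])]
    comp[[cl]][miss_idx[[cl]]] <- sample(obs, length(miss_idx[[cl]]),
                                         replace = TRUE)
  }

  bounded <- list(nihss = c(0L, 42L), prestroke_mrs = c(0L, 5L),
                  aspects = c(0L, 10L), collateral = c(0L, 3L))
  nonneg <- c("wml_volume", "old_infarct_volume", "onset_to_groin")

  for (cycle in seq_len(n_cycles)) {
    for (cl in miss_cols) {
      idx <- miss_idx[[cl]]
      pred <- .imputation_predictors(comp, exclude = cl)
      yobs <- df[[cl]]
      obs_rows <- which(!is.na(yobs))
      if (cl %in% c("occlusion", "icac")) {
        comp[[cl]][idx] <- .draw_multinomial(yobs[obs_rows],
                                             pred[obs_rows, , drop = FALSE],
                                             pred[idx, , drop = FALSE])
      } else if (cl %in% c("diabetes", "iv_alteplase")) {
        comp[[cl]][idx] <- .draw_logistic(yobs[obs_rows],
                                          pred[obs_rows, , drop = FALSE],
                                          pred[idx, , drop = FALSE])
      } else {
        draws <- .draw_linear(yobs[obs_rows], pred[obs_rows, , drop = FALSE],
                              pred[idx, , drop = FALSE])
        if (cl %in% names(bounded)) {
          b <- bounded[[cl]]
          draws <- pmin(pmax(round(draws), b[1L]), b[2L])
          draws <- as.integer(draws)
        } else if (cl %in% nonneg) {
          draws <- pmax(draws, 0)
        } else if (cl == "bpf") {
          draws <- pmin(pmax(draws, 1e-6), 100)
        } else if (cl == "age") {
          draws <- pmax(draws, 1)
        }
        comp[[cl]][idx] <- draws
      }
    }
  }
  comp
}

# numeric predictor matrix from all currently-complete columns except `exclude`
.imputation_predictors <- function(comp, exclude) {
  cols <- setdiff(c("evt", "mrs90", .covariate_cols), exclude)
  mats <- lapply(cols, function(cl) {
    v <- comp[[cl]]
    if (cl == "occlusion")
      return(cbind(occ_M1 = as.numeric(v == "M1"),
                   occ_M2 = as.numeric(v == "M2")))
    if (cl == "icac")
      return(cbind(icac_int = as.numeric(v == "INTIMAL"),
                   icac_med = as.numeric(v == "MEDIAL")))
    matrix(as.numeric(v), ncol = 1L, dimnames = list(NULL, cl))
  })
  do.call(cbind, mats)
}

# stochastic draws: linear model with residual-variance noise
.draw_linear <- function(y, Xobs, Xmis) {
  fit <- stats::lm.fit(cbind(1, Xobs), as.numeric(y))
  keep <- !is.na(fit$coefficients)
  co <- fit$coefficients[keep]
  sigma <- sqrt(sum(fit$residuals^2) /
                  max(1L, length(y) - sum(keep)))
  mu <- drop(cbind(1, Xmis)[, keep, drop = FALSE] %*% co)
  mu + stats::rnorm(length(mu), 0, sigma)
}

.draw_logistic <- function(y, Xobs, Xmis) {
  dat <- data.frame(y = as.integer(y), Xobs)
  fit <- suppressWarnings(stats::glm(y ~ ., data = dat, family = stats::binomial()))
  p <- stats::predict(fit, newdata = data.frame(Xmis), type = "response")
  as.integer(stats::rbinom(length(p), 1L, p))
}

.draw_multinomial <- function(y, Xobs, Xmis) {
  lev <- sort(unique(y))
  if (length(lev) == 1L) return(rep(lev, nrow(Xmis)))
  dat <- data.frame(y = factor(y, levels = lev), Xobs)
  fit <- nnet::multinom(y ~ ., data = dat, trace = FALSE)
  p <- stats::predict(fit, newdata = data.frame(Xmis), type = "probs")
  if (is.null(dim(p))) p <- cbind(1 - p, p)  # two levels
  apply(p, 1L, function(pr) sample(lev, 1L, prob = pr))
}

# seed save/restore helpers shared across the package
.save_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
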