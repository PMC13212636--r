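# Matched-pair construction and benefit-specific metrics.
#
# Treatment benefit is unobservable in an individual; observed benefit is
# defined on treated-control pairs matched on baseline characteristics
# (1:1, without replacement) as the difference of their good-outcome
# indicators, in {-1, 0, 1}. Predicted pair benefit is the mean of the
# two patients' model-predicted benefits.

#' Match treated and control patients 1:1
#'
#' Greedy nearest-neighbour matching without replacement: all
#' treated-control distances are computed (Mahalanobis over standardized
#' continuous plus dummy-coded categorical covariates, or the absolute
#' difference of predicted benefit) and pairs are accepted in ascending
#' distance order; ties are broken by a seeded shuffle. By default
#' matching is performed within trial, where treatment allocation is
#' randomized.
#'
#' @param cohort a complete `trial_cohort`.
#' @param covariates baseline covariate names used for the distance.
#' @param benefit per-patient predicted benefit, aligned with cohort rows
#'   (used as the match distance for `method = "predicted_benefit"` and
#'   recorded as the predicted pair benefit).
#' @param method `"mahalanobis"` (default) or `"predicted_benefit"`.
#' @param within_trial match within each trial (default `TRUE`).
#' @param seed integer seed for tie-breaking.
#' @param ridge diagonal regularization added to the covariance before
#'   inversion (singular covariance otherwise fails).
#' @return A `pair_set`: data.frame of pairs (`treated_id`, `control_id`,
#'   `trial_id`, `distance`, `observed`, `predicted`).
#' @export
match_pairs <- function(cohort, covariates, benefit,
                        method = c("mahalanobis", "predicted_benefit"),
                        within_trial = TRUE, seed = 1L, ridge = 1e-8) {
  method <- match.arg(method)
  df <- as.data.frame(cohort)
  stopifnot(length(benefit) == nrow(df))
  good <- as.integer(df$mrs90 <= 2L)
  strata <- if (within_trial) split(seq_len(nrow(df)), df$trial_id)
            else list(all = seq_len(nrow(df)))

  Z <- NULL
  if (method == "mahalanobis") {
    mats <- lapply(covariates, function(cl) {
      v <- df[[cl]]
      if (anyNA(v)) stop("missing values in matching covariate: ", cl,
                         call. = FALSE)
      if (cl == "occlusion")
        return(cbind(as.numeric(v == "M1"), as.numeric(v == "M2")))
      if (cl == "icac")
        return(cbind(as.numeric(v == "INTIMAL"), as.numeric(v == "MEDIAL")))
      matrix(as.numeric(v), ncol = 1L)
    })
    Z <- do.call(cbind, mats)
    Z <- scale(Z, center = TRUE,
               scale = apply(Z, 2L, function(cc) max(stats::sd(cc), 1e-12)))
    S <- stats::cov(Z) + diag(ridge, ncol(Z))
    W <- tryCatch(solve(S), error = function(e)
      stop("singular covariance in Mahalanobis matching; ",
           "increase the ridge regularization", call. = FALSE))
    R <- chol(W)
    Z <- Z %*% t(R)  # Euclidean distance in this space = Mahalanobis
  }

  old_seed <- .save_rng(seed)
  on.exit(.restore_rng(old_seed), add = TRUE)

  pairs <- lapply(strata, function(ix) {
    tr <- ix[df$evt[ix] == 1L]
    co <- ix[df$evt[ix] == 0L]
    if (length(tr) == 0L || length(co) == 0L) return(NULL)
    if (method == "mahalanobis") {
      D <- as.matrix(stats::dist(rbind(Z[tr, , drop = FALSE],
                                       Z[co, , drop = FALSE])))
      D <- D[seq_along(tr), length(tr) + seq_along(co), drop = FALSE]
    } else {
      D <- abs(outer(benefit[tr], benefit[co], "-"))
    }
    m <- min(length(tr), length(co))
    ij <- expand.grid(i = seq_along(tr), j = seq_along(co))
    shuffle <- sample.int(nrow(ij))
    ij <- ij[shuffle[order(D[cbind(ij$i, ij$j)][shuffle])], , drop = FALSE]
    used_t <- logical(length(tr)); used_c <- logical(length(co))
    sel <- integer(0)
    for (r in seq_len(nrow(ij))) {
      i <- ij$i[r]; j <- ij$j[r]
      if (!used_t[i] && !used_c[j]) {
        used_t[i] <- TRUE; used_c[j] <- TRUE
        sel <- c(sel, r)
        if (length(sel) == m) break
      }
    }
    ij <- ij[sel, , drop = FALSE]
    ti <- tr[ij$i]; ci <- co[ij$j]
    data.frame(treated_id = df$patient_id[ti], control_id = df$patient_id[ci],
               trial_id = df$trial_id[ti],
               distance = D[cbind(ij$i, ij$j)],
               observed = good[ti] - good[ci],
               predicted = (benefit[ti] + benefit[ci]) / 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(pairs[!vapply(pairs, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  structure(out, method = method, covariates = covariates,
            within_trial = within_trial,
            class = c("pair_set", "data.frame"))
}

#' @export
print.pair_set <- function(x, ...) {
  cat("Matched pair set: ", nrow(x), " treated-control pairs (",
      attr(x, "method"), if (isTRUE(attr(x, "within_trial")))
        ", within trial" else ", pooled", ")\n", sep = "")
  cat("  observed benefit -1/0/1: ",
      paste(table(factor(x$observed, levels = -1:1)), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' C-for-benefit
#'
#' Probability that of two randomly chosen matched pairs with unequal
#' observed benefit, the pair with greater observed benefit has the
#' strictly higher predicted benefit; predicted ties count 0.5.
#' Jackknife SE over pairs.
#'
#' @param pairs a `pair_set` (or data.frame with `observed`, `predicted`).
#' @return A `perf_estimate`.
#' @export
c_for_benefit <- function(pairs) {
  if (nrow(pairs) < 2L)
    stop("need at least two matched pairs", call. = FALSE)
  cc <- .concordance_grouped(as.numeric(pairs$observed), pairs$predicted)
  .perf_estimate("c_for_benefit", cc$value, cc$se, nrow(pairs),
                 "jackknife SE over pairs; ties 0.5")
}

#' Mean calibration of predicted benefit
#'
#' Mean observed pair benefit minus mean predicted pair benefit. Positive
#' values mean the model under-predicts benefit.
#'
#' @param pairs a `pair_set`.
#' @return Signed numeric difference.
#' @export
mean_calibration_benefit <- function(pairs) {
  if (nrow(pairs) < 1L) stop("empty pair set", call. = FALSE)
  mean(pairs$observed) - mean(pairs$predicted)
}

#' Binned benefit calibration curve
#'
#' Equal-count quantile bins of predicted pair benefit with per-bin mean
#' predicted and mean observed benefit.
#'
#' @param pairs a `pair_set`.
#' @param n_bins number of bins (default 5).
#' @return data.frame ordered by mean predicted benefit.
#' @export
benefit_calibration_curve <- function(pairs, n_bins = 5L) {
  m <- nrow(pairs)
  if (n_bins < 2L) stop("need at least 2 bins", call. = FALSE)
  if (m < n_bins) stop("fewer pairs than bins", call. = FALSE)
  ord <- order(pairs$predicted)
  bin <- integer(m)
  bin[ord] <- ceiling(seq_len(m) / (m / n_bins))
  bin <- pmin(bin, n_bins)
  out <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin = b, mean_predicted = mean(pairs$predicted[sel]),
               mean_observed = mean(pairs$observed[sel]), n = sum(sel))
  })
  do.call(rbind, out)
}
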