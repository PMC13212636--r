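# Discrimination and calibration of outcome predictions.
#
# Concordance is computed by a sorted-group counting algorithm: the
# outcome has few distinct levels, so all cross-group pair counts are
# obtained from binary searches into the sorted score vector of each
# group, O(L^2 n log n) overall, with exact per-observation pair credits
# feeding a jackknife standard error.

# group: integer, higher = better observed outcome; score: higher =
# predicted better outcome. Returns C, jackknife SE, pair count.
.concordance_grouped <- function(group, score) {
  n <- length(group)
  stopifnot(length(score) == n)
  lev <- sort(unique(group))
  if (length(lev) < 2L)
    stop("concordance undefined: all observed values are equal", call. = FALSE)
  credit <- numeric(n)   # concordant + 0.5 * tied score pairs involving i
  npair <- numeric(n)    # informative pairs involving i
  total_credit <- 0; total_pairs <- 0
  idx_by <- lapply(lev, function(l) which(group == l))
  sorted <- lapply(idx_by, function(ix) sort(score[ix]))
  for (a in seq_along(lev)) {
    for (b in seq_along(lev)) {
      if (a >= b) next
      # group b is the better outcome; concordant when its score is higher
      ia <- idx_by[[a]]; ib <- idx_by[[b]]
      sa <- sorted[[a]]
      sb_scores <- score[ib]
      less <- findInterval(sb_scores, sa, left.open = TRUE)  # a-scores < s_b
      leq <- findInterval(sb_scores, sa)                      # a-scores <= s_b
      eq <- leq - less
      cred_b <- less + 0.5 * eq
      credit[ib] <- credit[ib] + cred_b
      npair[ib] <- npair[ib] + length(ia)
      # mirror onto group a members
      sb <- sorted[[b]]
      sa_scores <- score[ia]
      greater <- length(sb) - findInterval(sa_scores, sb)     # b-scores > s_a
      eq_a <- findInterval(sa_scores, sb) - findInterval(sa_scores, sb, left.open = TRUE)
      credit[ia] <- credit[ia] + greater + 0.5 * eq_a
      npair[ia] <- npair[ia] + length(ib)
      total_credit <- total_credit + sum(cred_b)
      total_pairs <- total_pairs + length(ia) * length(ib)
    }
  }
  C <- total_credit / total_pairs
  # leave-one-out concordances from per-observation credits
  loo <- (total_credit - credit) / (total_pairs - npair)
  loo[!is.finite(loo)] <- C
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  list(value = C, se = se, n_pairs = total_pairs)
}

.perf_estimate <- function(metric, value, se, n_effective, note = "") {
  structure(list(metric = metric, value = value, se = se,
                 n_effective = n_effective, note = note),
            class = "perf_estimate")
}

#' @export
print.perf_estimate <- function(x, ...) {
  cat(x$metric, ": ", format(x$value, digits = 4), " (SE ",
      format(x$se, digits = 3), ", n = ", x$n_effective, ")\n", sep = "")
  invisible(x)
}

#' Ordinal C-statistic (Harrell's C for an ordinal outcome)
#'
#' Probability that of two randomly chosen patients with unequal observed
#' mRS, the one with the lower (better) observed mRS has the strictly
#' higher score; score ties count 0.5. The score must be oriented so
#' higher = predicted better outcome (e.g. the model's linear predictor).
#' Standard error by the jackknife.
#'
#' @param observed integer mRS vector.
#' @param score per-patient ranking score, higher = better predicted
#'   outcome.
#' @return A `perf_estimate`.
#' @export
c_ordinal <- function(observed, score) {
  cc <- .concordance_grouped(-as.numeric(observed), score)
  .perf_estimate("c_ordinal", cc$value, cc$se, length(observed),
                 "jackknife SE; ties 0.5")
}

#' Binary C-statistic for good functional outcome
#'
#' Concordance of predicted probabilities for the good-outcome (mRS 0-2)
#' indicator; ties count 0.5; jackknife SE.
#'
#' @param observed_good 0/1 indicator of good outcome.
#' @param p_good predicted probabilities.
#' @return A `perf_estimate`.
#' @export
c_binary <- function(observed_good, p_good) {
  if (length(unique(observed_good)) < 2L)
    stop("concordance undefined: single outcome class", call. = FALSE)
  cc <- .concordance_grouped(as.numeric(observed_good), p_good)
  .perf_estimate("c_good", cc$value, cc$se, length(observed_good),
                 "jackknife SE; ties 0.5")
}

#' Calibration slope and intercept on the logit scale
#'
#' Slope: coefficient of `logit(p)` in a logistic regression of the
#' observed indicator on `logit(p)`. Intercept: intercept of a logistic
#' regression with `logit(p)` as a fixed offset (slope held at 1).
#' Probabilities are clipped to `[1e-6, 1 - 1e-6]` before the logit.
#'
#' @param observed_good 0/1 indicator.
#' @param p_good predicted probabilities in (0, 1).
#' @return list with `slope`, `slope_se`, `intercept`, `intercept_se`.
#' @export
calibration_slope_intercept <- function(observed_good, p_good) {
  lp <- stats::qlogis(pmin(pmax(p_good, 1e-6), 1 - 1e-6))
  if (stats::var(lp) < 1e-12)
    stop("calibration undefined: predictions have zero spread", call. = FALSE)
  if (length(unique(observed_good)) < 2L)
    stop("calibration undefined: single outcome class", call. = FALSE)
  y <- as.integer(observed_good)
  fit_s <- stats::glm(y ~ lp, family = stats::binomial())
  fit_i <- stats::glm(y ~ 1 + offset(lp), family = stats::binomial())
  list(slope = unname(stats::coef(fit_s)[2L]),
       slope_se = unname(sqrt(diag(stats::vcov(fit_s)))[2L]),
       intercept = unname(stats::coef(fit_i)[1L]),
       intercept_se = unname(sqrt(diag(stats::vcov(fit_i)))[1L]))
}

#' Binned calibration curve
#'
#' Equal-count quantile bins of the predicted probability; per bin the
#' mean prediction, observed proportion, count, and a Wilson 95% CI.
#'
#' @param observed_good 0/1 indicator.
#' @param p_good predicted probabilities.
#' @param n_bins number of bins (default 10).
#' @return data.frame ordered by mean predicted probability.
#' @export
calibration_curve <- function(observed_good, p_good, n_bins = 10L) {
  n <- length(p_good)
  if (n_bins < 2L) stop("need at least 2 bins", call. = FALSE)
  if (n < n_bins) stop("fewer observations than bins", call. = FALSE)
  if (length(unique(p_good)) == 1L)
    warning("constant predictions: bins are not informative", call. = FALSE)
  ord <- order(p_good)
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) / (n / n_bins))
  bin <- pmin(bin, n_bins)
  out <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    k <- sum(observed_good[sel]); m <- sum(sel)
    phat <- k / m
    zz <- 1.959964
    den <- 1 + zz^2 / m
    ctr <- (phat + zz^2 / (2 * m)) / den
    hw <- zz * sqrt(phat * (1 - phat) / m + zz^2 / (4 * m^2)) / den
    data.frame(bin = b, mean_predicted = mean(p_good[sel]),
               observed_proportion = phat, n = m,
               lo = max(0, ctr - hw), hi = min(1, ctr + hw))
  })
  out <- do.call(rbind, out)
  out[order(out$mean_predicted), , drop = FALSE]
}
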