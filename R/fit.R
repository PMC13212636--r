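# Proportional-odds (cumulative logit, common odds ratio) model:
# maximum likelihood with a monotone intercept parameterization.
#
# Orientation: P(mRS <= k | x) = expit(alpha_k + x'beta), so exp(beta) > 1
# means better functional outcome. Intercepts are optimized as an
# unconstrained alpha_0 plus positive increments, which guarantees
# nondecreasing cumulative probabilities for every patient.

# negative log-likelihood and analytic gradient in the (alpha, beta)
# parameterization; z is the 0-based category index, K the category count
.po_nll_parts <- function(alpha, beta, X, z, K, w) {
  eta <- if (length(beta)) drop(X %*% beta) else numeric(nrow(X))
  A1 <- ifelse(z < K - 1L, alpha[pmin(z + 1L, K - 1L)] + eta, Inf)
  A0 <- ifelse(z > 0L, alpha[pmax(z, 1L)] + eta, -Inf)
  g1 <- stats::plogis(A1)
  g0 <- stats::plogis(A0)
  P <- pmax(g1 - g0, 1e-300)
  d1 <- ifelse(is.finite(A1), g1 * (1 - g1), 0)
  d0 <- ifelse(is.finite(A0), g0 * (1 - g0), 0)
  list(eta = eta, P = P, d1 = d1, d0 = d0)
}

.po_nll <- function(alpha, beta, X, z, K, w) {
  pr <- .po_nll_parts(alpha, beta, X, z, K, w)
  -sum(w * log(pr$P))
}

.po_grad <- function(alpha, beta, X, z, K, w) {
  pr <- .po_nll_parts(alpha, beta, X, z, K, w)
  r1 <- w * pr$d1 / pr$P   # weight on alpha_{z}
  r0 <- w * pr$d0 / pr$P   # weight on alpha_{z-1}
  ga <- numeric(K - 1L)
  up <- z < K - 1L
  if (any(up)) {
    s <- tapply(r1[up], z[up], sum)
    ga[as.integer(names(s)) + 1L] <- ga[as.integer(names(s)) + 1L] + s
  }
  lo <- z > 0L
  if (any(lo)) {
    s <- tapply(r0[lo], z[lo], sum)
    ga[as.integer(names(s))] <- ga[as.integer(names(s))] - s
  }
  gb <- if (length(beta)) drop(crossprod(X, r1 - r0)) else numeric(0)
  -c(ga, gb)   # gradient of the NEGATIVE log-likelihood
}

# theta -> (alpha, beta); alpha_0 = theta_1, alpha_k = alpha_{k-1} + exp(theta_{k+1})
.theta_to_ab <- function(theta, K, p) {
  a <- theta[seq_len(K - 1L)]
  alpha <- cumsum(c(a[1L], if (K > 2L) exp(a[-1L]) else numeric(0)))
  list(alpha = alpha, beta = theta[K - 1L + seq_len(p)])
}

# analytic Hessian of the NEGATIVE log-likelihood in (alpha, beta).
# Per observation, with g = expit, d = g(1-g), s = d(1-2g):
#   d2 logP = [s(A1) v1 v1' - s(A0) v0 v0'] / P - dlogP dlogP'
# where v1 = e_z + x, v0 = e_{z-1} + x in the (alpha, beta) blocks.
.po_hess <- function(alpha, beta, X, z, K, w) {
  p <- length(beta)
  eta <- if (p) drop(X %*% beta) else numeric(nrow(X))
  A1 <- ifelse(z < K - 1L, alpha[pmin(z + 1L, K - 1L)] + eta, Inf)
  A0 <- ifelse(z > 0L, alpha[pmax(z, 1L)] + eta, -Inf)
  g1 <- stats::plogis(A1); g0 <- stats::plogis(A0)
  P <- pmax(g1 - g0, 1e-300)
  d1 <- ifelse(is.finite(A1), g1 * (1 - g1), 0)
  d0 <- ifelse(is.finite(A0), g0 * (1 - g0), 0)
  s1 <- ifelse(is.finite(A1), d1 * (1 - 2 * g1), 0)
  s0 <- ifelse(is.finite(A0), d0 * (1 - 2 * g0), 0)
  r <- (d1 - d0) / P
  c11 <- s1 / P; c00 <- s0 / P
  nA <- K - 1L
  H <- matrix(0, nA + p, nA + p)

  # alpha-alpha block
  diag_add <- numeric(nA)
  up <- z < K - 1L; lo <- z > 0L
  acc <- function(vals, idx) {
    s <- rowsum(vals, idx)
    out <- numeric(nA); out[as.integer(rownames(s))] <- s
    out
  }
  if (any(up)) diag_add <- diag_add +
      acc(w[up] * (c11[up] - (d1[up] / P[up])^2), z[up] + 1L)
  if (any(lo)) diag_add <- diag_add +
      acc(w[lo] * (-c00[lo] - (d0[lo] / P[lo])^2), z[lo])
  H[cbind(seq_len(nA), seq_len(nA))] <- diag_add
  both <- up & lo
  if (any(both)) {
    cr <- acc(w[both] * d1[both] * d0[both] / P[both]^2, z[both])
    for (k in which(cr != 0)) {
      H[k + 1L, k] <- H[k + 1L, k] + cr[k]
      H[k, k + 1L] <- H[k, k + 1L] + cr[k]
    }
  }
  if (p) {
    # alpha-beta block
    B <- matrix(0, nA, p)
    if (any(up)) {
      vv <- rowsum(X[up, , drop = FALSE] *
                     (w[up] * (c11[up] - d1[up] * r[up] / P[up])), z[up] + 1L)
      B[as.integer(rownames(vv)), ] <- B[as.integer(rownames(vv)), ] + vv
    }
    if (any(lo)) {
      vv <- rowsum(X[lo, , drop = FALSE] *
                     (w[lo] * (-c00[lo] + d0[lo] * r[lo] / P[lo])), z[lo])
      B[as.integer(rownames(vv)), ] <- B[as.integer(rownames(vv)), ] + vv
    }
    H[seq_len(nA), nA + seq_len(p)] <- B
    H[nA + seq_len(p), seq_len(nA)] <- t(B)
    # beta-beta block
    cbb <- w * (c11 - c00 - r^2)
    H[nA + seq_len(p), nA + seq_len(p)] <- crossprod(X, X * cbb)
  }
  -H  # Hessian of the negative log-likelihood
}

#' Fit a proportional-odds model by maximum likelihood
#'
#' Cumulative-logit model `P(mRS <= k | x) = expit(alpha_k + x'beta)` fit
#' by quasi-Newton optimization with analytic gradients; intercept
#' monotonicity is enforced through a log-increment parameterization.
#' Standard errors come from the inverse observed information at the
#' optimum (finite differences of the analytic gradient).
#'
#' @param X numeric design matrix (see [build_design_matrix()]).
#' @param y integer outcome vector (mRS 0-6; any subset of levels works,
#'   a two-level outcome reduces to binary logistic regression).
#' @param weights optional nonnegative case weights.
#' @param tol gradient-norm convergence tolerance.
#' @return Object of class `po_fit`: intercepts `alpha`, coefficients
#'   `beta`, covariance `vcov` over `(alpha, beta)`, `logLik`, observed
#'   outcome `levels`, convergence diagnostics.
#' @export
fit_proportional_odds <- function(X, y, weights = NULL, tol = 1e-6) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  levels <- sort(unique(y))
  K <- length(levels)
  if (K < 2L) stop("outcome has a single observed level", call. = FALSE)
  z <- match(y, levels) - 1L
  p <- ncol(X)
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  if (nrow(X) <= p + K - 1L)
    stop("more parameters than observations", call. = FALSE)

  # start: empirical cumulative logits, beta = 0
  cw <- cumsum(rowsum(w, z))[-K]
  a0 <- stats::qlogis(pmin(pmax(cw / sum(w), 1e-4), 1 - 1e-4))
  a0 <- cummax(a0 + seq_len(K - 1L) * 1e-8)  # guard exact ties
  alpha <- a0
  beta <- rep(0, p)
  nA <- K - 1L

  # Newton-Raphson with step halving; the cumulative-logit log-likelihood
  # is concave in (alpha, beta), and intercept order is preserved by the
  # line search (a crossing makes a category probability vanish, which
  # blows up the objective and halves the step).
  nll <- .po_nll(alpha, beta, X, z, K, w)
  converged <- FALSE
  H <- NULL
  for (iter in seq_len(60L)) {
    grad <- .po_grad(alpha, beta, X, z, K, w)
    gnorm <- sqrt(sum(grad^2))
    if (gnorm < tol) { converged <- TRUE; break }
    H <- .po_hess(alpha, beta, X, z, K, w)
    step <- tryCatch(-solve(H, grad),
                     error = function(e) -grad / max(1, gnorm))
    lambda <- 1
    repeat {
      a_new <- alpha + lambda * step[seq_len(nA)]
      b_new <- beta + if (p) lambda * step[nA + seq_len(p)] else 0
      ok <- !is.unsorted(a_new, strictly = TRUE)
      nll_new <- if (ok) .po_nll(a_new, b_new, X, z, K, w) else Inf
      if (is.finite(nll_new) && nll_new <= nll + 1e-12 * abs(nll)) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { nll_new <- nll; a_new <- alpha; b_new <- beta; break }
    }
    alpha <- a_new; beta <- b_new; nll <- nll_new
  }
  grad <- .po_grad(alpha, beta, X, z, K, w)
  gnorm <- sqrt(sum(grad^2))
  converged <- gnorm < tol
  if (!converged)
    warning("proportional-odds fit: gradient norm ", signif(gnorm, 3),
            " above tolerance", call. = FALSE)
  separated <- any(abs(beta) > 15)
  if (separated)
    warning("possible complete separation: |coefficient| > 15", call. = FALSE)
  ab <- list(alpha = alpha, beta = beta)

  # covariance: inverse observed information at the optimum
  H <- .po_hess(alpha, beta, X, z, K, w)
  H <- (H + t(H)) / 2
  np <- nA + p
  vcov <- tryCatch(solve(H), error = function(e) {
    warning("singular information matrix; covariance by pseudo-inverse",
            call. = FALSE)
    ev <- eigen(H, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    ev$vectors[, pos, drop = FALSE] %*%
      (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
  })
  pn <- c(paste0("alpha_", seq_len(K - 1L) - 1L), colnames(X))
  dimnames(vcov) <- list(pn, pn)
  names(ab$alpha) <- pn[seq_len(K - 1L)]
  names(ab$beta) <- colnames(X)

  structure(list(alpha = ab$alpha, beta = ab$beta, vcov = vcov,
                 logLik = -nll, levels = levels, n = nrow(X),
                 n_params = np, converged = converged, grad_norm = gnorm,
                 separated = separated, spec = NULL),
            class = "po_fit")
}

#' @export
print.po_fit <- function(x, ...) {
  cat("Proportional-odds model (", x$n, " patients, ",
      length(x$levels), " outcome levels)\n", sep = "")
  cat("  log-likelihood: ", format(x$logLik, digits = 8), "\n", sep = "")
  if (length(x$beta)) {
    se <- sqrt(diag(x$vcov))[length(x$alpha) + seq_along(x$beta)]
    tab <- data.frame(coef = x$beta, OR = exp(x$beta),
                      lo = exp(x$beta - 1.96 * se),
                      hi = exp(x$beta + 1.96 * se))
    print(round(tab, 3))
  }
  invisible(x)
}

#' Fit an outcome model from a cohort and a declarative specification
#'
#' Resolves data-dependent knots on the cohort, builds the design matrix
#' and fits the proportional-odds model; the resolved spec travels with
#' the fit so predictions on new data reuse the training knots.
#'
#' @param cohort a complete `trial_cohort`.
#' @param spec a `model_spec`.
#' @param weights optional case weights.
#' @return A `po_fit` carrying the resolved `spec`.
#' @export
fit_outcome_model <- function(cohort, spec, weights = NULL) {
  spec <- resolve_spec(spec, cohort)
  X <- build_design_matrix(cohort, spec)
  fit <- fit_proportional_odds(X, as.data.frame(cohort)$mrs90, weights)
  fit$spec <- spec
  fit
}

.design_for <- function(model, newdata, force_evt = NULL) {
  if (is.matrix(newdata)) {
    if (!is.null(force_evt))
      stop("counterfactual prediction needs a cohort, not a matrix", call. = FALSE)
    if (!identical(colnames(newdata), names(model$beta)))
      stop("design matrix columns do not match the fitted model", call. = FALSE)
    return(newdata)
  }
  if (is.null(model$spec))
    stop("model has no spec; pass a design matrix", call. = FALSE)
  build_design_matrix(newdata, model$spec, force_evt = force_evt)
}

#' Linear predictor of a fitted model
#' @param model a `po_fit`.
#' @param newdata a `trial_cohort` or design matrix.
#' @return Numeric vector eta = x'beta.
#' @export
linear_predictor <- function(model, newdata) {
  drop(.design_for(model, newdata) %*% model$beta)
}

#' Predicted outcome distribution over mRS levels
#'
#' `P(mRS = k) = expit(alpha_k + eta) - expit(alpha_{k-1} + eta)`; rows
#' sum to one.
#'
#' @inheritParams linear_predictor
#' @return Matrix, one row per patient, one column per observed mRS level.
#' @export
predict_distribution <- function(model, newdata) {
  eta <- linear_predictor(model, newdata)
  K <- length(model$levels)
  cum <- cbind(outer(eta, model$alpha, function(e, a) stats::plogis(a + e)), 1)
  probs <- cum - cbind(0, cum[, -K, drop = FALSE])
  colnames(probs) <- paste0("mrs_", model$levels)
  probs
}

#' Predicted probability of good functional outcome (mRS 0-2)
#'
#' @inheritParams linear_predictor
#' @return Numeric vector `expit(alpha_2 + eta)` in (0, 1).
#' @export
predict_good_outcome <- function(model, newdata) {
  k2 <- max(which(model$levels <= 2L))
  if (model$levels[k2] > 2L || k2 > length(model$alpha))
    stop("model outcome levels do not admit an mRS 0-2 cut", call. = FALSE)
  stats::plogis(model$alpha[k2] + linear_predictor(model, newdata))
}

#' Predicted individual treatment benefit
#'
#' Evaluates the probability of good outcome under both counterfactual
#' arms (treatment indicator and its interaction columns set to 1, then
#' 0, all other covariates fixed); benefit is their difference.
#'
#' @param model a `po_fit` whose spec contains the treatment term.
#' @param cohort a `trial_cohort`.
#' @return data.frame with `p_good_evt`, `p_good_control`, `benefit`.
#' @export
predict_benefit <- function(model, cohort) {
  if (is.null(model$spec) || !model$spec$treatment)
    stop("model specification lacks a treatment term", call. = FALSE)
  p1 <- predict_good_outcome(model, .design_for(model, cohort, force_evt = 1))
  p0 <- predict_good_outcome(model, .design_for(model, cohort, force_evt = 0))
  data.frame(p_good_evt = p1, p_good_control = p0, benefit = p1 - p0)
}

#' Likelihood ratio test between nested proportional-odds fits
#'
#' @param full,reduced `po_fit` objects on the same rows; the reduced
#'   model's columns must be a subset of the full model's.
#' @return list with `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  if (!all(names(reduced$beta) %in% names(full$beta)))
    stop("models are not nested (reduced columns not a subset)", call. = FALSE)
  if (full$n != reduced$n)
    stop("models were fitted on different numbers of rows", call. = FALSE)
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  df <- length(full$beta) - length(reduced$beta)
  if (df < 0L) stop("full model has fewer columns than reduced", call. = FALSE)
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

# joint Wald test that all columns of a term block are zero
.wald_term_p <- function(fit, cols) {
  idx <- length(fit$alpha) + match(cols, names(fit$beta))
  b <- fit$beta[cols]
  V <- fit$vcov[idx, idx, drop = FALSE]
  stat <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
  if (is.na(stat)) return(NA_real_)
  stats::pchisq(stat, length(b), lower.tail = FALSE)
}

#' Backward elimination of model terms
#'
#' Iteratively refits the model, removing at each step the eligible
#' variable whose joint Wald p-value (all its design columns at once,
#' spline and dummy blocks as a unit) is largest and exceeds `p_remove`.
#' The treatment term, variables interacted with treatment, and any
#' `forced` variables are never removed.
#'
#' @param spec starting `model_spec`.
#' @param cohort complete `trial_cohort`.
#' @param p_remove removal threshold (default 0.20).
#' @param forced variable names exempt from elimination.
#' @return list with the reduced `spec`, the final `fit`, and a `trace`
#'   data.frame of removals.
#' @export
backward_eliminate <- function(spec, cohort, p_remove = 0.20,
                               forced = character()) {
  stopifnot(p_remove > 0, p_remove <= 1)
  protected <- unique(c(spec$interactions, forced))
  trace <- data.frame(step = integer(), variable = character(),
                      p = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fit <- fit_outcome_model(cohort, spec)
    term_map <- attr(build_design_matrix(cohort, fit$spec), "term_map")
    eligible <- setdiff(names(spec$terms), protected)
    if (length(eligible) == 0L) break
    pvals <- vapply(eligible, function(v)
      .wald_term_p(fit, names(term_map)[term_map == v]), numeric(1))
    worst <- which.max(pvals)
    if (length(worst) == 0L || is.na(pvals[worst]) ||
        pvals[worst] <= p_remove) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     variable = eligible[worst],
                                     p = pvals[worst]))
    spec$terms[[eligible[worst]]] <- NULL
  }
  list(spec = spec, fit = fit, trace = trace)
}

#' Odds-ratio summary table with piecewise spline effects
#'
#' Linear and categorical terms are reported as `exp(beta)` with Wald 95%
#' CIs. Spline terms are summarized as two per-unit odds ratios: the
#' exponentiated chord slope of the fitted curve from the first knot to
#' the inflection value, and from the inflection value to the last knot,
#' with delta-method CIs.
#'
#' @param model a `po_fit` with a resolved spec.
#' @param piecewise_points named list overriding the inflection value per
#'   spline variable (default: the middle knot).
#' @return data.frame with `variable`, `contrast`, `or`, `lo`, `hi`.
#' @export
summarize_effects <- function(model, piecewise_points = list()) {
  if (is.null(model$spec)) stop("model has no spec", call. = FALSE)
  spec <- model$spec
  nA <- length(model$alpha)
  rows <- list()
  add <- function(variable, contrast, est, se) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, contrast = contrast, or = exp(est),
      lo = exp(est - 1.96 * se), hi = exp(est + 1.96 * se),
      stringsAsFactors = FALSE)
  }
  beta_se <- sqrt(pmax(diag(model$vcov), 0))[nA + seq_along(model$beta)]
  for (nm in names(spec$terms)) {
    t <- spec$terms[[nm]]
    if (t$type == "linear") {
      unit <- if (t$scale != 1) sprintf("per %g units", t$scale) else "per unit"
      add(nm, unit, model$beta[[nm]], beta_se[[nm]])
    } else if (t$type == "categorical") {
      for (lev in t$levels[-1L]) {
        cn <- paste0(nm, "_", lev)
        add(nm, paste0(lev, " vs ", t$levels[1L]), model$beta[[cn]], beta_se[[cn]])
      }
    } else if (t$type == "spline") {
      kn <- t$knots / t$scale
      mid <- piecewise_points[[nm]] %||% t$knots[(length(t$knots) + 1L) %/% 2L]
      mid <- mid / t$scale
      if (mid <= kn[1L] || mid >= kn[length(kn)])
        warning("inflection point for '", nm, "' outside knot span", call. = FALSE)
      cols <- grep(paste0("^", nm, "(_s[0-9]+)?$"), names(model$beta), value = TRUE)
      idx <- nA + match(cols, names(model$beta))
      chord <- function(x0, x1) {
        cv <- (rcs_basis(x1, kn) - rcs_basis(x0, kn)) / (x1 - x0)
        est <- drop(cv %*% model$beta[cols])
        se <- sqrt(drop(cv %*% model$vcov[idx, idx] %*% t(cv)))
        c(est, se)
      }
      lo <- chord(kn[1L], mid)
      hi <- chord(mid, kn[length(kn)])
      unit <- if (t$scale != 1) sprintf("per %g units", t$scale) else "per unit"
      add(nm, sprintf("%s, below %g", unit, mid * t$scale), lo[1L], lo[2L])
      add(nm, sprintf("%s, above %g", unit, mid * t$scale), hi[1L], hi[2L])
    }
  }
  if (spec$treatment) add("evt", "EVT vs control", model$beta[["evt"]],
                          beta_se[["evt"]])
  for (v in spec$interactions) {
    cn <- grep(paste0("^evt_x_", v), names(model$beta), value = TRUE)
    for (c1 in cn) add(paste0("evt_x_", v), "interaction, per unit",
                       model$beta[[c1]], beta_se[[c1]])
  }
  do.call(rbind, rows)
}

#' Serialize / restore a fitted model as JSON
#'
#' Stores the resolved spec, intercepts, coefficients, covariance and
#' log-likelihood for exact reload.
#'
#' @param model a `po_fit`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  payload <- list(
    alpha = as.list(model$alpha), beta = as.list(model$beta),
    vcov = model$vcov, logLik = model$logLik, levels = model$levels,
    n = model$n, converged = model$converged,
    spec = if (!is.null(model$spec))
      list(terms = lapply(model$spec$terms, unclass),
           treatment = model$spec$treatment,
           interactions = as.list(model$spec$interactions)) else NULL)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  spec <- NULL
  if (!is.null(p$spec)) {
    terms <- lapply(p$spec$terms, function(t) {
      t$knots <- if (length(t$knots) > 0) as.numeric(t$knots) else NULL
      t$forced_middle <- if (length(t$forced_middle) > 0)
        as.numeric(t$forced_middle) else NULL
      structure(t, class = "model_term")
    })
    spec <- model_spec(terms, treatment = isTRUE(p$spec$treatment),
                       interactions = unlist(p$spec$interactions,
                                             use.names = FALSE) %||% character())
  }
  vcov <- matrix(unlist(p$vcov), nrow = length(p$alpha) + length(p$beta),
                 byrow = TRUE)
  pn <- c(names(p$alpha), names(p$beta))
  dimnames(vcov) <- list(pn, pn)
  structure(list(alpha = unlist(p$alpha), beta = unlist(p$beta),
                 vcov = vcov, logLik = p$logLik,
                 levels = as.integer(unlist(p$levels)), n = p$n,
                 converged = isTRUE(p$converged), spec = spec),
            class = "po_fit")
}
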