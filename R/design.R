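# Declarative model specifications and design-matrix construction:
# restricted cubic spline bases, reference-coded categoricals, and
# treatment-interaction columns.

#' Restricted cubic spline basis
#'
#' Natural cubic spline in the truncated-power parameterization with
#' linearity enforced beyond the boundary knots. For K knots the basis has
#' K-1 columns: the first is `x` itself, the remaining K-2 are the
#' restricted cubic terms normalized by the squared boundary-knot span so
#' coefficients stay on the variable's own scale. The resulting function
#' of `x` is continuous with continuous first and second derivatives, and
#' exactly linear outside the boundary knots.
#'
#' @param x numeric vector.
#' @param knots strictly increasing numeric vector, length >= 3.
#' @return Numeric matrix, `length(x)` rows and `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  knots <- as.numeric(knots)
  K <- length(knots)
  if (K < 3L) stop("restricted cubic spline needs at least 3 knots", call. = FALSE)
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing", call. = FALSE)
  x <- as.numeric(x)
  tK <- knots[K]; tKm1 <- knots[K - 1L]
  norm <- (tK - knots[1L])^2
  cube <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), K - 1L)
  out[, 1L] <- x
  for (j in seq_len(K - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (cube(x - tj) -
                        cube(x - tKm1) * (tK - tj) / (tK - tKm1) +
                        cube(x - tK) * (tKm1 - tj) / (tK - tKm1)) / norm
  }
  colnames(out) <- c("", paste0("_s", seq_len(K - 2L)))
  out
}

#' Default knot placement
#'
#' Outer quantiles with an optional forced middle knot: for `k = 3` the
#' 10th/50th/90th percentiles (type-7 quantiles); if `forced_middle` is
#' given the middle knot is replaced by it (used to pin the basis at a
#' clinically meaningful inflection value, e.g. brain parenchymal
#' fraction 80%).
#'
#' @param values sample of the covariate.
#' @param k number of knots (3, 4 or 5).
#' @param forced_middle optional replacement for the middle knot.
#' @return Strictly increasing knot vector of length `k`.
#' @export
default_knots <- function(values, k = 3L, forced_middle = NULL) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < k)
    stop("degenerate sample: fewer than ", k, " distinct values", call. = FALSE)
  probs <- switch(as.character(k),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                  stop("k must be 3, 4 or 5", call. = FALSE))
  kn <- unname(stats::quantile(values, probs, type = 7))
  if (!is.null(forced_middle)) {
    if (k %% 2L == 0L) stop("forced middle knot requires odd k", call. = FALSE)
    kn[(k + 1L) %/% 2L] <- forced_middle
  }
  if (any(diff(kn) <= 0))
    stop("degenerate sample: computed knots are not strictly increasing",
         call. = FALSE)
  kn
}

# ---- term descriptors -------------------------------------------------------

#' Model term descriptors
#'
#' Build the term list of a [model_spec()]. `scale` is a divisor applied
#' before the column enters the design (e.g. `scale = 5` for an effect
#' "per 5 mL"). A spline term may carry explicit `knots` or a policy
#' (`k`, `forced_middle`) resolved against the training data at fit time.
#'
#' @param var variable name from [cohort_dictionary()].
#' @param scale divisor applied to the raw value (default 1).
#' @param knots explicit knot vector (in the variable's raw units), or
#'   `NULL` to place knots from the training sample.
#' @param k number of knots when placing from data.
#' @param forced_middle optional forced middle knot.
#' @param levels closed category set, reference level first.
#' @name model_terms
NULL

#' @rdname model_terms
#' @export
term_linear <- function(var, scale = 1) {
  structure(list(type = "linear", var = var, scale = scale), class = "model_term")
}

#' @rdname model_terms
#' @export
term_spline <- function(var, knots = NULL, k = 3L, forced_middle = NULL,
                        scale = 1) {
  structure(list(type = "spline", var = var, knots = knots, k = k,
                 forced_middle = forced_middle, scale = scale),
            class = "model_term")
}

#' @rdname model_terms
#' @export
term_categorical <- function(var, levels) {
  structure(list(type = "categorical", var = var, levels = levels),
            class = "model_term")
}

#' Declarative ordinal model specification
#'
#' An ordered list of main-effect terms, a treatment indicator flag, and
#' treatment-interaction references. Interacted variables must carry a
#' main-effect term and are multiplied column-wise by the treatment
#' indicator.
#'
#' @param terms named list of [model_terms] descriptors (names are the
#'   variable names).
#' @param treatment include the EVT indicator (default `TRUE`).
#' @param interactions character vector of variable names interacted with
#'   treatment (default `"collateral"` style effect modification).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(terms, treatment = TRUE, interactions = character()) {
  if (is.null(names(terms)) || any(names(terms) == ""))
    names(terms) <- vapply(terms, function(t) t$var, character(1))
  known <- cohort_dictionary()$column
  for (t in terms)
    if (!t$var %in% known)
      stop("unknown variable in model spec: ", t$var, call. = FALSE)
  if (anyDuplicated(names(terms)))
    stop("duplicate term for variable: ",
         names(terms)[duplicated(names(terms))][1L], call. = FALSE)
  for (v in interactions)
    if (!v %in% names(terms))
      stop("interaction references variable without a main effect: ", v,
           call. = FALSE)
  if (length(interactions) > 0L && !treatment)
    stop("treatment interactions require the treatment term", call. = FALSE)
  structure(list(terms = terms, treatment = treatment,
                 interactions = interactions),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Ordinal model specification\n")
  for (nm in names(x$terms)) {
    t <- x$terms[[nm]]
    desc <- switch(t$type,
                   linear = sprintf("linear%s",
                                    if (t$scale != 1) sprintf(" (per %g)", t$scale) else ""),
                   spline = sprintf("rcs(%s)",
                                    if (is.null(t$knots)) paste0("k=", t$k,
                                      if (!is.null(t$forced_middle))
                                        paste0(", middle=", t$forced_middle) else "")
                                    else paste(signif(t$knots, 4), collapse = ", ")),
                   categorical = sprintf("categorical (ref %s)", t$levels[1L]))
    cat("  ", nm, ": ", desc, "\n", sep = "")
  }
  if (x$treatment) cat("  evt: treatment indicator\n")
  for (v in x$interactions) cat("  evt x ", v, ": interaction\n", sep = "")
  invisible(x)
}

#' Resolve data-dependent knots against a training cohort
#'
#' Spline terms without explicit knots get them placed by
#' [default_knots()] on the training sample (honouring any forced middle
#' knot). Returns a spec whose every spline term has concrete knots, so
#' design matrices built for new data reuse the training placement.
#'
#' @param spec a `model_spec`.
#' @param cohort training `trial_cohort`.
#' @return A `model_spec` with all knots resolved.
#' @export
resolve_spec <- function(spec, cohort) {
  df <- as.data.frame(cohort)
  for (nm in names(spec$terms)) {
    t <- spec$terms[[nm]]
    if (t$type == "spline" && is.null(t$knots)) {
      t$knots <- default_knots(df[[t$var]], k = t$k,
                               forced_middle = t$forced_middle)
      spec$terms[[nm]] <- t
    }
  }
  spec
}

#' Build the numeric design matrix for a model specification
#'
#' Reference-level dummy coding for categoricals, [rcs_basis()] expansion
#' for spline terms (knots must be resolved), division by `scale` for
#' per-unit effects, and element-wise products for treatment
#' interactions. Column labels are deterministic.
#'
#' @param cohort a `trial_cohort` (complete in all referenced covariates).
#' @param spec a resolved `model_spec`.
#' @param force_evt optionally override the treatment indicator with a
#'   constant 0 or 1 (counterfactual prediction).
#' @return Numeric matrix with a `term_map` attribute (column -> term).
#' @export
build_design_matrix <- function(cohort, spec, force_evt = NULL) {
  df <- as.data.frame(cohort)
  n <- nrow(df)
  evt <- if (is.null(force_evt)) as.numeric(df$evt) else rep(as.numeric(force_evt), n)
  cols <- list(); labels <- character(); map <- character()

  add <- function(mat, labs, term) {
    cols[[length(cols) + 1L]] <<- mat
    labels <<- c(labels, labs)
    map <<- c(map, rep(term, length(labs)))
  }

  for (nm in names(spec$terms)) {
    t <- spec$terms[[nm]]
    v <- df[[t$var]]
    if (t$type != "categorical" && anyNA(v) ||
        t$type == "categorical" && anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop("missing value of '", t$var, "' for patient ",
           df$patient_id[i], "; impute before building the design",
           call. = FALSE)
    }
    if (t$type == "linear") {
      add(matrix(as.numeric(v) / t$scale, ncol = 1L), nm, nm)
    } else if (t$type == "spline") {
      if (is.null(t$knots))
        stop("spline term '", nm, "' has unresolved knots; call resolve_spec()",
             call. = FALSE)
      b <- rcs_basis(as.numeric(v) / t$scale, t$knots / t$scale)
      add(b, paste0(nm, colnames(b)), nm)
    } else if (t$type == "categorical") {
      bad <- !v %in% t$levels
      if (any(bad))
        stop("value '", v[which(bad)[1L]], "' of '", t$var,
             "' outside its category set", call. = FALSE)
      for (lev in t$levels[-1L])
        add(matrix(as.numeric(v == lev), ncol = 1L),
            paste0(nm, "_", lev), nm)
    }
  }
  if (spec$treatment) add(matrix(evt, ncol = 1L), "evt", "evt")
  for (v in spec$interactions) {
    t <- spec$terms[[v]]
    main_cols <- which(map == v & labels != "evt")
    Xmain <- do.call(cbind, cols)[, main_cols, drop = FALSE]
    add(Xmain * evt, paste0("evt_x_", labels[main_cols]), paste0("evt_x_", v))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- labels
  attr(X, "term_map") <- stats::setNames(map, labels)
  X
}

# ---- shipped specifications -------------------------------------------------

#' Shipped model specifications
#'
#' `ct_imaging_spec()`: the CT-feature-only model (ASPECTS, occlusion
#' location, collateral score, WML volume per 5 mL, BPF as a restricted
#' cubic spline with middle knot pinned at 80%, ICAC subtype) plus the EVT
#' term and the EVT-by-collateral interaction.
#' `ct_extended_spec()`: the same model extended with age (spline, middle
#' knot 65 years) and baseline NIHSS.
#' `mr_predicts_spec()`: the reference clinical+imaging specification
#' (age, NIHSS, systolic blood pressure spline at 130 mmHg, IV alteplase,
#' diabetes, glucose spline at 120 mg/dL, pre-stroke mRS, onset-to-groin
#' time per 30 min, ASPECTS, occlusion, collateral) re-fit to the cohort
#' at hand.
#'
#' @param include_old_infarct keep old infarct volume in the CT model
#'   (dropped by default, as backward elimination removes it).
#' @return A `model_spec`.
#' @name shipped_specs
NULL

#' @rdname shipped_specs
#' @export
ct_imaging_spec <- function(include_old_infarct = FALSE) {
  terms <- list(
    aspects = term_linear("aspects"),
    occlusion = term_categorical("occlusion", .occlusion_levels),
    collateral = term_linear("collateral"),
    wml_volume = term_linear("wml_volume", scale = 5),
    bpf = term_spline("bpf", forced_middle = 80),
    icac = term_categorical("icac", .icac_levels))
  if (include_old_infarct)
    terms$old_infarct_volume <- term_linear("old_infarct_volume", scale = 5)
  model_spec(terms, treatment = TRUE, interactions = "collateral")
}

#' @rdname shipped_specs
#' @export
ct_extended_spec <- function(include_old_infarct = FALSE) {
  spec <- ct_imaging_spec(include_old_infarct)
  spec$terms <- c(list(age = term_spline("age", forced_middle = 65),
                       nihss = term_linear("nihss")),
                  spec$terms)
  spec
}

#' @rdname shipped_specs
#' @export
mr_predicts_spec <- function() {
  model_spec(list(
    age = term_spline("age", forced_middle = 65),
    nihss = term_linear("nihss"),
    sbp = term_spline("sbp", forced_middle = 130, scale = 10),
    iv_alteplase = term_linear("iv_alteplase"),
    diabetes = term_linear("diabetes"),
    glucose = term_spline("glucose", forced_middle = 120, scale = 10),
    prestroke_mrs = term_linear("prestroke_mrs"),
    onset_to_groin = term_linear("onset_to_groin", scale = 30),
    aspects = term_linear("aspects"),
    occlusion = term_categorical("occlusion", .occlusion_levels),
    collateral = term_linear("collateral")),
    treatment = TRUE, interactions = "collateral")
}

#' Serialize / restore a model specification as JSON
#'
#' @param spec a `model_spec`.
#' @param path file path.
#' @return `write_model_spec()` returns the path invisibly;
#'   `read_model_spec()` returns a `model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  payload <- list(terms = lapply(spec$terms, unclass),
                  treatment = spec$treatment,
                  interactions = as.list(spec$interactions))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  terms <- lapply(p$terms, function(t) {
    t$knots <- if (length(t$knots) > 0) as.numeric(t$knots) else NULL
    t$forced_middle <- if (length(t$forced_middle) > 0)
      as.numeric(t$forced_middle) else NULL
    structure(t, class = "model_term")
  })
  model_spec(terms, treatment = isTRUE(p$treatment),
             interactions = unlist(p$interactions, use.names = FALSE) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
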