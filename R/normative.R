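# Normative modelling: per-feature ordinary least squares on healthy controls
# (volume ~ age + sex), then z-scoring of every subject against the control
# residual distribution.

#' Fit per-feature normative age/sex models on controls
#'
#' For each hemisphere x region measure, fits `volume ~ age + sex` by ordinary
#' least squares on controls only and stores the coefficients together with
#' the control residual standard deviation (denominator n - p, where p is the
#' number of fitted coefficients).
#'
#' @param volumes Validated (typically harmonized) volume tibble.
#' @param demographics Validated demographics tibble; age and sex must be
#'   complete for controls.
#' @param covariates Covariates in the normative regression; default
#'   `c("age", "sex")`. `"age"` is years at scan; `"sex"` a male indicator.
#' @param min_controls Minimum number of controls required (default 10).
#' @return An object of class `normative_model`.
#' @export
fit_normative <- function(volumes, demographics,
                          covariates = c("age", "sex"),
                          min_controls = 10L) {
  check_cohort(volumes, demographics)
  ctrl <- demographics[demographics$group == "control", ]
  n <- nrow(ctrl)
  if (n < min_controls) {
    abort(sprintf("Need at least %d controls to fit the normative model; have %d.",
                  min_controls, n))
  }
  X <- normative_design(ctrl, covariates)
  p <- ncol(X)
  if (n < p + 2) {
    abort(sprintf("Too few controls (%d) for %d coefficients.", n, p))
  }
  Y <- feature_matrix(volumes)[ctrl$subject_id, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < p) abort("Normative design is rank deficient.")
  B <- solve(crossprod(X), crossprod(X, Y))
  resid <- Y - X %*% B
  rss <- colSums(resid^2)
  sigma <- sqrt(rss / (n - p))
  degenerate <- !is.finite(sigma) | sigma <= 1e-8 * mean(abs(Y))
  if (any(degenerate)) {
    zero <- colnames(Y)[degenerate]
    abort(sprintf("Zero control residual variance for feature(s): %s",
                  paste(zero, collapse = ", ")))
  }
  structure(list(
    coefficients = B,          # (p x features), rows: intercept + covariates
    sigma = sigma,             # control residual SD per feature, mm^3
    covariates = covariates,
    features = colnames(Y),
    n_controls = n,
    df_residual = n - p
  ), class = "normative_model")
}

normative_design <- function(demographics, covariates) {
  cols <- list("(Intercept)" = rep(1, nrow(demographics)))
  if ("age" %in% covariates) cols$age <- demographics$age_at_scan
  if ("sex" %in% covariates) cols$sex_male <- as.numeric(demographics$sex == "male")
  unknown <- setdiff(covariates, c("age", "sex"))
  for (cc in unknown) {
    if (!cc %in% names(demographics)) {
      abort(sprintf("Unknown normative covariate: %s", cc))
    }
    cols[[cc]] <- as.numeric(demographics[[cc]])
  }
  X <- do.call(cbind, cols)
  if (anyNA(X)) {
    bad <- demographics$subject_id[!complete.cases(X)]
    abort(sprintf("Missing covariate value(s) for subject(s): %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  X
}

#' Predicted normative volumes for a set of subjects
#'
#' @param object A `normative_model`.
#' @param demographics Demographics tibble for the subjects to predict.
#' @param ... Unused.
#' @return Matrix of predicted volumes, subjects x features.
#' @export
predict.normative_model <- function(object, demographics, ...) {
  X <- normative_design(demographics, object$covariates)
  pred <- X %*% object$coefficients
  rownames(pred) <- demographics$subject_id
  pred
}

#' Z-score volumes against the control-trained normative model
#'
#' For every subject (controls included, no leave-one-out),
#' `z = (observed - predicted(age, sex)) / control residual SD`, computed per
#' hemisphere and region.
#'
#' @param volumes Validated (typically harmonized) volume tibble.
#' @param demographics Validated demographics tibble covering all subjects.
#' @param model A `normative_model` from [fit_normative()].
#' @return A z-score tibble: `subject_id`, `hemisphere`, `region`, `z`.
#' @export
zscore <- function(volumes, demographics, model) {
  stopifnot(inherits(model, "normative_model"))
  check_cohort(volumes, demographics)
  Y <- feature_matrix(volumes, model$features)
  demographics <- demographics[match(rownames(Y), demographics$subject_id), ]
  pred <- predict(model, demographics)
  Z <- sweep(Y - pred, 2, model$sigma, `/`)
  out <- matrix_to_volumes(Z)
  names(out)[names(out) == "volume"] <- "z"
  out
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf(
    "Normative model: %d features, covariates [%s], fitted on %d controls (residual df %d)\n",
    length(x$features), paste(x$covariates, collapse = ", "),
    x$n_controls, x$df_residual
  ))
  invisible(x)
}

#' Serialize a normative model to JSON
#'
#' @param model A `normative_model`.
#' @param path Optional output path; `NULL` returns the JSON string.
#' @return JSON string, invisibly when written.
#' @export
normative_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "normative_model"))
  obj <- unclass(model)
  obj$coefficients <- as.data.frame(obj$coefficients)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
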