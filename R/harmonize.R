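# Location/scale empirical-Bayes batch harmonization (ComBat) with an explicit
# fit/apply split so the fitted adjustment can be audited, serialized and
# applied to data not seen at fit time (same batches only).

feature_matrix <- function(volumes, features = NULL) {
  wide <- volumes |>
    dplyr::mutate(feature = paste(.data$hemisphere, .data$region, sep = ".")) |>
    dplyr::select("subject_id", "feature", "volume") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "volume")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$subject_id
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(m))
    if (length(missing) > 0) {
      abort(sprintf("Volume table lacks feature(s): %s",
                    paste(missing, collapse = ", ")))
    }
    m <- m[, features, drop = FALSE]
  }
  if (anyNA(m)) abort("Volume table is not complete across subjects/features.")
  m
}

matrix_to_volumes <- function(m) {
  tibble::as_tibble(m, rownames = "subject_id") |>
    tidyr::pivot_longer(-"subject_id", names_to = "feature",
                        values_to = "volume") |>
    tidyr::separate_wider_delim("feature", delim = ".",
                                names = c("hemisphere", "region"))
}

# Biological covariate design preserved by harmonization: sex (male = 1),
# age in years, and presence of epilepsy (any non-control group).
combat_covariates <- function(demographics, covariates) {
  cols <- list()
  if ("sex" %in% covariates) {
    cols$sex_male <- as.numeric(demographics$sex == "male")
  }
  if ("age" %in% covariates || "age_at_scan" %in% covariates) {
    cols$age <- demographics$age_at_scan
  }
  if ("epilepsy" %in% covariates) {
    cols$epilepsy <- as.numeric(demographics$group != "control")
  }
  unknown <- setdiff(covariates, c("sex", "age", "age_at_scan", "epilepsy"))
  for (cc in unknown) {
    if (!cc %in% names(demographics)) {
      abort(sprintf("Unknown harmonization covariate: %s", cc))
    }
    cols[[cc]] <- as.numeric(demographics[[cc]])
  }
  if (length(cols) == 0) {
    matrix(numeric(0), nrow = nrow(demographics), ncol = 0)
  } else {
    do.call(cbind, cols)
  }
}

#' Fit a ComBat batch-harmonization model on regional volumes
#'
#' Fits, per feature (each hemisphere x region volume, including the whole
#' hippocampus), a linear model with batch indicators and biological
#' covariates; standardizes residual data by the pooled variance; estimates
#' per-batch location (gamma) and scale (delta^2) effects; and shrinks them by
#' parametric empirical Bayes (normal prior on gamma, inverse-gamma prior on
#' delta^2, hyperparameters by method of moments across features, posterior by
#' the standard iterative conditional scheme). Biological structure
#' attributable to the listed covariates is preserved.
#'
#' @param volumes Validated volume tibble (see [as_volume_table()]).
#' @param demographics Validated demographics tibble with the batch column and
#'   covariates complete for all subjects.
#' @param features Character vector of features to harmonize jointly, as
#'   `"hemisphere.region"`; defaults to all 10 (2 hemispheres x 5 measures).
#' @param batch Name of the demographics column holding the batch label
#'   (default `"scanner"`).
#' @param covariates Biological covariates to preserve; any of `"sex"`,
#'   `"age"`, `"epilepsy"` (epilepsy = any non-control group). Default all
#'   three.
#' @param eb Apply empirical-Bayes shrinkage (default `TRUE`). With
#'   `eb = FALSE` the raw per-batch location/scale estimates are used, which
#'   exactly equalizes batch means and variances for a covariate-free design.
#' @param tol Convergence tolerance on successive posterior estimates
#'   (default `1e-4`).
#' @param max_iter Maximum EB iterations (default 100).
#' @return An object of class `combat_model`.
#' @seealso [combat_apply()], [harmonize_volumes()]
#' @export
combat_fit <- function(volumes, demographics,
                       features = NULL,
                       batch = "scanner",
                       covariates = c("sex", "age", "epilepsy"),
                       eb = TRUE, tol = 1e-4, max_iter = 100L) {
  check_cohort(volumes, demographics)
  if (!batch %in% names(demographics)) {
    abort(sprintf("Batch column %s not found in demographics.", sQuote(batch)))
  }
  Y <- feature_matrix(volumes, features)
  demographics <- demographics[match(rownames(Y), demographics$subject_id), ]
  bf <- droplevels(factor(demographics[[batch]]))
  n_b <- table(bf)
  if (any(n_b < 2)) {
    abort(sprintf("Batch(es) with fewer than 2 samples: %s (batch variance undefined).",
                  paste(names(n_b)[n_b < 2], collapse = ", ")))
  }
  X_cov <- combat_covariates(demographics, covariates)

  if (nlevels(bf) == 1L) {
    warn("Single batch: harmonization model is an identity adjustment.")
    return(structure(list(identity = TRUE, batch = batch,
                          batches = levels(bf), features = colnames(Y),
                          covariates = covariates, eb = eb),
                     class = "combat_model"))
  }

  X_b <- model.matrix(~ 0 + bf)
  colnames(X_b) <- levels(bf)
  X <- cbind(X_b, X_cov)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("Harmonization design is rank deficient; collinear column(s): %s",
                  paste(dropped, collapse = ", ")))
  }
  n <- nrow(Y)
  B <- solve(crossprod(X), crossprod(X, Y))
  grand_mean <- drop((n_b / n) %*% B[levels(bf), , drop = FALSE])
  resid <- Y - X %*% B
  var_pooled <- colMeans(resid^2)
  if (any(var_pooled <= 0)) abort("Zero pooled variance for some feature(s).")

  cov_effect <- if (ncol(X_cov) > 0) {
    X_cov %*% B[seq(nlevels(bf) + 1, ncol(X)), , drop = FALSE]
  } else {
    matrix(0, n, ncol(Y))
  }
  stand_mean <- sweep(cov_effect, 2, grand_mean, `+`)
  Z <- sweep(Y - stand_mean, 2, sqrt(var_pooled), `/`)

  gamma_hat <- rowsum(Z, bf) / as.vector(n_b)
  delta_hat <- gamma_hat
  for (b in levels(bf)) {
    delta_hat[b, ] <- apply(Z[bf == b, , drop = FALSE], 2, var)
  }

  if (eb) {
    post <- eb_shrink(Z, bf, n_b, gamma_hat, delta_hat, tol, max_iter)
    gamma_star <- post$gamma
    delta_star <- post$delta
  } else {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
  }

  structure(list(
    identity = FALSE,
    batch = batch, batches = levels(bf), n_per_batch = as.vector(n_b),
    features = colnames(Y), covariates = covariates,
    grand_mean = grand_mean, var_pooled = var_pooled,
    cov_coef = if (ncol(X_cov) > 0) B[seq(nlevels(bf) + 1, ncol(X)), , drop = FALSE] else NULL,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    eb = eb, tol = tol, max_iter = max_iter
  ), class = "combat_model")
}

# Parametric EB posterior for batch effects: normal prior on gamma,
# inverse-gamma prior on delta^2, method-of-moments hyperparameters, iterated
# conditional posterior means until successive change < tol.
eb_shrink <- function(Z, bf, n_b, gamma_hat, delta_hat, tol, max_iter) {
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in levels(bf)) {
    g <- gamma_hat[b, ]
    d <- delta_hat[b, ]
    g_bar <- mean(g)
    t2 <- var(g)
    m <- mean(d)
    s2 <- var(d)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    nb <- n_b[[b]]
    Zb <- Z[bf == b, , drop = FALSE]
    g_new <- g
    d_new <- d
    for (it in seq_len(max_iter)) {
      g_old <- g_new
      d_old <- d_new
      g_new <- (nb * t2 * g + d_old * g_bar) / (nb * t2 + d_old)
      ss <- colSums(sweep(Zb, 2, g_new, `-`)^2)
      d_new <- (0.5 * ss + b_prior) / (nb / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / abs(d_old))
      if (is.finite(change) && change < tol) break
    }
    gamma_star[b, ] <- g_new
    delta_star[b, ] <- d_new
  }
  list(gamma = gamma_star, delta = delta_star)
}

#' Apply a fitted ComBat model to a volume table
#'
#' Each feature value is standardized with the stored grand mean, covariate
#' effects and pooled variance, recentred/rescaled by its batch's shrunken
#' location/scale effects, and mapped back to the volume scale. Batches unseen
#' at fit time are an error (no reference-batch extrapolation).
#'
#' @param model A `combat_model` from [combat_fit()].
#' @param volumes,demographics Cohort to adjust; all batch labels must have
#'   been present at fit time.
#' @return A volume tibble with harmonized volumes.
#' @export
combat_apply <- function(model, volumes, demographics) {
  stopifnot(inherits(model, "combat_model"))
  check_cohort(volumes, demographics)
  if (model$identity) return(volumes)
  Y <- feature_matrix(volumes, model$features)
  demographics <- demographics[match(rownames(Y), demographics$subject_id), ]
  bf <- as.character(demographics[[model$batch]])
  unseen <- setdiff(unique(bf), model$batches)
  if (length(unseen) > 0) {
    abort(sprintf("Batch label(s) not seen at fit time: %s",
                  paste(unseen, collapse = ", ")))
  }
  X_cov <- combat_covariates(demographics, model$covariates)
  cov_effect <- if (!is.null(model$cov_coef)) X_cov %*% model$cov_coef else 0
  stand_mean <- sweep(cov_effect + 0 * Y, 2, model$grand_mean, `+`)
  Z <- sweep(Y - stand_mean, 2, sqrt(model$var_pooled), `/`)
  adj <- Z
  for (b in model$batches) {
    rows <- bf == b
    if (!any(rows)) next
    adj[rows, ] <- sweep(
      sweep(Z[rows, , drop = FALSE], 2, model$gamma_star[b, ], `-`),
      2, sqrt(model$delta_star[b, ]), `/`
    )
  }
  Y_adj <- sweep(adj, 2, sqrt(model$var_pooled), `*`) + stand_mean
  out <- matrix_to_volumes(Y_adj)
  # restore original row order/columns
  key <- paste(out$subject_id, out$hemisphere, out$region)
  orig_key <- paste(volumes$subject_id, volumes$hemisphere, volumes$region)
  volumes$volume <- out$volume[match(orig_key, key)]
  volumes
}

#' Fit and apply ComBat harmonization in one call
#'
#' @inheritParams combat_fit
#' @return A volume tibble with harmonized volumes.
#' @export
harmonize_volumes <- function(volumes, demographics, batch = "scanner",
                              covariates = c("sex", "age", "epilepsy"),
                              eb = TRUE, tol = 1e-4, max_iter = 100L) {
  model <- combat_fit(volumes, demographics, batch = batch,
                      covariates = covariates, eb = eb, tol = tol,
                      max_iter = max_iter)
  combat_apply(model, volumes, demographics)
}

#' @export
print.combat_model <- function(x, ...) {
  if (x$identity) {
    cat("ComBat harmonization model: identity (single batch)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "ComBat harmonization model\n  batches: %s (n = %s)\n  features: %d\n  covariates preserved: %s\n  empirical Bayes: %s\n",
    paste(x$batches, collapse = ", "),
    paste(x$n_per_batch, collapse = ", "),
    length(x$features), paste(x$covariates, collapse = ", "),
    if (x$eb) "parametric" else "disabled"
  ))
  invisible(x)
}

#' Serialize a ComBat model to JSON for audit
#'
#' @param model A `combat_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
combat_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "combat_model"))
  json <- jsonlite::toJSON(unclass(model), auto_unbox = TRUE, digits = NA,
                           matrix = "rowmajor", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
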