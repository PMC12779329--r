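# broom-style tidiers for the fitted objects.

#' @export
tidy.normative_model <- function(x, ...) {
  tibble::as_tibble(t(x$coefficients), rownames = "feature") |>
    tidyr::separate_wider_delim("feature", delim = ".",
                                names = c("hemisphere", "region")) |>
    dplyr::mutate(residual_sd = unname(x$sigma))
}

#' @export
glance.normative_model <- function(x, ...) {
  tibble::tibble(n_controls = x$n_controls,
                 n_features = length(x$features),
                 df_residual = x$df_residual,
                 covariates = paste(x$covariates, collapse = ","))
}

#' @export
tidy.combat_model <- function(x, ...) {
  if (x$identity) {
    return(tibble::tibble(batch = character(), feature = character(),
                          gamma_star = numeric(), delta_star = numeric()))
  }
  purrr::map(x$batches, function(b) {
    tibble::tibble(batch = b, feature = x$features,
                   gamma_hat = x$gamma_hat[b, ], delta_hat = x$delta_hat[b, ],
                   gamma_star = x$gamma_star[b, ], delta_star = x$delta_star[b, ])
  }) |> purrr::list_rbind()
}

#' @export
glance.combat_model <- function(x, ...) {
  tibble::tibble(identity = x$identity,
                 n_batches = length(x$batches),
                 n_features = if (x$identity) NA_integer_ else length(x$features),
                 eb = x$eb)
}

#' @export
tidy.control_reference <- function(x, ...) {
  tibble::tibble(region = x$regions, mu = unname(x$mu),
                 variance = unname(diag(x$C)))
}

#' @export
glance.control_reference <- function(x, ...) {
  tibble::tibble(n = x$n, mode = x$mode,
                 min_eigenvalue = min(eigen(x$C, symmetric = TRUE,
                                            only.values = TRUE)$values))
}

#' @export
tidy.hm_report <- function(x, ...) x$comparisons

#' @export
glance.hm_report <- function(x, ...) {
  m <- x$comparisons[x$comparisons$measure == "mahalanobis" &
                       x$comparisons$group_b == "responder", ]
  tibble::tibble(n_subjects = dplyr::n_distinct(x$zscores$subject_id),
                 mahalanobis_nr_vs_r_p = m$p,
                 mahalanobis_nr_vs_r_r = m$r_rank_biserial,
                 mahalanobis_nr_vs_r_auc = m$auc,
                 harmonic_p_regions = x$region_family$harmonic_p[1])
}
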