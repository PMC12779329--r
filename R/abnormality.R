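# Hippocampus-of-interest selection and multivariate Mahalanobis abnormality
# scoring against the healthy-control reference.

zscore_wide <- function(zscores) {
  zscores |>
    tidyr::pivot_wider(names_from = "region", values_from = "z")
}

#' Select each subject's hippocampus of interest (HOI)
#'
#' The HOI is the hemisphere with the smaller mean z-score across the four
#' hippocampal sub-regions — the more atrophic side. Ties are broken by the
#' smaller whole-hippocampus z, then by preferring left.
#'
#' @param zscores A z-score tibble from [zscore()] with both hemispheres and
#'   all five measures per subject.
#' @return A tibble with one row per subject: `subject_id`, `hoi_side`, the
#'   four sub-region z-scores (columns `z_CA-DG`, `z_SRLM`, `z_subiculum`,
#'   `z_tail`) and `whole_hoi_z`.
#' @export
select_hoi <- function(zscores) {
  wide <- zscore_wide(zscores)
  counts <- dplyr::count(wide, .data$subject_id)
  if (any(counts$n != 2L) || anyNA(wide[all_regions()])) {
    bad <- counts$subject_id[counts$n != 2L]
    abort(sprintf("Both hemispheres with complete z-scores required; offending subject(s): %s",
                  paste(head(unique(c(bad, wide$subject_id[!complete.cases(wide)])), 5),
                        collapse = ", ")))
  }
  wide |>
    dplyr::mutate(
      mean_z = rowMeans(dplyr::pick(dplyr::all_of(hoi_regions())))
    ) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(.data$mean_z, .data$whole,
                   match(.data$hemisphere, hemispheres()),
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      subject_id = .data$subject_id,
      hoi_side = .data$hemisphere,
      "z_CA-DG" = .data[["CA-DG"]],
      z_SRLM = .data$SRLM,
      z_subiculum = .data$subiculum,
      z_tail = .data$tail,
      whole_hoi_z = .data$whole
    )
}

hoi_z_matrix <- function(hoi) {
  m <- as.matrix(hoi[c("z_CA-DG", "z_SRLM", "z_subiculum", "z_tail")])
  rownames(m) <- hoi$subject_id
  colnames(m) <- hoi_regions()
  m
}

#' Estimate the control reference distribution (mu, C)
#'
#' Computes the control mean vector and covariance matrix (denominator n - 1)
#' of the four-region z-vectors. In `"hoi"` mode (default) the control vectors
#' are the controls' own HOI vectors, selected with the same rule as patients;
#' in `"pooled"` mode both hemispheres of every control contribute a vector.
#' A ridge `eps * I` with `eps = 1e-8 * trace(C) / 4` is added only if C is
#' near-singular.
#'
#' @param zscores Z-score tibble covering the controls.
#' @param demographics Demographics tibble identifying controls.
#' @param mode `"hoi"` or `"pooled"`.
#' @param min_controls Warn below this many controls (default 20).
#' @return An object of class `control_reference` with elements `mu` (length
#'   4), `C` (4 x 4), `n`, `mode` and `regions` (canonical order).
#' @export
fit_reference <- function(zscores, demographics,
                          mode = c("hoi", "pooled"),
                          min_controls = 20L) {
  mode <- match.arg(mode)
  ctrl_ids <- demographics$subject_id[demographics$group == "control"]
  if (length(ctrl_ids) < min_controls) {
    warn(sprintf("Only %d controls for the reference (recommended >= %d).",
                 length(ctrl_ids), min_controls))
  }
  zc <- zscores[zscores$subject_id %in% ctrl_ids, ]
  vecs <- if (mode == "hoi") {
    hoi_z_matrix(select_hoi(zc))
  } else {
    wide <- zscore_wide(zc)
    m <- as.matrix(wide[hoi_regions()])
    colnames(m) <- hoi_regions()
    m
  }
  mu <- colMeans(vecs)
  C <- stats::cov(vecs)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-10 * sum(diag(C)) / 4
  if (min(ev) <= tol) {
    C <- C + diag(1e-8 * sum(diag(C)) / 4, nrow(C))
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      abort("Control covariance matrix is singular even after ridge regularization.")
    }
  }
  structure(list(mu = mu, C = C, n = nrow(vecs), mode = mode,
                 regions = hoi_regions()),
            class = "control_reference")
}

#' Mahalanobis abnormality score
#'
#' The multivariate distance of a subject's four-region z-vector from the
#' control centroid, `M = sqrt((Z - mu)' C^-1 (Z - mu))`, computed via
#' Cholesky factorization of C (triangular solve, no explicit inverse). The
#' score is agnostic to the direction of abnormality: atrophy and hypertrophy
#' at the same displacement give the same M.
#'
#' @param z A numeric vector of length 4 (canonical region order), or a
#'   matrix with one subject per row.
#' @param reference A `control_reference` from [fit_reference()].
#' @return Non-negative numeric vector of Mahalanobis distances.
#' @export
mahalanobis_score <- function(z, reference) {
  stopifnot(inherits(reference, "control_reference"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) != length(reference$mu)) {
    abort(sprintf("Expected %d-dimensional z-vectors, got %d.",
                  length(reference$mu), ncol(z)))
  }
  R <- chol(reference$C)
  centred <- sweep(z, 2, reference$mu, `-`)
  v <- backsolve(R, t(centred), transpose = TRUE)
  sqrt(colSums(v^2))
}

#' Score multivariate hippocampal abnormality for every subject
#'
#' Convenience wrapper: selects each subject's HOI, fits (or reuses) the
#' control reference, and attaches the Mahalanobis score. With
#' `both_hemispheres = TRUE` the score instead uses the 8-dimensional vector
#' of both hippocampi's region z-scores (left then right, canonical region
#' order) against an 8-dimensional control reference; the HOI columns are
#' still reported.
#'
#' @param zscores Z-score tibble for the full cohort.
#' @param demographics Demographics tibble.
#' @param reference Optional precomputed `control_reference`; fitted from the
#'   controls in `zscores` when `NULL`.
#' @param mode Reference mode when fitting, see [fit_reference()].
#' @param both_hemispheres Use the 8-region bilateral variant (default
#'   `FALSE`).
#' @return A tibble: `subject_id`, `hoi_side`, the four region z-scores,
#'   `whole_hoi_z`, `mahalanobis`; the `control_reference` used is attached
#'   as attribute `"reference"`.
#' @export
score_abnormality <- function(zscores, demographics, reference = NULL,
                              mode = c("hoi", "pooled"),
                              both_hemispheres = FALSE) {
  mode <- match.arg(mode)
  hoi <- select_hoi(zscores)
  if (both_hemispheres) {
    ctrl <- demographics$subject_id[demographics$group == "control"]
    Z <- bilateral_z_matrix(zscores)
    if (is.null(reference)) {
      reference <- reference_from_vectors(Z[rownames(Z) %in% ctrl, ,
                                            drop = FALSE],
                                          mode = "bilateral")
    }
    hoi$mahalanobis <- mahalanobis_score(Z[hoi$subject_id, , drop = FALSE],
                                         reference)
  } else {
    if (is.null(reference)) {
      reference <- fit_reference(zscores, demographics, mode = mode)
    }
    hoi$mahalanobis <- mahalanobis_score(hoi_z_matrix(hoi), reference)
  }
  attr(hoi, "reference") <- reference
  hoi
}

bilateral_z_matrix <- function(zscores) {
  wide <- zscores |>
    dplyr::filter(.data$region %in% hoi_regions()) |>
    dplyr::mutate(feature = paste(.data$hemisphere, .data$region, sep = ".")) |>
    dplyr::select("subject_id", "feature", "z") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "z")
  cols <- as.vector(outer(hoi_regions(), hemispheres(),
                          \(r, h) paste(h, r, sep = ".")))
  m <- as.matrix(wide[cols])
  rownames(m) <- wide$subject_id
  if (anyNA(m)) abort("Both hemispheres with complete z-scores required.")
  m
}

reference_from_vectors <- function(vecs, mode) {
  mu <- colMeans(vecs)
  C <- stats::cov(vecs)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  k <- ncol(vecs)
  if (min(ev) <= 1e-10 * sum(diag(C)) / k) {
    C <- C + diag(1e-8 * sum(diag(C)) / k, k)
    if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      abort("Control covariance matrix is singular even after ridge regularization.")
    }
  }
  structure(list(mu = mu, C = C, n = nrow(vecs), mode = mode,
                 regions = colnames(vecs)),
            class = "control_reference")
}

#' @export
print.control_reference <- function(x, ...) {
  cat(sprintf("Control reference (%s mode, n = %d vectors)\n  mu: %s\n",
              x$mode, x$n,
              paste(sprintf("%.3f", x$mu), collapse = ", ")))
  invisible(x)
}
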