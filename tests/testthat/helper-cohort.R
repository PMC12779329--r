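# Shared builders for small deterministic cohorts and hand-made tables.

# volume tibble from a subjects x features matrix (features "hemi.region")
volumes_from_matrix <- function(m) {
  tibble::as_tibble(m, rownames = "subject_id") |>
    tidyr::pivot_longer(-subject_id, names_to = "feature",
                        values_to = "volume") |>
    tidyr::separate_wider_delim(feature, delim = ".",
                                names = c("hemisphere", "region")) |>
    as_volume_table()
}

# bilateral 4-region volume table with iid noise and optional per-subject
# batch offsets; returns list(volumes, demographics)
flat_cohort <- function(n, base = 1000, sd = 30, batch = NULL,
                        batch_offset = 0, group = "control",
                        age = NULL, sex = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("s%03d", seq_len(n))
  feats <- as.vector(outer(hemispheres(), hoi_regions(), paste, sep = "."))
  m <- matrix(base + rnorm(n * 8, sd = sd), n, 8,
              dimnames = list(ids, feats))
  if (!is.null(batch)) {
    m <- m + batch_offset * (batch == levels(factor(batch))[2])
  }
  dem <- tibble::tibble(
    subject_id = ids,
    group = factor(rep_len(group, n), levels = group_levels()),
    sex = factor(sex %||% sample(c("female", "male"), n, replace = TRUE),
                 levels = c("female", "male")),
    age_at_scan = age %||% runif(n, 20, 70),
    scanner = factor(batch %||% rep("A", n))
  )
  list(volumes = volumes_from_matrix(m), demographics = dem)
}

# z-score tibble from per-subject named z lists: list(left = c(...5), right = ...)
zscores_from_list <- function(zl) {
  purrr::imap(zl, function(hemis, sid) {
    purrr::imap(hemis, function(z, h) {
      tibble::tibble(subject_id = sid, hemisphere = h,
                     region = all_regions(), z = z)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

`%||%` <- rlang::`%||%`
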