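# Synthetic cohort generator: control / responder / non-responder groups with
# the statistical structure the analysis assumes (age and sex effects,
# positive inter-region covariance, scanner batch effects, and heterogeneous
# single-region abnormality concentrated on one side in affected patients).

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the treatment-response study setting the package targets:
#' 100 controls, 42 responders and 50 non-responders scanned on one of two
#' sequences (FSPGR/MPRAGE) with additive and multiplicative batch effects;
#' regional volumes drawn from a compound-symmetric multivariate Gaussian
#' (rho = .6 across all 8 hemisphere x region measures) with linear age
#' decline and a male-larger sex effect; and abnormality injected as a mean
#' shift of `effect_sd` control-SDs in `n_affected_regions` randomly chosen
#' region(s) on a randomly chosen side, in 60% of non-responders and 20% of
#' responders, 85% of shifts being atrophy (the rest hypertrophy). The SRLM
#' shift is scaled by `srlm_boost`, giving that region the largest univariate
#' effect. Clinical covariates (lesion, hippocampal sclerosis, TLE/ETLE) are
#' assigned with the frequencies of the study cohort, including missingness.
#'
#' @param n_control,n_responder,n_nonresponder Group sizes.
#' @param region_means,region_sds Named per-region base volume means/SDs, mm^3.
#' @param rho Compound-symmetric inter-measure correlation in \[0, 1).
#' @param age_range Numeric length-2, years; ages drawn uniformly.
#' @param age_slopes Named per-region volume change per year (mm^3/year).
#' @param sex_effects Named per-region male - female volume difference (mm^3).
#' @param p_female Probability a subject is female, per group (named vector).
#' @param batches Length-2 character vector of batch labels; the second batch
#'   receives the batch effects.
#' @param p_batch1 Probability of the first batch, per group (named vector).
#' @param batch_shift_sd Additive effect on batch 2, in units of region SD.
#' @param batch_scale Multiplicative noise-SD factor for batch 2.
#' @param affected_fraction Named fractions of responders/non-responders
#'   carrying an injected abnormality.
#' @param n_affected_regions Regions shifted per affected subject (default 1).
#' @param effect_sd Size of the injected shift in control-SD units.
#' @param p_atrophy Probability an injected shift is atrophy (vs hypertrophy).
#' @param p_unilateral Probability the abnormality is unilateral.
#' @param srlm_boost Multiplier on the injected shift when SRLM is hit.
#' @param clinical_covariates Also simulate lesion/hs/location columns
#'   (default `TRUE`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_control = 100L, n_responder = 42L,
                       n_nonresponder = 50L,
                       region_means = c("CA-DG" = 1300, "SRLM" = 420,
                                        "subiculum" = 560, "tail" = 550),
                       region_sds = c("CA-DG" = 160, "SRLM" = 55,
                                      "subiculum" = 70, "tail" = 75),
                       rho = 0.6,
                       age_range = c(17, 71),
                       age_slopes = c("CA-DG" = -2.0, "SRLM" = -0.6,
                                      "subiculum" = -0.85, "tail" = -0.8),
                       sex_effects = c("CA-DG" = 90, "SRLM" = 30,
                                       "subiculum" = 40, "tail" = 38),
                       p_female = c(control = 0.62, responder = 0.48,
                                    non_responder = 0.66),
                       batches = c("FSPGR", "MPRAGE"),
                       p_batch1 = c(control = 0.30, responder = 0.62,
                                    non_responder = 0.60),
                       batch_shift_sd = 0.4,
                       batch_scale = 1.15,
                       affected_fraction = c(responder = 0.2,
                                             non_responder = 0.6),
                       n_affected_regions = 1L,
                       effect_sd = 3.0,
                       p_atrophy = 0.85,
                       p_unilateral = 0.8,
                       srlm_boost = 1.25,
                       clinical_covariates = TRUE) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_control > 0, cfg$n_responder > 0, cfg$n_nonresponder > 0,
            cfg$rho >= 0, cfg$rho < 1,
            all(cfg$region_sds > 0), is.finite(cfg$effect_sd),
            cfg$n_affected_regions >= 1,
            cfg$n_affected_regions <= length(hoi_regions()))
  structure(cfg, class = "sim_config")
}

#' Simulate a synthetic control/responder/non-responder cohort
#'
#' Draws a full cohort under [sim_config()]: per subject, uniform age,
#' group-specific sex and batch assignment, bilateral four-region volumes from
#' an 8-dimensional compound-symmetric Gaussian plus age/sex/batch effects,
#' and — for affected patients — a mean shift in randomly chosen region(s) on
#' a randomly chosen side. With the same `seed` the output is bitwise
#' identical across runs.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list with `volumes` (canonical long tibble, whole rows
#'   included), `demographics`, and `truth` (one row per subject recording
#'   whether and where abnormality was injected).
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  regions <- hoi_regions()
  groups <- rep(group_levels(),
                c(config$n_control, config$n_responder, config$n_nonresponder))
  n <- length(groups)
  ids <- sprintf("sub-%03d", seq_len(n))

  demographics <- tibble::tibble(
    subject_id = ids,
    group = factor(groups, levels = group_levels()),
    sex = factor(ifelse(runif(n) < unname(config$p_female[groups]),
                        "female", "male"),
                 levels = c("female", "male")),
    age_at_scan = round(runif(n, config$age_range[1], config$age_range[2]), 1),
    scanner = factor(ifelse(runif(n) < unname(config$p_batch1[groups]),
                            config$batches[1], config$batches[2]),
                     levels = config$batches)
  )

  # 8-dim compound-symmetric correlation scaled by per-region SDs
  sds8 <- rep(config$region_sds[regions], 2)
  corr <- matrix(config$rho, 8, 8); diag(corr) <- 1
  Sigma <- corr * tcrossprod(sds8)
  noise <- matrix(rnorm(n * 8), n, 8) %*% chol(Sigma)
  is_b2 <- demographics$scanner == config$batches[2]
  noise[is_b2, ] <- noise[is_b2, ] * config$batch_scale

  base <- rep(config$region_means[regions], 2)
  age_eff <- outer(demographics$age_at_scan - mean(config$age_range),
                   rep(config$age_slopes[regions], 2))
  sex_eff <- outer(as.numeric(demographics$sex == "male"),
                   rep(config$sex_effects[regions], 2))
  batch_eff <- outer(as.numeric(is_b2),
                     config$batch_shift_sd * sds8)
  vols <- sweep(age_eff + sex_eff + batch_eff + noise, 2, base, `+`)
  colnames(vols) <- paste(rep(hemispheres(), each = 4), regions, sep = ".")
  rownames(vols) <- ids

  truth <- inject_abnormality(vols, demographics, config)
  vols <- truth$vols
  # volumes are anatomically positive; floor the rare extreme-atrophy draw
  vols[vols < 5] <- 5

  volumes <- matrix_to_volumes(vols)
  volumes <- as_volume_table(volumes, add_whole = TRUE)
  if (config$clinical_covariates) {
    demographics <- add_clinical_covariates(demographics)
  }
  list(volumes = volumes, demographics = demographics, truth = truth$table)
}

inject_abnormality <- function(vols, demographics, config) {
  regions <- hoi_regions()
  rows <- list()
  for (i in seq_len(nrow(demographics))) {
    g <- as.character(demographics$group[i])
    frac <- if (g == "control") 0 else config$affected_fraction[[g]]
    affected <- runif(1) < frac
    if (!affected) {
      rows[[i]] <- tibble::tibble(subject_id = demographics$subject_id[i],
                                  group = g, affected = FALSE,
                                  side = NA_character_, region = NA_character_,
                                  direction = NA_character_,
                                  shift_mm3 = NA_character_)
      next
    }
    reg <- sample(regions, config$n_affected_regions)
    side <- if (runif(1) < config$p_unilateral) sample(hemispheres(), 1) else "both"
    dir <- if (runif(1) < config$p_atrophy) "atrophy" else "hypertrophy"
    sides <- if (side == "both") hemispheres() else side
    shifts <- numeric(length(reg))
    for (k in seq_along(reg)) {
      boost <- if (reg[k] == "SRLM") config$srlm_boost else 1
      shift <- config$effect_sd * boost * config$region_sds[[reg[k]]]
      shifts[k] <- if (dir == "atrophy") -shift else shift
      for (s in sides) {
        col <- paste(s, reg[k], sep = ".")
        vols[i, col] <- vols[i, col] + shifts[k]
      }
    }
    rows[[i]] <- tibble::tibble(subject_id = demographics$subject_id[i],
                                group = g, affected = TRUE, side = side,
                                region = paste(reg, collapse = ";"),
                                direction = dir,
                                shift_mm3 = paste(round(shifts, 1), collapse = ";"))
  }
  list(vols = vols, table = purrr::list_rbind(rows))
}

# Assign lesion / hippocampal-sclerosis / location labels to patients with
# exact study-cohort frequencies (yes:no:missing — lesion 31:18:1 NR and
# 16:25:1 R; HS 13:37 NR and 3:39 R; TLE:ETLE:missing 25:14:11 NR and
# 13:11:18 R), scaled proportionally for non-default group sizes.
add_clinical_covariates <- function(demographics) {
  assign_counts <- function(ids, counts, labels) {
    n <- length(ids)
    k <- round(counts / sum(counts) * n)
    while (sum(k) > n) k[which.max(k)] <- k[which.max(k)] - 1
    while (sum(k) < n) k[which.min(k)] <- k[which.min(k)] + 1
    setNames(sample(rep(labels, k)), ids)
  }
  nr <- demographics$subject_id[demographics$group == "non_responder"]
  rr <- demographics$subject_id[demographics$group == "responder"]
  lesion <- c(assign_counts(nr, c(31, 18, 1), c("yes", "no", NA)),
              assign_counts(rr, c(16, 25, 1), c("yes", "no", NA)))
  hs <- c(assign_counts(nr, c(13, 37), c("yes", "no")),
          assign_counts(rr, c(3, 39), c("yes", "no")))
  loc <- c(assign_counts(nr, c(25, 14, 11), c("TLE", "ETLE", NA)),
           assign_counts(rr, c(13, 11, 18), c("TLE", "ETLE", NA)))
  demographics$lesion <- factor(unname(lesion[demographics$subject_id]),
                                levels = c("yes", "no"))
  demographics$hs <- factor(unname(hs[demographics$subject_id]),
                            levels = c("yes", "no"))
  demographics$location <- factor(unname(loc[demographics$subject_id]),
                                  levels = c("TLE", "ETLE"))
  demographics
}

#' Write canonical CSV fixtures for a named scenario
#'
#' `"tiny"` is a 10-subject, human-checkable cohort (6 controls, 2
#' responders, 2 non-responders); `"paper_like"` is the full default cohort
#' (100/42/50). Regenerating with the same seed produces identical files.
#'
#' @param name `"tiny"` or `"paper_like"`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed (default 1).
#' @return Invisibly, the paths of the written files (volumes, demographics,
#'   truth).
#' @export
make_fixture <- function(name = c("tiny", "paper_like"), dir = tempdir(),
                         seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = sim_config(n_control = 6L, n_responder = 2L, n_nonresponder = 2L,
                      clinical_covariates = FALSE),
    paper_like = sim_config()
  )
  cohort <- simulate_cohort(cfg, seed = seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(name, "_", c("volumes", "demographics",
                                              "truth"), ".csv"))
  # fixtures carry the 4 sub-regions only; whole is reconstructed at read time
  readr::write_csv(dplyr::filter(cohort$volumes, .data$region != "whole"),
                   paths[1])
  readr::write_csv(cohort$demographics, paths[2])
  readr::write_csv(cohort$truth, paths[3])
  invisible(setNames(paths, c("volumes", "demographics", "truth")))
}
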