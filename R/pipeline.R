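# End-to-end orchestration: read -> harmonize -> z-score -> HOI ->
# Mahalanobis -> group statistics -> report bundle.

measure_directions <- function() {
  # a-priori one-tailed directions: abnormality greater in non-responders,
  # volume z smaller in non-responders
  c(mahalanobis = "greater", whole_hoi_z = "less",
    "z_CA-DG" = "less", z_SRLM = "less", z_subiculum = "less", z_tail = "less")
}

#' Run the full hippocampal-abnormality analysis
#'
#' Orchestrates the pipeline on a cohort: optional ComBat harmonization
#' across scanner batches; control-trained age/sex normative models and
#' z-scoring; hippocampus-of-interest selection; Mahalanobis abnormality
#' scoring; and the group-comparison battery (Mahalanobis for all three group
#' pairs; whole-HOI volume z and the four per-region z comparisons for
#' non-responders vs responders, the region family with BH, Bonferroni and
#' harmonic-mean-p corrections; chi-square/ANOVA demographics tests when
#' clinical covariates are present).
#'
#' @param volumes Volume tibble (or path to a CSV/TSV readable by
#'   [read_volume_table()]).
#' @param demographics Demographics tibble (or path readable by
#'   [read_demographics()]).
#' @param harmonize Apply ComBat across `batch` (default `TRUE`; forced off
#'   when only one batch is present, which is an identity adjustment anyway).
#' @param batch Demographics column holding the batch label.
#' @param reference_mode Control reference mode, `"hoi"` or `"pooled"`.
#' @param effect_thresholds Effect-size labelling thresholds (see
#'   [effect_label()]).
#' @param exact_wilcoxon Use exact Wilcoxon p-values where possible.
#' @return An object of class `hm_report`: a list with `zscores`,
#'   `abnormality`, `comparisons` (tibble), `region_family` (corrected
#'   region-level p-values), `demographics_tests`, the fitted models, and a
#'   run `log`.
#' @export
run_pipeline <- function(volumes, demographics,
                         harmonize = TRUE,
                         batch = "scanner",
                         reference_mode = c("hoi", "pooled"),
                         effect_thresholds = c(0.1, 0.3, 0.5),
                         exact_wilcoxon = FALSE) {
  reference_mode <- match.arg(reference_mode)
  if (is.character(volumes)) volumes <- read_volume_table(volumes)
  if (is.character(demographics)) demographics <- read_demographics(demographics)
  check_cohort(volumes, demographics)

  combat <- NULL
  harmonized <- volumes
  if (harmonize) {
    combat <- combat_fit(volumes, demographics, batch = batch)
    harmonized <- combat_apply(combat, volumes, demographics)
  }
  normative <- fit_normative(harmonized, demographics)
  zscores <- zscore(harmonized, demographics, normative)
  abnormality <- score_abnormality(zscores, demographics,
                                   mode = reference_mode)
  reference <- attr(abnormality, "reference")

  scored <- dplyr::inner_join(abnormality, demographics[c("subject_id", "group")],
                              by = "subject_id")
  comparisons <- compare_measures(scored, effect_thresholds, exact_wilcoxon)
  region_family <- region_family_tests(comparisons)
  dem_tests <- demographics_tests(demographics)

  structure(list(
    zscores = zscores,
    abnormality = abnormality,
    comparisons = comparisons,
    region_family = region_family,
    demographics_tests = dem_tests,
    models = list(combat = combat, normative = normative,
                  reference = reference),
    log = run_log(harmonize, batch, reference_mode, effect_thresholds)
  ), class = "hm_report")
}

compare_measures <- function(scored, thresholds, exact) {
  dirs <- measure_directions()
  pairs <- list(c("non_responder", "responder"),
                c("non_responder", "control"),
                c("responder", "control"))
  specs <- c(
    purrr::map(pairs, \(p) list(measure = "mahalanobis", pair = p)),
    purrr::map(setdiff(names(dirs), "mahalanobis"),
               \(m) list(measure = m, pair = c("non_responder", "responder")))
  )
  purrr::map(specs, function(s) {
    a <- scored[[s$measure]][scored$group == s$pair[1]]
    b <- scored[[s$measure]][scored$group == s$pair[2]]
    dir <- if (dirs[[s$measure]] == "greater") "x_greater" else "x_less"
    cmp <- wilcoxon_one_tailed(a, b, direction = dir, exact = exact,
                               labels = s$pair, thresholds = thresholds)
    dplyr::bind_cols(tibble::tibble(measure = s$measure), cmp)
  }) |> purrr::list_rbind()
}

region_family_tests <- function(comparisons) {
  fam <- comparisons[comparisons$measure %in%
                       paste0("z_", c("CA-DG", "SRLM", "subiculum", "tail")), ]
  tibble::tibble(
    measure = fam$measure,
    p = fam$p,
    p_bh = adjust_p(fam$p, "bh"),
    p_bonferroni = adjust_p(fam$p, "bonferroni"),
    harmonic_p = harmonic_mean_p(fam$p)
  )
}

#' Table-1-style demographics tests across response groups
#'
#' Chi-square tests for categorical covariates (sex and scanner across all
#' three groups; lesion, hippocampal sclerosis and location across
#' responders/non-responders) and one-way ANOVA for age. Covariates absent
#' from the table, or with missing values, are tested on complete cases;
#' absent columns are skipped.
#'
#' @param demographics Validated demographics tibble.
#' @return A tibble: `variable`, `test`, `statistic`, `df`, `p`.
#' @export
demographics_tests <- function(demographics) {
  pat <- demographics[demographics$group != "control", ]
  pat$group <- droplevels(pat$group)
  out <- list()
  xtab_test <- function(d, var, label) {
    d <- d[!is.na(d[[var]]), ]
    if (nrow(d) == 0 || nlevels(droplevels(d$group)) < 2) return(NULL)
    tab <- table(droplevels(d$group), droplevels(d[[var]]))
    if (any(dim(tab) < 2)) return(NULL)
    res <- chi_square(tab)
    tibble::tibble(variable = label, test = "chi_square",
                   statistic = res$chi2, df = res$df, p = res$p)
  }
  out$sex <- xtab_test(demographics, "sex", "sex")
  out$scanner <- xtab_test(demographics, "scanner", "scanner")
  av <- anova_oneway(demographics$age_at_scan, demographics$group)
  out$age <- tibble::tibble(variable = "age_at_scan", test = "anova",
                            statistic = av$F, df = av$df1, p = av$p)
  for (var in intersect(c("lesion", "hs", "location"), names(demographics))) {
    out[[var]] <- xtab_test(pat, var, var)
  }
  purrr::list_rbind(purrr::compact(out))
}

run_log <- function(harmonize, batch, reference_mode, thresholds) {
  cfg <- list(harmonize = harmonize, batch = batch,
              reference_mode = reference_mode,
              effect_thresholds = thresholds)
  list(config = cfg,
       config_hash = rlang::hash(cfg),
       package_version = as.character(utils::packageVersion("hippomahal")),
       r_version = R.version.string,
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Rerun the statistical battery on a filtered cohort
#'
#' Sensitivity analysis: subjects matching `exclude` are removed and all
#' group statistics are recomputed, *without* refitting the harmonization,
#' normative models or control reference (controls are assumed unaffected by
#' the exclusion; z-scores and Mahalanobis scores are reused as computed in
#' the main run).
#'
#' @param report An `hm_report` from [run_pipeline()].
#' @param demographics The demographics tibble used for the main run.
#' @param exclude A predicate taking the demographics tibble and returning a
#'   logical vector marking subjects to drop (e.g.
#'   `\(d) !is.na(d$hs) & d$hs == "yes"`).
#' @return An `hm_report` with recomputed `comparisons`, `region_family` and
#'   `demographics_tests`.
#' @export
sensitivity_exclude <- function(report, demographics, exclude) {
  stopifnot(inherits(report, "hm_report"))
  drop <- exclude(demographics)
  stopifnot(is.logical(drop), length(drop) == nrow(demographics))
  kept <- demographics[!drop, ]
  remaining <- table(factor(kept$group, levels = group_levels()))
  if (any(remaining[c("responder", "non_responder")] < 2)) {
    abort("Exclusion leaves fewer than 2 subjects in a compared group.")
  }
  scored <- dplyr::inner_join(report$abnormality,
                              kept[c("subject_id", "group")],
                              by = "subject_id")
  cfg <- report$log$config
  comparisons <- compare_measures(scored, cfg$effect_thresholds, FALSE)
  out <- report
  out$comparisons <- comparisons
  out$region_family <- region_family_tests(comparisons)
  out$demographics_tests <- demographics_tests(kept)
  out$log$sensitivity <- sprintf("excluded %d subject(s)", sum(drop))
  out
}

#' Write an analysis report bundle to disk
#'
#' Writes the z-score table and abnormality table as CSV and the statistics
#' (comparisons, region family, demographics tests, run log) as JSON.
#'
#' @param report An `hm_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "hm_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("zscores.csv", "abnormality.csv",
                            "statistics.json"))
  readr::write_csv(report$zscores, paths[1])
  readr::write_csv(report$abnormality, paths[2])
  stats <- list(comparisons = report$comparisons,
                region_family = report$region_family,
                demographics_tests = report$demographics_tests,
                log = report$log)
  jsonlite::write_json(stats, paths[3], dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(setNames(paths, c("zscores", "abnormality", "statistics")))
}

#' @export
print.hm_report <- function(x, ...) {
  cat("Hippocampal abnormality report\n")
  cat(sprintf("  %d subjects, %d comparisons\n",
              dplyr::n_distinct(x$zscores$subject_id), nrow(x$comparisons)))
  m <- x$comparisons[x$comparisons$measure == "mahalanobis" &
                       x$comparisons$group_b == "responder", ]
  if (nrow(m) == 1) {
    cat(sprintf(
      "  Mahalanobis non-responder vs responder: p = %.4g, r = %.2f, AUC = %.2f (%s)\n",
      m$p, m$r_rank_biserial, m$auc, m$effect_label))
  }
  invisible(x)
}
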