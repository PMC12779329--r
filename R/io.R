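#' Canonical labels for hippocampal parcels, hemispheres and groups
#'
#' The four hippocampal sub-regions used as multivariate features are the
#' combined cornu ammonis + dentate gyrus (`CA-DG`), the stratum
#' radiatum-lacunosum-moleculare (`SRLM`), the subicular complex
#' (`subiculum`) and the hippocampal `tail`. `whole` denotes the whole
#' hippocampus, used as a fifth univariate measure.
#'
#' @return Character vector of canonical labels.
#' @export
hoi_regions <- function() c("CA-DG", "SRLM", "subiculum", "tail")

#' @rdname hoi_regions
#' @export
all_regions <- function() c(hoi_regions(), "whole")

#' @rdname hoi_regions
#' @export
hemispheres <- function() c("left", "right")

#' @rdname hoi_regions
#' @export
group_levels <- function() c("control", "responder", "non_responder")

#' Default alias maps for region and group labels
#'
#' Region and group names in segmentation output vary across tools; these maps
#' translate common spellings to the canonical labels. Both maps are named
#' character vectors `alias -> canonical`; matching is case-insensitive.
#'
#' @return Named character vector.
#' @export
region_aliases <- function() {
  c(
    "ca-dg" = "CA-DG", "cadg" = "CA-DG", "ca_dg" = "CA-DG", "ca+dg" = "CA-DG",
    "ca" = "CA-DG", "cornu ammonis" = "CA-DG",
    "srlm" = "SRLM",
    "sub" = "subiculum", "subiculum" = "subiculum", "presubiculum" = "subiculum",
    "tail" = "tail", "hippocampal tail" = "tail", "ht" = "tail",
    "whole" = "whole", "whole_hippocampus" = "whole", "total" = "whole"
  )
}

#' @rdname region_aliases
#' @export
group_aliases <- function() {
  c(
    "control" = "control", "hc" = "control", "healthy" = "control",
    "ctrl" = "control", "c" = "control",
    "responder" = "responder", "r" = "responder", "resp" = "responder",
    "non_responder" = "non_responder", "non-responder" = "non_responder",
    "nonresponder" = "non_responder", "nr" = "non_responder",
    "non responder" = "non_responder"
  )
}

canonicalize <- function(x, aliases, what) {
  key <- tolower(trimws(as.character(x)))
  names(aliases) <- tolower(names(aliases))
  out <- unname(aliases[key])
  bad <- unique(x[is.na(out) & !is.na(x)])
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown %s label(s): %s. Extend the alias map to include them.",
      what, paste(sQuote(bad), collapse = ", ")
    ))
  }
  out
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
}

#' Read and validate a regional volume table
#'
#' Reads a CSV/TSV of hippocampal regional volumes into the canonical long
#' format: one row per subject x hemisphere x region, columns `subject_id`,
#' `hemisphere`, `region`, `volume` (mm^3). Wide input (one column per region)
#' is accepted and melted. Region labels are normalized through an alias map.
#'
#' Validation enforces: strictly positive volumes, no duplicate
#' (subject, hemisphere, region) keys, and all four sub-regions present for
#' every (subject, hemisphere) pair. A `whole` hippocampus row per hemisphere
#' is added as the sum of the four sub-regions when not supplied.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter; `NULL` (default) auto-detects from the header.
#' @param col_map Named list mapping canonical column names (`subject_id`,
#'   `hemisphere`, `region`, `volume`) to the names used in the file.
#' @param aliases Named character vector translating region spellings to
#'   canonical labels; see [region_aliases()].
#' @param add_whole Add per-hemisphere whole-hippocampus rows (sum of the four
#'   sub-regions) when absent. Default `TRUE`.
#' @return A validated volume tibble.
#' @export
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' cohort <- simulate_cohort(sim_config(n_control = 5, n_responder = 2,
#'                                      n_nonresponder = 2), seed = 1)
#' readr::write_csv(cohort$volumes, tmp)
#' vol <- read_volume_table(tmp)
read_volume_table <- function(path, delim = NULL, col_map = list(),
                              aliases = region_aliases(), add_whole = TRUE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- delim %||% detect_delim(path)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  names(raw) <- rename_from_map(names(raw), col_map)
  long <- if (all(c("region", "volume") %in% names(raw))) {
    raw
  } else {
    melt_wide_volumes(raw, aliases)
  }
  as_volume_table(long, aliases = aliases, add_whole = add_whole)
}

rename_from_map <- function(nms, col_map) {
  for (canon in names(col_map)) {
    nms[nms == col_map[[canon]]] <- canon
  }
  nms
}

melt_wide_volumes <- function(raw, aliases) {
  id_cols <- intersect(c("subject_id", "hemisphere"), names(raw))
  if (!all(c("subject_id", "hemisphere") %in% id_cols)) {
    abort("Volume table is missing required column(s): subject_id, hemisphere (or region/volume for long format).")
  }
  region_cols <- setdiff(names(raw), id_cols)
  known <- tolower(region_cols) %in% tolower(names(aliases))
  if (!any(known)) {
    abort("Wide volume table has no columns matching known region names.")
  }
  tidyr::pivot_longer(raw[, c(id_cols, region_cols[known])],
                      cols = dplyr::all_of(region_cols[known]),
                      names_to = "region", values_to = "volume")
}

#' Coerce and validate a data frame of regional volumes
#'
#' @param x Data frame with columns `subject_id`, `hemisphere`, `region`,
#'   `volume` (long format).
#' @inheritParams read_volume_table
#' @return A validated tibble sorted by subject, hemisphere and canonical
#'   region order.
#' @export
as_volume_table <- function(x, aliases = region_aliases(), add_whole = TRUE) {
  required <- c("subject_id", "hemisphere", "region", "volume")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("Volume table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  vol <- tibble::as_tibble(x[required])
  vol$subject_id <- as.character(vol$subject_id)
  vol$hemisphere <- canonicalize(vol$hemisphere,
                                 setNames(hemispheres(), hemispheres()),
                                 "hemisphere")
  vol$region <- canonicalize(vol$region, aliases, "region")
  vol$volume <- as.numeric(vol$volume)

  bad_vol <- !is.finite(vol$volume) | vol$volume <= 0
  if (any(bad_vol)) {
    abort(sprintf(
      "Volumes must be finite and strictly positive; offending rows: %s",
      paste(head(which(bad_vol), 5), collapse = ", ")
    ))
  }
  key <- paste(vol$subject_id, vol$hemisphere, vol$region, sep = "|")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    abort(sprintf("Duplicate (subject, hemisphere, region) key(s): %s",
                  paste(head(dups, 5), collapse = "; ")))
  }
  completeness <- vol |>
    dplyr::filter(.data$region %in% hoi_regions()) |>
    dplyr::count(.data$subject_id, .data$hemisphere)
  incomplete <- completeness$n != length(hoi_regions())
  if (any(incomplete)) {
    who <- completeness[incomplete, ]
    abort(sprintf(
      "Each (subject, hemisphere) must have all 4 sub-regions; incomplete: %s",
      paste(head(paste(who$subject_id, who$hemisphere), 5), collapse = "; ")
    ))
  }
  if (add_whole) vol <- add_whole_hippocampus(vol)
  vol |>
    dplyr::mutate(region = factor(.data$region, levels = all_regions())) |>
    dplyr::arrange(.data$subject_id, .data$hemisphere, .data$region) |>
    dplyr::mutate(region = as.character(.data$region))
}

#' Add whole-hippocampus rows as the sum of the four sub-region volumes
#'
#' Subjects/hemispheres that already carry a `whole` row are left untouched.
#'
#' @param volumes A volume tibble in canonical long format.
#' @return The tibble with one `whole` row per (subject, hemisphere).
#' @export
add_whole_hippocampus <- function(volumes) {
  have_whole <- volumes |>
    dplyr::filter(.data$region == "whole") |>
    dplyr::distinct(.data$subject_id, .data$hemisphere)
  sums <- volumes |>
    dplyr::filter(.data$region %in% hoi_regions()) |>
    dplyr::anti_join(have_whole, by = c("subject_id", "hemisphere")) |>
    dplyr::summarise(volume = sum(.data$volume),
                     .by = c("subject_id", "hemisphere")) |>
    dplyr::mutate(region = "whole")
  dplyr::bind_rows(volumes, sums)
}

#' Read and validate a demographics table
#'
#' Expects one row per subject with columns `subject_id`, `group`, `sex`,
#' `age_at_scan` (years) and `scanner` (batch label), plus optional clinical
#' covariates `lesion`, `hs` (hippocampal sclerosis) and `location`
#' (TLE/ETLE). Group labels are normalized through an alias map (e.g. `"HC"`
#' -> `"control"`, `"NR"` -> `"non_responder"`).
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter; `NULL` auto-detects.
#' @param col_map Named list mapping canonical column names to file columns.
#' @param aliases Named character vector translating group spellings; see
#'   [group_aliases()].
#' @return A validated demographics tibble.
#' @export
read_demographics <- function(path, delim = NULL, col_map = list(),
                              aliases = group_aliases()) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- delim %||% detect_delim(path)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  names(raw) <- rename_from_map(names(raw), col_map)
  as_demographics(raw, aliases = aliases)
}

#' Coerce and validate a demographics data frame
#'
#' @param x Data frame with at least `subject_id`, `group`, `sex`,
#'   `age_at_scan`, `scanner`.
#' @inheritParams read_demographics
#' @return A validated tibble with canonical factor codings.
#' @export
as_demographics <- function(x, aliases = group_aliases()) {
  required <- c("subject_id", "group", "sex", "age_at_scan", "scanner")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("Demographics table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  optional <- intersect(c("lesion", "hs", "location"), names(x))
  dem <- tibble::as_tibble(x[c(required, optional)])
  dem$subject_id <- as.character(dem$subject_id)
  if (anyDuplicated(dem$subject_id)) {
    dups <- unique(dem$subject_id[duplicated(dem$subject_id)])
    abort(sprintf("Duplicated subject_id(s): %s",
                  paste(head(dups, 5), collapse = ", ")))
  }
  dem$group <- factor(canonicalize(dem$group, aliases, "group"),
                      levels = group_levels())
  sex_map <- c("f" = "female", "female" = "female",
               "m" = "male", "male" = "male")
  dem$sex <- factor(canonicalize(dem$sex, sex_map, "sex"),
                    levels = c("female", "male"))
  dem$age_at_scan <- as.numeric(dem$age_at_scan)
  if (anyNA(dem$age_at_scan)) {
    abort(sprintf("Missing/non-numeric age_at_scan for subject(s): %s",
                  paste(head(dem$subject_id[is.na(dem$age_at_scan)], 5),
                        collapse = ", ")))
  }
  dem$scanner <- factor(as.character(dem$scanner))
  yn <- c("yes" = "yes", "y" = "yes", "1" = "yes",
          "no" = "no", "n" = "no", "0" = "no")
  for (cc in intersect(c("lesion", "hs"), optional)) {
    keep <- !is.na(dem[[cc]])
    dem[[cc]][keep] <- canonicalize(dem[[cc]][keep], yn, cc)
    dem[[cc]] <- factor(dem[[cc]], levels = c("yes", "no"))
  }
  if ("location" %in% optional) {
    keep <- !is.na(dem$location)
    loc_map <- c("tle" = "TLE", "etle" = "ETLE")
    dem$location[keep] <- canonicalize(dem$location[keep], loc_map, "location")
    dem$location <- factor(dem$location, levels = c("TLE", "ETLE"))
  }
  dem
}

#' Check that a volume table and demographics table describe the same cohort
#'
#' @param volumes Validated volume tibble.
#' @param demographics Validated demographics tibble.
#' @return Invisibly `TRUE`; errors with the offending subject ids otherwise.
#' @export
check_cohort <- function(volumes, demographics) {
  vs <- unique(volumes$subject_id)
  ds <- demographics$subject_id
  only_vol <- setdiff(vs, ds)
  only_dem <- setdiff(ds, vs)
  if (length(only_vol) > 0 || length(only_dem) > 0) {
    abort(paste0(
      "Volume and demographics tables do not describe the same subjects.",
      if (length(only_vol) > 0)
        sprintf(" Missing from demographics: %s.",
                paste(head(only_vol, 10), collapse = ", ")),
      if (length(only_dem) > 0)
        sprintf(" Missing from volumes: %s.",
                paste(head(only_dem, 10), collapse = ", "))
    ))
  }
  invisible(TRUE)
}
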