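# Metadata-quality profiling over ImagingStudy bundles: corpus counts,
# modality / body-region distributions, field completion rates, and the
# laterality-by-paired-region table. The unit of analysis is the series.

.raw_ext <- function(series, url) {
  for (e in series$extension %||% list()) {
    if (identical(e$url, url)) return(e$valueString)
  }
  NA_character_
}

# Flatten bundles to one row per series with the raw pre-mapping values.
series_frame <- function(bundles) {
  rows <- lapply(bundles, function(b) {
    res <- bundle_resource(b)
    do.call(rbind, lapply(res$series, function(s) {
      data.frame(
        study_uid = study_uid_of(res),
        modality = s$modality$code,
        body_region = .raw_ext(s, EXT_BODY_PART_RAW),
        laterality = .raw_ext(s, EXT_LATERALITY_RAW),
        n_instances = as.integer(s$numberOfInstances),
        stringsAsFactors = FALSE
      )
    }))
  })
  do.call(rbind, rows)
}

.valid_laterality <- c("L", "R", "B", "U")

#' Compute the metadata-quality report over a set of ImagingStudy bundles
#'
#' All percentages are series-level and kept as exact fractions; the print
#' method and [export_report()] additionally show them rounded half-up to
#' integers. "Present laterality" means a raw value in `{L, R, B, U}` ("U"
#' is valid but uncodeable); "present body region" means any non-empty raw
#' value; the body-region distribution (including its `MISSING` entry) uses
#' all series as denominator.
#'
#' @param bundles list of `fhir_bundle` objects, or a path to an NDJSON
#'   file of them.
#' @param non_acquisition modality codes classed as non-acquisition.
#' @return object of class `metrics_report` with fields `n_studies`,
#'   `n_series`, `n_instances`, `series_by_modality`,
#'   `acquisition_fraction`, `non_acquisition_fraction`,
#'   `series_by_body_region` (data.frame `region,count,pct`),
#'   `completion_rate_modality`, `completion_rate_body_region`,
#'   `completion_rate_laterality`, `laterality_missing_pct`,
#'   `body_region_missing_pct`, `body_region_missing_acquisition_only`,
#'   `mean_series_per_study`, `mean_instances_per_study`, `rejects`.
#'   Percentages are exact (unrounded) values in [0, 100].
#' @export
analyze <- function(bundles, non_acquisition = DEFAULT_NON_ACQUISITION) {
  if (is.character(bundles)) bundles <- read_ndjson(bundles)
  if (length(bundles) == 0) stop("no bundles to analyze")
  rejects <- 0L
  keep <- list()
  for (b in bundles) {
    bad <- tryCatch(validate_resource(bundle_resource(b)), error = function(e) "unreadable")
    if (length(bad)) {
      warning("skipping malformed bundle: ", bad[1])
      rejects <- rejects + 1L
    } else {
      keep[[length(keep) + 1L]] <- b
    }
  }
  if (length(keep) == 0) stop("no valid bundles to analyze")
  sf <- series_frame(keep)
  n_series <- nrow(sf)
  n_studies <- length(unique(sf$study_uid))
  n_instances <- sum(sf$n_instances)

  by_mod <- sort(table(sf$modality), decreasing = TRUE)
  acq <- vapply(sf$modality, classify_modality, character(1),
    non_acquisition = non_acquisition, warn_unknown = FALSE)
  acq_pct <- 100 * mean(acq == "acquisition")

  region <- ifelse(is.na(sf$body_region), "MISSING", sf$body_region)
  reg_tab <- table(region)
  # MISSING last, then by count desc, then name
  reg_names <- names(reg_tab)
  ord <- order(reg_names == "MISSING", -as.integer(reg_tab), reg_names)
  reg_df <- data.frame(
    region = reg_names[ord],
    count = as.integer(reg_tab)[ord],
    pct = 100 * as.integer(reg_tab)[ord] / n_series,
    stringsAsFactors = FALSE
  )

  lat_valid <- !is.na(sf$laterality) & sf$laterality %in% .valid_laterality
  acq_rows <- acq == "acquisition"

  structure(list(
    n_studies = n_studies,
    n_series = n_series,
    n_instances = n_instances,
    series_by_modality = by_mod,
    acquisition_fraction = acq_pct,
    non_acquisition_fraction = 100 - acq_pct,
    series_by_body_region = reg_df,
    completion_rate_modality = 100 * mean(!is.na(sf$modality) & nzchar(sf$modality)),
    completion_rate_body_region = 100 * mean(!is.na(sf$body_region)),
    completion_rate_laterality = 100 * mean(lat_valid),
    laterality_missing_pct = 100 * mean(!lat_valid),
    body_region_missing_pct = 100 * mean(is.na(sf$body_region)),
    body_region_missing_acquisition_only =
      100 * mean(is.na(sf$body_region[acq_rows])),
    mean_series_per_study = n_series / n_studies,
    mean_instances_per_study = n_instances / n_studies,
    rejects = rejects
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) paste0(round_half_up(v), "%")
  cat("<metadata quality report>\n")
  cat(sprintf("  %d studies, %d series, %d instances\n",
    x$n_studies, x$n_series, x$n_instances))
  cat(sprintf("  mean %.1f series and %.1f instances per study\n",
    x$mean_series_per_study, x$mean_instances_per_study))
  cat("  series by modality:", paste(names(x$series_by_modality),
    as.integer(x$series_by_modality), collapse = ", "), "\n")
  cat("  acquisition:", pct(x$acquisition_fraction),
    " non-acquisition:", pct(x$non_acquisition_fraction), "\n")
  cat("  completion — modality:", pct(x$completion_rate_modality),
    " body region:", pct(x$completion_rate_body_region),
    " laterality:", pct(x$completion_rate_laterality), "\n")
  cat("  body region missing:", pct(x$body_region_missing_pct),
    "(acquisition series only:", paste0(pct(x$body_region_missing_acquisition_only), ")"), "\n")
  cat("  laterality missing:", pct(x$laterality_missing_pct), "\n")
  top <- utils::head(x$series_by_body_region[x$series_by_body_region$region != "MISSING", ], 4)
  cat("  top regions:", paste(sprintf("%s %s", top$region, pct(top$pct)), collapse = ", "), "\n")
  if (x$rejects > 0) cat("  rejected bundles:", x$rejects, "\n")
  invisible(x)
}

#' Laterality distribution over paired body regions
#'
#' For each requested region present in the data, tallies the raw laterality
#' values of that region's series and reports the percentage missing, "L"
#' and "R" (denominator: all series of the region). "B" and "U" are tallied
#' in the underlying counts but not displayed as columns, matching the
#' usual reporting convention for paired regions.
#'
#' @param bundles list of `fhir_bundle` or NDJSON path.
#' @param regions raw region values to report on.
#' @return object of class `laterality_table`: data.frame with `region`,
#'   `n_series`, counts `n_missing,n_L,n_R,n_B,n_U` and exact percentages
#'   `pct_missing,pct_L,pct_R`. Requested regions absent from the data are
#'   omitted with a warning.
#' @export
laterality_by_region <- function(bundles,
                                 regions = c("KNEE", "HAND", "FOOT", "ANKLE", "SHOULDER")) {
  stopifnot(length(regions) >= 1)
  if (is.character(bundles)) bundles <- read_ndjson(bundles)
  sf <- series_frame(bundles)
  rows <- list()
  for (r in regions) {
    sel <- sf[!is.na(sf$body_region) & sf$body_region == toupper(r), ]
    if (nrow(sel) == 0) {
      warning("region ", r, " absent from data; row omitted")
      next
    }
    lat <- sel$laterality
    n <- nrow(sel)
    cnt <- function(v) sum(!is.na(lat) & lat == v)
    n_missing <- sum(is.na(lat) | !(lat %in% .valid_laterality))
    rows[[r]] <- data.frame(
      region = toupper(r), n_series = n,
      n_missing = n_missing, n_L = cnt("L"), n_R = cnt("R"),
      n_B = cnt("B"), n_U = cnt("U"),
      pct_missing = 100 * n_missing / n,
      pct_L = 100 * cnt("L") / n,
      pct_R = 100 * cnt("R") / n,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    region = character(), n_series = integer(), n_missing = integer(),
    n_L = integer(), n_R = integer(), n_B = integer(), n_U = integer(),
    pct_missing = numeric(), pct_L = numeric(), pct_R = numeric(),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("laterality_table", "data.frame")
  out
}

#' @export
print.laterality_table <- function(x, ...) {
  cat("<laterality by paired body region> (% of region's series)\n")
  df <- data.frame(
    region = x$region,
    missing = round_half_up(x$pct_missing),
    L = round_half_up(x$pct_L),
    R = round_half_up(x$pct_R)
  )
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Export a metrics report and laterality table as CSV files
#'
#' Writes `summary.csv` (one metric per row: exact value and the half-up
#' rounded display value), `series_by_modality.csv`, `series_by_region.csv`
#' and `laterality_by_region.csv` with deterministic column and row order,
#' so repeated exports of the same report are byte-identical.
#'
#' @param report a `metrics_report`.
#' @param table a `laterality_table` (optional).
#' @param out_dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
export_report <- function(report, table = NULL, out_dir) {
  stopifnot(inherits(report, "metrics_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scalars <- c(
    "n_studies", "n_series", "n_instances", "acquisition_fraction",
    "non_acquisition_fraction", "completion_rate_modality",
    "completion_rate_body_region", "completion_rate_laterality",
    "laterality_missing_pct", "body_region_missing_pct",
    "body_region_missing_acquisition_only", "mean_series_per_study",
    "mean_instances_per_study", "rejects"
  )
  sm <- data.frame(
    metric = scalars,
    value = vapply(scalars, function(k) as.numeric(report[[k]]), numeric(1)),
    display = vapply(scalars, function(k) round_half_up(as.numeric(report[[k]])), numeric(1)),
    stringsAsFactors = FALSE
  )
  files <- file.path(out_dir, c(
    "summary.csv", "series_by_modality.csv", "series_by_region.csv",
    "laterality_by_region.csv"
  ))
  utils::write.csv(sm, files[1], row.names = FALSE)
  utils::write.csv(
    data.frame(modality = names(report$series_by_modality),
      count = as.integer(report$series_by_modality)),
    files[2], row.names = FALSE
  )
  reg <- report$series_by_body_region
  reg$pct_display <- round_half_up(reg$pct)
  utils::write.csv(reg, files[3], row.names = FALSE)
  if (is.null(table)) {
    table <- data.frame(region = character(), n_series = integer(),
      n_missing = integer(), n_L = integer(), n_R = integer(),
      n_B = integer(), n_U = integer(), pct_missing = numeric(),
      pct_L = numeric(), pct_R = numeric())
  }
  tb <- as.data.frame(table)
  for (col in c("pct_missing", "pct_L", "pct_R")) {
    tb[[paste0(col, "_display")]] <- round_half_up(tb[[col]])
  }
  utils::write.csv(tb, files[4], row.names = FALSE)
  invisible(files)
}
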