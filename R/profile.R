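# Corpus profiles: the statistical recipe the synthetic generator realizes.

.frac_sum_ok <- function(x) abs(sum(x) - 1) <= 1e-9

#' Define a synthetic radiology corpus profile
#'
#' A corpus profile fixes everything the generator needs to emulate a
#' multi-department radiology workload: study/series topology, the
#' objects-per-study mixture, the modality mix, the body-region distribution
#' (including a `MISSING` share, part of which is forced onto modalities that
#' never carry a body region), per-region laterality splits, and an
#' incomplete-transfer fault fraction.
#'
#' @param n_studies number of studies (>= 1).
#' @param series_per_study series in every study.
#' @param objects_per_study data.frame with columns `n_objects`, `weight`:
#'   a mixture over studies (weights sum to 1).
#' @param modality_shares named fractions over modality codes, summing to 1.
#' @param body_region_shares named fractions of *all* series per raw
#'   BodyPartExamined value; must contain a `MISSING` entry; sums to 1.
#' @param missing_only_modalities modality codes whose series never carry a
#'   body region (their combined share must fit inside the `MISSING` share).
#' @param laterality_splits named list, region -> numeric length 5
#'   `(missing, L, R, B, U)` summing to 1. Regions not listed default to
#'   all-missing.
#' @param fault_fraction fraction of studies with one withheld object
#'   (the transfer manifest still expects the full count).
#' @param seed integer seed used in stochastic mode.
#' @param mode `"deterministic"` (largest-remainder apportionment; realized
#'   counts are exact) or `"stochastic"` (per-series sampling, reproducible
#'   per seed).
#' @param name optional profile label.
#' @return an object of class `corpus_profile`.
#' @seealso [builtin_profile()], [generate_corpus()]
#' @export
corpus_profile <- function(n_studies,
                           series_per_study = 1L,
                           objects_per_study = data.frame(n_objects = 1L, weight = 1),
                           modality_shares = c(CT = 1),
                           body_region_shares = c(MISSING = 1),
                           missing_only_modalities = character(),
                           laterality_splits = list(),
                           fault_fraction = 0,
                           seed = 1L,
                           mode = c("deterministic", "stochastic"),
                           name = "custom") {
  mode <- match.arg(mode)
  stopifnot(
    is_count(n_studies), n_studies >= 1,
    is_count(series_per_study), series_per_study >= 1,
    is.data.frame(objects_per_study),
    all(c("n_objects", "weight") %in% names(objects_per_study)),
    all(objects_per_study$n_objects >= 1),
    is.numeric(fault_fraction), fault_fraction >= 0, fault_fraction <= 1,
    is.numeric(seed), length(seed) == 1
  )
  if (!.frac_sum_ok(objects_per_study$weight)) stop("objects_per_study weights must sum to 1")
  if (!.frac_sum_ok(modality_shares)) stop("modality_shares must sum to 1")
  if (!.frac_sum_ok(body_region_shares)) stop("body_region_shares must sum to 1")
  if (!"MISSING" %in% names(body_region_shares)) {
    stop("body_region_shares must contain a MISSING entry (may be 0)")
  }
  if (is.null(names(modality_shares)) || anyDuplicated(names(modality_shares))) {
    stop("modality_shares must have unique names")
  }
  bad <- setdiff(missing_only_modalities, names(modality_shares))
  if (length(bad)) stop("missing_only_modalities not in modality_shares: ", paste(bad, collapse = ", "))
  mo_share <- sum(modality_shares[missing_only_modalities])
  if (mo_share > body_region_shares[["MISSING"]] + 1e-9) {
    stop("missing-only modality share exceeds the MISSING body-region share")
  }
  for (r in names(laterality_splits)) {
    s <- laterality_splits[[r]]
    if (length(s) != 5 || !.frac_sum_ok(s)) {
      stop("laterality split for ", r, " must be 5 fractions (missing,L,R,B,U) summing to 1")
    }
  }
  structure(list(
    name = name,
    n_studies = as.integer(n_studies),
    series_per_study = as.integer(series_per_study),
    objects_per_study = objects_per_study,
    modality_shares = modality_shares,
    body_region_shares = body_region_shares,
    missing_only_modalities = missing_only_modalities,
    laterality_splits = laterality_splits,
    fault_fraction = fault_fraction,
    seed = as.integer(seed),
    mode = mode
  ), class = "corpus_profile")
}

#' Built-in corpus profiles
#'
#' `"uhe2022"` pins the composition of a one-year, two-department university
#' hospital radiology workload at desk scale: 200 studies of 10 series each
#' (2,000 series), an objects-per-study mixture of 100 studies x 80 objects
#' and 100 studies x 150 objects (mean 115), modality mix CT 40% / MR 33% /
#' DX 12% / XA 8% / SR 5% / PR 2% (93% acquisition series), a body-region
#' distribution with 32% of series missing a value (all SR/PR/XA series plus
#' 17 points of CT/MR/DX series), and laterality splits over the paired
#' regions knee/hand/foot/ankle/shoulder chosen so e.g. 46% of knee series
#' lack laterality. `"uhe2022-faults"` is a 100-study single-series variant
#' with `fault_fraction` 0.04 for exercising transfer-completeness checks.
#'
#' @param name profile name: `"uhe2022"` or `"uhe2022-faults"`.
#' @param mode,seed passed through to [corpus_profile()].
#' @return a `corpus_profile`.
#' @export
#' @examples
#' builtin_profile("uhe2022")
builtin_profile <- function(name = c("uhe2022", "uhe2022-faults"),
                            mode = "deterministic", seed = 1L) {
  name <- match.arg(name)
  modality <- c(CT = 0.40, MR = 0.33, DX = 0.12, XA = 0.08, SR = 0.05, PR = 0.02)
  regions <- c(
    HEAD = 0.19, CHEST = 0.14, BRAIN = 0.09, HEART = 0.08, KNEE = 0.05,
    HAND = 0.03, FOOT = 0.02, ANKLE = 0.02, SHOULDER = 0.03, ABDOMEN = 0.03,
    MISSING = 0.32
  )
  lat <- list(
    KNEE = c(0.46, 0.29, 0.25, 0, 0),
    HAND = c(0.88, 0.03, 0.09, 0, 0),
    FOOT = c(0.78, 0.09, 0.13, 0, 0),
    ANKLE = c(0.70, 0.15, 0.15, 0, 0),
    SHOULDER = c(0.60, 0.20, 0.20, 0, 0)
  )
  if (name == "uhe2022") {
    corpus_profile(
      n_studies = 200L, series_per_study = 10L,
      objects_per_study = data.frame(n_objects = c(80L, 150L), weight = c(0.5, 0.5)),
      modality_shares = modality,
      body_region_shares = regions,
      missing_only_modalities = c("SR", "PR", "XA"),
      laterality_splits = lat,
      fault_fraction = 0, seed = seed, mode = mode, name = name
    )
  } else {
    corpus_profile(
      n_studies = 100L, series_per_study = 1L,
      objects_per_study = data.frame(n_objects = 10L, weight = 1),
      modality_shares = modality,
      body_region_shares = regions,
      missing_only_modalities = c("SR", "PR", "XA"),
      laterality_splits = lat,
      fault_fraction = 0.04, seed = seed, mode = mode, name = name
    )
  }
}

#' @export
print.corpus_profile <- function(x, ...) {
  cat("<corpus profile>", x$name, sprintf("[%s]", x$mode), "\n")
  cat(sprintf(
    "  %d studies x %d series; objects/study mixture: %s\n",
    x$n_studies, x$series_per_study,
    paste(sprintf("%dx%.2f", x$objects_per_study$n_objects, x$objects_per_study$weight),
      collapse = " + ")
  ))
  cat("  modalities:", paste(sprintf("%s %.2f", names(x$modality_shares), x$modality_shares),
    collapse = ", "), "\n")
  cat("  body regions:", paste(sprintf("%s %.2f", names(x$body_region_shares),
    x$body_region_shares), collapse = ", "), "\n")
  if (x$fault_fraction > 0) cat("  fault fraction:", x$fault_fraction, "\n")
  invisible(x)
}
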