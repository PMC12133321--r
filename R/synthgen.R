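# Synthetic DICOM corpus generator.
#
# plan_corpus() turns a profile into per-study / per-series assignment tables
# (the ground truth used by oracle tests); generate_corpus() materializes the
# plan as Part-10 files plus a transfer manifest.

UID_ROOT <- "1.2.826.0.1.3680043.10.1569."

# standard storage SOP classes per modality; SR/PR/KO get document classes
# and no pixel payload
.sop_class_for <- c(
  CT = "1.2.840.10008.5.1.4.1.1.2",
  MR = "1.2.840.10008.5.1.4.1.1.4",
  CR = "1.2.840.10008.5.1.4.1.1.1",
  DX = "1.2.840.10008.5.1.4.1.1.1.1",
  XA = "1.2.840.10008.5.1.4.1.1.12.1",
  US = "1.2.840.10008.5.1.4.1.1.6.1",
  NM = "1.2.840.10008.5.1.4.1.1.20",
  PT = "1.2.840.10008.5.1.4.1.1.128",
  SR = "1.2.840.10008.5.1.4.1.1.88.11",
  PR = "1.2.840.10008.5.1.4.1.1.11.1",
  KO = "1.2.840.10008.5.1.4.1.1.88.59"
)
.document_modalities <- c("SR", "PR", "KO")

.lat_codes <- c(NA_character_, "L", "R", "B", "U")

#' Plan a synthetic corpus
#'
#' Computes the full per-study and per-series attribute assignment implied by
#' a [corpus_profile()] without touching the disk. In deterministic mode,
#' category counts are apportioned at corpus level by largest remainder
#' ([apportion_largest_remainder()]) and assigned to series in study-major
#' index order, so realized counts are exact; in stochastic mode each series
#' samples its categories independently (reproducibly for a given seed).
#' The returned tables are the generator's ground truth and double as the
#' brute-force oracle for the analysis stage.
#'
#' @param profile a `corpus_profile`.
#' @return list with `studies` (data.frame: `study_idx`, `accession`,
#'   `patient_id`, `study_uid`, `study_date`, `n_objects`, `faulted`) and
#'   `series` (data.frame: `series_idx`, `study_idx`, `series_in_study`,
#'   `series_uid`, `modality`, `body_region` (NA = missing), `laterality`
#'   (NA = missing), `n_objects`).
#' @export
plan_corpus <- function(profile) {
  stopifnot(inherits(profile, "corpus_profile"))
  p <- profile
  stochastic <- p$mode == "stochastic"
  if (stochastic) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(p$seed)
  }
  n_studies <- p$n_studies
  spp <- p$series_per_study
  n_series <- n_studies * spp

  # objects per study: mixture over studies
  comp <- p$objects_per_study
  study_objects <- if (stochastic) {
    comp$n_objects[sample.int(nrow(comp), n_studies, replace = TRUE, prob = comp$weight)]
  } else {
    rep(comp$n_objects, apportion_largest_remainder(comp$weight, n_studies))
  }

  # faults: fixed count, evenly spaced (deterministic) or sampled
  n_fault <- as.integer(round_half_up(p$fault_fraction * n_studies))
  faulted <- rep(FALSE, n_studies)
  if (n_fault > 0) {
    idx <- if (stochastic) sample.int(n_studies, n_fault)
      else unique(as.integer(floor(seq(1, n_studies, length.out = n_fault))))
    faulted[idx] <- TRUE
  }

  studies <- data.frame(
    study_idx = seq_len(n_studies),
    accession = sprintf("UHE%07d", seq_len(n_studies)),
    patient_id = sprintf("PAT%06d", seq_len(n_studies)),
    study_uid = paste0(UID_ROOT, "2.", seq_len(n_studies)),
    study_date = format(as.Date("2022-01-03") + ((seq_len(n_studies) - 1L) %% 360L), "%Y%m%d"),
    n_objects = study_objects,
    faulted = faulted,
    stringsAsFactors = FALSE
  )

  # modality per series (study-major series index order)
  modality <- if (stochastic) {
    sample(names(p$modality_shares), n_series, replace = TRUE, prob = p$modality_shares)
  } else {
    rep(names(p$modality_shares), apportion_largest_remainder(p$modality_shares, n_series))
  }

  # body region: missing-only modalities never carry one; the remaining
  # series receive the named regions plus the leftover MISSING mass
  region <- rep(NA_character_, n_series)
  eligible <- !(modality %in% p$missing_only_modalities)
  named <- p$body_region_shares[setdiff(names(p$body_region_shares), "MISSING")]
  if (stochastic) {
    elig_frac <- 1 - sum(p$modality_shares[p$missing_only_modalities])
    probs <- c(named, MISSING = max(0, elig_frac - sum(named))) / elig_frac
    draw <- sample(names(probs), sum(eligible), replace = TRUE, prob = probs)
    draw[draw == "MISSING"] <- NA_character_
    region[eligible] <- draw
  } else {
    counts <- apportion_largest_remainder(p$body_region_shares, n_series)
    counts_named <- counts[setdiff(names(counts), "MISSING")]
    if (sum(counts_named) > sum(eligible)) {
      stop("profile infeasible: named body-region counts exceed region-eligible series")
    }
    region[which(eligible)[seq_len(sum(counts_named))]] <-
      rep(names(counts_named), counts_named)
  }

  # laterality per region
  laterality <- rep(NA_character_, n_series)
  for (r in names(p$laterality_splits)) {
    sel <- which(!is.na(region) & region == r)
    if (!length(sel)) next
    split <- p$laterality_splits[[r]]
    laterality[sel] <- if (stochastic) {
      sample(.lat_codes, length(sel), replace = TRUE, prob = split)
    } else {
      rep(.lat_codes, apportion_largest_remainder(split, length(sel)))
    }
  }

  study_idx <- rep(seq_len(n_studies), each = spp)
  # spread each study's objects evenly over its series (largest remainder)
  n_obj_series <- unlist(lapply(study_objects, function(n) {
    apportion_largest_remainder(rep(1 / spp, spp), n)
  }), use.names = FALSE)

  series <- data.frame(
    series_idx = seq_len(n_series),
    study_idx = study_idx,
    series_in_study = rep(seq_len(spp), n_studies),
    series_uid = paste0(UID_ROOT, "3.", seq_len(n_series)),
    modality = modality,
    body_region = region,
    laterality = laterality,
    n_objects = n_obj_series,
    stringsAsFactors = FALSE
  )
  list(studies = studies, series = series)
}

#' Generate a synthetic DICOM corpus on disk
#'
#' Materializes [plan_corpus()] as one Part-10 file per object, organized
#' one folder per study (named by accession number), and writes the transfer
#' manifest `manifest.csv` (`accession,expected_count`) into `out_dir`.
#' For faulted studies exactly one object — the last instance of the last
#' series — is withheld from disk while the manifest keeps the full expected
#' count, emulating an incomplete PACS transfer.
#'
#' @param profile a `corpus_profile`.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with `manifest` (data.frame `accession`,
#'   `expected_count`), `plan` (see [plan_corpus()]), `dir`, and `n_files`
#'   written.
#' @export
#' @examples
#' prof <- corpus_profile(n_studies = 2, series_per_study = 2,
#'   objects_per_study = data.frame(n_objects = 2, weight = 1))
#' gen <- generate_corpus(prof, tempfile())
#' gen$manifest
generate_corpus <- function(profile, out_dir) {
  plan <- plan_corpus(profile)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)

  studies <- plan$studies
  series <- plan$series
  instance_counter <- 0L
  n_files <- 0L

  for (si in seq_len(nrow(studies))) {
    st <- studies[si, ]
    sdir <- file.path(out_dir, st$accession)
    dir.create(sdir, showWarnings = FALSE)
    sser <- series[series$study_idx == st$study_idx, ]
    last_series <- nrow(sser)
    for (k in seq_len(last_series)) {
      se <- sser[k, ]
      sop_class <- .sop_class_for[[se$modality]] %||% .sop_class_for[["CT"]]
      with_pixels <- !(se$modality %in% .document_modalities)
      for (inst in seq_len(se$n_objects)) {
        instance_counter <- instance_counter + 1L
        withheld <- st$faulted && k == last_series && inst == se$n_objects
        if (withheld) next
        sop_uid <- paste0(UID_ROOT, "4.", instance_counter)
        write_dicom_instance(
          file.path(sdir, paste0(sop_uid, ".dcm")),
          list(
            sop_class_uid = sop_class,
            sop_instance_uid = sop_uid,
            study_instance_uid = st$study_uid,
            series_instance_uid = se$series_uid,
            modality = se$modality,
            body_part_examined = se$body_region,
            laterality = se$laterality,
            patient_id = st$patient_id,
            accession_number = st$accession,
            study_date = st$study_date,
            study_time = "080000",
            series_number = se$series_in_study,
            instance_number = inst,
            series_description = paste(se$modality,
              if (!is.na(se$body_region)) se$body_region else "SERIES", se$series_in_study)
          ),
          with_pixels = with_pixels
        )
        n_files <- n_files + 1L
      }
    }
  }

  manifest <- data.frame(
    accession = studies$accession,
    expected_count = studies$n_objects,
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(list(manifest = manifest, plan = plan, dir = out_dir, n_files = n_files))
}

#' Read a transfer manifest CSV
#'
#' @param path CSV with columns `accession,expected_count`.
#' @return data.frame with unique accessions and counts >= 1.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("accession", "expected_count") %in% names(m))) {
    stop("manifest must have columns accession,expected_count")
  }
  if (anyDuplicated(m$accession)) stop("manifest accession numbers must be unique")
  if (any(m$expected_count < 1)) stop("manifest expected counts must be >= 1")
  m[c("accession", "expected_count")]
}
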