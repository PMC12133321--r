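# DICOM Part-10 header reader: extracts conversion-relevant metadata and
# stops before the PixelData element, so full-size clinical objects parse
# in header time regardless of payload size.

.tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

# Tags retained by read_instance, keyed "GGGG,EEEE".
.wanted_tags <- c(
  "0008,0016" = "sop_class_uid",
  "0008,0018" = "sop_instance_uid",
  "0008,0020" = "study_date",
  "0008,0030" = "study_time",
  "0008,0050" = "accession_number",
  "0008,0060" = "modality",
  "0008,103E" = "series_description",
  "0010,0020" = "patient_id",
  "0018,0015" = "body_part_examined",
  "0020,000D" = "study_instance_uid",
  "0020,000E" = "series_instance_uid",
  "0020,0011" = "series_number",
  "0020,0013" = "instance_number",
  "0020,0060" = "laterality",
  "0020,0062" = "image_laterality"
)

.read_u16 <- function(x, i) as.integer(x[i]) + 256L * as.integer(x[i + 1L])
.read_u32 <- function(x, i) {
  as.integer(x[i]) + 256 * as.integer(x[i + 1L]) +
    65536 * as.integer(x[i + 2L]) + 16777216 * as.integer(x[i + 3L])
}

dicom_error <- function(path, msg) {
  stop(structure(
    class = c("dicom_parse_error", "error", "condition"),
    list(message = sprintf("%s: %s", path, msg), call = NULL)
  ))
}

# Walk one dataset encoded with the given transfer syntax, collecting wanted
# string values; stops at PixelData (7FE0,0010) or end of buffer.
.parse_dataset <- function(x, pos, explicit, path) {
  n <- length(x)
  out <- list()
  while (pos + 7L <= n) {
    group <- .read_u16(x, pos)
    element <- .read_u16(x, pos + 2L)
    pos <- pos + 4L
    if (group == 0x7FE0L && element == 0x0010L) break
    if (explicit) {
      vr <- rawToChar(x[pos:(pos + 1L)])
      if (vr %in% .short_vrs) {
        len <- .read_u16(x, pos + 2L)
        pos <- pos + 4L
      } else {
        len <- .read_u32(x, pos + 4L)
        pos <- pos + 8L
      }
    } else {
      len <- .read_u32(x, pos)
      pos <- pos + 4L
    }
    if (len >= 4294967295 || pos + len - 1L > n) {
      dicom_error(path, sprintf("element (%s) overruns file", .tag_key(group, element)))
    }
    key <- .tag_key(group, element)
    if (!is.na(.wanted_tags[key])) {
      val <- if (len > 0L) {
        b <- x[pos:(pos + len - 1L)]
        rawToChar(b[b != as.raw(0L)])   # strip UI nul padding
      } else ""
      out[[.wanted_tags[[key]]]] <- val
    }
    pos <- pos + len
  }
  out
}

#' Read the header of one DICOM Part-10 file
#'
#' Parses the file-meta group and dataset of a Part-10 object (Explicit or
#' Implicit VR Little Endian), stopping before PixelData, and returns the
#' metadata fields relevant to FHIR conversion and quality profiling.
#' String values are whitespace-trimmed; empty values become `NA`.
#' `body_part_examined` and `laterality` are upper-cased; laterality is taken
#' from tag (0020,0060) with Image Laterality (0020,0062) as fallback, the
#' only tag in which the bilateral/unpaired codes B and U are legal.
#'
#' @param path path to a DICOM Part-10 file.
#' @return an object of class `dicom_instance_meta`: a named list with
#'   `sop_instance_uid`, `sop_class_uid`, `study_instance_uid`,
#'   `series_instance_uid`, `modality`, `body_part_examined`, `laterality`,
#'   `patient_id`, `accession_number`, `study_date`, `study_time`,
#'   `series_number`, `instance_number`, `series_description` (optional
#'   fields are `NA` when absent).
#' @export
#' @examples
#' dir <- tempfile(); prof <- corpus_profile(n_studies = 1, series_per_study = 1,
#'   objects_per_study = data.frame(n_objects = 1, weight = 1))
#' gen <- generate_corpus(prof, dir)
#' read_instance(list.files(dir, recursive = TRUE, full.names = TRUE)[1])
read_instance <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- readBin(path, "raw", file.size(path))
  if (length(x) < 140L || rawToChar(x[129:132]) != "DICM") {
    dicom_error(path, "not a DICOM Part-10 file (missing preamble/DICM magic)")
  }
  # file-meta group: always explicit LE; group length tells us where it ends
  pos <- 133L
  if (.read_u16(x, pos) != 2L || .read_u16(x, pos + 2L) != 0L) {
    dicom_error(path, "file-meta group length element missing")
  }
  meta_len <- .read_u32(x, pos + 8L)   # UL, short form: value at +8
  meta_start <- pos + 12L
  meta <- .parse_meta_ts(x, meta_start, meta_start + meta_len, path)
  explicit <- if (meta == TS_EXPLICIT_LE) TRUE
    else if (meta == TS_IMPLICIT_LE) FALSE
    else dicom_error(path, paste0("unsupported transfer syntax ", meta))
  raw_fields <- .parse_dataset(x, meta_start + meta_len, explicit, path)

  get <- function(k) str_or_na(raw_fields[[k]] %||% NA_character_)
  lat <- get("laterality")
  if (is.na(lat)) lat <- get("image_laterality")
  m <- list(
    sop_instance_uid = get("sop_instance_uid"),
    sop_class_uid = get("sop_class_uid"),
    study_instance_uid = get("study_instance_uid"),
    series_instance_uid = get("series_instance_uid"),
    modality = get("modality"),
    body_part_examined = toupper(get("body_part_examined")),
    laterality = toupper(lat),
    patient_id = get("patient_id"),
    accession_number = get("accession_number"),
    study_date = get("study_date"),
    study_time = get("study_time"),
    series_number = suppressWarnings(as.integer(get("series_number"))),
    instance_number = suppressWarnings(as.integer(get("instance_number"))),
    series_description = get("series_description")
  )
  for (k in c("study_instance_uid", "series_instance_uid", "sop_instance_uid")) {
    if (is.na(m[[k]])) dicom_error(path, paste0("unprocessable object: missing ", k))
  }
  if (is.na(m$modality)) dicom_error(path, "unprocessable object: missing Modality")
  structure(m, class = "dicom_instance_meta", path = path)
}

# scan the file-meta group for the transfer syntax UID (0002,0010)
.parse_meta_ts <- function(x, pos, end, path) {
  while (pos + 7L <= end) {
    group <- .read_u16(x, pos)
    element <- .read_u16(x, pos + 2L)
    vr <- rawToChar(x[(pos + 4L):(pos + 5L)])
    if (vr %in% .short_vrs) {
      len <- .read_u16(x, pos + 6L)
      vstart <- pos + 8L
    } else {
      len <- .read_u32(x, pos + 8L)
      vstart <- pos + 12L
    }
    if (group == 2L && element == 16L) {
      b <- x[vstart:(vstart + len - 1L)]
      return(trimws(rawToChar(b[b != as.raw(0L)])))
    }
    pos <- vstart + len
  }
  dicom_error(path, "transfer syntax UID missing from file-meta group")
}

#' @export
print.dicom_instance_meta <- function(x, ...) {
  cat("<DICOM instance>", x$modality,
    if (!is.na(x$body_part_examined)) x$body_part_examined else "(no body part)",
    "\n  SOP instance:", x$sop_instance_uid,
    "\n  study/series:", x$study_instance_uid, "/", x$series_instance_uid, "\n")
  invisible(x)
}

#' Group instance metadata into the study/series hierarchy
#'
#' Groups a flat list of [read_instance()] results into one `study_set` per
#' StudyInstanceUID, with series ordered by SeriesNumber (absent last, then by
#' UID) and instances ordered by InstanceNumber likewise. Series-level
#' attributes (modality, body part, laterality) are taken from the series'
#' first instance; disagreement within a series, and duplicate
#' SOPInstanceUIDs (which are dropped), raise warnings.
#'
#' @param metas list of `dicom_instance_meta` objects.
#' @return list of `study_set` objects, ordered by StudyInstanceUID. Each has
#'   `study_instance_uid`, `accession_number`, `patient_id`, `started`
#'   (POSIXct or NA), and `series`: a list with per-series `modality`,
#'   `body_part_examined`, `laterality`, `series_number`, `instances`.
#' @export
group_instances <- function(metas) {
  if (length(metas) == 0) return(list())
  stopifnot(all(vapply(metas, inherits, logical(1), "dicom_instance_meta")))
  by_study <- split(metas, vapply(metas, `[[`, character(1), "study_instance_uid"))
  lapply(by_study, .build_study_set)
}

.order_key <- function(numbers, uids) {
  # numeric order with NAs last, UID as tie/fallback key
  order(is.na(numbers), numbers, uids)
}

.build_study_set <- function(metas) {
  by_series <- split(metas, vapply(metas, `[[`, character(1), "series_instance_uid"))
  series <- lapply(by_series, function(inst) {
    uids <- vapply(inst, `[[`, character(1), "sop_instance_uid")
    if (anyDuplicated(uids)) {
      dup <- uids[duplicated(uids)]
      warning("duplicate SOPInstanceUID(s) dropped: ", paste(unique(dup), collapse = ", "))
      inst <- inst[!duplicated(uids)]
      uids <- uids[!duplicated(uids)]
    }
    inst <- inst[.order_key(vapply(inst, function(m) m$instance_number %||% NA_integer_, integer(1)), uids)]
    first <- inst[[1]]
    for (f in c("modality", "body_part_examined", "laterality")) {
      vals <- unique(vapply(inst, function(m) m[[f]] %||% NA_character_, character(1)))
      if (length(vals[!is.na(vals)]) > 1) {
        warning(sprintf(
          "series %s: instances disagree on %s (%s); using first",
          first$series_instance_uid, f, paste(vals, collapse = "/")
        ))
      }
    }
    list(
      series_instance_uid = first$series_instance_uid,
      modality = first$modality,
      body_part_examined = first$body_part_examined,
      laterality = first$laterality,
      series_number = first$series_number,
      instances = inst
    )
  })
  series <- series[.order_key(
    vapply(series, function(s) s$series_number %||% NA_integer_, integer(1)),
    vapply(series, `[[`, character(1), "series_instance_uid")
  )]
  first <- series[[1]]$instances[[1]]
  started <- NA
  if (!is.na(first$study_date)) {
    tm <- if (!is.na(first$study_time)) substr(paste0(first$study_time, "000000"), 1, 6) else "000000"
    started <- paste0(
      substr(first$study_date, 1, 4), "-", substr(first$study_date, 5, 6), "-",
      substr(first$study_date, 7, 8), "T", substr(tm, 1, 2), ":", substr(tm, 3, 4),
      ":", substr(tm, 5, 6)
    )
  }
  structure(list(
    study_instance_uid = first$study_instance_uid,
    accession_number = first$accession_number,
    patient_id = first$patient_id,
    started = started,
    series = series
  ), class = "study_set")
}

#' @export
print.study_set <- function(x, ...) {
  n_inst <- sum(vapply(x$series, function(s) length(s$instances), integer(1)))
  cat("<DICOM study>", x$study_instance_uid, "\n  accession:", x$accession_number,
    " patient:", x$patient_id, "\n  series:", length(x$series),
    " instances:", n_inst, "\n")
  invisible(x)
}
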