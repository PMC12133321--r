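# Minimal DICOM Part-10 writer (Explicit VR Little Endian).
#
# Only what the synthetic-corpus generator needs: string/US elements, a
# conformant file-meta group, and a tiny monochrome pixel payload for image
# SOP classes. No sequences, no compressed transfer syntaxes.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
IMPLEMENTATION_CLASS_UID <- "1.2.826.0.1.3680043.10.1569.1"

# VRs encoded with a 2-byte length field; everything else uses the
# reserved+4-byte form (here only OB/OW occur).
.short_vrs <- c(
  "AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS", "LO", "LT",
  "PN", "SH", "SL", "SS", "ST", "TM", "UI", "UL", "US"
)

uint16_le <- function(x) as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L)))
uint32_le <- function(x) {
  as.raw(c(
    bitwAnd(x, 255L),
    bitwAnd(bitwShiftR(x, 8L), 255L),
    bitwAnd(bitwShiftR(x, 16L), 255L),
    bitwAnd(bitwShiftR(x, 24L), 255L)
  ))
}

# Pad a value to even length as the standard requires: UIDs with NUL,
# text with trailing space.
pad_even <- function(bytes, vr) {
  if (length(bytes) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    bytes <- c(bytes, pad)
  }
  bytes
}

dcm_element <- function(group, element, vr, value) {
  bytes <- if (vr == "US") {
    uint16_le(as.integer(value))
  } else if (is.raw(value)) {
    value
  } else {
    pad_even(charToRaw(as.character(value)), vr)
  }
  head <- c(uint16_le(group), uint16_le(element), charToRaw(vr))
  if (vr %in% .short_vrs) {
    c(head, uint16_le(length(bytes)), bytes)
  } else {
    c(head, as.raw(c(0L, 0L)), uint32_le(length(bytes)), bytes)
  }
}

# File-meta group 0002: always Explicit VR LE, preceded by its group length.
dcm_file_meta <- function(sop_class_uid, sop_instance_uid) {
  body <- c(
    dcm_element(2L, 1L, "OB", as.raw(c(0L, 1L))),
    dcm_element(2L, 2L, "UI", sop_class_uid),
    dcm_element(2L, 3L, "UI", sop_instance_uid),
    dcm_element(2L, 16L, "UI", TS_EXPLICIT_LE),
    dcm_element(2L, 18L, "UI", IMPLEMENTATION_CLASS_UID)
  )
  c(dcm_element(2L, 0L, "UL", uint32_le(length(body))), body)
}

#' Write one synthetic DICOM Part-10 object
#'
#' Serializes the minimal header set used throughout the package (identity
#' UIDs, modality, body part, laterality, patient and accession identifiers,
#' study date/time, numbering) as Explicit VR Little Endian, with a 2x2
#' 8-bit dummy pixel payload for image SOP classes. Fields passed as `NA`
#' are omitted from the header entirely.
#'
#' @param path output file path.
#' @param fields named list with elements `sop_class_uid`, `sop_instance_uid`,
#'   `study_instance_uid`, `series_instance_uid`, `modality`, `patient_id`,
#'   `accession_number` and optionally `body_part_examined`, `laterality`
#'   (written to tag (0020,0060) for L/R and to Image Laterality (0020,0062)
#'   for B/U), `study_date`, `study_time`, `series_number`, `instance_number`,
#'   `series_description`.
#' @param with_pixels write the dummy PixelData element (TRUE for image
#'   SOP classes, FALSE for SR/PR documents).
#' @return the path, invisibly.
#' @keywords internal
write_dicom_instance <- function(path, fields, with_pixels = TRUE) {
  f <- fields
  need <- c(
    "sop_class_uid", "sop_instance_uid", "study_instance_uid",
    "series_instance_uid", "modality", "patient_id", "accession_number"
  )
  miss <- need[!vapply(need, function(k) !is.null(f[[k]]) && !is.na(f[[k]]), logical(1))]
  if (length(miss)) stop("write_dicom_instance: missing fields: ", paste(miss, collapse = ", "))

  opt <- function(group, element, vr, key) {
    v <- f[[key]]
    if (is.null(v) || is.na(v)) NULL else dcm_element(group, element, vr, v)
  }
  lat <- f$laterality
  lat_el <- NULL
  if (!is.null(lat) && !is.na(lat)) {
    if (lat %in% c("L", "R")) {
      lat_el <- dcm_element(0x0020L, 0x0060L, "CS", lat)
    } else {
      # B and U are only legal in Image Laterality
      lat_el <- dcm_element(0x0020L, 0x0062L, "CS", lat)
    }
  }

  ds <- c(
    dcm_element(0x0008L, 0x0016L, "UI", f$sop_class_uid),
    dcm_element(0x0008L, 0x0018L, "UI", f$sop_instance_uid),
    opt(0x0008L, 0x0020L, "DA", "study_date"),
    opt(0x0008L, 0x0030L, "TM", "study_time"),
    dcm_element(0x0008L, 0x0050L, "SH", f$accession_number),
    dcm_element(0x0008L, 0x0060L, "CS", f$modality),
    opt(0x0008L, 0x103EL, "LO", "series_description"),
    dcm_element(0x0010L, 0x0020L, "LO", f$patient_id),
    opt(0x0018L, 0x0015L, "CS", "body_part_examined"),
    dcm_element(0x0020L, 0x000DL, "UI", f$study_instance_uid),
    dcm_element(0x0020L, 0x000EL, "UI", f$series_instance_uid),
    opt(0x0020L, 0x0011L, "IS", "series_number"),
    opt(0x0020L, 0x0013L, "IS", "instance_number"),
    lat_el
  )
  if (with_pixels) {
    ds <- c(
      ds,
      dcm_element(0x0028L, 0x0002L, "US", 1L),
      dcm_element(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
      dcm_element(0x0028L, 0x0010L, "US", 2L),
      dcm_element(0x0028L, 0x0011L, "US", 2L),
      dcm_element(0x0028L, 0x0100L, "US", 8L),
      dcm_element(0x0028L, 0x0101L, "US", 8L),
      dcm_element(0x0028L, 0x0102L, "US", 7L),
      dcm_element(0x0028L, 0x0103L, "US", 0L),
      dcm_element(0x7FE0L, 0x0010L, "OB", as.raw(c(0L, 64L, 128L, 255L)))
    )
  }
  out <- c(
    raw(128), charToRaw("DICM"),
    dcm_file_meta(f$sop_class_uid, f$sop_instance_uid),
    ds
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}
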