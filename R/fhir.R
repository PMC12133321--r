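# FHIR R4 ImagingStudy construction, validation and (ND)JSON serialization.
#
# Resources are plain nested lists mirroring the R4 JSON shape, so
# jsonlite::toJSON(auto_unbox = TRUE) emits them directly.

DICOM_UID_SYSTEM <- "urn:dicom:uid"
V2_0203_SYSTEM <- "http://terminology.hl7.org/CodeSystem/v2-0203"
PATIENT_ID_SYSTEM <- "urn:imgstudy:patient-id"
SOP_CLASS_SYSTEM <- "urn:ietf:rfc:3986"

# Series-level extensions carrying the raw DICOM strings. The quality
# analysis is defined over raw pre-mapping values (notably laterality "U",
# which has no concept in the R4 binding), which bodySite/laterality Codings
# alone cannot round-trip.
EXT_BODY_PART_RAW <- "https://imgstudy.dev/fhir/StructureDefinition/dicom-body-part-examined"
EXT_LATERALITY_RAW <- "https://imgstudy.dev/fhir/StructureDefinition/dicom-laterality"

#' Build a FHIR R4 ImagingStudy resource from a grouped DICOM study
#'
#' Mirrors the DICOM study/series/instance hierarchy into an R4 ImagingStudy:
#' study identifiers (study UID as a `urn:dicom:uid` identifier, accession
#' number as an ACSN identifier), a patient reference carrying the patient ID
#' as identifier, the distinct series modalities, per-series body site and
#' laterality codings obtained through the terminology context, and the raw
#' BodyPartExamined / laterality strings as series extensions.
#'
#' @param study a `study_set` from [group_instances()].
#' @param ctx a [terminology_context()].
#' @return a list of class `imaging_study` shaped like the R4 JSON resource.
#' @export
build_imaging_study <- function(study, ctx = terminology_context()) {
  stopifnot(inherits(study, "study_set"), inherits(ctx, "terminology_context"))
  if (length(study$series) == 0) stop("empty study: no series to convert")

  series <- list()
  for (s in study$series) {
    if (length(s$instances) == 0) {
      warning("series ", s$series_instance_uid, " has no instances; dropped")
      next
    }
    body_site <- map_body_part(s$body_part_examined, ctx$body_parts, ctx)
    laterality <- map_laterality(s$laterality)
    ext <- list()
    if (!is.na(s$body_part_examined %||% NA)) {
      ext <- c(ext, list(list(url = EXT_BODY_PART_RAW, valueString = s$body_part_examined)))
    }
    if (!is.na(s$laterality %||% NA)) {
      ext <- c(ext, list(list(url = EXT_LATERALITY_RAW, valueString = s$laterality)))
    }
    instances <- lapply(s$instances, function(m) {
      compact(list(
        uid = m$sop_instance_uid,
        sopClass = list(system = SOP_CLASS_SYSTEM, code = paste0("urn:oid:", m$sop_class_uid)),
        number = if (!is.na(m$instance_number)) m$instance_number else NULL
      ))
    })
    series[[length(series) + 1L]] <- compact(list(
      uid = s$series_instance_uid,
      number = if (!is.na(s$series_number %||% NA)) s$series_number else NULL,
      modality = list(system = DCM_URI, code = s$modality),
      description = if (!is.na(s$instances[[1]]$series_description %||% NA)) {
        s$instances[[1]]$series_description
      } else NULL,
      numberOfInstances = length(instances),
      bodySite = body_site,
      laterality = laterality,
      extension = if (length(ext)) ext else NULL,
      instance = instances
    ))
  }
  if (length(series) == 0) stop("empty study: all series were rejected")

  modalities <- unique(vapply(series, function(s) s$modality$code, character(1)))
  resource <- compact(list(
    resourceType = "ImagingStudy",
    identifier = list(
      list(system = DICOM_UID_SYSTEM, value = paste0("urn:oid:", study$study_instance_uid)),
      list(
        type = list(coding = list(list(system = V2_0203_SYSTEM, code = "ACSN"))),
        value = study$accession_number
      )
    ),
    status = "available",
    modality = lapply(modalities, function(m) list(system = DCM_URI, code = m)),
    subject = list(identifier = list(system = PATIENT_ID_SYSTEM, value = study$patient_id)),
    started = if (!is.na(study$started %||% NA)) study$started else NULL,
    numberOfSeries = length(series),
    numberOfInstances = sum(vapply(series, `[[`, integer(1), "numberOfInstances")),
    series = series
  ))
  class(resource) <- c("imaging_study", "list")
  resource
}

study_uid_of <- function(resource) {
  for (id in resource$identifier) {
    if (identical(id$system, DICOM_UID_SYSTEM)) {
      return(sub("^urn:oid:", "", id$value))
    }
  }
  NA_character_
}

accession_of <- function(resource) {
  for (id in resource$identifier) {
    if (!is.null(id$type)) return(id$value)
  }
  NA_character_
}

#' Wrap an ImagingStudy resource in a FHIR transaction bundle
#'
#' The single entry carries a conditional update (`PUT
#' ImagingStudy?identifier=...`) keyed on the study-UID identifier, so
#' replaying the same corpus against a server is idempotent.
#'
#' @param resource an `imaging_study`.
#' @return a list of class `fhir_bundle`.
#' @export
wrap_bundle <- function(resource) {
  stopifnot(inherits(resource, "imaging_study"))
  bundle <- list(
    resourceType = "Bundle",
    type = "transaction",
    entry = list(list(
      resource = resource,
      request = list(
        method = "PUT",
        url = paste0("ImagingStudy?identifier=", DICOM_UID_SYSTEM, "|urn:oid:",
          study_uid_of(resource))
      )
    ))
  )
  class(bundle) <- c("fhir_bundle", "list")
  bundle
}

#' Extract the ImagingStudy resource from a bundle
#' @param bundle a `fhir_bundle` (possibly re-read from NDJSON).
#' @return the `imaging_study` resource.
#' @export
bundle_resource <- function(bundle) {
  stopifnot(length(bundle$entry) >= 1)
  res <- bundle$entry[[1]]$resource
  class(res) <- c("imaging_study", "list")
  res
}

#' Validate the structural invariants of an ImagingStudy resource
#'
#' Checks the count coherence and identity rules the converter guarantees:
#' `numberOfSeries` / `numberOfInstances` match the series list, per-series
#' instance counts match, UIDs are non-empty and unique at their level, the
#' study-level modality list is duplicate-free and equals the set of series
#' modalities, and status is `"available"`.
#'
#' @param resource an `imaging_study` (possibly hand-built or deserialized).
#' @return character vector of violations; empty means valid.
#' @export
validate_resource <- function(resource) {
  v <- character()
  say <- function(...) v <<- c(v, sprintf(...))
  if (!identical(resource$resourceType, "ImagingStudy")) say("resourceType is not ImagingStudy")
  if (!identical(resource$status, "available")) say("status is not 'available'")
  uid <- study_uid_of(resource)
  if (is.na(uid) || !nzchar(uid)) say("missing study UID identifier")
  series <- resource$series %||% list()
  if (!length(series)) say("resource has no series")
  if (!identical(as.integer(resource$numberOfSeries %||% -1L), length(series))) {
    say("numberOfSeries %s != %d series entries", resource$numberOfSeries, length(series))
  }
  total <- 0L
  suids <- character()
  mods <- character()
  for (s in series) {
    suids <- c(suids, s$uid %||% "")
    mods <- c(mods, s$modality$code %||% "")
    inst <- s$instance %||% list()
    total <- total + length(inst)
    if (!identical(as.integer(s$numberOfInstances %||% -1L), length(inst))) {
      say("series %s: numberOfInstances %s != %d instances", s$uid,
        s$numberOfInstances, length(inst))
    }
    iuids <- vapply(inst, function(i) i$uid %||% "", character(1))
    if (any(!nzchar(iuids))) say("series %s: empty instance UID", s$uid)
    if (anyDuplicated(iuids)) say("series %s: duplicate instance UID", s$uid)
  }
  if (any(!nzchar(suids))) say("empty series UID")
  if (anyDuplicated(suids)) say("duplicate series UID")
  if (!identical(as.integer(resource$numberOfInstances %||% -1L), total)) {
    say("numberOfInstances %s != %d instances", resource$numberOfInstances, total)
  }
  listed <- vapply(resource$modality %||% list(), function(m) m$code %||% "", character(1))
  if (anyDuplicated(listed)) say("duplicate study-level modality coding")
  if (!setequal(listed, unique(mods))) {
    say("study-level modality list {%s} != series modalities {%s}",
      paste(listed, collapse = ","), paste(unique(mods), collapse = ","))
  }
  v
}

#' Serialize a FHIR resource or bundle to canonical JSON
#' @param x resource or bundle list.
#' @return length-1 character, no trailing newline.
#' @export
fhir_json <- function(x) {
  as.character(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA))
}

#' Write bundles as NDJSON (one bundle per line)
#' @param bundles list of `fhir_bundle`; @param path output file.
#' @param append append instead of truncating.
#' @return path, invisibly.
#' @export
write_ndjson <- function(bundles, path, append = FALSE) {
  lines <- vapply(bundles, fhir_json, character(1))
  con <- file(path, if (append) "ab" else "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read NDJSON bundles
#' @param path NDJSON file with one FHIR bundle per line.
#' @return list of `fhir_bundle` objects.
#' @export
read_ndjson <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    b <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    class(b) <- c("fhir_bundle", "list")
    b
  })
}

#' @export
print.imaging_study <- function(x, ...) {
  cat("<ImagingStudy>", study_uid_of(x), "\n  accession:", accession_of(x),
    "\n  series:", x$numberOfSeries, " instances:", x$numberOfInstances,
    " modalities:", paste(vapply(x$modality, `[[`, character(1), "code"), collapse = ","),
    "\n")
  invisible(x)
}

#' @export
print.fhir_bundle <- function(x, ...) {
  cat("<FHIR bundle>", x$type, "with", length(x$entry), "entry\n")
  print(bundle_resource(x))
  invisible(x)
}
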