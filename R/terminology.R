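# Terminology mapping: BodyPartExamined -> SNOMED CT, laterality -> SNOMED CT
# qualifier concepts, and modality -> acquisition / non-acquisition class.

SNOMED_URI <- "http://snomed.info/sct"
DCM_URI <- "http://dicom.nema.org/resources/ontology/DCM"

#' Default non-acquisition modality codes
#'
#' Modalities that produce derived or document objects rather than images:
#' structured reports, presentation states, key object selections,
#' segmentations, encapsulated documents, audio.
#' @export
DEFAULT_NON_ACQUISITION <- c("SR", "PR", "KO", "SEG", "DOC", "AU")

coded_concept <- function(system, code, display) {
  stopifnot(nzchar(system), nzchar(code), nzchar(display))
  list(system = system, code = code, display = display)
}

#' Load a BodyPartExamined to SNOMED CT mapping table
#'
#' Reads a CSV with columns `raw,snomed_code,display,min_edition,max_edition`
#' and keeps the rows valid for the requested edition of the DICOM standard
#' (editions are labelled `YYYYx` and compare lexicographically; empty bounds
#' are open). The packaged default table covers the regions produced by the
#' corpus generator plus common values; notably `LEG` is valid only up to
#' edition 2022d, after which `LOWERLEG` replaces it.
#'
#' @param path CSV path; default is the packaged table.
#' @param edition edition label the table should reflect (default `"2022b"`,
#'   a mid-2022 edition).
#' @return object of class `mapping_table`: list with `version_label` and
#'   `entries` (named list raw value -> coded concept).
#' @export
#' @examples
#' tbl <- body_part_table()
#' tbl$entries[["KNEE"]]$code
body_part_table <- function(path = NULL, edition = "2022b") {
  path <- path %||% system.file("extdata", "bodypart_snomed.csv", package = "imgstudy")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("raw", "snomed_code", "display", "min_edition", "max_edition")
  if (!all(need %in% names(df))) stop("mapping table needs columns ", paste(need, collapse = ","))
  keep <- (df$min_edition == "" | df$min_edition <= edition) &
    (df$max_edition == "" | edition <= df$max_edition)
  df <- df[keep, ]
  df$raw <- toupper(trimws(df$raw))
  if (anyDuplicated(df$raw)) {
    stop("duplicate raw keys in mapping table: ",
      paste(unique(df$raw[duplicated(df$raw)]), collapse = ", "))
  }
  entries <- stats::setNames(
    lapply(seq_len(nrow(df)), function(i) {
      coded_concept(SNOMED_URI, df$snomed_code[i], df$display[i])
    }),
    df$raw
  )
  structure(list(version_label = edition, entries = entries), class = "mapping_table")
}

#' @export
print.mapping_table <- function(x, ...) {
  cat("<body-part mapping table> edition", x$version_label, "-",
    length(x$entries), "raw values\n")
  invisible(x)
}

#' Map a raw BodyPartExamined value to a SNOMED CT concept
#'
#' Absent input maps to absent output. A present but unmapped value also
#' yields no concept, but is recorded as an unmapped-value event on the
#' terminology context when one is supplied — such values still count as
#' "present" in completeness statistics, only their coding is lost.
#'
#' @param raw raw tag value (or `NA`); matching is case- and
#'   whitespace-insensitive.
#' @param table a `mapping_table` from [body_part_table()].
#' @param ctx optional `terminology_context` collecting unmapped events.
#' @return a coded concept (list `system`, `code`, `display`) or `NULL`.
#' @export
map_body_part <- function(raw, table, ctx = NULL) {
  stopifnot(inherits(table, "mapping_table"))
  raw <- str_or_na(if (is.null(raw)) NA_character_ else raw)
  if (is.na(raw)) return(NULL)
  key <- toupper(raw)
  hit <- table$entries[[key]]
  if (is.null(hit) && !is.null(ctx)) {
    ctx$events$unmapped_body_parts <- c(ctx$events$unmapped_body_parts, key)
  }
  hit
}

# FHIR R4 ImagingStudy series.laterality example binding
.laterality_concepts <- list(
  L = list(system = SNOMED_URI, code = "419161000", display = "Unilateral left"),
  R = list(system = SNOMED_URI, code = "419465000", display = "Unilateral right"),
  B = list(system = SNOMED_URI, code = "51440002", display = "Right and left")
)

#' Map a raw laterality value to a SNOMED CT qualifier concept
#'
#' `L`, `R` and `B` map to the left / right / bilateral concepts of the
#' FHIR R4 ImagingStudy laterality example binding. `U` (unpaired) is a valid
#' DICOM value with no concept in that binding: it yields no coding but is
#' still a *present* value for completeness purposes (the analysis stage
#' treats it so). Anything else yields no coding and counts as invalid.
#'
#' @param raw raw value or `NA`; case/whitespace-insensitive.
#' @return coded concept or `NULL`.
#' @export
#' @examples
#' map_laterality("L")$code
map_laterality <- function(raw) {
  raw <- str_or_na(if (is.null(raw)) NA_character_ else raw)
  if (is.na(raw)) return(NULL)
  .laterality_concepts[[toupper(raw)]]
}

#' Classify a modality code as acquisition or non-acquisition
#'
#' @param modality DICOM modality code (non-empty).
#' @param non_acquisition set of codes treated as non-acquisition
#'   (default [DEFAULT_NON_ACQUISITION]).
#' @param warn_unknown warn when the code is neither a known acquisition nor
#'   non-acquisition modality (it is then classed acquisition, keeping
#'   completeness denominators conservative).
#' @return `"acquisition"` or `"non_acquisition"`.
#' @export
classify_modality <- function(modality, non_acquisition = DEFAULT_NON_ACQUISITION,
                              warn_unknown = TRUE) {
  m <- toupper(str_or_na(modality))
  if (is.na(m)) stop("modality must be non-empty")
  if (m %in% toupper(non_acquisition)) return("non_acquisition")
  known_acq <- c(
    "CT", "MR", "DX", "CR", "XA", "US", "NM", "PT", "MG", "RF", "XC", "OT",
    "OCT", "OP", "ES", "GM", "IO", "PX", "IVUS", "ECG", "EPS", "HD", "BDUS"
  )
  if (warn_unknown && !(m %in% known_acq)) {
    warning("unknown modality code '", m, "' classed as acquisition")
  }
  "acquisition"
}

#' Bundle the terminology configuration used by the FHIR builder
#'
#' @param body_parts a `mapping_table` (default: packaged table).
#' @param non_acquisition non-acquisition modality codes.
#' @return object of class `terminology_context`; its `events` environment
#'   accumulates unmapped body-part values (see [unmapped_body_parts()]).
#' @export
terminology_context <- function(body_parts = body_part_table(),
                                non_acquisition = DEFAULT_NON_ACQUISITION) {
  stopifnot(inherits(body_parts, "mapping_table"))
  ev <- new.env(parent = emptyenv())
  ev$unmapped_body_parts <- character()
  structure(
    list(body_parts = body_parts, non_acquisition = non_acquisition, events = ev),
    class = "terminology_context"
  )
}

#' Unmapped body-part values seen by a terminology context
#' @param ctx a `terminology_context`.
#' @return character vector of raw values that had no mapping (with repeats).
#' @export
unmapped_body_parts <- function(ctx) {
  stopifnot(inherits(ctx, "terminology_context"))
  ctx$events$unmapped_body_parts
}
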