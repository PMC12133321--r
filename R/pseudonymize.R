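# Pseudonymization: UID hashing into the 2.25 namespace and persisted
# patient/accession pseudonym maps (a file-based stand-in for an
# institutional trustee service).

#' Define a UID hashing policy
#'
#' @param salt non-empty secret string; keep it out of outputs and logs.
#'   Supply it from the environment (see `salt_env`) in scripted use.
#' @param salt_env alternatively, name of an environment variable holding
#'   the salt.
#' @param uid_root root of the derived UID namespace; `"2.25."` is the UUID-
#'   derived OID arc, guaranteeing the decimal digest form is a legal UID.
#' @return object of class `hashing_policy`.
#' @export
hashing_policy <- function(salt = NULL, salt_env = NULL, uid_root = "2.25.") {
  if (is.null(salt) && !is.null(salt_env)) salt <- Sys.getenv(salt_env, "")
  if (is.null(salt) || !nzchar(salt)) stop("hashing policy requires a non-empty salt")
  structure(list(salt = salt, uid_root = uid_root), class = "hashing_policy")
}

#' @export
print.hashing_policy <- function(x, ...) {
  # never echo the salt
  cat("<hashing policy> SHA-256, uid root", x$uid_root, "(salt set)\n")
  invisible(x)
}

# big-endian bytes -> decimal string (schoolbook base-256 to base-10)
.bytes_to_decimal <- function(bytes) {
  digits <- 0L # little-endian decimal digit vector
  for (b in as.integer(bytes)) {
    digits <- digits * 256L
    digits[1] <- digits[1] + b
    carry <- 0L
    i <- 1L
    while (i <= length(digits) || carry > 0L) {
      if (i > length(digits)) digits <- c(digits, 0L)
      val <- digits[i] + carry
      digits[i] <- val %% 10L
      carry <- val %/% 10L
      i <- i + 1L
    }
  }
  while (length(digits) > 1L && digits[length(digits)] == 0L) {
    digits <- digits[-length(digits)]
  }
  paste(rev(digits), collapse = "")
}

#' Hash a DICOM UID into a derived UID namespace
#'
#' Computes SHA-256 over `salt || uid` and renders the low 128 bits of the
#' digest as a decimal number under the policy's UID root (default `2.25.`,
#' the OID arc for UUID-derived UIDs), giving a deterministic, salted,
#' non-reversible UID of at most 44 characters.
#'
#' @param uid non-empty UID string.
#' @param policy a [hashing_policy()].
#' @return the derived UID.
#' @export
#' @examples
#' hash_uid("1.2.3", hashing_policy(salt = "s"))
hash_uid <- function(uid, policy) {
  stopifnot(inherits(policy, "hashing_policy"))
  if (is.null(uid) || is.na(uid) || !nzchar(uid)) stop("cannot hash an empty UID")
  d <- digest::digest(paste0(policy$salt, uid), algo = "sha256",
    serialize = FALSE, raw = TRUE)
  out <- paste0(policy$uid_root, .bytes_to_decimal(d[17:32]))
  stopifnot(nchar(out) <= 64, out != uid)
  out
}

#' Open (or create) a persisted pseudonym map
#'
#' The map allocates counter-based pseudonyms (`PSN-000001` for patient IDs,
#' `ACC-000001` for accession numbers) on first sight of an original value
#' and persists every allocation immediately as CSV
#' (`kind,original,pseudonym`), so linkage survives across runs. Single
#' writer is assumed.
#'
#' @param path CSV file backing the map (created when absent).
#' @return object of class `pseudonym_map` (environment-backed; mutable).
#' @export
pseudonym_map <- function(path) {
  e <- new.env(parent = emptyenv())
  e$path <- path
  e$patient <- character()
  e$accession <- character()
  if (file.exists(path)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    for (i in seq_len(nrow(df))) {
      kind <- df$kind[i]
      e[[kind]][df$original[i]] <- df$pseudonym[i]
    }
  } else {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(
      data.frame(kind = character(), original = character(), pseudonym = character()),
      path, row.names = FALSE
    )
  }
  class(e) <- "pseudonym_map"
  e
}

#' @export
print.pseudonym_map <- function(x, ...) {
  cat("<pseudonym map>", x$path, "\n  patients:", length(x$patient),
    " accessions:", length(x$accession), "\n")
  invisible(x)
}

.pm_prefix <- c(patient = "PSN-", accession = "ACC-")

#' Look up (allocating if new) the pseudonym for an original value
#'
#' @param map a [pseudonym_map()].
#' @param kind `"patient"` or `"accession"`.
#' @param original original identifier value.
#' @return the pseudonym string.
#' @export
pseudonym_for <- function(map, kind = c("patient", "accession"), original) {
  kind <- match.arg(kind)
  stopifnot(inherits(map, "pseudonym_map"), nzchar(original))
  hit <- map[[kind]][original]
  if (!is.na(hit)) return(unname(hit))
  psn <- sprintf("%s%06d", .pm_prefix[[kind]], length(map[[kind]]) + 1L)
  map[[kind]][original] <- psn
  line <- paste(kind, original, psn, sep = ",")
  cat(line, "\n", sep = "", file = map$path, append = TRUE)
  psn
}

#' Pseudonymize a FHIR ImagingStudy bundle
#'
#' Replaces the study, series and instance UIDs via [hash_uid()] (preserving
#' the hierarchy: equal inputs hash to equal outputs corpus-wide), and the
#' accession number and patient identifier via the persisted pseudonym map.
#' SOP Class UIDs — standard, non-identifying class designators — are
#' retained, as are study dates (a documented privacy caveat). All structural
#' count invariants of the resource are unaffected.
#'
#' @param bundle a `fhir_bundle`.
#' @param map a [pseudonym_map()] (updated and persisted as a side effect).
#' @param policy a [hashing_policy()].
#' @return the pseudonymized `fhir_bundle`.
#' @export
pseudonymize_bundle <- function(bundle, map, policy) {
  stopifnot(inherits(map, "pseudonym_map"), inherits(policy, "hashing_policy"))
  res <- bundle_resource(bundle)
  bad <- validate_resource(res)
  if (length(bad)) stop("refusing to pseudonymize an invalid resource: ", bad[1])

  for (i in seq_along(res$identifier)) {
    id <- res$identifier[[i]]
    if (identical(id$system, DICOM_UID_SYSTEM)) {
      res$identifier[[i]]$value <-
        paste0("urn:oid:", hash_uid(sub("^urn:oid:", "", id$value), policy))
    } else {
      res$identifier[[i]]$value <- pseudonym_for(map, "accession", id$value)
    }
  }
  if (!is.null(res$subject$identifier$value)) {
    res$subject$identifier$value <-
      pseudonym_for(map, "patient", res$subject$identifier$value)
  }
  for (i in seq_along(res$series)) {
    res$series[[i]]$uid <- hash_uid(res$series[[i]]$uid, policy)
    for (j in seq_along(res$series[[i]]$instance)) {
      res$series[[i]]$instance[[j]]$uid <-
        hash_uid(res$series[[i]]$instance[[j]]$uid, policy)
    }
  }
  wrap_bundle(res)
}
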