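# Sequential study processing: verify transfer completeness against the
# manifest, convert + pseudonymize, append to the NDJSON sink, delete the
# study's objects — one study at a time, in manifest order.

#' Process an inbox of DICOM studies against a transfer manifest
#'
#' Works through the manifest strictly sequentially. For each accession it
#' locates the study's folder in the inbox (folders are indexed by parsing
#' one object each), polls until the number of received (parseable and,
#' when a whitelist is given, whitelisted) objects reaches the expected
#' count or `wait_timeout` elapses, and then either converts the study to a
#' pseudonymized ImagingStudy bundle appended to the NDJSON sink (on a full
#' count) or records an incomplete transfer. In every terminal state the
#' study's files are deleted before the next study starts, keeping the
#' endpoint folder clean and bounded. On-disk studies with no manifest
#' entry are recorded as conversion errors and likewise removed.
#'
#' @param inbox directory containing one sub-folder per study.
#' @param manifest data.frame `accession,expected_count` (see
#'   [read_manifest()]).
#' @param sink NDJSON file to append pseudonymized bundles to (created).
#' @param map a [pseudonym_map()].
#' @param policy a [hashing_policy()].
#' @param wait_timeout seconds to wait for outstanding objects of one study.
#' @param poll_interval seconds between recounts while waiting.
#' @param sop_whitelist optional character vector of accepted SOP Class
#'   UIDs; objects of other classes are received-but-excluded (they do not
#'   count toward the expected number, emulating an endpoint that rejects
#'   certain SOP classes).
#' @param ctx [terminology_context()] used for conversion.
#' @param verbose emit one log line per study event.
#' @return object of class `run_report`: list with `results` (data.frame
#'   `accession,status,expected,received,emitted`), `completion_rate`
#'   (exact fraction in [0,1]) and `processed_count`.
#' @export
process_inbox <- function(inbox, manifest, sink, map, policy,
                          wait_timeout = 2, poll_interval = 0.2,
                          sop_whitelist = NULL,
                          ctx = terminology_context(),
                          verbose = FALSE) {
  stopifnot(dir.exists(inbox), nrow(manifest) >= 1)
  log_line <- function(acc, event) {
    if (verbose) {
      message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " INFO ", acc, " ", event)
    }
  }

  # index inbox folders by accession (parse one object per folder)
  dirs <- list.dirs(inbox, recursive = FALSE)
  acc_of_dir <- vapply(dirs, function(d) {
    f <- list.files(d, full.names = TRUE)
    for (path in f) {
      m <- tryCatch(read_instance(path), error = function(e) NULL)
      if (!is.null(m) && !is.na(m$accession_number)) return(m$accession_number)
    }
    NA_character_
  }, character(1))

  count_received <- function(d) {
    metas <- list()
    for (path in list.files(d, full.names = TRUE)) {
      m <- tryCatch(read_instance(path), error = function(e) NULL)
      if (is.null(m)) next
      if (!is.null(sop_whitelist) && !(m$sop_class_uid %in% sop_whitelist)) next
      metas[[length(metas) + 1L]] <- m
    }
    metas
  }

  results <- data.frame(
    accession = character(), status = character(), expected = integer(),
    received = integer(), emitted = logical(), stringsAsFactors = FALSE
  )
  add <- function(acc, status, expected, received, emitted) {
    results[nrow(results) + 1L, ] <<- list(acc, status, as.integer(expected),
      as.integer(received), emitted)
  }

  for (i in seq_len(nrow(manifest))) {
    acc <- manifest$accession[i]
    expected <- manifest$expected_count[i]
    d <- dirs[match(acc, acc_of_dir)]
    if (is.na(d)) {
      log_line(acc, "no objects received")
      add(acc, "incomplete_transfer", expected, 0L, FALSE)
      next
    }
    deadline <- Sys.time() + wait_timeout
    metas <- count_received(d)
    while (length(metas) < expected && Sys.time() < deadline) {
      Sys.sleep(poll_interval)
      metas <- count_received(d)
    }
    if (length(metas) < expected) {
      log_line(acc, sprintf("incomplete transfer (%d/%d)", length(metas), expected))
      add(acc, "incomplete_transfer", expected, length(metas), FALSE)
    } else {
      if (length(metas) > expected) {
        warning(acc, ": received ", length(metas), " objects, expected ", expected)
      }
      ok <- tryCatch({
        studies <- group_instances(metas)
        if (length(studies) != 1) {
          stop("objects for accession ", acc, " span ", length(studies), " studies")
        }
        bundle <- wrap_bundle(build_imaging_study(studies[[1]], ctx))
        write_ndjson(list(pseudonymize_bundle(bundle, map, policy)), sink, append = TRUE)
        TRUE
      }, error = function(e) {
        log_line(acc, paste("conversion error:", conditionMessage(e)))
        FALSE
      })
      if (ok) {
        log_line(acc, "converted and emitted")
        add(acc, "success", expected, length(metas), TRUE)
      } else {
        add(acc, "conversion_error", expected, length(metas), FALSE)
      }
    }
    unlink(d, recursive = TRUE)   # always clean up before the next study
  }

  # on-disk studies the manifest knows nothing about: error + delete
  for (j in seq_along(dirs)) {
    if (!dir.exists(dirs[j])) next
    if (is.na(acc_of_dir[j]) || !(acc_of_dir[j] %in% manifest$accession)) {
      acc <- if (is.na(acc_of_dir[j])) basename(dirs[j]) else acc_of_dir[j]
      log_line(acc, "not in manifest")
      add(acc, "conversion_error", 0L, 0L, FALSE)
      unlink(dirs[j], recursive = TRUE)
    }
  }

  structure(list(
    results = results,
    completion_rate = sum(results$status == "success") / nrow(results),
    processed_count = nrow(results)
  ), class = "run_report")
}

#' Completion rate of a run, as a display percentage
#'
#' @param report a `run_report` from [process_inbox()].
#' @param digits decimal places (default 0, the package-wide display
#'   rounding: half-up).
#' @return percentage in [0, 100].
#' @export
completion_rate <- function(report, digits = 0) {
  stopifnot(inherits(report, "run_report"))
  if (report$processed_count == 0) stop("empty run report")
  round_half_up(100 * report$completion_rate, digits)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<pipeline run>", x$processed_count, "studies,",
    sum(x$results$status == "success"), "converted",
    sprintf("(completion rate %s%%)\n", format(completion_rate(x, 1))))
  tab <- table(x$results$status)
  for (s in names(tab)) cat("  ", s, ":", tab[[s]], "\n")
  invisible(x)
}

#' Write a run report as CSV
#' @param report a `run_report`; @param path output CSV.
#' @return path, invisibly.
#' @export
write_run_report <- function(report, path) {
  utils::write.csv(report$results, path, row.names = FALSE)
  invisible(path)
}
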