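# Part-10 header parsing and study/series grouping.

test_that("generated headers round-trip through read_instance", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "a.dcm")
  write_dicom_instance(path, list(
    sop_class_uid = "1.2.840.10008.5.1.4.1.1.2", sop_instance_uid = "1.2.3.4.1",
    study_instance_uid = "1.2.3", series_instance_uid = "1.2.3.4",
    modality = "CT", body_part_examined = "KNEE", laterality = "L",
    patient_id = "P9", accession_number = "A9", study_date = "20220415",
    study_time = "101500", series_number = 3L, instance_number = 7L,
    series_description = "CT KNEE 3"
  ))
  m <- read_instance(path)
  expect_s3_class(m, "dicom_instance_meta")
  expect_equal(m$modality, "CT")
  expect_equal(m$body_part_examined, "KNEE")
  expect_equal(m$laterality, "L")
  expect_equal(m$series_number, 3L)
  expect_equal(m$instance_number, 7L)
  expect_equal(m$patient_id, "P9")
  expect_equal(m$study_date, "20220415")
})

test_that("blank values normalize to absent; B/U come from Image Laterality", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "b.dcm")
  write_dicom_instance(path, list(
    sop_class_uid = "1.2.840.10008.5.1.4.1.1.2", sop_instance_uid = "1.2.3.4.2",
    study_instance_uid = "1.2.3", series_instance_uid = "1.2.3.4",
    modality = "CT", body_part_examined = "  ", laterality = "U",
    patient_id = "P9", accession_number = "A9"
  ))
  m <- read_instance(path)
  expect_true(is.na(m$body_part_examined))   # blank -> absent
  expect_equal(m$laterality, "U")            # read back via (0020,0062)
  expect_true(is.na(m$series_number))
})

test_that("non-DICOM and truncated files are rejected with file identity", {
  dir <- withr::local_tempdir()
  txt <- file.path(dir, "not.dcm")
  writeLines("definitely not dicom, padded to well over 140 bytes ....................................................................................", txt)
  expect_error(read_instance(txt), "not.dcm.*DICM|DICM.*not.dcm")
  expect_error(read_instance(file.path(dir, "missing.dcm")), "no such file")
})

test_that("parsing stops before pixel data", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "c.dcm")
  write_dicom_instance(path, list(
    sop_class_uid = "1.2.840.10008.5.1.4.1.1.2", sop_instance_uid = "1.2.3.4.3",
    study_instance_uid = "1.2.3", series_instance_uid = "1.2.3.4",
    modality = "CT", patient_id = "P", accession_number = "A"
  ), with_pixels = TRUE)
  # corrupt the pixel payload; header parsing must be unaffected
  sz <- file.size(path)
  con <- file(path, "r+b"); seek(con, sz - 4, rw = "write")
  writeBin(as.raw(c(222, 173, 190, 239)), con); close(con)
  expect_equal(read_instance(path)$modality, "CT")
})

test_that("parsed fields agree with an independent pydicom header dump", {
  dir <- withr::local_tempdir()
  generate_corpus(oracle_profile(), dir)
  files <- list.files(dir, recursive = TRUE, full.names = TRUE, pattern = "[.]dcm$")
  files <- files[seq(1, length(files), length.out = min(20, length(files)))]
  script <- file.path(dir, "dump.py")
  writeLines(c(
    "import sys, json, pydicom",
    "out = []",
    "for p in sys.argv[1:]:",
    "    ds = pydicom.dcmread(p, stop_before_pixels=True)",
    "    out.append({",
    "        'modality': str(ds.Modality),",
    "        'study': str(ds.StudyInstanceUID),",
    "        'series': str(ds.SeriesInstanceUID),",
    "        'sop': str(ds.SOPInstanceUID),",
    "        'body': str(ds.BodyPartExamined) if 'BodyPartExamined' in ds else None,",
    "        'lat': str(ds.Laterality) if 'Laterality' in ds else (str(ds.ImageLaterality) if 'ImageLaterality' in ds else None),",
    "        'acc': str(ds.AccessionNumber),",
    "        'pat': str(ds.PatientID),",
    "        'inum': int(ds.InstanceNumber)})",
    "print(json.dumps(out))"
  ), script)
  res <- system2("python", c(script, files), stdout = TRUE)
  dump <- jsonlite::fromJSON(paste(res, collapse = ""), simplifyVector = FALSE)
  for (i in seq_along(files)) {
    m <- read_instance(files[i])
    d <- dump[[i]]
    expect_equal(m$modality, d$modality)
    expect_equal(m$study_instance_uid, d$study)
    expect_equal(m$series_instance_uid, d$series)
    expect_equal(m$sop_instance_uid, d$sop)
    expect_equal(m$body_part_examined, d$body %||% NA_character_)
    expect_equal(m$laterality, d$lat %||% NA_character_)
    expect_equal(m$accession_number, d$acc)
    expect_equal(m$patient_id, d$pat)
    expect_equal(m$instance_number, d$inum)
  }
})

test_that("grouping conserves counts and orders series and instances", {
  metas <- list(
    make_meta("i4", "s2", series_number = 2L, instance_number = 2L),
    make_meta("i1", "s1", series_number = 1L, instance_number = 1L),
    make_meta("i3", "s2", series_number = 2L, instance_number = 1L),
    make_meta("i2", "s1", series_number = 1L, instance_number = 2L),
    make_meta("j1", study_instance_uid = "9.9", series_instance_uid = "t1",
      accession_number = "A2")
  )
  sets <- group_instances(metas)
  expect_length(sets, 2)
  n_inst <- sum(vapply(sets, function(s) {
    sum(vapply(s$series, function(x) length(x$instances), integer(1)))
  }, integer(1)))
  expect_equal(n_inst, length(metas))
  s1 <- sets[["1.2.3"]]
  expect_equal(
    unname(vapply(s1$series, `[[`, character(1), "series_instance_uid")),
    c("s1", "s2")
  )
  expect_equal(
    vapply(s1$series[[2]]$instances, `[[`, character(1), "sop_instance_uid"),
    c("i3", "i4")
  )
  expect_equal(s1$started, "2022-01-01T08:00:00")
  expect_length(group_instances(list()), 0)
})

test_that("duplicate SOP instances are dropped with a warning, conserving the rest", {
  metas <- list(
    make_meta("i1", instance_number = 1L),
    make_meta("i1", instance_number = 1L),
    make_meta("i2", instance_number = 2L)
  )
  expect_warning(sets <- group_instances(metas), "duplicate SOPInstanceUID")
  expect_length(sets[[1]]$series[[1]]$instances, 2)
})

test_that("instances disagreeing on series attributes warn and use the first", {
  metas <- list(
    make_meta("i1", body_part_examined = "KNEE", instance_number = 1L),
    make_meta("i2", body_part_examined = "HEAD", instance_number = 2L)
  )
  expect_warning(sets <- group_instances(metas), "disagree on body_part_examined")
  expect_equal(sets[[1]]$series[[1]]$body_part_examined, "KNEE")
})

test_that("grouping an already-grouped flatten reproduces the topology", {
  dir <- withr::local_tempdir()
  generate_corpus(tiny_profile(n_studies = 3, series_per_study = 2, objects = 4), dir)
  files <- list.files(dir, recursive = TRUE, full.names = TRUE, pattern = "[.]dcm$")
  sets1 <- group_instances(lapply(files, read_instance))
  flat <- unlist(lapply(sets1, function(s) {
    unlist(lapply(s$series, `[[`, "instances"), recursive = FALSE)
  }), recursive = FALSE)
  sets2 <- group_instances(flat)
  topo <- function(sets) lapply(sets, function(s) {
    lapply(s$series, function(x) {
      unname(vapply(x$instances, `[[`, character(1), "sop_instance_uid"))
    })
  })
  expect_identical(topo(sets1), topo(sets2))
})
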