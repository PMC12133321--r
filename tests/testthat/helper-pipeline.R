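# Shared fixtures: small profiles, a hand-built meta constructor, and a
# memoised full round trip of the builtin corpus (computed once per run).

tiny_profile <- function(n_studies = 2, series_per_study = 2, objects = 2,
                         mode = "deterministic", seed = 1L, ...) {
  corpus_profile(
    n_studies = n_studies, series_per_study = series_per_study,
    objects_per_study = data.frame(n_objects = objects, weight = 1),
    mode = mode, seed = seed, ...
  )
}

# a profile small enough for brute-force oracle checks but exercising
# every attribute: 5 studies x 4 series = 20 series
oracle_profile <- function(mode = "deterministic", seed = 7L) {
  corpus_profile(
    n_studies = 5, series_per_study = 4,
    objects_per_study = data.frame(n_objects = c(4, 8), weight = c(0.6, 0.4)),
    modality_shares = c(CT = 0.5, MR = 0.25, SR = 0.15, XA = 0.10),
    body_region_shares = c(KNEE = 0.3, HEAD = 0.25, HAND = 0.1, MISSING = 0.35),
    missing_only_modalities = c("SR", "XA"),
    laterality_splits = list(
      KNEE = c(0.4, 0.3, 0.2, 0.1, 0),
      HAND = c(0.5, 0, 0, 0, 0.5)
    ),
    mode = mode, seed = seed, name = "oracle"
  )
}

make_meta <- function(sop_instance_uid, series_instance_uid = "1.2.3.1",
                      study_instance_uid = "1.2.3", modality = "CT",
                      body_part_examined = NA_character_,
                      laterality = NA_character_,
                      sop_class_uid = "1.2.840.10008.5.1.4.1.1.2",
                      patient_id = "P1", accession_number = "A1",
                      study_date = "20220101", study_time = "080000",
                      series_number = 1L, instance_number = 1L,
                      series_description = NA_character_) {
  structure(list(
    sop_instance_uid = sop_instance_uid, sop_class_uid = sop_class_uid,
    study_instance_uid = study_instance_uid,
    series_instance_uid = series_instance_uid, modality = modality,
    body_part_examined = body_part_examined, laterality = laterality,
    patient_id = patient_id, accession_number = accession_number,
    study_date = study_date, study_time = study_time,
    series_number = as.integer(series_number),
    instance_number = as.integer(instance_number),
    series_description = series_description
  ), class = "dicom_instance_meta")
}

# run generate -> parse -> convert -> pseudonymize -> analyze for a profile
run_pipeline <- function(profile, salt = "test-salt") {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  gen <- generate_corpus(profile, dir)
  files <- list.files(dir, recursive = TRUE, full.names = TRUE, pattern = "[.]dcm$")
  metas <- lapply(files, read_instance)
  studies <- group_instances(metas)
  ctx <- terminology_context()
  bundles <- lapply(studies, function(s) wrap_bundle(build_imaging_study(s, ctx)))
  map <- pseudonym_map(file.path(dir, "map.csv"))
  policy <- hashing_policy(salt = salt)
  pseud <- lapply(bundles, pseudonymize_bundle, map = map, policy = policy)
  sink <- file.path(dir, "bundles.ndjson")
  write_ndjson(pseud, sink)
  list(
    gen = gen, files = files, metas = metas, studies = studies,
    bundles = bundles, pseud = pseud, sink = sink, map = map,
    policy = policy, dir = dir
  )
}

# the full builtin-corpus round trip is expensive; memoise it across
# acceptance test blocks
.pipeline_cache <- new.env(parent = emptyenv())

uhe2022_report <- function() {
  if (is.null(.pipeline_cache$report)) {
    dir <- tempfile("uhe2022-")
    gen <- generate_corpus(builtin_profile("uhe2022"), dir)
    files <- list.files(dir, recursive = TRUE, full.names = TRUE, pattern = "[.]dcm$")
    studies <- group_instances(lapply(files, read_instance))
    ctx <- terminology_context()
    map <- pseudonym_map(file.path(dir, "map.csv"))
    policy <- hashing_policy(salt = "acceptance-salt")
    pseud <- lapply(studies, function(s) {
      pseudonymize_bundle(wrap_bundle(build_imaging_study(s, ctx)), map, policy)
    })
    sink <- file.path(dir, "bundles.ndjson")
    write_ndjson(pseud, sink)
    .pipeline_cache$plan <- gen$plan
    .pipeline_cache$report <- analyze(sink)
    .pipeline_cache$lat_table <- laterality_by_region(pseud)
    .pipeline_cache$bundles <- pseud
    unlink(file.path(dir, list.files(dir, pattern = "^UHE")), recursive = TRUE)
  }
  .pipeline_cache
}
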