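# Metadata-quality analysis: completion rates, distributions, the paired-
# region laterality table, CSV export.

test_that("a two-series study gives 50% body-region completion", {
  metas <- list(
    make_meta("i1", "s1", body_part_examined = "HEAD", instance_number = 1L),
    make_meta("i2", "s2", series_number = 2L)
  )
  b <- wrap_bundle(build_imaging_study(group_instances(metas)[[1]]))
  rep <- analyze(list(b))
  expect_equal(rep$n_studies, 1)
  expect_equal(rep$n_series, 2)
  expect_equal(rep$completion_rate_body_region, 50)
  expect_equal(rep$body_region_missing_pct, 50)
  expect_equal(rep$completion_rate_modality, 100)
})

test_that("U counts as valid laterality overall but as neither L nor R in the table", {
  metas <- list(
    make_meta("i1", "s1", body_part_examined = "HAND", laterality = "U"),
    make_meta("i2", "s2", body_part_examined = "HAND", laterality = "L",
      series_number = 2L)
  )
  b <- wrap_bundle(build_imaging_study(group_instances(metas)[[1]]))
  rep <- analyze(list(b))
  expect_equal(rep$completion_rate_laterality, 100)
  tab <- laterality_by_region(list(b), regions = "HAND")
  expect_equal(tab$n_series, 2)
  expect_equal(tab$n_U, 1)
  expect_equal(tab$pct_missing, 0)
  expect_equal(tab$pct_L, 50)
  expect_equal(tab$pct_R, 0)
})

test_that("a single-L region row reads (0, 100, 0)", {
  metas <- list(make_meta("i1", "s1", body_part_examined = "KNEE", laterality = "L"))
  b <- wrap_bundle(build_imaging_study(group_instances(metas)[[1]]))
  tab <- laterality_by_region(list(b), regions = "KNEE")
  expect_equal(unlist(tab[, c("pct_missing", "pct_L", "pct_R")], use.names = FALSE),
    c(0, 100, 0))
})

test_that("requested regions absent from the data are omitted with a warning", {
  metas <- list(make_meta("i1", "s1", body_part_examined = "KNEE"))
  b <- wrap_bundle(build_imaging_study(group_instances(metas)[[1]]))
  expect_warning(tab <- laterality_by_region(list(b), regions = c("KNEE", "FOOT")),
    "FOOT")
  expect_equal(tab$region, "KNEE")
})

test_that("analysis equals a brute-force tally of the generator's assignment list", {
  prof <- oracle_profile()   # 20 series: small enough to tally by hand-code
  pipe <- run_pipeline(prof)
  plan <- pipe$gen$plan$series
  rep <- analyze(pipe$sink)

  expect_equal(rep$n_series, nrow(plan))
  expect_equal(rep$n_studies, nrow(pipe$gen$plan$studies))
  expect_equal(rep$n_instances, sum(plan$n_objects))
  expect_equal(as.list(rep$series_by_modality),
    as.list(sort(table(plan$modality), decreasing = TRUE)))
  expect_equal(rep$acquisition_fraction, 100 * mean(!(plan$modality %in% c("SR", "PR"))))
  expect_equal(rep$body_region_missing_pct, 100 * mean(is.na(plan$body_region)))
  expect_equal(rep$completion_rate_laterality,
    100 * mean(plan$laterality %in% c("L", "R", "B", "U")))
  expect_equal(rep$mean_instances_per_study,
    sum(plan$n_objects) / nrow(pipe$gen$plan$studies))
  reg <- rep$series_by_body_region
  for (r in reg$region[reg$region != "MISSING"]) {
    expect_equal(reg$count[reg$region == r],
      sum(!is.na(plan$body_region) & plan$body_region == r))
  }
  tab <- laterality_by_region(pipe$pseud, regions = c("KNEE", "HAND"))
  knee <- plan[!is.na(plan$body_region) & plan$body_region == "KNEE", ]
  expect_equal(tab$n_missing[tab$region == "KNEE"], sum(is.na(knee$laterality)))
  expect_equal(tab$n_L[tab$region == "KNEE"], sum(knee$laterality %in% "L"))
  expect_equal(tab$n_B[tab$region == "KNEE"], sum(knee$laterality %in% "B"))
})

test_that("pseudonymization never changes the statistics", {
  pipe <- run_pipeline(oracle_profile())
  plain <- analyze(pipe$bundles)
  pseud <- analyze(pipe$pseud)
  plain_cmp <- plain; pseud_cmp <- pseud
  expect_equal(pseud_cmp, plain_cmp)
  expect_identical(
    laterality_by_region(pipe$bundles, regions = c("KNEE", "HAND"))[, -1],
    laterality_by_region(pipe$pseud, regions = c("KNEE", "HAND"))[, -1]
  )
})

test_that("malformed bundles are skipped, warned about, and counted", {
  metas <- list(make_meta("i1", "s1"))
  good <- wrap_bundle(build_imaging_study(group_instances(metas)[[1]]))
  bad <- good
  bad$entry[[1]]$resource$numberOfSeries <- 5L
  expect_warning(rep <- analyze(list(good, bad)), "malformed")
  expect_equal(rep$rejects, 1L)
  expect_equal(rep$n_series, 1)
  expect_error(suppressWarnings(analyze(list(bad))), "no valid bundles")
  expect_error(analyze(list()), "no bundles")
})

test_that("display rounding is half-up, as used for printed integers", {
  expect_equal(round_half_up(94.7), 95)
  expect_equal(round_half_up(26.5), 27)   # base round() would give 26
  expect_equal(round_half_up(5.3), 5)
  expect_equal(round_half_up(88.333, 1), 88.3)
})

test_that("CSV export is deterministic and round-trips the report values", {
  pipe <- run_pipeline(oracle_profile())
  rep <- analyze(pipe$sink)
  tab <- laterality_by_region(pipe$pseud, regions = c("KNEE", "HAND"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- export_report(rep, tab, d1)
  f2 <- export_report(rep, tab, d2)
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
  sm <- utils::read.csv(file.path(d1, "summary.csv"))
  expect_equal(sm$value[sm$metric == "n_series"], rep$n_series)
  expect_equal(sm$value[sm$metric == "laterality_missing_pct"], rep$laterality_missing_pct)
  reg <- utils::read.csv(file.path(d1, "series_by_region.csv"))
  expect_equal(sum(reg$count), rep$n_series)   # regions incl. MISSING partition series
  lt <- utils::read.csv(file.path(d1, "laterality_by_region.csv"))
  expect_equal(lt$n_missing + lt$n_L + lt$n_R + lt$n_B + lt$n_U, lt$n_series)
  # empty table exports a header-only CSV
  f <- export_report(rep, NULL, withr::local_tempdir())
  expect_length(readLines(f[4]), 1)
})
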