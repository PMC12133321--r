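# Corpus generator: apportionment arithmetic, on-disk layout, determinism.

test_that("largest-remainder apportionment matches hand-computed quotas", {
  # 0.5*7=3.5, 0.3*7=2.1, 0.2*7=1.4 -> floors 3,2,1; one leftover goes to
  # the largest remainder (.5)
  expect_equal(
    apportion_largest_remainder(c(a = 0.5, b = 0.3, c = 0.2), 7),
    c(a = 4L, b = 2L, c = 1L)
  )
  # remainder tie (.8, .8, .4): earlier-listed category wins
  expect_equal(
    unname(apportion_largest_remainder(c(0.88, 0.03, 0.09), 60)),
    c(53L, 2L, 5L)
  )
  expect_equal(unname(apportion_largest_remainder(c(1), 5)), 5L)
  expect_error(apportion_largest_remainder(c(0.5, 0.4), 10), "sum to 1")
})

test_that("apportionment conserves the total over random share vectors", {
  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    shares <- stats::runif(k)
    shares <- shares / sum(shares)
    total <- sample(1:500, 1)
    counts <- apportion_largest_remainder(shares, total)
    expect_identical(sum(counts), as.integer(total))
    expect_true(all(abs(counts - shares * total) < 1))
  }
})

test_that("a 2x2 study corpus yields one file per object and a full manifest", {
  dir <- withr::local_tempdir()
  gen <- generate_corpus(tiny_profile(n_studies = 2, series_per_study = 2, objects = 4), dir)
  files <- list.files(dir, recursive = TRUE, pattern = "[.]dcm$")
  expect_length(files, 8)
  expect_equal(gen$manifest$accession, c("UHE0000001", "UHE0000002"))
  expect_equal(gen$manifest$expected_count, c(4, 4))
  # one folder per study, named by accession
  expect_setequal(basename(list.dirs(dir, recursive = FALSE)), gen$manifest$accession)
  # manifest round-trips through its CSV
  expect_equal(read_manifest(file.path(dir, "manifest.csv")), gen$manifest)
})

test_that("stochastic mode is byte-reproducible per seed and varies by seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  generate_corpus(oracle_profile(mode = "stochastic", seed = 11L), d1)
  generate_corpus(oracle_profile(mode = "stochastic", seed = 11L), d2)
  generate_corpus(oracle_profile(mode = "stochastic", seed = 12L), d3)
  digest_dir <- function(d) {
    f <- list.files(d, recursive = TRUE, full.names = TRUE, pattern = "[.]dcm$")
    vapply(f[order(basename(f))], function(p) digest::digest(p, file = TRUE), character(1),
      USE.NAMES = FALSE)
  }
  expect_identical(digest_dir(d1), digest_dir(d2))
  expect_false(identical(digest_dir(d1), digest_dir(d3)))
})

test_that("deterministic plans realize category counts exactly", {
  plan <- plan_corpus(builtin_profile("uhe2022"))
  s <- plan$series
  expect_equal(nrow(s), 2000)
  expect_equal(as.list(table(s$modality)),
    list(CT = 800L, DX = 240L, MR = 660L, PR = 40L, SR = 100L, XA = 160L))
  # knee series: 100 of 2000, of which 46 lack laterality
  knee <- s[!is.na(s$body_region) & s$body_region == "KNEE", ]
  expect_equal(nrow(knee), 100)
  expect_equal(sum(is.na(knee$laterality)), 46)
  # region-missing series: all SR/PR/XA plus the apportioned remainder
  expect_equal(sum(is.na(s$body_region)), 640)
  expect_true(all(is.na(s$body_region[s$modality %in% c("SR", "PR", "XA")])))
  # conservation: regions partition the series
  expect_equal(sum(table(s$body_region)) + sum(is.na(s$body_region)), 2000)
  # objects: 100 studies x 80 + 100 x 150
  expect_equal(sort(unique(plan$studies$n_objects)), c(80, 150))
  expect_equal(sum(plan$studies$n_objects), 23000)
  expect_equal(mean(plan$studies$n_objects), 115)
})

test_that("builtin profile pins the published corpus composition", {
  p <- builtin_profile("uhe2022")
  acq <- 1 - sum(p$modality_shares[c("SR", "PR")])
  expect_equal(acq, 0.93)
  expect_equal(sum(p$body_region_shares), 1)
  expect_equal(p$body_region_shares[["MISSING"]], 0.32)
  pf <- builtin_profile("uhe2022-faults")
  expect_equal(round_half_up(pf$fault_fraction * pf$n_studies), 4)
  expect_error(builtin_profile("nope"))
})

test_that("fault injection withholds exactly one trailing object per faulted study", {
  dir <- withr::local_tempdir()
  gen <- generate_corpus(builtin_profile("uhe2022-faults"), dir)
  expect_equal(sum(gen$plan$studies$faulted), 4)
  # manifest still expects the full count
  expect_equal(sum(gen$manifest$expected_count), 1000)
  expect_equal(gen$n_files, 996)
  for (acc in gen$manifest$accession[gen$plan$studies$faulted]) {
    files <- list.files(file.path(dir, acc), full.names = TRUE)
    expect_length(files, 9)
    inst <- vapply(lapply(files, read_instance), `[[`, integer(1), "instance_number")
    expect_equal(sort(inst), 1:9)  # the last instance (10) is the withheld one
  }
})

test_that("invalid profiles are rejected", {
  expect_error(corpus_profile(n_studies = 0), "n_studies")
  expect_error(
    corpus_profile(n_studies = 1, modality_shares = c(CT = 0.6, MR = 0.3)),
    "sum to 1"
  )
  expect_error(
    corpus_profile(n_studies = 1, body_region_shares = c(HEAD = 1)),
    "MISSING"
  )
  expect_error(
    corpus_profile(n_studies = 1,
      modality_shares = c(CT = 0.5, SR = 0.5),
      body_region_shares = c(HEAD = 0.8, MISSING = 0.2),
      missing_only_modalities = "SR"),
    "exceeds"
  )
  expect_error(tiny_profile(fault_fraction = 1.5))
})
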