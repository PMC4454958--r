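test_that("ppm conversion follows the molar-volume relation and round-trips", {
  expect_identical(convert_ppm_to_mgm3(0, 154.21), 0)
  # hand arithmetic: 0.2 * 154.21 / 24.45
  expect_equal(convert_ppm_to_mgm3(0.2, 154.21), 1.261431, tolerance = 1e-6)
  expect_equal(convert_ppm_to_mgm3(1, 24.45, 24.45), 1)
  expect_error(convert_ppm_to_mgm3(1, -1), "positive")
  expect_error(convert_ppm_to_mgm3(1, 100, 0), "positive")
  expect_error(convert_ppm_to_mgm3(-0.1, 100), "non-negative")
  for (c in c(0.001, 0.2, 7, 300)) {
    back <- convert_mgm3_to_ppm(convert_ppm_to_mgm3(c, 154.21), 154.21)
    expect_equal(back, c, tolerance = 1e-12)
  }
})

test_that("loading a measurement table flags detection-limit values and converts units", {
  path <- write_exposure_file(c(0.001, 0.057, 0.240))
  ds <- load_exposure_table(path, detection_limit = 0.001)
  expect_s3_class(ds, "exposure_dataset")
  expect_equal(nrow(ds), 3)
  expect_equal(sum(ds$below_detection), 1)
  expect_equal(ds$concentration, c(0.001, 0.057, 0.240))

  # ppm file: every row must match the explicit conversion
  ppm <- c(0.01, 0.2, 0.5)
  path_ppm <- write_exposure_file(ppm, units = "ppm")
  ds_ppm <- load_exposure_table(path_ppm, detection_limit = 1e-6,
                                molecular_weight = 154.21)
  expect_equal(ds_ppm$concentration, convert_ppm_to_mgm3(ppm, 154.21))
  expect_error(load_exposure_table(path_ppm), "molecular_weight")

  # TSV dialect
  path_tsv <- write_exposure_file(c(0.01, 0.02), ext = "tsv")
  expect_equal(load_exposure_table(path_tsv)$concentration, c(0.01, 0.02))
})

test_that("malformed measurement tables fail with informative errors", {
  empty <- tempfile(fileext = ".csv")
  writeLines(c("# units: mg/m3", "workplace_id,sample_kind,concentration"), empty)
  expect_error(load_exposure_table(empty), "no data rows")

  neg <- write_exposure_file(c(0.01, -0.02))
  expect_error(load_exposure_table(neg), "row 2")

  miss <- tempfile(fileext = ".csv")
  writeLines(c("workplace_id,concentration", "A,0.01"), miss)
  expect_error(load_exposure_table(miss), "sample_kind")

  badunit <- write_exposure_file(0.01, units = "mol/L")
  expect_error(load_exposure_table(badunit), "unknown unit")

  badkind <- write_exposure_file(0.01, sample_kind = "static")
  expect_error(load_exposure_table(badkind), "sample_kind")

  expect_error(load_exposure_table(tempfile()), "not found")
})

test_that("workplace summaries reproduce hand-computed moments", {
  ds <- exposure_dataset(c("A", "A"), c("personal", "area"), c(0.01, 0.03),
                         detection_limit = 1e-4)
  s <- summarize_exposure(ds)
  tot <- s[s$workplace_id == "Total", ]
  expect_equal(tot$am, 0.02)
  expect_equal(tot$sd, 0.01414214, tolerance = 1e-6)  # n-1 denominator
  expect_equal(c(tot$range_lo, tot$range_hi), c(0.01, 0.03))

  const <- exposure_dataset(rep("A", 4), rep("personal", 4), rep(0.05, 4),
                            detection_limit = 1e-4)
  sc <- summarize_exposure(const)
  expect_equal(sc$am, rep(0.05, 2))
  expect_equal(sc$sd, rep(0, 2))
})

test_that("summaries are permutation-invariant and the overall mean is the n-weighted group mean", {
  set.seed(42)
  ds <- exposure_dataset(sample(c("A", "B", "C"), 30, replace = TRUE),
                         rep(c("personal", "area"), 15),
                         stats::rlnorm(30, -3.5, 1), detection_limit = 1e-5)
  s1 <- summarize_exposure(ds)
  perm <- ds[sample(nrow(ds)), ]
  class(perm) <- class(ds)
  attr(perm, "detection_limit") <- attr(ds, "detection_limit")
  s2 <- summarize_exposure(perm)
  expect_equal(s1, s2)

  groups <- s1[s1$workplace_id != "Total", ]
  overall <- s1[s1$workplace_id == "Total", ]
  expect_equal(overall$am, sum(groups$n * groups$am) / sum(groups$n),
               tolerance = 1e-12)
})

test_that("single-sample groups report SD 0 with a degeneracy flag", {
  ds <- exposure_dataset(c("A", "A", "B"), rep("personal", 3),
                         c(0.01, 0.02, 0.05), detection_limit = 1e-4)
  expect_warning(s <- summarize_exposure(ds), "single sample")
  b <- s[s$workplace_id == "B", ]
  expect_equal(b$sd, 0)
  expect_true(b$sd_degenerate)
})

test_that("dataset constructor enforces its invariants", {
  expect_error(exposure_dataset(character(0), character(0), numeric(0)),
               "at least one")
  expect_error(exposure_dataset("A", "personal", -1), "negative")
  expect_error(exposure_dataset("A", "personal", Inf), "finite")
  ds <- exposure_dataset("A", "personal", 0.0005, detection_limit = 0.001)
  expect_true(ds$below_detection)
  expect_equal(ds$concentration, 0.001)  # substitution at the DL surrogate
})

test_that("the shipped dossier file round-trips through the YAML reader", {
  path <- system.file("extdata", "biphenyl.yaml", package = "workrisk")
  d <- read_dossier(path)
  ref <- biphenyl_dossier()
  expect_equal(d$molecular_weight, ref$molecular_weight)
  expect_equal(d$oel_mgm3, ref$oel_mgm3)
  expect_equal(d$slope_factor, ref$slope_factor)
  expect_equal(sort(names(d$pods)), sort(names(ref$pods)))
  for (ep in names(ref$pods))
    expect_equal(d$pods[[ep]]$value, ref$pods[[ep]]$value)
  # the OEL pair is stored verbatim, not recomputed from MW
  expect_false(isTRUE(all.equal(d$oel_mgm3,
                                convert_ppm_to_mgm3(d$oel_ppm, d$molecular_weight))))
})
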