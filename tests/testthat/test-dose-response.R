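test_that("worker correction factor reproduces the published chain and is reciprocal", {
  expect_equal(signif_half_up(worker_correction_factor(), 2), 4.9)
  same <- reference_profile(15, 300, 45, 65)
  expect_equal(worker_correction_factor(same, same), 1)
  # halving only the inhalation volume doubles the factor
  expect_equal(worker_correction_factor(
    reference_profile(20, 365, 70, 70),
    worker_profile(10, 365, 70, 70)), 2)
  ref <- reference_profile(); wrk <- worker_profile()
  expect_equal(worker_correction_factor(ref, wrk) *
                 worker_correction_factor(wrk, ref), 1, tolerance = 1e-12)
  expect_error(worker_profile(exposure_days = 400), "365")
  expect_error(reference_profile(inhalation_volume = 0), "positive")
})

test_that("inhalation unit risk and workplace unit risk reproduce the published chain", {
  expect_equal(signif_half_up(iur_from_slope_factor(8.2e-3), 2), 2.3e-3)
  expect_equal(iur_from_slope_factor(0.5, reference_profile(70, 365, 70, 70)), 0.5)
  expect_equal(signif_half_up(iur_from_slope_factor(7e-2), 2), 2.0e-2)

  expect_equal(unit_risk_work(2.3e-3, 4.9)$ur_work, 4.7e-4)
  expect_equal(unit_risk_work(3.1e-5, 1)$ur_work, 3.1e-5)
  expect_equal(unit_risk_work(1e-2, 4)$ur_work, 2.5e-3)

  ur <- derive_unit_risk(8.2e-3)
  expect_equal(ur$iur, 2.3e-3)
  expect_equal(ur$cf, 4.9)
  expect_equal(ur$ur_work, 4.7e-4)
  audit <- attr(ur, "audit")
  expect_equal(audit$iur_raw, 8.2e-3 * 20 / 70, tolerance = 1e-12)
  expect_equal(audit$cf_raw, 2 * (365 / 260) * (70 / 40), tolerance = 1e-12)
})

test_that("duration bands select the longest matching factor", {
  expect_equal(duration_factor(104), 1)  # 2-year chronic study
  expect_equal(duration_factor(26), 1)
  expect_equal(duration_factor(13), 2)   # subchronic study
  expect_equal(duration_factor(9), 6)    # gestation-window study
  expect_equal(duration_factor(4), 6)
  expect_error(duration_factor(3), "shortest supported band")
  # schemas without a banding rule fall back to their table entry
  expect_equal(duration_factor(104, correction_schema("EPA")), 3)
  expect_equal(duration_factor(4, correction_schema("MHLW")), 1)
})

test_that("severity maps NOAEL/BMDL to 1 and LOAEL to 5", {
  expect_equal(severity_factor("BMDL"), 1)
  expect_equal(severity_factor("NOAEL"), 1)
  expect_equal(severity_factor("LOAEL"), 5)
})

test_that("route-to-route extrapolation converts oral PODs and passes inhalation through", {
  inh <- point_of_departure(157.75, "LOAEL", "inhalation", "inhalation_sto",
                            "mouse", 13)
  expect_equal(route_to_route(inh), 157.75)
  oral <- point_of_departure(23, "BMDL", "oral", "oral_sto", "rat", 104)
  expect_equal(route_to_route(oral, 2.78), 63.94)
  repro <- point_of_departure(20, "BMDL", "oral", "reproductive", "rat", 9)
  expect_equal(route_to_route(repro, 2.78), 55.6)
  expect_error(route_to_route(oral), "oral_to_air")
  expect_error(route_to_route(oral, NA), "oral_to_air")
})

test_that("RfC_work reproduces the three published biphenyl chains", {
  d <- biphenyl_dossier()
  # inhalation LOAEL: 157.75 x 0.5 / (3 x 5 x 2 x 5 x 1)
  inh <- rfc_work(d$pods$inhalation_sto, kosha)
  expect_equal(inh$rfc_work_raw, 157.75 * 0.5 / 150, tolerance = 1e-12)
  expect_equal(inh$rfc_work, 0.53)
  # oral BMDL, 2-year study: 23 x 2.78 x 0.5 / (3 x 5 x 1 x 1 x 1)
  oral <- rfc_work(d$pods$oral_sto, kosha)
  expect_equal(oral$rfc_work, 2.13)
  # reproductive BMDL, gestational study: 20 x 2.78 x 0.5 / (3 x 5 x 6)
  repro <- rfc_work(d$pods$reproductive, kosha)
  expect_equal(repro$rfc_work, 0.31)
})

test_that("the applied-factor audit trail reconstructs the unrounded RfC_work", {
  for (r in biphenyl_rfcs()) {
    f <- r$applied_factors
    recon <- r$pod$value *
      prod(f$value[f$op == "multiply"]) / prod(f$value[f$op == "divide"])
    expect_equal(recon, r$rfc_work_raw, tolerance = 1e-12)
    expect_true(all(f$value[f$op == "divide"] >= 1))
    expect_true(all(f$value[f$op == "multiply"] <= 2.78))
  }
})

test_that("RfC_work moves monotonically with the POD and each uncertainty divisor", {
  d <- biphenyl_dossier()
  for (pod in d$pods) {
    base <- rfc_work(pod, kosha)$rfc_work_raw
    bigger <- pod; bigger$value <- pod$value * 1.3
    expect_gt(rfc_work(bigger, kosha)$rfc_work_raw, base)
    for (uf in c("uf_interspecies", "uf_intraspecies", "uf_quality")) {
      harsher <- kosha; harsher[[uf]] <- kosha[[uf]] * 2
      expect_lt(rfc_work(pod, harsher)$rfc_work_raw, base)
    }
  }
})

test_that("the four agency schemas carry their published factor tables exactly", {
  expected <- list(
    KOSHA = c(0.5, 1, 3, 5, 2, 1, 1),
    EPA   = c(0.17, 1, 3, 10, 3, 1, 1),
    ECHA  = c(0.5, 1, 2.5, 5, 2, 1, 1),
    MHLW  = c(0.5, 1, 10, 1, 1, 1, 1))
  fields <- c("noael_adj", "noael_hec", "uf_interspecies", "uf_intraspecies",
              "uf_duration_default", "uf_severity_default", "uf_quality")
  for (ag in names(expected)) {
    sch <- correction_schema(ag)
    expect_identical(unname(vapply(fields, function(f) sch[[f]], numeric(1))),
                     expected[[ag]])
    expect_equal(unname(sch$severity_rule), c(1, 1, 5))
    expect_equal(sch$dose_scaling, 4)
  }
  expect_equal(unname(correction_schema("KOSHA")$duration_rule), c(1, 2, 6))
})

test_that("oral PODs under a schema with no conversion multiplier are a configuration error", {
  sch <- correction_schema("KOSHA", oral_to_air = NA)
  expect_error(rfc_work(biphenyl_dossier()$pods$oral_sto, sch), "oral_to_air")
  # inhalation PODs are unaffected
  expect_equal(rfc_work(biphenyl_dossier()$pods$inhalation_sto, sch)$rfc_work,
               0.53)
})
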