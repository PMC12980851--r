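test_that("JSON interchange round-trips to identical graphs", {
  gp <- make_patients(toy_model, 12, seed = 11, violation_rate = 0)
  doc <- bundles_to_json(gp$bundles, toy_model)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE)
  back <- ingest_json(txt, toy_model)
  expect_length(back, length(gp$bundles))
  for (k in seq_along(back)) {
    expect_true(quads_equal(
      bundle_to_quads(gp$bundles[[k]], toy_model, toy_policy),
      bundle_to_quads(back[[k]], toy_model, toy_policy)))
  }
})

test_that("tabular interchange round-trips to identical graphs", {
  gp <- make_patients(toy_model, 12, seed = 13, violation_rate = 0)
  tabs <- write_tabular(gp$bundles, toy_model)
  back <- ingest_tabular(tabs, toy_model)
  expect_length(back, length(gp$bundles))
  for (k in seq_along(back)) {
    expect_true(quads_equal(
      bundle_to_quads(gp$bundles[[k]], toy_model, toy_policy),
      bundle_to_quads(back[[k]], toy_model, toy_policy)))
  }
})

test_that("CSV files on disk round-trip through a directory", {
  gp <- make_patients(toy_model, 4, seed = 17, violation_rate = 0)
  dir <- tempfile("tabs-")
  write_tabular(gp$bundles, toy_model, dir)
  back <- ingest_tabular(dir, toy_model)
  expect_length(back, 4)
  expect_true(quads_equal(
    bundle_to_quads(gp$bundles[[1]], toy_model, toy_policy),
    bundle_to_quads(back[[1]], toy_model, toy_policy)))
})

test_that("schema-invalid JSON aborts with paths, or skips with reasons", {
  gp <- make_patients(toy_model, 3, seed = 19, violation_rate = 0)
  doc <- bundles_to_json(gp$bundles, toy_model)
  doc$patients[[2]]$hasAdministrativeSex <- NULL
  expect_error(ingest_json(doc, toy_model), "hasAdministrativeSex")
  got <- ingest_json(doc, toy_model, on_invalid = "skip")
  expect_length(got, 2)
  rej <- attr(got, "rejected")
  expect_equal(rej$patient, gp$bundles[[2]]$patient_local_id)
  expect_match(rej$reason, "required")
})

test_that("tabular ingestion rejects unknown and missing columns", {
  gp <- make_patients(toy_model, 2, seed = 23, violation_rate = 0)
  tabs <- write_tabular(gp$bundles, toy_model)
  t2 <- tabs; t2$subject$bogus <- "x"
  expect_error(ingest_tabular(t2, toy_model), "unknown column 'bogus'")
  t3 <- tabs; t3$subject$name <- NULL
  expect_error(ingest_tabular(t3, toy_model), "missing column 'name'")
})

test_that("enumerated-type misses quarantine the whole patient on tabular load", {
  gp <- make_patients(toy_model, 3, seed = 29, violation_rate = 0)
  tabs <- write_tabular(gp$bundles, toy_model)
  tabs$subject$administrative_sex[2] <- "sex-unknown"
  back <- ingest_tabular(tabs, toy_model)
  expect_length(back, 2)
  rej <- attr(back, "rejected")
  expect_equal(unique(rej$patient), gp$bundles[[2]]$patient_local_id)
  expect_match(rej$reason[1], "sex-unknown")
})

test_that("bundle structural checks name the patient and identifier", {
  b <- patient_bundle("p-1", list(
    instance_record("Subject", "p-1", list(hasAdministrativeSex = "sex-male"),
                    list(hasDiagnosis = "d-9"))))
  expect_error(check_bundle_structure(b, toy_model), "d-9")
  b2 <- patient_bundle("p-1", list(
    instance_record("Subject", "p-1", list(hasAdministrativeSex = "sex-male")),
    instance_record("Sample", "s-1"),
    instance_record("Sample", "s-1")))
  expect_error(check_bundle_structure(b2, toy_model), "s-1")
})

test_that("precheck routes malformed ids, enum misses and bad lexicals", {
  b <- patient_bundle("p 1", list(
    instance_record("Subject", "p 1",
                    list(hasAdministrativeSex = "sex-unknown",
                         hasBirthDate = "1980-13-40"))))
  pre <- precheck(b, toy_model)
  expect_setequal(pre$kind,
                  c("malformed_id", "bad_value_set", "bad_datatype"))
  # clean bundles produce no pre-check findings
  gp <- make_patients(toy_model, 5, seed = 31, violation_rate = 0)
  for (bb in gp$bundles) expect_equal(nrow(precheck(bb, toy_model)), 0)
})

test_that("precheck flags codes with whitespace as malformed", {
  b <- patient_bundle("p-1", list(
    instance_record("Subject", "p-1", list(hasAdministrativeSex = "sex-male"),
                    list(hasDiagnosis = "d-1")),
    instance_record("Diagnosis", "d-1",
                    list(hasCode = "https://example.org/toycodes/C 1"))))
  pre <- precheck(b, toy_model)
  expect_true("malformed_id" %in% pre$kind)
})
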