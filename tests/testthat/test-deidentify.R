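test_that("minted pseudonyms are well-formed version-4 UUIDs", {
  cfg <- deid_config(scramble_fields = list(c("Subject", "id")))
  log <- open_deid_log(config = cfg, seed = 5L)
  for (i in 1:50) {
    u <- pseudonymize_value(paste0("p-", i), c("Subject", "id"), cfg, log)
    expect_match(u,
      "^[0-9a-f]{8}-[0-9a-f]{4}-4[0-9a-f]{3}-[89ab][0-9a-f]{3}-[0-9a-f]{12}$")
  }
})

test_that("pseudonymization is consistent within and across deliveries", {
  cfg <- deid_config(scramble_fields = list(c("Subject", "id")),
                     project_salt = "salty")
  path <- tempfile("log-", fileext = ".json")
  log <- open_deid_log(path, "prj", cfg, seed = 7L)
  a1 <- pseudonymize_value("alice", c("Subject", "id"), cfg, log)
  b1 <- pseudonymize_value("bob", c("Subject", "id"), cfg, log)
  expect_equal(pseudonymize_value("alice", c("Subject", "id"), cfg, log), a1)
  save_deid_log(log)
  # second delivery replays the persisted log byte-identically
  log2 <- open_deid_log(path, "prj", cfg, seed = 99L)
  expect_equal(pseudonymize_value("alice", c("Subject", "id"), cfg, log2), a1)
  expect_equal(pseudonymize_value("bob", c("Subject", "id"), cfg, log2), b1)
})

test_that("unlisted selectors are refused", {
  cfg <- deid_config(scramble_fields = list(c("Subject", "id")))
  log <- open_deid_log(config = cfg)
  expect_error(pseudonymize_value("x", c("Sample", "id"), cfg, log),
               "not listed")
})

test_that("date offsets stay in range and replay per patient", {
  cfg <- deid_config(date_shift_range = c(-30L, 30L))
  log <- open_deid_log(config = cfg, seed = 3L)
  offs <- vapply(sprintf("p-%03d", 1:200), function(p)
    assign_date_offset(p, cfg, log), 0L)
  expect_true(all(offs >= -30 & offs <= 30))
  expect_equal(assign_date_offset("p-001", cfg, log), offs[["p-001"]])
})

test_that("date shifting preserves all pairwise day intervals", {
  gp <- make_patients(toy_model, 20, seed = 41, violation_rate = 0)
  cfg <- deid_config(date_shift_range = c(-30L, 30L))
  log <- open_deid_log(config = cfg, seed = 11L)
  collect_days <- function(b) {
    out <- numeric(0)
    for (r in b$records) {
      cd <- toy_model$concepts[[r$concept]]
      for (nm in names(r$fields)) {
        pd <- cd$properties[[nm]]
        if (pd$range_kind == "temporal") {
          out <- c(out, as.numeric(as.Date(substr(r$fields[[nm]], 1, 10))))
        }
      }
    }
    sort(out)
  }
  for (b in gp$bundles) {
    off <- assign_date_offset(b$patient_local_id, cfg, log)
    shifted <- deidentify_bundle(b, cfg, log, toy_model)
    d0 <- collect_days(b); d1 <- collect_days(shifted)
    expect_length(d1, length(d0))
    expect_equal(d1 - d0, rep(off, length(d0)))
    expect_equal(diff(d1), diff(d0))
  }
})

test_that("time of day survives the date shift", {
  b <- patient_bundle("p-1", list(
    instance_record("Subject", "p-1", list(hasAdministrativeSex = "sex-male"),
                    list(hasCase = "c-1")),
    instance_record("Admission", "c-1-admission",
                    list(hasAdmissionDatetime = "2020-05-01T13:45:59")),
    instance_record("AdministrativeCase", "c-1",
                    links = list(hasAdmission = "c-1-admission"))))
  shifted <- shift_dates(b, 10L, toy_model)
  adm <- find_record(shifted, "Admission", "c-1-admission")
  expect_equal(adm$fields$hasAdmissionDatetime[[1]], "2020-05-11T13:45:59")
})

test_that("identifier scrambling remaps links and the patient id coherently", {
  gp <- make_patients(toy_model, 5, seed = 43, violation_rate = 0)
  cfg <- default_deid()
  log <- open_deid_log(config = cfg, seed = 13L)
  for (b in gp$bundles) {
    d <- deidentify_bundle(b, cfg, log, toy_model)
    expect_false(d$patient_local_id == b$patient_local_id)
    expect_silent(check_bundle_structure(d, toy_model))
    # graph shape is preserved exactly (clean bundles stay clean)
    q <- bundle_to_quads(d, toy_model, toy_policy)
    expect_equal(nrow(as.data.frame(q)), oracle_quad_count(b))
    rep <- shacl_validate(q, gen_shacl(toy_model), list(toy$terminology),
                          toy_model)
    expect_true(rep$conforms)
  }
})

test_that("substitution rules support value lists and regexes", {
  b <- patient_bundle("p-1", list(
    instance_record("Subject", "p-1",
                    list(hasAdministrativeSex = "sex-male",
                         hasName = "Anna Keller"))))
  by_value <- substitute_values(b, list(
    list(values = list("Anna Keller"), replacement = "PERSON")))
  expect_equal(find_record(by_value, "Subject", "p-1")$fields$hasName[[1]],
               "PERSON")
  by_regex <- substitute_values(b, list(
    list(pattern = "Anna", replacement = "X")))
  expect_equal(find_record(by_regex, "Subject", "p-1")$fields$hasName[[1]],
               "X Keller")
})

test_that("logging-disabled mode refuses persistence and replay", {
  cfg <- deid_config(logging_enabled = FALSE)
  log <- open_deid_log(config = cfg)
  expect_error(save_deid_log(log, tempfile()), "disabled")
  path <- tempfile(fileext = ".json")
  ok_cfg <- deid_config()
  log2 <- open_deid_log(path, "p", ok_cfg)
  save_deid_log(log2)
  expect_error(open_deid_log(path, "p", cfg), "disabled")
})

test_that("the de-identification RNG stream leaves the global RNG untouched", {
  cfg <- deid_config(scramble_fields = list(c("Subject", "id")))
  log <- open_deid_log(config = cfg, seed = 21L)
  set.seed(123)
  expected <- stats::runif(2)[2]
  set.seed(123)
  invisible(stats::runif(1))
  invisible(pseudonymize_value("v", c("Subject", "id"), cfg, log))
  expect_equal(stats::runif(1), expected)
})

test_that("config validation rejects malformed settings", {
  expect_error(deid_config(date_shift_range = c(5L, -5L)), "lo <= hi")
  expect_error(deid_config(substitutions = list(list(replacement = "x"))),
               "values")
  expect_error(deid_config(substitutions = list(
    list(pattern = "(", replacement = "x"))), "pattern")
})
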