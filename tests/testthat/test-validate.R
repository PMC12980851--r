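mk_quads <- function(bundle) bundle_to_quads(bundle, toy_model, toy_policy)
toy_shapes <- gen_shacl(toy_model)

validate_b <- function(bundle) {
  shacl_validate(mk_quads(bundle), toy_shapes, list(toy$terminology),
                 toy_model, bundle$patient_local_id)
}

base_bundle <- function(...) {
  extra <- list(...)
  subj <- instance_record("Subject", "p-1",
                          list(hasAdministrativeSex = "sex-male"),
                          list(hasCase = "c-1"))
  adm <- instance_record("Admission", "a-1",
                         list(hasAdmissionDatetime = "2020-01-01T08:00:00",
                              hasDischargeDatetime = "2020-01-05T10:00:00"))
  case <- instance_record("AdministrativeCase", "c-1",
                          links = list(hasAdmission = "a-1"))
  patient_bundle("p-1", c(list(subj, adm, case), extra))
}

test_that("a well-formed bundle conforms", {
  rep <- validate_b(base_bundle())
  expect_true(rep$conforms)
  expect_equal(nrow(rep$findings), 0)
})

test_that("missing mandatory values raise min_count findings", {
  b <- base_bundle()
  b$records[[1]]$fields$hasAdministrativeSex <- NULL
  rep <- validate_b(b)
  expect_false(rep$conforms)
  expect_equal(rep$findings$constraint_kind, "min_count")
  expect_equal(rep$findings$property, "hasAdministrativeSex")
})

test_that("cardinality overruns raise max_count findings", {
  b <- base_bundle()
  b$records[[2]]$fields$hasAdmissionDatetime <-
    c("2020-01-01T08:00:00", "2020-01-02T08:00:00")
  rep <- validate_b(b)
  expect_true("max_count" %in% rep$findings$constraint_kind)
})

test_that("malformed temporal lexicals raise datatype findings", {
  b <- base_bundle()
  b$records[[2]]$fields$hasDischargeDatetime <- "not-a-timestamp"
  rep <- validate_b(b)
  expect_equal(rep$findings$constraint_kind, "datatype")
  expect_equal(rep$findings$property, "hasDischargeDatetime")
})

test_that("unknown terminology codes raise terminology findings", {
  d <- instance_record("Diagnosis", "d-1",
                       list(hasCode = "https://example.org/toycodes/C999"))
  b <- base_bundle(d)
  b$records[[1]]$links$hasDiagnosis <- "d-1"
  rep <- validate_b(b)
  expect_equal(rep$findings$constraint_kind, "terminology")
  expect_equal(rep$findings$property, "hasCode")
  # a known code passes
  b$records[[4]]$fields$hasCode <- "https://example.org/toycodes/C05"
  expect_true(validate_b(b)$conforms)
})

test_that("shapes from a different schema version are refused", {
  other <- sub('hkg:schemaPrefix "toy"', 'hkg:schemaPrefix "toy2"',
               toy$schema, fixed = TRUE)
  stale <- gen_shacl(parse_schema(other))
  expect_error(
    shacl_validate(mk_quads(base_bundle()), stale, list(), toy_model),
    "schema version")
})

test_that("start-after-end instances are flagged exactly once each", {
  b <- base_bundle()
  b$records[[2]]$fields$hasAdmissionDatetime <- "2020-02-01T08:00:00"
  lg <- logic_check_dates(mk_quads(b), toy_model)
  expect_equal(nrow(lg), 1)
  expect_equal(lg$constraint_kind, "start_after_end")
})

test_that("start equal to end produces no finding", {
  b <- base_bundle()
  b$records[[2]]$fields$hasAdmissionDatetime <- "2020-01-05T10:00:00"
  expect_equal(nrow(logic_check_dates(mk_quads(b), toy_model)), 0)
})

test_that("the interval verdict is invariant under date shifting", {
  bad <- base_bundle()
  bad$records[[2]]$fields$hasAdmissionDatetime <- "2020-02-01T08:00:00"
  good <- base_bundle()
  for (off in c(-30L, -1L, 1L, 30L)) {
    expect_equal(nrow(logic_check_dates(
      mk_quads(shift_dates(bad, off, toy_model)), toy_model)), 1)
    expect_equal(nrow(logic_check_dates(
      mk_quads(shift_dates(good, off, toy_model)), toy_model)), 0)
  }
})

test_that("completeness statistics count instances and filled properties", {
  d <- instance_record("Diagnosis", "d-1",
                       list(hasCode = "https://example.org/toycodes/C02"))
  b <- base_bundle(d)
  b$records[[1]]$links$hasDiagnosis <- "d-1"
  cs <- completeness_stats(mk_quads(b), toy_model)
  n_of <- function(concept, property) {
    if (is.na(property)) {
      cs$count[cs$concept == concept & is.na(cs$property)]
    } else {
      cs$count[cs$concept == concept & !is.na(cs$property) &
                 cs$property == property]
    }
  }
  expect_equal(n_of("Subject", NA), 1)
  expect_equal(n_of("Diagnosis", NA), 1)
  expect_equal(n_of("Diagnosis", "hasCode"), 1)
  expect_equal(n_of("Diagnosis", "hasRecordDatetime"), 0)
  expect_equal(n_of("Admission", "hasDischargeDatetime"), 1)
})

test_that("plausibility is out of scope: schema-valid extremes conform", {
  # an implausible but schema-valid value must not produce findings
  ttl <- '@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
@prefix hkg: <https://w3id.org/healthkg/dialect#> .
@prefix ex: <http://obs/> .
ex:o a owl:Ontology ; hkg:schemaPrefix "obs" .
ex:Subject a owl:Class ; hkg:isSubject true .
ex:BloodPressure a owl:Class .
ex:hasBloodPressure a owl:ObjectProperty ; rdfs:domain ex:Subject ;
  rdfs:range ex:BloodPressure ; hkg:minCount 0 ; hkg:maxCount "unbounded" .
ex:hasSystolicPressure a owl:DatatypeProperty ; rdfs:domain ex:BloodPressure ;
  rdfs:range xsd:double ; hkg:minCount 1 ; hkg:maxCount 1 .
'
  m <- parse_schema(ttl)
  pol <- iri_policy("CHE-1", m$schema_prefix)
  b <- patient_bundle("p-1", list(
    instance_record("Subject", "p-1", links = list(hasBloodPressure = "bp-1")),
    instance_record("BloodPressure", "bp-1",
                    list(hasSystolicPressure = "300"))))
  expect_equal(nrow(precheck(b, m)), 0)
  rep <- shacl_validate(bundle_to_quads(b, m, pol), gen_shacl(m), list(), m)
  expect_true(rep$conforms)
  expect_equal(nrow(rep$findings), 0)
})
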