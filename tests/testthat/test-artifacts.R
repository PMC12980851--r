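test_that("JSON Schema derivation covers the model with closed objects", {
  js <- gen_json_schema(toy_model)
  pat <- js$definitions$Patient
  expect_false(isTRUE(pat$additionalProperties))
  expect_setequal(unlist(pat$required), c("id", "hasAdministrativeSex"))
  expect_setequal(unlist(pat$properties$hasAdministrativeSex$enum),
                  c("sex-male", "sex-female", "sex-other"))
  expect_equal(pat$properties$hasBirthDate$format, "date")
  expect_equal(pat$properties$hasDiagnosis$items[["$ref"]],
               "#/definitions/Diagnosis")
  # terminology-backed codes are plain strings at the interchange layer
  expect_equal(js$definitions$Diagnosis$properties$hasCode$type, "string")
  expect_null(js$definitions$Diagnosis$properties$hasCode$enum)
  # embedded Admission appears inline under AdministrativeCase
  adm <- js$definitions$AdministrativeCase$properties$hasAdmission
  expect_equal(adm[["$ref"]], "#/definitions/Admission")
})

test_that("JSON Schema evaluator agrees with a hand-written mini oracle", {
  # independent mini-schema written by hand, not derived from the model
  mini <- list(
    type = "object", additionalProperties = FALSE,
    required = list("id", "sex"),
    properties = list(
      id = list(type = "string", pattern = "^[A-Za-z0-9._~-]+$"),
      sex = list(type = "string",
                 enum = list("sex-male", "sex-female", "sex-other")),
      born = list(type = "string", format = "date")))
  good <- list(id = "p-1", sex = "sex-male", born = "1980-02-29")
  expect_equal(nrow(validate_json(good, mini)), 0)
  bad <- list(id = "p 1", sex = "sex-unknown", born = "1980-13-01",
              extra = "x")
  errs <- validate_json(bad, mini)
  expect_true(any(grepl("pattern", errs$message)))
  expect_true(any(grepl("permitted set", errs$message)))
  expect_true(any(grepl("date", errs$message)))
  expect_true(any(grepl("unknown property", errs$message)))
  expect_equal(nrow(validate_json(list(sex = "sex-male"), mini)), 1)
})

test_that("embedded concepts flatten into prefixed owner-table columns", {
  t <- gen_tabular_templates(toy_model)
  case_cols <- t$tables$administrative_case$column_name
  expect_true("admission_admission_datetime" %in% case_cols)
  expect_true("admission_discharge_datetime" %in% case_cols)
  expect_false("admission" %in% names(t$tables))
  # core concepts each get their own table, keyed by patient and instance
  expect_setequal(names(t$tables),
                  c("subject", "diagnosis", "administrative_case", "sample"))
  for (df in t$tables) {
    expect_equal(df$column_name[1:2], c("patient_id", "id"))
  }
  # core links become foreign-key columns
  diag <- t$tables$diagnosis
  expect_equal(diag$references[diag$column_name == "administrative_case_id"],
               "administrative_case")
})

test_that("every model property is covered exactly once by the templates", {
  t <- gen_tabular_templates(toy_model)
  want <- do.call(rbind, lapply(toy_model$concepts, function(cd)
    data.frame(concept = cd$name, property = names(cd$properties),
               stringsAsFactors = FALSE)))
  got <- t$coverage[, c("concept", "property")]
  expect_equal(nrow(got), nrow(unique(got)))
  expect_setequal(paste(want$concept, want$property),
                  paste(got$concept, got$property))
})

test_that("DDL carries NOT NULL, CHECK enumerations and primary keys", {
  t <- gen_tabular_templates(toy_model)
  expect_match(t$ddl, "administrative_sex VARCHAR NOT NULL")
  expect_match(t$ddl,
               "CHECK \\(administrative_sex IN \\('sex-male', 'sex-female', 'sex-other'\\)\\)")
  expect_match(t$ddl, "PRIMARY KEY \\(patient_id, id\\)")
  expect_match(t$ddl, "admission_admission_datetime TIMESTAMP NOT NULL")
  # CSV headers mirror the table columns
  expect_equal(unname(t$headers[["subject"]]),
               paste(t$tables$subject$column_name, collapse = ","))
})

test_that("column collisions abort template generation with both property names", {
  ttl <- '@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
@prefix hkg: <https://w3id.org/healthkg/dialect#> .
@prefix ex: <http://e/> .
ex:o a owl:Ontology ; hkg:schemaPrefix "t" .
ex:A a owl:Class ; hkg:isSubject true .
ex:hasValue a owl:DatatypeProperty ; rdfs:domain ex:A ; rdfs:range xsd:string .
ex:value a owl:DatatypeProperty ; rdfs:domain ex:A ; rdfs:range xsd:string .
'
  m <- parse_schema(ttl)
  expect_error(gen_tabular_templates(m), "collision")
})

test_that("generated shapes describe every property and embed the model digest", {
  shp <- gen_shacl(toy_model)
  parsed <- healthkg:::read_shapes(shp)
  expect_equal(parsed$digest, healthkg:::model_digest(toy_model))
  per_concept <- vapply(parsed$shapes, function(s) length(s$properties), 0L)
  expect_equal(sum(per_concept),
               sum(vapply(toy_model$concepts,
                          function(cd) length(cd$properties), 0L)))
  # each property appears exactly once across all property shapes
  paths <- unlist(lapply(parsed$shapes, function(s)
    vapply(s$properties, function(p) p$path, "")))
  all_props <- unlist(lapply(toy_model$concepts, function(cd)
    vapply(cd$properties, function(p) p$iri, "")))
  expect_equal(sort(unname(paths)), sort(unname(all_props)))
})

test_that("generated and hand-written oracle shapes give identical verdicts", {
  gen <- gen_shacl(toy_model)
  gp <- make_patients(toy_model, 40, seed = 61, violation_rate = 0.3)
  for (b in gp$bundles) {
    if (nrow(precheck(b, toy_model)) > 0) next  # blocked before validation
    q <- bundle_to_quads(b, toy_model, toy_policy)
    r_gen <- shacl_validate(q, gen, list(toy$terminology), toy_model)
    r_orc <- shacl_validate(q, toy$oracle_shapes, list(toy$terminology))
    expect_equal(r_gen$conforms, r_orc$conforms)
    expect_equal(
      sort(paste(r_gen$findings$focus_node, r_gen$findings$constraint_kind)),
      sort(paste(r_orc$findings$focus_node, r_orc$findings$constraint_kind)))
  }
})
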