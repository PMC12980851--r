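test_that("minted IRIs follow the four-part convention", {
  pol <- iri_policy("CHE-111.222.333", "toy", "https://kg.example.org/data")
  iri <- mint_iri(pol, "Subject", "p-0001")
  expect_equal(iri,
    "https://kg.example.org/data/CHE-111.222.333/toy/Subject/p-0001")
  expect_error(mint_iri(pol, "Subject", "p 1"), "invalid")
  expect_error(mint_iri(pol, "Subject", ""), "invalid|id")
  expect_error(iri_policy("has space", "toy"), "IRI-safe")
})

test_that("quad counts match the record/field/link scan oracle", {
  gp <- make_patients(toy_model, 25, seed = 47, violation_rate = 0)
  for (b in gp$bundles) {
    q <- bundle_to_quads(b, toy_model, toy_policy)
    expect_equal(nrow(as.data.frame(q)), oracle_quad_count(b))
  }
})

test_that("every quad of a patient carries that patient's graph IRI", {
  gp <- make_patients(toy_model, 5, seed = 53, violation_rate = 0)
  for (b in gp$bundles) {
    q <- as.data.frame(bundle_to_quads(b, toy_model, toy_policy))
    g <- healthkg:::patient_graph_iri(toy_policy, toy_model,
                                      b$patient_local_id)
    expect_equal(unique(q$graph), g)
    expect_match(g, paste0("/Subject/", b$patient_local_id, "$"))
  }
})

test_that("field kinds map to the right term kinds", {
  b <- patient_bundle("p-1", list(
    instance_record("Subject", "p-1",
                    list(hasAdministrativeSex = "sex-female",
                         hasBirthDate = "1980-01-02"),
                    list(hasDiagnosis = "d-1", hasSample = "s-1")),
    instance_record("Diagnosis", "d-1",
                    list(hasCode = "https://example.org/toycodes/C03")),
    instance_record("Sample", "s-1",
                    shared = list(hasSharedIdentifier = "BIO-000042"))))
  q <- as.data.frame(bundle_to_quads(b, toy_model, toy_policy))
  ex <- function(p) paste0("https://example.org/toy#", p)
  # inline value-set member becomes the member IRI
  sex <- q[q$p == ex("hasAdministrativeSex"), ]
  expect_equal(sex$o, ex("sex-female"))
  expect_equal(sex$o_kind, "iri")
  # temporal value becomes a typed literal
  bd <- q[q$p == ex("hasBirthDate"), ]
  expect_equal(bd$o_kind, "literal")
  expect_equal(bd$dtype, "http://www.w3.org/2001/XMLSchema#date")
  # terminology code is an object IRI
  code <- q[q$p == ex("hasCode"), ]
  expect_equal(code$o_kind, "iri")
  # shared identifier bypasses minting and stays a plain literal
  shared <- q[q$p == ex("hasSharedIdentifier"), ]
  expect_equal(shared$o, "BIO-000042")
  expect_equal(shared$o_kind, "literal")
  # links point at minted IRIs
  lk <- q[q$p == ex("hasDiagnosis"), ]
  expect_equal(lk$o, mint_iri(toy_policy, "Diagnosis", "d-1"))
})

test_that("transformation refuses dangling links and unknown members", {
  b <- patient_bundle("p-1", list(
    instance_record("Subject", "p-1",
                    list(hasAdministrativeSex = "sex-male"),
                    list(hasDiagnosis = "missing"))))
  expect_error(bundle_to_quads(b, toy_model, toy_policy), "missing")
  b2 <- patient_bundle("p-1", list(
    instance_record("Subject", "p-1",
                    list(hasAdministrativeSex = "sex-nope"))))
  expect_error(bundle_to_quads(b2, toy_model, toy_policy), "member")
})

test_that("an empty bundle transforms to an empty quadset", {
  q <- bundle_to_quads(patient_bundle("p-1"), toy_model, toy_policy)
  expect_equal(nrow(as.data.frame(q)), 0)
})

test_that("serialized patient graphs are valid per an independent RDF stack", {
  gp <- make_patients(toy_model, 3, seed = 59, violation_rate = 0)
  q <- bundle_to_quads(gp$bundles[[1]], toy_model, toy_policy)
  n_expected <- nrow(as.data.frame(q))
  dir <- tempfile("oracle-"); dir.create(dir)
  writeLines(serialize_quads(q, "trig"), file.path(dir, "g.trig"))
  writeLines(serialize_quads(q, "nquads"), file.path(dir, "g.nq"))
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import sys, rdflib",
    "a = rdflib.Dataset(); a.parse(sys.argv[1], format='trig')",
    "b = rdflib.Dataset(); b.parse(sys.argv[2], format='nquads')",
    "qa = set(a.quads()); qb = set(b.quads())",
    "assert qa == qb, 'trig and nquads disagree'",
    "print(len(qa))"), script)
  out <- suppressWarnings(system2("python3",
    c(script, file.path(dir, "g.trig"), file.path(dir, "g.nq")),
    stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0)
  expect_equal(as.integer(out[length(out)]), n_expected)
})
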