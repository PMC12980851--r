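# Shared fixtures and small independent oracles used across the test files.

toy <- make_toy_schema()
toy_model <- parse_schema(toy$schema)
toy_policy <- iri_policy("CHE-123.456.789", toy_model$schema_prefix)

# Independent oracle: expected quad count of a bundle from a generic scan of
# its records (records + field/shared values + link values).
oracle_quad_count <- function(bundle) {
  n_fields <- sum(vapply(bundle$records, function(r)
    length(unlist(r$fields)) + length(unlist(r$shared)), 0))
  n_links <- sum(vapply(bundle$records, function(r)
    length(unlist(r$links)), 0))
  length(bundle$records) + n_fields + n_links
}

# Independent oracle: core concepts by a generic one-hop graph traversal of
# the raw schema triples (subject class plus ranges of its object properties
# that are declared classes).
oracle_core_concepts <- function(schema_text) {
  q <- as.data.frame(parse_quads(schema_text, "turtle"))
  hkg <- "https://w3id.org/healthkg/dialect#"
  rdfs <- "http://www.w3.org/2000/01/rdf-schema#"
  classes <- q$s[q$p == paste0(rdf_ns(), "type") &
                   q$o == "http://www.w3.org/2002/07/owl#Class"]
  subject <- q$s[q$p == paste0(hkg, "isSubject") & q$o == "true"]
  subj_props <- q$s[q$p == paste0(rdfs, "domain") & q$o == subject]
  hop <- q$o[q$s %in% subj_props & q$p == paste0(rdfs, "range")]
  sort(unname(vapply(intersect(c(subject, hop), classes),
                     function(iri) sub("^.*[#/]", "", iri), "")))
}

rdf_ns <- function() "http://www.w3.org/1999/02/22-rdf-syntax-ns#"

make_project_dir <- function() {
  root <- tempfile("kgprj-")
  on.exit(NULL)
  root
}

default_deid <- function(salt = "unit-salt") {
  deid_config(
    scramble_fields = list(c("Subject", "id"), c("Diagnosis", "id"),
                           c("AdministrativeCase", "id"), c("Admission", "id"),
                           c("Sample", "id")),
    date_shift_range = c(-30L, 30L),
    substitutions = list(list(pattern = "^[A-Z][a-z]+ [A-Z][a-z]+$",
                              replacement = "REDACTED")),
    project_salt = salt)
}

# Map from validation constraint kinds to the generator's injection kinds.
CONSTRAINT_TO_INJECTION <- c(min_count = "missing_mandatory",
                             value_set = "bad_value_set",
                             datatype = "bad_datatype",
                             terminology = "unknown_code",
                             start_after_end = "start_after_end")

# Detected (patient, violation_kind) pairs of a processed project: quarantine
# reasons plus constraint kinds of non-conforming released reports.
detected_violations <- function(project) {
  rows <- list()
  for (e in quarantine_entries(project)) {
    for (k in unique(e$findings$kind)) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient = e$patient, violation_kind = k, stringsAsFactors = FALSE)
    }
  }
  for (r in release_reports(project)) {
    if (!isTRUE(r$conforms)) {
      for (k in unique(r$findings$constraint_kind)) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient = r$patient_id,
          violation_kind = unname(CONSTRAINT_TO_INJECTION[k]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(patient = character(), violation_kind = character(),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, rows))
}
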