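# Project-scoped zone pipeline: Landing -> (pre-check) -> De-identification ->
# Transformation -> Validation -> Release, with a Quarantine zone for patients
# blocked before transformation. Every project lives under its own root
# directory; nothing is shared between projects.

ZONE_DIRS <- c("zones/landing", "zones/release", "zones/quarantine",
               "artifacts", "artifacts/headers", "terminology", "logs")

graph_ext <- function(format) {
  switch(format, trig = "trig", nquads = "nq",
         stop("unsupported graph format '", format, "'", call. = FALSE))
}

read_text_arg <- function(x) {
  # accept either literal text (contains a newline or prefix decl) or a path
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
}

#' Create a knowledge-graph project
#'
#' Sets up the project directory (artifact store, Landing/Release/Quarantine
#' zones, terminology store, logs), parses the schema, derives all ingestion
#' and validation artifacts from it (JSON Schema, SQL DDL, CSV header
#' templates, shapes graph) and writes them under `artifacts/`.
#'
#' @param root Project root directory (created; must not already contain a
#'   project).
#' @param project_id Project identifier.
#' @param schema Schema document: Turtle text or a file path.
#' @param provider_uid Data-provider identifier used in minted IRIs.
#' @param base_iri Base IRI of the naming convention.
#' @param format Serialization of released patient graphs (`"trig"` or
#'   `"nquads"`).
#' @param deid Optional [deid_config()]; `NULL` disables de-identification.
#' @param terminologies List of terminology graphs (Turtle text or paths)
#'   declaring permitted codes.
#' @param overwrite Refuse to reuse a non-empty root unless `TRUE`.
#' @return A `kg_project` object (see [load_project()]).
#' @export
create_project <- function(root, project_id, schema, provider_uid,
                           base_iri = DEFAULT_BASE_IRI, format = "trig",
                           deid = NULL, terminologies = list(),
                           overwrite = FALSE) {
  graph_ext(format)  # validates the format early
  if (file.exists(file.path(root, "config.json")) && !overwrite) {
    stop("project error: '", root, "' already contains a project",
         call. = FALSE)
  }
  if (!is.null(deid) && !inherits(deid, "deid_config")) {
    stop("project error: `deid` must be a deid_config or NULL", call. = FALSE)
  }
  for (d in ZONE_DIRS) {
    dir.create(file.path(root, d), recursive = TRUE, showWarnings = FALSE)
  }
  schema_text <- read_text_arg(schema)
  model <- parse_schema(schema_text)
  policy <- iri_policy(provider_uid, model$schema_prefix, base_iri)

  writeLines(schema_text, file.path(root, "artifacts", "schema.ttl"))
  jsonlite::write_json(gen_json_schema(model),
                       file.path(root, "artifacts", "json_schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  tmpl <- gen_tabular_templates(model)
  writeLines(tmpl$ddl, file.path(root, "artifacts", "ddl.sql"))
  for (tname in names(tmpl$headers)) {
    writeLines(tmpl$headers[[tname]],
               file.path(root, "artifacts", "headers",
                         paste0(tname, ".csv")))
  }
  writeLines(gen_shacl(model), file.path(root, "artifacts", "shapes.ttl"))
  for (i in seq_along(terminologies)) {
    writeLines(read_text_arg(terminologies[[i]]),
               file.path(root, "terminology", sprintf("term-%02d.ttl", i)))
  }

  cfg <- list(project_id = project_id, provider_uid = provider_uid,
              base_iri = base_iri, format = format,
              deid = if (is.null(deid)) NULL else unclass(deid))
  jsonlite::write_json(cfg, file.path(root, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  load_project(root)
}

#' Load an existing project from its root directory
#'
#' @param root Project root created by [create_project()].
#' @return A `kg_project` list: configuration, parsed `model`, IRI `policy`,
#'   shapes text, terminology texts and zone paths.
#' @export
load_project <- function(root) {
  cfg_path <- file.path(root, "config.json")
  if (!file.exists(cfg_path)) {
    stop("project error: no project found under '", root, "'", call. = FALSE)
  }
  cfg <- jsonlite::fromJSON(cfg_path, simplifyVector = FALSE)
  model <- parse_schema(read_text_arg(file.path(root, "artifacts",
                                                "schema.ttl")))
  deid <- NULL
  if (!is.null(cfg$deid)) {
    d <- cfg$deid
    deid <- deid_config(
      scramble_fields = lapply(d$scramble_fields, as.character),
      date_shift_range = as.integer(unlist(d$date_shift_range)),
      substitutions = lapply(d$substitutions, function(r)
        lapply(r, function(v) as.character(unlist(v)))),
      logging_enabled = isTRUE(d$logging_enabled),
      project_salt = as.character(d$project_salt))
  }
  term_files <- sort(list.files(file.path(root, "terminology"),
                                pattern = "\\.ttl$", full.names = TRUE))
  structure(list(
    root = root, project_id = cfg$project_id, format = cfg$format,
    model = model,
    policy = iri_policy(cfg$provider_uid, model$schema_prefix, cfg$base_iri),
    shapes = read_text_arg(file.path(root, "artifacts", "shapes.ttl")),
    terminologies = lapply(term_files, read_text_arg),
    deid = deid,
    landing = file.path(root, "zones", "landing"),
    release = file.path(root, "zones", "release"),
    quarantine = file.path(root, "zones", "quarantine"),
    deid_log_path = file.path(root, "logs", "deid_log.json")
  ), class = "kg_project")
}

#' @export
print.kg_project <- function(x, ...) {
  s <- project_status(x)
  cat("<kg_project> ", x$project_id, " at ", x$root, "\n",
      "  schema prefix: ", x$model$schema_prefix,
      "; format: ", x$format,
      "; de-identification: ", if (is.null(x$deid)) "off" else "on", "\n",
      "  landing: ", s$landing, "  released: ", s$released,
      "  quarantined: ", s$quarantined, "\n", sep = "")
  invisible(x)
}

# --- landing ------------------------------------------------------------------

bundle_to_list <- function(bundle) {
  list(patient_local_id = bundle$patient_local_id,
       records = lapply(bundle$records, function(r)
         list(concept = r$concept, id = r$id,
              fields = lapply(r$fields, as.list),
              links = lapply(r$links, as.list),
              shared = lapply(r$shared, as.list))))
}

bundle_from_list <- function(x) {
  patient_bundle(x$patient_local_id, lapply(x$records, function(r)
    instance_record(r$concept, r$id,
                    fields = lapply(r$fields, function(v) as.character(unlist(v))),
                    links = lapply(r$links, function(v) as.character(unlist(v))),
                    shared = lapply(r$shared, function(v) as.character(unlist(v))))))
}

landing_path <- function(project, patient_local_id) {
  file.path(project$landing, paste0(patient_local_id, ".json"))
}

#' Place patient bundles in the Landing zone
#'
#' Writes each bundle as a normalized intermediate JSON document named after
#' the patient. Existing documents for the same patient are replaced, which
#' is how corrected deliveries enter the pipeline.
#'
#' @param project A `kg_project`.
#' @param bundles List of `patient_bundle` objects.
#' @return Invisibly, the written file paths.
#' @export
land_bundles <- function(project, bundles) {
  paths <- vapply(bundles, function(b) {
    p <- landing_path(project, b$patient_local_id)
    jsonlite::write_json(bundle_to_list(b), p, auto_unbox = TRUE,
                         pretty = TRUE)
    p
  }, "")
  invisible(paths)
}

#' Ingest an interchange document into the Landing zone
#'
#' Accepts either a JSON document (validated against the project's derived
#' JSON Schema) or tabular data (validated against the derived templates).
#' Patients failing input validation are quarantined with a machine-readable
#' reason; the rest land normally.
#'
#' @param project A `kg_project`.
#' @param json JSON text/path (exclusive with `tables`).
#' @param tables Named list of data frames or a CSV directory.
#' @return Data frame with one row per patient: `patient`, `status`
#'   (`"landed"` or `"quarantined"`).
#' @export
land_delivery <- function(project, json = NULL, tables = NULL) {
  if (is.null(json) == is.null(tables)) {
    stop("provide exactly one of `json` or `tables`", call. = FALSE)
  }
  bundles <- if (!is.null(json)) {
    ingest_json(json, project$model, on_invalid = "skip")
  } else {
    ingest_tabular(tables, project$model)
  }
  rejected <- attr(bundles, "rejected")
  rows <- list()
  if (!is.null(rejected) && nrow(rejected) > 0) {
    for (p in unique(rejected$patient)) {
      reasons <- rejected[rejected$patient == p, , drop = FALSE]
      write_quarantine(project, p, "input_validation", reasons)
      rows[[length(rows) + 1L]] <- data.frame(
        patient = p, status = "quarantined", stringsAsFactors = FALSE)
    }
  }
  land_bundles(project, bundles)
  for (b in bundles) {
    rows[[length(rows) + 1L]] <- data.frame(
      patient = b$patient_local_id, status = "landed",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# --- quarantine ---------------------------------------------------------------

write_quarantine <- function(project, patient, stage, findings) {
  jsonlite::write_json(
    list(patient = patient, stage = stage, findings = findings),
    file.path(project$quarantine, paste0(patient, ".json")),
    auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
}

#' Read quarantine entries
#'
#' @param project A `kg_project`.
#' @return List of entries (`patient`, `stage`, `findings` data frame).
#' @export
quarantine_entries <- function(project) {
  files <- sort(list.files(project$quarantine, pattern = "\\.json$",
                           full.names = TRUE))
  lapply(files, function(f) {
    x <- jsonlite::fromJSON(f, simplifyVector = TRUE)
    x$findings <- as.data.frame(x$findings, stringsAsFactors = FALSE)
    x
  })
}

# --- processing ---------------------------------------------------------------

release_paths <- function(project, released_id) {
  base <- file.path(project$release, released_id)
  list(graph = paste0(base, ".", graph_ext(project$format)),
       report = paste0(base, ".report.json"))
}

process_one <- function(project, bundle, log) {
  model <- project$model
  original_pid <- bundle$patient_local_id

  quarantine <- function(stage, findings) {
    write_quarantine(project, original_pid, stage, findings)
    data.frame(patient = original_pid, status = "quarantined",
               conforms = NA, n_findings = nrow(findings),
               graph = NA_character_, stringsAsFactors = FALSE)
  }

  structural <- tryCatch({
    check_bundle_structure(bundle, model)
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(structural)) {
    return(quarantine("structure", data.frame(
      kind = "structural", concept = NA, property = NA, value = NA,
      message = structural, stringsAsFactors = FALSE)))
  }

  pre <- precheck(bundle, model)
  if (nrow(pre) > 0) return(quarantine("precheck", pre))

  if (!is.null(project$deid)) {
    bundle <- deidentify_bundle(bundle, project$deid, log, model)
  }

  quads <- tryCatch(bundle_to_quads(bundle, model, project$policy),
                    error = function(e) conditionMessage(e))
  if (is.character(quads)) {
    return(quarantine("transformation", data.frame(
      kind = "transformation", concept = NA, property = NA, value = NA,
      message = quads, stringsAsFactors = FALSE)))
  }

  report <- shacl_validate(quads, project$shapes, project$terminologies,
                           model, patient_id = bundle$patient_local_id)
  logic <- logic_check_dates(quads, model)
  findings <- rbind(report$findings, logic)
  conforms <- nrow(findings) == 0

  graph <- patient_graph_iri(project$policy, model, bundle$patient_local_id)
  paths <- release_paths(project, bundle$patient_local_id)
  writeLines(serialize_quads(quads, project$format), paths$graph)
  jsonlite::write_json(list(
    patient_id = bundle$patient_local_id, graph = graph,
    conforms = conforms, n_quads = nrow(as.data.frame(quads)),
    findings = findings, completeness = report$completeness),
    paths$report, auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")

  # a successfully transformed patient is no longer quarantined
  unlink(file.path(project$quarantine, paste0(original_pid, ".json")))
  data.frame(patient = original_pid, status = "released",
             conforms = conforms, n_findings = nrow(findings),
             graph = graph, stringsAsFactors = FALSE)
}

#' Process landed patients through the pipeline
#'
#' Runs pre-check, de-identification (when configured), transformation and
#' validation for each requested patient. Patients blocked before
#' transformation move to Quarantine with a machine-readable reason; all
#' others are written to the Release zone as one named graph per patient
#' together with a validation report — non-conforming graphs are released
#' too, flagged by their report. The de-identification log is replayed and
#' persisted under `logs/`.
#'
#' @param project A `kg_project`.
#' @param patients Patient identifiers to process; `NULL` processes every
#'   document in the Landing zone.
#' @param seed Seed for pseudonym minting and date-offset draws (combined
#'   with the project salt; replayed values are unaffected).
#' @return Data frame: `patient`, `status`, `conforms`, `n_findings`,
#'   `graph`.
#' @export
process_patients <- function(project, patients = NULL, seed = 1L) {
  if (is.null(patients)) {
    files <- sort(list.files(project$landing, pattern = "\\.json$"))
    patients <- sub("\\.json$", "", files)
  }
  log <- NULL
  if (!is.null(project$deid)) {
    log <- open_deid_log(project$deid_log_path, project$project_id,
                         project$deid, seed)
  }
  rows <- lapply(patients, function(p) {
    f <- landing_path(project, p)
    if (!file.exists(f)) {
      stop("pipeline error: patient '", p, "' is not in the Landing zone",
           call. = FALSE)
    }
    bundle <- bundle_from_list(jsonlite::fromJSON(f, simplifyVector = FALSE))
    process_one(project, bundle, log)
  })
  if (!is.null(log) && log$persist) save_deid_log(log)
  if (length(rows) == 0) {
    return(data.frame(patient = character(), status = character(),
                      conforms = logical(), n_findings = integer(),
                      graph = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Apply a delta load for one patient
#'
#' Lands the corrected bundle and reprocesses it; because one patient is one
#' named graph, only that patient's graph and report are replaced in the
#' Release store. Pseudonyms and date offsets are replayed from the project
#' log, so the patient keeps the same released identity.
#'
#' @param project A `kg_project`.
#' @param bundle The corrected `patient_bundle`.
#' @param seed Seed for any newly minted pseudonyms.
#' @return One-row data frame as in [process_patients()].
#' @export
delta_update <- function(project, bundle, seed = 1L) {
  land_bundles(project, list(bundle))
  process_patients(project, bundle$patient_local_id, seed = seed)
}

#' Revoke a patient's consent
#'
#' Removes the patient's named graph and validation report from the Release
#' zone entirely, along with any Landing or Quarantine documents for that
#' patient.
#'
#' @param project A `kg_project`.
#' @param released_id The patient identifier under which the graph was
#'   released (the final segment of the graph IRI).
#' @return Invisibly, the removed graph IRI.
#' @export
revoke_consent <- function(project, released_id) {
  paths <- release_paths(project, released_id)
  if (!file.exists(paths$graph)) {
    stop("revocation error: no released graph found for patient '",
         released_id, "'", call. = FALSE)
  }
  graph <- patient_graph_iri(project$policy, project$model, released_id)
  unlink(c(paths$graph, paths$report))
  unlink(landing_path(project, released_id))
  unlink(file.path(project$quarantine, paste0(released_id, ".json")))
  invisible(graph)
}

# --- store --------------------------------------------------------------------

#' Read the entire Release store as one canonical quadset
#'
#' @param project A `kg_project`.
#' @return A [quadset()] with the union of all released named graphs, in
#'   canonical order.
#' @export
release_store <- function(project) {
  ext <- graph_ext(project$format)
  files <- sort(list.files(project$release,
                           pattern = paste0("\\.", ext, "$"),
                           full.names = TRUE))
  parts <- lapply(files, function(f)
    parse_quads(read_text_arg(f), project$format))
  canonical_quads(do.call(quads_bind, c(parts, list(quadset()))))
}

#' Read released validation reports
#'
#' @param project A `kg_project`.
#' @return List of report entries (`patient_id`, `graph`, `conforms`,
#'   `n_quads`, `findings` data frame).
#' @export
release_reports <- function(project) {
  files <- sort(list.files(project$release, pattern = "\\.report\\.json$",
                           full.names = TRUE))
  lapply(files, function(f) {
    x <- jsonlite::fromJSON(f, simplifyVector = TRUE)
    x$findings <- as.data.frame(x$findings, stringsAsFactors = FALSE)
    x
  })
}

#' Zone occupancy of a project
#'
#' @param project A `kg_project`.
#' @return Data frame with counts: `landing`, `released`, `quarantined`.
#' @export
project_status <- function(project) {
  ext <- graph_ext(project$format)
  data.frame(
    landing = length(list.files(project$landing, pattern = "\\.json$")),
    released = length(list.files(project$release,
                                 pattern = paste0("\\.", ext, "$"))),
    quarantined = length(list.files(project$quarantine,
                                    pattern = "\\.json$")))
}
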