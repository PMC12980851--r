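# Ingestion: JSON and tabular patient data -> normalized patient bundles
# (the intermediate per-patient record set), plus the pre-check that runs
# before any RDF is generated. Both routes produce identical bundles for
# equivalent content; ingestion never silently drops a record (rejections are
# reported per patient, whole-patient atomicity).

#' Construct a patient bundle
#'
#' @param patient_local_id Provider-side patient identifier.
#' @param records List of instance records, each created by [instance_record()].
#' @return Object of class `patient_bundle`.
#' @export
patient_bundle <- function(patient_local_id, records = list()) {
  structure(list(patient_local_id = patient_local_id, records = records),
            class = "patient_bundle")
}

#' Construct an instance record
#'
#' @param concept Concept name (must exist in the model).
#' @param id Provider-side instance identifier (IRI-safe).
#' @param fields Named list of character vectors: property name -> lexical
#'   value(s).
#' @param links Named list of character vectors: concept-range property name
#'   -> instance identifier(s) of the linked records.
#' @param shared Named list: shared-identifier property name -> externally
#'   agreed identifier(s), exempt from IRI minting.
#' @export
instance_record <- function(concept, id, fields = list(), links = list(),
                            shared = list()) {
  list(concept = concept, id = id, fields = fields, links = links,
       shared = shared)
}

#' @export
print.patient_bundle <- function(x, ...) {
  cat("<patient_bundle> ", x$patient_local_id, ": ", length(x$records),
      " record(s)\n", sep = "")
  for (r in x$records) {
    cat("  ", r$concept, " ", r$id, " (", length(r$fields), " field(s), ",
        length(r$links), " link(s))\n", sep = "")
  }
  invisible(x)
}

#' Look up an instance record in a bundle
#'
#' @param bundle A `patient_bundle`.
#' @param concept Concept name.
#' @param id Instance identifier.
#' @return The matching `instance_record`, or `NULL`.
#' @export
find_record <- function(bundle, concept, id) {
  for (r in bundle$records) {
    if (r$concept == concept && r$id == id) return(r)
  }
  NULL
}

canonical_lex <- function(v) {
  if (is.logical(v)) ifelse(v, "true", "false")
  else if (is.numeric(v)) {
    vapply(v, function(x) format(x, scientific = FALSE, trim = TRUE), "")
  } else as.character(v)
}

#' Check a bundle's referential structure
#'
#' Errors on duplicate `(concept, id)` pairs and on links naming instances
#' absent from the bundle, naming the patient and the offending identifier.
#'
#' @param bundle A `patient_bundle`.
#' @param model A `concept_model`.
#' @return Invisibly `TRUE` when the bundle is structurally sound.
#' @export
check_bundle_structure <- function(bundle, model) {
  keys <- vapply(bundle$records, function(r) paste0(r$concept, "\r", r$id), "")
  if (anyDuplicated(keys)) {
    d <- bundle$records[[which(duplicated(keys))[1]]]
    stop("ingestion error for patient '", bundle$patient_local_id,
         "': duplicate instance id '", d$id, "' for concept ", d$concept,
         call. = FALSE)
  }
  for (r in bundle$records) {
    cd <- model$concepts[[r$concept]]
    for (ln in names(r$links)) {
      target <- cd$properties[[ln]]$target
      for (tid in r$links[[ln]]) {
        if (is.null(find_record(bundle, target, tid))) {
          stop("ingestion error for patient '", bundle$patient_local_id,
               "': link ", r$concept, ".", ln, " names missing ", target,
               " instance '", tid, "'", call. = FALSE)
        }
      }
    }
  }
  invisible(TRUE)
}

# --- JSON route ---------------------------------------------------------------

#' Ingest a JSON document into patient bundles
#'
#' The document must conform to the JSON Schema generated by
#' [gen_json_schema()] for the same model. Patients are processed atomically:
#' with `on_invalid = "skip"` a structurally invalid patient is dropped whole
#' (reported in the `rejected` attribute) and the remaining patients are
#' ingested; with `"error"` any schema violation aborts with a structured
#' error listing the offending JSON paths.
#'
#' @param doc JSON text, a file path, or a parsed list.
#' @param model A `concept_model`.
#' @param on_invalid `"error"` (default) or `"skip"`.
#' @return List of `patient_bundle` objects (attribute `rejected`: data frame
#'   of per-patient rejection reasons).
#' @export
ingest_json <- function(doc, model, on_invalid = c("error", "skip")) {
  on_invalid <- match.arg(on_invalid)
  if (is.character(doc) && length(doc) == 1) {
    if (!grepl("^[{[]", trimws(doc)) && file.exists(doc)) {
      doc <- paste(readLines(doc, warn = FALSE), collapse = "\n")
    }
    doc <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  }
  schema <- gen_json_schema(model)
  if (is.null(doc$patients) || !is.list(doc$patients)) {
    stop("schema-invalid document: /patients : required property missing",
         call. = FALSE)
  }

  bundles <- list()
  rejected <- list()
  for (k in seq_along(doc$patients)) {
    pobj <- doc$patients[[k]]
    errs <- validate_json_with_defs(pobj, schema$definitions$Patient,
                                    schema$definitions,
                                    paste0("/patients/", k - 1L))
    if (nrow(errs) > 0) {
      if (on_invalid == "error") {
        stop("schema-invalid document: ",
             paste(paste0(errs$path, " : ", errs$message), collapse = "; "),
             call. = FALSE)
      }
      rejected[[length(rejected) + 1L]] <- data.frame(
        patient = if (!is.null(pobj$id)) as.character(pobj$id)
                  else paste0("#", k),
        reason = paste(paste0(errs$path, " : ", errs$message), collapse = "; "),
        stringsAsFactors = FALSE)
      next
    }
    bundles[[length(bundles) + 1L]] <- json_patient_to_bundle(pobj, model)
  }
  for (b in bundles) check_bundle_structure(b, model)
  attr(bundles, "rejected") <- if (length(rejected) > 0) {
    do.call(rbind, rejected)
  } else {
    data.frame(patient = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  bundles
}

validate_json_with_defs <- function(x, sch, defs, path) {
  wrapper <- list(definitions = defs)
  wrapper[names(sch)] <- sch
  out <- validate_json(x, wrapper)
  if (nrow(out) > 0) out$path <- paste0(path, out$path)
  out
}

json_patient_to_bundle <- function(pobj, model) {
  core <- identify_core_concepts(model)
  records <- list()

  build_instance <- function(concept, obj, id) {
    cd <- model$concepts[[concept]]
    fields <- list(); links <- list(); shared <- list()
    for (pd in cd$properties) {
      val <- obj[[pd$name]]
      if (is.null(val)) next
      if (pd$range_kind == "concept") {
        if (pd$target %in% core) {
          ids <- if (pd$max_count > 1) vapply(val, as.character, "")
                 else as.character(val)
          links[[pd$name]] <- ids
        } else {
          vals <- if (pd$max_count > 1) val else list(val)
          ids <- character(0)
          for (j in seq_along(vals)) {
            child_id <- paste0(id, "-", to_snake(pd$name),
                               if (pd$max_count > 1) paste0("-", j) else "")
            build_instance(pd$target, vals[[j]], child_id)
            ids <- c(ids, child_id)
          }
          links[[pd$name]] <- ids
        }
      } else {
        lex <- canonical_lex(unlist(val))
        if (isTRUE(pd$shared_identifier)) shared[[pd$name]] <- lex
        else fields[[pd$name]] <- lex
      }
    }
    records[[length(records) + 1L]] <<-
      instance_record(concept, id, fields, links, shared)
    id
  }

  pid <- as.character(pobj$id)
  subj <- model$concepts[[model$subject_concept]]
  sfields <- list(); slinks <- list(); sshared <- list()
  for (pd in subj$properties) {
    val <- pobj[[pd$name]]
    if (is.null(val)) next
    if (pd$range_kind == "concept" && pd$target %in% core) {
      ids <- character(0)
      for (inst in val) {
        ids <- c(ids, build_instance(pd$target, inst, as.character(inst$id)))
      }
      slinks[[pd$name]] <- ids
    } else if (pd$range_kind == "concept") {
      vals <- if (pd$max_count > 1) val else list(val)
      ids <- character(0)
      for (j in seq_along(vals)) {
        child_id <- paste0(pid, "-", to_snake(pd$name),
                           if (pd$max_count > 1) paste0("-", j) else "")
        build_instance(pd$target, vals[[j]], child_id)
        ids <- c(ids, child_id)
      }
      slinks[[pd$name]] <- ids
    } else {
      lex <- canonical_lex(unlist(val))
      if (isTRUE(pd$shared_identifier)) sshared[[pd$name]] <- lex
      else sfields[[pd$name]] <- lex
    }
  }
  srec <- instance_record(model$subject_concept, pid, sfields, slinks, sshared)
  patient_bundle(pid, c(list(srec), records))
}

#' Render patient bundles as a JSON ingestion document
#'
#' Inverse of [ingest_json()]; the output conforms to the generated JSON
#' Schema. Used to materialize fixtures and for round-trip checks.
#'
#' @param bundles List of `patient_bundle` objects.
#' @param model A `concept_model`.
#' @return Nested list; serialize with `jsonlite::toJSON(x, auto_unbox =
#'   TRUE)`.
#' @export
bundles_to_json <- function(bundles, model) {
  core <- identify_core_concepts(model)

  record_obj <- function(bundle, rec, with_id) {
    cd <- model$concepts[[rec$concept]]
    obj <- list()
    if (with_id) obj$id <- rec$id
    for (pd in cd$properties) {
      nm <- pd$name
      if (pd$range_kind == "concept") {
        ids <- rec$links[[nm]]
        if (is.null(ids)) next
        if (pd$target %in% core) {
          obj[[nm]] <- if (pd$max_count > 1) as.list(ids) else ids[1]
        } else {
          nested <- lapply(ids, function(i)
            record_obj(bundle, find_record(bundle, pd$target, i), FALSE))
          obj[[nm]] <- if (pd$max_count > 1) nested else nested[[1]]
        }
      } else {
        v <- if (isTRUE(pd$shared_identifier)) rec$shared[[nm]] else rec$fields[[nm]]
        if (is.null(v)) next
        obj[[nm]] <- typed_json_value(v, pd)
      }
    }
    obj
  }

  patients <- lapply(bundles, function(b) {
    srec <- find_record(b, model$subject_concept, b$patient_local_id)
    subj <- model$concepts[[model$subject_concept]]
    obj <- list(id = b$patient_local_id)
    for (pd in subj$properties) {
      nm <- pd$name
      if (pd$range_kind == "concept" && pd$target %in% core) {
        ids <- srec$links[[nm]]
        if (is.null(ids) || length(ids) == 0) next
        obj[[nm]] <- lapply(ids, function(i)
          record_obj(b, find_record(b, pd$target, i), TRUE))
      } else if (pd$range_kind == "concept") {
        ids <- srec$links[[nm]]
        if (is.null(ids)) next
        nested <- lapply(ids, function(i)
          record_obj(b, find_record(b, pd$target, i), FALSE))
        obj[[nm]] <- if (pd$max_count > 1) nested else nested[[1]]
      } else {
        v <- if (isTRUE(pd$shared_identifier)) srec$shared[[nm]] else srec$fields[[nm]]
        if (is.null(v)) next
        obj[[nm]] <- typed_json_value(v, pd)
      }
    }
    obj
  })
  list(patients = patients)
}

typed_json_value <- function(v, pd) {
  conv <- function(x) {
    if (pd$range_kind == "scalar") {
      switch(pd$scalar_datatype,
             integer = as.integer(x),
             decimal = as.numeric(x),
             double = as.numeric(x),
             boolean = identical(x, "true"),
             x)
    } else x
  }
  if (pd$max_count > 1) lapply(as.list(v), conv) else conv(v[1])
}

# --- Tabular route ------------------------------------------------------------

#' Ingest tabular (CSV) patient data into bundles
#'
#' Tables must carry exactly the headers of the generated templates. Rows are
#' grouped into bundles by the `patient_id` column; reference (`*_id`)
#' columns become links; embedded prefixed columns are reassembled into
#' nested records. Rows whose inline value-set columns hold a non-permitted
#' member are rejected with their row number, and the whole patient is
#' quarantined (patient-level atomicity); rejections are reported in the
#' `rejected` attribute of the result.
#'
#' @param tables Named list of data frames (or a directory of `<table>.csv`
#'   files), names matching template table names.
#' @param model A `concept_model`.
#' @return List of `patient_bundle` objects with a `rejected` attribute.
#' @export
ingest_tabular <- function(tables, model) {
  tmpl <- gen_tabular_templates(model)
  if (is.character(tables) && length(tables) == 1 && dir.exists(tables)) {
    files <- list.files(tables, pattern = "\\.csv$", full.names = TRUE)
    tables <- stats::setNames(
      lapply(files, function(f) utils::read.csv(f, colClasses = "character",
                                                check.names = FALSE)),
      sub("\\.csv$", "", basename(files)))
  }
  for (nm in names(tables)) {
    if (!nm %in% names(tmpl$tables)) {
      stop("ingestion error: unknown table '", nm, "'", call. = FALSE)
    }
    got <- names(tables[[nm]])
    want <- tmpl$tables[[nm]]$column_name
    extra <- setdiff(got, want)
    if (length(extra) > 0) {
      stop("ingestion error: unknown column '", extra[1], "' in table '",
           nm, "'", call. = FALSE)
    }
    miss <- setdiff(want, got)
    if (length(miss) > 0) {
      stop("ingestion error: table '", nm, "' is missing column '",
           miss[1], "'", call. = FALSE)
    }
    tables[[nm]] <- tables[[nm]][, want, drop = FALSE]
  }

  # inline value-set screening: reject offending rows (and their patients)
  rejections <- list()
  bad_patients <- character(0)
  for (nm in names(tables)) {
    spec <- tmpl$tables[[nm]]
    df <- tables[[nm]]
    if (nrow(df) == 0) next
    for (i in seq_len(nrow(spec))) {
      if (is.na(spec$value_set[i])) next
      toks <- vs_member_tokens(model$value_sets[[spec$value_set[i]]])
      col <- df[[spec$column_name[i]]]
      bad <- which(nzchar(col) & !col %in% toks)
      for (r in bad) {
        rejections[[length(rejections) + 1L]] <- data.frame(
          table = nm, row = r, patient = df$patient_id[r],
          reason = paste0("value '", col[r], "' outside enumerated type of ",
                          spec$column_name[i]),
          stringsAsFactors = FALSE)
        bad_patients <- c(bad_patients, df$patient_id[r])
      }
    }
  }

  core <- identify_core_concepts(model)
  subj <- model$subject_concept
  sdf <- tables[[to_snake(subj)]]
  pids <- if (!is.null(sdf) && nrow(sdf) > 0) sdf$patient_id else character(0)
  pids <- setdiff(unique(pids), unique(bad_patients))

  # read a (possibly embedded) concept from a row under a column prefix
  read_instance <- function(concept, row, prefix, id, collector,
                            skip_subject_links = FALSE) {
    cd <- model$concepts[[concept]]
    fields <- list(); links <- list(); shared <- list()
    for (pd in cd$properties) {
      if (pd$max_count > 1) next  # side tables handled separately
      if (skip_subject_links && pd$range_kind == "concept" &&
          pd$target %in% core) next
      base <- to_snake(pd$name)
      if (pd$range_kind == "concept") {
        if (pd$target %in% core) {
          v <- row[[paste0(prefix, base, "_id")]]
          if (!is.null(v) && nzchar(v)) links[[pd$name]] <- v
        } else {
          child_id <- paste0(id, "-", base)
          sub_cols <- grep(paste0("^", prefix, base, "_"),
                           names(row), value = TRUE)
          if (length(sub_cols) > 0 && any(nzchar(unlist(row[sub_cols])))) {
            read_instance(pd$target, row, paste0(prefix, base, "_"),
                          child_id, collector)
            links[[pd$name]] <- child_id
          }
        }
      } else {
        v <- row[[paste0(prefix, base)]]
        if (!is.null(v) && nzchar(v)) {
          if (isTRUE(pd$shared_identifier)) shared[[pd$name]] <- v
          else fields[[pd$name]] <- v
        }
      }
    }
    collector$records[[length(collector$records) + 1L]] <-
      instance_record(concept, id, fields, links, shared)
    invisible(NULL)
  }

  apply_side_tables <- function(collector, pid) {
    for (nm in names(tables)) {
      if (!grepl("__", nm, fixed = TRUE)) next
      parts <- strsplit(nm, "__", fixed = TRUE)[[1]]
      owner_concept <- core[vapply(core, to_snake, "") == parts[1]]
      if (length(owner_concept) == 0) next
      cd <- model$concepts[[owner_concept]]
      hit <- vapply(cd$properties, function(p) to_snake(p$name), "") == parts[2]
      if (!any(hit)) next
      pd <- cd$properties[[which(hit)[1]]]
      df <- tables[[nm]]
      sel <- df[df$patient_id == pid, , drop = FALSE]
      if (nrow(sel) == 0) next
      vcol <- names(df)[3]
      for (r in seq_len(nrow(sel))) {
        v <- sel[[vcol]][r]
        if (!nzchar(v)) next
        for (k in seq_along(collector$records)) {
          rec <- collector$records[[k]]
          if (rec$concept == owner_concept && rec$id == sel$id[r]) {
            if (pd$range_kind == "concept") {
              rec$links[[pd$name]] <- c(rec$links[[pd$name]], v)
            } else if (isTRUE(pd$shared_identifier)) {
              rec$shared[[pd$name]] <- c(rec$shared[[pd$name]], v)
            } else {
              rec$fields[[pd$name]] <- c(rec$fields[[pd$name]], v)
            }
            collector$records[[k]] <- rec
          }
        }
      }
    }
  }

  bundles <- list()
  for (pid in pids) {
    collector <- new.env(parent = emptyenv())
    collector$records <- list()
    srow <- as.list(sdf[sdf$patient_id == pid, , drop = FALSE][1, ])
    read_instance(subj, srow, "", pid, collector, skip_subject_links = TRUE)
    srec_idx <- length(collector$records)

    slinks <- collector$records[[srec_idx]]$links
    for (pd in subject_link_properties(model)) {
      if (!pd$target %in% core) next
      tdf <- tables[[to_snake(pd$target)]]
      if (is.null(tdf) || nrow(tdf) == 0) next
      rows <- which(tdf$patient_id == pid)
      ids <- character(0)
      for (r in rows) {
        read_instance(pd$target, as.list(tdf[r, , drop = FALSE]),
                      "", tdf$id[r], collector)
        ids <- c(ids, tdf$id[r])
      }
      if (length(ids) > 0) slinks[[pd$name]] <- ids
    }
    collector$records[[srec_idx]]$links <- slinks
    apply_side_tables(collector, pid)

    recs <- collector$records
    bundles[[length(bundles) + 1L]] <-
      patient_bundle(pid, c(recs[srec_idx], recs[-srec_idx]))
  }
  for (b in bundles) check_bundle_structure(b, model)
  attr(bundles, "rejected") <- if (length(rejections) > 0) {
    do.call(rbind, rejections)
  } else {
    data.frame(table = character(), row = integer(), patient = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  bundles
}

#' Render patient bundles as tabular template tables
#'
#' Inverse of [ingest_tabular()]: emits one data frame per template table,
#' with columns in template (DDL) order. Used for fixtures and round-trip
#' checks.
#'
#' @param bundles List of `patient_bundle` objects.
#' @param model A `concept_model`.
#' @param dir Optional directory; when given, writes `<table>.csv` files.
#' @return Named list of data frames.
#' @export
write_tabular <- function(bundles, model, dir = NULL) {
  tmpl <- gen_tabular_templates(model)
  core <- identify_core_concepts(model)
  out <- lapply(tmpl$tables, function(spec) {
    stats::setNames(
      as.data.frame(matrix(character(0), nrow = 0, ncol = nrow(spec)),
                    stringsAsFactors = FALSE),
      spec$column_name)
  })

  fill_row <- function(bundle, rec, tname, prefix, row) {
    cd <- model$concepts[[rec$concept]]
    for (pd in cd$properties) {
      if (pd$max_count > 1) {
        st <- paste0(tname, "__", prefix, to_snake(pd$name))
        vals <- if (pd$range_kind == "concept") rec$links[[pd$name]]
                else if (isTRUE(pd$shared_identifier)) rec$shared[[pd$name]]
                else rec$fields[[pd$name]]
        for (v in vals) {
          out[[st]][nrow(out[[st]]) + 1L, ] <<-
            c(bundle$patient_local_id, rec$id, v)
        }
        next
      }
      base <- to_snake(pd$name)
      if (pd$range_kind == "concept") {
        if (pd$target %in% core) {
          v <- rec$links[[pd$name]]
          if (!is.null(v)) row[[paste0(prefix, base, "_id")]] <- v[1]
        } else {
          cid <- rec$links[[pd$name]]
          if (!is.null(cid)) {
            child <- find_record(bundle, pd$target, cid[1])
            row <- fill_row(bundle, child, tname, paste0(prefix, base, "_"), row)
          }
        }
      } else {
        v <- if (isTRUE(pd$shared_identifier)) rec$shared[[pd$name]]
             else rec$fields[[pd$name]]
        if (!is.null(v)) row[[paste0(prefix, base)]] <- v[1]
      }
    }
    row
  }

  slink_names <- vapply(subject_link_properties(model), `[[`, "", "name")
  for (b in bundles) {
    for (rec in b$records) {
      if (!rec$concept %in% core) next
      tname <- to_snake(rec$concept)
      spec <- tmpl$tables[[tname]]
      row <- stats::setNames(as.list(rep("", nrow(spec))), spec$column_name)
      row$patient_id <- b$patient_local_id
      row$id <- rec$id
      rec2 <- rec
      if (rec$concept == model$subject_concept) {
        # subject links are implicit (patient_id column of the linked tables)
        rec2$links <- rec$links[setdiff(names(rec$links), slink_names)]
      }
      row <- fill_row(b, rec2, tname, "", row)
      out[[tname]][nrow(out[[tname]]) + 1L, ] <- unlist(row[spec$column_name])
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      utils::write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  out
}

# --- Pre-check ----------------------------------------------------------------

#' Pre-check a patient bundle before RDF generation
#'
#' Enumerates findings that would make the bundle untransformable or
#' semantically unsafe: identifiers that are not IRI-safe (whitespace,
#' characters outside `[A-Za-z0-9._~-]`, empty), inline value-set members not
#' in the permitted set, unparseable temporal values and malformed scalar
#' lexicals. An empty result means the bundle is clean; in the pipeline any
#' finding quarantines the whole patient.
#'
#' @param bundle A `patient_bundle`.
#' @param model A `concept_model`.
#' @return Data frame of findings with columns `kind` (`malformed_id`,
#'   `bad_value_set`, `bad_datatype`), `concept`, `property`, `value`,
#'   `message`.
#' @export
precheck <- function(bundle, model) {
  rows <- list()
  add <- function(kind, concept, property, value, message) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, concept = concept, property = property,
      value = value, message = message, stringsAsFactors = FALSE)
  }
  check_id <- function(id, concept) {
    if (!nzchar(id) || !grepl(ID_PATTERN, id, perl = TRUE)) {
      add("malformed_id", concept, "id", id,
          paste0("identifier '", id, "' is not IRI-safe (must match ",
                 "[A-Za-z0-9._~-]+, no spaces or invalid characters)"))
    }
  }
  check_id(bundle$patient_local_id, model$subject_concept)
  for (rec in bundle$records) {
    if (!(rec$concept == model$subject_concept &&
          rec$id == bundle$patient_local_id)) {
      check_id(rec$id, rec$concept)
    }
    cd <- model$concepts[[rec$concept]]
    for (nm in names(rec$fields)) {
      pd <- cd$properties[[nm]]
      for (v in rec$fields[[nm]]) {
        if (pd$range_kind == "temporal") {
          ok <- if (pd$scalar_datatype == "date") is_valid_date(v)
                else is_valid_datetime(v)
          if (!ok) add("bad_datatype", rec$concept, nm, v,
                       paste0("'", v, "' is not a valid xsd:",
                              pd$scalar_datatype))
        } else if (pd$range_kind == "scalar") {
          ok <- switch(pd$scalar_datatype,
            integer = grepl("^[+-]?[0-9]+$", v),
            decimal = grepl("^[+-]?[0-9]+(\\.[0-9]+)?$", v),
            double = grepl("^[+-]?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$", v),
            boolean = v %in% c("true", "false"),
            TRUE)
          if (!ok) add("bad_datatype", rec$concept, nm, v,
                       paste0("'", v, "' is not a valid xsd:",
                              pd$scalar_datatype))
        } else if (pd$range_kind == "value_set") {
          vs <- model$value_sets[[pd$target]]
          if (isTRUE(vs$external)) {
            if (!nzchar(v) || grepl("[[:space:]<>\"{}|\\^`]", v)) {
              add("malformed_id", rec$concept, nm, v,
                  paste0("code '", v, "' is not a valid IRI (contains spaces ",
                         "or invalid characters)"))
            }
          } else if (!v %in% vs_member_tokens(vs)) {
            add("bad_value_set", rec$concept, nm, v,
                paste0("value '", v, "' is not a member of value set ",
                       pd$target))
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    data.frame(kind = character(), concept = character(),
               property = character(), value = character(),
               message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
}
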