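# Derivation of the three data-facing artifacts from a concept model:
# a JSON Schema for the JSON ingestion route, tabular templates (CSV headers
# + SQL DDL) for the tabular/database route, and SHACL shapes for validation.
# All three are pure functions of the model and regenerate byte-identically.

SHAPES_NS <- "https://w3id.org/healthkg/shapes#"

json_type_map <- c(string = "string", integer = "integer", decimal = "number",
                   double = "number", boolean = "boolean",
                   date = "string", dateTime = "string")

sql_type_map <- c(string = "VARCHAR", integer = "INTEGER", decimal = "DECIMAL",
                  double = "DOUBLE PRECISION", boolean = "BOOLEAN",
                  date = "DATE", dateTime = "TIMESTAMP")

ID_PATTERN <- "^[A-Za-z0-9._~-]+$"

vs_member_tokens <- function(vs) vapply(vs$members, iri_local_name, "")

# --- JSON Schema --------------------------------------------------------------

#' Generate a JSON Schema ingestion template
#'
#' Produces a draft-07-compatible JSON Schema describing the JSON ingestion
#' format: a top-level `patients` array, one object definition per core
#' concept, embedded concepts as nested objects, mandatory properties listed
#' as `required`, inline value sets as enumerations (member tokens), and
#' temporal properties constrained to ISO date / date-time string formats.
#'
#' @param model A `concept_model`.
#' @return The schema as a nested list; serialize with
#'   `jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)`.
#' @export
gen_json_schema <- function(model) {
  defs <- list()
  subj <- model$subject_concept
  core <- identify_core_concepts(model)

  prop_schema <- function(pd) {
    base <- switch(pd$range_kind,
      scalar = {
        s <- list(type = json_type_map[[pd$scalar_datatype]])
        s
      },
      temporal = list(
        type = "string",
        format = if (pd$scalar_datatype == "date") "date" else "date-time"
      ),
      value_set = {
        vs <- model$value_sets[[pd$target]]
        if (isTRUE(vs$external)) {
          list(type = "string", description = paste0(
            "code IRI from the '", pd$target, "' terminology"))
        } else {
          list(type = "string", enum = as.list(vs_member_tokens(vs)))
        }
      },
      concept = {
        if (pd$target %in% core) {
          list(type = "string", pattern = ID_PATTERN, description = paste0(
            "instance identifier of a ", pd$target, " record"))
        } else {
          list("$ref" = paste0("#/definitions/", pd$target))
        }
      }
    )
    if (pd$max_count > 1) {
      arr <- list(type = "array", items = base)
      if (pd$min_count >= 1) arr$minItems <- pd$min_count
      if (is.finite(pd$max_count)) arr$maxItems <- pd$max_count
      arr
    } else base
  }

  concept_def <- function(cd, with_id) {
    props <- list()
    req <- character(0)
    if (with_id) {
      props$id <- list(type = "string", pattern = ID_PATTERN)
      req <- "id"
    }
    for (pd in cd$properties) {
      props[[pd$name]] <- prop_schema(pd)
      if (pd$min_count >= 1) req <- c(req, pd$name)
    }
    out <- list(type = "object", additionalProperties = FALSE,
                properties = props)
    if (length(req) > 0) out$required <- as.list(req)
    out
  }

  # patient definition: subject concept, with core instances nested under the
  # subject-link property names
  patient_props <- list(id = list(type = "string", pattern = ID_PATTERN))
  patient_req <- "id"
  for (pd in model$concepts[[subj]]$properties) {
    if (pd$range_kind == "concept" && pd$target %in% core) {
      patient_props[[pd$name]] <- list(
        type = "array",
        items = list("$ref" = paste0("#/definitions/", pd$target))
      )
      if (pd$min_count >= 1) {
        patient_props[[pd$name]]$minItems <- pd$min_count
        patient_req <- c(patient_req, pd$name)
      }
    } else {
      patient_props[[pd$name]] <- prop_schema(pd)
      if (pd$min_count >= 1) patient_req <- c(patient_req, pd$name)
    }
  }
  defs[["Patient"]] <- list(type = "object", additionalProperties = FALSE,
                            properties = patient_props,
                            required = as.list(patient_req))

  for (cd in model$concepts) {
    if (cd$name == subj) next
    defs[[cd$name]] <- concept_def(cd, with_id = cd$name %in% core)
  }

  list(
    "$schema" = "http://json-schema.org/draft-07/schema#",
    title = paste0(model$schema_prefix, " patient data"),
    type = "object",
    additionalProperties = FALSE,
    required = list("patients"),
    properties = list(patients = list(
      type = "array",
      items = list("$ref" = "#/definitions/Patient")
    )),
    definitions = defs
  )
}

# --- Tabular templates --------------------------------------------------------

#' Generate tabular ingestion templates (CSV headers + SQL DDL)
#'
#' One table per core concept; one column per metadata element. Links between
#' core concepts become `<property>_id` reference columns holding instance
#' identifiers only; embedded concepts contribute prefixed columns
#' (underscore-joined path) to their owner's table; multi-valued properties
#' become a `<table>__<property>` side table. Inline value-set columns get SQL
#' CHECK constraints so only permitted members load.
#'
#' @param model A `concept_model`.
#' @return A `tabular_template`: list with `tables` (named list of column-spec
#'   data frames with `column_name`, `column_type`, `required`, `references`,
#'   `concept`, `property`), `ddl` (single SQL string), `headers` (named
#'   character vector of CSV header rows) and `coverage` (data frame mapping
#'   every schema property to its tabular location).
#' @export
gen_tabular_templates <- function(model) {
  core <- identify_core_concepts(model)
  subj <- model$subject_concept
  tables <- list()
  side_tables <- list()
  coverage <- list()

  col_row <- function(name, type, required, references, concept, property, vs = NA) {
    data.frame(column_name = name, column_type = type, required = required,
               references = references, concept = concept, property = property,
               value_set = vs, stringsAsFactors = FALSE)
  }

  add_cov <- function(concept, property, where) {
    coverage[[length(coverage) + 1L]] <<-
      data.frame(concept = concept, property = property, where = where,
                 stringsAsFactors = FALSE)
  }

  # expand a concept's properties into columns for table `tname`, with a path
  # prefix for embedded nesting; path is used in collision diagnostics
  expand_concept <- function(cd, tname, prefix, path, required_parent) {
    cols <- list()
    for (pd in cd$properties) {
      base <- to_snake(pd$name)
      required <- required_parent && pd$min_count >= 1
      if (pd$max_count > 1) {
        # unbounded/multi-valued: side table keyed by owner instance
        st_name <- paste0(tname, "__", prefix, base)
        vtype <- if (pd$range_kind %in% c("scalar", "temporal")) {
          sql_type_map[[pd$scalar_datatype]]
        } else "VARCHAR"
        vname <- if (pd$range_kind == "concept") paste0(prefix, base, "_id")
                 else paste0(prefix, base)
        refs <- if (pd$range_kind == "concept" && pd$target %in% core)
          to_snake(pd$target) else NA_character_
        vs <- if (pd$range_kind == "value_set" &&
                  !isTRUE(model$value_sets[[pd$target]]$external)) pd$target else NA
        side_tables[[st_name]] <<- rbind(
          col_row("patient_id", "VARCHAR", TRUE, NA_character_, cd$name, "(key)"),
          col_row("id", "VARCHAR", TRUE, NA_character_, cd$name, "(key)"),
          col_row(vname, vtype, TRUE, refs, cd$name, pd$name, vs)
        )
        add_cov(cd$name, pd$name, paste0(st_name, ".", vname))
        next
      }
      if (pd$range_kind == "concept") {
        if (pd$target %in% core) {
          cname <- paste0(prefix, base, "_id")
          cols[[length(cols) + 1L]] <-
            col_row(cname, "VARCHAR", required, to_snake(pd$target),
                    cd$name, pd$name)
          add_cov(cd$name, pd$name, paste0(tname, ".", cname))
        } else {
          # embedded concept: recurse with an extended prefix
          sub <- expand_concept(model$concepts[[pd$target]], tname,
                                paste0(prefix, base, "_"),
                                c(path, pd$name), required)
          cols <- c(cols, sub)
          add_cov(cd$name, pd$name, paste0(tname, ".", prefix, base, "_*"))
        }
      } else {
        cname <- paste0(prefix, base)
        type <- if (pd$range_kind == "value_set") "VARCHAR"
                else sql_type_map[[pd$scalar_datatype]]
        vs <- if (pd$range_kind == "value_set" &&
                  !isTRUE(model$value_sets[[pd$target]]$external)) pd$target else NA
        cols[[length(cols) + 1L]] <-
          col_row(cname, type, required, NA_character_, cd$name, pd$name, vs)
        add_cov(cd$name, pd$name, paste0(tname, ".", cname))
      }
    }
    cols
  }

  for (cname in core) {
    cd <- model$concepts[[cname]]
    tname <- to_snake(cname)
    cols <- list(
      col_row("patient_id", "VARCHAR", TRUE, NA_character_, cname, "(key)"),
      col_row("id", "VARCHAR", TRUE, NA_character_, cname, "(key)")
    )
    for (pd in cd$properties) {
      if (cname == subj && pd$range_kind == "concept" && pd$target %in% core) {
        # subject links are materialized as the patient_id column of the
        # linked concept's own table
        add_cov(cname, pd$name, paste0(to_snake(pd$target), ".patient_id"))
        next
      }
    }
    keep <- cd$properties
    if (cname == subj) {
      keep <- Filter(function(pd) !(pd$range_kind == "concept" &&
                                      pd$target %in% core), keep)
    }
    cdv <- cd; cdv$properties <- keep
    cols <- c(cols, expand_concept(cdv, tname, "", character(0), TRUE))
    df <- do.call(rbind, cols)
    dup <- df$column_name[duplicated(df$column_name)]
    if (length(dup) > 0) {
      first <- df[df$column_name == dup[1], , drop = FALSE]
      stop("template generation error: column name collision in table '",
           tname, "': '", dup[1], "' produced by properties ",
           paste(unique(first$property), collapse = " and "), call. = FALSE)
    }
    rownames(df) <- NULL
    tables[[tname]] <- df
  }
  tables <- c(tables, side_tables)

  cov <- do.call(rbind, coverage)
  ddl <- ddl_text(tables, model)
  headers <- vapply(tables, function(df) paste(df$column_name, collapse = ","), "")

  structure(list(tables = tables, ddl = ddl, headers = headers,
                 coverage = cov, core = core),
            class = "tabular_template")
}

#' @export
print.tabular_template <- function(x, ...) {
  cat("<tabular_template> ", length(x$tables), " table(s)\n", sep = "")
  for (nm in names(x$tables)) {
    cat("  ", nm, ": ", paste(x$tables[[nm]]$column_name, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

ddl_text <- function(tables, model) {
  stmts <- character(0)
  for (nm in names(tables)) {
    df <- tables[[nm]]
    defs <- paste0("  ", df$column_name, " ", df$column_type,
                   ifelse(df$required, " NOT NULL", ""))
    checks <- character(0)
    for (i in seq_len(nrow(df))) {
      if (!is.na(df$value_set[i])) {
        toks <- vs_member_tokens(model$value_sets[[df$value_set[i]]])
        checks <- c(checks, paste0(
          "  CHECK (", df$column_name[i], " IN (",
          paste0("'", toks, "'", collapse = ", "), "))"))
      }
    }
    pk <- if (grepl("__", nm, fixed = TRUE)) NULL
          else "  PRIMARY KEY (patient_id, id)"
    body <- paste(c(defs, checks, pk), collapse = ",\n")
    stmts <- c(stmts, paste0("CREATE TABLE ", nm, " (\n", body, "\n);"))
  }
  paste0(paste(stmts, collapse = "\n\n"), "\n")
}

# --- SHACL shapes -------------------------------------------------------------

#' Generate SHACL shapes from a concept model
#'
#' One node shape per concept targeting its class IRI; one property shape per
#' property carrying min/max-count constraints, a datatype constraint for
#' scalars and temporals, a class constraint for concept ranges, and an
#' `sh:in` membership list for inline value sets. Terminology-backed coded
#' properties are annotated with `hkg:terminologyCheck true`, which
#' [shacl_validate()] resolves against the terminology graphs loaded for the
#' project. The shapes graph embeds a fingerprint of the model so validation
#' can refuse shapes generated from a different schema version.
#'
#' @param model A `concept_model`.
#' @return Turtle text of the shapes graph.
#' @export
gen_shacl <- function(model) {
  lines <- c(
    paste0("@prefix sh: <", NS_SH, "> ."),
    paste0("@prefix xsd: <", NS_XSD, "> ."),
    paste0("@prefix hkg: <", HKG, "> ."),
    paste0("@prefix shp: <", SHAPES_NS, "> ."),
    "",
    paste0("shp:__meta hkg:modelDigest \"", model_digest(model), "\" ."),
    ""
  )
  for (cd in model$concepts) {
    node <- paste0("shp:", cd$name)
    lines <- c(lines, paste0(node, " a sh:NodeShape ;"),
               paste0("  sh:targetClass <", cd$iri, ">",
                      if (length(cd$properties) > 0) " ;" else " ."))
    pn <- names(cd$properties)
    for (k in seq_along(pn)) {
      lines <- c(lines, paste0("  sh:property shp:", cd$name, "-", pn[k],
                               if (k < length(pn)) " ;" else " ."))
    }
    lines <- c(lines, "")
  }
  for (cd in model$concepts) {
    for (pd in cd$properties) {
      node <- paste0("shp:", cd$name, "-", pd$name)
      parts <- c(paste0(node, " a sh:PropertyShape ;"),
                 paste0("  sh:path <", pd$iri, "> ;"))
      cons <- character(0)
      if (pd$min_count > 0) cons <- c(cons, paste0("  sh:minCount ", pd$min_count))
      if (is.finite(pd$max_count)) {
        cons <- c(cons, paste0("  sh:maxCount ", format(pd$max_count)))
      }
      if (pd$range_kind %in% c("scalar", "temporal")) {
        cons <- c(cons, paste0("  sh:datatype xsd:", pd$scalar_datatype))
      } else if (pd$range_kind == "value_set") {
        vs <- model$value_sets[[pd$target]]
        cons <- c(cons, "  sh:nodeKind sh:IRI")
        if (isTRUE(vs$external)) {
          cons <- c(cons, "  hkg:terminologyCheck true")
        } else {
          cons <- c(cons, paste0("  sh:in ( ",
                                 paste0("<", vs$members, ">", collapse = " "),
                                 " )"))
        }
      } else if (pd$range_kind == "concept") {
        cons <- c(cons, "  sh:nodeKind sh:IRI",
                  paste0("  sh:class <", model$concepts[[pd$target]]$iri, ">"))
      }
      body <- paste0(cons, c(rep(" ;", length(cons) - 1), " ."))
      lines <- c(lines, parts, body, "")
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
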