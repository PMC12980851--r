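# Validation of generated quads against the SHACL shapes derived from the
# schema, membership of coded values in loaded terminology graphs, the
# start-before-end logic check, and completeness statistics. The SHACL
# engine interprets exactly the constraint vocabulary gen_shacl() emits:
# sh:minCount, sh:maxCount, sh:datatype, sh:class, sh:nodeKind sh:IRI,
# sh:in lists, and the hkg:terminologyCheck annotation. Validation is
# side-effect-free and asserts schema compliance only, never data
# correctness: a physiologically absurd but schema-valid value yields no
# finding.

#' Construct a validation report
#'
#' @param patient_id Patient identifier (or `NA` for multi-patient input).
#' @param conforms `TRUE` iff `findings` contains no Violation.
#' @param findings Data frame with columns `severity`, `constraint_kind`,
#'   `focus_node`, `property`, `message`.
#' @param completeness Data frame of per-(concept, property) presence counts.
#' @return A `validation_report`.
#' @export
validation_report <- function(patient_id, conforms, findings, completeness) {
  structure(list(patient_id = patient_id, conforms = conforms,
                 findings = findings, completeness = completeness),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> patient ", x$patient_id, ": ",
      if (x$conforms) "conforms" else "DOES NOT conform", "\n", sep = "")
  if (nrow(x$findings) > 0) {
    cat(nrow(x$findings), "finding(s):\n")
    print(x$findings[, c("severity", "constraint_kind", "property", "message")])
  }
  invisible(x)
}

empty_findings <- function() {
  data.frame(severity = character(), constraint_kind = character(),
             focus_node = character(), property = character(),
             message = character(), stringsAsFactors = FALSE)
}

# Parse a shapes graph (Turtle text or quadset) into a flat shape table.
read_shapes <- function(shapes) {
  q <- if (inherits(shapes, "quadset")) as.data.frame(shapes)
       else as.data.frame(parse_quads(shapes, "turtle"))
  sh <- function(x) paste0(NS_SH, x)
  hkg <- function(x) paste0(HKG, x)
  digest <- q$o[q$p == hkg("modelDigest")]
  node_shapes <- q$s[q$p == IRI_RDF_TYPE & q$o == sh("NodeShape")]
  shapes_list <- list()
  for (ns in node_shapes) {
    target <- q$o[q$s == ns & q$p == sh("targetClass")]
    pshapes <- q$o[q$s == ns & q$p == sh("property")]
    props <- list()
    for (ps in pshapes) {
      path <- q$o[q$s == ps & q$p == sh("path")]
      inlist <- NULL
      in_head <- q[q$s == ps & q$p == sh("in"), , drop = FALSE]
      if (nrow(in_head) > 0) {
        inlist <- collect_rdf_list(q, in_head$o[1], in_head$o_kind[1])$o
      }
      g1 <- function(p) { v <- q$o[q$s == ps & q$p == p]
                          if (length(v) > 0) v[1] else NA_character_ }
      props[[length(props) + 1L]] <- list(
        shape = ps,
        path = path[1],
        min_count = g1(sh("minCount")),
        max_count = g1(sh("maxCount")),
        datatype = g1(sh("datatype")),
        class = g1(sh("class")),
        node_kind = g1(sh("nodeKind")),
        in_list = inlist,
        terminology_check = identical(g1(hkg("terminologyCheck")), "true")
      )
    }
    shapes_list[[length(shapes_list) + 1L]] <-
      list(shape = ns, target_class = target[1], properties = props)
  }
  list(digest = if (length(digest) > 0) digest[1] else NA_character_,
       shapes = shapes_list)
}

#' Validate quads against SHACL shapes and terminologies
#'
#' Reports every cardinality, datatype, class, node-kind, and value-set
#' membership violation with its focus node, and flags coded values absent
#' from the loaded terminology graphs. When `model` is given, the shapes
#' graph's embedded model fingerprint is checked first and a mismatch (shapes
#' generated from a different schema version) is a hard error.
#'
#' @param quads A [quadset()] (one patient graph or several).
#' @param shapes Shapes graph: Turtle text (from [gen_shacl()]) or a
#'   `quadset`.
#' @param terminologies List of terminology graphs (Turtle text or
#'   `quadset`s) declaring permitted code IRIs as `<code> a hkg:Code`.
#' @param model Optional `concept_model` for the version check and
#'   completeness statistics.
#' @param patient_id Identifier recorded in the report.
#' @return A [validation_report()].
#' @export
shacl_validate <- function(quads, shapes, terminologies = list(),
                           model = NULL, patient_id = NA_character_) {
  parsed <- read_shapes(shapes)
  if (!is.null(model)) {
    want <- model_digest(model)
    if (!is.na(parsed$digest) && parsed$digest != want) {
      stop("validation error: shapes graph was generated from a different ",
           "schema version (digest ", parsed$digest, ", expected ", want, ")",
           call. = FALSE)
    }
  }
  q <- as.data.frame(quads)
  codes <- terminology_codes(terminologies)
  rows <- list()
  add <- function(kind, focus, property, message) {
    rows[[length(rows) + 1L]] <<- data.frame(
      severity = "Violation", constraint_kind = kind, focus_node = focus,
      property = property, message = message, stringsAsFactors = FALSE)
  }

  for (nshape in parsed$shapes) {
    focus_nodes <- unique(q$s[q$p == IRI_RDF_TYPE & q$o == nshape$target_class])
    for (focus in focus_nodes) {
      for (ps in nshape$properties) {
        vals <- q[q$s == focus & q$p == ps$path, , drop = FALSE]
        n <- nrow(vals)
        pname <- iri_local_name(ps$path)
        if (!is.na(ps$min_count) && n < as.integer(ps$min_count)) {
          add("min_count", focus, pname,
              paste0("mandatory property ", pname, " has ", n,
                     " value(s), fewer than minCount ", ps$min_count))
        }
        if (!is.na(ps$max_count) && n > as.integer(ps$max_count)) {
          add("max_count", focus, pname,
              paste0("property ", pname, " has ", n,
                     " value(s), more than maxCount ", ps$max_count))
        }
        if (n == 0) next
        if (!is.na(ps$datatype)) {
          bad <- vals$o_kind != "literal" | vals$dtype != ps$datatype
          for (i in which(bad)) {
            add("datatype", focus, pname,
                paste0("value '", vals$o[i], "' of ", pname,
                       " is not a literal of datatype ",
                       iri_local_name(ps$datatype)))
          }
          # lexical-form check for the datatypes the dialect uses
          lexok <- lexical_ok(vals$o, ps$datatype)
          for (i in which(!bad & !lexok)) {
            add("datatype", focus, pname,
                paste0("value '", vals$o[i], "' is not a valid ",
                       iri_local_name(ps$datatype), " lexical form"))
          }
        }
        if (identical(ps$node_kind, paste0(NS_SH, "IRI"))) {
          for (i in which(vals$o_kind != "iri")) {
            add("node_kind", focus, pname,
                paste0("value of ", pname, " must be an IRI"))
          }
        }
        if (!is.null(ps$in_list)) {
          for (i in which(!vals$o %in% ps$in_list)) {
            add("value_set", focus, pname,
                paste0("value <", vals$o[i], "> of ", pname,
                       " is not in the permitted value list"))
          }
        }
        if (!is.na(ps$class)) {
          for (i in seq_len(n)) {
            if (vals$o_kind[i] != "iri") next
            typed <- any(q$s == vals$o[i] & q$p == IRI_RDF_TYPE &
                           q$o == ps$class)
            if (!typed) {
              add("class", focus, pname,
                  paste0("value <", vals$o[i], "> of ", pname,
                         " is not an instance of ", iri_local_name(ps$class)))
            }
          }
        }
        if (ps$terminology_check) {
          for (i in which(vals$o_kind == "iri")) {
            if (!vals$o[i] %in% codes) {
              add("terminology", focus, pname,
                  paste0("code <", vals$o[i], "> of ", pname,
                         " is absent from the loaded terminology graphs ",
                         "(unknown or outdated code)"))
            }
          }
        }
      }
    }
  }
  findings <- if (length(rows) == 0) empty_findings() else do.call(rbind, rows)
  completeness <- if (!is.null(model)) completeness_stats(quads, model) else
    data.frame()
  validation_report(patient_id, nrow(findings) == 0, findings, completeness)
}

terminology_codes <- function(terminologies) {
  codes <- character(0)
  for (tg in terminologies) {
    q <- if (inherits(tg, "quadset")) as.data.frame(tg)
         else as.data.frame(parse_quads(tg, "turtle"))
    codes <- c(codes, q$s[q$p == IRI_RDF_TYPE & q$o == paste0(HKG, "Code")])
  }
  unique(codes)
}

lexical_ok <- function(vals, datatype) {
  token <- iri_local_name(datatype)
  switch(token,
    date = vapply(vals, is_valid_date, TRUE),
    dateTime = vapply(vals, is_valid_datetime, TRUE),
    integer = grepl("^[+-]?[0-9]+$", vals),
    decimal = grepl("^[+-]?[0-9]+(\\.[0-9]+)?$", vals),
    double = grepl("^[+-]?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$", vals),
    boolean = vals %in% c("true", "false"),
    rep(TRUE, length(vals)))
}

#' Check that event start dates do not fall after their end dates
#'
#' For every concept whose schema declares a start/end property pair, each
#' instance whose start value is strictly after its end value yields one
#' Violation. Start equal to end passes (same-day admission and discharge are
#' routine), and verdicts are invariant under date shifting since a constant
#' shift preserves order.
#'
#' @param quads A [quadset()].
#' @param model A `concept_model`.
#' @return Findings data frame (same columns as in a [validation_report()]).
#' @export
logic_check_dates <- function(quads, model) {
  q <- as.data.frame(quads)
  rows <- list()
  for (cd in model$concepts) {
    if (is.na(cd$start_property) || is.na(cd$end_property)) next
    sp <- cd$properties[[cd$start_property]]
    ep <- cd$properties[[cd$end_property]]
    instances <- unique(q$s[q$p == IRI_RDF_TYPE & q$o == cd$iri])
    for (inst in instances) {
      sv <- q$o[q$s == inst & q$p == sp$iri]
      ev <- q$o[q$s == inst & q$p == ep$iri]
      if (length(sv) == 0 || length(ev) == 0) next
      s_t <- temporal_to_num(sv[1], sp$scalar_datatype)
      e_t <- temporal_to_num(ev[1], ep$scalar_datatype)
      if (is.na(s_t) || is.na(e_t)) next  # malformed lexicals are datatype findings
      if (s_t > e_t) {
        rows[[length(rows) + 1L]] <- data.frame(
          severity = "Violation", constraint_kind = "start_after_end",
          focus_node = inst, property = cd$start_property,
          message = paste0(cd$name, " instance has start '", sv[1],
                           "' after end '", ev[1], "'"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) empty_findings() else do.call(rbind, rows)
}

temporal_to_num <- function(v, datatype) {
  if (datatype == "date") {
    if (!is_valid_date(v)) return(NA_real_)
    as.numeric(as.Date(v)) * 86400
  } else {
    if (!is_valid_datetime(v)) return(NA_real_)
    as.numeric(as.Date(substr(v, 1, 10))) * 86400 +
      as.integer(substr(v, 12, 13)) * 3600 +
      as.integer(substr(v, 15, 16)) * 60 +
      as.integer(substr(v, 18, 19))
  }
}

#' Completeness statistics over quads
#'
#' Per (concept, property): the number of instances carrying at least one
#' value; per concept: the instance count. Presence counts, the minimal
#' quantitative completeness measure.
#'
#' @param quads A [quadset()] (any number of patient graphs).
#' @param model A `concept_model`.
#' @return Data frame with columns `concept`, `property` (`NA` on the
#'   instance-count rows) and `count`.
#' @export
completeness_stats <- function(quads, model) {
  q <- as.data.frame(quads)
  rows <- list()
  for (cd in model$concepts) {
    instances <- unique(q$s[q$p == IRI_RDF_TYPE & q$o == cd$iri])
    rows[[length(rows) + 1L]] <- data.frame(
      concept = cd$name, property = NA_character_,
      count = length(instances), stringsAsFactors = FALSE)
    for (pd in cd$properties) {
      with_val <- unique(q$s[q$p == pd$iri & q$s %in% instances])
      rows[[length(rows) + 1L]] <- data.frame(
        concept = cd$name, property = pd$name,
        count = length(with_val), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
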