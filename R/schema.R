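# Schema dialect and concept model.
#
# The dialect is a small, fully documented Turtle vocabulary:
#   - concepts are owl:Class declarations;
#   - the patient class carries `hkg:isSubject true`;
#   - properties are owl:DatatypeProperty / owl:ObjectProperty with
#     rdfs:domain and rdfs:range; cardinalities via hkg:minCount /
#     hkg:maxCount (integer, or the string "unbounded");
#   - inline value sets are `hkg:ValueSet` nodes with ordered `hkg:member`
#     IRIs; terminology-backed sets are `hkg:ExternalValueSet` nodes whose
#     permitted codes are supplied at project setup as terminology graphs;
#   - `hkg:sharedIdentifier true` marks a property exempt from IRI minting;
#   - `hkg:eventStart` / `hkg:eventEnd` on a class declare the property pair
#     checked by the start-before-end logic check;
#   - an optional owl:Ontology node may carry `hkg:schemaPrefix "..."`.
# All generated artifacts iterate concepts and properties in declaration
# order, with lexicographic tie-breaks, so regeneration is byte-stable.

#' Parse a schema document into a concept model
#'
#' Reads a Turtle schema written in the package's schema dialect (see
#' `vignette("healthkg-methods")`) and returns the internal concept model from
#' which all ingestion templates, SHACL shapes and transformation logic are
#' derived. The schema is the single source of truth: nothing downstream
#' consults the Turtle document again.
#'
#' @param schema_doc Turtle text or a path to a `.ttl` file.
#' @return A `concept_model` object: a list with `schema_prefix`,
#'   `concepts` (named list of concept definitions, declaration order),
#'   `value_sets`, and `subject_concept`. Each concept definition holds
#'   `name`, `iri`, `is_core`, `properties` (named list), and the optional
#'   `start_property`/`end_property` pair. Each property definition holds
#'   `name`, `iri`, `range_kind` (`"scalar"`, `"temporal"`, `"value_set"` or
#'   `"concept"`), `scalar_datatype`, `target`, `min_count`, `max_count`
#'   (`Inf` when unbounded) and `shared_identifier`.
#' @export
parse_schema <- function(schema_doc) {
  q <- parse_quads(schema_doc, "turtle")
  q <- as.data.frame(q)

  hkg <- function(x) paste0(HKG, x)
  type_of <- function(s) q$o[q$s == s & q$p == IRI_RDF_TYPE]

  # classes, in declaration order
  class_iris <- unique(q$s[q$p == IRI_RDF_TYPE & q$o == paste0(NS_OWL, "Class")])
  vs_iris <- unique(q$s[q$p == IRI_RDF_TYPE &
                          q$o %in% c(hkg("ValueSet"), hkg("ExternalValueSet"))])
  prop_iris <- unique(q$s[q$p == IRI_RDF_TYPE &
                            q$o %in% paste0(NS_OWL, c("DatatypeProperty", "ObjectProperty"))])

  if (length(class_iris) == 0) {
    stop("schema error: no concept (owl:Class) declarations found", call. = FALSE)
  }

  # subject class
  subj_flag <- q$s[q$p == hkg("isSubject") & q$o == "true"]
  subj_flag <- intersect(subj_flag, class_iris)
  if (length(subj_flag) != 1) {
    stop("schema configuration error: expected exactly one class marked ",
         "hkg:isSubject true, found ", length(subj_flag), call. = FALSE)
  }

  concept_names <- vapply(class_iris, iri_local_name, "")
  if (anyDuplicated(concept_names)) {
    stop("schema error: duplicate concept names: ",
         paste(unique(concept_names[duplicated(concept_names)]), collapse = ", "),
         call. = FALSE)
  }

  # value sets
  value_sets <- list()
  for (vi in vs_iris) {
    nm <- iri_local_name(vi)
    external <- hkg("ExternalValueSet") %in% type_of(vi)
    members <- q$o[q$s == vi & q$p == hkg("member")]
    if (!external && length(members) == 0) {
      stop("schema error: value set '", nm, "' has no members", call. = FALSE)
    }
    if (anyDuplicated(members)) {
      stop("schema error: value set '", nm, "' has duplicate members", call. = FALSE)
    }
    value_sets[[nm]] <- list(name = nm, iri = vi, members = members,
                             external = external)
  }
  if (anyDuplicated(names(value_sets))) {
    stop("schema error: duplicate value-set names", call. = FALSE)
  }

  xsd_scalar <- paste0(NS_XSD, c("string", "integer", "decimal", "double", "boolean"))
  xsd_temporal <- paste0(NS_XSD, c("date", "dateTime"))

  # properties, keyed by domain class
  props_by_domain <- stats::setNames(vector("list", length(class_iris)), class_iris)
  for (pi in prop_iris) {
    pname <- iri_local_name(pi)
    domains <- unique(q$o[q$s == pi & q$p == paste0(NS_RDFS, "domain")])
    ranges <- unique(q$o[q$s == pi & q$p == paste0(NS_RDFS, "range")])
    if (length(domains) != 1) {
      stop("schema error: property '", pname, "' must declare exactly one ",
           "rdfs:domain", call. = FALSE)
    }
    if (length(ranges) != 1) {
      stop("schema error: property '", pname, "' must declare exactly one ",
           "rdfs:range", call. = FALSE)
    }
    if (!domains %in% class_iris) {
      stop("schema error: property '", pname, "' has unknown domain <",
           domains, ">", call. = FALSE)
    }
    rng <- ranges
    if (rng %in% xsd_scalar) {
      range_kind <- "scalar"; dt <- iri_local_name(rng); target <- NA_character_
    } else if (rng %in% xsd_temporal) {
      range_kind <- "temporal"; dt <- iri_local_name(rng); target <- NA_character_
    } else if (rng %in% vs_iris) {
      range_kind <- "value_set"; dt <- NA_character_; target <- iri_local_name(rng)
    } else if (rng %in% class_iris) {
      range_kind <- "concept"; dt <- NA_character_; target <- iri_local_name(rng)
    } else {
      stop("schema error: property '", pname, "' has dangling range <",
           rng, ">: not a datatype, declared concept or value set", call. = FALSE)
    }
    mc <- q$o[q$s == pi & q$p == hkg("minCount")]
    xc <- q$o[q$s == pi & q$p == hkg("maxCount")]
    min_count <- if (length(mc) > 0) as.integer(mc[1]) else 0L
    max_count <- if (length(xc) == 0) 1 else if (xc[1] == "unbounded") Inf
                 else as.numeric(xc[1])
    if (is.finite(max_count) && min_count > max_count) {
      stop("schema error: property '", pname, "' has minCount > maxCount",
           call. = FALSE)
    }
    shared <- "true" %in% q$o[q$s == pi & q$p == hkg("sharedIdentifier")]
    props_by_domain[[domains]] <- c(props_by_domain[[domains]], list(list(
      name = pname, iri = pi, range_kind = range_kind, scalar_datatype = dt,
      target = target, min_count = min_count, max_count = max_count,
      shared_identifier = shared
    )))
  }

  concepts <- list()
  for (ci in class_iris) {
    nm <- iri_local_name(ci)
    props <- props_by_domain[[ci]]
    pnames <- vapply(props, `[[`, "", "name")
    if (anyDuplicated(pnames)) {
      stop("schema error: duplicate property names on concept '", nm, "'",
           call. = FALSE)
    }
    names(props) <- pnames
    sp <- q$o[q$s == ci & q$p == hkg("eventStart")]
    ep <- q$o[q$s == ci & q$p == hkg("eventEnd")]
    concepts[[nm]] <- list(
      name = nm, iri = ci, is_core = FALSE,
      properties = if (is.null(props)) list() else props,
      start_property = if (length(sp) > 0) iri_local_name(sp[1]) else NA_character_,
      end_property = if (length(ep) > 0) iri_local_name(ep[1]) else NA_character_
    )
  }

  # schema prefix from the optional ontology node
  ont <- q$s[q$p == IRI_RDF_TYPE & q$o == paste0(NS_OWL, "Ontology")]
  pfx <- if (length(ont) > 0) q$o[q$s == ont[1] & q$p == hkg("schemaPrefix")]
         else character(0)
  schema_prefix <- if (length(pfx) > 0) pfx[1] else "schema"

  model <- structure(list(
    schema_prefix = schema_prefix,
    concepts = concepts,
    value_sets = value_sets,
    subject_concept = iri_local_name(subj_flag)
  ), class = "concept_model")

  core <- identify_core_concepts(model)
  for (nm in names(model$concepts)) {
    model$concepts[[nm]]$is_core <- nm %in% core
  }
  validate_model(model)
  model
}

validate_model <- function(model) {
  for (cd in model$concepts) {
    for (pd in cd$properties) {
      if (pd$range_kind == "concept" && !pd$target %in% names(model$concepts)) {
        stop("schema error: property '", pd$name, "' references unknown concept '",
             pd$target, "'", call. = FALSE)
      }
      if (pd$range_kind == "value_set" && !pd$target %in% names(model$value_sets)) {
        stop("schema error: property '", pd$name, "' references unknown value set '",
             pd$target, "'", call. = FALSE)
      }
    }
  }
  if (!model$subject_concept %in% names(model$concepts)) {
    stop("schema configuration error: subject concept not declared", call. = FALSE)
  }
  invisible(model)
}

#' @export
print.concept_model <- function(x, ...) {
  core <- identify_core_concepts(x)
  cat("<concept_model> prefix '", x$schema_prefix, "': ",
      length(x$concepts), " concept(s), ", length(x$value_sets),
      " value set(s)\n", sep = "")
  for (cd in x$concepts) {
    cat("  ", cd$name, if (cd$name == x$subject_concept) " [subject]"
        else if (cd$name %in% core) " [core]" else " [embedded]",
        ": ", length(cd$properties), " propert",
        if (length(cd$properties) == 1) "y" else "ies", "\n", sep = "")
  }
  invisible(x)
}

#' Classify concepts as core or embedded
#'
#' A concept is *core* when it is directly linked to the patient: it is the
#' range of a property whose domain is the subject class (one hop), or it is
#' the subject class itself. Core concepts get their own ingestion tables and
#' carry provider-supplied instance identifiers; all other concepts are
#' *embedded* into the table of the concept that owns them.
#'
#' @param model A `concept_model`.
#' @return Character vector of core concept names, in declaration order.
#' @export
identify_core_concepts <- function(model) {
  subj <- model$concepts[[model$subject_concept]]
  targets <- vapply(subj$properties, function(pd) {
    if (pd$range_kind == "concept") pd$target else NA_character_
  }, "")
  core <- unique(c(model$subject_concept, stats::na.omit(targets)))
  names(model$concepts)[names(model$concepts) %in% core]
}

# Declaration-ordered helper views --------------------------------------------

subject_link_properties <- function(model) {
  subj <- model$concepts[[model$subject_concept]]
  Filter(function(pd) pd$range_kind == "concept", subj$properties)
}

core_concepts <- function(model) {
  core <- identify_core_concepts(model)
  model$concepts[core]
}

# Serialize a concept model back to dialect Turtle (deterministic).
#' Write a concept model as a schema document
#'
#' Inverse of [parse_schema()]: emits the model in the schema dialect, with
#' deterministic statement ordering. `parse_schema(write_schema(m))` yields a
#' model identical to `m`.
#'
#' @param model A `concept_model`.
#' @return Turtle text.
#' @export
write_schema <- function(model) {
  ns <- sub("[^#/]*$", "", model$concepts[[1]]$iri)
  lines <- c(
    paste0("@prefix owl: <", NS_OWL, "> ."),
    paste0("@prefix rdfs: <", NS_RDFS, "> ."),
    paste0("@prefix xsd: <", NS_XSD, "> ."),
    paste0("@prefix hkg: <", HKG, "> ."),
    "",
    paste0("<", ns, "ontology> a owl:Ontology ; hkg:schemaPrefix \"",
           model$schema_prefix, "\" ."),
    ""
  )
  for (vs in model$value_sets) {
    kind <- if (isTRUE(vs$external)) "hkg:ExternalValueSet" else "hkg:ValueSet"
    lines <- c(lines, paste0("<", vs$iri, "> a ", kind, " ."))
    for (m in vs$members) {
      lines <- c(lines, paste0("<", vs$iri, "> hkg:member <", m, "> ."))
    }
  }
  lines <- c(lines, "")
  for (cd in model$concepts) {
    lines <- c(lines, paste0("<", cd$iri, "> a owl:Class ."))
    if (cd$name == model$subject_concept) {
      lines <- c(lines, paste0("<", cd$iri, "> hkg:isSubject true ."))
    }
    if (!is.na(cd$start_property)) {
      sp <- cd$properties[[cd$start_property]]$iri
      ep <- cd$properties[[cd$end_property]]$iri
      lines <- c(lines,
                 paste0("<", cd$iri, "> hkg:eventStart <", sp, "> ."),
                 paste0("<", cd$iri, "> hkg:eventEnd <", ep, "> ."))
    }
  }
  lines <- c(lines, "")
  for (cd in model$concepts) {
    for (pd in cd$properties) {
      ptype <- if (pd$range_kind %in% c("scalar", "temporal"))
        "owl:DatatypeProperty" else "owl:ObjectProperty"
      rng <- if (pd$range_kind %in% c("scalar", "temporal")) {
        paste0("xsd:", pd$scalar_datatype)
      } else if (pd$range_kind == "value_set") {
        paste0("<", model$value_sets[[pd$target]]$iri, ">")
      } else {
        paste0("<", model$concepts[[pd$target]]$iri, ">")
      }
      xc <- if (is.infinite(pd$max_count)) "\"unbounded\""
            else format(pd$max_count)
      ln <- paste0("<", pd$iri, "> a ", ptype, " ; rdfs:domain <", cd$iri,
                   "> ; rdfs:range ", rng, " ; hkg:minCount ", pd$min_count,
                   " ; hkg:maxCount ", xc,
                   if (pd$shared_identifier) " ; hkg:sharedIdentifier true" else "",
                   " .")
      lines <- c(lines, ln)
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

# Stable fingerprint of a model, embedded into generated shapes so that
# validation can detect a shapes/model version mismatch.
model_digest <- function(model) {
  fnv1a32(write_schema(model))
}

# snake_case of a CamelCase/hasCamelCase token; used for column and table names
to_snake <- function(x) {
  x <- sub("^has(?=[A-Z])", "", x, perl = TRUE)
  x <- gsub("([a-z0-9])([A-Z])", "\\1_\\2", x)
  tolower(x)
}
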