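# Transformation of patient bundles into per-patient named graphs under the
# four-part IRI naming convention:
#   base / provider_uid / schema_prefix / ClassName / local_id
# The first three parts are supplied by the system; only the local id comes
# from the data provider. One patient = one named graph, no blank nodes.

#' Default base IRI of the naming convention
#' @format Length-one character vector.
#' @export
DEFAULT_BASE_IRI <- "https://kg.example.org/data"

#' Create an IRI minting policy
#'
#' @param provider_uid Data-provider enterprise identifier (for Swiss
#'   providers typically the UID, e.g. `"CHE-123.456.789"`).
#' @param schema_prefix Prefix naming the schema the instances follow.
#' @param base Base IRI (no trailing slash).
#' @return An `iri_policy` object.
#' @export
iri_policy <- function(provider_uid, schema_prefix,
                       base = DEFAULT_BASE_IRI) {
  for (part in c(provider_uid, schema_prefix)) {
    if (!nzchar(part) || !grepl(ID_PATTERN, part, perl = TRUE)) {
      stop("IRI policy error: '", part, "' contains characters that are not ",
           "IRI-safe", call. = FALSE)
    }
  }
  structure(list(base = sub("/+$", "", base), provider_uid = provider_uid,
                 schema_prefix = schema_prefix), class = "iri_policy")
}

#' Mint an instance IRI
#'
#' @param policy An [iri_policy()].
#' @param class_name Concept/class name of the instance.
#' @param local_id Provider-supplied instance identifier; must be IRI-safe
#'   (`[A-Za-z0-9._~-]+`, no spaces or invalid characters).
#' @return The minted IRI string.
#' @export
mint_iri <- function(policy, class_name, local_id) {
  if (!nzchar(local_id) || !grepl(ID_PATTERN, local_id, perl = TRUE)) {
    stop("IRI minting error: local id '", local_id, "' contains spaces or ",
         "invalid characters", call. = FALSE)
  }
  paste(policy$base, policy$provider_uid, policy$schema_prefix, class_name,
        local_id, sep = "/")
}

xsd_datatype_iri <- function(token) paste0(NS_XSD, token)

patient_graph_iri <- function(policy, model, patient_local_id) {
  mint_iri(policy, model$subject_concept, patient_local_id)
}

#' Transform a patient bundle into a named graph of quads
#'
#' Every record becomes a typed node (one `rdf:type` statement to its class
#' IRI); scalar and temporal fields become typed literals; value-set and
#' coded fields become object statements to the member/code IRI; links become
#' object statements to the minted IRIs of the linked instances;
#' shared-identifier fields are emitted verbatim as plain literals, bypassing
#' the IRI convention. All statements carry the patient's graph IRI (minted
#' like an instance IRI of the subject concept).
#'
#' @param bundle A `patient_bundle` (must have passed [precheck()]).
#' @param model A `concept_model`.
#' @param policy An [iri_policy()].
#' @return A [quadset()].
#' @export
bundle_to_quads <- function(bundle, model, policy) {
  if (length(bundle$records) == 0) return(quadset())
  graph <- patient_graph_iri(policy, model, bundle$patient_local_id)
  rows <- list()
  emit <- function(s, p, o, o_kind, dtype = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      s = s, s_kind = "iri", p = p, o = o, o_kind = o_kind, dtype = dtype,
      graph = graph, stringsAsFactors = FALSE)
  }
  for (rec in bundle$records) {
    cd <- model$concepts[[rec$concept]]
    node <- mint_iri(policy, rec$concept, rec$id)
    emit(node, IRI_RDF_TYPE, cd$iri, "iri")
    for (nm in names(rec$fields)) {
      pd <- cd$properties[[nm]]
      for (v in rec$fields[[nm]]) {
        if (pd$range_kind == "value_set") {
          vs <- model$value_sets[[pd$target]]
          if (isTRUE(vs$external)) {
            emit(node, pd$iri, v, "iri")
          } else {
            hit <- vs$members[vs_member_tokens(vs) == v]
            if (length(hit) == 0) {
              stop("transformation error: value '", v, "' of ", rec$concept,
                   ".", nm, " is not a member of value set ", pd$target,
                   call. = FALSE)
            }
            emit(node, pd$iri, hit[1], "iri")
          }
        } else {
          emit(node, pd$iri, v, "literal",
               xsd_datatype_iri(pd$scalar_datatype))
        }
      }
    }
    for (nm in names(rec$shared)) {
      pd <- cd$properties[[nm]]
      for (v in rec$shared[[nm]]) {
        # shared identifiers are exempt from the IRI naming convention
        emit(node, pd$iri, v, "literal", XSD_STRING)
      }
    }
    for (nm in names(rec$links)) {
      pd <- cd$properties[[nm]]
      for (tid in rec$links[[nm]]) {
        if (is.null(find_record(bundle, pd$target, tid))) {
          stop("transformation error: link ", rec$concept, ".", nm,
               " names ", pd$target, " instance '", tid,
               "' absent from the bundle", call. = FALSE)
        }
        emit(node, pd$iri, mint_iri(policy, pd$target, tid), "iri")
      }
    }
  }
  quadset(do.call(rbind, rows))
}
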