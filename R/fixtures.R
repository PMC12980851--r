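# Synthetic fixtures: a small hospital-style schema (patient, diagnoses,
# administrative cases with embedded admissions, samples), a toy diagnosis
# terminology, hand-written oracle shapes, and a seeded corpus generator
# that can inject a controlled set of violations recorded in a ledger.
# Everything is generated in code; no external downloads.

TOY_NS <- "https://example.org/toy#"
TOY_CODE_NS <- "https://example.org/toycodes/"

#' Generate the toy schema and its hand-written oracle shapes
#'
#' The schema covers the structures the pipeline must handle: a Subject
#' (patient) class with an administrative-sex value set, birth date and
#' free-text name; Diagnosis coded against a terminology-backed value set
#' and linked to an AdministrativeCase; AdministrativeCase with an embedded
#' (non-core) Admission holding the admission/discharge date-time pair used
#' by the start-before-end logic check; and a Sample carrying a shared
#' identifier exempt from IRI minting.
#'
#' The oracle shapes are written by hand, independently of [gen_shacl()],
#' and are compared with the generated shapes at the verdict level.
#'
#' @return List with `schema` (Turtle text), `oracle_shapes` (Turtle text)
#'   and `terminology` (Turtle text declaring the permitted diagnosis codes).
#' @export
make_toy_schema <- function() {
  schema <- paste0('@prefix owl: <', NS_OWL, '> .
@prefix rdfs: <', NS_RDFS, '> .
@prefix xsd: <', NS_XSD, '> .
@prefix hkg: <', HKG, '> .
@prefix ex: <', TOY_NS, '> .

ex:ontology a owl:Ontology ; hkg:schemaPrefix "toy" .

ex:AdministrativeSex a hkg:ValueSet ;
  hkg:member ex:sex-male, ex:sex-female, ex:sex-other .

ex:ToyDiagnosisCodes a hkg:ExternalValueSet .

ex:Subject a owl:Class ; hkg:isSubject true .
ex:Diagnosis a owl:Class .
ex:AdministrativeCase a owl:Class .
ex:Admission a owl:Class ;
  hkg:eventStart ex:hasAdmissionDatetime ;
  hkg:eventEnd ex:hasDischargeDatetime .
ex:Sample a owl:Class .

ex:hasAdministrativeSex a owl:ObjectProperty ; rdfs:domain ex:Subject ;
  rdfs:range ex:AdministrativeSex ; hkg:minCount 1 ; hkg:maxCount 1 .
ex:hasBirthDate a owl:DatatypeProperty ; rdfs:domain ex:Subject ;
  rdfs:range xsd:date ; hkg:minCount 0 ; hkg:maxCount 1 .
ex:hasName a owl:DatatypeProperty ; rdfs:domain ex:Subject ;
  rdfs:range xsd:string ; hkg:minCount 0 ; hkg:maxCount 1 .
ex:hasDiagnosis a owl:ObjectProperty ; rdfs:domain ex:Subject ;
  rdfs:range ex:Diagnosis ; hkg:minCount 0 ; hkg:maxCount "unbounded" .
ex:hasCase a owl:ObjectProperty ; rdfs:domain ex:Subject ;
  rdfs:range ex:AdministrativeCase ; hkg:minCount 0 ; hkg:maxCount "unbounded" .
ex:hasSample a owl:ObjectProperty ; rdfs:domain ex:Subject ;
  rdfs:range ex:Sample ; hkg:minCount 0 ; hkg:maxCount "unbounded" .

ex:hasCode a owl:ObjectProperty ; rdfs:domain ex:Diagnosis ;
  rdfs:range ex:ToyDiagnosisCodes ; hkg:minCount 1 ; hkg:maxCount 1 .
ex:hasRecordDatetime a owl:DatatypeProperty ; rdfs:domain ex:Diagnosis ;
  rdfs:range xsd:dateTime ; hkg:minCount 0 ; hkg:maxCount 1 .
ex:hasAdministrativeCase a owl:ObjectProperty ; rdfs:domain ex:Diagnosis ;
  rdfs:range ex:AdministrativeCase ; hkg:minCount 0 ; hkg:maxCount 1 .

ex:hasAdmission a owl:ObjectProperty ; rdfs:domain ex:AdministrativeCase ;
  rdfs:range ex:Admission ; hkg:minCount 1 ; hkg:maxCount 1 .

ex:hasAdmissionDatetime a owl:DatatypeProperty ; rdfs:domain ex:Admission ;
  rdfs:range xsd:dateTime ; hkg:minCount 1 ; hkg:maxCount 1 .
ex:hasDischargeDatetime a owl:DatatypeProperty ; rdfs:domain ex:Admission ;
  rdfs:range xsd:dateTime ; hkg:minCount 0 ; hkg:maxCount 1 .

ex:hasSharedIdentifier a owl:DatatypeProperty ; rdfs:domain ex:Sample ;
  rdfs:range xsd:string ; hkg:minCount 0 ; hkg:maxCount 1 ;
  hkg:sharedIdentifier true .
ex:hasCollectionDatetime a owl:DatatypeProperty ; rdfs:domain ex:Sample ;
  rdfs:range xsd:dateTime ; hkg:minCount 0 ; hkg:maxCount 1 .
')

  # Hand-written shapes: independent of gen_shacl(), same intended semantics.
  oracle_shapes <- paste0('@prefix sh: <', NS_SH, '> .
@prefix xsd: <', NS_XSD, '> .
@prefix hkg: <', HKG, '> .
@prefix ex: <', TOY_NS, '> .
@prefix orc: <urn:oracle:shapes:> .

orc:SubjectShape a sh:NodeShape ; sh:targetClass ex:Subject ;
  sh:property orc:sub-sex, orc:sub-birth, orc:sub-name,
    orc:sub-diag, orc:sub-case, orc:sub-sample .
orc:sub-sex a sh:PropertyShape ; sh:path ex:hasAdministrativeSex ;
  sh:minCount 1 ; sh:maxCount 1 ; sh:nodeKind sh:IRI ;
  sh:in ( ex:sex-male ex:sex-female ex:sex-other ) .
orc:sub-birth a sh:PropertyShape ; sh:path ex:hasBirthDate ;
  sh:maxCount 1 ; sh:datatype xsd:date .
orc:sub-name a sh:PropertyShape ; sh:path ex:hasName ;
  sh:maxCount 1 ; sh:datatype xsd:string .
orc:sub-diag a sh:PropertyShape ; sh:path ex:hasDiagnosis ;
  sh:nodeKind sh:IRI ; sh:class ex:Diagnosis .
orc:sub-case a sh:PropertyShape ; sh:path ex:hasCase ;
  sh:nodeKind sh:IRI ; sh:class ex:AdministrativeCase .
orc:sub-sample a sh:PropertyShape ; sh:path ex:hasSample ;
  sh:nodeKind sh:IRI ; sh:class ex:Sample .

orc:DiagnosisShape a sh:NodeShape ; sh:targetClass ex:Diagnosis ;
  sh:property orc:diag-code, orc:diag-dt, orc:diag-case .
orc:diag-code a sh:PropertyShape ; sh:path ex:hasCode ;
  sh:minCount 1 ; sh:maxCount 1 ; sh:nodeKind sh:IRI ;
  hkg:terminologyCheck true .
orc:diag-dt a sh:PropertyShape ; sh:path ex:hasRecordDatetime ;
  sh:maxCount 1 ; sh:datatype xsd:dateTime .
orc:diag-case a sh:PropertyShape ; sh:path ex:hasAdministrativeCase ;
  sh:maxCount 1 ; sh:nodeKind sh:IRI ; sh:class ex:AdministrativeCase .

orc:CaseShape a sh:NodeShape ; sh:targetClass ex:AdministrativeCase ;
  sh:property orc:case-adm .
orc:case-adm a sh:PropertyShape ; sh:path ex:hasAdmission ;
  sh:minCount 1 ; sh:maxCount 1 ; sh:nodeKind sh:IRI ;
  sh:class ex:Admission .

orc:AdmissionShape a sh:NodeShape ; sh:targetClass ex:Admission ;
  sh:property orc:adm-in, orc:adm-out .
orc:adm-in a sh:PropertyShape ; sh:path ex:hasAdmissionDatetime ;
  sh:minCount 1 ; sh:maxCount 1 ; sh:datatype xsd:dateTime .
orc:adm-out a sh:PropertyShape ; sh:path ex:hasDischargeDatetime ;
  sh:maxCount 1 ; sh:datatype xsd:dateTime .

orc:SampleShape a sh:NodeShape ; sh:targetClass ex:Sample ;
  sh:property orc:smp-shared, orc:smp-coll .
orc:smp-shared a sh:PropertyShape ; sh:path ex:hasSharedIdentifier ;
  sh:maxCount 1 ; sh:datatype xsd:string .
orc:smp-coll a sh:PropertyShape ; sh:path ex:hasCollectionDatetime ;
  sh:maxCount 1 ; sh:datatype xsd:dateTime .
')

  list(schema = schema, oracle_shapes = oracle_shapes,
       terminology = make_toy_terminology())
}

#' Generate the toy diagnosis terminology graph
#'
#' @param n_codes Number of permitted codes (`C01`, `C02`, ...).
#' @return Turtle text declaring each code IRI as a `hkg:Code`.
#' @export
make_toy_terminology <- function(n_codes = 12L) {
  codes <- sprintf("C%02d", seq_len(n_codes))
  paste0("@prefix hkg: <", HKG, "> .\n\n",
         paste0("<", TOY_CODE_NS, codes, "> a hkg:Code .", collapse = "\n"),
         "\n")
}

toy_code_iris <- function(n_codes = 12L) {
  paste0(TOY_CODE_NS, sprintf("C%02d", seq_len(n_codes)))
}

VIOLATION_KINDS <- c("missing_mandatory", "bad_value_set", "bad_datatype",
                     "start_after_end", "malformed_id", "unknown_code")

#' Generate a synthetic patient corpus with an injection ledger
#'
#' Builds `n` patient bundles for the toy schema with a realistic shape: one
#' to five administrative cases (each with an embedded admission;
#' admission <= discharge by construction), zero to ten diagnoses coded from
#' the toy terminology and usually linked to a case, and up to two samples.
#' A fraction of patients receives exactly one injected violation each,
#' drawn from the six supported kinds; every mutation actually applied is
#' recorded in the returned ledger, and with `violation_rate = 0` the corpus
#' passes pre-check, JSON Schema, SHACL and the logic check end to end.
#'
#' @param model The toy `concept_model` (from
#'   `parse_schema(make_toy_schema()$schema)`).
#' @param n Number of patients.
#' @param seed Integer seed; the corpus is a deterministic function of it.
#' @param violation_rate Fraction of patients receiving one injected
#'   violation (`round(violation_rate * n)` patients).
#' @return List with `bundles` (list of `patient_bundle`) and `ledger`
#'   (data frame: `patient_local_id`, `concept`, `property`,
#'   `violation_kind`).
#' @export
make_patients <- function(model, n, seed = 1L, violation_rate = 0) {
  stopifnot(violation_rate >= 0, violation_rate <= 1)
  set.seed(seed)
  sex_tokens <- c("sex-male", "sex-female", "sex-other")
  first_names <- c("Anna", "Luca", "Mia", "Noah", "Lea", "Elias", "Sara",
                   "David", "Nina", "Jonas")
  last_names <- c("Keller", "Meier", "Weber", "Huber", "Schneider", "Frei",
                  "Baumann", "Graf", "Roth", "Brunner")
  codes <- toy_code_iris()

  rand_date <- function(from, to) {
    as.Date(from) + sample.int(as.integer(as.Date(to) - as.Date(from)), 1L)
  }
  rand_dt <- function(date) {
    sprintf("%sT%02d:%02d:%02d", format(date, "%Y-%m-%d"),
            sample(0:23, 1), sample(0:59, 1), sample(0:59, 1))
  }

  bundles <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("p-%04d", i)
    records <- list()
    slinks <- list()

    n_cases <- sample(1:5, 1)
    case_ids <- sprintf("%s-c%02d", pid, seq_len(n_cases))
    for (j in seq_len(n_cases)) {
      adm_date <- rand_date("2015-01-01", "2023-12-31")
      adm_dt <- rand_dt(adm_date)
      adm_id <- paste0(case_ids[j], "-admission")
      afields <- list(hasAdmissionDatetime = adm_dt)
      # the first case always carries a discharge (>= admission)
      if (j == 1 || stats::runif(1) < 0.9) {
        dis_date <- adm_date + sample(0:30, 1)
        afields$hasDischargeDatetime <-
          sprintf("%sT%02d:%02d:%02d", format(dis_date, "%Y-%m-%d"),
                  sample(0:23, 1), sample(0:59, 1), sample(0:59, 1))
        # same-day stays keep discharge time at/after admission time
        if (dis_date == adm_date &&
            afields$hasDischargeDatetime < adm_dt) {
          afields$hasDischargeDatetime <- adm_dt
        }
      }
      records[[length(records) + 1L]] <-
        instance_record("Admission", adm_id, afields)
      records[[length(records) + 1L]] <-
        instance_record("AdministrativeCase", case_ids[j],
                        links = list(hasAdmission = adm_id))
    }
    slinks$hasCase <- case_ids

    n_diag <- sample(0:10, 1)
    if (n_diag > 0) {
      diag_ids <- sprintf("%s-d%02d", pid, seq_len(n_diag))
      for (j in seq_len(n_diag)) {
        dfields <- list(hasCode = sample(codes, 1))
        if (stats::runif(1) < 0.7) {
          dfields$hasRecordDatetime <-
            rand_dt(rand_date("2015-01-01", "2023-12-31"))
        }
        dlinks <- list()
        if (stats::runif(1) < 0.8) {
          dlinks$hasAdministrativeCase <- sample(case_ids, 1)
        }
        records[[length(records) + 1L]] <-
          instance_record("Diagnosis", diag_ids[j], dfields, dlinks)
      }
      slinks$hasDiagnosis <- diag_ids
    }

    n_samp <- sample(0:2, 1)
    if (n_samp > 0) {
      samp_ids <- sprintf("%s-s%02d", pid, seq_len(n_samp))
      for (j in seq_len(n_samp)) {
        sfields <- list()
        sshared <- list()
        if (stats::runif(1) < 0.5) {
          sshared$hasSharedIdentifier <- sprintf("BIO-%06d", sample.int(999999, 1))
        }
        if (stats::runif(1) < 0.8) {
          sfields$hasCollectionDatetime <-
            rand_dt(rand_date("2015-01-01", "2023-12-31"))
        }
        records[[length(records) + 1L]] <-
          instance_record("Sample", samp_ids[j], sfields, shared = sshared)
      }
      slinks$hasSample <- samp_ids
    }

    sfields <- list(
      hasAdministrativeSex = sample(sex_tokens, 1),
      hasBirthDate = format(rand_date("1930-01-01", "2005-12-31"), "%Y-%m-%d"),
      hasName = paste(sample(first_names, 1), sample(last_names, 1))
    )
    srec <- instance_record("Subject", pid, sfields, slinks)
    bundles[[i]] <- patient_bundle(pid, c(list(srec), records))
  }

  # violation injection: one mutation per selected patient, ledgered
  k <- round(violation_rate * n)
  ledger_rows <- list()
  if (k > 0) {
    victims <- sort(sample.int(n, k))
    for (i in victims) {
      b <- bundles[[i]]
      has_diag <- any(vapply(b$records, function(r) r$concept == "Diagnosis",
                             TRUE))
      kinds <- if (has_diag) VIOLATION_KINDS else
        setdiff(VIOLATION_KINDS, "unknown_code")
      kind <- sample(kinds, 1)
      res <- inject_violation(b, kind)
      bundles[[i]] <- res$bundle
      ledger_rows[[length(ledger_rows) + 1L]] <- data.frame(
        patient_local_id = b$patient_local_id, concept = res$concept,
        property = res$property, violation_kind = kind,
        stringsAsFactors = FALSE)
    }
  }
  ledger <- if (length(ledger_rows) > 0) do.call(rbind, ledger_rows) else
    data.frame(patient_local_id = character(), concept = character(),
               property = character(), violation_kind = character(),
               stringsAsFactors = FALSE)
  list(bundles = bundles, ledger = ledger)
}

rec_index <- function(bundle, concept) {
  which(vapply(bundle$records, function(r) r$concept == concept, TRUE))
}

inject_violation <- function(bundle, kind) {
  subj_idx <- rec_index(bundle, "Subject")[1]
  if (kind == "missing_mandatory") {
    bundle$records[[subj_idx]]$fields$hasAdministrativeSex <- NULL
    list(bundle = bundle, concept = "Subject", property = "hasAdministrativeSex")
  } else if (kind == "bad_value_set") {
    bundle$records[[subj_idx]]$fields$hasAdministrativeSex <- "sex-unknown"
    list(bundle = bundle, concept = "Subject", property = "hasAdministrativeSex")
  } else if (kind == "bad_datatype") {
    adm_idx <- rec_index(bundle, "Admission")[1]
    bundle$records[[adm_idx]]$fields$hasDischargeDatetime <- "not-a-timestamp"
    list(bundle = bundle, concept = "Admission",
         property = "hasDischargeDatetime")
  } else if (kind == "start_after_end") {
    adm_idx <- rec_index(bundle, "Admission")[1]
    rec <- bundle$records[[adm_idx]]
    dis <- rec$fields$hasDischargeDatetime[1]
    late <- shift_lex(dis, sample(1:5, 1), "dateTime")
    bundle$records[[adm_idx]]$fields$hasAdmissionDatetime <- late
    list(bundle = bundle, concept = "Admission",
         property = "hasAdmissionDatetime")
  } else if (kind == "malformed_id") {
    case_idx <- rec_index(bundle, "AdministrativeCase")[1]
    old_id <- bundle$records[[case_idx]]$id
    new_id <- paste("case", substring(old_id, 1))  # embeds a space
    bundle$records[[case_idx]]$id <- new_id
    bundle$records <- lapply(bundle$records, function(r) {
      for (ln in names(r$links)) {
        r$links[[ln]][r$links[[ln]] == old_id] <- new_id
      }
      r
    })
    list(bundle = bundle, concept = "AdministrativeCase", property = "id")
  } else if (kind == "unknown_code") {
    diag_idx <- rec_index(bundle, "Diagnosis")[1]
    bundle$records[[diag_idx]]$fields$hasCode <- paste0(TOY_CODE_NS, "C999")
    list(bundle = bundle, concept = "Diagnosis", property = "hasCode")
  } else {
    stop("unknown violation kind '", kind, "'", call. = FALSE)
  }
}
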