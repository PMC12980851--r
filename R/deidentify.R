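# De-identification: field pseudonymization (random UUID minting with a
# persistent original<->pseudonym log), per-patient date shifting, and
# list/regex value substitution. All randomness is drawn from a dedicated
# per-project RNG stream seeded from the project salt, so parallel projects
# never share a pseudonym sequence and full re-runs replay byte-identically
# from the log.

#' Create a de-identification configuration
#'
#' @param scramble_fields List of selectors, each `c(concept, property)`;
#'   the pseudo-property `"id"` selects the instance identifiers of a
#'   concept (use the subject concept to pseudonymize patient identifiers).
#' @param date_shift_range Integer pair `c(lo_days, hi_days)`; each patient
#'   receives one uniform offset from this closed range, applied to every
#'   temporal value.
#' @param substitutions List of rules; each rule is a list with either
#'   `values` (explicit value list) or `pattern` (regular expression), plus
#'   `replacement`.
#' @param logging_enabled When `FALSE` the original<->pseudonym map is kept
#'   in memory only; replay across deliveries is impossible (one-off exports).
#' @param project_salt Opaque text mixed into the project RNG seed.
#' @return A `deid_config` object.
#' @export
deid_config <- function(scramble_fields = list(),
                        date_shift_range = c(0L, 0L),
                        substitutions = list(),
                        logging_enabled = TRUE,
                        project_salt = "") {
  if (length(date_shift_range) != 2 ||
      date_shift_range[1] > date_shift_range[2]) {
    stop("de-identification configuration error: date_shift_range must be ",
         "[lo_days, hi_days] with lo <= hi", call. = FALSE)
  }
  for (rule in substitutions) {
    has_values <- !is.null(rule$values)
    has_pattern <- !is.null(rule$pattern)
    if (has_values == has_pattern || is.null(rule$replacement)) {
      stop("de-identification configuration error: each substitution rule ",
           "needs exactly one of 'values' or 'pattern', plus 'replacement'",
           call. = FALSE)
    }
    if (has_pattern) {
      ok <- tryCatch({
        suppressWarnings(grepl(rule$pattern, "", perl = TRUE))
        TRUE
      }, error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok) {
        stop("de-identification configuration error: invalid pattern '",
             rule$pattern, "'", call. = FALSE)
      }
    }
  }
  structure(list(
    scramble_fields = lapply(scramble_fields, function(s)
      c(concept = unname(s[1]), property = unname(s[2]))),
    date_shift_range = as.integer(date_shift_range),
    substitutions = substitutions,
    logging_enabled = isTRUE(logging_enabled),
    project_salt = project_salt
  ), class = "deid_config")
}

#' Read a de-identification configuration from JSON
#'
#' @param path JSON file with fields `scramble_fields` (array of
#'   `[concept, property]` pairs), `date_shift_range`, `substitutions`,
#'   `logging_enabled`, `project_salt`.
#' @return A `deid_config` object.
#' @export
read_deid_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  deid_config(
    scramble_fields = lapply(x$scramble_fields, unlist),
    date_shift_range = if (!is.null(x$date_shift_range))
      unlist(x$date_shift_range) else c(0L, 0L),
    substitutions = if (is.null(x$substitutions)) list() else x$substitutions,
    logging_enabled = if (is.null(x$logging_enabled)) TRUE
                      else isTRUE(x$logging_enabled),
    project_salt = if (is.null(x$project_salt)) "" else x$project_salt
  )
}

# --- De-identification log ----------------------------------------------------

#' Open (or create) a de-identification log
#'
#' The log persists the original->pseudonym value map and the per-patient
#' date offsets so that subsequent data deliveries for the same patient are
#' de-identified identically. It also carries the project RNG stream.
#'
#' @param path File path for the persisted log (JSON), or `NULL` for an
#'   in-memory log.
#' @param project_id Project identifier recorded in the log.
#' @param config A `deid_config`; the salt seeds the project RNG.
#' @param seed Integer seed combined with the salt.
#' @return A `deid_log` environment.
#' @export
open_deid_log <- function(path = NULL, project_id = "default",
                          config = deid_config(), seed = 1L) {
  log <- new.env(parent = emptyenv())
  log$project_id <- project_id
  log$path <- path
  log$persist <- config$logging_enabled
  log$value_map <- list()
  log$offset_map <- list()
  log$rng_state <- NULL
  log$seed <- derive_seed(config$project_salt, seed)
  if (!is.null(path) && file.exists(path)) {
    if (!config$logging_enabled) {
      stop("de-identification error: replay from a persisted log requested ",
           "but logging is disabled (logging-free mode is suitable only for ",
           "one-off exports)", call. = FALSE)
    }
    x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    log$project_id <- x$project_id
    log$value_map <- lapply(x$value_map, as.character)
    log$offset_map <- lapply(x$offset_map, as.integer)
    if (!is.null(x$rng_state)) log$rng_state <- as.integer(unlist(x$rng_state))
  }
  class(log) <- "deid_log"
  log
}

#' Persist a de-identification log
#'
#' @param log A `deid_log`.
#' @param path Target path (defaults to the path the log was opened with).
#' @export
save_deid_log <- function(log, path = log$path) {
  if (!log$persist) {
    stop("de-identification error: logging is disabled for this project; ",
         "the original<->pseudonym map cannot be persisted", call. = FALSE)
  }
  if (is.null(path)) stop("no path to save the de-identification log to",
                          call. = FALSE)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    project_id = log$project_id,
    value_map = log$value_map,
    offset_map = log$offset_map,
    rng_state = log$rng_state
  ), path, auto_unbox = TRUE, null = "null")
  invisible(log)
}

derive_seed <- function(salt, seed) {
  h <- fnv1a32(paste0(salt, "\r", seed))
  as.integer(strtoi(substr(h, 1, 7), 16L))
}

# Run expr under the log's private RNG stream, isolating the global RNG.
with_log_rng <- function(log, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  if (is.null(log$rng_state)) {
    set.seed(log$seed)
  } else {
    assign(".Random.seed", log$rng_state, envir = globalenv())
  }
  res <- expr
  log$rng_state <- get(".Random.seed", globalenv())
  res
}

random_uuid <- function() {
  b <- sample.int(256L, 16L, replace = TRUE) - 1L
  b[7] <- bitwOr(bitwAnd(b[7], 0x0F), 0x40)  # version 4
  b[9] <- bitwOr(bitwAnd(b[9], 0x3F), 0x80)  # RFC 4122 variant
  h <- sprintf("%02x", b)
  paste0(paste(h[1:4], collapse = ""), "-", paste(h[5:6], collapse = ""), "-",
         paste(h[7:8], collapse = ""), "-", paste(h[9:10], collapse = ""), "-",
         paste(h[11:16], collapse = ""))
}

# --- Operations ---------------------------------------------------------------

#' Pseudonymize a value
#'
#' Returns a UUID-format pseudonym for `original` under the given selector.
#' Within a project the same original always maps to the same pseudonym
#' (consistency across records and deliveries); the pseudonym is minted at
#' random on first encounter and carries no information derived from the
#' original value.
#'
#' @param original Original value (text).
#' @param selector `c(concept, property)` selector; must be listed in the
#'   config's `scramble_fields`.
#' @param config A `deid_config`.
#' @param log A `deid_log`.
#' @return The pseudonym (canonical 8-4-4-4-12 UUID string).
#' @export
pseudonymize_value <- function(original, selector, config, log) {
  sel_key <- paste(selector[1], selector[2], sep = ".")
  listed <- any(vapply(config$scramble_fields, function(s)
    s[1] == selector[1] && s[2] == selector[2], TRUE))
  if (!listed) {
    stop("de-identification error: selector ", sel_key,
         " is not listed in scramble_fields", call. = FALSE)
  }
  key <- paste0(sel_key, "\r", original)
  hit <- log$value_map[[key]]
  if (!is.null(hit)) return(hit)
  pseud <- with_log_rng(log, random_uuid())
  # injectivity guard: an astronomically unlikely collision would break
  # re-identification through the log, so regenerate rather than accept it
  known <- names(log$value_map)
  if (is.null(known)) known <- character(0)
  taken <- unlist(log$value_map[startsWith(known, paste0(sel_key, "\r"))])
  while (pseud %in% taken) pseud <- with_log_rng(log, random_uuid())
  log$value_map[[key]] <- pseud
  pseud
}

#' Assign (or replay) a patient's date-shift offset
#'
#' Draws one uniform integer offset from the configured day range; if the
#' patient already has a logged offset it is returned unchanged, so
#' subsequent deliveries shift dates identically.
#'
#' @param patient_local_id Patient identifier (pre-pseudonymization).
#' @param config A `deid_config`.
#' @param log A `deid_log`.
#' @return Signed integer number of days.
#' @export
assign_date_offset <- function(patient_local_id, config, log) {
  hit <- log$offset_map[[patient_local_id]]
  if (!is.null(hit)) return(as.integer(hit))
  lo <- config$date_shift_range[1]; hi <- config$date_shift_range[2]
  off <- with_log_rng(log, as.integer(sample(seq.int(lo, hi), 1L)))
  log$offset_map[[patient_local_id]] <- off
  off
}

#' Shift the date part of a temporal lexical value
#'
#' @param v Lexical `xsd:date` or `xsd:dateTime` value.
#' @param offset Signed number of days.
#' @param datatype `"date"` or `"dateTime"`.
#' @return The shifted lexical value (time of day preserved).
#' @export
shift_lex <- function(v, offset, datatype) {
  if (datatype == "date") {
    format(as.Date(v) + offset, "%Y-%m-%d")
  } else {
    d <- as.Date(substr(v, 1, 10))
    paste0(format(d + offset, "%Y-%m-%d"), substr(v, 11, nchar(v)))
  }
}

#' Shift all temporal values of a bundle by a fixed day offset
#'
#' Every temporal-valued field (per the model, not name heuristics) in every
#' record is shifted by exactly `offset` days; times of day are untouched, so
#' all pairwise intervals between a patient's dates are preserved.
#'
#' @param bundle A `patient_bundle`.
#' @param offset Signed integer days.
#' @param model A `concept_model`.
#' @return The shifted bundle.
#' @export
shift_dates <- function(bundle, offset, model) {
  bundle$records <- lapply(bundle$records, function(rec) {
    cd <- model$concepts[[rec$concept]]
    for (nm in names(rec$fields)) {
      pd <- cd$properties[[nm]]
      if (is.null(pd) || pd$range_kind != "temporal") next
      vals <- rec$fields[[nm]]
      ok <- if (pd$scalar_datatype == "date") vapply(vals, is_valid_date, TRUE)
            else vapply(vals, is_valid_datetime, TRUE)
      if (!all(ok)) {
        stop("date-shift error: record ", rec$concept, "/", rec$id,
             " property ", nm, " holds an unparseable temporal value '",
             vals[!ok][1], "'", call. = FALSE)
      }
      rec$fields[[nm]] <- vapply(vals, shift_lex, "", offset = offset,
                                 datatype = pd$scalar_datatype)
    }
    rec
  })
  bundle
}

#' Apply list/regex substitution rules to a bundle
#'
#' Rules with explicit `values` replace a field value when it equals one of
#' the listed values; rules with a `pattern` replace every match of the
#' regular expression inside the value with the replacement string.
#' Non-matching values are untouched.
#'
#' @param bundle A `patient_bundle`.
#' @param rules List of substitution rules (see [deid_config()]).
#' @return The substituted bundle.
#' @export
substitute_values <- function(bundle, rules) {
  if (length(rules) == 0) return(bundle)
  apply_rules <- function(v) {
    for (rule in rules) {
      if (!is.null(rule$values)) {
        v[v %in% unlist(rule$values)] <- rule$replacement
      } else {
        v <- gsub(rule$pattern, rule$replacement, v, perl = TRUE)
      }
    }
    v
  }
  bundle$records <- lapply(bundle$records, function(rec) {
    rec$fields <- lapply(rec$fields, apply_rules)
    rec
  })
  bundle
}

#' De-identify a patient bundle
#'
#' Applies, in order: value substitutions, field/identifier pseudonymization
#' (including link targets when instance identifiers are scrambled, and the
#' bundle's patient identifier when the subject concept's `id` is selected),
#' and the per-patient date shift. The date offset is keyed by the original
#' patient identifier so replays are stable across deliveries.
#'
#' @param bundle A `patient_bundle`.
#' @param config A `deid_config`.
#' @param log A `deid_log`.
#' @param model A `concept_model`.
#' @return The de-identified bundle.
#' @export
deidentify_bundle <- function(bundle, config, log, model) {
  original_pid <- bundle$patient_local_id
  bundle <- substitute_values(bundle, config$substitutions)

  for (sel in config$scramble_fields) {
    concept <- sel[1]; property <- sel[2]
    if (property == "id") {
      # scramble instance identifiers of `concept`; remap links pointing at them
      idmap <- list()
      bundle$records <- lapply(bundle$records, function(rec) {
        if (rec$concept == concept) {
          new_id <- pseudonymize_value(rec$id, sel, config, log)
          idmap[[rec$id]] <<- new_id
          rec$id <- new_id
        }
        rec
      })
      bundle$records <- lapply(bundle$records, function(rec) {
        cd <- model$concepts[[rec$concept]]
        for (ln in names(rec$links)) {
          if (cd$properties[[ln]]$target == concept) {
            rec$links[[ln]] <- vapply(rec$links[[ln]], function(i) {
              if (!is.null(idmap[[i]])) idmap[[i]] else i
            }, "")
          }
        }
        rec
      })
      if (concept == model$subject_concept &&
          !is.null(idmap[[bundle$patient_local_id]])) {
        bundle$patient_local_id <- idmap[[bundle$patient_local_id]]
      }
    } else {
      bundle$records <- lapply(bundle$records, function(rec) {
        if (rec$concept == concept && !is.null(rec$fields[[property]])) {
          rec$fields[[property]] <- vapply(rec$fields[[property]], function(v)
            pseudonymize_value(v, sel, config, log), "")
        }
        rec
      })
    }
  }

  rng <- config$date_shift_range
  if (!(rng[1] == 0 && rng[2] == 0)) {
    offset <- assign_date_offset(original_pid, config, log)
    bundle <- shift_dates(bundle, offset, model)
  }
  bundle
}
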