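# Evaluator for the JSON-Schema subset emitted by gen_json_schema():
# type, required, properties, additionalProperties=FALSE, items, enum,
# pattern, format (date / date-time), minItems, maxItems, $ref into
# #/definitions. Instances are jsonlite trees (simplifyVector = FALSE).

#' Validate a JSON instance against a generated schema
#'
#' @param instance Parsed JSON (nested list, `jsonlite::fromJSON(...,
#'   simplifyVector = FALSE)`) or JSON text.
#' @param schema Schema list as returned by [gen_json_schema()].
#' @return Data frame of findings with columns `path` (JSON-pointer-like) and
#'   `message`; zero rows means the instance is valid.
#' @export
validate_json <- function(instance, schema) {
  if (is.character(instance) && length(instance) == 1) {
    instance <- jsonlite::fromJSON(instance, simplifyVector = FALSE)
  }
  errs <- new.env(parent = emptyenv())
  errs$rows <- list()
  add <- function(path, message) {
    errs$rows[[length(errs$rows) + 1L]] <-
      data.frame(path = path, message = message, stringsAsFactors = FALSE)
  }
  defs <- schema$definitions

  json_type <- function(x) {
    if (is.null(x)) "null"
    else if (is.list(x)) { if (length(x) > 0 && !is.null(names(x)) &&
                               all(nzchar(names(x)))) "object"
                           else if (length(x) == 0 && !is.null(names(x))) "object"
                           else if (length(x) == 0) "array"  # ambiguous; treat [] as array
                           else if (is.null(names(x))) "array" else "object" }
    else if (is.character(x)) "string"
    else if (is.logical(x)) "boolean"
    else if (is.numeric(x)) "number"
    else "unknown"
  }

  check <- function(x, sch, path) {
    if (!is.null(sch[["$ref"]])) {
      nm <- sub("^#/definitions/", "", sch[["$ref"]])
      sch <- defs[[nm]]
      if (is.null(sch)) { add(path, paste0("unresolved $ref ", nm)); return() }
    }
    ty <- sch$type
    jt <- json_type(x)
    if (!is.null(ty)) {
      ok <- switch(ty,
        object = jt == "object",
        array = jt == "array",
        string = jt == "string" && length(x) == 1,
        boolean = jt == "boolean" && length(x) == 1,
        number = jt == "number" && length(x) == 1,
        integer = jt == "number" && length(x) == 1 && x == floor(x),
        TRUE
      )
      if (!ok) { add(path, paste0("expected ", ty, ", got ", jt)); return() }
    }
    if (!is.null(sch$enum)) {
      if (!(length(x) == 1 && as.character(x) %in% unlist(sch$enum))) {
        add(path, paste0("value '", as.character(x)[1],
                         "' not in permitted set"))
      }
    }
    if (!is.null(sch$pattern) && is.character(x)) {
      if (!grepl(sch$pattern, x, perl = TRUE)) {
        add(path, paste0("value '", x, "' does not match pattern ", sch$pattern))
      }
    }
    if (!is.null(sch$format) && is.character(x)) {
      ok <- if (sch$format == "date") is_valid_date(x)
            else if (sch$format == "date-time") is_valid_datetime(x)
            else TRUE
      if (!ok) add(path, paste0("value '", x, "' is not a valid ", sch$format))
    }
    if (identical(ty, "object")) {
      req <- unlist(sch$required)
      for (r in req) {
        if (is.null(x[[r]])) add(paste0(path, "/", r), "required property missing")
      }
      for (nm in names(x)) {
        sub <- sch$properties[[nm]]
        if (is.null(sub)) {
          if (isFALSE(sch$additionalProperties)) {
            add(paste0(path, "/", nm), "unknown property")
          }
        } else {
          check(x[[nm]], sub, paste0(path, "/", nm))
        }
      }
    }
    if (identical(ty, "array")) {
      if (!is.null(sch$minItems) && length(x) < sch$minItems) {
        add(path, paste0("fewer than ", sch$minItems, " item(s)"))
      }
      if (!is.null(sch$maxItems) && length(x) > sch$maxItems) {
        add(path, paste0("more than ", sch$maxItems, " item(s)"))
      }
      if (!is.null(sch$items)) {
        for (k in seq_along(x)) {
          check(x[[k]], sch$items, paste0(path, "/", k - 1L))
        }
      }
    }
  }

  check(instance, schema, "")
  if (length(errs$rows) == 0) {
    data.frame(path = character(), message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, errs$rows)
  }
}

# Temporal lexical checks (ISO-8601, the single dialect accepted on ingest)

is_valid_date <- function(x) {
  if (!grepl("^\\d{4}-\\d{2}-\\d{2}$", x)) return(FALSE)
  !is.na(as.Date(x, format = "%Y-%m-%d"))
}

is_valid_datetime <- function(x) {
  if (!grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}$", x)) return(FALSE)
  d <- substr(x, 1, 10)
  hh <- as.integer(substr(x, 12, 13)); mm <- as.integer(substr(x, 15, 16))
  ss <- as.integer(substr(x, 18, 19))
  is_valid_date(d) && hh <= 23 && mm <= 59 && ss <= 59
}
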