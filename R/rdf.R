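# Quad container and RDF serialization layer.
#
# The package works with a deliberately small RDF surface: the schema dialect,
# the generated shapes vocabulary and the patient graphs only ever use plain
# triples/quads with IRIs, typed literals, blank nodes and RDF collections.
# The reader/writer below covers exactly that surface (Turtle, TriG, N-Quads)
# with deterministic output ordering, so that regenerated artifacts are
# byte-identical.

# Well-known namespaces -------------------------------------------------------

NS_RDF  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
NS_OWL  <- "http://www.w3.org/2002/07/owl#"
NS_XSD  <- "http://www.w3.org/2001/XMLSchema#"
NS_SH   <- "http://www.w3.org/ns/shacl#"

#' Dialect namespace
#'
#' Annotation vocabulary of the schema dialect understood by
#' [parse_schema()]. The IRIs under this namespace are fixed constants;
#' see the package vignette for the full dialect description.
#' @format Length-one character vector.
#' @export
HKG <- "https://w3id.org/healthkg/dialect#"

IRI_RDF_TYPE  <- paste0(NS_RDF, "type")
IRI_RDF_FIRST <- paste0(NS_RDF, "first")
IRI_RDF_REST  <- paste0(NS_RDF, "rest")
IRI_RDF_NIL   <- paste0(NS_RDF, "nil")
XSD_STRING    <- paste0(NS_XSD, "string")

# Quadset ----------------------------------------------------------------------

quad_cols <- c("s", "s_kind", "p", "o", "o_kind", "dtype", "graph")

#' Create a set of RDF quads
#'
#' A `quadset` is the package's statement container: a data frame with one row
#' per statement and columns `s`, `s_kind` (`"iri"` or `"blank"`), `p`, `o`,
#' `o_kind` (`"iri"`, `"blank"` or `"literal"`), `dtype` (datatype IRI for
#' literals, `NA` otherwise) and `graph` (named-graph IRI, `NA` for the
#' default graph). Duplicate statements are collapsed: a quadset has set
#' semantics.
#'
#' @param df Data frame with the columns above (missing kind/dtype/graph
#'   columns are filled with defaults).
#' @return An object of class `quadset`.
#' @export
quadset <- function(df = NULL) {
  if (is.null(df) || nrow(df) == 0) {
    df <- data.frame(
      s = character(), s_kind = character(), p = character(),
      o = character(), o_kind = character(), dtype = character(),
      graph = character(), stringsAsFactors = FALSE
    )
  } else {
    if (is.null(df$s_kind)) df$s_kind <- "iri"
    if (is.null(df$o_kind)) df$o_kind <- "iri"
    if (is.null(df$dtype)) df$dtype <- NA_character_
    if (is.null(df$graph)) df$graph <- NA_character_
    df <- df[, quad_cols]
    # plain literals are xsd:string
    plain <- df$o_kind == "literal" & is.na(df$dtype)
    df$dtype[plain] <- XSD_STRING
    df <- unique(df)
    rownames(df) <- NULL
  }
  structure(df, class = c("quadset", "data.frame"))
}

#' @export
print.quadset <- function(x, ...) {
  cat("<quadset> ", nrow(x), " statement(s), ",
      length(unique(stats::na.omit(x$graph))), " named graph(s)\n", sep = "")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Combine quadsets with set semantics
#'
#' @param ... `quadset` objects (or quad data frames).
#' @return A [quadset()] holding the union of the inputs.
#' @export
quads_bind <- function(...) {
  parts <- Filter(function(q) !is.null(q) && nrow(q) > 0, list(...))
  if (length(parts) == 0) return(quadset())
  quadset(do.call(rbind, lapply(parts, as.data.frame)))
}

#' Canonical (sorted, de-duplicated) form of a quadset
#'
#' @param q A `quadset`.
#' @return The same statements in a deterministic order.
#' @export
canonical_quads <- function(q) {
  df <- as.data.frame(q)
  df <- unique(df)
  ord <- order(
    ifelse(is.na(df$graph), "", df$graph), df$s, df$p, df$o,
    ifelse(is.na(df$dtype), "", df$dtype)
  )
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  quadset(df)
}

#' Compare two quadsets as sets
#'
#' @param a,b `quadset` objects.
#' @return `TRUE` when both contain exactly the same statements.
#' @export
quads_equal <- function(a, b) {
  identical(canonical_quads(a), canonical_quads(b))
}

# subset helper: all values of property p for subject s (within optional graph)
q_objects <- function(q, s, p) {
  sel <- q$s == s & q$p == p
  q[sel, c("o", "o_kind", "dtype"), drop = FALSE]
}

q_values <- function(q, s, p) {
  q$o[q$s == s & q$p == p]
}

# Literal escaping -------------------------------------------------------------

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    if (!grepl("\\", s, fixed = TRUE)) { out[i] <- s; next }
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    res <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        nxt <- chars[j + 1L]
        res <- c(res, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\"" = "\"", "\\" = "\\", nxt))
        j <- j + 2L
      } else {
        res <- c(res, chars[j]); j <- j + 1L
      }
    }
    out[i] <- paste(res, collapse = "")
  }
  out
}

# Term formatting --------------------------------------------------------------

fmt_term_s <- function(s, kind) {
  ifelse(kind == "blank", paste0("_:", s), paste0("<", s, ">"))
}

fmt_term_o <- function(o, kind, dtype) {
  out <- character(length(o))
  iri <- kind == "iri"
  blk <- kind == "blank"
  lit <- kind == "literal"
  out[iri] <- paste0("<", o[iri], ">")
  out[blk] <- paste0("_:", o[blk])
  if (any(lit)) {
    base <- paste0("\"", escape_literal(o[lit]), "\"")
    dt <- dtype[lit]
    tag <- ifelse(is.na(dt) | dt == XSD_STRING, "", paste0("^^<", dt, ">"))
    out[lit] <- paste0(base, tag)
  }
  out
}

# Serializers ------------------------------------------------------------------

#' Serialize quads to an RDF file format
#'
#' Supported formats: `"trig"` and `"nquads"` keep the named-graph component;
#' `"turtle"` is only allowed when all statements live in a single graph (the
#' graph component is dropped). Statement ordering is deterministic, so equal
#' quadsets serialize to byte-identical output.
#'
#' @param quads A [quadset()].
#' @param format One of `"trig"`, `"nquads"`, `"turtle"`.
#' @return A single character string holding the serialized document.
#' @export
serialize_quads <- function(quads, format = c("trig", "nquads", "turtle")) {
  if (!format[1] %in% c("trig", "nquads", "turtle")) {
    stop("unsupported serialization format '", format[1],
         "'; supported formats: trig, nquads, turtle", call. = FALSE)
  }
  format <- format[1]
  df <- canonical_quads(quads)
  switch(format,
    nquads = ser_nquads(df),
    trig   = ser_trig(df),
    turtle = ser_turtle(df)
  )
}

ser_nquads <- function(df) {
  if (nrow(df) == 0) return("")
  g <- ifelse(is.na(df$graph), "", paste0(" <", df$graph, ">"))
  lines <- paste0(
    fmt_term_s(df$s, df$s_kind), " <", df$p, "> ",
    fmt_term_o(df$o, df$o_kind, df$dtype), g, " ."
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

ser_triples_block <- function(df, indent = "") {
  paste0(indent, fmt_term_s(df$s, df$s_kind), " <", df$p, "> ",
         fmt_term_o(df$o, df$o_kind, df$dtype), " .")
}

ser_trig <- function(df) {
  out <- character(0)
  dflt <- df[is.na(df$graph), , drop = FALSE]
  if (nrow(dflt) > 0) out <- c(out, ser_triples_block(dflt), "")
  for (g in unique(df$graph[!is.na(df$graph)])) {
    sub <- df[!is.na(df$graph) & df$graph == g, , drop = FALSE]
    out <- c(out, paste0("<", g, "> {"),
             ser_triples_block(sub, indent = "  "), "}", "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

ser_turtle <- function(df) {
  gs <- unique(df$graph)
  if (length(gs) > 1) {
    stop("turtle output supports a single graph only; got ",
         length(gs), " graphs (use trig or nquads)", call. = FALSE)
  }
  if (nrow(df) == 0) return("")
  paste0(paste(ser_triples_block(df), collapse = "\n"), "\n")
}

# Parsers ----------------------------------------------------------------------

#' Parse an RDF document into a quadset
#'
#' @param text Document text (single string) or a file path ending in
#'   `.ttl`, `.trig` or `.nq`.
#' @param format One of `"turtle"`, `"trig"`, `"nquads"`. Turtle and TriG share
#'   one grammar here (TriG adds `<graph> { ... }` blocks).
#' @return A [quadset()].
#' @export
parse_quads <- function(text, format = c("turtle", "trig", "nquads")) {
  format <- match.arg(format)
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  if (format == "nquads") parse_nquads(text) else parse_turtle_trig(text)
}

parse_nquads <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(quadset())
  term <- "(<[^>]*>|_:[A-Za-z0-9._-]+|\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^<[^>]*>)?)"
  rx <- paste0("^", term, "\\s+<([^>]*)>\\s+", term, "(?:\\s+<([^>]*)>)?\\s*\\.$")
  m <- regmatches(lines, regexec(rx, lines, perl = TRUE))
  bad <- which(vapply(m, length, 1L) == 0)
  if (length(bad) > 0) {
    stop("N-Quads parse error at line ", bad[1], ": ", lines[bad[1]], call. = FALSE)
  }
  parse_term <- function(tok) {
    if (startsWith(tok, "<")) {
      list(v = substr(tok, 2, nchar(tok) - 1), kind = "iri", dtype = NA_character_)
    } else if (startsWith(tok, "_:")) {
      list(v = substr(tok, 3, nchar(tok)), kind = "blank", dtype = NA_character_)
    } else {
      dt <- XSD_STRING
      lex <- tok
      caret <- regexpr("\"\\^\\^<", tok)
      if (caret > 0) {
        dt <- sub("^.*\\^\\^<([^>]*)>$", "\\1", tok)
        lex <- substr(tok, 1, caret)
      }
      lex <- sub("^\"", "", sub("\"$", "", lex))
      list(v = unescape_literal(lex), kind = "literal", dtype = dt)
    }
  }
  rows <- lapply(m, function(mm) {
    s <- parse_term(mm[2]); o <- parse_term(mm[4])
    g <- if (length(mm) >= 5 && nzchar(mm[5])) mm[5] else NA_character_
    data.frame(s = s$v, s_kind = s$kind, p = mm[3], o = o$v, o_kind = o$kind,
               dtype = o$dtype, graph = g, stringsAsFactors = FALSE)
  })
  quadset(do.call(rbind, rows))
}

# --- Turtle / TriG ------------------------------------------------------------

tokenize_turtle <- function(text) {
  toks_type <- character(0); toks_val <- character(0); toks_line <- integer(0)
  pos <- 1L; n <- nchar(text); line <- 1L
  push <- function(type, val) {
    toks_type[[length(toks_type) + 1L]] <<- type
    toks_val[[length(toks_val) + 1L]] <<- val
    toks_line[[length(toks_line) + 1L]] <<- line
  }
  pat <- list(
    WS      = "^[ \t\r\n]+",
    COMMENT = "^#[^\n]*",
    PREFIX  = "^@prefix",
    BASE    = "^@base",
    IRIREF  = "^<([^>]*)>",
    STRING  = "^\"((?:[^\"\\\\]|\\\\.)*)\"",
    CARETS  = "^\\^\\^",
    LANG    = "^@[A-Za-z][A-Za-z0-9-]*",
    BLANK   = "^_:([A-Za-z0-9._-]+)",
    BOOL    = "^(true|false)(?![A-Za-z0-9_])",
    NUMBER  = "^[+-]?[0-9]+(\\.[0-9]+)?(?![A-Za-z])",
    GRAPHKW = "^GRAPH(?![A-Za-z0-9_])",
    A       = "^a(?![A-Za-z0-9_:])",
    PNAME   = "^([A-Za-z][A-Za-z0-9._-]*)?:([A-Za-z0-9._~-]*)",
    PUNCT   = "^[.;,(){}\\[\\]]"
  )
  while (pos <= n) {
    rest <- substring(text, pos)
    matched <- FALSE
    for (tt in names(pat)) {
      m <- regexpr(pat[[tt]], rest, perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        val <- substring(rest, 1L, len)
        if (tt == "WS" || tt == "COMMENT") {
          line <- line + lengths(regmatches(val, gregexpr("\n", val, fixed = TRUE)))
        } else if (tt == "PUNCT") {
          push(val, val)
        } else {
          push(tt, val)
        }
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop("RDF parse error at line ", line, ": unexpected input near '",
           substring(rest, 1, 30), "'", call. = FALSE)
    }
  }
  data.frame(type = unlist(toks_type, use.names = FALSE),
             value = unlist(toks_val, use.names = FALSE),
             line = unlist(toks_line, use.names = FALSE),
             stringsAsFactors = FALSE)
}

parse_turtle_trig <- function(text) {
  toks <- tokenize_turtle(text)
  env <- new.env(parent = emptyenv())
  env$i <- 1L
  env$toks <- toks
  env$prefixes <- c(rdf = NS_RDF, rdfs = NS_RDFS, owl = NS_OWL,
                    xsd = NS_XSD, sh = NS_SH)
  env$bcount <- 0L
  env$rows <- vector("list", 0)
  env$graph <- NA_character_

  peek <- function(k = 0L) {
    j <- env$i + k
    if (j > nrow(env$toks)) list(type = "EOF", value = "", line = NA) else
      as.list(env$toks[j, ])
  }
  advance <- function() { t <- peek(); env$i <- env$i + 1L; t }
  expect <- function(type) {
    t <- advance()
    if (t$type != type) {
      stop("RDF parse error at line ", t$line, ": expected ", type,
           " but found '", t$value, "'", call. = FALSE)
    }
    t
  }
  emit <- function(s, s_kind, p, o, o_kind, dtype = NA_character_) {
    env$rows[[length(env$rows) + 1L]] <-
      list(s = s, s_kind = s_kind, p = p, o = o, o_kind = o_kind,
           dtype = dtype, graph = env$graph)
  }
  expand_pname <- function(tok) {
    parts <- regmatches(tok$value,
                        regexec("^([A-Za-z][A-Za-z0-9._-]*)?:(.*)$", tok$value))[[1]]
    pfx <- parts[2]; local <- parts[3]
    if (!pfx %in% names(env$prefixes)) {
      stop("RDF parse error at line ", tok$line, ": undefined prefix '",
           pfx, ":'", call. = FALSE)
    }
    paste0(env$prefixes[[pfx]], local)
  }
  fresh_blank <- function() {
    env$bcount <- env$bcount + 1L
    paste0("genid", env$bcount)
  }
  parse_object <- function() {
    t <- peek()
    if (t$type == "IRIREF") {
      advance(); list(v = sub("^<(.*)>$", "\\1", t$value), kind = "iri", dtype = NA)
    } else if (t$type == "PNAME") {
      advance(); list(v = expand_pname(t), kind = "iri", dtype = NA)
    } else if (t$type == "A") {
      stop("RDF parse error at line ", t$line, ": 'a' is not an object", call. = FALSE)
    } else if (t$type == "BLANK") {
      advance(); list(v = sub("^_:", "", t$value), kind = "blank", dtype = NA)
    } else if (t$type == "BOOL") {
      advance(); list(v = t$value, kind = "literal", dtype = paste0(NS_XSD, "boolean"))
    } else if (t$type == "NUMBER") {
      advance()
      dt <- if (grepl(".", t$value, fixed = TRUE)) "decimal" else "integer"
      list(v = t$value, kind = "literal", dtype = paste0(NS_XSD, dt))
    } else if (t$type == "STRING") {
      advance()
      lex <- unescape_literal(sub("^\"(.*)\"$", "\\1", t$value))
      dt <- XSD_STRING
      if (peek()$type == "CARETS") {
        advance()
        dtok <- advance()
        dt <- if (dtok$type == "IRIREF") sub("^<(.*)>$", "\\1", dtok$value)
              else expand_pname(dtok)
      } else if (peek()$type == "LANG") {
        advance()  # language tags accepted, dropped (dialect never uses them)
      }
      list(v = lex, kind = "literal", dtype = dt)
    } else if (t$type == "(") {
      advance()
      items <- list()
      while (peek()$type != ")") items[[length(items) + 1L]] <- parse_object()
      advance()
      if (length(items) == 0) return(list(v = IRI_RDF_NIL, kind = "iri", dtype = NA))
      nodes <- vapply(items, function(x) fresh_blank(), "")
      for (k in seq_along(items)) {
        it <- items[[k]]
        emit(nodes[k], "blank", IRI_RDF_FIRST, it$v, it$kind,
             if (is.na(it$dtype)) NA_character_ else it$dtype)
        rest <- if (k < length(items)) list(v = nodes[k + 1L], kind = "blank")
                else list(v = IRI_RDF_NIL, kind = "iri")
        emit(nodes[k], "blank", IRI_RDF_REST, rest$v, rest$kind)
      }
      list(v = nodes[1], kind = "blank", dtype = NA)
    } else {
      stop("RDF parse error at line ", t$line, ": unexpected '", t$value,
           "' where an object was expected", call. = FALSE)
    }
  }
  parse_predicate <- function() {
    t <- advance()
    if (t$type == "A") IRI_RDF_TYPE
    else if (t$type == "IRIREF") sub("^<(.*)>$", "\\1", t$value)
    else if (t$type == "PNAME") expand_pname(t)
    else stop("RDF parse error at line ", t$line, ": expected a predicate, found '",
              t$value, "'", call. = FALSE)
  }
  parse_triples <- function() {
    st <- peek()
    subj <- if (st$type == "BLANK") {
      advance(); list(v = sub("^_:", "", st$value), kind = "blank")
    } else if (st$type == "IRIREF") {
      advance(); list(v = sub("^<(.*)>$", "\\1", st$value), kind = "iri")
    } else if (st$type == "PNAME") {
      advance(); list(v = expand_pname(st), kind = "iri")
    } else {
      stop("RDF parse error at line ", st$line, ": expected a subject, found '",
           st$value, "'", call. = FALSE)
    }
    repeat {
      p <- parse_predicate()
      repeat {
        o <- parse_object()
        emit(subj$v, subj$kind, p, o$v, o$kind,
             if (is.na(o$dtype)) NA_character_ else o$dtype)
        if (peek()$type == ",") advance() else break
      }
      if (peek()$type == ";") {
        advance()
        # trailing ';' before '.' or '}'
        if (peek()$type %in% c(".", "}")) break
      } else break
    }
    if (peek()$type == ".") advance()
  }
  parse_graph_block <- function(graph_iri) {
    prev <- env$graph
    env$graph <- graph_iri
    expect("{")
    while (peek()$type != "}") parse_triples()
    expect("}")
    env$graph <- prev
  }

  while (peek()$type != "EOF") {
    t <- peek()
    if (t$type == "PREFIX") {
      advance()
      pn <- expect("PNAME")
      pfx <- sub(":.*$", "", pn$value)
      iri <- expect("IRIREF")
      env$prefixes[[pfx]] <- sub("^<(.*)>$", "\\1", iri$value)
      expect(".")
    } else if (t$type == "BASE") {
      advance(); expect("IRIREF"); expect(".")  # accepted, unused
    } else if (t$type == "GRAPHKW") {
      advance()
      gt <- advance()
      g <- if (gt$type == "IRIREF") sub("^<(.*)>$", "\\1", gt$value)
           else expand_pname(gt)
      parse_graph_block(g)
    } else if (t$type %in% c("IRIREF", "PNAME") &&
               peek(1L)$type == "{") {
      gt <- advance()
      g <- if (gt$type == "IRIREF") sub("^<(.*)>$", "\\1", gt$value)
           else expand_pname(gt)
      parse_graph_block(g)
    } else {
      parse_triples()
    }
  }
  if (length(env$rows) == 0) return(quadset())
  quadset(do.call(rbind, lapply(env$rows, function(r)
    data.frame(r, stringsAsFactors = FALSE))))
}

# RDF collection helper: follow rdf:first/rdf:rest from a head node
collect_rdf_list <- function(q, head, head_kind = "blank") {
  vals <- character(0); kinds <- character(0)
  node <- head
  while (!identical(node, IRI_RDF_NIL)) {
    f <- q[q$s == node & q$p == IRI_RDF_FIRST, , drop = FALSE]
    if (nrow(f) == 0) break
    vals <- c(vals, f$o[1]); kinds <- c(kinds, f$o_kind[1])
    r <- q[q$s == node & q$p == IRI_RDF_REST, , drop = FALSE]
    if (nrow(r) == 0) break
    node <- r$o[1]
  }
  data.frame(o = vals, o_kind = kinds, stringsAsFactors = FALSE)
}

iri_local_name <- function(iri) {
  sub("^.*[#/]", "", iri)
}

# 32-bit FNV-1a over a string; used to fingerprint models into shapes graphs
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 16 bits, which fit in an integer
    lo <- h %% 65536; hi <- h %/% 65536
    h <- hi * 65536 + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit multiply by 16777619 via split arithmetic to stay in double precision
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
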