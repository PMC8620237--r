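# DAG model of the Gene Ontology restricted to is_a/part_of, plus the lexical
# operations (tokenisation, word overlap) shared by the rest of the toolkit.

GO_ID_RE <- "^GO:[0-9]{7}$"

#' Tokenise a term or sentence string
#'
#' Lowercases and splits on whitespace; punctuation stays attached to tokens.
#' This single convention is used for word overlap, the linguistic test suite
#' and the lexical classifier features, so counts agree across modules.
#'
#' @param x A character string.
#' @return Character vector of lowercased tokens.
#' @export
go_tokens <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  toks <- strsplit(trimws(tolower(x)), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Word overlap between two term strings
#'
#' Size of the intersection of the two sets of lowercased whitespace tokens
#' (set semantics, not multiset). Used by the overlap strategy for
#' over-specific term selection: e.g. "feeding behavior" overlaps
#' "suckling behavior" in 1 token and "regulation of feeding behavior" in 2.
#'
#' @param term_a,term_b Non-empty term strings.
#' @return Non-negative integer count of shared distinct tokens.
#' @export
word_overlap <- function(term_a, term_b) {
  if (!nzchar(trimws(term_a)) || !nzchar(trimws(term_b))) {
    stop("word_overlap: both term strings must be non-empty")
  }
  length(intersect(go_tokens(term_a), go_tokens(term_b)))
}

#' Parse an OBO document into an ontology graph
#'
#' Reads `[Term]` stanzas of an OBO 1.2/1.4 flat file: `id`, `name`, `def`,
#' `synonym`, `is_a`, `relationship: part_of` and `is_obsolete`. Other stanza
#' types and relation types are ignored. The resulting graph restricted to
#' is_a/part_of edges is validated to be acyclic and edge targets must exist.
#'
#' @param obo_text OBO document as a single string or character vector of lines.
#' @return An object of class `ontology_graph`: list with `terms` (named list
#'   of `ontology_term`) and `edges` (data.frame child/parent/relation).
#' @export
parse_obo <- function(obo_text) {
  lines <- if (length(obo_text) == 1L && grepl("\n", obo_text, fixed = TRUE)) {
    strsplit(obo_text, "\n", fixed = TRUE)[[1]]
  } else {
    obo_text
  }
  lines <- sub("\r$", "", lines)

  # split into stanzas: a stanza starts at a [Header] line
  starts <- grep("^\\[[^]]+\\]$", lines)
  terms <- list()
  edges <- list()
  if (length(starts)) {
    bounds <- c(starts, length(lines) + 1L)
    for (k in seq_along(starts)) {
      header <- lines[starts[k]]
      if (header != "[Term]") next
      body <- lines[seq.int(starts[k] + 1L, bounds[k + 1L] - 1L)]
      body <- body[nzchar(trimws(body))]
      term <- parse_obo_stanza(body)
      terms[[term$term_id]] <- term
      if (nrow(term$parents)) {
        edges[[length(edges) + 1L]] <- data.frame(
          child = term$term_id,
          parent = term$parents$parent,
          relation = term$parents$relation,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(child = character(), parent = character(),
               relation = character(), stringsAsFactors = FALSE)

  graph <- structure(list(terms = terms, edges = edges),
                     class = "ontology_graph")
  validate_ontology_graph(graph)
  graph
}

parse_obo_stanza <- function(body) {
  fields <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
  bad <- vapply(fields, length, 1L) != 3L
  if (any(bad)) {
    stop("parse_obo: malformed line in stanza: ", sQuote(body[bad][1]))
  }
  keys <- vapply(fields, `[`, "", 2L)
  vals <- vapply(fields, `[`, "", 3L)

  grab <- function(key) vals[keys == key]
  id <- grab("id")
  if (length(id) != 1L || !grepl(GO_ID_RE, id)) {
    stop("parse_obo: stanza without a single valid GO id near ",
         sQuote(body[1]))
  }
  name <- grab("name")
  name <- if (length(name)) name[1] else ""
  defs <- grab("def")
  definition <- if (length(defs)) obo_quoted(defs[1]) else ""
  synonyms <- vapply(grab("synonym"), obo_quoted, "", USE.NAMES = FALSE)
  obsolete <- any(grepl("^true", grab("is_obsolete")))
  if (!obsolete && !nzchar(name)) {
    stop("parse_obo: non-obsolete term ", id, " has no name")
  }

  parents <- list()
  for (v in grab("is_a")) {
    parents[[length(parents) + 1L]] <- c(obo_target(v, id), "is_a")
  }
  for (v in grab("relationship")) {
    m <- regexec("^part_of\\s+(\\S+)", v)[[1]]
    if (m[1] != -1L) {
      target <- regmatches(v, regexec("^part_of\\s+(\\S+)", v))[[1]][2]
      if (!grepl(GO_ID_RE, target)) {
        stop("parse_obo: invalid part_of target in stanza ", id)
      }
      parents[[length(parents) + 1L]] <- c(target, "part_of")
    }
  }
  parents <- if (length(parents)) {
    data.frame(parent = vapply(parents, `[`, "", 1L),
               relation = vapply(parents, `[`, "", 2L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(parent = character(), relation = character(),
               stringsAsFactors = FALSE)
  }
  # obsolete terms never take part in traversal
  if (obsolete) parents <- parents[0, , drop = FALSE]

  structure(list(term_id = id, name = name, definition = definition,
                 synonyms = synonyms, is_obsolete = obsolete,
                 parents = parents),
            class = "ontology_term")
}

obo_quoted <- function(x) {
  m <- regmatches(x, regexec("\"((?:[^\"\\\\]|\\\\.)*)\"", x))[[1]]
  if (length(m) < 2L) return(trimws(x))
  gsub("\\\\(.)", "\\1", m[2])
}

obo_target <- function(x, stanza_id) {
  target <- trimws(sub("!.*$", "", x))
  if (!grepl(GO_ID_RE, target)) {
    stop("parse_obo: invalid is_a target ", sQuote(x), " in stanza ", stanza_id)
  }
  target
}

validate_ontology_graph <- function(graph) {
  edges <- graph$edges
  known <- names(graph$terms)
  missing <- setdiff(unique(c(edges$child, edges$parent)), known)
  if (length(missing)) {
    stop("ontology graph: dangling edge target(s): ",
         paste(missing, collapse = ", "))
  }
  # Kahn-style acyclicity check over child -> parent edges
  if (nrow(edges)) {
    indeg <- table(factor(edges$child, levels = known))
    adj <- split(edges$child, edges$parent)
    queue <- known[indeg == 0L]
    seen <- 0L
    indeg <- as.integer(indeg)
    names(indeg) <- known
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      seen <- seen + 1L
      for (w in adj[[v]]) {
        indeg[[w]] <- indeg[[w]] - 1L
        if (indeg[[w]] == 0L) queue <- c(queue, w)
      }
    }
    if (seen < length(known)) {
      stop("ontology graph: cycle detected over is_a/part_of edges")
    }
  }
  invisible(graph)
}

require_term <- function(graph, term_id) {
  term <- graph$terms[[term_id]]
  if (is.null(term)) stop("unknown GO term id: ", term_id)
  term
}

#' Direct descendants of a term
#'
#' Children one edge away over the requested relation types, obsolete children
#' excluded, sorted ascending by accession so seeded random choices downstream
#' are reproducible.
#'
#' @param graph An `ontology_graph`.
#' @param term_id GO accession.
#' @param relations Character subset of `c("is_a", "part_of")`.
#' @return Character vector of child accessions (possibly empty).
#' @export
direct_descendants <- function(graph, term_id,
                               relations = c("is_a", "part_of")) {
  term <- require_term(graph, term_id)
  if (term$is_obsolete) stop("term is obsolete: ", term_id)
  edges <- graph$edges
  kids <- edges$child[edges$parent == term_id & edges$relation %in% relations]
  kids <- unique(kids)
  kids <- kids[!vapply(kids, function(k) graph$terms[[k]]$is_obsolete, TRUE)]
  sort(kids)
}

#' Is a term a leaf of the DAG?
#'
#' A leaf has no non-obsolete direct descendants over is_a/part_of. Leaf terms
#' are skipped by over-specific (Type B) injection.
#'
#' @inheritParams direct_descendants
#' @return Logical scalar.
#' @export
is_leaf <- function(graph, term_id) {
  require_term(graph, term_id)
  length(direct_descendants(graph, term_id)) == 0L
}

#' Look a term up by name or synonym
#'
#' Case-insensitive exact match against the primary name and the synonyms of
#' non-obsolete terms; no fuzzy matching. Used to re-resolve a term after a
#' regulation-polarity swap.
#'
#' @param graph An `ontology_graph`.
#' @param name Term string to search for.
#' @return The matching accession, or `NULL` when absent.
#' @export
lookup_by_name <- function(graph, name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- tolower(trimws(name))
  hits <- character()
  for (term in graph$terms) {
    if (term$is_obsolete) next
    if (tolower(term$name) == key ||
        key %in% tolower(term$synonyms)) {
      hits <- c(hits, term$term_id)
    }
  }
  hits <- unique(hits)
  if (length(hits) == 0L) return(NULL)
  if (length(hits) > 1L) {
    stop("ambiguous term name ", sQuote(name), ": ",
         paste(sort(hits), collapse = ", "))
  }
  hits
}

#' @export
print.ontology_graph <- function(x, ...) {
  n_obs <- sum(vapply(x$terms, function(t) t$is_obsolete, TRUE))
  cat(sprintf("<ontology_graph> %d terms (%d obsolete), %d edges\n",
              length(x$terms), n_obs, nrow(x$edges)))
  invisible(x)
}
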