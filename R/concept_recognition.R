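# Dictionary-based GO concept recognition: transparent longest-match lookup
# over term names and synonyms, with light suffix stripping so adjectival
# mentions ("cytosolic") map back to the term ("cytosol").

norm_surface <- function(x) {
  gsub("\\s+", " ", trimws(tolower(x)))
}

# minimal morphological normalisation used at query time only
strip_suffix <- function(token) {
  for (suf in c("es", "s", "ic", "al")) {
    if (endsWith(token, suf) && nchar(token) - nchar(suf) >= 3L) {
      return(substr(token, 1L, nchar(token) - nchar(suf)))
    }
  }
  token
}

#' Build a concept dictionary from an ontology graph
#'
#' Every non-obsolete term contributes its primary name and all synonyms;
#' surface forms are normalised by lowercasing and whitespace collapse, the
#' same normalisation applied at query time.
#'
#' @param graph An `ontology_graph`.
#' @return Object of class `concept_dictionary`: named list mapping surface
#'   form to a character vector of term ids.
#' @export
build_dictionary <- function(graph) {
  if (!length(graph$terms)) stop("build_dictionary: empty graph")
  entries <- list()
  for (term in graph$terms) {
    if (term$is_obsolete) next
    for (surface in c(term$name, term$synonyms)) {
      key <- norm_surface(surface)
      if (!nzchar(key)) next
      entries[[key]] <- sort(unique(c(entries[[key]], term$term_id)))
    }
  }
  structure(entries, class = "concept_dictionary")
}

#' Write / read a concept dictionary as TSV
#'
#' Plain `surface_form<TAB>term_id` rows, one per (surface, term) pair.
#' @param dict A `concept_dictionary`.
#' @param path File path.
#' @export
write_dictionary <- function(dict, path) {
  rows <- unlist(lapply(names(dict), function(key) {
    paste(key, dict[[key]], sep = "\t")
  }))
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  rows <- strsplit(readLines(path, encoding = "UTF-8"), "\t", fixed = TRUE)
  entries <- list()
  for (r in rows) {
    entries[[r[1]]] <- sort(unique(c(entries[[r[1]]], r[2])))
  }
  structure(entries, class = "concept_dictionary")
}

#' Recognise GO concept mentions in a sentence
#'
#' Greedy longest-match-first scan over token windows: at each token the
#' longest dictionary entry that matches (either the raw lowercased tokens or
#' their suffix-stripped forms, which lets "cytosolic" match "cytosol") is
#' emitted and the scan resumes after it, so mentions never overlap. Matches
#' respect token boundaries; surrounding punctuation on a token is ignored
#' for matching but kept out of the mention span.
#'
#' @param sentence A string.
#' @param dict A `concept_dictionary`.
#' @return List of mentions, each `list(term_id, surface, span)` with the span
#'   0-based half-open into `sentence`; sorted by span start.
#' @export
recognise <- function(sentence, dict) {
  stopifnot(inherits(dict, "concept_dictionary"))
  m <- gregexpr("\\S+", sentence)[[1]]
  if (m[1] == -1L) return(list())
  tok_start <- as.integer(m)
  tok_end <- tok_start + attr(m, "match.length") - 1L
  raw <- substring(sentence, tok_start, tok_end)
  # strip punctuation hanging off token edges; adjust spans to the core
  first_an <- regexpr("[[:alnum:]]", raw)
  last_an <- nchar(sub("[^[:alnum:]]+$", "", raw))
  has_core <- first_an > 0L
  core_txt <- ifelse(has_core, substring(raw, first_an, last_an), "")
  core_start <- tok_start + pmax(first_an - 1L, 0L)
  core_end <- core_start + nchar(core_txt) - 1L
  low <- tolower(core_txt)
  stripped <- vapply(low, strip_suffix, "", USE.NAMES = FALSE)

  max_len <- max(c(1L, vapply(names(dict), function(k)
    length(strsplit(k, " ", fixed = TRUE)[[1]]), 1L)))
  n <- length(raw)
  mentions <- list()
  i <- 1L
  while (i <= n) {
    if (!has_core[i] || !nzchar(core_txt[i])) { i <- i + 1L; next }
    hit_k <- 0L
    hit_ids <- NULL
    for (k in seq.int(min(max_len, n - i + 1L), 1L)) {
      j <- i + k - 1L
      if (any(!has_core[i:j]) || any(!nzchar(core_txt[i:j]))) next
      key_raw <- paste(low[i:j], collapse = " ")
      key_strip <- paste(stripped[i:j], collapse = " ")
      ids <- dict[[key_raw]]
      if (is.null(ids)) ids <- dict[[key_strip]]
      if (is.null(ids) && k >= 2L) {
        # keep punctuation on interior tokens ("photosynthesis, light ...")
        inner <- if (k > 2L) tolower(raw[(i + 1L):(j - 1L)]) else character()
        ids <- dict[[paste(c(low[i], inner, low[j]), collapse = " ")]]
      }
      if (!is.null(ids)) { hit_k <- k; hit_ids <- ids; break }
    }
    if (hit_k > 0L) {
      j <- i + hit_k - 1L
      span <- c(core_start[i] - 1L, core_end[j])
      surface <- substr(sentence, core_start[i], core_end[j])
      for (id in hit_ids) {
        mentions[[length(mentions) + 1L]] <-
          list(term_id = id, surface = surface, span = span)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  mentions
}

#' Term ids mentioned in a sentence
#'
#' Convenience wrapper over [recognise()].
#' @inheritParams recognise
#' @return Character vector of unique term ids.
#' @export
recognised_ids <- function(sentence, dict) {
  unique(vapply(recognise(sentence, dict), function(m) m$term_id, ""))
}
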