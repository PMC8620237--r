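# Data model and I/O for evidence-grounded GOA corpora.
#
# Coordinates are 0-based half-open character offsets into the article-level
# text (BioC native offsets are preserved on read). An article's text is the
# concatenation of its passages; each passage records the offset of its first
# character.

#' The closed 10-category section scheme
#'
#' Raw article section titles are normalised into this fixed set; evidence
#' location is a strong signal for unsupportive-evidence detection.
#' @export
SECTION_CATEGORIES <- c(
  "Title", "Abstract", "Introduction", "Background", "Materials and method",
  "Results and discussion", "Conclusion", "Supporting information",
  "Supplementary", "Other"
)

#' Consistency labels
#'
#' `consistent` plus the four inconsistency types: A contradictory regulation
#' polarity, B over-specific term, C unsupportive evidence text, D erroneous
#' experimental evidence code.
#' @export
GOA_LABELS <- c("consistent", "A", "B", "C", "D")

#' Experimental-type GO evidence codes
#'
#' The codes eligible for evidence-code (Type D) error injection; summary
#' sentences carry code "NONE" and are never eligible.
#' @export
EXPERIMENTAL_CODES <- c("IDA", "IMP", "IPI", "IGI", "IEP")

GOA_FIELDS <- c(
  "instance_id", "article_id", "gene_id", "gene_name", "gene_synonyms",
  "evidence_text", "evidence_spans", "evidence_type", "evidence_code",
  "section_raw", "section_category", "go_id", "go_term", "go_definition",
  "go_synonyms", "label", "provenance"
)

#' Construct a sectioned article
#'
#' @param article_id Identifier string.
#' @param passages data.frame with columns `section_title`, `text`,
#'   `char_offset` (0-based offset of the passage's first character).
#' @return Object of class `goa_article`.
#' @export
article <- function(article_id, passages) {
  stopifnot(is.character(article_id), nzchar(article_id),
            is.data.frame(passages),
            all(c("section_title", "text", "char_offset") %in%
                  names(passages)))
  passages$char_offset <- as.integer(passages$char_offset)
  if (any(!nzchar(passages$text))) stop("article: empty passage text")
  if (nrow(passages) > 1L && any(diff(passages$char_offset) <= 0L)) {
    stop("article: passage offsets must be strictly increasing")
  }
  structure(list(article_id = article_id, passages = passages),
            class = "goa_article")
}

#' Slice article text by an absolute character interval
#'
#' @param art A `goa_article`.
#' @param span Integer pair `c(start, end)`, 0-based half-open.
#' @return The covered text; an error if the span crosses outside a passage.
#' @export
article_slice <- function(art, span) {
  p <- art$passages
  for (i in seq_len(nrow(p))) {
    off <- p$char_offset[i]
    len <- nchar(p$text[i])
    if (span[1] >= off && span[2] <= off + len) {
      return(substr(p$text[i], span[1] - off + 1L, span[2] - off))
    }
  }
  stop("span [", span[1], ",", span[2], ") outside passage bounds in article ",
       art$article_id)
}

#' Construct and validate a GOA instance
#'
#' One evidence-grounded annotation: evidence information (text, spans,
#' evidence code, section) paired with GO information (accession, term,
#' definition, synonyms) and a single consistency label.
#'
#' @param ... Named fields; see `GOA_FIELDS` for the full set.
#' @return Object of class `goa_instance`.
#' @export
goa_instance <- function(...) {
  x <- list(...)
  missing <- setdiff(setdiff(GOA_FIELDS, "provenance"), names(x))
  if (length(missing)) {
    stop("goa_instance: missing field(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(x$provenance)) x["provenance"] <- list(NULL)
  # canonical field types so serialisation round-trips are exact
  x$gene_synonyms <- unname(as.character(x$gene_synonyms))
  x$go_synonyms <- unname(as.character(x$go_synonyms))
  x$evidence_spans <- lapply(x$evidence_spans, function(sp)
    as.integer(sp[1:2]))
  for (f in c("instance_id", "article_id", "gene_id", "gene_name",
              "evidence_text", "evidence_type", "evidence_code",
              "section_raw", "section_category", "go_id", "go_term",
              "go_definition", "label")) {
    x[[f]] <- unname(as.character(x[[f]]))
  }
  inst <- structure(x[GOA_FIELDS], class = "goa_instance")
  validate_instance(inst)
  inst
}

validate_instance <- function(inst) {
  if (!is.character(inst$label) || length(inst$label) != 1L ||
      !(inst$label %in% GOA_LABELS)) {
    stop("goa_instance: label must be exactly one of ",
         paste(GOA_LABELS, collapse = "/"))
  }
  if (!(inst$section_category %in% SECTION_CATEGORIES)) {
    stop("goa_instance: section_category outside the 10-category scheme: ",
         inst$section_category)
  }
  if (identical(inst$evidence_code, "NONE") &&
      !identical(inst$evidence_type, "summary")) {
    stop("goa_instance: evidence_code NONE requires evidence_type summary")
  }
  if (!(inst$evidence_type %in% c("experiment", "summary"))) {
    stop("goa_instance: evidence_type must be experiment or summary")
  }
  if (!grepl(GO_ID_RE, inst$go_id)) {
    stop("goa_instance: invalid go_id ", inst$go_id)
  }
  if (!nzchar(inst$evidence_text)) stop("goa_instance: empty evidence_text")
  invisible(inst)
}

#' Concatenate multi-sentence evidence
#'
#' Evidence spanning several sentences is joined in document order with a
#' single space and no other normalisation, forming one long evidence string.
#'
#' @param span_texts Non-empty ordered character vector of sentence strings.
#' @return Single string.
#' @export
concat_evidence <- function(span_texts) {
  if (length(span_texts) == 0L) stop("concat_evidence: empty list")
  paste(span_texts, collapse = " ")
}

#' Normalise a raw section title into the 10-category scheme
#'
#' Total function: a case-insensitive keyword table maps any title to exactly
#' one category, with `Other` as the fallback.
#'
#' @param section_title Any string, possibly empty.
#' @return One of `SECTION_CATEGORIES`.
#' @export
normalize_section <- function(section_title) {
  s <- tolower(section_title)
  if (grepl("method", s)) return("Materials and method")
  if (grepl("result|discussion", s)) return("Results and discussion")
  if (grepl("supplement", s)) return("Supplementary")
  if (grepl("supporting", s)) return("Supporting information")
  if (grepl("background", s)) return("Background")
  if (grepl("intro", s)) return("Introduction")
  if (grepl("abstract", s)) return("Abstract")
  if (grepl("title", s)) return("Title")
  if (grepl("conclusion", s)) return("Conclusion")
  "Other"
}

SENT_ABBREV <- c(
  "fig.", "figs.", "eq.", "eqs.", "et al.", "e.g.", "i.e.", "vs.", "ca.",
  "cf.", "dr.", "no.", "approx.", "resp.", "st.", "al."
)

#' Segment text into sentences with offsets
#'
#' Rule-based splitter: a run of `.?!` ends a sentence when followed by
#' whitespace and an uppercase letter or digit (optionally after an opening
#' quote/bracket), unless the preceding token is a known abbreviation or a
#' single-initial pattern like "S.". Returned sentences are contiguous,
#' non-overlapping and cover all non-whitespace text; offsets are 0-based
#' half-open into the input.
#'
#' @param text Non-empty string.
#' @return data.frame with columns `text`, `start`, `end`.
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  n <- nchar(text)
  m <- gregexpr("[.?!]+", text)[[1]]
  breaks <- integer()
  if (m[1] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    for (e in ends) {
      if (e < n) {
        rest <- substr(text, e + 1L, n)
        if (!grepl("^\\s", rest)) next
        nxt <- sub("^\\s+", "", rest)
        if (nzchar(nxt) && !grepl("^[\"'(\\[]?[A-Z0-9]", nxt)) next
      }
      head_txt <- substr(text, 1L, e)
      pre1 <- sub(".*?(\\S+)$", "\\1", head_txt)
      pre2 <- sub(".*?(\\S+ \\S+)$", "\\1", head_txt)
      if (tolower(pre1) %in% SENT_ABBREV) next
      if (tolower(pre2) %in% SENT_ABBREV) next
      if (grepl("^[A-Z]\\.$", pre1)) next
      breaks <- c(breaks, e)
    }
  }
  starts1 <- c(1L, breaks + 1L)
  ends1 <- c(breaks, n)
  out <- list()
  for (i in seq_along(starts1)) {
    if (starts1[i] > ends1[i]) next
    raw <- substr(text, starts1[i], ends1[i])
    lead <- nchar(raw) - nchar(sub("^\\s+", "", raw))
    trail <- nchar(raw) - nchar(sub("\\s+$", "", raw))
    s1 <- starts1[i] + lead
    e1 <- ends1[i] - trail
    if (s1 > e1) next
    out[[length(out) + 1L]] <- data.frame(
      text = substr(text, s1, e1),
      start = s1 - 1L, end = e1,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# ---- JSONL round trip --------------------------------------------------------

#' Write GOA instances to JSONL
#'
#' One instance per line, UTF-8, stable field order; spans serialise as
#' `[start, end]` pairs and provenance as an object or null.
#'
#' @param instances List of `goa_instance`.
#' @param path Output file path.
#' @export
write_instances <- function(instances, path) {
  lines <- vapply(instances, function(inst) {
    validate_instance(inst)
    x <- unclass(inst)[GOA_FIELDS]
    x$gene_synonyms <- as.list(as.character(x$gene_synonyms))
    x$go_synonyms <- as.list(as.character(x$go_synonyms))
    x$evidence_spans <- lapply(x$evidence_spans, function(sp)
      as.integer(sp[1:2]))
    jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read GOA instances from JSONL
#'
#' Inverse of [write_instances()]: `read_instances(write_instances(x))` is
#' field-for-field identical. Instances violating the invariants are rejected.
#'
#' @param path JSONL file path.
#' @return List of `goa_instance`.
#' @export
read_instances <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(line) {
    x <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    x$gene_synonyms <- as.character(unlist(x$gene_synonyms))
    x$go_synonyms <- as.character(unlist(x$go_synonyms))
    x$evidence_spans <- lapply(x$evidence_spans, function(sp)
      as.integer(unlist(sp)))
    if (!is.null(x$provenance)) {
      x$provenance <- list(
        source_instance_id = as.character(x$provenance$source_instance_id),
        strategy = as.character(x$provenance$strategy),
        seed = as.integer(x$provenance$seed)
      )
    }
    for (f in c("instance_id", "article_id", "gene_id", "gene_name",
                "evidence_text", "evidence_type", "evidence_code",
                "section_raw", "section_category", "go_id", "go_term",
                "go_definition", "label")) {
      x[[f]] <- as.character(x[[f]])
    }
    do.call(goa_instance, x)
  })
}

# ---- BioC XML ----------------------------------------------------------------

#' Read BioC XML collections
#'
#' Parses documents into articles (passages keep section title and native
#' offsets) and raw annotations carrying GO id, evidence code/type, gene
#' fields and evidence spans (converted to 0-based half-open intervals).
#'
#' @param paths Character vector of BioC XML file paths.
#' @return List with elements `articles` (list of `goa_article`) and
#'   `annotations` (list of raw annotation records).
#' @export
read_corpus <- function(paths) {
  articles <- list()
  annotations <- list()
  for (path in paths) {
    doc <- xml2::read_xml(path)
    for (dnode in xml2::xml_find_all(doc, ".//document")) {
      aid <- xml2::xml_text(xml2::xml_find_first(dnode, "./id"))
      pnodes <- xml2::xml_find_all(dnode, "./passage")
      passages <- data.frame(
        section_title = vapply(pnodes, function(p) xml2::xml_text(
          xml2::xml_find_first(p, "./infon[@key='section_title']")), ""),
        text = vapply(pnodes, function(p) xml2::xml_text(
          xml2::xml_find_first(p, "./text")), ""),
        char_offset = vapply(pnodes, function(p) as.integer(xml2::xml_text(
          xml2::xml_find_first(p, "./offset"))), 1L),
        stringsAsFactors = FALSE
      )
      art <- article(aid, passages)
      articles[[aid]] <- art
      for (anode in xml2::xml_find_all(dnode, "./passage/annotation")) {
        infon <- function(key) {
          v <- xml2::xml_text(xml2::xml_find_first(
            anode, sprintf("./infon[@key='%s']", key)))
          if (is.na(v)) "" else v
        }
        locs <- xml2::xml_find_all(anode, "./location")
        spans <- lapply(locs, function(l) {
          off <- as.integer(xml2::xml_attr(l, "offset"))
          len <- as.integer(xml2::xml_attr(l, "length"))
          c(off, off + len)
        })
        span_texts <- vapply(spans, function(sp) article_slice(art, sp), "")
        syn <- infon("gene_synonyms")
        annotations[[length(annotations) + 1L]] <- list(
          annotation_id = xml2::xml_attr(anode, "id"),
          article_id = aid,
          go_id = infon("go_id"),
          evidence_type = infon("evidence_type"),
          evidence_code = infon("evidence_code"),
          gene_id = infon("gene_id"),
          gene_name = infon("gene_name"),
          gene_synonyms = if (nzchar(syn)) strsplit(syn, "|", fixed = TRUE)[[1]]
                          else character(),
          spans = spans,
          span_texts = span_texts,
          section_raw = infon("section_title")
        )
      }
    }
  }
  list(articles = articles, annotations = annotations)
}

#' Write articles and raw annotations as a BioC XML collection
#'
#' @param articles List of `goa_article`.
#' @param annotations List of raw annotation records as made by
#'   [read_corpus()] or [generate_corpus()].
#' @param path Output XML path.
#' @export
write_corpus <- function(articles, annotations, path) {
  doc <- xml2::xml_new_root("collection")
  xml2::xml_add_child(doc, "source", "goac")
  ann_by_article <- split(
    annotations, vapply(annotations, function(a) a$article_id, ""))
  for (art in articles) {
    dnode <- xml2::xml_add_child(doc, "document")
    xml2::xml_add_child(dnode, "id", art$article_id)
    p <- art$passages
    pnodes <- list()
    for (i in seq_len(nrow(p))) {
      pnode <- xml2::xml_add_child(dnode, "passage")
      inf <- xml2::xml_add_child(pnode, "infon", p$section_title[i])
      xml2::xml_set_attr(inf, "key", "section_title")
      xml2::xml_add_child(pnode, "offset", as.character(p$char_offset[i]))
      xml2::xml_add_child(pnode, "text", p$text[i])
      pnodes[[i]] <- pnode
    }
    for (ann in ann_by_article[[art$article_id]]) {
      first <- ann$spans[[1]][1]
      pidx <- max(which(p$char_offset <= first))
      anode <- xml2::xml_add_child(pnodes[[pidx]], "annotation")
      xml2::xml_set_attr(anode, "id", ann$annotation_id)
      add_infon <- function(key, value) {
        inf <- xml2::xml_add_child(anode, "infon", value)
        xml2::xml_set_attr(inf, "key", key)
      }
      add_infon("type", "goa")
      add_infon("go_id", ann$go_id)
      add_infon("evidence_type", ann$evidence_type)
      add_infon("evidence_code", ann$evidence_code)
      add_infon("gene_id", ann$gene_id)
      add_infon("gene_name", ann$gene_name)
      add_infon("gene_synonyms", paste(ann$gene_synonyms, collapse = "|"))
      add_infon("section_title", ann$section_raw)
      for (sp in ann$spans) {
        loc <- xml2::xml_add_child(anode, "location")
        xml2::xml_set_attr(loc, "offset", as.character(sp[1]))
        xml2::xml_set_attr(loc, "length", as.character(sp[2] - sp[1]))
      }
      xml2::xml_add_child(anode, "text", concat_evidence(ann$span_texts))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# ---- Splits ------------------------------------------------------------------

#' Split instances into train/dev/test by article
#'
#' Test instances come only from test articles; the development set is a
#' seeded simple random sample of `round(dev_fraction * n_train)` instances
#' drawn from the training articles, keeping the test set independent.
#'
#' @param instances List of `goa_instance`.
#' @param train_article_ids,test_article_ids Disjoint article id sets.
#' @param dev_fraction Proportion in (0, 1).
#' @param seed Integer seed for the dev draw.
#' @return Object of class `dataset_split` with `train`, `dev`, `test`,
#'   `split_seed`.
#' @export
split_dataset <- function(instances, train_article_ids, test_article_ids,
                          dev_fraction = 0.2, seed = 1L) {
  if (length(intersect(train_article_ids, test_article_ids))) {
    stop("split_dataset: train and test article sets overlap")
  }
  if (!(dev_fraction > 0 && dev_fraction < 1)) {
    stop("split_dataset: dev_fraction must be strictly between 0 and 1")
  }
  aid <- vapply(instances, function(x) x$article_id, "")
  train_pool <- instances[aid %in% train_article_ids]
  test <- instances[aid %in% test_article_ids]
  n_dev <- round(dev_fraction * length(train_pool))
  dev_idx <- with_seed(seed, sample.int(length(train_pool), n_dev))
  structure(list(
    train = train_pool[setdiff(seq_along(train_pool), dev_idx)],
    dev = train_pool[dev_idx],
    test = test,
    split_seed = as.integer(seed)
  ), class = "dataset_split")
}

#' Fraction of test-set GO ids unseen during training
#'
#' Reported for every split: high values indicate the open-world setting in
#' which most test GO terms never occur in train or dev.
#'
#' @param split A `dataset_split`.
#' @return Proportion in `[0, 1]`.
#' @export
unseen_go_fraction <- function(split) {
  seen <- unique(vapply(c(split$train, split$dev), function(x) x$go_id, ""))
  test_ids <- unique(vapply(split$test, function(x) x$go_id, ""))
  if (!length(test_ids)) return(0)
  mean(!(test_ids %in% seen))
}

# run code under a local RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
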