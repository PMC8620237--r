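# Typed inconsistency injection: transform consistent GOA instances into the
# four inconsistency classes with full provenance.
#
#   A  contradictory regulation polarity (positive <-> negative swap)
#   B  over-specific term (replace by a direct descendant)
#   C  unsupportive evidence text (similar non-evidence sentence, same article)
#   D  erroneous experimental evidence code (swap within the experimental set)
#
# Injectors return either a goa_instance or a goa_skip carrying the reason;
# skips are logged outcomes, not errors.

skip_instance <- function(reason) {
  structure(list(reason = reason), class = "goa_skip")
}

#' Did an injector skip this instance?
#' @param x Result of an injector.
#' @return Logical scalar.
#' @export
is_skip <- function(x) inherits(x, "goa_skip")

#' Injection configuration
#'
#' @param seed Master seed for all randomised choices.
#' @param type_b_strategy `"random"` (seeded uniform descendant) or
#'   `"overlap"` (descendant with greatest word overlap with the parent).
#' @param experimental_codes Codes eligible for Type D swapping.
#' @param similarity_backend Name of the sentence-embedding backend used for
#'   Type C candidate ranking; `"tfidf"` is the deterministic default.
#' @param overlap_article_fraction Fraction of training articles whose Type B
#'   instances use the overlap strategy (0.2 mirrors 20 of 100 articles); the
#'   remainder use the random strategy.
#' @return Object of class `injection_config`.
#' @export
injection_config <- function(seed = 7L,
                             type_b_strategy = c("random", "overlap"),
                             experimental_codes = EXPERIMENTAL_CODES,
                             similarity_backend = "tfidf",
                             overlap_article_fraction = 0.2) {
  type_b_strategy <- match.arg(type_b_strategy)
  if (!length(experimental_codes)) {
    stop("injection_config: experimental_codes must be non-empty")
  }
  if (overlap_article_fraction < 0 || overlap_article_fraction > 1) {
    stop("injection_config: overlap_article_fraction must be in [0, 1]")
  }
  structure(list(seed = as.integer(seed),
                 type_b_strategy = type_b_strategy,
                 experimental_codes = experimental_codes,
                 similarity_backend = similarity_backend,
                 overlap_article_fraction = overlap_article_fraction),
            class = "injection_config")
}

# ---- sentence embeddings -----------------------------------------------------

#' Deterministic TF-IDF sentence-embedding backend
#'
#' Builds a vocabulary and smoothed inverse document frequencies from a
#' reference set of sentences. Embeddings are term-frequency counts weighted
#' by idf; tokens outside the vocabulary are ignored. A pluggable, fully
#' deterministic similarity backend for ranking Type C candidates.
#'
#' @param sentences Character vector of reference sentences.
#' @return Object of class `embedding_backend`.
#' @export
tfidf_backend <- function(sentences) {
  stopifnot(length(sentences) > 0L)
  token_sets <- lapply(sentences, function(s) unique(go_tokens(s)))
  vocab <- sort(unique(unlist(token_sets)))
  df <- table(factor(unlist(token_sets), levels = vocab))
  n <- length(sentences)
  idf <- log((1 + n) / (1 + as.numeric(df))) + 1
  names(idf) <- vocab
  structure(list(name = "tfidf", vocab = vocab, idf = idf,
                 dim = length(vocab)),
            class = "embedding_backend")
}

#' Embed a sentence
#'
#' @param text Non-empty sentence.
#' @param backend An `embedding_backend`.
#' @return Object of class `sentence_embedding` with `vector` and `dim`.
#' @export
embed_sentence <- function(text, backend) {
  stopifnot(inherits(backend, "embedding_backend"), nzchar(text))
  toks <- go_tokens(text)
  tf <- table(factor(toks, levels = backend$vocab))
  vec <- as.numeric(tf) * backend$idf
  structure(list(vector = unname(vec), dim = backend$dim),
            class = "sentence_embedding")
}

#' Cosine similarity
#'
#' `dot(a, b) / (|a| |b|)`; defined as 0 when either vector is all-zero.
#'
#' @param a,b `sentence_embedding` objects or bare numeric vectors of the
#'   same dimension.
#' @return Number in `[-1, 1]`.
#' @export
cosine <- function(a, b) {
  va <- if (inherits(a, "sentence_embedding")) a$vector else as.numeric(a)
  vb <- if (inherits(b, "sentence_embedding")) b$vector else as.numeric(b)
  if (length(va) != length(vb)) {
    stop("cosine: dimension mismatch (", length(va), " vs ", length(vb), ")")
  }
  na <- sqrt(sum(va^2))
  nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  sum(va * vb) / (na * nb)
}

# ---- consistent instances ----------------------------------------------------

#' Build a consistent instance from a raw annotation
#'
#' Concatenates multi-sentence evidence into one string, fills the GO
#' definition and synonyms from the ontology graph, and normalises the
#' section title. Annotations on obsolete terms are skipped.
#'
#' @param raw_annotation Raw annotation record (see [read_corpus()]).
#' @param graph An `ontology_graph`.
#' @return A `goa_instance` with label `consistent`, or a skip.
#' @export
make_consistent <- function(raw_annotation, graph) {
  term <- require_term(graph, raw_annotation$go_id)
  if (term$is_obsolete) {
    return(skip_instance(paste0("obsolete term ", term$term_id)))
  }
  goa_instance(
    instance_id = raw_annotation$annotation_id,
    article_id = raw_annotation$article_id,
    gene_id = raw_annotation$gene_id,
    gene_name = raw_annotation$gene_name,
    gene_synonyms = raw_annotation$gene_synonyms,
    evidence_text = concat_evidence(raw_annotation$span_texts),
    evidence_spans = raw_annotation$spans,
    evidence_type = raw_annotation$evidence_type,
    evidence_code = raw_annotation$evidence_code,
    section_raw = raw_annotation$section_raw,
    section_category = normalize_section(raw_annotation$section_raw),
    go_id = term$term_id,
    go_term = term$name,
    go_definition = term$definition,
    go_synonyms = term$synonyms,
    label = "consistent",
    provenance = NULL
  )
}

replace_go_fields <- function(instance, term, label, strategy, seed = 0L) {
  instance$go_id <- term$term_id
  instance$go_term <- term$name
  instance$go_definition <- term$definition
  instance$go_synonyms <- term$synonyms
  instance$label <- label
  instance$provenance <- list(source_instance_id = instance$instance_id,
                              strategy = strategy, seed = as.integer(seed))
  instance$instance_id <- paste0(instance$instance_id, "-",
                                 tolower(label))
  validate_instance(instance)
  instance
}

#' Swap a term's regulation polarity phrase
#'
#' "positive regulation" becomes "negative regulation" and vice versa (first
#' occurrence, case-insensitive); an involution on term strings.
#'
#' @param name Term string.
#' @return Swapped string, or `NULL` when no polarity phrase is present.
#' @export
swap_polarity <- function(name) {
  if (grepl("positive regulation", name, ignore.case = TRUE)) {
    sub("positive regulation", "negative regulation", name,
        ignore.case = TRUE)
  } else if (grepl("negative regulation", name, ignore.case = TRUE)) {
    sub("negative regulation", "positive regulation", name,
        ignore.case = TRUE)
  } else {
    NULL
  }
}

#' Type A injection: contradictory regulation polarity
#'
#' Swaps the polarity phrase in the term name and re-resolves the swapped
#' name in the graph to refresh accession, definition and synonyms. Skips
#' when the term has no polarity phrase or the sibling term does not exist
#' (no GO id is ever fabricated).
#'
#' @param instance Consistent `goa_instance`.
#' @param graph An `ontology_graph`.
#' @return A `goa_instance` with label `A`, or a skip.
#' @export
inject_type_a <- function(instance, graph) {
  stopifnot(identical(instance$label, "consistent"))
  swapped <- swap_polarity(instance$go_term)
  if (is.null(swapped)) {
    return(skip_instance("no regulation polarity phrase in term"))
  }
  sibling_id <- lookup_by_name(graph, swapped)
  if (is.null(sibling_id)) {
    return(skip_instance(paste0("polarity sibling absent: ", swapped)))
  }
  replace_go_fields(instance, graph$terms[[sibling_id]], "A", "polarity_swap")
}

#' Type B injection: over-specific term
#'
#' Replaces the term by one of its direct is_a/part_of descendants. The
#' `random` strategy draws uniformly (seeded) over the accession-sorted
#' candidates; the `overlap` strategy takes the descendant with the greatest
#' word overlap with the parent name, ties broken by ascending accession.
#' Leaf terms are skipped.
#'
#' @param instance Consistent `goa_instance`.
#' @param graph An `ontology_graph`.
#' @param strategy `"random"` or `"overlap"`.
#' @param seed Seed for the random strategy.
#' @return A `goa_instance` with label `B`, or a skip.
#' @export
inject_type_b <- function(instance, graph,
                          strategy = c("random", "overlap"), seed = 0L) {
  stopifnot(identical(instance$label, "consistent"))
  strategy <- match.arg(strategy)
  kids <- direct_descendants(graph, instance$go_id)
  if (!length(kids)) return(skip_instance("leaf term"))
  child_id <- if (strategy == "random") {
    with_seed(seed, sample(kids, 1L))
  } else {
    ov <- vapply(kids, function(k)
      word_overlap(instance$go_term, graph$terms[[k]]$name), 1L)
    kids[which.max(ov)]  # kids sorted ascending: ties go to lowest accession
  }
  replace_go_fields(instance, graph$terms[[child_id]], "B",
                    paste0("descendant_", strategy), seed)
}

#' Unsupportive sentence pool of an article
#'
#' Segments every passage and keeps sentences that do not overlap any
#' evidence span of any instance in the article — the strict reading of
#' "text not annotated with a GO term is unsupportive".
#'
#' @param art A `goa_article`.
#' @param article_instances All instances grounded in this article.
#' @return data.frame with `text`, `start`, `end` (absolute offsets),
#'   `section_raw`.
#' @export
unsupportive_sentences <- function(art, article_instances) {
  spans <- do.call(rbind, lapply(article_instances, function(x)
    do.call(rbind, lapply(x$evidence_spans, function(sp) sp[1:2]))))
  pool <- list()
  p <- art$passages
  for (i in seq_len(nrow(p))) {
    sents <- segment_sentences(p$text[i])
    if (!nrow(sents)) next
    sents$start <- sents$start + p$char_offset[i]
    sents$end <- sents$end + p$char_offset[i]
    sents$section_raw <- p$section_title[i]
    pool[[length(pool) + 1L]] <- sents
  }
  pool <- do.call(rbind, pool)
  if (is.null(pool)) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      section_raw = character(), stringsAsFactors = FALSE))
  }
  if (!is.null(spans)) {
    keep <- vapply(seq_len(nrow(pool)), function(i) {
      !any(pool$start[i] < spans[, 2] & spans[, 1] < pool$end[i])
    }, TRUE)
    pool <- pool[keep, , drop = FALSE]
  }
  pool[order(pool$start), , drop = FALSE]
}

#' Type C injection: unsupportive evidence text
#'
#' Replaces the evidence sentence with the most similar unsupportive sentence
#' from the same article that mentions the instance's GO concept. Pipeline:
#' collect non-evidence sentences, keep those where dictionary recognition
#' finds the instance's concept, skip when the instance's own evidence
#' carries no recognisable GO concept, rank candidates by cosine similarity
#' of sentence embeddings (ties go to the earliest sentence), then replace
#' text, spans and section. The source's evidence type and code are kept.
#'
#' @param instance Consistent `goa_instance`.
#' @param art The `goa_article` the instance is grounded in.
#' @param article_instances All instances of that article (defines the
#'   evidence spans excluded from the unsupportive pool).
#' @param dict A `concept_dictionary`.
#' @param backend Optional `embedding_backend`; defaults to TF-IDF fitted on
#'   the evidence sentence plus the candidate pool.
#' @return A `goa_instance` with label `C`, or a skip.
#' @export
inject_type_c <- function(instance, art, article_instances, dict,
                          backend = NULL) {
  stopifnot(identical(instance$label, "consistent"))
  if (!length(recognised_ids(instance$evidence_text, dict))) {
    return(skip_instance("no GO concept recognised in evidence sentence"))
  }
  pool <- unsupportive_sentences(art, article_instances)
  if (!nrow(pool)) return(skip_instance("no unsupportive sentences"))
  keep <- vapply(pool$text, function(s)
    instance$go_id %in% recognised_ids(s, dict), TRUE, USE.NAMES = FALSE)
  pool <- pool[keep, , drop = FALSE]
  if (!nrow(pool)) {
    return(skip_instance("no unsupportive sentence mentions the GO concept"))
  }
  if (is.null(backend)) {
    backend <- tfidf_backend(c(instance$evidence_text, pool$text))
  }
  ev <- embed_sentence(instance$evidence_text, backend)
  sims <- vapply(pool$text, function(s)
    cosine(ev, embed_sentence(s, backend)), 1, USE.NAMES = FALSE)
  best <- which.max(sims)  # pool in document order: ties -> earliest sentence
  instance$provenance <- list(source_instance_id = instance$instance_id,
                              strategy = "unsupportive_similarity",
                              seed = 0L)
  instance$instance_id <- paste0(instance$instance_id, "-c")
  instance$evidence_text <- pool$text[best]
  instance$evidence_spans <- list(c(pool$start[best], pool$end[best]))
  instance$section_raw <- pool$section_raw[best]
  instance$section_category <- normalize_section(pool$section_raw[best])
  instance$label <- "C"
  validate_instance(instance)
  instance
}

#' Type D injection: erroneous experimental evidence code
#'
#' Only experiment-type instances whose code is in the experimental set are
#' eligible; summary sentences (code "NONE") do not support code selection
#' and are skipped. The replacement is a seeded uniform draw from the
#' remaining experimental codes, never the original.
#'
#' @param instance Consistent `goa_instance`.
#' @param config An `injection_config`.
#' @param seed Seed for the draw.
#' @return A `goa_instance` with label `D`, or a skip.
#' @export
inject_type_d <- function(instance, config = injection_config(), seed = 0L) {
  stopifnot(identical(instance$label, "consistent"))
  if (!identical(instance$evidence_type, "experiment") ||
      !(instance$evidence_code %in% config$experimental_codes)) {
    return(skip_instance("not an experimental-code instance"))
  }
  pool <- sort(setdiff(config$experimental_codes, instance$evidence_code))
  new_code <- if (length(pool) == 1L) pool else
    with_seed(seed, sample(pool, 1L))
  instance$provenance <- list(source_instance_id = instance$instance_id,
                              strategy = "code_swap", seed = as.integer(seed))
  instance$instance_id <- paste0(instance$instance_id, "-d")
  instance$evidence_code <- new_code
  instance$label <- "D"
  validate_instance(instance)
  instance
}

# deterministic per-instance sub-seed below 2^31
derive_seed <- function(seed, idx) {
  (as.numeric(seed) * 10007 + idx * 101) %% 2147483629
}

#' Generate the full five-class dataset
#'
#' Runs [make_consistent()] then all four injectors over every raw
#' annotation. The Type B strategy is assigned per article: a seeded sample
#' of `overlap_article_fraction` of the training articles uses the overlap
#' strategy, the rest (and all test articles) the random strategy. Skips are
#' logged with reasons; identical inputs and config give identical datasets.
#'
#' @param articles Named list of `goa_article`.
#' @param annotations Raw annotation records.
#' @param graph An `ontology_graph`.
#' @param config An `injection_config`.
#' @param train_article_ids,test_article_ids Disjoint article id sets.
#' @param dev_fraction Development-set fraction of training instances.
#' @return List with `split` (a `dataset_split`), `counts` (class-by-split
#'   table), and `skips` (data.frame of skip reasons).
#' @export
build_dataset <- function(articles, annotations, graph,
                          config = injection_config(),
                          train_article_ids, test_article_ids,
                          dev_fraction = 0.2) {
  dict <- build_dictionary(graph)
  skips <- list()
  note_skip <- function(id, stage, res) {
    skips[[length(skips) + 1L]] <<- data.frame(
      instance_id = id, stage = stage, reason = res$reason,
      stringsAsFactors = FALSE)
  }

  train_sorted <- sort(train_article_ids)
  n_overlap <- round(config$overlap_article_fraction * length(train_sorted))
  overlap_articles <- if (n_overlap > 0L) {
    with_seed(config$seed, sample(train_sorted, n_overlap))
  } else {
    character()
  }

  instances <- list()
  consistent <- list()
  for (i in seq_along(annotations)) {
    res <- make_consistent(annotations[[i]], graph)
    if (is_skip(res)) {
      note_skip(annotations[[i]]$annotation_id, "consistent", res)
    } else {
      consistent[[length(consistent) + 1L]] <- res
    }
  }
  by_article <- split(consistent,
                      vapply(consistent, function(x) x$article_id, ""))

  for (i in seq_along(consistent)) {
    inst <- consistent[[i]]
    sub_seed <- derive_seed(config$seed, i)
    instances[[length(instances) + 1L]] <- inst

    res <- inject_type_a(inst, graph)
    if (is_skip(res)) note_skip(inst$instance_id, "A", res) else
      instances[[length(instances) + 1L]] <- res

    strategy <- if (inst$article_id %in% overlap_articles) "overlap" else
      config$type_b_strategy
    res <- inject_type_b(inst, graph, strategy, sub_seed)
    if (is_skip(res)) note_skip(inst$instance_id, "B", res) else
      instances[[length(instances) + 1L]] <- res

    res <- inject_type_c(inst, articles[[inst$article_id]],
                         by_article[[inst$article_id]], dict)
    if (is_skip(res)) note_skip(inst$instance_id, "C", res) else
      instances[[length(instances) + 1L]] <- res

    res <- inject_type_d(inst, config, sub_seed)
    if (is_skip(res)) note_skip(inst$instance_id, "D", res) else
      instances[[length(instances) + 1L]] <- res
  }

  split <- split_dataset(instances, train_article_ids, test_article_ids,
                         dev_fraction, config$seed)
  skips <- if (length(skips)) do.call(rbind, skips) else
    data.frame(instance_id = character(), stage = character(),
               reason = character(), stringsAsFactors = FALSE)
  list(split = split, counts = dataset_counts(split), skips = skips)
}

#' Per-class instance counts by split
#'
#' @param split A `dataset_split`.
#' @return Integer matrix, rows = labels, columns = train/dev/test.
#' @export
dataset_counts <- function(split) {
  count <- function(xs) {
    table(factor(vapply(xs, function(x) x$label, ""), levels = GOA_LABELS))
  }
  m <- cbind(train = count(split$train), dev = count(split$dev),
             test = count(split$test))
  storage.mode(m) <- "integer"
  m
}

#' Export generated instances for manual review
#'
#' Writes a TSV with the fields a curator needs to confirm the intended
#' (in)consistency of each generated instance.
#'
#' @param instances List of `goa_instance`.
#' @param path Output TSV path.
#' @export
review_export <- function(instances, path) {
  df <- data.frame(
    instance_id = vapply(instances, function(x) x$instance_id, ""),
    label = vapply(instances, function(x) x$label, ""),
    go_id = vapply(instances, function(x) x$go_id, ""),
    go_term = vapply(instances, function(x) x$go_term, ""),
    evidence_code = vapply(instances, function(x) x$evidence_code, ""),
    section_category = vapply(instances, function(x) x$section_category, ""),
    evidence_text = vapply(instances, function(x) x$evidence_text, ""),
    strategy = vapply(instances, function(x)
      if (is.null(x$provenance)) "" else x$provenance$strategy, ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
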