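# Seeded generators for a mini GO-style ontology and a toy evidence-grounded
# corpus with the structural features the pipeline assumes: regulation
# polarity sibling pairs, multi-child parents, leaves, an obsolete term,
# digit/Roman/"of" term surface forms, experiment and summary evidence, and
# unsupportive distractor sentences mentioning annotated concepts.
#
# Fixture accessions use the reserved high range GO:9xxxxxx so they cannot
# collide with real GO ids. Sentences are template-generated with controlled
# lexical cues per class; they are structural stand-ins, not biology.

#' Fixture generator configuration
#'
#' Section mixes default to the observed distribution of evidence sections in
#' consistent instances (results-and-discussion dominated, 80.6%) and the
#' flatter distribution of unsupportive text.
#'
#' @param seed Master seed; the generators are byte-deterministic given it.
#' @param n_terms Approximate ontology size (>= 10).
#' @param n_articles Number of articles.
#' @param annotations_per_article Consistent annotations per article.
#' @param section_distribution Named probability vector over the 10 section
#'   categories for evidence sentences.
#' @param unsupportive_section_distribution Same, for distractor sentences.
#' @param polarity_pair_fraction Fraction of term families that carry
#'   positive/negative regulation siblings.
#' @param leaf_fraction Fraction of base terms left as leaves.
#' @param roman_digit_fraction Fraction of base terms decorated with a Roman
#'   numeral or digit token.
#' @param unsupportive_sentences_per_article Distractor sentences per article.
#' @param plant_obsolete Include one annotation on an obsolete term (which
#'   [make_consistent()] must skip)?
#' @return Object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 7L,
                           n_terms = 240L,
                           n_articles = 12L,
                           annotations_per_article = 6L,
                           section_distribution = NULL,
                           unsupportive_section_distribution = NULL,
                           polarity_pair_fraction = 0.6,
                           leaf_fraction = 0.3,
                           roman_digit_fraction = 0.25,
                           unsupportive_sentences_per_article = 6L,
                           plant_obsolete = TRUE) {
  if (is.null(section_distribution)) {
    section_distribution <- c(1.2, 11.4, 2.7, 0, 3.9, 80.6, 0.2, 0, 0, 0)
  }
  if (is.null(unsupportive_section_distribution)) {
    unsupportive_section_distribution <-
      c(1.8, 3.4, 13.4, 1.2, 12.6, 53.3, 0.6, 2.8, 10.5, 0.6)
  }
  norm <- function(p) {
    p <- as.numeric(p)
    stopifnot(length(p) == 10L, all(p >= 0), sum(p) > 0)
    stats::setNames(p / sum(p), SECTION_CATEGORIES)
  }
  stopifnot(n_terms >= 10L)
  for (f in c(polarity_pair_fraction, leaf_fraction, roman_digit_fraction)) {
    stopifnot(f >= 0, f <= 1)
  }
  structure(list(
    seed = as.integer(seed),
    n_terms = as.integer(n_terms),
    n_articles = as.integer(n_articles),
    annotations_per_article = as.integer(annotations_per_article),
    section_distribution = norm(section_distribution),
    unsupportive_section_distribution =
      norm(unsupportive_section_distribution),
    polarity_pair_fraction = polarity_pair_fraction,
    leaf_fraction = leaf_fraction,
    roman_digit_fraction = roman_digit_fraction,
    unsupportive_sentences_per_article =
      as.integer(unsupportive_sentences_per_article),
    plant_obsolete = plant_obsolete
  ), class = "fixture_config")
}

fixture_go_id <- function(i) sprintf("GO:9%06d", i)

#' Generate a mini ontology
#'
#' Builds a DAG of GO-style term families under a single root: base process
#' terms, "regulation of" children, positive/negative regulation sibling
#' pairs (so polarity swapping can fire), specific part_of/is_a descendants
#' (so over-specific injection can fire), decorated digit/Roman surface
#' forms, deliberate leaves, synonyms, and one obsolete term.
#'
#' @param config A `fixture_config`.
#' @return List with `obo_text` (a single OBO document string) and `graph`
#'   (the parsed `ontology_graph`).
#' @export
generate_ontology <- function(config = fixture_config()) {
  mods <- c("vesicle", "membrane", "protein", "lipid", "ion", "calcium",
            "pollen", "root", "leaf", "spore", "axon", "cuticle", "pigment",
            "starch", "hormone", "ribosome", "chromatin", "tubulin")
  procs <- c("fusion", "transport", "growth", "assembly", "repair",
             "migration", "signaling", "storage", "secretion", "folding")
  base_pool <- as.vector(outer(mods, procs, paste))

  with_seed(config$seed, {
    terms <- list()
    nid <- 0L
    new_term <- function(name, definition, parents = NULL, synonyms = character(),
                         obsolete = FALSE) {
      nid <<- nid + 1L
      id <- fixture_go_id(nid)
      terms[[id]] <<- list(term_id = id, name = name, definition = definition,
                           synonyms = synonyms, is_obsolete = obsolete,
                           parents = parents)
      id
    }
    root <- new_term("biological process",
                     "Any process specifically pertinent to the functioning of integrated living units.")
    bases <- sample(base_pool, length(base_pool))
    b <- 0L
    while (nid < config$n_terms - 1L && b < length(bases)) {
      b <- b + 1L
      name <- bases[b]
      u <- stats::runif(1)
      if (u < config$roman_digit_fraction / 2) {
        name <- paste(name, "II")
      } else if (u < config$roman_digit_fraction) {
        name <- paste0(name, " 3")
      }
      base_id <- new_term(
        name,
        paste0("The directed ", name,
               " that contributes to cellular organisation."),
        parents = list(c(root, "is_a")),
        synonyms = if (stats::runif(1) < 0.25) paste(name, "process")
                   else character()
      )
      if (stats::runif(1) < config$leaf_fraction) next
      reg_id <- new_term(
        paste("regulation of", name),
        paste0("Any process that modulates the frequency, rate or extent of ",
               name, "."),
        parents = list(c(base_id, "is_a"))
      )
      if (stats::runif(1) < config$polarity_pair_fraction) {
        new_term(
          paste("positive regulation of", name),
          paste0("Any process that activates or increases the frequency, ",
                 "rate or extent of ", name, "."),
          parents = list(c(reg_id, "is_a"))
        )
        new_term(
          paste("negative regulation of", name),
          paste0("Any process that stops, prevents or reduces the frequency, ",
                 "rate or extent of ", name, "."),
          parents = list(c(reg_id, "is_a"))
        )
      }
      specific_mod <- sample(c("larval", "embryonic", "cellular", "rapid",
                               "chronic"), 1)
      new_term(
        paste(specific_mod, name),
        paste0("The ", name, " occurring during the ", specific_mod,
               " stage."),
        parents = list(c(base_id,
                         if (stats::runif(1) < 0.3) "part_of" else "is_a"))
      )
    }
    new_term("deprecated larval behavior",
             "OBSOLETE. A behaviour term retired from the vocabulary.",
             obsolete = TRUE)
    obo_text <- render_obo(terms)
    list(obo_text = obo_text, graph = parse_obo(obo_text))
  })
}

render_obo <- function(terms) {
  stanzas <- vapply(terms[order(names(terms))], function(t) {
    lines <- c("[Term]",
               paste0("id: ", t$term_id),
               paste0("name: ", t$name),
               paste0("def: \"", t$definition, "\" [goac:fixture]"))
    for (s in t$synonyms) {
      lines <- c(lines, paste0("synonym: \"", s, "\" EXACT []"))
    }
    for (p in t$parents) {
      lines <- c(lines, if (p[2] == "is_a") paste0("is_a: ", p[1]) else
        paste0("relationship: part_of ", p[1]))
    }
    if (t$is_obsolete) lines <- c(lines, "is_obsolete: true")
    paste(lines, collapse = "\n")
  }, "")
  paste0("format-version: 1.2\nontology: goac-fixture\n\n",
         paste(stanzas, collapse = "\n\n"), "\n")
}

CODE_CUE_PHRASES <- c(
  IDA = "a direct enzymatic assay",
  IMP = "analysis of the mutant phenotype",
  IPI = "a two-hybrid binding interaction",
  IGI = "a genetic interaction between alleles",
  IEP = "the expression pattern of its transcript"
)

SECTION_RAW_TITLES <- c(
  "Title" = "Title",
  "Abstract" = "ABSTRACT",
  "Introduction" = "Introduction",
  "Background" = "Background",
  "Materials and method" = "Materials and Methods",
  "Results and discussion" = "RESULTS",
  "Conclusion" = "Conclusions",
  "Supporting information" = "Supporting Information",
  "Supplementary" = "Supplementary Material",
  "Other" = "Acknowledgements"
)

evidence_sentence <- function(gene, term_name, evidence_type, code) {
  pol <- term_polarity(term_name)
  verb <- if (pol > 0L) "activates" else if (pol < 0L) "inhibits" else
    "mediates"
  if (evidence_type == "experiment") {
    paste0("Our results demonstrate that ", gene, " ", verb, " ",
           term_name, " in treated cells, as established by ",
           CODE_CUE_PHRASES[[code]], ".")
  } else {
    paste0("Together these data show that ", gene, " ", verb, " ",
           term_name, " during development.")
  }
}

distractor_sentence <- function(term_name, k) {
  templates <- c(
    paste0("Samples enriched for ", term_name,
           " fractions were prepared for microscopy."),
    paste0("Earlier reports on ", term_name,
           " in related species remain inconclusive."),
    paste0("Buffers used throughout the ", term_name,
           " experiments were kept at 4 degrees."),
    paste0("A summary table lists ", term_name,
           " measurements across replicates.")
  )
  templates[(k - 1L) %% length(templates) + 1L]
}

#' Generate a toy evidence-grounded corpus
#'
#' Articles carry passages across the 10 section categories. Each consistent
#' annotation embeds its GO term name in a templated evidence sentence that
#' also carries a result-framing verb, a polarity verb matching the term's
#' regulation polarity, and (for experiment-type evidence) a keyword phrase
#' for its evidence code; summary evidence carries code "NONE". Distractor
#' sentences mention annotated GO concepts without gene-function framing and
#' follow a flatter section distribution, supplying Type C candidates.
#'
#' @param graph Graph from [generate_ontology()].
#' @param config A `fixture_config`.
#' @return List with `articles` (named list of `goa_article`) and
#'   `annotations` (raw annotation records accepted by [make_consistent()]).
#' @export
generate_corpus <- function(graph, config = fixture_config()) {
  eligible <- Filter(function(t) !t$is_obsolete &&
                       t$name != "biological process", graph$terms)
  ids <- vapply(eligible, function(t) t$term_id, "")
  is_pol <- vapply(eligible, function(t)
    term_polarity(t$name) != 0L, TRUE)
  is_parent <- vapply(eligible, function(t)
    !is_leaf(graph, t$term_id), TRUE)
  weight <- ifelse(is_pol, 2, 1) * ifelse(is_parent, 2, 1)
  obsolete_ids <- names(Filter(function(t) t$is_obsolete, graph$terms))

  # family = the depth-1 ancestor of a term (its base process). Articles draw
  # whole families without replacement, so a family's terms — including the
  # siblings and descendants that injection substitutes in — stay within one
  # article and test-set GO ids are mostly unseen during training (the
  # open-world setting).
  family_of <- function(id) {
    repeat {
      parents <- graph$terms[[id]]$parents
      if (!nrow(parents)) return(id)
      nxt <- parents$parent[1]
      if (!nrow(graph$terms[[nxt]]$parents)) return(id)
      id <- nxt
    }
  }
  fams <- vapply(ids, family_of, "")

  with_seed(config$seed + 1L, {
    articles <- list()
    annotations <- list()
    fam_pool <- unique(fams)
    for (a in seq_len(config$n_articles)) {
      aid <- sprintf("PMC%04d", a)
      gene_n <- (a - 1L) * 3L + 1L
      sentences <- list()  # text, category, ann (0 = distractor)
      add_sentence <- function(text, category, ann = 0L) {
        sentences[[length(sentences) + 1L]] <<-
          list(text = text, category = category, ann = ann)
      }
      n_ann <- config$annotations_per_article
      if (length(fam_pool) < n_ann) fam_pool <- unique(fams)
      picked_fams <- sample(fam_pool, n_ann, replace = FALSE)
      fam_pool <- setdiff(fam_pool, picked_fams)
      ann_terms <- unname(vapply(picked_fams, function(f) {
        members <- which(fams == f)
        if (length(members) == 1L) ids[members] else
          sample(ids[members], 1L, prob = weight[members])
      }, ""))
      plant_here <- config$plant_obsolete && a == 1L && length(obsolete_ids)
      for (k in seq_len(n_ann)) {
        gene <- paste0("GENE", gene_n + (k %% 3L))
        go_id <- if (plant_here && k == n_ann) obsolete_ids[1] else
          ann_terms[k]
        term_name <- graph$terms[[go_id]]$name
        evidence_type <- if (stats::runif(1) < 0.7) "experiment" else
          "summary"
        code <- if (evidence_type == "experiment") {
          sample(EXPERIMENTAL_CODES, 1)
        } else "NONE"
        category <- sample(SECTION_CATEGORIES, 1,
                           prob = config$section_distribution)
        texts <- evidence_sentence(gene, term_name, evidence_type, code)
        if (k %% 5L == 0L) {
          texts <- c(texts, paste0("This effect of ", gene,
                                   " was reproducible across replicates."))
        }
        for (txt in texts) add_sentence(txt, category, k)
        annotations[[length(annotations) + 1L]] <- list(
          annotation_id = sprintf("%s-%02d", aid, k),
          article_id = aid,
          go_id = go_id,
          evidence_type = evidence_type,
          evidence_code = code,
          gene_id = paste0("GID", gene_n + (k %% 3L)),
          gene_name = gene,
          gene_synonyms = paste0("g", gene_n + (k %% 3L)),
          spans = NULL,       # filled after passage assembly
          span_texts = texts,
          section_raw = SECTION_RAW_TITLES[[category]]
        )
      }
      for (k in seq_len(config$unsupportive_sentences_per_article)) {
        term_name <- graph$terms[[ann_terms[(k - 1L) %% n_ann + 1L]]]$name
        category <- sample(SECTION_CATEGORIES, 1,
                           prob = config$unsupportive_section_distribution)
        add_sentence(distractor_sentence(term_name, k), category, 0L)
      }

      # assemble passages in canonical section order; track sentence offsets
      cats <- vapply(sentences, function(s) s$category, "")
      offset <- 0L
      passages <- list()
      sent_abs <- vector("list", length(sentences))
      for (cat in SECTION_CATEGORIES) {
        idx <- which(cats == cat)
        if (!length(idx)) next
        texts <- vapply(sentences[idx], function(s) s$text, "")
        starts <- cumsum(c(0L, utils::head(nchar(texts) + 1L, -1L)))
        for (j in seq_along(idx)) {
          sent_abs[[idx[j]]] <- c(offset + starts[j],
                                  offset + starts[j] + nchar(texts[j]))
        }
        ptext <- paste(texts, collapse = " ")
        passages[[length(passages) + 1L]] <- data.frame(
          section_title = SECTION_RAW_TITLES[[cat]],
          text = ptext, char_offset = offset, stringsAsFactors = FALSE)
        offset <- offset + nchar(ptext) + 1L
      }
      articles[[aid]] <- article(aid, do.call(rbind, passages))

      # attach spans to this article's annotations
      anns_here <- which(vapply(annotations, function(x)
        x$article_id == aid, TRUE))
      for (ai in anns_here) {
        k <- as.integer(sub(".*-", "", annotations[[ai]]$annotation_id))
        sent_idx <- which(vapply(sentences, function(s) s$ann == k, TRUE))
        annotations[[ai]]$spans <- sent_abs[sent_idx]
      }
    }
    list(articles = articles, annotations = annotations)
  })
}

#' Select the instances relevant to a task
#'
#' Term task: labels consistent/A/B/C. Code task: labels consistent/D,
#' restricted to experiment-type instances (summary evidence with code
#' "NONE" cannot enter the code task).
#'
#' @param instances List of `goa_instance`.
#' @param task A `task_spec`.
#' @return Filtered list.
#' @export
task_instances <- function(instances, task) {
  keep <- vapply(instances, function(x) {
    x$label %in% task$classes &&
      (task$name == "term" || x$evidence_code != "NONE")
  }, TRUE)
  instances[keep]
}
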