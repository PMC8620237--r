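test_that("consistent instances are filled from the graph; obsolete skipped", {
  g <- feeding_graph()
  ann <- list(
    annotation_id = "A1", article_id = "ART1", go_id = "GO:0007631",
    evidence_type = "experiment", evidence_code = "IMP",
    gene_id = "GID1", gene_name = "GENE1", gene_synonyms = "g1",
    spans = list(c(0L, 10L), c(11L, 20L)),
    span_texts = c("Mice fed.", "They grew."),
    section_raw = "RESULTS"
  )
  inst <- make_consistent(ann, g)
  expect_s3_class(inst, "goa_instance")
  expect_equal(inst$evidence_text, "Mice fed. They grew.")
  expect_equal(inst$go_definition, g$terms[["GO:0007631"]]$definition)
  expect_equal(inst$section_category, "Results and discussion")
  expect_equal(inst$label, "consistent")

  ann$go_id <- "GO:0099999"
  expect_true(is_skip(make_consistent(ann, g)))
  ann$go_id <- "GO:1234567"
  expect_error(make_consistent(ann, g), "unknown")
})

test_that("polarity swap flips regulation direction and re-resolves the id", {
  g <- feeding_graph()
  src <- stub_instance("GO:0031340", g,
                       "SYT1 activates efficient vesicle fusion activity.")
  out <- inject_type_a(src, g)
  expect_equal(out$go_id, "GO:0031339")
  expect_equal(out$go_term, "negative regulation of vesicle fusion")
  expect_equal(out$label, "A")
  expect_equal(out$provenance$source_instance_id, src$instance_id)

  # swap is an involution on term strings
  expect_equal(swap_polarity(swap_polarity(src$go_term)), src$go_term)
  expect_null(swap_polarity("feeding behavior"))
  expect_true(is_skip(inject_type_a(
    stub_instance("GO:0007631", g, "Mice fed."), g)))
})

test_that("over-specific injection honours strategy, ties and leaf skips", {
  g <- feeding_graph()
  src <- stub_instance("GO:0007631", g, "Mice displayed feeding behavior.")

  out <- inject_type_b(src, g, "overlap")
  expect_equal(out$go_term, "regulation of feeding behavior")
  expect_equal(out$go_id, "GO:0060259")
  expect_equal(out$label, "B")
  expect_equal(out$provenance$strategy, "descendant_overlap")

  # random strategy with any seed returns some direct descendant
  kids <- direct_descendants(g, "GO:0007631")
  for (seed in 1:5) {
    drawn <- inject_type_b(src, g, "random", seed)
    expect_true(drawn$go_id %in% kids)
  }
  # single child: deterministic regardless of seed
  g1 <- parse_obo(paste(
    "[Term]\nid: GO:0000001\nname: growth\n",
    "[Term]\nid: GO:0000002\nname: root growth\nis_a: GO:0000001",
    sep = "\n"))
  single <- stub_instance("GO:0000001", g1, "Roots grew.")
  for (seed in c(1, 99)) {
    expect_equal(inject_type_b(single, g1, "random", seed)$go_id,
                 "GO:0000002")
  }
  expect_true(is_skip(inject_type_b(
    stub_instance("GO:0001967", g, "Pups suckled."), g, "random", 1)))
})

test_that("overlap ties break toward the smallest accession", {
  obo <- paste(
    "[Term]\nid: GO:0000009\nname: feeding behavior\n",
    "[Term]\nid: GO:0000005\nname: larva feeding behavior\nis_a: GO:0000009\n",
    "[Term]\nid: GO:0000003\nname: adult feeding behavior\nis_a: GO:0000009",
    sep = "\n")
  g <- parse_obo(obo)
  src <- stub_instance("GO:0000009", g, "Animals fed.")
  expect_equal(inject_type_b(src, g, "overlap")$go_id, "GO:0000003")
})

test_that("unsupportive replacement picks the most similar candidate", {
  g <- feeding_graph()
  ev <- "Cytosolic liver proteins from treated rats were resolved for analysis."
  distract1 <- "Cytosolic liver proteins were resolved by 1D PAGE."
  distract2 <- "The cytosol buffer was stored cold."
  filler <- "Unrelated housekeeping text without concepts."
  passages <- data.frame(
    section_title = c("RESULTS", "Materials and Methods"),
    text = c(ev, paste(distract1, distract2, filler)),
    char_offset = c(0L, nchar(ev) + 1L),
    stringsAsFactors = FALSE
  )
  art <- article("ART1", passages)
  src <- stub_instance("GO:0005829", g, ev, article_id = "ART1",
                       spans = list(c(0L, nchar(ev))))
  d <- build_dictionary(g)

  out <- inject_type_c(src, art, list(src), d)
  expect_equal(out$label, "C")
  expect_equal(out$evidence_text, distract1)
  expect_equal(out$section_category, "Materials and method")
  expect_equal(article_slice(art, out$evidence_spans[[1]]), distract1)
  # the replacement is never one of the article's evidence sentences
  expect_false(out$evidence_text == src$evidence_text)

  # a verbatim copy of the evidence wins with cosine 1
  passages2 <- passages
  passages2$text[2] <- paste(distract2, ev)
  art2 <- article("ART1", passages2)
  out2 <- inject_type_c(src, art2, list(src), d)
  expect_equal(out2$evidence_text, ev)

  # article whose only text is the evidence itself -> no candidates
  art3 <- article("ART1", passages[1, ])
  expect_true(is_skip(inject_type_c(src, art3, list(src), d)))

  # evidence without any recognisable concept -> skip
  no_concept <- "No recognisable mention occurs in this sentence."
  src2 <- stub_instance("GO:0005829", g, no_concept,
                        spans = list(c(0L, nchar(no_concept))))
  expect_true(is_skip(inject_type_c(src2, art, list(src), d)))
})

test_that("code swapping draws a different experimental code, seeded", {
  g <- feeding_graph()
  src <- stub_instance("GO:0007631", g, "Mice fed.", evidence_code = "IMP")
  cfg <- injection_config(seed = 1)
  for (seed in 1:10) {
    out <- inject_type_d(src, cfg, seed)
    expect_true(out$evidence_code %in% setdiff(EXPERIMENTAL_CODES, "IMP"))
    expect_equal(out$label, "D")
  }
  expect_identical(inject_type_d(src, cfg, 5)$evidence_code,
                   inject_type_d(src, cfg, 5)$evidence_code)

  summary_src <- stub_instance("GO:0007631", g, "Mice fed.",
                               evidence_type = "summary",
                               evidence_code = "NONE")
  expect_true(is_skip(inject_type_d(summary_src, cfg, 1)))

  two <- injection_config(seed = 1, experimental_codes = c("IDA", "IMP"))
  src_ida <- stub_instance("GO:0007631", g, "Mice fed.",
                           evidence_code = "IDA")
  expect_equal(inject_type_d(src_ida, two, 7)$evidence_code, "IMP")
})

test_that("cosine similarity follows the closed form", {
  expect_equal(cosine(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine(c(1, 2, 3), -c(1, 2, 3)), -1)
  expect_equal(cosine(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine(c(3, 4), c(4, 3)), 24 / 25)
  expect_equal(cosine(c(0, 0), c(1, 1)), 0)
  expect_error(cosine(c(1, 2), c(1, 2, 3)), "dimension")

  b <- tfidf_backend(c("alpha beta", "beta gamma"))
  e <- embed_sentence("alpha beta", b)
  expect_s3_class(e, "sentence_embedding")
  expect_equal(e$dim, 3L)
  expect_equal(cosine(e, e), 1)
})

test_that("each injected type differs from its source in exactly its facet", {
  ds <- fixture_pipeline()
  instances <- all_split_instances(ds$split)
  by_id <- stats::setNames(instances,
                           vapply(instances, function(x) x$instance_id, ""))
  go_fields <- c("go_id", "go_term", "go_definition", "go_synonyms")
  ev_fields <- c("evidence_text", "evidence_spans", "section_raw",
                 "section_category")
  bookkeeping <- c("instance_id", "label", "provenance")
  n_checked <- 0L
  for (inst in instances) {
    if (inst$label == "consistent") next
    src <- by_id[[inst$provenance$source_instance_id]]
    expect_false(is.null(src))
    changed <- switch(inst$label, A = go_fields, B = go_fields,
                      C = ev_fields, D = "evidence_code")
    same <- setdiff(GOA_FIELDS, c(changed, bookkeeping))
    for (f in same) expect_identical(inst[[f]], src[[f]])
    if (inst$label %in% c("A", "B")) {
      expect_false(identical(inst$go_id, src$go_id))
    }
    if (inst$label == "B") {
      expect_true(inst$go_id %in% direct_descendants(ds$graph, src$go_id))
    }
    if (inst$label == "A") {
      expect_equal(swap_polarity(inst$go_term), src$go_term)
    }
    if (inst$label == "C") {
      ev_sent <- unlist(lapply(
        Filter(function(x) x$article_id == inst$article_id &&
                 x$label == "consistent", instances),
        function(x) x$evidence_text))
      expect_false(inst$evidence_text %in% ev_sent)
    }
    if (inst$label == "D") {
      expect_false(identical(inst$evidence_code, src$evidence_code))
      expect_true(inst$evidence_code %in% EXPERIMENTAL_CODES)
    }
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 100L)
})

test_that("dataset generation is byte-identical under a fixed seed", {
  cfg <- fixture_config(seed = 31, n_terms = 80, n_articles = 5,
                        annotations_per_article = 4)
  run <- function() {
    ont <- generate_ontology(cfg)
    corp <- generate_corpus(ont$graph, cfg)
    aids <- sort(names(corp$articles))
    ds <- build_dataset(corp$articles, corp$annotations, ont$graph,
                        injection_config(seed = 31), aids[1:4], aids[5])
    path <- tempfile(fileext = ".jsonl")
    write_instances(all_split_instances(ds$split), path)
    on.exit(unlink(path))
    tools::md5sum(path)[[1]]
  }
  expect_identical(run(), run())
})

test_that("overlap fraction zero leaves no overlap provenance anywhere", {
  ds <- fixture_pipeline()  # built with overlap_article_fraction = 0.2
  strategies <- unlist(lapply(all_split_instances(ds$split), function(x)
    if (!is.null(x$provenance)) x$provenance$strategy))
  expect_true("descendant_overlap" %in% strategies)

  cfg <- fixture_config(seed = 31, n_terms = 80, n_articles = 5,
                        annotations_per_article = 4)
  ont <- generate_ontology(cfg)
  corp <- generate_corpus(ont$graph, cfg)
  aids <- sort(names(corp$articles))
  ds0 <- build_dataset(corp$articles, corp$annotations, ont$graph,
                       injection_config(seed = 31,
                                        overlap_article_fraction = 0),
                       aids[1:4], aids[5])
  strategies0 <- unlist(lapply(all_split_instances(ds0$split), function(x)
    if (!is.null(x$provenance)) x$provenance$strategy))
  expect_false("descendant_overlap" %in% strategies0)
  # all five classes are present in a default build
  expect_true(all(rowSums(ds0$counts) > 0))
})
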