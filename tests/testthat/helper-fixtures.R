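# Shared fixtures: a small hand-written OBO document around the worked
# examples (feeding behavior, vesicle fusion regulation, cytosol), and a
# memoised run of the full synthetic pipeline so expensive setup happens once.

FEEDING_OBO <- "
format-version: 1.2

[Term]
id: GO:0007631
name: feeding behavior
def: \"Behavior associated with the intake of food.\" [t]

[Term]
id: GO:0001967
name: suckling behavior
def: \"Specific actions of a newborn or infant mammal that result in the derivation of nourishment from the breast.\" [t]
is_a: GO:0007631

[Term]
id: GO:0060259
name: regulation of feeding behavior
def: \"Any process that modulates the rate, frequency or extent of the behavior associated with the intake of food.\" [t]
is_a: GO:0007631

[Term]
id: GO:0031338
name: regulation of vesicle fusion
def: \"Any process that modulates the frequency, rate or extent of vesicle fusion.\" [t]

[Term]
id: GO:0031339
name: negative regulation of vesicle fusion
def: \"Any process that stops, prevents, or reduces the frequency, rate or extent of vesicle fusion.\" [t]
is_a: GO:0031338

[Term]
id: GO:0031340
name: positive regulation of vesicle fusion
def: \"Any process that activates or increases the frequency, rate or extent of vesicle fusion.\" [t]
is_a: GO:0031338

[Term]
id: GO:0005829
name: cytosol
def: \"The part of the cytoplasm that does not contain organelles.\" [t]
synonym: \"cytosolic fraction\" EXACT []

[Term]
id: GO:0042756
name: drinking behavior
def: \"The specific behavior of an organism relating to the intake of liquids.\" [t]
is_a: GO:0007631

[Term]
id: GO:0030536
name: larva feeding behavior
def: \"Feeding behavior during the larval stage.\" [t]
relationship: part_of GO:0042756

[Term]
id: GO:0099999
name: retired behavior term
def: \"OBSOLETE.\" [t]
is_obsolete: true
"

feeding_graph <- function() parse_obo(FEEDING_OBO)

# a minimal consistent instance grounded in an ad-hoc article
stub_instance <- function(go_id, graph, evidence_text,
                          evidence_type = "experiment",
                          evidence_code = "IDA",
                          section_raw = "RESULTS",
                          article_id = "ART1",
                          instance_id = "I1",
                          spans = list(c(0L, nchar(evidence_text))),
                          label = "consistent") {
  term <- graph$terms[[go_id]]
  goa_instance(
    instance_id = instance_id, article_id = article_id,
    gene_id = "GID1", gene_name = "GENE1", gene_synonyms = "g1",
    evidence_text = evidence_text, evidence_spans = spans,
    evidence_type = evidence_type, evidence_code = evidence_code,
    section_raw = section_raw,
    section_category = normalize_section(section_raw),
    go_id = term$term_id, go_term = term$name,
    go_definition = term$definition, go_synonyms = term$synonyms,
    label = label, provenance = NULL
  )
}

# full synthetic pipeline at ~500 generated instances, computed once
fixture_env <- new.env(parent = emptyenv())

fixture_pipeline <- function() {
  if (!is.null(fixture_env$ds)) return(fixture_env$ds)
  cfg <- fixture_config(seed = 101L, n_terms = 500L, n_articles = 25L)
  ont <- generate_ontology(cfg)
  corp <- generate_corpus(ont$graph, cfg)
  aids <- sort(names(corp$articles))
  test_ids <- utils::tail(aids, 6L)
  ds <- build_dataset(corp$articles, corp$annotations, ont$graph,
                      injection_config(seed = 101L),
                      setdiff(aids, test_ids), test_ids)
  fixture_env$ds <- list(cfg = cfg, graph = ont$graph, corp = corp,
                         split = ds$split, counts = ds$counts,
                         skips = ds$skips)
  fixture_env$ds
}

all_split_instances <- function(split) c(split$train, split$dev, split$test)

# label-only stubs for baseline fitting/prediction tests
make_labelled <- function(labels) {
  lapply(seq_along(labels), function(i) {
    list(instance_id = sprintf("L%03d", i), label = labels[i],
         article_id = "A1")
  })
}
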