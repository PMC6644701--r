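# Shared fixtures: ontology files are generated once per test run into a
# session-local directory; word lists and independent oracles used by the
# morphology and statistics tests live here too.

fixture_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      d <- tempfile("verbowl-fixtures-")
      dir.create(d)
      fmts <- c("turtle", "rdfxml", "owlxml", "functional")
      write_paper_examples(d, formats = fmts)
      write_people_ontology(d, formats = fmts)
      dir <<- d
    }
    dir
  }
})

examples_path <- function(fmt = "turtle") {
  ext <- c(turtle = "ttl", rdfxml = "owl", owlxml = "owx", functional = "ofn")
  file.path(fixture_dir(), paste0("worked-examples.", ext[[fmt]]))
}

people_path <- function(fmt = "turtle") {
  ext <- c(turtle = "ttl", rdfxml = "owl", owlxml = "owx", functional = "ofn")
  file.path(fixture_dir(), paste0("people.", ext[[fmt]]))
}

# the package's reference sentences (worked examples), in the axiom set's
# deterministic order
GOLDEN_EXPLICIT <- c(
  "every human subject unable to give informed consent is a human subject",
  "every answer option text entity is something that is about a study requiring informed consent",
  "every duration measurement is an iao 0000032",
  "every Saturday is a week day"
)
GOLDEN_COMPACT_VARIANT <-
  "every answer option text entity is about a study requiring informed consent"

# independent tie-corrected rank computation: average ranks by counting,
# then the Pearson formula written out — no call into the implementation
brute_rank <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, 0)
}
brute_spearman <- function(x, y) {
  rx <- brute_rank(x); ry <- brute_rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# regular nouns for the pluralize/lemmatize round-trip property
REGULAR_NOUNS <- c(
  "cell", "gene", "protein", "tissue", "organ", "sample", "tube", "plate",
  "study", "assay", "test", "trial", "result", "value", "score", "rating",
  "label", "axiom", "class", "branch", "box", "marker", "term", "entity",
  "document", "form", "consent", "subject", "patient", "doctor", "nurse",
  "hospital", "clinic", "drug", "dose", "table", "figure", "chart", "graph",
  "node", "edge", "tree", "leaflet", "root", "stem", "flower", "seed",
  "animal", "dog", "cat", "horse", "cow", "goat", "bird", "shark",
  "house", "car", "train", "plane", "boat", "road", "bridge", "city",
  "town", "village", "country", "region", "area", "zone", "map", "route",
  "book", "page", "chapter", "verse", "word", "letter", "sentence", "phrase",
  "story", "poem", "song", "dance", "game", "match", "race", "prize",
  "week", "month", "year", "day", "hour", "minute", "second", "moment",
  "event", "meeting", "visit", "review", "report", "summary", "record",
  "batch", "dish", "glass", "brush", "church", "family", "party", "puppy"
)

# frozen 3rd-person-singular forms for 50 verb lemmas (hand-verified
# against standard English conjugation)
VERB_3SG_TABLE <- c(
  precede = "precedes", follow = "follows", contain = "contains",
  include = "includes", regulate = "regulates", inhibit = "inhibits",
  activate = "activates", bind = "binds", encode = "encodes",
  express = "expresses", produce = "produces", cause = "causes",
  prevent = "prevents", treat = "treats", affect = "affects",
  modify = "modifies", carry = "carries", study = "studies",
  try = "tries", apply = "applies", say = "says", play = "plays",
  enjoy = "enjoys", buy = "buys", catch = "catches", watch = "watches",
  teach = "teaches", reach = "reaches", push = "pushes", wash = "washes",
  fix = "fixes", mix = "mixes", pass = "passes", miss = "misses",
  buzz = "buzzes", go = "goes", do = "does", echo = "echoes",
  veto = "vetoes", be = "is", have = "has", know = "knows",
  see = "sees", use = "uses", make = "makes", take = "takes",
  give = "gives", find = "finds", run = "runs", overlap = "overlaps"
)
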