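---
title: "Verbalizing OWL 2 axioms for expert review: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verbalizing OWL 2 axioms for expert review: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(verbowl)
```

## The problem

Ontology verification — checking that encoded axioms faithfully represent
domain knowledge — needs the judgment of subject-matter experts, who
typically cannot be asked to read description logic or navigate an
ontology editor. verbowl's premise is that a logical axiom can be shown to
an expert as one English sentence, judged on defined scales, and the
judgments aggregated into quantitative evidence about ontology quality.
The package therefore has two halves: a deterministic axiom-to-sentence
translator, and a rating harness for the review protocol around the
sentences.

## The axiom model

An ontology is loaded (RDF/XML, Turtle, OWL/XML, or functional syntax)
into a flat list of axioms over a recursive class-expression tree. Exactly
14 axiom types are translated:

SubClassOf, EquivalentClasses, DisjointClasses, ClassAssertion,
ObjectPropertyDomain, ObjectPropertyRange, DataPropertyDomain,
DataPropertyRange, SymmetricObjectProperty, FunctionalObjectProperty,
FunctionalDataProperty, ObjectPropertyAssertion, DataPropertyAssertion,
DifferentIndividuals.

Axioms of any other type are counted and skipped at load, never silently
dropped. Class expressions cover named classes, intersection, union,
complement, existential and universal restrictions, and has-value
restrictions; constructors beyond that inventory (cardinalities, `oneOf`,
`hasSelf`, datatype facets) are carried as opaque Manchester text and
verbalize through a flagged generic fallback. The historical inventory
this scope descends from is reported inconsistently in its sources (a
12-plus-6 count next to a stated limit of 14); this package fixes the
enumerable 14 above as its contract.

Two loading behaviors are deliberate:

* **Imports are not auto-resolved.** An entity whose defining ontology was
  not merged into the file simply has no `rdfs:label`. An opt-in flag
  (`follow_imports = TRUE`) follows `owl:imports` for local files only, so
  everything stays offline and reproducible.
* **Determinism.** Axioms are deduplicated by logical identity and sorted
  by (axiom type, Manchester rendering); multiple `rdfs:label` values
  resolve to the lexicographically smallest (English-tagged first). Two
  loads of one file — or of the same axioms in different serializations —
  yield identical downstream output.

The serialization readers are implemented in-package (over `xml2` for the
two XML dialects, with small recursive-descent parsers for Turtle and
functional syntax) and are scoped to the OWL 2 constructs above rather
than being general RDF tooling; the test suite cross-checks the Turtle and
RDF/XML readers triple-by-triple against an independent RDF parser.

## Lexicalization

A sentence is only as good as its entity names:

* With an `rdfs:label`: tokens are the label split on whitespace, case
  preserved ("Saturday" keeps its capital; labels are never re-inflected).
* Without one: tokens come from the IRI's local fragment, split on
  underscores and camelCase, lowercased, digits kept — `IAO_0000032`
  becomes "iao 0000032". This fallback is honest by design: a reviewer
  should *see* that a term is unresolved, so the record is also flagged
  `unlabeled_entity`.

Property labels are classified by a prefix rule into copular ("is about",
"is realized in"), possessive ("has child", "has part"), and plain-verb
("precedes") shapes. Biomedical ontology property naming follows these
conventions closely, and a part-of-speech tagger would add nondeterminism
for little gain; the rule is a committed design decision, reviewable in
one place. Single-token labels classify as plain verbs.

Word normalization is lemmatization by exception table plus conservative
suffix rules — never suffix-stripping stemming, which is known to mangle
words in this setting ("data" must stay "data", not become "da"). A small
rule set also supplies regular pluralization and third-person-singular
verb forms; the tests pin these against frozen hand-verified tables and a
pluralize/lemmatize round-trip property. Specialized medical lexicon
integration is deliberately excluded to keep the package self-contained
and offline.

## Sentence templates

Each axiom type has one template; class expressions recurse. Following the
conventions of the evaluated output style, sentences are emitted in a
single line, without sentence-initial capitalization and without a final
period.

| Axiom | Template |
|---|---|
| C ⊑ D | every ⟦C⟧ *is* ⟦D⟧ |
| C ≡ D | every ⟦C⟧ *is* ⟦D⟧ *and vice versa* |
| Disjoint(C, D) | *no* ⟦C⟧ *is* ⟦D⟧ (pairwise, joined with *and*) |
| C(a) | ⟦a⟧ *is* ⟦C⟧ |
| Domain(R) = C | *everything that* ⟦R⟧ *something is* ⟦C⟧ |
| Range(R) = C | *everything that something* ⟦R⟧ *is* ⟦C⟧ |
| Domain(d) = C | *everything that has a* ⟦d-noun⟧ *is* ⟦C⟧ |
| Range(d) = T | *every* ⟦d-noun⟧ *is a* ⟦T⟧ *value* |
| Symmetric(R) | *if X* ⟦R⟧ *Y then Y* ⟦R⟧ *X* |
| Functional(R) | *everything* ⟦R⟧ *at most one thing* |
| Functional(d) | *everything has at most one* ⟦d-noun⟧ |
| R(a, b) | ⟦a⟧ ⟦R⟧ ⟦b⟧ |
| d(a, v) | *the* ⟦d-noun⟧ *of* ⟦a⟧ *is* v |
| Different(a, b) | ⟦a⟧ *and* ⟦b⟧ *are different* |

Inside predicates, a named class becomes an articled noun phrase ("a week
day" — article chosen by a vowel-letter heuristic with a pronunciation
exception list, giving "an hour" and "an iao 0000032" but "a university");
intersections join with "and", unions with "or", complements with "not";
and an existential restriction ∃R.D becomes "something that ⟦R⟧ ⟦D⟧",
recursing for nested restrictions (∃R.(∃Q.D) → "something that … something
that …"). A verb phrase realizes with its object according to its
classified shape: copular phrases keep their tokens ("is about a study
…"), possessive phrases re-order ("has a person as child"), and plain
verbs inflect to third-person singular.

Only the subsumption examples among the templates are anchored to
published outputs; the wording of the other eleven is unpublished, so the
forms above are this package's own commitments, chosen for the simplest
declarative reading and frozen by golden tests. The range template reads
awkwardly on purpose — object-property ranges are reported to score worst
on clarity, and the default should reproduce the evaluated behavior class
rather than quietly improve on it.

**Discourse styles.** The default *explicit* style inserts the "is
something that" bridge before every restriction predicate, mirroring the
evaluated tool's output; reviewers found that phrase stilted, so a
*compact* style is provided that collapses it for copular properties
("every answer option text entity is about a study requiring informed
consent"). The two styles differ in nothing else, which the tests assert.

**Totality.** Verbalization never aborts a run: an axiom whose template
cannot host an operand yields its Manchester rendering as the sentence,
flagged `generic_fallback`. On the bundled fixtures the fallback rate is
zero.

## Manchester rendering

Each record carries the axiom in Manchester syntax (keywords `SubClassOf:`,
`EquivalentTo:`, `DisjointWith:`, `Domain:`, `Range:`, `Type:`,
`Functional:`, `Symmetric:`, `DifferentFrom:`; constructors `some`, `only`,
`value`, `and`, `or`, `not`). The default naming policy is CURIEs (stable
identifiers, right for machine-read CSV), with a label policy for
human-facing sheets in which multi-word labels are single-quoted and
unlabeled entities fall back to CURIEs; IRIs with no known prefix render in
angle brackets. Since no independent Manchester implementation is
available in this package's dependency footprint, the round-trip check is
internal but dual-route: the renderer works by structural recursion, and a
separately written recursive-descent parser (with Manchester operator
precedence: `or` < `and` < `not` < restrictions) must re-parse every
rendering to a logically identical axiom, compared via a canonical key
that sorts unordered operands.

## The rating protocol

Each sentence is scored on three dimensions: **Clarity** (1 = clear, 2 =
clear but the axiom introduces ambiguity, 3 = not interpretable), **NL
Fidelity to Axiom** (yes/no: does the sentence express the logic), and
**Axiom Fidelity to Domain** (1 = reviewer agrees with the axiom, 2 =
disagrees or is uncertain about concepts *or* relationships, 3 = about
both). Rating sheets lay out item id, axiom type, logic, and sentence,
followed by three empty score columns per rater. Irreconcilable
disagreements remain as both raters' rows; the data model contains no
adjudicated third value.

Summaries follow these definitions:

* clarity and domain-fidelity means/SDs are over per-item mean scores
  across raters;
* the NL-fidelity percentage is over all individual votes;
* inter-rater agreement is the exact-match proportion per dimension,
  averaged over rater pairs when there are more than two — plain
  percentages, no chance correction, matching how such agreement is
  conventionally reported in this protocol;
* Spearman's ρ between clarity and domain fidelity uses tie-corrected
  ranks on the per-item means, with the standard large-sample p
  (`stats::cor.test`, `exact = FALSE`). Computing ρ on per-item means
  pooled across raters is a design choice: the protocol's published
  description does not say whether one rater's values or pooled values
  were used, and mean pooling is the symmetric option. With a constant
  score vector ρ does not exist; it is reported as `NA` with
  `spearman_defined = FALSE`, never as 0.

Per-axiom-type summaries apply the same definitions within each type;
pooled means equal the n-weighted recombination of per-type means, which
the tests verify.

## Synthetic fixtures: what they emulate and what they do not

The package generates its own test ontologies, in all four serializations,
bit-identically on every run:

* **Worked examples** — four subsumption axioms whose sentences are pinned
  byte-exactly in the tests, including one deliberately unlabeled external
  term exercising the fallback path.
* **Family-domain ("people") ontology** — a teaching-style ontology
  emulating the published profile of such a fixture: 13 classes, 8
  properties, 9 individuals, at least one axiom of each of the 14 types
  (including the five types that occur only in this kind of small
  ontology), with 11 SubClassOf and 4 ObjectPropertyDomain axioms. Only
  those counts are published constraints; the actual families, pets and
  ages are this package's own, so the fixture is an emulation, not a
  reconstruction. (The published instance count, "9 instances (90
  total)", is internally unclear; the fixture uses 9 individuals.)

**Simulated ratings** stand in for human experts: rater 1 draws from fixed
categorical distributions chosen to mirror the score profile such
evaluations report for a small clean ontology (clarity P(1,2,3) =
(.80,.15,.05), P(yes) = .90, domain fidelity P(1,2,3) = (.85,.10,.05));
each further rater copies rater 1 and independently replaces each
dimension's score with a *different* value with probability equal to the
disagreement rate. Expected exact-match agreement is therefore exactly
100·(1−rate), giving a closed-form binomial oracle; the bundled checks use
rate 0.14, i.e. 86% expected agreement, the scale reported for clarity in
practice. Problem sizes in the bundled checks — 1000 items for the
agreement/correlation oracle, 200 for the smaller property test — were
chosen once as comfortably inside binomial tolerance at the 99% level.

What passing these tests shows: the pipeline's mechanics (parsing,
template application, statistics) are correct on inputs with clean labels
and conventional property naming. What it does not show: performance on
real ontologies with idiosyncratic nomenclature, BFO-style upper-level
abstractions, or rater behavior that is not a perturbation model —
synthetic raters have no correlation between item difficulty and
disagreement, whereas human disagreement concentrates on unclear items.

## Numerical and degenerate-input choices

* Ordering ties: axiom sort is by (type name, Manchester CURIE rendering),
  radix order, so it cannot vary with locale.
* Label conflicts: lexicographically smallest English-tagged label, else
  smallest overall; logged when not quiet.
* Empty ontology: a valid empty result, not an error; empty rating sheets
  *are* an error (a sheet with nothing to rate is a mistake).
* Single rater: agreement is `NA`, means are defined.
* ρ on fewer than two distinct values: undefined, flagged.
* The CSV dialect is fixed (UTF-8, comma, RFC 4180 quoting, LF) so golden
  files compare byte-for-byte.

## Limitations

The 14-type inventory excludes much of OWL 2 (property hierarchies,
chains, cardinalities, negative assertions); unsupported axioms are
counted, not translated. Sentence quality is bounded by label quality —
the tool surfaces bad labels rather than repairing them. The prefix rule
for property phrases can misclassify unconventional labels (they fall
through to plain-verb treatment). English only; no word-sense
disambiguation or synonym handling; no document-level aggregation of
sentences. The evaluation harness computes descriptive statistics and
agreement, deliberately not chance-corrected kappa.
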