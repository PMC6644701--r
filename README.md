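# verbowl

Biomedical ontologies encode domain knowledge as OWL 2 logical axioms —
`SubClassOf`, `EquivalentClasses`, property domains and ranges, individual
assertions. Verifying that this content is *correct* requires subject-matter
experts, and most subject-matter experts do not read description logic.
verbowl closes that gap: it translates each axiom into one plain English
sentence so an expert can judge the content directly, and it implements the
three-scale rating protocol used to evaluate such sentences, with the
summary statistics that go with it.

## What it computes

**Verbalization.** For an ontology O, every axiom of the 14 supported types
is rendered by a type-specific template over recursively verbalized class
expressions. For example a subsumption C ⊑ D becomes

> every ⟦C⟧ is ⟦D⟧

and an existential restriction C ⊑ ∃R.D becomes, in the default *explicit*
style,

> every ⟦C⟧ is something that ⟦R⟧ a ⟦D⟧

(with a *compact* style available that drops the "is something that" bridge
for copular properties such as *is about*). Entity names ⟦·⟧ come from
`rdfs:label` annotations, tokenized with letter case preserved; an entity
with no label in the loaded file is named from its IRI fragment
(`IAO_0000032` → "iao 0000032") and flagged — the tool never invents a
label. Morphological realization (indefinite articles "a"/"an",
third-person-singular verb agreement) is rule-based and deterministic, and
word normalization uses lemmatization, not suffix-stripping stemming, so
"data" stays "data". Each record also carries the axiom in OWL Manchester
syntax.

**Evaluation harness.** Reviewers score each sentence on three scales:
*Clarity* (1–3), *NL Fidelity to Axiom* (yes/no), and *Axiom Fidelity to
Domain* (1–3). The harness generates rating sheets, ingests rating CSVs,
and computes per-ontology and per-axiom-type summaries: means and SDs over
per-item mean scores, the percentage of "yes" votes, exact-match
inter-rater percent agreement, and Spearman's ρ (tie-corrected ranks)
between clarity and domain fidelity.

Supported inputs: RDF/XML, Turtle, OWL/XML, and OWL functional syntax.
Loading is deterministic — axioms are ordered by (type, Manchester
rendering) — so repeated runs produce byte-identical CSVs.

## Worked example

```r
library(verbowl)

dir <- tempfile(); dir.create(dir)
paths <- write_paper_examples(dir)        # bundled worked-example ontology
ont <- load_ontology(paths[["turtle"]])
count_by_type(ont)
#> # A tibble: 1 × 2
#>   axiom_type     n
#>   <chr>      <int>
#> 1 SubClassOf     4

rec <- verbalize_all(ont)
rec$sentence
#> [1] "every human subject unable to give informed consent is a human subject"
#> [2] "every answer option text entity is something that is about a study requiring informed consent"
#> [3] "every duration measurement is an iao 0000032"
#> [4] "every Saturday is a week day"
rec$flags
#> [1] ""                 ""                 "unlabeled_entity" ""
```

Sentence 3 shows the unresolved-import fallback: `IAO_0000032` has no
`rdfs:label` in the file, so its IRI fragment is used and the record is
flagged. Sentence 4 is technically faithful to its ontology (Saturday *is*
modeled under "week day") — exactly the kind of domain-fidelity problem the
rating protocol is designed to surface.

Simulated ratings stand in for experts when exercising the harness:

```r
rt <- simulate_ratings(rec, n_raters = 2, disagreement_rate = 0.1, seed = 42)
summarize_ratings(rt)
#> <owl_eval_summary> 4 items, 2 raters
#>   clarity          1.75 (0.50)
#>   nl fidelity      100% yes
#>   domain fidelity  1.00 (0.00)
#>   agreement        100% / 100% / 100% (clarity / nl / domain)
#>   spearman rho     undefined (constant scores)
```

Note the explicit "undefined" — with a constant score vector the rank
correlation does not exist, and the harness says so rather than reporting 0.

## Command line

```sh
Rscript inst/cli/verbowl.R verbalize ontology.ttl --style explicit -o out.csv
Rscript inst/cli/verbowl.R make-sheet ontology.ttl --raters 2 -o sheet.csv
Rscript inst/cli/verbowl.R evaluate ratings.csv --sheet sheet.csv -o summary.csv
Rscript inst/cli/verbowl.R fixtures generate -d fixtures/
```

(after installation, the script lives at `system.file("cli", "verbowl.R",
package = "verbowl")`).

## Scope

The verbalizer covers the 14 axiom types listed by `owl_supported_types()`;
other axiom types are counted and skipped at load, and class-expression
constructors outside the supported inventory (cardinalities, `oneOf`,
`hasSelf`) fall back to inlined Manchester text with a `generic_fallback`
flag. Imports are not fetched from the network; `follow_imports = TRUE`
merges local files only. Reasoning, SPARQL, and writing OWL back out are
out of scope.
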