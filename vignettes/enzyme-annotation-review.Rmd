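---
title: "Methods: evidence-based review of enzyme annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence-based review of enzyme annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzcurate)
```

## The model

An enzyme class (say, ligases, EC 6.-.-.-) is anchored on an ontology
term; its candidate genes are everything any annotation source associates
with that term *or any of its descendants*. The package treats a review
of such a class as five coupled computations:

1. **Closure queries.** The ontology is a DAG of `is_a` edges (with
   optional `part_of`). `descendant_closure()` computes child-ward
   reachability; `hits_from_go()` returns the genes with at least one
   non-negated annotation inside the closure. A gene annotated only with
   a `NOT` qualifier is evidence *against* membership and is excluded; a
   gene with both positive and negated statements is included (it has
   positive support) but flagged downstream as conflicted.

2. **EC matching.** EC numbers are four-level codes; the class level is
   always concrete (1–7) and wildcards are suffix-only: `6.3.-.-` is
   legal, `6.-.3.-` is not. A query matches a concrete code iff all of
   its concrete levels agree (`ec_matches()`), which is exactly
   string-prefix comparison on the dotted form — one of the invariants
   the test suite checks by exhaustive enumeration.

3. **Orthology transfer.** Calls from well-characterised human enzymes
   carry an integer support score (the number of independent orthology
   algorithms agreeing). Calls with score ≤ 2 are discarded outright;
   calls with score ≥ 5 and the relevant enzymatic domain present are
   retained automatically; everything between goes to a manual-review
   list that the pipeline surfaces but never auto-admits. An explicit
   `admit` argument reproduces curator decisions on reviewed borderline
   cases.

4. **Confidence triage.** Evidence codes group into four classes:
   experimental (IDA/IMP/IGI), computational (ISS and its children,
   IBA), author statement (TAS/NAS) and electronic (IEA). Per gene:
   *high* needs ≥2 positive experimental annotations, or exactly one
   plus ≥1 computational/electronic supporter; *medium* needs zero
   experimental but ≥2 *independent* computational/electronic
   annotations; anything else with positive support is *low*; no
   positive support is *none*. A detected conflict always demotes to
   low. Rules are evaluated high → medium → low, first match wins.

5. **Evaluation.** Hit sets are scored against the verified gold set:
   P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R). Release-diff ledgers
   compare two snapshots of a class and satisfy
   `after = before + added − removed` by construction.

## Design choices where the procedure was genuinely open

**Independence of annotations (medium tier).** "Multiple independent
annotations" is interpreted as: two annotations are independent iff they
differ in evidence code *or* in assigning source/pipeline. Two IEA lines
produced by the same mapping pipeline are one piece of evidence; an IBA
from phylogenetic inference plus an IEA from a protein-signature mapping
are two. This is configurable in spirit but deliberately not a tuning
knob: it is the weakest reading that still blocks a single pipeline from
manufacturing medium-confidence genes by emitting duplicates.

**Deduplication before counting.** The same annotation (same term,
evidence code, source and reference) frequently reaches the reviewer
through two databases — an authoritative database's line re-exported by
an aggregator. `assess_gene()` deduplicates on that tuple before
counting, otherwise every re-export would inflate the evidence count and
a single assay could satisfy the "multiple experimental" rule.

**"Multiple" means ≥ 2.** The plain reading; nothing in the tier
definitions needs a larger threshold.

**Author statements never reach high or medium.** A gene supported by
any number of TAS/NAS lines stays low: author statements are the
weakest stratum in the evidence breakdown, and unrecognised evidence
codes are given the same weight (flagged `unknown`) so novel codes can
never silently promote a gene.

**Relation traversal defaults to `is_a` only.** Molecular-function
hierarchies are dominated by `is_a`; `part_of` traversal is an opt-in
flag on `descendant_closure()`. Obsolete terms are likewise excluded
from closures by default, with an `include_obsolete` flag for
asynchrony experiments where a source still uses a retired term.

**Conflict lineage check.** Positive-vs-`NOT` conflicts are flagged on
the same term and on ancestor/descendant pairs (a `NOT` on the parent
contradicts a positive on the child). A second, stricter predicate —
positives mapping to EC numbers in different sub-subclasses — ships
disabled (`cross_activity = FALSE`) because it needs EC cross-references
in the loaded ontology and is a heuristic, not a definition.

**Category order in reconciliation.** Candidates surfaced by EC or
orthology searches are categorised verified-first, then discarded, then
novel; a gene in both the verified and discarded sets is an integrity
error, never silently resolved.

## Rounding and degenerate inputs

Reported metrics are rounded **half-up to two decimals** at the
reporting boundary only; F1 is always computed from the unrounded
precision and recall. The distinction is visible: counts 104/12/17 give
P = 0.8966, R = 0.8595, F1 = 0.8776, which displays as 0.90/0.86/0.88 —
whereas harmonically combining the *displayed* 0.90 and 0.86 would
suggest 0.87. Metrics with an empty denominator are reported as
undefined (`NA`, flagged), never coerced to 0 or 1.

Ledger annotation deltas use the identity tuple (gene, term, evidence
code, source) and deliberately ignore dates, so a re-dated but otherwise
identical annotation does not count as a change.

Term identifiers are opaque strings — no `GO:nnnnnnn` shape is assumed —
so toy ontologies are first-class inputs. OBO parsing covers the subset
annotation pipelines actually use (`[Term]` stanzas; `id`, `name`,
`is_a`, `relationship: part_of`, `xref`, `is_obsolete`); EC
cross-references are read from `xref: EC:` lines and other prefixes are
ignored. Cyclic `is_a` input is rejected with the cycle named.

## The synthetic-data generator

Real multi-database annotation snapshots cannot be redistributed or
re-queried reproducibly, so the generator (`generate_bundle()`) emits
complete offline bundles: an ontology with ≥3 hierarchy levels and EC
cross-references per class, one GAF per simulated GO source, EC and
orthology tables, an accession→gene map, a gold list and a `truth.json`
bookkeeping file. Every member gene carries an evidence profile chosen
to realise its planted confidence tier, and every planted false positive
or negative is drawn by a named error mode:

| mode | mechanism | consequence |
|------|-----------|-------------|
| `erroneous_manual` | FP annotation to a non-member | FP in that source |
| `bad_keyword_mapping` | electronic (IEA) FP via keyword pipeline | FP |
| `stale_release` | source shows the previous snapshot | FN |
| `dropped_relation` | one `is_a` edge missing from the source's ontology view | FN for genes only reachable through it |
| `uncurated_literature` | support exists only in unreviewed papers | FN in every GO/EC source (orthology unaffected) |
| `no_ortholog` | member lacks a clear human ortholog | orthology FN |
| `missing_ec_xref` | term lacks an EC cross-reference in the provider's pipeline | EC-source FN |

Rates are per-gene Bernoulli draws except the two structural modes:
`dropped_relation` is the probability that the source's view lost one
randomly chosen mid-level edge (the affected view is also written out as
`ontology_<source>.obo`), and `missing_ec_xref` is per-term. Each
(source, mode) pair draws from its own deterministically derived
sub-seed, so adding one error mode never perturbs another's draws and
identical (config, seed) pairs yield byte-identical bundles.

Default conditions: 200 genes, two enzyme classes (60 and 40 true
members), tier mix 0.24/0.36/0.40 high/medium/low — the split observed
in a comprehensive manual review of a ligase class — and error rates of
3–10% per mode, chosen so that per-source precision and recall land in
the 0.70–0.95 band typical of real cross-database enzyme queries.
These defaults are the study conditions of the package's validation
suite, not tuning parameters.

The planted tier of a member that ends up absent from every GO source
(for example, drawn as uncurated literature) is recorded as `none`: the
bookkeeping describes what the emitted data can support, and the
parameter-recovery tests demand exact agreement.

`ligase_study_fixture()` is the deterministic special case: a
five-database benchmark whose planted per-source confusion counts
(94/18/27, 101/37/20, 82/13/39, 89/17/32, 104/12/17 against a 121-gene
gold set, plus a ten-gene literature-only source) reproduce the full
arithmetic of a published-scale review — 141 candidates from the four
database searches of which 40 (28%) are false, 121 + 46 true/false
members in the overall union, a 24/36/41 confidence split of the 101
GO-identified true positives, and a gene-group hierarchy where four
dual-activity genes bring six subgroups to 125 memberships over 121
unique genes. The fixture plants *counts and structure*, not real gene
identifiers: ids are synthetic (`LIG0001`, `FPG0001`) precisely so no
biological claim is implied.

### What the generator does and does not emulate

It emulates the statistical structure of multi-source disagreement:
evidence-profile heterogeneity, source-specific error modes, negated
annotations, accession-keyed sources needing ID resolution, and
ontology-view divergence. It does **not** emulate real release
calendars, annotation-extension semantics, taxon constraints,
inter-ontology links, or the long-tailed literature-curation process —
so a green validation suite shows the pipeline arithmetic is correct
under realistic error structure, not that any particular real database
has these error rates.

## Problem sizes and numerical tolerances in the validation suite

Property suites run on random DAGs of up to 50 terms against a
brute-force boolean-matrix reachability oracle; Venn region counts are
rechecked against per-gene signature tallies; tier recovery, confusion
bookkeeping and byte-identical regeneration are checked across 100
randomly configured bundles of 30–60 genes; the binomial scaling of
planted false positives is tested at 1200 genes within 3σ. All
count-valued checks are exact; displayed metrics are compared at their
two-decimal reporting precision.

## Known limitations

* OBO coverage is the annotation subset, not full OBO 1.4 semantics
  (no intersections, disjointness axioms or imports); reasoning is
  transitive closure only.
* `venn_counts()` enumerates regions for at most six sources; larger
  collections fall back to the membership matrix.
* The manual side of real curation — literature reading, BLAST rescue of
  unmapped accessions, judging borderline orthology — is represented
  only by its interfaces (review lists, quarantines, `admit` overrides),
  not simulated.
* Confidence tiers are ordinal labels, not calibrated probabilities; no
  uncertainty is attached to precision/recall estimates.
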