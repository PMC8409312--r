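---
title: "Detecting domain translocations, indels and duplications across orthologous proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting domain translocations, indels and duplications across orthologous proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domarch)
library(dplyr)
```

## The model

`domarch` treats a protein not as a sequence but as the set of Pfam
domains it contains, and treats a KEGG Orthology (KO) group as the unit
of orthology: all proteins sharing a KO number are considered orthologs.
Under this view, protein evolution is the "mix and merge" of domains,
and three kinds of events can be read off the comparative pattern of
domain presence/absence across the organisms of a KO:

* **Mobile domains.** Within one KO, let $A$ be the organisms whose
  proteins contain domain $d$, $B$ the organisms whose proteins lack it,
  and $T = A \cup B$ (with $A \cap B = \emptyset$). The domain is
  *mobile* iff $4 \le |A| < |T| - 4$; both the containing and the
  lacking group must be reasonably populated before the variation is
  treated as signal.
* **Translocations.** If $d$ is mobile in two KOs $k_1 < k_2$, the
  reciprocal groups are $A^{*} = A_1 \cap B_2$ (organisms that carry $d$
  in $k_1$ but not in $k_2$) and $B^{*} = A_2 \cap B_1$. The domain has
  undergone a *reciprocal translocation* between the two ortholog groups
  iff $|A^{*}| \ge 4$ and $|B^{*}| \ge 4$. One event is recorded per
  (domain, KO pair); a domain mobile in many KOs can therefore
  participate in many events.
* **Indels.** Translocation and indel are mutually exclusive: every
  mobile (domain, KO) record whose domain takes part in no translocation
  anywhere becomes one insertion/deletion event.
* **Duplications.** Copy numbers (of *putative* domains, see below) are
  compared within each KO: a domain is `nonduplicated` in a KO iff every
  member protein containing it has the same copy count, `duplicated`
  otherwise. Per-KO statuses are then aggregated over all KOs
  (see *Duplication aggregation* below).

Organism groups are classified by superdomain taxonomy — `Eukaryota`,
`Bacteria` or `Viruses` when all members agree, `Mixed` otherwise — and
events carry a composite `X-Y` label (the $A$/$A^{*}$ side first).

### From raw hits to domain content

Raw Pfam hits on one protein routinely overlap or are nested, which is
inconsistent with the linear structure of the protein. Two filters
produce the content sets the model works on:

1. **Putative domains**: hits are visited in decreasing bit score and
   accepted iff their envelope interval (1-based, closed) shares no
   residue with an already-accepted hit. This implements
   "highest-scoring hit per overlap conflict" as a deterministic greedy
   scan; nested hits count as overlapping.
2. **Unique putative domains**: among multiple surviving copies of the
   same domain name, the single highest-scoring copy represents the
   name. Presence/absence analyses (items, mobility, translocation,
   indel) use these sets; duplication analysis deliberately keeps the
   putative copies.

The full tie-break chain everywhere a "best hit" is chosen is: bit
score (descending), E-value (ascending), envelope start (ascending),
domain name (ascending). This makes outputs bit-stable under input
reordering.

### Architecture items

Each KO is partitioned into *items*: maximal groups of member proteins
with identical unique-putative domain sets. An item carries matched
organism and refseq lists (entry $i$ of one corresponds to entry $i$ of
the other); an organism listed twice contributes paralogous proteins.
For item $i$, `missing` is every domain present in some other item but
not in $i$, and `gained` is every domain of $i$ absent from at least one
other item. Both are purely comparative: with no outgroup or ancestral
reconstruction the polarity of a gain versus a loss is undefined, so the
two patterns are mirror images across the KO (a domain appears in some
item's `gained` iff it appears in another's `missing`). A KO with a
single item shows no variation and yields no events.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_group_size` | 4 organisms | lower bound on \|A\|, and on \|A*\| and \|B*\|; the mobility upper bound is \|T\| − `min_group_size` |
| `duplication_percentile` | 0.99 | percentile of the \|diff\| distribution a domain must reach for a global duplication call |
| `duplication_rule` | `"empirical"` | aggregation rule; `"cumsum-rank"` is the alternative reading (below) |
| `ambiguity_policy` | `"exclude"` | treatment of organisms with both containing and lacking paralogs |

The 4-organism cutoffs are modelling choices, not derived constants,
which is why they are exposed in `run_config()`; the defaults are the
model's published values, and all results in this package's tests are
computed at the defaults.

### Paralog-ambiguous organisms

The definitions of $A$ ("some protein contains $d$") and $B$ ("some
protein lacks $d$") are not disjoint when an organism carries both a
containing and a lacking paralog in the same KO, yet the model assumes
$A \cap B = \emptyset$. The package resolves this by placing such
organisms in an `excluded` set that counts toward neither $A$, $B$ nor
$T$ — this preserves the stated disjointness without biasing either
side. The alternatives (`to_A`, `to_B`) are available behind
`ambiguity_policy` for sensitivity analysis.

### Duplication aggregation

For each domain let `diff` be the number of KOs where it is
`duplicated` minus the number where it is `nonduplicated`. The published
description — a call when the difference is "significant, above the 99%
percentile of the cumulative sum of the differences" — admits two
readings, and the package implements both:

* `"empirical"` (default): a two-sided empirical-percentile test; the
  domain is globally `duplicated` when `diff > 0` and `|diff|` reaches
  the 99th percentile (inverse-ECDF quantile, type 1) of `|diff|` over
  all domains, `nonduplicated` symmetrically for `diff < 0`, and
  `undetermined` otherwise.
* `"cumsum-rank"`: domains are ranked by `|diff|` and those above the
  point where the cumulative `|diff|` mass passes 99% of the total are
  called.

Per-KO copy-number constancy is evaluated only over proteins that
contain the domain (copy $\ge 1$): including zero-copy proteins would
make every mobile domain trivially "duplicated".

## Numerical and determinism choices

* Overlap resolution is greedy per conflict, not exact weighted interval
  scheduling; the defining rule is "the highest-scoring domain of each
  overlapping group is chosen", which the score-descending greedy scan
  realises deterministically whether conflicts come as pairs or as
  connected groups.
* The score is the hit's bit score (the search tool's primary ranking
  statistic), not a transform of the E-value.
* Envelope coordinates are 1-based inclusive; "overlap" means the
  closed intervals share at least one residue.
* All character sorting uses C-collation (radix) order so that outputs
  are byte-identical across locales and platforms.
* KO pairs are oriented by the numeric part of the KO id
  (`K10637` before `K16822`); $A^{*}$ is defined from the numerically
  smaller KO's containing side. Swapping input labels permutes the two
  groups but never changes which events exist.
* Isoform ties (equal `length_aa` within a gene) break to the
  lexicographically smallest refseq accession; the tie rule is arbitrary
  but fixed.
* Empty domain sets, KOs with a single item, unknown KO queries and
  empty event tables are all legal inputs that produce empty outputs,
  not errors; genuinely malformed inputs (negative coordinates,
  non-numeric scores, unknown superdomains, broken referential
  integrity) raise classed errors naming the offending row or key.

## Architecture-set semantics

A domain architecture is modelled as the *unordered set* of
unique-putative domain names, not the N-to-C ordered sequence. Every
downstream definition tests only membership ($d \in p$), and the
unique-putative filter already collapses copies, so order adds no
information to the event calls; ordered-architecture comparisons are
explicitly out of scope. This is a deliberate semantic choice, recorded
here because an ordered reading would split some items into finer
classes without changing any mobility or translocation call.

## The synthetic cohort generator

Real inputs for this model are produced by genome-scale annotation runs
(Pfam searches and KO assignment over complete proteomes). To keep every
stage testable without downloads, `generate_cohort()` fabricates all
four input dialects from a `fixture_spec()` with *planted* events, and
emits a manifest stating exactly what a correct detector must find:

* a planted translocation `(d, k1, k2, |A*|, |B*|)` places disjoint
  reciprocal organism groups; shared-present organisms (domain in both
  KOs) pad each KO so the domain stays mobile even when a reciprocal
  group is deliberately undersized, and background organisms keep the
  lacking side above the mobility bound. Undersized groups
  (e.g. $|A^{*}| = 3$) must therefore yield exactly two indel records
  and no translocation.
* planted indels and duplications (constant vs varying copy numbers)
  work the same way within a single KO.
* decoy content exercises the ingest filters: overlapping low-score
  hits (removed by putative resolution), duplicate base-domain copies
  (collapsed by the unique-putative filter), shorter isoforms (removed
  by longest-isoform selection) and a protein with two significant KO
  assignments (dropped by the unique-KO rule).
* output is byte-deterministic under the `fixture_spec()` seed.

The generator emulates the *combinatorial structure* of real data —
presence/absence patterns, paralogy, isoforms, ambiguous organisms — but
not its biology: there are no real sequences, hit scores are arbitrary
constants, clan assignments are synthetic, and organism codes are
fabricated (except in the worked-example fixture, which uses the eleven
published organism codes). Passing tests therefore demonstrate that the
set algebra, filtering and thresholds are implemented correctly, not
that the biological conclusions drawn from any real corpus would be
recovered.

`ferm_c_fixture()` reconstructs the published worked example: the
FERM_C domain present in the FRMD6-like group (K16822) for CAA, CHL,
ECTE, ccar and lav and in the MYLIP-like group (K10637) for CHA, MIO,
PEM, cge, ola and rno. The per-organism protein counts in that fixture
are synthetic; only the group memberships, the single-event outcome and
the Eukaryota-Eukaryota class are asserted.

```{r ferm}
events <- run_pipeline(cohort_db(ferm_c_fixture()))
events
tidy(events)
```

## Verification strategy and problem sizes

The test suite validates the detectors against an independent
brute-force implementation of the inequalities (plain loops over every
(domain, organism) and (domain, KO-pair) combination), on 500 random
fixtures of up to 15 organisms × 6 KOs × 8 domains — sizes chosen to
cover every boundary case of the inequalities many times over while the
whole suite stays comfortably quick on a laptop. Planted-event recovery
runs the full file-to-events pipeline across 100 seeded cohorts and
requires sensitivity 1.0 with zero false calls at noiseless settings.
Structural invariants (non-overlap of putative hits, matched-list
alignment, $A \cap B = \emptyset$, translocation/indel exclusivity,
referential integrity, TSV and SQLite round-trip identity) are asserted
on every fixture.

## Known limitations

* Events are not dated or polarized on a phylogeny; "gained" and
  "missing" are comparative, not ancestral-state, statements.
* Corpus-scale results require corpus-scale inputs; the package parses
  the standard annotation dialects but does not download proteomes or
  run the annotators.
* Clan-competition filtering (overlap resolution *between* members of
  one clan as done by the Pfam website) is not re-implemented; reported
  hits are taken at face value.
* A KO with heavy paralog ambiguity can see most organisms excluded,
  silently shrinking $T$; the `excluded` column of the mobile-domain
  table makes this visible.
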