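# domarch

Domain-architecture evolution of orthologous proteins.

`domarch` is an R toolkit for studying protein evolution as the "mix and
merge" of protein domains. A protein is represented by its Pfam domain
content; proteins sharing a KEGG Orthology (KO) number form an
orthologous group; and each KO is partitioned into *architecture items* —
distinct domain-content sets with matched organism/protein lists. From
the comparative presence/absence patterns the package calls:

- **mobile domains** — a domain $d$ splits a KO's organisms into $A$
  (containing) and $B$ (lacking), $T = A \cup B$, and is mobile iff
  $4 \le |A| < |T| - 4$;
- **reciprocal translocations** — $d$ mobile in KOs $k_1 < k_2$ with
  $A^{*} = A_1 \cap B_2$, $B^{*} = A_2 \cap B_1$, called iff
  $|A^{*}| \ge 4$ and $|B^{*}| \ge 4$, one event per (domain, KO pair);
- **indel events** — mobile domains with no translocation anywhere
  (the two calls are mutually exclusive);
- **duplications** — per-KO copy-number constancy of putative domains,
  aggregated over KOs by an empirical-percentile rule on
  diff = #KOs duplicated − #KOs nonduplicated.

Events are classified by superdomain taxonomy (Eukaryota / Bacteria /
Viruses, or Mixed when a group disagrees) and summarized per Pfam clan
(super-family). The package is aimed at comparative genomicists who
already have per-proteome annotation output — `pfam_scan.pl` hit tables
and KoFamKOALA detail TSVs — and want the event calls, not the
annotators themselves.

## Worked example

The package ships a self-contained reconstruction of a reciprocal
FERM_C translocation between two ortholog groups (FRMD6-like, K16822,
and MYLIP-like, K10637) across eleven vertebrate and fish genomes:

```r
library(domarch)

events <- run_pipeline(cohort_db(ferm_c_fixture()))
events
#> <domarch_events>
#>   KOs partitioned:       2 (4 items)
#>   mobile domain records: 2 (1 distinct domains)
#>   translocation events:  1 (1 domains)
#>   indel events:          0 (0 domains)
#>   duplicated domains:    0 (global calls)

tidy(events)
#> # A tibble: 1 x 6
#>   domain_name ko1    ko2    A_star                  B_star                class_label
#>   <chr>       <chr>  <chr>  <chr>                   <chr>                 <chr>
#> 1 FERM_C      K10637 K16822 CHA,MIO,PEM,cge,ola,rno CAA,CHL,ECTE,ccar,lav Eukaryota-Eukaryota
```

Read this as: FERM_C is mobile in both KOs; six organisms (CHA, MIO,
PEM, cge, ola, rno) carry it in the MYLIP-like group but not the
FRMD6-like group, five (CAA, CHL, ECTE, ccar, lav) show the reverse
pattern; both reciprocal groups reach the 4-organism threshold, so a
single translocation event is called, classed Eukaryota-Eukaryota, and
FERM_C consequently contributes no indel events.

Typical real-data use replaces the fixture with your own files:

```r
registry <- read_organism_registry("registry.tsv")
proteins <- read_protein_table("proteins.tsv")
hits     <- read_pfam_hits("pfam_scan_output.txt")
ko_map   <- select_unique_ko(read_koala_assignments("kofamkoala.tsv"))

db <- build_db(registry, proteins, hits, ko_map)
db_write_sqlite(db, "store.sqlite")     # single-file relational store

events <- run_pipeline(db, run_config(min_group_size = 4))
glance(events)                          # one-row count summary
tidy(events, "indels")                  # flat event tables
autoplot(events)                        # per-superfamily counts
write_event_tables(events, "out/")      # supplementary-style TSVs
```

A command-line wrapper with `build`, `detect`, `summarize` and
`simulate` subcommands is installed at
`system.file("cli", "domarch.R", package = "domarch")`.

Synthetic cohorts with planted events (for benchmarking or CI) come
from `generate_cohort(fixture_spec(...))`; see the vignette
`vignettes/domain-architecture-evolution.Rmd` for the model's
assumptions, parameter meanings and the generator's design.

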