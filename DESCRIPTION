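Package: domarch
Title: Domain-Architecture Evolution of Orthologous Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents proteins as their Pfam domain content, groups them
    into KEGG-ortholog (KO) groups, partitions each KO into distinct domain
    architectures, and calls evolutionary events on domains: mobile domains,
    reciprocal translocations between KO pairs, indel events, and
    duplications, with superdomain-level (Eukaryota/Bacteria/Viruses)
    classification and per-superfamily summaries. Includes parsers for
    pfam_scan and KoFamKOALA output dialects, a six-relation embedded
    datastore with SQLite and TSV round-trips, and a deterministic synthetic
    cohort generator with planted events for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    DBI,
    RSQLite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
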