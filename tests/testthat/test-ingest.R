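write_registry_file <- function(rows, path = withr::local_tempfile(
                                  fileext = ".tsv", .local_envir = parent.frame())) {
  writeLines(c("org_id\tname\tsuperdomain\ttaxonomy_id\tsource_tags", rows),
             path)
  path
}

test_that("organism registry parses valid rows and rejects bad ones", {
  path <- write_registry_file(c(
    "hsa\tHomo sapiens\tEukaryota\t9606\tbiogrid",
    "eco\tEscherichia coli\tBacteria\t511145\tpathogen",
    "ECTE\tEchinops telfairi\tEukaryota\t9371\t"))
  reg <- read_organism_registry(path)
  expect_equal(nrow(reg), 3)
  expect_equal(reg$superdomain[reg$org_id == "hsa"], "Eukaryota")
  expect_type(reg$taxonomy_id, "integer")

  empty <- read_organism_registry(write_registry_file(character(0)))
  expect_equal(nrow(empty), 0)

  expect_error(
    read_organism_registry(write_registry_file("arc\tx\tArchaea\t1\t")),
    class = "domarch_format_error")
  expect_error(
    read_organism_registry(write_registry_file(
      c("hsa\ta\tEukaryota\t1\t", "hsa\tb\tEukaryota\t2\t"))),
    class = "domarch_uniqueness_error")
  expect_error(
    read_organism_registry(write_registry_file("toolong\tx\tViruses\t1\t")),
    class = "domarch_format_error")
})

test_that("organism registry round-trips byte-identically", {
  path <- write_registry_file(c(
    "hsa\tHomo sapiens\tEukaryota\t9606\tbiogrid",
    "MIO\tMicrotus ochrogaster\tEukaryota\t79684\thic"))
  reg <- read_organism_registry(path)
  out1 <- withr::local_tempfile(fileext = ".tsv")
  out2 <- withr::local_tempfile(fileext = ".tsv")
  write_organism_registry(reg, out1)
  write_organism_registry(read_organism_registry(out1), out2)
  expect_identical(readLines(out1), readLines(out2))
})

test_that("KoFamKOALA detail rows parse with significance and comments", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# gene name\tKO\tthrshld\tscore\tE-value\tKO definition",
    "*\tXP_1\tK16822\t50.2\t123.4\t1e-30\tFRMD6",
    "\tXP_2\tK00001\t80\t40.1\t0.5\tweak hit"), path)
  asg <- read_koala_assignments(path)
  expect_equal(nrow(asg), 2)
  expect_true(asg$significant[asg$refseq_id == "XP_1"])
  expect_false(asg$significant[asg$refseq_id == "XP_2"])
  expect_equal(asg$ko_number[1], "K16822")
  expect_equal(asg$e_value[1], 1e-30)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("*\tXP_1\tK16822\t50.2\tnot_a_number\t1e-30\tx", bad)
  expect_error(read_koala_assignments(bad), "line 1",
               class = "domarch_format_error")
})

test_that("KO assignments round-trip through the writer", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("*\tXP_1\tK16822\t50.2\t123.4\t1e-30\tFRMD6",
               "\tXP_2\tK00001\t80\t40.1\t0.5\tweak"), path)
  asg <- read_koala_assignments(path)
  out1 <- withr::local_tempfile(); out2 <- withr::local_tempfile()
  write_koala_assignments(asg, out1)
  write_koala_assignments(read_koala_assignments(out1), out2)
  expect_identical(readLines(out1), readLines(out2))
  expect_equal(read_koala_assignments(out1), asg)
})

test_that("unique-KO selection keeps exactly single-KO significant proteins", {
  asg <- tibble::tibble(
    refseq_id = c("p1", "p2", "p2"),
    ko_number = c("K00001", "K00001", "K00002"),
    threshold = 50, score = 100, e_value = 1e-20,
    significant = TRUE, definition = "")
  map <- select_unique_ko(asg)
  expect_equal(map$refseq_id, "p1")
  expect_equal(map$ko_number, "K00001")
  expect_equal(attr(map, "report")$n_ambiguous, 1)

  not_sig <- dplyr::mutate(asg[1, ], significant = FALSE)
  expect_equal(nrow(select_unique_ko(not_sig)), 0)

  dup_rows <- tibble::tibble(refseq_id = "p1", ko_number = "K00003",
                             threshold = 50, score = c(90, 95),
                             e_value = 1e-10, significant = TRUE,
                             definition = "")
  expect_equal(select_unique_ko(dup_rows)$ko_number, "K00003")
})

test_that("unique-KO selection matches a subset-enumeration oracle", {
  rows <- tibble::tibble(
    refseq_id = c("p1", "p1", "p1", "p2"),
    ko_number = c("K00001", "K00001", "K00002", "K00001"),
    threshold = 50, score = 100, e_value = 1e-20,
    significant = c(TRUE, TRUE, FALSE, TRUE), definition = "")
  for (mask in 0:15) {
    sel <- rows[bitwAnd(mask, 2^(0:3)) > 0, ]
    got <- select_unique_ko(sel)
    # oracle: count distinct significant KOs per protein directly
    expected <- list()
    for (p in unique(sel$refseq_id)) {
      kos <- unique(sel$ko_number[sel$refseq_id == p & sel$significant])
      if (length(kos) == 1) expected[[p]] <- kos
    }
    expect_setequal(got$refseq_id,
                    if (length(expected)) names(expected) else character(0))
    for (p in got$refseq_id) {
      expect_equal(got$ko_number[got$refseq_id == p], expected[[p]])
    }
  }
})

test_that("unique-KO selection is idempotent and order-independent", {
  set.seed(42)
  asg <- tibble::tibble(
    refseq_id = sample(paste0("p", 1:6), 20, replace = TRUE),
    ko_number = sample(sprintf("K%05d", 1:4), 20, replace = TRUE),
    threshold = 50, score = 100, e_value = 1e-20,
    significant = sample(c(TRUE, FALSE), 20, replace = TRUE),
    definition = "")
  base <- select_unique_ko(asg)
  for (i in 1:5) {
    perm <- asg[sample.int(nrow(asg)), ]
    expect_equal(as.data.frame(select_unique_ko(perm)), as.data.frame(base))
  }
  again <- select_unique_ko(
    dplyr::mutate(base, threshold = 0, score = 1, e_value = 0,
                  significant = TRUE, definition = ""))
  expect_equal(again$refseq_id, base$refseq_id)
})

make_protein <- function(refseq, len, group = "g1", org = "hsa") {
  tibble::tibble(refseq_id = refseq, gene_symbol = group, org_id = org,
                 length_aa = as.integer(len), chromosome = "chr1",
                 strand = "+", isoform_group = group, description = "")
}

test_that("longest-isoform selection picks maximal length with lexical tie-break", {
  recs <- dplyr::bind_rows(make_protein("XP_a", 300), make_protein("XP_b", 450))
  expect_equal(select_longest_isoform(recs)$refseq_id, "XP_b")

  tie <- dplyr::bind_rows(make_protein("XP_b", 300), make_protein("XP_a", 300))
  expect_equal(select_longest_isoform(tie)$refseq_id, "XP_a")
})

test_that("one isoform survives per group, the group maximum", {
  set.seed(7)
  groups <- list(g1 = 1, g2 = 2, g3 = 5)
  recs <- purrr::imap(groups, function(n, g) {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      make_protein(sprintf("XP_%s_%d", g, i), sample(100:900, 1), group = g)
    }))
  }) |> dplyr::bind_rows()
  sel <- select_longest_isoform(recs)
  expect_equal(nrow(sel), 3)
  expect_true(all(sel$is_longest))
  # brute-force max per group
  for (g in names(groups)) {
    sub <- recs[recs$isoform_group == g, ]
    expect_equal(sel$length_aa[sel$isoform_group == g], max(sub$length_aa))
  }
  # conservation for arbitrary random tables
  for (seed in 1:5) {
    set.seed(seed)
    r <- dplyr::bind_rows(lapply(1:20, function(i) {
      make_protein(paste0("XP_", i), sample(50:500, 1),
                   group = sample(paste0("g", 1:7), 1))
    }))
    expect_equal(nrow(select_longest_isoform(r)),
                 dplyr::n_distinct(r$isoform_group))
  }
})

test_that("protein table validates lengths, strand, and FASTA agreement", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::bind_rows(make_protein("XP_1", 120),
                                    make_protein("XP_2", 80, group = "g2")),
                   path)
  tab <- read_protein_table(path)
  expect_equal(tab$length_aa, c(120L, 80L))

  fasta <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">XP_1", strrep("M", 120), ">XP_2", strrep("A", 80)), fasta)
  expect_silent(read_protein_table(path, fasta = fasta))
  writeLines(c(">XP_1", strrep("M", 119)), fasta)
  expect_error(read_protein_table(path, fasta = fasta),
               class = "domarch_format_error")

  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::mutate(make_protein("XP_1", 120), strand = "?"), bad)
  expect_error(read_protein_table(bad), class = "domarch_format_error")
})
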