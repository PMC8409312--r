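#' Read an organism registry
#'
#' The registry is a UTF-8 TSV with header columns `org_id`, `name`,
#' `superdomain`, `taxonomy_id` and optionally `source_tags` (free-text
#' labels, carried as opaque metadata). Organism ids are 3–4 letter codes;
#' lowercase codes conventionally denote KEGG organism identifiers, and
#' comparisons are case-sensitive. `superdomain` must be one of
#' `Eukaryota`, `Bacteria`, `Viruses`.
#'
#' @param path Path to the registry TSV.
#' @return A tibble with columns `org_id`, `name`, `superdomain`,
#'   `taxonomy_id` (integer), `source_tags`.
#' @export
read_organism_registry <- function(path) {
  tab <- read_tsv_quiet(path)
  required <- c("org_id", "name", "superdomain", "taxonomy_id")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop_format("organism registry %s lacks column(s): %s", path,
                paste(missing, collapse = ", "))
  }
  if (!"source_tags" %in% names(tab)) tab$source_tags <- ""
  if (nrow(tab) == 0) {
    return(tibble(org_id = character(), name = character(),
                  superdomain = character(), taxonomy_id = integer(),
                  source_tags = character()))
  }
  bad_sd <- which(!tab$superdomain %in% SUPERDOMAINS)
  if (length(bad_sd) > 0) {
    stop_format("row %d: unknown superdomain '%s' (expected %s)",
                bad_sd[1], tab$superdomain[bad_sd[1]],
                paste(SUPERDOMAINS, collapse = "/"))
  }
  bad_id <- which(!is_valid_org_id(tab$org_id))
  if (length(bad_id) > 0) {
    stop_format("row %d: org_id '%s' is not a 3-4 letter code",
                bad_id[1], tab$org_id[bad_id[1]])
  }
  dup <- tab$org_id[duplicated(tab$org_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate org_id in registry: %s",
                  paste(unique(dup), collapse = ", ")),
          class = "domarch_uniqueness_error")
  }
  tibble(org_id = tab$org_id, name = tab$name,
         superdomain = tab$superdomain,
         taxonomy_id = as.integer(tab$taxonomy_id),
         source_tags = tab$source_tags)
}

#' Write an organism registry TSV
#'
#' Inverse of [read_organism_registry()]; canonical field formatting so that
#' a read/write cycle round-trips byte-identically.
#'
#' @param registry Registry tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_organism_registry <- function(registry, path) {
  write_tsv_plain(registry, path)
}

#' Read KO assignments in KoFamKOALA detail-TSV format
#'
#' Parses the `--format detail-tsv` dialect: tab-separated columns
#' significance (`*` or blank), gene name, KO number, adaptive score
#' threshold, bit score, E-value, KO definition. Lines starting with `#`
#' are comments. A row is significant when its first column is `*`
#' (the tool marks scores at or above the family's adaptive threshold).
#'
#' @param path Path to the detail TSV.
#' @return A tibble with columns `refseq_id`, `ko_number`, `threshold`,
#'   `score`, `e_value`, `significant`, `definition`.
#' @export
read_koala_assignments <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  idx <- which(keep)
  out <- tibble(refseq_id = character(), ko_number = character(),
                threshold = double(), score = double(), e_value = double(),
                significant = logical(), definition = character())
  if (length(idx) == 0) return(out)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 6)) {
    bad <- idx[which(n_fields < 6)[1]]
    stop_format("line %d: expected >= 6 tab-separated fields, got %d",
                bad, n_fields[which(n_fields < 6)[1]])
  }
  get <- function(i) map_chr(fields, ~ .x[[i]])
  num <- function(i, what) {
    raw <- get(i)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw))
    if (length(bad) > 0) {
      stop_format("line %d: non-numeric %s '%s'", idx[bad[1]], what,
                  raw[bad[1]])
    }
    val
  }
  defn <- map_chr(fields, function(f) {
    if (length(f) >= 7) paste(f[7:length(f)], collapse = "\t") else ""
  })
  tibble(
    refseq_id = get(2),
    ko_number = get(3),
    threshold = num(4, "threshold"),
    score = num(5, "score"),
    e_value = num(6, "E-value"),
    significant = trimws(get(1)) == "*",
    definition = defn
  )
}

#' Write KO assignments in KoFamKOALA detail-TSV format
#'
#' @param assignments Tibble as returned by [read_koala_assignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_koala_assignments <- function(assignments, path) {
  lines <- c(
    "# gene name\tKO\tthrshld\tscore\tE-value\tKO definition",
    sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s",
            ifelse(assignments$significant, "*", ""),
            assignments$refseq_id, assignments$ko_number,
            format(assignments$threshold, trim = TRUE),
            format(assignments$score, trim = TRUE),
            format(assignments$e_value, trim = TRUE),
            assignments$definition)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Keep proteins with a unique significant KO assignment
#'
#' Only significant rows are considered. A protein is retained iff it has
#' exactly one distinct significant KO; proteins with zero or two or more
#' distinct significant KOs are dropped. Repeated rows for the same
#' (protein, KO) pair count once.
#'
#' @param assignments Tibble from [read_koala_assignments()].
#' @return A tibble with columns `refseq_id`, `ko_number`, one row per
#'   retained protein. The attribute `"report"` carries counts of proteins
#'   dropped for ambiguous (>= 2 KOs) or absent significant assignment.
#' @export
select_unique_ko <- function(assignments) {
  sig <- assignments |>
    filter(.data$significant) |>
    distinct(.data$refseq_id, .data$ko_number)
  counts <- sig |> count(.data$refseq_id, name = "n_ko")
  unique_map <- sig |>
    semi_join(filter(counts, .data$n_ko == 1L), by = "refseq_id") |>
    arrange(.data$refseq_id)
  all_ids <- unique(assignments$refseq_id)
  n_ambiguous <- sum(counts$n_ko >= 2L)
  n_no_sig <- length(setdiff(all_ids, counts$refseq_id))
  structure(unique_map,
            report = tibble(n_input_proteins = length(all_ids),
                            n_unique = nrow(unique_map),
                            n_ambiguous = n_ambiguous,
                            n_without_significant = n_no_sig))
}

#' Read a protein metadata table
#'
#' TSV with header columns `refseq_id`, `gene_symbol`, `org_id`,
#' `length_aa`, `chromosome`, `strand`, `isoform_group` and optionally
#' `description`. Strand must be `+`, `-` or `unknown`; lengths are
#' positive integers. When `fasta` is supplied (protein FASTA whose ids are
#' refseq accessions) sequence lengths are cross-checked against
#' `length_aa` and any disagreement is an error.
#'
#' @param path Path to the TSV.
#' @param fasta Optional path to a companion protein FASTA.
#' @return A tibble of protein records (`is_longest` unset; see
#'   [select_longest_isoform()]).
#' @export
read_protein_table <- function(path, fasta = NULL) {
  tab <- read_tsv_quiet(path)
  required <- c("refseq_id", "gene_symbol", "org_id", "length_aa",
                "chromosome", "strand", "isoform_group")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop_format("protein table %s lacks column(s): %s", path,
                paste(missing, collapse = ", "))
  }
  if (!"description" %in% names(tab)) tab$description <- ""
  len <- suppressWarnings(as.integer(tab$length_aa))
  bad <- which(is.na(len) | len < 1L)
  if (length(bad) > 0) {
    stop_format("row %d: length_aa '%s' is not a positive integer",
                bad[1], tab$length_aa[bad[1]])
  }
  bad_strand <- which(!tab$strand %in% c("+", "-", "unknown"))
  if (length(bad_strand) > 0) {
    stop_format("row %d: strand '%s' (expected +, - or unknown)",
                bad_strand[1], tab$strand[bad_strand[1]])
  }
  out <- tibble(refseq_id = tab$refseq_id, gene_symbol = tab$gene_symbol,
                org_id = tab$org_id, length_aa = len,
                chromosome = tab$chromosome, strand = tab$strand,
                isoform_group = tab$isoform_group,
                description = tab$description)
  if (!is.null(fasta)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("Biostrings is required for FASTA length cross-checks")
    }
    seqs <- Biostrings::readAAStringSet(fasta)
    ids <- sub("\\s.*$", "", names(seqs))
    shared <- intersect(ids, out$refseq_id)
    lens <- setNames(Biostrings::width(seqs), ids)[shared]
    tab_lens <- setNames(out$length_aa, out$refseq_id)[shared]
    mismatch <- shared[lens != tab_lens]
    if (length(mismatch) > 0) {
      stop_format("length_aa mismatch with FASTA for %s (table %d, fasta %d)",
                  mismatch[1], tab_lens[mismatch[1]], lens[mismatch[1]])
    }
  }
  out
}

#' Write a protein metadata table
#'
#' @param proteins Protein tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(proteins, path) {
  cols <- c("refseq_id", "gene_symbol", "org_id", "length_aa",
            "chromosome", "strand", "isoform_group", "description")
  write_tsv_plain(proteins[, intersect(cols, names(proteins))], path)
}

#' Select the longest isoform per gene
#'
#' Alternative splicing maps one gene to several protein isoforms; to keep a
#' one-gene-one-protein mapping only the longest isoform of each
#' `isoform_group` is retained. Ties on `length_aa` break to the
#' lexicographically smallest `refseq_id`.
#'
#' @param records Protein tibble with `isoform_group` and `length_aa`.
#' @return The selected records, one per isoform group, with
#'   `is_longest = TRUE`.
#' @export
select_longest_isoform <- function(records) {
  records |>
    group_by(.data$isoform_group) |>
    arrange(desc(.data$length_aa), .data$refseq_id, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    mutate(is_longest = TRUE) |>
    arrange(.data$refseq_id)
}
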