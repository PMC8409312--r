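#' Read Pfam hits in pfam_scan tabular format
#'
#' Parses the 15-column whitespace-delimited `pfam_scan.pl` output:
#' seq id, alignment start/end, envelope start/end, hmm accession, hmm
#' name, type, hmm start/end/length, bit score, E-value, significance,
#' clan. Lines starting with `#` are skipped. Envelope coordinates
#' (`envfrom`/`envto`) delimit the widest residue interval supporting the
#' match and are 1-based inclusive. A clan of `No_clan` is mapped to the
#' Unknown clan sentinel `"9999.0"`.
#'
#' @param path Path to a pfam_scan output file.
#' @return A tibble of domain hits with columns `refseq_id`,
#'   `domain_name`, `domain_acc`, `clan_id`, `env_from`, `env_to`,
#'   `bit_score`, `e_value`.
#' @export
read_pfam_hits <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  idx <- which(keep)
  empty <- tibble(refseq_id = character(), domain_name = character(),
                  domain_acc = character(), clan_id = character(),
                  env_from = integer(), env_to = integer(),
                  bit_score = double(), e_value = double())
  if (length(idx) == 0) return(empty)
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  n_fields <- lengths(fields)
  if (any(n_fields < 15)) {
    bad <- which(n_fields < 15)[1]
    stop_format("line %d: expected 15 whitespace-delimited columns, got %d",
                idx[bad], n_fields[bad])
  }
  get <- function(i) map_chr(fields, ~ .x[[i]])
  num <- function(i, what) {
    raw <- get(i)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad) > 0) {
      stop_format("line %d: non-numeric %s '%s'", idx[bad[1]], what,
                  raw[bad[1]])
    }
    val
  }
  env_from <- as.integer(num(4, "env start"))
  env_to <- as.integer(num(5, "env end"))
  bad_env <- which(env_from > env_to | env_from < 1L)
  if (length(bad_env) > 0) {
    stop_format("line %d: invalid envelope %d..%d", idx[bad_env[1]],
                env_from[bad_env[1]], env_to[bad_env[1]])
  }
  clan <- get(15)
  clan[clan == "No_clan"] <- UNKNOWN_CLAN
  tibble(
    refseq_id = get(1),
    domain_name = get(7),
    domain_acc = get(6),
    clan_id = clan,
    env_from = env_from,
    env_to = env_to,
    bit_score = num(12, "bit score"),
    e_value = num(13, "E-value")
  )
}

#' Write Pfam hits in pfam_scan tabular format
#'
#' Emits the same 15-column dialect [read_pfam_hits()] reads; alignment
#' coordinates are written equal to the envelope and hmm columns are
#' filled with placeholders sufficient for round-tripping the fields this
#' package consumes.
#'
#' @param hits Tibble of domain hits.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfam_hits <- function(hits, path) {
  clan <- ifelse(hits$clan_id == UNKNOWN_CLAN, "No_clan", hits$clan_id)
  lines <- c(
    "# <seq id> <alignment start> <alignment end> <envelope start> <envelope end> <hmm acc> <hmm name> <type> <hmm start> <hmm end> <hmm length> <bit score> <E-value> <significance> <clan>",
    sprintf("%s %d %d %d %d %s %s Domain 1 %d %d %s %s 1 %s",
            hits$refseq_id, hits$env_from, hits$env_to,
            hits$env_from, hits$env_to, hits$domain_acc, hits$domain_name,
            hits$env_to - hits$env_from + 1L,
            hits$env_to - hits$env_from + 1L,
            format(hits$bit_score, trim = TRUE),
            format(hits$e_value, trim = TRUE), clan)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

# Ordering used everywhere a "best" hit must be picked deterministically:
# bit score desc, then E-value asc, then env_from asc, then name asc.
hit_priority_order <- function(hits) {
  order(-hits$bit_score, hits$e_value, hits$env_from, hits$domain_name)
}

#' Resolve overlapping hits to putative domains
#'
#' Overlapping domain predictions are inconsistent with the linear protein
#' structure; within each group of mutually overlapping hits the
#' highest-scoring one (the \emph{putative} domain) is kept. Selection is
#' greedy: hits are visited in decreasing bit score (ties broken by lower
#' E-value, then smaller `env_from`, then domain name) and accepted iff
#' their closed envelope interval shares no residue with any
#' already-accepted hit. Nested hits count as overlapping.
#'
#' @param hits Tibble of hits for a single protein.
#' @return The accepted hits, sorted by `env_from`.
#' @export
resolve_putative <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  if (length(unique(hits$refseq_id)) > 1) {
    stop_contract("resolve_putative expects hits for one protein, got %d",
                  length(unique(hits$refseq_id)))
  }
  ord <- hit_priority_order(hits)
  acc_from <- integer(0)
  acc_to <- integer(0)
  take <- logical(nrow(hits))
  for (i in ord) {
    if (!any(hits$env_from[i] <= acc_to & hits$env_to[i] >= acc_from)) {
      take[i] <- TRUE
      acc_from <- c(acc_from, hits$env_from[i])
      acc_to <- c(acc_to, hits$env_to[i])
    }
  }
  out <- hits[take, , drop = FALSE]
  out[order(out$env_from), , drop = FALSE]
}

#' Collapse putative domains to unique putative domains
#'
#' A protein may carry several non-overlapping copies of the same domain;
#' for presence/absence comparisons each domain name is represented by its
#' single highest-scoring putative hit (same tie-break chain as
#' [resolve_putative()]).
#'
#' @param putative Tibble of putative hits for one protein
#'   (output of [resolve_putative()]).
#' @return One row per distinct `domain_name`, the per-name best hit,
#'   sorted by `env_from`.
#' @export
resolve_unique_putative <- function(putative) {
  if (nrow(putative) == 0) return(putative)
  ord <- hit_priority_order(putative)
  best <- ord[!duplicated(putative$domain_name[ord])]
  out <- putative[sort_c(best), , drop = FALSE]
  out[order(out$env_from), , drop = FALSE]
}

#' Compute per-protein domain content flags
#'
#' Applies [resolve_putative()] and [resolve_unique_putative()] to every
#' protein in a hit table and returns the hits annotated with logical
#' `putative` and `unique_putative` columns (`unique_putative` implies
#' `putative`).
#'
#' @param hits Tibble of domain hits for any number of proteins.
#' @return The input hits with the two flag columns appended.
#' @export
domain_content <- function(hits) {
  if (nrow(hits) == 0) {
    return(mutate(hits, putative = logical(0), unique_putative = logical(0)))
  }
  hits$.row <- seq_len(nrow(hits))
  flagged <- hits |>
    group_by(.data$refseq_id) |>
    group_map(function(h, key) {
      put <- resolve_putative(mutate(h, refseq_id = key$refseq_id))
      uni <- resolve_unique_putative(put)
      tibble(.row = h$.row,
             putative = h$.row %in% put$.row,
             unique_putative = h$.row %in% uni$.row)
    }) |>
    bind_rows()
  out <- hits |>
    left_join(flagged, by = ".row") |>
    select(-".row")
  out
}
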