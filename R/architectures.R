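#' Partition a KO group into distinct domain architectures
#'
#' Proteins of one KO are grouped by identical unique-putative domain
#' content: each distinct content set is an "item" (a domain architecture,
#' DA) carrying matched organism and refseq lists (entry i of one list
#' corresponds to entry i of the other). An organism appearing more than
#' once in an item's list contributes paralogous proteins. Items are
#' numbered by decreasing member count, ties broken by the
#' lexicographically smallest domain name (then by the full sorted set).
#'
#' @param members KO membership as returned by [query_ko_members()]:
#'   tibble with `ko_number`, `refseq_id`, `org_id`, `domains` (list).
#' @return Tibble of architecture items: `ko_number`, `item_index`,
#'   `domain_set` (list of sorted character vectors), `org_ids`,
#'   `refseq_ids` (matched lists), `gained`, `missing` (lists, filled by
#'   [gain_loss_patterns()]).
#' @export
partition_ko <- function(members) {
  if (nrow(members) == 0) {
    stop_contract("partition_ko requires a non-empty KO membership")
  }
  if (length(unique(members$ko_number)) > 1) {
    stop_contract("partition_ko expects members of a single KO")
  }
  members <- members |>
    mutate(.key = map_chr(.data$domains, domain_set_key)) |>
    arrange(.data$refseq_id)
  items <- members |>
    group_by(.data$.key) |>
    summarise(ko_number = .data$ko_number[1],
              domain_set = list(sort_c(unique(unlist(.data$domains) %||% character(0)))),
              org_ids = list(.data$org_id),
              refseq_ids = list(.data$refseq_id),
              n_members = n(),
              .groups = "drop") |>
    mutate(first_domain = map_chr(.data$domain_set,
                                  ~ if (length(.x) == 0) "" else .x[[1]])) |>
    arrange(desc(.data$n_members), .data$first_domain, .data$.key) |>
    mutate(item_index = row_number()) |>
    select("ko_number", "item_index", "domain_set", "org_ids", "refseq_ids")
  items$gained <- rep(list(character(0)), nrow(items))
  items$missing <- rep(list(character(0)), nrow(items))
  gain_loss_patterns(items)
}

#' Fill gained/missing domain patterns across a KO's items
#'
#' For item i among the items of one KO, `missing` is the set of domains
#' present in some other item but absent from i, and `gained` is the set
#' of domains present in i but absent from at least one other item. Both
#' are purely comparative (no ancestral polarity). A KO with a single item
#' has empty patterns; at least two items are needed for any pattern to be
#' non-empty.
#'
#' @param items Architecture items of one KO ([partition_ko()] output).
#' @return `items` with `gained` and `missing` list-columns filled.
#' @export
gain_loss_patterns <- function(items) {
  keys <- map_chr(items$domain_set, domain_set_key)
  if (anyDuplicated(keys) > 0) {
    stop_contract("architecture items of one KO must have distinct domain sets")
  }
  n <- nrow(items)
  if (n <= 1) {
    items$gained <- rep(list(character(0)), n)
    items$missing <- rep(list(character(0)), n)
    return(items)
  }
  all_domains <- sort_c(unique(unlist(items$domain_set)))
  items$missing <- map(items$domain_set, ~ setdiff(all_domains, .x))
  items$gained <- imap(items$domain_set, function(set, i) {
    others <- items$domain_set[-i]
    keep(set, function(d) any(!map_lgl(others, ~ d %in% .x)))
  })
  items
}

#' Partition every KO in a datastore
#'
#' @param db A `domarch_db`.
#' @return Tibble of architecture items across all KOs with at least one
#'   member, gain/loss patterns filled.
#' @export
partition_all_kos <- function(db) {
  kos <- db_ko_numbers(db)
  purrr::map_dfr(kos, function(ko) partition_ko(query_ko_members(db, ko)))
}

#' Export architecture items as a flat TSV
#'
#' List-columns are comma-joined in the written file.
#'
#' @param items Architecture items.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_architecture_items <- function(items, path) {
  flat <- items |>
    mutate(across(c("domain_set", "org_ids", "refseq_ids", "gained",
                    "missing"),
                  ~ map_chr(.x, paste, collapse = ",")))
  write_tsv_plain(flat, path)
}
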