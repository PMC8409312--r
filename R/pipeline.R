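#' Run the full event-detection pipeline on a datastore
#'
#' Partitions every KO into architecture items, calls mobile domains,
#' translocations, indels and duplications, and tabulates per-superfamily
#' counts.
#'
#' @param db A `domarch_db`.
#' @param config A [run_config()].
#' @return An object of class `domarch_events`: list with elements
#'   `items`, `mobile`, `translocations`, `indels`, `duplications`,
#'   `superfamily_counts`, `config`.
#' @export
run_pipeline <- function(db, config = run_config()) {
  items <- partition_all_kos(db)
  mobile <- mobile_domains_all(items, config)
  translocations <- detect_translocations(mobile, db$taxonomy, config)
  indels <- classify_indels(mobile, translocations, db$taxonomy)
  duplications <- duplication_calls(db, config)
  structure(
    list(items = items,
         mobile = mobile,
         translocations = translocations,
         indels = indels,
         duplications = duplications,
         superfamily_counts = summarize_by_superfamily(translocations, db),
         config = config,
         db = db),
    class = "domarch_events"
  )
}

#' @export
print.domarch_events <- function(x, ...) {
  g <- glance(x)
  cat("<domarch_events>\n")
  cat(sprintf("  KOs partitioned:       %d (%d items)\n", g$n_kos, g$n_items))
  cat(sprintf("  mobile domain records: %d (%d distinct domains)\n",
              g$n_mobile_records, g$n_mobile_domains))
  cat(sprintf("  translocation events:  %d (%d domains)\n",
              g$n_translocation_events, g$n_translocation_domains))
  cat(sprintf("  indel events:          %d (%d domains)\n",
              g$n_indel_events, g$n_indel_domains))
  cat(sprintf("  duplicated domains:    %d (global calls)\n",
              g$n_duplicated_domains))
  invisible(x)
}

#' Tidy event-detection results
#'
#' @param x A `domarch_events` object.
#' @param type Which component to return: translocation events (default),
#'   indels, mobile records, architecture items, or duplication calls.
#' @param ... Unused.
#' @return A tibble; list-columns of organism groups are comma-joined into
#'   character columns for a flat, export-ready table.
#' @exportS3Method generics::tidy
tidy.domarch_events <- function(x, type = c("translocations", "indels",
                                            "mobile", "items",
                                            "duplications"), ...) {
  type <- match.arg(type)
  flatten_lists <- function(tb) {
    mutate(tb, across(where(is.list), ~ map_chr(.x, paste, collapse = ",")))
  }
  switch(type,
    translocations = flatten_lists(x$translocations),
    indels = flatten_lists(x$indels),
    mobile = flatten_lists(x$mobile),
    items = flatten_lists(x$items),
    duplications = x$duplications |>
      select("domain_name", "n_duplicated", "n_nonduplicated", "diff",
             "global_status")
  )
}

#' One-row summary of event-detection results
#'
#' @param x A `domarch_events` object.
#' @param ... Unused.
#' @return A one-row tibble of counts: KOs, items, mobile records/domains,
#'   translocation events/domains, indel events/domains, duplication
#'   calls.
#' @exportS3Method generics::glance
glance.domarch_events <- function(x, ...) {
  tibble(
    n_kos = length(unique(x$items$ko_number)),
    n_items = nrow(x$items),
    n_mobile_records = sum(x$mobile$is_mobile),
    n_mobile_domains = length(unique(x$mobile$domain_name[x$mobile$is_mobile])),
    n_translocation_events = nrow(x$translocations),
    n_translocation_domains = length(unique(x$translocations$domain_name)),
    n_indel_events = nrow(x$indels),
    n_indel_domains = length(unique(x$indels$domain_name)),
    n_duplicated_domains = sum(x$duplications$global_status == "duplicated"),
    n_nonduplicated_domains =
      sum(x$duplications$global_status == "nonduplicated")
  )
}

#' Plot per-superfamily translocation counts
#'
#' Bar chart of translocation events per clan (super-family), filled by
#' superdomain class composite.
#'
#' @param object A `domarch_events` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.domarch_events <- function(object, ...) {
  counts <- object$superfamily_counts
  if (nrow(counts) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No translocation events"))
  }
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = stats::reorder(.data$clan_name, .data$n),
                               y = .data$n, fill = .data$class_label)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "super-family (clan)", y = "translocation events",
                  fill = "superdomain class") +
    ggplot2::theme_minimal()
}

#' Plot a presence/absence map for one domain across KOs
#'
#' Shows, for the KOs where the domain is mobile, which organisms fall in
#' the containing (A) and lacking (B) groups — the raw material of
#' translocation calls.
#'
#' @param events A `domarch_events` object.
#' @param domain_name Domain to display.
#' @return A ggplot object.
#' @export
plot_domain_mobility <- function(events, domain_name) {
  rec <- filter(events$mobile, .data$domain_name == !!domain_name,
                .data$is_mobile)
  if (nrow(rec) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = sprintf("%s is not mobile", domain_name)))
  }
  long <- bind_rows(
    tibble(ko_number = rep(rec$ko_number, lengths(rec$A)),
           org_id = unlist(rec$A), group = "A (contains)"),
    tibble(ko_number = rep(rec$ko_number, lengths(rec$B)),
           org_id = unlist(rec$B), group = "B (lacks)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ko_number, y = .data$org_id,
                                     fill = .data$group)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::labs(title = domain_name, x = "KO group", y = "organism") +
    ggplot2::theme_minimal()
}

#' Write supplementary-style event tables
#'
#' Writes the flat event tables to a directory: `translocations.tsv`
#' (domain, clan, KO pair, A*/B* organisms, class),
#' `translocation_class_counts.tsv`, `indels.tsv`,
#' `indel_class_counts.tsv`, `indel_superfamily_counts.tsv` and
#' `superfamily_counts.tsv` (class, clan, count).
#'
#' @param events A `domarch_events` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_event_tables <- function(events, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  db <- events$db
  clan_of <- setNames(db$pfam_domain$clan_id, db$pfam_domain$domain_name)
  tr <- tidy(events, "translocations") |>
    mutate(clan_id = unname(clan_of[.data$domain_name]),
           .after = "domain_name")
  write_tsv_plain(tr, file.path(dir, "translocations.tsv"))
  write_tsv_plain(count(events$translocations, .data$class_label),
                  file.path(dir, "translocation_class_counts.tsv"))
  ind <- tidy(events, "indels") |>
    mutate(clan_id = unname(clan_of[.data$domain_name]),
           .after = "domain_name")
  write_tsv_plain(ind, file.path(dir, "indels.tsv"))
  write_tsv_plain(count(events$indels, .data$class_label),
                  file.path(dir, "indel_class_counts.tsv"))
  write_tsv_plain(summarize_by_superfamily(events$indels, db),
                  file.path(dir, "indel_superfamily_counts.tsv"))
  write_tsv_plain(events$superfamily_counts,
                  file.path(dir, "superfamily_counts.tsv"))
  write_tsv_plain(tidy(events, "duplications"),
                  file.path(dir, "duplications.tsv"))
  invisible(dir)
}
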