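DB_TABLES <- c("taxonomy", "ko_annotation", "clan_domain", "pfam_domain",
               "org_protein_annotation", "pfam_data")

#' Build the six-relation domain-architecture datastore
#'
#' Collates organism taxonomy, KO annotation, clan (super-family) and Pfam
#' family descriptions, protein records and per-hit domain content into a
#' single relational object with six tables:
#' `taxonomy` (org_id, superdomain, ranks), `ko_annotation`
#' (ko_number, description), `clan_domain` (clan_id, clan_name),
#' `pfam_domain` (domain_name, accession, clan_id), `org_protein_annotation`
#' (protein records incl. `ko_number`, `is_longest`) and `pfam_data`
#' (domain hits with `putative`/`unique_putative` flags).
#'
#' Longest-isoform selection and putative/unique-putative resolution are
#' applied here; proteins whose KO assignment is absent are retained in the
#' store but are excluded from event detection downstream. A sentinel
#' Unknown clan row (`"9999.0"`) is always present.
#'
#' @param registry Organism registry ([read_organism_registry()]).
#' @param proteins Protein table ([read_protein_table()]).
#' @param hits Domain hits ([read_pfam_hits()]).
#' @param ko_map Unique-KO map ([select_unique_ko()]), columns
#'   `refseq_id`, `ko_number`.
#' @param clan_map Optional tibble `clan_id`, `clan_name` describing clans.
#' @param ko_descriptions Optional tibble `ko_number`, `description`.
#' @return An object of class `domarch_db`: a named list of the six
#'   tibbles, with a `build_report` attribute of per-table row counts and
#'   dropped-protein counts.
#' @export
build_db <- function(registry, proteins, hits, ko_map,
                     clan_map = NULL, ko_descriptions = NULL) {
  unknown_org <- setdiff(proteins$org_id, registry$org_id)
  if (length(unknown_org) > 0) {
    stop_integrity("org_protein_annotation.org_id '%s' missing from taxonomy",
                   unknown_org[1])
  }
  longest <- select_longest_isoform(proteins)
  n_isoforms_dropped <- nrow(proteins) - nrow(longest)
  unknown_ref <- setdiff(hits$refseq_id, proteins$refseq_id)
  if (length(unknown_ref) > 0) {
    stop_integrity("pfam_data.refseq_id '%s' missing from org_protein_annotation",
                   unknown_ref[1])
  }

  prot <- proteins |>
    mutate(is_longest = .data$refseq_id %in% longest$refseq_id) |>
    left_join(ko_map, by = "refseq_id") |>
    arrange(.data$refseq_id)

  pfam_data <- domain_content(hits) |>
    arrange(.data$refseq_id, .data$env_from, .data$domain_name)

  pfam_domain <- pfam_data |>
    distinct(.data$domain_name, .data$domain_acc, .data$clan_id) |>
    arrange(.data$domain_name)
  dup_dom <- pfam_domain$domain_name[duplicated(pfam_domain$domain_name)]
  if (length(dup_dom) > 0) {
    stop_integrity("pfam_domain.domain_name '%s' has conflicting accession/clan",
                   dup_dom[1])
  }

  clan_domain <- tibble(clan_id = UNKNOWN_CLAN, clan_name = "Unknown")
  if (!is.null(clan_map) && nrow(clan_map) > 0) {
    clan_domain <- bind_rows(clan_domain,
                             filter(clan_map, .data$clan_id != UNKNOWN_CLAN))
  }
  extra_clans <- setdiff(pfam_domain$clan_id, clan_domain$clan_id)
  if (length(extra_clans) > 0) {
    clan_domain <- bind_rows(clan_domain,
                             tibble(clan_id = extra_clans,
                                    clan_name = extra_clans))
  }
  clan_domain <- arrange(distinct(clan_domain), .data$clan_id)

  kos <- sort_c(unique(stats::na.omit(prot$ko_number)))
  ko_annotation <- tibble(ko_number = kos, description = "")
  if (!is.null(ko_descriptions) && nrow(ko_descriptions) > 0) {
    ko_annotation <- ko_annotation |>
      select("ko_number") |>
      left_join(ko_descriptions, by = "ko_number") |>
      mutate(description = coalesce(.data$description, ""))
  }

  db <- structure(
    list(taxonomy = arrange(registry, .data$org_id),
         ko_annotation = ko_annotation,
         clan_domain = clan_domain,
         pfam_domain = pfam_domain,
         org_protein_annotation = prot,
         pfam_data = pfam_data),
    class = "domarch_db"
  )
  validate_db(db)
  attr(db, "build_report") <- tibble(
    table = c(DB_TABLES, "isoforms_dropped", "proteins_without_ko"),
    n = unname(c(vapply(db[DB_TABLES], nrow, integer(1)),
                 n_isoforms_dropped, sum(is.na(prot$ko_number))))
  )
  db
}

#' Check referential integrity of a datastore
#'
#' Verifies the foreign keys between the six tables and the flag
#' implication `unique_putative => putative`; errors name the violating
#' table and key.
#'
#' @param db A `domarch_db`.
#' @return `db`, invisibly, if valid.
#' @export
validate_db <- function(db) {
  stopifnot(inherits(db, "domarch_db"))
  miss <- setdiff(DB_TABLES, names(db))
  if (length(miss) > 0) stop_integrity("missing table '%s'", miss[1])
  bad <- setdiff(db$pfam_data$refseq_id, db$org_protein_annotation$refseq_id)
  if (length(bad) > 0) {
    stop_integrity("pfam_data.refseq_id '%s' missing from org_protein_annotation",
                   bad[1])
  }
  bad <- setdiff(db$org_protein_annotation$org_id, db$taxonomy$org_id)
  if (length(bad) > 0) {
    stop_integrity("org_protein_annotation.org_id '%s' missing from taxonomy",
                   bad[1])
  }
  bad <- setdiff(db$pfam_data$domain_name, db$pfam_domain$domain_name)
  if (length(bad) > 0) {
    stop_integrity("pfam_data.domain_name '%s' missing from pfam_domain",
                   bad[1])
  }
  bad <- setdiff(db$pfam_domain$clan_id, db$clan_domain$clan_id)
  if (length(bad) > 0) {
    stop_integrity("pfam_domain.clan_id '%s' missing from clan_domain", bad[1])
  }
  if (nrow(db$pfam_data) > 0 &&
      any(db$pfam_data$unique_putative & !db$pfam_data$putative)) {
    stop_integrity("pfam_data: unique_putative row is not putative")
  }
  invisible(db)
}

#' @export
print.domarch_db <- function(x, ...) {
  cat("<domarch_db> six-relation domain-architecture store\n")
  for (tb in DB_TABLES) {
    cat(sprintf("  %-24s %6d rows\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}

#' Query the longest-isoform members of a KO group
#'
#' Returns the KO-annotated, longest-isoform proteins of one KO with their
#' organisms and unique-putative domain content as index-aligned columns
#' (row i's refseq belongs to row i's organism).
#'
#' @param db A `domarch_db`.
#' @param ko_number KO id, e.g. `"K16822"`.
#' @return Tibble with columns `ko_number`, `refseq_id`, `org_id`,
#'   `domains` (list of character vectors); zero rows for an unknown KO.
#' @export
query_ko_members <- function(db, ko_number) {
  members <- db$org_protein_annotation |>
    filter(.data$is_longest, !is.na(.data$ko_number),
           .data$ko_number == !!ko_number)
  if (nrow(members) == 0) {
    return(tibble(ko_number = character(), refseq_id = character(),
                  org_id = character(), domains = list()))
  }
  content <- db$pfam_data |>
    filter(.data$unique_putative,
           .data$refseq_id %in% members$refseq_id) |>
    group_by(.data$refseq_id) |>
    summarise(domains = list(sort_c(.data$domain_name)), .groups = "drop")
  members |>
    left_join(content, by = "refseq_id") |>
    mutate(domains = map(.data$domains, ~ .x %||% character(0))) |>
    transmute(ko_number = .data$ko_number, refseq_id = .data$refseq_id,
              org_id = .data$org_id, domains = .data$domains) |>
    arrange(.data$refseq_id)
}

#' List KO groups present in the datastore
#'
#' @param db A `domarch_db`.
#' @return Character vector of KO ids with at least one longest-isoform
#'   member.
#' @export
db_ko_numbers <- function(db) {
  sort_c(unique(stats::na.omit(
    db$org_protein_annotation$ko_number[db$org_protein_annotation$is_longest]
  )))
}

#' Export / import the datastore as TSV relations
#'
#' One TSV per relation, header = column names, canonical row order; a
#' write/read cycle reproduces an identical store.
#'
#' @param db A `domarch_db`.
#' @param dir Directory for the six TSV files (created if needed).
#' @return `db_export_tsv`: the directory, invisibly. `db_import_tsv`: a
#'   `domarch_db`.
#' @export
db_export_tsv <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in DB_TABLES) {
    write_tsv_plain(db[[tb]], file.path(dir, paste0(tb, ".tsv")))
  }
  invisible(dir)
}

#' @rdname db_export_tsv
#' @export
db_import_tsv <- function(dir) {
  spec <- db_col_types()
  tabs <- lapply(DB_TABLES, function(tb) {
    readr::read_tsv(file.path(dir, paste0(tb, ".tsv")),
                    col_types = spec[[tb]], progress = FALSE,
                    na = "NA")
  })
  names(tabs) <- DB_TABLES
  tabs$taxonomy$source_tags[is.na(tabs$taxonomy$source_tags)] <- ""
  tabs$ko_annotation$description[is.na(tabs$ko_annotation$description)] <- ""
  tabs$org_protein_annotation$description[
    is.na(tabs$org_protein_annotation$description)] <- ""
  db <- structure(tabs, class = "domarch_db")
  validate_db(db)
  db
}

db_col_types <- function() {
  list(
    taxonomy = readr::cols(org_id = "c", name = "c", superdomain = "c",
                           taxonomy_id = "i", source_tags = "c"),
    ko_annotation = readr::cols(ko_number = "c", description = "c"),
    clan_domain = readr::cols(clan_id = "c", clan_name = "c"),
    pfam_domain = readr::cols(domain_name = "c", domain_acc = "c",
                              clan_id = "c"),
    org_protein_annotation = readr::cols(
      refseq_id = "c", gene_symbol = "c", org_id = "c", length_aa = "i",
      chromosome = "c", strand = "c", isoform_group = "c",
      description = "c", is_longest = "l", ko_number = "c"),
    pfam_data = readr::cols(refseq_id = "c", domain_name = "c",
                            domain_acc = "c", clan_id = "c",
                            env_from = "i", env_to = "i", bit_score = "d",
                            e_value = "d", putative = "l",
                            unique_putative = "l")
  )
}

#' Persist / load the datastore as a single-file SQLite database
#'
#' The six relations are written as SQLite tables of the same names,
#' giving a portable single-file SQL store.
#'
#' @param db A `domarch_db`.
#' @param path Path of the SQLite file.
#' @return `db_write_sqlite`: `path`, invisibly. `db_read_sqlite`: a
#'   `domarch_db`.
#' @export
db_write_sqlite <- function(db, path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  for (tb in DB_TABLES) {
    DBI::dbWriteTable(con, tb, as.data.frame(db[[tb]]), overwrite = TRUE)
  }
  invisible(path)
}

#' @rdname db_write_sqlite
#' @export
db_read_sqlite <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  tabs <- lapply(DB_TABLES, function(tb) as_tibble(DBI::dbReadTable(con, tb)))
  names(tabs) <- DB_TABLES
  for (tb in c("org_protein_annotation", "pfam_data")) {
    for (cl in intersect(c("is_longest", "putative", "unique_putative"),
                         names(tabs[[tb]]))) {
      tabs[[tb]][[cl]] <- as.logical(tabs[[tb]][[cl]])
    }
  }
  db <- structure(tabs, class = "domarch_db")
  validate_db(db)
  db
}
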