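#' Detection configuration
#'
#' Thresholds and policies used by the event detectors. The defaults are
#' the model's published choices; they are exposed because the 4-organism
#' cutoffs are modelling decisions, not derived constants.
#'
#' @param min_group_size Minimum organism-group size for mobility and for
#'   each reciprocal group of a translocation (default 4).
#' @param duplication_percentile Percentile of the |diff| distribution
#'   beyond which a global duplication call is made (default 0.99).
#' @param duplication_rule `"empirical"` (two-sided empirical-percentile
#'   test on diff) or `"cumsum-rank"` (rank cutoff on the cumulative sum
#'   of sorted |diff|).
#' @param ambiguity_policy What to do with an organism having both
#'   domain-containing and domain-lacking paralogs in one KO:
#'   `"exclude"` (count in neither A, B nor T), `"to_A"`, `"to_B"`.
#' @return A list of class `domarch_config`.
#' @export
run_config <- function(min_group_size = 4L,
                       duplication_percentile = 0.99,
                       duplication_rule = c("empirical", "cumsum-rank"),
                       ambiguity_policy = c("exclude", "to_A", "to_B")) {
  duplication_rule <- match.arg(duplication_rule)
  ambiguity_policy <- match.arg(ambiguity_policy)
  stopifnot(min_group_size >= 1, duplication_percentile > 0,
            duplication_percentile < 1)
  structure(list(min_group_size = as.integer(min_group_size),
                 duplication_percentile = duplication_percentile,
                 duplication_rule = duplication_rule,
                 ambiguity_policy = ambiguity_policy),
            class = "domarch_config")
}

#' Call mobile domains within one KO group
#'
#' For every domain occurring in the KO, organisms are split into A (all
#' of the organism's KO proteins contain the domain), B (none does), and
#' `excluded` (containing and lacking paralogs coexist; policy-dependent,
#' default counts in neither A, B nor T). With
#' \eqn{T = A \cup B}, the domain is \emph{mobile} iff
#' \eqn{g \le |A| < |T| - g} with g = `min_group_size`, which also forces
#' \eqn{|B| > g}.
#'
#' @param items Architecture items of one KO ([partition_ko()]).
#' @param config A [run_config()].
#' @return Tibble with one row per domain: `domain_name`, `ko_number`,
#'   `A`, `B`, `excluded` (list-columns of org ids), `T_size`,
#'   `is_mobile`.
#' @export
mobile_domains <- function(items, config = run_config()) {
  stopifnot(nrow(items) >= 1)
  ko <- items$ko_number[1]
  # per-organism presence: across all of an organism's proteins in the KO
  prot <- tibble(
    org_id = unlist(items$org_ids),
    item = rep(seq_len(nrow(items)), lengths(items$org_ids))
  )
  domains <- sort_c(unique(unlist(items$domain_set)))
  purrr::map_dfr(domains, function(d) {
    has_d <- map_lgl(items$domain_set, ~ d %in% .x)
    org_has <- unique(prot$org_id[has_d[prot$item]])
    org_lacks <- unique(prot$org_id[!has_d[prot$item]])
    both <- intersect(org_has, org_lacks)
    A <- setdiff(org_has, both)
    B <- setdiff(org_lacks, both)
    excluded <- both
    if (length(both) > 0 && config$ambiguity_policy != "exclude") {
      if (config$ambiguity_policy == "to_A") A <- union(A, both)
      else B <- union(B, both)
      excluded <- character(0)
    }
    A <- sort_c(A); B <- sort_c(B)
    t_size <- length(A) + length(B)
    g <- config$min_group_size
    mobile <- length(A) >= g && length(A) < t_size - g
    tibble(domain_name = d, ko_number = ko,
           A = list(A), B = list(B), excluded = list(sort_c(excluded)),
           T_size = t_size, is_mobile = mobile)
  })
}

#' Call mobile domains for every KO in a set of items
#'
#' KOs with fewer than two architecture items show no variation and are
#' skipped.
#'
#' @param items Architecture items across KOs ([partition_all_kos()]).
#' @param config A [run_config()].
#' @return Row-bound [mobile_domains()] results.
#' @export
mobile_domains_all <- function(items, config = run_config()) {
  out <- items |>
    group_by(.data$ko_number) |>
    group_split() |>
    keep(~ nrow(.x) >= 2) |>
    purrr::map_dfr(mobile_domains, config = config)
  if (nrow(out) == 0) {
    return(tibble(domain_name = character(), ko_number = character(),
                  A = list(), B = list(), excluded = list(),
                  T_size = integer(), is_mobile = logical()))
  }
  arrange(out, .data$domain_name, .data$ko_number)
}

#' Detect reciprocal translocations between KO pairs
#'
#' For each domain mobile in two KOs \eqn{k_1 < k_2} (numeric KO order),
#' the reciprocal groups are \eqn{A^* = A_1 \cap B_2} (organisms carrying
#' the domain in \eqn{k_1} but not \eqn{k_2}) and
#' \eqn{B^* = A_2 \cap B_1}. A translocation event is emitted iff both
#' groups have at least `min_group_size` members; one event per
#' (domain, KO-pair) triple. Each event carries the superdomain composite
#' class `X-Y` (A*-side first) per [superdomain_class()].
#'
#' @param records Mobile-domain records ([mobile_domains_all()]).
#' @param registry Organism registry (for superdomain lookup).
#' @param config A [run_config()].
#' @return Tibble of events: `domain_name`, `ko1`, `ko2`, `A_star`,
#'   `B_star` (list-columns), `class_label`.
#' @export
detect_translocations <- function(records, registry, config = run_config()) {
  empty <- tibble(domain_name = character(), ko1 = character(),
                  ko2 = character(), A_star = list(), B_star = list(),
                  class_label = character())
  mob <- filter(records, .data$is_mobile)
  if (nrow(mob) == 0) return(empty)
  g <- config$min_group_size
  events <- mob |>
    group_by(.data$domain_name) |>
    group_split() |>
    purrr::map_dfr(function(rec) {
      if (nrow(rec) < 2) return(empty)
      rec <- rec[order(ko_numeric(rec$ko_number)), ]
      pairs <- utils::combn(nrow(rec), 2, simplify = FALSE)
      purrr::map_dfr(pairs, function(p) {
        r1 <- rec[p[1], ]; r2 <- rec[p[2], ]
        a_star <- sort_c(intersect(r1$A[[1]], r2$B[[1]]))
        b_star <- sort_c(intersect(r2$A[[1]], r1$B[[1]]))
        if (length(a_star) >= g && length(b_star) >= g) {
          tibble(domain_name = rec$domain_name[1],
                 ko1 = r1$ko_number, ko2 = r2$ko_number,
                 A_star = list(a_star), B_star = list(b_star),
                 class_label = paste0(superdomain_class(a_star, registry),
                                      "-",
                                      superdomain_class(b_star, registry)))
        } else empty
      })
    })
  if (nrow(events) == 0) return(empty)
  arrange(events, .data$domain_name, .data$ko1, .data$ko2)
}

#' Classify remaining mobile domains as indel events
#'
#' Translocations and indels are mutually exclusive: every mobile
#' (domain, KO) record whose domain takes part in no translocation event
#' becomes one indel event; domains with at least one translocation
#' contribute none. The class label is `X-Y` with the domain-containing
#' side (A) first.
#'
#' @param records Mobile-domain records ([mobile_domains_all()]).
#' @param events Translocation events ([detect_translocations()]).
#' @param registry Organism registry.
#' @return Tibble of indel events: `domain_name`, `ko_number`, `A`, `B`,
#'   `class_label`.
#' @export
classify_indels <- function(records, events, registry) {
  mob <- filter(records, .data$is_mobile,
                !.data$domain_name %in% events$domain_name)
  if (nrow(mob) == 0) {
    return(tibble(domain_name = character(), ko_number = character(),
                  A = list(), B = list(), class_label = character()))
  }
  mob |>
    mutate(class_label = map2_chr(.data$A, .data$B, function(a, b) {
      paste0(superdomain_class(a, registry), "-",
             superdomain_class(b, registry))
    })) |>
    select("domain_name", "ko_number", "A", "B", "class_label") |>
    arrange(.data$domain_name, .data$ko_number)
}

#' Superdomain class of an organism group
#'
#' The superdomain taxonomy (Eukaryota, Bacteria, Viruses) shared by all
#' organisms in the group, or `"Mixed"` when members disagree.
#'
#' @param orgs Character vector of org ids (non-empty).
#' @param registry Organism registry with `org_id`, `superdomain`.
#' @return A single label.
#' @export
superdomain_class <- function(orgs, registry) {
  if (length(orgs) == 0) {
    stop_contract("superdomain_class requires a non-empty organism set")
  }
  unknown <- setdiff(orgs, registry$org_id)
  if (length(unknown) > 0) {
    abort(sprintf("unknown organism '%s'", unknown[1]),
          class = "domarch_lookup_error")
  }
  sd <- unique(registry$superdomain[match(orgs, registry$org_id)])
  if (length(sd) == 1) sd else "Mixed"
}

#' Call domain duplications
#'
#' Duplication works on \emph{putative} domains (copies retained, unlike
#' the unique-putative sets used for mobility). Within a KO a domain is
#' `nonduplicated` iff its copy number is identical in every
#' longest-isoform member protein that contains it, `duplicated`
#' otherwise. Globally, for each domain let
#' diff = (#KOs duplicated) − (#KOs nonduplicated); under the default
#' `"empirical"` rule the domain is `duplicated` when diff > 0 and |diff|
#' reaches the `duplication_percentile` quantile (inverse ECDF) of |diff|
#' over all domains, `nonduplicated` when diff < 0 with the same bound,
#' and `undetermined` otherwise. The `"cumsum-rank"` rule instead ranks
#' domains by |diff| and calls those above the percentile of the
#' cumulative |diff| mass.
#'
#' @param db A `domarch_db`.
#' @param config A [run_config()].
#' @return Tibble with one row per domain: `domain_name`, `per_ko_status`
#'   (list of named character vectors), `n_duplicated`,
#'   `n_nonduplicated`, `diff`, `global_status`.
#' @export
duplication_calls <- function(db, config = run_config()) {
  prot <- db$org_protein_annotation |>
    filter(.data$is_longest, !is.na(.data$ko_number)) |>
    select("refseq_id", "ko_number")
  counts <- db$pfam_data |>
    filter(.data$putative) |>
    inner_join(prot, by = "refseq_id") |>
    count(.data$ko_number, .data$refseq_id, .data$domain_name,
          name = "copies")
  if (nrow(counts) == 0) {
    return(tibble(domain_name = character(), per_ko_status = list(),
                  n_duplicated = integer(), n_nonduplicated = integer(),
                  diff = integer(), global_status = character()))
  }
  per_ko <- counts |>
    group_by(.data$domain_name, .data$ko_number) |>
    summarise(status = if (length(unique(.data$copies)) == 1L)
      "nonduplicated" else "duplicated", .groups = "drop")
  calls <- per_ko |>
    group_by(.data$domain_name) |>
    summarise(per_ko_status = list(setNames(.data$status, .data$ko_number)),
              n_duplicated = sum(.data$status == "duplicated"),
              n_nonduplicated = sum(.data$status == "nonduplicated"),
              .groups = "drop") |>
    mutate(diff = .data$n_duplicated - .data$n_nonduplicated)
  abs_diff <- abs(calls$diff)
  if (config$duplication_rule == "empirical") {
    cut <- stats::quantile(abs_diff, config$duplication_percentile,
                           type = 1, names = FALSE)
    called <- abs_diff >= cut & abs_diff > 0
  } else {
    ord <- order(abs_diff)
    cum <- cumsum(abs_diff[ord])
    total <- sum(abs_diff)
    called_ord <- if (total == 0) rep(FALSE, length(ord)) else
      cum > config$duplication_percentile * total
    called <- logical(length(ord))
    called[ord] <- called_ord & abs_diff[ord] > 0
  }
  calls |>
    mutate(global_status = case_when(
      called & .data$diff > 0 ~ "duplicated",
      called & .data$diff < 0 ~ "nonduplicated",
      .default = "undetermined"
    )) |>
    arrange(.data$domain_name)
}

#' Count translocation or indel events per superfamily and class
#'
#' Events are joined to their Pfam clan (super-family) and counted per
#' (class_label, clan); the Unknown clan is included like any other.
#'
#' @param events Events tibble carrying `domain_name` and `class_label`.
#' @param db A `domarch_db` (for the pfam_domain/clan_domain relations).
#' @return Tibble `class_label`, `clan_id`, `clan_name`, `n`, sorted by
#'   decreasing count.
#' @export
summarize_by_superfamily <- function(events, db) {
  if (nrow(events) == 0) {
    return(tibble(class_label = character(), clan_id = character(),
                  clan_name = character(), n = integer()))
  }
  events |>
    left_join(select(db$pfam_domain, "domain_name", "clan_id"),
              by = "domain_name") |>
    mutate(clan_id = coalesce(.data$clan_id, UNKNOWN_CLAN)) |>
    left_join(db$clan_domain, by = "clan_id") |>
    mutate(clan_name = coalesce(.data$clan_name, "Unknown")) |>
    count(.data$class_label, .data$clan_id, .data$clan_name) |>
    arrange(desc(.data$n), .data$clan_id, .data$class_label)
}
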