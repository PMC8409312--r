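# In-code fixture builders shared across tests.

# Random per-protein domain content across organisms and KOs; paralogs
# (second protein of an organism in a KO) appear at `paralog_rate`.
random_members <- function(seed, n_orgs = 15, n_kos = 6, n_domains = 8,
                           p_present = 0.4, paralog_rate = 0.15) {
  set.seed(seed)
  orgs <- sprintf("o%02d", seq_len(n_orgs))
  kos <- sprintf("K%05d", sample.int(99999, n_kos))
  doms <- paste0("D", seq_len(n_domains))
  rows <- list()
  for (ko in kos) {
    for (org in orgs) {
      n_prot <- 1 + stats::rbinom(1, 1, paralog_rate)
      for (p in seq_len(n_prot)) {
        present <- doms[stats::runif(n_domains) < p_present]
        rows[[length(rows) + 1]] <- tibble::tibble(
          ko = ko, org = org,
          refseq = sprintf("XP_%s_%s_%d", org, sub("K", "", ko), p),
          domains = list(sort(present, method = "radix")))
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Run the package detectors on a random membership table.
run_detectors <- function(prot, registry = NULL, config = run_config()) {
  if (is.null(registry)) {
    registry <- tibble::tibble(org_id = unique(prot$org),
                               name = unique(prot$org),
                               superdomain = "Eukaryota",
                               taxonomy_id = seq_along(unique(prot$org)),
                               source_tags = "")
  }
  items <- prot |>
    dplyr::group_by(ko) |>
    dplyr::group_split() |>
    purrr::map(function(sub) {
      partition_ko(tibble::tibble(ko_number = sub$ko, refseq_id = sub$refseq,
                                  org_id = sub$org, domains = sub$domains))
    }) |>
    dplyr::bind_rows()
  mobile <- mobile_domains_all(items, config)
  translocations <- detect_translocations(mobile, registry, config)
  indels <- classify_indels(mobile, translocations, registry)
  list(items = items, mobile = mobile, translocations = translocations,
       indels = indels)
}

pkg_event_keys <- function(tr) {
  sort(vapply(seq_len(nrow(tr)), function(i) {
    paste(tr$domain_name[i], tr$ko1[i], tr$ko2[i],
          paste(tr$A_star[[i]], collapse = "|"),
          paste(tr$B_star[[i]], collapse = "|"), sep = ";")
  }, character(1)), method = "radix")
}

pkg_mobile_keys <- function(mob) {
  mob <- mob[mob$is_mobile, ]
  sort(vapply(seq_len(nrow(mob)), function(i) {
    paste(mob$domain_name[i], mob$ko_number[i],
          paste(mob$A[[i]], collapse = "|"),
          paste(mob$B[[i]], collapse = "|"), sep = ";")
  }, character(1)), method = "radix")
}

pkg_indel_keys <- function(ind) {
  sort(paste(ind$domain_name, ind$ko_number, sep = ";"), method = "radix")
}

# Minimal hit-table row builder for parser/filter tests.
make_hit <- function(refseq = "XP_1", name = "SH3_1", from = 1L, to = 50L,
                     score = 50, evalue = 1e-10, acc = "PF00018",
                     clan = "CL0010") {
  tibble::tibble(refseq_id = refseq, domain_name = name, domain_acc = acc,
                 clan_id = clan, env_from = as.integer(from),
                 env_to = as.integer(to), bit_score = score,
                 e_value = evalue)
}

# One protein per organism whose content is `base` plus `dom` when the
# organism index is in `carriers`.
presence_members <- function(n_orgs, carriers, dom = "Mob",
                             ko = "K00001", base = "Base") {
  orgs <- sprintf("o%02d", seq_len(n_orgs))
  tibble::tibble(
    ko_number = ko,
    refseq_id = sprintf("XP_%s_%s", orgs, ko),
    org_id = orgs,
    domains = lapply(seq_len(n_orgs), function(i) {
      sort(c(base, if (i %in% carriers) dom), method = "radix")
    }))
}

euk_registry <- function(orgs) {
  tibble::tibble(org_id = orgs, name = orgs, superdomain = "Eukaryota",
                 taxonomy_id = seq_along(orgs), source_tags = "")
}
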