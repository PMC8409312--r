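#' Specify a synthetic proteome cohort
#'
#' Describes a fully synthetic multi-organism input set with planted
#' evolutionary events, from which [generate_cohort()] emits every input
#' dialect the package reads. Group sizes are in organisms; planted
#' translocations give the two reciprocal group sizes (|A*|, |B*|). The
#' generator pads each planted KO with shared-present organisms (domain in
#' both KOs) so the domain is mobile on both sides even when a reciprocal
#' group is deliberately undersized, and with background organisms lacking
#' the domain so the absent side stays above the mobility bound.
#'
#' @param n_eukaryota,n_bacteria,n_viruses Organisms per superdomain.
#' @param n_kos Number of KO groups (ids `K00001` ...).
#' @param domain_pool Tibble `domain_name`, `clan_id` of plantable domains.
#' @param planted_translocations Tibble `domain_name`, `ko1`, `ko2`,
#'   `size_a`, `size_b`.
#' @param planted_indels Tibble `domain_name`, `ko`, `size_a`.
#' @param planted_duplications Tibble `domain_name`, `ko`, `scheme`
#'   (`"constant"` or `"varying"` copy numbers).
#' @param paralog_rate Probability that an organism contributes a second
#'   (paralogous) protein to a KO.
#' @param ambiguity_rate Fraction of background organisms per planted
#'   domain given both a containing and a lacking paralog (ambiguous
#'   organisms, excluded from A/B under the default policy).
#' @param isoform_rate Probability that a gene carries an extra shorter
#'   isoform (removed by longest-isoform selection).
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `domarch_fixture_spec`.
#' @export
fixture_spec <- function(n_eukaryota = 12, n_bacteria = 0, n_viruses = 0,
                         n_kos = 2,
                         domain_pool = tibble(domain_name = "MobA",
                                              clan_id = "CL0001"),
                         planted_translocations = NULL,
                         planted_indels = NULL,
                         planted_duplications = NULL,
                         paralog_rate = 0, ambiguity_rate = 0,
                         isoform_rate = 0.1, seed = 1L) {
  empty_tr <- tibble(domain_name = character(), ko1 = character(),
                     ko2 = character(), size_a = integer(),
                     size_b = integer())
  empty_in <- tibble(domain_name = character(), ko = character(),
                     size_a = integer())
  empty_du <- tibble(domain_name = character(), ko = character(),
                     scheme = character())
  spec <- structure(
    list(n_eukaryota = n_eukaryota, n_bacteria = n_bacteria,
         n_viruses = n_viruses, n_kos = n_kos, domain_pool = domain_pool,
         planted_translocations = planted_translocations %||% empty_tr,
         planted_indels = planted_indels %||% empty_in,
         planted_duplications = planted_duplications %||% empty_du,
         paralog_rate = paralog_rate, ambiguity_rate = ambiguity_rate,
         isoform_rate = isoform_rate, seed = as.integer(seed)),
    class = "domarch_fixture_spec")
  spec
}

synthetic_org_codes <- function(n, prefix, upper = FALSE) {
  if (n == 0) return(character(0))
  stopifnot(n <= 26 * 26)
  suf <- expand.grid(b = letters, a = letters, stringsAsFactors = FALSE)
  codes <- paste0(prefix, suf$a, suf$b)[seq_len(n)]
  if (upper) toupper(codes) else codes
}

synthetic_registry <- function(spec) {
  tibble(
    org_id = c(synthetic_org_codes(spec$n_eukaryota, "e"),
               synthetic_org_codes(spec$n_bacteria, "b", upper = TRUE),
               synthetic_org_codes(spec$n_viruses, "v", upper = TRUE)),
    superdomain = rep(SUPERDOMAINS,
                      c(spec$n_eukaryota, spec$n_bacteria, spec$n_viruses))
  ) |>
    mutate(name = paste("Synthetic organism", .data$org_id),
           taxonomy_id = 100000L + row_number(),
           source_tags = "synthetic",
           .after = "org_id") |>
    relocate("org_id", "name", "superdomain", "taxonomy_id", "source_tags")
}

#' Generate a synthetic cohort with planted events
#'
#' Builds the four ingest inputs (organism registry, protein table, Pfam
#' hits in pfam_scan dialect, KO assignments in KoFamKOALA detail-TSV
#' dialect) plus a clan map and a manifest listing every planted event
#' with the detector output it implies. The hit table includes decoy
#' overlapping hits and duplicate domain copies so the putative /
#' unique-putative filters are exercised, a protein with two significant
#' KO assignments (dropped by the unique-KO rule) and optional short
#' isoforms (dropped by longest-isoform selection). Output is
#' deterministic under `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory; when given the ingest-dialect files are
#'   written there (`registry.tsv`, `proteins.tsv`, `pfam_hits.txt`,
#'   `koala.tsv`, `clans.tsv`, `manifest.tsv`).
#' @return A list of class `domarch_cohort` with elements `registry`,
#'   `proteins`, `hits`, `koala`, `clan_map`, `manifest`, `spec`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "domarch_fixture_spec"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(spec$seed)

  registry <- synthetic_registry(spec)
  orgs <- registry$org_id
  kos <- sprintf("K%05d", seq_len(spec$n_kos))
  planted_kos <- c(spec$planted_translocations$ko1,
                   spec$planted_translocations$ko2,
                   spec$planted_indels$ko, spec$planted_duplications$ko)
  if (length(setdiff(planted_kos, kos)) > 0) {
    abort(sprintf("planted KO '%s' outside 1..%d", setdiff(planted_kos, kos)[1],
                  spec$n_kos), class = "domarch_spec_error")
  }
  pool <- spec$domain_pool
  planted_doms <- c(spec$planted_translocations$domain_name,
                    spec$planted_indels$domain_name,
                    spec$planted_duplications$domain_name)
  if (anyDuplicated(planted_doms) > 0) {
    abort("each planted event must use a distinct domain",
          class = "domarch_spec_error")
  }
  if (length(setdiff(planted_doms, pool$domain_name)) > 0) {
    abort("planted domain missing from domain_pool",
          class = "domarch_spec_error")
  }

  # presence[[ko]][[domain]] -> list(A = containing orgs, amb = ambiguous)
  presence <- setNames(vector("list", length(kos)), kos)
  manifest <- list()

  plant_pair <- function(tr) {
    k1 <- tr$ko1; k2 <- tr$ko2; a <- tr$size_a; b <- tr$size_b
    n_pad <- max(0L, 4L - a, 4L - b)
    n_bg_min <- max(0L, 5L - a, 5L - b)
    if (a + b + n_pad + n_bg_min > length(orgs)) {
      abort(sprintf("planted translocation %s: group sizes exceed %d organisms",
                    tr$domain_name, length(orgs)),
            class = "domarch_spec_error")
    }
    core <- sample(orgs, a + b + n_pad)
    ga <- sort_c(core[seq_len(a)])
    gb <- sort_c(core[a + seq_len(b)])
    pad <- core[a + b + seq_len(n_pad)]
    rest <- setdiff(orgs, core)
    n_amb <- floor(spec$ambiguity_rate * length(rest))
    amb <- if (n_amb > 0) sample(rest, n_amb) else character(0)
    if (length(rest) - n_amb < n_bg_min) {
      abort(sprintf("planted translocation %s: %d organisms insufficient",
                    tr$domain_name, length(orgs)),
            class = "domarch_spec_error")
    }
    list(k1 = k1, k2 = k2, ga = ga, gb = gb, pad = pad, amb = amb)
  }

  for (i in seq_len(nrow(spec$planted_translocations))) {
    tr <- spec$planted_translocations[i, ]
    pl <- plant_pair(tr)
    d <- tr$domain_name
    presence[[pl$k1]][[d]] <- list(A = c(pl$ga, pl$pad), amb = pl$amb)
    presence[[pl$k2]][[d]] <- list(A = c(pl$gb, pl$pad), amb = pl$amb)
    if (tr$size_a >= 4 && tr$size_b >= 4) {
      swap <- ko_numeric(pl$k1) > ko_numeric(pl$k2)
      manifest[[length(manifest) + 1]] <- tibble(
        record = "translocation", domain_name = d,
        ko1 = if (swap) pl$k2 else pl$k1,
        ko2 = if (swap) pl$k1 else pl$k2,
        a_group = paste(if (swap) pl$gb else pl$ga, collapse = ","),
        b_group = paste(if (swap) pl$ga else pl$gb, collapse = ","),
        status = "")
    } else {
      for (kk in c(pl$k1, pl$k2)) {
        ina <- sort_c(presence[[kk]][[d]]$A)
        manifest[[length(manifest) + 1]] <- tibble(
          record = "indel", domain_name = d, ko1 = kk, ko2 = NA_character_,
          a_group = paste(ina, collapse = ","),
          b_group = paste(sort_c(setdiff(orgs, c(ina, pl$amb))), collapse = ","),
          status = "")
      }
    }
  }

  for (i in seq_len(nrow(spec$planted_indels))) {
    pi_ <- spec$planted_indels[i, ]
    d <- pi_$domain_name; a <- pi_$size_a
    ga <- sort_c(sample(orgs, a))
    rest <- setdiff(orgs, ga)
    n_amb <- floor(spec$ambiguity_rate * length(rest))
    amb <- if (n_amb > 0) sample(rest, n_amb) else character(0)
    if (a >= 4 && length(rest) - n_amb < 5) {
      abort(sprintf("planted indel %s: too few background organisms", d),
            class = "domarch_spec_error")
    }
    presence[[pi_$ko]][[d]] <- list(A = ga, amb = amb)
    if (a >= 4) {
      manifest[[length(manifest) + 1]] <- tibble(
        record = "indel", domain_name = d, ko1 = pi_$ko,
        ko2 = NA_character_, a_group = paste(ga, collapse = ","),
        b_group = paste(sort_c(setdiff(orgs, c(ga, amb))), collapse = ","),
        status = "")
    }
  }

  dup_copies <- list()  # [[ko]][[domain]] -> per-org copy counts
  for (i in seq_len(nrow(spec$planted_duplications))) {
    du <- spec$planted_duplications[i, ]
    copies <- if (du$scheme == "constant") rep(2L, length(orgs)) else
      rep_len(c(1L, 2L), length(orgs))
    dup_copies[[du$ko]][[du$domain_name]] <- setNames(copies, orgs)
    manifest[[length(manifest) + 1]] <- tibble(
      record = "duplication", domain_name = du$domain_name, ko1 = du$ko,
      ko2 = NA_character_, a_group = "", b_group = "",
      status = if (du$scheme == "constant") "nonduplicated" else "duplicated")
  }

  manifest <- if (length(manifest) > 0) bind_rows(manifest) else
    tibble(record = character(), domain_name = character(),
           ko1 = character(), ko2 = character(), a_group = character(),
           b_group = character(), status = character())

  # --- assemble proteins and hits -------------------------------------
  clan_of <- setNames(pool$clan_id, pool$domain_name)
  base_doms <- function(ko) paste0("Base", sub("^K0*", "", ko), c("A", "B"))
  proteins <- list(); hits <- list(); koala <- list()
  add_protein <- function(org, ko, idx, domains_multiset, iso_of = NULL,
                          shrink = 0L) {
    gene <- sprintf("g%s_%s", sub("^K0*", "", ko), org)
    ref <- sprintf("XP_%s_%s_%d", org, sub("^K0*", "", ko), idx)
    n_dom <- length(domains_multiset)
    len <- 80L * n_dom + 40L - shrink
    proteins[[length(proteins) + 1]] <<- tibble(
      refseq_id = ref, gene_symbol = gene, org_id = org,
      length_aa = len, chromosome = "chr1",
      strand = "+",
      isoform_group = iso_of %||%
        paste0(gene, if (idx != 1L) paste0("_", idx) else ""),
      description = "synthetic protein")
    pos <- 1L
    h <- list()
    for (j in seq_along(domains_multiset)) {
      d <- domains_multiset[j]
      h[[j]] <- tibble(refseq_id = ref, domain_name = d,
                       domain_acc = paste0("PF", sprintf("%05d", 1000 +
                         match(d, c(pool$domain_name, "DecoyOv",
                                    sort_c(unique(unlist(lapply(kos, base_doms)))))))),
                       clan_id = unname(clan_of[d]) %||% UNKNOWN_CLAN,
                       env_from = pos, env_to = pos + 49L,
                       bit_score = 60 + 2 * j, e_value = 1e-20 / j)
      pos <- pos + 60L
    }
    h <- bind_rows(h)
    h$clan_id[is.na(h$clan_id)] <- UNKNOWN_CLAN
    # decoy: lower-scoring hit overlapping the first block, filtered out
    decoy <- tibble(refseq_id = ref, domain_name = "DecoyOv",
                    domain_acc = "PF09999", clan_id = UNKNOWN_CLAN,
                    env_from = 10L, env_to = 70L, bit_score = 15,
                    e_value = 1e-3)
    hits[[length(hits) + 1]] <<- bind_rows(h, decoy)
    ref
  }
  for (ko in kos) {
    doms_here <- names(presence[[ko]])
    for (org in orgs) {
      ms <- rep(base_doms(ko), c(2L, 1L))  # duplicate first base copy
      for (d in doms_here) {
        if (org %in% presence[[ko]][[d]]$A) ms <- c(ms, d)
      }
      for (d in names(dup_copies[[ko]])) {
        ms <- c(ms, rep(d, dup_copies[[ko]][[d]][org]))
      }
      ref <- add_protein(org, ko, 1L, ms)
      koala[[length(koala) + 1]] <- tibble(
        refseq_id = ref, ko_number = ko, threshold = 50, score = 90,
        e_value = 1e-40, significant = TRUE,
        definition = paste("synthetic KO", ko))
      if (stats::runif(1) < spec$isoform_rate) {
        add_protein(org, ko, 2L, ms[-length(ms)],
                    iso_of = sprintf("g%s_%s", sub("^K0*", "", ko), org),
                    shrink = 30L)
      }
      if (stats::runif(1) < spec$paralog_rate) {
        ref2 <- add_protein(org, ko, 3L, ms)
        koala[[length(koala) + 1]] <- tibble(
          refseq_id = ref2, ko_number = ko, threshold = 50, score = 88,
          e_value = 1e-38, significant = TRUE,
          definition = paste("synthetic KO", ko))
      }
      # ambiguous organisms: containing and lacking paralogs coexist
      amb_doms <- doms_here[map_lgl(doms_here,
                                    ~ org %in% presence[[ko]][[.x]]$amb)]
      if (length(amb_doms) > 0) {
        ref3 <- add_protein(org, ko, 4L, c(rep(base_doms(ko), c(2L, 1L)),
                                           amb_doms))
        koala[[length(koala) + 1]] <- tibble(
          refseq_id = ref3, ko_number = ko, threshold = 50, score = 85,
          e_value = 1e-35, significant = TRUE,
          definition = paste("synthetic KO", ko))
      }
    }
  }
  # decoy protein with two significant KOs: dropped by unique-KO rule
  if (length(kos) >= 2) {
    ref <- add_protein(orgs[1], kos[1], 9L, base_doms(kos[1])[1])
    proteins[[length(proteins)]]$refseq_id <- "XP_multiKO"
    proteins[[length(proteins)]]$isoform_group <- "g_multiKO"
    hits[[length(hits)]]$refseq_id <- "XP_multiKO"
    for (ko in kos[1:2]) {
      koala[[length(koala) + 1]] <- tibble(
        refseq_id = "XP_multiKO", ko_number = ko, threshold = 50,
        score = 70, e_value = 1e-25, significant = TRUE,
        definition = paste("synthetic KO", ko))
    }
  }

  all_base <- sort_c(unique(unlist(lapply(kos, base_doms))))
  clan_map <- bind_rows(
    distinct(pool, .data$clan_id) |>
      mutate(clan_name = paste("Clan", .data$clan_id)),
    tibble(clan_id = UNKNOWN_CLAN, clan_name = "Unknown")
  ) |> distinct(.data$clan_id, .keep_all = TRUE)

  cohort <- structure(
    list(registry = registry,
         proteins = bind_rows(proteins),
         hits = bind_rows(hits),
         koala = bind_rows(koala),
         clan_map = clan_map,
         manifest = manifest,
         spec = spec),
    class = "domarch_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write a cohort's ingest-dialect files
#'
#' @param cohort A `domarch_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(registry = file.path(dir, "registry.tsv"),
             proteins = file.path(dir, "proteins.tsv"),
             hits = file.path(dir, "pfam_hits.txt"),
             koala = file.path(dir, "koala.tsv"),
             clans = file.path(dir, "clans.tsv"),
             manifest = file.path(dir, "manifest.tsv"))
  write_organism_registry(cohort$registry, paths["registry"])
  write_protein_table(cohort$proteins, paths["proteins"])
  write_pfam_hits(cohort$hits, paths["hits"])
  write_koala_assignments(cohort$koala, paths["koala"])
  write_tsv_plain(cohort$clan_map, paths["clans"])
  write_tsv_plain(cohort$manifest, paths["manifest"])
  invisible(paths)
}

#' Build a datastore directly from a cohort
#'
#' Runs the ingest filters (unique KO, longest isoform happens inside
#' [build_db()]) on in-memory cohort tables.
#'
#' @param cohort A `domarch_cohort` (or the list returned by
#'   [ferm_c_fixture()]).
#' @return A `domarch_db`.
#' @export
cohort_db <- function(cohort) {
  ko_map <- select_unique_ko(cohort$koala)
  build_db(cohort$registry, cohort$proteins, cohort$hits, ko_map,
           clan_map = cohort$clan_map)
}

#' The FERM_C reciprocal-translocation worked example
#'
#' A self-contained 11-organism fixture reproducing the published worked
#' example of a reciprocal domain translocation: the FERM_C domain is
#' present in the FRMD6-like orthologous group (K16822) and absent from
#' the MYLIP-like group (K10637) for organisms CAA, CHL, ECTE, ccar and
#' lav, and shows the reverse pattern for CHA, MIO, PEM, cge, ola and
#' rno. All organisms are Eukaryota, every KO contains two distinct
#' architectures, and the full pipeline finds exactly one translocation
#' event (reciprocal groups of five and six organisms, class
#' Eukaryota-Eukaryota) and no indel event for FERM_C. Protein counts per
#' organism are synthetic.
#'
#' @param dir Optional directory to write the ingest-dialect files to.
#' @return A `domarch_cohort` (see [generate_cohort()]).
#' @export
ferm_c_fixture <- function(dir = NULL) {
  side_a <- c("CAA", "CHL", "ECTE", "ccar", "lav")  # FERM_C in K16822
  side_b <- c("CHA", "MIO", "PEM", "cge", "ola", "rno")  # FERM_C in K10637
  orgs <- c(side_a, side_b)
  registry <- tibble(
    org_id = orgs,
    name = c("Carassius auratus", "Chinchilla lanigera",
             "Echinops telfairi", "Cyprinus carpio", "Loxodonta africana",
             "Chrysochloris asiatica", "Microtus ochrogaster",
             "Peromyscus maniculatus bairdii", "Cricetulus griseus",
             "Oryzias latipes", "Rattus norvegicus"),
    superdomain = "Eukaryota",
    taxonomy_id = c(7957L, 34839L, 9371L, 7962L, 9785L, 185453L, 79684L,
                    230844L, 10029L, 8090L, 10116L),
    source_tags = "worked-example")

  content <- list(
    K16822 = list(base = c("FERM_N", "FERM_M"), with_dom = side_a,
                  symbol = "FRMD6"),
    K10637 = list(base = c("FERM_N", "FERM_M", "zf-RING_2"),
                  with_dom = side_b, symbol = "MYLIP")
  )
  clan_map <- tibble(
    clan_id = c("CL0266", "CL0588", "CL0604", "CL0229", UNKNOWN_CLAN),
    clan_name = c("PH", "FERM-N", "FERM-M", "RING", "Unknown"))
  clans <- c(FERM_C = "CL0266", FERM_N = "CL0588", FERM_M = "CL0604",
             `zf-RING_2` = "CL0229")
  accs <- c(FERM_C = "PF09380", FERM_N = "PF09379", FERM_M = "PF00373",
            `zf-RING_2` = "PF13639")

  proteins <- list(); hits <- list(); koala <- list()
  for (ko in names(content)) {
    cc <- content[[ko]]
    for (org in orgs) {
      doms <- c(cc$base, if (org %in% cc$with_dom) "FERM_C")
      gene <- sprintf("%s_%s", cc$symbol, org)
      ref <- sprintf("XP_%s_%s", org, cc$symbol)
      proteins[[length(proteins) + 1]] <- tibble(
        refseq_id = ref, gene_symbol = gene, org_id = org,
        length_aa = 90L * length(doms) + 55L, chromosome = "chr2",
        strand = "+", isoform_group = gene,
        description = sprintf("%s-like protein", cc$symbol))
      pos <- 1L
      hits[[length(hits) + 1]] <- tibble(
        refseq_id = ref, domain_name = doms,
        domain_acc = unname(accs[doms]), clan_id = unname(clans[doms]),
        env_from = pos + 70L * (seq_along(doms) - 1L),
        env_to = pos + 70L * (seq_along(doms) - 1L) + 59L,
        bit_score = 65 + 3 * seq_along(doms), e_value = 1e-18)
      koala[[length(koala) + 1]] <- tibble(
        refseq_id = ref, ko_number = ko, threshold = 100, score = 250,
        e_value = 1e-80, significant = TRUE,
        definition = sprintf("%s ortholog", cc$symbol))
    }
  }
  manifest <- tibble(
    record = "translocation", domain_name = "FERM_C",
    ko1 = "K10637", ko2 = "K16822",
    a_group = paste(sort_c(side_b), collapse = ","),
    b_group = paste(sort_c(side_a), collapse = ","),
    status = "")
  cohort <- structure(
    list(registry = registry, proteins = bind_rows(proteins),
         hits = bind_rows(hits), koala = bind_rows(koala),
         clan_map = clan_map, manifest = manifest,
         spec = NULL),
    class = "domarch_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}
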