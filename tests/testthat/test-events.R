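test_that("the mobility inequality holds exactly at its boundaries", {
  # |T| = 9, |A| = 4: 4 <= 4 < 5 -> mobile
  rec9 <- mobile_domains(partition_ko(presence_members(9, 1:4)))
  expect_true(rec9$is_mobile[rec9$domain_name == "Mob"])
  # |T| = 8, |A| = 4: 4 < 4 fails -> not mobile
  rec8 <- mobile_domains(partition_ko(presence_members(8, 1:4)))
  expect_false(rec8$is_mobile[rec8$domain_name == "Mob"])
  # |A| = 3 with large |T|: lower bound fails
  rec3 <- mobile_domains(partition_ko(presence_members(20, 1:3)))
  expect_false(rec3$is_mobile[rec3$domain_name == "Mob"])
  # base domain present everywhere is never mobile
  expect_false(any(rec9$is_mobile[rec9$domain_name == "Base"]))
})

test_that("mobility calls equal the exhaustive oracle on random patterns", {
  for (seed in 1:20) {
    prot <- random_members(seed, n_orgs = 12, n_kos = 3, n_domains = 6)
    got <- run_detectors(prot)
    orc <- oracle_mobile(prot)
    expect_identical(pkg_mobile_keys(got$mobile), oracle_mobile_keys(orc))
  }
})

test_that("ambiguous organisms are excluded from A, B and T by default", {
  m <- dplyr::bind_rows(
    presence_members(10, 1:5),
    tibble::tibble(ko_number = "K00001", refseq_id = "XP_o01_par",
                   org_id = "o01", domains = list("Base")))
  rec <- mobile_domains(partition_ko(m))
  mob <- rec[rec$domain_name == "Mob", ]
  expect_equal(mob$excluded[[1]], "o01")
  expect_equal(mob$T_size, 9L)
  expect_false("o01" %in% c(mob$A[[1]], mob$B[[1]]))
  # policy override sends the organism to one side
  rec_a <- mobile_domains(partition_ko(m),
                          run_config(ambiguity_policy = "to_A"))
  expect_true("o01" %in% rec_a$A[[which(rec_a$domain_name == "Mob")]])
})

two_ko_members <- function(side_a, side_b, n_orgs = 12, dom = "Mob") {
  orgs <- sprintf("o%02d", seq_len(n_orgs))
  dplyr::bind_rows(
    presence_members(n_orgs, side_a, dom = dom, ko = "K00010",
                     base = "BaseX"),
    presence_members(n_orgs, side_b, dom = dom, ko = "K00020",
                     base = "BaseY"))
}

test_that("reciprocal groups of 4+ give a translocation, smaller give indels", {
  cfg <- run_config()
  reg <- euk_registry(sprintf("o%02d", 1:12))
  # A* = orgs 1..5 (carry in K00010), B* = orgs 6..11 (carry in K00020)
  m <- two_ko_members(1:5, 6:11)
  det <- run_detectors(dplyr::tibble(ko = m$ko_number, org = m$org_id,
                                     refseq = m$refseq_id,
                                     domains = m$domains), reg)
  expect_equal(nrow(det$translocations), 1)
  expect_equal(det$translocations$A_star[[1]], sprintf("o%02d", 1:5))
  expect_equal(det$translocations$B_star[[1]], sprintf("o%02d", 6:11))
  expect_equal(det$translocations$class_label, "Eukaryota-Eukaryota")
  expect_equal(nrow(det$indels), 0)

  # |A*| = 3: mobile on one side only via padding absent -> indel path
  m3 <- two_ko_members(1:4, 5:10)
  m3$domains[m3$ko_number == "K00010" & m3$org_id == "o04"] <-
    list(c("BaseX"))  # shrink A* to 3 in K00010
  det3 <- run_detectors(dplyr::tibble(ko = m3$ko_number, org = m3$org_id,
                                      refseq = m3$refseq_id,
                                      domains = m3$domains), reg)
  expect_equal(nrow(det3$translocations), 0)
  expect_gte(nrow(det3$indels), 1)
})

test_that("translocation and indel calls equal the exhaustive oracle", {
  for (seed in 1:20) {
    prot <- random_members(100 + seed, n_orgs = 15, n_kos = 4,
                           n_domains = 6, p_present = 0.5)
    got <- run_detectors(prot)
    orc_mob <- oracle_mobile(prot)
    orc_tr <- oracle_translocations(orc_mob)
    orc_in <- oracle_indels(orc_mob, orc_tr)
    expect_identical(pkg_event_keys(got$translocations),
                     oracle_event_keys(orc_tr))
    expect_identical(pkg_indel_keys(got$indels), oracle_indel_keys(orc_in))
  }
})

test_that("a domain mobile in a single KO yields one indel event", {
  reg <- euk_registry(sprintf("o%02d", 1:12))
  m <- presence_members(12, 1:5)
  det <- run_detectors(dplyr::tibble(ko = m$ko_number, org = m$org_id,
                                     refseq = m$refseq_id,
                                     domains = m$domains), reg)
  expect_equal(nrow(det$translocations), 0)
  expect_equal(nrow(det$indels), 1)
  expect_equal(det$indels$class_label, "Eukaryota-Eukaryota")
})

test_that("relabelling the KO pair leaves the event set invariant", {
  m <- two_ko_members(1:5, 6:11)
  reg <- euk_registry(sprintf("o%02d", 1:12))
  as_prot <- function(mm) dplyr::tibble(ko = mm$ko_number, org = mm$org_id,
                                        refseq = mm$refseq_id,
                                        domains = mm$domains)
  det1 <- run_detectors(as_prot(m), reg)
  swapped <- dplyr::mutate(m, ko_number = dplyr::recode(
    ko_number, K00010 = "K00020", K00020 = "K00010"))
  det2 <- run_detectors(as_prot(swapped), reg)
  strip_ko <- function(tr) {
    paste(tr$domain_name,
          vapply(tr$A_star, paste, "", collapse = "|"),
          vapply(tr$B_star, paste, "", collapse = "|"))
  }
  # groups swap sides with the labels; the unordered event content is equal
  expect_equal(nrow(det1$translocations), nrow(det2$translocations))
  pair1 <- list(det1$translocations$A_star[[1]],
                det1$translocations$B_star[[1]])
  pair2 <- list(det2$translocations$A_star[[1]],
                det2$translocations$B_star[[1]])
  expect_setequal(lapply(pair1, paste, collapse = "|"),
                  lapply(pair2, paste, collapse = "|"))
})

test_that("superdomain classification requires unanimity", {
  reg <- tibble::tibble(org_id = c("hsa", "mmu", "eco", "vir"),
                        name = c("human", "mouse", "ecoli", "virus"),
                        superdomain = c("Eukaryota", "Eukaryota",
                                        "Bacteria", "Viruses"),
                        taxonomy_id = 1:4, source_tags = "")
  expect_equal(superdomain_class(c("hsa", "mmu"), reg), "Eukaryota")
  expect_equal(superdomain_class(c("hsa", "eco"), reg), "Mixed")
  expect_equal(superdomain_class("vir", reg), "Viruses")
  expect_error(superdomain_class(character(0), reg),
               class = "domarch_contract_error")
  expect_error(superdomain_class(c("hsa", "zzz"), reg),
               class = "domarch_lookup_error")
  # permutation invariance
  set.seed(8)
  for (i in 1:5) {
    orgs <- sample(c("hsa", "mmu", "eco"))
    expect_equal(superdomain_class(orgs, reg),
                 superdomain_class(rev(orgs), reg))
  }
})

test_that("mobile records split exactly into translocation and indel domains", {
  for (seed in c(3, 17, 23)) {
    prot <- random_members(seed, n_orgs = 14, n_kos = 5, n_domains = 7,
                           p_present = 0.45)
    det <- run_detectors(prot)
    mobile_doms <- unique(det$mobile$domain_name[det$mobile$is_mobile])
    tr_doms <- unique(det$translocations$domain_name)
    in_doms <- unique(det$indels$domain_name)
    expect_length(intersect(tr_doms, in_doms), 0)
    expect_setequal(c(tr_doms, in_doms), mobile_doms)
  }
})

test_that("superfamily summaries count events and conserve totals", {
  db <- cohort_db(ferm_c_fixture())
  ev <- run_pipeline(db)
  counts <- summarize_by_superfamily(ev$translocations, db)
  expect_equal(sum(counts$n), nrow(ev$translocations))
  expect_equal(counts$clan_id, "CL0266")

  empty <- summarize_by_superfamily(ev$translocations[0, ], db)
  expect_equal(nrow(empty), 0)

  fake <- tibble::tibble(
    domain_name = c("FERM_C", "FERM_C", "FERM_C", "zf-RING_2"),
    class_label = "Eukaryota-Eukaryota")
  sm <- summarize_by_superfamily(fake, db)
  expect_equal(sm$n, c(3L, 1L))
  expect_equal(sum(sm$n), nrow(fake))
})
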