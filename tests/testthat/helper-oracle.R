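# Independent exhaustive implementation of the mobility / translocation /
# indel inequalities, written with plain base-R loops over every
# (domain, organism) and (domain, KO-pair) combination. Used as the oracle
# the package detectors are compared against; shares no code with them.
#
# `prot` is a data.frame with columns ko, org, refseq and a list column
# `domains` (unique domain names per protein).

oracle_mobile <- function(prot, g = 4) {
  out <- list()
  for (ko in unique(prot$ko)) {
    sub <- prot[prot$ko == ko, ]
    doms <- unique(unlist(sub$domains))
    for (d in doms) {
      A <- character(0); B <- character(0); excl <- character(0)
      for (org in unique(sub$org)) {
        sets <- sub$domains[sub$org == org]
        has <- vapply(sets, function(s) d %in% s, logical(1))
        if (all(has)) A <- c(A, org)
        else if (all(!has)) B <- c(B, org)
        else excl <- c(excl, org)
      }
      t_size <- length(A) + length(B)
      out[[length(out) + 1]] <- list(
        domain = d, ko = ko,
        A = sort(A, method = "radix"), B = sort(B, method = "radix"),
        excluded = sort(excl, method = "radix"),
        mobile = (length(A) >= g) && (length(A) < t_size - g))
    }
  }
  out
}

oracle_translocations <- function(mobile_records, g = 4) {
  recs <- Filter(function(r) r$mobile, mobile_records)
  events <- list()
  doms <- unique(vapply(recs, `[[`, character(1), "domain"))
  for (d in doms) {
    rd <- Filter(function(r) r$domain == d, recs)
    if (length(rd) < 2) next
    kos <- vapply(rd, `[[`, character(1), "ko")
    ord <- order(as.integer(sub("^K", "", kos)))
    rd <- rd[ord]
    for (i in seq_along(rd)) {
      for (j in seq_along(rd)) {
        if (i >= j) next
        a_star <- intersect(rd[[i]]$A, rd[[j]]$B)
        b_star <- intersect(rd[[j]]$A, rd[[i]]$B)
        if (length(a_star) >= g && length(b_star) >= g) {
          events[[length(events) + 1]] <- list(
            domain = d, ko1 = rd[[i]]$ko, ko2 = rd[[j]]$ko,
            A_star = sort(a_star, method = "radix"),
            B_star = sort(b_star, method = "radix"))
        }
      }
    }
  }
  events
}

oracle_indels <- function(mobile_records, events) {
  transloc_doms <- unique(vapply(events, `[[`, character(1), "domain"))
  out <- Filter(function(r) r$mobile && !(r$domain %in% transloc_doms),
                mobile_records)
  out
}

# Flat keys for comparisons
oracle_event_keys <- function(events) {
  sort(vapply(events, function(e) {
    paste(e$domain, e$ko1, e$ko2,
          paste(e$A_star, collapse = "|"),
          paste(e$B_star, collapse = "|"), sep = ";")
  }, character(1)), method = "radix")
}

oracle_mobile_keys <- function(mobile_records) {
  recs <- Filter(function(r) r$mobile, mobile_records)
  sort(vapply(recs, function(r) {
    paste(r$domain, r$ko,
          paste(r$A, collapse = "|"), paste(r$B, collapse = "|"), sep = ";")
  }, character(1)), method = "radix")
}

oracle_indel_keys <- function(indels) {
  sort(vapply(indels, function(r) paste(r$domain, r$ko, sep = ";"),
              character(1)), method = "radix")
}
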