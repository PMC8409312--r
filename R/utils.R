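# Internal helpers shared across modules.

SUPERDOMAINS <- c("Eukaryota", "Bacteria", "Viruses")

# Sentinel clan id for Pfam families without a clan ("No_clan").
UNKNOWN_CLAN <- "9999.0"

# Locale-independent (C collation) sort, so outputs are byte-stable
# across platforms.
sort_c <- function(x) sort(x, method = "radix")

stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "domarch_format_error")
}

stop_contract <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "domarch_contract_error")
}

stop_integrity <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "domarch_integrity_error")
}

# Numeric part of a KO id ("K10637" -> 10637); used to orient KO pairs.
ko_numeric <- function(ko) {
  as.integer(sub("^[Kk]", "", ko))
}

is_valid_org_id <- function(x) grepl("^[A-Za-z]{3,4}$", x)

# Canonical key for an unordered domain set.
domain_set_key <- function(domains) {
  paste(sort_c(unique(domains)), collapse = ",")
}

# readr wrapper: plain TSV with header, no progress/type noise.
read_tsv_quiet <- function(path, col_types = readr::cols(.default = readr::col_character())) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  na = character())
}

write_tsv_plain <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
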