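# Independent brute-force oracles, deliberately naive: plain loops and
# substring comparison, no shared code with the package internals.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

oracle_hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  sum(va != vb)
}

# number of forward-strand windows of seq equal to q or revcomp(q)
# (the canonical-count semantics: one count per double-stranded site)
oracle_kmer_count <- function(seq, q, circular = FALSE) {
  k <- nchar(q)
  scan <- if (circular) paste0(seq, substr(seq, 1, k - 1)) else seq
  qrc <- oracle_revcomp(q)
  hits <- 0
  for (i in seq_len(nchar(scan) - k + 1)) {
    w <- substr(scan, i, i + k - 1)
    if (grepl("N", w, fixed = TRUE)) next
    if (w == q || w == qrc) hits <- hits + 1
  }
  hits
}

# all PAM-prefixed 23-mers of both strands with their Hamming distance to a
# protospacer; returns a data.frame(fwd_start, strand, prefix, dist)
oracle_tier_scan <- function(seq, proto, prefixes = c("CC", "CT", "TC"),
                             circular = FALSE) {
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    scan <- if (circular) paste0(s, substr(s, 1, 22)) else s
    nstart <- if (circular) L else L - 22
    for (i in seq_len(max(nstart, 0))) {
      w <- substr(scan, i, i + 22)
      if (nchar(w) < 23 || grepl("N", w, fixed = TRUE)) next
      pre <- substr(w, 1, 2)
      if (!pre %in% prefixes) next
      fwd_start <- if (strand == "+") i - 1 else (L - (i - 1) - 23) %% L
      out[[length(out) + 1]] <- data.frame(
        fwd_start = fwd_start, strand = strand, prefix = pre,
        dist = oracle_hamming(substr(w, 4, 23), proto),
        win23 = w)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(fwd_start = integer(0), strand = character(0),
               prefix = character(0), dist = integer(0), win23 = character(0))
}

# full oracle off-target profile of one candidate
oracle_profile <- function(seq, site23, site_start, site_strand,
                           circular = FALSE) {
  proto <- substr(site23, 4, 23)
  sc <- oracle_tier_scan(seq, proto, circular = circular)
  self <- sc$fwd_start == site_start & sc$strand == site_strand
  scx <- sc[!self, ]
  rem8 <- substr(site23, 3, 10)
  rem13 <- substr(site23, 3, 15)
  list(
    n_region1_cc = oracle_kmer_count(seq, substr(site23, 1, 10), circular),
    n_region1_nearpam = oracle_kmer_count(seq, paste0("CT", rem8), circular) +
      oracle_kmer_count(seq, paste0("TC", rem8), circular),
    n_region12_cc = oracle_kmer_count(seq, substr(site23, 1, 15), circular),
    n_region12_nearpam = oracle_kmer_count(seq, paste0("CT", rem13), circular) +
      oracle_kmer_count(seq, paste0("TC", rem13), circular),
    n_exact23 = oracle_kmer_count(seq, site23, circular),
    n_mm1 = sum(scx$dist == 1), n_mm2 = sum(scx$dist == 2),
    n_mm3 = sum(scx$dist == 3), n_mm4 = sum(scx$dist == 4))
}

random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

random_spacer <- function(seed) random_dna(20, seed)
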