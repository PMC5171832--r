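#' Parameters of the guide-design screen
#'
#' Defaults encode the published screen: candidate sites are CC-prefixed
#' 23-mers (PAM trinucleotide `CCN` + 20-nt protospacer) whose first base lies
#' within 150 nt of the start codon; specificity is tested at the three screen
#' lengths 10 = CC + N + 7 (region I), 15 = CC + N + 12 (regions I+II) and 23,
#' with CT/TC near-PAM variants, plus Hamming mismatch tiers 1-4 over the
#' 20-nt protospacer (mismatches outside the PAM; the PAM N is a free
#' position).
#'
#' @param window_nt Maximum offset (nt) of a site's first base from the A of
#'   the start codon, 0-based. Default 150.
#' @param region1_len,region12_len PAM-proximal segment lengths (7 and 12 nt).
#' @param pam_prefix Dinucleotide anchoring a full-strength PAM on the scanned
#'   strand (`"CC"`, the reverse-strand reading of N-G-G).
#' @param near_pam_prefixes Weak-PAM dinucleotides (`"CT"`, `"TC"`; N-A-G and
#'   N-G-A read on the opposite strand).
#' @param site_len Full site length (23 = 3 + 20).
#' @param kmer_lens Index lengths used for exact-abundance tiers.
#' @param max_outside_pam_mm Mismatch count beyond which a candidate is no
#'   longer removed (removal uses exact, 1- and 2-mismatch tiers).
#' @param deep_mm_tiers Reported-only deep mismatch tiers.
#' @param scan_both_strands Also enumerate candidates on the template strand
#'   of each ORF window. Default `FALSE`: CRISPRi efficacy is strand-dependent
#'   and the screen reads the coding strand.
#' @param spacer_as_revcomp Hand the oligo builder the reverse complement of
#'   the genomic protospacer (the sequence that base-pairs as the sgRNA spacer
#'   in the N-G-G frame). Set `FALSE` to emit the protospacer verbatim;
#'   cassette orientation is strain-specific, so the choice is recorded in
#'   output headers.
#' @return A list of class `design_params`.
#' @export
design_params <- function(window_nt = 150L,
                          region1_len = 7L,
                          region12_len = 12L,
                          pam_prefix = "CC",
                          near_pam_prefixes = c("CT", "TC"),
                          site_len = 23L,
                          kmer_lens = c(10L, 15L, 23L),
                          max_outside_pam_mm = 2L,
                          deep_mm_tiers = c(3L, 4L),
                          scan_both_strands = FALSE,
                          spacer_as_revcomp = TRUE) {
  stopifnot(region1_len < region12_len, region12_len < site_len - 3L,
            nchar(pam_prefix) == 2L, all(nchar(near_pam_prefixes) == 2L))
  structure(list(
    window_nt = as.integer(window_nt), region1_len = as.integer(region1_len),
    region12_len = as.integer(region12_len), pam_prefix = pam_prefix,
    near_pam_prefixes = near_pam_prefixes, site_len = as.integer(site_len),
    kmer_lens = as.integer(kmer_lens),
    max_outside_pam_mm = as.integer(max_outside_pam_mm),
    deep_mm_tiers = as.integer(deep_mm_tiers),
    scan_both_strands = isTRUE(scan_both_strands),
    spacer_as_revcomp = isTRUE(spacer_as_revcomp)), class = "design_params")
}

#' @export
print.design_params <- function(x, ...) {
  cat("<design_params>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, paste(x[[nm]], collapse = ",")))
  invisible(x)
}

# 0-based half-open substring with circular wrap (b may exceed L)
substr_wrap <- function(seq, a, b, circular) {
  L <- nchar(seq)
  if (a < 0L) { a <- a + L; b <- b + L }
  if (b <= L) return(substr(seq, a + 1L, b))
  if (!circular) abort("interval runs past the end of a linear genome",
                       class = "guidescreenr_bounds_error")
  paste0(substr(seq, a + 1L, L), substr(seq, 1L, b - L))
}

#' Enumerate CC-prefixed candidate sites for validated ORFs
#'
#' Scans each valid ORF's coding strand from the start codon for positions
#' whose dinucleotide is the PAM prefix, keeping sites whose first base is
#' within `window_nt` of the start codon, starts inside the ORF, and whose
#' full 23-mer fits in the genome (it may cross the ORF 3' boundary). With
#' `scan_both_strands`, template-strand sites over the same window are added;
#' their offset is the coding-strand offset of the site's start-codon-proximal
#' base.
#'
#' @param orfs Validated ORF tibble (rows with `validation != "valid"` are
#'   rejected unless dropped first; pass only validated tables).
#' @param genome Single-record genome tibble.
#' @param params A [design_params()] list.
#' @return Tibble of candidates: `gene`, `offset_nt`, `scanned_strand`,
#'   `site_strand`, `site_start` (0-based forward coordinate of the 23-mer),
#'   `site23`, `pam3`, `region1`, `region2`, `protospacer20`,
#'   `spacer_for_cassette`; increasing offset within gene.
#' @export
enumerate_candidates <- function(orfs, genome, params = design_params()) {
  if (any(is.na(orfs$validation))) {
    abort("ORFs must be validated first; run validate_orfs()")
  }
  if (any(orfs$validation != "valid")) {
    abort("enumerate_candidates() accepts only ORFs with validation == 'valid'")
  }
  seq <- the_sequence(genome)
  L <- nchar(seq)
  circular <- genome$circular[[1]]
  rows <- purrr::pmap(orfs, function(gene, start, end, strand, ...) {
    enumerate_one(gene, start, end, strand, seq, L, circular, params)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(empty_candidates())
  out$spacer_for_cassette <- if (params$spacer_as_revcomp)
    dna_revcomp(out$protospacer20) else out$protospacer20
  out
}

empty_candidates <- function() {
  tibble(gene = character(0), offset_nt = integer(0),
         scanned_strand = character(0), site_strand = character(0),
         site_start = integer(0), site23 = character(0), pam3 = character(0),
         region1 = character(0), region2 = character(0),
         protospacer20 = character(0), spacer_for_cassette = character(0))
}

enumerate_one <- function(gene, start, end, strand, seq, L, circular, params) {
  slen <- params$site_len
  orf_len <- end - start
  maxo <- min(params$window_nt, orf_len - 1L)
  if (!circular) {
    bound <- if (strand == "+") L - start - slen else end - slen
    maxo <- min(maxo, bound)
  }
  if (maxo < 0L) return(NULL)
  S <- if (strand == "+") {
    substr_wrap(seq, start, start + maxo + slen, circular)
  } else {
    dna_revcomp(substr_wrap(seq, end - (maxo + slen), end, circular))
  }
  len <- nchar(S)
  cands <- scan_string_for_sites(S, maxo, params)
  res <- list()
  if (nrow(cands)) {
    res$coding <- dplyr::mutate(
      cands, scanned_strand = "coding", site_strand = strand,
      site_start = if (strand == "+") (start + .data$offset_nt) %% L
                   else (end - .data$offset_nt - slen) %% L)
  }
  if (params$scan_both_strands) {
    Tc <- dna_revcomp(S)
    tc <- scan_string_for_sites(Tc, len - slen, params)
    if (nrow(tc)) {
      # template offset -> coding offset of the site's ORF-proximal base
      j <- tc$offset_nt
      off <- len - slen - j
      keep <- off <= maxo
      tc <- tc[keep, , drop = FALSE]; off <- off[keep]
      if (nrow(tc)) {
        tc$offset_nt <- off
        res$template <- dplyr::mutate(
          tc, scanned_strand = "template",
          site_strand = if (strand == "+") "-" else "+",
          site_start = if (strand == "+") (start + .data$offset_nt) %% L
                       else (end - .data$offset_nt - slen) %% L)
      }
    }
  }
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) return(NULL)
  out <- dplyr::mutate(out, gene = gene)
  dplyr::arrange(out, .data$offset_nt, .data$scanned_strand) |>
    dplyr::relocate("gene")
}

scan_string_for_sites <- function(S, maxo, params) {
  slen <- params$site_len
  if (maxo < 0L || nchar(S) < slen) {
    return(tibble(offset_nt = integer(0), site23 = character(0),
                  pam3 = character(0), region1 = character(0),
                  region2 = character(0), protospacer20 = character(0)))
  }
  offs <- 0:maxo
  pre <- stringi::stri_sub(S, offs + 1L, offs + 2L)
  offs <- offs[pre == params$pam_prefix]
  site23 <- stringi::stri_sub(S, offs + 1L, offs + slen)
  keep <- !stringi::stri_detect_fixed(site23, "N") & nchar(site23) == slen
  offs <- offs[keep]; site23 <- site23[keep]
  tibble(
    offset_nt = as.integer(offs),
    site23 = site23,
    pam3 = substr(site23, 1L, 3L),
    region1 = substr(site23, 4L, 3L + params$region1_len),
    region2 = substr(site23, 4L + params$region1_len, 3L + params$region12_len),
    protospacer20 = substr(site23, 4L, slen))
}

# All PAM-prefixed 23-nt windows of both genome strands:
# tibble(site_strand, fwd_start, prefix, win20). Windows containing N skipped.
scan_prefix_windows <- function(genome, params = design_params()) {
  seq <- the_sequence(genome)
  L <- nchar(seq)
  circular <- genome$circular[[1]]
  slen <- params$site_len
  prefixes <- c(params$pam_prefix, params$near_pam_prefixes)
  one_strand <- function(s) {
    scan <- if (circular) paste0(s, substr(s, 1L, slen - 1L)) else s
    n_start <- if (circular) L else L - slen + 1L
    if (n_start < 1L) return(NULL)
    starts <- seq_len(n_start)
    pre <- stringi::stri_sub(scan, starts, starts + 1L)
    keep <- pre %in% prefixes
    starts <- starts[keep]; pre <- pre[keep]
    win <- stringi::stri_sub(scan, starts + 3L, starts + slen - 1L)
    ok <- !stringi::stri_detect_fixed(win, "N") &
      substr(scan, starts + 2L, starts + 2L) != "N"
    tibble(pos = starts[ok] - 1L, prefix = pre[ok], win20 = win[ok])
  }
  fwd <- one_strand(seq)
  rev <- one_strand(dna_revcomp(seq))
  out <- list()
  if (!is.null(fwd) && nrow(fwd)) {
    out$f <- dplyr::mutate(fwd, site_strand = "+", fwd_start = .data$pos)
  }
  if (!is.null(rev) && nrow(rev)) {
    out$r <- dplyr::mutate(rev, site_strand = "-",
                           fwd_start = (L - .data$pos - slen) %% L)
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    return(tibble(site_strand = character(0), fwd_start = integer(0),
                  prefix = character(0), win20 = character(0)))
  }
  dplyr::select(res, "site_strand", "fwd_start", "prefix", "win20")
}

#' Genome-wide off-target profile of candidate sites
#'
#' For each candidate, exact-abundance tiers come from canonical k-mer index
#' lookups: the CC-prefixed 10-, 15- and 23-mer of the site, plus the CT- and
#' TC-prefixed variants of the 10- and 15-mer (prefix substituted, remainder
#' kept). Mismatch tiers 1-4 come from a windowed scan of both genome strands
#' for PAM-prefixed (CC/CT/TC) 23-mers whose 20-nt protospacer lies at exactly
#' that Hamming distance from the candidate's protospacer; the candidate's own
#' genomic site is excluded from the mismatch tiers and included in
#' `n_exact23` (a unique guide has `n_exact23 == 1`).
#'
#' @param candidates Candidate tibble from [enumerate_candidates()].
#' @param genome Single-record genome tibble (the one the candidates came
#'   from).
#' @param indices Optional named list of `kmer_index` objects keyed by k
#'   (`"10"`, `"15"`, `"23"`); built on the fly when `NULL`.
#' @param params A [design_params()] list.
#' @return The candidate tibble with profile columns `n_region1_cc`,
#'   `n_region1_nearpam`, `n_region12_cc`, `n_region12_nearpam`, `n_exact23`,
#'   `n_mm1` .. `n_mm4` appended.
#' @export
off_target_profile <- function(candidates, genome, indices = NULL,
                               params = design_params()) {
  if (!nrow(candidates)) {
    return(dplyr::bind_cols(candidates, profile_cols(0L)))
  }
  if (is.null(indices)) {
    indices <- build_screen_indices(genome, params)
  }
  need <- as.character(params$kmer_lens)
  if (!all(need %in% names(indices))) {
    abort(sprintf("missing k-mer index for k in {%s}",
                  paste(setdiff(need, names(indices)), collapse = ",")))
  }
  i10 <- indices[["10"]]; i15 <- indices[["15"]]; i23 <- indices[["23"]]
  rem8 <- substr(candidates$site23, 3L, 10L)
  rem13 <- substr(candidates$site23, 3L, 15L)
  near <- params$near_pam_prefixes
  n_region1_cc <- kmer_count(i10, substr(candidates$site23, 1L, 10L))
  n_region1_nearpam <- Reduce(`+`, lapply(near, function(p)
    kmer_count(i10, paste0(p, rem8))))
  n_region12_cc <- kmer_count(i15, substr(candidates$site23, 1L, 15L))
  n_region12_nearpam <- Reduce(`+`, lapply(near, function(p)
    kmer_count(i15, paste0(p, rem13))))
  n_exact23 <- kmer_count(i23, candidates$site23)

  wins <- scan_prefix_windows(genome, params)
  mm <- purrr::pmap(
    list(candidates$protospacer20, candidates$site_start,
         candidates$site_strand),
    function(proto, sstart, sstrand) {
      d <- hamming_vec(wins$win20, proto)
      self <- wins$fwd_start == sstart & wins$site_strand == sstrand
      d <- d[!self]
      c(n_mm1 = sum(d == 1L), n_mm2 = sum(d == 2L),
        n_mm3 = sum(d == 3L), n_mm4 = sum(d == 4L))
    })
  mm <- do.call(rbind, mm)
  dplyr::bind_cols(
    candidates,
    tibble(n_region1_cc = n_region1_cc, n_region1_nearpam = n_region1_nearpam,
           n_region12_cc = n_region12_cc,
           n_region12_nearpam = n_region12_nearpam,
           n_exact23 = n_exact23,
           n_mm1 = as.integer(mm[, "n_mm1"]), n_mm2 = as.integer(mm[, "n_mm2"]),
           n_mm3 = as.integer(mm[, "n_mm3"]), n_mm4 = as.integer(mm[, "n_mm4"])))
}

profile_cols <- function(n) {
  tibble(n_region1_cc = integer(n), n_region1_nearpam = integer(n),
         n_region12_cc = integer(n), n_region12_nearpam = integer(n),
         n_exact23 = integer(n), n_mm1 = integer(n), n_mm2 = integer(n),
         n_mm3 = integer(n), n_mm4 = integer(n))
}

#' Build the three screen k-mer indices
#'
#' @param genome Single-record genome tibble.
#' @param params A [design_params()] list.
#' @param circular Optional circularity override.
#' @return Named list of `kmer_index` objects keyed by k.
#' @export
build_screen_indices <- function(genome, params = design_params(),
                                 circular = NULL) {
  setNames(lapply(params$kmer_lens, function(k)
    build_kmer_index(genome, k, circular = circular)),
    as.character(params$kmer_lens))
}

#' Filter and rank profiled candidates
#'
#' Removes candidates with any exact duplicate elsewhere in the genome
#' (`n_exact23 > 1`) or any 1- or 2-mismatch site; sorts survivors by
#' increasing region I abundance (`n_region1_cc + n_region1_nearpam`), ties
#' broken by increasing offset. Output order is deterministic and invariant
#' to input permutation.
#'
#' @param profiled Tibble from [off_target_profile()].
#' @return Tibble of surviving candidates, ranked within gene, with
#'   `region1_total` and `rank` columns.
#' @export
filter_and_rank <- function(profiled) {
  need <- c("n_exact23", "n_mm1", "n_mm2", "n_region1_cc", "n_region1_nearpam")
  if (!all(need %in% names(profiled))) {
    abort("filter_and_rank() needs a profiled candidate table; run off_target_profile()")
  }
  profiled |>
    dplyr::mutate(region1_total = .data$n_region1_cc + .data$n_region1_nearpam) |>
    dplyr::filter(.data$n_exact23 <= 1L, .data$n_mm1 == 0L, .data$n_mm2 == 0L) |>
    dplyr::arrange(.data$gene, .data$region1_total, .data$offset_nt) |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Least abundant region I site per gene
#'
#' For each gene, the candidate whose 10-mer (PAM + N + region I) has minimal
#' total region I abundance (CC + CT/TC); ties go to the smaller offset.
#'
#' @param profiled Tibble from [off_target_profile()].
#' @return Tibble: `gene`, `region1_site10`, `region1_total`, `offset_nt`.
#' @export
least_abundant_region1 <- function(profiled) {
  if (!nrow(profiled)) {
    return(tibble(gene = character(0), region1_site10 = character(0),
                  region1_total = integer(0), offset_nt = integer(0)))
  }
  profiled |>
    dplyr::mutate(region1_total = .data$n_region1_cc + .data$n_region1_nearpam,
                  region1_site10 = substr(.data$site23, 1L, 10L)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::arrange(.data$region1_total, .data$offset_nt, .by_group = TRUE) |>
    dplyr::slice_head(n = 1L) |>
    dplyr::ungroup() |>
    dplyr::select("gene", "region1_site10", "region1_total", "offset_nt")
}

#' Run the whole guide-design screen over a genome
#'
#' Composes validation, candidate enumeration, off-target profiling,
#' filtering and ranking for every annotated ORF, and reports one row per
#' gene: the top-ranked sgRNA (if any), its full off-target profile, and the
#' least-abundant region I site. Genes failing ORF validation carry their
#' failure class; genes whose candidates are all removed are flagged
#' `"no qualifying sgRNA"`.
#'
#' @param genome Single-record genome tibble.
#' @param orfs ORF tibble (validated or not; validation is (re)computed).
#' @param params A [design_params()] list.
#' @param indices Optional prebuilt screen indices.
#' @return A per-gene design tibble.
#' @export
design_genome <- function(genome, orfs, params = design_params(),
                          indices = NULL) {
  orfs <- validate_orfs(orfs, genome)
  valid <- dplyr::filter(orfs, .data$validation == "valid")
  cands <- enumerate_candidates(valid, genome, params)
  profiled <- off_target_profile(cands, genome, indices, params)
  ranked <- filter_and_rank(profiled)
  least <- least_abundant_region1(profiled)

  n_cand <- dplyr::count(profiled, .data$gene, name = "n_candidates")
  n_kept <- dplyr::count(ranked, .data$gene, name = "n_retained")
  top <- ranked |>
    dplyr::filter(.data$rank == 1L) |>
    dplyr::select("gene", selected_offset_nt = "offset_nt",
                  selected_site23 = "site23",
                  selected_spacer = "spacer_for_cassette",
                  "n_region1_cc", "n_region1_nearpam", "n_region12_cc",
                  "n_region12_nearpam", "n_exact23", "n_mm1", "n_mm2",
                  "n_mm3", "n_mm4", "region1_total")
  out <- orfs |>
    dplyr::select("gene", "validation") |>
    dplyr::left_join(n_cand, by = "gene") |>
    dplyr::left_join(n_kept, by = "gene") |>
    dplyr::left_join(top, by = "gene") |>
    dplyr::left_join(dplyr::select(least, "gene",
                                   least_region1_site10 = "region1_site10",
                                   least_region1_total = "region1_total"),
                     by = "gene") |>
    dplyr::mutate(
      n_candidates = dplyr::coalesce(.data$n_candidates, 0L),
      n_retained = dplyr::coalesce(.data$n_retained, 0L),
      status = dplyr::case_when(
        .data$validation != "valid" ~ .data$validation,
        .data$n_retained == 0L ~ "no qualifying sgRNA",
        TRUE ~ "ok"))
  dplyr::relocate(out, "status", .after = "validation")
}

#' Write a design table as TSV with a provenance header
#'
#' `#`-prefixed header lines record package version and screen parameters so
#' outputs are self-describing and diffable.
#'
#' @param design Tibble from [design_genome()].
#' @param path Output path.
#' @param params The [design_params()] used (echoed into the header).
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(design, path, params = design_params()) {
  hdr <- c(
    sprintf("# guidescreenr %s design table", as.character(packageVersion("guidescreenr"))),
    sprintf("# window_nt=%d site_len=%d pam_prefix=%s near_pam=%s",
            params$window_nt, params$site_len, params$pam_prefix,
            paste(params$near_pam_prefixes, collapse = ",")),
    sprintf("# scan_both_strands=%s spacer_as_revcomp=%s",
            params$scan_both_strands, params$spacer_as_revcomp))
  writeLines(hdr, path)
  readr::write_tsv(design, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
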