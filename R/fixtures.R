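#' Specify sites to plant in a synthetic genome
#'
#' Helper building the `planted_sites` table for [make_genome()]. Each row
#' plants one PAM-prefixed 23-nt site (`prefix + pam_n + 20-mer`) whose
#' 20-mer differs from `spacer` at exactly `n_mismatches` positions (sampled
#' within the 20-mer, hence always outside the PAM and the free N position).
#'
#' @param spacer 20-nt reference protospacer(s).
#' @param prefix PAM dinucleotide: `"CC"`, `"CT"` or `"TC"`.
#' @param n_mismatches 0-4 mismatches to plant.
#' @param host Gene name to plant inside (`NA` = intergenic).
#' @param strand Strand on which the site reads 5'-prefix...-3'.
#' @param pam_n The free PAM base (position 3); `NA` = randomised. Exact
#'   duplicates of a site must share `pam_n` to be duplicates of the full
#'   23-mer.
#' @param host_offset Offset of the site's first base from the host gene
#'   start (`NA` = randomised within the gene interior).
#' @return A tibble usable as `planted_sites`.
#' @export
planted_site <- function(spacer, prefix = "CC", n_mismatches = 0L,
                         host = NA_character_, strand = "+",
                         pam_n = NA_character_, host_offset = NA_integer_) {
  tibble(spacer = toupper(spacer), prefix = prefix,
         n_mismatches = as.integer(n_mismatches), host = host,
         strand = strand, pam_n = pam_n,
         host_offset = as.integer(host_offset))
}

#' Generate a synthetic annotated genome with planted guide sites
#'
#' Builds a random genome carrying non-overlapping forward-strand ORFs with
#' NTG starts and TAG/TGA/TAA stops; a requested number of ORFs violate
#' exactly one validation rule (alternating bad start / bad stop). Sites from
#' `planted_sites` are then written into gene interiors or intergenic gaps
#' with exactly the requested mismatch structure relative to their spacer.
#' All randomness flows from `seed`; the same seed gives byte-identical
#' output.
#'
#' @param genome_length Genome size in nt.
#' @param n_orfs Number of ORFs.
#' @param n_invalid_orfs How many ORFs violate one validation rule.
#' @param planted_sites Tibble from [planted_site()], or `NULL`.
#' @param circular Circular replicon flag.
#' @param seed Integer seed.
#' @param orf_len_range ORF length range in nt (rounded to codons).
#' @param id Genome record id.
#' @return A list: `genome` (genome tibble), `orfs` (ORF tibble, validation
#'   unset), `orf_truth` (gene, expected_validation), `site_truth` (one row
#'   per planted site: spacer, prefix, n_mismatches, strand, fwd_start,
#'   host, site23).
#' @export
make_genome <- function(genome_length = 5000L, n_orfs = 6L,
                        n_invalid_orfs = 0L, planted_sites = NULL,
                        circular = FALSE, seed = 1L,
                        orf_len_range = c(120L, 300L), id = "synthetic") {
  stopifnot(n_invalid_orfs <= n_orfs)
  withr::with_seed(seed, {
    starts_ok <- c("ATG", "GTG", "TTG", "CTG")
    stops_ok <- c("TAG", "TGA", "TAA")
    base <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)

    # lay ORFs left to right with random intergenic gaps
    lens <- 3L * sample(seq(orf_len_range[1] %/% 3L, orf_len_range[2] %/% 3L),
                        n_orfs, replace = TRUE)
    gaps <- sample(40:90, n_orfs, replace = TRUE)
    starts <- cumsum(gaps) + c(0L, cumsum(lens))[seq_len(n_orfs)]
    ends <- starts + lens
    if (n_orfs > 0 && max(ends) + 40L > genome_length) {
      abort(sprintf("infeasible packing: %d ORFs need %d nt, genome is %d nt",
                    n_orfs, max(ends) + 40L, genome_length),
            class = "guidescreenr_generation_error")
    }
    invalid <- if (n_invalid_orfs > 0) sort(sample(n_orfs, n_invalid_orfs)) else integer(0)
    expected <- rep("valid", n_orfs)
    genes <- sprintf("gene%03d", seq_len(n_orfs))
    for (i in seq_len(n_orfs)) {
      codon_start <- sample(starts_ok, 1)
      codon_stop <- sample(stops_ok, 1)
      if (i %in% invalid) {
        if (match(i, invalid) %% 2L == 1L) {
          codon_start <- "ATT"   # not an NTG start
          expected[i] <- "failed_start"
        } else {
          codon_stop <- "AAA"    # not a stop
          expected[i] <- "failed_stop"
        }
      }
      body <- sample(c("A", "C", "G", "T"), lens[i] - 6L, replace = TRUE)
      orf_seq <- c(strsplit(codon_start, "")[[1]], body,
                   strsplit(codon_stop, "")[[1]])
      base[(starts[i] + 1L):ends[i]] <- orf_seq
    }
    orfs <- orf_record(genes, starts, ends, strand = rep("+", n_orfs))

    # plant sites
    occupied <- logical(genome_length)
    if (n_orfs > 0) {
      for (i in seq_len(n_orfs)) {
        occupied[(starts[i] + 1L):ends[i]] <- TRUE
      }
    }
    site_truth <- tibble(spacer = character(0), prefix = character(0),
                         n_mismatches = integer(0), strand = character(0),
                         fwd_start = integer(0), host = character(0),
                         site23 = character(0))
    planted_occ <- logical(genome_length)
    if (!is.null(planted_sites) && nrow(planted_sites)) {
      for (r in seq_len(nrow(planted_sites))) {
        ps <- planted_sites[r, ]
        pam_n <- if (is.na(ps$pam_n)) sample(c("A", "C", "G", "T"), 1) else ps$pam_n
        proto <- strsplit(ps$spacer, "")[[1]]
        if (ps$n_mismatches > 0) {
          pos <- sample(20L, ps$n_mismatches)
          for (p in pos) proto[p] <- sample(setdiff(c("A", "C", "G", "T"), proto[p]), 1)
        }
        site23 <- paste0(ps$prefix, pam_n, paste(proto, collapse = ""))
        # choose a forward start position
        if (!is.na(ps$host)) {
          gi <- match(ps$host, genes)
          if (is.na(gi)) abort(sprintf("unknown host gene '%s'", ps$host),
                               class = "guidescreenr_generation_error")
          off <- if (!is.na(ps$host_offset)) ps$host_offset else {
            cand <- 3:(lens[gi] - 23L - 3L)
            free <- cand[vapply(cand, function(o)
              !any(planted_occ[(starts[gi] + o + 1L):(starts[gi] + o + 23L)]),
              logical(1))]
            if (!length(free)) abort("no room to plant site inside host gene",
                                     class = "guidescreenr_generation_error")
            sample(free, 1)
          }
          p0 <- starts[gi] + off
        } else {
          cand <- which(!occupied & !planted_occ) - 1L
          cand <- cand[cand + 23L <= genome_length]
          free <- cand[vapply(cand, function(p)
            !any(occupied[(p + 1L):(p + 23L)]) && !any(planted_occ[(p + 1L):(p + 23L)]),
            logical(1))]
          if (!length(free)) abort("no intergenic room to plant site",
                                   class = "guidescreenr_generation_error")
          p0 <- sample(free, 1)
        }
        written <- if (ps$strand == "-") dna_revcomp(site23) else site23
        base[(p0 + 1L):(p0 + 23L)] <- strsplit(written, "")[[1]]
        planted_occ[(p0 + 1L):(p0 + 23L)] <- TRUE
        site_truth <- dplyr::bind_rows(site_truth, tibble(
          spacer = ps$spacer, prefix = ps$prefix,
          n_mismatches = ps$n_mismatches, strand = ps$strand,
          fwd_start = as.integer(p0), host = ps$host, site23 = site23))
      }
    }
    list(genome = genome_record(paste(base, collapse = ""), id = id,
                                circular = circular),
         orfs = orfs,
         orf_truth = tibble(gene = genes, expected_validation = expected),
         site_truth = site_truth)
  })
}

#' Generate a paired expression table with one knocked-down target
#'
#' Baseline abundances are log-normal across genes (RPKM-like, median ~100,
#' sdlog 1.5, spanning the several-decade dynamic range of a bacterial
#' transcriptome); induced abundances multiply the baseline by log-normal
#' noise of the requested coefficient of variation, and the target gene is
#' additionally divided by `knockdown_fold`.
#'
#' @param n_genes Number of genes.
#' @param target_gene Name of the knocked-down gene (added if not among the
#'   generated names).
#' @param knockdown_fold Fold knockdown (>= 1; 1 = indistinguishable from
#'   null).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return Expression tibble with derived fold changes (see
#'   [load_expression()]).
#' @export
make_expression <- function(n_genes = 4000L, target_gene = "g0001",
                            knockdown_fold = 32, noise_cv = 0.2, seed = 1L) {
  stopifnot(knockdown_fold >= 1)
  withr::with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    if (!target_gene %in% genes) genes[1] <- target_gene
    u <- stats::rlnorm(n_genes, meanlog = log(100), sdlog = 1.5)
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- stats::rlnorm(n_genes, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    i <- u * noise
    i[genes == target_gene] <- i[genes == target_gene] / knockdown_fold
    expression_fold_changes(tibble(gene = genes, abundance_uninduced = u,
                                   abundance_induced = i))
  })
}

#' Write an expression table as TSV
#'
#' Canonical three-column layout: `gene`, `RPKM_uninduced`, `RPKM_induced`.
#'
#' @param table Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(table, path) {
  readr::write_tsv(
    tibble(gene = table$gene, RPKM_uninduced = table$abundance_uninduced,
           RPKM_induced = table$abundance_induced), path)
  invisible(path)
}

#' Generate a sigmoid dose-response table
#'
#' Concentrations span two decades (default 0.001-0.1 % w/v, the arabinose
#' range over which induction runs from near-leaky to saturating); signals
#' follow the rising logistic with optional multiplicative log-normal noise.
#'
#' @param f_max,x_half,gamma_rate True curve parameters (signal units,
#'   concentration, concentration).
#' @param concentrations Concentration grid (% w/v).
#' @param noise_cv Multiplicative noise CV (0 = exact curve).
#' @param seed Integer seed.
#' @return Tibble with columns `x`, `y`.
#' @export
make_dose_response <- function(f_max = 100, x_half = 0.03, gamma_rate = 0.01,
                               concentrations = exp(seq(log(0.001), log(0.1),
                                                        length.out = 8)),
                               noise_cv = 0, seed = 1L) {
  stopifnot(f_max >= 0, gamma_rate > 0)
  withr::with_seed(seed, {
    y <- f_max / (1 + exp(-(concentrations - x_half) / gamma_rate))
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      y <- y * stats::rlnorm(length(y), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    tibble(x = concentrations, y = y)
  })
}
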