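#' Load a paired expression table
#'
#' Reads a TSV of per-gene abundances in an uninduced and an induced culture
#' (RPKM-like units) and derives the per-gene log2 fold change. The first
#' column is the gene name; the next two numeric columns are taken as the
#' uninduced and induced abundances (canonical header:
#' `gene`, `RPKM_uninduced`, `RPKM_induced`). Fold change is defined only
#' when both abundances (plus pseudocount) are positive; other genes are
#' retained and flagged.
#'
#' @param path TSV path.
#' @param pseudocount Added to both abundances before the ratio (default 0:
#'   zero-abundance genes are excluded from tests rather than offset).
#' @return Tibble: `gene`, `abundance_uninduced`, `abundance_induced`,
#'   `log2_fold_change`, `fc_defined`.
#' @export
load_expression <- function(path, pseudocount = 0) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(tb) < 3) abort("expression table needs gene + two abundance columns")
  tb <- tb[, 1:3]
  names(tb) <- c("gene", "abundance_uninduced", "abundance_induced")
  tb$gene <- as.character(tb$gene)
  if (anyDuplicated(tb$gene)) {
    abort(sprintf("duplicate gene name(s) in expression table: %s",
                  paste(head(unique(tb$gene[duplicated(tb$gene)]), 3),
                        collapse = ", ")),
          class = "guidescreenr_format_error")
  }
  expression_fold_changes(tb, pseudocount)
}

#' Derive log2 fold changes for an expression table
#'
#' @param table Tibble with `gene`, `abundance_uninduced`,
#'   `abundance_induced`.
#' @param pseudocount See [load_expression()].
#' @return The table with `log2_fold_change` and `fc_defined` columns.
#' @export
expression_fold_changes <- function(table, pseudocount = 0) {
  u <- table$abundance_uninduced + pseudocount
  i <- table$abundance_induced + pseudocount
  ok <- u > 0 & i > 0
  dplyr::mutate(table,
                log2_fold_change = ifelse(ok, log2(i / u), NA_real_),
                fc_defined = ok)
}

#' Off-target gene subsets for a spacer, by match tier
#'
#' Builds the match-tier gene subsets used in the transcriptome-level
#' off-target audit. A gene joins a tier when any PAM-prefixed (CC/CT/TC)
#' 23-nt window fully inside its annotated extent, on either strand,
#' satisfies the tier condition against the 20-nt protospacer:
#' \describe{
#'   \item{`region1_exact`}{exact match over the PAM-proximal 7 nt (region I).}
#'   \item{`region12_le2mm`}{at most 2 mismatches over the PAM-proximal 12 nt
#'     (regions I + II).}
#'   \item{`mm3`, `mm4`}{exactly 3 or 4 mismatches over the full 20 nt.}
#' }
#' Tiers are not mutually exclusive. Each membership records the matched
#' site and its full-20-mer Hamming distance.
#'
#' @param genome Single-record genome tibble.
#' @param orfs ORF tibble (annotated extents; validation not required).
#' @param protospacer 20-nt protospacer in the CC-prefixed genomic frame
#'   (position 1 is PAM-proximal).
#' @param params A [design_params()] list.
#' @return Tibble: `tier`, `gene`, `site_start`, `site_strand`, `prefix`,
#'   `dist20`.
#' @export
build_subsets <- function(genome, orfs, protospacer, params = design_params()) {
  protospacer <- toupper(protospacer)
  stopifnot(nchar(protospacer) == 20L)
  wins <- scan_prefix_windows(genome, params)
  if (!nrow(wins)) return(empty_memberships())
  r1 <- params$region1_len
  r12 <- params$region12_len
  wins <- dplyr::mutate(
    wins,
    dist20 = hamming_vec(.data$win20, protospacer),
    d12 = hamming_vec(substr(.data$win20, 1L, r12), substr(protospacer, 1L, r12)),
    r1_exact = substr(.data$win20, 1L, r1) == substr(protospacer, 1L, r1))
  # assign windows to genes: window fully within the annotated extent
  hits <- purrr::pmap(dplyr::select(orfs, "gene", "start", "end"),
                      function(gene, start, end) {
    inside <- wins$fwd_start >= start & wins$fwd_start + params$site_len <= end
    if (!any(inside)) return(NULL)
    dplyr::mutate(wins[inside, ], gene = gene)
  })
  hits <- dplyr::bind_rows(hits)
  if (!nrow(hits)) return(empty_memberships())
  tiers <- dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(hits, .data$r1_exact), tier = "region1_exact"),
    dplyr::mutate(dplyr::filter(hits, .data$d12 <= 2L), tier = "region12_le2mm"),
    dplyr::mutate(dplyr::filter(hits, .data$dist20 == 3L), tier = "mm3"),
    dplyr::mutate(dplyr::filter(hits, .data$dist20 == 4L), tier = "mm4"))
  tiers |>
    dplyr::select("tier", "gene", site_start = "fwd_start", "site_strand",
                  "prefix", "dist20") |>
    dplyr::arrange(.data$tier, .data$gene, .data$site_start)
}

empty_memberships <- function() {
  tibble(tier = character(0), gene = character(0), site_start = integer(0),
         site_strand = character(0), prefix = character(0),
         dist20 = integer(0))
}

#' Genes belonging to one tier of a membership table
#'
#' @param memberships Tibble from [build_subsets()].
#' @param tier Tier name.
#' @return Character vector of gene names.
#' @export
subset_genes <- function(memberships, tier) {
  unique(memberships$gene[memberships$tier == tier])
}

#' Compare a gene subset's fold changes to the global distribution
#'
#' Two-sample test of the subset's log2 fold changes against all genes with a
#' defined fold change. Default is the two-sided Kolmogorov-Smirnov test
#' (Mann-Whitney available); no multiple-testing correction is applied.
#'
#' @param table Expression tibble with `log2_fold_change` (see
#'   [load_expression()]).
#' @param genes Character vector of subset gene names.
#' @param test `"ks"` or `"wilcox"`.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n_subset`,
#'   `n_global`, `testable`.
#' @export
compare_to_global <- function(table, genes, test = c("ks", "wilcox")) {
  test <- match.arg(test)
  def <- dplyr::filter(table, .data$fc_defined)
  sub_fc <- def$log2_fold_change[def$gene %in% genes]
  if (!length(sub_fc)) {
    return(tibble(test = test, statistic = NA_real_, p_value = NA_real_,
                  n_subset = 0L, n_global = nrow(def), testable = FALSE))
  }
  res <- suppressWarnings(
    if (test == "ks") ks.test(sub_fc, def$log2_fold_change)
    else wilcox.test(sub_fc, def$log2_fold_change))
  tibble(test = test, statistic = unname(res$statistic),
         p_value = res$p.value, n_subset = length(sub_fc),
         n_global = nrow(def), testable = TRUE)
}

#' Rank of the on-target gene within its match subset
#'
#' Genes are sorted by ascending log2 fold change (rank 1 = most repressed);
#' ties share the better rank.
#'
#' @param table Expression tibble (see [load_expression()]).
#' @param genes Subset gene names (must contain `target_gene`).
#' @param target_gene The targeted gene.
#' @return Integer rank.
#' @export
on_target_rank <- function(table, genes, target_gene) {
  if (!target_gene %in% genes) {
    abort(sprintf("target gene '%s' is not in the subset", target_gene))
  }
  def <- dplyr::filter(table, .data$fc_defined, .data$gene %in% genes)
  if (!target_gene %in% def$gene) {
    abort(sprintf("target gene '%s' has no defined fold change", target_gene))
  }
  r <- rank(def$log2_fold_change, ties.method = "min")
  as.integer(r[def$gene == target_gene])
}

#' Correlation of match distance with repression
#'
#' Spearman rank correlation between each subset member's minimal Hamming
#' distance to the spacer (over the 20-mer) and its log2 fold change, probing
#' whether closer off-target matches are more repressed.
#'
#' @param table Expression tibble.
#' @param memberships Tibble from [build_subsets()] (any tier mix; distances
#'   are minimised per gene).
#' @return One-row tibble: `rho`, `p_value`, `n`, `testable`, `note`.
#' @export
hamming_vs_repression <- function(table, memberships) {
  per_gene <- memberships |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(min_dist = min(.data$dist20), .groups = "drop")
  dat <- dplyr::inner_join(per_gene, dplyr::filter(table, .data$fc_defined),
                           by = "gene")
  if (nrow(dat) < 3L) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n = nrow(dat),
                  testable = FALSE, note = "fewer than 3 members with defined FC"))
  }
  if (stats::sd(dat$log2_fold_change) == 0 || stats::sd(dat$min_dist) == 0) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n = nrow(dat),
                  testable = FALSE, note = "zero variance; correlation undefined"))
  }
  ct <- suppressWarnings(
    cor.test(dat$min_dist, dat$log2_fold_change, method = "spearman",
             exact = FALSE))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(dat),
         testable = TRUE, note = NA_character_)
}

#' One-stop off-target expression audit
#'
#' Builds the match-tier subsets for a spacer, tests each tier's fold-change
#' distribution against the global distribution, and ranks the on-target
#' gene in every tier containing it.
#'
#' @param table Expression tibble (see [load_expression()]).
#' @param genome,orfs Genome and annotations the spacer was designed against.
#' @param protospacer 20-nt protospacer (CC-prefixed genomic frame).
#' @param target_gene Optional targeted gene for rank reporting.
#' @param params A [design_params()] list.
#' @param test Passed to [compare_to_global()].
#' @return A list with `memberships` (tibble) and `report` (per-tier tibble:
#'   `tier`, `n_genes`, `statistic`, `p_value`, `on_target_rank`).
#' @export
audit_expression <- function(table, genome, orfs, protospacer,
                             target_gene = NULL, params = design_params(),
                             test = "ks") {
  memberships <- build_subsets(genome, orfs, protospacer, params)
  tiers <- c("region1_exact", "region12_le2mm", "mm3", "mm4")
  report <- purrr::map(tiers, function(tr) {
    genes <- subset_genes(memberships, tr)
    cmp <- compare_to_global(table, genes, test = test)
    rk <- if (!is.null(target_gene) && target_gene %in% genes) {
      on_target_rank(table, genes, target_gene)
    } else NA_integer_
    dplyr::mutate(cmp, tier = tr, n_genes = length(genes), on_target_rank = rk)
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("tier", "n_genes", "test", "statistic", "p_value",
                  "on_target_rank", "testable")
  list(memberships = memberships, report = report)
}
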