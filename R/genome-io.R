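#' Construct a genome record table
#'
#' A genome record is a one-row-per-sequence tibble with columns `id`,
#' `sequence` (upper-case DNA over `{A,C,G,T,N}`) and `circular`. All scanning
#' functions in the package take this table as their genome argument; most
#' operate on a single-record genome (a bacterial chromosome).
#'
#' @param sequence Character vector of DNA sequences.
#' @param id Character vector of record identifiers.
#' @param circular Logical vector; whether each replicon is circular.
#' @return A tibble with columns `id`, `sequence`, `circular`.
#' @examples
#' genome_record("acgtACGT", id = "chr")
#' @export
genome_record <- function(sequence, id = "genome", circular = FALSE) {
  stopifnot(length(sequence) >= 1)
  sequence <- toupper(sequence)
  if (any(nchar(sequence) < 1)) abort("genome sequences must have length >= 1")
  id <- rep_len(as.character(id), length(sequence))
  circular <- rep_len(as.logical(circular), length(sequence))
  assert_acgtn(sequence, id)
  tibble(id = id, sequence = sequence, circular = circular)
}

the_sequence <- function(genome) {
  stopifnot(is.data.frame(genome), nrow(genome) == 1)
  genome$sequence[[1]]
}

#' Read a genome from FASTA or GenBank
#'
#' Sequences are upper-cased on ingest; characters outside `{A,C,G,T,N}` are
#' rejected with the offending record and position named. Circularity is read
#' from the GenBank LOCUS line when available, otherwise `FALSE`.
#'
#' @param path Path to the file.
#' @param format `"fasta"` or `"genbank"`.
#' @return A genome tibble (see [genome_record()]), one row per record in
#'   file order.
#' @export
read_genome <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("cannot read genome: no such file '%s'", path),
          class = "guidescreenr_io_error")
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    genome_record(unname(as.character(ss)), id = sub("\\s.*$", "", names(ss)),
                  circular = FALSE)
  } else {
    recs <- parse_genbank(path)
    genome_record(
      vapply(recs, `[[`, character(1), "sequence"),
      id = vapply(recs, `[[`, character(1), "id"),
      circular = vapply(recs, `[[`, logical(1), "circular")
    )
  }
}

#' Construct an ORF table
#'
#' ORF (open reading frame) records use 0-based half-open genomic coordinates
#' internally; all file I/O converts from/to the 1-based inclusive GenBank/GFF3
#' convention at the boundary. `validation` is `NA` until [validate_orfs()]
#' has been run.
#'
#' @param gene Character vector of gene names.
#' @param start,end Integer 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @param validation Optional validation status (see [validate_orf()]).
#' @return A tibble with columns `gene`, `start`, `end`, `strand`,
#'   `validation`.
#' @export
orf_record <- function(gene, start, end, strand = "+", validation = NA_character_) {
  stopifnot(all(start >= 0), all(end > start), all(strand %in% c("+", "-")))
  tibble(gene = as.character(gene), start = as.integer(start),
         end = as.integer(end), strand = strand,
         validation = rep_len(as.character(validation), length(gene)))
}

#' Read ORF annotations from GFF3 or GenBank
#'
#' CDS features are extracted and converted to 0-based half-open coordinates.
#' Compound (`join`) locations — multi-segment CDS — are skipped with a
#' warning, since the single-window screen is defined on simple intervals.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"genbank"`.
#' @param genome Optional genome tibble; when given, features running past the
#'   sequence end of a non-circular genome raise an annotation error.
#' @return An ORF tibble (see [orf_record()]) with `validation = NA`.
#' @export
read_annotations <- function(path, format = c("gff3", "genbank"), genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("cannot read annotations: no such file '%s'", path),
          class = "guidescreenr_io_error")
  }
  orfs <- if (format == "gff3") read_annotations_gff3(path) else
    read_annotations_genbank(path)
  if (!is.null(genome) && nrow(orfs)) {
    L <- nchar(the_sequence(genome))
    if (!genome$circular[[1]] && any(orfs$end > L)) {
      bad <- orfs$gene[orfs$end > L][1]
      abort(sprintf(
        "annotation error: feature '%s' extends past the end of linear sequence '%s' (length %d)",
        bad, genome$id[[1]], L), class = "guidescreenr_annotation_error")
    }
  }
  orfs
}

read_annotations_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("CDS", "ORF")
  gr <- gr[keep]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(seq_along(gr))
  multi <- ids %in% ids[duplicated(ids)]
  if (any(multi)) {
    warn(sprintf("skipping %d multi-segment (join) CDS feature(s): %s",
                 length(unique(ids[multi])),
                 paste(unique(ids[multi]), collapse = ", ")))
    gr <- gr[!multi]
  }
  if (!length(gr)) return(orf_record(character(0), integer(0), integer(0))[0, ])
  nm <- rep(NA_character_, length(gr))
  for (col in c("gene", "Name", "locus_tag", "ID")) {
    if (!is.null(S4Vectors::mcols(gr)[[col]])) {
      v <- as.character(S4Vectors::mcols(gr)[[col]])
      nm <- ifelse(is.na(nm) & !is.na(v), v, nm)
    }
  }
  nm[is.na(nm)] <- paste0("feature_", seq_len(sum(is.na(nm))))
  orf_record(nm, start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "-", "+"))
}

read_annotations_genbank <- function(path) {
  recs <- parse_genbank(path)
  feats <- dplyr::bind_rows(lapply(recs, `[[`, "features"))
  if (!nrow(feats)) return(orf_record(character(0), integer(0), integer(0))[0, ])
  orf_record(feats$gene, start = feats$start, end = feats$end,
             strand = feats$strand)
}

#' Extract the coding-strand sequence of an ORF
#'
#' Returns each ORF's 5'->3' coding-strand sequence: the forward-strand slice
#' for `+` features, its reverse complement for `-` features. On a circular
#' genome, features whose `end` exceeds the sequence length wrap through the
#' origin.
#'
#' @param orfs ORF tibble.
#' @param genome Single-record genome tibble.
#' @return Character vector of coding sequences, one per ORF row.
#' @export
coding_sequence <- function(orfs, genome) {
  seq <- the_sequence(genome)
  L <- nchar(seq)
  circular <- genome$circular[[1]]
  if (any(orfs$end > L)) {
    if (!circular) {
      abort("ORF extends past the end of a linear genome",
            class = "guidescreenr_bounds_error")
    }
    if (any(orfs$end > 2L * L)) abort("wrapped ORF longer than the genome")
    seq <- paste0(seq, seq)
  }
  s <- stringi::stri_sub(seq, orfs$start + 1L, orfs$end)
  ifelse(orfs$strand == "-", dna_revcomp(s), s)
}

#' Validate coding sequences by start and stop codon
#'
#' The screen used to admit ORFs for guide design: the first codon must be an
#' NTG start (`ATG`, `GTG`, `TTG`, `CTG`) and the last codon a stop (`TAG`,
#' `TGA`, `TAA`), both read on the coding strand. Sequences shorter than two
#' codons are `too_short`; a bad start takes precedence over a bad stop. A
#' codon containing `N` fails its membership test. Frame (length divisible by
#' 3) is deliberately not a failure criterion.
#'
#' @param coding Character vector of 5'->3' coding-strand sequences.
#' @return Character vector over
#'   `{"valid","failed_start","failed_stop","too_short"}`.
#' @examples
#' validate_orf(c("ATGAAATAA", "GTGAAATGA", "ATTAAATAA"))
#' @export
validate_orf <- function(coding) {
  starts <- c("ATG", "GTG", "TTG", "CTG")
  stops <- c("TAG", "TGA", "TAA")
  n <- nchar(coding)
  first <- substr(coding, 1L, 3L)
  last <- substr(coding, n - 2L, n)
  dplyr::case_when(
    n < 6L ~ "too_short",
    !first %in% starts ~ "failed_start",
    !last %in% stops ~ "failed_stop",
    TRUE ~ "valid"
  )
}

#' Validate every ORF of an annotation table against a genome
#'
#' Fills the `validation` column by extracting each coding sequence and
#' applying [validate_orf()]. ORFs whose length is not a multiple of 3 trigger
#' a single frame warning (they are not failed for it).
#'
#' @param orfs ORF tibble.
#' @param genome Single-record genome tibble.
#' @return The ORF tibble with `validation` filled in.
#' @export
validate_orfs <- function(orfs, genome) {
  if (!nrow(orfs)) return(orfs)
  cs <- coding_sequence(orfs, genome)
  out <- dplyr::mutate(orfs, validation = validate_orf(cs))
  off_frame <- orfs$gene[(orfs$end - orfs$start) %% 3L != 0L]
  if (length(off_frame)) {
    warn(sprintf("%d ORF(s) not a multiple of 3 nt (reported, not failed): %s",
                 length(off_frame), paste(head(off_frame, 5), collapse = ", ")))
  }
  out
}

#' Write an ORF validation report
#'
#' Tab-separated table of `gene`, `start`, `end` (0-based half-open), `strand`
#' and `validation`.
#'
#' @param orfs Validated ORF tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orf_report <- function(orfs, path) {
  readr::write_tsv(orfs, path)
  invisible(path)
}

#' Write ORFs as GFF3
#'
#' Converts the internal 0-based half-open coordinates back to the 1-based
#' inclusive GFF3 convention. A table written and re-read with
#' [read_annotations()] round-trips exactly.
#'
#' @param orfs ORF tibble.
#' @param path Output path.
#' @param seqid Sequence identifier for column 1.
#' @return `path`, invisibly.
#' @export
write_orfs_gff3 <- function(orfs, path, seqid = "genome") {
  lines <- c("##gff-version 3",
             sprintf("%s\tguidescreenr\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;gene=%s",
                     seqid, orfs$start + 1L, orfs$end, orfs$strand,
                     orfs$gene, orfs$gene))
  writeLines(lines, path)
  invisible(path)
}

#' Write a genome as FASTA
#'
#' @param genome Genome tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
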