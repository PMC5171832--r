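#' Canonical form of a k-mer
#'
#' The lexicographically smaller of a k-mer and its reverse complement, so both
#' strands of a double-stranded site share a single representative. All
#' abundance lookups in the off-target screen are canonical.
#'
#' @param kmer Character vector of DNA k-mers over `{A,C,G,T}`.
#' @return Character vector of canonical k-mers.
#' @examples
#' canonicalize(c("TTTT", "ACGT"))
#' @export
canonicalize <- function(kmer) {
  if (any(stringi::stri_detect_regex(kmer, "[^ACGT]"))) {
    abort("canonicalize() requires k-mers over {A,C,G,T}")
  }
  rc <- dna_revcomp(kmer)
  ifelse(kmer <= rc, kmer, rc)
}

#' Build a canonical k-mer abundance index of a genome
#'
#' Slides a k-wide window along the forward strand (wrapping k-1 positions
#' past the end when the replicon is circular), skips windows containing `N`,
#' and counts each window under its canonical form. Each double-stranded
#' genomic site is therefore counted exactly once. The guide screen uses
#' indices at k = 10, 15 and 23 (PAM dinucleotide + N + 7 / 12 / 20 nt).
#'
#' @param genome Single-record genome tibble.
#' @param k Window length (>= 1; <= genome length on a linear genome).
#' @param circular Override the genome's circularity flag.
#' @return An object of class `kmer_index`: list with `k`, `counts` (named
#'   integer vector keyed by canonical k-mer), `source_length`, `circular`.
#' @examples
#' g <- genome_record("ACGTA")
#' build_kmer_index(g, k = 4)
#' @export
build_kmer_index <- function(genome, k, circular = NULL) {
  seq <- the_sequence(genome)
  L <- nchar(seq)
  k <- as.integer(k)
  if (is.null(circular)) circular <- genome$circular[[1]]
  if (k < 1L) abort("k must be >= 1")
  if (!circular && k > L) {
    abort(sprintf("k = %d exceeds linear genome length %d", k, L))
  }
  scan <- if (circular) paste0(seq, substr(seq, 1L, k - 1L)) else seq
  starts <- seq_len(nchar(scan) - k + 1L)
  wins <- stringi::stri_sub(scan, starts, starts + k - 1L)
  wins <- wins[!stringi::stri_detect_fixed(wins, "N")]
  counts <- table(canonicalize(wins))
  structure(
    list(k = k,
         counts = setNames(as.integer(counts), names(counts)),
         source_length = L,
         circular = circular),
    class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d distinct canonical k-mers, %d counted windows (%s genome of %d nt)\n",
              x$k, length(x$counts), sum(x$counts),
              if (x$circular) "circular" else "linear", x$source_length))
  invisible(x)
}

#' @exportS3Method
tidy.kmer_index <- function(x, ...) {
  tibble(kmer = names(x$counts), count = unname(x$counts))
}

#' Canonical abundance of a query k-mer
#'
#' The number of double-stranded genomic sites matching the query on either
#' strand; 0 when absent.
#'
#' @param index A `kmer_index`.
#' @param query Character vector of k-mers of length `index$k`.
#' @return Integer vector of counts.
#' @export
kmer_count <- function(index, query) {
  stopifnot(inherits(index, "kmer_index"))
  if (any(nchar(query) != index$k)) {
    abort(sprintf("query length must equal index k = %d", index$k))
  }
  out <- unname(index$counts[canonicalize(query)])
  out[is.na(out)] <- 0L
  out
}

#' Write / read a k-mer index as TSV
#'
#' Two columns, `kmer` and `count`; canonical keys only.
#'
#' @param index A `kmer_index`.
#' @param path File path.
#' @return `path` invisibly (write); a `kmer_index` (read).
#' @export
write_kmer_index <- function(index, path) {
  readr::write_tsv(tidy(index), path)
  invisible(path)
}

#' @param k,source_length,circular Metadata to attach on read.
#' @rdname write_kmer_index
#' @export
read_kmer_index <- function(path, k = NULL, source_length = NA_integer_,
                            circular = FALSE) {
  tb <- readr::read_tsv(path, col_types = "ci")
  if (is.null(k)) k <- nchar(tb$kmer[[1]])
  structure(
    list(k = as.integer(k),
         counts = setNames(as.integer(tb$count), tb$kmer),
         source_length = as.integer(source_length),
         circular = circular),
    class = "kmer_index")
}
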