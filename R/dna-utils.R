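#' Reverse complement of DNA strings
#'
#' Vectorised Watson-Crick reverse complement over the alphabet `{A,C,G,T,N}`
#' (case preserved).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @examples
#' dna_revcomp("ACCGT")
#' @export
dna_revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

#' Hamming distance between two equal-length DNA strings
#'
#' The number of positions at which `a` and `b` differ. Used throughout the
#' off-target screen: mismatch tiers are defined by exact Hamming distance
#' between a genomic window and a candidate protospacer.
#'
#' @param a,b Single DNA strings of equal length.
#' @return Integer count of mismatching positions.
#' @examples
#' hamming_distance("AAAA", "AAAT")
#' @export
hamming_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (nchar(a) != nchar(b)) {
    abort(sprintf("hamming_distance() needs equal lengths, got %d and %d",
                  nchar(a), nchar(b)))
  }
  sum(charToRaw(a) != charToRaw(b))
}

# vectorised Hamming of many same-length strings against one pattern
hamming_vec <- function(x, pattern) {
  if (length(x) == 0L) return(integer(0))
  pm <- charToRaw(pattern)
  vapply(x, function(s) sum(charToRaw(s) != pm), integer(1), USE.NAMES = FALSE)
}

# first offending position of a non-ACGTN character, NA if clean
first_bad_base <- function(seq) {
  loc <- stringi::stri_locate_first_regex(seq, "[^ACGTN]")
  loc[, 1]
}

assert_acgtn <- function(seq, id = "sequence") {
  pos <- first_bad_base(seq)
  bad <- which(!is.na(pos))
  if (length(bad)) {
    i <- bad[1]
    abort(sprintf(
      "record '%s': illegal character '%s' at position %d (alphabet is A,C,G,T,N)",
      id[[min(i, length(id))]],
      substr(seq[i], pos[i], pos[i]), pos[i]
    ), class = "guidescreenr_format_error")
  }
  invisible(seq)
}
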