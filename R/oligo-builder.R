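#' Homology-arm configuration for the one-step recombineering oligo
#'
#' The 90-nt oligo that converts the generic tet-sacB strain into a
#' gene-specific CRISPRi strain is `homology5 + spacer + homology3`: 35 nt of
#' homology to the sgRNA cassette on each side of the 20-nt spacer. The arm
#' sequences are strain-specific (the cassette context on the chromosome) and
#' must be supplied; the package ships a clearly labelled synthetic
#' placeholder pair for testing only (see
#' `system.file("extdata", "synthetic_homology_arms.fasta", package = "guidescreenr")`).
#'
#' @param homology5,homology3 35-nt DNA strings over `{A,C,G,T}`.
#' @param emit_reverse_complement Emit the reverse complement of the whole
#'   90-mer (lagging-strand orientation for recombineering is strain-specific).
#' @return A list of class `oligo_config`.
#' @export
oligo_config <- function(homology5, homology3, emit_reverse_complement = FALSE) {
  check_arm <- function(arm, name) {
    arm <- toupper(arm)
    if (nchar(arm) != 35L) {
      abort(sprintf("%s must be exactly 35 nt, got %d", name, nchar(arm)))
    }
    if (stringi::stri_detect_regex(arm, "[^ACGT]")) {
      abort(sprintf("%s must be over {A,C,G,T}", name))
    }
    arm
  }
  structure(list(homology5 = check_arm(homology5, "homology5"),
                 homology3 = check_arm(homology3, "homology3"),
                 emit_reverse_complement = isTRUE(emit_reverse_complement)),
            class = "oligo_config")
}

#' Read homology arms from a two-record FASTA
#'
#' Expects records named `homology5` and `homology3` (order-insensitive).
#'
#' @param path FASTA path.
#' @param emit_reverse_complement Passed to [oligo_config()].
#' @return An `oligo_config`.
#' @export
read_homology_arms <- function(path, emit_reverse_complement = FALSE) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (!all(c("homology5", "homology3") %in% nm)) {
    abort("arms FASTA must contain records named 'homology5' and 'homology3'")
  }
  oligo_config(as.character(ss[[which(nm == "homology5")[1]]]),
               as.character(ss[[which(nm == "homology3")[1]]]),
               emit_reverse_complement)
}

#' Build the 90-nt recombineering oligo for one spacer
#'
#' `homology5 + spacer + homology3`, exactly 90 nt (35 + 20 + 35); the spacer
#' occupies positions 36-55 of the forward-orientation product. With
#' `emit_reverse_complement` the whole 90-mer is reverse-complemented.
#'
#' @param spacer 20-nt DNA spacer.
#' @param config An [oligo_config()].
#' @return A single 90-nt DNA string.
#' @examples
#' cfg <- oligo_config(strrep("A", 35), strrep("T", 35))
#' nchar(build_oligo(strrep("ACGT", 5), cfg))
#' @export
build_oligo <- function(spacer, config) {
  stopifnot(inherits(config, "oligo_config"))
  spacer <- toupper(spacer)
  if (nchar(spacer) != 20L) {
    abort(sprintf("spacer must be exactly 20 nt, got %d", nchar(spacer)))
  }
  if (stringi::stri_detect_regex(spacer, "[^ACGT]")) {
    abort("spacer must be over {A,C,G,T}")
  }
  oligo <- paste0(config$homology5, spacer, config$homology3)
  if (config$emit_reverse_complement) oligo <- dna_revcomp(oligo)
  oligo
}

#' Build oligos for every qualifying gene of a design table
#'
#' One oligo per gene with a selected spacer; genes without a qualifying
#' sgRNA are omitted with a warning. Record ids are `<gene>_tCRISPRi_oligo`.
#'
#' @param design Tibble from [design_genome()] (needs `gene`, `status`,
#'   `selected_spacer`).
#' @param config An [oligo_config()].
#' @return Tibble: `gene`, `id`, `oligo` (90-nt strings).
#' @export
batch_oligos <- function(design, config) {
  ok <- dplyr::filter(design, .data$status == "ok", !is.na(.data$selected_spacer))
  skipped <- setdiff(design$gene, ok$gene)
  if (length(skipped)) {
    warn(sprintf("no oligo for %d gene(s) without a qualifying sgRNA: %s",
                 length(skipped), paste(head(skipped, 5), collapse = ", ")))
  }
  tibble(gene = ok$gene,
         id = paste0(ok$gene, "_tCRISPRi_oligo"),
         oligo = vapply(ok$selected_spacer, build_oligo, character(1),
                        config = config, USE.NAMES = FALSE))
}

#' Write an oligo table as FASTA
#'
#' @param oligos Tibble from [batch_oligos()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_oligos_fasta <- function(oligos, path) {
  ss <- Biostrings::DNAStringSet(setNames(as.character(oligos$oligo), oligos$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
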