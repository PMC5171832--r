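# Minimal GenBank flat-file reader: LOCUS (id + circular flag), FEATURES
# (CDS with simple or complement() locations; join() skipped with a warning),
# ORIGIN (sequence). Coordinates are converted from 1-based inclusive to the
# package's 0-based half-open convention here, at the I/O boundary.

parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_idx <- grep("^LOCUS", lines)
  if (!length(locus_idx)) {
    abort(sprintf("'%s' does not look like a GenBank flat file (no LOCUS line)", path),
          class = "guidescreenr_format_error")
  }
  end_idx <- grep("^//", lines)
  lapply(seq_along(locus_idx), function(i) {
    from <- locus_idx[i]
    to <- end_idx[end_idx > from][1]
    if (is.na(to)) to <- length(lines)
    parse_genbank_record(lines[from:to])
  })
}

parse_genbank_record <- function(rec) {
  locus <- rec[1]
  id <- strsplit(trimws(locus), "\\s+")[[1]][2]
  circular <- grepl("\\bcircular\\b", locus, ignore.case = TRUE)

  origin <- grep("^ORIGIN", rec)[1]
  seq <- ""
  if (!is.na(origin)) {
    body <- rec[(origin + 1):length(rec)]
    body <- body[!grepl("^//", body)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }

  feat_start <- grep("^FEATURES", rec)[1]
  features <- tibble(gene = character(0), start = integer(0),
                     end = integer(0), strand = character(0))
  if (!is.na(feat_start)) {
    feat_end <- if (!is.na(origin)) origin - 1L else length(rec)
    features <- parse_genbank_features(rec[(feat_start + 1):feat_end])
  }
  list(id = id, circular = circular, sequence = seq, features = features)
}

parse_genbank_features <- function(flines) {
  # a feature starts with a key at column 6 preceded by exactly 5 spaces
  starts <- grep("^ {5}\\S", flines)
  out <- list()
  for (j in seq_along(starts)) {
    from <- starts[j]
    to <- if (j < length(starts)) starts[j + 1] - 1L else length(flines)
    block <- flines[from:to]
    key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
    if (key != "CDS") next
    # location may continue over lines until the first qualifier (/xxx)
    qual_at <- grep("^ {10,}/", block)
    loc_to <- if (length(qual_at)) qual_at[1] - 1L else length(block)
    loc <- gsub("\\s", "", paste(
      c(sub("^ {5}\\S+\\s*", "", block[1]), trimws(block[seq_len(loc_to)[-1]])),
      collapse = ""))
    gene <- genbank_qualifier(block, "gene")
    if (is.na(gene)) gene <- genbank_qualifier(block, "locus_tag")
    if (is.na(gene)) gene <- sprintf("CDS_%d", length(out) + 1L)
    if (grepl("join", loc)) {
      warn(sprintf("skipping compound (join) CDS location for '%s': %s", gene, loc))
      next
    }
    strand <- if (grepl("^complement\\(", loc)) "-" else "+"
    nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
    if (length(nums) < 2) {
      warn(sprintf("skipping unparseable CDS location for '%s': %s", gene, loc))
      next
    }
    a <- as.integer(nums[1]); b <- as.integer(nums[length(nums)])
    out[[length(out) + 1L]] <- tibble(gene = gene, start = a - 1L, end = b,
                                      strand = strand)
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble(gene = character(0), start = integer(0), end = integer(0),
           strand = character(0))
}

genbank_qualifier <- function(block, name) {
  hit <- grep(sprintf("^\\s+/%s=", name), block, value = TRUE)
  if (!length(hit)) return(NA_character_)
  gsub('^\\s+/[a-z_]+="?|"$', "", hit[1])
}
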