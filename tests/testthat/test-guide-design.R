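test_that("hamming_distance counts mismatching positions", {
  expect_equal(hamming_distance("AAAA", "AAAT"), 1)
  expect_equal(hamming_distance("ACGT", "ACGT"), 0)
  expect_equal(hamming_distance("AAAA", "TTTT"), 4)
  expect_error(hamming_distance("AAA", "AAAA"), "equal lengths")
})

test_that("candidates appear exactly at CC positions within the window", {
  # hand-built ORF: CC planted at coding offsets 5 and 40, none elsewhere
  # in the window (background alternates A/T, so no accidental CC)
  body <- strsplit(strrep("AT", 60), "")[[1]]
  body[6:7] <- c("C", "C")
  body[41:42] <- c("C", "C")
  coding <- paste0("ATG", paste(body, collapse = ""), "TAA")
  # recheck the fixture by exhaustive search
  cc_at <- which(vapply(seq_len(nchar(coding) - 1), function(i)
    substr(coding, i, i + 1) == "CC", logical(1))) - 1L
  expect_equal(cc_at, c(8L, 43L))

  genome <- genome_record(paste0(strrep("G", 10), coding, strrep("G", 40)))
  orfs <- orf_record("g1", 10, 10 + nchar(coding))
  orfs <- validate_orfs(orfs, genome)
  cand <- enumerate_candidates(orfs, genome)
  expect_equal(cand$offset_nt, c(8L, 43L))
  expect_true(all(substr(cand$site23, 1, 2) == "CC"))
  expect_equal(cand$protospacer20, substr(cand$site23, 4, 23))
  expect_equal(cand$region1, substr(cand$site23, 4, 10))
  expect_equal(paste0(cand$region1, cand$region2),
               substr(cand$protospacer20, 1, 12))
  expect_equal(cand$spacer_for_cassette, dna_revcomp(cand$protospacer20))
})

test_that("the positional window bounds the site's first base", {
  # CC at offset 151 is excluded under the default 150-nt window
  body <- strsplit(strrep("AT", 120), "")[[1]]
  body[149:150] <- c("C", "C")  # coding offset 151 (after ATG)
  coding <- paste0("ATG", paste(body, collapse = ""), "TAA")
  genome <- genome_record(paste0(strrep("G", 5), coding, strrep("G", 40)))
  orfs <- validate_orfs(orf_record("g", 5, 5 + nchar(coding)), genome)
  expect_equal(nrow(enumerate_candidates(orfs, genome)), 0)
  wide <- design_params(window_nt = 160)
  expect_equal(enumerate_candidates(orfs, genome, wide)$offset_nt, 151L)
})

test_that("candidates may cross the ORF 3' end but need a full genomic 23-mer", {
  # CC two bases before the stop codon: 23-mer runs past the ORF end
  coding <- paste0("ATG", strrep("ATA", 7), "CCA", "TAA")
  genome <- genome_record(paste0(coding, strrep("G", 30)))
  orfs <- validate_orfs(orf_record("g", 0, nchar(coding)), genome)
  cand <- enumerate_candidates(orfs, genome)
  expect_equal(cand$offset_nt, 24L)
  # same ORF at the very end of the genome: no room for the 23-mer
  genome2 <- genome_record(coding)
  orfs2 <- validate_orfs(orf_record("g", 0, nchar(coding)), genome2)
  expect_equal(nrow(enumerate_candidates(orfs2, genome2)), 0)
})

test_that("unvalidated or invalid ORFs are rejected", {
  genome <- genome_record(strrep("ACGT", 30))
  orfs <- orf_record("g", 0, 30)
  expect_error(enumerate_candidates(orfs, genome), "validate")
  orfs$validation <- "failed_start"
  expect_error(enumerate_candidates(orfs, genome), "valid")
})

test_that("profiles of planted sites match construction and the oracle", {
  spacer <- random_spacer(202)
  fx <- make_genome(
    genome_length = 4000, n_orfs = 3, seed = 55,
    planted_sites = dplyr::bind_rows(
      planted_site(spacer, "CC", 0, host = "gene002", pam_n = "A",
                   host_offset = 10),
      planted_site(spacer, "CC", 0, pam_n = "A"),          # exact duplicate
      planted_site(spacer, "CC", 1),                       # 1 mismatch
      planted_site(spacer, "CT", 0),                       # near-PAM exact
      planted_site(spacer, "CC", 3, strand = "-")))        # deep, minus strand
  orfs <- validate_orfs(fx$orfs, fx$genome)
  cand <- enumerate_candidates(orfs, fx$genome)
  cand <- cand[cand$gene == "gene002" & cand$offset_nt == 10, ]
  expect_equal(nrow(cand), 1)
  expect_equal(cand$protospacer20, spacer)
  prof <- off_target_profile(cand, fx$genome)
  expect_equal(prof$n_exact23, 2L)       # self + planted duplicate
  expect_gte(prof$n_mm1, 1L)
  expect_gte(prof$n_mm3, 1L)
  expect_gte(prof$n_region1_nearpam, 1L)
  orc <- oracle_profile(fx$genome$sequence[[1]], cand$site23, cand$site_start,
                        cand$site_strand)
  for (nm in names(orc)) {
    expect_equal(prof[[nm]], as.integer(orc[[nm]]), info = nm)
  }
})

test_that("a planted single-substitution site lands in tier 1 only", {
  spacer <- random_spacer(77)
  fx <- make_genome(genome_length = 3000, n_orfs = 2, seed = 78,
                    planted_sites = dplyr::bind_rows(
                      planted_site(spacer, "CC", 0, host = "gene001",
                                   pam_n = "G", host_offset = 12),
                      planted_site(spacer, "CC", 1)))
  orfs <- validate_orfs(fx$orfs, fx$genome)
  cand <- enumerate_candidates(orfs, fx$genome)
  cand <- cand[cand$offset_nt == 12 & cand$gene == "gene001", ]
  prof <- off_target_profile(cand, fx$genome)
  expect_equal(prof$n_exact23, 1L)
  expect_equal(prof$n_mm1, 1L)
  expect_equal(prof$n_mm2, 0L)
})

test_that("prefix nesting n_region1_cc >= n_region12_cc >= n_exact23 always holds", {
  fx <- make_genome(genome_length = 5000, n_orfs = 5, seed = 91)
  orfs <- validate_orfs(fx$orfs, fx$genome)
  prof <- off_target_profile(enumerate_candidates(orfs, fx$genome), fx$genome)
  expect_gt(nrow(prof), 0)
  expect_true(all(prof$n_region1_cc >= prof$n_region12_cc))
  expect_true(all(prof$n_region12_cc >= prof$n_exact23))
  expect_true(all(prof$n_exact23 >= 1L))
})

test_that("filtering removes exact/1-mm/2-mm candidates and sorts by region I", {
  spacer <- random_spacer(300)
  fx <- make_genome(genome_length = 5000, n_orfs = 4, seed = 301,
                    planted_sites = dplyr::bind_rows(
                      planted_site(spacer, "CC", 0, host = "gene001",
                                   pam_n = "T", host_offset = 20),
                      planted_site(spacer, "CC", 0, pam_n = "T")))
  orfs <- validate_orfs(fx$orfs, fx$genome)
  prof <- off_target_profile(enumerate_candidates(orfs, fx$genome), fx$genome)
  kept <- filter_and_rank(prof)
  # the duplicated candidate is gone
  dup <- prof$gene == "gene001" & prof$offset_nt == 20
  expect_true(any(dup))
  expect_false(any(kept$gene == "gene001" & kept$offset_nt == 20))
  # survivors qualify and are sorted by region I totals within gene
  expect_true(all(kept$n_exact23 == 1 & kept$n_mm1 == 0 & kept$n_mm2 == 0))
  ord <- kept |>
    dplyr::group_by(gene) |>
    dplyr::summarise(sorted = !is.unsorted(region1_total))
  expect_true(all(ord$sorted))
})

test_that("ranking is a total order: permutation of input does not change output", {
  fx <- make_genome(genome_length = 5000, n_orfs = 5, seed = 400)
  orfs <- validate_orfs(fx$orfs, fx$genome)
  prof <- off_target_profile(enumerate_candidates(orfs, fx$genome), fx$genome)
  kept1 <- filter_and_rank(prof)
  kept2 <- filter_and_rank(prof[sample(nrow(prof)), ])
  expect_equal(kept1, kept2)
})

test_that("least_abundant_region1 takes the minimum with offset tie-break", {
  prof <- tibble::tibble(
    gene = c("g", "g", "g", "h", "h"),
    offset_nt = c(5L, 40L, 80L, 9L, 2L),
    site23 = strrep(c("A", "C", "G", "T", "A"), 23),
    n_region1_cc = c(3L, 1L, 9L, 2L, 2L),
    n_region1_nearpam = c(1L, 1L, 0L, 0L, 0L))
  la <- least_abundant_region1(prof)
  expect_equal(la$offset_nt[la$gene == "g"], 40L)
  expect_equal(la$region1_total[la$gene == "g"], 2L)
  # tie in h: smaller offset wins
  expect_equal(la$offset_nt[la$gene == "h"], 2L)
})

test_that("design_genome composes the screen and flags failures", {
  spacer <- random_spacer(500)
  fx <- make_genome(genome_length = 5000, n_orfs = 4, n_invalid_orfs = 1,
                    seed = 501,
                    planted_sites = dplyr::bind_rows(
                      planted_site(spacer, "CC", 0, host = "gene002",
                                   pam_n = "C", host_offset = 15),
                      planted_site(spacer, "CC", 0, pam_n = "C")))
  suppressWarnings(d <- design_genome(fx$genome, fx$orfs))
  expect_equal(nrow(d), 4)
  expect_equal(sum(d$validation != "valid"), 1)
  expect_true(all(d$status[d$validation != "valid"] != "ok"))
  # gene002 still has other candidates; the duplicated one must not be selected
  sel <- d[d$gene == "gene002", ]
  if (sel$status == "ok") expect_false(sel$selected_offset_nt == 15)

  # determinism: two runs are byte-identical on disk
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_design_tsv(d, f1)
  suppressWarnings(write_design_tsv(design_genome(fx$genome, fx$orfs), f2))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a gene whose only candidate is duplicated is flagged as unqualifying", {
  # single-candidate ORF: C-free background and spacer, so the planted CC
  # site is the only candidate
  spacer <- "ATGATGATGATGATGATGAT"
  site23 <- paste0("CC", "A", spacer)
  body <- strrep("AT", 45)
  coding <- paste0("ATG", substr(body, 1, 20), site23,
                   substr(body, 44, nchar(body)), "TAA")
  genome <- genome_record(paste0(strrep("GA", 20), coding, strrep("GA", 30),
                                 site23, strrep("GA", 10)))
  orfs <- orf_record("solo", 40, 40 + nchar(coding))
  d <- suppressWarnings(design_genome(genome, orfs))
  expect_equal(d$n_candidates, 1L)
  expect_equal(d$status, "no qualifying sgRNA")
})

test_that("both-strand scanning adds template-strand candidates within the window", {
  # plant a CC site on the minus strand inside a plus-strand gene
  spacer <- random_spacer(700)
  fx <- make_genome(genome_length = 3000, n_orfs = 2, seed = 701,
                    planted_sites = planted_site(spacer, "CC", 0,
                                                 host = "gene001",
                                                 strand = "-", pam_n = "A",
                                                 host_offset = 30))
  orfs <- validate_orfs(fx$orfs, fx$genome)
  both <- enumerate_candidates(orfs, fx$genome,
                               design_params(scan_both_strands = TRUE))
  coding_only <- enumerate_candidates(orfs, fx$genome)
  expect_gt(nrow(both), nrow(coding_only))
  tmpl <- both[both$scanned_strand == "template" & both$gene == "gene001", ]
  expect_true(any(tmpl$protospacer20 == spacer))
  expect_true(all(both$offset_nt <= 150))
})
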