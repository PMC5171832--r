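test_that("expression tables load with derived fold changes and flags", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tRPKM_uninduced\tRPKM_induced",
               "a\t100\t25", "b\t0\t5", "c\t10\t10"), f)
  tb <- load_expression(f)
  expect_equal(nrow(tb), 3)
  expect_equal(tb$log2_fold_change[tb$gene == "a"], -2)
  expect_true(is.na(tb$log2_fold_change[tb$gene == "b"]))
  expect_false(tb$fc_defined[tb$gene == "b"])
  expect_equal(tb$log2_fold_change[tb$gene == "c"], 0)

  dupf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tu\ti", "a\t1\t1", "a\t2\t2"), dupf)
  expect_error(load_expression(dupf), "duplicate")
})

test_that("match subsets recover planted sites inside genes", {
  spacer <- random_spacer(41)
  fx <- make_genome(
    genome_length = 6000, n_orfs = 5, seed = 42,
    planted_sites = dplyr::bind_rows(
      planted_site(spacer, "CC", 0, host = "gene001", host_offset = 30),
      planted_site(spacer, "CT", 0, host = "gene003", host_offset = 40,
                   strand = "-"),
      planted_site(spacer, "CC", 2, host = "gene004", host_offset = 25),
      planted_site(spacer, "TC", 3, host = "gene005", host_offset = 50)))
  m <- build_subsets(fx$genome, fx$orfs, spacer)
  expect_true("gene001" %in% subset_genes(m, "region1_exact"))
  expect_true("gene003" %in% subset_genes(m, "region1_exact"))  # minus strand
  expect_true("gene001" %in% subset_genes(m, "region12_le2mm"))
  expect_true("gene005" %in% subset_genes(m, "mm3"))
  # the 2-mismatch site joins region12_le2mm only if its mismatches fall in
  # the first 12 nt; either way it cannot be a 3- or 4-mismatch member
  expect_false("gene004" %in% subset_genes(m, "mm3"))
  expect_false("gene004" %in% subset_genes(m, "mm4"))
  # memberships record the planted distances
  expect_equal(min(m$dist20[m$gene == "gene001"]), 0L)

  # oracle equivalence of the underlying window scan, per gene extent
  sc <- oracle_tier_scan(fx$genome$sequence[[1]], spacer)
  for (g in fx$orfs$gene) {
    o <- fx$orfs[fx$orfs$gene == g, ]
    inside <- sc[sc$fwd_start >= o$start & sc$fwd_start + 23 <= o$end, ]
    expect_equal(sort(unique(m$dist20[m$gene == g])),
                 sort(unique(inside$dist[
                   (inside$dist %in% c(3, 4)) |
                     vapply(inside$win23, function(w)
                       substr(w, 4, 10) == substr(spacer, 1, 7) ||
                       oracle_hamming(substr(w, 4, 15),
                                      substr(spacer, 1, 12)) <= 2,
                       logical(1))])),
                 info = g)
  }
})

test_that("no planted deep-mismatch sites means an empty mm4 tier", {
  spacer <- random_spacer(43)
  fx <- make_genome(genome_length = 3000, n_orfs = 2, seed = 44,
                    planted_sites = planted_site(spacer, "CC", 0,
                                                 host = "gene001",
                                                 host_offset = 10))
  m <- build_subsets(fx$genome, fx$orfs, spacer)
  expect_equal(subset_genes(m, "mm4"), character(0))
})

test_that("self-comparison gives statistic 0 and p = 1", {
  tb <- make_expression(n_genes = 300, knockdown_fold = 1, seed = 9)
  res <- compare_to_global(tb, tb$gene)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  empty <- compare_to_global(tb, character(0))
  expect_false(empty$testable)
})

test_that("a shifted subset is detected, a null subset is not biased", {
  tb <- make_expression(n_genes = 4000, knockdown_fold = 1, seed = 10)
  # synthetic alternative: shift 50 genes down 2 log2 units
  shifted <- tb
  idx <- 101:150
  shifted$abundance_induced[idx] <- shifted$abundance_induced[idx] / 4
  shifted <- expression_fold_changes(shifted[, 1:3])
  res <- compare_to_global(shifted, shifted$gene[idx])
  expect_lt(res$p_value, 0.01)

  # small null calibration here; the full 1000-replicate calibration runs in
  # the acceptance suite
  withr::with_seed(11, {
    p <- replicate(150, {
      sub <- sample(tb$gene, 50)
      compare_to_global(tb, sub)$p_value
    })
  })
  expect_gt(mean(p < 0.05), 0.005)
  expect_lt(mean(p < 0.05), 0.12)
})

test_that("the on-target gene ranks first under a strong knockdown", {
  tb <- make_expression(n_genes = 500, target_gene = "g0042",
                        knockdown_fold = 32, noise_cv = 0.2, seed = 12)
  sub <- c("g0042", sprintf("g%04d", 1:40))
  expect_equal(on_target_rank(tb, sub, "g0042"), 1L)
  expect_error(on_target_rank(tb, sub, "missing"), "not in the subset")
})

test_that("tied fold changes share the better rank; worst case is |subset|", {
  tb <- expression_fold_changes(tibble::tibble(
    gene = c("a", "b", "c"),
    abundance_uninduced = c(100, 100, 100),
    abundance_induced = c(25, 25, 400)))
  expect_equal(on_target_rank(tb, c("a", "b", "c"), "a"), 1L)
  expect_equal(on_target_rank(tb, c("a", "b", "c"), "b"), 1L)
  expect_equal(on_target_rank(tb, c("a", "b", "c"), "c"), 3L)
})

test_that("hamming_vs_repression finds monotone relations and handles degeneracy", {
  # perfectly monotone synthetic relation
  tb <- expression_fold_changes(tibble::tibble(
    gene = sprintf("g%02d", 1:10),
    abundance_uninduced = rep(100, 10),
    abundance_induced = 100 * 2^(seq(-5, -0.5, by = 0.5))))
  m <- tibble::tibble(tier = "region1_exact", gene = tb$gene,
                      site_start = 0L, site_strand = "+", prefix = "CC",
                      dist20 = 1:10)
  res <- hamming_vs_repression(tb, m)
  expect_equal(res$rho, 1)

  # independence: |rho| small at n = 200
  withr::with_seed(13, {
    tb2 <- make_expression(n_genes = 200, knockdown_fold = 1, seed = 14)
    m2 <- tibble::tibble(tier = "mm3", gene = tb2$gene, site_start = 0L,
                         site_strand = "+", prefix = "CC",
                         dist20 = sample(0:4, 200, replace = TRUE))
    res2 <- hamming_vs_repression(tb2, m2)
    expect_lt(abs(res2$rho), 0.15)
  })

  # constant fold change -> undefined
  tb3 <- expression_fold_changes(tibble::tibble(
    gene = c("a", "b", "c"), abundance_uninduced = c(1, 1, 1),
    abundance_induced = c(2, 2, 2)))
  m3 <- m[1:3, ]; m3$gene <- c("a", "b", "c")
  expect_false(hamming_vs_repression(tb3, m3)$testable)
  # fewer than 3 members -> not testable
  expect_false(hamming_vs_repression(tb3, m3[1:2, ])$testable)
})

test_that("audit_expression reports per tier and ranks the target", {
  spacer <- random_spacer(60)
  fx <- make_genome(genome_length = 5000, n_orfs = 4, seed = 61,
                    planted_sites = planted_site(spacer, "CC", 0,
                                                 host = "gene002",
                                                 host_offset = 12))
  genes <- fx$orfs$gene
  tb <- make_expression(n_genes = 200, target_gene = "gene002",
                        knockdown_fold = 16, noise_cv = 0.2, seed = 62)
  # row 1 carries the knockdown; map the remaining fixture genes onto rows 2-4
  tb$gene[2:4] <- setdiff(genes, "gene002")
  tb <- expression_fold_changes(tb[, 1:3])
  aud <- audit_expression(tb, fx$genome, fx$orfs, spacer,
                          target_gene = "gene002")
  expect_setequal(aud$report$tier,
                  c("region1_exact", "region12_le2mm", "mm3", "mm4"))
  r1 <- aud$report[aud$report$tier == "region1_exact", ]
  expect_equal(r1$on_target_rank, 1L)
  expect_true("gene002" %in% subset_genes(aud$memberships, "region1_exact"))
})
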