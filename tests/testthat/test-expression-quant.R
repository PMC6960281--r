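test_that("one proper pair spreads mass 1/N over its span", {
  g <- sim_genome(400L, gc = 0.5, seed = 420, contig_ids = "chr1")
  sam <- withr::local_tempfile(fileext = ".sam")
  sim_sam(tibble::tibble(contig = "chr1", start = 100L, end = 199L), g, sam)
  cov <- fragment_coverage(sam, g)
  v <- coverage_vector(cov, "chr1")
  expect_equal(cov$total_fragments, 1L)
  expect_equal(v[100:199], rep(0.01, 100))
  expect_equal(sum(v), 1.0, tolerance = 1e-9)
  expect_equal(v[99], 0)
  expect_equal(v[200], 0)
})

test_that("distinct spans produce the expected plateau heights and total mass", {
  g <- sim_genome(1000L, gc = 0.5, seed = 421, contig_ids = "chr1")
  frs <- tibble::tibble(contig = "chr1",
                        start = c(1L, 101L, 301L),
                        end = c(50L, 200L, 450L))  # spans 50, 100, 150
  sam <- withr::local_tempfile(fileext = ".sam")
  sim_sam(frs, g, sam)
  cov <- fragment_coverage(sam, g)
  v <- coverage_vector(cov, "chr1")
  expect_equal(sum(v), 3.0, tolerance = 1e-9)
  expect_equal(unique(v[1:50]), 1 / 50)
  expect_equal(unique(v[101:200]), 1 / 100)
  expect_equal(unique(v[301:450]), 1 / 150)
})

test_that("an empty SAM gives a zero vector; RPKM on it is an error", {
  g <- sim_genome(200L, gc = 0.5, seed = 422, contig_ids = "chr1")
  sam <- withr::local_tempfile(fileext = ".sam")
  sim_sam(tibble::tibble(contig = character(0), start = integer(0),
                         end = integer(0)), g, sam)
  cov <- fragment_coverage(sam, g)
  expect_equal(cov$total_fragments, 0L)
  expect_equal(sum(coverage_vector(cov, "chr1")), 0)
  genes <- tibble::tibble(feature_id = "g1", contig = "chr1",
                          start = 1L, end = 100L)
  expect_error(gene_rpkm(cov, genes), "zero usable fragments")
})

test_that("unmapped, secondary and malformed records are skipped and tallied", {
  g <- genome_set(c(chr1 = strrep("ACGT", 100)))
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:400",
    # a good single-end read of 50 bp at 11
    paste("r1", 0, "chr1", 11, 60, "50M", "*", 0, 0,
          strrep("A", 50), "*", sep = "\t"),
    # unmapped
    paste("r2", 4, "*", 0, 0, "*", "*", 0, 0, "*", "*", sep = "\t"),
    # secondary alignment
    paste("r3", 256, "chr1", 20, 60, "50M", "*", 0, 0,
          strrep("A", 50), "*", sep = "\t"),
    # pair whose fragment runs off the contig
    paste("r4", 99, "chr1", 390, 60, "10M", "=", 395, 20,
          strrep("A", 10), "*", sep = "\t"),
    paste("r4", 147, "chr1", 395, 60, "10M", "=", 390, -20,
          strrep("A", 10), "*", sep = "\t")
  ), sam)
  cov <- fragment_coverage(sam, g)
  expect_equal(cov$total_fragments, 1L)
  expect_gte(cov$n_skipped, 3L)
  v <- coverage_vector(cov, "chr1")
  expect_equal(sum(v), 1.0, tolerance = 1e-9)
  expect_equal(unique(v[11:60]), 1 / 50)
})

test_that("RPKM unit arithmetic and pseudocount floor behave as stated", {
  g <- sim_genome(2000L, gc = 0.5, seed = 423, contig_ids = "chr1")
  # 10 fragments wholly inside a 1 kb gene; nothing elsewhere
  frs <- tibble::tibble(contig = "chr1",
                        start = as.integer(seq(101, by = 80, length.out = 10)),
                        end = as.integer(seq(101, by = 80, length.out = 10)) + 59L)
  sam <- withr::local_tempfile(fileext = ".sam")
  sim_sam(frs, g, sam)
  cov <- fragment_coverage(sam, g)
  genes <- tibble::tibble(feature_id = c("on", "off"), contig = "chr1",
                          start = c(101L, 1201L), end = c(1100L, 1400L))
  t_off <- gene_rpkm(cov, genes, pseudocount_mode = "off")
  # mass 10 over 1 kb in a 10-fragment library: 10 / 1 / (10/1e6) = 1e6
  expect_equal(t_off$fragment_mass, c(10, 0), tolerance = 1e-9)
  expect_equal(t_off$rpkm[1], 1e6, tolerance = 1e-6)
  expect_equal(t_off$rpkm[2], 0)

  t_pg <- gene_rpkm(cov, genes, pseudocount_mode = "per_gene")
  expect_equal(t_pg$fragment_mass, c(11, 1), tolerance = 1e-9)
  # zero-coverage gene floor: 1 / (0.2 kb) / (10/1e6)
  expect_equal(t_pg$rpkm[2], 1 / 0.2 / (10 / 1e6), tolerance = 1e-9)

  t_pp <- gene_rpkm(cov, genes, pseudocount_mode = "per_position",
                    pseudocount = 0.01)
  expect_equal(t_pp$fragment_mass, c(10 + 0.01 * 1000, 0 + 0.01 * 200),
               tolerance = 1e-9)
  expect_true(all(t_pp$rpkm > 0))
})

test_that("RPKM is invariant under duplicating every alignment", {
  b <- make_fixture_bundle("rnaseq-demo", seed = 424,
                           out_dir = withr::local_tempdir())
  g <- read_genome_fasta(b$paths$genome)
  cov1 <- fragment_coverage(b$paths$sam_b, g)
  doubled <- dplyr::bind_rows(b$fragments_b, b$fragments_b)
  sam2 <- withr::local_tempfile(fileext = ".sam")
  sim_sam(doubled, g, sam2)
  cov2 <- fragment_coverage(sam2, g)
  expect_equal(cov2$total_fragments, 2L * cov1$total_fragments)
  t1 <- gene_rpkm(cov1, b$genes, "off")
  t2 <- gene_rpkm(cov2, b$genes, "off")
  expect_equal(t2$rpkm, t1$rpkm, tolerance = 1e-9)
})

test_that("mass is conserved and planted fold changes are recovered", {
  b <- make_fixture_bundle("rnaseq-demo", seed = 425,
                           out_dir = withr::local_tempdir())
  g <- read_genome_fasta(b$paths$genome)
  cov_a <- fragment_coverage(b$paths$sam_a, g)
  cov_b <- fragment_coverage(b$paths$sam_b, g)
  for (cov in list(cov_a, cov_b)) {
    total_mass <- sum(vapply(names(cov$coverage),
                             function(cid) sum(coverage_vector(cov, cid)),
                             numeric(1)))
    expect_equal(total_mass, cov$total_fragments, tolerance = 1e-6)
  }
  lfc <- log2_fold_change(gene_rpkm(cov_a, b$genes, "off"),
                          gene_rpkm(cov_b, b$genes, "off"))
  merged <- dplyr::left_join(lfc, b$ledger, by = "feature_id")
  expect_equal(merged$log2_ratio,
               merged$expected_log2_ratio_no_pseudocount,
               tolerance = 1e-9)
  # induction relative to the unperturbed genes is exactly log2(4) = 2
  induced <- merged$log2_ratio[merged$fragments_experimental >
                                 merged$fragments_control]
  baseline <- stats::median(merged$log2_ratio)
  expect_equal(induced - baseline, 2, tolerance = 1e-9)

  # with the default per-gene pseudocount everything stays finite and close
  lfc_pg <- log2_fold_change(gene_rpkm(cov_a, b$genes),
                             gene_rpkm(cov_b, b$genes))
  expect_true(all(is.finite(lfc_pg$log2_ratio)))
  merged_pg <- dplyr::left_join(lfc_pg, b$ledger, by = "feature_id")
  expect_equal(
    merged_pg$log2_ratio[merged_pg$fragments_experimental >
                           merged_pg$fragments_control] -
      stats::median(merged_pg$log2_ratio),
    2, tolerance = 0.25)
})

test_that("identical and doubled tables give log-ratios 0 and 1", {
  b <- make_fixture_bundle("rnaseq-demo", seed = 426,
                           out_dir = withr::local_tempdir())
  g <- read_genome_fasta(b$paths$genome)
  cov <- fragment_coverage(b$paths$sam_b, g)
  tb <- gene_rpkm(cov, b$genes)
  expect_equal(log2_fold_change(tb, tb)$log2_ratio, rep(0, nrow(tb)))
  tb2 <- dplyr::mutate(tb, rpkm = rpkm * 2)
  expect_equal(log2_fold_change(tb2, tb)$log2_ratio, rep(1, nrow(tb)))
  expect_error(log2_fold_change(tb[-1, ], tb), "gene sets differ")
})
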