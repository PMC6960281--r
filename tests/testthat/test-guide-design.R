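sth3 <- crispri_systems()$Sth3
base28 <- "TTTTTTTTTTTTTTTTTTTTAGGCGTTT"

tss_row <- function(pos, strand, id = "geneX", contig = "c1",
                    cds = NA_integer_) {
  tibble::tibble(feature_id = id, operon_id = NA_character_,
                 contig = contig, tss_pos = as.integer(pos),
                 strand = strand, cds_start = as.integer(cds))
}

test_that("the default window is 150 bp, oriented and clipped correctly", {
  g <- genome_set(c(c1 = strrep("A", 2000)))
  w_plus <- transcript_window(tss_row(1000, "+"), g)
  expect_equal(c(w_plus$win_start, w_plus$win_end), c(950L, 1099L))
  expect_equal(w_plus$win_end - w_plus$win_start + 1L, 150L)

  w_minus <- transcript_window(tss_row(1000, "-"), g)
  expect_equal(c(w_minus$win_start, w_minus$win_end), c(901L, 1050L))
  expect_equal(w_minus$win_end - w_minus$win_start + 1L, 150L)

  w_clip <- transcript_window(tss_row(10, "+"), g)
  expect_equal(c(w_clip$win_start, w_clip$win_end), c(1L, 109L))

  g_small <- genome_set(c(c1 = strrep("A", 30)))
  w_off <- transcript_window(tss_row(5, "-"), g_small,
                             upstream = -200, downstream = -100)
  expect_true(is.na(w_off$win_start))

  expect_error(transcript_window(tss_row(10, "+"), g, upstream = 100,
                                 downstream = -50), "upstream")
})

test_that("targeting-class bookkeeping follows base-pairing with the nontemplate strand", {
  expect_equal(classify_targeting_strand("-", "+"), "nontemplate")
  expect_equal(classify_targeting_strand("+", "+"), "template")
  expect_equal(classify_targeting_strand("+", "-"), "nontemplate")
  expect_equal(classify_targeting_strand("-", "-"), "template")
  expect_error(classify_targeting_strand("*", "+"), "strand")
})

test_that("single-TSS design matches manual bookkeeping on the 28-mer", {
  g <- genome_set(c(c1 = base28))
  # gene on "-" with TSS at 28: the + strand protospacer is nontemplate
  des <- design_for_tss(g, tss_row(28, "-"), sth3)
  expect_equal(nrow(des), 1)
  expect_equal(c(des$proto_start, des$proto_end), c(1L, 20L))
  expect_equal(des$strand, "+")
  expect_equal(des$targeting_class, "nontemplate")
  expect_true(des$unique)
  expect_equal(des$tss_offset, 8L)

  # gene on "+" with TSS at 1: same protospacer is template class
  expect_equal(nrow(design_for_tss(g, tss_row(1, "+"), sth3)), 0)
  all_rows <- design_for_tss(g, tss_row(1, "+"), sth3, class = "all")
  expect_equal(all_rows$targeting_class, "template")

  # TSS with no PAM in window
  g2 <- genome_set(c(c1 = strrep("A", 400)))
  expect_equal(nrow(design_for_tss(g2, tss_row(200, "+"), sth3)), 0)
})

test_that("emitted candidates sit inside their windows and carry the genome sequence", {
  b <- make_fixture_bundle("coverage-demo", seed = 11, out_dir = withr::local_tempdir())
  g <- read_genome_fasta(b$paths$genome)
  tss <- read_tss_table(b$paths$tss, g)
  des <- design_guides(g, tss, crispri_systems(), class = "all")
  expect_gt(nrow(des), 0)
  expect_true(all(des$proto_start >= des$win_start &
                    des$proto_end <= des$win_end))
  seqs <- setNames(as.character(g), names(g))
  fwd <- vapply(seq_len(nrow(des)), function(i) {
    substr(seqs[[des$contig[i]]], des$proto_start[i], des$proto_end[i])
  }, character(1))
  on_strand <- ifelse(des$strand == "+", fwd,
                      vapply(fwd, oracle_revcomp, character(1), USE.NAMES = FALSE))
  expect_equal(on_strand, des$targeting_seq)
  # nontemplate candidates: revcomp(targeting) is the gene-strand sequence
  nt <- des[des$targeting_class == "nontemplate", ]
  expect_true(all(nt$strand != nt$gene_strand))
})

test_that("design is invariant under genome reflection", {
  withr::with_seed(406, {
    for (i in 1:10) {
      b <- make_fixture_bundle("coverage-demo", seed = 500 + i,
                               out_dir = tempfile())
      g <- read_genome_fasta(b$paths$genome)
      tss <- read_tss_table(b$paths$tss, g)
      L <- Biostrings::width(g)[1]
      des <- design_guides(g, tss, crispri_systems())

      g_rc <- genome_set(setNames(oracle_revcomp(as.character(g[[1]])),
                                  names(g)[1]))
      tss_rc <- tss
      tss_rc$tss_pos <- L - tss$tss_pos + 1L
      tss_rc$strand <- ifelse(tss$strand == "+", "-", "+")
      tss_rc$cds_start <- ifelse(is.na(tss$cds_start), NA_integer_,
                                 L - tss$cds_start + 1L)
      des_rc <- design_guides(g_rc, tss_rc, crispri_systems())

      expect_equal(nrow(des), nrow(des_rc))
      key <- function(d, mirror = FALSE) {
        s <- if (mirror) L - d$proto_end + 1L else d$proto_start
        e <- if (mirror) L - d$proto_start + 1L else d$proto_end
        sort(paste(d$system, d$feature_id, s, e, d$targeting_seq,
                   d$unique))
      }
      expect_equal(key(des), key(des_rc, mirror = TRUE))
      expect_equal(sort(des$tss_offset), sort(des_rc$tss_offset))
    }
  })
})

test_that("genome-wide design recovers planting ledgers exactly", {
  withr::with_seed(407, {
    systems <- crispri_systems()
    for (i in 1:50) {
      g <- sim_genome(4000L, gc = 0, contig_ids = "chr1")
      n_genes <- 3L
      tss <- tibble::tibble(
        feature_id = paste0("g", 1:n_genes),
        operon_id = NA_character_, contig = "chr1",
        tss_pos = c(400L, 1800L, 3200L),
        strand = sample(c("+", "-"), n_genes, replace = TRUE),
        cds_start = NA_integer_
      )
      ledger <- list()
      for (j in 1:n_genes) {
        sp <- systems[[sample(1:2, 1)]]
        pos <- tss$tss_pos[j] + if (tss$strand[j] == "+") 10L else -40L
        pl <- plant_guide_site(g, sp, gene_strand = tss$strand[j],
                               position = pos,
                               feature_id = tss$feature_id[j])
        g <- pl$genome
        ledger[[j]] <- pl$ledger
      }
      ledger <- dplyr::bind_rows(ledger)
      des <- design_guides(g, tss, systems)
      # exact recovery: no false positives, no false negatives
      key <- function(d, sys, st) {
        sort(paste(d[[sys]], d$feature_id, d$proto_start, d$proto_end,
                   d[[st]], d$targeting_seq))
      }
      expect_equal(key(des, "system", "strand"),
                   key(ledger, "system", "proto_strand"))
      expect_true(all(des$unique))
      expect_true(all(des$targeting_class == "nontemplate"))
    }
  })
})

test_that("genes with several TSS records are designed independently", {
  g <- genome_set(c(c1 = paste0(base28, strrep("A", 100), base28)))
  tss <- dplyr::bind_rows(tss_row(28, "-", id = "geneX"),
                          tss_row(156, "-", id = "geneX"))
  des <- design_guides(g, tss, sth3)
  # both planted copies share a seed -> non-unique, but both TSSs get a row
  expect_equal(nrow(des), 2)
  expect_equal(des$tss_pos, c(28L, 156L))
  expect_true(all(!des$unique))
  expect_equal(des$seed_count, c(2L, 2L))
})

test_that("beyond_cds_start flags protospacers at or past the start codon", {
  # + strand gene whose nontemplate candidate sits on "-" at [9,28]
  g <- genome_set(c(c1 = paste0(oracle_revcomp(base28), strrep("A", 22))))
  des1 <- design_for_tss(g, tss_row(1, "+", cds = 35), sth3)
  expect_equal(c(des1$proto_start, des1$proto_end), c(9L, 28L))
  expect_false(des1$beyond_cds_start)
  des2 <- design_for_tss(g, tss_row(1, "+", cds = 20), sth3)
  expect_true(des2$beyond_cds_start)
  # gene on "-": a protospacer downstream of the start codon is flagged
  g3 <- genome_set(c(c1 = base28))
  des3 <- design_for_tss(g3, tss_row(28, "-", cds = 21), sth3)
  expect_true(des3$beyond_cds_start)  # proto [1,20] wholly past cds 21
})

test_that("the PAM containment toggle drops edge-straddling PAMs", {
  g <- genome_set(c(c1 = base28))
  tss <- tss_row(28, "-")
  # window [1,24] contains the protospacer [1,20] but clips PAM [21,25]
  des_loose <- design_guides(g, tss, sth3, upstream = 4L, downstream = 28L)
  expect_equal(nrow(des_loose), 1)
  des_strict <- design_guides(g, tss, sth3, upstream = 4L,
                              downstream = 28L,
                              require_pam_in_window = TRUE)
  expect_equal(nrow(des_strict), 0)
})

test_that("design output is deterministic file to file", {
  b <- make_fixture_bundle("minimal", seed = 21, out_dir = withr::local_tempdir())
  g <- read_genome_fasta(b$paths$genome)
  tss <- read_tss_table(b$paths$tss, g)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_candidates(design_guides(g, tss, crispri_systems()), f1, "tsv")
  write_candidates(design_guides(g, tss, crispri_systems()), f2, "tsv")
  expect_identical(readLines(f1), readLines(f2))
})
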