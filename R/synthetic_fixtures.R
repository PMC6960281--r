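#' Simulate a random genome with a given GC content
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1-gc)/2` from a seeded Mersenne-Twister generator, so
#' the same `(length, gc, seed)` always yields the same sequence on any
#' platform. A GC of 0.67 emulates a GC-rich alphaproteobacterial genome.
#'
#' @param length Contig length(s) in bp (vector for multiple contigs).
#' @param gc GC fraction in `[0, 1]` (default 0.67).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param contig_ids Contig names (defaults `chr1`, `chr2`, ...).
#' @param topology Passed to [genome_set()].
#' @return A genome.
#' @examples
#' sim_genome(100, gc = 0.67, seed = 1)
#' @export
sim_genome <- function(length, gc = 0.67, seed = NULL,
                       contig_ids = NULL, topology = "linear") {
  stopifnot(gc >= 0, gc <= 1, all(length > 0))
  contig_ids <- contig_ids %||% paste0("chr", seq_along(length))
  stopifnot(length(contig_ids) == length(length))
  draw <- function() {
    seqs <- vapply(length, function(L) {
      paste(sample(c("G", "C", "A", "T"), L, replace = TRUE,
                   prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
            collapse = "")
    }, character(1))
    genome_set(setNames(seqs, contig_ids), topology = topology)
  }
  if (is.null(seed)) draw() else with_fixture_seed(seed, draw())
}

# All fixture randomness goes through one pinned RNG configuration.
with_fixture_seed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

# Least-degenerate concrete instantiation of an IUPAC motif: each
# ambiguity code is replaced by the first base of its set (N -> A), so
# NGGNG plants as AGGAG and NNGTGA as AAGTGA.
concrete_pam <- function(pam) {
  paste(vapply(strsplit(pam, "", fixed = TRUE)[[1]],
               function(ch) IUPAC_SETS[[ch]][1], character(1)),
        collapse = "")
}

# Brute-force count of PAM-adjacent occurrences of `seed` in a genome
# string, both strands (generator-internal sanity check for re-rolling).
count_seed_adjacent_chr <- function(seq_chr, seed, pam) {
  pat_sets <- function(s) IUPAC_SETS[strsplit(s, "", fixed = TRUE)[[1]]]
  matches_at <- function(chars, sets, at) {
    all(mapply(function(set, off) chars[at + off - 1] %in% set,
               sets, seq_along(sets)))
  }
  count_one_strand <- function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    sets <- c(pat_sets(seed), pat_sets(pam))
    w <- length(sets)
    n <- 0L
    if (length(chars) < w) return(0L)
    for (at in seq_len(length(chars) - w + 1)) {
      if (matches_at(chars, sets, at)) n <- n + 1L
    }
    n
  }
  count_one_strand(seq_chr) + count_one_strand(revcomp(seq_chr))
}

#' Plant a guide site into a genome
#'
#' Writes a protospacer followed by a concrete PAM instantiation into the
#' genome so that a gene on `gene_strand` gains a candidate of the desired
#' targeting class at a known position. For a nontemplate-class candidate
#' the protospacer goes on the genomic strand opposite the gene; for
#' template class, on the gene's strand. When `unique = FALSE` a second
#' PAM-adjacent copy of the seed is written at `dup_position`. The random
#' targeting sequence is re-rolled (up to `max_tries`) until its
#' genome-wide PAM-adjacent seed count matches the expectation, so the
#' returned ledger entry is guaranteed to hold in the emitted genome.
#'
#' @param genome Genome to modify.
#' @param spec A [pam_spec()].
#' @param gene_strand Strand of the (notional) gene, `"+"` or `"-"`.
#' @param position Forward-axis 1-based start of the planted block
#'   (protospacer + PAM, total `protospacer_len + nchar(pam)` bases).
#' @param class Desired targeting class (default `"nontemplate"`).
#' @param unique Should the planted seed be genome-wide unique?
#' @param feature_id Label recorded in the ledger.
#' @param contig Contig to plant into (default: first).
#' @param dup_position Start of the seed+PAM duplicate when
#'   `unique = FALSE`.
#' @param alphabet Bases the random targeting sequence is drawn from. The
#'   default `c("A","T")` guarantees, in an A/T backbone, that the planted
#'   block contains exactly one occurrence of the system's motif (G/C-free
#'   spacers cannot form additional NGGNG/NNGTGA windows), so ledger
#'   expectations are exact; pass all four bases for realistic spacers.
#' @param max_tries Re-roll attempts before giving up.
#' @return List with `genome` (modified) and `ledger` (one-row tibble:
#'   coordinates, strand, sequences, expected class and uniqueness).
#' @export
plant_guide_site <- function(genome, spec, gene_strand, position,
                             class = c("nontemplate", "template"),
                             unique = TRUE, feature_id = NA_character_,
                             contig = NULL, dup_position = NULL,
                             alphabet = c("A", "T"), max_tries = 50L) {
  class <- match.arg(class)
  stopifnot(gene_strand %in% c("+", "-"))
  contig <- contig %||% names(genome)[1]
  seq_chr <- as.character(genome[[contig]])
  L <- nchar(seq_chr)
  P <- spec$protospacer_len
  m <- nchar(spec$pam)
  block_len <- P + m
  if (position < 1 || position + block_len - 1 > L) {
    abort("insufficient space to plant the site")
  }
  if (!unique && is.null(dup_position)) {
    abort("dup_position is required when unique = FALSE")
  }
  if (!unique) {
    dup_len <- spec$seed_len + m
    if (dup_position < 1 || dup_position + dup_len - 1 > L) {
      abort("insufficient space for the seed duplicate")
    }
  }
  proto_strand <- if (class == "nontemplate") {
    if (gene_strand == "+") "-" else "+"
  } else {
    gene_strand
  }
  pam_concrete <- concrete_pam(spec$pam)
  want <- if (unique) 1L else 2L

  for (try in seq_len(max_tries)) {
    targeting <- paste(sample(alphabet, P, replace = TRUE), collapse = "")
    seed_seq <- substr(targeting, P - spec$seed_len + 1L, P)
    block <- paste0(targeting, pam_concrete)
    fwd_block <- if (proto_strand == "+") block else revcomp(block)
    trial <- seq_chr
    substr(trial, position, position + block_len - 1L) <- fwd_block
    if (!unique) {
      dup <- paste0(seed_seq, pam_concrete)
      substr(trial, dup_position, dup_position + nchar(dup) - 1L) <- dup
    }
    got <- count_seed_adjacent_chr(trial, seed_seq, spec$pam)
    if (got == want) {
      seq_chr <- trial
      break
    }
    if (try == max_tries) {
      abort("could not plant a site with the requested seed multiplicity")
    }
  }

  if (proto_strand == "+") {
    proto_start <- position; proto_end <- position + P - 1L
    pam_start <- position + P; pam_end <- position + block_len - 1L
  } else {
    pam_start <- position; pam_end <- position + m - 1L
    proto_start <- position + m; proto_end <- position + block_len - 1L
  }
  seqs <- setNames(as.character(genome), names(genome))
  seqs[[contig]] <- seq_chr
  ledger <- tibble(
    feature_id = feature_id, system = spec$system_name, contig = contig,
    gene_strand = gene_strand, targeting_class = class,
    proto_strand = proto_strand,
    proto_start = as.integer(proto_start), proto_end = as.integer(proto_end),
    pam_start = as.integer(pam_start), pam_end = as.integer(pam_end),
    targeting_seq = targeting, seed_seq = seed_seq,
    expected_unique = unique
  )
  list(genome = genome_set(seqs, genome_topology(genome)), ledger = ledger)
}

#' Write synthetic paired-end alignments as SAM
#'
#' Emits one proper pair per requested fragment: two `read_len`-base
#' mates at the fragment ends with TLEN set to the span, so the fragment
#' contributes exactly mass 1 to [fragment_coverage()].
#'
#' @param fragments Tibble with `contig`, `start`, `end` (1-based
#'   inclusive fragment spans).
#' @param genome Genome the fragments refer to (for `@SQ` lines and read
#'   sequences).
#' @param path Output SAM path.
#' @param read_len Mate length (shrunk when a fragment is shorter than
#'   two mates).
#' @return `path`, invisibly.
#' @export
sim_sam <- function(fragments, genome, path, read_len = 50L) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  seqs <- setNames(as.character(genome), names(genome))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens), con)
  if (nrow(fragments) > 0) {
    for (i in seq_len(nrow(fragments))) {
      cid <- fragments$contig[i]
      s <- fragments$start[i]
      e <- fragments$end[i]
      span <- e - s + 1L
      rl <- max(1L, min(read_len, span %/% 2L))
      qn <- sprintf("frag%05d", i)
      p1 <- s
      p2 <- e - rl + 1L
      sq1 <- substr(seqs[[cid]], p1, p1 + rl - 1L)
      sq2 <- substr(seqs[[cid]], p2, p2 + rl - 1L)
      cg <- paste0(rl, "M")
      writeLines(paste(qn, 99L, cid, p1, 60L, cg, "=", p2, span,
                       sq1, strrep("I", rl), sep = "\t"), con)
      writeLines(paste(qn, 147L, cid, p2, 60L, cg, "=", p1, -span,
                       revcomp(sq2), strrep("I", rl), sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Generate a named, self-consistent fixture bundle on disk
#'
#' Profiles: `"minimal"` (1 contig, 2 genes, 1 planted nontemplate
#' guide), `"coverage-demo"` (6 genes with TSSs; unique nontemplate
#' guides planted for 4, a deliberately non-unique site for 1, nothing
#' for 1 - gene-level targetability 4/6) and `"rnaseq-demo"`
#' (10 genes, paired-end SAMs for an experimental and a control library
#' with a 4-fold induction planted on one gene). The design-oriented
#' profiles use an A/T-only backbone so the planted blocks are the only
#' PAM sources and ledger expectations are exact; `rnaseq-demo` uses a
#' GC-rich (0.67) backbone. Every bundle is byte-reproducible from
#' `(profile, seed)` and ships a planting ledger (JSON) whose every entry
#' is verifiable against the emitted FASTA.
#'
#' @param profile One of `"minimal"`, `"coverage-demo"`, `"rnaseq-demo"`.
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`genome`, `tss`,
#'   `ledger`, profile-specific extras) and the written `paths`.
#' @export
make_fixture_bundle <- function(profile = c("minimal", "coverage-demo",
                                            "rnaseq-demo"),
                                seed = 1L, out_dir) {
  profile <- match.arg(profile)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- with_fixture_seed(seed, switch(profile,
    "minimal" = fixture_minimal(),
    "coverage-demo" = fixture_coverage_demo(),
    "rnaseq-demo" = fixture_rnaseq_demo()
  ))
  paths <- list(
    genome = file.path(out_dir, "genome.fasta"),
    tss = file.path(out_dir, "tss.tsv"),
    ledger = file.path(out_dir, "ledger.json"),
    readme = file.path(out_dir, "README.txt")
  )
  write_genome_fasta(bundle$genome, paths$genome)
  write_tss_table(bundle$tss, paths$tss)
  jsonlite::write_json(bundle$ledger, paths$ledger, dataframe = "rows",
                       digits = NA, pretty = TRUE)
  if (!is.null(bundle$genes)) {
    paths$genes <- file.path(out_dir, "genes.tsv")
    readr::write_tsv(bundle$genes, paths$genes, progress = FALSE)
  }
  if (!is.null(bundle$fragments_a)) {
    paths$sam_a <- file.path(out_dir, "reads_experimental.sam")
    paths$sam_b <- file.path(out_dir, "reads_control.sam")
    sim_sam(bundle$fragments_a, bundle$genome, paths$sam_a)
    sim_sam(bundle$fragments_b, bundle$genome, paths$sam_b)
  }
  writeLines(c(
    sprintf("profile: %s", profile),
    sprintf("seed: %d", seed),
    "expectations: see ledger.json; every planted site is recoverable",
    "by scan -> index -> design and matches the recorded class and",
    "uniqueness; rnaseq-demo fragment masses reproduce the stated",
    "fold change through fragment_coverage/gene_rpkm/log2_fold_change."
  ), paths$readme)
  invisible(c(bundle, list(paths = paths, profile = profile,
                           seed = seed)))
}

fixture_minimal <- function() {
  sp <- crispri_systems()$Sth3
  g <- sim_genome(2000L, gc = 0, contig_ids = "chr1")
  tss <- tibble(
    feature_id = c("geneA", "geneB"),
    operon_id = c("op1", "op2"),
    contig = "chr1",
    tss_pos = c(500L, 1500L),
    strand = c("+", "-"),
    cds_start = c(560L, 1440L)
  )
  # nontemplate site for geneA (+): protospacer on "-", block PAM+proto,
  # protospacer inside window [450, 599]
  pl <- plant_guide_site(g, sp, gene_strand = "+", position = 470L,
                         feature_id = "geneA")
  list(genome = pl$genome, tss = tss, ledger = pl$ledger)
}

fixture_coverage_demo <- function() {
  systems <- crispri_systems()
  g <- sim_genome(8000L, gc = 0, contig_ids = "chr1")
  n_genes <- 6L
  tss <- tibble(
    feature_id = sprintf("gene%02d", seq_len(n_genes)),
    operon_id = sprintf("op%02d", c(1L, 1L, 2L, 3L, 4L, 5L)),
    contig = "chr1",
    tss_pos = as.integer(seq(600L, by = 1200L, length.out = n_genes)),
    strand = rep(c("+", "-"), length.out = n_genes),
    cds_start = NA_integer_
  )
  ledger <- list()
  # unique nontemplate guides for genes 1-4 (genes 1+3 Sth3, 2+4 Spa)
  for (i in 1:4) {
    sp <- if (i %% 2 == 1) systems$Sth3 else systems$Spa
    p <- tss$tss_pos[i] + if (tss$strand[i] == "+") 10L else -35L
    pl <- plant_guide_site(g, sp, gene_strand = tss$strand[i],
                           position = p, feature_id = tss$feature_id[i])
    g <- pl$genome
    ledger[[i]] <- pl$ledger
  }
  # gene 5: planted site whose seed is duplicated -> filtered out
  pl <- plant_guide_site(g, systems$Sth3, gene_strand = tss$strand[5],
                         position = tss$tss_pos[5] - 35L, unique = FALSE,
                         dup_position = 7800L,
                         feature_id = tss$feature_id[5])
  g <- pl$genome
  ledger[[5]] <- pl$ledger
  # gene 6: nothing planted (may or may not be targetable by chance
  # background PAMs; the ledger records only planted sites)
  list(genome = g, tss = tss, ledger = bind_rows(ledger))
}

fixture_rnaseq_demo <- function() {
  g <- sim_genome(12000L, gc = 0.67, contig_ids = "chr1")
  n_genes <- 10L
  starts <- as.integer(seq(201L, by = 1000L, length.out = n_genes))
  genes <- tibble(
    feature_id = sprintf("gene%02d", seq_len(n_genes)),
    contig = "chr1",
    start = starts,
    end = starts + 499L
  )
  tss <- genes |>
    mutate(operon_id = NA_character_, tss_pos = .data$start,
           strand = "+", cds_start = .data$start) |>
    select("feature_id", "operon_id", "contig", "tss_pos", "strand",
           "cds_start")
  base_frags <- 8L
  induced_gene <- "gene03"
  fold <- 4L
  frag_rows <- function(gene_row, n) {
    # n fragments of span 300 tiled inside the gene
    off <- as.integer(round(seq(0L, 200L, length.out = n)))
    tibble(contig = gene_row$contig,
           start = gene_row$start + off,
           end = gene_row$start + off + 299L)
  }
  frags_b <- purrr::map(seq_len(n_genes), function(i) {
    frag_rows(genes[i, ], base_frags)
  }) |> bind_rows()
  frags_a <- purrr::map(seq_len(n_genes), function(i) {
    n <- if (genes$feature_id[i] == induced_gene) base_frags * fold
         else base_frags
    frag_rows(genes[i, ], n)
  }) |> bind_rows()
  ledger <- tibble(
    feature_id = genes$feature_id,
    fragments_experimental = ifelse(genes$feature_id == induced_gene,
                                    base_frags * fold, base_frags),
    fragments_control = base_frags,
    expected_log2_ratio_no_pseudocount =
      ifelse(genes$feature_id == induced_gene, log2(fold), 0) -
      log2(sum(ifelse(genes$feature_id == induced_gene,
                      base_frags * fold, base_frags)) /
           (n_genes * base_frags))
  )
  list(genome = g, tss = tss, genes = genes, ledger = ledger,
       fragments_a = frags_a, fragments_b = frags_b)
}
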