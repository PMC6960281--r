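#' Fractional fragment coverage from paired-end alignments
#'
#' Each properly paired fragment deposits a total mass of 1, spread
#' uniformly over its span: every position from the 5' end of the leftmost
#' mate to the 3' end of the rightmost mate receives `1/N`, with `N` the
#' fragment length. Unpaired mapped reads (or pairs whose mate is
#' unmapped) contribute `1/read-length` over the read span. Unmapped,
#' secondary and supplementary records are ignored; records with a
#' nonpositive or off-contig span are skipped and tallied, never fatal.
#'
#' @param sam Path to a SAM file (with `@SQ` header lines) or an existing
#'   BAM file.
#' @param genome Genome the alignments refer to (contig names must match).
#' @return Object of class `fragment_coverage`: per-contig run-length
#'   encoded coverage, `total_fragments` (fragments used),
#'   `n_skipped`.
#' @export
fragment_coverage <- function(sam, genome) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  bam <- if (grepl("\\.bam$", sam, ignore.case = TRUE)) {
    sam
  } else {
    Rsamtools::asBam(sam, destination = tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "isize"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- rec$flag
  n_in <- length(flag)
  keep <- !is.na(flag) &
    bitwAnd(flag, 0x4) == 0 &    # mapped
    bitwAnd(flag, 0x100) == 0 &  # primary
    bitwAnd(flag, 0x800) == 0    # not supplementary
  d <- tibble(flag = flag[keep],
              contig = as.character(rec$rname[keep]),
              pos = rec$pos[keep],
              cigar = rec$cigar[keep],
              isize = rec$isize[keep])
  paired <- bitwAnd(d$flag, 0x1) > 0
  mate_unmapped <- bitwAnd(d$flag, 0x8) > 0
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(d$cigar)

  # One row per fragment. Paired fragments are represented once, by the
  # leftmost mate (TLEN > 0); the mate's record carries TLEN < 0.
  frag_left <- paired & !mate_unmapped & !is.na(d$isize) & d$isize > 0
  single <- !paired | mate_unmapped
  mate_right <- paired & !mate_unmapped & !is.na(d$isize) & d$isize < 0

  spans <- bind_rows(
    tibble(contig = d$contig[frag_left], start = d$pos[frag_left],
           end = d$pos[frag_left] + d$isize[frag_left] - 1L),
    tibble(contig = d$contig[single], start = d$pos[single],
           end = d$pos[single] + ref_w[single] - 1L)
  )
  # Paired primary records that are neither a leftmost mate, a rightmost
  # mate, nor mate-unmapped (e.g. TLEN 0) cannot be placed: skip + tally.
  n_undetermined <- sum(keep) - sum(frag_left) - sum(mate_right) - sum(single)

  ok <- !is.na(spans$start) & spans$end >= spans$start &
    spans$contig %in% names(lens) &
    spans$start >= 1 & spans$end <= lens[spans$contig]
  used <- spans[ok, ]
  n_skipped <- (n_in - sum(keep)) + n_undetermined + sum(!ok)

  cov <- purrr::map(names(lens), function(cid) {
    u <- used[used$contig == cid, ]
    if (nrow(u) == 0) {
      return(S4Vectors::Rle(0, lens[[cid]]))
    }
    IRanges::coverage(IRanges::IRanges(u$start, u$end),
                      weight = 1 / (u$end - u$start + 1),
                      width = lens[[cid]])
  })
  structure(
    list(coverage = setNames(cov, names(lens)),
         total_fragments = nrow(used),
         n_skipped = n_skipped),
    class = "fragment_coverage"
  )
}

#' @export
print.fragment_coverage <- function(x, ...) {
  cat(sprintf(
    "<fragment_coverage> %d contig(s), %d fragments used, %d skipped\n",
    length(x$coverage), x$total_fragments, x$n_skipped))
  invisible(x)
}

#' @rdname fragment_coverage
#' @param x A `fragment_coverage`.
#' @param ... Unused.
#' @method tidy fragment_coverage
#' @export
tidy.fragment_coverage <- function(x, ...) {
  purrr::map2(names(x$coverage), x$coverage, function(cid, r) {
    tibble(contig = cid, length_bp = length(r), mass = sum(r))
  }) |> bind_rows()
}

#' @rdname fragment_coverage
#' @method glance fragment_coverage
#' @export
glance.fragment_coverage <- function(x, ...) {
  tibble(n_contigs = length(x$coverage),
         total_fragments = x$total_fragments,
         n_skipped = x$n_skipped,
         total_mass = sum(vapply(x$coverage, sum, numeric(1))))
}

#' Extract the coverage of one contig as a numeric vector
#' @param coverage A [fragment_coverage()] result.
#' @param contig Contig id.
#' @return Numeric vector of per-position coverage.
#' @export
coverage_vector <- function(coverage, contig) {
  as.numeric(coverage$coverage[[contig]])
}

#' Per-gene RPKM from fragment coverage
#'
#' Sums the fractional coverage over each gene interval (fragment mass),
#' applies a pseudocount, and normalizes by gene length and library size:
#' `rpkm = mass / (length/1e3) / (total_fragments/1e6)`. Pseudocount
#' modes: `"per_gene"` (default) adds `pseudocount` fragment-equivalents
#' of mass to every gene, a length-independent floor that keeps every
#' log-ratio finite; `"per_position"` adds `pseudocount` at every position
#' of the interval (mass grows by `pseudocount * length`); `"off"` adds
#' nothing.
#'
#' @param coverage A [fragment_coverage()] result.
#' @param genes Tibble with `feature_id`, `contig`, `start`, `end`
#'   (1-based inclusive).
#' @param pseudocount_mode `"per_gene"`, `"per_position"` or `"off"`.
#' @param pseudocount Pseudocount magnitude (default 1).
#' @return Tibble: `feature_id`, `contig`, `start`, `end`, `length_bp`,
#'   `fragment_mass`, `rpkm`.
#' @export
gene_rpkm <- function(coverage, genes,
                      pseudocount_mode = c("per_gene", "per_position", "off"),
                      pseudocount = 1) {
  pseudocount_mode <- match.arg(pseudocount_mode)
  if (coverage$total_fragments == 0) {
    abort("library has zero usable fragments: RPKM is undefined")
  }
  if (!all(genes$contig %in% names(coverage$coverage))) {
    abort("gene table refers to contigs absent from the coverage")
  }
  len <- genes$end - genes$start + 1L
  if (any(len < 1)) abort("gene intervals must have end >= start")
  mass <- vapply(seq_len(nrow(genes)), function(i) {
    r <- coverage$coverage[[genes$contig[i]]]
    if (genes$end[i] > length(r)) {
      abort(sprintf("gene '%s' extends beyond its contig",
                    genes$feature_id[i]))
    }
    sum(S4Vectors::window(r, genes$start[i], genes$end[i]))
  }, numeric(1))
  mass <- switch(pseudocount_mode,
    per_gene = mass + pseudocount,
    per_position = mass + pseudocount * len,
    off = mass
  )
  tibble(feature_id = genes$feature_id, contig = genes$contig,
         start = as.integer(genes$start), end = as.integer(genes$end),
         length_bp = as.integer(len), fragment_mass = mass,
         rpkm = mass / (len / 1e3) / (coverage$total_fragments / 1e6))
}

#' Per-gene log2 expression ratio between two RPKM tables
#'
#' @param table_a,table_b Tibbles from [gene_rpkm()] over the same gene
#'   set (`a` = experimental condition, `b` = control).
#' @return Tibble: `feature_id`, `rpkm_a`, `rpkm_b`, `log2_ratio`.
#' @export
log2_fold_change <- function(table_a, table_b) {
  only_a <- setdiff(table_a$feature_id, table_b$feature_id)
  only_b <- setdiff(table_b$feature_id, table_a$feature_id)
  if (length(only_a) > 0 || length(only_b) > 0) {
    abort(paste0(
      "gene sets differ",
      if (length(only_a)) paste0("; only in a: ",
                                 paste(head(only_a, 5), collapse = ", ")),
      if (length(only_b)) paste0("; only in b: ",
                                 paste(head(only_b, 5), collapse = ", "))))
  }
  left_join(
    select(table_a, "feature_id", rpkm_a = "rpkm"),
    select(table_b, "feature_id", rpkm_b = "rpkm"),
    by = "feature_id"
  ) |>
    mutate(log2_ratio = log2(.data$rpkm_a / .data$rpkm_b))
}

#' Write an expression table with a provenance header
#' @param table Tibble from [gene_rpkm()] or [log2_fold_change()].
#' @param path Output path.
#' @param provenance Optional named character vector of `# key: value`
#'   header lines (e.g. pseudocount mode).
#' @return `path`, invisibly.
#' @export
write_expression <- function(table, path, provenance = NULL) {
  write_tsv_with_header(table, path, provenance)
}
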