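# Independent brute-force oracles, written with plain string ops only
# (no Biostrings), against which the package's scanner and seed index are
# checked exactly.

iupac_oracle <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# All 1-based start positions where `pam` matches `seq_chr` (one strand).
oracle_match_starts <- function(seq_chr, pam) {
  chars <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
  pat <- strsplit(pam, "", fixed = TRUE)[[1]]
  m <- length(pat)
  L <- length(chars)
  if (L < m) return(integer(0))
  ok <- rep(TRUE, L - m + 1)
  for (j in seq_len(m)) {
    ok <- ok & chars[j:(L - m + j)] %in% iupac_oracle[[pat[j]]]
  }
  which(ok)
}

# Both-strand sliding-window scan; forward-axis 1-based intervals.
oracle_scan <- function(seq_chr, pam, contig = "chr1") {
  m <- nchar(pam)
  L <- nchar(seq_chr)
  fwd <- oracle_match_starts(seq_chr, pam)
  rev_starts <- oracle_match_starts(oracle_revcomp(seq_chr), pam)
  rev_fwd_start <- sort(L - (rev_starts + m - 1) + 1)
  out <- rbind(
    if (length(fwd)) data.frame(contig = contig, pam_start = fwd,
                                pam_end = fwd + m - 1, strand = "+"),
    if (length(rev_fwd_start)) data.frame(contig = contig,
                                          pam_start = rev_fwd_start,
                                          pam_end = rev_fwd_start + m - 1,
                                          strand = "-")
  )
  if (is.null(out)) {
    return(data.frame(contig = character(0), pam_start = integer(0),
                      pam_end = integer(0), strand = character(0)))
  }
  out[order(out$pam_start, match(out$strand, c("+", "-"))), , drop = FALSE]
}

# Genome-wide count of occurrences of each seed immediately 5' of a PAM
# (both strands), by direct slicing around every oracle-scanned site.
oracle_seed_counts <- function(seq_chr, pam, seed_len) {
  sites <- oracle_scan(seq_chr, pam)
  if (nrow(sites) == 0) return(integer(0))
  seeds <- vapply(seq_len(nrow(sites)), function(i) {
    if (sites$strand[i] == "+") {
      s <- sites$pam_start[i] - seed_len
      if (s < 1) return(NA_character_)
      substr(seq_chr, s, sites$pam_start[i] - 1)
    } else {
      e <- sites$pam_end[i] + seed_len
      if (e > nchar(seq_chr)) return(NA_character_)
      oracle_revcomp(substr(seq_chr, sites$pam_end[i] + 1, e))
    }
  }, character(1))
  seeds <- seeds[!is.na(seeds) & !grepl("N", seeds, fixed = TRUE)]
  table(seeds)
}

rand_genome_chr <- function(L, gc) {
  paste(sample(c("G", "C", "A", "T"), L, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}
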