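#' Describe a type IIA Cas9 system for guide design
#'
#' A PAM specification bundles everything the scanner and designer need to
#' know about one Cas9 system: its degenerate protospacer-adjacent motif
#' (PAM, written 5'->3' in IUPAC code, located immediately 3' of the
#' protospacer), the spacer length, the seed length used for the off-target
#' uniqueness filter, and optionally the sgRNA scaffold (crRNA direct
#' repeat + tracrRNA) used by [assemble_constructs()].
#'
#' @param system_name Short system label, e.g. `"Sth3"`.
#' @param pam PAM motif in IUPAC DNA code, e.g. `"NGGNG"`.
#' @param protospacer_len Spacer length in bases (default 20).
#' @param seed_len Seed length in bases, the PAM-proximal portion of the
#'   spacer sufficient for dCas9 binding (default 12); must not exceed
#'   `protospacer_len`.
#' @param scaffold Optional DNA sequence of the sgRNA scaffold.
#' @return An object of class `pam_spec`.
#' @examples
#' pam_spec("Sth3", "NGGNG")
#' @export
pam_spec <- function(system_name, pam, protospacer_len = 20L,
                     seed_len = 12L, scaffold = NULL) {
  pam <- toupper(pam)
  if (!nzchar(pam) || grepl(paste0("[^", paste(names(IUPAC_SETS), collapse = ""), "]"), pam)) {
    abort(paste0("PAM motif '", pam, "' contains non-IUPAC characters"))
  }
  protospacer_len <- as.integer(protospacer_len)
  seed_len <- as.integer(seed_len)
  if (protospacer_len < 1L) abort("protospacer_len must be positive")
  if (seed_len < 1L || seed_len > protospacer_len) {
    abort("seed_len must satisfy 0 < seed_len <= protospacer_len")
  }
  if (!is.null(scaffold)) {
    scaffold <- toupper(scaffold)
    if (grepl("[^ACGT]", scaffold)) {
      abort("scaffold must be plain A/C/G/T DNA")
    }
  }
  structure(
    list(system_name = system_name, pam = pam,
         protospacer_len = protospacer_len, seed_len = seed_len,
         scaffold = scaffold),
    class = "pam_spec"
  )
}

#' @export
print.pam_spec <- function(x, ...) {
  cat(sprintf("<pam_spec> %s: PAM %s, %d-nt spacer, %d-nt seed%s\n",
              x$system_name, x$pam, x$protospacer_len, x$seed_len,
              if (is.null(x$scaffold)) "" else
                sprintf(", %d-nt scaffold", nchar(x$scaffold))))
  invisible(x)
}

#' Built-in CRISPRi system presets
#'
#' The two type IIA systems shown to silence genes efficiently in
#' GC-rich alphaproteobacterial genomes: Streptococcus thermophilus
#' CRISPR3 (`Sth3`, PAM `NGGNG`) and S. pasteurianus (`Spa`, consensus PAM
#' `NNGTGA`), both with the canonical 20-nt spacer and 12-nt seed.
#' Scaffolds are deliberately not shipped: they are plasmid-specific
#' cloning sequences, supplied via the `scaffold` argument or config.
#'
#' @param scaffolds Optional named list/character vector of scaffold
#'   sequences keyed by system name.
#' @return Named list of [pam_spec()] objects.
#' @examples
#' crispri_systems()$Sth3
#' @export
crispri_systems <- function(scaffolds = NULL) {
  sc <- function(nm) {
    if (!is.null(scaffolds) && nm %in% names(scaffolds)) scaffolds[[nm]]
    else NULL
  }
  list(
    Sth3 = pam_spec("Sth3", "NGGNG", scaffold = sc("Sth3")),
    Spa  = pam_spec("Spa", "NNGTGA", scaffold = sc("Spa"))
  )
}

# Fetch bases s..e (1-based inclusive on the forward axis) from a contig of
# length L. Coordinates outside [1, L] are legal only on circular contigs,
# where they wrap; NA is returned when the span falls off a linear contig.
fetch_span <- function(seq_chr, s, e, circular) {
  L <- nchar(seq_chr)
  if (e < s) return(NA_character_)
  if (s >= 1 && e <= L) return(substr(seq_chr, s, e))
  if (!circular || (e - s + 1) > L) return(NA_character_)
  s2 <- ((s - 1) %% L) + 1
  substr(paste0(seq_chr, seq_chr), s2, s2 + (e - s))
}

#' Enumerate all PAM occurrences in a genome
#'
#' Every window matching the system's IUPAC PAM motif on the requested
#' strand(s) yields one site; overlapping occurrences are all reported.
#' A genome `N` never satisfies any motif letter (not even motif `N`).
#' On circular contigs the scan crosses the origin; reported coordinates
#' stay on the forward axis and a site spanning the origin has
#' `pam_end > contig length` (interpret modulo the length).
#'
#' @param genome Genome from [genome_set()]/[read_genome_fasta()].
#' @param spec A [pam_spec()].
#' @param strands `"both"` (default), `"forward"` or `"reverse"`.
#' @return Tibble with columns `system`, `contig`, `pam_start`, `pam_end`
#'   (1-based inclusive, forward axis), `strand`, `pam_seq` (matched bases
#'   read 5'->3' on the site's strand), ordered by contig, start, strand
#'   (`+` before `-`).
#' @examples
#' g <- genome_set(c(c1 = "TTTTTTTTTTTTTTTTTTTTAGGCGTTT"))
#' scan_pams(g, pam_spec("Sth3", "NGGNG"))
#' @export
scan_pams <- function(genome, spec, strands = c("both", "forward", "reverse")) {
  strands <- match.arg(strands)
  stopifnot(inherits(spec, "pam_spec"))
  topo <- genome_topology(genome)
  m <- nchar(spec$pam)
  per_contig <- purrr::map(seq_along(genome), function(i) {
    cid <- names(genome)[i]
    seq_chr <- as.character(genome[[i]])
    L <- nchar(seq_chr)
    circular <- topo[[cid]] == "circular"
    subject_chr <- if (circular && L >= m) {
      paste0(seq_chr, substr(seq_chr, 1, m - 1))
    } else {
      seq_chr
    }
    if (nchar(subject_chr) < m) return(NULL)
    subject <- Biostrings::DNAString(subject_chr)
    res <- list()
    if (strands %in% c("both", "forward")) {
      hits <- Biostrings::matchPattern(Biostrings::DNAString(spec$pam),
                                       subject, fixed = "subject")
      st <- BiocGenerics::start(hits)
      sq <- as.character(hits)
      keep <- st <= L & !grepl("N", sq, fixed = TRUE)
      if (any(keep)) {
        res$fwd <- tibble(contig = cid, pam_start = st[keep],
                          pam_end = st[keep] + m - 1L, strand = "+",
                          pam_seq = sq[keep])
      }
    }
    if (strands %in% c("both", "reverse")) {
      rc <- Biostrings::DNAString(revcomp(spec$pam))
      hits <- Biostrings::matchPattern(rc, subject, fixed = "subject")
      st <- BiocGenerics::start(hits)
      sq <- as.character(hits)
      keep <- st <= L & !grepl("N", sq, fixed = TRUE)
      if (any(keep)) {
        res$rev <- tibble(contig = cid, pam_start = st[keep],
                          pam_end = st[keep] + m - 1L, strand = "-",
                          pam_seq = revcomp(sq[keep]))
      }
    }
    if (length(res) == 0) NULL else bind_rows(res)
  })
  out <- bind_rows(per_contig)
  if (nrow(out) == 0) {
    return(tibble(system = character(0), contig = character(0),
                  pam_start = integer(0), pam_end = integer(0),
                  strand = character(0), pam_seq = character(0)))
  }
  out |>
    mutate(system = spec$system_name,
           contig = factor(.data$contig, levels = names(genome))) |>
    arrange(.data$contig, .data$pam_start,
            factor(.data$strand, levels = c("+", "-"))) |>
    mutate(contig = as.character(.data$contig),
           pam_start = as.integer(.data$pam_start),
           pam_end = as.integer(.data$pam_end)) |>
    select("system", "contig", "pam_start", "pam_end", "strand", "pam_seq")
}

#' Count PAM occurrences genome-wide
#'
#' @inheritParams scan_pams
#' @return Number of PAM sites (both strands by default).
#' @export
count_pams <- function(genome, spec, strands = "both") {
  nrow(scan_pams(genome, spec, strands = strands))
}

#' Extract candidate protospacers 5' of PAM sites
#'
#' For each PAM site, takes the `protospacer_len` bases that end
#' immediately 5' of the PAM on the site's strand (on the forward axis
#' this abuts the PAM on the left for `+` sites and on the right for `-`
#' sites). Sites whose protospacer would run off a linear contig are
#' rejected as `too_close_to_edge`; windows containing `N` are rejected as
#' `ambiguous_base`. On circular contigs the window may wrap the origin.
#'
#' @param sites Tibble from [scan_pams()].
#' @inheritParams scan_pams
#' @param keep_rejected Keep rejected sites (with `status` saying why and
#'   `NA` sequences)? Default `TRUE`.
#' @return `sites` with added columns `proto_start`, `proto_end` (1-based
#'   inclusive, forward axis), `targeting_seq`, `seed_seq` (both 5'->3' on
#'   the site's strand; the seed is the PAM-proximal suffix of the
#'   targeting sequence) and `status` (`"ok"`, `"too_close_to_edge"`,
#'   `"ambiguous_base"`).
#' @export
extract_protospacers <- function(sites, genome, spec, keep_rejected = TRUE) {
  stopifnot(inherits(spec, "pam_spec"))
  P <- spec$protospacer_len
  K <- spec$seed_len
  topo <- genome_topology(genome)
  n <- nrow(sites)
  if (n == 0) {
    out <- sites |>
      mutate(proto_start = integer(0), proto_end = integer(0),
             targeting_seq = character(0), seed_seq = character(0),
             status = character(0))
    return(out)
  }
  if (!all(sites$contig %in% names(genome))) {
    abort("sites refer to contigs absent from the genome")
  }
  seqs <- setNames(as.character(genome), names(genome))
  plus <- sites$strand == "+"
  proto_start <- ifelse(plus, sites$pam_start - P, sites$pam_end + 1L)
  proto_end <- ifelse(plus, sites$pam_start - 1L, sites$pam_end + P)
  fwd_seq <- vapply(seq_len(n), function(i) {
    fetch_span(seqs[[sites$contig[i]]], proto_start[i], proto_end[i],
               circular = topo[[sites$contig[i]]] == "circular")
  }, character(1))
  targeting <- ifelse(plus, fwd_seq, revcomp(fwd_seq))
  status <- dplyr::case_when(
    is.na(targeting) ~ "too_close_to_edge",
    grepl("N", targeting, fixed = TRUE) ~ "ambiguous_base",
    TRUE ~ "ok"
  )
  targeting[status != "ok"] <- NA_character_
  out <- sites |>
    mutate(proto_start = as.integer(proto_start),
           proto_end = as.integer(proto_end),
           targeting_seq = targeting,
           seed_seq = ifelse(is.na(targeting), NA_character_,
                             substr(targeting, P - K + 1L, P)),
           status = status)
  if (!keep_rejected) out <- filter(out, .data$status == "ok")
  out
}
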