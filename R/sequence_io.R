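#' Build a genome object from named sequences
#'
#' The genome container used throughout the package is a
#' [Biostrings::DNAStringSet] whose element names are contig ids and whose
#' metadata records per-contig topology. Sequences are normalized to
#' uppercase DNA over `{A,C,G,T,N}` (lowercase input and `U` are accepted
#' and converted; anything else is an error).
#'
#' @param seqs Named character vector of contig sequences, or a
#'   `DNAStringSet`.
#' @param topology Either a single value (`"linear"` or `"circular"`)
#'   recycled to all contigs, or a character vector named by contig id.
#' @return A `DNAStringSet` with a `topology` entry in its metadata.
#' @examples
#' g <- genome_set(c(chr = "acgtACGT"))
#' as.character(g)
#' @export
genome_set <- function(seqs, topology = "linear") {
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("every contig must be named")
  }
  if (anyDuplicated(names(seqs))) {
    dup <- unique(names(seqs)[duplicated(names(seqs))])
    abort(paste0("duplicate contig id(s): ", paste(dup, collapse = ", ")))
  }
  norm <- chartr("u", "T", chartr("U", "T", toupper(seqs)))
  bad <- regexpr("[^ACGTN]", norm)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(sprintf("illegal residue '%s' in contig '%s' at offset %d",
                  substr(norm[i], bad[i], bad[i]), names(norm)[i], bad[i]))
  }
  if (sum(nchar(norm)) == 0) abort("genome has zero total length")
  topo <- check_topology(topology, names(norm))
  g <- Biostrings::DNAStringSet(norm)
  S4Vectors::metadata(g)$topology <- topo
  g
}

check_topology <- function(topology, ids) {
  if (!all(topology %in% c("linear", "circular"))) {
    abort("topology values must be 'linear' or 'circular'")
  }
  if (length(topology) == 1 && is.null(names(topology))) {
    return(setNames(rep(topology, length(ids)), ids))
  }
  out <- setNames(rep("linear", length(ids)), ids)
  known <- intersect(names(topology), ids)
  out[known] <- topology[known]
  out
}

#' Per-contig topology of a genome
#' @param genome A genome built by [genome_set()] or [read_genome_fasta()].
#' @return Named character vector, `"linear"` or `"circular"` per contig.
#' @export
genome_topology <- function(genome) {
  topo <- S4Vectors::metadata(genome)$topology
  if (is.null(topo)) {
    topo <- setNames(rep("linear", length(genome)), names(genome))
  }
  topo
}

#' Read a genome from a FASTA file
#'
#' Multi-line records are concatenated; the header up to the first
#' whitespace becomes the contig id; sequences are normalized as in
#' [genome_set()].
#'
#' @param path Path to a FASTA file.
#' @inheritParams genome_set
#' @return A genome (`DNAStringSet` with topology metadata).
#' @export
read_genome_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) abort(paste0("no FASTA records in ", path))
  ids <- sub("\\s.*$", "", names(raw))
  genome_set(setNames(as.character(raw), ids), topology = topology)
}

#' Write a genome to a FASTA file
#' @inheritParams genome_topology
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70) {
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}

#' Read a transcription-start-site annotation table
#'
#' Expects tab-separated text with a header naming at least `feature_id`,
#' `contig`, `position` and `strand`; optional columns `operon_id` and
#' `cds_start` are carried through. Lines starting with `#` are ignored.
#' Positions are 1-based coordinates of the first transcribed base. A gene
#' may appear on several rows (multiple TSSs); the
#' `(feature_id, position, strand)` triple must be unique.
#'
#' @param path Path to the TSV file.
#' @param genome Optional genome; when given, each row is validated against
#'   it (contig must exist, position must be within the contig).
#' @return A tibble with columns `feature_id`, `operon_id`, `contig`,
#'   `tss_pos`, `strand`, `cds_start`.
#' @export
read_tss_table <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("feature_id", "contig", "position", "strand")
  missing_cols <- setdiff(need, names(tb))
  if (length(missing_cols) > 0) {
    abort(paste0("TSS table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tb <- tb |>
    mutate(
      feature_id = as.character(.data$feature_id),
      contig = as.character(.data$contig),
      tss_pos = as.integer(.data$position),
      strand = as.character(.data$strand),
      operon_id = if ("operon_id" %in% names(tb))
        as.character(.data$operon_id) else NA_character_,
      cds_start = if ("cds_start" %in% names(tb))
        as.integer(.data$cds_start) else NA_integer_
    ) |>
    select("feature_id", "operon_id", "contig", "tss_pos", "strand",
           "cds_start")
  validate_tss(tb, genome)
  tb
}

validate_tss <- function(tb, genome = NULL) {
  bad_strand <- which(!tb$strand %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    abort(sprintf("row %d: strand '%s' is not '+' or '-'",
                  bad_strand[1], tb$strand[bad_strand[1]]))
  }
  bad_pos <- which(is.na(tb$tss_pos) | tb$tss_pos < 1)
  if (length(bad_pos) > 0) {
    abort(sprintf("row %d: position must be a 1-based integer", bad_pos[1]))
  }
  if (anyDuplicated(tb[c("feature_id", "tss_pos", "strand")])) {
    i <- which(duplicated(tb[c("feature_id", "tss_pos", "strand")]))[1]
    abort(sprintf("row %d: duplicate (feature_id, position, strand) record",
                  i))
  }
  if (!is.null(genome)) {
    lens <- setNames(Biostrings::width(genome), names(genome))
    bad_contig <- which(!tb$contig %in% names(lens))
    if (length(bad_contig) > 0) {
      abort(sprintf("row %d: unknown contig '%s'",
                    bad_contig[1], tb$contig[bad_contig[1]]))
    }
    over <- which(tb$tss_pos > lens[tb$contig])
    if (length(over) > 0) {
      abort(sprintf("row %d: position %d beyond end of contig '%s'",
                    over[1], tb$tss_pos[over[1]], tb$contig[over[1]]))
    }
  }
  invisible(tb)
}

#' Write a TSS table
#' @param tss Tibble as returned by [read_tss_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_table <- function(tss, path) {
  out <- tss |> rename(position = "tss_pos")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write guide candidates to TSV, BED or FASTA
#'
#' TSV carries every column with 1-based inclusive coordinates and can be
#' read back losslessly with [read_candidates()]. BED6 carries the
#' protospacer interval in 0-based half-open convention with the
#' protospacer strand. FASTA carries the targeting sequence (the exact
#' 5'->3' sequence the sgRNA spacer would contain).
#'
#' @param candidates Tibble of candidates (from [extract_protospacers()] or
#'   [design_guides()]); needs at least `contig`, `proto_start`,
#'   `proto_end`, `strand`, `targeting_seq`.
#' @param path Output path.
#' @param format One of `"tsv"`, `"bed"`, `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path, format = c("tsv", "bed", "fasta")) {
  format <- match.arg(format)
  ids <- candidate_ids(candidates)
  switch(format,
    tsv = readr::write_tsv(candidates, path, progress = FALSE),
    bed = {
      bed <- tibble(
        chrom = candidates$contig,
        chromStart = candidates$proto_start - 1L,
        chromEnd = candidates$proto_end,
        name = ids,
        score = 0L,
        strand = candidates$strand
      )
      readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
    },
    fasta = {
      seqs <- Biostrings::DNAStringSet(setNames(candidates$targeting_seq, ids))
      Biostrings::writeXStringSet(seqs, path)
    }
  )
  invisible(path)
}

candidate_ids <- function(candidates) {
  if (nrow(candidates) == 0) return(character(0))
  base <- paste(candidates$contig, candidates$proto_start,
                candidates$strand, sep = "_")
  if ("feature_id" %in% names(candidates)) {
    base <- paste(candidates$feature_id, base, sep = "|")
  }
  if ("system" %in% names(candidates)) {
    base <- paste(candidates$system, base, sep = "|")
  }
  make.unique(base, sep = "#")
}

#' Read back a candidate TSV written by [write_candidates()]
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_candidates <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
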