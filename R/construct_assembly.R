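#' Assemble full sgRNA construct sequences
#'
#' An sgRNA is the 20-nt targeting region followed by the system-specific
#' scaffold (crRNA direct repeat + tracrRNA, which carries the dCas9
#' handle and a transcriptional terminator). For constitutive expression
#' the transcription start is placed at the 5' end of the targeting
#' sequence, so the construct sequence is simply
#' `targeting_seq + scaffold`, 5'->3'. Output stays in the DNA alphabet
#' (cloning-oriented); set `rna = TRUE` in [write_constructs_fasta()] for
#' a T->U transliteration on output only.
#'
#' @param targeting Either a design tibble (its `targeting_seq` column is
#'   used; `feature_id`/`system` carried into ids) or a character vector
#'   of targeting sequences.
#' @param spec A [pam_spec()] whose `scaffold` is set.
#' @return Tibble of class `sgrna_constructs`: `id`, `system`,
#'   `targeting_seq`, `scaffold`, `full_seq`.
#' @examples
#' sp <- pam_spec("Sth3", "NGGNG", scaffold = strrep("GT", 10))
#' assemble_constructs(strrep("A", 20), sp)
#' @export
assemble_constructs <- function(targeting, spec) {
  stopifnot(inherits(spec, "pam_spec"))
  if (is.null(spec$scaffold)) {
    abort(paste0("system '", spec$system_name,
                 "' has no scaffold sequence configured"))
  }
  if (is.data.frame(targeting)) {
    ids <- candidate_ids(targeting)
    seqs <- targeting$targeting_seq
  } else {
    seqs <- toupper(targeting)
    ids <- if (!is.null(names(seqs)) && all(nzchar(names(seqs)))) {
      names(seqs)
    } else {
      paste0("sgRNA_", seq_along(seqs))
    }
  }
  bad_len <- which(nchar(seqs) != spec$protospacer_len)
  if (length(bad_len) > 0) {
    abort(sprintf(
      "targeting sequence %d has length %d; system '%s' requires %d",
      bad_len[1], nchar(seqs[bad_len[1]]), spec$system_name,
      spec$protospacer_len))
  }
  bad_chr <- which(grepl("[^ACGT]", seqs))
  if (length(bad_chr) > 0) {
    abort(sprintf("targeting sequence %d contains ambiguous bases",
                  bad_chr[1]))
  }
  out <- tibble(id = ids, system = spec$system_name,
                targeting_seq = unname(seqs), scaffold = spec$scaffold,
                full_seq = paste0(unname(seqs), spec$scaffold))
  class(out) <- c("sgrna_constructs", class(out))
  out
}

#' Write assembled constructs to FASTA
#'
#' @param constructs Tibble from [assemble_constructs()].
#' @param path Output path.
#' @param rna Transliterate T to U for display (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_constructs_fasta <- function(constructs, path, rna = FALSE) {
  seqs <- constructs$full_seq
  if (rna) {
    seqs <- chartr("T", "U", seqs)
    set <- Biostrings::RNAStringSet(setNames(seqs, constructs$id))
  } else {
    set <- Biostrings::DNAStringSet(setNames(seqs, constructs$id))
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
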