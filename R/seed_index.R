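#' Build a genome-wide index of PAM-adjacent seed sequences
#'
#' The off-target filter rests on the observation that dCas9 binding needs
#' only an exact match over the seed (the PAM-proximal `seed_len` bases of
#' the spacer) next to an appropriate PAM. The index counts, for one Cas9
#' system, how many times each seed sequence occurs in the genome
#' immediately 5' of a PAM of that system, over both strands. Adjacency
#' requires only `seed_len` on-contig, N-free bases 5' of the PAM: a PAM
#' too close to a contig edge for a full protospacer still contributes an
#' off-target occurrence (conservative filtering).
#'
#' @inheritParams scan_pams
#' @return An object of class `seed_index` wrapping the per-seed counts.
#' @examples
#' g <- genome_set(c(c1 = "TTTTTTTTTTTTTTTTTTTTAGGCGTTT"))
#' idx <- build_seed_index(g, pam_spec("Sth3", "NGGNG"))
#' tidy(idx)
#' @export
build_seed_index <- function(genome, spec) {
  stopifnot(inherits(spec, "pam_spec"))
  sites <- scan_pams(genome, spec, strands = "both")
  K <- spec$seed_len
  topo <- genome_topology(genome)
  seqs <- setNames(as.character(genome), names(genome))
  seeds <- character(0)
  if (nrow(sites) > 0) {
    plus <- sites$strand == "+"
    s <- ifelse(plus, sites$pam_start - K, sites$pam_end + 1L)
    e <- ifelse(plus, sites$pam_start - 1L, sites$pam_end + K)
    fwd <- vapply(seq_len(nrow(sites)), function(i) {
      fetch_span(seqs[[sites$contig[i]]], s[i], e[i],
                 circular = topo[[sites$contig[i]]] == "circular")
    }, character(1))
    seeds <- ifelse(plus, fwd, revcomp(fwd))
    seeds <- seeds[!is.na(seeds) & !grepl("N", seeds, fixed = TRUE)]
  }
  counts <- if (length(seeds) > 0) {
    tab <- table(seeds)
    setNames(as.integer(tab), names(tab))
  } else {
    setNames(integer(0), character(0))
  }
  structure(
    list(system_name = spec$system_name, seed_len = K, counts = counts),
    class = "seed_index"
  )
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> %s: %d distinct %d-nt seeds, %d occurrences\n",
              x$system_name, length(x$counts), x$seed_len,
              sum(x$counts)))
  invisible(x)
}

#' @rdname build_seed_index
#' @param x A `seed_index`.
#' @param ... Unused.
#' @method tidy seed_index
#' @export
tidy.seed_index <- function(x, ...) {
  tibble(seed = names(x$counts), count = unname(x$counts)) |>
    arrange(.data$seed)
}

#' @rdname build_seed_index
#' @method glance seed_index
#' @export
glance.seed_index <- function(x, ...) {
  tibble(system = x$system_name, seed_len = x$seed_len,
         n_distinct_seeds = length(x$counts),
         n_occurrences = sum(x$counts),
         n_unique_seeds = sum(x$counts == 1L))
}

#' Genome-wide multiplicity of candidate seeds
#'
#' Looks up each candidate's seed in the index. A candidate drawn from the
#' same genome/system always has multiplicity at least 1 (its own locus is
#' indexed); a seed absent from the index therefore signals a genome/spec
#' mismatch and is an error, as is a system-name mismatch.
#'
#' @param candidates Tibble with `seed_seq` (and `system`, if present,
#'   checked against the index).
#' @param index A [build_seed_index()] result.
#' @return Integer vector of multiplicities, one per candidate row.
#' @export
seed_multiplicity <- function(candidates, index) {
  stopifnot(inherits(index, "seed_index"))
  if ("system" %in% names(candidates) && nrow(candidates) > 0 &&
      !all(candidates$system == index$system_name)) {
    abort(sprintf("candidates are for system '%s' but index is for '%s'",
                  candidates$system[1], index$system_name))
  }
  seeds <- candidates$seed_seq
  hit <- index$counts[seeds]
  if (any(is.na(hit) & !is.na(seeds))) {
    missing <- seeds[is.na(hit) & !is.na(seeds)][1]
    abort(paste0("seed '", missing,
                 "' not present in the index: candidates and index were ",
                 "built from different genomes or specs"))
  }
  as.integer(hit)
}

#' Annotate candidates with seed multiplicity and uniqueness
#'
#' @inheritParams seed_multiplicity
#' @return `candidates` with added `seed_count` and `unique` (logical,
#'   `seed_count == 1`) columns.
#' @export
annotate_uniqueness <- function(candidates, index) {
  cnt <- seed_multiplicity(candidates, index)
  candidates |>
    mutate(seed_count = cnt, unique = .data$seed_count == 1L)
}

#' Keep only candidates whose seed is unique genome-wide
#'
#' A candidate is retained iff its seed occurs exactly once in the genome
#' next to a PAM of the system (the candidate's own locus counts, so
#' unique means multiplicity 1). Input order is preserved; rejected rows
#' are attached as the `"rejected"` attribute with their multiplicities.
#' The filter is idempotent.
#'
#' @inheritParams seed_multiplicity
#' @return Tibble of retained candidates with `seed_count`/`unique`
#'   columns; rejected candidates in `attr(, "rejected")`.
#' @export
filter_unique <- function(candidates, index) {
  ann <- annotate_uniqueness(candidates, index)
  keep <- filter(ann, .data$unique)
  attr(keep, "rejected") <- filter(ann, !.data$unique)
  keep
}
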