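#' Map a TSS-anchored design window onto genomic coordinates
#'
#' The design window is expressed on the transcript axis: offset 0 is the
#' TSS base itself, negative offsets run upstream, and the interval is
#' inclusive at `upstream` and exclusive at `downstream` (so the defaults
#' -50..+100 give a 150-bp window). The window is oriented along the
#' direction of transcription and clipped to the contig; a window falling
#' entirely off-contig is empty (`NA` bounds), not an error.
#'
#' @param tss TSS tibble (see [read_tss_table()]) with `contig`, `tss_pos`,
#'   `strand` columns.
#' @param genome Genome, used for clipping to contig bounds.
#' @param upstream,downstream Window bounds on the transcript axis
#'   (defaults -50 and +100); `upstream < downstream` required.
#' @return `tss` with added `win_start`, `win_end` columns (1-based
#'   inclusive, forward genomic axis).
#' @examples
#' g <- genome_set(c(c1 = strrep("A", 2000)))
#' tss <- tibble::tibble(feature_id = "geneA", contig = "c1",
#'                       tss_pos = 1000L, strand = "+")
#' transcript_window(tss, g)
#' @export
transcript_window <- function(tss, genome, upstream = -50L, downstream = 100L) {
  if (!(upstream < downstream)) abort("upstream must be < downstream")
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (!all(tss$contig %in% names(lens))) {
    abort("TSS table refers to contigs absent from the genome")
  }
  p <- tss$tss_pos
  plus <- tss$strand == "+"
  ws <- ifelse(plus, p + upstream, p - downstream + 1L)
  we <- ifelse(plus, p + downstream - 1L, p - upstream)
  L <- unname(lens[tss$contig])
  ws <- pmax(ws, 1L)
  we <- pmin(we, L)
  empty <- ws > we
  tss |>
    mutate(win_start = as.integer(ifelse(empty, NA, ws)),
           win_end = as.integer(ifelse(empty, NA, we)))
}

#' Classify a candidate as template- or nontemplate-targeting
#'
#' An sgRNA's spacer has the protospacer's sequence, so it base-pairs with
#' the strand opposite the protospacer. CRISPRi is effective when the
#' sgRNA base-pairs with the nontemplate (coding) strand, which happens
#' exactly when the protospacer lies on the gene's template strand, i.e.
#' the genomic strand opposite the annotated gene strand.
#'
#' @param proto_strand,gene_strand Character vectors over `{"+","-"}`;
#'   recycled against each other.
#' @return Character vector, `"nontemplate"` where the strands differ,
#'   `"template"` where they agree.
#' @examples
#' classify_targeting_strand(c("-", "+"), c("+", "+"))
#' @export
classify_targeting_strand <- function(proto_strand, gene_strand) {
  ok <- c("+", "-")
  if (!all(proto_strand %in% ok) || !all(gene_strand %in% ok)) {
    abort("strands must be '+' or '-'")
  }
  ifelse(proto_strand == gene_strand, "template", "nontemplate")
}

# Signed transcript-axis offset of the protospacer base nearest the TSS
# (0 when the protospacer covers the TSS base; negative = fully upstream).
nearest_tss_offset <- function(proto_start, proto_end, tss_pos, gene_strand) {
  plus <- gene_strand == "+"
  dplyr::case_when(
    proto_start <= tss_pos & tss_pos <= proto_end ~ 0L,
    plus & proto_end < tss_pos ~ as.integer(proto_end - tss_pos),
    plus ~ as.integer(proto_start - tss_pos),
    proto_end < tss_pos ~ as.integer(tss_pos - proto_end),
    TRUE ~ as.integer(tss_pos - proto_start)
  )
}

#' Design guide candidates genome-wide
#'
#' Runs the whole design procedure for one or more Cas9 systems: scan all
#' PAMs on both strands, extract protospacers, annotate genome-wide seed
#' uniqueness, intersect with the TSS-anchored windows of every annotated
#' feature, classify template/nontemplate targeting, and assemble one row
#' per (candidate, TSS, system). Candidates must have their full
#' protospacer inside the window (the PAM may extend past either edge
#' unless `require_pam_in_window`). Rows for one TSS are ordered by
#' distance to the TSS (|`tss_offset`| ascending, ties by forward-axis
#' start then `+` before `-`); the table is deterministic for fixed
#' inputs.
#'
#' @inheritParams transcript_window
#' @param specs A [pam_spec()] or list of them.
#' @param class Keep only `"nontemplate"` candidates (default, the
#'   CRISPRi-effective class) or `"all"` (template rows retained, flagged).
#' @param require_pam_in_window Also require the PAM interval inside the
#'   window (default `FALSE`).
#' @param indices Optional named list of pre-built [build_seed_index()]
#'   objects keyed by system name (rebuilt when absent).
#' @return Tibble, one row per candidate, with design, uniqueness and
#'   annotation columns (see Details in the package vignette).
#' @export
design_guides <- function(genome, tss, specs, upstream = -50L,
                          downstream = 100L,
                          class = c("nontemplate", "all"),
                          require_pam_in_window = FALSE,
                          indices = NULL) {
  class <- match.arg(class)
  if (inherits(specs, "pam_spec")) specs <- list(specs)
  if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
    names(specs) <- vapply(specs, function(s) s$system_name, character(1))
  }
  if (!"operon_id" %in% names(tss)) tss$operon_id <- NA_character_
  if (!"cds_start" %in% names(tss)) tss$cds_start <- NA_integer_
  validate_tss(tss, genome)
  win <- transcript_window(tss, genome, upstream, downstream) |>
    mutate(.tss_row = row_number())

  per_system <- purrr::map(specs, function(spec) {
    sites <- scan_pams(genome, spec, strands = "both")
    cands <- extract_protospacers(sites, genome, spec, keep_rejected = FALSE)
    idx <- indices[[spec$system_name]] %||% build_seed_index(genome, spec)
    cands <- annotate_uniqueness(cands, idx)
    hits <- purrr::map(split(seq_len(nrow(win)), win$contig), function(rows) {
      w <- win[rows, ]
      w <- filter(w, !is.na(.data$win_start))
      if (nrow(w) == 0) return(NULL)
      cc <- filter(cands, .data$contig == w$contig[1])
      if (nrow(cc) == 0) return(NULL)
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(cc$proto_start, cc$proto_end),
        IRanges::IRanges(w$win_start, w$win_end),
        type = "within"
      )
      if (length(ov) == 0) return(NULL)
      cand <- cc[S4Vectors::queryHits(ov), ]
      ctx <- w[S4Vectors::subjectHits(ov), ]
      bind_cols_design(cand, ctx)
    })
    bind_rows(hits)
  })
  out <- bind_rows(per_system)
  if (nrow(out) == 0) return(empty_design_table())
  if (require_pam_in_window) {
    out <- filter(out, .data$pam_start >= .data$win_start,
                  .data$pam_end <= .data$win_end)
  }
  out <- out |>
    mutate(
      targeting_class = classify_targeting_strand(.data$strand,
                                                  .data$gene_strand),
      tss_offset = nearest_tss_offset(.data$proto_start, .data$proto_end,
                                      .data$tss_pos, .data$gene_strand),
      beyond_cds_start = ifelse(
        is.na(.data$cds_start), NA,
        ifelse(.data$gene_strand == "+",
               .data$proto_end >= .data$cds_start,
               .data$proto_start <= .data$cds_start))
    )
  if (class == "nontemplate") {
    out <- filter(out, .data$targeting_class == "nontemplate")
  }
  out |>
    arrange(.data$system, .data$.tss_row, abs(.data$tss_offset),
            .data$proto_start, factor(.data$strand, levels = c("+", "-"))) |>
    select(-".tss_row") |>
    select("system", "feature_id", "operon_id", "contig", "gene_strand",
           "tss_pos", "cds_start", "win_start", "win_end",
           "proto_start", "proto_end", "strand", "targeting_seq",
           "seed_seq", "pam_start", "pam_end", "pam_seq",
           "targeting_class", "tss_offset", "beyond_cds_start",
           "seed_count", "unique")
}

bind_cols_design <- function(cand, ctx) {
  cand |>
    select(-"status") |>
    mutate(feature_id = ctx$feature_id,
           operon_id = ctx$operon_id,
           gene_strand = ctx$strand,
           tss_pos = ctx$tss_pos,
           cds_start = ctx$cds_start,
           win_start = ctx$win_start,
           win_end = ctx$win_end,
           .tss_row = ctx$.tss_row)
}

empty_design_table <- function() {
  tibble(
    system = character(0), feature_id = character(0),
    operon_id = character(0), contig = character(0),
    gene_strand = character(0), tss_pos = integer(0),
    cds_start = integer(0), win_start = integer(0), win_end = integer(0),
    proto_start = integer(0), proto_end = integer(0), strand = character(0),
    targeting_seq = character(0), seed_seq = character(0),
    pam_start = integer(0), pam_end = integer(0), pam_seq = character(0),
    targeting_class = character(0), tss_offset = integer(0),
    beyond_cds_start = logical(0), seed_count = integer(0),
    unique = logical(0)
  )
}

#' Design guide candidates for a single TSS
#'
#' Convenience wrapper over [design_guides()] for one TSS record.
#'
#' @inheritParams design_guides
#' @param tss A one-row TSS tibble.
#' @return Design tibble for that TSS.
#' @export
design_for_tss <- function(genome, tss, specs, upstream = -50L,
                           downstream = 100L,
                           class = c("nontemplate", "all"),
                           require_pam_in_window = FALSE, indices = NULL) {
  stopifnot(nrow(tss) == 1)
  design_guides(genome, tss, specs, upstream = upstream,
                downstream = downstream, class = class,
                require_pam_in_window = require_pam_in_window,
                indices = indices)
}
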