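#' Summarize genome-wide targetability
#'
#' A gene (or operon) is *targetable* under a set of Cas9 systems when at
#' least one of its TSS records carries at least one unique
#' nontemplate-strand candidate from any system in the set. Denominators
#' count units with at least one TSS record. The report carries one row
#' per single system plus one row for the union of all requested systems
#' (when more than one), with percentages rounded half-up to one decimal.
#'
#' @param design Design table from [design_guides()] (class filter
#'   `"nontemplate"`, uniqueness annotated).
#' @param tss TSS table covering all units (denominator source).
#' @param unit `"gene"` (feature_id grouping) or `"operon"` (operon_id
#'   grouping; rows without an operon id are excluded from both numerator
#'   and denominator, and an error is raised if none are present).
#' @param systems Character vector of systems to report (default: all in
#'   `design`).
#' @return Tibble of class `targetability_report` with columns `systems`,
#'   `unit`, `n_units_with_tss`, `n_units_targetable`,
#'   `fraction_targetable` (percent).
#' @export
summarize_targetability <- function(design, tss, unit = c("gene", "operon"),
                                    systems = NULL) {
  unit <- match.arg(unit)
  key <- if (unit == "gene") "feature_id" else "operon_id"
  if (unit == "operon") {
    if (!"operon_id" %in% names(tss) || all(is.na(tss$operon_id))) {
      abort("operon-level report requested but no operon ids are present")
    }
    tss <- filter(tss, !is.na(.data$operon_id))
    design <- filter(design, !is.na(.data$operon_id))
  }
  systems <- systems %||% sort(unique(design$system))
  denom_units <- unique(tss[[key]])
  n_with_tss <- length(denom_units)

  eligible <- design |>
    filter(.data$targeting_class == "nontemplate", .data$unique,
           .data[[key]] %in% denom_units)

  one_row <- function(sys_set, label) {
    hit <- eligible |> filter(.data$system %in% sys_set)
    n_t <- dplyr::n_distinct(hit[[key]])
    tibble(systems = label, unit = unit,
           n_units_with_tss = n_with_tss,
           n_units_targetable = n_t,
           fraction_targetable = if (n_with_tss > 0)
             round_half_up(100 * n_t / n_with_tss, 1) else NA_real_)
  }
  rows <- purrr::map(systems, function(s) one_row(s, s))
  if (length(systems) > 1) {
    rows <- c(rows, list(one_row(systems, paste(systems, collapse = "+"))))
  }
  out <- bind_rows(rows)
  class(out) <- c("targetability_report", class(out))
  out
}

#' Write a targetability report with a provenance header
#'
#' @param report Tibble from [summarize_targetability()].
#' @param path Output path.
#' @param provenance Optional named character vector written as `# key:
#'   value` comment lines (genome id, annotation digest, window, rules).
#' @return `path`, invisibly.
#' @export
write_targetability <- function(report, path, provenance = NULL) {
  body <- report
  class(body) <- setdiff(class(body), "targetability_report")
  write_tsv_with_header(body, path, provenance)
}

# TSV with optional '# key: value' comment header lines.
write_tsv_with_header <- function(body, path, provenance = NULL) {
  lines <- character(0)
  if (!is.null(provenance)) {
    lines <- sprintf("# %s: %s", names(provenance), provenance)
  }
  body_txt <- strsplit(readr::format_tsv(body), "\n", fixed = TRUE)[[1]]
  writeLines(c(lines, body_txt), path)
  invisible(path)
}

#' @method glance targetability_report
#' @export
glance.targetability_report <- function(x, ...) {
  tibble(n_rows = nrow(x),
         unit = unique(x$unit),
         n_units_with_tss = unique(x$n_units_with_tss),
         best_fraction = max(x$fraction_targetable))
}
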