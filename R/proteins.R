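#' Read a protein quantitation table
#'
#' Reads a TSV with columns `gene`, `accession`, `significance` (on the
#' `-10*log10(p)` scale, so 20 corresponds to p = 0.01), one or more
#' `ratio_<contrast>` columns (positive fold-change ratios), and optionally
#' `n_distinct` / `n_unique` peptide counts. Tables exported by quantitation
#' software that already applied the peptide-count inclusion rules may omit
#' the count columns; the rules are then treated as satisfied upstream.
#'
#' @param path TSV file path.
#' @return data frame of protein ratio records.
#' @export
read_protein_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "accession", "significance")
  if (!all(need %in% names(tab))) {
    stop("protein table must have columns: ", paste(need, collapse = ", "))
  }
  if (!any(startsWith(names(tab), "ratio_"))) {
    stop("protein table must have at least one ratio_<contrast> column")
  }
  tab
}

protein_ratios <- function(records, contrast) {
  col <- paste0("ratio_", contrast)
  if (!col %in% names(records)) {
    stop("contrast '", contrast, "' not present (no column ", col, ")")
  }
  r <- records[[col]]
  if (any(!is.na(r) & r <= 0)) stop("ratios must be > 0")
  r
}

#' Classify protein fold changes
#'
#' Applies the differential-cargo classification used for EV proteome
#' quantitation tables: a record is `"excluded"` if it fails the
#' significance threshold (`significance < min_significance`, i.e.
#' p > 0.01 at the default of 20 on the `-10*log10(p)` scale) or the
#' peptide-count rules (at least `min_distinct` distinct and `min_unique`
#' unique peptides, when counts are present); otherwise `"up"` if its ratio
#' is at least `up`, `"down"` if at most `down`, else `"unchanged"`.
#' Thresholds are inclusive, so a ratio of exactly 1.5 is up and 0.66 is
#' down, while 1.49 is unchanged.
#'
#' @param records data frame from [read_protein_table()] (or a single row).
#' @param contrast contrast name selecting the `ratio_<contrast>` column.
#' @param up,down fold-change thresholds (defaults 1.5 and 0.66).
#' @param min_significance minimum significance score (default 20).
#' @param min_distinct,min_unique peptide-count rules, applied only when the
#'   table carries `n_distinct` / `n_unique` columns.
#' @return character vector of labels: `"up"`, `"down"`, `"unchanged"` or
#'   `"excluded"`.
#' @export
classify_fold_change <- function(records, contrast, up = 1.5, down = 0.66,
                                 min_significance = 20, min_distinct = 2,
                                 min_unique = 1) {
  r <- protein_ratios(records, contrast)
  excluded <- records$significance < min_significance
  if ("n_distinct" %in% names(records)) {
    excluded <- excluded | records$n_distinct < min_distinct
  }
  if ("n_unique" %in% names(records)) {
    excluded <- excluded | records$n_unique < min_unique
  }
  label <- ifelse(excluded, "excluded",
           ifelse(r >= up, "up",
           ifelse(r <= down, "down", "unchanged")))
  label[is.na(r)] <- NA_character_
  label
}

#' Log2 coordinates for the two-contrast ratio plot
#'
#' Maps significance-filtered records to the coordinates of the
#' two-dimensional fold-change plot: `log2` of each contrast's ratio, with
#' the differential thresholds at +/- log2(1.5) = +/- 0.58. Records below
#' the significance threshold (p > 0.01, score < 20) are not plotted.
#'
#' @param records data frame from [read_protein_table()].
#' @param contrast_x,contrast_y contrast names for the two axes.
#' @param min_significance significance filter (default 20).
#' @return data frame with `gene`, `log2_x`, `log2_y`, plus `threshold`
#'   attribute giving the guide-line position.
#' @export
ratio_plot_coords <- function(records, contrast_x, contrast_y,
                              min_significance = 20) {
  rx <- protein_ratios(records, contrast_x)
  ry <- protein_ratios(records, contrast_y)
  keep <- records$significance >= min_significance & !is.na(rx) & !is.na(ry)
  out <- data.frame(gene = records$gene[keep],
                    log2_x = log2(rx[keep]), log2_y = log2(ry[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- log2(1.5)
  out
}

#' Convert between p-values and the -10*log10(p) significance scale
#'
#' @param p p-value(s).
#' @param significance score(s) on the `-10*log10(p)` scale.
#' @return the converted value(s); `significance_score(0.01)` is 20.
#' @export
significance_score <- function(p) -10 * log10(p)

#' @rdname significance_score
#' @export
significance_to_p <- function(significance) 10^(-significance / 10)
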