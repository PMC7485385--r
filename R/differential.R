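#' Classify fold changes as up-, down- or unchanged
#'
#' Thresholds are strict: up iff `fc > up_threshold`, down iff
#' `fc < down_threshold`, everything else (boundaries included) is
#' unchanged. The default asymmetric pair (1.5, 0.6) is the conventional
#' cut for small-n qPCR panel studies that call regulation by effect size
#' rather than by FDR-corrected p-values.
#'
#' @param fc Positive fold change(s).
#' @param up_threshold,down_threshold Fold thresholds,
#'   `down_threshold < up_threshold`.
#' @return Character vector over `fc` with values `"up"`, `"down"`,
#'   `"unchanged"`.
#' @export
classify_fc <- function(fc, up_threshold = 1.5, down_threshold = 0.6) {
  if (any(!is.finite(fc)) || any(fc <= 0))
    stop("fold changes must be finite and > 0")
  if (!(down_threshold < up_threshold))
    stop("'down_threshold' must be below 'up_threshold'")
  ifelse(fc > up_threshold, "up",
         ifelse(fc < down_threshold, "down", "unchanged"))
}

#' Per-feature fold changes between two groups
#'
#' The fold change of a feature is computed from the difference of
#' group-mean delta-Ct values, `fc = 2^-(mean_dct_test - mean_dct_ref)`,
#' i.e. a ratio of geometric means on the linear scale — the scale-stable
#' convention for qPCR. Optionally a per-feature two-sided pooled t-test
#' on the delta-Ct values (log scale) is attached; classification is by
#' fold-change thresholds, not p-values.
#'
#' @param norm A `delta_ct_matrix`.
#' @param sheet A sample sheet covering the columns of `norm`.
#' @param test_group,reference_group Group labels
#'   (`"<genotype>.<treatment>"`).
#' @param up_threshold,down_threshold Passed to [classify_fc()].
#' @param with_p Attach per-feature pooled t-test p-values (needs n >= 2
#'   per group).
#' @return A data frame of class `fold_change_table` with columns
#'   `feature_id`, `comparison`, `fc`, `log2fc`, `class` and optionally
#'   `p`; attribute `comparison` holds the label
#'   `"<test> vs <reference>"`.
#' @export
group_fold_change <- function(norm, sheet, test_group, reference_group,
                              up_threshold = 1.5, down_threshold = 0.6,
                              with_p = FALSE) {
  stopifnot(inherits(norm, "delta_ct_matrix"))
  grp <- sheet$group[match(colnames(norm), sheet$sample_id)]
  for (g in c(test_group, reference_group))
    if (!g %in% grp) stop("unknown group label: ", g)
  tc <- which(grp == test_group)
  rc <- which(grp == reference_group)
  m <- unclass(norm)
  ddct <- rowMeans(m[, tc, drop = FALSE]) - rowMeans(m[, rc, drop = FALSE])
  fc <- 2^-ddct
  label <- paste(test_group, "vs", reference_group)
  out <- data.frame(feature_id = rownames(norm), comparison = label,
                    fc = unname(fc), log2fc = unname(-ddct),
                    class = classify_fc(fc, up_threshold, down_threshold),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (with_p) {
    if (length(tc) < 2 || length(rc) < 2)
      stop("per-feature t-tests need n >= 2 in both groups")
    out$p <- vapply(seq_len(nrow(m)), function(i)
      ttest_raw(m[i, tc], m[i, rc])$p, numeric(1))
  }
  structure(out, comparison = label,
            class = c("fold_change_table", "data.frame"))
}

#' Up- and down-regulated feature sets of one comparison
#'
#' @param records A `fold_change_table` (or data frame with
#'   `feature_id`, `comparison`, `class`) from a single comparison.
#' @return List with character vectors `up` and `down` (disjoint).
#' @export
regulated_sets <- function(records) {
  if (length(unique(records$comparison)) > 1)
    stop("records mix multiple comparisons: ",
         paste(unique(records$comparison), collapse = "; "))
  list(up = records$feature_id[records$class == "up"],
       down = records$feature_id[records$class == "down"])
}

#' @export
print.fold_change_table <- function(x, ...) {
  cat(sprintf("fold_change_table: %s — %d features (%d up, %d down)\n",
              attr(x, "comparison"), nrow(x),
              sum(x$class == "up"), sum(x$class == "down")))
  invisible(x)
}

#' Write a fold-change table, sorted by descending fold change
#'
#' @param records A `fold_change_table`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_fold_changes <- function(records, path, sep = "\t") {
  df <- as.data.frame(records)[order(-records$fc), , drop = FALSE]
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
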