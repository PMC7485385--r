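#' Global-mean normalization of a Ct matrix
#'
#' For each sample the normalizer is the arithmetic mean Ct over the
#' reliably detected feature set (arithmetic mean on the Ct scale equals
#' the geometric mean of the linear quantities), and
#' `delta_ct(f, s) = Ct(f, s) - normalizer(s)`. The mean is taken over
#' the detected set rather than all wells so that non-amplifying assays
#' cannot distort it.
#'
#' @param ct A [ct_matrix()].
#' @param detected Character vector of feature ids to normalize (and
#'   average over), typically `filter_detected(ct)$detected`.
#' @return A `delta_ct_matrix`: numeric features-by-samples matrix of
#'   delta-Ct values (cycles, may be negative) with attributes `method`
#'   (`"global_mean"`) and `normalizer` (named per-sample mean Ct).
#' @export
global_mean_normalize <- function(ct, detected) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (inherits(detected, "detection_report")) detected <- detected$detected
  if (length(detected) == 0) stop("'detected' feature set is empty")
  bad <- setdiff(detected, rownames(ct))
  if (length(bad))
    stop("detected feature(s) not in matrix: ", paste(bad, collapse = ", "))
  sub <- unclass(ct)[detected, , drop = FALSE]
  if (anyNA(sub)) {
    holes <- rownames(sub)[apply(is.na(sub), 1, any)]
    stop("missing Ct among supposedly detected feature(s): ",
         paste(utils::head(holes, 5), collapse = ", "))
  }
  normalizer <- colMeans(sub)
  dct <- sweep(sub, 2, normalizer, "-")
  structure(dct, method = "global_mean", normalizer = normalizer,
            class = c("delta_ct_matrix", "matrix"))
}

#' Reference-gene normalization of a Ct matrix
#'
#' Classic single-reference delta-Ct:
#' `delta_ct(f, s) = Ct(f, s) - Ct(reference, s)` (e.g. reference = U6
#' snRNA). The reference must be detected in every sample; its own
#' delta-Ct row is identically zero. Features with any missing well are
#' dropped from the result, since a normalized matrix carries no missing
#' values.
#'
#' @param ct A [ct_matrix()].
#' @param reference_feature Feature id of the reference assay.
#' @return A `delta_ct_matrix` with attributes `method`
#'   (`"reference_gene"`), `normalizer` (the reference Ct per sample) and
#'   `reference_feature`.
#' @export
reference_normalize <- function(ct, reference_feature) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!reference_feature %in% rownames(ct))
    stop("reference feature not in matrix: ", reference_feature)
  ref <- unclass(ct)[reference_feature, ]
  if (anyNA(ref))
    stop("reference feature '", reference_feature,
         "' not detected in sample(s): ",
         paste(names(ref)[is.na(ref)], collapse = ", "))
  m <- unclass(ct)
  complete <- !apply(is.na(m), 1, any)
  dct <- sweep(m[complete, , drop = FALSE], 2, ref, "-")
  structure(dct, method = "reference_gene", normalizer = ref,
            reference_feature = reference_feature,
            class = c("delta_ct_matrix", "matrix"))
}

#' @export
print.delta_ct_matrix <- function(x, ...) {
  cat(sprintf("delta_ct_matrix (%s): %d features x %d samples\n",
              attr(x, "method"), nrow(x), ncol(x)))
  invisible(x)
}

#' Relative quantity from delta-Ct values (2^-ddCt)
#'
#' `rq = 2^-(delta_ct_sample - delta_ct_reference)`: the fold difference
#' in template between a sample and a reference sample under perfect
#' doubling per cycle. A ddCt of -1 is a doubling; +1 a halving.
#'
#' @param delta_ct_sample,delta_ct_reference Finite delta-Ct values in
#'   cycles (vectorized).
#' @return Positive fold change(s), unitless.
#' @export
relative_quantity <- function(delta_ct_sample, delta_ct_reference) {
  if (any(!is.finite(delta_ct_sample)) || any(!is.finite(delta_ct_reference)))
    stop("delta-Ct values must be finite")
  2^-(delta_ct_sample - delta_ct_reference)
}

#' Per-group delta-Ct summaries
#'
#' Mean, SEM (sample SD with n-1 denominator over sqrt(n)) and n of the
#' delta-Ct values of each feature within each experimental group. SEM
#' is `NA` for groups of a single sample.
#'
#' @param norm A `delta_ct_matrix`.
#' @param sheet A sample sheet covering every column of `norm`.
#' @return Long data frame: `feature_id`, `group`, `mean_dct`, `sem`, `n`.
#' @export
group_delta_ct <- function(norm, sheet) {
  stopifnot(inherits(norm, "delta_ct_matrix"))
  missing_samples <- setdiff(colnames(norm), sheet$sample_id)
  if (length(missing_samples))
    stop("sample(s) absent from sheet: ",
         paste(missing_samples, collapse = ", "))
  grp <- sheet$group[match(colnames(norm), sheet$sample_id)]
  groups <- unique(grp)
  out <- lapply(groups, function(g) {
    cols <- which(grp == g)
    if (!length(cols)) stop("group with no samples: ", g)
    sub <- unclass(norm)[, cols, drop = FALSE]
    n <- length(cols)
    data.frame(feature_id = rownames(norm), group = g,
               mean_dct = rowMeans(sub),
               sem = if (n > 1) apply(sub, 1, stats::sd) / sqrt(n)
                     else NA_real_,
               n = n, stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}
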