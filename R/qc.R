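#' Detection filter for a Ct matrix
#'
#' A non-control feature is *detected* when its Ct value is non-missing
#' and strictly below `threshold` in every sample of `scope`. This joint
#' rule across all samples of all groups is the standard reliability
#' filter for high-density qPCR panels; with the default threshold a well
#' at exactly Ct = 28.0 fails. Control-flagged features are never in the
#' detected set.
#'
#' @param ct A [ct_matrix()].
#' @param threshold Ct cycles; strict upper bound for detection.
#' @param scope Character vector of sample ids the rule is evaluated
#'   over; defaults to all samples.
#' @return A `detection_report`: list with `detected` (character vector
#'   of feature ids), `dropped` (data.frame `feature_id`, `sample_id`,
#'   `reason` with reason `"missing"` or `"ct_above_threshold"`, one row
#'   per failing well), `threshold` and `scope`.
#' @export
filter_detected <- function(ct, threshold = 28, scope = colnames(ct)) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("'threshold' must be a single positive number of cycles")
  if (length(scope) == 0) stop("'scope' must contain at least one sample")
  bad <- setdiff(scope, colnames(ct))
  if (length(bad))
    stop("scope sample(s) not in matrix: ", paste(bad, collapse = ", "))
  feats <- assay_features(ct)
  sub <- unclass(ct)[feats, scope, drop = FALSE]
  ok <- !is.na(sub) & sub < threshold
  detected <- feats[rowSums(ok) == length(scope)]
  fail <- which(!ok, arr.ind = TRUE)
  dropped <- data.frame(
    feature_id = feats[fail[, 1]],
    sample_id = scope[fail[, 2]],
    reason = ifelse(is.na(sub[fail]), "missing", "ct_above_threshold"),
    stringsAsFactors = FALSE)
  dropped <- dropped[!dropped$feature_id %in% detected, , drop = FALSE]
  dropped <- dropped[order(match(dropped$feature_id, feats),
                           match(dropped$sample_id, scope)), , drop = FALSE]
  rownames(dropped) <- NULL
  structure(list(detected = detected, dropped = dropped,
                 threshold = threshold, scope = scope),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf(
    "detection_report: %d features detected (Ct < %g in all %d samples), %d dropped\n",
    length(x$detected), x$threshold, length(x$scope),
    length(unique(x$dropped$feature_id))))
  invisible(x)
}

#' Internal-control sanity checks
#'
#' Advisory QC on the control-flagged assays: a negative control that
#' amplifies below `threshold` in any sample suggests contamination
#' (`warn`); an endogenous control missing in any sample suggests a
#' failed well (`warn`). Findings never remove data.
#'
#' @param ct A [ct_matrix()].
#' @param threshold Ct cycles below which a negative-control signal is
#'   treated as real amplification.
#' @return Data frame with columns `control_id`, `flag`, `status`
#'   (`"pass"`/`"warn"`) and `message`.
#' @export
check_controls <- function(ct, threshold = 28) {
  stopifnot(inherits(ct, "ct_matrix"))
  flags <- control_flags(ct)
  ids <- names(flags)[flags != "none"]
  res <- lapply(ids, function(id) {
    row <- unclass(ct)[id, ]
    if (flags[[id]] == "negative_control") {
      hot <- names(row)[!is.na(row) & row < threshold]
      if (length(hot))
        list(status = "warn",
             message = sprintf("negative control amplified (Ct < %g) in: %s",
                               threshold, paste(hot, collapse = ", ")))
      else
        list(status = "pass", message = "no amplification, as expected")
    } else {
      absent <- names(row)[is.na(row)]
      if (length(absent))
        list(status = "warn",
             message = paste("endogenous control not detected in:",
                             paste(absent, collapse = ", ")))
      else
        list(status = "pass", message = "detected in all samples")
    }
  })
  data.frame(control_id = ids,
             flag = unname(flags[ids]),
             status = vapply(res, `[[`, character(1), "status"),
             message = vapply(res, `[[`, character(1), "message"),
             stringsAsFactors = FALSE)
}
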