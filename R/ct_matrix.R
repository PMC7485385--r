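#' Construct a Ct matrix
#'
#' A `ct_matrix` holds raw qPCR cycle-threshold values as a numeric
#' features-by-samples matrix. Non-detected wells are `NA`. Each feature
#' carries a control flag: `"none"` for a biological assay,
#' `"negative_control"` for a no-template/foreign-species control that is
#' expected never to amplify, or `"endogenous_control"` for a small-RNA
#' reference assay (e.g. U6 snRNA) expected to amplify in every sample.
#' Control-flagged features never enter the detected set or downstream
#' statistics unless explicitly selected as a normalizer.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Row and column names are required and must be unique. Non-missing
#'   values must be finite and strictly positive (PCR cycles).
#' @param negative_controls Character vector of feature ids flagged as
#'   negative controls.
#' @param endogenous_controls Character vector of feature ids flagged as
#'   endogenous controls.
#' @return An object of class `ct_matrix`: the numeric matrix with a
#'   `control_flags` attribute (named character vector, one entry per
#'   feature).
#' @examples
#' m <- matrix(c(20, 22, 21, 23), nrow = 2,
#'             dimnames = list(c("mmu-miR-155", "mmu-miR-134"),
#'                             c("s1", "s2")))
#' ct <- ct_matrix(m)
#' @export
ct_matrix <- function(values, negative_controls = character(),
                      endogenous_controls = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("'values' must have feature row names and sample column names")
  if (anyDuplicated(fid))
    stop("duplicate feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  v <- values[!is.na(values)]
  if (any(!is.finite(v)) || any(v <= 0))
    stop("non-missing Ct values must be finite and > 0")
  bad <- setdiff(c(negative_controls, endogenous_controls), fid)
  if (length(bad))
    stop("control feature(s) not in matrix: ", paste(bad, collapse = ", "))
  if (length(intersect(negative_controls, endogenous_controls)))
    stop("a feature cannot be both a negative and an endogenous control")
  flags <- stats::setNames(rep("none", length(fid)), fid)
  flags[negative_controls] <- "negative_control"
  flags[endogenous_controls] <- "endogenous_control"
  structure(values, control_flags = flags, class = c("ct_matrix", "matrix"))
}

#' @export
print.ct_matrix <- function(x, ...) {
  flags <- control_flags(x)
  cat(sprintf("ct_matrix: %d features x %d samples\n", nrow(x), ncol(x)))
  cat(sprintf("  controls: %d negative, %d endogenous\n",
              sum(flags == "negative_control"),
              sum(flags == "endogenous_control")))
  cat(sprintf("  missing (non-detected) wells: %d of %d\n",
              sum(is.na(x)), length(x)))
  invisible(x)
}

#' Control flags of a Ct matrix
#'
#' @param ct A `ct_matrix`.
#' @return Named character vector over features with values `"none"`,
#'   `"negative_control"` or `"endogenous_control"`.
#' @export
control_flags <- function(ct) {
  stopifnot(inherits(ct, "ct_matrix"))
  attr(ct, "control_flags")
}

#' Feature ids of the non-control assays
#'
#' @param ct A `ct_matrix`.
#' @return Character vector of feature ids whose control flag is `"none"`.
#' @export
assay_features <- function(ct) {
  flags <- control_flags(ct)
  names(flags)[flags == "none"]
}
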