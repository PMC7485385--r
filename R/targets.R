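#' Per-source configuration for miRNA-target tables
#'
#' Each target source is either *validated* (experimentally supported
#' links, e.g. miRTarBase, TarBase; no score needed) or *predicted*
#' (score-carrying, e.g. TargetScan, miRDB). Predicted sources declare
#' how their raw scores are oriented and how they map to the common
#' [0, 1] confidence scale:
#' \itemize{
#'   \item `"fixed_range"`: a fixed linear map `range_raw -> range_scaled`;
#'     the miRDB convention is raw scores on \[50, 100\] mapped to
#'     \[0.5, 1\] (the database drops targets scoring below 50, with a
#'     maximum of 100, so the map is uniquely raw/100).
#'   \item `"minmax"`: the observed extreme in the "stronger" direction
#'     maps to 1, the opposite extreme to 0. TargetScan-style context
#'     scores are more negative when stronger (`lower_is_stronger`).
#'   \item `"none"`: validated sources.
#' }
#'
#' @param name Source name (e.g. `"miRDB"`).
#' @param evidence `"validated"` or `"predicted"`.
#' @param score_direction `"higher_is_stronger"` or `"lower_is_stronger"`.
#' @param rescale `"none"`, `"minmax"` or `"fixed_range"`.
#' @param range_raw,range_scaled Numeric length-2 endpoints for
#'   `"fixed_range"`.
#' @return An object of class `source_config`.
#' @export
source_config <- function(name,
                          evidence = c("validated", "predicted"),
                          score_direction = c("higher_is_stronger",
                                              "lower_is_stronger"),
                          rescale = c("none", "minmax", "fixed_range"),
                          range_raw = NULL, range_scaled = c(0, 1)) {
  evidence <- match.arg(evidence)
  score_direction <- match.arg(score_direction)
  rescale <- match.arg(rescale)
  if (evidence == "predicted" && rescale == "none")
    stop("predicted sources must define a rescale rule")
  if (rescale == "fixed_range") {
    if (is.null(range_raw) || length(range_raw) != 2)
      stop("'fixed_range' needs a length-2 'range_raw'")
    stopifnot(length(range_scaled) == 2)
  }
  structure(list(name = name, evidence = evidence,
                 score_direction = score_direction, rescale = rescale,
                 range_raw = range_raw, range_scaled = range_scaled),
            class = "source_config")
}

#' Preset source configurations
#'
#' `mirdb_config()`: predicted, fixed linear map \[50, 100\] -> \[0.5, 1\].
#' `targetscan_config()`: predicted, minmax with lower-is-stronger
#' orientation. `validated_config(name)`: validated, no score.
#'
#' @param name Source name.
#' @return A [source_config()].
#' @export
mirdb_config <- function(name = "miRDB") {
  source_config(name, evidence = "predicted",
                score_direction = "higher_is_stronger",
                rescale = "fixed_range",
                range_raw = c(50, 100), range_scaled = c(0.5, 1))
}

#' @rdname mirdb_config
#' @export
targetscan_config <- function(name = "TargetScan") {
  source_config(name, evidence = "predicted",
                score_direction = "lower_is_stronger", rescale = "minmax")
}

#' @rdname mirdb_config
#' @export
validated_config <- function(name = "miRTarBase") {
  source_config(name, evidence = "validated")
}

#' Build a target-record table
#'
#' @param mirna,gene Character vectors of equal length.
#' @param source Source name (recycled).
#' @param evidence `"validated"` or `"predicted"` (recycled).
#' @param raw_score Numeric raw prediction scores, `NA` for validated.
#' @param rescaled_score Numeric in \[0, 1\] or `NA` before rescaling.
#' @return Data frame with the five columns above.
#' @export
target_records <- function(mirna, gene, source, evidence,
                           raw_score = NA_real_,
                           rescaled_score = NA_real_) {
  n <- length(mirna)
  data.frame(mirna = as.character(mirna), gene = as.character(gene),
             source = rep_len(source, n), evidence = rep_len(evidence, n),
             raw_score = rep_len(as.numeric(raw_score), n),
             rescaled_score = rep_len(as.numeric(rescaled_score), n),
             stringsAsFactors = FALSE)
}

#' Read a per-source target table
#'
#' Tab-separated with header columns `mirna`, `gene` and optionally
#' `score` (blank for validated sources).
#'
#' @param path Path to the file.
#' @param config The [source_config()] of this table.
#' @param sep Field separator.
#' @return A target-record data frame (not yet rescaled).
#' @export
read_target_table <- function(path, config, sep = "\t") {
  stopifnot(inherits(config, "source_config"))
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  need <- c("mirna", "gene")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("target table missing column(s): ", paste(miss, collapse = ", "))
  raw <- if ("score" %in% colnames(df))
    suppressWarnings(as.numeric(df$score)) else NA_real_
  target_records(df$mirna, df$gene, config$name, config$evidence,
                 raw_score = raw)
}

#' Rescale raw prediction scores to the common confidence scale
#'
#' Applies the source's rescale rule (see [source_config()]). Validated
#' records pass through with rescaled score 1. For `"fixed_range"`, a
#' raw score outside the declared range is an error naming the record.
#'
#' @param records Target-record data frame, all rows from `config`'s
#'   source.
#' @param config A [source_config()].
#' @return The records with `rescaled_score` filled in (always in
#'   \[0, 1\]).
#' @export
rescale_scores <- function(records, config) {
  stopifnot(inherits(config, "source_config"))
  if (nrow(records) == 0) return(records)
  if (any(records$source != config$name))
    stop("records from source(s) other than '", config$name, "'")
  if (config$evidence == "validated") {
    records$rescaled_score <- 1
    return(records)
  }
  if (anyNA(records$raw_score))
    stop("predicted records must carry raw scores")
  raw <- records$raw_score
  if (config$rescale == "fixed_range") {
    lo <- config$range_raw[1]; hi <- config$range_raw[2]
    out <- which(raw < lo | raw > hi)
    if (length(out))
      stop(sprintf("raw score %g for %s -> %s outside declared range [%g, %g]",
                   raw[out[1]], records$mirna[out[1]], records$gene[out[1]],
                   lo, hi))
    f <- (raw - lo) / (hi - lo)
  } else { # minmax on the observed scores
    lo <- min(raw); hi <- max(raw)
    if (hi == lo) {
      f <- rep(1, length(raw))  # a single observed value is the strongest
    } else {
      f <- (raw - lo) / (hi - lo)
      if (config$score_direction == "lower_is_stronger") f <- 1 - f
    }
  }
  if (config$rescale == "fixed_range" &&
      config$score_direction == "lower_is_stronger")
    f <- 1 - f
  s <- config$range_scaled
  records$rescaled_score <- s[1] + f * (s[2] - s[1])
  records
}

#' Drop weak predicted targets
#'
#' Predicted records with `rescaled_score` strictly below `min_rescaled`
#' are removed; a record at exactly the cutoff is retained. Validated
#' records are always retained — the filter applies to prediction scores
#' only.
#'
#' @param records Rescaled target-record data frame.
#' @param min_rescaled Cutoff on the common \[0, 1\] scale.
#' @return Filtered records.
#' @export
filter_by_score <- function(records, min_rescaled = 0.5) {
  if (nrow(records) == 0) return(records)
  pred <- records$evidence == "predicted"
  if (any(pred & is.na(records$rescaled_score)))
    stop("predicted records must be rescaled before filtering")
  keep <- !pred | records$rescaled_score >= min_rescaled
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge target tables from multiple sources
#'
#' One record per distinct (miRNA, gene) pair: evidence is `"validated"`
#' if any contributing source is validated (with rescaled score 1),
#' otherwise `"predicted"` with the maximum rescaled score across
#' sources. Provenance is kept in `source` as a sorted
#' semicolon-separated list. The result is sorted by (miRNA, gene), so
#' merging is idempotent and independent of input order.
#'
#' @param ... Rescaled (and typically filtered) target-record data
#'   frames, or a single list of them.
#' @return Merged target-record data frame.
#' @export
merge_sources <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && !is.data.frame(args[[1]]))
    args <- args[[1]]
  all <- do.call(rbind, args)
  if (is.null(all) || nrow(all) == 0)
    return(target_records(character(), character(), character(),
                          character()))
  key <- paste(all$mirna, all$gene, sep = "\r")
  idx <- split(seq_len(nrow(all)), key)
  rows <- lapply(idx, function(i) {
    validated <- any(all$evidence[i] == "validated")
    data.frame(
      mirna = all$mirna[i[1]], gene = all$gene[i[1]],
      source = paste(sort(unique(unlist(
        strsplit(all$source[i], ";", fixed = TRUE))), method = "radix"),
        collapse = ";"),
      evidence = if (validated) "validated" else "predicted",
      raw_score = NA_real_,
      rescaled_score = if (validated) 1 else max(all$rescaled_score[i]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes supported by multiple regulated miRNAs
#'
#' For each gene, the supporting miRNAs are the members of `regulated`
#' with a retained target record to that gene; genes supported by fewer
#' than `min_support` regulated miRNAs are excluded. Restricting pathway
#' analysis to genes hit by at least two co-regulated miRNAs suppresses
#' single-prediction noise.
#'
#' @param records Merged/filtered target-record data frame.
#' @param regulated Character vector of regulated miRNA ids (one
#'   direction, one condition).
#' @param min_support Minimum number of supporting regulated miRNAs.
#' @return Data frame `gene`, `support_count`, plus list-column
#'   `supporting_mirnas`, sorted by decreasing support then gene.
#' @export
aggregate_gene_support <- function(records, regulated, min_support = 2) {
  if (length(regulated) == 0)
    stop("'regulated' miRNA set is empty")
  sub <- records[records$mirna %in% regulated, , drop = FALSE]
  if (nrow(sub) == 0)
    return(data.frame(gene = character(), support_count = integer(),
                      stringsAsFactors = FALSE))
  sup <- lapply(split(sub$mirna, sub$gene), function(m) sort(unique(m)))
  counts <- lengths(sup)
  keep <- counts >= min_support
  out <- data.frame(gene = names(sup)[keep],
                    support_count = unname(counts[keep]),
                    stringsAsFactors = FALSE)
  out$supporting_mirnas <- unname(sup[keep])
  out <- out[order(-out$support_count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
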