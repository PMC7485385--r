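#' Read a Ct matrix from a delimited text file
#'
#' The canonical layout is tab-separated text: the first row is a header
#' `feature_id<TAB>sample1<TAB>sample2...`, one feature per subsequent row.
#' Non-detected wells may be encoded as `Undetermined`, `NA` or an empty
#' field; all are read as missing.
#'
#' @param path Path to the file.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @param missing Strings interpreted as a non-detected well.
#' @param negative_controls,endogenous_controls Feature ids to flag as
#'   controls (see [ct_matrix()]).
#' @return A [ct_matrix()].
#' @export
read_ct_matrix <- function(path, sep = "\t",
                           missing = c("Undetermined", "NA", ""),
                           negative_controls = character(),
                           endogenous_controls = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "", na.strings = NULL)
  if (ncol(raw) < 2) stop("Ct matrix needs a feature column plus >= 1 sample")
  fid <- raw[[1L]]
  if (anyDuplicated(fid))
    stop("duplicate feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  sid <- colnames(raw)[-1L]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  is_missing <- vals %in% missing
  dim(is_missing) <- dim(vals)
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(!is_missing & is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric Ct value '%s' at feature '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], fid[bad[1, 1]], sid[bad[1, 2]]))
  num[is_missing] <- NA_real_
  dimnames(num) <- list(fid, sid)
  ct_matrix(num, negative_controls = negative_controls,
            endogenous_controls = endogenous_controls)
}

#' Write a Ct matrix
#'
#' Missing (non-detected) wells are written as `Undetermined`.
#'
#' @param ct A [ct_matrix()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_ct_matrix <- function(ct, path, sep = "\t") {
  stopifnot(inherits(ct, "ct_matrix"))
  out <- format(unclass(ct), trim = TRUE, digits = 15)
  out[is.na(ct)] <- "Undetermined"
  df <- data.frame(feature_id = rownames(ct), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(ct))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with header columns `sample_id`, `genotype`, `treatment`
#' and optionally `pool_members` (semicolon-separated animal ids). The
#' experimental group of a sample is the cross of genotype and treatment,
#' stored in a derived `group` column as `"<genotype>.<treatment>"`.
#'
#' @param path Path to the file.
#' @param sep Field separator.
#' @return A `data.frame` with columns `sample_id`, `genotype`,
#'   `treatment`, `group` and a list-column `pool_members`.
#' @export
read_sample_sheet <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  need <- c("sample_id", "genotype", "treatment")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("sample sheet contains no samples")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s) in sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  pm <- if ("pool_members" %in% colnames(df))
    strsplit(df$pool_members, ";", fixed = TRUE)
  else
    as.list(df$sample_id)
  sample_sheet(df$sample_id, df$genotype, df$treatment, pool_members = pm)
}

#' Construct a sample sheet
#'
#' @param sample_id,genotype,treatment Character vectors of equal length.
#' @param pool_members List of character vectors of animal ids (each of
#'   length >= 1); defaults to one pseudo-animal per sample.
#' @return A `data.frame` as described in [read_sample_sheet()].
#' @export
sample_sheet <- function(sample_id, genotype, treatment,
                         pool_members = as.list(sample_id)) {
  n <- length(sample_id)
  stopifnot(length(genotype) == n, length(treatment) == n,
            length(pool_members) == n)
  if (n == 0) stop("sample sheet contains no samples")
  if (anyDuplicated(sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (any(lengths(pool_members) < 1))
    stop("every sample must pool >= 1 animal")
  df <- data.frame(sample_id = as.character(sample_id),
                   genotype = as.character(genotype),
                   treatment = as.character(treatment),
                   group = paste(genotype, treatment, sep = "."),
                   stringsAsFactors = FALSE)
  df$pool_members <- pool_members
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Write a sample sheet
#'
#' @param sheet A sample sheet.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path, sep = "\t") {
  df <- data.frame(sample_id = sheet$sample_id, genotype = sheet$genotype,
                   treatment = sheet$treatment,
                   pool_members = vapply(sheet$pool_members, paste,
                                         character(1), collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check Ct matrix / sample sheet agreement
#'
#' Errors unless the sheet's sample ids and the matrix's sample ids are
#' exactly the same set, listing every mismatch.
#'
#' @param ct A [ct_matrix()].
#' @param sheet A sample sheet.
#' @return `TRUE`, invisibly.
#' @export
validate_samples <- function(ct, sheet) {
  only_sheet <- setdiff(sheet$sample_id, colnames(ct))
  only_ct <- setdiff(colnames(ct), sheet$sample_id)
  if (length(only_sheet) || length(only_ct))
    stop("sample sheet / Ct matrix mismatch",
         if (length(only_sheet))
           paste0("; in sheet only: ", paste(only_sheet, collapse = ", ")),
         if (length(only_ct))
           paste0("; in matrix only: ", paste(only_ct, collapse = ", ")))
  invisible(TRUE)
}

#' Construct a gene-set collection
#'
#' @param term_id Character vector of unique term identifiers.
#' @param term_name Character vector of human-readable names (recycled
#'   from `term_id` if omitted).
#' @param genes List of character vectors of gene symbols; duplicates
#'   within a term are dropped; empty sets are an error.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(term_id, genes, term_name = term_id) {
  stopifnot(length(term_id) == length(genes),
            length(term_name) == length(term_id))
  if (anyDuplicated(term_id))
    stop("duplicate term id(s): ",
         paste(unique(term_id[duplicated(term_id)]), collapse = ", "))
  genes <- lapply(genes, function(g) unique(as.character(g)))
  if (any(lengths(genes) == 0)) stop("every gene set must be non-empty")
  structure(list(term_id = as.character(term_id),
                 term_name = as.character(term_name),
                 genes = stats::setNames(genes, term_id)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms, %d distinct genes\n",
              length(x$term_id), length(unique(unlist(x$genes)))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$term_id)

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated
#' `term_id<TAB>term_name<TAB>gene1<TAB>gene2...`; at least three fields
#' per line. Genes are deduplicated within a term; term order is kept.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  gene_set_collection(
    term_id = vapply(fields, `[`, character(1), 1L),
    term_name = vapply(fields, `[`, character(1), 2L),
    genes = lapply(fields, function(f) f[-(1:2)]))
}

#' Write a GMT gene-set file
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- mapply(function(id, nm, g) paste(c(id, nm, g), collapse = "\t"),
                  collection$term_id, collection$term_name,
                  collection$genes)
  writeLines(lines, path)
  invisible(path)
}
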