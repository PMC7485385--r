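#' Run the full panel analysis pipeline
#'
#' Orchestrates the canonical end-to-end analysis of a qPCR miRNA panel
#' experiment: detection filtering and control QC, global-mean
#' normalization, per-comparison fold-change classification, Venn
#' partitioning of regulated sets across comparison pairs, per-condition
#' target aggregation (up- and down-regulated branches kept separate)
#' and over-representation analysis of the supported gene lists. Given
#' identical inputs the run is fully deterministic; when `out_dir` is
#' set, every stage writes a TSV report plus a JSON manifest of
#' parameters and stage counts.
#'
#' @param ct A [ct_matrix()] or a path readable by [read_ct_matrix()].
#' @param sheet A sample sheet or a path readable by
#'   [read_sample_sheet()].
#' @param negative_controls,endogenous_controls Control feature ids,
#'   used when `ct` is read from a path.
#' @param comparisons List of length-2 character vectors
#'   `c(test_group, reference_group)`.
#' @param threshold Detection Ct threshold (strict).
#' @param up_threshold,down_threshold Fold-change classification cuts.
#' @param venn_pairs Optional list of length-2 vectors of comparison
#'   labels (`"<test> vs <reference>"`) to partition against each other.
#' @param target_tables Optional named list of raw per-source
#'   target-record data frames.
#' @param source_configs List of [source_config()]s matching
#'   `target_tables` by name.
#' @param min_support Minimum regulated miRNAs per gene.
#' @param min_rescaled Prediction-score cutoff for [filter_by_score()].
#' @param gene_sets Optional [gene_set_collection()] for enrichment.
#' @param alpha Adjusted-p significance cutoff.
#' @param top Top-k terms kept in enrichment reports.
#' @param out_dir Optional output directory for TSV/JSON reports.
#' @return List with elements `detection`, `controls`, `normalized`,
#'   `fold_changes` (named by comparison label), `regulated`, `venn`,
#'   `targets` (merged records), `support` and `enrichment` (nested by
#'   comparison label then direction), and `manifest`.
#' @export
run_pipeline <- function(ct, sheet, comparisons,
                         negative_controls = character(),
                         endogenous_controls = character(),
                         threshold = 28,
                         up_threshold = 1.5, down_threshold = 0.6,
                         venn_pairs = NULL,
                         target_tables = NULL, source_configs = NULL,
                         min_support = 2, min_rescaled = 0.5,
                         gene_sets = NULL, alpha = 0.05, top = 20,
                         out_dir = NULL) {
  if (is.character(ct))
    ct <- read_ct_matrix(ct, negative_controls = negative_controls,
                         endogenous_controls = endogenous_controls)
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  validate_samples(ct, sheet)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))

  detection <- stage("qc", filter_detected(ct, threshold = threshold))
  controls <- stage("qc", check_controls(ct, threshold = threshold))
  normalized <- stage("normalize",
                      global_mean_normalize(ct, detection$detected))

  fold_changes <- list()
  regulated <- list()
  for (cmp in comparisons) {
    fc <- stage("diffexpr",
                group_fold_change(normalized, sheet, cmp[1], cmp[2],
                                  up_threshold = up_threshold,
                                  down_threshold = down_threshold))
    label <- attr(fc, "comparison")
    fold_changes[[label]] <- fc
    regulated[[label]] <- regulated_sets(fc)
  }

  venn <- list()
  if (!is.null(venn_pairs)) {
    for (pair in venn_pairs) {
      a <- regulated[[pair[1]]]; b <- regulated[[pair[2]]]
      if (is.null(a) || is.null(b))
        stop("pipeline stage 'venn' failed: unknown comparison in pair: ",
             paste(pair, collapse = " / "), call. = FALSE)
      venn[[paste(pair, collapse = " | ")]] <-
        stage("venn", venn_partition(a$up, a$down, b$up, b$down,
                                     labels = pair))
    }
  }

  targets <- NULL
  support <- list()
  enrichment <- list()
  if (!is.null(target_tables)) {
    if (is.null(source_configs))
      stop("'target_tables' given without 'source_configs'")
    names(source_configs) <- vapply(source_configs, `[[`,
                                    character(1), "name")
    processed <- lapply(names(target_tables), function(nm) {
      cfg <- source_configs[[nm]]
      if (is.null(cfg)) stop("no source_config for table '", nm, "'")
      filter_by_score(rescale_scores(target_tables[[nm]], cfg),
                      min_rescaled = min_rescaled)
    })
    targets <- stage("targets", merge_sources(processed))
    for (label in names(regulated)) {
      support[[label]] <- list()
      enrichment[[label]] <- list()
      for (dir in c("up", "down")) {
        reg <- regulated[[label]][[dir]]
        sup <- if (length(reg))
          stage("targets",
                aggregate_gene_support(targets, reg,
                                       min_support = min_support))
        else
          data.frame(gene = character(), support_count = integer(),
                     stringsAsFactors = FALSE)
        support[[label]][[dir]] <- sup
        annotated <- if (!is.null(gene_sets))
          unique(unlist(gene_sets$genes)) else character()
        if (length(intersect(sup$gene, annotated)))
          enrichment[[label]][[dir]] <-
            stage("enrich", enrich(sup$gene, gene_sets, alpha = alpha,
                                   top = top))
      }
    }
  }

  manifest <- list(
    package = "panelmiR",
    version = as.character(utils::packageVersion("panelmiR")),
    parameters = list(threshold = threshold,
                      up_threshold = up_threshold,
                      down_threshold = down_threshold,
                      min_support = min_support,
                      min_rescaled = min_rescaled,
                      alpha = alpha, top = top),
    counts = c(
      list(n_features = nrow(ct), n_samples = ncol(ct),
           n_detected = length(detection$detected)),
      lapply(regulated, function(r)
        list(up = length(r$up), down = length(r$down))))
  )

  if (!is.null(out_dir)) {
    safe <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)
    utils::write.table(
      data.frame(feature_id = detection$detected),
      file.path(out_dir, "detected_features.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(controls, file.path(out_dir, "control_qc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    norm_df <- data.frame(feature_id = rownames(normalized),
                          unclass(normalized), check.names = FALSE)
    utils::write.table(norm_df, file.path(out_dir, "delta_ct.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (label in names(fold_changes))
      write_fold_changes(fold_changes[[label]],
                         file.path(out_dir,
                                   paste0("fc_", safe(label), ".tsv")))
    for (label in names(venn)) {
      s <- overlap_summary(venn[[label]])
      utils::write.table(
        data.frame(cell = names(s$counts), count = unname(s$counts)),
        file.path(out_dir, paste0("venn_", safe(label), ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (label in names(support))
      for (dir in names(support[[label]])) {
        sup <- support[[label]][[dir]]
        df <- data.frame(gene = sup$gene,
                         support_count = sup$support_count)
        utils::write.table(
          df, file.path(out_dir, paste0("support_", safe(label), "_",
                                        dir, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    for (label in names(enrichment))
      for (dir in names(enrichment[[label]]))
        utils::write.table(
          as.data.frame(enrichment[[label]][[dir]]),
          file.path(out_dir, paste0("enrichment_", safe(label), "_",
                                    dir, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(detection = detection, controls = controls,
                 normalized = normalized, fold_changes = fold_changes,
                 regulated = regulated, venn = venn, targets = targets,
                 support = support, enrichment = enrichment,
                 manifest = manifest))
}
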