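#' Simulation configuration for a synthetic qPCR panel experiment
#'
#' Describes a high-density qPCR miRNA profiling design: a 754-assay
#' panel with four internal controls (one negative), four
#' genotype-by-treatment groups of three samples each, every sample a
#' pool of two animals. Expression acts on the Ct scale with one log2
#' unit per cycle at perfect efficiency (higher expression, lower Ct).
#'
#' Noise has two components: an animal-level biological deviation
#' (`bio_sd`, averaged over the `pool_size` animals of a pool) and a
#' technical per-well deviation (`noise_sd`). Wells whose Ct exceeds
#' `dropout_ct` are non-detected. Baseline Ct values are drawn once per
#' feature from `N(baseline_mean, baseline_sd)`.
#'
#' Group effects are planted on features: `n_planted` features are
#' chosen (among features whose Ct stays comfortably below the detection
#' threshold in every group, cap `plant_max_ct`) and shifted by
#' `planted_log2fc` log2 units in `planted_group`. The true log2 fold
#' change of any comparison is the difference of the two groups'
#' effects.
#'
#' @param n_features Number of biological assays on the panel.
#' @param groups Data frame `genotype`, `treatment`, `n_samples`.
#' @param pool_size Animals pooled per sample.
#' @param baseline_mean,baseline_sd Across-feature baseline Ct
#'   distribution (cycles).
#' @param bio_sd Animal-level biological SD (cycles).
#' @param noise_sd Technical per-well SD (cycles).
#' @param dropout_ct Ct above which a well reads as non-detected.
#' @param n_planted Number of features carrying a planted effect.
#' @param planted_log2fc Planted log2 fold changes (recycled to
#'   `n_planted`; signs respected).
#' @param planted_group Group label receiving the effects (default: the
#'   last group in `groups`).
#' @param plant_max_ct Baseline cap so planted features stay detectable
#'   in every group.
#' @param seed Default seed for [generate_ct_dataset()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_features = 754,
                              groups = data.frame(
                                genotype = c("wt", "wt", "ko", "ko"),
                                treatment = c("vehicle", "KA",
                                              "vehicle", "KA"),
                                n_samples = 3,
                                stringsAsFactors = FALSE),
                              pool_size = 2,
                              baseline_mean = 28, baseline_sd = 3.5,
                              bio_sd = 0.25, noise_sd = 0.25,
                              dropout_ct = 35,
                              n_planted = 0, planted_log2fc = 2,
                              planted_group = NULL,
                              plant_max_ct = 26.5, seed = 1) {
  stopifnot(n_features > 0, pool_size >= 1, bio_sd >= 0, noise_sd >= 0,
            dropout_ct > 0, n_planted >= 0)
  groups$label <- paste(groups$genotype, groups$treatment, sep = ".")
  if (anyDuplicated(groups$label))
    stop("duplicate group label(s) in design")
  if (is.null(planted_group)) planted_group <- groups$label[nrow(groups)]
  if (n_planted > 0 && !planted_group %in% groups$label)
    stop("'planted_group' not in the design: ", planted_group)
  if (n_planted > n_features)
    stop("cannot plant more effects than features")
  structure(list(n_features = n_features, groups = groups,
                 pool_size = pool_size, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, bio_sd = bio_sd,
                 noise_sd = noise_sd, dropout_ct = dropout_ct,
                 n_planted = n_planted,
                 planted_log2fc = rep_len(planted_log2fc,
                                          max(n_planted, 1)),
                 planted_group = planted_group,
                 plant_max_ct = plant_max_ct, seed = seed),
            class = "simulation_config")
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic Ct dataset with ground truth
#'
#' Draws a Ct matrix, sample sheet and truth table from a
#' [simulation_config()]. Per sample, a feature's Ct is
#' `baseline - effect + mean(pool_size animal deviations) + technical
#' noise`; wells above the dropout Ct become missing. Four internal
#' controls are appended: `ath-miR159a` (negative control, never
#' amplifies) and `RNU44`, `RNU48`, `U6-snRNA` (endogenous, low stable
#' Ct). A fixed seed gives bit-identical output; the caller's RNG state
#' is untouched.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List with `ct` (a [ct_matrix()]), `sheet` (sample sheet) and
#'   `truth`: list with `baseline` (named Ct vector), `effects` (data
#'   frame `feature_id`, `group`, `log2fc`) and `planted_features`.
#' @export
generate_ct_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(seed, {
    fid <- sprintf("sim-miR-%04d", seq_len(config$n_features))
    baseline <- pmax(stats::rnorm(config$n_features, config$baseline_mean,
                                  config$baseline_sd), 8)
    names(baseline) <- fid

    effects <- data.frame(feature_id = character(), group = character(),
                          log2fc = numeric(), stringsAsFactors = FALSE)
    if (config$n_planted > 0) {
      l2fc <- config$planted_log2fc[seq_len(config$n_planted)]
      cap <- config$plant_max_ct - max(0, max(-l2fc))
      eligible <- fid[baseline <= cap]
      if (length(eligible) < config$n_planted)
        stop("too few features below the planting Ct cap; ",
             "lower 'baseline_mean' or raise 'plant_max_ct'")
      planted <- sample(eligible, config$n_planted)
      effects <- data.frame(feature_id = planted,
                            group = config$planted_group,
                            log2fc = l2fc, stringsAsFactors = FALSE)
    }

    groups <- config$groups
    sample_id <- character(); genotype <- character()
    treatment <- character(); pool_members <- list()
    cols <- list()
    animal_counter <- 0L
    for (gi in seq_len(nrow(groups))) {
      g <- groups$label[gi]
      eff <- stats::setNames(rep(0, config$n_features), fid)
      pg <- effects$feature_id[effects$group == g]
      eff[pg] <- effects$log2fc[effects$group == g]
      latent <- baseline - eff
      for (si in seq_len(groups$n_samples[gi])) {
        animals <- matrix(stats::rnorm(config$n_features *
                                         config$pool_size,
                                       0, config$bio_sd),
                          nrow = config$n_features)
        ct <- latent + rowMeans(animals) +
          stats::rnorm(config$n_features, 0, config$noise_sd)
        ct[ct > config$dropout_ct] <- NA_real_
        sid <- sprintf("%s_%d", g, si)
        sample_id <- c(sample_id, sid)
        genotype <- c(genotype, groups$genotype[gi])
        treatment <- c(treatment, groups$treatment[gi])
        pool_members <- c(pool_members, list(
          sprintf("%s_animal%02d", g,
                  animal_counter + seq_len(config$pool_size))))
        animal_counter <- animal_counter + config$pool_size
        cols[[sid]] <- ct
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- fid

    n_samp <- length(sample_id)
    ctrl_ids <- c("ath-miR159a", "RNU44", "RNU48", "U6-snRNA")
    ctrl <- rbind(
      rep(NA_real_, n_samp),
      matrix(stats::rnorm(3 * n_samp, rep(c(17.5, 18, 18.5), n_samp),
                          config$noise_sd),
             nrow = 3))
    rownames(ctrl) <- ctrl_ids
    values <- rbind(values, ctrl)

    list(ct = ct_matrix(values,
                        negative_controls = "ath-miR159a",
                        endogenous_controls = ctrl_ids[-1]),
         sheet = sample_sheet(sample_id, genotype, treatment,
                              pool_members = pool_members),
         truth = list(baseline = baseline, effects = effects,
                      planted_features = effects$feature_id))
  })
}

#' True log2 fold changes of a simulated comparison
#'
#' @param truth Truth table from [generate_ct_dataset()].
#' @param test_group,reference_group Group labels.
#' @return Named numeric vector over biological features: effect in the
#'   test group minus effect in the reference group.
#' @export
true_log2fc <- function(truth, test_group, reference_group) {
  fid <- names(truth$baseline)
  eff <- function(g) {
    e <- stats::setNames(rep(0, length(fid)), fid)
    rows <- truth$effects$group == g
    e[truth$effects$feature_id[rows]] <- truth$effects$log2fc[rows]
    e
  }
  eff(test_group) - eff(reference_group)
}

#' Generate synthetic per-source miRNA-target tables
#'
#' Random miRNA-to-gene edges per source at the given density, with
#' source-appropriate score distributions: fixed-range sources draw raw
#' scores uniformly on their declared range (miRDB-style, 50-100),
#' minmax sources draw on a negative scale (TargetScan-style context
#' scores), validated sources carry no score. Planted "hub" genes
#' receive exactly `support` edges from the supplied regulated miRNA
#' set, as validated evidence so they always survive score filtering;
#' hub genes receive no other edges, making their true support counts
#' exact.
#'
#' @param mirnas Character vector of miRNA ids in the universe.
#' @param n_genes Number of background genes (ids `GENE00001`...).
#' @param density Probability of an edge per (miRNA, gene, source).
#' @param sources List of [source_config()]s (>= 1 validated when hubs
#'   are planted).
#' @param planted_hubs Optional data frame `gene`, `support`.
#' @param regulated Regulated miRNA ids used to support hubs.
#' @param seed Integer seed.
#' @return List with `tables` (named list of raw target-record data
#'   frames), `configs` and `truth` (data frame `gene`, `support`, plus
#'   list-column `mirnas`).
#' @export
generate_target_db <- function(mirnas, n_genes, density = 0.02,
                               sources = list(
                                 validated_config("miRTarBase"),
                                 targetscan_config(), mirdb_config()),
                               planted_hubs = NULL, regulated = character(),
                               seed = 1) {
  stopifnot(density > 0, density <= 1, n_genes >= 1)
  with_seed(seed, {
    genes <- sprintf("GENE%05d", seq_len(n_genes))
    tables <- stats::setNames(vector("list", length(sources)),
                              vapply(sources, `[[`, character(1), "name"))
    for (src in sources) {
      hit <- which(stats::runif(length(mirnas) * n_genes) < density)
      mi <- mirnas[(hit - 1) %% length(mirnas) + 1]
      ge <- genes[(hit - 1) %/% length(mirnas) + 1]
      raw <- if (src$evidence == "validated") NA_real_
        else if (src$rescale == "fixed_range")
          stats::runif(length(hit), src$range_raw[1], src$range_raw[2])
        else
          stats::runif(length(hit), -1.2, -0.01)
      tables[[src$name]] <- target_records(mi, ge, src$name,
                                           src$evidence, raw_score = raw)
    }
    truth <- data.frame(gene = character(), support = integer(),
                        stringsAsFactors = FALSE)
    truth$mirnas <- list()
    if (!is.null(planted_hubs) && nrow(planted_hubs)) {
      val <- which(vapply(sources, `[[`, character(1),
                          "evidence") == "validated")
      if (!length(val))
        stop("planting hubs requires at least one validated source")
      vname <- sources[[val[1]]]$name
      hub_rows <- list()
      hub_mirnas <- list()
      for (i in seq_len(nrow(planted_hubs))) {
        k <- planted_hubs$support[i]
        if (k > length(regulated))
          stop("hub '", planted_hubs$gene[i], "' demands ", k,
               " supporting miRNAs but only ", length(regulated),
               " regulated miRNAs exist")
        sup <- sample(regulated, k)
        hub_mirnas[[i]] <- sort(sup)
        hub_rows[[i]] <- target_records(sup, planted_hubs$gene[i],
                                        vname, "validated")
      }
      tables[[vname]] <- rbind(tables[[vname]], do.call(rbind, hub_rows))
      truth <- data.frame(gene = planted_hubs$gene,
                          support = planted_hubs$support,
                          stringsAsFactors = FALSE)
      truth$mirnas <- hub_mirnas
    }
    list(tables = tables, configs = sources, truth = truth)
  })
}

#' Generate a synthetic gene-set collection with a planted enriched term
#'
#' Random terms over a gene universe plus a query list over-sampled from
#' one designated term: a fraction `planted_fraction` of the query is
#' drawn from the planted term, the rest uniformly from the remaining
#' universe. With `planted_fraction` at the term's base rate the query
#' is an unenriched random draw.
#'
#' @param n_terms Number of terms.
#' @param term_size_range Integer range of term sizes.
#' @param universe Gene universe: a character vector or an integer size
#'   (ids `GENE00001`...).
#' @param planted_fraction Fraction of the query drawn from the planted
#'   term, in (0, 1].
#' @param query_size Query list size.
#' @param seed Integer seed.
#' @return List with `collection` (a [gene_set_collection()]) and
#'   `truth`: list with `planted_term` (`"TERM001"`) and `query`.
#' @export
generate_gene_sets <- function(n_terms = 50, term_size_range = c(20, 60),
                               universe = 1000, planted_fraction = 0.8,
                               query_size = 40, seed = 1) {
  stopifnot(n_terms >= 1, planted_fraction > 0, planted_fraction <= 1)
  if (is.numeric(universe) && length(universe) == 1)
    universe <- sprintf("GENE%05d", seq_len(universe))
  if (max(term_size_range) > length(universe))
    stop("term sizes exceed the universe")
  with_seed(seed, {
    sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                    n_terms, replace = TRUE)
    ids <- sprintf("TERM%03d", seq_len(n_terms))
    genes <- lapply(sizes, function(k) sample(universe, k))
    collection <- gene_set_collection(ids, genes,
                                      term_name = paste("synthetic term",
                                                        seq_len(n_terms)))
    planted_genes <- genes[[1]]
    k_in <- round(planted_fraction * query_size)
    k_in <- min(k_in, length(planted_genes))
    query <- c(sample(planted_genes, k_in),
               sample(setdiff(universe, planted_genes),
                      query_size - k_in))
    list(collection = collection,
         truth = list(planted_term = ids[1], query = query))
  })
}
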