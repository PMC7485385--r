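test_that("miRDB-style fixed-range rescaling maps 50 -> 0.5 and 100 -> 1", {
  rec <- target_records(c("m1", "m2", "m3"), c("g1", "g2", "g3"),
                        "miRDB", "predicted",
                        raw_score = c(50, 100, 75))
  out <- rescale_scores(rec, mirdb_config())
  expect_equal(out$rescaled_score, c(0.5, 1.0, 0.75))

  bad <- target_records("m1", "g1", "miRDB", "predicted", raw_score = 42)
  expect_error(rescale_scores(bad, mirdb_config()), "m1.*g1")
})

test_that("minmax rescaling maps the strongest observed score to 1", {
  rec <- target_records(paste0("m", 1:3), paste0("g", 1:3),
                        "TargetScan", "predicted",
                        raw_score = c(-0.9, -0.1, -0.5))
  out <- rescale_scores(rec, targetscan_config())
  # lower (more negative) is stronger
  expect_equal(out$rescaled_score, c(1.0, 0.0, 0.5))
  expect_true(all(out$rescaled_score >= 0 & out$rescaled_score <= 1))

  tie <- rescale_scores(
    target_records("m1", "g1", "TargetScan", "predicted",
                   raw_score = -0.3),
    targetscan_config())
  expect_equal(tie$rescaled_score, 1)

  val <- rescale_scores(
    target_records("m1", "g1", "miRTarBase", "validated"),
    validated_config())
  expect_equal(val$rescaled_score, 1)
})

test_that("score filtering is strict for predictions and spares validated links", {
  rec <- rbind(
    target_records("m1", "g1", "TS", "predicted",
                   rescaled_score = 0.49),
    target_records("m2", "g2", "TS", "predicted",
                   rescaled_score = 0.50),
    target_records("m3", "g3", "mtb", "validated",
                   rescaled_score = 1))
  out <- filter_by_score(rec)
  expect_setequal(out$mirna, c("m2", "m3"))
  rec$rescaled_score[1] <- NA
  expect_error(filter_by_score(rec), "rescaled")
})

test_that("merging keeps one record per pair with validated evidence winning", {
  a <- target_records("m1", "g1", "miRTarBase", "validated",
                      rescaled_score = 1)
  b <- target_records(c("m1", "m2"), c("g1", "g9"), "TargetScan",
                      "predicted", rescaled_score = c(0.8, 0.7))
  m <- merge_sources(a, b)
  expect_equal(nrow(m), 2L)
  r <- m[m$mirna == "m1" & m$gene == "g1", ]
  expect_equal(r$evidence, "validated")
  expect_equal(r$rescaled_score, 1)
  expect_equal(r$source, "TargetScan;miRTarBase")
  expect_equal(m$evidence[m$mirna == "m2"], "predicted")

  # idempotence and order independence
  expect_identical(merge_sources(m), m)
  expect_identical(merge_sources(b, a), m)
})

test_that("merged tables equal a brute-force pair-keyed union on random input", {
  set.seed(31)
  for (i in 1:10) {
    tabs <- lapply(1:3, function(s) {
      n <- sample(5:25, 1)
      target_records(sample(paste0("m", 1:6), n, TRUE),
                     sample(paste0("g", 1:8), n, TRUE),
                     paste0("src", s),
                     if (s == 1) "validated" else "predicted",
                     rescaled_score = if (s == 1) 1 else round(runif(n), 3))
    })
    got <- merge_sources(tabs)
    all <- do.call(rbind, tabs)
    keys <- unique(paste(all$mirna, all$gene))
    expect_equal(nrow(got), length(keys))
    for (j in seq_len(nrow(got))) {
      rows <- all[all$mirna == got$mirna[j] & all$gene == got$gene[j], ]
      if (any(rows$evidence == "validated")) {
        expect_equal(got$evidence[j], "validated")
        expect_equal(got$rescaled_score[j], 1)
      } else {
        expect_equal(got$rescaled_score[j], max(rows$rescaled_score))
      }
    }
  }
})

test_that("gene support counts regulated miRNAs and applies the >=2 rule", {
  rec <- rbind(
    target_records(c("m1", "m2", "m3"), "gA", "s1", "validated", rescaled_score = 1),
    target_records("m1", "gB", "s1", "validated", rescaled_score = 1),
    target_records(c("m1", "m9"), "gC", "s2", "predicted", rescaled_score = 0.9))
  sup <- aggregate_gene_support(rec, regulated = c("m1", "m2", "m3"))
  expect_equal(sup$gene, "gA")                 # gB and gC have 1 regulated hit
  expect_equal(sup$support_count, 3L)
  expect_equal(sup$supporting_mirnas[[1]], c("m1", "m2", "m3"))

  # support via different sources still counts distinct miRNAs once
  two <- merge_sources(
    target_records("m1", "gX", "s1", "validated", rescaled_score = 1),
    target_records(c("m1", "m2"), "gX", "s2", "predicted",
                   rescaled_score = 0.8))
  expect_equal(aggregate_gene_support(two, c("m1", "m2"))$support_count, 2L)

  # monotone shrinkage in min_support
  for (k in 1:4)
    expect_lte(nrow(aggregate_gene_support(rec, c("m1", "m2", "m3"),
                                           min_support = k + 1)),
               nrow(aggregate_gene_support(rec, c("m1", "m2", "m3"),
                                           min_support = k)))
  expect_error(aggregate_gene_support(rec, character()), "empty")
})

test_that("planted hub genes are recovered end-to-end from a synthetic database", {
  regulated <- sprintf("sim-miR-%04d", 1:10)
  hubs <- data.frame(gene = c("HUBA", "HUBB"), support = c(3L, 5L),
                     stringsAsFactors = FALSE)
  db <- generate_target_db(sprintf("sim-miR-%04d", 1:40), n_genes = 120,
                           density = 0.03, planted_hubs = hubs,
                           regulated = regulated, seed = 6)
  processed <- mapply(function(tab, cfg)
    filter_by_score(rescale_scores(tab, cfg)),
    db$tables, db$configs, SIMPLIFY = FALSE)
  merged <- merge_sources(processed)
  sup <- aggregate_gene_support(merged, regulated)
  expect_equal(sup$support_count[match(hubs$gene, sup$gene)],
               hubs$support)
  for (i in 1:2)
    expect_equal(sup$supporting_mirnas[[match(hubs$gene[i], sup$gene)]],
                 db$truth$mirnas[[i]])
  # no gene exceeds its brute-force true support from the raw tables
  raw <- do.call(rbind, db$tables)
  raw_true <- tapply(raw$mirna[raw$mirna %in% regulated],
                     raw$gene[raw$mirna %in% regulated],
                     function(m) length(unique(m)))
  for (j in seq_len(nrow(sup)))
    expect_lte(sup$support_count[j], raw_true[[sup$gene[j]]])
  expect_error(
    generate_target_db(sprintf("m%d", 1:5), 10, planted_hubs =
                         data.frame(gene = "H", support = 9),
                       regulated = c("m1", "m2"), seed = 1),
    "demands")
})
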