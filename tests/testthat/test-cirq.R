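make_records <- function(...) {
  # rows as lists: peptide, accession, flags, score, experiment, ratios
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(peptide = r[[1]], accession = r[[2]], flags = r[[3]],
               score = r[[4]], experiment = r[[5]],
               ratio_a = r[[6]], ratio_b = r[[7]],
               stringsAsFactors = FALSE)))
}

test_that("the filter cascade applies all three exclusion rules", {
  recs <- make_records(
    list("AAA", "P1", "", 30, "exp1", 1.0, 1.1),   # score not strictly > 30
    list("BBB", "P1", "REVERSED", 80, "exp1", 1.0, 1.1), # decoy
    list("CCC", "P1", "Fragment", 80, "exp1", 1.0, 1.1), # fragment
    list("DDD", "P1", "", 50, "exp1", NA, 1.1),     # null ratio
    list("EEE", "P1", "", 50, "exp1", 0, 1.1),      # 0.0 ratio
    list("FFF", "P1", "", 31, "exp1", 0.9, 1.1)     # retained
  )
  out <- filter_peptides(recs)
  expect_equal(out$peptide, "FFF")
  rep <- attr(out, "filter_report")
  expect_equal(unname(rep["input"]), 6L)
  expect_equal(unname(rep["low_score"]), 1L)
  expect_equal(unname(rep["null_ratio"]), 2L)
  expect_equal(unname(rep["flagged"]), 2L)
  expect_equal(unname(rep["retained"]), 1L)
})

test_that("filtering is idempotent and order preserving", {
  recs <- random_jpf_records(400, seed = 31)
  once <- filter_peptides(recs)
  twice <- filter_peptides(once)
  attr(once, "filter_report") <- attr(twice, "filter_report") <- NULL
  expect_identical(once, twice)
  # retained records appear in their original relative order
  key <- function(df) do.call(paste, df)
  keep <- key(recs) %in% key(once)
  expect_identical(key(once), key(recs)[keep])
})

test_that("filtering matches the brute-force rule check", {
  recs <- random_jpf_records(500, seed = 32)
  got <- filter_peptides(recs)
  attr(got, "filter_report") <- NULL
  expect_identical(got, naive_filter(recs))
})

test_that("frequency index counts distinct experiments per pair", {
  recs <- make_records(
    list("AAA", "P1", "", 50, "exp1", 1.0, 1.1),
    list("AAA", "P1", "", 50, "exp3", 1.0, 1.1),
    list("AAA", "P1", "", 50, "exp5", 1.0, 1.1),
    list("BBB", "P2", "", 50, "exp2", 0.8, 1.1),
    list("BBB", "P2", "", 50, "exp2", 0.9, 1.2)
  )
  cat <- build_catalogue(filter_peptides(recs), n_experiments = 5)
  e <- cat$entries
  expect_equal(e$frequency_index[e$peptide == "AAA"], 3L)
  expect_equal(e$frequency_index[e$peptide == "BBB"], 1L)
  # duplicates count once for the index but keep both observations
  obs_b <- cat$observations[cat$observations$peptide == "BBB" &
                              cat$observations$condition == "a", ]
  expect_equal(sort(obs_b$ratio), c(0.8, 0.9))
})

test_that("frequency index agrees with a brute-force set count", {
  recs <- filter_peptides(random_jpf_records(300, seed = 33))
  cat <- build_catalogue(recs, n_experiments = 5)
  expect_equal(cat$entries[, c("peptide", "accession", "frequency_index")],
               naive_frequency_index(recs),
               ignore_attr = TRUE)
})

test_that("top-frequency selection keeps indices at or above n_required", {
  recs <- make_records(
    list("A1", "P1", "", 50, "exp1", 1, 1), list("A1", "P1", "", 50, "exp2", 1, 1),
    list("A1", "P1", "", 50, "exp3", 1, 1), list("A1", "P1", "", 50, "exp4", 1, 1),
    list("A1", "P1", "", 50, "exp5", 1, 1),
    list("B1", "P2", "", 50, "exp1", 1, 1), list("B1", "P2", "", 50, "exp2", 1, 1),
    list("B1", "P2", "", 50, "exp3", 1, 1), list("B1", "P2", "", 50, "exp4", 1, 1),
    list("C1", "P3", "", 50, "exp1", 1, 1), list("C1", "P3", "", 50, "exp2", 1, 1),
    list("C1", "P3", "", 50, "exp3", 1, 1), list("C1", "P3", "", 50, "exp4", 1, 1),
    list("C1", "P3", "", 50, "exp5", 1, 1),
    list("D1", "P4", "", 50, "exp1", 1, 1), list("D1", "P4", "", 50, "exp2", 1, 1)
  )
  cat <- build_catalogue(recs, n_experiments = 5)
  expect_equal(sort(cat$entries$frequency_index), c(2L, 4L, 5L, 5L))
  top <- select_top_frequency(cat, 5)
  expect_equal(nrow(top$entries), 2L)
  all_of_them <- select_top_frequency(cat, 1)
  expect_equal(nrow(all_of_them$entries), 4L)
  expect_warning(sel <- select_top_frequency(
    build_catalogue(recs[recs$peptide == "D1", ], n_experiments = 5), 5),
    "frequency index")
  expect_equal(nrow(sel$entries), 0L)
})

test_that("protein medians use the even-count mean-of-central convention", {
  recs <- make_records(
    list("A1", "P1", "", 50, "exp1", 0.8, 1.0),
    list("A2", "P1", "", 50, "exp1", 1.0, 2.0),
    list("A3", "P1", "", 50, "exp1", 1.2, NA)
  )
  recs <- recs[, names(recs) != "ratio_b"]
  recs$ratio_a <- c(0.8, 1.0, 1.2)
  cat <- build_catalogue(recs, n_experiments = 1)
  q <- aggregate_protein_ratios(select_top_frequency(cat, 1))
  expect_equal(q$overall$ratio[q$overall$condition == "a"], 1.0)
  recs2 <- recs[1:2, ]
  recs2$ratio_a <- c(1.0, 2.0)
  q2 <- aggregate_protein_ratios(build_catalogue(recs2, n_experiments = 1))
  expect_equal(q2$overall$ratio, 1.5)
})

test_that("overall and series medians match a sort-and-pick oracle", {
  recs <- filter_peptides(random_jpf_records(400, seed = 34))
  cat <- build_catalogue(recs, n_experiments = 5)
  q <- aggregate_protein_ratios(cat)
  obs <- cat$observations
  for (i in sample(nrow(q$overall), 25)) {
    acc <- q$overall$accession[i]; cond <- q$overall$condition[i]
    vals <- obs$ratio[obs$accession == acc & obs$condition == cond]
    vals <- vals[!is.na(vals)]
    expect_equal(q$overall$ratio[i], naive_median(vals))
  }
  for (i in sample(nrow(q$series), 25)) {
    acc <- q$series$accession[i]; cond <- q$series$condition[i]
    ex <- q$series$experiment[i]
    vals <- obs$ratio[obs$accession == acc & obs$condition == cond &
                        obs$experiment == ex]
    vals <- vals[!is.na(vals)]
    expect_equal(q$series$ratio[i], naive_median(vals))
  }
})

test_that("aggregation is invariant to record order", {
  recs <- filter_peptides(random_jpf_records(300, seed = 35))
  set.seed(1)
  perm <- recs[sample(nrow(recs)), ]
  q1 <- aggregate_protein_ratios(build_catalogue(recs, n_experiments = 5))
  q2 <- aggregate_protein_ratios(build_catalogue(perm, n_experiments = 5))
  expect_equal(q1$overall, q2$overall)
  expect_equal(q1$series, q2$series)
})

test_that("the median resists corruption of a minority of peptides", {
  set.seed(9)
  for (k in c(3, 5, 8, 11)) {
    vals <- exp(rnorm(k, 0, 0.1))
    n_bad <- (k - 1) %/% 2
    corrupted <- vals
    if (n_bad > 0) corrupted[seq_len(n_bad)] <- corrupted[seq_len(n_bad)] * 100
    med <- naive_median(corrupted)
    expect_gte(med, min(vals))
    expect_lte(med, max(vals))
    # package median agrees
    recs <- data.frame(peptide = sprintf("p%d", seq_len(k)),
                       accession = "P1", flags = "", score = 50,
                       experiment = "exp1", ratio_a = corrupted,
                       stringsAsFactors = FALSE)
    q <- aggregate_protein_ratios(build_catalogue(recs, n_experiments = 1))
    expect_equal(q$overall$ratio, med)
  }
})

test_that("zero-noise synthetic data recovers every fold exactly", {
  cfg <- sim_config(n_proteins = 50, n_experiments = 5, noise_sd_log = 0,
                    missing_rate = 0, decoy_rate = 0, low_score_rate = 0,
                    seed = 12)
  sim <- simulate_study(cfg)
  jpf <- lapply(sim$psms, quantify_psms,
                reference_condition = cfg$reference_condition)
  filtered <- lapply(jpf, filter_peptides)
  cat <- build_catalogue(filtered, n_experiments = 5)
  # no dropout: every peptide reaches the top frequency index
  expect_true(all(cat$entries$frequency_index == 5L))
  q <- aggregate_protein_ratios(select_top_frequency(cat))
  fold <- sim$truth$proteins$fold[match(q$overall$accession,
                                        sim$truth$proteins$protein_id)]
  expect_equal(q$overall$ratio, fold, tolerance = 1e-12)
})
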