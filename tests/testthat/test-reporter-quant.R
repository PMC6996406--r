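test_that("reporter extraction sums peaks inside the mass window", {
  peaks <- cbind(c(114.11, 115.11), c(1000, 500))
  got <- extract_reporter_intensities(peaks, tolerance = 0.05)
  expect_equal(unname(got), c(1000, 500, 0, 0))
  expect_named(got, c("114", "115", "116", "117"))
  # empty spectrum -> all zeros
  expect_equal(unname(extract_reporter_intensities(NULL)), rep(0, 4))
  expect_equal(unname(extract_reporter_intensities(
    matrix(numeric(0), ncol = 2))), rep(0, 4))
})

test_that("extraction matches a naive per-peak loop on random spectra", {
  set.seed(8)
  peaks <- cbind(runif(200, 113.8, 117.5), runif(200, 0, 1e4))
  expect_equal(extract_reporter_intensities(peaks, 0.05),
               naive_window_sums(peaks, 0.05))
  # additive in the peak list: splitting one peak preserves the sum
  split_peaks <- rbind(peaks, c(peaks[1, 1], 0))
  split_peaks[1, 2] <- peaks[1, 2] / 2
  split_peaks[nrow(split_peaks), 2] <- peaks[1, 2] / 2
  expect_equal(extract_reporter_intensities(split_peaks, 0.05),
               extract_reporter_intensities(peaks, 0.05))
})

test_that("overlapping extraction windows are refused", {
  peaks <- cbind(115, 100)
  expect_error(extract_reporter_intensities(peaks, tolerance = 0.5),
               "overlap")
  expect_error(extract_reporter_intensities(peaks, tolerance = 0),
               "> 0")
})

test_that("isotope correction inverts the mixing system", {
  M <- isotope_correction_matrix()
  expect_true(all(colSums(M) <= 1 + 1e-12))
  expect_true(all(diag(M) > 0.8))
  # identity matrix leaves intensities unchanged
  x <- c(100, 200, 300, 400)
  expect_equal(as.numeric(correct_isotope_impurities(x, diag(4))), x)
  # round-trip: obs = M x recovers x
  obs <- as.numeric(M %*% x)
  rec <- correct_isotope_impurities(obs, M)
  expect_equal(as.numeric(rec), x, tolerance = 1e-9)
  # all-zero observations stay zero
  expect_equal(as.numeric(correct_isotope_impurities(rep(0, 4), M)), rep(0, 4))
  expect_error(correct_isotope_impurities(x, matrix(1, 4, 4)), "singular")
})

test_that("round-trip holds for random diagonally dominant matrices", {
  set.seed(21)
  for (rep in 1:20) {
    off <- matrix(runif(16, 0, 0.06), 4, 4)
    diag(off) <- 0
    M <- off + diag(1 - colSums(off))
    x <- runif(4, 0, 1e5)
    rec <- correct_isotope_impurities(as.numeric(M %*% x), M)
    expect_equal(as.numeric(rec), x, tolerance = 1e-9)
  }
})

test_that("negative corrected intensities are clipped and counted", {
  M <- isotope_correction_matrix()
  obs <- c(0, 1000, 0, 0) # impossible under M with non-negative signal
  rec <- correct_isotope_impurities(obs, M)
  expect_true(all(rec >= 0))
  expect_gt(attr(rec, "clipped"), 0)
})

test_that("shipped correction config reproduces the default matrix", {
  path <- system.file("extdata/itraq4_correction_factors.tsv",
                      package = "itraqr")
  expect_equal(read_isotope_correction(path), isotope_correction_matrix())
})

test_that("peptide ratios divide by the reference channel", {
  tag_map <- make_tag_rotation(1, c("ref", "b", "c", "d"))
  r <- compute_peptide_ratios(c("114" = 1000, "115" = 500,
                                "116" = 1000, "117" = 2000),
                              tag_map, "ref")
  expect_equal(r, c(ref = 1, b = 0.5, c = 1, d = 2))
  # zero reference -> all null
  r0 <- compute_peptide_ratios(c("114" = 0, "115" = 500,
                                 "116" = 1000, "117" = 2000),
                               tag_map, "ref")
  expect_true(all(is.na(r0)))
  # one zero channel -> only that condition null
  r1 <- compute_peptide_ratios(c("114" = 1000, "115" = 0,
                                 "116" = 1000, "117" = 2000),
                               tag_map, "ref")
  expect_true(is.na(r1["b"]))
  expect_equal(unname(r1[c("ref", "c", "d")]), c(1, 1, 2))
  expect_error(compute_peptide_ratios(r0[1:4], tag_map, "nope"),
               "reference")
})

test_that("ratios are invariant to a common intensity scale", {
  tag_map <- make_tag_rotation(3, c("w", "x", "y", "z"))
  set.seed(4)
  for (rep in 1:10) {
    v <- stats::setNames(runif(4, 1, 1e5), c("114", "115", "116", "117"))
    k <- runif(1, 1e-3, 1e3)
    expect_equal(compute_peptide_ratios(v, tag_map, "w"),
                 compute_peptide_ratios(k * v, tag_map, "w"))
  }
})

test_that("jpf tables round-trip with NA-serialized null ratios", {
  cfg <- quick_cfg(n_proteins = 25)
  psm <- simulate_experiment(simulate_ground_truth(cfg), cfg, 1)
  jpf <- quantify_psms(psm, reference_condition = cfg$reference_condition)
  expect_true(anyNA(as.matrix(jpf[grep("^ratio_", names(jpf))])))
  path <- withr::local_tempfile(fileext = ".jpf")
  write_jpf(jpf, path)
  back <- read_jpf(path)
  expect_equal(back$score, jpf$score, tolerance = 1e-9)
  for (col in grep("^ratio_", names(jpf), value = TRUE))
    expect_equal(back[[col]], jpf[[col]], tolerance = 1e-9)
})

test_that("the MGF extraction path agrees with the tabular path", {
  cfg <- quick_cfg(n_proteins = 20)
  psm <- simulate_experiment(simulate_ground_truth(cfg), cfg, 1)
  spectra <- psms_to_spectra(psm)
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(spectra, path)
  back <- read_mgf(path)
  expect_length(back, nrow(psm))
  rot <- attr(psm, "rotation")
  ids <- psm[, c("spectrum_id", "peptide", "accession", "flags",
                 "score", "experiment")]
  via_mgf <- quantify_spectra(back, ids, rot, cfg$reference_condition)
  via_tab <- quantify_psms(psm, reference_condition =
                             cfg$reference_condition)
  for (col in grep("^ratio_", names(via_tab), value = TRUE))
    expect_equal(via_mgf[[col]], via_tab[[col]], tolerance = 1e-6)
})

test_that("isotope correction in quantify_psms matches the vector op", {
  cfg <- quick_cfg(n_proteins = 10, missing_rate = 0)
  psm <- simulate_experiment(simulate_ground_truth(cfg), cfg, 1)
  M <- isotope_correction_matrix()
  jpf <- quantify_psms(psm, reference_condition = cfg$reference_condition,
                       correction = M)
  rot <- attr(psm, "rotation")
  i <- 7
  obs <- as.numeric(psm[i, paste0("I", c(114, 115, 116, 117))])
  corr <- correct_isotope_impurities(obs, M)
  want <- compute_peptide_ratios(corr, rot, cfg$reference_condition)
  for (cond in setdiff(unname(rot), cfg$reference_condition))
    expect_equal(jpf[[paste0("ratio_", cond)]][i], unname(want[cond]),
                 tolerance = 1e-9)
})
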