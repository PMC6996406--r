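# Brute-force reference implementations used as independent oracles.
# These are deliberately naive (loops, sort-and-pick, exhaustive sums)
# and share no code with the package internals they check.

naive_window_sums <- function(peaks, tolerance = 0.05) {
  masses <- c("114" = 114.1112, "115" = 115.1083,
              "116" = 116.1116, "117" = 117.1150)
  out <- setNames(numeric(4), names(masses))
  for (i in seq_len(NROW(peaks))) {
    for (ch in names(masses)) {
      if (abs(peaks[i, 1] - masses[ch]) <= tolerance)
        out[ch] <- out[ch] + peaks[i, 2]
    }
  }
  out
}

naive_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

naive_frequency_index <- function(records) {
  pairs <- unique(records[, c("peptide", "accession")])
  idx <- integer(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    seen <- character(0)
    for (j in seq_len(nrow(records))) {
      if (records$peptide[j] == pairs$peptide[i] &&
          records$accession[j] == pairs$accession[i])
        seen <- union(seen, records$experiment[j])
    }
    idx[i] <- length(seen)
  }
  pairs$frequency_index <- idx
  pairs[order(pairs$accession, pairs$peptide), ]
}

naive_binom_tail <- function(observed, n, p, direction) {
  ks <- if (direction == "+") observed:n else 0:observed
  sum(choose(n, ks) * p^ks * (1 - p)^(n - ks))
}

# naive agglomerative clustering on raw coordinates; returns the member
# sets merged at each step (as sorted index vectors) and merge heights
naive_agglomerate <- function(points, linkage = "average") {
  d <- matrix(0, nrow(points), nrow(points))
  for (i in seq_len(nrow(points))) for (j in seq_len(nrow(points)))
    d[i, j] <- sqrt(sum((points[i, ] - points[j, ])^2))
  clusters <- as.list(seq_len(nrow(points)))
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      pd <- d[clusters[[a]], clusters[[b]], drop = FALSE]
      dd <- switch(linkage,
                   average = mean(pd),
                   complete = max(pd),
                   single = min(pd))
      if (dd < best_d) { best_d <- dd; best <- c(a, b) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    heights <- c(heights, best_d)
    clusters <- c(clusters[-best], list(merged))
  }
  list(merges = merges, heights = heights)
}

# member sets merged at each step of an hclust result
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  members <- function(k) {
    if (k < 0) return(-k)
    sets[[k]]
  }
  for (i in seq_len(nrow(hc$merge))) {
    sets[[i]] <- sort(c(members(hc$merge[i, 1]), members(hc$merge[i, 2])))
  }
  sets
}

# random peptide quantitation records exercising every filter rule
random_jpf_records <- function(n, seed, n_experiments = 5) {
  set.seed(seed)
  ratios <- function() {
    r <- exp(rnorm(n, 0, 0.4))
    r[runif(n) < 0.10] <- NA      # uncalculated
    r[runif(n) < 0.05] <- 0       # 0.0 ratios
    r
  }
  data.frame(
    peptide = sprintf("PEP%03d", sample(60, n, replace = TRUE)),
    accession = sprintf("ACC%02d", sample(25, n, replace = TRUE)),
    flags = sample(c("", "", "", "", "REVERSED", "Fragment"), n,
                   replace = TRUE),
    score = round(runif(n, 10, 80), 2),
    experiment = paste0("exp", sample(n_experiments, n, replace = TRUE)),
    ratio_a = ratios(), ratio_b = ratios(), ratio_c = ratios(),
    stringsAsFactors = FALSE
  )
}

naive_filter <- function(records, cutoff = 30) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- c(records$ratio_a[i], records$ratio_b[i], records$ratio_c[i])
    keep[i] <- records$score[i] > cutoff &&
      !any(is.na(r)) && all(r > 0) &&
      !records$flags[i] %in% c("REVERSED", "Fragment")
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# shared small simulation config for fast tests
quick_cfg <- function(...) {
  args <- list(n_proteins = 60, n_experiments = 3, noise_sd_log = 0.02,
               missing_rate = 0.02, decoy_rate = 0.05,
               low_score_rate = 0.1, seed = 11)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}
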