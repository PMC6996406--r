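#' CiR-C filtering cascade for peptide quantitation records
#'
#' Applies the three exclusion rules in order: (a) identification
#' confidence — the score must be strictly greater than `score_cutoff`
#' (default 30, i.e. random-match probability below 5%); (b)
#' quantification confidence — every condition ratio must be present and
#' positive (records with 0.0 or uncalculated "null" ratios are
#' discarded); (c) annotation — records flagged `Fragment` or `REVERSED`
#' (decoys) are discarded. Record order is preserved and a per-rule
#' removal report is attached as attribute `"filter_report"`.
#'
#' @param records peptide quantitation data frame (see [quantify_psms()]);
#'   ratio columns are those named `ratio_*`.
#' @param score_cutoff retention cutoff, strict inequality (default 30).
#' @return The retained records, with attribute `"filter_report"` — a
#'   named integer vector `input, low_score, null_ratio, flagged,
#'   retained`.
#' @export
filter_peptides <- function(records, score_cutoff = 30) {
  stopifnot(is.data.frame(records))
  rcols <- grep("^ratio_", names(records), value = TRUE)
  if (length(rcols) == 0L) stop("no ratio_* columns in records")
  n0 <- nrow(records)
  keep_a <- records$score > score_cutoff
  r1 <- records[keep_a, , drop = FALSE]
  rmat <- as.matrix(r1[, rcols, drop = FALSE])
  keep_b <- rowSums(is.na(rmat) | rmat <= 0) == 0L
  r2 <- r1[keep_b, , drop = FALSE]
  keep_c <- !grepl("Fragment|REVERSED", r2$flags)
  out <- r2[keep_c, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- c(
    input = n0,
    low_score = n0 - nrow(r1),
    null_ratio = nrow(r1) - nrow(r2),
    flagged = nrow(r2) - nrow(out),
    retained = nrow(out)
  )
  out
}

#' Cross-replicate peptide catalogue with frequency index
#'
#' Builds the exhaustive catalogue of retained (peptide sequence,
#' accession) pairs over all replicate experiments. The frequency index
#' of a pair is the number of distinct experiments in which at least one
#' retained record exists; duplicate records within one experiment
#' contribute their ratio observations individually but count once
#' toward the index.
#'
#' @param filtered a single filtered record data frame carrying an
#'   `experiment` column, or a list of per-experiment data frames.
#' @param n_experiments total number of replicate experiments (default:
#'   number of distinct experiment labels seen).
#' @return An object of class `"peptide_catalogue"`: list with
#'   `entries` (peptide, accession, frequency_index), `observations`
#'   (peptide, accession, experiment, condition, ratio — long format),
#'   and `n_experiments`.
#' @export
build_catalogue <- function(filtered, n_experiments = NULL) {
  if (is.data.frame(filtered)) filtered <- list(filtered)
  combined <- do.call(rbind, lapply(filtered, function(df) {
    df <- as.data.frame(df)
    attr(df, "filter_report") <- NULL
    df
  }))
  stopifnot("experiment" %in% names(combined))
  rcols <- grep("^ratio_", names(combined), value = TRUE)
  if (is.null(n_experiments))
    n_experiments <- length(unique(combined$experiment))
  key <- paste(combined$peptide, combined$accession, sep = "\r")
  freq <- tapply(combined$experiment, key,
                 function(e) length(unique(e)))
  first <- !duplicated(key)
  entries <- data.frame(
    peptide = combined$peptide[first],
    accession = combined$accession[first],
    stringsAsFactors = FALSE
  )
  entries$frequency_index <- as.integer(freq[key[first]])
  entries <- entries[order(entries$accession, entries$peptide), ]
  rownames(entries) <- NULL
  obs <- do.call(rbind, lapply(rcols, function(col) {
    data.frame(peptide = combined$peptide,
               accession = combined$accession,
               experiment = combined$experiment,
               condition = sub("^ratio_", "", col),
               ratio = combined[[col]],
               stringsAsFactors = FALSE)
  }))
  rownames(obs) <- NULL
  structure(list(entries = entries, observations = obs,
                 n_experiments = as.integer(n_experiments),
                 n_required = NA_integer_),
            class = "peptide_catalogue")
}

#' @export
print.peptide_catalogue <- function(x, ...) {
  cat("Peptide catalogue:", nrow(x$entries), "(peptide, accession) pairs,",
      length(unique(x$entries$accession)), "accessions,",
      x$n_experiments, "experiments\n")
  print(table(frequency_index = x$entries$frequency_index))
  invisible(x)
}

#' Restrict a catalogue to peptides at a required frequency index
#'
#' Keeps only (peptide, accession) pairs identified in at least
#' `n_required` experiments — by default all of them, reproducing the
#' "highest frequency index" catalogue (at the maximum, at-least and
#' exactly coincide).
#'
#' @param catalogue a `"peptide_catalogue"`.
#' @param n_required required frequency index (default: `n_experiments`).
#' @return The restricted catalogue; warns (does not error) when empty.
#' @export
select_top_frequency <- function(catalogue,
                                 n_required = catalogue$n_experiments) {
  stopifnot(inherits(catalogue, "peptide_catalogue"),
            n_required <= catalogue$n_experiments)
  keep <- catalogue$entries$frequency_index >= n_required
  entries <- catalogue$entries[keep, , drop = FALSE]
  if (nrow(entries) == 0L)
    warning("no peptides reach frequency index ", n_required)
  key <- paste(catalogue$observations$peptide,
               catalogue$observations$accession, sep = "\r")
  okey <- paste(entries$peptide, entries$accession, sep = "\r")
  obs <- catalogue$observations[key %in% okey, , drop = FALSE]
  rownames(entries) <- rownames(obs) <- NULL
  structure(list(entries = entries, observations = obs,
                 n_experiments = catalogue$n_experiments,
                 n_required = as.integer(n_required)),
            class = "peptide_catalogue")
}

#' Median protein ratios from a peptide catalogue
#'
#' For each accession and condition, the overall ratio is the median over
#' all (experiment, peptide) ratio observations pooled across replicates;
#' the series-specific ratio is the median within each experiment. An
#' even observation count yields the arithmetic mean of the two central
#' values (the usual sample median).
#'
#' @param catalogue a `"peptide_catalogue"`, typically after
#'   [select_top_frequency()].
#' @return An object of class `"protein_quant"`: list with `overall`
#'   (accession, condition, ratio, n_obs, n_peptides, frequency_index)
#'   and `series` (accession, experiment, condition, ratio), plus
#'   `n_required`.
#' @export
aggregate_protein_ratios <- function(catalogue) {
  stopifnot(inherits(catalogue, "peptide_catalogue"))
  obs <- catalogue$observations
  obs <- obs[!is.na(obs$ratio), , drop = FALSE]
  if (nrow(obs) == 0L) stop("catalogue has no ratio observations")
  overall <- stats::aggregate(ratio ~ accession + condition, data = obs,
                              FUN = stats::median)
  nobs <- stats::aggregate(ratio ~ accession + condition, data = obs,
                           FUN = length)
  overall$n_obs <- nobs$ratio[match(paste(overall$accession,
                                          overall$condition),
                                    paste(nobs$accession, nobs$condition))]
  ent <- catalogue$entries
  npep <- tapply(ent$peptide, ent$accession,
                 function(p) length(unique(p)))
  fidx <- tapply(ent$frequency_index, ent$accession, min)
  overall$n_peptides <- as.integer(npep[overall$accession])
  overall$frequency_index <- as.integer(fidx[overall$accession])
  overall <- overall[order(overall$accession, overall$condition), ]
  series <- stats::aggregate(ratio ~ accession + experiment + condition,
                             data = obs, FUN = stats::median)
  series <- series[order(series$accession, series$experiment,
                         series$condition), ]
  rownames(overall) <- rownames(series) <- NULL
  structure(list(overall = overall, series = series,
                 n_required = catalogue$n_required),
            class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat("Protein quantitation:", length(unique(x$overall$accession)),
      "accessions x", length(unique(x$overall$condition)),
      "conditions (frequency index",
      if (is.na(x$n_required)) "unrestricted" else x$n_required, ")\n")
  print(utils::head(x$overall))
  invisible(x)
}

#' Write the protein catalogue as TSV
#'
#' One row per accession: overall median per condition, per-experiment
#' medians, peptide count and frequency index.
#'
#' @param quant a `"protein_quant"` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_protein_catalogue <- function(quant, path) {
  ov <- quant$overall
  conds <- sort(unique(ov$condition))
  wide <- data.frame(accession = sort(unique(ov$accession)),
                     stringsAsFactors = FALSE)
  for (cond in conds) {
    sub <- ov[ov$condition == cond, ]
    wide[[paste0("overall_", cond)]] <-
      sub$ratio[match(wide$accession, sub$accession)]
  }
  se <- quant$series
  for (exp in sort(unique(se$experiment))) for (cond in conds) {
    sub <- se[se$experiment == exp & se$condition == cond, ]
    wide[[paste0(exp, "_", cond)]] <-
      sub$ratio[match(wide$accession, sub$accession)]
  }
  wide$n_peptides <- ov$n_peptides[match(wide$accession, ov$accession)]
  wide$frequency_index <-
    ov$frequency_index[match(wide$accession, ov$accession)]
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
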