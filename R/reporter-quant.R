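#' Nominal iTRAQ 4-plex reporter masses
#'
#' @return Named numeric vector of the four reporter ion m/z values (Da),
#'   names `"114".."117"`.
#' @export
itraq_channels <- function() {
  c("114" = 114.1112, "115" = 115.1083, "116" = 116.1116, "117" = 117.1150)
}

#' Extract reporter-ion intensities from a fragment spectrum
#'
#' Sums all peak intensities within `tolerance` Da of each nominal
#' reporter mass. Channels with no peak in the window read 0.
#'
#' @param peaks two-column numeric matrix or data frame `(mz, intensity)`;
#'   may have zero rows.
#' @param tolerance reporter mass tolerance in Da (default 0.05). Must be
#'   smaller than half the inter-channel spacing, otherwise windows
#'   overlap and extraction is ill-defined.
#' @return Named numeric vector of 4 non-negative channel intensities.
#' @examples
#' extract_reporter_intensities(cbind(c(114.11, 115.11), c(1000, 500)))
#' @export
extract_reporter_intensities <- function(peaks, tolerance = 0.05) {
  masses <- itraq_channels()
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (tolerance >= min(diff(masses)) / 2)
    stop("tolerance ", tolerance, " Da makes reporter windows overlap")
  out <- stats::setNames(numeric(4L), names(masses))
  if (is.null(peaks) || NROW(peaks) == 0L) return(out)
  peaks <- as.matrix(peaks)
  stopifnot(ncol(peaks) >= 2L)
  mz <- peaks[, 1]; int <- peaks[, 2]
  if (any(mz <= 0) || any(int < 0)) stop("invalid peak list")
  for (j in seq_along(masses)) {
    hit <- abs(mz - masses[j]) <= tolerance
    if (any(hit)) out[j] <- sum(int[hit])
  }
  out
}

#' Default iTRAQ 4-plex isotope-impurity correction matrix
#'
#' Builds the 4x4 mixing matrix from per-tag isotope impurity percentages
#' (-2, -1, +1, +2 Da satellites). Entry (i, j) is the fraction of tag
#' j's signal observed in channel i; impurities falling outside the
#' 114-117 panel are lost. The shipped defaults are representative 4-plex
#' purity values; real analyses should substitute the percentages from
#' the vendor certificate of the reagent lot
#' (see `system.file("extdata/itraq4_correction_factors.tsv",
#' package = "itraqr")`).
#'
#' @param impurities 4x4 numeric matrix or data frame, one row per tag
#'   (114..117), columns `minus2, minus1, plus1, plus2` in percent.
#' @return 4x4 correction matrix with channels as rows, tags as columns.
#' @export
isotope_correction_matrix <- function(impurities = NULL) {
  if (is.null(impurities)) {
    impurities <- matrix(c(0.0, 1.0, 5.9, 0.2,
                           0.0, 2.0, 5.6, 0.1,
                           0.0, 3.0, 4.5, 0.1,
                           0.1, 4.0, 3.5, 0.1),
                         nrow = 4, byrow = TRUE,
                         dimnames = list(names(itraq_channels()),
                                         c("minus2", "minus1",
                                           "plus1", "plus2")))
  }
  impurities <- as.matrix(impurities) / 100
  stopifnot(all(dim(impurities) == c(4L, 4L)), all(impurities >= 0))
  ch <- names(itraq_channels())
  M <- matrix(0, 4, 4, dimnames = list(channel = ch, tag = ch))
  offsets <- c(-2L, -1L, 1L, 2L)
  for (j in seq_len(4L)) {
    M[j, j] <- 1 - sum(impurities[j, ])
    for (k in seq_len(4L)) {
      i <- j + offsets[k]
      if (i >= 1L && i <= 4L) M[i, j] <- impurities[j, k]
    }
  }
  M
}

#' Read isotope-impurity percentages from a TSV config
#'
#' Expects columns `tag, minus2, minus1, plus1, plus2` (percent).
#'
#' @param path TSV file.
#' @return The 4x4 correction matrix (see [isotope_correction_matrix()]).
#' @export
read_isotope_correction <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("tag", "minus2", "minus1", "plus1", "plus2")
  stopifnot(all(need %in% names(df)))
  df <- df[order(df$tag), ]
  isotope_correction_matrix(df[, need[-1]])
}

#' Correct observed reporter intensities for isotope impurities
#'
#' Solves the linear mixing system `M x = observed` for the true tag
#' signals `x`, where column j of `M` gives the fraction of tag j's
#' signal appearing in each channel. Negative solutions (possible when
#' noise exceeds a small true signal) are clipped to 0; the number of
#' clipped channels is attached as attribute `"clipped"` for QC.
#'
#' @param observed named numeric vector of 4 observed channel intensities.
#' @param M 4x4 correction matrix; must be invertible.
#' @return Corrected intensities (named, non-negative), attribute
#'   `"clipped"`.
#' @export
correct_isotope_impurities <- function(observed, M) {
  stopifnot(length(observed) == 4L, all(dim(M) == c(4L, 4L)))
  if (abs(det(M)) < 1e-12) stop("correction matrix is singular")
  x <- as.numeric(solve(M, as.numeric(observed)))
  clipped <- sum(x < 0)
  x[x < 0] <- 0
  names(x) <- names(itraq_channels())
  attr(x, "clipped") <- clipped
  x
}

#' Per-peptide condition ratios from corrected channel intensities
#'
#' Divides each condition's channel intensity by the reference
#' condition's. A ratio is `NA` (a "null ratio") whenever the reference
#' channel or the condition's channel reads 0; the reference condition
#' itself gets ratio 1 when computable.
#'
#' @param intensities named numeric vector of 4 channel intensities
#'   (names `"114".."117"`).
#' @param tag_map named character vector mapping channels to conditions,
#'   as from [make_tag_rotation()].
#' @param reference_condition the denominator condition.
#' @return Named numeric vector over all conditions; `NA` marks null
#'   ratios.
#' @export
compute_peptide_ratios <- function(intensities, tag_map,
                                   reference_condition) {
  stopifnot(length(intensities) == 4L, length(tag_map) == 4L)
  if (!reference_condition %in% tag_map)
    stop("reference condition not present in tag map")
  ref_ch <- names(tag_map)[tag_map == reference_condition]
  ref <- as.numeric(intensities[ref_ch])
  out <- stats::setNames(rep(NA_real_, 4L), unname(tag_map))
  if (is.na(ref) || ref <= 0) return(out)
  for (ch in names(tag_map)) {
    v <- as.numeric(intensities[ch])
    out[tag_map[ch]] <- if (is.na(v) || v <= 0) NA_real_ else v / ref
  }
  out
}

#' Quantify a PSM table into per-peptide condition ratios
#'
#' The tabular analogue of the spectrum path: applies optional isotope
#' correction to the four reporter columns of each PSM and computes
#' condition ratios against the reference channel of the experiment's tag
#' rotation. One output row per PSM, with one ratio column per
#' non-reference condition (the `.jpf` dialect).
#'
#' @param psms PSM data frame with columns `peptide`, `accession`,
#'   `flags`, `score`, `experiment` and `I114`..`I117`.
#' @param rotation tag/condition map for this experiment (attribute
#'   `"rotation"` of the PSM table is used when omitted).
#' @param reference_condition denominator condition.
#' @param correction optional 4x4 isotope correction matrix; `NULL`
#'   applies none.
#' @return A peptide quantitation data frame: `peptide`, `accession`,
#'   `flags`, `score`, `experiment`, then `ratio_<condition>` for each
#'   non-reference condition; `NA` marks null ratios.
#' @export
quantify_psms <- function(psms, rotation = attr(psms, "rotation"),
                          reference_condition, correction = NULL) {
  stopifnot(is.data.frame(psms), length(rotation) == 4L)
  icols <- paste0("I", names(itraq_channels()))
  stopifnot(all(icols %in% names(psms)))
  if (!reference_condition %in% rotation)
    stop("reference condition not present in tag rotation")
  intens <- as.matrix(psms[, icols])
  colnames(intens) <- names(itraq_channels())
  if (!is.null(correction)) {
    if (abs(det(correction)) < 1e-12) stop("correction matrix is singular")
    intens <- t(solve(correction, t(intens)))
    intens[intens < 0] <- 0
    colnames(intens) <- names(itraq_channels())
  }
  ref_ch <- names(rotation)[rotation == reference_condition]
  ref <- intens[, ref_ch]
  conds <- unname(rotation[rotation != reference_condition])
  out <- psms[, c("peptide", "accession", "flags", "score", "experiment")]
  for (cond in conds) {
    ch <- names(rotation)[rotation == cond]
    v <- intens[, ch] / ref
    v[!is.finite(v) | intens[, ch] <= 0 | ref <= 0] <- NA_real_
    out[[paste0("ratio_", cond)]] <- v
  }
  rownames(out) <- NULL
  out
}

#' Quantify identified spectra read from MGF
#'
#' Joins an identification table to a list of spectra by `spectrum_id`,
#' extracts reporter intensities within the mass tolerance, applies
#' optional isotope correction, and computes condition ratios.
#'
#' @param spectra list of spectra from [read_mgf()].
#' @param ids data frame with `spectrum_id`, `peptide`, `accession`,
#'   `flags`, `score`, `experiment`.
#' @param rotation tag/condition map for this experiment.
#' @param reference_condition denominator condition.
#' @param tolerance reporter mass tolerance in Da (default 0.05).
#' @param correction optional 4x4 isotope correction matrix.
#' @return A peptide quantitation data frame (see [quantify_psms()]).
#' @export
quantify_spectra <- function(spectra, ids, rotation, reference_condition,
                             tolerance = 0.05, correction = NULL) {
  titles <- vapply(spectra, function(s) s$spectrum_id, "")
  keep <- ids$spectrum_id %in% titles
  ids <- ids[keep, , drop = FALSE]
  intens <- t(vapply(ids$spectrum_id, function(id)
    extract_reporter_intensities(spectra[[match(id, titles)]]$peaks,
                                 tolerance),
    numeric(4L)))
  psms <- cbind(ids, stats::setNames(as.data.frame(intens),
                                     paste0("I", names(itraq_channels()))))
  quantify_psms(psms, rotation = rotation,
                reference_condition = reference_condition,
                correction = correction)
}

# ---- .jpf dialect -------------------------------------------------------

#' Read/write the tab-delimited peptide quantitation (`.jpf`) dialect
#'
#' Header row with columns `peptide  accession  flags  score  experiment`
#' followed by one `ratio_<condition>` column per non-reference
#' condition; null ratios are serialized as `NA`.
#'
#' @param x peptide quantitation data frame.
#' @param path file path.
#' @return `path` (writer); the data frame (reader).
#' @export
write_jpf <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_jpf
#' @export
read_jpf <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(flags = "character"))
}

# ---- MGF ----------------------------------------------------------------

#' Read a Mascot Generic Format (MGF) file
#'
#' Minimal reader for the `BEGIN IONS`/`END IONS` block structure: TITLE,
#' PEPMASS, CHARGE headers and `m/z intensity` peak lines.
#'
#' @param path MGF file.
#' @return List of spectra; each a list with `spectrum_id`, `pepmass`,
#'   `charge`, and a two-column `peaks` matrix `(mz, intensity)`.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  stopifnot(length(starts) == length(ends))
  lapply(seq_along(starts), function(k) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1L)
    vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), "")
    pk <- block[!hdr & nzchar(trimws(block))]
    peaks <- if (length(pk)) {
      do.call(rbind, lapply(strsplit(trimws(pk), "[ \t]+"), function(p)
        as.numeric(p[1:2])))
    } else matrix(numeric(0), ncol = 2L)
    colnames(peaks) <- c("mz", "intensity")
    list(spectrum_id = if ("TITLE" %in% keys) vals[keys == "TITLE"][1] else
           paste0("spectrum_", k),
         pepmass = if ("PEPMASS" %in% keys)
           as.numeric(strsplit(vals[keys == "PEPMASS"][1], " ")[[1]][1])
         else NA_real_,
         charge = if ("CHARGE" %in% keys) vals[keys == "CHARGE"][1]
         else NA_character_,
         peaks = peaks)
  })
}

#' Write spectra to Mascot Generic Format (MGF)
#'
#' @param spectra list of spectra as returned by [read_mgf()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$spectrum_id), con)
    if (!is.null(s$pepmass) && !is.na(s$pepmass))
      writeLines(paste0("PEPMASS=", format(s$pepmass, digits = 10)), con)
    if (!is.null(s$charge) && !is.na(s$charge))
      writeLines(paste0("CHARGE=", s$charge), con)
    if (NROW(s$peaks))
      writeLines(sprintf("%.6f %.6f", s$peaks[, 1], s$peaks[, 2]), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Reporter-region spectra for a simulated PSM table
#'
#' Emits one small spectrum per PSM containing only the four reporter
#' peaks (channels with zero intensity are omitted), for exercising the
#' MGF extraction path.
#'
#' @param psms PSM data frame from [simulate_experiment()].
#' @param mz_jitter maximum absolute m/z offset applied to each reporter
#'   peak (default 0, exact nominal masses).
#' @return List of spectra suitable for [write_mgf()].
#' @export
psms_to_spectra <- function(psms, mz_jitter = 0) {
  masses <- itraq_channels()
  icols <- paste0("I", names(masses))
  lapply(seq_len(nrow(psms)), function(i) {
    int <- as.numeric(psms[i, icols])
    keep <- int > 0
    mz <- masses[keep]
    if (mz_jitter > 0)
      mz <- mz + stats::runif(sum(keep), -mz_jitter, mz_jitter)
    peaks <- cbind(mz = unname(mz), intensity = int[keep])
    list(spectrum_id = psms$spectrum_id[i], pepmass = 445.12, charge = "2+",
         peaks = peaks)
  })
}
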