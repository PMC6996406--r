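#' Expected class count under the reference proportion
#'
#' The number of input proteins expected in a class if the input list
#' were a random draw from the reference proteome:
#' `input_size * reference_count / reference_total`.
#'
#' @param reference_count proteins of the class in the reference list.
#' @param reference_total size of the reference list.
#' @param input_size size of the submitted protein list.
#' @return Expected count (real, proteins).
#' @examples
#' expected_count(20, 21324, 128) # 0.12 at 2 d.p.
#' @export
expected_count <- function(reference_count, reference_total, input_size) {
  if (any(reference_total <= 0)) stop("reference_total must be positive")
  stopifnot(all(reference_count >= 0),
            all(reference_count <= reference_total),
            all(input_size > 0))
  input_size * reference_count / reference_total
}

#' Fold enrichment and direction
#'
#' @param observed observed class count in the input list.
#' @param expected expected count (see [expected_count()]).
#' @return A list with `direction` (`"+"` for over-representation,
#'   `"-"` for under) and `fold` = observed/expected (`NA` when
#'   expected is 0).
#' @examples
#' fold_enrichment(4, expected_count(20, 21324, 128)) # +, 33.32
#' @export
fold_enrichment <- function(observed, expected) {
  fold <- ifelse(expected > 0, observed / expected, NA_real_)
  list(direction = ifelse(observed > expected, "+", "-"), fold = fold)
}

#' One-sided binomial tail probability for class membership
#'
#' Tests whether the observed class count is surprising under random
#' sampling from the reference: `P(X >= observed)` for
#' over-representation, `P(X <= observed)` for under-representation,
#' with `X ~ Binomial(input_size, p)`.
#'
#' @param observed observed class count.
#' @param input_size input list size.
#' @param p class proportion in the reference
#'   (`reference_count / reference_total`); strictly inside (0, 1).
#' @param direction `"+"`/`"over"` or `"-"`/`"under"`.
#' @return The one-sided tail probability.
#' @examples
#' binomial_pvalue(10, 10, 0.5, "+") # 0.5^10
#' @export
binomial_pvalue <- function(observed, input_size, p, direction = "+") {
  stopifnot(observed >= 0, observed <= input_size, p > 0, p < 1)
  direction <- match.arg(direction, c("+", "-", "over", "under"))
  if (direction %in% c("+", "over"))
    stats::pbinom(observed - 1, input_size, p, lower.tail = FALSE)
  else
    stats::pbinom(observed, input_size, p)
}

#' Protein-class over-representation test
#'
#' For each class, computes the expected count, fold enrichment,
#' direction, and a one-sided p-value (exact binomial by default,
#' Fisher's exact as an option), then applies Bonferroni correction.
#' The correction multiplier defaults to the number of classes with at
#' least one observed input protein.
#'
#' @param classes data frame with columns `class_id` (or `class_name`),
#'   `reference_count` and `observed`.
#' @param reference_total size of the reference proteome list.
#' @param input_size size of the submitted protein list.
#' @param alpha significance level for retention (default 0.05).
#' @param m Bonferroni multiplier; default `NULL` uses the number of
#'   classes with `observed >= 1`.
#' @param method `"binomial"` (exact one-sided tail) or `"fisher"`.
#' @return A data frame of class `"enrichment_result"`: one row per
#'   class with `reference_count`, `observed`, `expected`, `direction`,
#'   `fold_enrichment`, `p_raw`, `p_corrected`, `retained`; attributes
#'   `reference_total`, `input_size`, `m`, `alpha`, `method`.
#' @export
enrichment_test <- function(classes, reference_total, input_size,
                            alpha = 0.05, m = NULL,
                            method = c("binomial", "fisher")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(classes),
            all(c("reference_count", "observed") %in% names(classes)))
  out <- classes
  out$expected <- expected_count(out$reference_count, reference_total,
                                 input_size)
  fe <- fold_enrichment(out$observed, out$expected)
  out$direction <- fe$direction
  out$fold_enrichment <- fe$fold
  out$p_raw <- vapply(seq_len(nrow(out)), function(i) {
    p <- out$reference_count[i] / reference_total
    if (p <= 0 || p >= 1) return(NA_real_)
    if (method == "binomial") {
      binomial_pvalue(out$observed[i], input_size, p, out$direction[i])
    } else {
      alt <- if (out$direction[i] == "+") "greater" else "less"
      tab <- matrix(c(out$observed[i],
                      input_size - out$observed[i],
                      out$reference_count[i] - out$observed[i],
                      reference_total - input_size -
                        out$reference_count[i] + out$observed[i]),
                    nrow = 2)
      stats::fisher.test(tab, alternative = alt)$p.value
    }
  }, numeric(1))
  if (is.null(m)) m <- sum(out$observed >= 1)
  out$p_corrected <- pmin(1, m * out$p_raw)
  out$retained <- !is.na(out$p_corrected) & out$p_corrected < alpha
  structure(out, reference_total = reference_total,
            input_size = input_size, m = m, alpha = alpha,
            method = method, class = c("enrichment_result", "data.frame"))
}

#' Bonferroni filtering of enrichment rows
#'
#' Corrects raw p-values by `p_corrected = min(1, m * p_raw)` and
#' retains rows with `p_corrected < alpha` (strict).
#'
#' @param rows data frame with a `p_raw` column.
#' @param alpha significance level (default 0.05).
#' @param m number of tests; must be at least `nrow(rows)` (default:
#'   exactly that).
#' @return The retained rows, with `p_corrected` added.
#' @export
bonferroni_filter <- function(rows, alpha = 0.05, m = nrow(rows)) {
  stopifnot(is.data.frame(rows), "p_raw" %in% names(rows),
            m >= nrow(rows))
  rows$p_corrected <- pmin(1, m * rows$p_raw)
  out <- rows[!is.na(rows$p_corrected) & rows$p_corrected < alpha, ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read/write protein-class annotation tables
#'
#' The table is two-plus columns of TSV (`class_id`, `reference_count`,
#' optionally `class_name`, `observed`) preceded by a comment header line
#' `# reference_total: <N>` (and optionally `# input_size: <N>`).
#'
#' @param path TSV file.
#' @return Data frame with attributes `reference_total` and (when
#'   present) `input_size`.
#' @export
read_annotation_table <- function(path) {
  hdr <- readLines(path, n = 5L)
  grab <- function(key) {
    ln <- grep(paste0("^#\\s*", key), hdr, value = TRUE)
    if (length(ln)) as.numeric(sub(".*[:=]\\s*", "", ln[1])) else NA_real_
  }
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  attr(df, "reference_total") <- grab("reference_total")
  attr(df, "input_size") <- grab("input_size")
  df
}

#' @rdname read_annotation_table
#' @param classes annotation data frame.
#' @param reference_total,input_size header values to record.
#' @export
write_annotation_table <- function(classes, path, reference_total,
                                   input_size = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# reference_total: ", reference_total), con)
  if (!is.na(input_size))
    writeLines(paste0("# input_size: ", input_size), con)
  utils::write.table(classes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an enrichment result as a report-shaped TSV
#'
#' Numeric report columns are rounded to 2 decimal places (expected and
#' fold enrichment), matching the conventional report layout; p-values
#' keep full precision.
#'
#' @param result an `"enrichment_result"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(result, path) {
  out <- as.data.frame(result)
  out$expected <- round(out$expected, 2)
  out$fold_enrichment <- round(out$fold_enrichment, 2)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
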