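#' Protein x condition ratio matrix
#'
#' Builds the numeric matrix clustered for heat-map display: rows are
#' accessions, columns are the non-reference conditions, values are
#' overall median ratios. Rows with any missing condition are dropped
#' (clustering requires complete vectors).
#'
#' @param quant a `"protein_quant"` object.
#' @return Numeric matrix with accession rownames.
#' @export
ratio_matrix <- function(quant) {
  stopifnot(inherits(quant, "protein_quant"))
  ov <- quant$overall
  conds <- sort(unique(ov$condition))
  accs <- sort(unique(ov$accession))
  m <- matrix(NA_real_, length(accs), length(conds),
              dimnames = list(accs, conds))
  m[cbind(match(ov$accession, accs), match(ov$condition, conds))] <- ov$ratio
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Pairwise Euclidean distances between matrix rows
#'
#' @param m numeric matrix with at least 2 rows.
#' @return Full symmetric distance matrix with zero diagonal.
#' @examples
#' euclidean_distances(rbind(a = c(0, 0), b = c(3, 4)))["a", "b"] # 5
#' @export
euclidean_distances <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 rows")
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Standard agglomerative merge sequence under the chosen linkage.
#' Ties between equal inter-cluster distances are broken by the lowest
#' row index (the order rows appear in the input).
#'
#' @param distances full symmetric distance matrix or a `dist` object.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An object of class `"ratio_dendrogram"`: list with `merge`,
#'   `height`, `order` (leaf permutation), `labels`, `linkage`, and the
#'   underlying `hclust` object.
#' @export
agglomerate <- function(distances,
                        linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  d <- if (inherits(distances, "dist")) distances else
    stats::as.dist(as.matrix(distances))
  hc <- stats::hclust(d, method = linkage)
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, linkage = linkage, hclust = hc),
            class = "ratio_dendrogram")
}

#' @export
print.ratio_dendrogram <- function(x, ...) {
  cat("Agglomerative clustering (", x$linkage, " linkage): ",
      length(x$order), " leaves, ", nrow(x$merge), " merges\n", sep = "")
  invisible(x)
}

#' @export
plot.ratio_dendrogram <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}

#' Cluster a ratio matrix for heat-map ordering
#'
#' Clusters rows (and optionally columns) by Euclidean distance and the
#' chosen linkage, and returns the reordered matrix.
#'
#' @param m numeric ratio matrix (proteins x conditions).
#' @param linkage linkage method (default `"average"`).
#' @param cluster_columns also cluster and reorder columns (default
#'   `FALSE`).
#' @return List with `rows` (`ratio_dendrogram`), `columns` (or `NULL`),
#'   and `matrix` (the reordered matrix).
#' @export
cluster_ratio_matrix <- function(m, linkage = "average",
                                 cluster_columns = FALSE) {
  rows <- agglomerate(euclidean_distances(m), linkage)
  cols <- NULL
  ord_m <- m[rows$order, , drop = FALSE]
  if (cluster_columns && ncol(m) >= 2L) {
    cols <- agglomerate(euclidean_distances(t(m)), linkage)
    ord_m <- ord_m[, cols$order, drop = FALSE]
  }
  list(rows = rows, columns = cols, matrix = ord_m)
}

#' Write the row-ordered matrix and dendrogram
#'
#' @param clustering result of [cluster_ratio_matrix()], or a
#'   `ratio_dendrogram` for the newick writer.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ordered_matrix <- function(clustering, path) {
  m <- clustering$matrix
  df <- data.frame(accession = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ordered_matrix
#' @export
write_dendrogram_newick <- function(clustering, path) {
  dend <- if (inherits(clustering, "ratio_dendrogram")) clustering else
    clustering$rows
  phy <- ape::as.phylo(dend$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
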