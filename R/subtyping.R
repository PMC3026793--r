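# ---------------------------------------------------------------------------
# Phenotypic subtyping: profile distances, complete-linkage clustering,
# Figure-style ordered profile report
# ---------------------------------------------------------------------------

#' Pairwise distances between participant deficit profiles
#'
#' Euclidean distance over the columns both participants completed,
#' rescaled by `sqrt(n_total / n_shared)` so that pairs with missing data
#' are compared on the same scale as complete pairs (pairwise-complete
#' policy).  The rescaled distances need not satisfy the triangle
#' inequality; complete-linkage clustering does not require it.
#'
#' @param ztab a [zScoreTable()].
#' @param columns columns to use (default: the aggregate columns if any,
#'   else all columns).
#' @param policy `"pairwise"` (rescaled pairwise-complete, default) or
#'   `"complete"` (drop participants with any missing value).
#' @return A symmetric distance matrix of class `cpDistance` with a
#'   `policy` attribute; participants with no usable column are dropped
#'   with a warning.
#' @export
pairwiseDistance <- function(ztab, columns = NULL,
                             policy = c("pairwise", "complete")) {
  stopifnot(inherits(ztab, "zScoreTable"))
  policy <- match.arg(policy)
  if (is.null(columns)) {
    ag <- attr(ztab, "aggregates")
    columns <- if (length(ag) > 0) ag else colnames(ztab)
  }
  m <- unclass(ztab)[, columns, drop = FALSE]
  usable <- rowSums(!is.na(m)) > 0
  if (!all(usable)) {
    warning("dropping participants with all columns missing: ",
            paste(rownames(m)[!usable], collapse = ", "))
    m <- m[usable, , drop = FALSE]
  }
  if (policy == "complete") {
    full <- rowSums(is.na(m)) == 0
    m <- m[full, , drop = FALSE]
  }
  n <- nrow(m)
  if (n < 2) stop("need at least 2 participants with usable columns")
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  K <- ncol(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sh <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(sh))
        stop("participants ", rownames(m)[i], " and ", rownames(m)[j],
             " share no non-missing column")
      d2 <- sum((m[i, sh] - m[j, sh])^2)
      D[i, j] <- D[j, i] <- sqrt(d2 * K / sum(sh))
    }
  }
  structure(D, policy = policy, columns = columns,
            class = c("cpDistance", "matrix", "array"))
}

#' Complete-linkage agglomerative clustering
#'
#' Merges clusters so that each merge height equals the maximum pairwise
#' distance between the merged clusters' members (complete linkage, via
#' [stats::hclust()]).  The final merge height is the overall maximum
#' pairwise distance.
#'
#' @param dist a `cpDistance` matrix (or any symmetric distance matrix).
#' @return A `cpDendrogram`: `merge` (hclust-style merge matrix),
#'   `height` (nondecreasing), `order` (leaf order), `labels`, plus the
#'   underlying `hclust` object.
#' @export
completeLinkage <- function(dist) {
  D <- unclass(dist)
  if (!is.matrix(D) || nrow(D) < 2)
    stop("need a distance matrix over at least 2 participants")
  hc <- hclust(as.dist(D), method = "complete")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, hclust = hc),
            class = "cpDendrogram")
}

#' @export
print.cpDendrogram <- function(x, ...) {
  cat("complete-linkage dendrogram over", length(x$labels),
      "participants\n")
  cat("  merge heights:", paste(round(x$height, 3), collapse = ", "), "\n")
  cat("  leaf order:", paste(x$labels[x$order], collapse = " "), "\n")
  invisible(x)
}

#' Cut a dendrogram into k cluster labels
#'
#' @param dendro a [completeLinkage()] result.
#' @param k number of clusters.
#' @return Named integer vector of cluster labels.
#' @export
cutDendrogram <- function(dendro, k) {
  stopifnot(inherits(dendro, "cpDendrogram"))
  cutree(dendro$hclust, k = k)
}

#' Ordered deficit-profile report
#'
#' Emits the clustered overview table: one row per participant in
#' dendrogram leaf order, aggregate (summary) columns first and separate
#' test columns after, each cell carrying the z-score, a deficit flag and
#' an explicit missing marker.
#'
#' @param ztab a [zScoreTable()] with aggregates.
#' @param deficits a [deficitCalls()] table for `ztab`.
#' @param dendro a [completeLinkage()] result whose labels are a subset of
#'   the table's participants.
#' @return A data.frame in leaf order with columns `participant_id`,
#'   `group`, then `<column>_z`, `<column>_deficit`, `<column>_missing`
#'   triples for every column.
#' @export
profileReport <- function(ztab, deficits, dendro) {
  stopifnot(inherits(ztab, "zScoreTable"),
            inherits(dendro, "cpDendrogram"))
  ord <- dendro$labels[dendro$order]
  extra <- setdiff(ord, rownames(ztab))
  if (length(extra) > 0)
    stop("dendrogram contains unknown participants: ",
         paste(extra, collapse = ", "))
  ag <- attr(ztab, "aggregates")
  cols <- c(ag, setdiff(colnames(ztab), ag))
  g <- attr(ztab, "group")[match(ord, rownames(ztab))]
  out <- data.frame(participant_id = ord, group = g,
                    stringsAsFactors = FALSE)
  defKey <- paste(deficits$participant_id, deficits$column)
  for (cl in cols) {
    zc <- unclass(ztab)[ord, cl]
    dK <- match(paste(ord, cl), defKey)
    out[[paste0(cl, "_z")]] <- round(zc, 3)
    out[[paste0(cl, "_deficit")]] <- !is.na(zc) & deficits$is_deficit[dK]
    out[[paste0(cl, "_missing")]] <- is.na(zc)
  }
  out
}
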