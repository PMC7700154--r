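# Descriptor filtering and mRMR/MIQ feature ranking.
#
# Fragment counts are binarized to presence/absence before any mutual
# information is computed (counts are sparse and heavy-tailed, and the
# activity label is binary). MI is measured in nats; the unit cancels in the
# relevance/redundancy quotient.

#' Remove rare descriptors
#'
#' Drops every column present (count > 0) in less than `min_fraction` of the
#' compounds; a column is kept iff its presence fraction is at least
#' `min_fraction`.
#'
#' @param table Descriptor count matrix (sparse or dense) with column labels.
#' @param min_fraction Minimum presence fraction (default 0.01, i.e. 1%).
#' @return The filtered matrix (possibly with zero columns).
#' @export
frequency_filter <- function(table, min_fraction = 0.01) {
  stopifnot(nrow(table) > 0)
  pres <- Matrix::colMeans(table > 0)
  table[, pres >= min_fraction, drop = FALSE]
}

# Vectorized plug-in MI (nats) between each column of binary matrix X and a
# binary vector y, from the 2x2 contingency counts.
.mi_cols <- function(X, y) {
  n <- length(y)
  ny1 <- sum(y)
  cs <- as.numeric(Matrix::colSums(X))
  a <- as.numeric(Matrix::crossprod(X, y))  # x=1, y=1
  b <- cs - a                               # x=1, y=0
  cc <- ny1 - a                             # x=0, y=1
  d <- n - a - b - cc                       # x=0, y=0
  term <- function(nij, ni, nj) {
    out <- numeric(length(nij))
    pos <- nij > 0
    out[pos] <- (nij[pos] / n) * log(n * nij[pos] / (ni[pos] * nj[pos]))
    out
  }
  nx1 <- cs; nx0 <- n - cs
  term(a, nx1, rep(ny1, length(a))) +
    term(b, nx1, rep(n - ny1, length(a))) +
    term(cc, nx0, rep(ny1, length(a))) +
    term(d, nx0, rep(n - ny1, length(a)))
}

#' Mutual information between two binary vectors
#'
#' Plug-in estimate from the 2x2 contingency table, in nats, with the
#' convention 0 log 0 = 0.
#'
#' @param x,y Binary (0/1 or logical) vectors of equal length.
#' @return MI in nats (non-negative).
#' @examples
#' y <- rep(c(0, 1), 10)
#' mutual_info_binary(y, y)  # ln 2
#' @export
mutual_info_binary <- function(x, y) {
  if (length(x) != length(y)) stop2("x and y must have equal length")
  stopifnot(length(x) >= 1)
  x <- as.numeric(x != 0)
  y <- as.numeric(y != 0)
  as.numeric(.mi_cols(matrix(x, ncol = 1), y))
}

#' Greedy mRMR feature ranking with the MIQ score
#'
#' Forward selection over binarized descriptors: the first feature maximizes
#' relevance I(f; y); each later step maximizes the Mutual Information
#' Quotient, relevance divided by the mean MI between the candidate and the
#' already-selected features. Stops after `k` features or when the columns are
#' exhausted.
#'
#' Ties (and near-zero mean redundancy, below 1e-12) are resolved
#' reproducibly: the quotient is capped, ties broken by higher relevance and
#' then lexicographic label.
#'
#' @param table Descriptor matrix (columns = features, labeled).
#' @param labels Binary activity labels, one per row.
#' @param k Number of features to keep (default 500).
#' @return A `feature_ranking`: data frame with columns `rank`, `label`,
#'   `relevance` (MI with the label, nats) and `redundancy` (mean MI with the
#'   previously selected set at the time of selection).
#' @export
mrmr_miq_select <- function(table, labels, k = 500) {
  if (!is_count(k) || k <= 0) stop2("k must be a positive integer")
  stopifnot(nrow(table) == length(labels))
  y <- as.numeric(labels != 0)
  X <- (table > 0) * 1  # presence/absence, sparse or dense
  p <- ncol(X)
  labs <- colnames(X)
  eps <- 1e-12
  cap <- 1e15
  rel <- .mi_cols(X, y)
  k <- min(k, p)
  selected <- integer(0)
  red_at_sel <- numeric(0)
  redsum <- numeric(p)
  remaining <- rep(TRUE, p)
  for (step in seq_len(k)) {
    cand <- which(remaining)
    if (step == 1) {
      score <- rel[cand]
      meanred <- numeric(length(cand))
    } else {
      meanred <- redsum[cand] / length(selected)
      score <- ifelse(meanred < eps, pmin(rel[cand] / eps, cap),
                      rel[cand] / meanred)
    }
    # scores are compared at 12 significant digits so mathematically tied
    # features (equal up to summation order) fall through to the tie-breaks
    ord <- order_c(-signif(score, 12), -signif(rel[cand], 12), labs[cand])
    pick <- cand[ord[1]]
    selected <- c(selected, pick)
    red_at_sel <- c(red_at_sel, if (step == 1) 0 else meanred[ord[1]])
    remaining[pick] <- FALSE
    if (any(remaining) && step < k) {
      redsum[remaining] <- redsum[remaining] +
        .mi_cols(X[, remaining, drop = FALSE], as.numeric(X[, pick]))
    }
  }
  out <- data.frame(rank = seq_along(selected),
                    label = labs[selected],
                    relevance = rel[selected],
                    redundancy = red_at_sel,
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Write a feature ranking
#'
#' @param ranking A [mrmr_miq_select()] result.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_ranking <- function(ranking, path) {
  write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
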