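# Class balancing via Ward clustering of the majority class, and stratified
# train/external splitting.
#
# The majority class is clustered (Ward linkage, Euclidean distance on the
# raw descriptor vectors) and downsampled to the minority-class size with
# per-cluster quotas proportional to cluster sizes, so the retained compounds
# keep the chemical-space coverage of the full majority class.

#' Construct a labeled dataset
#'
#' @param ids Compound ids.
#' @param x Feature matrix (rows aligned with `ids`).
#' @param y Binary labels (0/1).
#' @param cell_line Cell-line tag.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(ids, x, y, cell_line = "CL") {
  x <- as.matrix(x)
  stopifnot(length(ids) == nrow(x), length(y) == nrow(x))
  y <- as.integer(y != 0)
  rownames(x) <- ids
  structure(list(ids = as.character(ids), x = x, y = y, cell_line = cell_line),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %s: %d compounds (%d active / %d inactive), %d features\n",
              x$cell_line, length(x$ids), sum(x$y == 1), sum(x$y == 0), ncol(x$x)))
  invisible(x)
}

#' Cluster the majority class
#'
#' Agglomerative hierarchical clustering with Ward's method on Euclidean
#' distances. Either a fixed number of clusters or a linkage-height threshold
#' must be given (the choice replaces a by-eye dendrogram cut and is exposed
#' explicitly for reproducibility).
#'
#' @param x Feature matrix of the majority-class compounds.
#' @param n_clusters Number of clusters, or `NULL`.
#' @param h Linkage-height threshold, used when `n_clusters` is `NULL`.
#' @return Integer cluster assignment, one entry per row of `x`.
#' @export
cluster_majority_class <- function(x, n_clusters = NULL, h = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop2("clustering needs at least 2 compounds")
  if (!is.null(n_clusters) && n_clusters > nrow(x)) {
    stop2("n_clusters exceeds the number of compounds")
  }
  if (is.null(n_clusters) && is.null(h)) stop2("give n_clusters or h")
  hc <- hclust(dist(x, method = "euclidean"), method = "ward.D2")
  if (!is.null(n_clusters)) unname(cutree(hc, k = n_clusters))
  else unname(cutree(hc, h = h))
}

# Largest-remainder allocation of `target` draws over cluster sizes, with a
# floor of one per non-empty cluster whenever target >= number of clusters,
# and quotas capped at cluster sizes.
.cluster_quotas <- function(sizes, target) {
  kcl <- length(sizes)
  total <- sum(sizes)
  stopifnot(target <= total)
  q <- target * sizes / total
  base <- floor(q)
  if (target >= kcl) base <- pmax(base, 1)
  base <- pmin(base, sizes)
  frac <- q - floor(q)
  # add or remove units to hit the target exactly
  repeat {
    diffn <- target - sum(base)
    if (diffn == 0) break
    if (diffn > 0) {
      cand <- which(base < sizes)
      ord <- cand[order(-frac[cand], -sizes[cand], cand)]
      take <- ord[seq_len(min(diffn, length(ord)))]
      base[take] <- base[take] + 1
    } else {
      floor1 <- if (target >= kcl) 1 else 0
      cand <- which(base > floor1)
      ord <- cand[order(frac[cand], -base[cand], cand)]
      take <- ord[seq_len(min(-diffn, length(ord)))]
      base[take] <- base[take] - 1
    }
  }
  base
}

#' Stratified downsampling over clusters
#'
#' Draws `target` members without replacement, with per-cluster quotas
#' proportional to cluster sizes (largest-remainder rounding). Whenever
#' `target` is at least the number of clusters, every non-empty cluster
#' contributes at least one member.
#'
#' @param clusters Integer cluster assignment, one entry per member.
#' @param target Number of members to keep.
#' @param seed RNG seed for the within-cluster draws.
#' @return Integer indices (into `clusters`) of the selected members.
#' @export
stratified_downsample <- function(clusters, target, seed = 1) {
  if (!is_count(target) || target < 0) stop2("target must be a non-negative integer")
  n <- length(clusters)
  if (target > n) stop2("target exceeds the number of members")
  if (target == 0) return(integer(0))
  cl <- sort(unique(clusters))
  sizes <- vapply(cl, function(c) sum(clusters == c), numeric(1))
  quota <- .cluster_quotas(sizes, target)
  withr::with_seed(seed, {
    picks <- lapply(seq_along(cl), function(k) {
      members <- which(clusters == cl[k])
      if (quota[k] == 0) return(integer(0))
      if (quota[k] == length(members)) return(members)
      sort(sample(members, quota[k]))
    })
    sort(unlist(picks))
  })
}

#' Balance a dataset to a 1:1 class ratio
#'
#' Downsamples the majority class to the minority-class size using
#' cluster-stratified sampling, so the retained majority compounds span the
#' clustered chemical space. The ids removed from the majority class are kept
#' in the `removed_ids` attribute (they are reusable as presumed inactives in
#' a screening set).
#'
#' @param dataset A [labeled_dataset()].
#' @param clusters Cluster assignment for the majority-class rows (in their
#'   order of appearance), or `NULL` to compute one.
#' @param n_clusters Number of Ward clusters when `clusters` is `NULL`.
#' @param seed RNG seed.
#' @return A balanced `labeled_dataset` with attribute `removed_ids`.
#' @export
balance_dataset <- function(dataset, clusters = NULL, n_clusters = 4, seed = 1) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n1 <- sum(dataset$y == 1); n0 <- sum(dataset$y == 0)
  if (n1 == 0 || n0 == 0) stop2("both classes must be non-empty")
  if (n1 == n0) {
    out <- dataset
    attr(out, "removed_ids") <- character(0)
    return(out)
  }
  maj <- if (n0 > n1) 0L else 1L
  maj_rows <- which(dataset$y == maj)
  min_rows <- which(dataset$y != maj)
  if (is.null(clusters)) {
    k <- min(n_clusters, length(maj_rows))
    clusters <- cluster_majority_class(dataset$x[maj_rows, , drop = FALSE],
                                       n_clusters = k)
  }
  stopifnot(length(clusters) == length(maj_rows))
  keep_in_maj <- stratified_downsample(clusters, target = length(min_rows),
                                       seed = seed)
  keep <- sort(c(min_rows, maj_rows[keep_in_maj]))
  removed <- setdiff(maj_rows, maj_rows[keep_in_maj])
  out <- labeled_dataset(dataset$ids[keep], dataset$x[keep, , drop = FALSE],
                         dataset$y[keep], dataset$cell_line)
  attr(out, "removed_ids") <- dataset$ids[removed]
  out
}

#' Split into training and external sets
#'
#' Class-stratified random 75/25 split (fraction configurable). Per-class
#' training counts are rounded by largest remainder while preserving the
#' rounded total.
#'
#' @param dataset A [labeled_dataset()].
#' @param train_fraction Fraction of compounds for training (default 0.75).
#' @param seed RNG seed.
#' @return A `split_pair`: list with `train`, `external` (both
#'   `labeled_dataset`) and `seed`.
#' @export
split_train_external <- function(dataset, train_fraction = 0.75, seed = 1) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- length(dataset$ids)
  if (n < 4) stop2("need at least 4 compounds to split")
  for (cls in c(0L, 1L)) {
    if (sum(dataset$y == cls) < 2) stop2("class ", cls, " has fewer than 2 members")
  }
  n_train <- round(train_fraction * n)
  n1 <- sum(dataset$y == 1)
  q <- .cluster_quotas(c(n1, n - n1), n_train)  # per-class largest remainder
  withr::with_seed(seed, {
    tr1 <- sample(which(dataset$y == 1), q[1])
    tr0 <- sample(which(dataset$y == 0), q[2])
  })
  tr <- sort(c(tr1, tr0))
  ex <- setdiff(seq_len(n), tr)
  out <- list(
    train = labeled_dataset(dataset$ids[tr], dataset$x[tr, , drop = FALSE],
                            dataset$y[tr], dataset$cell_line),
    external = labeled_dataset(dataset$ids[ex], dataset$x[ex, , drop = FALSE],
                               dataset$y[ex], dataset$cell_line),
    seed = seed
  )
  class(out) <- "split_pair"
  out
}

#' @export
print.split_pair <- function(x, ...) {
  cat(sprintf("<split_pair> train %d / external %d (seed %s)\n",
              length(x$train$ids), length(x$external$ids), format(x$seed)))
  invisible(x)
}

#' Write a dataset manifest
#'
#' @param split A `split_pair`.
#' @param path Output TSV path.
#' @param clusters Optional named cluster assignment to include.
#' @return Invisibly, `path`.
#' @export
write_dataset_manifest <- function(split, path, clusters = NULL) {
  df <- rbind(
    data.frame(compound_id = split$train$ids, label = split$train$y,
               split = "train", stringsAsFactors = FALSE),
    data.frame(compound_id = split$external$ids, label = split$external$y,
               split = "external", stringsAsFactors = FALSE)
  )
  df$cluster <- if (is.null(clusters)) NA else clusters[df$compound_id]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
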