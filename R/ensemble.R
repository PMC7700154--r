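# Multi-objective desirability ensembles.
#
# Qualified base models (external accuracy strictly above 0.8) are grouped by
# cell line. For a compound, the desirability of cell line k is the geometric
# mean of the member-model activity scores for that line, and the global
# desirability D1 is the geometric mean of the per-cell-line desirabilities:
# D1 = (d(y_1) d(y_2) ... d(y_k))^(1/k). All combinations (non-empty subsets
# of the qualified models of each cell line, every cell line represented) are
# explored exhaustively and judged by early-recognition metrics on a labeled
# screening set.

#' Build a desirability ensemble
#'
#' @param models List of qualified [train_base_model()] results (at least one
#'   cell line with one model).
#' @return An `ensemble_model`: members grouped by cell line.
#' @export
ensemble_model <- function(models) {
  if (inherits(models, "base_model")) models <- list(models)
  stopifnot(length(models) >= 1)
  ok <- vapply(models, function(m) inherits(m, "base_model"), logical(1))
  if (!all(ok)) stop2("all members must be base_model objects")
  if (!all(vapply(models, function(m) isTRUE(m$qualified), logical(1)))) {
    stop2("all ensemble members must be qualified (external AC > 0.8)")
  }
  lines <- vapply(models, function(m) m$cell_line, character(1))
  groups <- split(models, lines)
  groups <- groups[sort_c(names(groups))]
  structure(list(groups = groups, k = length(groups)),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d cell lines\n", x$k))
  for (ln in names(x$groups)) {
    cat(" ", ln, ":",
        paste(vapply(x$groups[[ln]], function(m) m$learner, character(1)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

member_ids <- function(ensemble) {
  unlist(lapply(ensemble$groups, function(g) {
    vapply(g, function(m) m$model_id, character(1))
  }), use.names = FALSE)
}

#' Per-cell-line desirability
#'
#' Geometric mean of the member-model activity scores of one cell line.
#'
#' @param scores Numeric vector (one compound) or matrix (compounds x models)
#'   of scores in (0, 1].
#' @return Desirability value(s) in (0, 1].
#' @examples
#' cell_line_desirability(c(0.9, 0.4))  # 0.6
#' @export
cell_line_desirability <- function(scores) {
  if (is.null(scores) || length(scores) == 0) stop2("no scores given")
  if (is.matrix(scores)) {
    if (ncol(scores) == 0) stop2("no scores given")
    if (any(scores <= 0)) stop2("scores must be positive")
    return(exp(rowMeans(log(scores))))
  }
  if (any(scores <= 0)) stop2("scores must be positive")
  exp(mean(log(scores)))
}

#' Global desirability D1
#'
#' Geometric mean of the per-cell-line desirabilities:
#' `D1 = (prod d(y_k))^(1/k)`.
#'
#' @param d Numeric vector (one compound) or matrix (compounds x cell lines)
#'   of per-cell-line desirabilities in (0, 1].
#' @return D1 value(s) in (0, 1].
#' @examples
#' global_desirability(c(0.9, 0.4, 0.1))  # (0.036)^(1/3)
#' @export
global_desirability <- function(d) {
  if (is.matrix(d)) {
    if (any(d <= 0)) stop2("desirabilities must be positive")
    return(exp(rowMeans(log(d))))
  }
  stopifnot(length(d) >= 1)
  if (any(d <= 0)) stop2("desirabilities must be positive")
  exp(mean(log(d)))
}

# score every member model once; returns compounds x models matrix with
# model_id columns
.member_scores <- function(models, table, seed = 1) {
  ids <- vapply(models, function(m) m$model_id, character(1))
  S <- vapply(models, function(m) score_compounds(m, table, seed = seed),
              numeric(nrow(table)))
  S <- matrix(S, nrow = nrow(table),
              dimnames = list(rownames(table), ids))
  S
}

#' Score and rank a screening library
#'
#' Computes every member model's activity score, per-cell-line desirabilities
#' and the global desirability D1 for each library compound, and returns the
#' library ranked by D1 (descending); D1 ties are broken by compound id so
#' the ordering is invariant to the input permutation.
#'
#' @param ensemble An [ensemble_model()].
#' @param table Descriptor matrix of the library (fragment labels as column
#'   names, compound ids as row names).
#' @param seed RNG seed for score computation.
#' @return A `screening_result` data frame: `rank`, `compound_id`, `D1`, one
#'   `d_<cell line>` column per cell line and one score column per member
#'   model.
#' @export
screen_library <- function(ensemble, table, seed = 1) {
  stopifnot(inherits(ensemble, "ensemble_model"))
  if (nrow(table) == 0) stop2("library is empty")
  all_models <- unlist(ensemble$groups, recursive = FALSE)
  S <- .member_scores(all_models, table, seed = seed)
  dmat <- vapply(names(ensemble$groups), function(ln) {
    ids <- vapply(ensemble$groups[[ln]], function(m) m$model_id, character(1))
    cell_line_desirability(S[, ids, drop = FALSE])
  }, numeric(nrow(table)))
  dmat <- matrix(dmat, nrow = nrow(table),
                 dimnames = list(rownames(table),
                                 paste0("d_", names(ensemble$groups))))
  D1 <- global_desirability(dmat)
  ids <- rownames(table) %||% as.character(seq_len(nrow(table)))
  ord <- order_c(-D1, ids)
  out <- data.frame(rank = seq_along(ord), compound_id = ids[ord],
                    D1 = D1[ord], stringsAsFactors = FALSE)
  out <- cbind(out, dmat[ord, , drop = FALSE], S[ord, , drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("screening_result", "data.frame")
  out
}

#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  screen_library(object, newdata, ...)
}

#' Enumerate all ensemble combinations
#'
#' Cartesian product over the non-empty subsets of each cell line's qualified
#' models; every cell line stays represented, so the number of combinations is
#' `prod(2^m_k - 1)` for `m_k` qualified models in cell line `k`.
#'
#' @param models List of qualified `base_model`s (every cell line with at
#'   least one).
#' @param max_combinations Safety cap (default 1e6).
#' @return List of [ensemble_model()] objects.
#' @export
enumerate_model_combinations <- function(models, max_combinations = 1e6) {
  lines <- vapply(models, function(m) m$cell_line, character(1))
  groups <- split(models, lines)
  groups <- groups[sort_c(names(groups))]
  m <- vapply(groups, length, integer(1))
  if (any(m == 0)) stop2("a cell line has no qualified models")
  total <- prod(2^m - 1)
  if (total > max_combinations) {
    stop2("combination space too large: ", total, " > ", max_combinations)
  }
  subsets_per_line <- lapply(groups, function(g) {
    idx <- seq_along(g)
    subs <- list()
    for (size in idx) {
      ch <- combn(idx, size, simplify = FALSE)
      subs <- c(subs, lapply(ch, function(s) g[s]))
    }
    subs
  })
  grid <- expand.grid(lapply(subsets_per_line, seq_along))
  combos <- lapply(seq_len(nrow(grid)), function(r) {
    members <- unlist(lapply(seq_along(subsets_per_line), function(lk) {
      subsets_per_line[[lk]][[grid[r, lk]]]
    }), recursive = FALSE)
    ensemble_model(members)
  })
  combos
}

#' Select the best model combination on a screening set
#'
#' Ranks a labeled screening set with every candidate combination and keeps
#' the combination with the best early-recognition profile: primary criterion
#' BEDROC at `alpha`, ties broken by EF at `chi`, then by AUC. Member-model
#' scores are computed once and shared across combinations.
#'
#' @param combinations List of [ensemble_model()]s (e.g. from
#'   [enumerate_model_combinations()]).
#' @param table Descriptor matrix of the screening set.
#' @param active Logical active flags aligned with the rows of `table`.
#' @param chi,theta,z,alpha Metric settings; `alpha` defaults to
#'   [solve_alpha()] of `theta` and `z`.
#' @param seed RNG seed for score computation.
#' @return List with `best` (the winning `ensemble_model`), `best_index`, and
#'   `table` (one audit row per combination: members, BEDROC, EF, AUC).
#' @export
select_best_combination <- function(combinations, table, active, chi = 0.01,
                                    theta = 0.80, z = 0.01, alpha = NULL,
                                    seed = 1) {
  stopifnot(length(combinations) >= 1, nrow(table) == length(active))
  active <- as.logical(active)
  if (!any(active) || all(active)) {
    stop2("screening set needs at least one active and one inactive")
  }
  alpha <- alpha %||% solve_alpha(theta, z)
  all_ids <- unique(unlist(lapply(combinations, member_ids)))
  pool <- list()
  for (cmb in combinations) {
    for (m in unlist(cmb$groups, recursive = FALSE)) pool[[m$model_id]] <- m
  }
  S <- .member_scores(pool[all_ids], table, seed = seed)
  ids <- rownames(table) %||% as.character(seq_len(nrow(table)))
  eval_one <- function(cmb) {
    dmat <- vapply(names(cmb$groups), function(ln) {
      mid <- vapply(cmb$groups[[ln]], function(m) m$model_id, character(1))
      cell_line_desirability(S[, mid, drop = FALSE])
    }, numeric(nrow(table)))
    D1 <- global_desirability(matrix(dmat, nrow = nrow(table)))
    ord <- order_c(-D1, ids)
    rl <- ranked_list(ids[ord], active[ord])
    c(BEDROC = bedroc(rl, alpha), EF = enrichment_factor(rl, chi),
      AUC = auc(rl))
  }
  res <- t(vapply(combinations, eval_one, numeric(3)))
  audit <- data.frame(
    combination = seq_along(combinations),
    members = vapply(combinations, function(cmb) {
      paste(sort_c(member_ids(cmb)), collapse = "+")
    }, character(1)),
    BEDROC = res[, "BEDROC"], EF = res[, "EF"], AUC = res[, "AUC"],
    stringsAsFactors = FALSE
  )
  best <- order(-audit$BEDROC, -audit$EF, -audit$AUC, audit$combination)[1]
  list(best = combinations[[best]], best_index = best, table = audit,
       alpha = alpha)
}
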