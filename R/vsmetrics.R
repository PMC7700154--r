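# Early-recognition metrics for ranked screening lists.
#
# AUC = 1 - mean relative rank of the actives; EF at fraction chi with the
# ceiling cutoff k = ceil(chi * N); BEDROC = (RIE - RIEmin)/(RIEmax - RIEmin)
# where RIE is the exponentially weighted hit sum and RIEmin/RIEmax are the
# RIE values of the worst and best possible orderings (closed-form geometric
# sums), so BEDROC is exactly 1 for a list with all actives on top and
# exactly 0 with all actives at the bottom. The weighting parameter alpha is
# the positive root of theta * (1 - e^-alpha) - 1 + e^(-alpha z) = 0, tying
# the expected contribution theta of the top z fraction to the weights.

#' Construct a ranked list
#'
#' @param ids Compound ids, best-ranked first.
#' @param active Logical active flags aligned with `ids`.
#' @return An object of class `ranked_list` with fields `ids`, `active`, `N`,
#'   `n`, `ranks` (1-based ranks of the actives) and `x` (relative ranks).
#' @export
ranked_list <- function(ids, active) {
  stopifnot(length(ids) == length(active))
  active <- as.logical(active)
  if (anyNA(active)) stop2("active flags must be TRUE/FALSE")
  ranks <- which(active)
  structure(list(ids = as.character(ids), active = active,
                 N = length(ids), n = length(ranks),
                 ranks = ranks, x = ranks / length(ids)),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("<ranked_list> N = %d, n = %d actives\n", x$N, x$n))
  invisible(x)
}

#' Area under the accumulation curve
#'
#' `AUC = 1 - (1/n) * sum(x_i)` with `x_i` the relative rank of active `i`.
#'
#' @param ranked A [ranked_list()].
#' @return AUC value.
#' @examples
#' auc(make_ranked_fixture(10, 2, c(1, 2)))  # 0.85
#' @export
auc <- function(ranked) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (ranked$n == 0) stop2("AUC undefined: no actives in the list")
  1 - mean(ranked$x)
}

#' Enrichment factor
#'
#' Ratio of the active-retrieval rate in the top `chi` fraction of the list
#' (cutoff `k = ceiling(chi * N)` positions) to the rate expected under
#' uniform ranking: `EF = (a / n) / (k / N)` with `a` actives among the top
#' `k`.
#'
#' @param ranked A [ranked_list()].
#' @param chi Fraction of the list, in (0, 1].
#' @return EF value (>= 0); `EF = 1` at `chi = 1` for any list.
#' @export
enrichment_factor <- function(ranked, chi) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (!is.numeric(chi) || length(chi) != 1 || chi <= 0 || chi > 1) {
    stop2("chi must lie in (0, 1]")
  }
  if (ranked$n == 0) stop2("EF undefined: no actives in the list")
  k <- ceiling(chi * ranked$N)
  a <- sum(ranked$ranks <= k)
  (a / ranked$n) / (k / ranked$N)
}

# exponentially weighted hit sum, shared by bedroc()
.rie <- function(x, n, N, alpha) {
  mean(exp(-alpha * x)) / ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
}

#' BEDROC early-recognition score
#'
#' Boltzmann-enhanced discrimination of ROC: the exponentially weighted hit
#' sum RIE, normalized by its extrema over orderings so the score lies in
#' [0, 1] (exactly 1 when all actives occupy the top `n` ranks, exactly 0
#' when they occupy the bottom `n`).
#'
#' @param ranked A [ranked_list()] with `0 < n < N`.
#' @param alpha Positive early-recognition weight (see [solve_alpha()]).
#' @return BEDROC value in [0, 1].
#' @export
bedroc <- function(ranked, alpha) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    stop2("alpha must be a positive number")
  }
  N <- ranked$N; n <- ranked$n
  if (n == 0 || n == N) stop2("BEDROC undefined for n = 0 or n = N")
  rie <- .rie(ranked$x, n, N, alpha)
  rie_max <- .rie(seq_len(n) / N, n, N, alpha)
  rie_min <- .rie((N - n + seq_len(n)) / N, n, N, alpha)
  (rie - rie_min) / (rie_max - rie_min)
}

#' Solve for the BEDROC alpha parameter
#'
#' Finds the positive root of
#' `theta * (1 - e^-alpha) - 1 + e^(-alpha * z) = 0`,
#' which calibrates alpha so that the top `z` fraction of the list accounts
#' for the expected contribution `theta` of the total weight. Solved by
#' bracketed root-finding, polished to a residual below 1e-10.
#'
#' @param theta Expected contribution at the `z` fraction, in (0, 1);
#'   default 0.80 (the conventional calibration).
#' @param z List fraction at which enrichment matters, in (0, 1); default 0.01.
#' @return The positive root alpha.
#' @examples
#' solve_alpha(0.80, 0.01)  # about 160.9
#' @export
solve_alpha <- function(theta = 0.80, z = 0.01) {
  stopifnot(theta > 0, theta < 1, z > 0, z < 1)
  if (theta <= z) stop2("no positive root: theta must exceed z")
  f <- function(a) theta * (1 - exp(-a)) - 1 + exp(-a * z)
  lo <- 1e-8
  hi <- 10
  while (f(hi) > 0 && hi < 1e12) hi <- hi * 10
  if (f(hi) > 0) stop2("no sign change found while bracketing the root")
  root <- uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  # Newton polish for a residual below 1e-10
  fp <- function(a) theta * exp(-a) - z * exp(-a * z)
  for (i in 1:20) {
    r <- f(root)
    if (abs(r) < 1e-12) break
    root <- root - r / fp(root)
  }
  if (abs(f(root)) > 1e-10) stop2("alpha solver failed to reach tolerance")
  root
}

#' Accumulation curve
#'
#' Fraction of actives retrieved as a function of the fraction of the list
#' screened; a monotone step curve from (0, 0) to (1, 1).
#'
#' @param ranked A [ranked_list()] with at least one active.
#' @return Data frame with columns `fraction_screened` and
#'   `fraction_retrieved`.
#' @export
accumulation_curve <- function(ranked) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (ranked$n == 0) stop2("accumulation curve undefined: no actives")
  data.frame(
    fraction_screened = c(0, seq_len(ranked$N) / ranked$N),
    fraction_retrieved = c(0, cumsum(ranked$active) / ranked$n)
  )
}

#' Full early-recognition report
#'
#' @param ranked A [ranked_list()].
#' @param chi EF fraction (default 0.01).
#' @param theta,z Alpha calibration (defaults 0.80 and 0.01); ignored when
#'   `alpha` is given.
#' @param alpha Early-recognition weight; solved from `theta`/`z` when `NULL`.
#' @return An `early_recognition_report`: list with `AUC`, `EF`, `BEDROC`,
#'   `alpha`, `theta`, `z`, `chi`, `Ra`, `RIE`, `RIE_min`, `RIE_max`.
#' @export
early_recognition_report <- function(ranked, chi = 0.01, theta = 0.80,
                                     z = 0.01, alpha = NULL) {
  alpha <- alpha %||% solve_alpha(theta, z)
  N <- ranked$N; n <- ranked$n
  structure(list(
    AUC = auc(ranked),
    EF = enrichment_factor(ranked, chi),
    BEDROC = bedroc(ranked, alpha),
    alpha = alpha, theta = theta, z = z, chi = chi,
    Ra = n / N,
    RIE = .rie(ranked$x, n, N, alpha),
    RIE_min = .rie((N - n + seq_len(n)) / N, n, N, alpha),
    RIE_max = .rie(seq_len(n) / N, n, N, alpha)
  ), class = "early_recognition_report")
}

#' @export
print.early_recognition_report <- function(x, ...) {
  cat(sprintf("AUC %.3f  EF(%.2g) %.2f  BEDROC(alpha = %.4g) %.3f\n",
              x$AUC, x$chi, x$EF, x$alpha, x$BEDROC))
  invisible(x)
}

#' Read/write ranked lists
#'
#' `read_ranked_list()` reads a TSV with columns `rank`, `compound_id`,
#' `score`, `is_active`; `write_ranked_list()` writes one.
#'
#' @param path TSV path.
#' @return A `ranked_list` (read) or `path` invisibly (write).
#' @export
read_ranked_list <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  df <- df[order(df$rank), , drop = FALSE]
  ranked_list(df$compound_id, as.logical(df$is_active))
}

#' @rdname read_ranked_list
#' @param ranked A `ranked_list`.
#' @param scores Optional score column.
#' @export
write_ranked_list <- function(ranked, path, scores = NULL) {
  df <- data.frame(rank = seq_len(ranked$N), compound_id = ranked$ids,
                   score = scores %||% rev(seq_len(ranked$N)) / ranked$N,
                   is_active = ranked$active)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
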