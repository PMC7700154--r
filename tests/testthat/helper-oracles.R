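# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive everything from first principles (recursive
# enumeration, literal formula evaluation) and share no code with R/.

# ---- fragment oracles -------------------------------------------------------

oracle_adjacency <- function(g) {
  n <- nrow(g$atoms)
  A <- matrix(FALSE, n, n)
  if (nrow(g$bonds)) {
    A[cbind(g$bonds$i, g$bonds$j)] <- TRUE
    A[cbind(g$bonds$j, g$bonds$i)] <- TRUE
  }
  A
}

oracle_atom_sym <- function(g) paste0(g$atoms$symbol, ifelse(g$atoms$aromatic, "a", ""))

oracle_bond_sym <- function(g) {
  n <- nrow(g$atoms)
  B <- matrix(NA_character_, n, n)
  if (nrow(g$bonds)) {
    s <- ifelse(g$bonds$aromatic, "~", c("-", "=", "#")[pmin(g$bonds$order, 3)])
    B[cbind(g$bonds$i, g$bonds$j)] <- s
    B[cbind(g$bonds$j, g$bonds$i)] <- s
  }
  B
}

# recursive exhaustive enumeration of all simple paths of exactly len atoms
oracle_all_paths <- function(A, len) {
  n <- nrow(A)
  res <- list()
  recurse <- function(path) {
    if (length(path) == len) {
      res[[length(res) + 1L]] <<- path
      return(invisible())
    }
    last <- path[length(path)]
    for (w in seq_len(n)) {
      if (A[last, w] && !(w %in% path)) recurse(c(path, w))
    }
  }
  for (s in seq_len(n)) recurse(s)
  res
}

oracle_sequence_counts <- function(g, min_len = 2, max_len = 8) {
  A <- oracle_adjacency(g)
  asym <- oracle_atom_sym(g)
  B <- oracle_bond_sym(g)
  render <- function(p) {
    out <- asym[p[1]]
    for (k in seq_along(p)[-1]) out <- paste0(out, B[p[k - 1], p[k]], asym[p[k]])
    out
  }
  labels <- character(0)
  for (len in min_len:max_len) {
    for (p in oracle_all_paths(A, len)) {
      # undirected: count each path once
      if (p[1] < p[length(p)]) {
        f <- render(p); r <- render(rev(p))
        labels <- c(labels, if (r < f) r else f)
      }
    }
  }
  if (!length(labels)) return(setNames(integer(0), character(0)))
  tt <- table(labels)
  out <- as.integer(tt); names(out) <- names(tt)
  out[sort(names(out), method = "radix")]
}

# Floyd-Warshall shortest paths (independent of the package's BFS)
oracle_distances <- function(g) {
  n <- nrow(g$atoms)
  D <- matrix(Inf, n, n); diag(D) <- 0
  if (nrow(g$bonds)) {
    D[cbind(g$bonds$i, g$bonds$j)] <- 1
    D[cbind(g$bonds$j, g$bonds$i)] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

oracle_triplet_counts <- function(g) {
  n <- nrow(g$atoms)
  if (n < 3) return(setNames(integer(0), character(0)))
  D <- oracle_distances(g)
  asym <- oracle_atom_sym(g)
  labels <- character(0)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ds <- c(D[i, j], D[i, k], D[j, k])
    if (any(is.infinite(ds))) next
    comp <- c(
      paste0(asym[i], "(", min(D[i, j], D[i, k]), ",", max(D[i, j], D[i, k]), ")"),
      paste0(asym[j], "(", min(D[i, j], D[j, k]), ",", max(D[i, j], D[j, k]), ")"),
      paste0(asym[k], "(", min(D[i, k], D[j, k]), ",", max(D[i, k], D[j, k]), ")")
    )
    labels <- c(labels, paste(sort(comp, method = "radix"), collapse = "."))
  }
  if (!length(labels)) return(setNames(integer(0), character(0)))
  tt <- table(labels)
  out <- as.integer(tt); names(out) <- names(tt)
  out[sort(names(out), method = "radix")]
}

# ---- information-theoretic oracles ------------------------------------------

# plug-in MI from an explicit 2x2 table, in nats
oracle_mi <- function(x, y) {
  x <- as.integer(x != 0); y <- as.integer(y != 0)
  n <- length(x)
  mi <- 0
  for (a in 0:1) for (b in 0:1) {
    nij <- sum(x == a & y == b)
    if (nij > 0) {
      mi <- mi + (nij / n) * log(n * nij / (sum(x == a) * sum(y == b)))
    }
  }
  mi
}

# literal re-evaluation of the greedy MIQ rule: at each step score every
# remaining feature and take the maximum (ties: higher relevance, then label)
oracle_mrmr <- function(X, y, k) {
  X <- (X > 0) * 1
  labs <- colnames(X)
  rel <- vapply(seq_len(ncol(X)), function(j) oracle_mi(X[, j], y), numeric(1))
  selected <- integer(0)
  for (step in seq_len(min(k, ncol(X)))) {
    remaining <- setdiff(seq_len(ncol(X)), selected)
    score <- vapply(remaining, function(j) {
      if (!length(selected)) return(rel[j])
      red <- mean(vapply(selected, function(s) oracle_mi(X[, j], X[, s]),
                         numeric(1)))
      if (red < 1e-12) min(rel[j] / 1e-12, 1e15) else rel[j] / red
    }, numeric(1))
    ord <- order(-signif(score, 12), -signif(rel[remaining], 12),
                 match(labs[remaining], sort(labs[remaining], method = "radix")))
    selected <- c(selected, remaining[ord[1]])
  }
  labs[selected]
}

# ---- BEDROC literal oracle ---------------------------------------------------

# literal evaluation of the exponentially weighted formulation, with the
# extrema evaluated as explicit sums over the best/worst rank vectors
oracle_bedroc <- function(ranks, n, N, alpha) {
  rie_of <- function(r) {
    (sum(exp(-alpha * r / N)) / n) /
      ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  }
  rie <- rie_of(ranks)
  rie_max <- rie_of(1:n)
  rie_min <- rie_of((N - n + 1):N)
  (rie - rie_min) / (rie_max - rie_min)
}

# ---- misc helpers ------------------------------------------------------------

# tiny labeled dataset with one perfectly informative feature and noise
toy_signal_dataset <- function(n = 60, p = 10, flips = 3, seed = 1,
                               cell_line = "TOY") {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    X <- matrix(rbinom(n * p, 1, 0.5), n, p,
                dimnames = list(NULL, paste0("f", sprintf("%02d", 1:p))))
    X[, 1] <- y
    if (flips > 0) {
      fl <- sample(n, flips)
      X[fl, 1] <- 1L - X[fl, 1]
    }
    labeled_dataset(sprintf("T%03d", 1:n), X, y, cell_line)
  })
}

# minimal stand-in for a qualified base model (combination enumeration only;
# carries no fitted learner)
stub_model <- function(cell_line, learner, qualified = TRUE) {
  structure(list(cell_line = cell_line, learner = learner,
                 features = "S:C-C", metrics = list(AC = 0.9),
                 qualified = qualified,
                 model_id = paste(cell_line, learner, sep = "-")),
            class = "base_model")
}
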