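# 2D substructural fragment descriptors.
#
# Three fragment families over the molecular graph, in the spirit of
# sequence/atom-centered/triplet substructural counts:
#   * sequences  -- simple paths of 2..8 atoms, labeled by alternating
#                   atom and bond symbols, each undirected path counted once;
#   * atom-centered -- per atom, the sorted concatenation of the labels of all
#                   simple paths rooted at that atom (variable length up to
#                   max_len, or exactly fixed_length for the fixed variant);
#   * triplets   -- unordered atom triples labeled by the three atom symbols
#                   together with the pairwise topological distances,
#                   canonicalized by sorting.
#
# Label alphabet: element symbol with an "a" suffix for aromatic atoms;
# bond symbols "-" single, "=" double, "#" triple, "~" aromatic. A path label
# is rendered forward and reversed and the lexicographically smaller string
# is kept, so labels are independent of atom numbering.

atom_symbol <- function(g) {
  paste0(g$atoms$symbol, ifelse(g$atoms$aromatic, "a", ""))
}

bond_symbol_matrix <- function(g) {
  n <- nrow(g$atoms)
  B <- matrix(NA_character_, n, n)
  if (nrow(g$bonds)) {
    sym <- ifelse(g$bonds$aromatic, "~",
                  c("-", "=", "#")[pmin(g$bonds$order, 3L)])
    B[cbind(g$bonds$i, g$bonds$j)] <- sym
    B[cbind(g$bonds$j, g$bonds$i)] <- sym
  }
  B
}

# All simple paths (as atom index vectors) starting at `root` with
# 2..max_len atoms. Iterative DFS over the adjacency list.
.paths_from <- function(adj, root, max_len) {
  out <- list()
  # stack of partial paths
  stack <- list(root)
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    last <- p[length(p)]
    for (w in adj[[last]]) {
      if (w %in% p) next
      q <- c(p, w)
      out[[length(out) + 1L]] <- q
      if (length(q) < max_len) stack[[length(stack) + 1L]] <- q
    }
  }
  out
}

.path_label <- function(path, asym, B) {
  k <- length(path)
  parts <- character(2 * k - 1)
  parts[seq(1, 2 * k - 1, by = 2)] <- asym[path]
  if (k > 1) {
    parts[seq(2, 2 * k - 2, by = 2)] <- B[cbind(path[-k], path[-1])]
  }
  paste(parts, collapse = "")
}

.canon_path_label <- function(path, asym, B) {
  f <- .path_label(path, asym, B)
  r <- .path_label(rev(path), asym, B)
  if (r < f) r else f
}

as_mol_graph <- function(x) {
  if (inherits(x, "mol_graph")) return(x)
  if (is.character(x) && length(x) == 1) return(mol_from_smiles(x))
  stop2("expected a mol_graph or a single SMILES string")
}

#' Enumerate sequence fragments
#'
#' Counts all simple paths of `min_len` to `max_len` atoms in the molecular
#' graph, each undirected path counted once, labeled by alternating atom and
#' bond symbols (canonicalized over the two reading directions).
#'
#' @param g A `mol_graph` (see [mol_from_smiles()]) or a SMILES string.
#' @param min_len,max_len Path length bounds in atoms (defaults 2 and 8).
#' @return Named integer vector: fragment label -> count.
#' @examples
#' enumerate_sequence_fragments("CCC")  # C-C x2, C-C-C x1
#' @export
enumerate_sequence_fragments <- function(g, min_len = 2, max_len = 8) {
  g <- as_mol_graph(g)
  stopifnot(min_len >= 2, max_len >= min_len)
  n <- nrow(g$atoms)
  if (n < 2 || nrow(g$bonds) == 0) return(setNames(integer(0), character(0)))
  adj <- adjacency_list(g)
  asym <- atom_symbol(g)
  B <- bond_symbol_matrix(g)
  labels <- character(0)
  for (root in seq_len(n)) {
    for (p in .paths_from(adj, root, max_len)) {
      # each undirected path is produced twice (once from each end);
      # keep the traversal whose endpoints are in increasing index order
      if (length(p) >= min_len && p[1] < p[length(p)]) {
        labels[length(labels) + 1L] <- .canon_path_label(p, asym, B)
      }
    }
  }
  .count_labels(labels)
}

#' Enumerate atom-centered fragments
#'
#' For every atom, collects the labels of all simple paths rooted at that atom
#' (read outward from the root) with 2..`max_len` atoms -- or exactly
#' `fixed_length` atoms for the fixed-length variant -- sorts them, and emits
#' their concatenation as a single centered-fragment label. An isolated atom
#' contributes a label encoding only the center.
#'
#' @param g A `mol_graph` or SMILES string.
#' @param max_len Maximum path length in atoms for the variable-length variant.
#' @param fixed_length If non-`NULL`, only paths with exactly this many atoms
#'   contribute (must lie in 2..8).
#' @return Named integer vector: centered-fragment label -> count.
#' @export
enumerate_atom_centered_fragments <- function(g, max_len = 8, fixed_length = NULL) {
  g <- as_mol_graph(g)
  if (!is.null(fixed_length)) {
    if (!is_count(fixed_length) || fixed_length < 2 || fixed_length > 8) {
      stop2("fixed_length must be an integer in [2, 8]")
    }
  }
  n <- nrow(g$atoms)
  if (n == 0) return(setNames(integer(0), character(0)))
  adj <- adjacency_list(g)
  asym <- atom_symbol(g)
  B <- bond_symbol_matrix(g)
  lim <- if (is.null(fixed_length)) max_len else fixed_length
  labels <- vapply(seq_len(n), function(root) {
    paths <- .paths_from(adj, root, lim)
    if (!is.null(fixed_length)) {
      paths <- paths[vapply(paths, length, integer(1)) == fixed_length]
    }
    if (!length(paths)) return(asym[root])
    br <- vapply(paths, .path_label, character(1), asym = asym, B = B)
    paste0(asym[root], "[", paste(sort_c(br), collapse = "|"), "]")
  }, character(1))
  .count_labels(labels)
}

#' Enumerate triplet fragments
#'
#' For every unordered triple of atoms lying in one connected component, emits
#' a label built from the three atom symbols and the three pairwise
#' topological (shortest-path) distances: each atom contributes
#' `symbol(d1,d2)` with its two sorted incident distances, and the three
#' contributions are sorted and joined. Triples spanning disconnected parts
#' are skipped.
#'
#' @param g A `mol_graph` or SMILES string.
#' @return Named integer vector: triplet label -> count.
#' @export
enumerate_triplet_fragments <- function(g) {
  g <- as_mol_graph(g)
  n <- nrow(g$atoms)
  if (n < 3) return(setNames(integer(0), character(0)))
  D <- topological_distances(g)
  asym <- atom_symbol(g)
  tri <- combn(n, 3)
  d12 <- D[cbind(tri[1, ], tri[2, ])]
  d13 <- D[cbind(tri[1, ], tri[3, ])]
  d23 <- D[cbind(tri[2, ], tri[3, ])]
  ok <- is.finite(d12) & is.finite(d13) & is.finite(d23)
  if (!any(ok)) return(setNames(integer(0), character(0)))
  part <- function(sym_idx, da, db) {
    paste0(asym[sym_idx], "(", pmin(da, db), ",", pmax(da, db), ")")
  }
  p1 <- part(tri[1, ok], d12[ok], d13[ok])
  p2 <- part(tri[2, ok], d12[ok], d23[ok])
  p3 <- part(tri[3, ok], d13[ok], d23[ok])
  # sort the three components per triple via integer codes (radix order)
  lev <- sort_c(unique(c(p1, p2, p3)))
  M <- cbind(match(p1, lev), match(p2, lev), match(p3, lev))
  lo <- pmin(M[, 1], M[, 2], M[, 3])
  hi <- pmax(M[, 1], M[, 2], M[, 3])
  mid <- M[, 1] + M[, 2] + M[, 3] - lo - hi
  labels <- paste(lev[lo], lev[mid], lev[hi], sep = ".")
  .count_labels(labels)
}

.count_labels <- function(labels) {
  if (!length(labels)) return(setNames(integer(0), character(0)))
  tt <- table(labels)
  out <- as.integer(tt)
  names(out) <- names(tt)
  out[sort_c(names(out))]
}

#' Fragmentation configuration
#'
#' @param sequences,atom_centered,atom_centered_fixed,triplets Enable the
#'   corresponding fragment family.
#' @param min_len,max_len Sequence length bounds in atoms.
#' @param fixed_length Path length for the fixed atom-centered variant.
#' @return A list of class `fragment_config`.
#' @export
fragment_config <- function(sequences = TRUE, atom_centered = TRUE,
                            atom_centered_fixed = FALSE, triplets = TRUE,
                            min_len = 2, max_len = 8, fixed_length = 3) {
  structure(list(sequences = sequences, atom_centered = atom_centered,
                 atom_centered_fixed = atom_centered_fixed, triplets = triplets,
                 min_len = min_len, max_len = max_len,
                 fixed_length = fixed_length),
            class = "fragment_config")
}

.fragment_counts_one <- function(g, config) {
  out <- list()
  if (config$sequences) {
    v <- enumerate_sequence_fragments(g, config$min_len, config$max_len)
    if (length(v)) names(v) <- paste0("S:", names(v))
    out$S <- v
  }
  if (config$atom_centered) {
    v <- enumerate_atom_centered_fragments(g, max_len = config$max_len)
    if (length(v)) names(v) <- paste0("AC:", names(v))
    out$AC <- v
  }
  if (config$atom_centered_fixed) {
    v <- enumerate_atom_centered_fragments(g, fixed_length = config$fixed_length)
    if (length(v)) names(v) <- paste0("ACF:", names(v))
    out$ACF <- v
  }
  if (config$triplets) {
    v <- enumerate_triplet_fragments(g)
    if (length(v)) names(v) <- paste0("T:", names(v))
    out$T <- v
  }
  unlist(unname(out))
}

#' Build the sparse descriptor table
#'
#' Computes fragment counts for every compound and assembles the sparse
#' compounds-by-fragments count matrix. Column labels carry a family prefix
#' (`S:`, `AC:`, `ACF:`, `T:`) and are ordered lexicographically; rows follow
#' the input compound order. Identical structures yield identical rows.
#'
#' @param compounds Data frame with `compound_id` and `smiles` (standardized),
#'   or a character vector of SMILES.
#' @param config A [fragment_config()].
#' @return A `descriptor_table`: sparse non-negative integer count matrix
#'   (class `dgCMatrix`) with compound ids as row names and fragment labels as
#'   column names.
#' @export
build_descriptor_table <- function(compounds, config = fragment_config()) {
  if (is.character(compounds)) {
    compounds <- data.frame(compound_id = as.character(seq_along(compounds)),
                            smiles = compounds, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("compound_id", "smiles") %in% names(compounds)))
  ids <- compounds$compound_id
  smi <- compounds$smiles
  if (nrow(compounds) == 0) {
    m <- Matrix::Matrix(0, 0, 0, sparse = TRUE)
    return(structure(m, class = class(m)))
  }
  uniq <- unique(smi)
  counts <- lapply(uniq, function(s) {
    g <- mol_from_smiles(s)
    .fragment_counts_one(g, config)
  })
  all_labels <- sort_c(unique(unlist(lapply(counts, names))))
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  rowmap <- match(smi, uniq)
  for (r in seq_along(ids)) {
    v <- counts[[rowmap[r]]]
    if (length(v)) {
      jj <- c(jj, match(names(v), all_labels))
      ii <- c(ii, rep.int(r, length(v)))
      xx <- c(xx, unname(v))
    }
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(ids), length(all_labels)),
                            dimnames = list(ids, all_labels))
  m
}

#' Write a descriptor table
#'
#' Writes the sparse count matrix as MatrixMarket (`.mtx`) with row/column
#' label sidecar TSVs, or as a dense CSV for small tables.
#'
#' @param table Descriptor matrix from [build_descriptor_table()].
#' @param path Output path stem (extensions are appended).
#' @param format `"mtx"` or `"csv"`.
#' @return Invisibly, the paths written.
#' @export
write_descriptor_table <- function(table, path, format = c("mtx", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    p <- paste0(path, ".csv")
    df <- as.data.frame(as.matrix(table))
    df <- cbind(compound_id = rownames(table), df)
    write.table(df, p, sep = ",", quote = FALSE, row.names = FALSE)
    return(invisible(p))
  }
  p <- paste0(path, ".mtx")
  Matrix::writeMM(methods::as(table, "dgCMatrix"), p)
  pl <- paste0(path, ".labels.tsv")
  write.table(data.frame(kind = c(rep("row", nrow(table)), rep("col", ncol(table))),
                         label = c(rownames(table), colnames(table))),
              pl, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p, pl))
}
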