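# Molecular graph backend.
#
# SMILES parsing, canonicalization and SMARTS matching are delegated to
# OpenBabel through ChemmineR/ChemmineOB. The package works on a light
# molecular-graph representation (heavy atoms + bonds) extracted from the
# V2000 connection table that OpenBabel produces for a canonical SMILES;
# aromatic atom flags are recovered from the lowercase atom tokens of the
# canonical SMILES itself (OpenBabel preserves atom order in the conversion).

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical SMILES. Invalid inputs yield `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of the same length; `NA` where the input did not
#'   parse to a molecule.
#' @examples
#' canonical_smiles(c("OCC", "C1CC"))
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  idx <- which(ok)
  src <- paste(paste0(trimws(smiles[idx]), "\tq", seq_along(idx)), collapse = "\n")
  res <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", source = src))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    can <- vapply(parts, `[`, character(1), 1L)
    tag <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, character(1))
    pos <- match(tag, paste0("q", seq_along(idx)))
    keep <- !is.na(pos) & nzchar(can)
    out[idx[pos[keep]]] <- can[keep]
  }
  out
}

# MDL V2000 old-style charge codes -> formal charge
.chg_code <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)

# Lex the atom tokens of a SMILES string in order: bracket atoms first, then
# two-letter aromatic metalloids/halogens, then the organic subset. Returns
# element symbol, aromatic flag and formal charge per atom.
.smiles_atom_tokens <- function(smiles) {
  pat <- "\\[[^]]*\\]|Cl|Br|se|as|[BCNOPSFI]|[bcnops]"
  m <- gregexpr(pat, smiles)[[1]]
  empty <- data.frame(element = character(0), aromatic = logical(0),
                      charge = integer(0))
  if (m[1] == -1) return(empty)
  tok <- regmatches(smiles, gregexpr(pat, smiles))[[1]]
  rows <- lapply(tok, function(t) {
    if (startsWith(t, "[")) {
      body <- sub("^\\[\\d*", "", sub("\\]$", "", t))
      el <- regmatches(body, regexpr("^([A-Z][a-z]?|se|as|[a-z])", body))
      chg <- 0L
      cm <- regmatches(body, regexpr("[+-]\\d*$|\\++$|-+$", body))
      if (length(cm)) {
        chg <- if (grepl("^[+-]\\d+$", cm)) {
          as.integer(cm)
        } else {
          nchar(cm) * if (startsWith(cm, "+")) 1L else -1L
        }
      }
      arom <- grepl("^[a-z]", el)
      data.frame(element = paste0(toupper(substr(el, 1, 1)), substring(el, 2)),
                 aromatic = arom, charge = chg)
    } else {
      arom <- grepl("^[a-z]", t)
      data.frame(element = if (arom) toupper(t) else t,
                 aromatic = arom, charge = 0L)
    }
  })
  do.call(rbind, rows)
}

.smiles_atom_aromatic <- function(smiles) {
  .smiles_atom_tokens(smiles)$aromatic
}

.sdf_to_graph <- function(sdf, aromatic_atoms = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  sym <- sub("_\\d+$", "", rownames(ab))
  n <- length(sym)
  charge <- integer(n)
  if ("C6" %in% colnames(ab)) {
    code <- as.character(ab[, "C6"])
    charge <- unname(ifelse(code %in% names(.chg_code), .chg_code[code], 0L))
  }
  # ChemmineR renders an empty bond block as a 1 x 2 zero matrix
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
    data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    b <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                    order = as.integer(bb[, 3]))
    b[b$i >= 1 & b$j >= 1, , drop = FALSE]
  }
  # drop explicit hydrogens if the writer emitted any
  if (any(sym == "H")) {
    keep <- which(sym != "H")
    remap <- match(seq_len(n), keep)
    bonds <- bonds[bonds$i %in% keep & bonds$j %in% keep, , drop = FALSE]
    bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    sym <- sym[keep]; charge <- charge[keep]
    if (!is.null(aromatic_atoms)) aromatic_atoms <- aromatic_atoms[keep]
    n <- length(sym)
  }
  arom <- if (is.null(aromatic_atoms)) logical(n) else aromatic_atoms
  if (length(arom) != n) arom <- logical(n)
  g <- list(atoms = data.frame(symbol = sym, aromatic = arom, charge = charge,
                               stringsAsFactors = FALSE),
            bonds = bonds)
  class(g) <- "mol_graph"
  g$bonds$aromatic <- .aromatic_bonds(g)
  g
}

# A bond is flagged aromatic when both endpoints are aromatic and the bond
# lies on a cycle (rules out e.g. the biphenyl bridge bond).
.aromatic_bonds <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0) return(logical(0))
  both <- g$atoms$aromatic[g$bonds$i] & g$atoms$aromatic[g$bonds$j]
  out <- logical(nb)
  adj <- adjacency_list(g)
  for (b in which(both)) {
    out[b] <- .connected_without_edge(adj, g$bonds$i[b], g$bonds$j[b])
  }
  out
}

.connected_without_edge <- function(adj, i, j) {
  # BFS from i to j skipping the direct i-j edge once
  seen <- logical(length(adj))
  seen[i] <- TRUE
  queue <- i
  first <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nxt <- adj[[v]]
    if (v == i && first) { nxt <- nxt[nxt != j]; first <- FALSE }
    nxt <- nxt[!seen[nxt]]
    if (j %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  FALSE
}

#' Build a molecular graph from a SMILES string
#'
#' Parses a SMILES string into the package's light molecular-graph
#' representation: a data frame of heavy atoms (element symbol, aromatic
#' flag, formal charge) and a data frame of bonds (atom indices, bond order,
#' aromatic flag). Aromaticity follows OpenBabel's perception.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `mol_graph`.
#' @examples
#' g <- mol_from_smiles("c1ccccc1O")
#' g$atoms
#' @export
mol_from_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop2("SMILES does not parse to a valid molecule: ", smiles)
  tokens <- .smiles_atom_tokens(can)
  if (nrow(tokens) == 1) {
    # single heavy atom: the SDF connection table is degenerate, build directly
    g <- list(atoms = data.frame(symbol = tokens$element,
                                 aromatic = tokens$aromatic,
                                 charge = tokens$charge,
                                 stringsAsFactors = FALSE),
              bonds = data.frame(i = integer(0), j = integer(0),
                                 order = integer(0), aromatic = logical(0)))
    class(g) <- "mol_graph"
  } else {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(can))
    g <- .sdf_to_graph(sdf[[1]], aromatic_atoms = tokens$aromatic)
  }
  attr(g, "smiles") <- can
  g
}

# Parse many SMILES at once; returns a list of mol_graph (NULL where invalid).
mols_from_smiles <- function(smiles) {
  lapply(smiles, function(s) {
    tryCatch(mol_from_smiles(s), error = function(e) NULL)
  })
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms, %d bonds", nrow(x$atoms), nrow(x$bonds)))
  if (!is.null(attr(x, "smiles"))) cat("  ", attr(x, "smiles"))
  cat("\n")
  invisible(x)
}

adjacency_list <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer(0)
  if (nrow(g$bonds)) {
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[b]; j <- g$bonds$j[b]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# Unweighted all-pairs shortest path matrix (Inf across components).
topological_distances <- function(g) {
  n <- nrow(g$atoms)
  adj <- adjacency_list(g)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(D[s, w])) {
          D[s, w] <- D[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  D
}

connected_components <- function(g) {
  n <- nrow(g$atoms)
  comp <- integer(n)
  adj <- adjacency_list(g)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nxt <- adj[[v]][comp[adj[[v]]] == 0L]
        comp[nxt] <- cur
        queue <- c(queue, nxt)
      }
    }
  }
  comp
}

#' Count substructure matches with SMARTS
#'
#' @param smiles Character vector of SMILES.
#' @param smarts A single SMARTS pattern.
#' @return Logical vector: does each molecule contain the substructure?
#' @export
has_substructure <- function(smiles, smarts) {
  stopifnot(is.character(smiles), length(smarts) == 1)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  suppressWarnings(ChemmineR::cid(sdf) <- paste0("m", seq_along(smiles)))
  cnt <- ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = FALSE)
  unname(cnt > 0)
}
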