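# Synthetic study generator.
#
# Produces download-free fixtures that emulate the shape of a ChEMBL-style
# activity export and a screening library: valence-valid small organic
# molecules assembled from a template grammar (rings, chains, common
# substituents), a planted substructure-driven activity signal per
# pseudo-cell-line (members of the pharmacophore substructure receive assay
# values below 10 uM, non-members above, with label flips at a configurable
# noise rate), property-matched decoys at roughly 50 per active, and ranked
# lists with actives at prescribed positions for metric tests.

.SUBSTITUENTS <- c(
  "C", "CC", "CCC", "C(C)C", "O", "OC", "OCC", "N", "NC", "N(C)C",
  "Cl", "F", "Br", "I", "C#N", "C(=O)C", "C(=O)O", "C(=O)OC", "C(=O)N",
  "[N+](=O)[O-]", "S", "SC", "C(F)(F)F", "CO", "CCO", "C=C"
)

# ring cores: atom symbols plus the positions a substituent may occupy
.CORES <- list(
  list(kind = "ring", atoms = c("c", "c", "c", "c", "c", "c"), slots = 1:5),
  list(kind = "ring", atoms = c("c", "c", "c", "n", "c", "c"), slots = c(1:3, 5)),
  list(kind = "ring", atoms = c("c", "c", "c", "c", "o"), slots = 1:4),
  list(kind = "ring", atoms = c("C", "C", "C", "C", "C", "C"), slots = 1:5),
  list(kind = "ring", atoms = c("C", "C", "C", "C", "C"), slots = 1:4),
  list(kind = "chain", atoms = c("C", "C", "C"), slots = 1:3),
  list(kind = "chain", atoms = c("C", "C", "C", "C"), slots = 1:4),
  list(kind = "chain", atoms = c("C", "C", "C", "C", "C", "C"), slots = 1:6)
)

.assemble_smiles <- function(core, subs) {
  n <- length(core$atoms)
  parts <- character(n)
  for (i in seq_len(n)) {
    a <- core$atoms[i]
    ring_digit <- if (core$kind == "ring" && (i == 1 || i == n)) "1" else ""
    branch <- if (nzchar(subs[i])) paste0("(", subs[i], ")") else ""
    # never substitute the ring-closing atom
    if (core$kind == "ring" && i == n) branch <- ""
    parts[i] <- paste0(a, ring_digit, branch)
  }
  paste(parts, collapse = "")
}

#' Generate a synthetic molecule library
#'
#' Assembles `n` valence-valid molecules from a template grammar: a ring or
#' chain core decorated with 0-3 substituents drawn from a fixed set of
#' common organic groups. All molecules parse and standardize cleanly.
#'
#' @param n Number of molecules.
#' @param seed RNG seed; identical seeds give identical libraries.
#' @param id_prefix Prefix for the generated compound ids.
#' @param motif Optional substituent SMILES planted on a fraction of the
#'   molecules (used to seed a pharmacophore signal).
#' @param motif_frac Fraction of molecules that receive `motif`.
#' @return Data frame with `compound_id` and `smiles`.
#' @export
generate_library <- function(n, seed = 1, id_prefix = "SYN", motif = NULL,
                             motif_frac = 0) {
  if (!is_count(n) || n < 1) stop2("n must be a positive integer")
  withr::with_seed(seed, {
    smiles <- vapply(seq_len(n), function(i) {
      core <- .CORES[[sample.int(length(.CORES), 1)]]
      subs <- rep("", length(core$atoms))
      n_sub <- sample(0:3, 1, prob = c(0.15, 0.35, 0.3, 0.2))
      n_sub <- min(n_sub, length(core$slots))
      if (n_sub > 0) {
        where <- sample(core$slots, n_sub)
        subs[where] <- sample(.SUBSTITUENTS, n_sub, replace = TRUE)
      }
      if (!is.null(motif) && runif(1) < motif_frac) {
        slot <- sample(core$slots, 1)
        subs[slot] <- motif
      }
      .assemble_smiles(core, subs)
    }, character(1))
    data.frame(compound_id = sprintf("%s%05d", id_prefix, seq_len(n)),
               smiles = smiles, stringsAsFactors = FALSE)
  })
}

#' Plant a substructure-driven activity signal
#'
#' Emits one activity record per molecule: molecules containing the
#' pharmacophore substructure draw a standard value from the active range
#' (below 10 uM), the rest from the inactive range (above 10 uM), with labels
#' flipped at `noise_rate`. Values are drawn log-uniformly and never equal
#' exactly 10 uM. Assay types are sampled from IC50/GI50/EC50.
#'
#' @param library Data frame with `compound_id` and `smiles`.
#' @param pharmacophore SMARTS pattern defining the planted signal.
#' @param noise_rate Label-flip probability, in [0, 0.5).
#' @param cell_line Cell-line tag for the records.
#' @param active_range,inactive_range Value ranges in uM (must exclude 10).
#' @param seed RNG seed.
#' @return Activity-record data frame (`compound_id`, `smiles`, `cell_line`,
#'   `assay_type`, `standard_value`) with attributes `member` (substructure
#'   membership) and `label` (the planted class after noise).
#' @export
plant_activity_signal <- function(library, pharmacophore, noise_rate = 0.05,
                                  cell_line = "CL1",
                                  active_range = c(0.05, 8),
                                  inactive_range = c(12, 500), seed = 1) {
  stopifnot(noise_rate >= 0, noise_rate < 0.5)
  stopifnot(all(active_range < 10), all(inactive_range > 10))
  member <- has_substructure(library$smiles, pharmacophore)
  if (!any(member) || all(member)) {
    stop2("pharmacophore matches ", sum(member), " of ", length(member),
          " molecules: no learnable signal")
  }
  n <- nrow(library)
  withr::with_seed(seed, {
    flip <- runif(n) < noise_rate
    label <- xor(member, flip)
    runif_log <- function(k, range) exp(runif(k, log(range[1]), log(range[2])))
    value <- numeric(n)
    value[label] <- runif_log(sum(label), active_range)
    value[!label] <- runif_log(sum(!label), inactive_range)
    out <- data.frame(compound_id = library$compound_id,
                      smiles = library$smiles,
                      cell_line = cell_line,
                      assay_type = sample(ASSAY_TYPES, n, replace = TRUE),
                      standard_value = value,
                      stringsAsFactors = FALSE)
    attr(out, "member") <- member
    attr(out, "label") <- as.integer(label)
    out
  })
}

.simple_properties <- function(smiles) {
  graphs <- mols_from_smiles(smiles)
  bad <- vapply(graphs, is.null, logical(1))
  if (any(bad)) stop2(sum(bad), " molecules failed to parse for property matching")
  t(vapply(graphs, function(g) {
    n_heavy <- nrow(g$atoms)
    n_bonds <- nrow(g$bonds)
    n_comp <- length(unique(connected_components(g)))
    c(heavy_atoms = n_heavy,
      rings = n_bonds - n_heavy + n_comp,
      hetero_fraction = mean(!g$atoms$symbol %in% c("C", "H")))
  }, numeric(3)))
}

#' Generate property-matched decoys
#'
#' For each active, selects the `n_per_active` pool molecules nearest in a
#' simple graph-derived property space (heavy-atom count, ring count,
#' heteroatom fraction; scaled by the pool's spread), excluding pool
#' molecules whose standardized structure equals any active. The union over
#' actives is deduplicated.
#'
#' @param actives Character vector of active SMILES (or a data frame with a
#'   `smiles` column).
#' @param pool Data frame with `compound_id` and `smiles`.
#' @param n_per_active Decoys per active (default 50).
#' @param seed Kept for interface symmetry; selection is deterministic
#'   (distance ties broken by compound id).
#' @return Data frame of unique decoys (`compound_id`, `smiles`) with
#'   attribute `per_active`: the ids matched to each active.
#' @export
generate_decoys <- function(actives, pool, n_per_active = 50, seed = 1) {
  if (is.data.frame(actives)) actives <- actives$smiles
  act_std <- vapply(actives, function(s) standardize_structure(s), character(1),
                    USE.NAMES = FALSE)
  pool_std <- standardize_structures(pool$smiles, pool$compound_id)
  eligible <- !(pool_std$smiles_std %in% act_std) & !is.na(pool_std$smiles_std)
  if (sum(eligible) < n_per_active) {
    stop2("decoy pool too small: ", sum(eligible), " eligible molecules, need ",
          n_per_active, " per active (shortfall ", n_per_active - sum(eligible), ")")
  }
  P_act <- .simple_properties(act_std)
  P_pool <- .simple_properties(pool_std$smiles_std[eligible])
  sc <- apply(P_pool, 2, stats::sd)
  sc[sc == 0 | !is.finite(sc)] <- 1
  pool_ids <- pool$compound_id[eligible]
  per_active <- lapply(seq_along(act_std), function(a) {
    d <- sqrt(colSums(((t(P_pool) - P_act[a, ]) / sc)^2))
    pool_ids[order_c(d, pool_ids)][seq_len(n_per_active)]
  })
  ids <- sort_c(unique(unlist(per_active)))
  out <- pool[match(ids, pool$compound_id), c("compound_id", "smiles")]
  rownames(out) <- NULL
  attr(out, "per_active") <- per_active
  out
}

#' Construct a ranked-list fixture
#'
#' Builds a [ranked_list()] of `N` compounds with actives exactly at the given
#' 1-based ranks.
#'
#' @param N List length.
#' @param n Number of actives.
#' @param active_positions Integer set of ranks (length `n`, within 1..N,
#'   no duplicates).
#' @return A `ranked_list`.
#' @examples
#' make_ranked_fixture(772, 14, c(1, 2, 3, 5, 100 + 1:10))
#' @export
make_ranked_fixture <- function(N, n, active_positions) {
  stopifnot(is_count(N), N >= 1)
  active_positions <- as.integer(active_positions)
  if (anyDuplicated(active_positions)) stop2("duplicate active positions")
  if (length(active_positions) != n) stop2("need exactly n active positions")
  if (any(active_positions < 1 | active_positions > N)) {
    stop2("active positions must lie in 1..N")
  }
  active <- logical(N)
  active[active_positions] <- TRUE
  ranked_list(sprintf("CMP%05d", seq_len(N)), active)
}

# pharmacophore motifs used by synthetic_study(); substituent SMILES to plant
# and the SMARTS that detects it
.MOTIFS <- list(
  list(name = "nitro", sub = "[N+](=O)[O-]", smarts = "[N+](=O)[O-]"),
  list(name = "carboxyl", sub = "C(=O)O", smarts = "C(=O)[OX2H1]"),
  list(name = "trifluoromethyl", sub = "C(F)(F)F", smarts = "C(F)(F)F"),
  list(name = "nitrile", sub = "C#N", smarts = "C#N"),
  list(name = "sulfide", sub = "SC", smarts = "[#16X2][CH3]"),
  list(name = "dimethylamino", sub = "N(C)C", smarts = "[NX3](C)C")
)

#' Generate a complete synthetic study
#'
#' Builds the full input set of a multi-cell-line screening study: one
#' molecule library and activity table per pseudo-cell-line with a planted
#' pharmacophore signal (distinct but chemically overlapping motifs across
#' lines), a panel of multi-target reference actives carrying every line's
#' pharmacophore (withheld from modeling via the blocklist, they seed the
#' virtual-screening set), and property-matched decoys drawn from a separate
#' pharmacophore-free pool at `n_decoys_per_active` per reference compound.
#'
#' @param n_compounds Compounds per cell line (default 300).
#' @param n_cell_lines Number of pseudo-cell-lines (default 3, max 6).
#' @param noise_rate Label-flip rate of the planted signal (default 0.05).
#' @param n_reference Number of withheld multi-target actives (default 10).
#' @param n_decoys_per_active Decoys per reference active (default 50).
#' @param pool_size Size of the decoy candidate pool (default 1200).
#' @param motif_frac Fraction of library molecules that receive the line's
#'   pharmacophore substituent (default 0.45).
#' @param seed Master seed; regeneration with the same seed is byte-identical.
#' @return An object of class `synthetic_study`.
#' @export
synthetic_study <- function(n_compounds = 300, n_cell_lines = 3,
                            noise_rate = 0.05, n_reference = 10,
                            n_decoys_per_active = 50, pool_size = 1200,
                            motif_frac = 0.45, seed = 1) {
  if (n_cell_lines < 1 || n_cell_lines > length(.MOTIFS)) {
    stop2("n_cell_lines must lie in 1..", length(.MOTIFS))
  }
  motifs <- .MOTIFS[seq_len(n_cell_lines)]
  cell_lines <- list()
  for (i in seq_len(n_cell_lines)) {
    lib <- generate_library(n_compounds, seed = seed + 101L * i,
                            id_prefix = sprintf("L%d_", i),
                            motif = motifs[[i]]$sub, motif_frac = motif_frac)
    act <- plant_activity_signal(lib, motifs[[i]]$smarts,
                                 noise_rate = noise_rate,
                                 cell_line = paste0("CL", i),
                                 seed = seed + 101L * i + 1L)
    cell_lines[[paste0("CL", i)]] <- list(pharmacophore = motifs[[i]]$smarts,
                                          motif = motifs[[i]]$sub,
                                          library = lib, activity = act)
  }
  # multi-target reference actives: every line's motif on one scaffold
  reference <- withr::with_seed(seed + 7777L, {
    smi <- vapply(seq_len(n_reference), function(r) {
      core <- .CORES[[sample(c(1L, 4L), 1)]]  # six-membered rings
      subs <- rep("", length(core$atoms))
      slots <- sample(core$slots, length(motifs))
      for (m in seq_along(motifs)) subs[slots[m]] <- motifs[[m]]$sub
      free <- setdiff(core$slots, slots)
      if (length(free) && runif(1) < 0.7) {
        subs[sample(free, 1)] <- sample(.SUBSTITUENTS, 1)
      }
      .assemble_smiles(core, subs)
    }, character(1))
    data.frame(compound_id = sprintf("REF%03d", seq_len(n_reference)),
               smiles = smi, stringsAsFactors = FALSE)
  })
  # reference records are appended to every cell line's activity table
  for (ln in names(cell_lines)) {
    val <- withr::with_seed(seed + 887L + match(ln, names(cell_lines)), {
      exp(runif(n_reference, log(0.05), log(8)))
    })
    ref_rec <- data.frame(compound_id = reference$compound_id,
                          smiles = reference$smiles, cell_line = ln,
                          assay_type = "IC50", standard_value = val,
                          stringsAsFactors = FALSE)
    act <- cell_lines[[ln]]$activity
    member <- attr(act, "member"); labl <- attr(act, "label")
    act <- rbind(act, ref_rec)
    attr(act, "member") <- member; attr(act, "label") <- labl
    cell_lines[[ln]]$activity <- act
  }
  pool <- generate_library(pool_size, seed = seed + 33333L, id_prefix = "P")
  hits <- Reduce(`|`, lapply(motifs, function(m) {
    has_substructure(pool$smiles, m$smarts)
  }))
  pool <- pool[!hits, , drop = FALSE]
  decoys <- generate_decoys(reference, pool,
                            n_per_active = n_decoys_per_active, seed = seed)
  structure(list(cell_lines = cell_lines, reference = reference,
                 decoys = decoys, decoy_pool = pool,
                 blocklist = reference$compound_id,
                 noise_rate = noise_rate, seed = seed,
                 params = list(n_compounds = n_compounds,
                               n_cell_lines = n_cell_lines,
                               n_reference = n_reference,
                               n_decoys_per_active = n_decoys_per_active,
                               pool_size = pool_size,
                               motif_frac = motif_frac)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d cell lines x %d compounds, noise %.2f, seed %s\n",
              length(x$cell_lines), x$params$n_compounds, x$noise_rate,
              format(x$seed)))
  cat(sprintf("  %d reference actives, %d decoys (pool %d)\n",
              nrow(x$reference), nrow(x$decoys), nrow(x$decoy_pool)))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits the same CSV / SMILES formats the curation module consumes:
#' one activity CSV per cell line, the screening components as `.smi` files
#' and the blocklist as a plain text file.
#'
#' @param study A [synthetic_study()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ln in names(study$cell_lines)) {
    p <- file.path(dir, paste0("activity_", ln, ".csv"))
    write.table(study$cell_lines[[ln]]$activity, p, sep = ",", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  wsmi <- function(df, name) {
    p <- file.path(dir, name)
    writeLines(paste(df$smiles, df$compound_id, sep = "\t"), p)
    p
  }
  paths <- c(paths,
             wsmi(study$reference, "reference.smi"),
             wsmi(study$decoys, "decoys.smi"),
             wsmi(study$decoy_pool, "decoy_pool.smi"))
  pb <- file.path(dir, "blocklist.txt")
  writeLines(study$blocklist, pb)
  invisible(c(paths, pb))
}
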