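# Activity-table ingestion, structure standardization, activity labeling and
# deduplication.
#
# Curation mirrors common ChEMBL-export practice: assay records (IC50 / GI50 /
# EC50 standard values in micromolar) are mapped to a binary activity class
# with a 10 uM threshold, conflicting replicate assays are resolved by a
# strict >75% majority vote, structures are standardized (salt stripping,
# nitro normalization, canonical aromatic form) and duplicates merged before
# classification so that label conflicts between duplicates are resolved by
# the same majority rule.

ASSAY_TYPES <- c("IC50", "GI50", "EC50")

#' Default dialect for activity tables
#'
#' Maps the package's record fields to column names of a delimited activity
#' table and fixes the field separator.
#'
#' @param sep Field separator; `NULL` infers from the file extension
#'   (`.csv` is comma, anything else tab).
#' @param compound_id,smiles,cell_line,assay_type,standard_value Column names.
#' @return A list usable as the `dialect` argument of [parse_activity_table()].
#' @export
activity_dialect <- function(sep = NULL, compound_id = "compound_id",
                             smiles = "smiles", cell_line = "cell_line",
                             assay_type = "assay_type",
                             standard_value = "standard_value") {
  list(sep = sep, compound_id = compound_id, smiles = smiles,
       cell_line = cell_line, assay_type = assay_type,
       standard_value = standard_value)
}

#' Parse an activity table
#'
#' Reads a CSV/TSV activity table into validated activity records. Every row
#' either yields a record or a logged rejection; rows with a missing id or
#' SMILES, a missing/non-positive/non-numeric standard value, or an assay type
#' outside IC50/GI50/EC50 are rejected with a reason code.
#'
#' @param path Path to the table.
#' @param dialect Column mapping, see [activity_dialect()].
#' @return A list with `records` (data frame: compound_id, smiles, cell_line,
#'   assay_type, standard_value in uM) and `rejections` (data frame: row,
#'   compound_id, reason).
#' @export
parse_activity_table <- function(path, dialect = activity_dialect()) {
  if (!file.exists(path)) stop2("activity table not found: ", path)
  sep <- dialect$sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    quote = "\"", comment.char = "", check.names = FALSE)
  need <- c(dialect$compound_id, dialect$smiles, dialect$cell_line,
            dialect$assay_type, dialect$standard_value)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop2("activity table lacks mapped columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(
    compound_id = as.character(raw[[dialect$compound_id]]),
    smiles = as.character(raw[[dialect$smiles]]),
    cell_line = as.character(raw[[dialect$cell_line]]),
    assay_type = toupper(trimws(as.character(raw[[dialect$assay_type]]))),
    standard_value_raw = as.character(raw[[dialect$standard_value]]),
    stringsAsFactors = FALSE
  )
  val <- suppressWarnings(as.numeric(df$standard_value_raw))
  reason <- rep(NA_character_, nrow(df))
  bad_id <- is.na(df$compound_id) | !nzchar(trimws(df$compound_id))
  bad_smi <- is.na(df$smiles) | !nzchar(trimws(df$smiles))
  bad_val <- is.na(val) | val <= 0
  bad_assay <- !(df$assay_type %in% ASSAY_TYPES)
  reason[bad_assay] <- "unknown_assay_type"
  reason[bad_val] <- "missing_or_nonpositive_value"
  reason[bad_smi] <- "missing_smiles"
  reason[bad_id] <- "missing_id"
  keep <- is.na(reason)
  records <- data.frame(
    compound_id = trimws(df$compound_id[keep]),
    smiles = trimws(df$smiles[keep]),
    cell_line = trimws(df$cell_line[keep]),
    assay_type = df$assay_type[keep],
    standard_value = val[keep],
    stringsAsFactors = FALSE
  )
  rejections <- data.frame(row = which(!keep),
                           compound_id = df$compound_id[!keep],
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  list(records = records, rejections = rejections)
}

# Locate neutral nitro groups on a kekulized connection table: uncharged N
# with two terminal O neighbours attached by double bonds.
.find_neutral_nitro <- function(g) {
  deg <- integer(nrow(g$atoms))
  if (nrow(g$bonds)) {
    t1 <- table(c(g$bonds$i, g$bonds$j))
    deg[as.integer(names(t1))] <- as.integer(t1)
  }
  hits <- list()
  for (a in which(g$atoms$symbol == "N" & g$atoms$charge == 0L)) {
    bsel <- which((g$bonds$i == a | g$bonds$j == a) & g$bonds$order == 2L)
    if (length(bsel) < 2) next
    other <- ifelse(g$bonds$i[bsel] == a, g$bonds$j[bsel], g$bonds$i[bsel])
    term_o <- bsel[g$atoms$symbol[other] == "O" & deg[other] == 1L]
    if (length(term_o) >= 2) {
      oxy <- ifelse(g$bonds$i[term_o] == a, g$bonds$j[term_o], g$bonds$i[term_o])
      pick <- which.min(oxy)
      hits[[length(hits) + 1L]] <- list(n = a, bond = term_o[pick], o = oxy[pick])
    }
  }
  hits
}

.normalize_nitro <- function(can) {
  # cheap prefilter: pattern needs an N and a double-bonded O
  if (!grepl("N", can) || !grepl("=O|O=", can)) return(can)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(can))[[1]]
  g <- .sdf_to_graph(sdf)
  hits <- .find_neutral_nitro(g)
  if (!length(hits)) return(can)
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (!"C6" %in% colnames(ab)) stop2("unexpected atom block layout")
  for (h in hits) {
    bb[h$bond, 3] <- 1
    ab[h$n, "C6"] <- 3   # +1
    ab[h$o, "C6"] <- 5   # -1
  }
  edited <- new("SDF", header = ChemmineR::header(sdf), atomblock = ab,
                bondblock = bb, datablock = ChemmineR::datablock(sdf))
  smi <- as.character(suppressWarnings(
    ChemmineR::sdf2smiles(new("SDFset", SDF = list(edited), ID = "x"))))
  out <- canonical_smiles(smi)
  if (is.na(out)) can else out
}

.heavy_atoms <- function(g) sum(g$atoms$symbol != "H")

#' Standardize a chemical structure
#'
#' Produces the canonical standardized form of a SMILES string: explicit
#' hydrogens are folded in, the largest organic covalent fragment is kept
#' (salt/small-fragment stripping), neutral nitro spellings are rewritten to
#' the charge-separated representation, aromatic rings are perceived, and the
#' result is an OpenBabel canonical SMILES. The operation is idempotent.
#'
#' Largest-fragment ties are broken by heavy-atom count, then by the
#' lexicographic order of the fragment's canonical SMILES.
#'
#' @param smiles A single SMILES string.
#' @param id Optional identifier used in error messages.
#' @return The standardized canonical SMILES (character scalar).
#' @examples
#' standardize_structure("CCO.Cl")
#' @export
standardize_structure <- function(smiles, id = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  can <- canonical_smiles(smiles)
  if (is.na(can)) {
    stop2("SMILES does not parse to a valid molecule",
          if (!is.null(id)) paste0(" [id: ", id, "]") else "", ": ", smiles)
  }
  comps <- strsplit(can, ".", fixed = TRUE)[[1]]
  if (length(comps) > 1) {
    cc <- canonical_smiles(comps)
    ok <- !is.na(cc)
    cc <- cc[ok]
    graphs <- mols_from_smiles(cc)
    valid <- !vapply(graphs, is.null, logical(1))
    cc <- cc[valid]; graphs <- graphs[valid]
    if (!length(cc)) {
      stop2("no parsable covalent fragment",
            if (!is.null(id)) paste0(" [id: ", id, "]") else "", ": ", smiles)
    }
    organic <- vapply(graphs, function(g) any(g$atoms$symbol == "C"), logical(1))
    pool <- if (any(organic)) which(organic) else seq_along(cc)
    heavy <- vapply(graphs, .heavy_atoms, numeric(1))
    ord <- pool[order_c(-heavy[pool], cc[pool])]
    can <- cc[ord[1]]
  }
  .normalize_nitro(can)
}

#' Standardize a batch of SMILES
#'
#' Vectorized wrapper around [standardize_structure()] that collects failures
#' instead of stopping.
#'
#' @param smiles Character vector of SMILES.
#' @param ids Optional identifiers (defaults to the index).
#' @return Data frame with columns `compound_id`, `smiles`, `smiles_std`
#'   (`NA` on failure) and `reason` (`NA` on success).
#' @export
standardize_structures <- function(smiles, ids = NULL) {
  ids <- ids %||% as.character(seq_along(smiles))
  uniq <- unique(smiles)
  std <- vapply(uniq, function(s) {
    tryCatch(standardize_structure(s), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  m <- match(smiles, uniq)
  data.frame(compound_id = ids, smiles = smiles, smiles_std = std[m],
             reason = ifelse(is.na(std[m]), "unparsable_smiles", NA_character_),
             stringsAsFactors = FALSE)
}

#' Assign a binary activity class from assay values
#'
#' Each assay value below 10 uM votes "active" (1), each value above 10 uM
#' votes "inactive" (0); a value of exactly 10 uM is unclassifiable and is
#' excluded from the vote. With several assays the majority class is accepted
#' only when its share strictly exceeds 75%, otherwise the compound is
#' rejected (`NA`).
#'
#' @param values Numeric vector of standard values in uM for one compound and
#'   cell line.
#' @param threshold Activity threshold in uM (default 10).
#' @param majority Strict share a majority class must exceed (default 0.75).
#' @return `1L` (active), `0L` (inactive) or `NA_integer_` (rejected).
#' @examples
#' assign_activity_class(5)                    # active
#' assign_activity_class(c(1, 2, 3, 4, 40))    # 0.8 share -> active
#' assign_activity_class(c(1, 2, 3, 40))       # 0.75 share -> rejected
#' @export
assign_activity_class <- function(values, threshold = 10, majority = 0.75) {
  stopifnot(length(values) >= 1, is.numeric(values))
  cls <- ifelse(values < threshold, 1L, ifelse(values > threshold, 0L, NA_integer_))
  cls <- cls[!is.na(cls)]
  if (!length(cls)) return(NA_integer_)
  share_active <- mean(cls == 1L)
  if (share_active > majority) return(1L)
  if ((1 - share_active) > majority) return(0L)
  NA_integer_
}

#' Merge duplicate structures and classify
#'
#' Groups standardized activity records by canonical SMILES within each cell
#' line, merges the assay values of duplicates *before* class assignment (so
#' label conflicts between duplicate structures resolve through the strict
#' 75% majority rule) and returns one classified compound per structure.
#'
#' @param records Data frame of activity records carrying a `smiles_std`
#'   column (see [standardize_structures()]).
#' @param threshold,majority Passed to [assign_activity_class()].
#' @return A list with `compounds` (compound_id, smiles, cell_line, label,
#'   n_records, merged_ids) and `rejections` (compound_id, cell_line, reason).
#'   The representative `compound_id` is the lexicographically smallest merged
#'   id.
#' @export
deduplicate_compounds <- function(records, threshold = 10, majority = 0.75) {
  stopifnot(all(c("compound_id", "smiles_std", "cell_line", "standard_value")
                %in% names(records)))
  if (any(is.na(records$smiles_std))) {
    stop2("records contain unstandardized structures; run standardize_structures() first")
  }
  key <- paste(records$cell_line, records$smiles_std, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  groups <- groups[sort_c(names(groups))]
  rows <- lapply(groups, function(ix) {
    ids <- sort_c(unique(records$compound_id[ix]))
    lab <- assign_activity_class(records$standard_value[ix],
                                 threshold = threshold, majority = majority)
    data.frame(compound_id = ids[1],
               smiles = records$smiles_std[ix[1]],
               cell_line = records$cell_line[ix[1]],
               label = lab,
               n_records = length(ix),
               merged_ids = paste(ids, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(compound_id = character(0), smiles = character(0),
                      cell_line = character(0), label = integer(0),
                      n_records = integer(0), merged_ids = character(0))
  }
  rej <- out[is.na(out$label), c("compound_id", "cell_line"), drop = FALSE]
  rej$reason <- if (nrow(rej)) "ambiguous_activity_class" else character(0)
  list(compounds = out[!is.na(out$label), , drop = FALSE],
       rejections = rej)
}

#' Curate an activity record set end to end
#'
#' Standardizes structures, merges duplicates, assigns activity classes and
#' applies an optional blocklist of withheld reference compounds (matched by
#' id or by standardized structure) after deduplication. Withheld compounds
#' are returned separately so they can seed a virtual-screening set.
#'
#' @param records Activity records as returned by [parse_activity_table()].
#' @param blocklist Character vector of compound ids and/or SMILES to withhold.
#' @param threshold,majority Passed to [assign_activity_class()].
#' @return List with `compounds`, `withheld` and `rejections` data frames.
#' @export
curate_compounds <- function(records, blocklist = NULL, threshold = 10,
                             majority = 0.75) {
  std <- standardize_structures(records$smiles, records$compound_id)
  records$smiles_std <- std$smiles_std
  bad <- is.na(records$smiles_std)
  rej_parse <- data.frame(compound_id = records$compound_id[bad],
                          cell_line = records$cell_line[bad],
                          reason = rep("unparsable_smiles", sum(bad)),
                          stringsAsFactors = FALSE)
  dd <- deduplicate_compounds(records[!bad, , drop = FALSE],
                              threshold = threshold, majority = majority)
  compounds <- dd$compounds
  withheld <- compounds[0, , drop = FALSE]
  if (!is.null(blocklist) && nrow(compounds)) {
    merged <- strsplit(compounds$merged_ids, ",", fixed = TRUE)
    hit_id <- vapply(merged, function(m) any(m %in% blocklist), logical(1))
    # entries not matched as ids are treated as SMILES
    as_smiles <- setdiff(blocklist, unlist(merged))
    block_smi <- suppressWarnings(
      vapply(as_smiles, function(b) {
        tryCatch(standardize_structure(b), error = function(e) NA_character_)
      }, character(1), USE.NAMES = FALSE))
    hit_smi <- compounds$smiles %in% block_smi[!is.na(block_smi)]
    hit <- hit_id | hit_smi
    withheld <- compounds[hit, , drop = FALSE]
    compounds <- compounds[!hit, , drop = FALSE]
  }
  list(compounds = compounds, withheld = withheld,
       rejections = rbind(rej_parse, dd$rejections))
}

#' Read a compound library
#'
#' Reads a screening library from a SMILES file (one `SMILES<TAB>id` per
#' line) or an SDF V2000 file.
#'
#' @param path File path; format chosen by extension (`.sdf` vs anything else).
#' @return Data frame with `compound_id` and `smiles`.
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop2("library file not found: ", path)
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    sdf <- ChemmineR::read.SDFset(path)
    smi <- as.character(suppressWarnings(ChemmineR::sdf2smiles(sdf)))
    ids <- ChemmineR::sdfid(sdf)
    if (any(!nzchar(ids)) || anyDuplicated(ids)) ids <- paste0("SDF", seq_along(smi))
    return(data.frame(compound_id = ids, smiles = smi, stringsAsFactors = FALSE))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  data.frame(
    compound_id = vapply(seq_along(parts), function(k) {
      if (length(parts[[k]]) >= 2) parts[[k]][2] else paste0("SMI", k)
    }, character(1)),
    smiles = vapply(parts, `[`, character(1), 1L),
    stringsAsFactors = FALSE
  )
}

#' Write curated compounds and rejection log
#'
#' @param curated Result of [curate_compounds()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_curated <- function(curated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "curated_compounds.tsv")
  p2 <- file.path(dir, "rejections.tsv")
  write.table(curated$compounds, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(curated$rejections, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
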