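# Activity-table parsing, structure standardization, activity labeling,
# deduplication.

write_activity_csv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c("compound_id,smiles,cell_line,assay_type,standard_value", rows),
             path)
  path
}

test_that("well-formed rows become records and numeric values parse", {
  p <- write_activity_csv(c("A1,CCO,HOS,IC50,5",
                            "A2,CCN,HOS,GI50,12.5",
                            "A3,CCC,MG63,EC50,5e0"))
  out <- parse_activity_table(p)
  expect_equal(nrow(out$records), 3)
  expect_equal(nrow(out$rejections), 0)
  expect_equal(out$records$standard_value, c(5, 12.5, 5))
})

test_that("incomplete or invalid rows are rejected with logged reasons", {
  p <- write_activity_csv(c("A1,,HOS,IC50,5",        # missing smiles
                            ",CCO,HOS,IC50,5",        # missing id
                            "A3,CCO,HOS,KD,5",        # unknown assay
                            "A4,CCO,HOS,IC50,-2",     # nonpositive value
                            "A5,CCO,HOS,IC50,oops",   # non-numeric value
                            "A6,CCO,HOS,IC50,7"))
  out <- parse_activity_table(p)
  expect_equal(nrow(out$records), 1)
  expect_equal(out$records$compound_id, "A6")
  expect_setequal(out$rejections$reason,
                  c("missing_smiles", "missing_id", "unknown_assay_type",
                    "missing_or_nonpositive_value"))
  expect_error(parse_activity_table(tempfile()), "not found")
})

test_that("standardization strips salts, keeps benzene, unifies nitro spellings", {
  expect_equal(standardize_structure("CCO.Cl"), "CCO")
  benz <- standardize_structure("c1ccccc1")
  expect_equal(canonical_smiles(benz), benz)
  charged <- standardize_structure("O=[N+]([O-])c1ccccc1")
  neutral <- standardize_structure("O=N(=O)c1ccccc1")
  expect_identical(charged, neutral)
  expect_error(standardize_structure("C1CC", id = "BAD1"), "BAD1")
})

test_that("standardization is idempotent on a generated library", {
  lib <- generate_library(25, seed = 11)
  std1 <- vapply(lib$smiles, standardize_structure, character(1),
                 USE.NAMES = FALSE)
  std2 <- vapply(std1, standardize_structure, character(1), USE.NAMES = FALSE)
  expect_identical(std1, std2)
  # single covalent fragment, no explicit hydrogens
  expect_false(any(grepl(".", std1, fixed = TRUE)))
  expect_false(any(grepl("[H]", std1, fixed = TRUE)))
})

test_that("activity classes follow the 10 uM threshold and strict 75% rule", {
  expect_equal(assign_activity_class(5), 1L)
  expect_equal(assign_activity_class(20), 0L)
  expect_equal(assign_activity_class(c(5, 20)), NA_integer_)       # 0.5 share
  expect_equal(assign_activity_class(c(1, 2, 3, 4, 40)), 1L)       # 0.8 share
  expect_equal(assign_activity_class(c(1, 2, 3, 40)), NA_integer_) # exactly 0.75
  expect_equal(assign_activity_class(c(40, 50, 60, 70, 5)), 0L)
  # a value of exactly 10 uM is unclassifiable and drops out of the vote
  expect_equal(assign_activity_class(10), NA_integer_)
  expect_equal(assign_activity_class(c(10, 5)), 1L)
})

test_that("duplicates merge before classification; conflicts reject", {
  rec <- data.frame(
    compound_id = c("A", "B", "C"),
    smiles = c("OCC", "CCO", "CCN"),
    cell_line = "HOS", assay_type = "IC50",
    standard_value = c(5, 50, 2),
    stringsAsFactors = FALSE
  )
  rec$smiles_std <- standardize_structures(rec$smiles)$smiles_std
  out <- deduplicate_compounds(rec)
  # A and B are the same structure with conflicting assays -> merged, rejected
  expect_equal(nrow(out$compounds), 1)
  expect_equal(out$compounds$compound_id, "C")
  expect_equal(out$rejections$reason, "ambiguous_activity_class")
  expect_equal(out$rejections$compound_id, "A")  # lexicographic representative

  # same structure, agreeing assays -> one compound, ids merged
  rec2 <- rec
  rec2$standard_value <- c(5, 6, 2)
  out2 <- deduplicate_compounds(rec2)
  expect_equal(nrow(out2$compounds), 2)
  expect_equal(out2$compounds$merged_ids[out2$compounds$compound_id == "A"], "A,B")
  expect_equal(out2$compounds$label, c(1L, 1L))
})

test_that("n distinct structures stay distinct and curation is deterministic", {
  lib <- generate_library(12, seed = 3)
  rec <- data.frame(compound_id = lib$compound_id, smiles = lib$smiles,
                    cell_line = "CL", assay_type = "IC50",
                    standard_value = rep(c(2, 30), 6), stringsAsFactors = FALSE)
  c1 <- curate_compounds(rec)
  c2 <- curate_compounds(rec)
  expect_identical(c1, c2)
  expect_equal(nrow(c1$compounds), length(unique(c1$compounds$smiles)))
  expect_true(all(c1$compounds$label %in% c(0L, 1L)))
})

test_that("the blocklist withholds reference compounds after deduplication", {
  rec <- data.frame(compound_id = c("R1", "X1", "X2"),
                    smiles = c("CCO", "CCN", "CCCC"),
                    cell_line = "CL", assay_type = "IC50",
                    standard_value = c(1, 2, 50), stringsAsFactors = FALSE)
  out <- curate_compounds(rec, blocklist = c("R1", "NCC"))  # id + SMILES form
  expect_setequal(out$withheld$compound_id, c("R1", "X1"))
  expect_equal(out$compounds$compound_id, "X2")
})

test_that("SMILES and SDF libraries read back with ids", {
  lib <- generate_library(5, seed = 9)
  smi_path <- withr::local_tempfile(fileext = ".smi")
  writeLines(paste(lib$smiles, lib$compound_id, sep = "\t"), smi_path)
  back <- read_library(smi_path)
  expect_equal(back$compound_id, lib$compound_id)
  expect_equal(canonical_smiles(back$smiles), canonical_smiles(lib$smiles))

  sdf_path <- withr::local_tempfile(fileext = ".sdf")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(lib$smiles))
  suppressWarnings(ChemmineR::cid(sdf) <- lib$compound_id)
  ChemmineR::write.SDF(sdf, sdf_path, cid = TRUE)
  back2 <- read_library(sdf_path)
  expect_equal(nrow(back2), 5)
  expect_equal(canonical_smiles(back2$smiles), canonical_smiles(lib$smiles))
})
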