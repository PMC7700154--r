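# Fragment enumeration and the descriptor table.

test_that("propane sequence fragments match hand enumeration", {
  counts <- enumerate_sequence_fragments("CCC")
  expect_equal(counts[["C-C"]], 2L)
  expect_equal(counts[["C-C-C"]], 1L)
  expect_length(counts, 2)
})

test_that("a single atom yields no sequences; benzene collapses by symmetry", {
  expect_length(enumerate_sequence_fragments("C"), 0)
  benz <- enumerate_sequence_fragments("c1ccccc1", max_len = 2)
  expect_length(benz, 1)
  expect_equal(unname(benz[1]), 6L)          # six equivalent aromatic edges
  expect_match(names(benz), "~")             # aromatic bond symbol
})

test_that("linear alkanes give the closed-form path counts n-k+1", {
  for (n in 4:8) {
    smi <- paste(rep("C", n), collapse = "")
    counts <- enumerate_sequence_fragments(smi)
    for (k in 2:n) {
      lab <- paste(rep("C", k), collapse = "-")
      expect_equal(unname(counts[[lab]]), n - k + 1,
                   info = sprintf("n=%d k=%d", n, k))
    }
  }
})

test_that("atom-centered fragments aggregate rooted branches", {
  counts <- enumerate_atom_centered_fragments("CCC", fixed_length = 2)
  # central atom has two C-C branches, the two terminals one each
  expect_equal(counts[["C[C-C|C-C]"]], 1L)
  expect_equal(counts[["C[C-C]"]], 2L)
  # an isolated atom encodes only the center
  lone <- enumerate_atom_centered_fragments("C")
  expect_equal(unname(lone[["C"]]), 1L)
  expect_error(enumerate_atom_centered_fragments("CCC", fixed_length = 9),
               "fixed_length")
})

test_that("triplets: propane has one, ethane none, benzene three label classes", {
  tp <- enumerate_triplet_fragments("CCC")
  expect_length(tp, 1)
  expect_equal(unname(tp[1]), 1L)
  expect_match(names(tp), "\\(1,1\\)")   # apex atom sees distances {1,1}
  expect_match(names(tp), "\\(1,2\\)")
  expect_length(enumerate_triplet_fragments("CC"), 0)
  benz <- enumerate_triplet_fragments("c1ccccc1")
  expect_length(benz, 3)
  expect_equal(sum(benz), choose(6, 3))
})

test_that("fragment multisets are invariant to atom relabeling", {
  pairs <- list(c("CCO", "OCC"),
                c("Cc1ccccc1", "c1ccc(C)cc1"),
                c("NC(=O)c1ccccc1O", "Oc1ccccc1C(N)=O"))
  for (p in pairs) {
    g1 <- mol_from_smiles(p[1]); g2 <- mol_from_smiles(p[2])
    expect_identical(enumerate_sequence_fragments(g1),
                     enumerate_sequence_fragments(g2))
    expect_identical(enumerate_atom_centered_fragments(g1),
                     enumerate_atom_centered_fragments(g2))
    expect_identical(enumerate_triplet_fragments(g1),
                     enumerate_triplet_fragments(g2))
  }
})

test_that("counts agree with the exhaustive recursive oracle", {
  mols <- c("CCC", "CCO", "c1ccccc1", "CC(C)C", "C1CC1", "c1ccoc1",
            "CC(=O)O", "N#CC=C")
  for (smi in mols) {
    g <- mol_from_smiles(smi)
    expect_identical(enumerate_sequence_fragments(g),
                     oracle_sequence_counts(g), info = smi)
    expect_identical(enumerate_triplet_fragments(g),
                     oracle_triplet_counts(g), info = smi)
  }
})

test_that("descriptor table: identical rows for duplicates, disjoint columns for disjoint chemistry", {
  cmp <- data.frame(compound_id = c("a", "b", "c", "d"),
                    smiles = c("CCCC", "CCCC", "c1ccccc1", "CCO"),
                    stringsAsFactors = FALSE)
  tab <- build_descriptor_table(cmp)
  expect_equal(rownames(tab), cmp$compound_id)
  expect_identical(as.numeric(tab["a", ]), as.numeric(tab["b", ]))
  # butane (alkane) and benzene (pure aromatic) share no sequence fragments
  seq_cols <- grepl("^S:", colnames(tab))
  a_cols <- which(as.numeric(tab["a", ]) > 0 & seq_cols)
  c_cols <- which(as.numeric(tab["c", ]) > 0 & seq_cols)
  expect_length(intersect(a_cols, c_cols), 0)
  # deterministic lexicographic column order
  expect_identical(colnames(tab), sort(colnames(tab), method = "radix"))
  # empty input
  empty <- build_descriptor_table(data.frame(compound_id = character(0),
                                             smiles = character(0)))
  expect_equal(dim(empty), c(0, 0))
})

test_that("family switches control which columns appear", {
  tab <- build_descriptor_table("CCC",
                                fragment_config(atom_centered = FALSE,
                                                triplets = FALSE))
  expect_true(all(startsWith(colnames(tab), "S:")))
  tab2 <- build_descriptor_table("CCC",
                                 fragment_config(sequences = FALSE,
                                                 atom_centered = FALSE,
                                                 atom_centered_fixed = TRUE,
                                                 triplets = FALSE))
  expect_true(all(startsWith(colnames(tab2), "ACF:")))
})
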