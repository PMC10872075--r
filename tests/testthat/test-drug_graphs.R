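test_that("SMILES featurization counts heavy atoms and bonds correctly", {
  g <- featurize_smiles("CCO")
  expect_equal(g$n_atoms, 3L)
  expect_equal(nrow(g$bonds), 2L)
  expect_equal(sort(g$elements), c("C", "C", "O"))
  fn <- graph_feature_names()
  expect_equal(colnames(g$atom_features), fn$atom)
  expect_equal(colnames(g$bond_features), fn$bond)
  # ethanol hydrogens: CH3 (3), CH2 (2), OH (1)
  expect_equal(sum(g$atom_features[, "n_H"]), 6)
})

test_that("featurization is invariant to SMILES spelling", {
  a <- featurize_smiles("CCO")
  b <- featurize_smiles("OCC")
  expect_equal(a$canonical, b$canonical)
  # same multiset of atom feature rows
  expect_equal(sort(a$atom_features[, "degree"]),
               sort(b$atom_features[, "degree"]))
  expect_equal(sort(a$atom_features[, "n_H"]),
               sort(b$atom_features[, "n_H"]))
})

test_that("malformed and empty SMILES are rejected by name", {
  expect_error(featurize_smiles("C("), "unbalanced parentheses")
  expect_error(featurize_smiles("C1CC"), "ring-closure")
  expect_error(featurize_smiles(""), "empty")
  expect_error(featurize_smiles("[C"), "unbalanced brackets")
})

test_that("aromatic perception feeds atom and bond features", {
  g <- featurize_smiles("c1ccccc1")
  expect_equal(sum(g$atom_features[, "aromatic"]), 6)
  expect_equal(sum(g$bond_features[, "bond_aromatic"]), 6)
  expect_equal(sum(g$bond_features[, "in_ring"]), 6)
  h <- featurize_smiles("C1CCCCC1")
  expect_equal(sum(h$atom_features[, "aromatic"]), 0)
  expect_equal(sum(h$bond_features[, "in_ring"]), 6)
})

test_that("ECFP fingerprints are deterministic spelling-invariant bit vectors", {
  f1 <- ecfp("CCO")
  f2 <- ecfp("OCC")
  expect_identical(f1, f2)
  expect_length(f1, 2048L)
  expect_true(all(f1 %in% c(0L, 1L)))
  expect_false(identical(ecfp("C"), f1))
  expect_gt(sum(ecfp("C")), 0)          # even methane sets bits
  expect_error(ecfp(""), "empty")
  # repeated computation is identical (pure function)
  expect_identical(ecfp("Cc1ccccc1O", n_bits = 512), ecfp("Cc1ccccc1O", n_bits = 512))
})

test_that("Murcko scaffolds group ring systems and isolate acyclic molecules", {
  expect_equal(murcko_scaffold("c1ccccc1"), murcko_scaffold("Cc1ccccc1"))
  expect_false(murcko_scaffold("C1CCCCC1") == murcko_scaffold("c1ccccc1"))
  expect_equal(murcko_scaffold("CCO"), "ACYCLIC:CCO")
  # side chains of arbitrary length prune to the same scaffold
  expect_equal(murcko_scaffold("CCCCc1ccc(CC)cc1"), murcko_scaffold("c1ccccc1"))
  # two-ring scaffold retains the linker
  expect_equal(murcko_scaffold("c1ccc(CCc2ccccc2)cc1"),
               murcko_scaffold("Cc1ccc(CCc2ccccc2C)cc1"))
})

test_that("SMARTS matching finds the acryloyl warhead", {
  expect_gt(smarts_matches("C=CC(=O)N1CCCC1", "C=CC(=O)N"), 0)
  expect_equal(smarts_matches("CCO", "C=CC(=O)N"), 0L)
})

test_that("graph encoder latents are invariant to atom order", {
  p <- afp_params(d_hidden = 16L, seed = 3L)
  pairs <- list(
    c("Cc1ccccc1O", "Oc1ccccc1C"),
    c("CC(=O)Nc1ccccc1", "c1ccccc1NC(C)=O"),
    c("N#CCC1CCCC1", "C1CCCC1CC#N"),
    c("CCOC(=O)c1cncc(Br)c1", "Brc1cncc(C(=O)OCC)c1"))
  for (pr in pairs) {
    z1 <- attentivefp_encode(featurize_smiles(pr[1]), p)
    z2 <- attentivefp_encode(featurize_smiles(pr[2]), p)
    expect_lt(max(abs(z1 - z2)), 1e-5)
  }
})

test_that("graph encoder handles degenerate graphs and separates molecules", {
  p <- afp_params(d_hidden = 8L, seed = 5L)
  z <- attentivefp_encode(featurize_smiles("C"), p)    # single atom, no bonds
  expect_all_finite(z)
  zz <- attentivefp_encode(list(featurize_smiles("CCO"),
                                featurize_smiles("c1ccncc1")), p)
  expect_equal(dim(zz), c(2L, 8L))
  expect_gt(max(abs(zz[1, ] - zz[2, ])), 1e-3)
  # batch encoding equals single encoding
  z1 <- attentivefp_encode(featurize_smiles("CCO"), p)
  expect_equal(zz[1, ], z1[1, ], tolerance = 1e-8)
})

test_that("gradients flow to atom features through the encoder", {
  p <- afp_params(d_hidden = 8L, seed = 11L)
  g <- featurize_smiles("CCO")
  batch <- batch_graphs(list(g))
  tape <- drpfuse:::ad_tape()
  P <- lapply(p, function(x) drpfuse:::ad_const(tape, x))
  xn <- drpfuse:::ad_input(tape, batch$atom_features)
  out <- drpfuse:::afp_forward(tape, P, batch, p, atom_input = xn)
  set.seed(1)
  head_w <- matrix(rnorm(8), 8, 1)
  y <- drpfuse:::ad_sum(drpfuse:::ad_matmul(out$latent,
                                            drpfuse:::ad_const(tape, head_w)))
  grad <- drpfuse:::ad_backward(y)(xn)
  expect_all_finite(grad)
  expect_gt(max(abs(grad)), 0)
})
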