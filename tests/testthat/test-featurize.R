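test_that("node features are 31 wide with one hot entry per slot group", {
  slot_groups <- list(element = 1:5, hybridization = 6:11, degree = 12:17,
                      h_count = 18:22, chirality = 23:25, charge = 28:30)
  set.seed(201)
  seqs <- c(AA20, replicate(5, paste(sample(AA20, 6, replace = TRUE),
                                     collapse = "")))
  for (s in seqs) {
    x <- node_features(build_peptide(s))
    expect_equal(ncol(x), 31)
    for (g in slot_groups) {
      expect_true(all(rowSums(x[, g, drop = FALSE]) == 1), info = s)
    }
    expect_true(all(x[, 31] == 0))  # no radicals in canonical peptides
  }
})

test_that("glycine alpha-carbon and hydrogen encodings match template chemistry", {
  m <- build_peptide("G")
  # CA is atom 2 in the backbone template: bonded to N, C and two H
  ca <- node_feature_vector(m, 2)
  expect_equal(ca[1:5], c(0, 1, 0, 0, 0))        # element C
  expect_equal(ca[6:11], c(1, 0, 0, 0, 0, 0))    # SP3
  expect_equal(ca[12:17], c(0, 0, 0, 0, 1, 0))   # degree 4
  expect_equal(ca[18:22], c(0, 0, 1, 0, 0))      # 2 bonded H
  expect_equal(ca[26:27], c(0, 0))               # not aromatic, not in ring
  h_idx <- which(m$atoms$element == "H")[1]
  h <- node_feature_vector(m, h_idx)
  expect_equal(h[1:5], c(1, 0, 0, 0, 0))         # element H
  expect_equal(h[6:11], c(0, 0, 0, 1, 0, 0))     # hybridization "S"
  expect_equal(h[12:17], c(0, 1, 0, 0, 0, 0))    # degree 1
  expect_equal(h[18:22], c(1, 0, 0, 0, 0))       # 0 bonded H
})

test_that("degree slots satisfy the handshake lemma", {
  set.seed(202)
  for (i in 1:8) {
    s <- paste(sample(AA20, sample(1:8, 1), replace = TRUE), collapse = "")
    m <- build_peptide(s)
    x <- node_features(m)
    degrees <- as.vector(x[, 12:17] %*% 0:5)
    expect_equal(sum(degrees), 2 * nrow(m$bonds), info = s)
  }
})

test_that("edge features are 12 wide and encode amide conjugation and aromatic rings", {
  m <- build_peptide("GF")
  ef <- t(vapply(seq_len(nrow(m$bonds)), function(k) edge_feature_vector(m, k),
                 numeric(12)))
  expect_equal(ncol(ef), 12)
  expect_true(all(rowSums(ef[, 1:4, drop = FALSE]) == 1))
  expect_true(all(rowSums(ef[, 5:10, drop = FALSE]) == 1))
  expect_true(all(ef[, 8] == 1))  # stereo "none" everywhere
  # the peptide C-N bond: single, conjugated, not in a ring
  amide <- which(!m$bonds$aromatic & m$bonds$order == 1 &
                   m$atoms$element[m$bonds$a1] == "C" &
                   m$atoms$element[m$bonds$a2] == "N" &
                   m$bonds$conjugated & !m$bonds$in_ring)
  expect_true(length(amide) >= 1)
  expect_equal(unname(ef[amide[1], c(1, 11, 12)]), c(1, 0, 1))
  # phenylalanine ring bonds: aromatic, ring, conjugated
  ring_b <- which(m$bonds$aromatic)
  expect_true(all(ef[ring_b, 2] == 1))
  expect_true(all(ef[ring_b, 11] == 1))
  expect_true(all(ef[ring_b, 12] == 1))
})

test_that("ring membership matches a brute-force bridge oracle on all residues", {
  for (code in AA20) {
    m <- build_peptide(code)
    rm <- ring_membership(m)
    oracle <- oracle_ring_bonds(m$bonds$a1, m$bonds$a2, nrow(m$atoms))
    expect_identical(rm$bonds, oracle, info = code)
    atoms_oracle <- rep(FALSE, nrow(m$atoms))
    atoms_oracle[unique(c(m$bonds$a1[oracle], m$bonds$a2[oracle]))] <- TRUE
    expect_identical(rm$atoms, atoms_oracle, info = code)
  }
  expect_equal(sum(ring_membership(build_peptide("P"))$atoms), 5)
  expect_equal(sum(ring_membership(build_peptide("W"))$atoms), 9 + 0)
  expect_equal(sum(ring_membership(build_peptide("W"))$bonds), 10)
})

test_that("featurize_pair produces a two-component graph with doubled directed edges", {
  g <- featurize_pair("GG", "G", 1)
  expect_equal(g$n_nodes, 27)
  expect_equal(g$n_components, 2)
  expect_equal(g$y, 1)
  gg <- featurize_pair("G", "G", 0)
  expect_equal(ncol(gg$edge_index), 2 * 18)  # 9 bonds per glycine, both directions
  expect_equal(nrow(gg$edge_attr), ncol(gg$edge_index))
  expect_equal(ncol(gg$x), 31)
  expect_equal(ncol(gg$edge_attr), 12)
  # the two directed copies of each bond carry identical features
  nb <- ncol(gg$edge_index) / 2
  expect_identical(gg$edge_attr[seq_len(nb), ],
                   gg$edge_attr[nb + seq_len(nb), ])
  expect_identical(gg$edge_index[, seq_len(nb)],
                   gg$edge_index[2:1, nb + seq_len(nb)])
  expect_true(all(gg$edge_index >= 1 & gg$edge_index <= gg$n_nodes))
})

test_that("atom permutation permutes node features and relabels edges consistently", {
  m <- build_peptide("AS")
  g <- featurize_molecule(m, 1)
  set.seed(203)
  perm <- sample(nrow(m$atoms))
  m2 <- m
  m2$atoms <- m$atoms[order(perm), ]
  inv <- order(perm)  # new index of old atom i is perm[i]
  m2$atoms <- m$atoms[inv, ]
  m2$bonds$a1 <- perm[m$bonds$a1]
  m2$bonds$a2 <- perm[m$bonds$a2]
  g2 <- featurize_molecule(m2, 1)
  expect_equal(g2$x[perm[seq_len(nrow(m$atoms))], ], g$x)
  expect_equal(g2$edge_index, matrix(perm[g$edge_index], nrow = 2))
  expect_equal(g2$edge_attr, g$edge_attr)
})
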