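test_that("column entropy matches direct evaluation and flags undefined columns", {
  # all 20 residues equally represented: log2(20) = 4.32 at 2 dp
  u20 <- columnEntropy(c("A","C","D","E","F","G","H","I","K","L",
                         "M","N","P","Q","R","S","T","V","W","Y"))
  expect_equal(round(u20$H, 2), 4.32)
  expect_equal(u20$M, 20L)
  # single residue type: 0 bits
  expect_equal(columnEntropy(rep("W", 7))$H, 0)
  # AAAB-style column: -(0.75 log2 0.75 + 0.25 log2 0.25)
  expect_equal(columnEntropy(c("A", "A", "A", "C"))$H,
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)),
               tolerance = 1e-12)
  expect_equal(columnEntropy(c("A", "A", "V", "V"))$H, 1)
  # gaps and X are excluded from the composition, not counted as types
  gapped <- columnEntropy(c("A", "A", "-", "X", "."))
  expect_equal(gapped$H, 0)
  expect_equal(gapped$n_eff, 2L)
  # an all-gap column has no defined entropy (NA, never 0)
  expect_true(is.na(columnEntropy(c("-", "-", "."))$H))
  expect_error(columnEntropy(c("A", "B")), "unknown residue")
})

test_that("reduced alphabet groups chemical classes and is idempotent", {
  expect_equal(reduceAlphabet("KR"), "KK")       # positively charged
  expect_equal(reduceAlphabet("LVIMC"), "LLLLL") # aliphatic/hydrophobic
  expect_equal(reduceAlphabet("FYW"), "FFF")     # aromatic
  expect_equal(reduceAlphabet("EDNQ"), "EEEE")   # acidic/amide
  expect_equal(reduceAlphabet("ST"), "SS")
  expect_equal(reduceAlphabet("AG"), "AA")
  r1 <- reduceAlphabet("MKVLHWDESTPAGRNQYIFC")
  expect_identical(reduceAlphabet(r1), r1)       # idempotent
  expect_equal(reduceAlphabet("M-K.X"), "L-K.X") # gaps/X pass through
  expect_error(reduceAlphabet("MKZ"), "unknown")
})

test_that("reduced-alphabet entropy never exceeds full-alphabet entropy", {
  withr::with_seed(11, {
    for (k in 1:300) {
      depth <- sample(3:40, 1)
      col <- sample(c("A","C","D","E","F","G","H","I","K","L","M","N",
                      "P","Q","R","S","T","V","W","Y","X","-"),
                    depth, TRUE)
      f <- columnEntropy(col, "full20")
      r <- columnEntropy(col, "reduced8")
      if (is.na(f$H)) { expect_true(is.na(r$H)); next }
      expect_lte(r$H, f$H + 1e-12)
      expect_gte(f$H, 0); expect_lte(f$H, log2(20))
      expect_lte(r$H, 3)
    }
  })
})

test_that("entropy profiles expose planted subclade conservation", {
  # invariant alignment: all-zero profile
  flat <- entropyProfile(c(a = "MKVL", b = "MKVL", c = "MKVL"))
  expect_equal(flat$H_full, rep(0, 4))
  # planted motif: conserved within subclade, divergent across
  withr::with_seed(5, {
    rowsA <- replicate(10, paste0("DDD", paste(
      sample(c("K","R","E","D","S","T","L","V"), 5, TRUE), collapse = "")))
    rowsB <- replicate(10, paste0("KKK", paste(
      sample(c("K","R","E","D","S","T","L","V"), 5, TRUE), collapse = "")))
  })
  msa <- setNames(c(rowsA, rowsB), sprintf("s%02d", 1:20))
  part <- setNames(rep(c("sub1", "sub2"), each = 10), names(msa))
  prof <- entropyProfile(msa, partition = part)
  subs <- attr(prof, "subclades")
  # motif columns 1-3: zero entropy within each subclade, ~1 bit pooled
  for (j in 1:3) {
    expect_equal(subs$sub1$H_full[j], 0)
    expect_equal(subs$sub2$H_full[j], 0)
    expect_equal(prof$H_full[j], 1)
  }
  expect_false(attr(subs$sub1, "low_support"))
  # a one-row subclade is flagged low-support
  p2 <- entropyProfile(msa, partition = setNames(
    c("solo", rep("rest", 19)), names(msa)))
  expect_true(attr(attr(p2, "subclades")$solo, "low_support"))
})

test_that("neighbor joining recovers additive trees exactly", {
  withr::with_seed(31, {
    for (k in 1:30) {
      n <- sample(4:12, 1)
      tr <- ape::rtree(n)
      d <- ape::cophenetic.phylo(tr)
      got <- njTree(d)
      expect_equal(rfDistance(tr, got), 0L)
      # branch lengths reproduce the generating metric
      expect_equal(ape::cophenetic.phylo(got)[rownames(d), colnames(d)],
                   d, tolerance = 1e-6)
    }
  })
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2)), "3 taxa")
  bad <- matrix(c(0, 1, 2, 1, 0, 3, 2.5, 3, 0), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(njTree(bad), "symmetric")
})

test_that("planted two-clade distance structure bipartitions the NJ tree", {
  ids <- c(sprintf("a%d", 1:4), sprintf("b%d", 1:4))
  d <- matrix(0.8, 8, 8, dimnames = list(ids, ids))
  d[1:4, 1:4] <- 0.2; d[5:8, 5:8] <- 0.2
  diag(d) <- 0
  tr <- njTree(d)
  bip <- oracleBipartitions(tr)
  expect_true(paste(sort(ids[1:4]), collapse = "|") %in% bip ||
              paste(sort(ids[5:8]), collapse = "|") %in% bip)
})

test_that("Robinson-Foulds distance equals the bipartition-set oracle", {
  # two distinct resolved quartets differ by 2
  q1 <- ape::read.tree(text = "((a,b),(c,d));")
  q2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rfDistance(q1, q2), 2L)
  expect_equal(rfDistance(q1, q1), 0L)
  withr::with_seed(17, {
    for (k in 1:40) {
      t1 <- ape::rtree(8); t2 <- ape::rtree(8)
      t2$tip.label <- sample(t1$tip.label)
      expect_equal(rfDistance(t1, t2), oracleRF(t1, t2))
      expect_equal(rfDistance(t1, t2), rfDistance(t2, t1))  # symmetry
      expect_lte(rfDistance(t1, t2), 2L * (8L - 3L))
    }
  })
  t3 <- ape::rtree(5)
  t4 <- ape::rtree(5); t4$tip.label <- paste0("z", 1:5)
  expect_error(rfDistance(t3, t4), "identical tip label set")
})

test_that("clade congruence is 1 for coevolving pairs and ~0 under permutation", {
  pf <- genPairedFamilies(seqsPerSubclade = 5, seed = 3)
  pa <- setNames(pf$A$truth$subclade, pf$A$truth$id)
  pb <- setNames(pf$B$truth$subclade, pf$B$truth$id)
  cc <- cladeCongruence(pa, pb, pf$pairing)
  expect_equal(cc$ari, 1)
  expect_equal(cc$agreement, 1)
  # fully shuffled partners: ARI near zero
  aris <- vapply(1:10, function(s) {
    pfs <- genPairedFamilies(seqsPerSubclade = 17, shuffle = 1, seed = s)
    cladeCongruence(setNames(pfs$A$truth$subclade, pfs$A$truth$id),
                    setNames(pfs$B$truth$subclade, pfs$B$truth$id),
                    pfs$pairing)$ari
  }, 0)
  expect_true(all(abs(aris) < 0.1))
  # degenerate single-cluster case: defined as 1 with a warning
  expect_warning(
    deg <- cladeCongruence(c(x1 = "c", x2 = "c"), c(y1 = "c", y2 = "c"),
                           data.frame(a = c("x1", "x2"), b = c("y1", "y2"))),
    "degenerate|single cluster")
  expect_equal(deg$ari, 1)
  expect_true(deg$degenerate)
  expect_error(cladeCongruence(pa, pb, pf$pairing[0, ]), "at least 2")
})

test_that("optimal label matching equals brute-force permutation search", {
  withr::with_seed(23, {
    for (k in 1:20) {
      n <- sample(2:5, 1)
      cost <- matrix(sample(0:20, n * n, TRUE), n)
      asg <- dndscape:::solveAssignment(cost)
      expect_equal(sum(cost[cbind(seq_len(n), asg)]),
                   oracleAssignmentCost(cost))
    }
  })
})

test_that("capture-clade counts match the edge-side oracle and planted truth", {
  # one labeled clade: a single capture
  t1 <- ape::read.tree(text = "(((L1,L2),L3),(u1,(u2,u3)));")
  expect_equal(countCaptureClades(t1, c("L1", "L2", "L3")), 1L)
  # alternating caterpillar: every labeled tip is its own capture
  t2 <- ape::read.tree(
    text = "(((((((L1,u1),L2),u2),L3),u3),L4),u4);")
  expect_equal(countCaptureClades(t2, sprintf("L%d", 1:4)), 4L)
  expect_equal(countCaptureClades(t2, sprintf("L%d", 1:4)),
               oracleCaptureClades(t2, sprintf("L%d", 1:4)))
  # random trees with random labeled subsets agree with the oracle
  withr::with_seed(41, {
    for (k in 1:25) {
      tr <- ape::rtree(10)
      lab <- sample(tr$tip.label, sample(2:8, 1))
      expect_equal(countCaptureClades(tr, lab),
                   oracleCaptureClades(tr, lab))
    }
  })
  # planted grafts across 1..8 capture events
  for (g in c(1L, 3L, 6L, 8L)) {
    ct <- genCaptureTree(g, seed = g + 100L)
    expect_equal(countCaptureClades(ct$tree, ct$labeled), g)
  }
  expect_error(countCaptureClades(t1, t1$tip.label), "outgroup")
  expect_error(countCaptureClades(t1, character(0)), "non-empty")
})
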