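randomSeqs <- function(n, len, seed) {
  withr::with_seed(seed, setNames(
    vapply(seq_len(n), function(i)
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                   len, TRUE), collapse = ""), ""),
    sprintf("r%03d", seq_len(n))))
}

test_that("global alignment matches closed forms and handles X", {
  a <- globalAlign("MKV", "MKV")
  expect_equal(a$identity, 100)
  expect_equal(a$coverage, 1)
  expect_equal(a$alignedLen, 3L)
  m <- oracleScoringMatrix()
  expect_equal(globalAlign("AAAA", "AAAA")$score, 4 * m["A", "A"])
  # X scores zero against everything, including itself
  expect_equal(globalAlign("XXXX", "MKVL")$score, 0)
  expect_error(globalAlign("", "MKV"), "empty")
})

test_that("alignment scores equal an independent affine-gap DP oracle", {
  m <- oracleScoringMatrix()
  withr::with_seed(99, {
    for (k in 1:40) {
      la <- sample(10:30, 1); lb <- sample(10:30, 1)
      a <- paste(sample(rownames(m)[1:20], la, TRUE), collapse = "")
      b <- paste(sample(rownames(m)[1:20], lb, TRUE), collapse = "")
      expect_equal(globalAlign(a, b)$score, oracleAlignScore(a, b, m))
    }
  })
})

test_that("single-linkage clusters equal brute-force connected components", {
  for (seed in 1:8) {
    fam <- genFamily(nClades = 2, subcladesPerClade = 3,
                     seqsPerSubclade = 3, length = 40,
                     withinRate = 0.1, betweenRate = 0.45, seed = seed)
    cs <- clusterSingleLinkage(fam$seqs, L = 0.8, S = 55)
    edges <- pairTable(cs)
    comp <- oracleComponents(names(fam$seqs),
                             edges[edges$edge, c("id1", "id2")])
    got <- membership(cs)$cluster[match(names(comp), membership(cs)$id)]
    # same partition (labels may differ)
    expect_equal(mclust::adjustedRandIndex(got, comp), 1)
  }
})

test_that("chained similarity groups by single linkage; duplicates collapse; high S isolates", {
  base <- randomSeqs(1, 60, 1)[[1]]
  withr::with_seed(2, {
    bORc <- mutateSeq(base, 0.18)
    seqs <- c(A = base, B = bORc, C = mutateSeq(bORc, 0.18))
  })
  g <- similarityGraph(seqs)
  idAB <- g$identity[g$id1 == "A" & g$id2 == "B"]
  idBC <- g$identity[g$id1 == "B" & g$id2 == "C"]
  idAC <- g$identity[g$id1 == "A" & g$id2 == "C"]
  expect_lt(idAC, min(idAB, idBC))   # genuine chain at this fixed seed
  S <- (idAC + min(idAB, idBC)) / 2
  cs <- clusterSingleLinkage(seqs, L = 0.8, S = S)
  expect_equal(length(unique(membership(cs)$cluster)), 1L)
  dup <- c(x = base, y = base, z = base)
  csd <- clusterSingleLinkage(dup, L = 0.9, S = 95)
  expect_equal(length(unique(membership(csd)$cluster)), 1L)
  css <- clusterSingleLinkage(seqs, L = 0.9, S = 101)
  expect_equal(length(unique(membership(css)$cluster)), 3L)
})

test_that("clustering is invariant to input order and representatives are deterministic", {
  fam <- genFamily(nClades = 2, subcladesPerClade = 2,
                   seqsPerSubclade = 4, length = 50, seed = 5)
  cs1 <- clusterSingleLinkage(fam$seqs, L = 0.8, S = 60)
  perm <- withr::with_seed(1, sample(length(fam$seqs)))
  cs2 <- clusterSingleLinkage(fam$seqs[perm], L = 0.8, S = 60)
  m1 <- membership(cs1); m2 <- membership(cs2)
  expect_identical(m1[order(m1$id), ],
                   `rownames<-`(m2[order(m2$id), ], NULL))
  expect_identical(sort(representatives(cs1)), sort(representatives(cs2)))
})

test_that("tightening S or L only splits clusters, never merges them", {
  fam <- genFamily(nClades = 2, subcladesPerClade = 3,
                   seqsPerSubclade = 4, length = 60,
                   withinRate = 0.08, betweenRate = 0.4, seed = 9)
  g <- similarityGraph(fam$seqs)
  loose <- clusterSingleLinkage(fam$seqs, L = 0.7, S = 40, graph = g)
  for (tight in list(c(0.7, 60), c(0.9, 40), c(0.95, 75))) {
    cs <- clusterSingleLinkage(fam$seqs, L = tight[1], S = tight[2],
                               graph = g)
    mL <- membership(loose); mT <- membership(cs)
    joined <- merge(mL, mT, by = "id")
    # each tight cluster maps into exactly one loose cluster
    split_ok <- tapply(joined$cluster.x, joined$cluster.y,
                       function(v) length(unique(v)) == 1L)
    expect_true(all(split_ok))
  }
})

test_that("12 planted subclades are recovered as exactly 12 clusters", {
  fam <- genFamily(nClades = 2, subcladesPerClade = 6,
                   seqsPerSubclade = 5, length = 100,
                   withinRate = 0.05, betweenRate = 0.40, seed = 13)
  cs <- clusterSingleLinkage(fam$seqs, L = 0.9, S = 65)
  m <- membership(cs)
  expect_equal(length(unique(m$cluster)), 12L)
  expect_equal(mclust::adjustedRandIndex(
    m$cluster, fam$truth$subclade[match(m$id, fam$truth$id)]), 1)
})

test_that("singlets merge only with both reciprocal-best-hit and shared context", {
  fam <- genFamily(nClades = 1, subcladesPerClade = 2,
                   seqsPerSubclade = 4, length = 60,
                   withinRate = 0.05, betweenRate = 0.5, seed = 17)
  # a divergent member of subclade 1 that misses the identity threshold
  withr::with_seed(4, {
    stray <- mutateSeq(fam$seqs[[1]], 0.25)
  })
  seqs <- c(fam$seqs, stray = stray)
  cs <- clusterSingleLinkage(seqs, L = 0.9, S = 85)
  m0 <- membership(cs)
  expect_true(sum(m0$cluster == m0$cluster[m0$id == "stray"]) == 1L)
  target <- m0$cluster[m0$id == names(fam$seqs)[1]]
  arch <- setNames(rep("+A|+B", length(seqs)), names(seqs))
  merged <- mergeSinglets(cs, arch)
  m1 <- membership(merged)
  expect_equal(m1$cluster[m1$id == "stray"], target)
  expect_true(attr(merged, "merges")$rbh[1])
  # alien context blocks the merge under the conjunction rule
  archAlien <- arch; archAlien["stray"] <- "+Z|+Q"
  notMerged <- mergeSinglets(cs, archAlien)
  m2 <- membership(notMerged)
  expect_true(sum(m2$cluster == m2$cluster[m2$id == "stray"]) == 1L)
  # but the disjunction flag relaxes it
  relaxed <- mergeSinglets(cs, archAlien, requireBoth = FALSE)
  m3 <- membership(relaxed)
  expect_equal(m3$cluster[m3$id == "stray"], target)
})

test_that("CLANS-style embedding separates planted families and is seed-deterministic", {
  fam <- genFamily(nClades = 2, subcladesPerClade = 1,
                   seqsPerSubclade = 6, length = 60,
                   withinRate = 0.05, betweenRate = 0.5, seed = 7)
  g <- similarityGraph(fam$seqs)
  g$bits[g$identity < 60] <- 0   # no inter-family attraction
  em1 <- clansEmbed(g, iterations = 150, seed = 3, radius = 2)
  em2 <- clansEmbed(g, iterations = 150, seed = 3, radius = 2)
  expect_identical(em1$coords, em2$coords)
  lab <- fam$truth$clade[match(rownames(em1$coords), fam$truth$id)]
  dm <- as.matrix(dist(em1$coords))
  same <- outer(lab, lab, "==") & upper.tri(dm)
  diff <- outer(lab, lab, "!=") & upper.tri(dm)
  # silhouette-like separation: centroids further apart than spread
  expect_gt(mean(dm[diff]), mean(dm[same]))
  expect_equal(length(unique(em1$labels[lab == lab[1]])), 1L)
  expect_error(clansEmbed(g, iterations = 0), "positive")
  single <- clansEmbed(g[0, ], ids = "only")
  expect_equal(unname(single$coords[1, ]), c(0, 0))
})
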