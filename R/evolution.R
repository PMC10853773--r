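# Reduced 8-class amino-acid alphabet (hydrophobicity/charge classes);
# each class is written as one of its own members so reduction is
# idempotent.  Overridable via options(dndscape.reduced8 = <named chr>).
REDUCED8 <- c(
  L = "L", V = "L", I = "L", M = "L", C = "L",  # aliphatic/hydrophobic
  A = "A", G = "A",                             # small
  S = "S", T = "S",                             # hydroxyl
  P = "P",                                      # proline
  F = "F", Y = "F", W = "F",                    # aromatic
  E = "E", D = "E", N = "E", Q = "E",           # acidic/amide polar
  K = "K", R = "K",                             # positively charged
  H = "H")                                      # histidine

reducedMap <- function() {
  m <- getOption("dndscape.reduced8", REDUCED8)
  if (!setequal(names(m), AA20))
    bail("reduced alphabet must map exactly the 20 standard residues")
  m
}

#' Map residues onto the reduced 8-class alphabet
#'
#' Deterministic many-to-one reduction of the 20 amino acids onto 8
#' chemical classes: \{L,V,I,M,C\}, \{A,G\}, \{S,T\}, \{P\}, \{F,Y,W\},
#' \{E,D,N,Q\}, \{K,R\}, \{H\}.  Each class is encoded by one of its own
#' members, so the mapping is idempotent.  Gaps (`-`, `.`) and `X` pass
#' through unchanged; any other character is an error.
#'
#' @param x character vector of sequences (or single characters).
#' @return reduced sequences, same shape as `x`.
#' @export
reduceAlphabet <- function(x) {
  map <- reducedMap()
  vapply(x, function(s) {
    ch <- strsplit(s, "")[[1]]
    out <- map[ch]
    pass <- ch %in% MSA_EXTRA
    out[pass] <- ch[pass]
    if (anyNA(out))
      bail("unknown residue character(s): ",
           paste(unique(ch[is.na(out) & !pass]), collapse = ""))
    paste(out, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Shannon entropy of one alignment column
#'
#' `H = -sum_i P_i log2 P_i` over the residue types observed in the
#' column after removing gaps and `X`; `P_i` is the count of type `i`
#' divided by the number of non-gap characters.  Under the full alphabet
#' H ranges from 0 (one residue type) to `log2(20) = 4.32` (all twenty
#' equally represented); under the reduced 8-class alphabet the ceiling
#' is 3 bits.  An all-gap column has no defined entropy and returns
#' `NA` rather than 0.
#'
#' @param column character vector of single characters, or one string.
#' @param alphabet `"full20"` or `"reduced8"`.
#' @return named list: `H` (bits, `NA` if undefined), `M` (residue types
#'   observed), `n_eff` (non-gap characters).
#' @export
columnEntropy <- function(column, alphabet = c("full20", "reduced8")) {
  alphabet <- match.arg(alphabet)
  if (length(column) == 1L && nchar(column) > 1L)
    column <- strsplit(column, "")[[1]]
  keep <- !(column %in% c("-", ".", "X"))
  res <- column[keep]
  if (!length(res)) return(list(H = NA_real_, M = 0L, n_eff = 0L))
  bad <- setdiff(unique(res), AA20)
  if (length(bad)) bail("unknown residue character(s): ",
                        paste(bad, collapse = ""))
  if (alphabet == "reduced8") res <- reducedMap()[res]
  p <- table(res) / length(res)
  H <- -sum(p * log2(p))
  if (H <= 0) H <- 0   # clamp; also normalises IEEE negative zero
  list(H = H, M = length(p), n_eff = length(res))
}

#' Column-wise entropy profile of an alignment
#'
#' Computes per-column Shannon entropy under both the full 20-letter and
#' the reduced 8-class alphabet (the dual above/below-zero presentation
#' used for fast-evolving families).  Given a partition of the rows into
#' subclades, additionally returns per-subclade profiles on the same
#' columns; a subclade with fewer than 2 rows is flagged low-support.
#'
#' @param msa named character vector of equal-length aligned sequences.
#' @param partition optional named vector, sequence id -> subclade label.
#' @return `data.frame` with `col` (1-based), `H_full`, `H_reduced`, `M`,
#'   `n_eff`; with a partition, attribute `"subclades"` holds a named
#'   list of such data.frames plus a `low_support` flag each.
#' @export
entropyProfile <- function(msa, partition = NULL) {
  if (length(unique(nchar(msa))) != 1L)
    bail("alignment rows must have equal length")
  chars <- do.call(rbind, strsplit(msa, ""))
  profileOf <- function(rows) {
    m <- chars[rows, , drop = FALSE]
    res <- lapply(seq_len(ncol(m)), function(j) {
      f <- columnEntropy(m[, j], "full20")
      r <- columnEntropy(m[, j], "reduced8")
      c(H_full = f$H, H_reduced = r$H, M = f$M, n_eff = f$n_eff)
    })
    out <- as.data.frame(do.call(rbind, res))
    out$col <- seq_len(ncol(m))
    out[, c("col", "H_full", "H_reduced", "M", "n_eff")]
  }
  prof <- profileOf(seq_along(msa))
  if (!is.null(partition)) {
    ids <- names(msa)
    subs <- lapply(split(ids, partition[ids]), function(members) {
      p <- profileOf(match(members, ids))
      attr(p, "low_support") <- length(members) < 2L
      p
    })
    attr(prof, "subclades") <- subs
  }
  prof
}

#' Write an entropy profile as TSV
#'
#' @param profile output of [entropyProfile()].
#' @param path output file (columns `col`, `H_full`, `H_reduced`,
#'   `n_eff`).
#' @export
writeEntropyProfile <- function(profile, path) {
  write.table(profile[, c("col", "H_full", "H_reduced", "n_eff")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Identity-based distance matrix for tree building
#'
#' `1 - fractional identity` from global pairwise alignment, optionally
#' Poisson-corrected (`-log(identity)`), as a deterministic input for
#' [njTree()].
#'
#' @param seqs named character vector of protein sequences.
#' @param correction `"none"` (default) or `"poisson"`.
#' @return symmetric matrix with zero diagonal.
#' @export
identityDistances <- function(seqs, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  g <- similarityGraph(seqs)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  p <- g$identity / 100
  val <- if (correction == "poisson") -log(pmax(p, 1e-6)) else 1 - p
  d[cbind(g$id1, g$id2)] <- val
  d[cbind(g$id2, g$id1)] <- val
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining on a symmetric distance matrix (delegated to
#' `ape::nj`), with negative branch lengths clamped to zero.  Exact on
#' additive matrices.  Serves as the package's deterministic tree engine
#' where likelihood inference is out of scope.
#'
#' @param d symmetric numeric matrix with zero diagonal, `n >= 3`,
#'   dimnames = tip labels.
#' @return an unrooted `ape::phylo`.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) bail("need at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    bail("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) bail("diagonal must be zero")
  tr <- ape::nj(d)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Robinson-Foulds distance between unrooted trees
#'
#' The count of non-trivial bipartitions present in exactly one of the
#' two trees (range 0 to `2(n-3)` for binary trees on `n` shared tips).
#'
#' @param t1,t2 `ape::phylo` objects with identical tip label sets.
#' @return integer RF distance.
#' @export
rfDistance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    bail("trees must share an identical tip label set")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

# --- optimal label matching (Hungarian assignment) ---------------------

# minimal-cost assignment on a square cost matrix; returns for each row
# the assigned column.  O(n^3) shortest augmenting path with potentials.
solveAssignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n)          # row potentials, rows 1..n
  v <- numeric(n + 1L)     # column potentials, cols 0..n at index j+1
  p <- integer(n + 1L)     # p[j+1]: row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0] - v[j + 1L]
        if (cur < minv[j]) { minv[j] <- cur; way[j + 1L] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

#' Clade congruence of two operonically paired families
#'
#' Tests whether the subclade structure of family A mirrors that of its
#' operonic partner family B.  The pairing (one A member to its B partner
#' from the same neighborhood) induces two label vectors; agreement is
#' the fraction of pairs whose labels correspond under the best
#' one-to-one label matching (optimal assignment on the contingency
#' table), and the adjusted Rand index gives the chance-corrected
#' agreement.  Perfect coevolution gives ARI 1; independent partners give
#' ARI near 0.  When both sides form a single cluster the ARI is defined
#' as 1 and flagged degenerate.
#'
#' @param partA,partB named vectors: member id -> clade/subclade label.
#' @param pairing `data.frame` with columns `a`, `b` (partner ids); needs
#'   at least 2 pairs.
#' @return list with `agreement`, `ari`, `contingency`, `degenerate`.
#' @export
cladeCongruence <- function(partA, partB, pairing) {
  if (is.null(pairing) || nrow(pairing) < 2L)
    bail("pairing must map at least 2 members")
  la <- partA[as.character(pairing$a)]
  lb <- partB[as.character(pairing$b)]
  if (anyNA(la) || anyNA(lb))
    bail("both partitions must cover every paired id")
  tab <- table(la, lb)
  degenerate <- nrow(tab) == 1L && ncol(tab) == 1L
  if (degenerate) {
    warning("single cluster on both sides; ARI defined as 1", call. = FALSE)
    ari <- 1
  } else {
    ari <- mclust::adjustedRandIndex(la, lb)
  }
  k <- max(dim(tab))
  cost <- matrix(0, k, k)
  cost[seq_len(nrow(tab)), seq_len(ncol(tab))] <- -tab
  asg <- solveAssignment(cost)
  matched <- sum(vapply(seq_len(nrow(tab)), function(i) {
    j <- asg[i]
    if (j <= ncol(tab)) tab[i, j] else 0L
  }, 0L))
  list(agreement = matched / length(la), ari = ari,
       contingency = tab, degenerate = degenerate)
}

#' Count capture clades of a labeled tip set
#'
#' Given a gene tree and the set of tips belonging to a family of
#' interest, counts the maximal monophyletic groups formed by those tips
#' under the rooting (on an edge adjacent to unlabeled context) that
#' minimises the count.  A single clade (count 1) means one acquisition;
#' a count of k means the labeled sequences are dispersed through the
#' radiation as k independent captures.
#'
#' @param tree unrooted `ape::phylo`.
#' @param labeled character vector of labeled tip ids; must be a proper
#'   non-empty subset of the tips.
#' @return integer count of maximal labeled-only clades.
#' @export
countCaptureClades <- function(tree, labeled) {
  tips <- tree$tip.label
  if (!length(labeled) || !all(labeled %in% tips))
    bail("labeled must be a non-empty subset of the tips")
  if (setequal(labeled, tips))
    bail("labeled set equals all tips: no outgroup context to root on")
  out <- setdiff(tips, labeled)[1]
  tr <- ape::root(ape::unroot(tree), outgroup = out, resolve.root = TRUE)
  nTip <- length(tr$tip.label)
  isLab <- tr$tip.label %in% labeled
  nNode <- nTip + tr$Nnode
  pure <- logical(nNode)
  pure[seq_len(nTip)] <- isLab
  # postorder: a node is pure iff all its children are pure; edges below
  # a child are guaranteed to be processed before the edge to its parent
  po <- ape::reorder.phylo(tr, "postorder")
  acc <- rep(TRUE, nNode)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    if (ch > nTip) pure[ch] <- acc[ch]
    acc[par] <- acc[par] && pure[ch]
  }
  rootNode <- nTip + 1L
  pure[rootNode] <- acc[rootNode]
  parent <- integer(nNode)
  parent[po$edge[, 2L]] <- po$edge[, 1L]
  # maximal pure subtrees: pure node whose parent subtree is impure
  sum(vapply(seq_len(nNode), function(v) {
    if (!pure[v]) return(FALSE)
    if (v == rootNode) return(TRUE)   # cannot happen: outgroup unlabeled
    !pure[parent[v]]
  }, TRUE))
}
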