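# Independent oracles used to cross-check the package implementations.
# Each is written against the definition, not the production code path.

# quadratic-space affine-gap global alignment score:
# gap of length L costs open + L * ext (both positive)
oracleAlignScore <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # a[i] aligned to b[j]
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[A[i], B[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext,
                             X[i + 1, j] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# the scoring table the package aligns with (BLOSUM62, X scored 0)
oracleScoringMatrix <- function() {
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  m <- get("BLOSUM62", envir = e)
  keep <- c(LETTERS[LETTERS %in% colnames(m)])
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y","X")
  m <- m[aa, aa]
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

# connected components by breadth-first search over an edge list
oracleComponents <- function(ids, edges) {
  adj <- lapply(setNames(vector("list", length(ids)), ids), identity)
  for (k in seq_len(nrow(edges))) {
    a <- edges$id1[k]; b <- edges$id2[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  cur <- 0L
  for (s in ids) {
    if (!is.na(comp[[s]])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[[v]])) next
      comp[[v]] <- cur
      queue <- c(queue, adj[[v]])
    }
  }
  comp
}

# non-trivial bipartitions of an unrooted tree as canonical strings
oracleBipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  n <- length(tips)
  nTip <- length(tree$tip.label)
  edges <- tree$edge
  # adjacency over the full node set
  nodes <- seq_len(nTip + tree$Nnode)
  adj <- lapply(nodes, function(i) integer(0))
  for (k in seq_len(nrow(edges))) {
    adj[[edges[k, 1]]] <- c(adj[[edges[k, 1]]], edges[k, 2])
    adj[[edges[k, 2]]] <- c(adj[[edges[k, 2]]], edges[k, 1])
  }
  sideTips <- function(from, banned) {
    seen <- c(banned)
    stack <- from
    out <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v %in% seen) next
      seen <- c(seen, v)
      if (v <= nTip) out <- c(out, v)
      stack <- c(stack, adj[[v]])
    }
    out
  }
  splits <- character(0)
  for (k in seq_len(nrow(edges))) {
    side <- sort(tree$tip.label[sideTips(edges[k, 2], edges[k, 1])])
    if (length(side) <= 1L || length(side) >= n - 1L) next  # trivial
    if (!(tips[1] %in% side)) side <- setdiff(tips, side)   # canonical
    splits <- c(splits, paste(side, collapse = "|"))
  }
  unique(splits)
}

oracleRF <- function(t1, t2) {
  b1 <- oracleBipartitions(t1)
  b2 <- oracleBipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# capture-clade count by edge-side enumeration: number of maximal edge
# sides whose tips are all labeled
oracleCaptureClades <- function(tree, labeled) {
  tree <- ape::unroot(tree)
  nTip <- length(tree$tip.label)
  edges <- tree$edge
  nodes <- seq_len(nTip + tree$Nnode)
  adj <- lapply(nodes, function(i) integer(0))
  for (k in seq_len(nrow(edges))) {
    adj[[edges[k, 1]]] <- c(adj[[edges[k, 1]]], edges[k, 2])
    adj[[edges[k, 2]]] <- c(adj[[edges[k, 2]]], edges[k, 1])
  }
  sideTips <- function(from, banned) {
    seen <- banned; stack <- from; out <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v %in% seen) next
      seen <- c(seen, v)
      if (v <= nTip) out <- c(out, v)
      stack <- c(stack, adj[[v]])
    }
    out
  }
  pure <- list()
  for (k in seq_len(nrow(edges))) for (dirn in 1:2) {
    side <- tree$tip.label[sideTips(edges[k, dirn],
                                    edges[k, 3L - dirn])]
    if (length(side) && all(side %in% labeled))
      pure[[length(pure) + 1L]] <- sort(side)
  }
  pure <- unique(pure)
  maximal <- vapply(seq_along(pure), function(i) {
    !any(vapply(seq_along(pure), function(j)
      i != j && all(pure[[i]] %in% pure[[j]]) &&
        length(pure[[j]]) > length(pure[[i]]), TRUE))
  }, TRUE)
  sum(maximal)
}

# brute-force minimal assignment cost by permutation enumeration (k <= 6)
oracleAssignmentCost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(n)), function(p)
    sum(cost[cbind(seq_len(n), p)]), 0))
}
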