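# BLOSUM62 with X scored 0 against everything, restricted to the
# residues the pipeline admits.  Computed once per session.
alignmentMatrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      data("BLOSUM62", package = "Biostrings", envir = environment())
      m <- get("BLOSUM62", envir = environment())
      keep <- c(AA20, "X")
      m <- m[keep, keep]
      m["X", ] <- 0L
      m[, "X"] <- 0L
      cache <<- m
    }
    cache
  }
})

# lambda-to-bits scaling for BLOSUM62 raw scores (approximation keeping
# BLASTCLUST's bits-per-aligned-column semantics without Karlin-Altschul)
BITS_PER_RAW <- 0.267

# vectorised stats straight off a PairwiseAlignments object:
# identity over all alignment columns (gaps in the denominator),
# coverage = residue-to-residue columns / length of the shorter sequence
alnStats <- function(aln, lenA, lenB) {
  ncolAln <- Biostrings::nchar(aln)
  ident <- Biostrings::nmatch(aln)
  both <- ident + Biostrings::nmismatch(aln)
  sc <- Biostrings::score(aln)
  data.frame(score = sc,
             identity = 100 * ident / ncolAln,
             alignedLen = ncolAln,
             coverage = both / pmin(lenA, lenB),
             bits = sc * BITS_PER_RAW / ncolAln)
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch with a BLOSUM62 substitution table (X scores 0
#' against everything) and affine gaps (open 11, extend 1), delegated to
#' `Biostrings::pairwiseAlignment`.  Identity is computed over all
#' alignment columns (gap columns count in the denominator); coverage is
#' the fraction of the shorter sequence aligned residue-to-residue.
#'
#' @param a,b amino-acid strings (20 standard letters plus `X`).
#' @param gapOpen,gapExtend affine gap penalties (positive costs).
#' @return list with `score`, `identity` (percent), `alignedLen`
#'   (columns), `coverage` in `[0,1]`, and `bits` (score per aligned
#'   column on an approximate bit scale).
#' @export
globalAlign <- function(a, b, gapOpen = 11, gapExtend = 1) {
  if (!nzchar(a) || !nzchar(b)) bail("cannot align an empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = alignmentMatrix(),
    gapOpening = gapOpen, gapExtension = gapExtend, type = "global")
  as.list(alnStats(aln, nchar(a), nchar(b)))
}

#' All-against-all similarity graph
#'
#' Aligns every pair of sequences and tabulates score, percent identity,
#' coverage of the shorter sequence, and bits per aligned column -- the
#' edge weights a CLANS-style analysis and the L/S clustering thresholds
#' operate on.
#'
#' @param seqs named character vector of protein sequences.
#' @inheritParams globalAlign
#' @return `data.frame` with one row per unordered pair: `id1`, `id2`,
#'   `score`, `identity`, `alignedLen`, `coverage`, `bits`.
#' @export
similarityGraph <- function(seqs, gapOpen = 11, gapExtend = 1) {
  n <- length(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    bail("sequences must carry unique names")
  if (any(!nzchar(seqs))) bail("cannot align an empty sequence")
  ids <- names(seqs)
  rows <- vector("list", max(0L, n - 1L))
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqs[js]), Biostrings::AAString(seqs[[i]]),
      substitutionMatrix = alignmentMatrix(),
      gapOpening = gapOpen, gapExtension = gapExtend, type = "global")
    st <- alnStats(aln, nchar(seqs[js]), nchar(seqs[[i]]))
    rows[[i]] <- cbind(data.frame(id1 = ids[i], id2 = ids[js],
                                  stringsAsFactors = FALSE), st)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id1 = character(), id2 = character(), score = numeric(),
               identity = numeric(), alignedLen = numeric(),
               coverage = numeric(), bits = numeric())
  rownames(out) <- NULL
  out
}

#' Threshold-graph single-linkage clustering
#'
#' BLASTCLUST-style homolog grouping: a pair is connected when the
#' aligned coverage of the shorter sequence reaches `L` and the score
#' metric reaches `S` (percent identity in `identity` mode, bits per
#' aligned column in `bits` mode); clusters are the connected components
#' of that graph, so a chain A~B~C groups even when A and C fall below
#' threshold.  Numbering is deterministic: clusters are ordered by their
#' lexicographically smallest member id.  The representative of a cluster
#' is its longest member (ties broken by lexicographic id).
#'
#' @param seqs named character vector of protein sequences.
#' @param L minimum coverage of the shorter sequence, in `[0,1]`.
#' @param S score threshold (`identity` mode: percent in `[0,100]`;
#'   `bits` mode: bits per aligned column).
#' @param mode `"identity"` or `"bits"`.
#' @param graph optionally, a precomputed [similarityGraph()] for `seqs`.
#' @return a [SequenceClusterSet-class].
#' @export
clusterSingleLinkage <- function(seqs, L = 0.9, S = 50,
                                 mode = c("identity", "bits"),
                                 graph = NULL) {
  mode <- match.arg(mode)
  stopifnot(L >= 0, L <= 1, S >= 0, length(seqs) >= 1L)
  if (is.null(graph)) graph <- similarityGraph(seqs)
  metric <- if (mode == "identity") graph$identity else graph$bits
  graph$edge <- graph$coverage >= L & metric >= S
  ids <- names(seqs)
  g <- igraph::graph_from_data_frame(
    graph[graph$edge, c("id1", "id2"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- as.character(igraph::components(g)$membership[ids])
  # deterministic numbering by smallest member id
  minId <- vapply(split(ids, comp), min, "")
  renum <- stats::setNames(seq_along(minId), names(minId)[order(minId)])
  cluster <- sprintf("C%03d", renum[comp])
  membership <- data.frame(id = ids, cluster = cluster,
                           stringsAsFactors = FALSE)
  reps <- vapply(split(ids, cluster), function(m) {
    m[order(-nchar(seqs[m]), m)][1]
  }, "")
  new("SequenceClusterSet", membership = membership,
      representatives = reps, pairs = graph,
      params = list(L = L, S = S, mode = mode))
}

#' Evidence-based merging of singlet clusters
#'
#' A sequence left in its own cluster merges into the cluster of its best
#' overall hit when (i) the hit is reciprocal -- the target's own best
#' hit outside its cluster is the singlet -- and (ii) the singlet's
#' neighborhood architecture matches the architecture of at least one
#' member of the target cluster.  Both lines of evidence are required by
#' default; `requireBoth = FALSE` relaxes the rule to either one.
#'
#' @param cs a [SequenceClusterSet-class].
#' @param archOf named character vector, sequence id -> architecture key
#'   (see [architectureKeys()]); ids without context never satisfy the
#'   context criterion.
#' @param requireBoth conjunction (default) or disjunction of the two
#'   evidence types.
#' @return a new [SequenceClusterSet-class]; the merge log (a
#'   `data.frame` of singlet, target cluster, and the evidence used) is
#'   attached as attribute `"merges"`.
#' @export
mergeSinglets <- function(cs, archOf, requireBoth = TRUE) {
  m <- membership(cs)
  pairs <- pairTable(cs)
  sizes <- table(m$cluster)
  singlets <- m$id[m$cluster %in% names(sizes)[sizes == 1L]]
  clusterOf <- stats::setNames(m$cluster, m$id)
  bestHit <- function(id, excludeIds = character()) {
    sub <- pairs[(pairs$id1 == id | pairs$id2 == id), , drop = FALSE]
    if (!nrow(sub)) return(NA_character_)
    other <- ifelse(sub$id1 == id, sub$id2, sub$id1)
    keep <- !(other %in% excludeIds)
    if (!any(keep)) return(NA_character_)
    other[keep][which.max(sub$bits[keep])]
  }
  log <- data.frame(singlet = character(), into = character(),
                    rbh = logical(), context = logical(),
                    stringsAsFactors = FALSE)
  for (s in singlets) {
    hit <- bestHit(s)
    if (is.na(hit)) next
    target <- clusterOf[[hit]]
    if (sizes[[target]] <= 1L) next
    members <- m$id[m$cluster == target]
    rbh <- identical(bestHit(hit, excludeIds = setdiff(members, s)), s)
    context <- !is.na(archOf[s]) &&
      archOf[[s]] %in% stats::na.omit(archOf[members])
    ok <- if (requireBoth) rbh && context else rbh || context
    if (ok) {
      clusterOf[[s]] <- target
      log <- rbind(log, data.frame(singlet = s, into = target,
                                   rbh = rbh, context = context,
                                   stringsAsFactors = FALSE))
    }
  }
  m$cluster <- unname(clusterOf[m$id])
  reps <- cs@representatives[unique(m$cluster)]
  out <- new("SequenceClusterSet", membership = m,
             representatives = reps[!is.na(reps)], pairs = pairs,
             params = cs@params)
  attr(out, "merges") <- log
  out
}

#' Force-directed embedding of a similarity graph
#'
#' A CLANS-style layout: every connected pair attracts in proportion to
#' its normalised bit weight and separation, every pair repels with an
#' inverse-distance force, and the step size anneals over iterations.
#' Deterministic for a given seed.  A single node sits at the origin.
#' Cluster labels are assigned by single linkage on the embedded
#' distances, cut at `radius`.
#'
#' @param graph a [similarityGraph()] `data.frame`; only rows with
#'   `bits > 0` attract (pass a pre-thresholded graph for sharper maps).
#' @param ids node ids (defaults to all ids present in `graph`).
#' @param dims embedding dimension (default 2).
#' @param iterations annealing iterations (> 0).
#' @param seed RNG seed for the initial placement.
#' @param radius single-linkage cut height on embedded distances.
#' @return list with `coords` (ids x dims matrix) and `labels` (named
#'   integer cluster labels).
#' @export
clansEmbed <- function(graph, ids = NULL, dims = 2L, iterations = 300L,
                       seed = 1L, radius = 1) {
  if (iterations <= 0) bail("iterations must be positive")
  if (is.null(ids)) ids <- sort(unique(c(graph$id1, graph$id2)))
  n <- length(ids)
  if (!n) bail("no nodes to embed")
  if (n == 1L) {
    coords <- matrix(0, 1L, dims, dimnames = list(ids, NULL))
    return(list(coords = coords,
                labels = stats::setNames(1L, ids)))
  }
  w <- graph$bits
  w[w < 0] <- 0
  if (max(w) > 0) w <- w / max(w)
  i1 <- match(graph$id1, ids)
  i2 <- match(graph$id2, ids)
  coords <- withStream(seed, 0L,
    matrix(stats::runif(n * dims, -1, 1), n, dims))
  for (it in seq_len(iterations)) {
    step <- 0.1 * (1 - (it - 1) / iterations)
    # attraction along weighted edges
    disp <- matrix(0, n, dims)
    d12 <- coords[i2, , drop = FALSE] - coords[i1, , drop = FALSE]
    att <- d12 * w
    for (d in seq_len(dims)) {
      disp[, d] <- disp[, d] +
        tapply(c(att[, d], -att[, d]), c(i1, i2), sum)[as.character(seq_len(n))]
    }
    disp[is.na(disp)] <- 0
    # uniform pairwise repulsion, O(n^2) via distance matrix
    dm <- as.matrix(dist(coords))
    diag(dm) <- Inf
    inv <- 1 / (dm * dm)
    for (d in seq_len(dims)) {
      diffd <- outer(coords[, d], coords[, d], "-")  # xi - xj
      disp[, d] <- disp[, d] + 0.05 * rowSums(diffd * inv)
    }
    coords <- coords + step * disp
  }
  rownames(coords) <- ids
  labels <- cutree(hclust(dist(coords), method = "single"), h = radius)
  list(coords = coords, labels = labels)
}
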