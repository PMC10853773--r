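#' Filter configuration for neighborhood analysis
#'
#' Bundles the validity-filter parameters: the intergenic-gap ceiling
#' between consecutive run members (boundary-inclusive, so a gap of
#' exactly `maxGapNt` passes), the per-side window size, the minimum
#' number of distinct phyla a retained pattern must span, and whether
#' runs are restricted to genes on the anchor's strand.
#'
#' @param maxGapNt intergenic gap ceiling in nucleotides (default 100).
#' @param windowW genes collected per side of the anchor (default 5).
#' @param minPhyla minimum distinct phyla in a retained pattern (default 2).
#' @param requireCodirectional restrict runs to the anchor's strand?
#' @return a list of class `FilterConfig`.
#' @export
filterConfig <- function(maxGapNt = 100L, windowW = 5L, minPhyla = 2L,
                         requireCodirectional = TRUE) {
  stopifnot(maxGapNt >= 0, minPhyla >= 1, windowW >= 1)
  structure(list(maxGapNt = as.integer(maxGapNt),
                 windowW = as.integer(windowW),
                 minPhyla = as.integer(minPhyla),
                 requireCodirectional = isTRUE(requireCodirectional)),
            class = "FilterConfig")
}

#' Extract the gene neighborhood around an anchor
#'
#' Walks outward from the anchor along its contig, collecting up to `W`
#' genes per side in positional order moving away from the anchor.  The
#' intergenic gap attached to each flanking gene is the distance back
#' toward the anchor side (`next.start - prev.end` under 0-based
#' half-open coordinates, i.e. the count of nucleotides strictly between
#' the two genes; overlaps clip to 0).  A side that hits the contig end
#' before `W` genes is flagged as truncated.
#'
#' @param assembly a [GenomeAssembly-class].
#' @param anchorId gene id of the anchor.
#' @param W window size per side (>= 1).
#' @return a [Neighborhood-class].
#' @export
extractNeighborhood <- function(assembly, anchorId, W = 5L) {
  stopifnot(W >= 1)
  g <- genes(assembly)
  hit <- which(g$gene_id == anchorId)
  if (!length(hit)) bail("anchor '", anchorId, "' not found in assembly ",
                         assemblyId(assembly))
  ctg <- g[g$contig_id == g$contig_id[hit], , drop = FALSE]
  i <- which(ctg$gene_id == anchorId)
  gapBetween <- function(left, right)  # left precedes right positionally
    max(0L, right$start - left$end)
  takeSide <- function(idx, towardAnchor) {
    # idx: candidate indices ordered moving away from the anchor
    out <- ctg[idx, , drop = FALSE]
    gaps <- integer(length(idx))
    prev <- i
    for (k in seq_along(idx)) {
      a <- min(idx[k], prev); b <- max(idx[k], prev)
      gaps[k] <- gapBetween(ctg[a, ], ctg[b, ])
      prev <- idx[k]
    }
    out$gap_nt <- gaps
    rownames(out) <- NULL
    out
  }
  upIdx <- rev(seq_len(i - 1L))
  upIdx <- utils::head(upIdx, W)
  downIdx <- seq_len(nrow(ctg))[-seq_len(i)]
  downIdx <- utils::head(downIdx, W)
  phylum <- if (length(assembly@lineage) >= 2L) assembly@lineage[2L]
            else NA_character_
  new("Neighborhood",
      anchor = ctg[i, , drop = FALSE],
      assemblyId = assemblyId(assembly),
      speciesTaxId = speciesTaxId(assembly),
      phylum = phylum,
      up = takeSide(upIdx),
      down = takeSide(downIdx),
      truncated = c(up = length(upIdx) < W, down = length(downIdx) < W),
      window = as.integer(W))
}

#' Maximal codirectional run containing the anchor
#'
#' The operon proxy: starting at the anchor, extend into each flank while
#' every gene lies on the anchor's strand and every consecutive intergenic
#' gap is at most `maxGapNt` (a gap of exactly `maxGapNt` continues the
#' run; one nucleotide more stops it).  Genes beyond a strand flip or an
#' oversized gap remain recorded context in the neighborhood but are not
#' part of the run.
#'
#' @param nbh a [Neighborhood-class].
#' @param maxGapNt gap ceiling in nucleotides.
#' @param requireCodirectional if `FALSE`, strand flips do not stop the
#'   run (only the gap constraint applies).
#' @return `data.frame` of run members in genomic (positional) order, with
#'   attribute `anchor_index` giving the anchor's row.
#' @export
codirectionalRun <- function(nbh, maxGapNt = 100L,
                             requireCodirectional = TRUE) {
  anc <- nbh@anchor
  extend <- function(side) {
    keep <- 0L
    for (k in seq_len(nrow(side))) {
      ok <- side$gap_nt[k] <= maxGapNt &&
        (!requireCodirectional || side$strand[k] == anc$strand)
      if (!ok) break
      keep <- k
    }
    if (keep) side[seq_len(keep), , drop = FALSE] else side[0, , drop = FALSE]
  }
  up <- extend(nbh@up)       # ordered moving away from anchor
  down <- extend(nbh@down)
  run <- rbind(up[rev(seq_len(nrow(up))), , drop = FALSE][,
                 names(anc), drop = FALSE],
               anc, down[, names(anc), drop = FALSE])
  rownames(run) <- NULL
  attr(run, "anchor_index") <- nrow(up) + 1L
  run
}

#' Build conserved neighborhood patterns from runs
#'
#' Maps every run member to its family label, normalises the architecture
#' so the anchor reads on the plus strand (minus-strand anchors mirror the
#' order and flip every sign), and aggregates identical architectures
#' across assemblies into [NeighborhoodPattern-class] objects.  Pattern
#' identity is order + family + relative strand only; gap magnitudes do
#' not enter.
#'
#' @param neighborhoods list of [Neighborhood-class] objects.
#' @param familyOf named character vector, gene id -> family label; run
#'   members without a label get `"UNKNOWN"`.
#' @param cfg a [filterConfig()]; its `maxGapNt` and
#'   `requireCodirectional` delimit the runs.
#' @return list of [NeighborhoodPattern-class] objects, one per distinct
#'   architecture, ordered by decreasing support.
#' @export
buildPatterns <- function(neighborhoods, familyOf, cfg = filterConfig()) {
  pats <- list()
  for (nbh in neighborhoods) {
    run <- codirectionalRun(nbh, cfg$maxGapNt, cfg$requireCodirectional)
    fams <- familyOf[run$gene_id]
    fams[is.na(fams)] <- "UNKNOWN"
    signs <- ifelse(run$strand == nbh@anchor$strand, "+", "-")
    if (nbh@anchor$strand == "-") {   # normalise anchor to +
      fams <- rev(fams)
      signs <- rev(signs)
    }
    arch <- paste0(signs, fams)
    key <- paste(arch, collapse = "|")
    sup <- data.frame(assembly_id = nbh@assemblyId,
                      species_tax_id = nbh@speciesTaxId,
                      phylum = nbh@phylum, stringsAsFactors = FALSE)
    af <- unname(familyOf[nbh@anchor$gene_id])
    if (is.na(af)) af <- "UNKNOWN"
    if (is.null(pats[[key]])) {
      pats[[key]] <- list(arch = arch, anchorFamily = af, sup = sup)
    } else {
      pats[[key]]$sup <- rbind(pats[[key]]$sup, sup)
    }
  }
  out <- lapply(pats, function(p)
    new("NeighborhoodPattern", architecture = p$arch,
        anchorFamily = p$anchorFamily, supporting = unique(p$sup)))
  out[order(-vapply(out, function(p) nrow(p@supporting), 1L),
            names(pats))]
}

#' Apply the phylum-spread validity filter to patterns
#'
#' Retains patterns whose supporting set spans at least `cfg$minPhyla`
#' distinct phyla ("presence in more than one phylum" at the default).
#'
#' @param patterns list of [NeighborhoodPattern-class].
#' @param cfg a [filterConfig()].
#' @return list with `retained` (patterns) and `dropped` (`data.frame`
#'   of architecture keys with the reason for removal).
#' @export
filterPatterns <- function(patterns, cfg = filterConfig()) {
  nPhyla <- vapply(patterns, function(p)
    length(unique(stats::na.omit(p@supporting$phylum))), 1L)
  keep <- nPhyla >= cfg$minPhyla
  dropped <- data.frame(
    architecture = vapply(patterns[!keep],
                          function(p) paste(p@architecture, collapse = "|"),
                          ""),
    n_phyla = nPhyla[!keep],
    reason = sprintf("supported by %d phylum/phyla < minPhyla=%d",
                     nPhyla[!keep], cfg$minPhyla),
    stringsAsFactors = FALSE)
  list(retained = patterns[keep], dropped = dropped)
}

# architecture key of a gene's own run, for context-based singlet merging
#' Architecture key for each anchor gene
#'
#' Convenience used by [mergeSinglets()]: computes, for every
#' neighborhood, the normalised architecture key of its codirectional run.
#'
#' @inheritParams buildPatterns
#' @return named character vector, anchor gene id -> architecture key.
#' @export
architectureKeys <- function(neighborhoods, familyOf, cfg = filterConfig()) {
  keys <- vapply(neighborhoods, function(nbh) {
    run <- codirectionalRun(nbh, cfg$maxGapNt, cfg$requireCodirectional)
    fams <- familyOf[run$gene_id]
    fams[is.na(fams)] <- "UNKNOWN"
    signs <- ifelse(run$strand == nbh@anchor$strand, "+", "-")
    if (nbh@anchor$strand == "-") { fams <- rev(fams); signs <- rev(signs) }
    paste(paste0(signs, fams), collapse = "|")
  }, "")
  names(keys) <- vapply(neighborhoods, function(n) n@anchor$gene_id, "")
  keys
}
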