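# draw a random protein sequence (uniform over the 20 residues)
randomProtein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                     collapse = "")

#' Per-site substitution of a protein sequence
#'
#' Each site independently mutates with probability `rate` to one of the
#' 19 alternative residues (uniformly).  The uniform replacement model
#' keeps the expected pairwise identity in closed form: two sequences
#' derived from a common ancestor at rate `r` match at a site with
#' probability `(1-r)^2 + r^2/19`.
#'
#' @param seq amino-acid string.
#' @param rate per-site substitution probability in `[0,1]`.
#' @return mutated string.
#' @export
mutateSeq <- function(seq, rate) {
  stopifnot(rate >= 0, rate <= 1)
  ch <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(a)
      sample(setdiff(AA20, a), 1L), "")
  paste(ch, collapse = "")
}

#' Expected pairwise identity between descendants of one ancestor
#'
#' Closed form under the uniform replacement model of [mutateSeq()]:
#' both lineages mutated at `rateA` and `rateB` respectively.
#'
#' @param rateA,rateB per-site substitution probabilities.
#' @return expected fraction of identical sites.
#' @export
expectedIdentity <- function(rateA, rateB = rateA) {
  (1 - rateA) * (1 - rateB) +                       # neither changed
    (rateA * (1 - rateB) + rateB * (1 - rateA)) * 0 +
    rateA * rateB / 19                              # both hit same target
}

#' Generate a clade/subclade-structured protein family
#'
#' Emulates a family with two (or more) deeply diverged major clades,
#' each split into subclades: a root sequence spawns major-clade
#' ancestors (`cladeRate`), each spawns subclade ancestors
#' (`betweenRate`), and members descend from their subclade ancestor at
#' `withinRate`.  By construction within-subclade identity exceeds
#' between-subclade identity whenever `withinRate < betweenRate`.
#'
#' @param nClades major clades (default 2).
#' @param subcladesPerClade subclades per major clade (default 6).
#' @param seqsPerSubclade members per subclade.
#' @param length protein length.
#' @param withinRate,betweenRate per-site substitution rates; must
#'   satisfy `withinRate < betweenRate`.
#' @param cladeRate divergence of major-clade ancestors from the root.
#' @param seed master seed.
#' @param prefix id prefix.
#' @return list with `seqs` (named character) and `truth` (`data.frame`
#'   `id`, `clade`, `subclade`).
#' @export
genFamily <- function(nClades = 2L, subcladesPerClade = 6L,
                      seqsPerSubclade = 10L, length = 120L,
                      withinRate = 0.05, betweenRate = 0.40,
                      cladeRate = 0.55, seed = 1L, prefix = "seq") {
  if (withinRate >= betweenRate)
    bail("withinRate must be below betweenRate")
  withStream(seed, 1L, {
    root <- randomProtein(length)
    seqs <- character(0)
    truth <- list()
    for (cl in seq_len(nClades)) {
      cladeAnc <- mutateSeq(root, cladeRate)
      for (sc in seq_len(subcladesPerClade)) {
        scAnc <- mutateSeq(cladeAnc, betweenRate)
        for (m in seq_len(seqsPerSubclade)) {
          id <- sprintf("%s_c%d.%d_%02d", prefix, cl, sc, m)
          seqs[id] <- mutateSeq(scAnc, withinRate)
          truth[[id]] <- data.frame(
            id = id, clade = sprintf("clade-%d", cl),
            subclade = sprintf("clade-%d.%d", cl, sc),
            stringsAsFactors = FALSE)
        }
      }
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(seqs = seqs, truth = truth)
  })
}

#' Generate two coevolving (operonically paired) families
#'
#' Emulates an obligate gene dyad: families A and B share the planted
#' clade/subclade structure, and member i of A subclade s is paired with
#' member i of B subclade s.  In perfect mode partner subclade labels are
#' identical by construction; `shuffle` re-draws that fraction of
#' partners across subclades (a random permutation among the selected
#' pairs), degrading congruence towards chance at `shuffle = 1`.
#'
#' @inheritParams genFamily
#' @param shuffle fraction of pairs whose partners are permuted, in
#'   `[0,1]`; 0 is perfect coevolution.
#' @return list with `A`, `B` (as from [genFamily()]) and `pairing`
#'   (`data.frame` `a`, `b`).
#' @export
genPairedFamilies <- function(nClades = 2L, subcladesPerClade = 6L,
                              seqsPerSubclade = 10L, length = 120L,
                              withinRate = 0.05, betweenRate = 0.40,
                              cladeRate = 0.55, shuffle = 0,
                              seed = 1L) {
  if (shuffle < 0 || shuffle > 1) bail("shuffle must be in [0,1]")
  A <- genFamily(nClades, subcladesPerClade, seqsPerSubclade, length,
                 withinRate, betweenRate, cladeRate,
                 seed = seed * 2L + 11L, prefix = "famA")
  B <- genFamily(nClades, subcladesPerClade, seqsPerSubclade, length,
                 withinRate, betweenRate, cladeRate,
                 seed = seed * 2L + 12L, prefix = "famB")
  pairing <- data.frame(a = A$truth$id, b = B$truth$id,
                        stringsAsFactors = FALSE)
  k <- roundHalfUp(shuffle * nrow(pairing))
  if (k > 1L) {
    withStream(seed, 3L, {
      sel <- sample(nrow(pairing), k)
      pairing$b[sel] <- pairing$b[sample(sel)]
    })
  }
  list(A = A, B = B, pairing = pairing)
}

#' Generate annotated genomes with a planted gene cassette
#'
#' Writes GenBank flat files plus a taxonomy table for
#' `nPhyla * speciesPerPhylum * assembliesPerSpecies` assemblies.  Every
#' assembly carries the planted cassette (ordered family list, gaps drawn
#' from `gapNt`, a configurable fraction placed on the minus strand) on a
#' single contig, surrounded by decoy genes whose proteins are
#' independent random sequences.  Duplicate assemblies per species
#' exercise the species-level deduplication downstream; the emitted
#' ground truth is sufficient to score every pipeline stage.
#'
#' @param nPhyla,speciesPerPhylum,assembliesPerSpecies study design.
#' @param cassette character vector of family labels in operon order.
#' @param gapNt intergenic gap(s) within the cassette, recycled; a single
#'   number plants constant gaps.
#' @param minusStrandFraction fraction of assemblies whose cassette sits
#'   on the minus strand.
#' @param decoysPerSide decoy genes on each side of the cassette.
#' @param proteinLength length of planted family proteins.
#' @param withinRate per-site divergence of each cassette protein from
#'   its family ancestor.
#' @param seed master seed.
#' @param dir output directory for GenBank files and `taxonomy.tsv`
#'   (created if needed).
#' @return list: `files` (GenBank paths), `taxonomyFile`, `taxonomy`
#'   (`data.frame`), and `truth` with `familyOf` (gene id -> family),
#'   `anchors` (`data.frame` of anchor gene ids per assembly), and
#'   `cassette`.
#' @export
genGenomes <- function(nPhyla = 3L, speciesPerPhylum = 4L,
                       assembliesPerSpecies = 2L,
                       cassette = c("DndD", "DndE", "DndC"),
                       gapNt = 50L, minusStrandFraction = 0.25,
                       decoysPerSide = 3L, proteinLength = 80L,
                       withinRate = 0.05, seed = 1L,
                       dir = tempfile("genomes")) {
  stopifnot(nPhyla >= 1, speciesPerPhylum >= 1, assembliesPerSpecies >= 1,
            length(cassette) >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ancestors <- withStream(seed, 10L,
    stats::setNames(vapply(cassette, function(f)
      randomProtein(proteinLength), ""), cassette))
  files <- character(0)
  taxRows <- list()
  famOf <- character(0)
  anchors <- list()
  aIdx <- 0L
  for (ph in seq_len(nPhyla)) for (sp in seq_len(speciesPerPhylum)) {
    speciesTax <- 1000L * ph + sp
    for (as_ in seq_len(assembliesPerSpecies)) {
      aIdx <- aIdx + 1L
      acc <- sprintf("GCA_%06d.1", aIdx)
      genome <- withStream(seed, 100L + aIdx, {
        minus <- stats::runif(1) < minusStrandFraction
        gaps <- rep_len(as.integer(gapNt), length(cassette) - 1L)
        rows <- list(); pos <- 200L; gid <- 0L
        addGene <- function(rows, pos, fam, translation, strand) {
          gid <<- gid + 1L
          id <- sprintf("%s_g%03d", acc, gid)
          lenNt <- 3L * nchar(translation) + 3L
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = id, contig_id = "ctg1",
            start = pos, end = pos + lenNt, strand = strand,
            product = fam, translation = translation,
            stringsAsFactors = FALSE)
          rows
        }
        for (k in seq_len(decoysPerSide)) {
          rows <- addGene(rows, pos, "decoy",
                          randomProtein(proteinLength),
                          sample(c("+", "-"), 1L))
          pos <- rows[[length(rows)]]$end + sample(150:400, 1L)
        }
        cas <- if (minus) rev(cassette) else cassette
        casGaps <- if (minus) rev(gaps) else gaps
        for (k in seq_along(cas)) {
          rows <- addGene(rows, pos, cas[k],
                          mutateSeq(ancestors[[cas[k]]], withinRate),
                          if (minus) "-" else "+")
          if (k < length(cas))
            pos <- rows[[length(rows)]]$end + casGaps[k]
        }
        pos <- rows[[length(rows)]]$end + sample(150:400, 1L)
        for (k in seq_len(decoysPerSide)) {
          rows <- addGene(rows, pos, "decoy",
                          randomProtein(proteinLength),
                          sample(c("+", "-"), 1L))
          pos <- rows[[length(rows)]]$end + sample(150:400, 1L)
        }
        do.call(rbind, rows)
      })
      fams <- stats::setNames(genome$product, genome$gene_id)
      famOf <- c(famOf, fams[fams != "decoy"])
      anchorFam <- cassette[1]
      anchors[[acc]] <- data.frame(
        assembly_id = acc,
        gene_id = genome$gene_id[genome$product == anchorFam],
        stringsAsFactors = FALSE)
      asm <- GenomeAssembly(acc, genome, taxId = 100000L + aIdx,
                            speciesTaxId = speciesTax,
                            lineage = c("Bacteria",
                                        sprintf("Phylum%02d", ph),
                                        sprintf("Genus%03d", 10L * ph + sp)))
      f <- file.path(dir, paste0(acc, ".gbk"))
      writeGenBank(asm, f, organism = sprintf("Genus%03d sp%d",
                                              10L * ph + sp, sp))
      files <- c(files, f)
      taxRows[[acc]] <- data.frame(
        assembly_id = acc, tax_id = 100000L + aIdx,
        species_tax_id = speciesTax,
        genus = sprintf("Genus%03d", 10L * ph + sp),
        phylum = sprintf("Phylum%02d", ph),
        superkingdom = "Bacteria", stringsAsFactors = FALSE)
    }
  }
  taxonomy <- do.call(rbind, taxRows)
  rownames(taxonomy) <- NULL
  taxFile <- file.path(dir, "taxonomy.tsv")
  writeTaxonomyTable(taxonomy, taxFile)
  list(files = files, taxonomyFile = taxFile, taxonomy = taxonomy,
       truth = list(familyOf = famOf,
                    anchors = do.call(rbind, anchors),
                    cassette = cassette))
}

#' Generate a composition-controlled alignment
#'
#' Columns are drawn i.i.d. from per-column target compositions (named
#' probability vectors over residues, gaps allowed).  With
#' `exact = TRUE` the counts are placed exactly (each
#' `composition * nrow` must be an integer), which realises the analytic
#' extremes: a uniform 20-residue column at `H = log2(20)` and a
#' constant column at `H = 0`.
#'
#' @param nrow alignment depth.
#' @param compositions list of named numeric vectors, one per column,
#'   each summing to 1.
#' @param exact place exact counts instead of sampling.
#' @param seed RNG seed.
#' @return named character vector of aligned rows (`row01`...).
#' @export
genMsa <- function(nrow, compositions, exact = FALSE, seed = 1L) {
  withStream(seed, 2L, {
    cols <- lapply(seq_along(compositions), function(j) {
      comp <- compositions[[j]]
      if (abs(sum(comp) - 1) > 1e-8)
        bail("composition for column ", j, " does not sum to 1")
      if (is.null(names(comp)) ||
          !all(names(comp) %in% c(AA20, MSA_EXTRA)))
        bail("composition for column ", j, " has invalid residue names")
      if (exact) {
        counts <- comp * nrow
        if (any(abs(counts - round(counts)) > 1e-8))
          bail("exact composition for column ", j,
               " requires integer counts at nrow=", nrow)
        sample(rep(names(comp), round(counts)))
      } else {
        names(comp)[sample.int(length(comp), nrow, replace = TRUE,
                               prob = comp)]
      }
    })
    m <- do.call(cbind, cols)
    stats::setNames(apply(m, 1L, paste, collapse = ""),
                    sprintf("row%03d", seq_len(nrow)))
  })
}

#' Simulate a gene tree with planted capture events
#'
#' Builds a caterpillar backbone of unlabeled context tips with
#' `nGrafts` labeled clades inserted at separated positions, so the true
#' number of maximal labeled-only clades is exactly `nGrafts`.
#'
#' @param nGrafts planted capture events (>= 1).
#' @param cladeSize labeled tips per grafted clade.
#' @param seed RNG seed (randomises branch lengths and clade sizes).
#' @return list with `tree` (`ape::phylo`) and `labeled` (tip ids).
#' @export
genCaptureTree <- function(nGrafts = 6L, cladeSize = 3L, seed = 1L) {
  stopifnot(nGrafts >= 1, cladeSize >= 1)
  withStream(seed, 4L, {
    bl <- function() stats::runif(1, 0.05, 1)
    cladeNwk <- function(g) {
      sz <- max(1L, cladeSize + sample(-1:1, 1L))
      tips <- sprintf("cap%02d_%02d:%.3f", g, seq_len(sz),
                      stats::runif(sz, 0.05, 1))
      s <- tips[1]
      for (t in tips[-1]) s <- sprintf("(%s,%s):%.3f", s, t, bl())
      s
    }
    s <- sprintf("ctx00:%.3f", bl())
    for (g in seq_len(nGrafts)) {
      s <- sprintf("(%s,%s):%.3f", s, cladeNwk(g), bl())
      s <- sprintf("(%s,ctx%02d:%.3f):%.3f", s, g, bl(), bl())
    }
    tree <- ape::read.tree(text = paste0("(", s, sprintf(",ctx%02d:%.3f",
                                                         nGrafts + 1L, bl()),
                                         ");"))
    labeled <- grep("^cap", tree$tip.label, value = TRUE)
    list(tree = ape::unroot(tree), labeled = labeled)
  })
}
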