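#' GenomeAssembly: an annotated prokaryotic genome
#'
#' Holds the gene complement of one assembly: every CDS feature with its
#' contig, coordinates, strand, product and translation, together with the
#' assembly's taxonomic placement.  Coordinates are stored 0-based,
#' half-open (`start < end` always); they are converted back to the 1-based
#' inclusive GenBank dialect on output.
#'
#' @slot assemblyId GCA-style accession string.
#' @slot taxId NCBI taxonomy id of the sequenced strain (`NA` if unknown).
#' @slot speciesTaxId species-level taxonomy id used for phyletic
#'   deduplication (`NA` admits the assembly but excludes it from
#'   presence/absence counting).
#' @slot lineage ordered character vector, superkingdom first, species last.
#' @slot genes `data.frame` with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), `product`, `translation`,
#'   `has_translation`, `compound` (TRUE for join/compound locations
#'   collapsed to their minimal span).  Sorted by contig, start, end.
#'
#' @export
setClass("GenomeAssembly",
  representation(
    assemblyId   = "character",
    taxId        = "integer",
    speciesTaxId = "integer",
    lineage      = "character",
    genes        = "data.frame"
  )
)

setValidity("GenomeAssembly", function(object) {
  g <- object@genes
  need <- c("gene_id", "contig_id", "start", "end", "strand",
            "product", "translation", "has_translation", "compound")
  if (!all(need %in% names(g)))
    return(paste("genes must have columns:", paste(need, collapse = ", ")))
  if (nrow(g)) {
    if (any(g$start < 0L) || any(g$start >= g$end))
      return("gene coordinates must satisfy 0 <= start < end")
    if (anyDuplicated(g$gene_id))
      return("gene_id must be unique within an assembly")
    if (!all(g$strand %in% c("+", "-")))
      return("strand must be '+' or '-'")
    o <- order(g$contig_id, g$start, g$end)
    if (!identical(o, seq_len(nrow(g))))
      return("genes must be sorted by contig_id, start, end")
  }
  if (length(object@assemblyId) != 1L) return("assemblyId must be length 1")
  TRUE
})

#' Neighborhood: genes flanking an anchor
#'
#' The result of walking outward from an anchor gene along its contig.
#' `up` and `down` hold at most `W` genes each, ordered moving away from
#' the anchor, with the intergenic gap (`gap_nt`) back toward the anchor
#' side; overlapping genes have gap 0.
#'
#' @slot anchor one-row `data.frame` (a row of `genes(assembly)`).
#' @slot assemblyId,speciesTaxId,phylum provenance used when patterns are
#'   aggregated across assemblies.
#' @slot up,down `data.frame`s of flanking genes plus a `gap_nt` column.
#' @slot truncated named logical of length 2 (`up`, `down`): TRUE when the
#'   contig ended before `W` genes were collected.
#' @slot window the requested per-side window size `W`.
#' @export
setClass("Neighborhood",
  representation(
    anchor       = "data.frame",
    assemblyId   = "character",
    speciesTaxId = "integer",
    phylum       = "character",
    up           = "data.frame",
    down         = "data.frame",
    truncated    = "logical",
    window       = "integer"
  )
)

setValidity("Neighborhood", function(object) {
  if (nrow(object@anchor) != 1L) return("anchor must be a single gene row")
  if (!identical(sort(names(object@truncated)), c("down", "up")))
    return("truncated must be a named logical c(up=, down=)")
  if (nrow(object@up) > object@window || nrow(object@down) > object@window)
    return("flank lists exceed the window size")
  if (nrow(object@up) && any(object@up$gap_nt < 0)) return("gap_nt < 0")
  if (nrow(object@down) && any(object@down$gap_nt < 0)) return("gap_nt < 0")
  TRUE
})

#' NeighborhoodPattern: a conserved gene-order architecture
#'
#' An architecture is the ordered tuple of family labels in a
#' codirectional run, with strand signs normalised so the anchor reads
#' `+`; `supporting` records every (assembly, species, phylum) in which
#' the identical architecture was observed.
#'
#' @slot architecture character vector such as `c("+DndD","+DndE","-URI")`.
#' @slot anchorFamily family label of the anchor gene.
#' @slot supporting `data.frame` with columns `assembly_id`,
#'   `species_tax_id`, `phylum`.
#' @export
setClass("NeighborhoodPattern",
  representation(
    architecture = "character",
    anchorFamily = "character",
    supporting   = "data.frame"
  )
)

setValidity("NeighborhoodPattern", function(object) {
  if (!length(object@architecture)) return("architecture must be non-empty")
  if (!nrow(object@supporting)) return("supporting set must be non-empty")
  need <- c("assembly_id", "species_tax_id", "phylum")
  if (!all(need %in% names(object@supporting)))
    return("supporting needs assembly_id, species_tax_id, phylum")
  TRUE
})

#' SequenceClusterSet: a partition of proteins into homolog groups
#'
#' Produced by [clusterSingleLinkage()].  Clusters partition the input;
#' numbering is deterministic (ascending smallest member id); each cluster
#' has a representative (longest member, ties broken lexicographically).
#' The full all-vs-all pair table is retained so that singlet merging can
#' consult best hits that fell below the clustering thresholds.
#'
#' @slot membership `data.frame` with columns `id`, `cluster`.
#' @slot representatives named character: cluster -> representative id.
#' @slot pairs `data.frame` of all scored pairs: `id1`, `id2`, `score`,
#'   `identity`, `coverage`, `bits`, `edge` (passed the L/S thresholds).
#' @slot params list with `L`, `S`, `mode`.
#' @export
setClass("SequenceClusterSet",
  representation(
    membership      = "data.frame",
    representatives = "character",
    pairs           = "data.frame",
    params          = "list"
  )
)

setValidity("SequenceClusterSet", function(object) {
  m <- object@membership
  if (!all(c("id", "cluster") %in% names(m)))
    return("membership needs columns id, cluster")
  if (anyDuplicated(m$id)) return("each sequence must be in exactly one cluster")
  reps <- object@representatives
  if (!all(reps %in% m$id)) return("representatives must be members")
  TRUE
})

#' PresenceAbsenceMatrix: species-level phyletic profile
#'
#' One row per species-level taxonomy id (assemblies of the same species
#' are OR-aggregated, so database redundancy cannot inflate counts); one
#' logical column per gene family.
#'
#' @slot mat logical matrix, rownames = species tax ids.
#' @slot meta `data.frame` aligned with rows: `species_tax_id`, `genus`,
#'   `phylum`, `superkingdom`.
#' @export
setClass("PresenceAbsenceMatrix",
  representation(mat = "matrix", meta = "data.frame")
)

setValidity("PresenceAbsenceMatrix", function(object) {
  if (!is.logical(object@mat)) return("cells must be logical")
  if (nrow(object@mat) != nrow(object@meta))
    return("meta must align with matrix rows")
  if (anyDuplicated(rownames(object@mat)))
    return("one row per species_tax_id")
  need <- c("species_tax_id", "genus", "phylum", "superkingdom")
  if (!all(need %in% names(object@meta)))
    return("meta needs species_tax_id, genus, phylum, superkingdom")
  TRUE
})
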