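#' @rdname GenomeAssembly-class
#' @param x a `GenomeAssembly`.
#' @export
setGeneric("assemblyId", function(x) standardGeneric("assemblyId"))
#' @rdname GenomeAssembly-class
#' @export
setGeneric("speciesTaxId", function(x) standardGeneric("speciesTaxId"))
#' @rdname GenomeAssembly-class
#' @export
setGeneric("lineage", function(x) standardGeneric("lineage"))
#' @rdname GenomeAssembly-class
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname SequenceClusterSet-class
#' @param x a `SequenceClusterSet`.
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
#' @rdname SequenceClusterSet-class
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))
#' @rdname SequenceClusterSet-class
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname PresenceAbsenceMatrix-class
#' @param x a `PresenceAbsenceMatrix`.
#' @export
setGeneric("pamMatrix", function(x) standardGeneric("pamMatrix"))
#' @rdname PresenceAbsenceMatrix-class
#' @export
setGeneric("pamMeta", function(x) standardGeneric("pamMeta"))

#' @rdname NeighborhoodPattern-class
#' @param x a `NeighborhoodPattern`.
#' @export
setGeneric("architecture", function(x) standardGeneric("architecture"))
#' @rdname NeighborhoodPattern-class
#' @export
setGeneric("supporting", function(x) standardGeneric("supporting"))

setMethod("assemblyId", "GenomeAssembly", function(x) x@assemblyId)
setMethod("speciesTaxId", "GenomeAssembly", function(x) x@speciesTaxId)
setMethod("lineage", "GenomeAssembly", function(x) x@lineage)
setMethod("genes", "GenomeAssembly", function(x) x@genes)

setMethod("membership", "SequenceClusterSet", function(x) x@membership)
setMethod("representatives", "SequenceClusterSet", function(x) x@representatives)
setMethod("pairTable", "SequenceClusterSet", function(x) x@pairs)

setMethod("pamMatrix", "PresenceAbsenceMatrix", function(x) x@mat)
setMethod("pamMeta", "PresenceAbsenceMatrix", function(x) x@meta)

setMethod("architecture", "NeighborhoodPattern", function(x) x@architecture)
setMethod("supporting", "NeighborhoodPattern", function(x) x@supporting)

setMethod("show", "GenomeAssembly", function(object) {
  g <- object@genes
  cat("GenomeAssembly", object@assemblyId,
      sprintf("(tax %s, species %s)\n",
              object@taxId, object@speciesTaxId))
  cat("  ", length(unique(g$contig_id)), "contig(s),", nrow(g), "genes\n")
  if (length(object@lineage))
    cat("  lineage:", paste(object@lineage, collapse = "; "), "\n")
})

setMethod("show", "Neighborhood", function(object) {
  cat("Neighborhood around", object@anchor$gene_id,
      "on", object@anchor$contig_id,
      sprintf("[%s]\n", object@assemblyId))
  cat("  up:", nrow(object@up), "genes",
      if (object@truncated[["up"]]) "(truncated at contig edge)" else "", "\n")
  cat("  down:", nrow(object@down), "genes",
      if (object@truncated[["down"]]) "(truncated at contig edge)" else "", "\n")
})

setMethod("show", "NeighborhoodPattern", function(object) {
  cat("NeighborhoodPattern:", paste(object@architecture, collapse = " "), "\n")
  cat("  anchor family:", object@anchorFamily, "\n")
  cat("  supported by", nrow(object@supporting), "assemblies across",
      length(unique(object@supporting$phylum)), "phyla\n")
})

setMethod("show", "SequenceClusterSet", function(object) {
  k <- length(unique(object@membership$cluster))
  cat("SequenceClusterSet:", nrow(object@membership), "sequences in",
      k, "clusters",
      sprintf("(L=%.2f, S=%g, mode=%s)\n", object@params$L,
              object@params$S, object@params$mode))
})

setMethod("show", "PresenceAbsenceMatrix", function(object) {
  cat("PresenceAbsenceMatrix:", nrow(object@mat), "species x",
      ncol(object@mat), "families\n")
  cat("  phyla:", length(unique(object@meta$phylum)), " genera:",
      length(unique(object@meta$genus)), "\n")
})
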