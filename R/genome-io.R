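#' Construct a GenomeAssembly from a gene table
#'
#' @param assemblyId GCA-style accession.
#' @param genes data.frame with at least `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand`; `product`, `translation`,
#'   `has_translation`, `compound` are filled with defaults when absent.
#' @param taxId,speciesTaxId NCBI taxonomy ids (`NA` allowed).
#' @param lineage ordered lineage, superkingdom first.
#' @return a validated [GenomeAssembly-class] object, genes sorted by
#'   contig, start, end.
#' @export
GenomeAssembly <- function(assemblyId, genes, taxId = NA_integer_,
                           speciesTaxId = NA_integer_,
                           lineage = character()) {
  if (!nrow(genes)) bail("assembly '", assemblyId, "' has no genes")
  if (is.null(genes$product)) genes$product <- "hypothetical protein"
  if (is.null(genes$translation)) genes$translation <- NA_character_
  if (is.null(genes$has_translation))
    genes$has_translation <- !is.na(genes$translation) &
      nzchar(genes$translation)
  if (is.null(genes$compound)) genes$compound <- FALSE
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes <- genes[order(genes$contig_id, genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  new("GenomeAssembly", assemblyId = assemblyId,
      taxId = as.integer(taxId), speciesTaxId = as.integer(speciesTaxId),
      lineage = as.character(lineage), genes = genes)
}

# --- GenBank flat files ------------------------------------------------

# parse a GenBank location string into (start0, end, strand, compound);
# 1-based inclusive in, 0-based half-open out
parseLocation <- function(loc, locus) {
  raw <- loc
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  compound <- FALSE
  if (grepl("^(join|order)\\(", loc)) {
    compound <- TRUE
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(\\d+)\\.\\.(\\d+)$", parts))
  if (any(lengths(m) != 3L))
    bail("malformed feature location '", raw, "' in locus ", locus)
  starts <- as.integer(vapply(m, `[`, "", 2L))
  ends <- as.integer(vapply(m, `[`, "", 3L))
  if (any(starts > ends))
    bail("malformed feature location '", raw, "' in locus ", locus)
  # compound/join locations collapse to their minimal span for
  # neighborhood-distance purposes; the record is flagged
  list(start = min(starts) - 1L, end = max(ends),
       strand = strand, compound = compound)
}

#' Parse a GenBank flat file into a GenomeAssembly
#'
#' Reads the CDS features (coordinates, strand, locus tag, product,
#' translation) of every record (contig) in a GenBank flat file.  GenBank's
#' 1-based inclusive coordinates become the internal 0-based half-open
#' convention.  Compound (`join`) locations are collapsed to their minimal
#' span and flagged; CDS without a `/translation` qualifier are retained
#' but flagged (`has_translation = FALSE`) so neighborhood geometry is
#' preserved while clustering skips them.
#'
#' Taxonomy (species tax id, lineage) is attached from `taxonomy` (see
#' [readTaxonomyTable()]) keyed by the assembly id found on the `DBLINK
#' Assembly:` line; an assembly absent from the table is admitted with a
#' warning and excluded from phyletic operations.
#'
#' @param path GenBank flat file (may contain multiple contig records).
#' @param taxonomy optional `data.frame` from [readTaxonomyTable()].
#' @return a [GenomeAssembly-class].
#' @export
parseGenBank <- function(path, taxonomy = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines)))
    bail("no GenBank records in '", path, "'")
  recStart <- grep("^LOCUS", lines)
  recEnd <- grep("^//\\s*$", lines)
  if (length(recEnd) < length(recStart))
    bail("unterminated GenBank record in '", path, "'")
  assembly <- NA_character_
  taxId <- NA_integer_
  rows <- vector("list", 0L)
  for (r in seq_along(recStart)) {
    rec <- lines[recStart[r]:recEnd[r]]
    locus <- strsplit(sub("^LOCUS\\s+", "", rec[1]), "\\s+")[[1]][1]
    dbl <- grep("Assembly:", rec, value = TRUE)
    if (length(dbl))
      assembly <- sub(".*Assembly:\\s*", "", dbl[1])
    featAt <- grep("^FEATURES", rec)
    if (!length(featAt)) next
    body <- rec[(featAt + 1L):length(rec)]
    body <- body[!grepl("^(ORIGIN|CONTIG|//)", body)]
    # feature lines start at column 6; qualifier/continuation at column 22
    isFeat <- grepl("^ {5}\\S", body)
    featIdx <- which(isFeat)
    for (k in seq_along(featIdx)) {
      i0 <- featIdx[k]
      i1 <- if (k < length(featIdx)) featIdx[k + 1L] - 1L else length(body)
      key <- sub("^\\s+", "", substr(body[i0], 1, 20))
      key <- sub("\\s.*$", "", key)
      block <- c(sub("^ {5}\\S+\\s+", "", body[i0]),
                 sub("^\\s+", "", body[(i0 + 1L):i1][i0 < i1]))
      # re-join qualifier lines: qualifiers start with '/'
      qStart <- c(1L, grep("^/", block))
      qStart <- sort(unique(qStart))
      pieces <- character(0)
      for (q in seq_along(qStart)) {
        a <- qStart[q]
        b <- if (q < length(qStart)) qStart[q + 1L] - 1L else length(block)
        pieces <- c(pieces, paste0(block[a:b], collapse = ""))
      }
      locStr <- pieces[1]
      quals <- pieces[-1]
      getQual <- function(name) {
        hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub("\"", "", sub(paste0("^/", name, "="), "", hit[1]))
      }
      if (key == "source") {
        tx <- getQual("db_xref")
        if (!is.na(tx) && grepl("^taxon:", tx))
          taxId <- as.integer(sub("^taxon:", "", tx))
        next
      }
      if (key != "CDS") next
      pos <- parseLocation(locStr, locus)
      tr <- getQual("translation")
      tag <- getQual("locus_tag")
      if (is.na(tag)) tag <- sprintf("%s_cds%04d", locus, k)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = tag, contig_id = locus,
        start = pos$start, end = pos$end, strand = pos$strand,
        product = if (is.na(getQual("product"))) "hypothetical protein"
                  else getQual("product"),
        translation = tr,
        has_translation = !is.na(tr) && nzchar(tr),
        compound = pos$compound,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) bail("no CDS features found in '", path, "'")
  genes <- do.call(rbind, rows)
  speciesTaxId <- NA_integer_
  lin <- character()
  if (!is.null(taxonomy) && !is.na(assembly) &&
      assembly %in% taxonomy$assembly_id) {
    row <- taxonomy[match(assembly, taxonomy$assembly_id), ]
    taxId <- as.integer(row$tax_id)
    speciesTaxId <- as.integer(row$species_tax_id)
    lin <- c(row$superkingdom, row$phylum, row$genus)
  } else if (!is.null(taxonomy)) {
    warning("assembly '", assembly,
            "' not in taxonomy table; excluded from phyletic operations",
            call. = FALSE)
  }
  GenomeAssembly(if (is.na(assembly)) basename(path) else assembly,
                 genes, taxId = taxId, speciesTaxId = speciesTaxId,
                 lineage = lin)
}

#' Write a GenomeAssembly as a GenBank flat file
#'
#' Emits one record per contig with `source` and `CDS` features.
#' Coordinates are converted back to 1-based inclusive; minus-strand genes
#' are written as `complement(a..b)`.  The assembly id is recorded on a
#' `DBLINK Assembly:` line so that [parseGenBank()] round-trips it.
#'
#' @param assembly a [GenomeAssembly-class].
#' @param path output file.
#' @param organism organism name written into the source feature.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(assembly, path, organism = "synthetic organism") {
  g <- genes(assembly)
  con <- file(path, "w")
  on.exit(close(con))
  wrap <- function(prefix, text, width = 58L) {
    chunks <- substring(text, seq(1L, nchar(text), width),
                        pmin(seq(1L, nchar(text), width) + width - 1L,
                             nchar(text)))
    c(paste0(prefix, chunks[1]),
      paste0(strrep(" ", 21L), chunks[-1]))
  }
  for (ctg in unique(g$contig_id)) {
    gg <- g[g$contig_id == ctg, , drop = FALSE]
    len <- max(gg$end) + 50L
    writeLines(sprintf(
      "LOCUS       %-16s %d bp    DNA     linear   BCT 01-JAN-2024",
      ctg, len), con)
    writeLines(sprintf("DEFINITION  %s, contig %s.", organism, ctg), con)
    writeLines(sprintf("ACCESSION   %s", ctg), con)
    writeLines(sprintf("DBLINK      Assembly: %s", assembly@assemblyId), con)
    writeLines(sprintf("SOURCE      %s", organism), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", len), con)
    writeLines(sprintf("                     /organism=\"%s\"", organism), con)
    if (!is.na(assembly@taxId))
      writeLines(sprintf("                     /db_xref=\"taxon:%d\"",
                         assembly@taxId), con)
    for (i in seq_len(nrow(gg))) {
      loc <- sprintf("%d..%d", gg$start[i] + 1L, gg$end[i])
      if (gg$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"",
                         gg$gene_id[i]), con)
      writeLines(sprintf("                     /product=\"%s\"",
                         gg$product[i]), con)
      if (gg$has_translation[i])
        writeLines(wrap("                     /translation=\"",
                        paste0(gg$translation[i], "\"")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

# --- FASTA -------------------------------------------------------------

#' Read / write protein FASTA
#'
#' Thin wrappers around Biostrings with the pipeline's validation: headers
#' must be unique, and for MSA inputs (`msa = TRUE`) characters must come
#' from the 20 amino acids plus `X`, `-` and `.`.
#'
#' @param path FASTA file.
#' @param msa validate as an aligned FASTA (equal lengths, gap characters
#'   allowed)?
#' @return named character vector of sequences.
#' @export
readProteinFasta <- function(path, msa = FALSE) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    bail("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(x))
  names(seqs) <- ids
  bad <- setdiff(unique(unlist(strsplit(seqs, ""))), c(AA20, MSA_EXTRA))
  if (length(bad))
    bail("non-amino-acid characters in '", path, "': ",
         paste(bad, collapse = ""))
  if (msa) {
    if (length(unique(nchar(seqs))) != 1L)
      bail("aligned FASTA must have equal-length rows")
  } else if (any(grepl("[-.]", seqs))) {
    bail("gap characters in unaligned FASTA '", path, "'")
  }
  seqs
}

#' @rdname readProteinFasta
#' @param records named character vector of sequences.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(records, path) {
  if (anyDuplicated(names(records))) bail("duplicate record ids")
  x <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

# --- taxonomy table ----------------------------------------------------

#' Read / write the assembly taxonomy table
#'
#' TSV with header columns `assembly_id`, `tax_id`, `species_tax_id`,
#' `genus`, `phylum`, `superkingdom`; one row per assembly, many
#' assemblies may share a `species_tax_id`.
#'
#' @param path TSV file.
#' @return `data.frame` with the six columns above.
#' @export
readTaxonomyTable <- function(path) {
  tt <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("assembly_id", "tax_id", "species_tax_id",
            "genus", "phylum", "superkingdom")
  if (!all(need %in% names(tt)))
    bail("taxonomy table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tt$assembly_id))
    bail("taxonomy table must have one row per assembly_id")
  tt
}

#' @rdname readTaxonomyTable
#' @param taxonomy the table to write.
#' @export
writeTaxonomyTable <- function(taxonomy, path) {
  write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
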