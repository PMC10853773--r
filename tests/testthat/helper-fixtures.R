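# Fixture builders exercising the phyletic summary arithmetic on
# species sets engineered to the headline counts of the Dnd survey
# (4287 modification-carrying taxa, 1798 restriction taxa, 316 with all
# eight genes, per-gene counts 1384/2227/3010/4018/4006/1798/1732/1688).

dndCountsFixture <- function() {
  species <- 1:5228
  fam <- list(
    DndA = 1:1384,
    DndB = 1:2227,
    DndC = 1:3010,
    DndD = 1:4018,                      # the DndD/CxC ABC-ATPase
    DndE = 1:4006,
    CxC  = 3900:4287,                   # related CxC-core systems
    DndF = c(1:316, 3747:4287, 4288:5228),
    DndG = c(1:316, 3813:4287, 4288:5228),          # F minus 66
    DndH = c(1:316, 3747:3812, 3923:4287, 4288:5228) # F minus 110
  )
  annotations <- do.call(rbind, lapply(names(fam), function(f)
    data.frame(assembly_id = sprintf("GCA_%07d.1", fam[[f]]),
               family = f, stringsAsFactors = FALSE)))
  nPhyla <- 20L
  taxonomy <- data.frame(
    assembly_id = sprintf("GCA_%07d.1", species),
    tax_id = 2000000L + species,
    species_tax_id = species,
    genus = sprintf("Genus%04d", (species - 1L) %/% 4L),
    phylum = sprintf("Phylum%02d", species %% nPhyla),
    superkingdom = ifelse(species > 4800, "Archaea", "Bacteria"),
    stringsAsFactors = FALSE)
  # duplicate assemblies for the first 10 species, splitting the
  # annotations across the two assemblies (exercises OR-aggregation)
  dup <- data.frame(
    assembly_id = sprintf("GCA_%07d.2", 1:10),
    tax_id = 3000000L + 1:10,
    species_tax_id = 1:10,
    genus = taxonomy$genus[1:10],
    phylum = taxonomy$phylum[1:10],
    superkingdom = taxonomy$superkingdom[1:10],
    stringsAsFactors = FALSE)
  moveMask <- annotations$assembly_id %in% sprintf("GCA_%07d.1", 1:10) &
    annotations$family %in% c("DndA", "DndF")
  annotations$assembly_id[moveMask] <-
    sub("\\.1$", ".2", annotations$assembly_id[moveMask])
  list(annotations = annotations, taxonomy = rbind(taxonomy, dup),
       expected = list(
         family = c(DndA = 1384L, DndB = 2227L, DndC = 3010L,
                    DndD = 4018L, DndE = 4006L, DndF = 1798L,
                    DndG = 1732L, DndH = 1688L),
         nSpecies = 5228L, modificationAny = 4287L,
         restrictionAny = 1798L, allEight = 316L))
}

dndModules <- function() {
  list(
    modification = moduleDefinition(
      "modification", "DndA | DndB | DndC | DndD | DndE | CxC"),
    core = moduleDefinition("core", "DndD & DndE"),
    restriction = moduleDefinition("restriction", "DndF & DndG & DndH"),
    restrictionAny = moduleDefinition("restrictionAny",
                                      "DndF | DndG | DndH"),
    allEight = moduleDefinition(
      "allEight",
      "DndA & DndB & DndC & DndD & DndE & DndF & DndG & DndH"))
}

# 401 bacterial + 39 archaeal genera absent from the reference survey,
# each spread over 1-3 species with 1-2 assemblies, mixed with known
# genera that are all present in the reference list
genusNoveltyFixture <- function(seed = 42L) {
  withr::with_seed(seed, {
    rows <- list()
    addGenus <- function(rows, genus, sk, known) {
      nSpecies <- sample(1:3, 1L)
      for (s in seq_len(nSpecies)) {
        sp <- 10000L * length(rows) + s + 1L
        for (a in seq_len(sample(1:2, 1L))) {
          rows[[length(rows) + 1L]] <- data.frame(
            assembly_id = sprintf("GCA_N%05d.%d", length(rows) + 1L, a),
            tax_id = 5000000L + length(rows),
            species_tax_id = sp,
            genus = genus, phylum = paste0(sk, "_phylum"),
            superkingdom = sk, stringsAsFactors = FALSE)
        }
      }
      rows
    }
    known <- sprintf("KnownGenus%03d", 1:50)
    for (g in sprintf("NovelBact%03d", 1:401))
      rows <- addGenus(rows, g, "Bacteria", FALSE)
    for (g in sprintf("NovelArch%03d", 1:39))
      rows <- addGenus(rows, g, "Archaea", FALSE)
    for (g in known[1:30])
      rows <- addGenus(rows, g, "Bacteria", TRUE)
    taxonomy <- do.call(rbind, rows)
    taxonomy <- taxonomy[!duplicated(taxonomy$assembly_id), ]
    # species_tax_id must be unique per species, not per assembly row;
    # collapse duplicates introduced by the generator
    annotations <- data.frame(assembly_id = taxonomy$assembly_id,
                              family = "DndE", stringsAsFactors = FALSE)
    list(annotations = annotations, taxonomy = taxonomy,
         reference = known)
  })
}

# small annotated assembly built directly from a gene table
toyAssembly <- function() {
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:7),
    contig_id = "c1",
    start = c(0L, 300L, 700L, 1100L, 1500L, 2200L, 2600L),
    end   = c(200L, 600L, 1000L, 1400L, 2000L, 2500L, 2900L),
    strand = c("+", "+", "+", "+", "+", "-", "+"),
    product = "p",
    translation = strrep("MKVL", 10),
    stringsAsFactors = FALSE)
  GenomeAssembly("GCA_TOY00001.1", genes, taxId = 1L, speciesTaxId = 1L,
                 lineage = c("Bacteria", "PhylumT", "GenusT"))
}
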