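#' Build a species-level presence/absence matrix
#'
#' Aggregates family annotations over assemblies into one row per
#' species-level taxonomy id: a family is present in a species when any
#' assembly of that species carries it (OR-aggregation).  This is the
#' deduplication that keeps database redundancy -- many assemblies per
#' taxon -- from inflating phyletic counts.  Assemblies without a
#' `species_tax_id` in the taxonomy table are excluded with a warning.
#'
#' @param annotations `data.frame` with columns `assembly_id`, `family`
#'   (one row per detected family occurrence; duplicates are harmless).
#' @param taxonomy taxonomy table ([readTaxonomyTable()] layout).  Every
#'   species listed here gets a row, so species in which no family was
#'   detected appear as all-`FALSE` rows.
#' @return a [PresenceAbsenceMatrix-class].
#' @export
buildPAM <- function(annotations, taxonomy) {
  stopifnot(all(c("assembly_id", "family") %in% names(annotations)))
  bad <- is.na(taxonomy$species_tax_id)
  if (any(bad)) {
    warning(sum(bad), " assembly(ies) lack species_tax_id; excluded",
            call. = FALSE)
    taxonomy <- taxonomy[!bad, , drop = FALSE]
  }
  orphan <- !(annotations$assembly_id %in% taxonomy$assembly_id)
  if (any(orphan)) {
    warning("annotations for ", length(unique(
      annotations$assembly_id[orphan])),
      " assembly(ies) missing from the taxonomy table; excluded",
      call. = FALSE)
    annotations <- annotations[!orphan, , drop = FALSE]
  }
  species <- sort(unique(taxonomy$species_tax_id))
  fams <- sort(unique(annotations$family))
  mat <- matrix(FALSE, length(species), length(fams),
                dimnames = list(as.character(species), fams))
  if (nrow(annotations)) {
    sp <- taxonomy$species_tax_id[match(annotations$assembly_id,
                                        taxonomy$assembly_id)]
    mat[cbind(as.character(sp), annotations$family)] <- TRUE
  }
  first <- taxonomy[!duplicated(taxonomy$species_tax_id), , drop = FALSE]
  first <- first[match(species, first$species_tax_id), , drop = FALSE]
  meta <- data.frame(species_tax_id = species,
                     genus = first$genus, phylum = first$phylum,
                     superkingdom = first$superkingdom,
                     stringsAsFactors = FALSE)
  new("PresenceAbsenceMatrix", mat = mat, meta = meta)
}

#' Define a gene-family module by a completeness rule
#'
#' A module is a named boolean rule over family columns, e.g.
#' `"(DndD | CxC) & DndE"` for the obligate modification core or
#' `"DndF & DndG & DndH"` for the restriction module.  Rules are kept as
#' configuration (strings / TSV), not code, because several groupings are
#' analysed side by side.
#'
#' @param name module name.
#' @param rule boolean expression over family column names using `&`,
#'   `|`, `!` and parentheses.
#' @return a list of class `ModuleDefinition`.
#' @export
moduleDefinition <- function(name, rule) {
  structure(list(name = name, rule = rule), class = "ModuleDefinition")
}

#' Read module definitions from TSV
#'
#' Expects header columns `module_name` and `rule`.
#'
#' @param path TSV file.
#' @return list of [moduleDefinition()] objects.
#' @export
readModuleDefinitions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("module_name", "rule") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i)
    moduleDefinition(df$module_name[i], df$rule[i]))
}

evalRule <- function(pam, module) {
  mat <- pamMatrix(pam)
  vars <- all.vars(parse(text = module$rule))
  missingCols <- setdiff(vars, colnames(mat))
  if (length(missingCols))
    bail("module '", module$name, "' references unknown families: ",
         paste(missingCols, collapse = ", "))
  env <- as.data.frame(mat)
  as.logical(eval(parse(text = module$rule), envir = env))
}

#' Species counts per family, per module, and per phylum
#'
#' @param pam a [PresenceAbsenceMatrix-class].
#' @param modules list of [moduleDefinition()] objects.
#' @return list with `family` (family, n_species), `module`
#'   (module, n_species), and `familyByPhylum` (family, phylum,
#'   n_species) -- the table behind a phylum-by-family heatmap.
#' @export
moduleCounts <- function(pam, modules = list()) {
  mat <- pamMatrix(pam)
  meta <- pamMeta(pam)
  fam <- data.frame(family = colnames(mat), n_species = unname(colSums(mat)),
                    stringsAsFactors = FALSE)
  mod <- data.frame(module = vapply(modules, `[[`, "", "name"),
                    n_species = vapply(modules, function(m)
                      sum(evalRule(pam, m)), 0),
                    stringsAsFactors = FALSE)
  byPhy <- do.call(rbind, lapply(colnames(mat), function(f) {
    tab <- tapply(mat[, f], meta$phylum, sum)
    data.frame(family = f, phylum = names(tab),
               n_species = as.integer(tab), stringsAsFactors = FALSE)
  }))
  rownames(byPhy) <- NULL
  list(family = fam, module = mod, familyByPhylum = byPhy)
}

#' Integer percentages under an explicit rounding policy
#'
#' `floor` (the default) truncates `100 * num / den`; `round` rounds
#' half-up.  The policy used is recorded as an attribute so summary
#' tables are self-describing.
#'
#' @param num,den numerator and denominator (vectorised; `den > 0`).
#' @param policy `"floor"` or `"round"`.
#' @return integer percentages with attribute `policy`.
#' @export
pct <- function(num, den, policy = c("floor", "round")) {
  policy <- match.arg(policy)
  if (any(den <= 0)) bail("pct: denominator must be positive")
  x <- 100 * num / den
  out <- as.integer(if (policy == "floor") floor(x) else roundHalfUp(x))
  attr(out, "policy") <- policy
  out
}

#' Co-occurrence of two modules across species
#'
#' The 2x2 species-level contingency of two module rules (both, A only,
#' B only, neither), percentages of the overlap relative to each module,
#' and a per-phylum stratification -- the arithmetic behind statements
#' such as "all eight genes co-occur in only 7% of
#' modification-carrying taxa".
#'
#' @param pam a [PresenceAbsenceMatrix-class].
#' @param moduleA,moduleB [moduleDefinition()] objects.
#' @param policy percentage policy, see [pct()].
#' @return list with `counts` (both/A_only/B_only/neither),
#'   `pct_both_of_A`, `pct_both_of_B`, and `byPhylum`.
#' @export
cooccurrenceSummary <- function(pam, moduleA, moduleB,
                                policy = c("floor", "round")) {
  policy <- match.arg(policy)
  a <- evalRule(pam, moduleA)
  b <- evalRule(pam, moduleB)
  meta <- pamMeta(pam)
  counts <- c(both = sum(a & b), A_only = sum(a & !b),
              B_only = sum(!a & b), neither = sum(!a & !b))
  byPhy <- do.call(rbind, lapply(split(seq_along(a), meta$phylum),
    function(idx) data.frame(
      phylum = meta$phylum[idx[1]],
      both = sum(a[idx] & b[idx]), A_only = sum(a[idx] & !b[idx]),
      B_only = sum(!a[idx] & b[idx]), neither = sum(!a[idx] & !b[idx]),
      stringsAsFactors = FALSE)))
  rownames(byPhy) <- NULL
  list(counts = counts,
       pct_both_of_A = if (sum(a)) pct(counts[["both"]], sum(a), policy)
                       else NA_integer_,
       pct_both_of_B = if (sum(b)) pct(counts[["both"]], sum(b), policy)
                       else NA_integer_,
       byPhylum = byPhy)
}

#' Count genera absent from a reference list
#'
#' Deduplicates genus labels across species (and therefore across
#' assemblies) and reports how many are missing from a reference set of
#' previously surveyed genera, per superkingdom and in total.
#'
#' @param pam a [PresenceAbsenceMatrix-class]; only species carrying at
#'   least one family (any `TRUE` cell) are considered detected.
#' @param referenceGenera character vector of known genus labels.
#' @return list with `total`, `bySuperkingdom` (named integer), and
#'   `genera` (the novel labels).
#' @export
genusNovelty <- function(pam, referenceGenera) {
  meta <- pamMeta(pam)
  detected <- rowSums(pamMatrix(pam)) > 0
  meta <- meta[detected, , drop = FALSE]
  u <- meta[!duplicated(meta$genus), , drop = FALSE]
  novel <- u[!(u$genus %in% referenceGenera), , drop = FALSE]
  bySk <- table(novel$superkingdom)
  list(total = nrow(novel),
       bySuperkingdom = stats::setNames(as.integer(bySk), names(bySk)),
       genera = novel$genus)
}

#' Write a presence/absence matrix (and summaries) as TSV
#'
#' @param pam a [PresenceAbsenceMatrix-class].
#' @param path output file; columns are `species_tax_id`, the metadata,
#'   then one 0/1 column per family.
#' @export
writePAM <- function(pam, path) {
  df <- cbind(pamMeta(pam),
              as.data.frame(pamMatrix(pam) * 1L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
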