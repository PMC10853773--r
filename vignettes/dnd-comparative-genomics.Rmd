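---
title: "Methods: neighborhood, clustering, phyletic and phylogenetic analysis of Dnd systems"
author: "dndscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neighborhood, clustering, phyletic and phylogenetic analysis of Dnd systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dndscape)
```

# Scope and model

`dndscape` implements the comparative-genomics workflow used to
characterise prokaryotic defense operons such as the DndABCDE
phosphorothioate modification module and the DndFGH restriction module:
reconstruct the gene neighborhoods around anchor genes, group the
encoded proteins into homolog families, profile family presence/absence
across a deduplicated species set, and quantify coevolution and
repeated acquisition on gene trees.  Everything runs at desk scale on
deterministic inputs; the synthetic-data generators supply genomes,
families and alignments with planted ground truth so that every stage
can be scored exactly.

# Coordinates and the genome model

Internally all gene coordinates are 0-based, half-open; GenBank input
(1-based, inclusive) is converted on parse and converted back on write,
so the two conventions never mix.  Compound (`join`) CDS locations are
collapsed to their minimal span and flagged: the neighborhood logic
operates on gene-level spans, and a spliced representation would add
nothing to intergenic distances.  CDS features without a `/translation`
qualifier are kept (flagged) so that neighborhood geometry is not
distorted by annotation gaps, but they are excluded from clustering.
Neighborhoods truncated by a contig edge carry a flag rather than a
guess about what lay beyond the break — fragmentary assemblies are a
documented source of spurious absences in this kind of survey, and the
flag lets downstream counting decide how to treat them.

# Neighborhoods and validity filters

A neighborhood is the `W` genes (default 5) on each side of an anchor
on its contig.  Three filters define a *valid* conserved architecture:

* **Intergenic distance.**  The gap between consecutive run members is
  `next.start − prev.end` (the count of nucleotides strictly between
  the genes; overlapping genes count 0).  The ceiling defaults to
  100 nt and is boundary-inclusive: a 100 nt gap continues the run, a
  101 nt gap stops it.  Inclusivity makes the default value itself
  meaningful rather than an off-by-one curiosity.
* **Directionality.**  The operon proxy is the maximal run of
  consecutive genes on the anchor's strand containing the anchor.  A
  strand flip delimits the run rather than invalidating the
  neighborhood, because adjacent divergently oriented systems are a
  real and informative configuration.
* **Phylum spread.**  An architecture must be supported in at least 2
  distinct phyla (configurable).  Conservation across distant taxa is
  what distinguishes a functional gene block from lineage-local noise.

Pattern identity is the ordered tuple of family labels with
anchor-relative strand signs, with the anchor normalised to the plus
strand; a reverse-complemented cassette therefore folds into the same
pattern.  Gap magnitudes are deliberately not part of pattern identity:
conserved architectures are order/strand diagrams, and gap variation
within the ceiling is biologically uninformative at this resolution.

# Clustering: L/S thresholds and single linkage

Pairwise similarity uses exhaustive Needleman–Wunsch global alignment
(BLOSUM62, affine gap open 11 / extend 1, `X` scored 0 against
everything) rather than a heuristic local search engine: inputs are
desk-scale, and exact DP is reproducible and oracle-checkable.  Percent
identity is computed over all alignment columns (gap columns in the
denominator); coverage is the fraction of the shorter sequence aligned
residue-to-residue.  A pair is connected when coverage ≥ `L` and the
score metric ≥ `S`; `S` is percent identity in `identity` mode, or
score × 0.267 / aligned columns in `bits` mode — an approximate
lambda-to-bits scaling that preserves bits-per-residue semantics
without the full Karlin–Altschul machinery, and is documented as an
approximation.  Clusters are connected components of the threshold
graph (single linkage), numbered deterministically by smallest member
id, with the longest member (ties lexicographic) as representative.

Singlet merging automates the judgment call of folding a divergent
sequence into an established family.  It requires *both* a reciprocal
best hit into the target cluster *and* a shared neighborhood
architecture with at least one member.  The conjunction is deliberately
conservative — automation should not loosely reproduce manual curation —
and a `requireBoth = FALSE` flag exposes the disjunctive reading.

The CLANS-style map (`clansEmbed()`) uses attraction proportional to
normalised bit weight times separation and inverse-square repulsion
between all pairs, with an annealing step size; given a seed it is
fully deterministic, and a single node sits at the origin.  Cluster
labels come from single linkage on embedded distances cut at a stated
radius.

# Phyletic profiling

All counting is at the level of species tax IDs, not genomes: a family
is present in a species when *any* assembly of that species carries it.
The OR-aggregation avoids inflating counts through database redundancy
while not penalising fragmented assemblies in which different genes
survive in different assembly versions.  Module completeness rules
(e.g. `(DndD | CxC) & DndE` for the obligate modification core,
`DndF & DndG & DndH` for restriction) are configuration strings, not
code, because several groupings are routinely analysed side by side.

Integer percentages use a floor (truncation) policy by default, with
half-up rounding exposed as an alternative; the policy is recorded in
the output.  Published percentage sets of this kind are often mutually
inconsistent under any single rounding rule (e.g. a value printed as
51% that rounds to 52%, alongside one printed as 80% that floors to
79%), so the package makes the policy explicit instead of chasing any
particular printed table; floor reproduces the majority of such
tables, and the worked-example fixtures in the test suite only assert
cases that are stable under the stated policy.  Likewise, where a
co-occurrence fraction is quoted against "all recovered taxa" but is
arithmetically a fraction of the modification-carrying subset, the
package computes it against the subset that makes the arithmetic
consistent.

# Entropy under two alphabets

For a column with residue-type fractions \(P_i\) over \(M\) observed
types, \(H = -\sum_{i=1}^{M} P_i \log_2 P_i\) bits.  The bounds are 0
(one residue type) and \(\log_2 20 \approx 4.32\) (all twenty equally
represented), which forces the negative sign even where the formula is
sometimes printed without it.  Gaps and `X` are excluded and \(P\) is
renormalised over the `n_eff` observed residues: exclusion keeps the
0–4.32 range exact, whereas counting gaps as a 21st type would break
it.  This gap handling is a documented package decision, not a claim
about any particular published profile.  An all-gap column has no
defined entropy and is returned as `NA`, never 0.  The reduced 8-class
alphabet — {L,V,I,M,C} {A,G} {S,T} {P} {F,Y,W} {E,D,N,Q} {K,R} {H} — is
a standard hydrophobicity/charge grouping consistent with the property
classes (hydrophobic, small, polar, aromatic, charged) used when
colouring such alignments; no single canonical 8-letter scheme exists,
so the mapping is an overridable option
(`options(dndscape.reduced8 = ...)`).  Since the reduction merges
categories, reduced-alphabet entropy can never exceed full-alphabet
entropy — high entropy in *both* alphabets flags positions selected
for chemical diversity.

# Trees, congruence, capture clades

Tree inference here is deliberately modest: neighbor-joining on
`1 − fractional identity` distances (a Poisson correction is available
by flag), with negative branch lengths clamped to zero.  NJ is exact on
additive matrices, deterministic, and sufficient for the topology-level
statistics the package computes; likelihood inference is out of scope.
Robinson–Foulds distance counts bipartitions unique to either tree.

`cladeCongruence()` formalises the mirror-tree question for operonic
dyads such as the DndD/CxC ATPase and DndE: the pairing induces two
label vectors, agreement is scored under the optimal one-to-one label
matching (a Hungarian assignment on the contingency table), and the
adjusted Rand index gives the chance-corrected summary.  The degenerate
single-cluster-on-both-sides case is defined as ARI 1 with a warning
flag: it avoids NaN propagation while remaining visible.

`countCaptureClades()` formalises repeated domain acquisition: the
number of maximal subtrees consisting solely of labeled tips, under
rooting in the unlabeled context.  Because a labeled-only subtree can
never contain an unlabeled tip, the count is invariant to which
unlabeled-adjacent rooting is chosen; the tests verify this against a
brute-force edge-side enumeration.  A count of 1 is monophyly; a count
of 6 across a radiation of HerA/FtsK-like translocase domains is six
independent captures.

# Synthetic data: what it emulates, and what it does not

The generators are first-class, tested code, and their defaults are the
study conditions for the test suite:

* `genGenomes()` — multi-assembly, multi-phylum genome sets (defaults:
  3 phyla × 4 species × 2 assemblies) carrying a planted cassette
  (default `DndD–DndE–DndC`, 50 nt gaps, 25% of assemblies on the minus
  strand) among random decoy genes.  Decoy proteins are independent
  random sequences, so they cannot cluster with planted families at
  sane parameters and ground truth stays unambiguous.
* `genFamily()` — a root sequence spawns major-clade ancestors (rate
  0.55), subclade ancestors (rate 0.40) and members (rate 0.05), with
  per-site uniform replacement over the 19 alternatives.  The uniform
  model keeps expected identity in closed form
  (`(1−r)² + r²/19` for two descendants at rate `r`), which is what
  makes the generator itself testable to ±3 identity points.  Two
  clades of six subclades each mirror the clade-1.1–1.6 / 2.1–2.6
  structure seen in DndE.
* `genPairedFamilies()` — perfect mode pairs member *i* of A-subclade
  *s* with member *i* of B-subclade *s*; `shuffle = p` permutes the
  partners of a fraction *p* of pairs, driving congruence toward
  chance at `p = 1` while keeping the pairing a bijection.
* `genMsa()` — i.i.d. columns from per-column compositions, with an
  exact-counts mode that realises the analytic entropy extremes.
* One master seed fans out to per-component RNG streams, so components
  regenerate independently and runs are byte-identical.

What the generators do **not** emulate: homologous recombination,
rate heterogeneity across sites (a flagged extension point),
insertions/deletions within families (members are equal-length, so
planted identity is Hamming identity), pseudogenisation, contig
fragmentation beyond simple truncation, and any real taxonomy.  A
green suite therefore demonstrates that the machinery is correct on
data matching its assumptions, not that real GenBank annotation noise
is handled gracefully.

# Numerical choices and problem sizes

Deterministic tie-breaks throughout: cluster numbering by smallest
member id, representatives longest-then-lexicographic, NJ via a
deterministic implementation.  Alignment of an empty sequence, a
denominator of zero, inverted divergence rates, a labeled set equal to
all tips, and an empty pairing are errors, not silent defaults.  The
test suite runs at sizes chosen to keep the full run around a minute
while still separating signal from noise: 200 alignment-oracle pairs at
up to 60 residues, 50 clustering-oracle seeds, 100 tree pairs for the
Robinson–Foulds oracle, 200 NJ-exactness seeds at up to 12 taxa,
10,000 random columns for the entropy inequality, and 100 seeds of the
six-capture simulation.

# Known limitations

* The bits-mode threshold is an approximation to database-search bit
  scores; use identity mode where exactness matters.
* `mergeSinglets()` consults best hits only through the recorded pair
  table; sequences absent from the clustering run cannot attract
  merges.
* NJ trees inherit the noise of identity distances at high divergence;
  they are context for congruence statistics, not publication-grade
  phylogenies.
* GenBank parsing targets the annotated-CDS dialect the pipeline needs
  (LOCUS/DBLINK/FEATURES with `source` and `CDS`); it is not a general
  GenBank reader.
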