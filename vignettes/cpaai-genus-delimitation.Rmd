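---
title: "Genus delimitation with core-proteome amino acid identity"
author: "cpaaiDelimit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genus delimitation with core-proteome amino acid identity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpaaiDelimit)
```

# The problem

Bacterial genera are increasingly delimited from whole-genome data rather
than phenotype. A practical and reproducible recipe, used extensively for
the family *Rhizobiaceae*, combines three ingredients:

1. a **core-proteome average amino acid identity (cpAAI)** matrix computed
   from a concatenated alignment of a fixed panel of marker proteins,
2. a **phylogenomic tree** over the same strains, and
3. the requirement that every genus be **monophyletic**.

A cpAAI threshold of roughly 86.5% separates most genera; where threshold
clustering and tree topology disagree, a slightly higher threshold is
explored locally because monophyly is non-negotiable while the threshold
is only a guideline. Species-level questions (synonymous names) are
settled with overall genome relatedness indices: an average nucleotide
identity (ANI) screen at 95%, a 96% ANI species cut-off, and the 70%
digital DNA-DNA hybridization (dDDH) rule.

cpaaiDelimit implements this workflow end to end at desk scale: marker
extraction from assemblies, supermatrix construction, cpAAI, tree
building and monophyly testing, genus delimitation, and the synonymy
decision rule, plus a calibrated synthetic-data generator so that every
stage can be validated against planted ground truth without downloading
genomes.

# The model and its statistics

## cpAAI

For strains $i, j$ with aligned supermatrix rows $x_i, x_j$ of width $L$,

$$\mathrm{cpAAI}(i,j) = 100 \times
  \frac{\#\{c : x_{ic} = x_{jc},\ c \in C_{ij}\}}{|C_{ij}|},
  \qquad
  C_{ij} = \{c : x_{ic}, x_{jc} \notin \{\text{'-'}, \mathrm{X}\}\}.$$

This is the *pairwise deletion* p-distance on amino acids, scaled to a
percentage and subtracted from 100. Two consequences drive the design:

* **Gap proteins.** A marker missing from one assembly is replaced by an
  all-X placeholder of reference length before alignment. Because X is in
  the missing set, the placeholder contributes no columns to $C_{ij}$ for
  any pair that involves it — the missing marker is statistically
  invisible. The test suite asserts this *placeholder neutrality*
  exactly: cpAAI with an all-X marker equals cpAAI with that marker's
  columns deleted.
* **X as missing, not as a 21st state.** Counting X as a residue would
  make a placeholder count as 0% identity against everything, defeating
  the padding. The missing set is exposed as an argument
  (`missingChars`) for users who want different semantics.

## Marker extraction

Markers are located by a six-frame translated homology search: each
contig is translated in all six frames (stops as `*`, N-containing
codons as X), frames are split into stop-free segments, and segments
that share a length-4 amino-acid word with a reference marker are
locally aligned to it with BLOSUM62 (X scored 0 against everything,
affine gap open 11 / extend 1). Per marker the single best-scoring hit
is kept if its score is at least 50 matrix units and it covers at least
50% of the reference. These two acceptance thresholds are this package's
choice: they reject every hit on i.i.d. random genomes (tested over
several seeds) while retaining markers diverged by 30% or more from the
reference. Ties break deterministically (contig id, then start, then +
strand). Because alignment happens inside stop-free segments, a reported
hit never crosses a stop codon; a marker interrupted by an internal stop
contributes its best single segment. Coordinates are 0-based half-open
on the forward strand internally and 1-based inclusive in written
reports.

An external translated-search or alignment tool can replace the
built-in stages (`alignerCmd`, `trimmerCmd` accept `{input}`/`{output}`
command templates); the built-in path keeps the toolkit dependency-free
and deterministic.

## Alignment and trimming

The built-in per-marker aligner is a deterministic center-star
progressive alignment: the center is the sequence with the maximal
summed pairwise global-alignment score (ties broken by input order), all
other sequences are aligned to it, and the pairwise alignments are
merged under once-a-gap-always-a-gap. This is not a re-implementation of
any production multiple aligner — it is a transparent, testable
surrogate whose sum-of-pairs score provably beats naive padding on the
suite's fixtures, and the external-command hook exists precisely because
production users will plug in a real aligner. Switching aligners shifts
cpAAI slightly (historically on the order of half a percent), which is
one reason the genus threshold is treated as a guideline.

Trimming removes columns whose gap fraction strictly exceeds
`maxGapFraction` (default 0.9). Only `-` counts as a gap here: X counts
as a residue so that placeholder-heavy columns — which carry the
pairwise-deletion semantics — are not destroyed before cpAAI sees them.
The production heuristic this stands in for is a named third-party
trimmer; the gap-fraction rule is a documented approximation, and an
external trimmer can be plugged in.

## Tree building and monophyly

The built-in tree is neighbor joining on the percent difference
$100 - \mathrm{cpAAI}$, with negative branch lengths clamped to zero
(the clamped deficit is reported). Maximum-likelihood inference, model
selection and branch-support resampling are deliberately out of scope:
the delimitation logic needs only topology and rooting, and an
externally inferred tree in newick format can be ingested instead.
Rooting is strictly outgroup-based: the outgroup must be a clan (one
side of an edge) of the unrooted tree, and the root is placed at the
midpoint of the separating edge. Monophyly of a leaf set is decided by
comparing it with the tip set under its most recent common ancestor,
and is tested exhaustively against brute-force clade enumeration.

## Delimitation

Clusters are connected components of the graph with an edge wherever
cpAAI $\ge \tau$ (single linkage; order-independent and faithful to the
"clean separation" idea; complete linkage is available as a sensitivity
flag). Defaults: $\tau = 86.5$, raised locally in steps of 0.1 up to
$\tau_{\max} = 89$. A non-monophyletic cluster is re-clustered among its
own members at the smallest raised threshold at which every resulting
sub-cluster is monophyletic; raising is always local to the cluster,
mirroring per-clade reasoning, and the cap guards against over-splitting.
If no threshold up to the cap separates the members cleanly, the cluster
is surfaced as `manual_review` with its cpAAI evidence printed — expert
judgment calls (for instance keeping a clade together because all values
are "reasonably close" to the threshold) are deliberately not automated.

Proposed actions follow the type-species logic: a cluster anchored by
exactly one genus type species keeps that name and mislabelled members
become transfer proposals; two or more type species in one cluster flags
a merge; none flags a novel genus with a placeholder name; a named genus
scattered over several clusters is flagged paraphyletic. Every action
cites the cluster's minimum within-cpAAI, its maximum cpAAI to the
outside, and its monophyly status.

## Species synonymy

The decision rule for a strain pair, in order: ANI below 95 → distinct;
ANI at or above 95 without dDDH → needs dDDH; dDDH $\ge 70$ and ANI
above 96 → synonym; dDDH below 70 → distinct; dDDH $\ge 70$ but ANI at
or most 96 → conflict, flagged rather than silently resolved (the
reference data never exercise this branch). dDDH is always consumed from
tables, never computed — its defining formulas belong to an external
calculator. The packaged fixture of ten Rhizobiaceae type-strain pairs
reproduces the published screen: eight distinct pairs and two
heterotypic synonyms.

The built-in ANI estimator cuts the query into 1020-bp fragments, places
each on the subject via exact 16-mer seeds on both strands, aligns
locally, and averages the identity of fragments passing the classical
30%-identity / 70%-coverage filters, averaging both directions in
symmetric mode. It is a transparent fragment-based estimator, not a
sketch-based tool; all reference-facing results flow through the table
path. Calibration: on 200-kb genomes mutated site-wise at rate $d$, the
estimate lands within one percentage point of $100(1-d)$, and identical
or reverse-complemented copies give exactly 100.

# The synthetic-data generator

`simulateTree()` plants an ultrametric tree in which each genus is a
clade: leaves at height 0, genus crowns at `withinDepth`, all genus
ancestors joining at `betweenDepth` (the root polytomy is resolved with
zero-length edges). `evolveMarkers()` draws i.i.d. uniform root proteins
and applies Poisson substitution with uniform replacement, so two leaves
at path length $\ell$ have expected identity

$$100\left(e^{-r\ell} + \frac{1 - e^{-r\ell}}{20}\right),$$

which `expectedIdentity()` exposes. The package defaults invert this
formula: `withinDepth = 0.044` and `betweenDepth = 0.118` at rate 1 put
crown within-genus pairs at cpAAI 92.0 and between-genus pairs at 80.0 —
comfortably either side of the 86.5 threshold, the regime the
delimitation logic is designed for. `buildGenomes()` reverse-translates
each marker with uniform synonymous-codon choice and scatters markers
over random strands and orders with random intergenic spacers, recording
every placement and dropout as ground truth; `mutateGenome()` provides
site-wise divergence for ANI calibration.

What the generator does **not** emulate: indel evolution within markers
(substitutions only), genome architecture (operons, GC skew, repeats),
empirical amino-acid exchangeabilities, horizontal transfer, and
contamination. Passing the end-to-end tests therefore demonstrates that
the machinery is correct under the stated model, not that real
assemblies are free of the upstream complications (fragmented or
contaminated assemblies, paralogy) that practitioners must still watch
for.

# Numerical choices and degenerate inputs

* Thresholds are percentages in $[0, 100]$ throughout; raised thresholds
  are reported to the 0.1 step they were found at.
* Ties in the marker search, the center-star center choice, NJ input,
  and cluster ordering are all broken deterministically; rerunning the
  pipeline on identical inputs is checksum-identical (asserted via the
  manifest).
* A pair with zero comparable supermatrix columns (disjoint placeholder
  patterns) is an error naming the pair, not a silent NA.
* Trimming that would delete every column errors with a suggestion to
  raise the threshold; a two-genome dataset errors at the tree stage.
* An ANI query with no aligning fragment yields an NA record flagged
  "not comparable" with a warning.
* Newick round-trips preserve topology, labels and branch lengths to
  $10^{-9}$.

# Problem sizes used in validation

The shipped validation suite runs entirely from simulation: supermatrix
checks at 20 strains × 5,000 columns; NJ recovery on random binary trees
up to 12 leaves over 10 seeds; monophyly against exhaustive enumeration
on trees up to 8 leaves; the full pipeline on five replicates of 5
genera × 4 strains with a 24-marker × 100-residue panel; ANI calibration
on 200-kb genomes. These sizes were chosen so the whole suite completes
in a few minutes on a single core while every statistical check retains
enough sites for its stated sampling bounds; the machinery itself has no
hard-coded size limits, and the 170-marker defaults of the panel
generator match the real Rhizobiaceae panel.

# Known limitations

* The built-in aligner and ANI estimator are desk-scale surrogates;
  production analyses should plug in external tools via the command
  hooks and table ingestion.
* dDDH is never computed.
* The delimitation logic reports evidence and flags judgment calls; it
  does not make nomenclatural decisions, and placeholder names
  (`NOVEL-1`, ...) are not proposals.
* Threshold raising explores only upward adjustments, as the workflow
  prescribes; lowering a threshold to merge clusters is left to the
  analyst.

# A compact worked example

```{r example, eval = FALSE}
ds <- simulateDataset(nGenera = 3, strainsPerGenus = 3,
                      nMarkers = 10, markerLengths = 80, seed = 1)
cfg <- pipelineConfig(ds$genomes, ds$panel, ds$metadata,
                      outDir = tempfile("demo"),
                      outgroup = names(ds$genusAssignment)[
                        ds$genusAssignment == "G1"])
res <- runPipeline(cfg)
clusterTable(res$partition)
synonymyReport(readOgriTable(system.file("extdata",
  "rhizobiaceae_type_strain_ogri.tsv", package = "cpaaiDelimit")))$counts
```
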