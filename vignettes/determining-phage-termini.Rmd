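---
title: "Determining bacteriophage genome termini from run-off reads"
author: "phageTermini"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining bacteriophage genome termini from run-off reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(phageTermini)
```

## The problem

Shotgun assembly of a linear double-stranded phage genome almost always
returns a *circular* contig: the physical DNA ends are joined in silico
because terminally redundant or cohesive genomes carry the same sequence at
both ends. The assembly is a faithful map of the gene content, but it erases
the one property that governs packaging and cloning: **where the physical
molecule starts and ends, and what the ends look like**.

`phageTermini` implements the classical wet-lab strategy for answering this
question as an in silico workflow:

1. find restriction enzymes that cut the genome exactly once
   (`singleCutters`), so that a digest releases two *terminal* fragments;
2. obtain run-off sequencing reads off the two physical ends
   (in the package these come from `simulateTerminalReads`, which models a
   primer-extension reaction that polymerizes to the end of its template
   strand and stops);
3. map both reads onto the circular assembly and classify the terminus
   (`classifyTermini`);
4. rebuild the physical molecule (`reconstructPhysical`) and check the
   chemistry with an in silico S1 nuclease digestion (`s1Trim`): cohesive
   (single-stranded) overhangs are trimmed away, a double-stranded terminal
   repeat is S1-resistant.

## The model

A physical molecule is represented by its **union sequence** `u` — the
top-strand sense sequence covering everything either strand contains — plus
the architecture and repeat/overhang length `L`:

* `blunt`: both strands run `1..n`; `L = 0`.
* `cos_5`: the bottom strand protrudes; top strand covers `1..n-L`,
  bottom covers `L+1..n` (in top coordinates). After circularization the
  overhang appears once.
* `cos_3`: the top strand protrudes on both ends, mirrored.
* `dtr` (direct terminal repeat): both strands are flush and the first `L`
  bases equal the last `L` bases; the repeat is fully double-stranded.

The circular assembly of all four architectures is the same object: the unit
circle of length `n_unit`, with the repeat/overhang collapsed to a single
copy.

### Classification

Both run-off reads are mapped *exactly* onto the doubled unit circle (the
minus read as its reverse complement). Let `a` be the unit-circle position
where the left read ends and `b` where the right read ends. The two reads
approach the junction from opposite sides, and three situations arise:

* the reads stop at adjacent positions (`gap 0`) — blunt ends;
* the reads *pass each other* and share a region of length `L >= 1` that is
  both an exact sequence match and consistent with the mapped coordinates —
  cohesive ends (`cos_5`/`cos_3`, decided by which strand protrudes) when
  `L < 100`, a direct terminal repeat when `L >= 100`;
* the reads leave a gap — no terminus within reach (an error).

The 100 bp cut-off between cohesive overhangs and terminal repeats mirrors
the biological range of known cos sites (a few to a few dozen bases) versus
terminal redundancies (hundreds to thousands).

A deliberate design choice: the shared terminal region is accepted only when
the *coordinates* of the two exact read mappings agree with it, not merely
when the read suffix/prefix strings match. String matching alone misreads
about 0.4% of error-free blunt genomes (a chance 4-base suffix/prefix match
looks like a cos overhang) and can never detect overhangs of 1–3 bases. With
unique exact mapping, coordinates are authoritative, so the package recovers
`L` exactly over the full range `1..99` and `100..5000` (this is tested at
20 seeds per configuration). A `minOverlap` argument is still honoured as a
*trust* threshold: calls with `L < minOverlap` carry a cautionary note rather
than being suppressed.

Reads with errors can be admitted via `maxMismatchRate`, which switches the
mapper to a seeded (20 nt exact seed) scan with a per-read mismatch budget.

### Worked example

```{r workflow}
g <- generateGenome(syntheticGenomeSpec(length = 20000L, architecture = "dtr",
                                        L = 400L, nCds = 25L, nTrna = 3L,
                                        plantedSites = NULL, seed = 7L))
reads <- simulateTerminalReads(g$molecule, anchor = 400)
call <- classifyTermini(g$assembly, reads$right, reads$left)
call
mol <- reconstructPhysical(g$assembly, call)
architecture(s1Trim(mol))   # dtr is S1-resistant: still "dtr"
```

## Restriction analysis

`findSites` scans both strands for (possibly degenerate IUPAC) recognition
sites, including origin-spanning sites on circular records; ambiguity
letters in the *genome* never match. `digest` cuts duplex DNA only — sites
falling inside a single-stranded overhang are ignored — and returns
fragments with explicit overhang chemistry (sequence and 5'/3' polarity) so
that terminal fragments of a physical molecule show one blunt ("none") outer
end. A circular molecule is linearized at its first cut, which is how a
single-cutter digest of the *assembly* differs from the same digest of the
*physical molecule*: only the latter releases the two terminal bands whose
sizes identify the true ends on a gel.

## Repeats

`scanRepeats` reports **maximal** exact repeats of three kinds — direct,
inverted (reverse complement) and mirror (reversed) — via a C++ seed-and-
extend scanner. Semantics worth knowing:

* occurrences may overlap for direct repeats (`pos1 < pos2`), but
  inverted/mirror pairs are reported as disjoint occurrences; a
  symmetric, centre-crossing match (a DNA palindrome) is reported as its
  two disjoint halves;
* ambiguity codes never match, not even `N == N`;
* results are sorted by length (descending), then position.

The scanner is validated against an independent brute-force oracle (diagonal
and anti-diagonal run scanning in R) on hundreds of random sequences,
including low-complexity and `N`-containing ones.

## Composition analyses

**GC skew.** `gcSkewProfile` computes per-window `(G-C)/(G+C)` and the
cumulative skew. For circular records the origin predictor minimizes the
*detrended* cumulative skew (the cumulative series minus its linear ramp):
the raw cumulative minimum depends on where the circle was linearized, while
the detrended minimum is rotation-invariant. `predictOrigin` returns the end
coordinate of the minimizing window; on genomes with a planted skew switch it
recovers the switch within one window.

**Codon usage.** `codonUsage` tabulates codons over a CDS set and computes
RSCU = observed / (family total / family size); within every observed
synonymous family the mean RSCU is 1 by construction (tested to 1e-9).
`trnaAdvantage` compares phage versus host per-1000 usage of the codons
decoded by each phage-encoded tRNA (anticodons restrict the comparison to
the exact decoded codon) and flags ratios ≥ 1.5 — the signature of a phage
carrying tRNAs for codons it uses more heavily than its host does.

## Homology

`dotplot` returns sparse exact word-match coordinates (default word 9) in
forward and reverse-complement channels. `localProteinScore` is a BLOSUM62
Smith–Waterman local score with affine gaps (open 11, extend 1), validated
against a hand-written dynamic-programming oracle. `coreGenes` counts
reference genes whose best score against *every* other proteome reaches a
threshold (default 100), the conventional core-genome criterion.

## The synthetic generator

`generateGenome` produces a genome with **planted ground truth**: terminal
architecture and `L`, restriction-site positions, gene layout, and the GC
skew switch. Defaults describe a PaP1-like phage: 91,715 bp, GC 49.36%, a
1190 bp direct terminal repeat, 157 CDS of mean span 504 bp plus 12 tRNAs
with 13.8% non-coding, and exactly one NarI and one NotI site.

Generator realism and limits, stated plainly:

* genes are head-to-tail with small frame-shifting overlaps sized so the
  coding union hits the non-coding target *exactly* while keeping the mean
  CDS span exact — overlap sizes are never multiples of 3, because an
  in-frame same-strand overlap would force one gene's stop codon into the
  other's frame;
* every annotated CDS is a clean ORF (ATG start, single terminal stop);
  internal stops arising during carving are removed by GC-neutral third-base
  edits so the GC target is not perturbed;
* accidental occurrences of planted recognition sites are destroyed with
  substitutions consistent with every overlapping CDS;
* intergenic composition is i.i.d. with a strand-bias switch — there is no
  oligonucleotide structure, promoter/terminator signal, or real gene
  content. The generator validates the *workflow*, not biology.

Problem sizes used in the package's own validation (12 kb genomes for the
classification sweep, 50 kb for origin recovery, 157-gene proteomes for the
core-genome count) are the package's choices, balancing coverage against
test runtime; the classifier's exactness does not depend on genome size, and
the full PaP1-scale case is exercised end-to-end as well.

## Reproducing the headline numbers

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

writes the main computed quantities (terminus call and recovery rate,
genome/annotation statistics, single cutters and terminal fragment sizes,
repeat maxima, origin estimate, RSCU calibration, tRNA advantage flags,
protein masses, core-genome count) as JSON. The testthat suite
(`tests/testthat`) contains one file per module plus `test-acceptance.R`
with one block per headline criterion.

```{r session}
sessionInfo()
```
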