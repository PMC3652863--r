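# phageTermini

Determine the terminal architecture of a linear double-stranded phage genome
— blunt ends, 3′- or 5′-protruding cohesive (cos) ends, or a direct terminal
repeat (DTR) — from its circular assembly plus two terminal run-off reads,
and characterize the genome along the way.

## The science in one paragraph

Assemblers return phage genomes as circles: terminally redundant or cohesive
ends make the two physical ends of the molecule overlap, so the contig
closes on itself and the true termini are erased. The classical wet-lab
answer is to (i) find a restriction enzyme that cuts the genome exactly
once, so a digest releases two *terminal* fragments, (ii) run primer
extension ("run-off") reactions toward each physical end — the polymerase
falls off exactly at the end of its template strand — and (iii) compare
where the two reads stop on the circular map. If they stop at adjacent
positions the ends are blunt; if they pass each other and share a short
region, the genome has cohesive ends (the protruding strand tells you 3′ vs
5′); if the shared region is long (≥ 100 bp), it is a terminal repeat.
An S1 nuclease digestion distinguishes the two chemistries: single-stranded
cos overhangs are trimmed away, a double-stranded DTR is S1-resistant.
`phageTermini` implements this entire workflow in silico, with exact
classification over the full range of overhang/repeat lengths, plus the
surrounding genome characterization: restriction maps and digest
simulation, maximal direct/inverted/mirror repeat scanning, GC-skew origin
prediction, codon usage (RSCU) and phage-versus-host tRNA advantage, genome
dotplots, and core-genome homolog counting across phage proteomes.

## Worked example

Generate a genome with planted ground truth (a 20 kb phage with a 12 nt
5′-protruding cohesive end), simulate the two run-off reads, and recover the
terminus:

```r
library(phageTermini)

g <- generateGenome(syntheticGenomeSpec(length = 20000L, architecture = "cos_5",
                                        L = 12L, nCds = 25L, nTrna = 3L,
                                        plantedSites = NULL, seed = 7L))
g$assembly
#> GenomeRecord 'synthetic_seed7': 20000 bp, circular; 28 features (25 CDS, 3 tRNA)

reads <- simulateTerminalReads(g$molecule, anchor = 400)
call  <- classifyTermini(g$assembly, reads$right, reads$left)
call
#> TerminusCall: cos_5, L = 12, ends a = 1, b = 12

mol <- reconstructPhysical(g$assembly, call)    # the physical molecule
architecture(s1Trim(mol))                       # cos overhangs are S1-labile
#> [1] "blunt"
```

The package's reference configuration (the default
`syntheticGenomeSpec()`) is a PaP1-like phage: 91,715 bp, GC ≈ 49.36%, a
1190 bp DTR, 157 CDS (mean span 504 bp) + 12 tRNAs with 13.8% non-coding,
and exactly one NarI and one NotI site:

```r
g <- generateGenome(syntheticGenomeSpec(seed = 1L))
singleCutters(g$assembly)
#>   name position
#> 1 NarI     2112
#> 2 NotI    85269

annotationStats(g$assembly)[c("n_cds", "n_trna", "noncoding_pct", "mean_cds_len")]
#>   n_cds n_trna noncoding_pct mean_cds_len
#> 1   157     12          13.8          504
```

Digesting the *physical* molecule (not the circular assembly) with a
single cutter releases the two terminal bands whose sizes identify the true
ends on a gel:

```r
narI <- builtinEnzymes()[builtinEnzymes()$name == "NarI", ]
fragmentTable(digest(g$molecule, narI))[, c("length", "left_polarity", "right_polarity")]
```

## Command-line interface

A thin CLI over the same functions ships with the package:

```sh
TOOL=$(Rscript -e 'cat(system.file("scripts", "termtool.R", package = "phageTermini"))')
Rscript "$TOOL" simulate --seed 7 --length 12000 --architecture dtr --L 300 \
        --cds 18 --trna 2 --prefix genome
Rscript "$TOOL" stats --genbank genome.gbk
Rscript "$TOOL" single-cutters --fasta genome.fasta
Rscript "$TOOL" termini --fasta genome.fasta --right right.fa --left left.fa
```

All commands emit JSON (to `--out <path>` or stdout) and exit nonzero on
error. See the header of `termtool.R` for the full command list
(`digest`, `repeats`, `skew`, `codon`, `dotplot`, `coregenes`, …).

## Notes on scope

Phylogenetic tree construction, BLAST database searches, promoter/terminator
prediction, and wet-lab observables are deliberately out of scope; the
package neither provides nor emulates them.
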