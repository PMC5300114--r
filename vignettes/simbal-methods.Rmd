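---
title: "Methods: partition-labeled subsequence scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partition-labeled subsequence scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simbal)
```

This vignette is the package's own account of the science it implements: the
model and its assumptions, the parameters that matter, the numerical and
design choices made where the procedure left them open, and what the test
suite's synthetic benchmarks do and do not demonstrate about real data.

## The model

The object of study is a protein superfamily whose members share detectable
homology but not a single function. The working hypothesis is that a specific
function correlates, across genomes, with the presence (or genomic proximity)
of a second family — the *attribute*. Genomic context then supplies labels
that no amount of within-family sequence comparison could: target-family
proteins from genomes where the attribute is confidently present are labeled
YES, those from genomes where it is confidently absent are labeled NO, and
everything in between is discarded rather than guessed at.

### Partitioning semantics

Rules are evaluated per genome, on full-sequence profile-HMM bit scores:

* A clause `H>t` asserts the family is present (some hit strictly above `t`);
  `H<t` asserts it is absent (no hit at or above `t`). Using a library's
  trusted cutoff for `>` and noise cutoff for `<` leaves a gray zone in
  between, and a genome falling in it for any clause becomes *indeterminate*
  and contributes nothing. Strictness is deliberate and documented so users
  can mirror TC/NC conventions exactly.
* Separate `NO:` lines AND together; clauses inside one parenthesized `YES:`
  group OR together; separate `YES:` lines AND as groups. This reproduces the
  two canonical behaviors: "genomes hitting any of the markers are YES" and
  "genomes hitting none of them are NO".
* With a distance rule `[N]`, a target from a YES-eligible genome goes to YES
  only if its gene lies within `N` bp of an *above-threshold* attribute gene
  (a sub-threshold hit must not anchor a neighborhood). The genome's remaining
  targets go to FAR — but only when the genome contributed at least one YES
  record; an attribute-bearing genome whose targets are all far contributes
  nothing at all, since the attribute's subsystem partner is then unresolved.
* Distance is the strand-agnostic nucleotide gap between gene intervals on
  the same replicon (0 for overlap/abutment, infinite across replicons).
  "Within N bp" most naturally measures the intergenic gap; strand is ignored
  because operonic neighborhoods are read from either strand.
* Targets are defined by `TARGET SCORE` with strict `>`; a genome with no
  target-family hits contributes nothing regardless of verdict.

These choices make the partitions provably disjoint by (genome, protein), and
monotone in the target cutoff — both are enforced by property tests.

### Training sets, not truth sets

The YES set need only be *enriched* in the function of interest. Redundancy,
however, breaks the sampling model: near-identical sequences are not
independent observations. The package ships a greedy centroid clusterer
(process longest-first, join the first centroid at ≥ 80% identity, otherwise
found a new one) whose contract — FASTA in, centroid FASTA out — matches the
external tools users may prefer (USEARCH, CD-HIT, blastclust). Identity is
computed from an ends-free global alignment, excluding terminal-gap columns,
so domain cuts with unequal flanks still cluster together. Centroids are
always input records, never consensus chimeras. Domain extraction (envelope ±
flank, clamped to the sequence) precedes clustering in the pipeline, since
architecture differences would otherwise masquerade as diversity.

### The score

For one query window, the labeled database is searched and hits are ranked
best-first, at most one entry per database record (the unit being sampled is
a labeled *sequence*, not an HSP). Scanning down the list, depth $k$ with $y$
YES labels gives the upper binomial tail

$$P_k = \Pr(X \ge y), \qquad X \sim \mathrm{Binomial}(k,\; p),\quad
p = \frac{Y}{Y+N},$$

and the window's score is $-\log_{10} \min_k P_k$. The binomial (sampling
with replacement) is used deliberately, exactly as the procedure defines it —
not a hypergeometric. Because homologous hits are correlated, the scores are
*comparative*, ranking regions within a query; they are not calibrated
significance values, and the package's documentation repeats that caveat
wherever scores surface.

Numerics: tails are computed by `pbinom` on the log scale, so a prefix of
hundreds of consecutive YES labels scores finitely instead of underflowing to
a zero probability. Rank ties are broken by (significance, raw score
descending, record id lexicographic via C-locale radix order) so rankings are
reproducible across runs, backends and platforms. Self-hits are retained —
a query drawn from the training set simply ranks itself first, matching a
naive search of the combined database.

### Resolution parameters

`min_length` defaults to 6 (9 is a common preset — alignment statistics below
~9 residues are weak, which the rescoring step exists to compensate).
`length_step` and `position_step` are the classic `-j`/`-w` flags: a
204-residue query at full resolution enumerates exactly
$\sum_{L=6}^{204}(204-L+1) = 19{,}900$ windows, and `-j 3 -w 3` reduces that
about nine-fold. The full query length is always included even when it is off
the length grid, so the heat map retains its apex.

### Backends

The default backend computes Smith-Waterman local alignments (BLOSUM62, gap
open 11 / extend 1) through Biostrings and ranks by raw score, keeping the
pipeline free of external executables; records with no positive-scoring local
alignment are dropped, so an uninformative window has an empty list and
scores 0. The `blast` backend formats the labeled database once
(`YES|id` / `NO|id` deflines) and runs `blastp` with an E-value ceiling of
10, composition-based statistics off, low-complexity filtering off, and the
`blastp-short` task below 30 residues — settings chosen so that very short
windows can return hits at all; each is overridable at the command line. The
builtin backend doubles as the rank-agreement oracle in tests on fixtures
with well-separated similarities; it is not intended as a BLAST clone, and on
borderline rankings the two may legitimately differ.

## Post-processing

### Inheritance rescoring

High scores concentrate in V-shaped "plumes" whose base points at the
signature, but the base itself — the shortest windows — is depressed by
short-peptide search noise. The rescoring pass runs once from the longest
length to the shortest, replacing each score by

$$\mathrm{new}(s, L) = (1-h)\,\mathrm{raw}(s, L) +
h \cdot \overline{\mathrm{new}(\text{parents}(s, L))}$$

where the parents are the windows at the next length present in the grid
whose spans contain $(s, L)$ — the two windows one residue longer at full
resolution, possibly one at grid edges, possibly several when
`length_step > 1` (containment, not offset, defines parenthood). Windows
with no parent keep their raw score. The source material describes "a
weighted average of a subsequence's own raw score and those of its two
minimally longer parents" without printing coefficients; averaging the
parents first and then blending with weight $h$ on the inherited part is this
package's reading, chosen so that $h$ reads literally as heritability
($h = 0$ identity, $h \to 1$ full inheritance) and matching the strong
smoothing visible at the reference value $h = 0.93$. The recurrence makes
every rescored value a convex combination of raw values (hence bounded by the
raw range) and monotone in each raw input — both are tested, along with a
hand-evaluated three-length grid.

### Residue extrapolation

`residue_scores(result, W)` averages, per residue, all length-`W` windows
containing it (up to `W` of them; fewer within `W − 1` of the termini, and
the `support` column records how many). It requires the scan to contain the
complete length-`W` row at position step 1 and refuses to interpolate
otherwise. The profile is an interpretive approximation — the scan asserts
nothing at single-residue scale — and is meant to direct attention in
alignments and structures, not to rank residues statistically.

## Visualization

The triangular heat map plots one mark per window at (midpoint, length),
colored by a "short rainbow" from blue (floor) to red (cap) that avoids
purple entirely, since purple reads ambiguously between the two ends of the
scale. The traversal is deliberately non-uniform: human vision compresses a
wide band of the spectrum into "green", so the map crosses the green hues
quickly (hue 240/180/120/60/0° at t = 0, 0.30, 0.50, 0.65, 1 — fixed,
documented control points; the original implementation's exact rate function
is not recoverable, only its endpoints and qualitative behavior). A flat scan
— a legitimate negative-control outcome — renders uniform blue rather than
erroring. Fixing `score_cap` across plots puts a query and its paralogs on
one color scale, the recommended way to read negative controls. A sidecar
TSV (midpoint, length, scaled score, hex color) accompanies every image so
the rendering is auditable and replottable.

## The synthetic benchmark

`generate_genome_set()` draws, from a single seed, a family consensus and a
population of genomes: with probability `p_attribute` (default 0.5) a genome
carries an attribute protein, exactly one motif-bearing true target, and
Poisson-distributed decoy paralogs (means 2.7 / 1.5 for attribute-positive /
negative genomes, emulating a family whose YES partition is diluted by
paralogs); all targets are consensus mutants at 40% per-residue divergence —
recognizably homologous yet uninformative about the attribute — and each true
target's motif copy is itself mutated at 10% per residue. Hit tables are
synthesized directly from the truth table rather than by running a profile
search, so the rule engine is tested independently of any HMMER executable,
and gene coordinates place true targets inside the 500 bp distance rule and
decoys far outside it. Default sizes (40 genomes, 120-residue targets,
12-residue motif) keep a full-resolution scan of a true-target query at 6,670
windows — the whole planted-signature recovery, including its label-swap
control, runs in about three minutes in plain R, and smaller scaled-down
variants of the same generator drive the file-based pipeline tests.

What passing shows: end-to-end truth recovery (partition counts match the
truth table exactly; the peak window and the per-residue argmax fall inside
the planted span; swapping the labels collapses the motif-region scores to
background). What it does not show: performance on real proteomes, where
homology is tree-structured rather than i.i.d.-mutant, training sets are
larger and noisier, paralog similarity is graded, and annotation errors
contaminate both partitions. The planted fixture validates the machinery,
not the biology.

On the label-swap control, two readings of "the control's peak" are possible:
the peak over windows overlapping the planted motif (the signal the control
is meant to kill) or the global maximum anywhere in the swapped scan. The
acceptance test asserts the first — the motif-region peak must fall below a
quarter of the true peak — because the swapped scan's global background
maximum is governed by chance runs at the inverted label fraction
$p' = N/(Y+N)$, not by the planted signal; both numbers are reported by the
acceptance script.

## Degenerate inputs and edge cases

* Empty FASTA files parse to empty sets; duplicate ids and zero-length
  records are errors naming the offender.
* Residues outside the 20 standard letters plus X are closed to X with a
  warning (downstream aligners need a closed alphabet).
* Repeated hit-table lines for one protein/HMM pair merge to the maximum
  full-sequence score with the union of envelopes — conservative for
  threshold tests.
* An empty ranked list scores 0 with `k_at_min = 0`; an empty partition is
  rejected when the database is built (`Y ≥ 1`, `N ≥ 1`).
* A genome satisfying both YES and NO criteria (possible only with inverted
  thresholds) resolves to YES-eligible; with sane `YES ≥ NO` thresholds the
  two are mutually exclusive.

## Known limitations

* Scores are uncalibrated by design; no multiple-testing control is offered
  or appropriate.
* The greedy clusterer is quadratic in the worst case and intended for
  training-set scale (hundreds to a few thousand sequences), not for
  proteome-scale non-redundification.
* Genome acquisition is out of scope: the package reads locally stored
  per-genome FASTA/GFF3/hit files and does not download or cache assemblies.
* Single-host execution only; `n_jobs` forks over windows (and provably does
  not change the output), but no grid/scheduler integration is provided.
* The blast backend requires a modern NCBI BLAST+ on `PATH`; WU-BLAST-era
  behavior is not emulated.
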