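---
title: "Multigene concatemer expression profiling: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multigene concatemer expression profiling: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgcgep)
```

## The method

Multigene concatemer gene expression profiling (MgC-GEP) is a SAGE-style
tag-counting protocol for a moderate number of genes (10--50). Each target
transcript is reverse-transcribed and amplified with a *chimeric* primer
pair: a 16--20 nt gene-specific 3' part fused to a universal 5' adaptor
tag. The 18-nt forward adaptor carries one BamHI site (GGATCC), the 19-nt
reverse adaptor one HindIII site (AAGCTT). After the first cycles the
universal adaptors alone act as primers, so all targets amplify with
(approximately) equal efficiency. Double digestion releases one 60--70 bp
tag per gene; T4 ligase joins tags end-to-end into concatemers; products
of 500--1200 bp are gel-selected, cloned into a BamHI+HindIII-cut vector,
and ~300 clones per sample are sequenced. The per-gene tag occurrence
count, normalised by an internal control (ACT1), measures relative
transcript abundance between conditions. The method is *relative* only:
absolute transcript levels are out of reach by construction.

This package implements the whole loop in silico: panel design,
protocol simulation from a known ground truth, read deconvolution, and
quantification, so that every analysis step can be validated by parameter
recovery.

## Melting-temperature model

The design software used for the original panels is proprietary and its
model unstated, so the package uses standard nearest-neighbor
thermodynamics (unified dinucleotide parameters, SantaLucia 1998) with

* duplex initiation terms per terminal base pair,
* entropy salt correction `0.368 (n-1) ln[Na+eq]`, with divalent
  magnesium folded in as `[Na+eq] = mono + 120 sqrt(Mg)` (mM), and
* strand-concentration term `R ln(C/4)`.

Defaults (`tm_params()`): 50 mM monovalent salt, 5 mM Mg, 0.25 uM primer
-- the multiplex PCR buffer of the protocol. Under these conditions a
typical 18-mer at 60% GC melts near 67 C, which is where the reported
panels sit (67.3 +/- 1.8 C); the synthetic gene generator therefore
draws sequence at 60% GC. The parameter table is closed under reverse
complement, making `melting_temperature()` exactly strand-symmetric.

## Adaptor geometry and tag length

Digestion cuts G^GATCC and A^AGCTT, leaving 4-nt 5' overhangs (GATC /
AGCT). A tag's canonical form is written 5'->3', BamHI end first,
*including the full reconstituted hexamer at both ends*. In a concatemer
each junction hexamer is therefore shared by the two flanking tags, and
the simulator and the parser use the identical convention -- splitting a
read at junction starts and re-attaching the hexamer to both sides
round-trips exactly.

With the hexamer at 0-based offset `f` in the forward tag and offset `r`
in the reverse tag, a product of length `L` yields a tag of `L - f - r`.
The shipped default adaptors use `f = r = 10`, so the central 85-bp
product releases a 65-bp tag and the designed panels stay inside the
60--70 bp band quoted for the protocol. The true adaptor sequences are
not published in the paper body; the defaults are synthetic stand-ins
satisfying the stated geometry and are user-overridable.

## Panel design

`design_panel()` must keep all gene-specific primer melting temperatures
within 5 C of each other and every product inside 85 +/- 7 bp (product
length includes both adaptor tags; the genomic span is 48 +/- 7 bp).
Candidate enumeration is exhaustive over (start, forward length, reverse
length); a candidate is rejected if the assembled product carries any
GGATCC/AAGCTT beyond the two adaptor sites, because an internal site
would be cleaved during digestion and destroy the tag (a constraint
forced by the chemistry, not stated in the protocol).

Selection objective, in order:

1. per gene, restrict to candidates with the smallest achievable
   `|product length - 85|`;
2. over these, minimise the panel-wide Tm spread (max - min), solved
   exactly by sweeping candidate lower bounds with the tightest
   attainable upper bound per gene;
3. ties: smallest feasible window lower bound, then leftmost start, then
   shortest primers.

Step 1 deserves a note. A pure min-spread objective chases
thermodynamically meaningless fractions of a degree: with thousands of
candidates per gene the optimum spread is often below 0.5 C, attained
only by pushing products to the 78/92 bp window edges -- which drags
digested tags to 58--72 bp, outside the band the protocol reports.
Centring first costs a fraction of a degree of spread (the packaged
panel still achieves 0.40 C, far under the 5 C cap) and pins every tag
at 65 bp. The brute-force oracle used in the tests implements the same
documented objective.

## Protocol simulation

The simulator tracks truth (gene, orientation, clone) through every
stage; all stochastic steps draw from one seeded RNG stream.

* **Amplification** is modelled as bias-free multinomial sampling of
  `tag_pool_depth` (default 1e5) molecules from the profile weights --
  the universal-primer argument for equal per-amplicon efficiency, taken
  at face value. A per-gene efficiency multiplier exists for robustness
  experiments; it is not part of the default world.
* **Ligation** is sequential random chain growth: a random seed tag in a
  random orientation, extended by uniformly random compatible tags, with
  termination probability `stop_prob = 0.075` per step (mean chain
  ~13 tags, chosen so the 500--1200 bp window is well populated).
  Sticky-end compatibility (GATC with GATC, AGCT with AGCT) forces
  strictly alternating orientations and alternating GGATCC/AAGCTT
  junctions. Circularisation is ignored.
* **Cloneability**: a chain is clonable into a BamHI+HindIII-cut vector
  iff its termini expose one BamHI and one HindIII end. Under strict
  alternation this happens exactly for odd tag counts -- a model
  *prediction*, not a protocol claim (the protocol only reports "at
  least 10 tags per clone"). With 65-bp tags, retained inserts carry
  9--19 tags (lengths `59k + 6` for odd `k` in the window), so the mean
  clears 10 comfortably.
* **Size selection** retains clonable inserts with length in the
  inclusive window [500, 1200].
* **Sequencing** samples 300 clones uniformly with replacement and emits
  full-length, insert-only reads with i.i.d. substitution errors
  (default rate 0). Real traces from the two vector primers, quality
  values, and indels are not modelled; a green round-trip test
  establishes parser/simulator consistency, not robustness to real
  chromatogram artefacts.

The reported ~800 bp average insert of the original experiment depends
on unmodelled ligation kinetics and is deliberately not used as a target.

## Deconvolution

Reads are split at exact junction hexamers under the shared-boundary
convention. Orientation follows from the flanking junctions (a canonical
tag starts GGATCC and ends AAGCTT); it is advisory only, since
assignment always checks both strands. Fragments outside the plausible
tag window (default 55--75 bp, i.e. the 60--70 bp band plus slack) are
flagged, never silently dropped. A sequencing error inside a junction
hexamer merges two tags; merged fragments are rescued by a single split
at the best degenerate hexamer (<= 1 mismatch to either site, ties to
the most central position), with the consensus hexamer restored on both
halves.

Assignment is an internal ungapped matcher, not an external alignment
program: at >= 60 bp the tags are effectively unique, and removing the
external dependency makes the pipeline hermetic. Distance is Hamming at
equal length, otherwise the best sliding offset plus the length
difference. A tag is assigned iff the best distance is <= 2
(`max_mismatch`) *and* beats the runner-up gene by >= 2 -- the margin
rule that prevents silent misassignment between homologous tags. The
original analysis counted tags "manually" with BLAST and states no
threshold; these defaults are the package's own and are configurable.

## Quantification

For gene *g* with tag counts `a` (treated), `b` (untreated) and control
counts `c_t`, `c_u`:

`ratio = (a / c_t) / (b / c_u)`

with a Katz log-normal interval, `SE = sqrt(1/a + 1/c_t + 1/b + 1/c_u)`,
continuity correction +0.5 on zero cells (flagged). Calls are `up` /
`down` when the 95% CI excludes 1, else `unchanged`; no multiplicity
correction by default at 20 genes. The protocol itself reports no
count statistic, so the interval is explicitly artifact-defined.

The comparative-CT path implements the sign convention exactly as the
protocol words it: `dCT = CT(control) - CT(target)`, so larger dCT means
more transcript and `fold = 2^(dCT_t - dCT_u)`. This inverts the common
target-minus-reference convention; the output column is named
`dct_control_minus_target` rather than silently normalising.
Amplification efficiency `E = 10^(-1/slope) - 1` is fitted from dilution
standard curves and reported, but not used to correct fold changes by
default (plain comparative CT, as in the protocol).

qPCR direction calls for the concordance table use a 1.5-fold threshold;
with CT noise of 0.2 cycles this separates the simulated +/-1 log2
classes cleanly.

## The synthetic world

The packaged fixture is a 20-gene set (ACT1 + 19 ORF systematic names
from the validation study; sequences are synthetic stand-ins): 160 bp
per gene at 60% GC, scrubbed of restriction sites. The default truth
profile spans a 16-fold baseline range (weights 1, 2, 4, 8, 16; control
at 8) with true log2 fold changes of +1/+2 for the 10 induced genes,
-1/-2 for the 9 repressed ones, 0 for the control. Defaults everywhere
are the protocol's printed numbers: 300 clones/sample, 500--1200 bp
selection, 85 +/- 7 bp products, 5 C Tm spread, 16--20 nt specific
parts. (The original text gives the reverse-specific length as 16--20 nt
in the methods and 19--22 nt in the results; the package uses 16--20.)

What a green suite establishes: the parser inverts the simulator
exactly at error rate 0; direction calls recover a known truth at
protocol depth; the design respects its constraints and matches
brute-force optima on small instances. What it does not establish:
robustness to amplification bias, partial digestion, chimeric ligation
beyond single-base junction errors, or real base-caller error profiles.

## Numerical conventions

Coordinates are 0-based half-open on the gene's forward strand.
Floating-point comparisons in the design sweep use a 1e-12 guard; Tm
ties in selection are broken by the documented deterministic order.
Degenerate inputs error early and by name: all-zero profiles, zero
control counts, missing control CT, fewer than 3 dilution points,
products with missing or extra restriction sites.
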