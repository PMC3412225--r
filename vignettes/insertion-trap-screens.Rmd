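---
title: "Models and methods behind retrotrap"
author: "retrotrap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retrotrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrotrap)
```

`retrotrap` analyses insertion-trap screens for de novo LINE-1 (L1)
retrotransposition in sperm DNA. This vignette is the package's account
of its models: the assumptions behind each estimator, the tunable
parameters and their defaults, the numerical choices, what the
synthetic-data generator does and does not emulate, and the known
limitations.

## The experiment being modelled

A panel of ~5 kb genomic target loci devoid of L1 sequence is amplified
by multiplex long PCR from sperm DNA at the single-molecule level. A
target that has acquired an L1 insertion yields a ~11 kb amplicon that
can be captured by hybridization with biotinylated oligonucleotides
complementary to the L1 3′ terminus (the 3′ end is always retained
because reverse transcription initiates there, so 5′-truncated
insertions remain recoverable). Candidate amplicons are sequenced and
judged against the structural hallmarks of target-primed reverse
transcription (TPRT): an L1 segment with a 3′ poly-A tract, flanked on
both sides by collinear target sequence, usually with a short target
site duplication (TSD). A screen that recovers no genuine insertion
still yields information: an exact Poisson upper bound on the insertion
frequency at the screened loci.

## Limiting-dilution Poisson estimation

**Model.** Amplifiable molecules are Poisson-distributed across wells;
a well with input $m$ pg is PCR-positive iff it received at least one
molecule, so $P(\text{positive}) = 1 - e^{-\lambda m}$ with $\lambda$
in molecules/pg. Independence across wells and absence of inhibition or
clumping are assumed; neither is modelled.

**Estimation.** `estimateMolecules()` maximizes the product-binomial
likelihood over all dilutions jointly. The score function is strictly
decreasing in $\lambda$, so the MLE is found by root-finding on
$[10^{-6}, 10^{3}]$ molecules/pg (tolerance $10^{-14}$), which matches
the single-dilution closed form $-\ln(k_{neg}/n)/m$ to full precision.
The 95% interval is the profile-likelihood set at the $\chi^2_1$ cutoff
(3.841), obtained by root-finding on the deviance. Boundary data are
flagged rather than estimated: an all-negative series has MLE 0 with a
one-sided upper limit, an all-positive series has no finite MLE.
Coverage of the profile interval, checked by simulation at the screen's
calibration regime ($\lambda = 1/12$ per pg, eight replicate wells at
1–100 pg), is ~95%.

**Efficiency.** `pcrEfficiency()` divides the observed concentration by
the expected one ($\text{copies}/\text{genome pg}$). One amplifiable
molecule per 12 pg for a heterozygous insertion in a 6 pg diploid
genome is 50% efficiency; one per 6 pg for the short empty allele is
~100%. The deficit for long amplicons is attributed to inefficient long
PCR rather than template damage.

## Molecule accounting

The accounting model is deterministic expectation arithmetic, matching
how such experiments are budgeted; no branching-process variance is
modelled. Parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `gainEmpty` | 1.8 | per-cycle gain, empty (~5 kb) sites |
| `gainFilled` | 1.6 | per-cycle gain, filled (~11 kb) sites |
| `cycles` | 20 | multiplex PCR cycles |
| `recoveryFilled` | 0.02 | fraction of L1 molecules kept per capture round |
| `recoveryEmpty` | 4.5e-8 | fraction of empty molecules kept per round |

The per-round recoveries fold the protocol's re-extractions into one
net figure. With these constants a single insertion molecule in 0.5 µg
of DNA yields $1.6^{20} \approx 12{,}000$ products against
$\approx 10^{11}$ empty products over ten targets (one in ~8 million);
a single capture round improves the ratio by $0.02 / 4.5\times10^{-8}
\approx 4.4\times10^{5}$-fold to about one in twenty. Note that with
these printed recovery fractions the computed round factor is
$4.4\times10^{5}$ and the post-round ratio 1/18.75; quoted figures of
">500,000-fold" and ">1/16" are consistent only under additional
rounding, so the package reports the computed values and leaves
headline rounding to the explicit helpers `toSigFigs()`,
`floorToNearest()` and `nearestPowerOfTen()`, which are never applied
inside computations.

## Screening depth and the frequency bound

`screenChain()` composes: effective target size (X-linked loci count
half, because they are present in half of sperm — the halving lives in
the target size, not in molecule counts), sperm equivalents
($\mu g \times 10^6 / 3\,pg$), amplifiable molecules per target (sperm
× filled-site efficiency), kb screened, and the frequency bound. For
$k$ observed events the bound is the smallest $\lambda$ with
$P(X \le k; \lambda) \le \alpha$ — the exact one-sided Poisson bound,
computed by root-finding on the CDF; for $k = 0$ it is $-\ln\alpha$,
about 3 at $\alpha = 0.05$. This choice of bound is the unique
convention that turns "no insertions" into "three expected insertions
at P = 0.05". The haploid genome is fixed at $3\times10^6$ kb.
Genomes-per-event is floored to the nearest hundred only in the
reporting layer. The chain lands on the same headline figure (400)
whether the intermediate constants are rounded (38 kb, $3.7\times10^9$
kb) or carried exactly (37,782.5 bp, $3.63\times10^9$ kb).

Incidence interconversions (`incidenceToMass()`, `perSpermRate()`,
`ejaculateExpectation()`) translate the literature's "one insertion per
$n$ births" into pg of DNA per insertion, per-sperm rates for a target
of given size, and expected insertions per ejaculate.

## The amplicon classifier

**Alignment.** Local dynamic programming (via Biostrings) with match
+1, mismatch −1, gap open 2, gap extend 1. Interactive alignment tools
cannot give reproducible verdicts, so all thresholds are fixed and
configurable (`classifierThresholds()`): flanks ≥ 0.90 identity over
≥ 50 nt; L1 segment ≥ 0.85 identity over ≥ 100 nt (old genomic L1
copies still align at this level); poly-A ≥ 10 nt at ≥ 0.8 A-fraction
starting within 10 bp of the element 3′ end (a T-tract 5′ of the
element for minus-strand insertions); TSD 4–30 nt; junction window
20 nt with an A/T-rich call at ≥ 0.70.

**Junction artifacts and their handling.** Raw local alignments
misbehave at TPRT junctions in two systematic ways. First, when the
insert is short, the single best alignment of amplicon to target
bridges *both* flanks across the insert with one long gap, diluting the
pooled identity below threshold; alignments are therefore split into
collinear segments at gap runs of ≥ 40 bases. Second, alignment ends
slip through A-rich micro-homology — the TSD begins with the AAAA of
the endonuclease site, the poly-A tail abuts target A-runs, and L1 is
itself A/T-rich — displacing inferred boundaries by tens of bases.
Segment ends are therefore trimmed by a maximal-scoring-suffix rule
that removes any end whose local mismatch/gap density exceeds ~30%.
After trimming, the reported 5′-truncation offset of the element is
accurate to a few bases (tests allow ±25 bp), and residual junction
ambiguity of a few bases remains irreducible wherever two A-tracts
meet.

**TSD.** On the target reference the two flank projections of a genuine
insertion overlap over exactly the duplicated tract, so `findTSD()`
reports that overlap (minimum 4 nt), after correcting the 3′ flank
start for poly-A overrun. TSDs corroborate but are not required for a
`genuine` verdict, since a blunt (TSD-less) integration is structurally
possible; their absence is recorded in the evidence.

**Verdicts.** `genuine`: both flanks present and collinear (target
projections meeting within the TSD window plus slack, flanks ordered on
the amplicon with room for the insert), an L1 segment, and a poly-A at
the element 3′ end. `no_insertion`: target-derived sequence with no L1
segment (including fusions with L1-free molecules). `chimera`: an L1
segment with a missing or discordant flank; the discordance junction is
refined to the most A/T-rich position within ±10 bases — mirroring how
template-switch points are annotated manually to the A-rich linker they
fall in — and its composition recorded. `unresolved`: anything else
(e.g. collinear flanks with an element but no tail, or an element with
no flank at all). Ties between equal-scoring alignments are broken
toward the smaller start coordinate by the underlying aligner;
coordinates are reported 0-based half-open in all serialized output
(in-memory objects use 1-based `IRanges`, the Bioconductor convention).

## The synthetic-data generator

The generator produces every input with known truth, standing in for
raw screen data that cannot be shipped. Choices, and what they do and
do not emulate:

- **Backgrounds** are i.i.d. nucleotides at the requested GC (default
  0.42 for targets; 0.40 for the element, since L1 is A/T-rich) — the
  simplest model satisfying the scan constraints. Real loci have
  repeats, homopolymers and CpG structure that i.i.d. sequence lacks,
  so passing round-trips here do not certify performance on repetitive
  genomic DNA.
- **Endonuclease sites** (5′-TTAAAA-3′, the canonical L1 nick
  consensus; configurable) are planted in a motif-scrubbed background
  with G guard bases, so the census is exact by construction.
- **Genuine amplicons** follow the TPRT convention: the bases 5′ of the
  nick are duplicated around a 5′-truncatable, orientable element with
  a pure poly-A tail (an error-rate knob can degrade it). Truth TSD
  lengths default to 7–20 nt. The nick is placed inside the motif
  (between TT and AAAA).
- **Chimeras** fuse the target prefix to a donor suffix at the midpoint
  of a planted 25 nt A-linker in each molecule, mirroring the anatomy
  of template-switch artifacts fused in A-rich linkers between Alu
  monomers; the donor carries a truncated element so the product
  contains the L1 3′ end but no TSD and no 5′ element/target junction.
- **Probe oligos** are exact reverse complements of evenly spaced
  windows in the element's 3′-terminal 1.5 kb; real capture-oligo sets
  are chosen for subfamily conservation, which a single random element
  cannot represent.
- **Dilution series** draw independent Bernoulli wells at
  $1 - e^{-\lambda m}$.

Every generator is byte-deterministic given a seed; per-generator seeds
are derived from the user seed with a tag hash so the streams are
independent.

## Problem sizes used in the test suite

Classifier behaviour depends on junction structure, not on segment
length, so the round-trip test batteries use compact loci — 1.2 kb
targets and 2 kb elements (the minimum; most genomic L1 copies are
short 3′ fragments) with truncations up to 1.6 kb — keeping the
300-amplicon truth-table run to a few minutes on one CPU. The
generator defaults (5 kb targets, 6 kb full-length element) remain the
study-scale conditions and are exercised in the unit tests. CI coverage
is assessed over 500 simulated series; composition checks use 3
binomial standard errors.

## Known limitations

- The accounting model is expectation-only; stochastic yield variance
  across PCR cycles and capture rounds is out of scope.
- The classifier does not detect twin-priming/inversion structures, nor
  does it search genome-wide for a chimera's donor locus; donor
  identification requires external alignment resources.
- The dilution model ignores PCR inhibition and well
  cross-contamination.
- Repeat annotation is consumed as BED input; the package does not run
  repeat-masking software.
- The oligo mismatch screen is gapless (substitution counting), on both
  strands — amplicons are double-stranded, so either strand can
  cross-hybridize; single-strand scanning can be emulated by passing
  pre-oriented oligos.
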