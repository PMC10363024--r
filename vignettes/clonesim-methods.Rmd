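---
title: "clonesim: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clonesim: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonesim)
```

`clonesim` simulates single-cell copy number data from tumors: a timed
cell genealogy, two-allele genome evolution by multi-scale copy number
events, ground-truth and error-injected copy number profiles (CNPs), and
haplotype-aware paired-end reads. This vignette documents the models, the
parameters that matter, the numerical conventions, and the design choices
made where the design was genuinely open.

## The cell lineage model

The sampled tumor cells are modeled retrospectively by the Kingman
coalescent. Time is measured in coalescent (population-size-scaled) units,
with 0 at the present; while $k$ lineages remain, pairwise mergers occur
at instantaneous rate

$$\frac{k(k-1)}{2}\,\frac{1}{N(t)},\qquad
N(t) = e^{-\alpha t}\prod_{s:\,t_s \le t}\sigma_s,$$

where $\alpha \ge 0$ is the exponential growth rate of the tumor
(backward in time the population shrinks, accelerating coalescence) and
each selective sweep $s$ is modeled as an instantaneous bottleneck that
multiplies the population size by a severity $\sigma_s \in (0,1]$ at time
$t_s$. A severe sweep (say $\sigma = 0.01$) makes the coalescence rate
jump 100-fold for lineages that survive past it, which is exactly the
"burst of coalescence" signature of a sweep seen backward in time. A
logistic fixation trajectory would be more mechanistic but adds parameters
without changing the induced tree shapes at the resolution this simulator
targets, so the bottleneck formulation was chosen. A sweep older than the
sample's TMRCA has no effect and is silently inert.

Waiting times are drawn exactly by inverting the piecewise cumulative
hazard (closed form in $\alpha$ per inter-sweep segment), so there is no
time discretization anywhere. With $\alpha = 0$ and no sweeps the model
reduces to the standard coalescent, which gives the package its strongest
external checks: $E[T_{\mathrm{MRCA}}] = 2(1 - 1/n)$ and expected total
tree length $2\sum_{k=1}^{n-1} 1/k$. The test suite verifies both by
Monte Carlo.

Absolute calendar time is never needed: branch lengths are converted to
expected event counts through a per-unit event rate, so the coalescent
unit is the only clock.

**Outgroup dilution.** The tumor MRCA is marked as the *tumor founder*. A
stem of configurable length is added above it, and normal plus
pseudo-normal cells attach as pendant outgroups at evenly spaced points
along the stem — normals closest to the root, pseudo-normals between the
normals and the founder — all contemporaneous with the tumor sample.
Even spacing (rather than random attachment) keeps the topology a pure
function of the counts, which is worth more to reproducibility than the
extra realism of random spacing; whether normals or pseudo-normals should
sit closer to the root is not identifiable from data of this kind, and
fixing normals outermost gives pseudo-normals the shorter divergence
their near-diploid genomes imply.

**Subclones.** Subclones are disjoint clades of at least `min_subclone_size`
tumor leaves. Selection is greedy-random (shuffle internal candidates,
accept while disjoint), which samples maximal valid sets without the cost
of exhaustive enumeration; feasibility is first decided exactly by a
dynamic program over the tumor clade so that an infeasible request fails
immediately, reporting the achievable maximum. The founder itself is not a
candidate: a subclone is a *diverging* subpopulation, and the whole tumor
is not a subclone of itself.

## Genome representation and the event model

Each chromosome is discretized into uniform `region_size`-bp regions (the
unit of the event model). A cell genome is, per chromosome, a set of
**allele lineages**: ordered sequences of reference-region identifiers,
initialized as two identity sequences labeled `A` and `B`. All coordinates
are 0-based and half-open; the last region of a chromosome may be short,
which is honored in sequence reconstruction and in length-weighted bin
averaging but not in the event model (the short region is an ordinary
citizen there).

Events are applied along tree edges in a top-down traversal; each edge's
events are applied in draw order, so the coordinates of later events refer
to the already-mutated allele sequence, which makes interval semantics
under prior insertions and deletions well-defined.

* **Focal events** arrive on each tumor edge as
  $\mathrm{Poisson}(\lambda_f \cdot \ell)$ in the branch length $\ell$.
  The target allele lineage is chosen with probability proportional to its
  current region count, making the per-bp rate uniform across the genome
  as it mutates. Lengths are `min_length` plus a geometric draw whose mean
  matches `mean_length` (a discretized exponential — the conventional
  length law for focal CNAs — truncated so the event fits the allele);
  gains add $1 + \mathrm{Geometric}(p_{mag})$ tandem copies; losses delete
  the segment. A Poisson placement law was chosen over a fixed per-edge
  count because it composes correctly with branch lengths.
* **Copy-neutral LOH** reclassifies a focal event with probability
  `p_cnloh` when another allele lineage carries the whole locus. It is
  implemented as a *move*: the target allele loses the segment and the
  homolog gains a tandem duplicate of the same reference regions — the
  biological mechanism of CNLOH (one homolog's copy lost, the other's
  duplicated) — so the per-region total copy number is invariant by
  construction. CNLOH is restricted to the focal scale.
* **Chromosomal events** (whole-arm or whole-chromosome) are concentrated
  where tumor biology puts them: $\mathrm{Poisson}(\mu_{founder})$ of them
  on the edge into the tumor founder (after an optional WGD, before that
  edge's focal events) and $1 + \mathrm{Poisson}(\mu_{sc})$ on each edge
  into a subclone root. Each subclone's multiset of (chromosome, arm,
  type) is resampled (up to 100 attempts) until unique across subclones,
  so every subclone carries a distinguishing chromosomal signature. A
  whole-chromosome gain copies a carrier lineage into a **new allele
  lineage** (label `<source>.dup<i>`), and WGD copies every lineage
  (`<source>.wgd<i>`): newly created chromosomes are new alleles, and the
  leading letter of a label always records the founding haplotype.
* **Normal cells** receive no events, ever — they are the diploid anchors
  of the experiment — and therefore the outgroup stem above the founder is
  also event-free. **Pseudo-normal cells** receive
  $\mathrm{Poisson}(\mu_{pn})$ focal events on their pendant edge only,
  never chromosomal events or WGD: they are near-diploid by definition.
* **Degenerate targets.** An event whose target no longer exists (a fully
  deleted chromosome, say) is skipped with a warning and omitted from the
  event log; long simulations must not die because a lineage nullisomic
  for one chromosome was asked to lose it again.

Every applied event is logged with its edge and coordinates, and
`replay_event_log()` deterministically reproduces every genome from the
log — the package's own strongest internal consistency check, exercised
over randomized configurations in the test suite.

## Copy number profiles and the error model

The ground-truth total copy number of a region is its number of
occurrences across all allele lineages; the allele-specific pair partitions
that count by founding haplotype. Bins of `bin_size` bp report the
length-weighted mean of their regions' copy numbers, **rounded half away
from zero** — fixed rounding (rather than R's round-half-even) so that
profiles are reproducible across platforms and a bin straddling a 2/3
boundary reports 3.

Noisy profiles apply two error layers, in a fixed order chosen to mirror
the generative process of a CNA caller: boundary noise first (segmentation
breakpoint error on the latent signal), then jitter (read-count noise on
top).

* **Boundary noise.** Each within-chromosome boundary between bins of
  differing total copy number is, with probability $p_b$, displaced by
  $\mathrm{Geometric}(p_s)$ bins (support $1, 2, \dots$; mean $1/p_s$) in
  a uniformly random direction; displaced bins adopt the full state (total
  and allele split) of the segment the boundary moved away from. The
  expected number of displaced bins per boundary is $p_b/p_s$. Boundaries
  are detected on, and adopt values from, the original profile, processed
  left to right; displacement is clipped against the *current* occupancy
  so that the invaded segment always retains at least one bin. The
  clipping rule deserves a note: clipping against the original boundaries
  alone would let the two flanks of a short segment each overwrite it
  "except one bin" and jointly erase it, silently deleting a true copy
  number state from the chromosome. Clipping against the current state
  keeps segmentation error an error of *position*, never of existence.
* **Jitter.** A bin at state $c > 0$ becomes
  $\max(0, \mathrm{round}(c + \varepsilon))$ with
  $\varepsilon \sim N(0, (\sigma_j c)^2)$, independently per bin and cell;
  zero-copy bins stay zero (no reads, no signal). Proportionality of the
  noise scale to the state is the defining property; the Gaussian law is a
  choice, made for its single parameter. Rounding is the only
  nonlinearity. The allele split of a jittered bin is rescaled
  proportionally and re-rounded — callers rarely report reliable
  allele-specific values at this noise level, so no independent
  allele-level noise process is modeled.

With both error parameters zero the noisy pipeline is the identity, down
to the output bytes — a property the tests assert on files, not just in
memory.

## Sequencing reads

For read generation each of the two founding haplotypes gets its own
haploid reference: haplotype 1 is the reference itself, haplotype 2
carries $\mathrm{Binomial}(L, \theta)$ substituted sites (recorded in a
truth table), and every allele lineage reconstructs its full sequence from
the haplotype its founding label names. Reads are therefore
haplotype-aware by construction, and with zero error rate every read is an
exact substring of its source haplotype sequence.

Each allele sequence is partitioned into non-overlapping windows of
`window_size` bp. Per-window log-rate multipliers follow a stationary
AR(1) process, $x_t = \rho x_{t-1} + N(0, \sigma_c^2(1-\rho^2))$,
exponentiated with a $-\sigma_c^2/2$ correction so the mean multiplier is
exactly 1: one knob for dispersion ($\sigma_c$), one for smoothness
($\rho$). Read pairs per window *per genome copy* are
$\mathrm{Poisson}\!\big(\tfrac{C}{2}\, w\, r_w / (2L_r)\big)$, which makes
expected depth at a copy-number-$c$ locus equal $(c/2)\,C\,r_w$ — depth
proportional to copy number is exact by construction, not an emergent
approximation. Fragments start uniformly in the window with
$N(\mu_{ins}, \sigma_{ins})$ lengths clipped to at least the read length
and to the sequence end; mate 2 is the reverse complement of the
fragment's 3' end; substitution errors are uniform at rate $e$ with
constant Phred-30 qualities.

Read generation is implemented internally rather than by shelling out to
an external short-read simulator so that the package is self-contained and
bit-reproducible; the per-window read counts are available through the
read names for anyone who wants to drive an external simulator instead.
WGA chimeras, allelic dropout, GC bias and learned quality profiles are
out of scope.

## Defaults and their rationale

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `region_size` | 1,000 | bp | event-model resolution; keeps human-scale genomes in memory |
| `bin_size` | 1,000,000 | bp | common CNA-caller reporting resolution |
| `growth_rate` | 5 | per coalescent unit | clearly star-like tumor genealogy without degenerating to a comb |
| `focal_rate` | 3 | events per unit length | a handful of focal events per cell over a typical tree |
| `min_length`, `mean_length` | 100, 1,000 | regions | 100 kb–1 Mb focal CNAs at the default region size |
| `p_gain`, `p_cnloh`, `p_mag` | 0.5, 0.1, 0.5 | — | balanced gains/losses; CNLOH a minority; mean magnitude 2 |
| `founder_event_mean`, `subclone_event_mean` | 5, 2 | events | founder burst larger than subclone divergence |
| `p_arm`, `p_chrom_gain` | 0.75, 0.5 | — | arm-level events dominate chromosomal CNAs |
| `p_boundary`, `p_shift`, `jitter_sd` | 0.5, 0.5, 0.15 | — | visible but not overwhelming caller-like noise |
| `coverage`, `read_length`, `insert_mean` | 0.1x, 100, 350 | x, bp, bp | low-coverage scDNA-seq regime |
| `coverage_sd`, `autocorrelation` | 0.3, 0.5 | log scale, — | mild, smooth coverage waviness |
| `snp_rate` | 0.001 | per bp | human heterozygosity scale |

All of these are exposed in `default_config()` and validated by
`validate_config()`, which rejects unknown keys and aggregates every range
violation into one report. One master seed fans out to fixed per-stage
seeds (`derive_seed()`), so enabling read generation does not perturb the
tree, and identical configurations reproduce identical output bytes.

## What the synthetic data does and does not emulate

The built-in reference generator writes i.i.d.-base FASTA with a chosen GC
fraction and a matching chromosome-arm table, so nothing needs to be
downloaded to run or test the package; real references (FASTA plus a UCSC
cytoband file via `read_ucsc_cytoband()`) drop in wherever the synthetic
one is used. The synthetic reference has no repeats, no mappability
structure, no telomere/centromere sequence and uniform base composition —
so passing tests demonstrate the correctness of the simulator's
bookkeeping and calibration, not that downstream callers will behave on
real genomes the way they behave on these sequences. Similarly, the error
model reproduces the two dominant *patterns* of single-cell CNP error
(boundary wander, state-proportional fluctuation), not any particular
caller's artifacts, and the read model deliberately omits amplification
artifacts.

## Numerical conventions and degenerate inputs

* Coalescent waiting times by exact hazard inversion; simultaneous event
  times have probability zero and would be broken by node id.
* `n = 1` tumor samples are legal (a single-leaf tree of length zero).
* Rounding is always half away from zero (`round_half_away()`).
* Newick branch lengths are printed with 12 significant digits, enough for
  round-trips through standard parsers at $10^{-9}$ tolerance.
* Integer region identifiers and seeded draws only — no
  platform-dependent floating-point accumulation affects any output.

## Problem sizes in the test suite

The statistical tests run at desk scale, chosen so the whole suite
finishes in about two minutes on one CPU: 2,000 coalescent replicates for
the moment checks, 200 randomized toy runs (two chromosomes, tens of
regions) for the brute-force copy-number oracle, 100 randomized
configurations for event-log replay, $10^5$ replicates for the
boundary-noise and jitter calibration, and a two-chromosome 1 Mb genome at
5x for the depth-proportionality check of the read generator. The same
quantities are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

SNVs, indels, structural insertions, breakage–fusion–bridge cycles,
translocations, chromothripsis/chromoplexy and kataegis are not modeled;
chromosome-arm events approximate the net copy number effect of some of
those mechanisms without their breakpoint structure. Bulk and exome data,
temporal sampling, mappability/misalignment error patterns and
amplification artifacts are likewise out of scope. The coalescent is
neutral apart from sweeps; there is no spatial structure and no explicit
generation-time calibration.
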