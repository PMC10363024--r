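# clonesim

Simulation of single-cell copy number profiles and DNA sequencing reads
from tumor cell lineages.

## What problem this solves

Methods that call copy number alterations (CNAs) from low-coverage
single-cell DNA sequencing, or that reconstruct tumor phylogenies and
subclonal structure from copy number profiles (CNPs), are hard to
benchmark: real scDNA-seq data has high error rates and essentially no
ground truth. `clonesim` generates fully ground-truthed synthetic data for
such benchmarks. It simulates, end to end:

1. **A timed cell genealogy.** The sampled tumor cells coalesce under the
   neutral Kingman coalescent with exponential population growth and
   optional selective sweeps (instantaneous bottlenecks that produce
   bursts of coalescence). The sample can be diluted with normal diploid
   cells and with pseudo-normal (near-diploid, non-tumor) cells attached
   as outgroups above the tumor founder, and clades within the tumor can
   be designated as subclones.
2. **Genome evolution by multi-scale CNAs.** Each chromosome is
   discretized into uniform regions and each cell carries, per chromosome,
   a set of *allele lineages* — ordered region sequences descending from
   the two founding haplotypes. Along each tumor edge, focal gains, losses
   and copy-neutral LOH arrive as a Poisson process in branch length; the
   edge into the tumor founder carries an optional whole-genome
   duplication (WGD) plus a burst of chromosome-arm and whole-chromosome
   events, and each subclone root edge carries a unique chromosomal
   signature. Chromosomes created by WGD or whole-chromosome duplication
   are tracked as new alleles.
3. **Observed data.** Ground-truth binned CNPs (total and allele-specific)
   for every observed cell, plus error-injected CNPs that mimic CNA-caller
   output: segmentation noise at copy-number segment boundaries, and
   Gaussian jitter proportional to the copy number state (read-count
   nonuniformity). Optionally, haplotype-aware paired-end FASTQ reads with
   a smooth lognormal-AR(1) per-window coverage landscape, so that
   expected depth is proportional to local copy number by construction.

In coalescent units, while `k` lineages remain mergers occur at rate
`k(k-1)/2 / N(t)` with `N(t) = exp(-alpha t) * prod(severities of sweeps
older than t)`; branch lengths convert to event counts through the focal
rate `lambda_f` per unit time. Focal event lengths are
`min_length + Geometric` (mean-matched), magnitudes `1 + Geometric(p_mag)`,
and boundary noise displaces each CN boundary with probability `p_b` by
`Geometric(p_s)` bins; a bin at state `c` is jittered by
`Normal(0, (sigma_j c)^2)` and re-rounded.

## Worked example

```r
library(clonesim)
manifest <- run_simulation(list(
  n_cells = 40, n_normal = 3, n_pseudo_normal = 2,
  n_subclones = 2, min_subclone_size = 4,
  n_chromosomes = 2, chrom_length = 2e7,
  wgd = TRUE, mode = "cnp", out_dir = "demo", seed = 7))
str(manifest$counts)
#> List of 3
#>  $ n_leaves    : int 45
#>  $ n_events    : int 30
#>  $ n_read_pairs: int 0

prof <- read_profiles("demo/profiles/noisy_long.tsv")
prof
#> copy number profile: 45 cell(s) x 40 bins on 2 chromosome(s)

table(prof$total[grep("^tumor", rownames(prof$total)), ])
#>   1   2   3   4   5   6
#>  20 555 609 320  92   4

el <- read.table("demo/event_log.tsv", header = TRUE, sep = "\t")
table(el$scale, el$type)
#>              cnloh gain loss
#>   arm            0    4    6
#>   chromosome     0    0    1
#>   focal          2   10    6
#>   wgd            0    1    0
```

The 45 cells are the 40 tumor cells plus 3 normals and 2 pseudo-normals.
Because this run applies a WGD at tumor onset, noisy tumor bins
concentrate around copy number 3–4 (the WGD baseline of 4 eroded by
losses and blurred by the error model), while the ground-truth normal
cells are exactly 2 everywhere (see `demo/profiles/truth_long.tsv`). The
event log lists every applied event with its edge, scale, type, allele
lineage and coordinates; replaying it from a fresh diploid genome with
`replay_event_log()` reproduces every leaf genome exactly. `demo/tree.nwk`
holds the genealogy in newick, with leaf names encoding cell class and
subclone (`tumor_0012_sc1`, `normal_0001`, ...).

A thin command-line wrapper with the same parameter surface is installed
at `inst/scripts/clonesim`:

```sh
Rscript inst/scripts/clonesim -n 100 --wgd --subclones 2 --mode cnp --seed 1 --out demo_cli
```

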