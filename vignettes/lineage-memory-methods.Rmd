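---
title: "Quantifying gene expression memory and state switching from lineage barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene expression memory and state switching from lineage barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagemem)
```

## The problem

Drug-naive melanoma populations harbour a rare, transiently heritable
*primed* state (NT5E/EGFR/AXL-high, SOX10/MITF-low) whose cells
preferentially survive targeted BRAF/MEK therapy, alongside a majority
*drug-susceptible* state. Because the states interconvert, the relevant
quantities are dynamical: how long does a state persist through cell
divisions (gene expression memory), and how often do cells switch
(`k_on`: susceptible to primed, `k_off`: primed to susceptible)?

Transcribed lineage barcodes make these quantities measurable: a
semi-random barcode delivered before an expansion of a few doublings
marks all descendants of each founder, and single-cell RNA-seq at the
endpoint reads both the barcode and the transcriptional state. A lineage
whose cells occupy both states at the endpoint has witnessed a switching
event. `lineagemem` implements the full path from barcode reads to
switching-rate estimates, together with a synthetic-data module that
generates every input with known ground truth.

## The two-state branching model

Each cell is in state S (drug-susceptible) or P (primed). S cells divide
at rate `r_S` per day and die at rate `d_S`; P cells at `r_P`, `d_P`. At
each division, every daughter independently switches to the other state
with probability `p_on` (S mother) or `p_off` (P mother). This
*per-daughter* convention matches how switching rates are naturally
reported in divisions: "one event every N divisions" corresponds to a
per-daughter probability `1/(2N)`, since a division draws two daughters
(`divisions_to_prob()` / `prob_to_divisions()`). A continuous-time
switching mode (independent per-cell events at the per-time-equivalent
rates `2 p_on r_S`, `2 p_off r_P`) is available behind
`switch_mode = "continuous"` for sensitivity checks; both modes share the
same mean-field flow.

In the deterministic limit,

    S' = (r_S (1 - 2 p_on) - d_S) S + 2 p_off r_P P
    P' = 2 p_on r_S S + (r_P (1 - 2 p_off) - d_P) P,

and the primed fraction `f = P/(S+P)` obeys a quadratic fixed-point
equation solved analytically by `steady_state_fraction()` (the stable
root in [0, 1] is returned; the tests verify agreement with numerical
ODE integration to 1e-6). The rarity of the primed state at steady state
forces the asymmetry in rates: a small equilibrium fraction with ongoing
exchange requires `k_off` to be much faster than `k_on`.

`simulate_population()` is an exact event-driven (Gillespie) simulation
with per-cell lineage bookkeeping, implemented in C++ for speed and
driven by R's RNG so that every run is reproducible from a seed.
An optional coupling `gamma` makes S-to-P switching easier in lineages
that already contain primed cells
(`p_on_eff = p_on (1 + gamma * lineage primed fraction)`); it defaults
to 0.

Death rates default to 0: in the drug-naive expansions modelled here
death is negligible relative to division, and treatments that kill are
expressed as per-plate overrides.

## Experimental designs

`experiment_design()` describes the two layouts used throughout:

- *sorted wells* (independent samples): founders of known state expand
  for ~4 susceptible doublings and are captured; each sample's barcodes
  are private, so a barcode appearing in two samples is an artifact
  (`assign_lineages(..., sharing_design = "independent_samples")`).
- *split plates* (shared lineages): one barcoded pool expands ~4-7
  doublings, is split across condition plates, treated for a few days,
  and captured; here the same barcode legitimately appears in every
  condition (`"shared_split"`), and cells with the same barcode on
  different plates act as copies of the same founder.

Capture is modelled as uniform subsampling without replacement plus an
independent barcode detection probability (default 0.60, the typical
recovered fraction when a transcribed barcode is read out alongside the
transcriptome in droplet experiments).

## From reads to lineages

Barcode recovery follows the standard feature-barcode logic: scan each
read for the constant anchor preceding the barcode (Hamming scan with a
configurable mismatch budget, via `Biostrings`), extract the following
100 nt, and UMI-collapse per cell. Error correction then merges sequence
variants greedily in descending read count: a sequence joins an existing
canonical barcode when the Levenshtein distance is at most `max_dist`
(default 5 for 100-nt barcodes) and the canonical's count is at least
`merge_ratio` (default 5) times its own — the documented defaults of the
standard message-less clustering tools at this barcode length. The
greedy rule is deterministic (ties broken lexicographically), idempotent,
and simple enough to verify against a brute-force oracle, which the test
suite does.

Three filters follow, each only ever removing cells, never reassigning
them: cross-sample elimination (design-dependent, above), a minimum
lineage size (default 3 cells), and an oversize filter. For the oversize
threshold, note that under stochastic exponential growth a lineage's
size after `d` doublings is approximately geometric with mean `2^d`, so
`P(size > s * 2^d) ~ exp(-s)`; the default slack `s = 7` therefore cuts
at the 0.1% upper tail, whereas a slack of 2 — intuitive under
deterministic doubling — would discard roughly a tenth of genuine
lineages. Cells carrying several barcodes are kept only when the same
sorted barcode combination is seen in at least two cells (a real
multi-integration lineage); singleton combinations are ambiguous and
dropped.

## From counts to states

Counts are library-size normalized and log-transformed
(`log(1 + 10^4 x / colsum)`, natural log). Signature scoring is the
rank-based statistic used for single-cell gene sets: per cell, genes are
ranked by decreasing expression (average ranks on ties), ranks are
clipped at `rmax = 1500`, and with `m` signature genes the score is
`1 - U/(m rmax)` with `U = sum(ranks) - m(m+1)/2`. Being rank-based it
is invariant to monotone transforms of expression, which the tests
assert directly.

State calling deliberately replaces graph clustering with a reproducible
one-dimensional decision on the primed signature score: either a
two-component Gaussian mixture (`mclust`, boundary at equal posterior)
or a top-quantile rule (default 2%, the primed prevalence in the
untreated line). Graph clustering depends on a neighbourhood graph, a
resolution, and a random initialization; a scored threshold is auditable
and oracle-checkable, and the chosen method is recorded on the output.

Differential expression uses the two-sided Wilcoxon rank-sum test per
gene (exact when both groups have at most 10 cells and no ties; normal
approximation with tie correction otherwise), Bonferroni correction over
the genes actually tested, and significance at adjusted p < 0.05 with
|log2 fold change| at least 0.25, computed on means with pseudocount 1.
The 0.25 cutoff is taken in log2 (the log base is a convention choice;
log2 is the common reporting scale and is documented here). Genes
detected in fewer than 10% of cells in both groups, or constant across
both, are excluded before testing and reported as NA. The primed gene
set is the significant positive tail of the primed-vs-susceptible
comparison.

The *intermediate* state — drug-susceptible cells transcriptionally en
route to the primed state — is called by scoring all cells against the
up-regulated genes of *crossing* lineages (lineages that switched from
susceptible to primed) and relabelling the top 2% of drug-susceptible
cells globally (a per-sample option exists); primed labels are never
touched. The flow-cytometry analogue calibrates an intensity threshold
so that exactly `ceiling(0.02 N)` untreated events lie at or above it;
events at or above the threshold are primed. With distinct control
values the control percentage is exactly `ceiling(qN)/N`.

## Memory statistics

Lineages are classified by founder state and endpoint composition into
pure-susceptible, pure-primed, and the two switching categories; the
four categories partition the lineages, and intermediate cells count as
drug-susceptible (the intermediate state is a subpopulation of the
susceptible state). Per-gene memory is the one-way intraclass
correlation with lineage as the grouping factor (expected value
`sigma_b^2/(sigma_b^2 + sigma_w^2)`, verified on planted variance
components). A quick moment estimator inverts lineage purity:
a complete `d`-doubling tree makes `2(2^d - 1)` daughter draws, so
`p_hat = 1 - purity^(1/(2(2^d-1)))` — a small-`p` approximation that
ignores back-switching, checked against exhaustive tree enumeration for
`d <= 3`.

For matched treatment analyses, `matched_lineage_fractions()` selects
the lineages that are 100% in the reference state in the untreated
condition and tracks their primed fraction per condition;
`fraction_reduced()` uses a strict inequality, so ties count as not
reduced.

## Simulation-based inference

`fit_grid()` is deliberately a grid ABC: log-spaced grids over the free
parameters, `sims_per_point` simulated replicates of the design per
point, and a Euclidean distance over summary statistics standardized by
the replicate spread (estimated once from pilot replicates at the grid
midpoint; zero-spread components get 1). A grid is auditable and
deterministic given the seed, which we prefer to a stochastic search for
a four-parameter model; the budget is a setting. The accepted set (best
1% of points) is reported as a crude uncertainty region and is
explicitly not a posterior.

The summary statistics are the overall primed fraction (over all cells,
barcoded or not), the four category fractions, lineage-size quartiles
per founder state, and a 10-bin histogram of per-lineage primed
fractions.

For *scenario selection* — deciding whether a treatment effect acts by
switching, growth, or killing — per-plate summaries are provably too
weak at desk scale: raising `k_off` tenfold and killing primed cells
produce nearly indistinguishable marginal distributions. The
discriminating information lives in the matched lineages of the
split-plate design: switching flips a twin lineage's states while
preserving its cell count, whereas killing shrinks or deletes the twin.
`paired_lineage_stats()` captures this with eight components (for
primed-dominated and pure-susceptible reference lineages: the fraction
of twins that changed side, their median primed fraction, the median
log2 size ratio, and the fraction of absent twins), and
`scenario_selection(..., paired_observed = )` appends them to the
treated summaries, simulating the paired design at every grid point.
All scenario distances share one standardization spread, estimated under
the null modification, so the ranking compares like with like; ranking
ties break toward the smallest relative parameter change.

## The synthetic-data module

`gen_barcode_library()` draws WSN-repeat barcodes (W = A/T at positions
0 mod 3, S = G/C at 1 mod 3, N anywhere at 2 mod 3; the canonical 100-nt
barcode truncates its 34th repeat). At 100 nt, 200 random barcodes have
minimum pairwise Levenshtein distance well above 10, so error-correction
at distance 5 is unambiguous. `gen_reads()` emits anchor+barcode reads
with i.i.d. substitutions (default 1% per base; substitutions only by
default so the clustering oracle stays exact — an indel-free error model
is what keeps distances Hamming-bounded). `gen_counts()` draws negative
binomial counts (mean 1 baseline, dispersion 0.5, variance
`mu + 0.5 mu^2`) with an 8-fold mean shift on each state's marker genes
(NT5E, EGFR, AXL, FN1, SERPINE2 up in primed; SOX10, MITF up in
susceptible); the baseline mean of 1 is a realistic detection level for
marker-panel genes and gives the planted markers a rank-AUC above 0.9 at
the default fold change. `gen_flow()` draws a lognormal mixture with a
configurable log-scale shift for the primed component.

What the generator does *not* emulate: ambient RNA, doublets, UMI
collisions, read-quality structure, batch effects, or any
transcriptional continuum between states beyond the planted
intermediates. Passing tests therefore demonstrate the correctness of
the algorithms under a clean two-state world, not robustness to every
artifact of real droplet data.

## Problem sizes and numerical choices

The packaged tests and the acceptance script run the study-condition
simulations at desk scale, chosen as the package's own working sizes:
switching-rate recovery uses 1000 + 1000 founders expanded 4 doublings,
fitted on a 20x20 log-spaced grid with 10 replicates of 1000 founders
per point; scenario selection uses 200-300 founders per replicate with
2000-8000 captured cells per plate and an 8-point grid per scenario.
Division-rate ratio `r_P/r_S = 0.5` reflects the roughly twofold slower
primed proliferation. Ties are handled by average ranks everywhere; the
flow gate uses at-or-above; quantile state calls break score ties
deterministically by cell id; degenerate inputs (constant scores,
all-zero cells, empty marker sets) warn or error as documented on each
function.

## Known limitations

- The purity-based moment estimator ignores back-switching and is biased
  upward once `p` is large enough that double events matter; the grid
  fit does not share this limitation.
- Grid inference inherits the identifiability of the summary statistics:
  parameters whose effects cancel in all components (e.g. simultaneous
  proportional changes to both division rates) are not distinguishable.
- The paired statistics require enough primed-dominated reference
  lineages; in designs where the primed state is very rare or the
  expansion long, the primed side of the comparison carries little
  information and mechanism discrimination degrades accordingly.
- The accepted-set "uncertainty region" has no probabilistic calibration.
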