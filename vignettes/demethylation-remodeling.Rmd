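---
title: "Models and methods: demethylation, hemimethylation, and nucleosome remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: demethylation, hemimethylation, and nucleosome remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azanome)
```

This vignette is the package's own account of the models it implements:
what is being simulated and measured, which parameters matter, the
numerical conventions, and what the synthetic-data tests do and do not
demonstrate about real data.

## Coordinates and site annotation

All positions are 0-based indices on the reference top strand; intervals
are half-open `[start, end)`. A CpG or GpC site is identified by the
top-strand index of its cytosine. `annotate_sites()` partitions the
cytosines of every CpG and GpC dinucleotide into three disjoint classes by
top-strand trinucleotide context:

* **HCG** (preceding base A/C/T): endogenous CpG methylation readout;
* **GCH** (following base A/C/T): GpC methyltransferase accessibility
  readout;
* **GCG**: one cytosine carrying both signals — excluded from both
  readouts, because enzyme-deposited and endogenous methylation cannot be
  separated there.

A boundary cytosine lacking its flanking base is kept in the informative
class (the absent base cannot be the disqualifying G).

Bottom-strand clones are represented as their PCR top-strand image, so a
bottom-strand cytosine is read at the guanine it pairs with: position
`p + 1` for a CpG at `p`, position `q − 1` for a GpC at `q`. One further
exclusion follows from this geometry: in a `CGC` context (`q = p + 2`) the
two bottom-strand readouts coincide on the same guanine, so both calls are
reported `missing` for bottom-strand clones; top-strand reads are
unaffected. `random_amplicon()` therefore never designates such CpGs as
primer sites, mirroring how a primer designer would avoid ambiguous
contexts.

## The replication model

`simulate_timecourse()` evolves `n_molecules` duplexes, initially
methylated at every CpG, through `divisions_per_day` synchronous doublings
per day. Replication is semiconservative: each daughter keeps one parental
strand and synthesises a new one. While the drug is present (days up to
`washout_day`) a replication event is *inhibited* with probability
`incorporation_prob`, in which case the new strand carries no methylation;
otherwise maintenance methylation copies the parental pattern. After
washout every division is maintenance, optionally with per-site de novo
remethylation (`remethylation_prob`) at new-strand sites whose parental
partner is unmethylated. The population is held constant by uniform
subsampling after each doubling.

Two exact consequences anchor the tests: under full inhibition the
hemimethylated fraction after `k` divisions is `2^(1−k)` and the fully
methylated fraction is 0 for `k ≥ 1`; and once the drug is gone, perfect
maintenance resolves each hemimethylated duplex into one fully methylated
and one unmethylated daughter, which leaves the *strand-level* methylated
fraction `m0 = F + H/2` invariant — methylation measured per strand stays
flat after washout even as duplex classes redistribute.

Defaults (`incorporation_prob = 0.9`, `washout_day = 2`,
`divisions_per_day = 1`, `remethylation_prob = 0`, `n_molecules = 2000`)
give a day-2 population dominated by hemimethylated duplexes with a large
symmetrically demethylated minority and little residual full methylation.
They are illustrative, not fitted: only qualitative washout kinetics are
available to calibrate against, and `remethylation_prob` in particular has
no measured counterpart.

## The remodeling model

`apply_remodeling()` encodes the central structural hypothesis: complete
nucleosome depletion occurs only on symmetrically demethylated DNA. A
molecule whose window CpGs are unmethylated on both strands acquires an
occupancy gap covering the window with probability `p_ndr` (default 0.4),
multiplied by `srcap_kd_factor` (default 0.3) when remodeling is run under
the SRCAP-knockdown flag; its flanks are packed with 147-bp nucleosome
cores. All other molecules are tiled across the region with 147-bp cores,
a 50-bp linker and a uniformly random phase per molecule — occupancy is
specified, phasing is not, so phase is left random. Cores are truncated
only at region edges.

`apply_mcvipi()` then marks uncovered GCH cytosines, per strand, with
probability `mcvipi_efficiency`. The default is 1, modeling the saturating
excess-enzyme protocol; note that with per-site miss rate ε a true
window-wide gap is detected as fully accessible only with probability
(1−ε)^k over k in-window sites, so efficiency is exposed for sensitivity
analyses rather than folded into the statistics.

`bisulfite_reads()` applies conversion chemistry per strand: unmethylated
cytosines convert with `conversion_rate` (default 0.995), methylated ones
with `inappropriate_conversion` (default 0.005). Clone QC compares the
observed conversion rate — estimated from cytosines outside any
HCG/GCH/GCG context, which must convert — against `qc_min_conversion`
(default 0.95); failing clones are excluded from all fractions.

## Footprints, spans, and windows

`segment_clone()` collapses the ordered non-missing GCH calls of one clone
into maximal same-state runs; missing calls neither break runs nor
contribute sites. A run from site `p_first` to `p_last` has **span**
`p_last − p_first + 2` bp, covering both terminal GpC dinucleotides and
never extrapolating past the outermost observed sites. For display and
overlap the runs are also given drawn intervals that tile the observed
span exactly, meeting at the midpoint between opposite-state boundary
sites (the published clone diagrams draw continuous blocks without stating
a rule; the midpoint is the symmetric choice).

`call_ndr()` requires an accessible span strictly greater than 146 bp
(`min_span_bp = 147`, a flag) — wide enough to have evicted a ~147-bp
nucleosome — overlapping the promoter window by ≥ 1 bp. The default window
is `tss_window()`, TSS ± 100; windows anchored at the −1 nucleosome must
be supplied per region. `window_depletion_fraction()` instead asks whether
a fixed window (e.g. 250 bp covering the −1 nucleosome plus 100 bp
downstream) is entirely accessible, judging flank intrusion on a protected
run's observed site span rather than its drawn interval, so a protected
run whose sites all lie outside the window never disqualifies a clone.
Both statistics return exact binomial 95% confidence intervals
(`stats::binom.test`).

One practical caveat the simulator makes visible: a window can only ever
yield an NDR call if its GCH sites span more than 146 bp. Sparse or
clustered GpC layouts (as happen in GC-poor stretches) cap the observable
span below the threshold regardless of the underlying chromatin; check
`annotate_sites()` output before interpreting zero fractions.

## Hemimethylation deconvolution

Hpa II cuts CCGG only when the internal CpG is unmethylated on both
strands; hemimethylated and fully methylated sites resist. With PCR
reading both strands of every surviving duplex, the Ms-SNuPE
methylated-strand fraction is `m0 = F + H/2` undigested and
`m1 = (F + H/2)/(F + H)` after digestion, giving

```
H = 2·m0·(1/m1 − 1),   F = m0·(2 − 1/m1),   U = 1 − H − F.
```

The inversion is derived here from the digestion chemistry (the original
equations are cited but not printed in the source literature), and the
forward model `uhf_forward()` ships alongside so the inversion can be
verified: the two are mutually inverse on the whole feasible simplex, as
the test suite checks on a 0.05 grid. Feasibility requires `m1 ≥ 1/2`
(every digestion survivor carries at least one methylated strand) and
`m0 ≤ m1`; estimates outside `[0, 1]` by more than `tol = 1e-6` raise an
error with the residual, smaller violations are clamped and renormalised.
Digestion is modeled as complete (enzyme excess); `digest_hpaii()` exposes
an `efficiency` parameter, default 1, for sensitivity analysis — whether
the original published equations carried such a correction is unknown.
With several CCGG sites a molecule is destroyed if *any* listed site is
symmetrically unmethylated, while deconvolution applies to the single
assayed site.

`select_hemimethylated_strands()` composes digestion, read generation and
demethylation-selective PCR (`filter_demethylated_strands()`, which keeps
clones unmethylated at every primer CpG; a missing primer call drops the
clone, since amplification cannot be confirmed). By construction the
surviving demethylated strands derive from hemimethylated duplexes, whose
occupancy can then be footprinted separately.

## Genome-scale statistics

Beta values are classified hypo (< 0.2) / hyper (> 0.8) / intermediate
(boundaries inclusive in the intermediate class). A probe is called
demethylated when its control beta exceeds `hyper_threshold = 0.8` and the
control-minus-treated difference is at least `delta = 0.25`; the
difference threshold is applied as ≥ (the source convention is unstated;
the flag is configurable), probes with missing values are excluded and
counted, and genes collapse by "any probe selected".

`sam_two_class()` follows the original SAM recipe: moderated score
`d = (x̄2 − x̄1)/(s + s0)` with the exchangeability offset `s0` chosen as
the percentile of the pooled standard errors minimising the coefficient of
variation of the windowed MAD of `d`; `s0` is tuned once on the observed
labelling and reused for permutations. The null uses all distinct label
assignments when `choose(n, n2) ≤ n_perm` (for 4 vs 4, all 70), otherwise
`n_perm` seeded uniform draws. For each gene the false-call estimate at
its |d| is the median across permutations of the number of null scores at
least as extreme, scaled by π0 (estimated from the fraction of observed
scores inside the permuted interquartile range) and divided by the
observed count; q-values are forced monotone in |d| (take the minimum over
less-significant thresholds, BH-style). Symmetric |d| cutoffs are used
rather than the asymmetric delta sweep of the original plotting
convention; on the null and planted-effect simulations in the test suite
this calibrates to ~0 spurious calls at `q ≤ 0.05` and full recovery of
4-SD effects.

Knockdown attenuation of reactivation is tested by a paired two-sided
Wilcoxon signed-rank test on per-gene log2 fold-change differences (the
test behind the published p-value is unnamed; the signed-rank test is the
robust default, a paired t-test is available), with quartile summaries for
box plots and `p = 1` flagged degenerate when all differences vanish. Row
clustering of demethylated probes uses Euclidean distance with average
linkage (unspecified in the source display; both configurable), imputing
missing values by row means for the distance only. The overlap of
significant sets is reported with an explicit denominator convention
(default: the control-arm set).

`generate_array_data()` plants the ground truth: bimodal control betas
(Beta(1,15)/Beta(15,1) modes), demethylated probes starting in 0.85–0.98
and dropping 0.30–0.60 in both siRNA arms, and reactivated genes — a
subset of the demethylated ones, 44 by default — gaining `effect_log2 = 2`
under drug in the control arm and `kd_attenuation × 2` (default 0.5)
under knockdown, with N(0, 0.5²) residuals over 4 replicates per
condition.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run at desk scale, chosen to
make binomial/permutation noise small relative to the tolerances: 10,000
molecules for replication kinetics, 600-bp amplicons with ~30 GCH sites,
1,000–2,000 clones per pool, 2,000 transcripts with 4 vs 4 replicates and
up to 1,000 permutations. Every stochastic function takes a seed and
restores the caller's RNG state (`withr::with_seed`); `run_pipeline()`
derives per-stage streams from one master seed and reruns reproduce every
artifact byte for byte, as the manifest md5s record.

## What the simulations do and do not show

The generator reproduces the statistical structure the analyses assume —
duplex-class mixtures from semiconservative replication,
methylation-conditional occupancy, strand-resolved conversion chemistry,
bimodal betas with planted effects. It deliberately omits: cell-cycle
structure and drug cytotoxicity (the population is well-mixed and
generational); sequence-dependent nucleosome positioning (phases are
random); enzyme sequence preferences beyond the GCH context; indels and
base-quality noise in clone reads (Sanger amplicons are modeled as exact
coordinate maps); array normalisation artefacts (matrices are generated
already normalised); and any ChIP-level signal. Passing the suite
therefore demonstrates correctness of the estimators under the stated
models, not robustness to every failure mode of real libraries — the QC
and sensitivity parameters (`qc_min_conversion`, `mcvipi_efficiency`,
digestion `efficiency`) are the intended instruments for exploring the
latter.
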