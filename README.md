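# azanome

Single-molecule nucleosome footprinting and demethylation dynamics after
DNMT inhibition.

## The problem

5-Aza-2'-deoxycytidine (decitabine) is incorporated into replicating DNA,
traps DNA methyltransferases, and so demethylates CpG sites *passively*:
each semiconservative replication under inhibition pairs a methylated
parental strand with an unmethylated daughter strand. The immediate product
is therefore **hemimethylated** DNA (H); only further divisions produce
**symmetrically demethylated** duplexes (U) alongside residual **fully
methylated** ones (F). Whether a silenced promoter actually reopens — loses
its nucleosomes and reactivates — turns out to depend on which of these
duplex states the molecule is in, and on H2A.Z deposition by the SRCAP
remodeler.

`azanome` implements the analysis chain needed to study this at both
scales, for epigenomics researchers working with amplicon-level NOMe-seq
clones and promoter methylation/expression arrays:

* **NOMe-seq footprinting** (`annotate_sites`, `call_clone`,
  `segment_clone`, `ndr_fraction`): dual-enzyme bisulfite readout in which
  endogenous methylation is read at HCG sites and M.CviPI-deposited GpC
  methylation marks accessible (linker/NDR) DNA at GCH sites; ambiguous
  GCG contexts are excluded. A clone carries a nucleosome-depleted region
  (NDR) when an accessible run spans more than 146 bp — enough to evict at
  least one ~147-bp nucleosome core — and overlaps the promoter window.
* **Hemimethylation deconvolution** (`digest_hpaii`, `deconvolve_uhf`):
  Hpa II cuts CCGG only when the internal CpG is unmethylated on both
  strands. With m0 the methylated-strand fraction measured by Ms-SNuPE
  without digestion and m1 the same after digestion, the duplex-class
  fractions follow from m0 = F + H/2 and m1 = (F + H/2)/(F + H):

      H = 2·m0·(1/m1 − 1),   F = m0·(2 − 1/m1),   U = 1 − H − F.

* **Strand-selective assays** (`filter_demethylated_strands`,
  `select_hemimethylated_strands`): demethylation-specific PCR retains only
  strands unmethylated at the primer CpGs; pre-digestion with Hpa II
  destroys the U duplexes so that surviving demethylated strands derive
  exclusively from hemimethylated DNA.
* **Genome-scale statistics** (`classify_beta`, `call_demethylated`,
  `sam_two_class`, `reactivation_comparison`): Infinium-style beta values
  are bimodal (hypo < 0.2, hyper > 0.8); a probe is drug-demethylated when
  its control beta exceeds 0.8 and drops by ≥ 0.25. Differential expression
  uses a SAM permutation test, d = (x̄2 − x̄1)/(s + s0) with
  median-false-positive q-values, and knockdown attenuation of
  reactivation is tested by a paired Wilcoxon signed-rank test on per-gene
  log2 fold changes.
* **A ground-truthed simulator** (`simulate_timecourse`,
  `apply_remodeling`, `apply_mcvipi`, `bisulfite_reads`,
  `generate_array_data`) that evolves duplex methylation by
  semiconservative replication, places nucleosomes conditional on
  symmetric demethylation (NDR probability `p_ndr`, attenuated by
  `srcap_kd_factor` under knockdown), applies the GpC methyltransferase and
  bisulfite chemistry, and plants demethylation/reactivation effects in
  array matrices — so every stage is testable without external data.

## Worked example

```r
library(azanome)

ref <- random_amplicon(length = 600, seed = 20, gc = 0.55)   # synthetic promoter
cfg <- simulation_config(seed = 1)                           # drug until day 2
tc  <- simulate_timecourse(cfg, ref)
tc$day2
#> duplex_population 'synthetic_promoter': 2000 molecules, 40 CpGs
#>   (U=893 H=996 F=111), 0 with NDR

# Hpa II hemimethylation assay at the region's CCGG site
m <- measure_snupe(tc$day2)
deconvolve_uhf(m$m_undigested, m$m_digested)
#> hemi_estimate: U = 0.447, H = 0.498, F = 0.055 (residual 0)

# nucleosome remodeling + NOMe-seq on the day-2 population
win   <- tss_window(ref, flank = 150)
pop   <- apply_remodeling(tc$day2, cfg, win, seed = 2)
ann   <- annotate_sites(ref)
flags <- apply_mcvipi(pop, ann, seed = 3)
clones <- bisulfite_reads(pop, flags, cfg, 50, seed = 4)
cs <- mapply(call_clone, clones$reads, clone_id = names(clones$reads),
             MoreArgs = list(reference = ref, annotation = ann),
             SIMPLIFY = FALSE)

dem <- filter_demethylated_strands(cs, ref)   # demethylation-selective PCR
ndr_fraction(dem, ann, win)
#> 5/31 = 16.1% (exact 95% CI 5.5-33.7%)

hemi <- select_hemimethylated_strands(pop, flags, cfg, n_clones = 50, seed = 5)
window_depletion_fraction(hemi$callsets, ann, win)
#> 0/25 = 0.0% (exact 95% CI 0.0-13.7%)
```

Reading: one day after washout about half the duplexes are hemimethylated
and 45% symmetrically demethylated. Among demethylated strands 16% already
show an NDR wider than a nucleosome; the Hpa II-selected hemimethylated
strands show none — nucleosome depletion is confined to symmetrically
demethylated DNA. `run_pipeline(run_config(out_dir))` runs all five stages
and writes FASTA/TSV/BED artifacts plus a seed-stamped `manifest.json`.

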