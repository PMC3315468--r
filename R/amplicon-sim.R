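#' Generate a synthetic promoter amplicon reference
#'
#' Draws a random top-strand sequence with a fixed TSS and verifies that it
#' carries enough readout sites to be usable (HCG sites for methylation,
#' GCH sites for accessibility, and at least one CCGG motif for Hpa II
#' work). The outermost HCG sites whose readout is unambiguous on both
#' strands (no CGC overlap with a neighbouring GpC, see [call_clone()])
#' are designated as the demethylation-selective primer CpGs, as a primer
#' designer would avoid such contexts.
#'
#' @param length Amplicon length in bp (default 600).
#' @param seed Integer seed.
#' @param region_id Region name.
#' @param tss TSS position (default: midpoint).
#' @param gc GC content of the random draw (default 0.5).
#' @param min_hcg,min_gch,min_ccgg Minimum site counts the draw must
#'   satisfy (re-drawn up to 100 times); the defaults scale with amplicon
#'   length.
#' @return An [amplicon_reference()].
#' @export
random_amplicon <- function(length = 600L, seed = 1L,
                            region_id = "synthetic_promoter",
                            tss = length %/% 2L, gc = 0.5,
                            min_hcg = max(3L, length %/% 120L),
                            min_gch = max(8L, length %/% 30L),
                            min_ccgg = 1L) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed_opt(seed, {
    for (try in seq_len(100L)) {
      s <- paste(sample(names(p), length, replace = TRUE, prob = p),
                 collapse = "")
      ref <- amplicon_reference(region_id, s, tss)
      ann <- annotate_sites(ref)
      clean_hcg <- ann$hcg_sites[!(ann$hcg_sites + 2L) %in% ann$gch_sites]
      if (length(ann$hcg_sites) >= min_hcg &&
          length(ann$gch_sites) >= min_gch &&
          length(ccgg_positions(ref)) >= min_ccgg &&
          length(clean_hcg) >= 2L) {
        primer <- range(clean_hcg)
        return(amplicon_reference(region_id, s, tss, primer))
      }
    }
    stop("no draw satisfied the site-count constraints in 100 tries")
  })
}
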