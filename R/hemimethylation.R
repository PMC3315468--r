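#' Classify a DNA duplex by its strand methylation states
#'
#' @param top_meth,bottom_meth Logical (vectorised): is the strand
#'   methylated?
#' @return Factor with levels `U` (neither strand methylated), `H`
#'   (hemimethylated, exactly one) and `F` (fully methylated, both).
#' @examples
#' classify_duplex(c(FALSE, TRUE, TRUE), c(FALSE, FALSE, TRUE))  # U H F
#' @export
classify_duplex <- function(top_meth, bottom_meth) {
  factor(c("U", "H", "F")[top_meth + bottom_meth + 1L],
         levels = c("U", "H", "F"))
}

#' Digest a duplex population with Hpa II
#'
#' Hpa II cuts its CCGG target only when the internal CpG is unmethylated on
#' both strands; fully and hemimethylated configurations resist digestion.
#' A molecule is destroyed when at least one of the listed CCGG sites is
#' symmetrically unmethylated; survivors are returned unchanged.
#'
#' @param pop A `duplex_population`.
#' @param ccgg_internal_cpg_positions 0-based positions of the CCGG-internal
#'   CpG cytosines to digest at; every position must sit inside a CCGG motif
#'   of the reference. Default: every CCGG site of the region.
#' @param efficiency Probability that a cuttable molecule is actually
#'   destroyed (default 1: digestion with enzyme excess is complete).
#' @param seed Optional seed (only relevant when `efficiency < 1`).
#' @return The surviving sub-population.
#' @export
digest_hpaii <- function(pop, ccgg_internal_cpg_positions = NULL,
                         efficiency = 1, seed = NULL) {
  valid <- ccgg_positions(pop$reference)
  pos <- if (is.null(ccgg_internal_cpg_positions)) valid else
    as.integer(ccgg_internal_cpg_positions)
  if (!length(pos)) stop("region has no CCGG site")
  if (!all(pos %in% valid)) {
    stop("position(s) ", paste(setdiff(pos, valid), collapse = ", "),
         " are not CCGG-internal CpG cytosines of the reference")
  }
  idx <- match(pos, pop$cpg_positions)
  cuttable <- rowSums(pop$top[, idx, drop = FALSE] |
                        pop$bottom[, idx, drop = FALSE]) < length(idx)
  with_seed_opt(seed, {
    destroyed <- cuttable &
      (efficiency >= 1 | stats::runif(length(cuttable)) < efficiency)
    pop_subset(pop, which(!destroyed))
  })
}

#' Forward model: strand-methylation measurements of a U/H/F mixture
#'
#' Predicts the Ms-SNuPE readout at a CCGG-internal CpG for a duplex mixture
#' with fractions `(U, H, F)`. PCR after bisulfite conversion reads both
#' strands of every template, so the methylated-strand fraction of the
#' undigested sample is `m0 = F + H/2`. Hpa II destroys only U duplexes, so
#' the digested sample measures `m1 = (F + H/2) / (F + H)`.
#'
#' @param U,H,F Duplex-class fractions (must sum to 1; `H + F > 0`).
#' @return List with `m_undigested` and `m_digested`.
#' @seealso [deconvolve_uhf()] for the inverse.
#' @export
uhf_forward <- function(U, H, F) {
  if (abs(U + H + F - 1) > 1e-9) stop("U + H + F must equal 1")
  if (H + F <= 0) stop("m_digested is undefined when H + F = 0")
  list(m_undigested = F + H / 2,
       m_digested = (F + H / 2) / (F + H))
}

#' Deconvolve duplex-class fractions from digestion Ms-SNuPE measurements
#'
#' Inverts the model of [uhf_forward()]: given the methylated-strand
#' fraction at one CCGG-internal CpG measured without digestion (`m0`) and
#' after Hpa II digestion (`m1`),
#' \deqn{H = 2 m_0 (1/m_1 - 1), \quad F = m_0 (2 - 1/m_1), \quad
#'       U = 1 - H - F.}
#' Because only hemimethylated and fully methylated duplexes survive
#' digestion, a feasible measurement requires `m1 >= 1/2` (survivors carry
#' at least one methylated strand each) and `m0 <= m1` (digestion removes
#' only unmethylated strands). Estimates violating `[0, 1]` by at most
#' `tol` are clamped; larger violations raise an error with the residual.
#'
#' @param m_undigested,m_digested Methylated-strand fractions before/after
#'   digestion, both in `[0, 1]`.
#' @param tol Feasibility tolerance (default 1e-6).
#' @return Object of class `hemi_estimate`: fractions `U`, `H`, `F`
#'   (summing to 1 within 1e-9) and the clamping `residual`.
#' @examples
#' deconvolve_uhf(0.4, 2 / 3)  # a 0.4 / 0.4 / 0.2 U/H/F mixture
#' @export
deconvolve_uhf <- function(m_undigested, m_digested, tol = 1e-6) {
  m0 <- m_undigested; m1 <- m_digested
  for (m in c(m0, m1)) {
    if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0 || m > 1) {
      stop("measurements must be fractions in [0, 1]")
    }
  }
  if (m1 == 0) stop("m_digested = 0: no surviving methylated strand, model undefined")
  if (m1 < 0.5 - tol) {
    stop(sprintf(
      "infeasible measurement: m_digested = %.4f < 1/2 (every digestion survivor carries >= 1 methylated strand)", m1))
  }
  if (m0 > m1 + tol) {
    stop(sprintf(
      "infeasible measurement: m_undigested (%.4f) > m_digested (%.4f); digestion can only enrich methylated strands", m0, m1))
  }
  H <- 2 * m0 * (1 / m1 - 1)
  F <- m0 * (2 - 1 / m1)
  U <- 1 - H - F
  est <- c(U = U, H = H, F = F)
  residual <- max(0, max(-est), max(est - 1))
  if (residual > tol) {
    stop(sprintf(
      "inconsistent measurement: deconvolved fractions leave [0, 1] by %.3g (U=%.4f H=%.4f F=%.4f)",
      residual, U, H, F))
  }
  est <- pmin(pmax(est, 0), 1)
  est <- est / sum(est)
  structure(list(U = est[["U"]], H = est[["H"]], F = est[["F"]],
                 residual = residual),
            class = "hemi_estimate")
}

#' @export
print.hemi_estimate <- function(x, ...) {
  cat(sprintf("hemi_estimate: U = %.3f, H = %.3f, F = %.3f (residual %.2g)\n",
              x$U, x$H, x$F, x$residual))
  invisible(x)
}

#' Measure a simulated population as a digestion Ms-SNuPE pair
#'
#' Convenience bridge from simulation to deconvolution: computes the
#' methylated-strand fraction at one CCGG-internal CpG in the population
#' and in its Hpa II digest, i.e. noise-free `m0`/`m1` measurements.
#'
#' @param pop A `duplex_population`.
#' @param ccgg_pos Position of the assayed CCGG-internal CpG (default:
#'   the region's first CCGG site).
#' @return List with `m_undigested`, `m_digested`.
#' @export
measure_snupe <- function(pop, ccgg_pos = ccgg_positions(pop$reference)[1L]) {
  if (is.na(ccgg_pos)) stop("region has no CCGG site")
  idx <- match(ccgg_pos, pop$cpg_positions)
  if (is.na(idx)) stop("ccgg_pos is not a CpG position of the region")
  frac_meth <- function(p) {
    (sum(p$top[, idx]) + sum(p$bottom[, idx])) / (2L * n_molecules(p))
  }
  dig <- digest_hpaii(pop, ccgg_pos)
  if (n_molecules(dig) == 0L) stop("digestion destroyed every molecule")
  list(m_undigested = frac_meth(pop), m_digested = frac_meth(dig))
}

#' Hemimethylated-strand selection: Hpa II digestion + demethylation PCR
#'
#' Composes the combined assay for footprinting hemimethylated DNA:
#' the GpC-marked population is digested with Hpa II (destroying duplexes
#' symmetrically unmethylated at a CCGG site), bisulfite clone reads are
#' generated from the survivors, and only clones unmethylated at every
#' primer CpG are retained. Surviving demethylated strands therefore derive
#' from hemimethylated duplexes, whose nucleosome occupancy can then be
#' analysed with [ndr_fraction()] / [window_depletion_fraction()].
#'
#' @param pop A `duplex_population` (after [apply_remodeling()]).
#' @param gch_flags From [apply_mcvipi()].
#' @param config A [simulation_config()].
#' @param n_clones Strands to sample from the digestion survivors (capped at
#'   the available count).
#' @param ccgg_internal_cpg_positions Passed to [digest_hpaii()].
#' @param qc_min_conversion Passed to [call_clone()].
#' @param seed Optional seed.
#' @return List: retained `callsets`, the full `clone_set` (`clones`), the
#'   digestion survivor population (`survivors`), and `truth` rows for the
#'   retained clones.
#' @export
select_hemimethylated_strands <- function(pop, gch_flags, config, n_clones,
                                          ccgg_internal_cpg_positions = NULL,
                                          qc_min_conversion = 0.95,
                                          seed = NULL) {
  reference <- pop$reference
  if (!length(reference$primer_cpg_positions)) {
    stop("reference has no primer_cpg_positions for demethylation selection")
  }
  with_seed_opt(seed, {
    surv <- digest_hpaii(pop, ccgg_internal_cpg_positions)
    surv_idx <- survivor_indices(pop, ccgg_internal_cpg_positions)
    flags <- list(gch_top = gch_flags$gch_top[surv_idx, , drop = FALSE],
                  gch_bottom = gch_flags$gch_bottom[surv_idx, , drop = FALSE],
                  gch_sites = gch_flags$gch_sites)
    class(flags) <- "gch_flags"
    if (n_molecules(surv) == 0L) {
      return(list(callsets = list(), clones = NULL, survivors = surv,
                  truth = NULL))
    }
    n_clones <- min(n_clones, 2L * n_molecules(surv))
    clones <- bisulfite_reads(surv, flags, config, n_clones)
    ann <- annotate_sites(reference)
    callsets <- mapply(function(read, id) {
      call_clone(read, reference, ann, qc_min_conversion, clone_id = id)
    }, clones$reads, names(clones$reads), SIMPLIFY = FALSE)
    retained <- filter_demethylated_strands(callsets, reference, ann)
    truth <- clones$truth[clones$truth$clone_id %in%
                            vapply(retained, `[[`, "", "clone_id"), ]
    list(callsets = retained, clones = clones, survivors = surv,
         truth = truth)
  })
}

## indices of molecules resisting complete Hpa II digestion
survivor_indices <- function(pop, ccgg_internal_cpg_positions = NULL) {
  pos <- if (is.null(ccgg_internal_cpg_positions)) {
    ccgg_positions(pop$reference)
  } else as.integer(ccgg_internal_cpg_positions)
  idx <- match(pos, pop$cpg_positions)
  which(rowSums(pop$top[, idx, drop = FALSE] |
                  pop$bottom[, idx, drop = FALSE]) == length(idx))
}

#' Deconvolve a table of digestion Ms-SNuPE measurements
#'
#' @param path TSV with columns `region_id`, `m_undigested`, `m_digested`.
#' @param out Optional output TSV path (adds `U`, `H`, `F`, `residual`).
#' @return data.frame with the deconvolved fractions per region.
#' @export
deconvolve_uhf_table <- function(path, out = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("region_id", "m_undigested", "m_digested") %in% names(tab)))
  est <- lapply(seq_len(nrow(tab)), function(i) {
    deconvolve_uhf(tab$m_undigested[i], tab$m_digested[i])
  })
  tab$U <- vapply(est, `[[`, 0, "U")
  tab$H <- vapply(est, `[[`, 0, "H")
  tab$F <- vapply(est, `[[`, 0, "F")
  tab$residual <- vapply(est, `[[`, 0, "residual")
  if (!is.null(out)) {
    utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab
}
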