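## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state;
## a NULL seed continues the current stream.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Simulation parameters for the demethylation time course
#'
#' Collects and validates every tunable of the synthetic-data generator.
#' The generator models passive demethylation under a replication-dependent
#' DNMT inhibitor: while the drug is present each replication event is, with
#' probability `incorporation_prob`, a fully inhibited one whose newly
#' synthesised strand carries no CpG methylation; otherwise maintenance
#' methyltransfer copies the parental pattern onto the new strand.
#'
#' @param n_molecules Number of DNA duplexes carried through the time course
#'   (population held constant by uniform subsampling after each doubling).
#' @param days Integer day indices at which snapshots are returned
#'   (ascending, day 0 = untreated start).
#' @param divisions_per_day Cell doublings per day (positive real; default 1).
#' @param incorporation_prob Probability that a replication event is
#'   drug-inhibited while the drug is present (1 = full DNMT inhibition).
#' @param remethylation_prob Per-site probability, after drug washout, that
#'   maintenance synthesis remethylates a new-strand CpG whose parental
#'   partner is unmethylated (de novo recovery; default 0).
#' @param washout_day Last day on which the drug is present; divisions on
#'   later days are never inhibited.
#' @param p_ndr Probability that a symmetrically demethylated duplex acquires
#'   a nucleosome-depleted region over the promoter window (see
#'   [apply_remodeling()]).
#' @param srcap_kd_factor Multiplier applied to `p_ndr` when remodeling is
#'   run under the SRCAP-knockdown flag (attenuated H2A.Z deposition).
#' @param conversion_rate Bisulfite conversion probability of an
#'   unmethylated cytosine.
#' @param inappropriate_conversion Conversion probability of a methylated
#'   cytosine (bisulfite over-conversion failure mode).
#' @param mcvipi_efficiency Probability that the GpC methyltransferase marks
#'   an accessible GCH site. The default 1 models the saturating
#'   excess-enzyme protocol; lower it for sensitivity analyses of
#'   incomplete marking.
#' @param seed Integer seed used by [simulate_timecourse()].
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_molecules = 2000L,
                              days = 0:5,
                              divisions_per_day = 1,
                              incorporation_prob = 0.9,
                              remethylation_prob = 0,
                              washout_day = 2L,
                              p_ndr = 0.4,
                              srcap_kd_factor = 0.3,
                              conversion_rate = 0.995,
                              inappropriate_conversion = 0.005,
                              mcvipi_efficiency = 1,
                              seed = 1L) {
  cfg <- list(n_molecules = as.integer(n_molecules),
              days = as.integer(days),
              divisions_per_day = divisions_per_day,
              incorporation_prob = incorporation_prob,
              remethylation_prob = remethylation_prob,
              washout_day = as.integer(washout_day),
              p_ndr = p_ndr, srcap_kd_factor = srcap_kd_factor,
              conversion_rate = conversion_rate,
              inappropriate_conversion = inappropriate_conversion,
              mcvipi_efficiency = mcvipi_efficiency,
              seed = as.integer(seed))
  if (cfg$n_molecules < 1L) stop("n_molecules must be >= 1")
  if (any(cfg$days < 0L)) stop("negative day index")
  if (is.unsorted(cfg$days, strictly = TRUE)) stop("days must be sorted ascending")
  if (cfg$divisions_per_day <= 0) stop("divisions_per_day must be positive")
  for (f in c("incorporation_prob", "remethylation_prob", "p_ndr",
              "srcap_kd_factor", "conversion_rate",
              "inappropriate_conversion", "mcvipi_efficiency")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(f, " must be a fraction in [0, 1]")
    }
  }
  structure(cfg, class = "simulation_config")
}

#' Construct a duplex population from explicit strand states
#'
#' Builds the molecule container used throughout the simulator from
#' per-CpG methylation flags, e.g. to assemble defined U/H/F mixtures.
#'
#' @param reference An [amplicon_reference()].
#' @param top,bottom Logical matrices (molecules x CpG sites, columns
#'   aligned to the region's CpG positions); a single logical value per
#'   molecule is recycled across sites.
#' @return A `duplex_population` (no occupancy assigned; see
#'   [apply_remodeling()]).
#' @export
duplex_population <- function(reference, top, bottom) {
  m <- length(cpg_positions(reference))
  expand <- function(x) {
    if (is.matrix(x)) {
      stopifnot(ncol(x) == m)
      x
    } else {
      matrix(rep(as.logical(x), m), nrow = length(x))
    }
  }
  top <- expand(top); bottom <- expand(bottom)
  stopifnot(nrow(top) == nrow(bottom))
  new_duplex_population(reference, top, bottom)
}

## internal constructor: per-CpG top/bottom methylation flags as n x m
## logical matrices plus a per-molecule occupancy list
new_duplex_population <- function(reference, top, bottom,
                                  occupancy = NULL, ndr = NULL) {
  n <- nrow(top)
  structure(
    list(reference = reference,
         region_id = reference$region_id,
         cpg_positions = cpg_positions(reference),
         top = top, bottom = bottom,
         occupancy = if (is.null(occupancy)) vector("list", n) else occupancy,
         ndr = if (is.null(ndr)) rep(FALSE, n) else ndr),
    class = "duplex_population")
}

#' @export
print.duplex_population <- function(x, ...) {
  cls <- table(duplex_classes(x))
  cat(sprintf(
    "duplex_population '%s': %d molecules, %d CpGs (U=%d H=%d F=%d), %d with NDR\n",
    x$region_id, nrow(x$top), ncol(x$top),
    cls[["U"]], cls[["H"]], cls[["F"]], sum(x$ndr)))
  invisible(x)
}

n_molecules <- function(pop) nrow(pop$top)

## subset molecules of a population
pop_subset <- function(pop, idx) {
  pop$top <- pop$top[idx, , drop = FALSE]
  pop$bottom <- pop$bottom[idx, , drop = FALSE]
  pop$occupancy <- pop$occupancy[idx]
  pop$ndr <- pop$ndr[idx]
  pop
}

#' Duplex class (U/H/F) of every molecule in a population
#'
#' @param pop A `duplex_population`.
#' @param positions Optional subset of CpG positions over which to classify;
#'   default: all CpGs of the region.
#' @return Factor with levels `U`, `H`, `F` (see [classify_duplex()]).
#' @export
duplex_classes <- function(pop, positions = NULL) {
  idx <- if (is.null(positions)) {
    seq_along(pop$cpg_positions)
  } else {
    i <- match(positions, pop$cpg_positions)
    if (anyNA(i)) stop("positions must be CpG positions of the region")
    i
  }
  top_any <- rowSums(pop$top[, idx, drop = FALSE]) > 0
  bot_any <- rowSums(pop$bottom[, idx, drop = FALSE]) > 0
  classify_duplex(top_any, bot_any)
}

#' Simulate semiconservative demethylation under DNMT inhibition
#'
#' Starts from a population of duplexes fully methylated at every CpG and
#' replicates them semiconservatively, day by day. Each daughter duplex keeps
#' one parental strand and gains a newly synthesised strand that is
#' unmethylated at every CpG if the replication event was drug-inhibited
#' (probability `incorporation_prob` while the drug is present), and
#' otherwise mirrors the parental pattern by maintenance methylation, with
#' optional per-site de novo remethylation after washout. The population is
#' held at `n_molecules` by uniform subsampling after each doubling.
#'
#' With full inhibition and no remethylation, the expected hemimethylated
#' fraction after k divisions is 2^(1-k) and the fully methylated fraction is
#' 0 for k >= 1: the first division converts every duplex to hemimethylated,
#' and each further division halves the hemimethylated pool.
#'
#' @param config A [simulation_config()].
#' @param region An [amplicon_reference()] with at least one CpG.
#' @return Named list, one `duplex_population` per requested day
#'   (names `"day0"`, `"day1"`, ...).
#' @export
simulate_timecourse <- function(config, region) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(region, "amplicon_reference"))
  cpg <- cpg_positions(region)
  if (!length(cpg)) stop("region '", region$region_id, "' has no CpG site")
  with_seed_opt(config$seed, {
    n <- config$n_molecules
    m <- length(cpg)
    top <- matrix(TRUE, n, m)
    bottom <- matrix(TRUE, n, m)
    out <- list()
    if (0L %in% config$days) {
      out[["day0"]] <- new_duplex_population(region, top, bottom)
    }
    cum_div <- function(d) floor(d * config$divisions_per_day + 1e-9)
    for (d in seq_len(max(config$days, 0L))) {
      drug_active <- d <= config$washout_day
      for (division in seq_len(cum_div(d) - cum_div(d - 1L))) {
        res <- replicate_once(top, bottom,
                              incorporation_prob = if (drug_active) config$incorporation_prob else 0,
                              remethylation_prob = if (drug_active) 0 else config$remethylation_prob)
        keep <- sample.int(nrow(res$top), n)
        top <- res$top[keep, , drop = FALSE]
        bottom <- res$bottom[keep, , drop = FALSE]
      }
      if (d %in% config$days) {
        out[[paste0("day", d)]] <- new_duplex_population(region, top, bottom)
      }
    }
    out
  })
}

## One synchronous doubling of the population. Daughter 1 inherits the
## parental top strand (new bottom strand); daughter 2 inherits the parental
## bottom strand (new top strand).
replicate_once <- function(top, bottom, incorporation_prob, remethylation_prob) {
  n <- nrow(top)
  new_strand <- function(parental) {
    inhibited <- stats::runif(n) < incorporation_prob
    ns <- parental
    ns[inhibited, ] <- FALSE
    if (remethylation_prob > 0) {
      gaps <- !parental & !inhibited
      denovo <- gaps & (matrix(stats::runif(length(parental)),
                               nrow(parental)) < remethylation_prob)
      ns[denovo] <- TRUE
    }
    ns
  }
  list(top = rbind(top, new_strand(bottom)),
       bottom = rbind(new_strand(top), bottom))
}

#' Place nucleosomes conditional on promoter methylation state
#'
#' Implements the remodeling model in which complete nucleosome depletion
#' occurs only on symmetrically demethylated DNA: a molecule whose CpGs
#' inside `window` are all unmethylated on both strands acquires, with
#' probability `p_ndr` (times `srcap_kd_factor` when `srcap_kd = TRUE`), an
#' occupancy gap covering the window, its flanks packed with nucleosomes.
#' Every other molecule — fully methylated or hemimethylated — is tiled
#' across the whole region with 147-bp nucleosome cores separated by
#' `linker` bp, at a uniformly random phase per molecule.
#'
#' @param pop A `duplex_population` from [simulate_timecourse()].
#' @param config A [simulation_config()] (supplies `p_ndr` and
#'   `srcap_kd_factor`).
#' @param window An [ndr_window()] inside the region.
#' @param srcap_kd Logical; apply the knockdown attenuation factor.
#' @param linker Linker length between tiled nucleosome cores (bp).
#' @param seed Optional seed (RNG state restored afterwards).
#' @return The population with `occupancy` intervals and the per-molecule
#'   `ndr` flag filled in.
#' @export
apply_remodeling <- function(pop, config, window, srcap_kd = FALSE,
                             linker = 50L, seed = NULL) {
  L <- region_length(pop$reference)
  if (window$start < 0L || window$end > L) {
    stop("NDR window [", window$start, ", ", window$end,
         ") lies outside the region [0, ", L, ")")
  }
  with_seed_opt(seed, {
    idx <- which(pop$cpg_positions >= window$start &
                   pop$cpg_positions < window$end)
    if (!length(idx)) warning("no CpG inside the NDR window")
    sym_unmeth <- rowSums(pop$top[, idx, drop = FALSE]) == 0 &
      rowSums(pop$bottom[, idx, drop = FALSE]) == 0
    p <- config$p_ndr * (if (srcap_kd) config$srcap_kd_factor else 1)
    n <- n_molecules(pop)
    gets_ndr <- sym_unmeth & (stats::runif(n) < p)
    period <- 147L + as.integer(linker)
    phases <- sample.int(period, n, replace = TRUE) - 1L
    pop$occupancy <- lapply(seq_len(n), function(i) {
      if (gets_ndr[i]) {
        tile_around_gap(L, window$start, window$end, period)
      } else {
        tile_region(L, phases[i], period)
      }
    })
    pop$ndr <- gets_ndr
    pop
  })
}

## 147-bp cores tiled across [0, L) at the given phase, truncated at edges
tile_region <- function(L, phase, period) {
  starts <- seq.int(-phase, L - 1L, by = period)
  iv <- cbind(pmax(starts, 0L), pmin(starts + 147L, L))
  iv[iv[, 2L] > iv[, 1L], , drop = FALSE]
}

## cores packed outward from a protected gap [gap_start, gap_end)
tile_around_gap <- function(L, gap_start, gap_end, period) {
  left <- if (gap_start > 0L) {
    starts <- rev(seq.int(gap_start - 147L, by = -period,
                          length.out = ceiling(gap_start / period) + 1L))
    cbind(pmax(starts, 0L), pmin(starts + 147L, gap_start))
  }
  right <- if (gap_end < L) {
    starts <- seq.int(gap_end, by = period,
                      length.out = ceiling((L - gap_end) / period) + 1L)
    cbind(pmax(starts, gap_end), pmin(starts + 147L, L))
  }
  iv <- rbind(left, right)
  iv[iv[, 2L] > iv[, 1L], , drop = FALSE]
}

## is reference position pos covered by any occupancy interval of `iv`?
pos_covered <- function(iv, pos) {
  if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(iv[, 1L] <= p & p < iv[, 2L]), logical(1L))
}

#' Apply GpC methyltransferase footprinting to a population
#'
#' The exogenous enzyme methylates GCH cytosines in linker and
#' nucleosome-depleted DNA: each annotated GCH site whose strand cytosine is
#' not covered by an occupancy interval is marked methylated (accessible)
#' with probability `efficiency`, independently per strand; covered sites
#' are never marked. Top-strand GCH cytosines sit at the annotated position,
#' bottom-strand ones at position - 1 (the paired guanine's partner).
#'
#' @param pop A `duplex_population` with occupancy assigned
#'   ([apply_remodeling()]).
#' @param annotation `site_annotation` of the same region.
#' @param efficiency Marking probability at accessible sites.
#' @param seed Optional seed.
#' @return List of class `gch_flags`: logical matrices `gch_top`,
#'   `gch_bottom` (molecules x GCH sites) and the `gch_sites` positions.
#' @export
apply_mcvipi <- function(pop, annotation, efficiency = 0.95, seed = NULL) {
  stopifnot(annotation$region_id == pop$region_id)
  with_seed_opt(seed, {
    g <- annotation$gch_sites
    n <- n_molecules(pop)
    acc_top <- t(vapply(pop$occupancy, function(iv) !pos_covered(iv, g),
                        logical(length(g))))
    acc_bot <- t(vapply(pop$occupancy, function(iv) !pos_covered(iv, g - 1L),
                        logical(length(g))))
    if (length(g) == 1L) { acc_top <- t(acc_top); acc_bot <- t(acc_bot) }
    structure(
      list(gch_top = acc_top & matrix(stats::runif(n * length(g)), n) < efficiency,
           gch_bottom = acc_bot & matrix(stats::runif(n * length(g)), n) < efficiency,
           gch_sites = g),
      class = "gch_flags")
  })
}

#' Generate bisulfite clone reads from a simulated population
#'
#' Samples strands (each of the 2n strands at most once), applies bisulfite
#' chemistry — unmethylated cytosines convert with probability
#' `conversion_rate`, methylated ones with probability
#' `inappropriate_conversion` — and emits every read in the reference frame:
#' top strands as C->T images, bottom strands as their PCR top-strand image
#' (G->A at converted bottom-strand cytosines). Methylated cytosines are the
#' endogenously methylated CpGs plus the GCH sites marked by
#' [apply_mcvipi()]; a GCG-context cytosine carries its endogenous CpG state.
#'
#' @param pop A `duplex_population`.
#' @param gch_flags A `gch_flags` object from [apply_mcvipi()] (NULL for
#'   DNA never exposed to the enzyme).
#' @param config A [simulation_config()] (conversion parameters).
#' @param n_clones Number of strands to sample (`1 <= n_clones <= 2 *
#'   molecules`).
#' @param seed Optional seed.
#' @return List of class `clone_set`: `reads` (named character vector in
#'   reference frame) and `truth` (data.frame: clone_id, molecule, strand,
#'   duplex_class, has_ndr, occupancy).
#' @export
bisulfite_reads <- function(pop, gch_flags = NULL, config, n_clones,
                            seed = NULL) {
  n <- n_molecules(pop)
  n_clones <- as.integer(n_clones)
  if (n_clones <= 0L) stop("n_clones must be positive")
  if (n_clones > 2L * n) stop("n_clones exceeds the 2 x n_molecules strands")
  with_seed_opt(seed, {
    strand_ids <- sample.int(2L * n, n_clones)
    molecule <- ((strand_ids - 1L) %% n) + 1L
    strand <- ifelse(strand_ids <= n, "top", "bottom")
    classes <- as.character(duplex_classes(pop))
    s <- strsplit(pop$reference$sequence, "", fixed = TRUE)[[1L]]
    top_c <- which(s == "C") - 1L
    ref_g <- which(s == "G") - 1L
    gch <- if (is.null(gch_flags)) integer() else gch_flags$gch_sites
    reads <- character(n_clones)
    for (k in seq_len(n_clones)) {
      i <- molecule[k]
      if (strand[k] == "top") {
        meth <- pop$cpg_positions[pop$top[i, ]]
        if (length(gch)) meth <- c(meth, gch[gch_flags$gch_top[i, ]])
        reads[k] <- convert_strand(s, top_c, meth, "T", config)
      } else {
        meth <- pop$cpg_positions[pop$bottom[i, ]] + 1L
        if (length(gch)) meth <- c(meth, gch[gch_flags$gch_bottom[i, ]] - 1L)
        reads[k] <- convert_strand(s, ref_g, meth, "A", config)
      }
    }
    names(reads) <- sprintf("clone_%03d", seq_len(n_clones))
    occ_str <- vapply(pop$occupancy[molecule], function(iv) {
      if (is.null(iv) || nrow(iv) == 0L) return("")
      paste(sprintf("%d-%d", iv[, 1L], iv[, 2L]), collapse = ";")
    }, character(1L))
    truth <- data.frame(clone_id = names(reads), molecule = molecule,
                        strand = strand, duplex_class = classes[molecule],
                        has_ndr = pop$ndr[molecule], occupancy = occ_str,
                        stringsAsFactors = FALSE)
    structure(list(reads = reads, truth = truth,
                   region_id = pop$region_id),
              class = "clone_set")
  })
}

## bisulfite-convert one strand given its cytosine positions (reference
## frame) and the subset that is methylated; converted bases become `to`
convert_strand <- function(s, cyt_pos, meth_pos, to, config) {
  meth <- cyt_pos %in% meth_pos
  u <- stats::runif(length(cyt_pos))
  p_convert <- ifelse(meth, config$inappropriate_conversion,
                      config$conversion_rate)
  s[cyt_pos[u < p_convert] + 1L] <- to
  paste(s, collapse = "")
}

#' Write clone reads as FASTA with a truth table TSV
#'
#' @param clones A `clone_set` from [bisulfite_reads()].
#' @param fasta_path Output FASTA path.
#' @param truth_path Output TSV path (default: FASTA path with
#'   `.truth.tsv`).
#' @param seed Seed recorded in the truth-table header comment.
#' @return `fasta_path`, invisibly.
#' @export
write_clone_fasta <- function(clones, fasta_path,
                              truth_path = sub("\\.fa(sta)?$", "", fasta_path),
                              seed = NA) {
  dss <- Biostrings::DNAStringSet(clones$reads)
  names(dss) <- sprintf("%s molecule=%d strand=%s class=%s",
                        clones$truth$clone_id, clones$truth$molecule,
                        clones$truth$strand, clones$truth$duplex_class)
  Biostrings::writeXStringSet(dss, fasta_path)
  truth_path <- paste0(truth_path, ".truth.tsv")
  con <- file(truth_path, "w")
  writeLines(sprintf("# region=%s seed=%s", clones$region_id, seed), con)
  utils::write.table(clones$truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(fasta_path)
}
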