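#' Amplicon reference region
#'
#' Bundles the top-strand sequence of a PCR amplicon with its transcription
#' start site and, optionally, the CpG positions covered by
#' methylation-selective PCR primers.
#'
#' All coordinates in the package are 0-based positions on the reference top
#' strand; intervals are half-open `[start, end)`. A CpG site's position is
#' the top-strand index of its cytosine; a GpC site's position is likewise
#' the index of its (top-strand) cytosine.
#'
#' @param region_id Character scalar naming the region (e.g. a gene promoter).
#' @param sequence Top-strand DNA sequence (character scalar over A/C/G/T, or
#'   a [Biostrings::DNAString]).
#' @param tss 0-based position of the transcription start site within the
#'   amplicon.
#' @param primer_cpg_positions Optional integer vector of CpG cytosine
#'   positions covered by the demethylation-selective primers; used by
#'   [filter_demethylated_strands()].
#' @return An object of class `amplicon_reference`.
#' @seealso [annotate_sites()], [call_clone()]
#' @export
amplicon_reference <- function(region_id, sequence, tss,
                               primer_cpg_positions = integer()) {
  sequence <- toupper(as.character(sequence))
  stopifnot(length(sequence) == 1L, length(region_id) == 1L)
  bad <- gregexpr("[^ACGT]", sequence)[[1L]]
  if (bad[1L] != -1L) {
    stop("non-ACGT character in sequence of '", region_id,
         "' at 0-based position ", bad[1L] - 1L)
  }
  n <- nchar(sequence)
  tss <- as.integer(tss)
  if (tss < 0L || tss >= n) stop("tss must lie within [0, region length)")
  primer_cpg_positions <- sort(unique(as.integer(primer_cpg_positions)))
  ref <- structure(
    list(region_id = region_id, sequence = sequence, tss = tss,
         primer_cpg_positions = primer_cpg_positions),
    class = "amplicon_reference")
  if (length(primer_cpg_positions)) {
    cpg <- cpg_positions(ref)
    if (!all(primer_cpg_positions %in% cpg)) {
      stop("primer_cpg_positions must be CpG cytosine positions of the region")
    }
  }
  ref
}

#' @export
print.amplicon_reference <- function(x, ...) {
  ann <- annotate_sites(x)
  cat(sprintf(
    "amplicon_reference '%s': %d bp, TSS at %d; %d HCG, %d GCH, %d GCG sites\n",
    x$region_id, nchar(x$sequence), x$tss,
    length(ann$hcg_sites), length(ann$gch_sites), length(ann$excluded_gcg)))
  invisible(x)
}

region_length <- function(reference) nchar(reference$sequence)

## 0-based positions of all CpG cytosines (top strand)
cpg_positions <- function(reference) {
  s <- charToRaw(reference$sequence)
  which(s[-length(s)] == charToRaw("C") & s[-1L] == charToRaw("G")) - 1L
}

## 0-based positions of all CCGG-internal CpG cytosines (the second C)
ccgg_positions <- function(reference) {
  m <- gregexpr("CCGG", reference$sequence, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer())
  as.integer(m)  # 1-based motif start == 0-based position of second C
}

#' Annotate HCG, GCH and GCG readout sites of an amplicon
#'
#' Scans every trinucleotide context on the top strand and partitions the
#' cytosines of CpG and GpC dinucleotides into three disjoint classes:
#' `hcg_sites` (HCG context: endogenous CpG methylation readout),
#' `gch_sites` (GCH context: GpC methyltransferase accessibility readout) and
#' `excluded_gcg` (GCG context, where the two signals overlap and cannot be
#' separated; excluded from both readouts).
#'
#' A CpG whose cytosine is the first base of the sequence counts as HCG, and
#' a GpC whose cytosine is the last base counts as GCH (the missing flanking
#' base cannot be a G/C respectively).
#'
#' @param reference An [amplicon_reference()].
#' @return An object of class `site_annotation` with integer vectors
#'   `hcg_sites`, `gch_sites`, `excluded_gcg` (0-based cytosine positions)
#'   and the `region_id`.
#' @examples
#' ref <- amplicon_reference("toy", "AACGTTAGCATTAGCGTT", tss = 5)
#' annotate_sites(ref)
#' @export
annotate_sites <- function(reference) {
  s <- strsplit(reference$sequence, "", fixed = TRUE)[[1L]]
  n <- length(s)
  isC <- s == "C"
  nxt <- c(s[-1L], "")   # base after each position
  prv <- c("", s[-n])    # base before each position
  cpg <- isC & nxt == "G"
  gpc <- isC & prv == "G"
  gcg <- cpg & gpc                 # GCG trinucleotide: one shared cytosine
  hcg <- cpg & !gpc                # preceding base is A/C/T (or absent)
  gch <- gpc & !cpg                # following base is A/C/T (or absent)
  structure(
    list(region_id = reference$region_id,
         hcg_sites = which(hcg) - 1L,
         gch_sites = which(gch) - 1L,
         excluded_gcg = which(gcg) - 1L),
    class = "site_annotation")
}

#' @export
print.site_annotation <- function(x, ...) {
  cat(sprintf("site_annotation '%s': %d HCG, %d GCH, %d excluded GCG\n",
              x$region_id, length(x$hcg_sites), length(x$gch_sites),
              length(x$excluded_gcg)))
  invisible(x)
}

## Reference-frame positions read for each site class on a given strand.
##
## Top-strand reads report the annotated cytosine itself (C = methylated,
## T = converted). Bottom-strand reads are represented as their PCR
## top-strand image, so the informative base is the guanine paired with the
## bottom-strand cytosine: for a CpG at p that is p+1, for a GpC at q it is
## q-1 (G = methylated, A = converted). A GCG cytosine at r maps to the two
## bottom-strand cytosines at r-1 and r+1; all are excluded from readout.
strand_site_positions <- function(annotation, strand) {
  strand <- match.arg(strand, c("top", "bottom"))
  if (strand == "top") {
    list(hcg = annotation$hcg_sites,
         gch = annotation$gch_sites,
         excluded = annotation$excluded_gcg,
         meth_base = "C", conv_base = "T", cyt_ref_base = "C")
  } else {
    list(hcg = annotation$hcg_sites + 1L,
         gch = annotation$gch_sites - 1L,
         excluded = sort(unique(c(annotation$excluded_gcg - 1L,
                                  annotation$excluded_gcg + 1L))),
         meth_base = "G", conv_base = "A", cyt_ref_base = "G")
  }
}

## positions of strand cytosines outside any HCG/GCH/GCG context, i.e. the
## sites used to estimate the bisulfite conversion rate
nonctx_cytosine_positions <- function(reference, annotation, strand) {
  sp <- strand_site_positions(annotation, strand)
  s <- strsplit(reference$sequence, "", fixed = TRUE)[[1L]]
  cyt <- which(s == sp$cyt_ref_base) - 1L
  setdiff(cyt, c(sp$hcg, sp$gch, sp$excluded))
}

#' Infer the bisulfite strand of origin of a clone read
#'
#' Amplicon clone reads are stored in the reference frame. A read derived
#' from the top strand can differ from the reference only by C->T conversion;
#' a bottom-strand read (in its PCR top-strand image) only by G->A. The read
#' is assigned to the strand whose conversion model explains it with fewer
#' mismatches.
#'
#' @param read Character scalar, same length as the reference sequence.
#' @param reference An [amplicon_reference()].
#' @param max_mismatch_frac Reject the read if the best model still leaves
#'   more than this fraction of positions unexplained (default 0.10).
#' @return `"top"` or `"bottom"`. Ties are broken toward `"top"` with a
#'   warning.
#' @export
infer_bisulfite_strand <- function(read, reference, max_mismatch_frac = 0.10) {
  read <- toupper(as.character(read))
  n <- nchar(reference$sequence)
  if (nchar(read) != n) {
    stop("read length (", nchar(read), ") != reference length (", n, ")")
  }
  r <- strsplit(read, "", fixed = TRUE)[[1L]]
  s <- strsplit(reference$sequence, "", fixed = TRUE)[[1L]]
  mm_top <- sum(ifelse(s == "C", !(r %in% c("C", "T")), r != s))
  mm_bot <- sum(ifelse(s == "G", !(r %in% c("G", "A")), r != s))
  if (min(mm_top, mm_bot) > max_mismatch_frac * n) {
    stop(sprintf(
      "read does not fit either bisulfite strand model (mismatch %.1f%% top, %.1f%% bottom)",
      100 * mm_top / n, 100 * mm_bot / n))
  }
  if (mm_top == mm_bot) {
    warning("equal mismatch count under both strand models; assigning 'top'")
    return("top")
  }
  if (mm_top < mm_bot) "top" else "bottom"
}

#' Call methylation and accessibility states of one bisulfite clone
#'
#' Reads the retained/converted state of every annotated HCG site
#' (endogenous CpG methylation) and GCH site (GpC methyltransferase
#' accessibility) of a clone read, after inferring its strand of origin.
#' The observed bisulfite conversion rate is estimated from cytosines
#' outside any HCG/GCH/GCG context, which are unmethylated in vivo and must
#' convert; clones below `qc_min_conversion` fail QC.
#'
#' In a `CGC` context the bottom-strand images of the CpG readout and of
#' the downstream GpC readout coincide on one guanine, so endogenous
#' methylation and enzyme marking cannot be separated there: both calls are
#' reported `missing` for bottom-strand clones (the top strand reads the
#' two cytosines directly and is unaffected).
#'
#' @param read Clone read in the reference frame (character scalar).
#' @param reference An [amplicon_reference()].
#' @param annotation A `site_annotation` for the same region (computed from
#'   the reference when omitted).
#' @param qc_min_conversion Minimum observed conversion rate to pass QC
#'   (default 0.95).
#' @param clone_id Identifier stored in the result.
#' @return An object of class `clone_callset`: `strand`, factor vectors
#'   `hcg_calls` (levels methylated/unmethylated/missing) and `gch_calls`
#'   (levels accessible/inaccessible/missing) aligned to the annotation site
#'   lists, `conversion_rate_observed`, `passed_qc`, and
#'   `conversion_indeterminate` (TRUE when no informative non-context
#'   cytosine was observed).
#' @export
call_clone <- function(read, reference, annotation = annotate_sites(reference),
                       qc_min_conversion = 0.95, clone_id = "clone") {
  strand <- infer_bisulfite_strand(read, reference)
  r <- strsplit(toupper(as.character(read)), "", fixed = TRUE)[[1L]]
  sp <- strand_site_positions(annotation, strand)

  call_at <- function(pos, pos_label, neg_label) {
    base <- r[pos + 1L]
    out <- rep("missing", length(pos))
    out[base == sp$meth_base] <- pos_label
    out[base == sp$conv_base] <- neg_label
    out
  }
  hcg_raw <- call_at(sp$hcg, "methylated", "unmethylated")
  gch_raw <- call_at(sp$gch, "accessible", "inaccessible")
  if (strand == "bottom") {
    # CGC overlap: both readouts image onto the same guanine
    hcg_raw[(annotation$hcg_sites + 2L) %in% annotation$gch_sites] <- "missing"
    gch_raw[(annotation$gch_sites - 2L) %in%
              c(annotation$hcg_sites, annotation$excluded_gcg)] <- "missing"
  }
  hcg_calls <- factor(hcg_raw,
                      levels = c("methylated", "unmethylated", "missing"))
  gch_calls <- factor(gch_raw,
                      levels = c("accessible", "inaccessible", "missing"))

  nc <- nonctx_cytosine_positions(reference, annotation, strand)
  base <- r[nc + 1L]
  informative <- base %in% c(sp$meth_base, sp$conv_base)
  n_inf <- sum(informative)
  if (n_inf == 0L) {
    conv <- NA_real_
    passed <- NA
    indeterminate <- TRUE
  } else {
    conv <- sum(base[informative] == sp$conv_base) / n_inf
    passed <- conv >= qc_min_conversion
    indeterminate <- FALSE
  }
  structure(
    list(clone_id = clone_id, region_id = reference$region_id,
         strand = strand, hcg_calls = hcg_calls, gch_calls = gch_calls,
         conversion_rate_observed = conv, passed_qc = passed,
         conversion_indeterminate = indeterminate),
    class = "clone_callset")
}

#' @export
print.clone_callset <- function(x, ...) {
  cat(sprintf(
    "clone_callset '%s' (%s strand): %d/%d HCG methylated, %d/%d GCH accessible, conversion %.3f, QC %s\n",
    x$clone_id, x$strand,
    sum(x$hcg_calls == "methylated"), length(x$hcg_calls),
    sum(x$gch_calls == "accessible"), length(x$gch_calls),
    x$conversion_rate_observed,
    if (isTRUE(x$passed_qc)) "pass" else if (isFALSE(x$passed_qc)) "FAIL" else "indeterminate"))
  invisible(x)
}

#' Retain clones whose primer CpG sites are all unmethylated
#'
#' Emulates PCR primers designed against the bisulfite-converted,
#' demethylated sequence: only strands unmethylated at every primer-covered
#' CpG amplify. Clones with a methylated or missing call at any primer CpG
#' are removed; input order is preserved, and the operation is idempotent.
#'
#' @param callsets List of [call_clone()] results.
#' @param reference An [amplicon_reference()] with non-empty
#'   `primer_cpg_positions`.
#' @param annotation Matching `site_annotation` (recomputed when omitted).
#' @return The retained subset of `callsets`.
#' @export
filter_demethylated_strands <- function(callsets, reference,
                                        annotation = annotate_sites(reference)) {
  pos <- reference$primer_cpg_positions
  if (!length(pos)) stop("reference has no primer_cpg_positions")
  idx <- match(pos, annotation$hcg_sites)
  if (anyNA(idx)) {
    stop("primer CpG position(s) ", paste(pos[is.na(idx)], collapse = ", "),
         " are not annotated HCG sites (GCG-context CpGs cannot be primer-selected)")
  }
  keep <- vapply(callsets, function(cs) {
    all(cs$hcg_calls[idx] == "unmethylated")
  }, logical(1L))
  callsets[keep]
}

#' Write a per-clone call table
#'
#' One row per clone, one column per annotated site, with symbols
#' `M`/`U` (HCG methylated/unmethylated), `A`/`I` (GCH
#' accessible/inaccessible) and `.` for missing calls.
#'
#' @param callsets List of `clone_callset` objects.
#' @param annotation The shared `site_annotation`.
#' @param path Output TSV path.
#' @return The table, invisibly (also written to `path` when non-NULL).
#' @export
write_call_table <- function(callsets, annotation, path = NULL) {
  sym_hcg <- c(methylated = "M", unmethylated = "U", missing = ".")
  sym_gch <- c(accessible = "A", inaccessible = "I", missing = ".")
  site_pos <- c(annotation$hcg_sites, annotation$gch_sites)
  ord <- order(site_pos)
  rows <- lapply(callsets, function(cs) {
    c(sym_hcg[as.character(cs$hcg_calls)],
      sym_gch[as.character(cs$gch_calls)])[ord]
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- paste0(
    c(rep("hcg_", length(annotation$hcg_sites)),
      rep("gch_", length(annotation$gch_sites)))[ord], site_pos[ord])
  tab <- cbind(
    clone_id = vapply(callsets, `[[`, "", "clone_id"),
    strand = vapply(callsets, `[[`, "", "strand"),
    conversion = vapply(callsets, `[[`, 0, "conversion_rate_observed"),
    passed_qc = vapply(callsets, function(cs) isTRUE(cs$passed_qc), NA),
    tab)
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tab)
}

#' Read an amplicon region table
#'
#' Expects columns `region_id`, `tss` and optionally `primer_cpgs` (a
#' comma-separated list of 0-based CpG positions), joined against a FASTA of
#' reference sequences.
#'
#' @param region_tsv Path to the region table.
#' @param fasta Path to the reference FASTA (names must match `region_id`).
#' @return A named list of [amplicon_reference()] objects.
#' @export
read_regions <- function(region_tsv, fasta) {
  tab <- utils::read.delim(region_tsv, stringsAsFactors = FALSE)
  stopifnot(all(c("region_id", "tss") %in% names(tab)))
  seqs <- Biostrings::readDNAStringSet(fasta)
  refs <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$region_id[i]
    if (!id %in% names(seqs)) stop("region '", id, "' not found in FASTA")
    primer <- integer()
    if ("primer_cpgs" %in% names(tab) && nzchar(tab$primer_cpgs[i])) {
      primer <- as.integer(strsplit(tab$primer_cpgs[i], ",")[[1L]])
    }
    amplicon_reference(id, as.character(seqs[[id]]), tab$tss[i], primer)
  })
  names(refs) <- tab$region_id
  refs
}
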