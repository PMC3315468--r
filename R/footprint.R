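#' Promoter window for nucleosome-depletion calls
#'
#' @param start,end 0-based half-open bp interval on the reference.
#' @param label Free-text description (e.g. `"TSS+/-100"`,
#'   `"-1 nucleosome + 100 bp"`).
#' @return An `ndr_window` object.
#' @export
ndr_window <- function(start, end, label = sprintf("%d-%d", start, end)) {
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop("window end must exceed start")
  structure(list(start = start, end = end, label = label),
            class = "ndr_window")
}

#' Default promoter window around a TSS
#'
#' @param reference An [amplicon_reference()].
#' @param flank Half-width in bp (default 100, i.e. TSS +/- 100).
#' @return An [ndr_window()], clipped to the region.
#' @export
tss_window <- function(reference, flank = 100L) {
  ndr_window(max(0L, reference$tss - flank),
             min(region_length(reference), reference$tss + flank),
             sprintf("TSS+/-%d", flank))
}

#' Segment a clone's GCH calls into accessible/protected footprints
#'
#' Collapses the ordered non-missing GCH calls of one clone into maximal
#' same-state runs. Missing calls never break a run; they simply contribute
#' no sites. Each segment records its site run (`first_site`, `last_site`,
#' `n_sites`), the footprint span `last - first + 2` bp (covering both
#' terminal GpC dinucleotides; no extrapolation past the outermost observed
#' sites), and a drawn interval `[start, end)`: adjacent opposite-state runs
#' meet at the midpoint between their boundary sites, so the intervals tile
#' the observed GCH span exactly.
#'
#' @param callset A [call_clone()] result.
#' @param annotation Matching `site_annotation`.
#' @return data.frame of class `footprint_segments` with columns `state`
#'   (accessible/protected), `start`, `end`, `span`, `n_sites`,
#'   `first_site`, `last_site`; zero rows (with a warning) when every GCH
#'   call is missing.
#' @export
segment_clone <- function(callset, annotation) {
  keep <- callset$gch_calls != "missing"
  if (!any(keep)) {
    warning("clone '", callset$clone_id, "': all GCH calls missing")
    return(empty_segments())
  }
  pos <- annotation$gch_sites[keep]
  acc <- callset$gch_calls[keep] == "accessible"
  r <- rle(as.vector(acc))
  last_idx <- cumsum(r$lengths)
  first_idx <- last_idx - r$lengths + 1L
  first <- pos[first_idx]
  last <- pos[last_idx]
  nseg <- length(r$values)
  # tiling boundaries: outer edges one bp beyond the terminal dinucleotides,
  # interior edges at the midpoint between flanking opposite-state sites
  bounds <- c(first[1L] - 1L,
              if (nseg > 1L) (last[-nseg] + first[-1L]) %/% 2L,
              last[nseg] + 1L)
  out <- data.frame(
    state = ifelse(r$values, "accessible", "protected"),
    start = bounds[-length(bounds)],
    end = bounds[-1L],
    span = last - first + 2L,
    n_sites = r$lengths,
    first_site = first,
    last_site = last,
    stringsAsFactors = FALSE)
  class(out) <- c("footprint_segments", "data.frame")
  out
}

empty_segments <- function() {
  out <- data.frame(state = character(), start = integer(), end = integer(),
                    span = integer(), n_sites = integer(),
                    first_site = integer(), last_site = integer(),
                    stringsAsFactors = FALSE)
  class(out) <- c("footprint_segments", "data.frame")
  out
}

#' Does a clone carry a nucleosome-depleted region over a window?
#'
#' TRUE iff some accessible segment spans more than `min_span_bp - 1` bp
#' (default: strictly longer than 146 bp, enough to evict at least one
#' nucleosome core) and its drawn interval overlaps the window by at least
#' one bp.
#'
#' @param segments Output of [segment_clone()].
#' @param window An [ndr_window()].
#' @param min_span_bp Minimum qualifying span (default 147, i.e. > 146 bp).
#' @return Logical scalar.
#' @export
call_ndr <- function(segments, window, min_span_bp = 147L) {
  if (nrow(segments) == 0L) return(FALSE)
  acc <- segments$state == "accessible" & segments$span >= min_span_bp
  any(acc &
        pmax(segments$start, window$start) < pmin(segments$end, window$end))
}

## exact binomial fraction with 95% CI
fraction_stat <- function(k, n) {
  ci <- stats::binom.test(k, n)$conf.int
  structure(list(k = k, n = n, fraction = k / n,
                 ci_lower = ci[1L], ci_upper = ci[2L]),
            class = "fraction_stat")
}

#' @export
print.fraction_stat <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (exact 95%% CI %.1f-%.1f%%)\n",
              x$k, x$n, 100 * x$fraction, 100 * x$ci_lower,
              100 * x$ci_upper))
  invisible(x)
}

## restrict to QC-passing callsets, with a message when any are dropped
qc_passed <- function(callsets) {
  ok <- vapply(callsets, function(cs) isTRUE(cs$passed_qc), logical(1L))
  if (any(!ok)) {
    message(sum(!ok), " clone(s) excluded (failed or indeterminate QC)")
  }
  callsets[ok]
}

#' Fraction of clones with a nucleosome-depleted region
#'
#' @param callsets List of QC-passing [call_clone()] results (clones failing
#'   QC are dropped with a message).
#' @param annotation Shared `site_annotation`.
#' @param window An [ndr_window()].
#' @param min_span_bp Passed to [call_ndr()].
#' @return A `fraction_stat` (k qualifying clones out of n, exact binomial
#'   95% CI).
#' @export
ndr_fraction <- function(callsets, annotation, window, min_span_bp = 147L) {
  callsets <- qc_passed(callsets)
  if (!length(callsets)) stop("no QC-passing clones")
  k <- sum(vapply(callsets, function(cs) {
    call_ndr(segment_clone(cs, annotation), window, min_span_bp)
  }, logical(1L)))
  fraction_stat(k, length(callsets))
}

#' Fraction of clones fully depleted over a fixed window
#'
#' A clone counts as depleted when every informative GCH call inside the
#' window is accessible (at least one such call is required) and no
#' protected footprint longer than 146 bp intrudes into the window from the
#' flanks. Intrusion is judged on the protected run's observed site span
#' (`[first_site - 1, last_site + 1)`), not the midpoint-extended drawn
#' interval, so a protected run whose sites all lie outside the window never
#' disqualifies a clone.
#'
#' @inheritParams ndr_fraction
#' @param max_protected_span Protected spans above this value disqualify a
#'   clone when they overlap the window (default 146 bp).
#' @return A `fraction_stat`.
#' @export
window_depletion_fraction <- function(callsets, annotation, window,
                                      max_protected_span = 146L) {
  in_win <- annotation$gch_sites >= window$start &
    annotation$gch_sites < window$end
  if (!any(in_win)) {
    stop("no GCH site inside window [", window$start, ", ", window$end, ")")
  }
  callsets <- qc_passed(callsets)
  if (!length(callsets)) stop("no QC-passing clones")
  k <- sum(vapply(callsets, function(cs) {
    calls <- cs$gch_calls[in_win]
    informative <- calls != "missing"
    if (!any(informative) || !all(calls[informative] == "accessible")) {
      return(FALSE)
    }
    seg <- segment_clone(cs, annotation)
    prot <- seg$state == "protected" & seg$span > max_protected_span
    !any(prot &
           pmax(seg$first_site - 1L, window$start) <
             pmin(seg$last_site + 1L, window$end))
  }, logical(1L)))
  fraction_stat(k, length(callsets))
}

#' Write per-clone footprint segments as BED
#'
#' Region-relative, 0-based half-open coordinates; `name` is the segment
#' state, `score` the footprint span in bp.
#'
#' @param callsets List of `clone_callset` objects.
#' @param annotation Shared `site_annotation`.
#' @param path Output BED path.
#' @return The BED data.frame, invisibly.
#' @export
write_segments_bed <- function(callsets, annotation, path = NULL) {
  rows <- lapply(callsets, function(cs) {
    seg <- segment_clone(cs, annotation)
    if (nrow(seg) == 0L) return(NULL)
    data.frame(chrom = cs$region_id, start = seg$start, end = seg$end,
               name = paste(cs$clone_id, seg$state, sep = ":"),
               score = pmin(seg$span, 1000L), strand = ".",
               stringsAsFactors = FALSE)
  })
  bed <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(bed)
}
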