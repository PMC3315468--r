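# Hand-checkable 29-bp amplicon:
#   pos:  0123456789...
#   seq:  TTACGTTAGCATTAGCGTTCCGGAACGTT
# HCG cytosines at 3, 20, 25; GCH at 9; GCG at 15; CCGG motif internal CpG
# at 20; one non-context cytosine at 19.
toy_sequence <- "TTACGTTAGCATTAGCGTTCCGGAACGTT"

toy_ref <- function(primer = c(3L, 25L)) {
  amplicon_reference("toy", toy_sequence, tss = 14L,
                     primer_cpg_positions = primer)
}

# fully converted top-strand read of `ref` with chosen sites retained as C
make_top_read <- function(ref, keep_c = integer()) {
  s <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  conv <- which(s == "C") - 1L
  s[setdiff(conv, keep_c) + 1L] <- "T"
  paste(s, collapse = "")
}

# fully converted bottom-strand read (reference frame) with chosen
# reference-G positions retained as G
make_bottom_read <- function(ref, keep_g = integer()) {
  s <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  conv <- which(s == "G") - 1L
  s[setdiff(conv, keep_g) + 1L] <- "A"
  paste(s, collapse = "")
}

# clone_callset built directly from call vectors (for footprint unit tests)
make_callset <- function(hcg_calls, gch_calls, clone_id = "c",
                         strand = "top", conversion = 1, passed = TRUE) {
  structure(
    list(clone_id = clone_id, region_id = "direct", strand = strand,
         hcg_calls = factor(hcg_calls,
                            levels = c("methylated", "unmethylated",
                                       "missing")),
         gch_calls = factor(gch_calls,
                            levels = c("accessible", "inaccessible",
                                       "missing")),
         conversion_rate_observed = conversion, passed_qc = passed,
         conversion_indeterminate = FALSE),
    class = "clone_callset")
}

# annotation with arbitrary GCH positions (HCG irrelevant for footprints)
make_annotation <- function(gch_sites, hcg_sites = integer(),
                            region_id = "direct") {
  structure(list(region_id = region_id, hcg_sites = as.integer(hcg_sites),
                 gch_sites = as.integer(gch_sites),
                 excluded_gcg = integer()),
            class = "site_annotation")
}

# duplex population with explicitly chosen strand states; `top`/`bottom`
# are logical vectors (one per molecule) applied to every CpG
make_pop <- function(ref, top, bottom) {
  m <- length(azanome:::cpg_positions(ref))
  azanome:::new_duplex_population(
    ref,
    matrix(rep(top, m), nrow = length(top)),
    matrix(rep(bottom, m), nrow = length(bottom)))
}

# ---- independent oracles -------------------------------------------------

# exact duplex-class distribution after k fully inhibited semiconservative
# divisions starting from a fully methylated duplex, by direct enumeration
enumerate_division_classes <- function(k) {
  duplexes <- list(c(top = 1, bottom = 1))
  for (i in seq_len(k)) {
    duplexes <- unlist(lapply(duplexes, function(d) {
      list(c(top = d[["top"]], bottom = 0),   # keep top parent, new bottom
           c(top = 0, bottom = d[["bottom"]]))# keep bottom parent, new top
    }), recursive = FALSE)
  }
  cls <- vapply(duplexes, function(d) {
    c("U", "H", "F")[d[["top"]] + d[["bottom"]] + 1L]
  }, character(1))
  table(factor(cls, levels = c("U", "H", "F"))) / length(cls)
}

# brute-force footprint scan: explicit loop over non-missing GCH calls
brute_segments <- function(callset, annotation) {
  pos <- annotation$gch_sites
  calls <- as.character(callset$gch_calls)
  keep <- calls != "missing"
  pos <- pos[keep]; calls <- calls[keep]
  if (!length(pos)) return(NULL)
  out <- list()
  run_start <- 1L
  for (i in seq_along(pos)) {
    if (i == length(pos) || calls[i + 1L] != calls[i]) {
      out[[length(out) + 1L]] <- list(
        state = if (calls[i] == "accessible") "accessible" else "protected",
        first = pos[run_start], last = pos[i],
        n_sites = i - run_start + 1L,
        span = pos[i] - pos[run_start] + 2L)
      run_start <- i + 1L
    }
  }
  out
}

brute_ndr <- function(callset, annotation, window, min_span = 147L) {
  segs <- brute_segments(callset, annotation)
  if (is.null(segs)) return(FALSE)
  # drawn interval: midpoints with flanking runs, outer edges +-1 bp
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (s$state != "accessible" || s$span < min_span) next
    lo <- if (i == 1L) s$first - 1L else
      (segs[[i - 1L]]$last + s$first) %/% 2L
    hi <- if (i == length(segs)) s$last + 1L else
      (s$last + segs[[i + 1L]]$first) %/% 2L
    if (max(lo, window$start) < min(hi, window$end)) return(TRUE)
  }
  FALSE
}

# random clone over an annotation, mixing the three call states
random_callset <- function(annotation, id, p_missing = 0.1) {
  g <- length(annotation$gch_sites)
  gch <- sample(c("accessible", "inaccessible", "missing"), g,
                replace = TRUE,
                prob = c((1 - p_missing) / 2, (1 - p_missing) / 2,
                         p_missing))
  h <- length(annotation$hcg_sites)
  hcg <- sample(c("methylated", "unmethylated"), h, replace = TRUE)
  make_callset(hcg, gch, clone_id = id)
}
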