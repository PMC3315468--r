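#' Classify an Infinium beta value
#'
#' Beta values on methylation arrays are bimodal; probes are grouped into a
#' hypomethylated class (beta < 0.2), a hypermethylated class (beta > 0.8)
#' and an intermediate remainder.
#'
#' @param beta Numeric vector of beta values in `[0, 1]` (NA allowed).
#' @return Factor with levels `hypo`, `intermediate`, `hyper`.
#' @export
classify_beta <- function(beta) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  # strict thresholds: exactly 0.2 and 0.8 are intermediate
  cl <- ifelse(beta < 0.2, "hypo", ifelse(beta > 0.8, "hyper", "intermediate"))
  factor(cl, levels = c("hypo", "intermediate", "hyper"))
}

#' Call drug-demethylated probes from paired beta values
#'
#' A probe is called demethylated when it is hypermethylated under control
#' treatment (`beta_control > hyper_threshold`) and loses at least `delta`
#' beta units under the demethylating drug. Gene-level calls collapse by
#' "any probe selected".
#'
#' @param beta_control,beta_treated Numeric vectors named by probe id (or
#'   unnamed but positionally matched).
#' @param probe_genes Optional character vector mapping each probe to a gene
#'   symbol (same order/names as `beta_control`).
#' @param hyper_threshold Control-methylation floor (default 0.8).
#' @param delta Minimum beta-value decrease (default 0.25, applied as >=).
#' @return List: `probes` (selected probe ids), `genes` (unique symbols of
#'   selected probes, NULL without a mapping), `n_tested`, `n_missing`
#'   (probes dropped for missing values).
#' @export
call_demethylated <- function(beta_control, beta_treated, probe_genes = NULL,
                              hyper_threshold = 0.8, delta = 0.25) {
  if (!is.null(names(beta_control)) && !is.null(names(beta_treated))) {
    shared <- intersect(names(beta_control), names(beta_treated))
    if (!length(shared)) stop("no shared probe ids")
    beta_control <- beta_control[shared]
    beta_treated <- beta_treated[shared]
    if (!is.null(probe_genes)) probe_genes <- probe_genes[shared]
  } else if (length(beta_control) != length(beta_treated)) {
    stop("unnamed beta vectors must have equal length")
  }
  ids <- if (is.null(names(beta_control))) {
    as.character(seq_along(beta_control))
  } else names(beta_control)
  missing <- is.na(beta_control) | is.na(beta_treated)
  sel <- !missing & beta_control > hyper_threshold &
    (beta_control - beta_treated) >= delta
  genes <- if (is.null(probe_genes)) NULL else
    sort(unique(probe_genes[sel]))
  list(probes = ids[sel], genes = genes,
       n_tested = sum(!missing), n_missing = sum(missing))
}

#' Overlap fraction of two gene sets
#'
#' @param setA,setB Character vectors (duplicates ignored).
#' @param denominator Which set sizes the fraction: `"A"`, `"B"` or
#'   `"smaller"`.
#' @return List: `fraction`, `n_overlap`, `denominator`, `n_denominator`.
#' @export
overlap_fraction <- function(setA, setB,
                             denominator = c("A", "B", "smaller")) {
  denominator <- match.arg(denominator)
  A <- unique(setA); B <- unique(setB)
  den <- switch(denominator,
                A = A, B = B,
                smaller = if (length(A) <= length(B)) A else B)
  if (!length(den)) stop("denominator set is empty")
  list(fraction = length(intersect(A, B)) / length(den),
       n_overlap = length(intersect(A, B)),
       denominator = denominator, n_denominator = length(den))
}

#' Compare demethylation-induced reactivation between conditions
#'
#' Tests whether per-gene log2 reactivation fold changes are attenuated in
#' one condition (e.g. under remodeler knockdown) relative to another, with
#' a paired two-sided Wilcoxon signed-rank test on `fc_nc - fc_kd`; a paired
#' t-test is available as an alternative. Box-plot summary statistics
#' (quartiles) are returned for both vectors.
#'
#' @param fc_nc,fc_kd Matched numeric vectors of per-gene log2 fold changes
#'   (same genes, same order; >= 5 pairs).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return List: `p_value`, `statistic`, `median_difference`, `n`,
#'   `quartiles_nc`, `quartiles_kd`, `degenerate` (TRUE when all
#'   differences are zero, in which case `p_value = 1`).
#' @export
reactivation_comparison <- function(fc_nc, fc_kd,
                                    test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  if (length(fc_nc) != length(fc_kd)) stop("fold-change vectors must match")
  if (length(fc_nc) < 5L) stop("need at least 5 gene pairs")
  d <- fc_nc - fc_kd
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  if (all(d == 0)) {
    return(list(p_value = 1, statistic = NA_real_, median_difference = 0,
                n = length(d), quartiles_nc = qs(fc_nc),
                quartiles_kd = qs(fc_kd), degenerate = TRUE))
  }
  ht <- if (test == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(fc_nc, fc_kd, paired = TRUE,
                                        exact = FALSE))
  } else {
    stats::t.test(fc_nc, fc_kd, paired = TRUE)
  }
  list(p_value = ht$p.value, statistic = unname(ht$statistic),
       median_difference = stats::median(d), n = length(d),
       quartiles_nc = qs(fc_nc), quartiles_kd = qs(fc_kd),
       degenerate = FALSE)
}

#' One-dimensional hierarchical clustering of probe rows
#'
#' Clusters the rows of a probes x samples matrix (columns stay fixed),
#' as used to display demethylated probes across conditions. Missing values
#' are imputed by the row mean for distance computation only.
#'
#' @param x Numeric matrix with row names (>= 2 rows).
#' @param distance Distance metric for [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return List: `order` (row indices in leaf order), `labels`, and the
#'   `hclust` object (`tree`).
#' @export
cluster_rows <- function(x, distance = "euclidean", linkage = "average") {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows")
  all_missing <- rowSums(!is.na(x)) == 0L
  if (any(all_missing)) {
    stop("row(s) entirely missing: ",
         paste(rownames(x)[all_missing], collapse = ", "))
  }
  imp <- x
  rm_ <- rowMeans(x, na.rm = TRUE)
  idx <- which(is.na(imp), arr.ind = TRUE)
  if (nrow(idx)) imp[idx] <- rm_[idx[, 1L]]
  tree <- stats::hclust(stats::dist(imp, method = distance),
                        method = linkage)
  list(order = tree$order, labels = rownames(x)[tree$order], tree = tree)
}
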