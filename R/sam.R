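#' Two-class SAM permutation test
#'
#' Significance analysis of microarrays for an unpaired two-group design.
#' Each transcript gets a moderated score
#' \deqn{d_i = \frac{\bar x_{i2} - \bar x_{i1}}{s_i + s_0},}
#' where \eqn{s_i} is the pooled standard error and the exchangeability
#' offset \eqn{s_0} is the percentile of the \eqn{s_i} distribution that
#' minimises the coefficient of variation of the score's median absolute
#' deviation across windows of \eqn{s_i} (computed once from the observed
#' data and reused for permutations). The null distribution is built from
#' group-label permutations: all distinct assignments when their number does
#' not exceed `n_perm`, otherwise `n_perm` uniform random ones. For each
#' transcript the false discovery rate at its absolute score is the median,
#' across permutations, of the number of null scores at least as extreme,
#' scaled by the estimated null proportion \eqn{\pi_0} and divided by the
#' observed count at that threshold; q-values are made monotone in |d|.
#'
#' @param expr Numeric matrix, transcripts x samples (row names = transcript
#'   ids).
#' @param labels Two-level factor/vector of group assignments, one per
#'   column; scores are oriented as second level minus first.
#' @param n_perm Maximum number of permutations (default 1000).
#' @param q_cutoff Significance threshold on the q-value (default 0.05).
#' @param seed Seed for random permutations (RNG state restored).
#' @return Object of class `sam_result`: data.frame `table` (transcript,
#'   score, q_value), `significant` (transcript ids with q <= cutoff), `s0`,
#'   `pi0`, `n_perm_used`, `exhaustive`, `q_cutoff`, `seed`.
#' @references Tusher, Tibshirani & Chu (2001) PNAS 98:5116-5121.
#' @export
sam_two_class <- function(expr, labels, n_perm = 1000L, q_cutoff = 0.05,
                          seed = NULL) {
  expr <- as.matrix(expr)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (length(labels) != ncol(expr)) stop("one label per expression column")
  if (min(table(labels)) < 2L) stop("need >= 2 samples per group")
  g2 <- labels == levels(labels)[2L]
  n1 <- sum(!g2); n2 <- sum(g2); n <- n1 + n2

  d_obs <- sam_scores(expr, g2, s0 = NULL)
  s0 <- d_obs$s0
  perms <- sam_permutations(n, n2, n_perm, seed)
  if (ncol(perms) < 2L) stop("fewer than 2 distinct permutations available")

  null_d <- vapply(seq_len(ncol(perms)), function(b) {
    g2b <- logical(n)
    g2b[perms[, b]] <- TRUE
    sam_scores(expr, g2b, s0 = s0)$d
  }, numeric(nrow(expr)))                      # transcripts x perms

  t_obs <- abs(d_obs$d)
  ord <- order(t_obs, decreasing = TRUE)
  thresholds <- t_obs[ord]
  counts <- vapply(seq_len(ncol(null_d)), function(b) {
    sd_abs <- sort(abs(null_d[, b]))
    length(sd_abs) - findInterval(thresholds - 1e-12, sd_abs)
  }, numeric(length(thresholds)))              # thresholds x perms
  fp_med <- apply(counts, 1L, stats::median)
  pooled_null <- as.vector(null_d)
  q25 <- stats::quantile(pooled_null, 0.25)
  q75 <- stats::quantile(pooled_null, 0.75)
  pi0 <- min(1, sum(d_obs$d > q25 & d_obs$d < q75) / (0.5 * nrow(expr)))

  R <- seq_along(thresholds)                   # observed count >= threshold
  raw_q <- pmin(1, pi0 * fp_med / R)
  q_sorted <- rev(cummin(rev(raw_q)))          # monotone in |d|
  q <- numeric(length(q_sorted))
  q[ord] <- q_sorted

  ids <- if (is.null(rownames(expr))) as.character(seq_len(nrow(expr))) else
    rownames(expr)
  tab <- data.frame(transcript = ids, score = d_obs$d, q_value = q,
                    stringsAsFactors = FALSE)
  structure(
    list(table = tab, significant = ids[q <= q_cutoff], s0 = s0, pi0 = pi0,
         n_perm_used = ncol(perms),
         exhaustive = attr(perms, "exhaustive"),
         q_cutoff = q_cutoff, seed = seed),
    class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf(
    "sam_result: %d transcripts, %d significant at q <= %g (%s, %d permutations, s0 = %.4g, pi0 = %.3f)\n",
    nrow(x$table), length(x$significant), x$q_cutoff,
    if (x$exhaustive) "exhaustive" else "sampled", x$n_perm_used, x$s0,
    x$pi0))
  invisible(x)
}

## moderated scores for one labelling; when s0 is NULL it is tuned on this
## labelling by the coefficient-of-variation criterion
sam_scores <- function(expr, g2, s0 = NULL) {
  n1 <- sum(!g2); n2 <- sum(g2)
  m1 <- rowMeans(expr[, !g2, drop = FALSE])
  m2 <- rowMeans(expr[, g2, drop = FALSE])
  ss1 <- rowSums((expr[, !g2, drop = FALSE] - m1)^2)
  ss2 <- rowSums((expr[, g2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  r <- m2 - m1
  if (is.null(s0)) s0 <- choose_s0(r, s)
  list(d = r / (s + s0), s0 = s0)
}

## s0 = the percentile of s minimising the coefficient of variation of the
## windowed MAD of d (Chu-Tibshirani tuning)
choose_s0 <- function(r, s, alphas = seq(0, 1, by = 0.05)) {
  m <- length(s)
  n_win <- max(2L, min(100L, m %/% 20L))
  win <- cut(rank(s, ties.method = "first"), breaks = n_win, labels = FALSE)
  cand <- stats::quantile(s, alphas, names = FALSE)
  cv <- vapply(cand, function(s0c) {
    d <- r / (s + s0c)
    v <- tapply(d, win, stats::mad)
    if (mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1L))
  cand[which.min(cv)]
}

## distinct two-group label permutations: columns are the index sets
## assigned to group 2
sam_permutations <- function(n, n2, n_perm, seed = NULL) {
  n_all <- choose(n, n2)
  if (n_all <= n_perm) {
    perms <- utils::combn(n, n2)
    attr(perms, "exhaustive") <- TRUE
    perms
  } else {
    perms <- with_seed_opt(if (is.null(seed)) NULL else seed, {
      vapply(seq_len(n_perm), function(b) sort(sample.int(n, n2)),
             integer(n2))
    })
    attr(perms, "exhaustive") <- FALSE
    perms
  }
}
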