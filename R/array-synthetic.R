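#' Generate methylation and expression matrices with planted effects
#'
#' Emulates the genome-scale stage of a DNMT-inhibitor experiment run in a
#' 2 x 2 design: control or remodeler-knockdown siRNA (`NC`/`KD`) crossed
#' with vehicle or drug (`PBS`/`aza`). Control beta values follow the
#' bimodal distribution seen on Infinium promoter arrays (a hypomethylated
#' mode below 0.2 and a hypermethylated mode above 0.8). Planted
#' demethylated probes start above 0.8 and lose at least 0.25 beta units
#' under drug in both siRNA arms (knockdown leaves demethylation itself
#' untouched); planted reactivated genes — drawn from the demethylated genes
#' — gain `effect_log2` log2 expression units under drug in the NC arm and
#' `kd_attenuation * effect_log2` in the KD arm.
#'
#' @param n_probes Number of probes (mapped 1:1 to genes `gene_00001`, ...).
#' @param n_genes_planted_demeth Number of planted demethylated probes/genes.
#' @param n_genes_planted_reactivated Number of planted reactivated genes
#'   (must not exceed the demethylated count; reactivated genes are a subset
#'   of demethylated genes).
#' @param kd_attenuation Fraction in `[0, 1]` multiplying the reactivation
#'   effect in the knockdown arm (1 = knockdown has no effect).
#' @param seed Integer seed.
#' @param n_reps Expression replicates per condition (default 4).
#' @param effect_log2 Planted log2 reactivation effect (default 2).
#' @param expr_sd Residual SD of log2 expression (default 0.5).
#' @param beta_noise_sd SD of the technical noise added to every beta value
#'   (default 0.02; set 0 for noise-free matrices).
#' @return List of class `array_sim`: `beta` (probes x 4 condition matrix,
#'   columns `NC_PBS`, `NC_aza`, `KD_PBS`, `KD_aza`), `expr` (genes x
#'   4*n_reps matrix), `samples` (sample sheet data.frame), `probe_genes`
#'   (probe -> gene map) and `truth` (planted probe/gene sets and effect
#'   sizes).
#' @export
generate_array_data <- function(n_probes = 2000L,
                                n_genes_planted_demeth = 50L,
                                n_genes_planted_reactivated = 44L,
                                kd_attenuation = 0.5,
                                seed = 1L,
                                n_reps = 4L,
                                effect_log2 = 2,
                                expr_sd = 0.5,
                                beta_noise_sd = 0.02) {
  if (kd_attenuation < 0 || kd_attenuation > 1) {
    stop("kd_attenuation must lie in [0, 1]")
  }
  if (n_genes_planted_demeth > n_probes) {
    stop("planted demethylated count exceeds n_probes")
  }
  if (n_genes_planted_reactivated > n_genes_planted_demeth) {
    stop("planted reactivated genes must be a subset of demethylated genes")
  }
  with_seed_opt(seed, {
    probes <- sprintf("probe_%05d", seq_len(n_probes))
    genes <- sprintf("gene_%05d", seq_len(n_probes))
    names(genes) <- probes

    # bimodal control betas: hypo mode Beta(1, 15), hyper mode Beta(15, 1)
    hyper_mode <- stats::runif(n_probes) < 0.5
    base <- ifelse(hyper_mode,
                   stats::rbeta(n_probes, 15, 1),
                   stats::rbeta(n_probes, 1, 15))
    demeth_idx <- sample.int(n_probes, n_genes_planted_demeth)
    base[demeth_idx] <- stats::runif(n_genes_planted_demeth, 0.85, 0.98)
    drop <- numeric(n_probes)
    drop[demeth_idx] <- stats::runif(n_genes_planted_demeth, 0.30, 0.60)

    noisy <- function(x) {
      if (beta_noise_sd == 0) return(x)
      pmin(pmax(x + stats::rnorm(n_probes, 0, beta_noise_sd), 0), 1)
    }
    beta <- cbind(NC_PBS = noisy(base),
                  NC_aza = noisy(base - drop),
                  KD_PBS = noisy(base),
                  KD_aza = noisy(base - drop))
    rownames(beta) <- probes

    react_idx <- sample(demeth_idx, n_genes_planted_reactivated)
    conds <- c("NC_PBS", "NC_aza", "KD_PBS", "KD_aza")
    samples <- data.frame(
      sample = paste0(rep(conds, each = n_reps), "_r", seq_len(n_reps)),
      sirna = rep(c("NC", "NC", "KD", "KD"), each = n_reps),
      treatment = rep(c("PBS", "aza", "PBS", "aza"), each = n_reps),
      stringsAsFactors = FALSE)
    mu <- stats::rnorm(n_probes, 8, 1.5)
    shift <- matrix(0, n_probes, nrow(samples))
    shift[react_idx, samples$sirna == "NC" & samples$treatment == "aza"] <-
      effect_log2
    shift[react_idx, samples$sirna == "KD" & samples$treatment == "aza"] <-
      kd_attenuation * effect_log2
    expr <- mu + shift +
      matrix(stats::rnorm(n_probes * nrow(samples), 0, expr_sd), n_probes)
    dimnames(expr) <- list(genes, samples$sample)

    structure(
      list(beta = beta, expr = expr, samples = samples, probe_genes = genes,
           truth = list(demeth_probes = sort(probes[demeth_idx]),
                        demeth_genes = sort(genes[demeth_idx]),
                        reactivated_genes = sort(genes[react_idx]),
                        effect_log2 = effect_log2,
                        kd_attenuation = kd_attenuation),
           seed = seed),
      class = "array_sim")
  })
}

#' Write an `array_sim` object as TSV matrices
#'
#' @param sim From [generate_array_data()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_array_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("beta.tsv", "expression.tsv", "samples.tsv",
                            "truth_demeth_probes.txt",
                            "truth_reactivated_genes.txt"))
  wt <- function(x, path, gene = NULL) {
    df <- data.frame(id = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (!is.null(gene)) df <- cbind(df[1L], gene = gene, df[-1L])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(sim$beta, paths[1L], gene = unname(sim$probe_genes))
  wt(sim$expr, paths[2L])
  utils::write.table(sim$samples, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sim$truth$demeth_probes, paths[4L])
  writeLines(sim$truth$reactivated_genes, paths[5L])
  invisible(paths)
}
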