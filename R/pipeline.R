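#' Assemble and validate a pipeline run configuration
#'
#' Collects everything [run_pipeline()] needs: the reference region, the
#' simulation parameters, analysis thresholds and the output directory.
#' Threshold overrides supplied here take precedence over values stored in
#' a YAML file (`config_file`), which in turn override the defaults.
#'
#' @param out_dir Output directory (created by [run_pipeline()]).
#' @param seed Master seed; every stage derives its own stream from it and
#'   it is recorded in all outputs.
#' @param stages Subset of `c("simulate", "nome", "footprint", "hemi",
#'   "arrays")` to execute (dependency order is enforced).
#' @param region An [amplicon_reference()]; default: a
#'   [random_amplicon()] drawn from `seed`.
#' @param sim A [simulation_config()]; its seed is overridden by `seed`.
#' @param window Promoter [ndr_window()]; default [tss_window()] of the
#'   region.
#' @param n_clones Clones sequenced per condition (default 50).
#' @param qc_min_conversion,min_span_bp,delta_beta,q_cutoff,n_perm Analysis
#'   thresholds (see [call_clone()], [call_ndr()], [call_demethylated()],
#'   [sam_two_class()]).
#' @param config_file Optional YAML file of overrides (any of the above
#'   scalar fields).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("simulate", "nome", "footprint", "hemi",
                                  "arrays"),
                       region = NULL, sim = NULL, window = NULL,
                       n_clones = 50L, qc_min_conversion = 0.95,
                       min_span_bp = 147L, delta_beta = 0.25,
                       q_cutoff = 0.05, n_perm = 1000L,
                       config_file = NULL) {
  defaults <- list(seed = seed, n_clones = n_clones,
                   qc_min_conversion = qc_min_conversion,
                   min_span_bp = min_span_bp, delta_beta = delta_beta,
                   q_cutoff = q_cutoff, n_perm = n_perm)
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      stop("config_file does not exist: ", config_file)
    }
    overrides <- yaml::read_yaml(config_file)
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    supplied <- names(as.list(match.call()))  # explicit args beat the file
    for (key in setdiff(names(overrides), supplied)) {
      defaults[[key]] <- overrides[[key]]
    }
  }
  known <- c("simulate", "nome", "footprint", "hemi", "arrays")
  stages <- match.arg(stages, known, several.ok = TRUE)
  seed <- as.integer(defaults$seed)
  if (is.null(region)) region <- random_amplicon(seed = seed)
  if (is.null(sim)) sim <- simulation_config(seed = seed)
  sim$seed <- seed
  if (is.null(window)) window <- tss_window(region)
  cfg <- c(list(out_dir = out_dir, stages = known[known %in% stages],
                region = region, sim = sim, window = window),
           defaults[-1L], list(seed = seed))
  structure(cfg, class = "run_config")
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Executes the requested stages in dependency order — time-course
#' simulation, NOMe-seq clone generation and calling, footprint statistics,
#' hemimethylation deconvolution, and genome-scale array statistics — and
#' writes all artifacts plus a manifest (`manifest.json` with seed, stage
#' status and md5 per output file) into `out_dir`. Reruns with the same
#' configuration and seed reproduce every output byte for byte.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("azanome")),
                   region_id = config$region$region_id,
                   stages = list())
  state <- new.env(parent = emptyenv())

  add_stage <- function(name, outputs) {
    manifest$stages[[name]] <<- list(
      status = "complete",
      outputs = lapply(outputs, function(f) {
        list(file = basename(f), md5 = unname(tools::md5sum(f)))
      }))
  }

  runners <- list(
    simulate = function() stage_simulate(config, state),
    nome = function() stage_nome(config, state),
    footprint = function() stage_footprint(config, state),
    hemi = function() stage_hemi(config, state),
    arrays = function() stage_arrays(config, state))
  # stages not requested but required by later ones still run (dependency
  # order is the declaration order above); only requested stages that fail
  # mark the manifest
  needed <- union(config$stages,
                  names(runners)[seq_len(max(match(config$stages,
                                                   names(runners))))])
  needed <- names(runners)[names(runners) %in% needed]
  for (name in needed) {
    outputs <- tryCatch(runners[[name]](), error = function(e) {
      manifest$stages[[name]] <- list(status = "failed",
                                      error = conditionMessage(e))
      write_manifest(manifest, config$out_dir)
      stop("stage '", name, "' failed: ", conditionMessage(e))
    })
    add_stage(name, outputs)
  }
  write_manifest(manifest, config$out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

stage_simulate <- function(config, state) {
  tc <- simulate_timecourse(config$sim, config$region)
  state$timecourse <- tc
  tab <- do.call(rbind, lapply(names(tc), function(day) {
    cls <- table(duplex_classes(tc[[day]]))
    n <- n_molecules(tc[[day]])
    data.frame(day = day, U = cls[["U"]] / n, H = cls[["H"]] / n,
               F = cls[["F"]] / n, n_molecules = n,
               stringsAsFactors = FALSE)
  }))
  f <- file.path(config$out_dir, "timecourse_classes.tsv")
  write_seeded_tsv(tab, f, config$seed)
  f
}

stage_nome <- function(config, state) {
  if (is.null(state$timecourse)) stage_simulate(config, state)
  pop <- state$timecourse[[length(state$timecourse)]]
  pop <- apply_remodeling(pop, config$sim, config$window,
                          seed = config$seed + 1L)
  flags <- apply_mcvipi(pop, annotate_sites(config$region),
                        efficiency = config$sim$mcvipi_efficiency,
                        seed = config$seed + 2L)
  clones <- bisulfite_reads(pop, flags, config$sim, config$n_clones,
                            seed = config$seed + 3L)
  state$pop <- pop
  state$flags <- flags
  state$clones <- clones
  ann <- annotate_sites(config$region)
  state$callsets <- mapply(function(read, id) {
    call_clone(read, config$region, ann, config$qc_min_conversion, id)
  }, clones$reads, names(clones$reads), SIMPLIFY = FALSE)
  fa <- file.path(config$out_dir, "clones.fa")
  write_clone_fasta(clones, fa, seed = config$seed)
  calls_f <- file.path(config$out_dir, "clone_calls.tsv")
  write_call_table(state$callsets, ann, calls_f)
  lolli_f <- file.path(config$out_dir, "lollipop.txt")
  render_lollipop(state$callsets, ann, "text", path = lolli_f)
  c(fa, paste0(fa, ".truth.tsv"), calls_f, lolli_f)
}

stage_footprint <- function(config, state) {
  if (is.null(state$callsets)) stage_nome(config, state)
  ann <- annotate_sites(config$region)
  bed_f <- file.path(config$out_dir, "segments.bed")
  write_segments_bed(state$callsets, ann, bed_f)
  ndr <- ndr_fraction(state$callsets, ann, config$window,
                      config$min_span_bp)
  dep <- window_depletion_fraction(state$callsets, ann, config$window)
  tab <- data.frame(
    region = config$region$region_id,
    statistic = c("ndr_fraction", "window_depletion_fraction"),
    k = c(ndr$k, dep$k), n = c(ndr$n, dep$n),
    fraction = c(ndr$fraction, dep$fraction),
    ci_lower = c(ndr$ci_lower, dep$ci_lower),
    ci_upper = c(ndr$ci_upper, dep$ci_upper),
    stringsAsFactors = FALSE)
  sum_f <- file.path(config$out_dir, "footprint_summary.tsv")
  write_seeded_tsv(tab, sum_f, config$seed)
  c(bed_f, sum_f)
}

stage_hemi <- function(config, state) {
  if (is.null(state$pop)) stage_nome(config, state)
  ccgg <- ccgg_positions(config$region)[1L]
  meas <- measure_snupe(state$pop, ccgg)
  est <- deconvolve_uhf(meas$m_undigested, meas$m_digested)
  truth <- table(duplex_classes(state$pop, ccgg))
  n <- n_molecules(state$pop)
  tab <- data.frame(
    region_id = config$region$region_id, ccgg_pos = ccgg,
    m_undigested = meas$m_undigested, m_digested = meas$m_digested,
    U = est$U, H = est$H, F = est$F, residual = est$residual,
    U_true = truth[["U"]] / n, H_true = truth[["H"]] / n,
    F_true = truth[["F"]] / n, stringsAsFactors = FALSE)
  f <- file.path(config$out_dir, "hemimethylation.tsv")
  write_seeded_tsv(tab, f, config$seed)
  f
}

stage_arrays <- function(config, state) {
  sim <- generate_array_data(seed = config$seed + 4L)
  state$array_sim <- sim
  ann_dir <- file.path(config$out_dir, "arrays")
  paths <- write_array_data(sim, ann_dir)
  demeth <- call_demethylated(sim$beta[, "NC_PBS"], sim$beta[, "NC_aza"],
                              sim$probe_genes, delta = config$delta_beta)
  nc <- sim$samples$sirna == "NC"
  kd <- sim$samples$sirna == "KD"
  lab <- function(sel) factor(sim$samples$treatment[sel],
                              levels = c("PBS", "aza"))
  sam_nc <- sam_two_class(sim$expr[, nc], lab(nc), config$n_perm,
                          config$q_cutoff, seed = config$seed + 5L)
  sam_kd <- sam_two_class(sim$expr[, kd], lab(kd), config$n_perm,
                          config$q_cutoff, seed = config$seed + 6L)
  ov <- overlap_fraction(sam_nc$significant, sam_kd$significant, "A")
  genes <- intersect(sam_nc$significant, demeth$genes)
  fc <- function(sel_treat, sel_ctrl) {
    rowMeans(sim$expr[genes, sel_treat, drop = FALSE]) -
      rowMeans(sim$expr[genes, sel_ctrl, drop = FALSE])
  }
  s <- sim$samples
  cmp <- reactivation_comparison(
    fc(nc & s$treatment == "aza", nc & s$treatment == "PBS"),
    fc(kd & s$treatment == "aza", kd & s$treatment == "PBS"))
  summary <- list(
    seed = config$seed,
    n_demethylated_probes = length(demeth$probes),
    n_demethylated_genes = length(demeth$genes),
    n_reactivated_nc = length(sam_nc$significant),
    n_reactivated_kd = length(sam_kd$significant),
    overlap_fraction = ov$fraction,
    n_demethylated_and_reactivated = length(genes),
    reactivation_median_log2fc_difference = cmp$median_difference,
    reactivation_p_value = cmp$p_value)
  f <- file.path(ann_dir, "summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  c(paths, f)
}

## TSV with a seed-recording header comment
write_seeded_tsv <- function(tab, path, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# seed=%d", seed), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
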