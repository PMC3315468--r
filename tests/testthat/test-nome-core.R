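test_that("annotate_sites classifies trinucleotide contexts", {
  cases <- list(
    list(seq = "AACGTT", hcg = 2L, gch = integer(), gcg = integer()),
    list(seq = "AGCATT", hcg = integer(), gch = 2L, gcg = integer()),
    list(seq = "AGCGTT", hcg = integer(), gch = integer(), gcg = 2L))
  for (cs in cases) {
    ann <- annotate_sites(amplicon_reference("x", cs$seq, tss = 0))
    expect_identical(ann$hcg_sites, cs$hcg, info = cs$seq)
    expect_identical(ann$gch_sites, cs$gch, info = cs$seq)
    expect_identical(ann$excluded_gcg, cs$gcg, info = cs$seq)
  }
  ann <- annotate_sites(toy_ref())
  expect_identical(ann$hcg_sites, c(3L, 20L, 25L))
  expect_identical(ann$gch_sites, 9L)
  expect_identical(ann$excluded_gcg, 15L)
})

test_that("annotate_sites partitions every CpG and GpC cytosine", {
  for (seed in 1:5) {
    ref <- random_amplicon(length = 400, seed = seed)
    ann <- annotate_sites(ref)
    s <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
    n <- length(s)
    cpg_c <- which(s == "C" & c(s[-1], "") == "G") - 1L
    gpc_c <- which(s == "C" & c("", s[-n]) == "G") - 1L
    all_sites <- sort(union(cpg_c, gpc_c))
    got <- sort(c(ann$hcg_sites, ann$gch_sites, ann$excluded_gcg))
    expect_identical(got, all_sites)
    expect_length(intersect(ann$hcg_sites, ann$gch_sites), 0)
    expect_length(intersect(ann$hcg_sites, ann$excluded_gcg), 0)
    expect_length(intersect(ann$gch_sites, ann$excluded_gcg), 0)
  }
})

test_that("non-ACGT input is rejected with its position", {
  expect_error(amplicon_reference("x", "ACGNTT", tss = 0), "position 3")
})

test_that("strand inference recognises conversion images and rejects noise", {
  ref <- toy_ref()
  expect_identical(infer_bisulfite_strand(make_top_read(ref), ref), "top")
  expect_identical(infer_bisulfite_strand(make_bottom_read(ref), ref),
                   "bottom")
  # a random sequence mismatches ~3/4 of positions under either model
  set.seed(42)
  junk <- paste(sample(c("A", "C", "G", "T"), nchar(ref$sequence),
                       replace = TRUE), collapse = "")
  expect_error(infer_bisulfite_strand(junk, ref), "does not fit")
})

test_that("call_clone reads retained and converted bases on both strands", {
  ref <- toy_ref()
  ann <- annotate_sites(ref)
  # fully converted top read: everything unmethylated / inaccessible
  cs <- call_clone(make_top_read(ref), ref, ann)
  expect_true(all(cs$hcg_calls == "unmethylated"))
  expect_true(all(cs$gch_calls == "inaccessible"))
  expect_equal(cs$conversion_rate_observed, 1.0)
  expect_true(cs$passed_qc)
  # top read retaining the HCG at 3 and the GCH at 9
  cs <- call_clone(make_top_read(ref, keep_c = c(3L, 9L)), ref, ann)
  expect_equal(as.character(cs$hcg_calls),
               c("methylated", "unmethylated", "unmethylated"))
  expect_equal(as.character(cs$gch_calls), "accessible")
  # bottom read: HCG at p reads the G at p+1, GCH at q reads the G at q-1
  cs <- call_clone(make_bottom_read(ref, keep_g = c(21L, 8L)), ref, ann)
  expect_identical(cs$strand, "bottom")
  expect_equal(as.character(cs$hcg_calls),
               c("unmethylated", "methylated", "unmethylated"))
  expect_equal(as.character(cs$gch_calls), "accessible")
})

test_that("incomplete conversion fails QC at the stated threshold", {
  ref <- random_amplicon(length = 400, seed = 2)
  ann <- annotate_sites(ref)
  nonctx <- azanome:::nonctx_cytosine_positions(ref, ann, "top")
  expect_gt(length(nonctx), 20)
  # leave 10% of non-context cytosines unconverted
  n_keep <- ceiling(0.1 * length(nonctx))
  read <- make_top_read(ref, keep_c = nonctx[seq_len(n_keep)])
  cs <- call_clone(read, ref, ann, qc_min_conversion = 0.95)
  expect_lt(cs$conversion_rate_observed, 0.95)
  expect_false(cs$passed_qc)
})

test_that("clone calls round-trip through the simulator truth", {
  ref <- random_amplicon(length = 500, seed = 5)
  ann <- annotate_sites(ref)
  cfg <- simulation_config(n_molecules = 40, days = 0:2, seed = 9,
                           conversion_rate = 1, inappropriate_conversion = 0,
                           mcvipi_efficiency = 1)
  pop <- simulate_timecourse(cfg, ref)$day2
  pop <- apply_remodeling(pop, cfg, tss_window(ref), seed = 10)
  flags <- apply_mcvipi(pop, ann, efficiency = 1, seed = 11)
  clones <- bisulfite_reads(pop, flags, cfg, n_clones = 50, seed = 12)
  cpg_idx <- match(ann$hcg_sites, azanome:::cpg_positions(ref))
  # CGC contexts: readouts that coincide on the bottom strand
  amb_hcg <- (ann$hcg_sites + 2L) %in% ann$gch_sites
  amb_gch <- (ann$gch_sites - 2L) %in%
    c(ann$hcg_sites, ann$excluded_gcg)
  for (k in seq_along(clones$reads)) {
    cs <- call_clone(clones$reads[[k]], ref, ann,
                     clone_id = clones$truth$clone_id[k])
    i <- clones$truth$molecule[k]
    st <- clones$truth$strand[k]
    expect_identical(cs$strand, st)
    meth <- if (st == "top") pop$top[i, cpg_idx] else pop$bottom[i, cpg_idx]
    want_hcg <- ifelse(meth, "methylated", "unmethylated")
    acc <- if (st == "top") flags$gch_top[i, ] else flags$gch_bottom[i, ]
    want_gch <- ifelse(acc, "accessible", "inaccessible")
    if (st == "bottom") {
      want_hcg[amb_hcg] <- "missing"
      want_gch[amb_gch] <- "missing"
    }
    expect_equal(as.character(cs$hcg_calls), want_hcg)
    expect_equal(as.character(cs$gch_calls), want_gch)
  }
})

test_that("demethylated-strand filter keeps exactly primer-unmethylated clones", {
  ref <- toy_ref(primer = c(3L, 25L))
  ann <- annotate_sites(ref)
  unmeth <- call_clone(make_top_read(ref), ref, ann, clone_id = "u")
  meth_one <- call_clone(make_top_read(ref, keep_c = 3L), ref, ann,
                         clone_id = "m")
  kept <- filter_demethylated_strands(list(meth_one, unmeth, meth_one), ref)
  expect_length(kept, 1)
  expect_identical(kept[[1]]$clone_id, "u")
  # idempotent, order preserving, subset
  expect_identical(filter_demethylated_strands(kept, ref), kept)
  # truth audit on a simulated pool: retained clones = strands unmethylated
  # at the primer CpGs in the generator's state matrices
  ref2 <- random_amplicon(length = 500, seed = 6)
  ann2 <- annotate_sites(ref2)
  cfg <- simulation_config(n_molecules = 60, days = 0:2, seed = 13,
                           conversion_rate = 1, inappropriate_conversion = 0)
  pop <- simulate_timecourse(cfg, ref2)$day2
  clones <- bisulfite_reads(pop, NULL, cfg, n_clones = 80, seed = 14)
  callsets <- mapply(call_clone, clones$reads,
                     clone_id = names(clones$reads),
                     MoreArgs = list(reference = ref2, annotation = ann2),
                     SIMPLIFY = FALSE)
  kept_ids <- vapply(filter_demethylated_strands(callsets, ref2),
                     `[[`, "", "clone_id")
  p_idx <- match(ref2$primer_cpg_positions, azanome:::cpg_positions(ref2))
  truth_unmeth <- vapply(seq_len(nrow(clones$truth)), function(k) {
    i <- clones$truth$molecule[k]
    strand <- if (clones$truth$strand[k] == "top") pop$top else pop$bottom
    !any(strand[i, p_idx])
  }, logical(1))
  expect_setequal(kept_ids, clones$truth$clone_id[truth_unmeth])
})

test_that("primer positions outside the annotation are rejected", {
  ref <- toy_ref(primer = c(3L, 25L))
  ref$primer_cpg_positions <- c(3L, 15L)  # 15 is GCG context
  cs <- call_clone(make_top_read(ref), ref)
  expect_error(filter_demethylated_strands(list(cs), ref), "not annotated")
})
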