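test_that("simulation_config validates its fractions and days", {
  expect_error(simulation_config(incorporation_prob = 1.2), "fraction")
  expect_error(simulation_config(n_molecules = 0), "n_molecules")
  expect_error(simulation_config(days = c(2, 1)), "ascending")
  expect_error(simulation_config(days = c(-1, 0)), "negative")
  expect_error(
    simulate_timecourse(simulation_config(), amplicon_reference("x", "ATTA", 0)),
    "no CpG")
})

test_that("no inhibition leaves every molecule fully methylated", {
  ref <- random_amplicon(length = 300, seed = 1)
  cfg <- simulation_config(n_molecules = 200, days = 0:3,
                           incorporation_prob = 0, seed = 2)
  tc <- simulate_timecourse(cfg, ref)
  for (day in names(tc)) {
    expect_true(all(tc[[day]]$top), info = day)
    expect_true(all(tc[[day]]$bottom), info = day)
  }
})

test_that("semiconservative kinetics match the enumeration oracle", {
  # oracle: exact class fractions after k fully inhibited divisions
  expect_equal(as.vector(enumerate_division_classes(1)), c(0, 1, 0))
  expect_equal(as.vector(enumerate_division_classes(2)), c(0.5, 0.5, 0))
  ref <- random_amplicon(length = 300, seed = 1)
  cfg <- simulation_config(n_molecules = 10000, days = 0:2,
                           incorporation_prob = 1, remethylation_prob = 0,
                           washout_day = 10, seed = 3)
  tc <- simulate_timecourse(cfg, ref)
  expect_true(all(duplex_classes(tc$day1) == "H"))
  frac2 <- table(duplex_classes(tc$day2)) / 10000
  oracle <- enumerate_division_classes(2)
  for (cls in c("U", "H", "F")) {
    p <- oracle[[cls]]
    tol <- 3 * sqrt(p * (1 - p) / 10000)
    expect_lt(abs(frac2[[cls]] - p), tol + 1e-12)
  }
})

test_that("class fractions always partition the population", {
  ref <- random_amplicon(length = 300, seed = 4)
  cfg <- simulation_config(n_molecules = 500, days = c(0, 2, 5), seed = 5)
  tc <- simulate_timecourse(cfg, ref)
  for (day in names(tc)) {
    expect_equal(sum(table(duplex_classes(tc[[day]]))), 500)
  }
})

test_that("the time course is bit-reproducible under a fixed seed", {
  ref <- random_amplicon(length = 300, seed = 6)
  cfg <- simulation_config(n_molecules = 100, days = 0:3, seed = 7)
  a <- simulate_timecourse(cfg, ref)
  b <- simulate_timecourse(cfg, ref)
  expect_identical(a$day3$top, b$day3$top)
  expect_identical(a$day3$bottom, b$day3$bottom)
  ca <- bisulfite_reads(a$day3, NULL, cfg, 20, seed = 8)
  cb <- bisulfite_reads(b$day3, NULL, cfg, 20, seed = 8)
  expect_identical(ca$reads, cb$reads)
})

test_that("remodeling gates the NDR on symmetric demethylation", {
  ref <- random_amplicon(length = 600, seed = 8)
  cfg <- simulation_config(p_ndr = 1, srcap_kd_factor = 1, seed = 9)
  win <- tss_window(ref)
  pop <- make_pop(ref,
                  top = c(TRUE, TRUE, FALSE),
                  bottom = c(TRUE, FALSE, FALSE))  # F, H, U
  pop <- apply_remodeling(pop, cfg, win, seed = 10)
  expect_identical(pop$ndr, c(FALSE, FALSE, TRUE))
  # fully methylated and hemimethylated molecules: nucleosome-occupied —
  # any uncovered stretch in the window is a linker, far below core size
  for (i in 1:2) {
    cov <- azanome:::pos_covered(pop$occupancy[[i]],
                                 seq(win$start, win$end - 1L))
    gaps <- rle(cov)
    max_gap <- max(c(0, gaps$lengths[!gaps$values]))
    expect_lt(max_gap, 147, label = paste("molecule", i, "max gap"))
  }
  # symmetric-unmethylated molecule: gap covers the window exactly
  iv <- pop$occupancy[[3]]
  expect_false(any(iv[, 1] < win$end & iv[, 2] > win$start))
})

test_that("occupancy intervals are disjoint 147-bp cores within the region", {
  ref <- random_amplicon(length = 600, seed = 11)
  cfg <- simulation_config(n_molecules = 50, days = 0:3, seed = 12)
  pop <- simulate_timecourse(cfg, ref)$day3
  pop <- apply_remodeling(pop, cfg, tss_window(ref), seed = 13)
  L <- nchar(ref$sequence)
  for (iv in pop$occupancy) {
    expect_true(all(iv[, 1] >= 0 & iv[, 2] <= L))
    w <- iv[, 2] - iv[, 1]
    expect_true(all(w > 0 & w <= 147))
    # cores not touching a region edge are full length
    interior <- iv[, 1] > 0 & iv[, 2] < L
    expect_true(all(w[interior] == 147))
    if (nrow(iv) > 1) {
      ord <- order(iv[, 1])
      expect_true(all(iv[ord[-1], 1] >= iv[ord[-nrow(iv)], 2]))
    }
  }
})

test_that("GpC methyltransferase marks only uncovered sites", {
  ref <- random_amplicon(length = 400, seed = 14)
  ann <- annotate_sites(ref)
  pop <- make_pop(ref, top = c(TRUE, TRUE), bottom = c(TRUE, TRUE))
  # no occupancy at all: every site marked at efficiency 1
  flags <- apply_mcvipi(pop, ann, efficiency = 1, seed = 15)
  expect_true(all(flags$gch_top))
  expect_true(all(flags$gch_bottom))
  # full occupancy: nothing marked
  L <- nchar(ref$sequence)
  pop$occupancy <- list(matrix(c(0L, L), 1), matrix(c(0L, L), 1))
  flags <- apply_mcvipi(pop, ann, efficiency = 1, seed = 16)
  expect_false(any(flags$gch_top))
  expect_false(any(flags$gch_bottom))
})

test_that("marking efficiency behaves binomially at accessible sites", {
  ref <- random_amplicon(length = 400, seed = 17)
  ann <- annotate_sites(ref)
  n_mol <- ceiling(1000 / length(ann$gch_sites))
  pop <- make_pop(ref, top = rep(TRUE, n_mol), bottom = rep(TRUE, n_mol))
  flags <- apply_mcvipi(pop, ann, efficiency = 0.9, seed = 18)
  n_draws <- length(flags$gch_top)
  phat <- mean(flags$gch_top)
  expect_lt(abs(phat - 0.9), 3 * sqrt(0.9 * 0.1 / n_draws))
})

test_that("bisulfite chemistry converts the right cytosines", {
  ref <- toy_ref()
  cfg <- simulation_config(conversion_rate = 1,
                           inappropriate_conversion = 0, seed = 19)
  # fully unmethylated molecule, top strand: every C becomes T
  pop <- make_pop(ref, top = FALSE, bottom = FALSE)
  cl <- bisulfite_reads(pop, NULL, cfg, n_clones = 2, seed = 20)
  top_read <- cl$reads[cl$truth$strand == "top"]
  if (length(top_read)) {
    expect_false(grepl("C", top_read))
  }
  bottom_read <- cl$reads[cl$truth$strand == "bottom"]
  if (length(bottom_read)) {
    expect_false(grepl("G", bottom_read))
  }
  # fully methylated CpGs: CpG cytosines stay C, all other Cs convert
  pop <- make_pop(ref, top = TRUE, bottom = TRUE)
  cl <- bisulfite_reads(pop, NULL, cfg, n_clones = 2, seed = 21)
  top_read <- cl$reads[cl$truth$strand == "top"][1]
  expect_identical(unname(top_read), make_top_read(ref, keep_c = c(3L, 15L, 20L, 25L)))
})

test_that("read generation rejects invalid clone counts", {
  ref <- toy_ref()
  cfg <- simulation_config(seed = 1)
  pop <- make_pop(ref, top = TRUE, bottom = TRUE)
  expect_error(bisulfite_reads(pop, NULL, cfg, 0), "positive")
  expect_error(bisulfite_reads(pop, NULL, cfg, 3), "exceeds")
})

test_that("clone FASTA and truth table round-trip to disk", {
  ref <- random_amplicon(length = 300, seed = 22)
  cfg <- simulation_config(n_molecules = 10, days = 0:1, seed = 23)
  pop <- simulate_timecourse(cfg, ref)$day1
  cl <- bisulfite_reads(pop, NULL, cfg, 8, seed = 24)
  fa <- tempfile(fileext = ".fa")
  write_clone_fasta(cl, fa, seed = 23)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(unname(as.character(back)), unname(cl$reads))
  truth <- utils::read.delim(paste0(sub("\\.fa$", "", fa), ".truth.tsv"),
                             comment.char = "#")
  expect_equal(truth$duplex_class, cl$truth$duplex_class)
})
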