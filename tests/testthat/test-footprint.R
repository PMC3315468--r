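test_that("a single accessible run spans the terminal dinucleotides", {
  gch <- c(10L, 50L, 120L, 200L)
  ann <- make_annotation(gch)
  cs <- make_callset(character(), rep("accessible", 4))
  seg <- segment_clone(cs, ann)
  expect_equal(nrow(seg), 1)
  expect_identical(seg$state, "accessible")
  expect_equal(seg$span, 200 - 10 + 2)
  expect_equal(seg$start, 9)
  expect_equal(seg$end, 201)
})

test_that("alternating calls yield one segment per site", {
  gch <- c(10L, 20L, 30L, 40L)
  ann <- make_annotation(gch)
  cs <- make_callset(character(),
                     c("accessible", "inaccessible", "accessible",
                       "inaccessible"))
  seg <- segment_clone(cs, ann)
  expect_equal(nrow(seg), 4)
  expect_equal(seg$n_sites, rep(1L, 4))
  expect_equal(seg$span, rep(2L, 4))
  expect_identical(seg$state,
                   rep(c("accessible", "protected"), 2))
})

test_that("missing calls neither break runs nor contribute sites", {
  gch <- c(10L, 30L, 50L, 70L)
  ann <- make_annotation(gch)
  cs <- make_callset(character(),
                     c("accessible", "missing", "accessible",
                       "inaccessible"))
  seg <- segment_clone(cs, ann)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$n_sites, c(2L, 1L))
  expect_equal(seg$span[1], 50 - 10 + 2)
  cs_all_missing <- make_callset(character(), rep("missing", 4))
  expect_warning(seg0 <- segment_clone(cs_all_missing, ann), "missing")
  expect_equal(nrow(seg0), 0)
})

test_that("segments tile the observed GCH span exactly", {
  set.seed(101)
  for (i in 1:50) {
    g <- sort(sample(0:500, sample(5:40, 1)))
    g <- g[c(TRUE, diff(g) >= 3)]  # GCH sites are >= 3 bp apart
    ann <- make_annotation(g)
    cs <- random_callset(ann, "c")
    keep <- cs$gch_calls != "missing"
    if (!any(keep)) next
    seg <- segment_clone(cs, ann)
    pos <- ann$gch_sites[keep]
    expect_equal(sum(seg$end - seg$start),
                 (max(pos) + 1) - (min(pos) - 1))
    expect_true(all(seg$start[-1] == seg$end[-nrow(seg)]))
  }
})

test_that("segmentation matches a brute-force scan on random clones", {
  set.seed(202)
  for (i in 1:300) {
    g <- sort(sample(0:600, sample(3:50, 1)))
    g <- g[c(TRUE, diff(g) >= 3)]
    ann <- make_annotation(g)
    cs <- random_callset(ann, paste0("c", i))
    oracle <- brute_segments(cs, ann)
    if (is.null(oracle)) {
      expect_warning(seg <- segment_clone(cs, ann))
      expect_equal(nrow(seg), 0)
      next
    }
    seg <- segment_clone(cs, ann)
    expect_equal(nrow(seg), length(oracle))
    expect_identical(seg$state, vapply(oracle, `[[`, "", "state"))
    expect_equal(seg$span, vapply(oracle, function(o) o$span, 1L))
    expect_equal(seg$first_site, vapply(oracle, function(o) o$first, 1L))
    expect_equal(seg$last_site, vapply(oracle, function(o) o$last, 1L))
  }
})

test_that("NDR calls require both span and window overlap", {
  win <- ndr_window(150, 350)
  seg <- data.frame(state = "accessible", start = 100, end = 261,
                    span = 161L, n_sites = 10L, first_site = 101L,
                    last_site = 260L)
  expect_true(call_ndr(seg, win))
  seg$span <- 120L
  expect_false(call_ndr(seg, win))
  seg_prot <- data.frame(state = "protected", start = 0, end = 500,
                         span = 400L, n_sites = 20L, first_site = 1L,
                         last_site = 499L)
  expect_false(call_ndr(seg_prot, win))
  # long accessible segment not touching the window
  seg_far <- data.frame(state = "accessible", start = 400, end = 600,
                        span = 200L, n_sites = 10L, first_site = 401L,
                        last_site = 599L)
  expect_false(call_ndr(seg_far, ndr_window(0, 300)))
})

test_that("call_ndr is monotone in accessibility", {
  set.seed(303)
  win <- ndr_window(200, 400)
  for (i in 1:50) {
    g <- sort(sample(0:600, 30))
    g <- g[c(TRUE, diff(g) >= 3)]
    ann <- make_annotation(g)
    cs <- random_callset(ann, "c", p_missing = 0)
    before <- call_ndr(segment_clone(cs, ann), win)
    flip <- which(cs$gch_calls == "inaccessible")
    if (!length(flip)) next
    cs$gch_calls[sample(flip, 1)] <- "accessible"
    after <- call_ndr(segment_clone(cs, ann), win)
    expect_true(after >= before)
  }
})

test_that("ndr_fraction counts clones and is order invariant", {
  ann <- make_annotation(seq(100L, 500L, by = 20L))
  n_sites <- length(ann$gch_sites)
  open_clone <- function(id) make_callset(character(),
                                          rep("accessible", n_sites), id)
  shut_clone <- function(id) make_callset(character(),
                                          rep("inaccessible", n_sites), id)
  win <- ndr_window(250, 350)
  callsets <- c(lapply(1:6, function(i) open_clone(paste0("o", i))),
                lapply(1:19, function(i) shut_clone(paste0("s", i))))
  fs <- ndr_fraction(callsets, ann, win)
  expect_equal(fs$k, 6)
  expect_equal(fs$n, 25)
  expect_equal(fs$fraction, 0.24)
  set.seed(1)
  fs2 <- ndr_fraction(sample(callsets), ann, win)
  expect_equal(fs2$fraction, fs$fraction)
  expect_true(fs$ci_lower < 0.24 && 0.24 < fs$ci_upper)
  expect_error(ndr_fraction(list(), ann, win), "no QC-passing")
})

test_that("window depletion counts fully accessible windows only", {
  ann <- make_annotation(seq(100L, 500L, by = 20L))
  n_sites <- length(ann$gch_sites)
  win <- ndr_window(250, 350)
  open_cs <- make_callset(character(), rep("accessible", n_sites), "open")
  shut_cs <- make_callset(character(), rep("inaccessible", n_sites), "shut")
  fs <- window_depletion_fraction(list(open_cs, shut_cs), ann, win)
  expect_equal(fs$k, 1)
  expect_equal(fs$n, 2)
  expect_error(window_depletion_fraction(list(open_cs), ann,
                                         ndr_window(0, 50)),
               "no GCH site")
  # a >146-bp protected run whose observed sites all stop short of the
  # window does not disqualify the clone, even though its midpoint-drawn
  # interval would graze the window edge
  ann2 <- make_annotation(c(50L, 100L, 150L, 200L, 240L, 266L, 290L,
                            320L, 340L))
  mixed <- make_callset(character(),
                        c(rep("inaccessible", 5), rep("accessible", 4)),
                        "mixed")
  seg <- segment_clone(mixed, ann2)
  expect_gt(seg$span[seg$state == "protected"], 146)
  expect_gt(seg$end[seg$state == "protected"], win$start)  # drawn interval
  fs2 <- window_depletion_fraction(list(mixed), ann2, win)
  expect_equal(fs2$k, 1)
})

test_that("QC failures are excluded from fractions", {
  ann <- make_annotation(seq(100L, 400L, by = 50L))
  n_sites <- length(ann$gch_sites)
  good <- make_callset(character(), rep("accessible", n_sites), "g")
  bad <- make_callset(character(), rep("accessible", n_sites), "b",
                      conversion = 0.8, passed = FALSE)
  expect_message(fs <- ndr_fraction(list(good, bad), ann,
                                    ndr_window(150, 350)),
                 "excluded")
  expect_equal(fs$n, 1)
})

test_that("knockdown attenuation is recovered from depletion fractions", {
  ref <- random_amplicon(length = 600, seed = 31)
  ann <- annotate_sites(ref)
  cfg <- simulation_config(n_molecules = 1500, days = 0:2, seed = 32,
                           incorporation_prob = 1, washout_day = 10,
                           p_ndr = 0.5, srcap_kd_factor = 0.4)
  pop0 <- simulate_timecourse(cfg, ref)$day2  # 50% U, 50% H
  win <- tss_window(ref)
  measure <- function(kd, seed_off) {
    pop <- apply_remodeling(pop0, cfg, win, srcap_kd = kd,
                            seed = 33 + seed_off)
    flags <- apply_mcvipi(pop, ann, efficiency = 1, seed = 34 + seed_off)
    clones <- bisulfite_reads(pop, flags, cfg, 1200, seed = 35 + seed_off)
    callsets <- mapply(call_clone, clones$reads,
                       clone_id = names(clones$reads),
                       MoreArgs = list(reference = ref, annotation = ann),
                       SIMPLIFY = FALSE)
    u_clones <- callsets[clones$truth$duplex_class == "U"]
    window_depletion_fraction(u_clones, ann, win)$fraction
  }
  f_nc <- measure(FALSE, 0)
  f_kd <- measure(TRUE, 10)
  expect_lt(abs(f_nc - 0.5), 0.06)
  expect_lt(abs(f_kd / f_nc - 0.4), 0.12)
})
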