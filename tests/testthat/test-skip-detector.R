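test_that("deletion gaps are extracted with the minimum-length floor", {
  recs <- records_from_cigars("100M213D150M", ref_start = 1000L)
  g <- extract_gaps(recs)
  expect_equal(g$start, 1100L)
  expect_equal(g$end, 1313L)
  # small error-scale deletions are not candidate gaps
  expect_equal(nrow(extract_gaps(records_from_cigars("50M2D50M1D80M3D20M"))), 0L)
  g2 <- extract_gaps(records_from_cigars("10M50D10M213D10M"))
  expect_equal(g2$start, c(10L, 70L))
  expect_equal(g2$end, c(60L, 283L))
})

test_that("gap scores follow the boundary-offset formula and its bounds", {
  m <- lars_demo_model()
  e20 <- m$exons[20, ]
  expect_equal(score_gap(e20$start, e20$end, m)$score, 1.0)
  expect_equal(score_gap(e20$start + 1L, e20$end + 2L, m)$score, 0.5)
  expect_equal(score_gap(e20$start, e20$end + 8L, m)$score, 1 / 3)
  # strictly decreasing in either offset, max 1 only at (0,0)
  sc <- vapply(0:6, function(k) score_gap(e20$start + k, e20$end, m)$score, 0)
  expect_true(all(diff(sc) < 0))
  expect_true(all(sc[-1] < 1))
})

test_that("events aggregate per exon span and apply the retention threshold", {
  m <- lars_demo_model()
  e20 <- m$exons[20, ]
  exact <- data.frame(read_id = sprintf("r%d", 1:10),
                      start = e20$start, end = e20$end)
  ev <- aggregate_skip_events(score_gaps(exact, m))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$total_score, 10)
  expect_equal(ev$span, "20-20")
  expect_equal(ev$n_reads, 10L)

  lone <- data.frame(read_id = "r1", start = e20$start + 1L, end = e20$end + 2L)
  expect_equal(nrow(aggregate_skip_events(score_gaps(lone, m))), 0L)

  mixed <- rbind(exact,
                 data.frame(read_id = sprintf("q%d", 1:3),
                            start = m$exons$start[5], end = m$exons$end[6]))
  ev2 <- aggregate_skip_events(score_gaps(mixed, m))
  expect_setequal(ev2$span, c("20-20", "5-6"))

  # oracle: independent tapply-based grouping over oracle-mapped spans
  set.seed(21)
  rg <- data.frame(read_id = sprintf("x%d", 1:40),
                   start = sample(0:3700, 40))
  rg$end <- pmin(rg$start + sample(30:250, 40, TRUE), 3900L)
  sg <- score_gaps(rg, m)
  okey <- vapply(seq_len(40), function(i) {
    o <- oracle_nearest(rg$start[i], rg$end[i], m)
    paste0(o["exon_from"], "-", o["exon_to"])
  }, "")
  oscore <- (1 + abs(rg$start - vapply(seq_len(40), function(i)
    oracle_nearest(rg$start[i], rg$end[i], m)["near_start"], 0)) +
    abs(rg$end - vapply(seq_len(40), function(i)
      oracle_nearest(rg$start[i], rg$end[i], m)["near_end"], 0)))^(-0.5)
  otot <- tapply(oscore, okey, sum)
  otot <- sort(otot[otot >= 1], decreasing = TRUE)
  ev3 <- aggregate_skip_events(sg)
  expect_equal(ev3$span, names(otot))
  expect_equal(ev3$total_score, unname(otot))
})

test_that("read classification enforces the interior and margin thresholds", {
  # one 200 nt exon with 150 nt flanks
  seqs <- paste(rep("ACGT", 125), collapse = "")
  m <- transcript_model("c", seqs, data.frame(
    exon_index = 1:3, start = c(0, 150, 350), end = c(150, 350, 500)))
  ev <- data.frame(exon_from = 2L, exon_to = 2L)
  L <- 500L
  mk_read <- function(unaligned_frac, margin_aligned = TRUE) {
    n_un <- round(unaligned_frac * 200)
    iv <- data.frame(start = c(0L, 150L + n_un), end = c(150L, 500L))
    if (!margin_aligned) iv <- data.frame(start = 150L + n_un, end = 500L)
    iv[iv$end > iv$start, , drop = FALSE]
  }
  pm <- make_presence(list(mk_read(1), mk_read(0.79), mk_read(0.85)), L)
  calls <- classify_reads(pm, m, ev)
  expect_equal(calls$skip_call, c(TRUE, FALSE, TRUE))
  expect_equal(calls$interior_unaligned_frac[2], 0.79)

  # interior fully unaligned but margins mostly absent -> not callable as skip
  lowmar <- make_presence(list(data.frame(
    start = c(94L, 366L), end = c(110L, 500L))), L)
  # left margin [110,150) unaligned except part; construct 40% margin alignment:
  # margins are [110,150) and [350,390): aligned positions 94-110 and 366-390
  calls2 <- classify_reads(lowmar, m, ev)
  expect_true(calls2$margin_aligned_frac < 0.5)
  expect_false(calls2$skip_call)

  # reads not spanning the exon plus margins are excluded from the denominator
  short <- make_presence(list(data.frame(start = 200L, end = 500L)), L)
  calls3 <- classify_reads(short, m, ev)
  expect_false(calls3$spanning)
  expect_false(calls3$skip_call)
})

test_that("isoform catalog groups skip patterns and labels by abundance", {
  mk_calls <- function(n_full, n_skip, span_from = 20L, span_to = 20L) {
    ids <- sprintf("r%04d", seq_len(n_full + n_skip))
    data.frame(read_id = ids, span = paste0(span_from, "-", span_to),
               exon_from = span_from, exon_to = span_to, spanning = TRUE,
               interior_unaligned_frac = c(rep(0, n_full), rep(1, n_skip)),
               margin_aligned_frac = 1,
               skip_call = c(rep(FALSE, n_full), rep(TRUE, n_skip)))
  }
  cat1 <- catalog_isoforms(mk_calls(780, 220))
  expect_equal(nrow(cat1), 2L)
  expect_equal(cat1$pct[cat1$pattern == "20"], 22.0)
  expect_equal(cat1$label[cat1$pattern == "20"], "LSV1")
  expect_equal(cat1$label[cat1$pattern == ""], "FULL")

  cat2 <- catalog_isoforms(mk_calls(50, 0))
  expect_equal(cat2$label, "FULL")

  multi <- mk_calls(0, 5, 18L, 19L)
  cat3 <- catalog_isoforms(multi)
  expect_equal(cat3$pattern, "18,19")
  expect_equal(cat3$n_reads, 5L)
})

test_that("co-occurrence table is descriptive and handles exclusivity", {
  calls <- data.frame(read_id = sprintf("r%d", 1:6), span = "5-5",
                      exon_from = 5L, exon_to = 5L, spanning = TRUE,
                      interior_unaligned_frac = 0, margin_aligned_frac = 1,
                      skip_call = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  flags <- stats::setNames(c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
                           calls$read_id)
  tab <- cooccurrence_table(calls, flags)
  expect_equal(tab["TRUE", "TRUE"], 0L)
  expect_equal(tab["TRUE", "FALSE"], 2L)
  expect_equal(tab["FALSE", "TRUE"], 2L)
  empty <- cooccurrence_table(calls[0, ], flags)
  expect_equal(sum(empty), 0L)
})

test_that("noiseless simulations give zero misclassification", {
  m <- tiny_model()
  cfg <- sim_config(40, list(full = isoform_spec(), skip = isoform_spec(5L)),
                    weights = c(0.5, 0.5), seed = 4L)
  sim <- simulate_reads(m, cfg)
  run <- run_pipeline(m, reads = sim$reads)
  called <- vapply(split(run$calls, run$calls$read_id),
                   function(g) any(g$skip_call), TRUE)
  truth <- stats::setNames(sim$truth$has_skip, sim$truth$read_id)
  expect_equal(unname(called[names(truth)]), unname(truth))
})

test_that("the pipeline recovers true skip fractions within 3 points", {
  m <- mid_model()
  for (seed in 1:3) {
    for (f in c(0.05, 0.22, 0.80)) {
      cfg <- sim_config(250, list(full = isoform_spec(), skip = isoform_spec(8L)),
                        weights = c(1 - f, f), mismatch_rate = 0.01,
                        insertion_rate = 0.005, deletion_rate = 0.005,
                        seed = seed)
      sim <- simulate_reads(m, cfg)
      run <- run_pipeline(m, reads = sim$reads)
      est <- run$psi$psi_percent[run$psi$exon_index == 8L]
      expect_equal(length(est), 1L)
      expect_lt(abs(est - 100 * mean(sim$truth$has_skip)), 3)
    }
  }
})
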