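test_that("frame consequence classifies in-frame, frameshift and truncating events", {
  m <- lars_demo_model()
  cq <- frame_consequence(isoform_spec(20L), m)
  expect_equal(cq$status, "in_frame")
  expect_true(cq$in_frame)
  expect_equal(cq$aa_removed, 71L)
  expect_equal(cq$deleted_cds_length, 213L)

  # 214 nt deletion: frameshift
  e20 <- m$exons[20, ]
  fs <- frame_consequence(isoform_spec(
    partial_events = list(list(start = e20$start, end = e20$end + 1L))), m)
  expect_equal(fs$status, "frameshift")
  expect_false(fs$in_frame)
  expect_equal(fs$frameshift_codon, as.integer(e20$start %/% 3L + 1L))

  # 3 nt deletion: one codon
  one <- frame_consequence(isoform_spec(
    partial_events = list(list(start = 300L, end = 303L))), m)
  expect_equal(one$aa_removed, 1L)

  expect_equal(frame_consequence(isoform_spec(), m)$status, "reference")

  # event crossing the CDS boundary is truncating, not scored
  m2 <- transcript_model("t", strrep("ACGT", 100),
    data.frame(exon_index = 1:2, start = c(0, 200), end = c(200, 400)),
    cds_start = 30L, cds_end = 330L)
  tr <- frame_consequence(isoform_spec(
    partial_events = list(list(start = 10L, end = 40L))), m2)
  expect_equal(tr$status, "truncating")
  nc <- frame_consequence(isoform_spec(
    partial_events = list(list(start = 340L, end = 370L))), m2)
  expect_equal(nc$status, "non_coding")
})

test_that("in-frame consequences agree with direct translation of the isoform", {
  m <- lars_demo_model()
  ref_aa <- Biostrings::translate(Biostrings::DNAString(m$sequence),
                                  if.fuzzy.codon = "X")
  set.seed(8)
  tried <- 0
  while (tried < 10) {
    sk <- sort(sample(2:32, sample(1:3, 1)))
    sp <- isoform_spec(sk)
    cq <- frame_consequence(sp, m)
    if (cq$status != "in_frame") next
    tried <- tried + 1
    iso_aa <- Biostrings::translate(
      Biostrings::DNAString(build_isoform_sequence(m, sp)), if.fuzzy.codon = "X")
    expect_equal(length(ref_aa) - length(iso_aa), cq$aa_removed)
  }
})

test_that("amplicon prediction subtracts internal deletions and detects primer loss", {
  m <- lars_demo_model()
  span <- primer_span_around_exon(m, 20L, 721L)
  expect_equal(predict_amplicon(span, isoform_spec(20L), m)$product_length, 508L)
  expect_equal(predict_amplicon(span, isoform_spec(), m)$product_length, 721L)
  # skipping an exon outside the span leaves the product unchanged
  expect_equal(predict_amplicon(span, isoform_spec(5L), m)$product_length, 721L)
  # deletion covering a primer site: no product
  del_over_start <- isoform_spec(partial_events = list(
    list(start = span[1] - 10L, end = span[1] + 30L)))
  out <- predict_amplicon(span, del_over_start, m)
  expect_equal(out$outcome, "no_product")
  expect_true(is.na(out$product_length))
  # additivity over disjoint internal deletions
  set.seed(12)
  for (i in 1:15) {
    a <- sort(sample((span[1] + 5L):(span[2] - 5L), 4))
    if (a[2] - a[1] < 2 || a[4] - a[3] < 2 || a[3] - a[2] < 1) next
    sp <- isoform_spec(partial_events = list(
      list(start = a[1], end = a[2]), list(start = a[3], end = a[4])))
    expect_equal(predict_amplicon(span, sp, m)$product_length,
                 721L - (a[2] - a[1]) - (a[4] - a[3]))
  }
})

test_that("PSI estimates are exact counts with a Wilson interval", {
  mk_calls <- function(n_skip, n_span) data.frame(
    read_id = sprintf("r%d", seq_len(n_span)), span = "20-20",
    exon_from = 20L, exon_to = 20L, spanning = TRUE,
    interior_unaligned_frac = 0, margin_aligned_frac = 1,
    skip_call = c(rep(TRUE, n_skip), rep(FALSE, n_span - n_skip)))
  p <- estimate_psi(mk_calls(220, 1000), 20L)
  expect_equal(p$psi_percent, 22.0)
  expect_true(p$ci_lower < 22 && 22 < p$ci_upper)
  wil <- 100 * stats::prop.test(220, 1000, correct = FALSE)$conf.int
  expect_equal(c(p$ci_lower, p$ci_upper), as.numeric(wil))
  expect_equal(estimate_psi(mk_calls(0, 50), 20L)$psi_percent, 0)
  expect_equal(estimate_psi(mk_calls(50, 50), 20L)$psi_percent, 100)
  none <- suppressMessages(estimate_psi(mk_calls(5, 10)[0, ], 20L))
  expect_true(is.na(none$psi_percent))
})

test_that("PSI is exact on noiseless simulations", {
  m <- tiny_model()
  cfg <- sim_config(50, list(full = isoform_spec(), skip = isoform_spec(5L)),
                    weights = c(0.7, 0.3), seed = 19L)
  sim <- simulate_reads(m, cfg)
  run <- run_pipeline(m, reads = sim$reads)
  est <- run$psi$psi_percent[run$psi$exon_index == 5L]
  expect_equal(est, 100 * mean(sim$truth$has_skip))
})
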