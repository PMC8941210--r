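test_that("island bridging merges deletions split by tiny aligned islands", {
  g <- data.frame(read_id = "r1", start = c(100L, 202L), end = c(200L, 300L))
  b <- bridge_islands(g)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start, b$end), c(100L, 300L))

  g2 <- data.frame(read_id = "r1", start = c(100L, 204L), end = c(200L, 300L))
  b2 <- bridge_islands(g2)
  expect_equal(nrow(b2), 2L)

  g3 <- data.frame(read_id = "r1", start = 100L, end = 200L)
  expect_equal(bridge_islands(g3), g3)

  # chains merge iteratively and never yield overlapping gaps
  set.seed(31)
  for (trial in 1:20) {
    n <- sample(2:6, 1)
    starts <- sort(sample(0:800, n))
    ends <- starts + sample(20:60, n, TRUE)
    ends <- pmin(ends, c(starts[-1] - 1L, 900L))
    ok <- ends > starts
    g <- data.frame(read_id = "r", start = starts[ok], end = ends[ok])
    b <- bridge_islands(g)
    expect_true(all(b$start[-1] > b$end[-nrow(b)]))
    # deleted + island length conserved across each merge
    expect_equal(sum(b$end - b$start),
                 sum(g$end - g$start) +
                   sum(pmax(0, (g$start[-1] - g$end[-nrow(g)]))[
                     (g$start[-1] - g$end[-nrow(g)]) <= 3]))
  }
})

test_that("partial candidates need one off-boundary endpoint and 4 supporting reads", {
  m <- tiny_model()
  ex <- m$exons[5, ]
  mk <- function(n, s, e) data.frame(read_id = sprintf("r%d", seq_len(n)),
                                     start = s, end = e)
  five <- mk(5, ex$start + 10L, ex$end)
  res <- find_partial_candidates(five, m)
  expect_equal(nrow(res), 1L)
  expect_equal(res$support, 5L)
  expect_equal(c(res$start, res$end), c(ex$start + 10L, ex$end))
  expect_false(res$start_at_boundary)
  expect_true(res$end_at_boundary)
  expect_equal(res$nearest_exon, 5L)
  expect_equal(res$boundary_offset, 10L)

  three <- mk(3, ex$start + 10L, ex$end)
  expect_equal(nrow(find_partial_candidates(three, m)), 0L)

  both_off <- mk(5, ex$start + 10L, ex$end - 7L)
  res2 <- find_partial_candidates(both_off, m)
  expect_equal(nrow(res2), 0L)
  expect_equal(nrow(attr(res2, "other")), 5L)
})

test_that("near-identical candidates merge by endpoint distance with a modal interval", {
  m <- tiny_model()
  ex <- m$exons[5, ]
  g <- rbind(
    data.frame(read_id = sprintf("a%d", 1:3), start = ex$start + 10L, end = ex$end),
    data.frame(read_id = sprintf("b%d", 1:2), start = ex$start + 13L, end = ex$end))
  res <- find_partial_candidates(g, m)
  expect_equal(nrow(res), 1L)        # dStart = 3 links them
  expect_equal(res$support, 5L)
  expect_equal(res$start, ex$start + 10L)  # modal tie resolves to smallest

  g2 <- rbind(
    data.frame(read_id = sprintf("a%d", 1:4), start = ex$start + 10L, end = ex$end),
    data.frame(read_id = sprintf("b%d", 1:4), start = ex$start + 14L, end = ex$end))
  res2 <- find_partial_candidates(g2, m)
  expect_equal(nrow(res2), 2L)       # dStart = 4 keeps them apart

  # identical gaps from different reads: one cluster, support = read count
  g3 <- data.frame(read_id = sprintf("c%d", 1:6), start = ex$start + 20L, end = ex$end)
  res3 <- find_partial_candidates(g3, m)
  expect_equal(res3$support, 6L)
  expect_equal(res3$n_members, 6L)
})

test_that("merging is invariant to input row order", {
  m <- tiny_model()
  ex <- m$exons[5, ]
  set.seed(17)
  g <- rbind(
    data.frame(read_id = sprintf("a%d", 1:4), start = ex$start + 10L, end = ex$end),
    data.frame(read_id = sprintf("b%d", 1:3), start = ex$start + 12L, end = ex$end),
    data.frame(read_id = sprintf("d%d", 1:5), start = m$exons$start[7],
               end = m$exons$end[7] - 8L))
  ref <- find_partial_candidates(g, m)
  for (i in 1:20) {
    shuf <- g[sample(nrow(g)), ]
    got <- find_partial_candidates(shuf, m)
    expect_equal(got, ref, ignore_attr = TRUE)
  }
})

test_that("simulated alternative splice sites are recovered near-exactly", {
  m <- mid_model()
  for (seed in 1:3) {
    part <- inject_partial_event(m, 8L, 25L)
    cfg <- sim_config(60, list(full = isoform_spec(), alt = part),
                      weights = c(0.5, 0.5), mismatch_rate = 0.01,
                      insertion_rate = 0.005, deletion_rate = 0.005, seed = seed)
    sim <- simulate_reads(m, cfg)
    recs <- quality_filter(align_reads(sim$reads, m))
    gaps <- snap_gaps_to_boundaries(
      bridge_islands(extract_gaps(recs)), m)
    res <- find_partial_candidates(gaps, m)
    expect_gte(nrow(res), 1L)
    tru <- part$partial_events[[1]]
    d <- abs(res$start - tru$start) + abs(res$end - tru$end)
    expect_lte(min(d), 2L)
    expect_true(all(res$support >= 4L))
    expect_true(all(xor(res$start_at_boundary, res$end_at_boundary)))
  }
})
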