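# Shared fixtures and independent oracles for the test suite.

# Small transcript (fast to align): 8 exons tiling ~860 nt.
tiny_model <- function(seed = 11L) {
  lens <- c(90L, 110L, 120L, 105L, 123L, 96L, 114L, 103L)
  total <- sum(lens)
  seqs <- splicegap:::with_local_seed(seed,
    paste(sample(c("A", "C", "G", "T"), total, replace = TRUE), collapse = ""))
  ends <- cumsum(lens)
  transcript_model("TINY", seqs,
                   data.frame(exon_index = seq_along(lens),
                              start = ends - lens, end = ends),
                   cds_start = 0L, cds_end = total)
}

# Mid-size transcript (2.4 kb, 16 exons) for parameter-recovery runs where
# read length matters to the QC filter.
mid_model <- function(seed = 23L) {
  lens <- c(150L, 160L, 140L, 170L, 155L, 145L, 165L, 210L,
            150L, 140L, 160L, 135L, 155L, 125L, 150L, 90L)
  total <- sum(lens)
  seqs <- splicegap:::with_local_seed(seed,
    paste(sample(c("A", "C", "G", "T"), total, replace = TRUE), collapse = ""))
  ends <- cumsum(lens)
  transcript_model("MID", seqs,
                   data.frame(exon_index = seq_along(lens),
                              start = ends - lens, end = ends),
                   cds_start = 0L, cds_end = total)
}

# Brute-force affine-gap semi-global DP (score only): read consumed in
# full, reference end gaps free, gap of length L costs open + L * extend.
oracle_semiglobal_score <- function(read, ref, match = 2, mismatch = -4,
                                    gap_open = 4, gap_extend = 1) {
  a <- strsplit(read, "", fixed = TRUE)[[1L]]
  b <- strsplit(ref, "", fixed = TRUE)[[1L]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)   # ends in aligned pair
  X <- matrix(NEG, n + 1L, m + 1L)   # ends in read-consuming gap (insertion)
  Y <- matrix(NEG, n + 1L, m + 1L)   # ends in ref-consuming gap (deletion)
  H <- function(i, j) max(M[i, j], X[i, j], Y[i, j])
  M[1L, ] <- 0                        # free leading reference gap
  for (i in 2L:(n + 1L)) {
    X[i, 1L] <- -(gap_open + (i - 1L) * gap_extend)
    for (j in seq_len(m + 1L)[-1L]) {
      s <- if (a[i - 1L] == b[j - 1L]) match else mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - gap_open - gap_extend,
                     X[i - 1L, j] - gap_extend,
                     Y[i - 1L, j] - gap_open - gap_extend)
      Y[i, j] <- max(M[i, j - 1L] - gap_open - gap_extend,
                     X[i, j - 1L] - gap_open - gap_extend,
                     Y[i, j - 1L] - gap_extend)
    }
  }
  max(vapply(seq_len(m + 1L), function(j) H(n + 1L, j), 0))
}

# Exhaustive nearest-boundary scan, independent of the package path.
oracle_nearest <- function(gap_start, gap_end, model) {
  ds <- abs(gap_start - model$exons$start)
  de <- abs(gap_end - model$exons$end)
  i <- which(ds == min(ds))[1L]
  j <- which(de == min(de))[1L]
  c(near_start = model$exons$start[i], near_end = model$exons$end[j],
    exon_from = model$exons$exon_index[i], exon_to = model$exons$exon_index[j])
}

# Regex oracle for IUPAC motif scanning (overlapping matches).
oracle_motif_positions <- function(sequence, motif) {
  map <- Biostrings::IUPAC_CODE_MAP
  cls <- vapply(strsplit(toupper(motif), "", fixed = TRUE)[[1L]],
                function(ch) paste0("[", map[[ch]], "]"), "")
  pat <- paste0("(?=", paste(cls, collapse = ""), ")")
  m <- gregexpr(pat, toupper(sequence), perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# Hand-built presence matrix from per-read aligned intervals
# (list of data.frames with start/end, 0-based half-open).
make_presence <- function(intervals, L, ids = NULL) {
  n <- length(intervals)
  m <- matrix(FALSE, n, L)
  for (i in seq_len(n)) {
    iv <- intervals[[i]]
    for (k in seq_len(nrow(iv))) m[i, (iv$start[k] + 1L):iv$end[k]] <- TRUE
  }
  rownames(m) <- if (is.null(ids)) sprintf("read_%05d", seq_len(n)) else ids
  structure(list(matrix = m, coverage = if (n) colMeans(m) else rep(NA_real_, L)),
            class = "presence_matrix")
}

# Minimal SAM text writer for ingestion tests.
write_test_sam <- function(path, ref_name, ref_len, rows) {
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len))
  for (r in rows)
    lines <- c(lines, paste(r$qname, r$flag, r$rname, r$pos, 60, r$cigar,
                            "*", 0, 0, r$seq %||% "*", "*", sep = "\t"))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Alignment records data.frame from cigar strings (for QC/gaps unit tests).
records_from_cigars <- function(cigars, ref_start = 0L, ids = NULL) {
  n <- length(cigars)
  if (n == 0L) return(splicegap:::empty_records())
  ab <- vapply(cigars, function(cg) {
    ops <- parse_cigar(cg); sum(ops$len[ops$op %in% c("M", "=", "X")])
  }, 0L)
  ni <- vapply(cigars, function(cg) nrow(parse_cigar(cg)), 0L)
  data.frame(read_id = if (is.null(ids)) sprintf("read_%05d", seq_len(n)) else ids,
             ref_start = rep_len(ref_start, n), cigar = unname(cigars),
             aligned_bases = unname(ab), cigar_instructions = unname(ni),
             score = NA_real_, aligned = TRUE, stringsAsFactors = FALSE)
}
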