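#' Configuration for the synthetic long-read simulator
#'
#' The simulator stands in for a gene-targeted PacBio cDNA library: reads are
#' drawn from a weighted mixture of isoforms of one transcript, optionally
#' 5'-truncated, then corrupted with independent per-base mismatches and
#' short geometric-length indels mimicking long-read error. Error indels are
#' capped at `max_error_indel_length` nt so they stay well below true splice
#' deletions.
#'
#' @param n_reads number of reads to emit.
#' @param isoforms named list of [isoform_spec()] objects.
#' @param weights numeric mixture weights, same names/order as `isoforms`;
#'   must be nonnegative and sum to 1 (tolerance 1e-9).
#' @param mismatch_rate,insertion_rate,deletion_rate per-base error
#'   fractions, each in [0, 0.25]: the expected fraction of bases affected
#'   by each error class, the usual convention for quoting long-read error
#'   rates. An indel event of length L affects L bases, so indel events are
#'   initiated at `rate / E[indel length]` per base.
#' @param max_error_indel_length cap on error-indel length (nt).
#' @param indel_length_p geometric success parameter for indel lengths
#'   (length 1 dominant).
#' @param truncate_frac fraction of reads given a truncated 5' start
#'   (incomplete cDNA); the start is uniform on the first half of the
#'   isoform. Default 0 = full-length spans.
#' @param seed RNG seed; one stream, consumed in read-index order, so adding
#'   reads never perturbs earlier reads.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_reads, isoforms, weights,
                       mismatch_rate = 0, insertion_rate = 0, deletion_rate = 0,
                       max_error_indel_length = 5L, indel_length_p = 0.7,
                       truncate_frac = 0, seed = 1L) {
  if (n_reads < 0) stop("config error: n_reads must be >= 0")
  if (length(isoforms) == 0L || length(weights) != length(isoforms))
    stop("config error: isoforms and weights must have equal positive length")
  if (is.null(names(isoforms))) names(isoforms) <- paste0("iso", seq_along(isoforms))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("config error: weights must be nonnegative and sum to 1")
  rates <- c(mismatch_rate, insertion_rate, deletion_rate)
  if (any(rates < 0) || any(rates > 0.25))
    stop("config error: error rates must lie in [0, 0.25]")
  structure(list(n_reads = as.integer(n_reads), isoforms = isoforms,
                 weights = as.numeric(weights),
                 mismatch_rate = mismatch_rate, insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 max_error_indel_length = as.integer(max_error_indel_length),
                 indel_length_p = indel_length_p,
                 truncate_frac = truncate_frac, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate long reads with known ground truth
#'
#' @param model a [transcript_model()].
#' @param config a [sim_config()].
#' @param fasta_path,truth_path optional output paths (FASTA reads, TSV
#'   truth table). Written only when non-NULL.
#' @return list with `reads` (named [Biostrings::DNAStringSet]) and `truth`
#'   (data.frame, one row per read: isoform name, skipped exons, feature
#'   flags, span on the isoform, injected error-op counts).
#' @export
simulate_reads <- function(model, config, fasta_path = NULL, truth_path = NULL) {
  stopifnot(inherits(model, "transcript_model"), inherits(config, "sim_config"))
  iso_seq <- vapply(config$isoforms, function(sp) build_isoform_sequence(model, sp), "")
  iso_truth <- lapply(config$isoforms, function(sp) list(
    skipped = paste(sp$skipped_exons, collapse = ","),
    has_skip = length(sp$skipped_exons) > 0L,
    has_partial = length(sp$partial_events) > 0L,
    has_retained_intron = length(sp$retained_introns) > 0L))
  n <- config$n_reads
  set.seed(config$seed)
  reads <- character(n)
  rows <- vector("list", n)
  for (r in seq_len(n)) {
    k <- if (length(iso_seq) == 1L) 1L else
      sample.int(length(iso_seq), 1L, prob = config$weights)
    s <- iso_seq[[k]]
    span_start <- 0L
    if (config$truncate_frac > 0 && stats::runif(1) < config$truncate_frac)
      span_start <- sample.int(max(1L, nchar(s) %/% 2L), 1L) - 1L
    s <- substr(s, span_start + 1L, nchar(s))
    err <- inject_errors(s, config)
    reads[r] <- err$seq
    tr <- iso_truth[[k]]
    rows[[r]] <- data.frame(
      read_id = sprintf("read_%05d", r), isoform = names(iso_seq)[k],
      skipped_exons = tr$skipped, has_skip = tr$has_skip,
      has_partial = tr$has_partial, has_retained_intron = tr$has_retained_intron,
      span_start = span_start, span_end = span_start + nchar(s),
      n_mismatch = err$n_mismatch, n_ins = err$n_ins, n_del = err$n_del,
      stringsAsFactors = FALSE)
  }
  truth <- if (n) do.call(rbind, rows) else data.frame(
    read_id = character(), isoform = character(), skipped_exons = character(),
    has_skip = logical(), has_partial = logical(), has_retained_intron = logical(),
    span_start = integer(), span_end = integer(),
    n_mismatch = integer(), n_ins = integer(), n_del = integer())
  dna <- Biostrings::DNAStringSet(reads)
  names(dna) <- truth$read_id
  if (!is.null(fasta_path)) Biostrings::writeXStringSet(dna, fasta_path)
  if (!is.null(truth_path))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(reads = dna, truth = truth)
}

#' Expected length of a capped-geometric error indel
#' @param p geometric success parameter (length 1 dominant).
#' @param cap maximum indel length (nt).
#' @return expected indel length in nt.
#' @export
mean_indel_length <- function(p = 0.7, cap = 5L) {
  k <- seq_len(cap - 1L)
  sum(k * p * (1 - p)^(k - 1L)) + cap * (1 - p)^(cap - 1L)
}

# Corrupt one read with mismatches and short indels; returns op counts.
# Indel events start at rate / E[length] per base so that the expected
# fraction of bases hit matches the configured per-base error fraction.
inject_errors <- function(s, config) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  bases <- c("A", "C", "G", "T")
  mlen <- mean_indel_length(config$indel_length_p, config$max_error_indel_length)
  n_mm <- n_ins <- n_del <- 0L
  if (config$mismatch_rate > 0) {
    mm <- which(stats::runif(n) < config$mismatch_rate)
    for (p in mm) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    n_mm <- length(mm)
  }
  keep <- rep(TRUE, n)
  if (config$deletion_rate > 0) {
    dstart <- which(stats::runif(n) < config$deletion_rate / mlen)
    for (p in dstart) {
      len <- min(stats::rgeom(1L, config$indel_length_p) + 1L,
                 config$max_error_indel_length)
      keep[p:min(n, p + len - 1L)] <- FALSE
    }
    n_del <- length(dstart)
  }
  ins_txt <- rep("", n)
  if (config$insertion_rate > 0) {
    ipos <- which(stats::runif(n) < config$insertion_rate / mlen)
    for (p in ipos) {
      len <- min(stats::rgeom(1L, config$indel_length_p) + 1L,
                 config$max_error_indel_length)
      ins_txt[p] <- paste(sample(bases, len, replace = TRUE), collapse = "")
    }
    n_ins <- length(ipos)
  }
  out <- paste0(ifelse(keep, chars, ""), ins_txt)
  list(seq = paste(out, collapse = ""),
       n_mismatch = n_mm, n_ins = n_ins, n_del = n_del)
}

#' Build an alternative splice-site (partial exon-skipping) isoform spec
#'
#' A positive offset moves the deletion start `offset` nt inside the exon
#' (leaving the 5' remnant aligned, deletion ends at the exon end); a
#' negative offset keeps the deletion start at the exon start and ends it
#' `|offset|` nt before the exon end. Either way exactly one deletion
#' endpoint sits off an annotated boundary.
#'
#' @param model a [transcript_model()].
#' @param exon_index exon ordinal.
#' @param new_boundary_offset signed nt; must be nonzero and smaller in
#'   magnitude than the exon length.
#' @return an [isoform_spec()] with one partial event.
#' @export
inject_partial_event <- function(model, exon_index, new_boundary_offset) {
  idx <- match(exon_index, model$exons$exon_index)
  if (is.na(idx)) stop("spec error: exon not in model")
  ex <- model$exons[idx, ]
  off <- as.integer(new_boundary_offset)
  if (off == 0L) stop("spec error: zero offset degenerates to a full skip")
  if (abs(off) >= ex$length) stop("spec error: offset leaves no exon remnant")
  iv <- if (off > 0L) c(ex$start + off, ex$end) else c(ex$start, ex$end + off)
  isoform_spec(partial_events = list(list(
    start = iv[1L], end = iv[2L],
    description = sprintf("exon %d alternative %s splice site (offset %+d)",
                          exon_index, if (off > 0L) "3'" else "5'", off))))
}
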