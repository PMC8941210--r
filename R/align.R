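#' Default alignment scoring
#'
#' Match +2, mismatch -4, gap open -4 (charged once per gap), gap extend -1
#' per base. The heavy open / light extend combination favors one long
#' deletion over scattered short gaps, which is exactly the splice-deletion
#' signal the detector looks for.
#' @return named list of scoring parameters.
#' @export
default_scoring <- function() {
  list(match = 2, mismatch = -4, gap_open = -4, gap_extend = -1)
}

#' Align reads semi-globally to the transcript
#'
#' Optimal affine-gap semi-global (glocal) alignment: the read is consumed
#' in full while end gaps on the reference are free, matching the geometry
#' of gene-targeted cDNA reads that are subsequences of the transcript.
#' Backed by [Biostrings::pairwiseAlignment()] (`type = "global-local"`).
#' Reads scoring below `min_score` are flagged unaligned (e.g. reverse
#' complements).
#'
#' @param reads a [Biostrings::DNAStringSet] or named character vector.
#' @param model a [transcript_model()].
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (see [default_scoring()]).
#' @param min_score minimum accepted alignment score.
#' @param length_margin warn when a read exceeds the reference length by
#'   more than this many nt.
#' @return data.frame of alignment records: `read_id`, `ref_start` (0-based),
#'   `cigar` (M/I/D runs), `aligned_bases` (read bases opposite reference
#'   bases), `cigar_instructions` (number of runs), `score`, `aligned`.
#' @export
align_reads <- function(reads, model, scoring = default_scoring(),
                        min_score = 0, length_margin = 200L) {
  if (is.character(reads)) {
    nm <- names(reads)
    reads <- Biostrings::DNAStringSet(reads)
    names(reads) <- nm
  }
  if (length(reads) == 0L) return(empty_records())
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    names(reads) <- sprintf("read_%05d", seq_along(reads))
  if (any(Biostrings::width(reads) == 0L)) stop("input error: empty read")
  too_long <- Biostrings::width(reads) > nchar(model$sequence) + length_margin
  if (any(too_long))
    warning(sum(too_long), " read(s) exceed the reference length by more than ",
            length_margin, " nt")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    reads, Biostrings::DNAString(model$sequence), type = "global-local",
    substitutionMatrix = mat, gapOpening = abs(scoring$gap_open),
    gapExtension = abs(scoring$gap_extend))
  gp <- as.character(Biostrings::alignedPattern(aln))
  gs <- as.character(Biostrings::alignedSubject(aln))
  ref_start <- BiocGenerics::start(Biostrings::subject(aln)) - 1L
  sc <- Biostrings::score(aln)
  recs <- lapply(seq_along(reads), function(i) {
    cg <- cigar_from_gapped(gp[i], gs[i])
    data.frame(read_id = names(reads)[i], ref_start = ref_start[i],
               cigar = cg$cigar, aligned_bases = cg$aligned_bases,
               cigar_instructions = cg$n_ops, score = sc[i],
               aligned = sc[i] >= min_score, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Align a single read
#' @inheritParams align_reads
#' @param read a single nucleotide string.
#' @return one-row alignment record data.frame (see [align_reads()]).
#' @export
align_semiglobal <- function(read, model, scoring = default_scoring(),
                             min_score = 0) {
  align_reads(stats::setNames(as.character(read), "read_00001"), model,
              scoring = scoring, min_score = min_score)
}

empty_records <- function() {
  data.frame(read_id = character(), ref_start = integer(), cigar = character(),
             aligned_bases = integer(), cigar_instructions = integer(),
             score = numeric(), aligned = logical(), stringsAsFactors = FALSE)
}

# CIGAR from the two gapped alignment strings (no clips in glocal mode).
cigar_from_gapped <- function(gapped_pattern, gapped_subject) {
  p <- strsplit(gapped_pattern, "", fixed = TRUE)[[1L]]
  s <- strsplit(gapped_subject, "", fixed = TRUE)[[1L]]
  op <- ifelse(p == "-", "D", ifelse(s == "-", "I", "M"))
  r <- rle(op)
  list(cigar = paste0(r$lengths, r$values, collapse = ""),
       aligned_bases = sum(r$lengths[r$values == "M"]),
       n_ops = length(r$lengths))
}

#' Parse a CIGAR string into operation runs
#' @param cigar CIGAR string (MIDNSHP=X operations).
#' @return data.frame with columns `op` and `len`.
#' @export
parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  toks <- regmatches(cigar, list(m))[[1L]]
  data.frame(op = substring(toks, nchar(toks)),
             len = as.integer(substring(toks, 1L, nchar(toks) - 1L)),
             stringsAsFactors = FALSE)
}

#' Read alignments from SAM/BAM
#'
#' Unmapped, secondary and supplementary records are dropped (count reported
#' via message and the `"dropped"` attribute). `aligned_bases` counts read
#' bases placed opposite reference bases (M/=/X); `cigar_instructions`
#' counts all CIGAR runs including clips.
#'
#' @param path SAM (text) or BAM file.
#' @param model a [transcript_model()]; the reference name must match.
#' @return alignment-record data.frame (see [align_reads()]).
#' @export
read_sam <- function(path, model) {
  ext <- tolower(tools::file_ext(path))
  bam <- if (ext == "sam") {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else path
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar")))[[1L]]
  n <- length(b$qname)
  if (n == 0L) {
    res <- empty_records(); attr(res, "dropped") <- 0L; return(res)
  }
  keep <- !bitwAnd(b$flag, 0x4) & !bitwAnd(b$flag, 0x100) & !bitwAnd(b$flag, 0x800)
  dropped <- sum(!keep)
  if (dropped) message(dropped, " unmapped/secondary/supplementary record(s) dropped")
  if (any(keep) && !all(as.character(b$rname[keep]) == model$name))
    stop("input error: SAM reference name does not match the transcript model")
  recs <- lapply(which(keep), function(i) {
    ops <- parse_cigar(b$cigar[i])
    data.frame(read_id = b$qname[i], ref_start = b$pos[i] - 1L,
               cigar = b$cigar[i],
               aligned_bases = sum(ops$len[ops$op %in% c("M", "=", "X")]),
               cigar_instructions = nrow(ops), score = NA_real_,
               aligned = TRUE, stringsAsFactors = FALSE)
  })
  res <- if (length(recs)) do.call(rbind, recs) else empty_records()
  attr(res, "dropped") <- dropped
  res
}

#' Write alignment records as SAM
#'
#' @param records alignment-record data.frame from [align_reads()].
#' @param model a [transcript_model()].
#' @param path output SAM file.
#' @param reads optional [Biostrings::DNAStringSet] supplying SEQ fields.
#' @export
write_sam <- function(records, model, path, reads = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", model$name, nchar(model$sequence))),
             con)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    seq <- if (!is.null(reads) && r$read_id %in% names(reads))
      as.character(reads[[r$read_id]]) else "*"
    if (isTRUE(r$aligned)) {
      writeLines(paste(r$read_id, 0L, model$name, r$ref_start + 1L, 60L,
                       r$cigar, "*", 0L, 0L, seq, "*", sep = "\t"), con)
    } else {
      writeLines(paste(r$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, seq, "*",
                       sep = "\t"), con)
    }
  }
  invisible(path)
}
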