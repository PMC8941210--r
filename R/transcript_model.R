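#' Construct a transcript model
#'
#' A transcript model bundles a single reference mRNA sequence with its
#' ordered exon annotation and (optionally) the CDS interval. It is the
#' coordinate frame for every downstream stage: alignments, deletion gaps,
#' exon-boundary scoring and coding-consequence annotation all live in
#' transcript (mRNA) space, not genome space.
#'
#' Internally all coordinates are 0-based half-open (BED convention); report
#' output is converted to 1-based inclusive only at I/O boundaries.
#'
#' @param name reference identifier (used as the SAM reference name).
#' @param sequence nucleotide string (A/C/G/T/N).
#' @param exons data.frame with columns `exon_index` (1-based ordinal),
#'   `start`, `end` (0-based half-open transcript coordinates). Exons must be
#'   non-overlapping and sorted by start; gaps between exons are permitted.
#' @param cds_start,cds_end CDS interval (0-based half-open). `NULL` for a
#'   model without a declared CDS.
#' @param complete_cds if `TRUE` (default when a CDS is declared), the CDS
#'   length must be divisible by 3.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(name, sequence, exons,
                             cds_start = NULL, cds_end = NULL,
                             complete_cds = !is.null(cds_start)) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("input error: empty reference sequence")
  L <- nchar(sequence)
  exons <- as.data.frame(exons)
  req <- c("exon_index", "start", "end")
  if (!all(req %in% names(exons)))
    stop("annotation error: exon table must have columns exon_index, start, end")
  exons <- exons[order(exons$start), req, drop = FALSE]
  exons$exon_index <- as.integer(exons$exon_index)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) == 0L) stop("annotation error: exon table is empty")
  if (any(exons$end <= exons$start))
    stop("annotation error: exon end must exceed exon start")
  if (any(exons$start < 0L) || any(exons$end > L))
    stop("bounds error: exon interval outside [0, transcript length)")
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("annotation error: overlapping exons")
  if (any(duplicated(exons$exon_index)))
    stop("annotation error: duplicated exon_index")
  exons$length <- exons$end - exons$start
  if (!is.null(cds_start)) {
    cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
    if (cds_start < 0L || cds_end > L || cds_start >= cds_end)
      stop("bounds error: invalid CDS interval")
    if (complete_cds && (cds_end - cds_start) %% 3L != 0L)
      stop("annotation error: complete CDS length not divisible by 3")
  }
  structure(list(name = as.character(name), sequence = sequence,
                 exons = exons, cds_start = cds_start, cds_end = cds_end),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("Transcript model:", x$name, "\n")
  cat("  length:", nchar(x$sequence), "nt;", nrow(x$exons), "exons\n")
  if (!is.null(x$cds_start))
    cat("  CDS: [", x$cds_start, ", ", x$cds_end, ")\n", sep = "")
  invisible(x)
}

#' Load a transcript model from FASTA plus an exon table
#'
#' The exon table is either 4-column BED (no header: name, start, end,
#' exon_index; 0-based half-open) or TSV with a header row containing
#' `exon_index`, `start`, `end` in 0-based half-open coordinates.
#'
#' @param fasta_path FASTA file with exactly one record.
#' @param exon_table_path BED or TSV exon table.
#' @param format `"auto"` (by extension), `"bed"` or `"tsv"`.
#' @param cds_start,cds_end optional CDS interval, passed through.
#' @return a [transcript_model()].
#' @export
load_transcript <- function(fasta_path, exon_table_path,
                            format = c("auto", "bed", "tsv"),
                            cds_start = NULL, cds_end = NULL) {
  format <- match.arg(format)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("input error: FASTA contains no record")
  if (length(seqs) > 1L) stop("input error: FASTA must contain exactly one record")
  name <- sub("\\s.*$", "", names(seqs)[1L])
  if (format == "auto")
    format <- if (tolower(tools::file_ext(exon_table_path)) == "bed") "bed" else "tsv"
  if (format == "bed") {
    tab <- utils::read.table(exon_table_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 3L) stop("annotation error: BED needs >= 3 columns")
    exons <- data.frame(
      exon_index = if (ncol(tab) >= 4L) as.integer(tab[[4L]]) else seq_len(nrow(tab)),
      start = as.integer(tab[[2L]]), end = as.integer(tab[[3L]]))
  } else {
    tab <- utils::read.delim(exon_table_path, stringsAsFactors = FALSE)
    if (!all(c("exon_index", "start", "end") %in% names(tab)))
      stop("annotation error: TSV exon table must have header exon_index, start, end")
    exons <- tab[, c("exon_index", "start", "end")]
  }
  transcript_model(name, as.character(seqs[[1L]]), exons,
                   cds_start = cds_start, cds_end = cds_end)
}

#' Write an exon table
#'
#' @param model a [transcript_model()].
#' @param path output file.
#' @param format `"tsv"` (header, 0-based half-open) or `"bed"`.
#' @export
write_exon_table <- function(model, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  ex <- model$exons
  if (format == "tsv") {
    utils::write.table(ex[, c("exon_index", "start", "end")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    bed <- data.frame(model$name, ex$start, ex$end, ex$exon_index)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write the reference sequence as FASTA
#' @param model a [transcript_model()].
#' @param path output FASTA file.
#' @export
write_reference_fasta <- function(model, path) {
  seqs <- Biostrings::DNAStringSet(model$sequence)
  names(seqs) <- model$name
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Specify an isoform as a set of splice events on a transcript
#'
#' @param skipped_exons integer vector of exon ordinals that are skipped
#'   entirely.
#' @param partial_events list of `list(start =, end =, description =)`
#'   deletions (0-based half-open) with one endpoint off an exon boundary
#'   (alternative 3'/5' splice sites).
#' @param retained_introns list of `list(position =, sequence =)` insertions
#'   relative to the reference (simulation only).
#' @return an object of class `isoform_spec`.
#' @export
isoform_spec <- function(skipped_exons = integer(),
                         partial_events = list(),
                         retained_introns = list()) {
  structure(list(skipped_exons = as.integer(sort(unique(skipped_exons))),
                 partial_events = partial_events,
                 retained_introns = retained_introns),
            class = "isoform_spec")
}

# All deleted intervals (0-based half-open) implied by a spec on a model.
deleted_intervals <- function(spec, model) {
  iv <- NULL
  if (length(spec$skipped_exons)) {
    idx <- match(spec$skipped_exons, model$exons$exon_index)
    if (anyNA(idx)) stop("spec error: skipped exon index not in model")
    iv <- data.frame(start = model$exons$start[idx], end = model$exons$end[idx])
  }
  if (length(spec$partial_events)) {
    pe <- do.call(rbind, lapply(spec$partial_events, function(p)
      data.frame(start = as.integer(p$start), end = as.integer(p$end))))
    iv <- rbind(iv, pe)
  }
  if (is.null(iv)) return(data.frame(start = integer(), end = integer()))
  iv <- iv[order(iv$start), , drop = FALSE]
  L <- nchar(model$sequence)
  if (any(iv$start < 0L) || any(iv$end > L) || any(iv$end <= iv$start))
    stop("spec error: deleted interval outside transcript or empty")
  if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)]))
    stop("spec error: overlapping splice events")
  iv
}

#' Build the nucleotide sequence of an isoform
#'
#' Applies the spec's deletions (skipped exons, partial events) and retained
#' introns (insertions) to the reference. With an empty spec the reference is
#' returned unchanged; the output length is always
#' `full length - sum(deleted) + sum(retained)`.
#'
#' @param model a [transcript_model()].
#' @param spec an [isoform_spec()].
#' @return nucleotide string.
#' @export
build_isoform_sequence <- function(model, spec) {
  iv <- deleted_intervals(spec, model)
  s <- model$sequence
  L <- nchar(s)
  keep <- rep(TRUE, L)
  if (nrow(iv)) for (i in seq_len(nrow(iv))) keep[(iv$start[i] + 1L):iv$end[i]] <- FALSE
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  ins_after <- rep("", L + 1L)          # ins_after[p + 1] inserted before 0-based position p
  for (ri in spec$retained_introns) {
    pos <- as.integer(ri$position)
    if (pos < 0L || pos > L) stop("spec error: retained intron outside transcript")
    ins_after[pos + 1L] <- paste0(ins_after[pos + 1L], toupper(as.character(ri$sequence)))
  }
  body <- paste0(ins_after[seq_len(L)], ifelse(keep, chars, ""))
  paste0(paste(body, collapse = ""), ins_after[L + 1L])
}

#' Map a deletion gap to the nearest exon boundaries
#'
#' The gap start is matched to the exon *start* minimizing the absolute
#' offset, the gap end to the exon *end* minimizing its offset; the implied
#' exon span runs from the first exon to the second. Ties resolve to the
#' lower exon index.
#'
#' @param gap_start,gap_end gap interval (0-based half-open).
#' @param model a [transcript_model()].
#' @return list with `near_start`, `near_end` (boundary coordinates),
#'   `start_offset`, `end_offset` (absolute distances), `exon_from`,
#'   `exon_to` (ordinals) and `span` (integer vector of exon ordinals).
#' @export
nearest_boundaries <- function(gap_start, gap_end, model) {
  ex <- model$exons
  if (nrow(ex) == 0L) stop("annotation error: model has no exons")
  if (gap_start < 0 || gap_end <= gap_start || gap_end > nchar(model$sequence))
    stop("bounds error: invalid gap interval")
  i <- which.min(abs(gap_start - ex$start))   # which.min takes the first = lower index
  j <- which.min(abs(gap_end - ex$end))
  list(near_start = ex$start[i], near_end = ex$end[j],
       start_offset = abs(gap_start - ex$start[i]),
       end_offset = abs(gap_end - ex$end[j]),
       exon_from = ex$exon_index[i], exon_to = ex$exon_index[j],
       span = if (j >= i) ex$exon_index[i:j] else integer(0))
}
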