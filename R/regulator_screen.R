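#' Parse an rMATS skipped-exon (SE) output table
#'
#' Reads the standard rMATS SE TSV. Required columns: `exonStart_0base`,
#' `exonEnd`, `PValue`, `FDR`, `IncLevelDifference`. Rows with unparsable
#' or out-of-range values are rejected with row-numbered messages. Only the
#' SE event class is handled; other rMATS classes must be filtered upstream.
#'
#' @param path rMATS SE TSV file.
#' @param cell_line,target source experiment tags attached to every record
#'   (used when the file lacks `cell_line` / `target` columns).
#' @return data.frame of skipped-exon records.
#' @export
parse_rmats_se <- function(path, cell_line = NA_character_, target = NA_character_) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("exonStart_0base", "exonEnd", "PValue", "FDR", "IncLevelDifference")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("format error: missing rMATS SE column(s): ", paste(miss, collapse = ", "))
  for (col in req) tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  bad <- !stats::complete.cases(tab[, req]) |
    tab$PValue < 0 | tab$PValue > 1 | tab$FDR < 0 | tab$FDR > 1 |
    abs(tab$IncLevelDifference) > 1
  if (any(bad))
    message("rejected malformed rMATS row(s): ", paste(which(bad), collapse = ", "))
  tab <- tab[!bad, , drop = FALSE]
  if (!"cell_line" %in% names(tab)) tab$cell_line <- rep(cell_line, nrow(tab))
  if (!"target" %in% names(tab)) tab$target <- rep(target, nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Filter rMATS records by p-value
#' @param records data.frame from [parse_rmats_se()].
#' @param p_threshold exclusive upper bound on `PValue`.
#' @return the retained records.
#' @export
filter_rmats <- function(records, p_threshold = 0.01) {
  records[records$PValue < p_threshold, , drop = FALSE]
}

#' Summarize per-knockdown changes in percent exon skipping
#'
#' Joins each record's exon interval to the transcript's exon annotation
#' (interval equality within `tol` nt, absorbing 0/1-based discrepancies
#' between annotation sources) and reports the change in percent exon
#' skipping as `-100 x IncLevelDifference`: skipping is the complement of
#' inclusion, so a knockdown that lowers inclusion raises skipping. Rows
#' matching no annotated exon are flagged `unmapped` and excluded from the
#' per-exon summary. Cell lines are never averaged: one row per
#' (target, cell line, exon).
#'
#' @param records filtered records (see [filter_rmats()]).
#' @param model a [transcript_model()] supplying the exon annotation.
#' @param tol interval-join tolerance (nt).
#' @return data.frame: `target`, `cell_line`, `exon_index`,
#'   `delta_skip_pct`, `PValue`, `FDR`; attribute `"unmapped"` carries the
#'   excluded rows.
#' @export
summarize_delta_skipping <- function(records, model, tol = 1L) {
  ex <- model$exons
  idx <- vapply(seq_len(nrow(records)), function(i) {
    hit <- which(abs(ex$start - records$exonStart_0base[i]) <= tol &
                   abs(ex$end - records$exonEnd[i]) <= tol)
    if (length(hit)) ex$exon_index[hit[1L]] else NA_integer_
  }, 0L)
  unmapped <- records[is.na(idx), , drop = FALSE]
  if (nrow(unmapped))
    message(nrow(unmapped), " record(s) matched no annotated exon; flagged unmapped")
  keep <- !is.na(idx)
  out <- data.frame(target = records$target[keep],
                    cell_line = records$cell_line[keep],
                    exon_index = idx[keep],
                    delta_skip_pct = -100 * records$IncLevelDifference[keep],
                    PValue = records$PValue[keep], FDR = records$FDR[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$exon_index, out$target, out$cell_line), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  attr(out, "sign_convention") <- "delta_skip_pct = -100 * IncLevelDifference (skipping = 1 - inclusion)"
  out
}

#' Scan a sequence window for IUPAC motifs
#'
#' Every position where a motif's IUPAC pattern matches is reported
#' (overlapping hits allowed), via [Biostrings::matchPattern()] with
#' `fixed = FALSE`. Output positions are 1-based.
#'
#' @param sequence nucleotide string (the window to scan).
#' @param motifs character vector of IUPAC motif strings.
#' @return data.frame: `motif`, `position` (1-based), `match`.
#' @export
scan_motifs <- function(sequence, motifs) {
  if (length(motifs) == 0L) stop("motif error: empty motif list")
  valid <- names(Biostrings::IUPAC_CODE_MAP)
  subject <- Biostrings::DNAString(toupper(as.character(sequence)))
  out <- lapply(motifs, function(m) {
    mu <- toupper(m)
    chars <- strsplit(mu, "", fixed = TRUE)[[1L]]
    if (!all(chars %in% valid))
      stop("motif error: invalid IUPAC character in motif '", m, "'")
    hits <- Biostrings::matchPattern(mu, subject, fixed = FALSE)
    if (length(hits) == 0L)
      return(data.frame(motif = character(), position = integer(),
                        match = character(), stringsAsFactors = FALSE))
    data.frame(motif = mu, position = BiocGenerics::start(hits),
               match = as.character(hits), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a motif list TSV
#' @param path TSV with a header containing at least a `motif` column.
#' @return data.frame.
#' @export
read_motif_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"motif" %in% names(tab)) stop("format error: motif table needs a 'motif' column")
  tab
}
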