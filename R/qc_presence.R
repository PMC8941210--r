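#' Alignment quality filter
#'
#' Retains an alignment iff `ln(AlignedBases / CigarInstructions) >=
#' threshold` (default 4, i.e. ratio >= e^4 ~ 54.6). Alignments shredded by
#' many small indels have many CIGAR runs per aligned base and fail the
#' filter; clean long alignments pass. Because the source formula defines
#' neither term precisely, both conventions are switchable:
#' `include_clips` counts soft/hard clip runs among the CIGAR instructions
#' (default TRUE), and `aligned_bases_mode` counts either read bases opposite
#' reference bases (`"opposite"`, M/=/X, default) or all read-consuming
#' bases (`"read"`, adds I and S).
#'
#' @param records alignment-record data.frame (see [align_reads()]);
#'   unaligned records are removed first.
#' @param threshold natural-log threshold, inclusive.
#' @param include_clips count clip runs in `CigarInstructions`.
#' @param aligned_bases_mode `"opposite"` or `"read"`.
#' @return the retained records with added columns `aligned_bases`,
#'   `cigar_instructions` (recomputed under the chosen convention) and
#'   `ln_ratio`; attribute `"counts"` holds retained/removed totals, and
#'   attribute `"report"` the per-record QC table for all input records.
#' @export
quality_filter <- function(records, threshold = 4,
                           include_clips = TRUE,
                           aligned_bases_mode = c("opposite", "read")) {
  aligned_bases_mode <- match.arg(aligned_bases_mode)
  records <- records[records$aligned %in% TRUE, , drop = FALSE]
  if (nrow(records)) {
    stats <- lapply(records$cigar, function(cg) {
      ops <- parse_cigar(cg)
      keep_ops <- if (include_clips) ops else ops[!ops$op %in% c("S", "H"), , drop = FALSE]
      ab_ops <- if (aligned_bases_mode == "opposite") c("M", "=", "X")
                else c("M", "=", "X", "I", "S")
      c(ab = sum(ops$len[ops$op %in% ab_ops]), ni = nrow(keep_ops))
    })
    records$aligned_bases <- vapply(stats, `[[`, 0, "ab")
    records$cigar_instructions <- vapply(stats, `[[`, 0, "ni")
  }
  invalid <- records$cigar_instructions == 0
  if (any(invalid)) message(sum(invalid), " record(s) with zero CIGAR instructions rejected")
  records$ln_ratio <- ifelse(records$cigar_instructions > 0,
                             log(records$aligned_bases / records$cigar_instructions),
                             NA_real_)
  records$retained <- !invalid & is.finite(records$ln_ratio) &
    records$ln_ratio >= threshold
  report <- records
  out <- records[records$retained, , drop = FALSE]
  attr(out, "counts") <- c(retained = nrow(out), removed = nrow(report) - nrow(out))
  attr(out, "report") <- report
  out
}

#' Per-position base-presence matrix
#'
#' Builds the reads x transcript-positions indicator underlying a base
#' presence graph: a position is present in a read iff an aligned-base
#' CIGAR run (M/=/X) covers it; deletions and clips mark absence. The
#' per-position coverage fraction is the column mean.
#'
#' @param records alignment-record data.frame (typically after
#'   [quality_filter()]).
#' @param model a [transcript_model()].
#' @return object of class `presence_matrix`: list with `matrix` (logical,
#'   reads x positions, rownames = read ids) and `coverage` (numeric vector;
#'   all-NA when there are no reads).
#' @export
presence_matrix <- function(records, model) {
  L <- nchar(model$sequence)
  n <- nrow(records)
  m <- matrix(FALSE, nrow = n, ncol = L,
              dimnames = list(records$read_id, NULL))
  for (i in seq_len(n)) {
    pos <- records$ref_start[i]
    ops <- parse_cigar(records$cigar[i])
    for (j in seq_len(nrow(ops))) {
      if (ops$op[j] %in% c("M", "=", "X")) {
        m[i, (pos + 1L):min(L, pos + ops$len[j])] <- TRUE
        pos <- pos + ops$len[j]
      } else if (ops$op[j] %in% c("D", "N")) {
        pos <- pos + ops$len[j]
      }
    }
  }
  structure(list(matrix = m,
                 coverage = if (n) colMeans(m) else rep(NA_real_, L)),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("Base-presence matrix:", nrow(x$matrix), "reads x",
      ncol(x$matrix), "positions\n")
  if (nrow(x$matrix))
    cat("  mean coverage fraction:", round(mean(x$coverage), 3), "\n")
  invisible(x)
}

#' Export the per-record QC table
#' @param filtered result of [quality_filter()].
#' @param path output TSV.
#' @export
write_qc_table <- function(filtered, path) {
  rep <- attr(filtered, "report")
  utils::write.table(
    rep[, c("read_id", "aligned_bases", "cigar_instructions", "ln_ratio", "retained")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
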