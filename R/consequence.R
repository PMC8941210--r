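#' Coding consequence of a splice-event spec
#'
#' Sums the deleted CDS length across the spec's events; divisibility by 3
#' decides in-frame versus frameshift. In-frame events report the number of
#' amino acids removed (deleted CDS length / 3, sequence-level: a deletion
#' splitting two codons that re-fuse in frame still counts length/3 codons).
#' Events overlapping the CDS start or end are reported as truncating;
#' events entirely outside the CDS as non-coding.
#'
#' @param spec an [isoform_spec()].
#' @param model a [transcript_model()] with a declared CDS.
#' @return object of class `consequence_report`: list with `status`
#'   (`"in_frame"`, `"frameshift"`, `"truncating"`, `"non_coding"`,
#'   `"reference"`), `in_frame`, `aa_removed`, `frameshift_codon`,
#'   `deleted_cds_length`, `cds_interval`.
#' @export
frame_consequence <- function(spec, model) {
  if (is.null(model$cds_start)) stop("annotation error: model has no declared CDS")
  iv <- deleted_intervals(spec, model)
  cs <- model$cds_start; ce <- model$cds_end
  mk <- function(status, in_frame = NA, aa = NA_integer_, fs = NA_integer_, del = 0L)
    structure(list(status = status, in_frame = in_frame, aa_removed = aa,
                   frameshift_codon = fs, deleted_cds_length = del,
                   cds_interval = c(cs, ce)), class = "consequence_report")
  if (nrow(iv) == 0L) return(mk("reference", in_frame = TRUE, aa = 0L))
  crosses <- (iv$start < cs & iv$end > cs) | (iv$start < ce & iv$end > ce)
  if (any(crosses)) return(mk("truncating"))
  ov_start <- pmax(iv$start, cs); ov_end <- pmin(iv$end, ce)
  del <- sum(pmax(0L, ov_end - ov_start))
  if (del == 0L) return(mk("non_coding", in_frame = TRUE, aa = 0L, del = 0L))
  if (del %% 3L == 0L) return(mk("in_frame", in_frame = TRUE,
                                 aa = del %/% 3L, del = del))
  first <- min(ov_start[ov_end > ov_start])
  mk("frameshift", in_frame = FALSE,
     fs = as.integer((first - cs) %/% 3L + 1L), del = del)
}

#' @export
print.consequence_report <- function(x, ...) {
  cat("Coding consequence:", x$status, "\n")
  if (isTRUE(x$in_frame) && x$status %in% c("in_frame", "reference"))
    cat("  amino acids removed:", x$aa_removed, "\n")
  if (x$status == "frameshift")
    cat("  frameshift at codon:", x$frameshift_codon, "\n")
  invisible(x)
}

#' Predict an in-silico RT-PCR amplicon length
#'
#' The product length is the primer-span length minus the parts of the
#' spec's deletions lying inside the span. A deletion covering a primer
#' site (the outermost `primer_length` bases at each end of the span) means
#' the primer cannot anneal: the outcome is "no product" (`NA` length), not
#' an error. A deletion only partially inside the span has its overlapping
#' portion subtracted, with a warning.
#'
#' @param primer_span numeric `c(start, end)` on the full transcript
#'   (0-based half-open).
#' @param spec an [isoform_spec()].
#' @param model a [transcript_model()].
#' @param primer_length width of each primer site in nt.
#' @return list with `product_length` (NA when no product) and `outcome`
#'   (`"product"` / `"no_product"`).
#' @export
predict_amplicon <- function(primer_span, spec, model, primer_length = 1L) {
  s <- as.integer(primer_span[1L]); e <- as.integer(primer_span[2L])
  if (s < 0L || e <= s || e > nchar(model$sequence))
    stop("input error: invalid primer span")
  iv <- deleted_intervals(spec, model)
  span_len <- e - s
  if (nrow(iv) == 0L)
    return(list(product_length = span_len, outcome = "product"))
  left_primer <- c(s, s + primer_length)
  right_primer <- c(e - primer_length, e)
  hits_primer <- (iv$start < left_primer[2L] & iv$end > left_primer[1L]) |
    (iv$start < right_primer[2L] & iv$end > right_primer[1L])
  if (any(hits_primer))
    return(list(product_length = NA_integer_, outcome = "no_product"))
  ov <- pmax(0L, pmin(iv$end, e) - pmax(iv$start, s))
  partial <- ov > 0L & (iv$start < s | iv$end > e)
  if (any(partial))
    warning("deletion(s) partially overlapping the primer span; overlapping portion subtracted")
  list(product_length = span_len - sum(ov), outcome = "product")
}

#' Percent exon skipping (PSI) with a Wilson confidence interval
#'
#' Percent skipping = 100 x (reads called skipping) / (reads spanning the
#' exon plus margins). The 95% Wilson score interval is attached (an
#' addition beyond the detection rules themselves, labelled as such in the
#' output).
#'
#' @param calls data.frame from [classify_reads()].
#' @param exon_index exon ordinal to summarize.
#' @return data.frame: `exon_index`, `n_skip`, `n_span`, `psi_percent`,
#'   `ci_lower`, `ci_upper` (Wilson 95%); `psi_percent` is `NA` with a
#'   message when no read spans the exon.
#' @export
estimate_psi <- function(calls, exon_index) {
  sel <- calls$exon_from <= exon_index & calls$exon_to >= exon_index
  sub <- calls[sel & calls$spanning %in% TRUE, , drop = FALSE]
  n <- length(unique(sub$read_id))
  k <- length(unique(sub$read_id[sub$skip_call]))
  if (n == 0L) {
    message("no reads span exon ", exon_index, "; PSI undefined")
    return(data.frame(exon_index = exon_index, n_skip = 0L, n_span = 0L,
                      psi_percent = NA_real_, ci_lower = NA_real_,
                      ci_upper = NA_real_))
  }
  ci <- stats::prop.test(k, n, correct = FALSE)$conf.int  # Wilson score interval
  data.frame(exon_index = exon_index, n_skip = k, n_span = n,
             psi_percent = 100 * k / n,
             ci_lower = 100 * ci[1L], ci_upper = 100 * ci[2L])
}
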