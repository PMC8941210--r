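#' Synthetic LARS-like transcript model
#'
#' Builds a deterministic synthetic transcript emulating the scale of the
#' human leucyl-tRNA synthetase (LARS) mRNA: 33 coding exons tiling a 3,900 nt
#' sequence, with exon 20 exactly 213 nt so that skipping it is in-frame and
#' removes 71 codons. The sequence is random but fixed by `seed`, so the
#' fixture is reproducible without shipping any data file. The CDS spans the
#' whole transcript.
#'
#' @param seed integer fixing the exon-length draw and the sequence.
#' @param n_exons number of exons.
#' @param total_length transcript length in nt.
#' @param target_exon ordinal of the fixed-length exon.
#' @param target_exon_length its length in nt.
#' @return a [transcript_model()].
#' @export
lars_demo_model <- function(seed = 20L, n_exons = 33L, total_length = 3900L,
                            target_exon = 20L, target_exon_length = 213L) {
  stopifnot(n_exons >= 2L, target_exon >= 1L, target_exon <= n_exons,
            total_length %% 3L == 0L)
  rest <- total_length - target_exon_length
  with_local_seed(seed, {
    raw <- sample(50:220, n_exons - 1L, replace = TRUE)
    lens <- pmax(40L, as.integer(round(raw * rest / sum(raw))))
    lens[length(lens)] <- lens[length(lens)] + (rest - sum(lens))
    lens <- append(lens, target_exon_length, after = target_exon - 1L)
    sequence <- paste(sample(c("A", "C", "G", "T"), total_length, replace = TRUE),
                      collapse = "")
    ends <- cumsum(lens)
    exons <- data.frame(exon_index = seq_len(n_exons),
                        start = ends - lens, end = ends)
    transcript_model("SYN_LARS_LIKE", sequence, exons,
                     cds_start = 0L, cds_end = total_length)
  })
}

#' Primer span around an exon
#'
#' Returns a primer span of the requested length centred on an exon, i.e. the
#' transcript interval an RT-PCR amplicon would cover, for use with
#' [predict_amplicon()].
#'
#' @param model a [transcript_model()].
#' @param exon_index target exon ordinal.
#' @param span_length amplicon span in nt (must exceed the exon length).
#' @return integer vector `c(start, end)`, 0-based half-open.
#' @export
primer_span_around_exon <- function(model, exon_index = 20L, span_length = 721L) {
  idx <- match(exon_index, model$exons$exon_index)
  if (is.na(idx)) stop("annotation error: exon not in model")
  ex <- model$exons[idx, ]
  flank <- span_length - ex$length
  if (flank < 2L) stop("spec error: span shorter than exon plus primers")
  start <- ex$start - flank %/% 2L
  start <- max(0L, min(start, nchar(model$sequence) - span_length))
  c(start = start, end = start + span_length)
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
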