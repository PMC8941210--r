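#' Default pipeline parameters
#'
#' All stage thresholds in one place: alignment-quality filter threshold
#' (ln-ratio 4), event retention TotalScore (1), per-read interior-unaligned
#' threshold (0.80), pooled-margin aligned threshold (0.50), margin width
#' (0.20 of the candidate deletion), minimum partial-event support (4
#' reads), endpoint merge distance (3 nt), island bridge width (3 nt) and
#' minimum candidate gap length (20 nt).
#'
#' @return named list of parameters.
#' @export
pipeline_params <- function() {
  list(filter_threshold = 4, retention_threshold = 1,
       interior_threshold = 0.80, margin_threshold = 0.50,
       margin_width_frac = 0.20, min_support = 4L,
       merge_distance = 3L, max_island = 3L, min_gap = 20L,
       min_score = 0, include_clips = TRUE, pooled_margins = TRUE)
}

#' Run the full exon-skipping detection pipeline
#'
#' Align (or ingest) reads, apply the alignment-quality filter, build the
#' base-presence matrix, extract and bridge deletion gaps, score them
#' against exon boundaries, aggregate and retain skipping events, classify
#' reads, catalog isoforms, detect partial events, annotate coding
#' consequences, and estimate percent skipping per affected exon. All
#' tables are written to `out_dir` (TSV; 1-based inclusive coordinates)
#' together with a machine-readable JSON manifest of every parameter and
#' input checksum.
#'
#' @param model a [transcript_model()].
#' @param reads a [Biostrings::DNAStringSet], a FASTA path, or `NULL` when
#'   `sam` is given.
#' @param sam optional SAM/BAM path used instead of internal alignment.
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @param params list from [pipeline_params()] (partial overrides allowed).
#' @param scoring aligner scoring (see [default_scoring()]).
#' @return object of class `splicegap_run`: list of all result tables,
#'   stage drop counts and the parameters used.
#' @export
run_pipeline <- function(model, reads = NULL, sam = NULL, out_dir = NULL,
                         params = list(), scoring = default_scoring()) {
  p <- utils::modifyList(pipeline_params(), params)
  if (is.null(reads) && is.null(sam)) stop("input error: supply reads or a SAM/BAM file")
  if (!is.null(sam)) {
    records <- read_sam(sam, model)
  } else {
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
      reads <- Biostrings::readDNAStringSet(reads)
    records <- align_reads(reads, model, scoring = scoring, min_score = p$min_score)
  }
  n_unaligned <- sum(!records$aligned)
  filtered <- quality_filter(records, threshold = p$filter_threshold,
                             include_clips = p$include_clips)
  presence <- presence_matrix(filtered, model)
  gaps <- extract_gaps(filtered, min_gap = p$min_gap)
  bridged <- bridge_islands(gaps, max_island = p$max_island)
  bridged <- snap_gaps_to_boundaries(bridged, model)
  scored <- score_gaps(bridged, model)
  events <- aggregate_skip_events(scored, retention_threshold = p$retention_threshold)
  calls <- classify_reads(presence, model, events,
                          interior_threshold = p$interior_threshold,
                          margin_threshold = p$margin_threshold,
                          margin_width_frac = p$margin_width_frac,
                          pooled_margins = p$pooled_margins)
  partials <- find_partial_candidates(bridged, model,
                                      min_support = p$min_support,
                                      max_endpoint_dist = p$merge_distance)
  flags <- read_feature_flags(filtered, bridged, model, partials,
                              min_gap = p$min_gap,
                              merge_distance = p$merge_distance)
  cooc <- cooccurrence_table(calls, flags)
  catalog <- catalog_isoforms(calls)
  consequences <- if (nrow(events) && !is.null(model$cds_start)) {
    do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
      sp <- isoform_spec(skipped_exons = events$exon_from[i]:events$exon_to[i])
      cq <- frame_consequence(sp, model)
      data.frame(span = events$span[i], status = cq$status,
                 in_frame = isTRUE(cq$in_frame), aa_removed = cq$aa_removed,
                 deleted_cds_length = cq$deleted_cds_length,
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(span = character(), status = character(),
                    in_frame = logical(), aa_removed = integer(),
                    deleted_cds_length = integer(), stringsAsFactors = FALSE)
  exons_hit <- if (nrow(events))
    sort(unique(unlist(mapply(seq, events$exon_from, events$exon_to,
                              SIMPLIFY = FALSE)))) else integer(0)
  psi <- if (length(exons_hit))
    do.call(rbind, lapply(exons_hit, function(e) estimate_psi(calls, e)))
  else data.frame(exon_index = integer(), n_skip = integer(), n_span = integer(),
                  psi_percent = numeric(), ci_lower = numeric(), ci_upper = numeric())
  run <- structure(list(
    model_name = model$name, params = p,
    n_records = nrow(records), n_unaligned = n_unaligned,
    qc_counts = attr(filtered, "counts"),
    records = records, filtered = filtered, presence = presence,
    gaps = bridged, scored_gaps = scored, events = events, calls = calls,
    catalog = catalog, partials = partials, cooccurrence = cooc,
    consequences = consequences, psi = psi), class = "splicegap_run")
  if (!is.null(out_dir)) write_run(run, out_dir, model)
  run
}

# Write every result table plus the manifest.
write_run <- function(run, out_dir, model) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- run$events
  w(ev, "events.tsv")
  calls <- run$calls
  w(calls, "read_calls.tsv")
  w(run$catalog, "catalog.tsv")
  write_partials_table(run$partials, file.path(out_dir, "partials.tsv"))
  w(run$consequences, "consequences.tsv")
  w(run$psi, "psi.tsv")
  cooc_df <- as.data.frame(run$cooccurrence)
  w(cooc_df, "cooccurrence.tsv")
  write_qc_table(run$filtered, file.path(out_dir, "qc.tsv"))
  manifest <- list(
    package = "splicegap",
    version = as.character(utils::packageVersion("splicegap")),
    r_version = R.version.string,
    model = list(name = model$name, length = nchar(model$sequence),
                 n_exons = nrow(model$exons),
                 sequence_md5 = unname(tools::md5sum(
                   write_reference_fasta(model, tempfile(fileext = ".fa"))))),
    parameters = run$params,
    counts = list(records = run$n_records, unaligned = run$n_unaligned,
                  qc_retained = unname(run$qc_counts["retained"]),
                  qc_removed = unname(run$qc_counts["removed"])))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.splicegap_run <- function(x, ...) {
  cat("splicegap run on", x$model_name, "\n")
  cat("  alignments:", x$n_records, "(", x$n_unaligned, "unaligned;",
      x$qc_counts["removed"], "failed QC )\n")
  cat("  skip events retained:", nrow(x$events), "\n")
  cat("  partial events:", nrow(x$partials), "\n")
  cat("  isoform catalog entries:", nrow(x$catalog), "\n")
  invisible(x)
}

#' @export
summary.splicegap_run <- function(object, ...) {
  cat("== splicegap run summary ==\n")
  print(object)
  if (nrow(object$events)) {
    cat("\nTop events (span, TotalScore, reads):\n")
    print(utils::head(object$events, 5))
  }
  if (nrow(object$psi)) {
    cat("\nPercent skipping per affected exon:\n")
    print(object$psi)
  }
  if (nrow(object$catalog)) {
    cat("\nIsoform catalog:\n")
    print(object$catalog)
  }
  invisible(object)
}

#' Plot per-position coverage (base-presence) fractions
#'
#' @param x a `splicegap_run`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.splicegap_run <- function(x, ...) {
  cov <- x$presence$coverage
  graphics::plot(seq_along(cov), cov, type = "l", xlab = "transcript position",
                 ylab = "coverage fraction", ylim = c(0, 1), ...)
  invisible(x)
}
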