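#' Extract deletion gaps from an alignment record set
#'
#' One gap per deletion CIGAR run of at least `min_gap` nt, in transcript
#' coordinates (0-based half-open). Shorter deletions are treated as
#' sequencing error, far below the smallest real exon.
#'
#' @param records alignment-record data.frame (after [quality_filter()]).
#' @param min_gap minimum deletion length to report (nt).
#' @return data.frame with `read_id`, `start`, `end`.
#' @export
extract_gaps <- function(records, min_gap = 20L) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    pos <- records$ref_start[i]
    ops <- parse_cigar(records$cigar[i])
    for (j in seq_len(nrow(ops))) {
      op <- ops$op[j]; len <- ops$len[j]
      if (op %in% c("D", "N")) {
        if (len >= min_gap)
          out[[length(out) + 1L]] <- data.frame(
            read_id = records$read_id[i], start = pos, end = pos + len,
            stringsAsFactors = FALSE)
        pos <- pos + len
      } else if (op %in% c("M", "=", "X")) pos <- pos + len
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(read_id = character(), start = integer(), end = integer(),
                  stringsAsFactors = FALSE)
}

#' Normalize ambiguous deletion placements toward exon boundaries
#'
#' When the bases flanking a deletion repeat across the junction, the
#' optimal alignment can place the gap anywhere in a window of
#' score-equivalent positions (the usual indel left/right-shift ambiguity).
#' Among the equivalent placements this picks the one minimizing the total
#' offset to the nearest annotated exon boundaries (ties to the leftmost),
#' so that genuine splice junctions are reported boundary-exact whenever an
#' equivalent placement allows it. Placements that are not score-equivalent
#' are never altered.
#'
#' @param gaps data.frame from [extract_gaps()].
#' @param model a [transcript_model()].
#' @param max_shift maximum shift explored in either direction (nt).
#' @return the gap table with adjusted `start`/`end`.
#' @export
snap_gaps_to_boundaries <- function(gaps, model, max_shift = 10L) {
  if (nrow(gaps) == 0L) return(gaps)
  chars <- strsplit(model$sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  for (i in seq_len(nrow(gaps))) {
    s <- gaps$start[i]; e <- gaps$end[i]
    kl <- 0L
    while (kl < max_shift && s - kl - 1L >= 0L &&
           chars[s - kl] == chars[e - kl]) kl <- kl + 1L
    kr <- 0L
    while (kr < max_shift && e + kr + 1L <= L &&
           chars[e + kr + 1L] == chars[s + kr + 1L]) kr <- kr + 1L
    if (kl == 0L && kr == 0L) next
    shifts <- (-kl):kr
    cost <- vapply(shifts, function(k) {
      nb <- nearest_boundaries(s + k, e + k, model)
      nb$start_offset + nb$end_offset
    }, 0)
    best <- shifts[which.min(cost)]  # which.min ties to the leftmost shift
    gaps$start[i] <- s + best; gaps$end[i] <- e + best
  }
  gaps
}

#' Gap-quality score of one deletion
#'
#' `(1 + |Start - NearExonStart| + |End - NearExonEnd|)^(-1/2)`: a deletion
#' whose endpoints coincide with annotated exon boundaries scores exactly 1;
#' the score decays with the total boundary offset, down-weighting gaps that
#' look like alignment noise rather than splicing.
#'
#' @param gap_start,gap_end deletion interval (0-based half-open).
#' @param model a [transcript_model()].
#' @return list with `score`, `start_offset`, `end_offset`, `exon_from`,
#'   `exon_to`, `span`.
#' @export
score_gap <- function(gap_start, gap_end, model) {
  nb <- nearest_boundaries(gap_start, gap_end, model)
  nb$score <- (1 + nb$start_offset + nb$end_offset)^(-0.5)
  nb
}

#' Score a table of gaps against exon boundaries
#'
#' @param gaps data.frame from [extract_gaps()].
#' @param model a [transcript_model()].
#' @return the gap table with `near_start`, `near_end`, `start_offset`,
#'   `end_offset`, `exon_from`, `exon_to`, `span` (label `"a-b"`) and
#'   `score` columns appended.
#' @export
score_gaps <- function(gaps, model) {
  if (nrow(gaps) == 0L) {
    for (col in c("near_start", "near_end", "start_offset", "end_offset",
                  "exon_from", "exon_to", "score"))
      gaps[[col]] <- numeric(0)
    gaps$span <- character(0)
    return(gaps)
  }
  sc <- lapply(seq_len(nrow(gaps)),
               function(i) score_gap(gaps$start[i], gaps$end[i], model))
  gaps$near_start <- vapply(sc, `[[`, 0, "near_start")
  gaps$near_end <- vapply(sc, `[[`, 0, "near_end")
  gaps$start_offset <- vapply(sc, `[[`, 0, "start_offset")
  gaps$end_offset <- vapply(sc, `[[`, 0, "end_offset")
  gaps$exon_from <- vapply(sc, `[[`, 0L, "exon_from")
  gaps$exon_to <- vapply(sc, `[[`, 0L, "exon_to")
  gaps$span <- paste0(gaps$exon_from, "-", gaps$exon_to)
  gaps$score <- vapply(sc, `[[`, 0, "score")
  gaps
}

#' Aggregate scored gaps into exon-skipping events
#'
#' Gaps are grouped by their implied exon span; per-gap scores are summed
#' into a TotalScore and events with TotalScore below `retention_threshold`
#' (default 1) are discarded, so an event needs either one boundary-exact
#' gap or enough noisy support to survive.
#'
#' @param scored_gaps data.frame from [score_gaps()].
#' @param retention_threshold minimum TotalScore to retain an event.
#' @return data.frame sorted by TotalScore descending: `span`, `exon_from`,
#'   `exon_to`, `total_score`, `n_gaps`, `n_reads`.
#' @export
aggregate_skip_events <- function(scored_gaps, retention_threshold = 1) {
  empty <- data.frame(span = character(), exon_from = integer(),
                      exon_to = integer(), total_score = numeric(),
                      n_gaps = integer(), n_reads = integer(),
                      stringsAsFactors = FALSE)
  # a gap whose nearest end-boundary precedes its nearest start-boundary
  # implies no exon span: junction-hugging noise, never a skip candidate
  scored_gaps <- scored_gaps[scored_gaps$exon_to >= scored_gaps$exon_from, ,
                             drop = FALSE]
  if (nrow(scored_gaps) == 0L) return(empty)
  sp <- split(scored_gaps, scored_gaps$span)
  ev <- do.call(rbind, lapply(sp, function(g) data.frame(
    span = g$span[1L], exon_from = g$exon_from[1L], exon_to = g$exon_to[1L],
    total_score = sum(g$score), n_gaps = nrow(g),
    n_reads = length(unique(g$read_id)), stringsAsFactors = FALSE)))
  ev <- ev[ev$total_score >= retention_threshold, , drop = FALSE]
  ev <- ev[order(-ev$total_score), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# Candidate deletion interval and margins for an exon span (0-based).
span_interval <- function(model, exon_from, exon_to,
                          margin_width_frac = 0.20) {
  i <- match(exon_from, model$exons$exon_index)
  j <- match(exon_to, model$exons$exon_index)
  if (is.na(i) || is.na(j) || j < i) stop("annotation error: bad exon span")
  d_start <- model$exons$start[i]
  d_end <- model$exons$end[j]
  w <- max(1L, as.integer(round(margin_width_frac * (d_end - d_start))))
  L <- nchar(model$sequence)
  list(d_start = d_start, d_end = d_end, width = w,
       left = c(max(0L, d_start - w), d_start),
       right = c(d_end, min(L, d_end + w)))
}

#' Classify reads for exon skipping by interior/margin base presence
#'
#' A read is called as skipping a candidate exon span iff at least
#' `interior_threshold` (default 80%) of positions inside the span have no
#' aligned base and at least `margin_threshold` (default half) of the
#' positions in the margins around the potential deletion have an aligned
#' base, each margin being `margin_width_frac` (default 20%) of the span
#' length. Reads whose alignment does not cover the span plus both margins
#' cannot testify either way and are excluded from the denominator
#' (`spanning = FALSE`).
#'
#' @param presence a [presence_matrix()].
#' @param model a [transcript_model()].
#' @param events event data.frame from [aggregate_skip_events()] (columns
#'   `exon_from`, `exon_to`); each row defines one candidate deletion.
#' @param interior_threshold minimum unaligned fraction inside the span.
#' @param margin_threshold minimum aligned fraction in the margins.
#' @param margin_width_frac margin width as a fraction of the span length.
#' @param pooled_margins if `TRUE` (default) the aligned fraction is pooled
#'   over both margins; otherwise each margin must pass on its own.
#' @return data.frame with one row per (read, span): `read_id`, `span`,
#'   `exon_from`, `exon_to`, `spanning`, `interior_unaligned_frac`,
#'   `margin_aligned_frac`, `skip_call`.
#' @export
classify_reads <- function(presence, model, events,
                           interior_threshold = 0.80,
                           margin_threshold = 0.50,
                           margin_width_frac = 0.20,
                           pooled_margins = TRUE) {
  m <- presence$matrix
  empty <- data.frame(read_id = character(), span = character(),
                      exon_from = integer(), exon_to = integer(),
                      spanning = logical(), interior_unaligned_frac = numeric(),
                      margin_aligned_frac = numeric(), skip_call = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(m) == 0L || nrow(events) == 0L) return(empty)
  first_aln <- apply(m, 1L, function(r) if (any(r)) which(r)[1L] - 1L else NA_integer_)
  last_aln <- apply(m, 1L, function(r) if (any(r)) max(which(r)) else NA_integer_)
  out <- list()
  for (e in seq_len(nrow(events))) {
    si <- span_interval(model, events$exon_from[e], events$exon_to[e],
                        margin_width_frac)
    int_idx <- (si$d_start + 1L):si$d_end
    l_idx <- if (si$left[2L] > si$left[1L]) (si$left[1L] + 1L):si$left[2L] else integer(0)
    r_idx <- if (si$right[2L] > si$right[1L]) (si$right[1L] + 1L):si$right[2L] else integer(0)
    if (!length(l_idx) && !length(r_idx)) {
      message("span ", events$exon_from[e], "-", events$exon_to[e],
              ": margins outside transcript; reads excluded")
      next
    }
    spanning <- !is.na(first_aln) & first_aln <= min(c(l_idx, int_idx)) - 1L &
      last_aln >= max(c(r_idx, int_idx))
    int_unal <- rowMeans(!m[, int_idx, drop = FALSE])
    if (pooled_margins) {
      mar_al <- rowMeans(m[, c(l_idx, r_idx), drop = FALSE])
      mar_ok <- mar_al >= margin_threshold
    } else {
      la <- if (length(l_idx)) rowMeans(m[, l_idx, drop = FALSE]) else 1
      ra <- if (length(r_idx)) rowMeans(m[, r_idx, drop = FALSE]) else 1
      mar_al <- (la + ra) / 2
      mar_ok <- la >= margin_threshold & ra >= margin_threshold
    }
    out[[length(out) + 1L]] <- data.frame(
      read_id = rownames(m), span = paste0(events$exon_from[e], "-", events$exon_to[e]),
      exon_from = events$exon_from[e], exon_to = events$exon_to[e],
      spanning = spanning, interior_unaligned_frac = int_unal,
      margin_aligned_frac = mar_al,
      skip_call = spanning & int_unal >= interior_threshold & mar_ok,
      stringsAsFactors = FALSE)
  }
  if (length(out)) {
    res <- do.call(rbind, out); rownames(res) <- NULL; res
  } else empty
}

#' Catalog splice-variant isoforms from read calls
#'
#' Each distinct skip pattern (the set of exon ordinals a read skips) becomes
#' a catalog entry with its read count and percentage of classified reads.
#' Non-full-length patterns are labelled LSV1, LSV2, ... in descending count
#' order; the full-length pattern is reported separately as `FULL`.
#'
#' @param calls data.frame from [classify_reads()].
#' @param frame_flags optional named logical vector (pattern -> frameshift)
#'   appended as a `frameshift` column when supplied.
#' @return data.frame: `label`, `pattern`, `n_reads`, `pct`.
#' @export
catalog_isoforms <- function(calls, frame_flags = NULL) {
  empty <- data.frame(label = character(), pattern = character(),
                      n_reads = integer(), pct = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) return(empty)
  spl <- split(calls, calls$read_id)
  pat <- vapply(spl, function(g) {
    if (!any(g$spanning)) return(NA_character_)
    ex <- sort(unique(unlist(lapply(which(g$skip_call), function(i)
      g$exon_from[i]:g$exon_to[i]))))
    if (length(ex)) paste(ex, collapse = ",") else ""
  }, "")
  pat <- pat[!is.na(pat)]
  if (!length(pat)) return(empty)
  tab <- sort(table(pat), decreasing = TRUE)
  df <- data.frame(pattern = names(tab), n_reads = as.integer(tab),
                   pct = 100 * as.integer(tab) / length(pat),
                   stringsAsFactors = FALSE)
  full <- df$pattern == ""
  lab <- character(nrow(df))
  lab[full] <- "FULL"
  lab[!full] <- paste0("LSV", seq_len(sum(!full)))
  df$label <- lab
  df <- df[, c("label", "pattern", "n_reads", "pct")]
  if (!is.null(frame_flags))
    df$frameshift <- unname(frame_flags[df$pattern])
  rownames(df) <- NULL
  df
}

#' Co-occurrence of exon skipping with other splicing features
#'
#' Descriptive 2x2 contingency counts of the per-read skip call against a
#' per-read "any other alternative-splicing feature" flag (partial event,
#' off-boundary deletion, long insertion). No test statistic is computed.
#'
#' @param calls data.frame from [classify_reads()].
#' @param other_flags named logical vector (read_id -> other-feature flag).
#' @return 2x2 integer table (skip x other feature).
#' @export
cooccurrence_table <- function(calls, other_flags) {
  reads <- unique(calls$read_id[calls$spanning %in% TRUE])
  skip <- vapply(reads, function(r)
    any(calls$skip_call[calls$read_id == r]), TRUE)
  other <- other_flags[reads]
  other[is.na(other)] <- FALSE
  table(skip = factor(skip, c(FALSE, TRUE)),
        other_feature = factor(other, c(FALSE, TRUE)))
}

#' Per-read flags for non-skipping splice features
#'
#' Flags a read when one of its deletion gaps supports a reported partial
#' event (endpoints within `merge_distance` nt of a support-filtered
#' candidate from [find_partial_candidates()]) or when it carries an
#' insertion run of at least `min_gap` nt. Isolated off-boundary gaps
#' without event-level support are treated as alignment noise, not as
#' splicing features.
#'
#' @param records alignment records (after [quality_filter()]).
#' @param gaps bridged gap table (see [bridge_islands()]).
#' @param model a [transcript_model()].
#' @param partials reported partial events (see [find_partial_candidates()]).
#' @param min_gap minimum insertion length flagged.
#' @param merge_distance endpoint radius for matching a partial event (nt).
#' @return named logical vector over `records$read_id`.
#' @export
read_feature_flags <- function(records, gaps, model, partials = NULL,
                               min_gap = 20L, merge_distance = 3L) {
  flags <- stats::setNames(rep(FALSE, nrow(records)), records$read_id)
  if (!is.null(partials) && nrow(partials) && nrow(gaps)) {
    for (i in seq_len(nrow(gaps))) {
      hit <- any(abs(gaps$start[i] - partials$start) <= merge_distance &
                   abs(gaps$end[i] - partials$end) <= merge_distance)
      if (hit) flags[gaps$read_id[i]] <- TRUE
    }
  }
  for (i in seq_len(nrow(records))) {
    ops <- parse_cigar(records$cigar[i])
    if (any(ops$op == "I" & ops$len >= min_gap)) flags[records$read_id[i]] <- TRUE
  }
  flags
}
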