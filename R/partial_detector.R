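#' Bridge small aligned islands between deletions within a read
#'
#' Two deletions in the same read separated by an aligned island of at most
#' `max_island` bases (default 3) merge into one deletion spanning both,
#' absorbing the sequencing/alignment errors that split a single splice
#' deletion. Applied iteratively left-to-right until stable.
#'
#' @param gaps data.frame from [extract_gaps()] (any number of reads).
#' @param max_island maximum island width bridged (nt).
#' @return merged gap data.frame (`read_id`, `start`, `end`).
#' @export
bridge_islands <- function(gaps, max_island = 3L) {
  if (nrow(gaps) == 0L) return(gaps)
  out <- lapply(split(gaps, gaps$read_id), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    starts <- g$start[1L]; ends <- g$end[1L]
    for (i in seq_len(nrow(g))[-1L]) {
      island <- g$start[i] - ends[length(ends)]
      if (island <= max_island) {
        ends[length(ends)] <- max(ends[length(ends)], g$end[i])
      } else {
        starts <- c(starts, g$start[i]); ends <- c(ends, g$end[i])
      }
    }
    data.frame(read_id = g$read_id[1L], start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# For each gap, whether each endpoint sits on an annotated boundary
# (within tol nt). Starts are compared to exon starts, ends to exon ends.
endpoint_on_boundary <- function(gaps, model, tol = 0L) {
  ex <- model$exons
  start_on <- vapply(gaps$start, function(s) any(abs(s - ex$start) <= tol), TRUE)
  end_on <- vapply(gaps$end, function(e) any(abs(e - ex$end) <= tol), TRUE)
  list(start_on = start_on, end_on = end_on)
}

#' Detect alternative 3'/5' splice-site (partial exon-skipping) events
#'
#' A deletion is a partial-event candidate iff exactly one endpoint
#' coincides (within `boundary_tol`, default 0) with an annotated exon
#' boundary. Candidates whose respective endpoints lie at most
#' `max_endpoint_dist` nt apart (both start-start and end-end) are merged
#' into clusters by transitive closure; each cluster's interval is the modal
#' (start, end) pair among members (ties to the smallest coordinates).
#' Clusters supported by fewer than `min_support` distinct reads are
#' discarded.
#'
#' @param gaps island-bridged gap data.frame (see [bridge_islands()]).
#' @param model a [transcript_model()].
#' @param boundary_tol tolerance for "at a boundary" (nt).
#' @param min_support minimum distinct supporting reads.
#' @param max_endpoint_dist merge radius on each endpoint (nt).
#' @return data.frame of partial events: `start`, `end`, `n_members`,
#'   `support`, `start_at_boundary`, `end_at_boundary`, `nearest_exon`,
#'   `boundary_offset`. Attribute `"other"` carries gaps with both
#'   endpoints off-boundary (logged, not reported as partial events).
#' @export
find_partial_candidates <- function(gaps, model, boundary_tol = 0L,
                                    min_support = 4L, max_endpoint_dist = 3L) {
  empty <- data.frame(start = integer(), end = integer(), n_members = integer(),
                      support = integer(), start_at_boundary = logical(),
                      end_at_boundary = logical(), nearest_exon = integer(),
                      boundary_offset = integer(), stringsAsFactors = FALSE)
  if (nrow(gaps) == 0L) { attr(empty, "other") <- gaps; return(empty) }
  onb <- endpoint_on_boundary(gaps, model, boundary_tol)
  is_partial <- xor(onb$start_on, onb$end_on)
  other <- gaps[!onb$start_on & !onb$end_on, , drop = FALSE]
  if (nrow(other))
    message(nrow(other), " deletion(s) with both endpoints off-boundary logged as other features")
  cand <- gaps[is_partial, , drop = FALSE]
  if (nrow(cand) == 0L) { attr(empty, "other") <- other; return(empty) }
  comp <- endpoint_clusters(cand$start, cand$end, max_endpoint_dist)
  res <- do.call(rbind, lapply(split(seq_len(nrow(cand)), comp), function(idx) {
    g <- cand[idx, , drop = FALSE]
    key <- paste(g$start, g$end)
    tab <- table(key)
    best <- names(tab)[tab == max(tab)]
    ord <- order(as.integer(sub(" .*", "", best)), as.integer(sub(".* ", "", best)))
    modal <- as.integer(strsplit(best[ord][1L], " ")[[1L]])
    onb1 <- endpoint_on_boundary(data.frame(start = modal[1L], end = modal[2L]),
                                 model, boundary_tol)
    nb <- nearest_boundaries(modal[1L], modal[2L], model)
    off <- if (onb1$start_on) nb$end_offset else nb$start_offset
    nearest <- if (onb1$start_on) nb$exon_to else nb$exon_from
    data.frame(start = modal[1L], end = modal[2L], n_members = nrow(g),
               support = length(unique(g$read_id)),
               start_at_boundary = onb1$start_on, end_at_boundary = onb1$end_on,
               nearest_exon = nearest, boundary_offset = off,
               stringsAsFactors = FALSE)
  }))
  res <- res[res$support >= min_support, , drop = FALSE]
  # A merged interval must itself have exactly one off-boundary endpoint.
  bad <- res$start_at_boundary == res$end_at_boundary
  if (any(bad)) {
    message(sum(bad), " merged candidate(s) lost the single-off-boundary property; dropped")
    res <- res[!bad, , drop = FALSE]
  }
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "other") <- other
  res
}

# Connected components under |dStart| <= d AND |dEnd| <= d (union-find).
endpoint_clusters <- function(starts, ends, d) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    if (abs(starts[i] - starts[j]) <= d && abs(ends[i] - ends[j]) <= d) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 0L)
}

#' Write the partial-events table (1-based inclusive coordinates)
#' @param partials data.frame from [find_partial_candidates()].
#' @param path output TSV.
#' @export
write_partials_table <- function(partials, path) {
  out <- partials
  if (nrow(out)) { out$start <- out$start + 1L }  # 1-based inclusive report
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
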