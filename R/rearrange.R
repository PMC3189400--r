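## Rearrangement detection: discordant mate-pair clusters, orientation
## segments along test-genome chromosomes, inversion calling, and recovery
## scoring against planted truth.

#' Attach test-genome ordering to anchored placements
#'
#' Orientation-segment scanning needs clones ordered along the test
#' genome's chromosomes.  That assignment comes from an independent source
#' (karyotype or genetic map in a real project; the simulator's clone truth
#' table here), not from the reference alignments being examined.
#'
#' @param anchored anchored placements from [anchor_bacs()].
#' @param clones clone truth table (id, chrom, start on the test genome).
#' @return anchored with `test_chrom` and `test_pos` columns.
#' @export
add_test_order <- function(anchored, clones) {
  i <- match(anchored$clone, clones$id)
  anchored$test_chrom <- clones$chrom[i]
  anchored$test_pos <- clones$start[i]
  anchored
}

#' Cluster discordant mate pairs
#'
#' Inconsistent mate pairs are grouped by discordance signature
#' (same-strand, distance/facing violation, inter-chromosomal) and by
#' proximity of both anchor loci (single linkage, both anchors within
#' `cluster_gap`).  Clusters below `min_support` are dropped but kept in
#' the `minor` attribute.
#'
#' @param statuses mate-pair status table.
#' @param cluster_gap single-linkage gap in bp applied at both anchors.
#' @param min_support minimum member count for a reported cluster.
#' @return data.frame of clusters: chrom_l, chrom_r, signature, strands,
#'   left_start, left_end, right_start, right_end, support, members.
#' @export
cluster_discordant <- function(statuses, cluster_gap = 5e4,
                               min_support = 3) {
  x <- statuses[statuses$status == "inconsistent" &
                  !is.na(statuses$a1_chrom), , drop = FALSE]
  empty <- data.frame(chrom_l = character(0), chrom_r = character(0),
                      signature = character(0), strands = character(0),
                      left_start = numeric(0), left_end = numeric(0),
                      right_start = numeric(0), right_end = numeric(0),
                      support = integer(0), members = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(x)) return(empty)
  ## orient anchors: left = smaller midpoint (or smaller chrom name)
  swap <- (x$a1_chrom > x$a2_chrom) |
    (x$a1_chrom == x$a2_chrom &
       (x$a1_start + x$a1_end) > (x$a2_start + x$a2_end))
  for (f in c("chrom", "start", "end", "strand")) {
    a <- x[[paste0("a1_", f)]]; b <- x[[paste0("a2_", f)]]
    x[[paste0("l_", f)]] <- ifelse(swap, b, a)
    x[[paste0("r_", f)]] <- ifelse(swap, a, b)
  }
  x$signature <- ifelse(x$l_chrom != x$r_chrom, "inter_chromosomal",
                        ifelse(x$l_strand == x$r_strand, "same_strand",
                               "distance_exceeded"))
  x$strands <- paste0(x$l_strand, x$r_strand)
  key <- paste(x$signature, x$strands, x$l_chrom, x$r_chrom)
  rows <- list()
  minor <- list()
  for (grp in split(x, key)) {
    lmid <- (grp$l_start + grp$l_end) / 2
    rmid <- (grp$r_start + grp$r_end) / 2
    n <- nrow(grp)
    adj <- outer(lmid, lmid, function(a, b) abs(a - b)) <= cluster_gap &
      outer(rmid, rmid, function(a, b) abs(a - b)) <= cluster_gap
    memb <- igraph::components(igraph::graph_from_adjacency_matrix(
      adj, mode = "undirected"))$membership
    for (cl in split(seq_len(n), memb)) {
      g <- grp[cl, , drop = FALSE]
      row <- data.frame(
        chrom_l = g$l_chrom[1], chrom_r = g$r_chrom[1],
        signature = g$signature[1], strands = g$strands[1],
        left_start = min(g$l_start), left_end = max(g$l_end),
        right_start = min(g$r_start), right_end = max(g$r_end),
        support = nrow(g),
        members = paste(sort(g$clone), collapse = ","),
        stringsAsFactors = FALSE)
      if (nrow(g) >= min_support) rows[[length(rows) + 1L]] <- row
      else minor[[length(minor) + 1L]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$chrom_l, out$left_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "minor") <- if (length(minor)) do.call(rbind, minor) else empty
  out
}

#' Orientation segments along test-genome chromosomes
#'
#' Anchored clones are scanned in test-genome order; a new segment starts
#' when the reference chromosome changes, when the alignment orientation
#' flips and persists for at least two consecutive clones, or when a
#' reference-coordinate gap larger than `segment_gap` occurs.  Segments
#' whose reference span is below `min_segment` are merged into their
#' neighbour and flagged.
#'
#' @param anchored anchored placements carrying `test_chrom`/`test_pos`
#'   (see [add_test_order()]).
#' @param min_segment minimum reported segment span in bp.
#' @param segment_gap reference gap starting a new segment, in bp.
#' @return data.frame: test_chrom, segment, ref_chrom, ref_start, ref_end,
#'   orientation, n_clones; merged short segments in attribute
#'   `short_merged`.
#' @export
orientation_segments <- function(anchored, min_segment = 5e4,
                                 segment_gap = 1e6) {
  stopifnot(all(c("test_chrom", "test_pos") %in% colnames(anchored)))
  segs <- list()
  short <- list()
  for (tc in sort(unique(anchored$test_chrom))) {
    a <- anchored[anchored$test_chrom == tc, , drop = FALSE]
    a <- a[order(a$test_pos, a$clone), , drop = FALSE]
    n <- nrow(a)
    brk <- rep(FALSE, n)
    for (i in seq_len(n)[-1]) {
      if (a$chrom[i] != a$chrom[i - 1]) { brk[i] <- TRUE; next }
      gap <- max(a$start[i] - a$end[i - 1], a$start[i - 1] - a$end[i], 0)
      if (gap > segment_gap) { brk[i] <- TRUE; next }
      if (a$orientation[i] != a$orientation[i - 1] &&
          (i < n && a$orientation[i + 1] == a$orientation[i]))
        brk[i] <- TRUE
    }
    grp <- cumsum(brk) + 1L
    chrom_segs <- lapply(split(seq_len(n), grp), function(ix) {
      g <- a[ix, , drop = FALSE]
      data.frame(test_chrom = tc, segment = NA_integer_,
                 ref_chrom = g$chrom[1], ref_start = min(g$start),
                 ref_end = max(g$end),
                 orientation = names(which.max(table(g$orientation))),
                 n_clones = nrow(g), stringsAsFactors = FALSE)
    })
    ## merge short segments into the previous (or next) neighbour
    keep <- list()
    for (s in chrom_segs) {
      if (s$ref_end - s$ref_start < min_segment && length(keep)) {
        prev <- keep[[length(keep)]]
        if (prev$ref_chrom == s$ref_chrom) {
          prev$ref_start <- min(prev$ref_start, s$ref_start)
          prev$ref_end <- max(prev$ref_end, s$ref_end)
          prev$n_clones <- prev$n_clones + s$n_clones
          keep[[length(keep)]] <- prev
          short[[length(short) + 1L]] <- s
          next
        }
      }
      keep[[length(keep) + 1L]] <- s
    }
    for (i in seq_along(keep)) keep[[i]]$segment <- i
    segs <- c(segs, keep)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  attr(out, "short_merged") <- if (length(short)) do.call(rbind, short)
  else NULL
  out
}

#' Call inversions from clusters and orientation segments
#'
#' Two evidence channels: (1) minus-orientation segments of the segment
#' map; (2) pairs of same-strand discordant clusters bracketing the two
#' breakpoints of an inversion (the `++` cluster from clones spanning the
#' left breakpoint, the `--` cluster from clones spanning the right one;
#' their inner anchor edges localize the breakpoints to within the clone
#' spacing).  Overlapping candidates from the two channels are unified;
#' calls supported by a single channel carry a low-confidence flag but are
#' never dropped.
#'
#' @param clusters cluster table from [cluster_discordant()].
#' @param segmap segment map from [orientation_segments()].
#' @param hits,probes,anchored optional; when all are given, dual-probe
#'   support (clones hybridizing to probes that flank the inversion on the
#'   reference but are adjacent in the test genome) is counted into
#'   `support_probe`.
#' @param params [alignment_params()] (max_span scales the dual-probe
#'   windows).
#' @param major_threshold size in bp from which a call is major (~100 kb).
#' @return data.frame of calls: chrom, start, end, size, major, source,
#'   support_bes, support_probe, low_confidence.
#' @export
call_inversions <- function(clusters, segmap, hits = NULL, probes = NULL,
                            anchored = NULL,
                            params = alignment_params(),
                            major_threshold = 1e5) {
  cand <- list()
  if (!is.null(segmap) && nrow(segmap)) {
    neg <- segmap[segmap$orientation == "-", , drop = FALSE]
    for (i in seq_len(nrow(neg)))
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = neg$ref_chrom[i], start = neg$ref_start[i],
        end = neg$ref_end[i], source = "segment", support_bes = 0L,
        low_confidence = FALSE, stringsAsFactors = FALSE)
  }
  ss <- clusters[clusters$signature == "same_strand", , drop = FALSE]
  if (nrow(ss)) {
    for (ch in unique(ss$chrom_l)) {
      pp <- ss[ss$chrom_l == ch & ss$strands == "++", , drop = FALSE]
      mm <- ss[ss$chrom_l == ch & ss$strands == "--", , drop = FALSE]
      used_mm <- rep(FALSE, nrow(mm))
      for (i in seq_len(nrow(pp))) {
        ## partner: -- cluster whose anchors sit just inside/after ours
        j <- which(!used_mm &
                     mm$left_start >= pp$left_start[i] &
                     mm$left_start - pp$left_end[i] <= params$max_span &
                     mm$right_start >= pp$right_start[i] &
                     mm$right_start - pp$right_end[i] <= params$max_span)
        if (length(j)) {
          j <- j[which.min(mm$left_start[j])]
          used_mm[j] <- TRUE
          cand[[length(cand) + 1L]] <- data.frame(
            chrom = ch,
            start = (pp$left_end[i] + mm$left_start[j]) / 2,
            end = (pp$right_end[i] + mm$right_start[j]) / 2,
            source = "cluster_pair",
            support_bes = pp$support[i] + mm$support[j],
            low_confidence = FALSE, stringsAsFactors = FALSE)
        } else {
          cand[[length(cand) + 1L]] <- data.frame(
            chrom = ch, start = pp$left_end[i], end = pp$right_end[i],
            source = "cluster", support_bes = pp$support[i],
            low_confidence = TRUE, stringsAsFactors = FALSE)
        }
      }
      for (j in which(!used_mm))
        cand[[length(cand) + 1L]] <- data.frame(
          chrom = ch, start = mm$left_start[j], end = mm$right_start[j],
          source = "cluster", support_bes = mm$support[j],
          low_confidence = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), size = numeric(0),
                      major = logical(0), source = character(0),
                      support_bes = integer(0), support_probe = integer(0),
                      low_confidence = logical(0)))
  cand <- do.call(rbind, cand)
  ## unify overlapping candidates on the same chromosome
  n <- nrow(cand)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    cand$chrom[i] == cand$chrom[j] &
      cand$start[i] < cand$end[j] & cand$start[j] < cand$end[i])
  grp <- igraph::components(igraph::graph_from_adjacency_matrix(
    adj, mode = "undirected"))$membership
  prio <- c(cluster_pair = 1, segment = 2, cluster = 3)
  calls <- do.call(rbind, lapply(split(seq_len(n), grp), function(ix) {
    g <- cand[ix, , drop = FALSE]
    best <- g[order(prio[g$source]), , drop = FALSE][1, ]
    data.frame(chrom = best$chrom, start = best$start, end = best$end,
               source = paste(sort(unique(g$source)), collapse = "+"),
               support_bes = sum(g$support_bes),
               low_confidence = all(g$low_confidence) &&
                 length(unique(g$source)) == 1,
               stringsAsFactors = FALSE)
  }))
  calls$size <- calls$end - calls$start
  calls$major <- calls$size >= major_threshold
  calls$support_probe <- 0L
  if (!is.null(hits) && !is.null(probes) && nrow(hits)) {
    W <- params$max_span / 2
    ploc <- probes[match(hits$probe, probes$id), c("chrom", "pos")]
    for (i in seq_len(nrow(calls))) {
      onchr <- ploc$chrom == calls$chrom[i]
      nearL <- onchr & abs(ploc$pos - calls$start[i]) <= W
      nearR <- onchr & abs(ploc$pos - calls$end[i]) <= W
      dual <- intersect(hits$clone[nearL], hits$clone[nearR])
      calls$support_probe[i] <- length(dual)
    }
  }
  calls <- calls[order(calls$chrom, calls$start),
                 c("chrom", "start", "end", "size", "major", "source",
                   "support_bes", "support_probe", "low_confidence")]
  rownames(calls) <- NULL
  calls
}

#' Annotate calls near declared centromere positions
#'
#' Centromere handling is declarative: no de-novo detection is attempted.
#' When a scenario declares centromere positions, calls with a breakpoint
#' within `dist` of one are marked centromere-adjacent.
#'
#' @param calls inversion-call table.
#' @param centromeres named list/vector of reference positions per
#'   chromosome.
#' @param dist annotation distance in bp.
#' @return calls with a logical `centromere_adjacent` column.
#' @export
annotate_centromeres <- function(calls, centromeres, dist = 5e5) {
  calls$centromere_adjacent <- logical(nrow(calls))
  if (is.null(centromeres) || !nrow(calls)) return(calls)
  for (i in seq_len(nrow(calls))) {
    p <- centromeres[[calls$chrom[i]]]
    if (is.null(p)) next
    calls$centromere_adjacent[i] <-
      min(abs(calls$start[i] - p), abs(calls$end[i] - p)) <= dist
  }
  calls
}

#' Count major rearrangement calls
#'
#' @param calls inversion-call table.
#' @param threshold size in bp from which a call counts as major.
#' @return integer count.
#' @export
count_major <- function(calls, threshold = 1e5) {
  if (!nrow(calls)) return(0L)
  sum(calls$size >= threshold)
}

#' Score inversion calls against planted truth
#'
#' A planted inversion is recovered when some call places both breakpoints
#' within `tol` of the true ones.  Precision and recall are computed over
#' major events only (size at or above `major_threshold`).
#'
#' @param calls inversion-call table.
#' @param truth data.frame of planted inversions (chrom, start, end) in
#'   reference coordinates, or a list of [inversion()] events (valid when
#'   the events were planted before any length-changing event).
#' @param tol breakpoint tolerance in bp (typically the mean insert
#'   length).
#' @param major_threshold major-event size threshold in bp.
#' @return list of class `recovery_report`: per-event table (detected,
#'   breakpoint errors), `precision`, `recall`, `spurious` (unmatched major
#'   calls).
#' @export
score_recovery <- function(calls, truth, tol = 175e3,
                           major_threshold = 1e5) {
  if (is.list(truth) && !is.data.frame(truth)) {
    truth <- do.call(rbind, lapply(truth, function(ev) {
      if (ev$kind != "inversion") return(NULL)
      data.frame(chrom = ev$chrom, start = ev$start, end = ev$end,
                 stringsAsFactors = FALSE)
    }))
  }
  truth$size <- truth$end - truth$start
  truth$major <- truth$size >= major_threshold
  truth$detected <- FALSE
  truth$err_left <- NA_real_
  truth$err_right <- NA_real_
  matched_call <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(truth))) {
    if (!nrow(calls)) break
    el <- abs(calls$start - truth$start[i])
    er <- abs(calls$end - truth$end[i])
    ok <- calls$chrom == truth$chrom[i] & el <= tol & er <= tol
    if (any(ok)) {
      j <- which(ok)[which.min(el[ok] + er[ok])]
      truth$detected[i] <- TRUE
      truth$err_left[i] <- el[j]
      truth$err_right[i] <- er[j]
      matched_call[j] <- TRUE
    }
  }
  major_calls <- which(calls$size >= major_threshold)
  major_truth <- which(truth$major)
  recall <- if (length(major_truth))
    mean(truth$detected[major_truth]) else NA_real_
  precision <- if (length(major_calls))
    mean(matched_call[major_calls]) else NA_real_
  structure(list(events = truth, precision = precision, recall = recall,
                 spurious = calls[setdiff(major_calls,
                                          which(matched_call)), ,
                                  drop = FALSE]),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> precision =", x$precision,
      " recall =", x$recall, "\n")
  invisible(x)
}
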