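## Reference-anchored comparative BAC map: two-anchor placement, interval
## chaining into contigs, evidence-based merging, and contig statistics.

#' Anchor BAC clones on the reference
#'
#' A clone is anchored when (a) its mate pair is consistent (two BES
#' anchors), or (b) it has one unique BES plus an overgo hit whose probe
#' design locus falls inside the single-end default-span placement on the
#' same chromosome (BES + overgo anchors).  Overgo-only clones are recorded
#' in the `overgo_only` attribute but not anchored.
#'
#' @param statuses mate-pair status table, after [place_single_end()] so
#'   single-end rows carry their default-span placement.
#' @param hits probe-hit table (probe, clone, grade).
#' @param probes probe table with reference design loci (id, chrom, pos).
#' @param params [alignment_params()] (max_span bounds anchored intervals).
#' @return data.frame of anchored placements: clone, chrom, start, end,
#'   orientation, anchors (`"bes,bes"` or `"bes,overgo"`).
#' @export
anchor_bacs <- function(statuses, hits = NULL, probes = NULL,
                        params = alignment_params()) {
  cons <- statuses[statuses$status == "consistent", , drop = FALSE]
  out <- data.frame(clone = cons$clone, chrom = cons$chrom,
                    start = cons$start, end = cons$end,
                    orientation = cons$orientation,
                    anchors = "bes,bes", stringsAsFactors = FALSE)
  overgo_only <- character(0)
  if (!is.null(hits) && !is.null(probes) && nrow(hits)) {
    ploc <- probes[match(hits$probe, probes$id), c("chrom", "pos")]
    se <- statuses[statuses$status == "single_end", , drop = FALSE]
    if (nrow(se)) {
      add <- vapply(seq_len(nrow(se)), function(i) {
        h <- which(hits$clone == se$clone[i] &
                     ploc$chrom == se$chrom[i] &
                     ploc$pos >= se$start[i] & ploc$pos < se$end[i])
        length(h) > 0 && (se$end[i] - se$start[i]) <= params$max_span
      }, logical(1))
      if (any(add))
        out <- rbind(out, data.frame(
          clone = se$clone[add], chrom = se$chrom[add],
          start = se$start[add], end = se$end[add],
          orientation = se$orientation[add], anchors = "bes,overgo",
          stringsAsFactors = FALSE))
    }
    overgo_only <- setdiff(unique(hits$clone), out$clone)
  }
  out <- out[order(out$chrom, out$start, out$clone), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "overgo_only") <- overgo_only
  out
}

#' Chain anchored placements into comparative contigs
#'
#' Per chromosome, placements sorted by start are chained while consecutive
#' members overlap by at least `min_overlap` bp; each run becomes a contig
#' and the spaces between runs are reported as gaps.
#'
#' @param anchored anchored placement table from [anchor_bacs()].
#' @param min_overlap minimum overlap in bp for chaining (default 1).
#' @return object of class `comparative_map`: `contigs` (list with id,
#'   chrom, start, end, members) and `gaps` (data.frame).
#' @export
build_comparative_contigs <- function(anchored, min_overlap = 1) {
  contigs <- list()
  gaps <- list()
  for (ch in sort(unique(anchored$chrom))) {
    a <- anchored[anchored$chrom == ch, , drop = FALSE]
    a <- a[order(a$start, a$end, a$clone), , drop = FALSE]
    run_start <- 1L
    cur_end <- a$end[1]
    flush <- function(from, to, cur_end) {
      m <- a[from:to, , drop = FALSE]
      list(id = NA_character_, chrom = ch, start = min(m$start),
           end = cur_end, members = m)
    }
    for (i in seq_len(nrow(a))[-1]) {
      if (a$start[i] <= cur_end - min_overlap) {
        cur_end <- max(cur_end, a$end[i])
      } else {
        contigs[[length(contigs) + 1L]] <- flush(run_start, i - 1L, cur_end)
        gaps[[length(gaps) + 1L]] <- data.frame(
          chrom = ch, gap_start = cur_end, gap_end = a$start[i],
          width = a$start[i] - cur_end)
        run_start <- i
        cur_end <- a$end[i]
      }
    }
    contigs[[length(contigs) + 1L]] <- flush(run_start, nrow(a), cur_end)
  }
  for (i in seq_along(contigs)) contigs[[i]]$id <- sprintf("cc%03d", i)
  names(contigs) <- vapply(contigs, `[[`, character(1), "id")
  structure(list(contigs = contigs,
                 gaps = if (length(gaps)) do.call(rbind, gaps)
                 else data.frame(chrom = character(0),
                                 gap_start = numeric(0),
                                 gap_end = numeric(0), width = numeric(0))),
            class = "comparative_map")
}

#' @export
print.comparative_map <- function(x, ...) {
  cat("<comparative_map> ", length(x$contigs), " contig(s), ",
      nrow(x$gaps), " gap(s)\n", sep = "")
  invisible(x)
}

cmp_terminals <- function(ctg, side, end_depth = 2) {
  m <- ctg$members
  m <- m[order(m$start, m$end), , drop = FALSE]
  n <- nrow(m)
  if (side == "left") m$clone[seq_len(min(end_depth, n))]
  else m$clone[seq(max(1, n - end_depth + 1), n)]
}

#' Merge adjacent comparative contigs on independent evidence
#'
#' Adjacent contigs on the same chromosome, separated by at most `max_gap`,
#' merge when (a) a terminal clone of each side lies in one fingerprint
#' contig, (b) one overgo probe hits a terminal clone of each side, or (c)
#' both terminal clones are hit by a probe whose single design locus falls
#' in the gap.  Merges never join chromosomes and applying the pass twice
#' produces no new merges.
#'
#' @param cmap a `comparative_map`.
#' @param fpc_map optional `fpc_map` supplying fingerprint-contig evidence.
#' @param hits optional probe-hit table supplying shared-probe evidence.
#' @param probes optional probe table (design loci, for evidence kind c).
#' @param max_gap maximum gap bridged by a merge, in bp.
#' @param end_depth clones per contig end considered terminal.
#' @return list with `map` (merged `comparative_map`) and `evidence`
#'   (data.frame: left, right, kind, support).
#' @export
merge_contigs <- function(cmap, fpc_map = NULL, hits = NULL, probes = NULL,
                          max_gap = 2e6, end_depth = 2) {
  ctgs <- cmap$contigs
  n <- length(ctgs)
  if (n < 2)
    return(list(map = cmap, evidence = data.frame(
      left = character(0), right = character(0), kind = character(0),
      support = character(0))))
  clone2fpc <- NULL
  if (!is.null(fpc_map))
    clone2fpc <- setNames(
      rep(names(fpc_map$contigs), vapply(fpc_map$contigs, function(c)
        length(c$members), integer(1))),
      unlist(lapply(fpc_map$contigs, `[[`, "members")))
  ord <- order(vapply(ctgs, `[[`, character(1), "chrom"),
               vapply(ctgs, `[[`, numeric(1), "start"))
  ctgs <- ctgs[ord]
  ev <- list()
  pairs <- list()
  for (i in seq_len(n - 1)) {
    L <- ctgs[[i]]; R <- ctgs[[i + 1]]
    if (L$chrom != R$chrom) next
    gap <- R$start - L$end
    if (gap > max_gap) next
    tl <- cmp_terminals(L, "right", end_depth)
    tr <- cmp_terminals(R, "left", end_depth)
    kind <- NULL; support <- NULL
    if (!is.null(clone2fpc)) {
      fl <- clone2fpc[tl]; fr <- clone2fpc[tr]
      common <- intersect(fl[!is.na(fl)], fr[!is.na(fr)])
      if (length(common)) { kind <- "fingerprint_contig"; support <- common[1] }
    }
    if (is.null(kind) && !is.null(hits) && nrow(hits)) {
      pl <- hits$probe[hits$clone %in% tl]
      pr <- hits$probe[hits$clone %in% tr]
      common <- intersect(pl, pr)
      if (length(common)) {
        kind <- "shared_overgo"; support <- common[1]
        if (!is.null(probes)) {
          loc <- probes[match(common, probes$id), , drop = FALSE]
          ingap <- loc$chrom == L$chrom & loc$pos >= L$end &
            loc$pos < R$start
          if (any(ingap)) support <- loc$id[ingap][1]
        }
      }
    }
    if (!is.null(kind)) {
      pairs[[length(pairs) + 1L]] <- data.frame(i = i, j = i + 1, S = gap)
      ev[[length(ev) + 1L]] <- data.frame(
        left = L$id, right = R$id, kind = kind, support = support,
        stringsAsFactors = FALSE)
    }
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else
    data.frame(left = character(0), right = character(0),
               kind = character(0), support = character(0))
  if (!length(pairs))
    return(list(map = cmap, evidence = evidence))
  grp <- merge_groups(n, do.call(rbind, pairs))
  merged <- lapply(split(seq_len(n), grp), function(ix) {
    mm <- do.call(rbind, lapply(ctgs[ix], `[[`, "members"))
    mm <- mm[order(mm$start, mm$end, mm$clone), , drop = FALSE]
    list(id = NA_character_, chrom = ctgs[[ix[1]]]$chrom,
         start = min(vapply(ctgs[ix], `[[`, numeric(1), "start")),
         end = max(vapply(ctgs[ix], `[[`, numeric(1), "end")),
         members = mm)
  })
  merged <- unname(merged)
  for (i in seq_along(merged)) merged[[i]]$id <- sprintf("cc%03d", i)
  names(merged) <- vapply(merged, `[[`, character(1), "id")
  out <- structure(list(contigs = merged, gaps = cmap$gaps),
                   class = "comparative_map")
  list(map = out, evidence = evidence)
}

#' N50/N90-style length statistic
#'
#' The length L such that contigs of length >= L cover at least `frac` of
#' the total assembled length.
#'
#' @param lengths contig lengths.
#' @param frac covered fraction (0.5 for N50, 0.9 for N90).
#' @return the statistic, or 0 for empty input.
#' @export
n_stat <- function(lengths, frac = 0.5) {
  if (!length(lengths)) return(0)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= frac * sum(s))[1]]
}

#' Comparative contig statistics
#'
#' Per-chromosome contig counts and lengths with a TOTALS row, plus global
#' N50 and N90.
#'
#' @param cmap a `comparative_map`.
#' @return list with `table` (data.frame: chrom, n_contigs, total_length,
#'   avg_length; last row TOTALS) and `n50`, `n90`.
#' @export
contig_stats <- function(cmap) {
  lens <- vapply(cmap$contigs, function(c) c$end - c$start, numeric(1))
  chroms <- vapply(cmap$contigs, `[[`, character(1), "chrom")
  per <- do.call(rbind, lapply(sort(unique(chroms)), function(ch) {
    l <- lens[chroms == ch]
    data.frame(chrom = ch, n_contigs = length(l), total_length = sum(l),
               avg_length = round_half_up(sum(l) / length(l)))
  }))
  tot <- data.frame(chrom = "TOTALS", n_contigs = length(lens),
                    total_length = sum(lens),
                    avg_length = round_half_up(sum(lens) /
                                                 max(1, length(lens))))
  list(table = rbind(per, tot),
       n50 = n_stat(lens, 0.5), n90 = n_stat(lens, 0.9))
}
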