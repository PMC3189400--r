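## FPC-style fingerprint contig assembly: single-linkage clustering at a
## Sulston-score cutoff, greedy consensus ordering, DQ re-assembly, end
## merging, marker incorporation, singleton adoption and physical length
## estimation.

## ---- internal building blocks ------------------------------------------

## greedy 1-D placement of a connected component; offsets in band units
order_component <- function(ids, m, S, nb) {
  k <- length(ids)
  off <- setNames(rep(NA_real_, k), ids)
  if (k == 1) { off[1] <- 0; return(off) }
  d <- outer(nb, nb, "+") / 2 - m      # estimated start distance, band units
  Sv <- S
  diag(Sv) <- Inf
  idx <- which(Sv == min(Sv), arr.ind = TRUE)
  idx <- idx[order(pmin(idx[, 1], idx[, 2]), pmax(idx[, 1], idx[, 2])), ,
             drop = FALSE][1, ]
  a <- min(idx); b <- max(idx)
  off[a] <- 0
  off[b] <- max(0, d[a, b])
  placed <- c(a, b)
  unplaced <- setdiff(seq_len(k), placed)
  while (length(unplaced)) {
    sub <- Sv[unplaced, placed, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    x <- unplaced[best[1]]
    pb <- placed[best[2]]
    dd <- max(0, d[x, pb])
    cands <- c(off[pb] - dd, off[pb] + dd)
    sc <- vapply(cands, function(o) {
      pred <- pmax(0, pmin(nb[x], nb[placed]) - abs(o - off[placed]))
      -sum(abs(pred - m[x, placed]))
    }, numeric(1))
    off[x] <- cands[which.max(sc)]
    placed <- c(placed, x)
    unplaced <- setdiff(unplaced, x)
  }
  off - min(off)
}

## Positional consensus: walking members in offset order, each clone's
## bands are matched one-to-one against the classes contributed by clones
## whose offset span overlaps it; unmatched bands open new classes.  The
## class count approximates the number of distinct restriction fragments
## of the spanned region, and the matched fraction per member is its fit
## to the consensus at its placement.
build_consensus <- function(members, offsets, fps, tol) {
  cls_val <- numeric(0)     # class band values, kept sorted
  cls_lo <- numeric(0)      # contributing span (band units)
  cls_hi <- numeric(0)
  cls_n <- integer(0)       # number of contributing clones
  for (i in seq_along(members)) {
    b <- fps[[members[i]]]
    nb <- length(b)
    if (!nb) next
    o <- offsets[i]
    span_end <- o + nb
    act <- which(cls_hi >= o & cls_lo <= span_end)
    if (length(act)) {
      flags <- .match_flags_cpp(as.integer(b), cls_val[act], tol)
      ## classes re-observed by this clone gain a contributor
      mf <- .match_flags_cpp(as.integer(round(cls_val[act])),
                             as.numeric(b), tol)
      hit <- act[mf]
      cls_n[hit] <- cls_n[hit] + 1L
      cls_hi[hit] <- pmax(cls_hi[hit], span_end)
      cls_lo[hit] <- pmin(cls_lo[hit], o)
    } else flags <- rep(FALSE, nb)
    new_val <- b[!flags]
    if (length(new_val)) {
      cls_val <- c(cls_val, new_val)
      cls_lo <- c(cls_lo, rep(o, length(new_val)))
      cls_hi <- c(cls_hi, rep(span_end, length(new_val)))
      cls_n <- c(cls_n, rep(1L, length(new_val)))
      ord <- order(cls_val)
      cls_val <- cls_val[ord]
      cls_lo <- cls_lo[ord]
      cls_hi <- cls_hi[ord]
      cls_n <- cls_n[ord]
    }
  }
  ## second pass: fit of each member against classes confirmed by at
  ## least two clones and active at its placement
  fit <- setNames(rep(1, length(members)), members)
  conf <- cls_n >= 2L
  for (i in seq_along(members)) {
    b <- fps[[members[i]]]
    if (!length(b)) next
    o <- offsets[i]
    act <- which(conf & cls_hi >= o & cls_lo <= o + length(b))
    if (!length(act)) next
    fit[i] <- mean(.match_flags_cpp(as.integer(b), cls_val[act], tol))
  }
  list(values = cls_val, fit = fit)
}

make_contig <- function(ids, fps, params, id, min_fit = 0.5) {
  ids <- sort(ids)
  pw <- pairwise_sulston(fps[ids], params)
  nb <- lengths(fps[ids])
  off <- order_component(ids, pw$m, pw$S, nb)
  members <- names(sort(off))
  cc <- build_consensus(members, sort(off), fps, params$tolerance)
  ctg <- structure(list(id = id, members = members,
                        offsets = off[members],
                        consensus = cc$values,
                        n_consensus = length(cc$values),
                        member_fit = cc$fit,
                        q_clones = character(0)),
                   class = "fingerprint_contig")
  ctg$q_clones <- flag_q_clones(ctg, fps, min_fit = min_fit,
                                tolerance = params$tolerance)
  ctg
}

#' @export
print.fingerprint_contig <- function(x, ...) {
  cat("<fingerprint_contig> ", x$id, ": ", length(x$members),
      " clones, ", x$n_consensus, " consensus bands, ",
      length(x$q_clones), " Q\n", sep = "")
  invisible(x)
}

new_fpc_map <- function(contigs, singletons, params, min_fit) {
  names(contigs) <- vapply(contigs, `[[`, character(1), "id")
  structure(list(contigs = contigs, singletons = sort(singletons),
                 params = params, min_fit = min_fit),
            class = "fpc_map")
}

#' @export
print.fpc_map <- function(x, ...) {
  cat("<fpc_map> ", length(x$contigs), " contig(s), ",
      length(x$singletons), " singleton(s), ",
      sum(vapply(x$contigs, function(c) length(c$members), integer(1))),
      " clones in contigs\n", sep = "")
  invisible(x)
}

## single-linkage components at a score cutoff; returns list of id vectors
## (including singleton components)
score_components <- function(fps, params, cutoff) {
  ids <- sort(names(fps))
  pw <- pairwise_sulston(fps[ids], params)
  adj <- pw$S <= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  comps <- split(ids, memb)
  comps[order(vapply(comps, min, character(1)))]
}

## ---- public assembly operations ----------------------------------------

#' Assemble fingerprint contigs
#'
#' Single-linkage clustering of clones whose pairwise Sulston score is at or
#' below the cutoff, followed by a greedy 1-D consensus placement within
#' each component (seeded at the best-scoring pair; each remaining clone is
#' attached at the offset that best reproduces its shared-band counts with
#' the already-placed clones).  Deterministic given input and lexicographic
#' tie-breaking.
#'
#' @param fps named list of quality-filtered band vectors.
#' @param params [sulston_params()].
#' @param min_fit minimum fraction of a member's bands matching
#'   multi-member consensus band classes before it is flagged questionable.
#' @return object of class `fpc_map`: `contigs` (list of
#'   `fingerprint_contig`), `singletons` (clone ids), plus the parameters.
#' @export
build_contigs <- function(fps, params = sulston_params(), min_fit = 0.5) {
  comps <- score_components(fps, params, params$cutoff)
  big <- comps[lengths(comps) >= 2]
  singles <- unlist(comps[lengths(comps) < 2], use.names = FALSE)
  contigs <- lapply(seq_along(big), function(i)
    make_contig(big[[i]], fps, params, sprintf("ctg%04d", i), min_fit))
  new_fpc_map(contigs, singles %||% character(0), params, min_fit)
}

#' Flag questionable clones in a contig
#'
#' A member is questionable when fewer than `min_fit` of its bands match
#' the consensus band classes active at its placement (classes contributed
#' by the clones it overlaps).
#'
#' @param contig a `fingerprint_contig`.
#' @param fps fingerprint list covering the members.
#' @param min_fit minimum fraction of matching bands.
#' @param tolerance band-matching tolerance in sizing units.
#' @return character vector of questionable clone ids.
#' @export
flag_q_clones <- function(contig, fps, min_fit = 0.5, tolerance = 7) {
  fit <- contig$member_fit
  if (is.null(fit))
    fit <- build_consensus(contig$members,
                           contig$offsets[contig$members], fps,
                           tolerance)$fit
  contig$members[fit < min_fit]
}

#' DQ re-assembly of a questionable contig
#'
#' If the contig's questionable-clone fraction exceeds the threshold, its
#' members are re-clustered at each of the stepped (stricter) stringencies;
#' the stringency producing the fewest contigs while bringing the
#' questionable fraction below the threshold is kept.  The output clone
#' multiset always equals the input.
#'
#' @param contig a `fingerprint_contig`.
#' @param fps fingerprint list covering the members.
#' @param stringencies stepped cutoffs tried, strictest first (default
#'   1e-11, 1e-10, 1e-09).
#' @param q_threshold questionable fraction that triggers re-assembly.
#' @param params [sulston_params()] used for scoring.
#' @param min_fit see [build_contigs()].
#' @return list of `fingerprint_contig` (single-member components are
#'   returned as one-clone contigs so that clones are conserved).
#' @export
dq_reassemble <- function(contig, fps,
                          stringencies = c(1e-11, 1e-10, 1e-09),
                          q_threshold = 0.1, params = sulston_params(),
                          min_fit = 0.5) {
  qfrac <- length(contig$q_clones) / length(contig$members)
  if (qfrac <= q_threshold) return(list(contig))
  sub <- fps[contig$members]
  eval_one <- function(cut) {
    comps <- score_components(sub, params, cut)
    ctgs <- lapply(seq_along(comps), function(i)
      make_contig(comps[[i]], fps, params,
                  sprintf("%s.%d", contig$id, i), min_fit))
    nq <- sum(vapply(ctgs, function(c) length(c$q_clones), integer(1)))
    nm <- sum(vapply(ctgs, function(c)
      if (length(c$members) >= 2) length(c$members) else 0L, integer(1)))
    list(ctgs = ctgs, n = length(ctgs),
         qfrac = if (nm > 0) nq / nm else 0)
  }
  res <- lapply(sort(stringencies), eval_one)
  ok <- vapply(res, function(r) r$qfrac <= q_threshold, logical(1))
  pick <- if (any(ok)) {
    cand <- which(ok)
    cand[which.min(vapply(res[cand], `[[`, numeric(1), "n"))]
  } else 1L
  res[[pick]]$ctgs
}

## apply dq_reassemble across a map
#' @rdname dq_reassemble
#' @param map an `fpc_map`.
#' @export
dq_pass <- function(map, fps, stringencies = c(1e-11, 1e-10, 1e-09),
                    q_threshold = 0.1) {
  out <- list(); singles <- map$singletons
  for (ctg in map$contigs) {
    pieces <- dq_reassemble(ctg, fps, stringencies, q_threshold,
                            map$params, map$min_fit)
    for (p in pieces) {
      if (length(p$members) >= 2) out[[length(out) + 1L]] <- p
      else singles <- c(singles, p$members)
    }
  }
  out <- renumber_contigs(out)
  new_fpc_map(out, singles, map$params, map$min_fit)
}

renumber_contigs <- function(contigs) {
  if (!length(contigs)) return(contigs)
  ord <- order(vapply(contigs, function(c) min(c$members), character(1)))
  contigs <- contigs[ord]
  for (i in seq_along(contigs)) contigs[[i]]$id <- sprintf("ctg%04d", i)
  contigs
}

terminal_clones <- function(contig, end_depth = 2) {
  n <- length(contig$members)
  unique(c(head(contig$members, min(end_depth, n)),
           tail(contig$members, min(end_depth, n))))
}

## union-find over contig indices given qualifying pairs sorted best-first
merge_groups <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    a <- find(as.integer(pairs$i[r])); b <- find(as.integer(pairs$j[r]))
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Merge contigs by terminal-clone overlap
#'
#' Terminal clones of every contig are scored against terminal clones of all
#' other contigs; two contigs merge when some terminal pair has a Sulston
#' score at or below the loosest cutoff in `cutoffs` AND shares at least
#' `min_shared` bands.  Merges are applied best-score-first and
#' transitively.
#'
#' @param map an `fpc_map`.
#' @param fps fingerprint list.
#' @param cutoffs cutoff range; the loosest value bounds acceptance.
#' @param min_shared minimum shared bands between terminal clones.
#' @param end_depth how many clones at each contig end count as terminal.
#' @return merged `fpc_map`.
#' @export
end_merge <- function(map, fps, cutoffs = 10^seq(-20, -7), min_shared = 10,
                      end_depth = 2) {
  n <- length(map$contigs)
  if (n < 2) return(map)
  smax <- max(cutoffs)
  terms <- lapply(map$contigs, terminal_clones, end_depth = end_depth)
  tids <- sort(unique(unlist(terms)))
  pw <- pairwise_sulston(fps[tids], map$params)
  cand <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    S <- pw$S[terms[[i]], terms[[j]], drop = FALSE]
    m <- pw$m[terms[[i]], terms[[j]], drop = FALSE]
    ok <- S <= smax & m >= min_shared
    if (any(ok))
      cand[[length(cand) + 1L]] <- data.frame(i = i, j = j,
                                              S = min(S[ok]))
  }
  if (!length(cand)) return(map)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$S, cand$i, cand$j), , drop = FALSE]
  grp <- merge_groups(n, cand)
  rebuilt <- lapply(split(seq_len(n), grp), function(ix) {
    ids <- unlist(lapply(map$contigs[ix], `[[`, "members"))
    make_contig(ids, fps, map$params, "tmp", map$min_fit)
  })
  new_fpc_map(renumber_contigs(unname(rebuilt)), map$singletons,
              map$params, map$min_fit)
}

#' Incorporate hybridization markers and merge marker-linked contigs
#'
#' Contigs sharing at least one probe are merge candidates; a candidate pair
#' merges only when some cross-contig clone pair scores at or below the
#' loosest cutoff of the relaxed range.  Probes hitting more than
#' `max_contigs` contigs are flagged promiscuous and excluded.
#'
#' @param map an `fpc_map`.
#' @param hits probe-hit table (probe, clone, grade).
#' @param fps fingerprint list.
#' @param cutoffs relaxed cutoff range for marker-supported merges.
#' @param max_contigs promiscuity bound for probes.
#' @return `fpc_map` with fields `marker_index` (data.frame probe, contig,
#'   n_clones) and `promiscuous_probes` added.
#' @export
incorporate_markers <- function(map, hits, fps,
                                cutoffs = 10^seq(-8, -4), max_contigs = 5) {
  clone2ctg <- setNames(
    rep(names(map$contigs),
        vapply(map$contigs, function(c) length(c$members), integer(1))),
    unlist(lapply(map$contigs, `[[`, "members")))
  hits <- hits[hits$clone %in% names(clone2ctg), , drop = FALSE]
  probe_ctgs <- lapply(split(clone2ctg[hits$clone], hits$probe),
                       function(x) sort(unique(x)))
  promiscuous <- names(probe_ctgs)[lengths(probe_ctgs) > max_contigs]
  if (length(promiscuous))
    message(sprintf("excluding %d promiscuous probe(s): %s",
                    length(promiscuous),
                    paste(promiscuous, collapse = ", ")))
  usable <- probe_ctgs[!(names(probe_ctgs) %in% promiscuous)]
  smax <- max(cutoffs)
  pairs <- unique(do.call(rbind, lapply(usable, function(cs) {
    if (length(cs) < 2) return(NULL)
    t(utils::combn(cs, 2))
  })))
  cand <- list()
  if (!is.null(pairs) && nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    mi <- map$contigs[[pairs[r, 1]]]$members
    mj <- map$contigs[[pairs[r, 2]]]$members
    pw <- pairwise_sulston(fps[c(mi, mj)], map$params)
    S <- pw$S[mi, mj, drop = FALSE]
    if (min(S) <= smax)
      cand[[length(cand) + 1L]] <- data.frame(
        i = match(pairs[r, 1], names(map$contigs)),
        j = match(pairs[r, 2], names(map$contigs)), S = min(S))
  }
  n <- length(map$contigs)
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$S, cand$i, cand$j), , drop = FALSE]
    grp <- merge_groups(n, cand)
    rebuilt <- lapply(split(seq_len(n), grp), function(ix) {
      ids <- unlist(lapply(map$contigs[ix], `[[`, "members"))
      make_contig(ids, fps, map$params, "tmp", map$min_fit)
    })
    map <- new_fpc_map(renumber_contigs(unname(rebuilt)), map$singletons,
                       map$params, map$min_fit)
    clone2ctg <- setNames(
      rep(names(map$contigs),
          vapply(map$contigs, function(c) length(c$members), integer(1))),
      unlist(lapply(map$contigs, `[[`, "members")))
  }
  idx <- do.call(rbind, lapply(names(probe_ctgs), function(p) {
    cl <- hits$clone[hits$probe == p]
    tab <- table(clone2ctg[cl])
    if (!length(tab)) return(NULL)
    data.frame(probe = p, contig = names(tab),
               n_clones = as.integer(tab), stringsAsFactors = FALSE)
  }))
  map$marker_index <- idx %||% data.frame(probe = character(0),
                                          contig = character(0),
                                          n_clones = integer(0))
  map$promiscuous_probes <- promiscuous
  map
}

#' Attach singletons to existing contigs
#'
#' Each singleton is attached to the contig of its best-scoring partner
#' clone if the score is at or below the loosest cutoff.  No contig-contig
#' merges happen in this pass, so the contig count never decreases.
#'
#' @param map an `fpc_map`.
#' @param fps fingerprint list (must cover singletons and members).
#' @param cutoffs cutoff range; the loosest value bounds acceptance.
#' @return updated `fpc_map`.
#' @export
add_singletons <- function(map, fps, cutoffs = 10^seq(-20, -5)) {
  if (!length(map$singletons) || !length(map$contigs)) return(map)
  smax <- max(cutoffs)
  member_ids <- unlist(lapply(map$contigs, `[[`, "members"))
  owner <- setNames(
    rep(names(map$contigs),
        vapply(map$contigs, function(c) length(c$members), integer(1))),
    member_ids)
  assign <- list()
  for (s in map$singletons) {
    sc <- vapply(member_ids, function(mid)
      sulston_score(fps[[s]], fps[[mid]], map$params), numeric(1))
    best <- which.min(sc)
    if (sc[best] <= smax)
      assign[[s]] <- owner[[member_ids[best]]]
  }
  if (!length(assign)) return(map)
  contigs <- map$contigs
  for (ct in unique(unlist(assign))) {
    add <- names(assign)[unlist(assign) == ct]
    ids <- c(contigs[[ct]]$members, add)
    contigs[[ct]] <- make_contig(ids, fps, map$params, ct, map$min_fit)
  }
  new_fpc_map(unname(contigs), setdiff(map$singletons, names(assign)),
              map$params, map$min_fit)
}

#' Estimate physical length from consensus bands
#'
#' Length in kb is the consensus band count times a kb-per-band constant.
#' The default 2.9 kb/band is consistent with published whole-genome maps
#' built from 35-500 bp capillary fingerprints; [calibrate_kb_per_band()]
#' recomputes it from the data at hand.
#'
#' @param x a `fingerprint_contig`, an `fpc_map`, or a consensus band count.
#' @param kb_per_band kb of physical length per consensus band.
#' @return estimated length in kb (summed over contigs for a map).
#' @export
estimate_physical_length <- function(x, kb_per_band = 2.9) {
  n <- if (inherits(x, "fingerprint_contig")) x$n_consensus
  else if (inherits(x, "fpc_map"))
    sum(vapply(x$contigs, `[[`, integer(1), "n_consensus"))
  else x
  n * kb_per_band
}

#' @rdname estimate_physical_length
#' @param mean_insert_kb mean clone insert size in kb.
#' @param fps fingerprint list used to estimate bands per clone.
#' @export
calibrate_kb_per_band <- function(mean_insert_kb, fps) {
  mean_insert_kb / mean(lengths(fps))
}

#' Sweep assembly stringency parameters
#'
#' Rebuilds the map across a (tolerance, cutoff) grid and tabulates contig,
#' singleton and questionable-clone counts, reproducing the curves used to
#' select assembly stringency.
#'
#' @param fps fingerprint list.
#' @param tolerances tolerances to test.
#' @param cutoffs cutoffs to test.
#' @param gel_states band state count G.
#' @param min_fit see [build_contigs()].
#' @return data.frame with one row per grid point: tolerance, cutoff,
#'   n_contigs, n_singletons, n_q_clones.
#' @export
parameter_sweep <- function(fps, tolerances = 7, cutoffs = 1e-08,
                            gel_states = 4651, min_fit = 0.5) {
  rows <- list()
  for (t in tolerances) for (cut in cutoffs) {
    params <- sulston_params(tolerance = t, gel_states = gel_states,
                             cutoff = cut)
    map <- build_contigs(fps, params, min_fit)
    rows[[length(rows) + 1L]] <- data.frame(
      tolerance = t, cutoff = cut,
      n_contigs = length(map$contigs),
      n_singletons = length(map$singletons),
      n_q_clones = sum(vapply(map$contigs, function(c)
        length(c$q_clones), integer(1))))
  }
  do.call(rbind, rows)
}
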