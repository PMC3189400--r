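## Seed-and-extend mapping of BAC-end sequences against the reference, and
## mate-pair consistency classification.

#' BES alignment and mate-pair consistency parameters
#'
#' @param min_identity minimum alignment identity (default 0.90).
#' @param min_length minimum alignable read length in bp (default 50).
#' @param evalue_max significance threshold retained for imported external
#'   alignment tables (the built-in aligner uses the identity/length pair).
#' @param min_span,max_span mate-pair span bounds in bp (default 10-400 kb).
#' @param unplaced_names reference sequence names treated as unplaced; hits
#'   on them count as failed matches.
#' @param seed_k exact seed length for the built-in aligner.
#' @param n_seeds seeds taken per read (spread evenly).
#' @param unique_margin a best hit is unique when its score exceeds the
#'   runner-up by this factor.
#' @return list of class `alignment_params`.
#' @export
alignment_params <- function(min_identity = 0.90, min_length = 50,
                             evalue_max = 1e-05, min_span = 10e3,
                             max_span = 400e3,
                             unplaced_names = character(0),
                             seed_k = 16, n_seeds = 5,
                             unique_margin = 1.2) {
  if (min_span >= max_span) stopf("min_span must be below max_span")
  structure(list(min_identity = min_identity, min_length = min_length,
                 evalue_max = evalue_max, min_span = min_span,
                 max_span = max_span, unplaced_names = unplaced_names,
                 seed_k = as.integer(seed_k), n_seeds = as.integer(n_seeds),
                 unique_margin = unique_margin),
            class = "alignment_params")
}

#' Index a reference genome for BES alignment
#'
#' @param ref reference genome ([Biostrings::DNAStringSet]).
#' @return object of class `ref_index`.
#' @export
ref_index <- function(ref) {
  structure(list(seq = ref, chars = as.character(ref),
                 lens = genome_lengths(ref)),
            class = "ref_index")
}

empty_aln <- function() {
  data.frame(id = character(0), chrom = character(0), start = integer(0),
             end = integer(0), strand = character(0), identity = numeric(0),
             length = integer(0), score = numeric(0), unique = logical(0),
             n_hits = integer(0), stringsAsFactors = FALSE)
}

## identity between two equal-length strings
string_identity <- function(a, b) {
  ai <- utf8ToInt(a); bi <- utf8ToInt(b)
  sum(ai == bi) / length(ai)
}

#' Align BES reads to an indexed reference
#'
#' Exact k-mer seeds spread along each read (and its reverse complement) are
#' located with a pre-built dictionary match against the reference; each
#' candidate placement is evaluated by ungapped full-read comparison.  Hits
#' passing the identity threshold over at least `min_length` bases are
#' reported; hits on `unplaced_names` are discarded as failed matches.  A
#' read is uniquely mapped when it has a single reported hit or its best hit
#' outscores the runner-up by `unique_margin`.
#'
#' @param reads data.frame with columns `id` and `seq` (e.g. from
#'   [extract_bes()]).
#' @param index a [ref_index()] (passing a raw genome is an error).
#' @param params [alignment_params()].
#' @return data.frame of alignments: id, chrom, start, end (0-based
#'   half-open), strand, identity, length, score (matching bases), unique,
#'   n_hits.
#' @export
align_bes_reads <- function(reads, index, params = alignment_params()) {
  if (!inherits(index, "ref_index"))
    stopf("reference not indexed; call ref_index() first")
  reads <- reads[nchar(reads$seq) >= params$min_length, , drop = FALSE]
  if (!nrow(reads)) return(empty_aln())
  k <- params$seed_k
  ## seed table: (read row, strand, offset within oriented read)
  seed_rows <- list()
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") reads$seq else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads$seq)))
    for (ri in seq_len(nrow(reads))) {
      len <- nchar(oriented[ri])
      if (len < k) next
      offs <- unique(as.integer(floor(
        seq(0, len - k, length.out = min(params$n_seeds,
                                         max(1, len - k + 1))))))
      seed_rows[[length(seed_rows) + 1L]] <- data.frame(
        read = ri, strand = strand, off = offs,
        seed = substring(oriented[ri], offs + 1L, offs + k),
        stringsAsFactors = FALSE)
    }
  }
  seeds <- do.call(rbind, seed_rows)
  keep <- !grepl("[^ACGT]", seeds$seed)
  seeds <- seeds[keep, , drop = FALSE]
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds$seed))

  cand <- list()
  for (ci in seq_along(index$seq)) {
    mi <- Biostrings::matchPDict(pd, index$seq[[ci]])
    st <- Biostrings::startIndex(mi)
    nhit <- lengths(st)
    which_hit <- which(nhit > 0)
    if (!length(which_hit)) next
    cand[[length(cand) + 1L]] <- data.frame(
      read = rep(seeds$read[which_hit], nhit[which_hit]),
      strand = rep(seeds$strand[which_hit], nhit[which_hit]),
      chrom = names(index$seq)[ci],
      start = unlist(st[which_hit]) - 1L -
        rep(seeds$off[which_hit], nhit[which_hit]),
      stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(empty_aln())
  cand <- do.call(rbind, cand)
  ## collapse near-identical diagonals (same read/chrom/strand, start +-3)
  cand <- cand[order(cand$read, cand$chrom, cand$strand, cand$start), ]
  dup <- c(FALSE, cand$read[-1] == cand$read[-nrow(cand)] &
             cand$chrom[-1] == cand$chrom[-nrow(cand)] &
             cand$strand[-1] == cand$strand[-nrow(cand)] &
             abs(cand$start[-1] - cand$start[-nrow(cand)]) <= 3)
  cand <- cand[!dup, , drop = FALSE]

  out <- list()
  rc_cache <- list()
  for (r in seq_len(nrow(cand))) {
    ri <- cand$read[r]
    len <- nchar(reads$seq[ri])
    s <- cand$start[r]
    if (s < 0 || s + len > index$lens[[cand$chrom[r]]]) next
    gseq <- substring(index$chars[[cand$chrom[r]]], s + 1L, s + len)
    q <- if (cand$strand[r] == "+") reads$seq[ri] else {
      key <- as.character(ri)
      if (is.null(rc_cache[[key]]))
        rc_cache[[key]] <- revcomp_chr(reads$seq[ri])
      rc_cache[[key]]
    }
    idy <- string_identity(q, gseq)
    if (idy >= params$min_identity)
      out[[length(out) + 1L]] <- data.frame(
        id = reads$id[ri], chrom = cand$chrom[r], start = s,
        end = s + len, strand = cand$strand[r], identity = idy,
        length = len, score = idy * len, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_aln())
  aln <- do.call(rbind, out)
  aln <- aln[!(aln$chrom %in% params$unplaced_names), , drop = FALSE]
  if (!nrow(aln)) return(empty_aln())
  ## uniqueness per read
  aln <- aln[order(aln$id, -aln$score), , drop = FALSE]
  sp <- split(seq_len(nrow(aln)), aln$id)
  aln$unique <- FALSE
  aln$n_hits <- 0L
  for (ix in sp) {
    aln$n_hits[ix] <- length(ix)
    if (length(ix) == 1) aln$unique[ix] <- TRUE
    else if (aln$score[ix[1]] >= params$unique_margin * aln$score[ix[2]])
      aln$unique[ix[1]] <- TRUE
  }
  rownames(aln) <- NULL
  aln
}

#' @rdname align_bes_reads
#' @param read a single read: list/row with `id` and `seq`.
#' @export
align_bes <- function(read, index, params = alignment_params()) {
  align_bes_reads(data.frame(id = read$id, seq = read$seq,
                             stringsAsFactors = FALSE), index, params)
}

## does (plus-strand aln, minus-strand aln) form a consistent facing-inward
## pair? returns span or NA
pair_span <- function(a1, a2, params) {
  if (a1$chrom != a2$chrom) return(NA_real_)
  if (a1$strand == a2$strand) return(NA_real_)
  p <- if (a1$strand == "+") a1 else a2
  m <- if (a1$strand == "+") a2 else a1
  if (p$start >= m$end) return(NA_real_)   # must face inward
  span <- m$end - p$start
  if (span < params$min_span || span > params$max_span) return(NA_real_)
  span
}

status_row <- function(clone, status, color, chrom = NA, start = NA,
                       end = NA, orientation = NA, end_label = NA,
                       a1 = NULL, a2 = NULL) {
  data.frame(clone = clone, status = status, color = color,
             chrom = chrom, start = start, end = end,
             orientation = orientation, end_label = end_label,
             a1_chrom = if (is.null(a1)) NA else a1$chrom,
             a1_start = if (is.null(a1)) NA else a1$start,
             a1_end = if (is.null(a1)) NA else a1$end,
             a1_strand = if (is.null(a1)) NA else a1$strand,
             a2_chrom = if (is.null(a2)) NA else a2$chrom,
             a2_start = if (is.null(a2)) NA else a2$start,
             a2_end = if (is.null(a2)) NA else a2$end,
             a2_strand = if (is.null(a2)) NA else a2$strand,
             stringsAsFactors = FALSE)
}

#' Classify a mate pair from its two alignment lists
#'
#' Both ends uniquely aligned on one chromosome, on opposite strands facing
#' inward, 10-400 kb apart: consistent (green).  Both unique otherwise:
#' inconsistent (yellow) - the rearrangement signal.  One unique, the other
#' absent: single-end (blue).  Repetitive sides are passed through
#' [resolve_repetitive()]; a uniquely resolvable combination is adopted as
#' consistent (tan), otherwise the clone stays repetitive.  No alignments at
#' all: unmapped.
#'
#' @param alnsT7,alnsSP6 alignment data.frames for the two ends (possibly
#'   empty).
#' @param params [alignment_params()].
#' @param clone clone id for the output row.
#' @return one-row data.frame: clone, status, color, placement
#'   (chrom/start/end/orientation), end_label of the aligned end for
#'   single-end placements, and the two raw anchor alignments (a1_*, a2_*).
#' @export
classify_mate_pair <- function(alnsT7, alnsSP6,
                               params = alignment_params(),
                               clone = "clone") {
  state <- function(a) {
    if (is.null(a) || nrow(a) == 0) "absent"
    else if (any(a$unique)) "unique"
    else "repetitive"
  }
  s1 <- state(alnsT7); s2 <- state(alnsSP6)
  u <- function(a) a[a$unique, , drop = FALSE][1, , drop = FALSE]
  if (s1 == "unique" && s2 == "unique") {
    a1 <- u(alnsT7); a2 <- u(alnsSP6)
    span <- pair_span(a1, a2, params)
    if (!is.na(span))
      return(status_row(clone, "consistent", "green", a1$chrom,
                        min(a1$start, a2$start), max(a1$end, a2$end),
                        a1$strand, a1 = a1, a2 = a2))
    return(status_row(clone, "inconsistent", "yellow", a1 = a1, a2 = a2))
  }
  if (s1 == "unique" && s2 == "absent")
    return(status_row(clone, "single_end", "blue", u(alnsT7)$chrom,
                      u(alnsT7)$start, u(alnsT7)$end, u(alnsT7)$strand,
                      end_label = "T7", a1 = u(alnsT7)))
  if (s2 == "unique" && s1 == "absent")
    return(status_row(clone, "single_end", "blue", u(alnsSP6)$chrom,
                      u(alnsSP6)$start, u(alnsSP6)$end, u(alnsSP6)$strand,
                      end_label = "SP6", a2 = u(alnsSP6)))
  if (s1 == "absent" && s2 == "absent")
    return(status_row(clone, "unmapped", NA_character_))
  ## at least one repetitive side
  resolve_repetitive(alnsT7, alnsSP6, params, clone)
}

#' Resolve a repetitive mate pair
#'
#' Searches all combinations of the two hit lists; if exactly one
#' combination satisfies the consistency rule it is adopted (status
#' consistent, colour tan).  Zero or multiple consistent combinations leave
#' the clone unresolved (status repetitive, colour tan).
#'
#' @inheritParams classify_mate_pair
#' @return one-row status data.frame as in [classify_mate_pair()].
#' @export
resolve_repetitive <- function(alnsT7, alnsSP6,
                               params = alignment_params(),
                               clone = "clone") {
  n1 <- if (is.null(alnsT7)) 0L else nrow(alnsT7)
  n2 <- if (is.null(alnsSP6)) 0L else nrow(alnsSP6)
  if (n1 == 0 || n2 == 0)
    return(status_row(clone, "repetitive", "tan"))
  found <- NULL; n_found <- 0L
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    a1 <- alnsT7[i, , drop = FALSE]; a2 <- alnsSP6[j, , drop = FALSE]
    if (!is.na(pair_span(a1, a2, params))) {
      n_found <- n_found + 1L
      if (n_found == 1L) found <- list(a1 = a1, a2 = a2)
      if (n_found > 1L) break
    }
  }
  if (n_found == 1L)
    return(status_row(clone, "consistent", "tan", found$a1$chrom,
                      min(found$a1$start, found$a2$start),
                      max(found$a1$end, found$a2$end), found$a1$strand,
                      a1 = found$a1, a2 = found$a2))
  status_row(clone, "repetitive", "tan")
}

#' Classify all mate pairs of a clone set
#'
#' @param alns alignment table from [align_bes_reads()], with read ids
#'   `<clone>.T7` / `<clone>.SP6`.
#' @param clones clone table (ids define the universe; clones without reads
#'   are unmapped).
#' @param params [alignment_params()].
#' @return data.frame with one status row per clone.
#' @export
classify_mate_pairs <- function(alns, clones,
                                params = alignment_params()) {
  ids <- clones$id
  sp <- split(alns, alns$id)
  out <- lapply(ids, function(cl) {
    classify_mate_pair(sp[[paste0(cl, ".T7")]],
                       sp[[paste0(cl, ".SP6")]], params, cl)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Place single-end clones by library-default span
#'
#' A clone with only one aligned end is assigned an interval extending from
#' the aligned end inward (to the right of a plus-strand read, to the left
#' of a minus-strand read) by the library's default span, clipped at
#' chromosome bounds.
#'
#' @param statuses status table from [classify_mate_pairs()].
#' @param clones clone table (for the library of each clone).
#' @param spans named vector of default spans in bp per library (e.g.
#'   `c(CHORI = 200e3, TKNMI = 150e3)`).
#' @param chrom_lengths named vector of reference chromosome lengths.
#' @return statuses with single-end rows given chrom/start/end placements
#'   and a `clipped` logical column.
#' @export
place_single_end <- function(statuses, clones, spans, chrom_lengths) {
  statuses$clipped <- FALSE
  idx <- which(statuses$status == "single_end")
  for (i in idx) {
    lib <- clones$library[match(statuses$clone[i], clones$id)]
    if (is.na(lib) || !(lib %in% names(spans)))
      stopf("no default span configured for library '%s'", lib)
    span <- spans[[lib]]
    L <- chrom_lengths[[statuses$chrom[i]]]
    if (statuses$orientation[i] == "+") {
      s <- statuses$start[i]; e <- s + span
    } else {
      e <- statuses$end[i]; s <- e - span
    }
    if (s < 0 || e > L) statuses$clipped[i] <- TRUE
    statuses$start[i] <- max(0, s)
    statuses$end[i] <- min(L, e)
  }
  statuses
}

#' Read an external 12-column alignment table
#'
#' Accepts the standard tabular pairwise-alignment format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, evalue, bitscore) so external aligner output can substitute
#' for the built-in aligner.  Rows failing the identity/length/e-value
#' thresholds are dropped; uniqueness is recomputed from bitscore.
#'
#' @param path tab-separated alignment file without header.
#' @param params [alignment_params()].
#' @return alignment data.frame as from [align_bes_reads()].
#' @export
read_alignment_table <- function(path, params = alignment_params()) {
  x <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  colnames(x) <- c("id", "chrom", "pident", "length", "mismatch", "gapopen",
                   "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- x[x$pident / 100 >= params$min_identity &
           x$length >= params$min_length &
           x$evalue <= params$evalue_max &
           !(x$chrom %in% params$unplaced_names), , drop = FALSE]
  strand <- ifelse(x$sstart <= x$send, "+", "-")
  aln <- data.frame(id = x$id, chrom = x$chrom,
                    start = pmin(x$sstart, x$send) - 1L,
                    end = pmax(x$sstart, x$send),
                    strand = strand, identity = x$pident / 100,
                    length = x$length, score = x$bitscore,
                    stringsAsFactors = FALSE)
  aln <- aln[order(aln$id, -aln$score), , drop = FALSE]
  aln$unique <- FALSE
  aln$n_hits <- 0L
  for (ix in split(seq_len(nrow(aln)), aln$id)) {
    aln$n_hits[ix] <- length(ix)
    if (length(ix) == 1) aln$unique[ix] <- TRUE
    else if (aln$score[ix[1]] >= params$unique_margin * aln$score[ix[2]])
      aln$unique[ix[1]] <- TRUE
  }
  rownames(aln) <- NULL
  aln
}
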