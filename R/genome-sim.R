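## Synthetic genomes: a reference, and a derived genome produced from it by
## planted rearrangements with a full ground-truth lift-over.

#' Simulate a reference genome
#'
#' Generates independent random chromosomes with a given base composition and,
#' optionally, interspersed copies of a fixed repeat motif (to exercise
#' repetitive-read handling downstream).  Planted repeat intervals are
#' recorded in `S4Vectors::metadata()$repeats`.
#'
#' The default base composition (GC = 0.36) is a calibration: with
#' independent bases it reproduces the density of detectable restriction
#' bands observed in real BamHI/EcoRI/HaeIII capillary fingerprints of
#' 160-190 kb clones (about 54 bands per clone in the 35-500 bp window);
#' real avian GC (~0.42) over-produces frequent-cutter sites under an iid
#' model because real genomes cluster their motifs.
#'
#' @param n_chroms number of chromosomes.
#' @param lengths chromosome lengths in bp (recycled to `n_chroms`).
#' @param gc GC fraction, strictly between 0 and 1.
#' @param repeat_density fraction of bases covered by planted repeat copies.
#' @param repeat_length length in bp of the repeat motif.
#' @param seed integer RNG seed; the genome is deterministic given the seed.
#' @return a named [Biostrings::DNAStringSet] with `metadata()` fields
#'   `repeats` (data.frame chrom/start/end, 0-based half-open) and `params`.
#' @export
simulate_reference <- function(n_chroms = 1, lengths = 1e5, gc = 0.36,
                               repeat_density = 0, repeat_length = 500,
                               seed = 1) {
  if (any(lengths <= 0)) stopf("chromosome lengths must be positive")
  if (gc <= 0 || gc >= 1) stopf("gc must be strictly between 0 and 1")
  lengths <- as.integer(rep_len(lengths, n_chroms))
  set.seed(as.integer(seed))
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lengths, function(L) {
    paste(sample(names(base_p), L, replace = TRUE, prob = base_p),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(n_chroms))

  rep_log <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0))
  if (repeat_density > 0) {
    motif <- paste(sample(names(base_p), repeat_length, replace = TRUE,
                          prob = base_p), collapse = "")
    for (ci in seq_len(n_chroms)) {
      L <- lengths[ci]
      n_cop <- round(repeat_density * L / repeat_length)
      if (n_cop < 1) next
      ## place copies on a coarse grid to guarantee non-overlap
      slots <- seq(0L, L - repeat_length, by = repeat_length * 2L)
      if (length(slots) < n_cop)
        stopf("repeat density too high for chromosome of %d bp", L)
      starts <- sort(sample(slots, n_cop))
      s <- seqs[[ci]]
      for (st in starts)
        substr(s, st + 1L, st + repeat_length) <- motif
      seqs[[ci]] <- s
      rep_log <- rbind(rep_log, data.frame(
        chrom = names(seqs)[ci], start = starts,
        end = starts + repeat_length))
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  S4Vectors::metadata(out) <- list(
    repeats = rep_log,
    params = list(gc = gc, repeat_density = repeat_density,
                  repeat_length = repeat_length, seed = seed))
  out
}

## ---- rearrangement events ----------------------------------------------

new_event <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "rearrangement_event")
}

#' Rearrangement event constructors
#'
#' Events are expressed on the genome state at their turn (0-based half-open
#' intervals) and applied in list order by [apply_rearrangements()].
#'
#' @param chrom chromosome name the event acts on.
#' @param start,end half-open interval of the affected segment.
#' @param pos fission point.
#' @param dest_chrom,dest_pos destination locus for duplications and
#'   transpositions.
#' @return an object of class `rearrangement_event`.
#' @name rearrangement_events
NULL

#' @rdname rearrangement_events
#' @export
inversion <- function(chrom, start, end)
  new_event("inversion", chrom = chrom, start = as.integer(start),
            end = as.integer(end))

#' @rdname rearrangement_events
#' @export
centric_fission <- function(chrom, pos)
  new_event("centric_fission", chrom = chrom, pos = as.integer(pos))

#' @rdname rearrangement_events
#' @export
segmental_duplication <- function(chrom, start, end, dest_chrom, dest_pos)
  new_event("segmental_duplication", chrom = chrom, start = as.integer(start),
            end = as.integer(end), dest_chrom = dest_chrom,
            dest_pos = as.integer(dest_pos))

#' @rdname rearrangement_events
#' @export
transposition <- function(chrom, start, end, dest_chrom, dest_pos)
  new_event("transposition", chrom = chrom, start = as.integer(start),
            end = as.integer(end), dest_chrom = dest_chrom,
            dest_pos = as.integer(dest_pos))

#' @export
print.rearrangement_event <- function(x, ...) {
  flds <- vapply(setdiff(names(x), "kind"),
                 function(f) paste0(f, "=", x[[f]]), character(1))
  cat("<", x$kind, "> ", paste(flds, collapse = " "), "\n", sep = "")
  invisible(x)
}

## ---- lift-over bookkeeping ---------------------------------------------

identity_liftover <- function(seqs) {
  data.frame(der_chrom = names(seqs), der_start = 0L,
             der_end = nchar(seqs), ref_chrom = names(seqs),
             ref_start = 0L, ref_end = nchar(seqs),
             strand = "+", duplicate = FALSE,
             stringsAsFactors = FALSE)
}

## ensure a piece boundary exists at derived position `pos` on `chrom`
lift_split <- function(lift, chrom, pos) {
  hit <- which(lift$der_chrom == chrom & lift$der_start < pos &
                 lift$der_end > pos)
  if (length(hit) == 0) return(lift)
  stopifnot(length(hit) == 1)
  r <- lift[hit, ]
  L1 <- pos - r$der_start
  left <- r; right <- r
  left$der_end <- pos
  right$der_start <- pos
  if (r$strand == "+") {
    left$ref_end <- r$ref_start + L1
    right$ref_start <- r$ref_start + L1
  } else {
    left$ref_start <- r$ref_end - L1
    right$ref_end <- r$ref_end - L1
  }
  rbind(lift[seq_len(hit - 1), , drop = FALSE], left, right,
        lift[-seq_len(hit), , drop = FALSE])
}

lift_order <- function(lift) lift[order(lift$der_chrom, lift$der_start), ]

#' Apply planted rearrangements to a reference genome
#'
#' Applies inversions, centric fissions, segmental duplications and
#' transpositions in list order.  An inversion reverse-complements its
#' interval in place; a fission splits a chromosome into `<chrom>_f1` and
#' `<chrom>_f2`; a duplication inserts a copy of the segment at the
#' destination locus (the copy is flagged `duplicate` in the lift-over); a
#' transposition excises the segment and re-inserts it at the destination.
#' The lift-over map is maintained piecewise so that every derived base maps
#' back to its reference origin and orientation.
#'
#' @param ref reference genome ([Biostrings::DNAStringSet]).
#' @param events list of [rearrangement_events].
#' @return object of class `derived_genome`: list with `seq`
#'   (`DNAStringSet`), `event_log`, and `liftover` (data.frame with columns
#'   der_chrom, der_start, der_end, ref_chrom, ref_start, ref_end, strand,
#'   duplicate; 0-based half-open).
#' @export
apply_rearrangements <- function(ref, events = list()) {
  if (inherits(events, "rearrangement_event")) events <- list(events)
  seqs <- as.character(ref)
  lift <- identity_liftover(seqs)

  for (i in seq_along(events)) {
    ev <- events[[i]]
    chk <- function(cond, what)
      if (!cond) stopf("event %d (%s): %s", i, ev$kind, what)
    chk(ev$chrom %in% names(seqs), paste("unknown chromosome", ev$chrom))
    L <- nchar(seqs[[ev$chrom]])
    switch(ev$kind,
      inversion = {
        chk(ev$start >= 0 && ev$end <= L && ev$end > ev$start,
            "interval out of bounds")
        s <- ev$start; e <- ev$end
        lift <- lift_split(lift, ev$chrom, s)
        lift <- lift_split(lift, ev$chrom, e)
        sel <- lift$der_chrom == ev$chrom & lift$der_start >= s &
          lift$der_end <= e
        ds <- lift$der_start[sel]; de <- lift$der_end[sel]
        lift$der_start[sel] <- s + (e - de)
        lift$der_end[sel] <- s + (e - ds)
        lift$strand[sel] <- ifelse(lift$strand[sel] == "+", "-", "+")
        x <- seqs[[ev$chrom]]
        substr(x, s + 1L, e) <- revcomp_chr(substr(x, s + 1L, e))
        seqs[[ev$chrom]] <- x
      },
      centric_fission = {
        chk(ev$pos > 0 && ev$pos < L, "fission point out of bounds")
        p <- ev$pos
        lift <- lift_split(lift, ev$chrom, p)
        n1 <- paste0(ev$chrom, "_f1"); n2 <- paste0(ev$chrom, "_f2")
        chk(!(n1 %in% names(seqs)) && !(n2 %in% names(seqs)),
            "fission product name collision")
        sel1 <- lift$der_chrom == ev$chrom & lift$der_end <= p
        sel2 <- lift$der_chrom == ev$chrom & lift$der_start >= p
        lift$der_chrom[sel1] <- n1
        lift$der_chrom[sel2] <- n2
        lift$der_start[sel2] <- lift$der_start[sel2] - p
        lift$der_end[sel2] <- lift$der_end[sel2] - p
        x <- seqs[[ev$chrom]]
        keep <- setdiff(names(seqs), ev$chrom)
        seqs <- c(seqs[keep],
                  setNames(c(substr(x, 1L, p), substr(x, p + 1L, L)),
                           c(n1, n2)))
      },
      segmental_duplication = {
        chk(ev$start >= 0 && ev$end <= L && ev$end > ev$start,
            "interval out of bounds")
        chk(ev$dest_chrom %in% names(seqs), "unknown destination chromosome")
        dl <- nchar(seqs[[ev$dest_chrom]])
        chk(ev$dest_pos >= 0 && ev$dest_pos <= dl,
            "destination out of bounds")
        chk(!(ev$dest_chrom == ev$chrom && ev$dest_pos > ev$start &&
                ev$dest_pos < ev$end),
            "destination inside the duplicated interval")
        s <- ev$start; e <- ev$end; len <- e - s
        lift <- lift_split(lift, ev$chrom, s)
        lift <- lift_split(lift, ev$chrom, e)
        src <- lift[lift$der_chrom == ev$chrom & lift$der_start >= s &
                      lift$der_end <= e, , drop = FALSE]
        seg <- substr(seqs[[ev$chrom]], s + 1L, e)
        lift <- lift_split(lift, ev$dest_chrom, ev$dest_pos)
        shift <- lift$der_chrom == ev$dest_chrom &
          lift$der_start >= ev$dest_pos
        lift$der_start[shift] <- lift$der_start[shift] + len
        lift$der_end[shift] <- lift$der_end[shift] + len
        src$der_chrom <- ev$dest_chrom
        off <- src$der_start - s
        src$der_start <- ev$dest_pos + off
        src$der_end <- src$der_start + (src$der_end - (s + off))
        src$duplicate <- TRUE
        lift <- rbind(lift, src)
        x <- seqs[[ev$dest_chrom]]
        seqs[[ev$dest_chrom]] <- paste0(substr(x, 1L, ev$dest_pos), seg,
                                        substr(x, ev$dest_pos + 1L, dl))
      },
      transposition = {
        chk(ev$start >= 0 && ev$end <= L && ev$end > ev$start,
            "interval out of bounds")
        chk(ev$dest_chrom %in% names(seqs), "unknown destination chromosome")
        chk(!(ev$dest_chrom == ev$chrom && ev$dest_pos >= ev$start &&
                ev$dest_pos <= ev$end),
            "destination inside the moved interval")
        s <- ev$start; e <- ev$end; len <- e - s
        lift <- lift_split(lift, ev$chrom, s)
        lift <- lift_split(lift, ev$chrom, e)
        isrc <- lift$der_chrom == ev$chrom & lift$der_start >= s &
          lift$der_end <= e
        src <- lift[isrc, , drop = FALSE]
        lift <- lift[!isrc, , drop = FALSE]
        seg <- substr(seqs[[ev$chrom]], s + 1L, e)
        x <- seqs[[ev$chrom]]
        seqs[[ev$chrom]] <- paste0(substr(x, 1L, s), substr(x, e + 1L, L))
        after <- lift$der_chrom == ev$chrom & lift$der_start >= e
        lift$der_start[after] <- lift$der_start[after] - len
        lift$der_end[after] <- lift$der_end[after] - len
        dpos <- ev$dest_pos
        if (ev$dest_chrom == ev$chrom && dpos >= e) dpos <- dpos - len
        dl <- nchar(seqs[[ev$dest_chrom]])
        chk(dpos >= 0 && dpos <= dl, "destination out of bounds")
        lift <- lift_split(lift, ev$dest_chrom, dpos)
        shift <- lift$der_chrom == ev$dest_chrom & lift$der_start >= dpos
        lift$der_start[shift] <- lift$der_start[shift] + len
        lift$der_end[shift] <- lift$der_end[shift] + len
        src$der_chrom <- ev$dest_chrom
        new_start <- dpos + (src$der_start - s)
        new_end <- dpos + (src$der_end - s)
        src$der_start <- new_start
        src$der_end <- new_end
        x <- seqs[[ev$dest_chrom]]
        seqs[[ev$dest_chrom]] <- paste0(substr(x, 1L, dpos), seg,
                                        substr(x, dpos + 1L, dl))
        lift <- rbind(lift, src)
      },
      stopf("event %d: unknown kind '%s'", i, ev$kind))
  }

  structure(list(seq = Biostrings::DNAStringSet(seqs),
                 event_log = events,
                 liftover = lift_order(lift)),
            class = "derived_genome")
}

#' @export
print.derived_genome <- function(x, ...) {
  cat("<derived_genome> ", length(x$seq), " chromosome(s), ",
      length(x$event_log), " event(s), ",
      nrow(x$liftover), " lift-over piece(s)\n", sep = "")
  invisible(x)
}

#' Map derived-genome coordinates back to the reference
#'
#' @param dg a `derived_genome`.
#' @param chrom derived chromosome name (recycled).
#' @param pos 0-based derived positions.
#' @return data.frame with ref_chrom, ref_pos, strand, duplicate; NA rows for
#'   positions outside any lift-over piece.
#' @export
lift_to_reference <- function(dg, chrom, pos) {
  chrom <- rep_len(chrom, length(pos))
  lift <- dg$liftover
  out <- data.frame(ref_chrom = NA_character_, ref_pos = NA_integer_,
                    strand = NA_character_, duplicate = NA,
                    stringsAsFactors = FALSE)[rep(1, length(pos)), ]
  rownames(out) <- NULL
  for (i in seq_along(pos)) {
    r <- lift[lift$der_chrom == chrom[i] & lift$der_start <= pos[i] &
                lift$der_end > pos[i], , drop = FALSE]
    if (nrow(r) == 0) next
    r <- r[1, ]
    out$ref_chrom[i] <- r$ref_chrom
    out$ref_pos[i] <- if (r$strand == "+")
      r$ref_start + (pos[i] - r$der_start)
    else
      r$ref_end - 1L - (pos[i] - r$der_start)
    out$strand[i] <- r$strand
    out$duplicate[i] <- r$duplicate
  }
  out
}

## chromosome lengths of either a DNAStringSet or a derived_genome
genome_lengths <- function(g) {
  if (inherits(g, "derived_genome")) g <- g$seq
  setNames(Biostrings::width(g), names(g))
}

genome_seqs <- function(g) {
  if (inherits(g, "derived_genome")) g$seq else g
}
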