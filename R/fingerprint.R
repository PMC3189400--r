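## In-silico restriction fingerprints: end-labeled digest model, sizing
## noise, quality filtering, and the plain-text bands file format.

#' Digest parameters
#'
#' Models a high-information-content fingerprinting chemistry: fragments cut
#' by one of the labeled enzymes carry a detectable dye label, and a
#' frequent cutter reduces labeled fragments to capillary-sizable lengths.
#' Only fragments with at least one labeled end, sized within the window,
#' become bands.
#'
#' Band values are stored as integers in capillary sizing units of
#' `1/size_scale` bp (default tenths of a bp), the convention for
#' high-information-content capillary fingerprints; the matching tolerance
#' is expressed in those units, so the default tolerance 7 means 0.7 bp.
#'
#' @param labeled_motifs recognition sequences of the labeled enzymes
#'   (defaults stand for BamHI and EcoRI).
#' @param cutter_motif frequent-cutter recognition sequence (stands for
#'   HaeIII).
#' @param window detectable band-size window in bp, default `c(35, 500)`.
#' @param sizing_sd capillary sizing error (bp standard deviation).
#' @param tolerance band-matching tolerance in sizing units (absolute).
#' @param size_scale sizing units per bp (default 10: band values are
#'   tenths of a bp).
#' @return list of class `digest_params`.
#' @export
digest_params <- function(labeled_motifs = c("GGATCC", "GAATTC"),
                          cutter_motif = "GGCC", window = c(35, 500),
                          sizing_sd = 0.2, tolerance = 7,
                          size_scale = 10) {
  if (window[1] >= window[2]) stopf("window min must be below max")
  if (sizing_sd < 0 || tolerance < 0) stopf("sd and tolerance must be >= 0")
  structure(list(labeled_motifs = toupper(labeled_motifs),
                 cutter_motif = toupper(cutter_motif),
                 window = as.integer(window), sizing_sd = sizing_sd,
                 tolerance = as.integer(tolerance),
                 size_scale = as.integer(size_scale)),
            class = "digest_params")
}

## cut positions of a recognition motif: at the centre of each site (both
## strands for non-palindromic motifs), so digestion commutes with reverse
## complementation for the palindromic default enzymes
motif_cuts <- function(subject, motif) {
  s <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(motif), subject)) - 1L
  rc <- revcomp_chr(motif)
  if (rc != motif)
    s <- c(s, Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(rc), subject)) - 1L)
  sort(unique(s + nchar(motif) %/% 2L))
}

#' Noise-free restriction digest of one clone
#'
#' Cuts the sequence at every motif occurrence (both strands for
#' non-palindromic motifs); a fragment becomes a band iff at least one of
#' its ends is a labeled-enzyme cut; bands outside the size window are
#' dropped.  Sequence ends count as unlabeled.
#'
#' @param sequence clone insert (character or [Biostrings::DNAString]).
#' @param params [digest_params()].
#' @return sorted integer vector of band sizes in sizing units
#'   (`size_scale` per bp; possibly empty).
#' @export
digest_clone <- function(sequence, params = digest_params()) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  L <- length(sequence)
  if (L == 0) stopf("sequence must be non-empty")
  lab <- sort(unique(unlist(lapply(params$labeled_motifs, motif_cuts,
                                   subject = sequence))))
  cutr <- motif_cuts(sequence, params$cutter_motif)
  bounds <- sort(unique(c(0L, lab, cutr, L)))
  sizes <- diff(bounds)
  left <- bounds[-length(bounds)]
  right <- bounds[-1]
  labeled <- (left %in% lab) | (right %in% lab)
  sizes <- sizes[labeled]
  sizes <- sizes[sizes >= params$window[1] & sizes <= params$window[2]]
  sort(sizes * params$size_scale)
}

#' Fingerprint a set of clones
#'
#' Convenience wrapper: digests every non-empty clone and optionally applies
#' sizing noise.
#'
#' @param genome the genome the clones were sampled from.
#' @param clones clone table.
#' @param params [digest_params()]; its `sizing_sd` drives the noise.
#' @param noise apply sizing noise (`params$sizing_sd`)?
#' @param seed RNG seed for the noise model.
#' @return named list of sorted integer band vectors.
#' @export
fingerprint_clones <- function(genome, clones, params = digest_params(),
                               noise = TRUE, seed = 1) {
  ins <- clone_sequences(genome, clones)
  fps <- lapply(seq_along(ins), function(i) digest_clone(ins[[i]], params))
  names(fps) <- names(ins)
  if (noise && params$sizing_sd > 0) {
    set.seed(as.integer(seed))
    fps <- lapply(fps, function(fp)
      add_sizing_noise(fp, params$sizing_sd, seed = NULL,
                       window = params$window,
                       size_scale = params$size_scale))
  }
  fps
}

#' Add capillary sizing noise to a fingerprint
#'
#' Each band is perturbed by independent Normal(0, sd) error, rounded to an
#' integer, re-filtered to the size window and re-sorted.
#'
#' @param fp integer band vector (sizing units).
#' @param sd sizing error standard deviation in bp.
#' @param seed RNG seed, or NULL to use the current RNG state.
#' @param window band-size window in bp used for re-filtering.
#' @param size_scale sizing units per bp (must match the digest).
#' @return perturbed sorted integer band vector.
#' @export
add_sizing_noise <- function(fp, sd, seed = NULL, window = c(35, 500),
                             size_scale = 10) {
  if (sd < 0) stopf("sd must be >= 0")
  if (sd == 0 || length(fp) == 0) return(fp)
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- as.integer(round(fp + rnorm(length(fp), 0, sd * size_scale)))
  w <- as.integer(window) * size_scale
  sort(x[x >= w[1] & x <= w[2]])
}

#' Quality-filter fingerprints by band count
#'
#' Clones with too few bands carry too little overlap information; clones
#' with extreme counts are likely artifacts.
#'
#' @param fps named list of band vectors.
#' @param min_bands,max_bands inclusive retention bounds (defaults 16 and
#'   320).
#' @return list with `valid` and `rejected` (both named lists).
#' @export
quality_filter <- function(fps, min_bands = 16, max_bands = 320) {
  n <- lengths(fps)
  keep <- n >= min_bands & n <= max_bands
  message(sprintf("quality_filter: %d retained, %d rejected",
                  sum(keep), sum(!keep)))
  list(valid = fps[keep], rejected = fps[!keep])
}

#' Write fingerprints to a bands file
#'
#' Plain text, one clone per block: a header line `> <clone_id> <n_bands>`
#' followed by one integer band size per line, ascending.
#'
#' @param fps named list of band vectors.
#' @param path output file.
#' @export
write_bands_file <- function(fps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(fps)) {
    writeLines(sprintf("> %s %d", id, length(fps[[id]])), con)
    if (length(fps[[id]]))
      writeLines(as.character(fps[[id]]), con)
  }
  invisible(path)
}

#' Read a bands file
#'
#' Tolerates blank lines and `#` comments.
#'
#' @param path bands file written by [write_bands_file()] or compatible.
#' @return named list of sorted integer band vectors.
#' @export
read_bands_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- startsWith(lines, ">")
  if (!any(hdr)) return(setNames(list(), character(0)))
  grp <- cumsum(hdr)
  ids <- vapply(strsplit(sub("^>\\s*", "", lines[hdr]), "\\s+"),
                `[`, character(1), 1)
  fps <- lapply(split(lines[!hdr], grp[!hdr]), function(v) sort(as.integer(v)))
  out <- rep(list(integer(0)), sum(hdr))
  names(out) <- ids
  out[as.integer(names(fps))] <- fps
  names(out) <- ids
  out
}
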