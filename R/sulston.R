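## Sulston-type coincidence scoring of restriction fingerprints.

#' Sulston scoring parameters
#'
#' @param tolerance band-matching tolerance t in sizing units (default 7 =
#'   0.7 bp at the default tenth-of-a-bp sizing).
#' @param gel_states number of distinguishable integer band values G
#'   (default 4651 = (500 - 35) x 10 + 1 for the 35-500 bp window sized in
#'   tenths of a bp).
#' @param cutoff score threshold below which two clones are considered to
#'   overlap.
#' @return list of class `sulston_params`.
#' @export
sulston_params <- function(tolerance = 7, gel_states = 4651,
                           cutoff = 1e-08) {
  if (gel_states <= 2 * tolerance + 1)
    stopf("gel_states must exceed 2*tolerance + 1")
  if (cutoff <= 0 || cutoff >= 1) stopf("cutoff must be in (0,1)")
  structure(list(tolerance = as.integer(tolerance),
                 gel_states = as.integer(gel_states), cutoff = cutoff),
            class = "sulston_params")
}

#' Count shared bands between two fingerprints
#'
#' Greedy one-to-one pairing over the two ascending band lists: the pointer
#' at the smaller value advances; a pair is made when the values are within
#' the tolerance.  Symmetric by construction; ties broken
#' smallest-size-first.
#'
#' @param fpA,fpB sorted integer band vectors.
#' @param t tolerance in sizing units.
#' @return integer number of matched band pairs.
#' @export
count_shared_bands <- function(fpA, fpB, t = 7) {
  .shared_bands_cpp(as.integer(fpA), as.integer(fpB), as.integer(t))
}

## binomial-tail coincidence probability; nL/nH are the smaller/larger band
## counts, m the observed shared count
sulston_prob <- function(nL, nH, m, t, G) {
  p <- 1 - (1 - (2 * t + 1) / G)^nH
  pbinom(m - 1, nL, p, lower.tail = FALSE)
}

#' Sulston coincidence score of two fingerprints
#'
#' Probability that the two band lists share at least the observed number of
#' bands by coincidence, under the model that each band of the smaller clone
#' independently matches the larger clone with probability
#' `p = 1 - (1 - (2t+1)/G)^nH`.  Lower scores indicate stronger overlap
#' evidence; `m = 0` gives a score of 1.
#'
#' @param fpA,fpB sorted integer band vectors.
#' @param params [sulston_params()].
#' @return numeric score in `[0, 1]`.
#' @export
sulston_score <- function(fpA, fpB, params = sulston_params()) {
  m <- count_shared_bands(fpA, fpB, params$tolerance)
  nL <- min(length(fpA), length(fpB))
  nH <- max(length(fpA), length(fpB))
  sulston_prob(nL, nH, m, params$tolerance, params$gel_states)
}

## all-pairs shared-band and score matrices for a fingerprint list
pairwise_sulston <- function(fps, params) {
  n <- length(fps)
  m <- .pairwise_shared_cpp(unname(lapply(fps, as.integer)),
                            params$tolerance)
  nb <- lengths(fps)
  nL <- outer(nb, nb, pmin)
  nH <- outer(nb, nb, pmax)
  p <- 1 - (1 - (2 * params$tolerance + 1) / params$gel_states)^nH
  S <- matrix(pbinom(as.vector(m) - 1, as.vector(nL), as.vector(p),
                     lower.tail = FALSE), n, n)
  diag(S) <- 0
  dimnames(m) <- dimnames(S) <- list(names(fps), names(fps))
  list(m = m, S = S)
}

#' Monte-Carlo coincidence simulation
#'
#' Estimates the probability that two band lists drawn iid-uniform over `G`
#' integer states share at least `m` bands under the greedy one-to-one
#' matcher.  Serves as a simulation cross-check of the analytic
#' [sulston_score()]; uses R's RNG, so `set.seed()` controls
#' reproducibility.
#'
#' @param nL,nH band counts of the two lists.
#' @param m shared-band threshold.
#' @param t tolerance in bp.
#' @param G number of band states.
#' @param trials number of simulated pairs.
#' @return estimated tail probability.
#' @export
simulate_coincidence <- function(nL, nH, m, t = 7, G = 4651, trials = 1e5) {
  .coincidence_mc_cpp(as.integer(nL), as.integer(nH), as.integer(t),
                      as.integer(G), as.integer(m), as.integer(trials))
}
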