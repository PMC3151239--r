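# Expected likelihood weights over a candidate-tree set, via RELL
# bootstrap: sites are resampled with replacement, per-candidate replicate
# log-likelihoods are sums of resampled sitewise values (no re-optimisation),
# and each replicate assigns candidates their normalised likelihood weights.

#' Expected likelihood weights (RELL bootstrap)
#'
#' For each bootstrap replicate, sites are resampled with replacement, the
#' replicate log-likelihood of each candidate is the sum of its resampled
#' sitewise log-likelihoods, and the candidates receive weights
#' `exp(l_i - l_max) / sum_j exp(l_j - l_max)` (log-sum-exp form). The
#' expected likelihood weight of a candidate is its mean weight over the
#' `B` replicates. Weights sum to 1 over the candidate set and quantify the
#' relative weight of evidence for each candidate topology.
#'
#' @param site_ll Matrix of sitewise log-likelihoods, candidates in rows,
#'   sites in columns (candidate names kept if present).
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return An object of class `ogd_elw`: numeric vector of ELW values (one
#'   per candidate, summing to 1) with attributes `B` and `seed`.
#' @export
expected_likelihood_weights <- function(site_ll, B = 1000L, seed = 1L) {
  site_ll <- as.matrix(site_ll)
  if (nrow(site_ll) < 1L || ncol(site_ll) < 1L) {
    abort("Need at least one candidate and one site.")
  }
  if (any(!is.finite(site_ll))) {
    bad <- which(apply(!is.finite(site_ll), 1L, any))
    abort(paste0("Non-finite site log-likelihoods for candidate(s) ",
                 paste(bad, collapse = ", "), "."))
  }
  B <- as.integer(B)
  if (B < 1L) abort("`B` must be >= 1.")
  s <- ncol(site_ll)
  counts <- withr::with_seed(as.integer(seed),
                             rmultinom(B, s, rep(1 / s, s)))
  repl <- site_ll %*% counts                     # candidates x B
  mx <- apply(repl, 2L, max)
  w <- exp(repl - rep(mx, each = nrow(repl)))
  w <- w / rep(colSums(w), each = nrow(w))
  elw <- rowMeans(w)
  structure(setNames(elw, rownames(site_ll)),
            class = "ogd_elw", B = B, seed = as.integer(seed))
}

#' @export
print.ogd_elw <- function(x, ...) {
  cat("Expected likelihood weights over", length(x), "candidates (B =",
      attr(x, "B"), ")\n")
  print(unclass(x)[order(-unclass(x))][seq_len(min(5L, length(x)))])
  invisible(x)
}

#' ELW confidence set
#'
#' The smallest prefix of the ELW-descending ranking whose cumulative weight
#' reaches `level` (ties broken by candidate order).
#'
#' @param elw An `ogd_elw` or plain numeric vector of weights.
#' @param level Cumulative weight to cover, in `(0, 1]`.
#' @return Integer indices of the selected candidates, in ranking order.
#' @export
confidence_set <- function(elw, level = 0.95) {
  if (level <= 0 || level > 1) abort("`level` must be in (0, 1].")
  w <- as.numeric(elw)
  ord <- order(-w, seq_along(w))
  if (level == 1) return(ord[w[ord] > 0])
  cum <- cumsum(w[ord])
  ord[seq_len(which(cum >= level - 1e-12)[1L])]
}
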