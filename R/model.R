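# Amino-acid substitution model: JTT exchangeabilities with model or
# empirical ("+F") stationary frequencies, discrete-gamma rate categories.

#' Standard amino-acid ordering
#'
#' The 20 amino acids in the ordering used throughout the package
#' (the ordering of Jones et al. 1992 / the PAML `jones.dat` file):
#' `A R N D C Q E G H I L K M F P S T W Y V`.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Residues treated as missing data (gap / ambiguity codes).
MISSING_RESIDUES <- c("-", ".", "?", "*", "X", "B", "Z", "J", "U", "O")

# JTT exchangeabilities, lower triangle by row (row 2..20, columns 1..row-1),
# and stationary frequencies. Values as published by Jones, Taylor & Thornton
# (1992, CABIOS 8:275-282), in the form distributed with standard
# phylogenetics software (PAML's jones.dat).
JTT_EXCHANGE <- c(
   58,
   54,  45,
   81,  16, 528,
   56, 113,  34,  10,
   57, 310,  86,  49,   9,
  105,  29,  58, 767,   5, 323,
  179, 137,  81, 130,  59,  26, 119,
   27, 328, 391, 112,  69, 597,  26,  23,
   36,  22,  47,  11,  17,   9,  12,   6,  16,
   30,  38,  12,   7,  23,  72,   9,   6,  56, 229,
   35, 646, 263,  26,   7, 292, 181,  27,  45,  21,  14,
   54,  44,  30,  15,  31,  43,  18,  14,  33, 479, 388,  65,
   15,   5,  10,   4,  78,   4,   5,   5,  40,  89, 248,   4,  43,
  194,  74,  15,  15,  14, 164,  18,  24, 115,  10, 102,  21,  16,  17,
  378, 101, 503,  59, 223,  53,  30, 201,  73,  40,  59,  47,  29,  92, 285,
  475,  64, 232,  38,  42,  51,  32,  33,  46, 245,  25, 103, 226,  12, 118, 477,
    9, 126,   8,   4, 115,  18,  10,  55,   8,   9,  52,  10,  24,  53,   6,  35,  12,
   11,  20,  70,  46, 209,  24,   7,   8, 573,  32,  24,   8,  18, 536,  10,  63,  21,  71,
  298,  17,  16,  31,  62,  20,  45,  47,  11, 961, 180,  14, 323,  62,  23,  38, 112,  25,  16
)

JTT_FREQS <- c(
  0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
  0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
  0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005
)

jtt_exchange_matrix <- function() {
  s <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  k <- 1L
  for (i in 2:20) {
    for (j in 1:(i - 1L)) {
      s[i, j] <- s[j, i] <- JTT_EXCHANGE[k]
      k <- k + 1L
    }
  }
  s
}

#' Construct the JTT substitution model
#'
#' Builds a reversible rate matrix `Q` from the published JTT
#' exchangeabilities and either the model's own stationary frequencies or
#' empirical frequencies observed in an alignment (the "+F" convention).
#' `Q` is normalised so that the expected number of substitutions per unit
#' branch length is 1, i.e. branch lengths are in substitutions per site.
#'
#' @param frequencies Either the string `"model"` (JTT frequencies) or a
#'   numeric vector of 20 stationary frequencies summing to 1, in
#'   [AA_ALPHABET] order (e.g. from [empirical_frequencies()]).
#' @return An object of class `ogd_model`: list with the rate matrix `Q`,
#'   frequencies `pi`, and a cached spectral decomposition used by
#'   [transition_probabilities()].
#' @examples
#' m <- jtt_model()
#' rowSums(m$Q)            # ~0
#' -sum(m$pi * diag(m$Q))  # 1
#' @export
jtt_model <- function(frequencies = "model") {
  if (is.character(frequencies)) {
    if (!identical(frequencies, "model")) {
      abort("`frequencies` must be \"model\" or a numeric vector of length 20.")
    }
    pi <- JTT_FREQS / sum(JTT_FREQS)
  } else {
    pi <- as.numeric(frequencies)
    if (length(pi) != 20 || any(!is.finite(pi)) || any(pi <= 0)) {
      abort("Empirical frequencies must be 20 positive finite values.")
    }
    if (abs(sum(pi) - 1) > 1e-6) {
      abort("Empirical frequencies must sum to 1.")
    }
    pi <- pi / sum(pi)
  }
  names(pi) <- AA_ALPHABET

  s <- jtt_exchange_matrix()
  q <- s * rep(pi, each = 20)   # Q_ij = S_ij * pi_j
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  mu <- -sum(pi * diag(q))      # expected rate; rescale to 1 subst/site
  q <- q / mu

  # spectral decomposition of the pi-symmetrised matrix for fast exp(Qt)
  sq <- sqrt(pi)
  b <- q * (sq / rep(sq, each = 20))  # diag(sq) Q diag(1/sq), symmetric
  b <- (b + t(b)) / 2
  eig <- eigen(b, symmetric = TRUE)
  structure(
    list(
      Q = q,
      pi = pi,
      eigenvalues = eig$values,
      U = eig$vectors / sq,           # diag(1/sq) %*% V
      Uinv = t(eig$vectors) * rep(sq, each = 20)  # t(V) %*% diag(sq)
    ),
    class = "ogd_model"
  )
}

#' @export
print.ogd_model <- function(x, ...) {
  cat("JTT amino-acid substitution model\n")
  cat("  frequencies:",
      if (max(abs(x$pi - JTT_FREQS / sum(JTT_FREQS))) < 1e-12) "model" else "empirical",
      "\n")
  cat("  rate normalisation: 1 expected substitution per unit branch length\n")
  invisible(x)
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q * t * rate)` for a branch of length `t` (substitutions per
#' site) and a relative rate (a discrete-gamma category rate, default 1).
#'
#' @param model An `ogd_model` from [jtt_model()].
#' @param t Branch length, `>= 0`.
#' @param rate Relative rate multiplier, default 1.
#' @return 20x20 stochastic matrix (rows sum to 1).
#' @export
transition_probabilities <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "ogd_model"))
  if (!is.finite(t) || t < 0) abort("Branch length `t` must be finite and >= 0.")
  p <- model$U %*% (exp(model$eigenvalues * t * rate) * model$Uinv)
  p[p < 0] <- 0
  dimnames(p) <- dimnames(model$Q)
  p
}

#' Discrete-gamma rate heterogeneity
#'
#' Discretises a Gamma(alpha, alpha) rate distribution (mean 1) into `ncat`
#' equal-probability categories, using the mean rate within each category
#' (Yang 1994). The category rates average exactly to 1.
#'
#' @param alpha Gamma shape parameter, `> 0`.
#' @param ncat Number of categories, `>= 1`.
#' @return An object of class `ogd_rates`: list with `alpha`, `ncat`, and the
#'   strictly increasing category rates `rates`.
#' @examples
#' discrete_gamma(0.5, 4)$rates
#' @export
discrete_gamma <- function(alpha, ncat) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0) {
    abort("`alpha` must be a single positive number.")
  }
  ncat <- as.integer(ncat)
  if (ncat < 1) abort("`ncat` must be >= 1.")
  if (ncat == 1L) {
    r <- 1
  } else {
    cuts <- qgamma(seq_len(ncat - 1L) / ncat, shape = alpha, rate = alpha)
    upper <- pgamma(c(cuts, Inf), shape = alpha + 1, rate = alpha)
    lower <- pgamma(c(0, cuts), shape = alpha + 1, rate = alpha)
    r <- ncat * (upper - lower)   # E[X | category] since E[X] = 1
    r <- r / mean(r)              # exact mean-1 guard against rounding
  }
  structure(list(alpha = alpha, ncat = ncat, rates = r), class = "ogd_rates")
}

#' @export
print.ogd_rates <- function(x, ...) {
  cat("Discrete-gamma rates: alpha =", x$alpha, ", ", x$ncat, "categories\n")
  cat(" ", format(x$rates, digits = 4), "\n")
  invisible(x)
}

category_rates <- function(rates) {
  if (is.null(rates)) return(1)
  stopifnot(inherits(rates, "ogd_rates"))
  rates$rates
}

#' Empirical amino-acid frequencies of an alignment
#'
#' Observed residue proportions, with gaps and ambiguity codes excluded and
#' unobserved residues floored at a small pseudo-frequency so the rate matrix
#' stays irreducible.
#'
#' @param alignment Character matrix (taxa x sites) of amino-acid states, as
#'   returned by [read_alignment()] or [evolve_alignment()].
#' @param floor Pseudo-frequency for unobserved residues (default `1e-6`).
#' @return Named numeric vector of 20 frequencies summing to 1.
#' @export
empirical_frequencies <- function(alignment, floor = 1e-6) {
  enc <- encode_alignment(alignment)
  counts <- tabulate(enc[!is.na(enc)], nbins = 20L)
  if (sum(counts) == 0) {
    abort("Alignment contains no unambiguous residues.")
  }
  p <- counts / sum(counts)
  p[p < floor] <- floor
  p <- p / sum(p)
  setNames(p, AA_ALPHABET)
}
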