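#' @keywords internal
"_PACKAGE"

# Canonical 20-letter amino-acid alphabet, PAML ordering.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Residues treated as missing data alongside the gap character: ambiguity
# codes and the rare translated residues.
AA_MISSING <- c("-", ".", "B", "Z", "X", "U", "O", "J", "*", "?")

# Jones-Taylor-Thornton (1992) accepted point mutation counts, strict lower
# triangle in column-major order over the PAML alphabet above. These integers
# are the published empirical exchangeability counts; the generator built from
# them is rescaled so branch lengths are expected substitutions per site.
JTT_EXCHANGE <- c(
   58,  54,  81,  56,  57, 105, 179,  27,  36,  30,  35,  54,  15, 194, 378,
  475,   9,  11, 298,  45,  16, 113, 310,  29, 137, 328,  22,  38, 646,  44,
    5,  74, 101,  64, 126,  20,  17, 528,  34,  86,  58,  81, 391,  47,  12,
  263,  30,  10,  15, 503, 232,   8,  70,  16,  10,  49, 767, 130, 112,  11,
    7,  26,  15,   4,  15,  59,  38,   4,  46,  31,   9,   5,  59,  69,  17,
   23,   7,  31,  78,  14, 223,  42, 115, 209,  62, 323,  26, 597,   9,  72,
  292,  43,   4, 164,  53,  51,  18,  24,  20, 119,  26,  12,   9, 181,  18,
    5,  18,  30,  32,  10,   7,  45,  23,   6,   6,  27,  14,   5,  24, 201,
   33,  55,   8,  47,  16,  56,  45,  33,  40, 115,  73,  46,   8, 573,  11,
  229,  21, 479,  89,  10,  40, 245,   9,  32, 961,  14, 388, 248, 102,  59,
   25,  52,  24, 180,  65,   4,  21,  47, 103,  10,   8,  14,  43,  16,  29,
  226,  24,  18, 323,  17,  92,  12,  53, 536,  62, 285, 118,   6,  10,  23,
  477,  35,  63,  38,  12,  21, 112,  71,  25,  16)

# JTT equilibrium amino-acid frequencies (normalised to sum exactly to 1).
JTT_FREQS <- c(
  0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
  0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
  0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005)

#' The JTT amino-acid substitution model
#'
#' Builds the Jones-Taylor-Thornton empirical model as a reversible
#' continuous-time Markov generator: the published exchangeability counts are
#' combined with the JTT equilibrium frequencies and the generator is rescaled
#' to one expected substitution per site per unit branch length, the standard
#' convention so that branch lengths and pairwise distances are in units of
#' expected substitutions per site. Site rates are uniform (no gamma
#' heterogeneity).
#'
#' The returned object caches the eigendecomposition of the (symmetrizable)
#' generator, so transition matrices \eqn{P(d) = \exp(Qd)} are cheap to
#' evaluate repeatedly during likelihood optimisation and simulation.
#'
#' @return An object of class `jtt_model`: a list with elements
#'   `alphabet` (20 residues), `freqs` (equilibrium frequencies, named),
#'   `exchange` (symmetric exchangeability matrix), `Q` (generator, rows sum
#'   to zero, mean rate 1 at equilibrium), and the cached spectral
#'   decomposition used by [jtt_transition_matrix()].
#' @examples
#' m <- jtt_model()
#' range(rowSums(m$Q))            # rows of a generator sum to 0
#' sum(m$freqs)                   # frequencies sum to 1
#' @export
jtt_model <- function() {
  k <- length(AA_ALPHABET)
  pi <- JTT_FREQS / sum(JTT_FREQS)
  names(pi) <- AA_ALPHABET

  S <- matrix(0, k, k, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  S[lower.tri(S)] <- JTT_EXCHANGE
  S <- S + t(S)

  Q <- S * rep(pi, each = k)            # q_ij = s_ij * pi_j for i != j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))              # expected rate at equilibrium
  Q <- Q / mu

  # Symmetrize with pi^(1/2) scaling: B = D^(1/2) Q D^(-1/2) is symmetric by
  # detailed balance, so the spectrum is real and exp(Qd) is stable.
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)

  structure(list(
    alphabet = AA_ALPHABET,
    freqs = pi,
    exchange = S,
    Q = Q,
    eig_values = eig$values,
    # P(d) = D^(-1/2) V exp(Lambda d) V' D^(1/2)
    eig_left = (1 / sp) * eig$vectors,
    eig_right = t(eig$vectors * sp)
  ), class = "jtt_model")
}

#' Transition probability matrix under the JTT model
#'
#' Evaluates \eqn{P(d) = \exp(Qd)} for a branch length `d` in expected
#' substitutions per site, via the model's cached eigendecomposition.
#'
#' @param model A [jtt_model()] object.
#' @param d Non-negative finite branch length.
#' @return A 20x20 row-stochastic matrix; entry (i, j) is the probability
#'   that residue i is observed as residue j after divergence `d`.
#' @export
jtt_transition_matrix <- function(model, d) {
  stopifnot(inherits(model, "jtt_model"))
  if (!is.finite(d) || d < 0) {
    stop("branch length must be finite and non-negative, got ", d)
  }
  P <- model$eig_left %*% (exp(model$eig_values * d) * model$eig_right)
  # Guard tiny negative values from roundoff at large d.
  P[P < 0] <- 0
  dimnames(P) <- list(model$alphabet, model$alphabet)
  P
}

#' Expected proportion of differing sites at a given JTT divergence
#'
#' The expected p-distance \eqn{1 - \sum_i \pi_i P_{ii}(d)} between two
#' sequences separated by total path length `d` at stationarity. Used as an
#' independent check on simulated alignments and as a lower-bound reference
#' for the maximum-likelihood distance.
#'
#' @inheritParams jtt_transition_matrix
#' @return Expected fraction of differing aligned sites, in [0, 1).
#' @export
jtt_expected_p_distance <- function(model, d) {
  P <- jtt_transition_matrix(model, d)
  1 - sum(model$freqs * diag(P))
}

#' @export
print.jtt_model <- function(x, ...) {
  cat("JTT amino-acid substitution model\n")
  cat("  20 states, uniform site rates, mean rate 1 at equilibrium\n")
  cat(sprintf("  frequency range: %.6f .. %.6f\n",
              min(x$freqs), max(x$freqs)))
  invisible(x)
}
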