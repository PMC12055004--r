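# Brute-force mirrortree correlation: enumerates every unordered taxon pair
# explicitly over the alphabetically sorted common taxa and applies the
# Pearson formula directly. Kept independent of the package's vectorized
# upper-triangle path.
brute_force_mirror_r <- function(dm1, dm2) {
  taxa <- sort(intersect(rownames(dm1), rownames(dm2)), method = "radix")
  R <- S <- numeric(0)
  for (i in seq_along(taxa)) {
    for (j in seq_along(taxa)) {
      if (j > i) {
        R <- c(R, dm1[taxa[i], taxa[j]])
        S <- c(S, dm2[taxa[i], taxa[j]])
      }
    }
  }
  num <- sum((R - mean(R)) * (S - mean(S)))
  den <- sqrt(sum((R - mean(R))^2)) * sqrt(sum((S - mean(S))^2))
  num / den
}

# Random labeled symmetric distance matrix with zero diagonal.
random_distance_matrix <- function(n, labels = sprintf("s%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.05, 2)
  m + t(m)
}

# Four-point (additivity) violation of a distance matrix over sampled
# quartets: for an additive matrix the two largest of the three pairings
# d(i,j)+d(k,l), d(i,k)+d(j,l), d(i,l)+d(j,k) coincide.
max_four_point_violation <- function(dm, n_quartets = 200) {
  n <- nrow(dm)
  worst <- 0
  for (q in seq_len(n_quartets)) {
    idx <- sample.int(n, 4)
    s <- sort(c(dm[idx[1], idx[2]] + dm[idx[3], idx[4]],
                dm[idx[1], idx[3]] + dm[idx[2], idx[4]],
                dm[idx[1], idx[4]] + dm[idx[2], idx[3]]))
    worst <- max(worst, s[3] - s[2])
  }
  worst
}

# Observed Fisher information of the pairwise JTT distance at its MLE,
# by central finite differences of the pair log-likelihood.
analytic_distance_se <- function(seq_a, seq_b, model, h = 1e-4) {
  d_hat <- as.numeric(jtt_pairwise_distance(seq_a, seq_b, model))
  ll <- function(d) {
    P <- jtt_transition_matrix(model, d)
    a <- match(seq_a, model$alphabet)
    b <- match(seq_b, model$alphabet)
    keep <- !is.na(a) & !is.na(b)
    sum(log(model$freqs[a[keep]] * P[cbind(a[keep], b[keep])]))
  }
  info <- -(ll(d_hat + h) - 2 * ll(d_hat) + ll(d_hat - h)) / h^2
  1 / sqrt(info)
}
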