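# Encode residue characters as 1..20 (NA for gaps/ambiguity codes).
encode_residues <- function(chars) {
  idx <- match(toupper(chars), AA_ALPHABET)
  idx
}

# 20x20 site-pattern counts for one sequence pair after pairwise deletion.
pair_counts <- function(code_a, code_b) {
  keep <- !is.na(code_a) & !is.na(code_b)
  if (!any(keep)) return(NULL)
  tabulate((code_a[keep] - 1L) * 20L + code_b[keep], nbins = 400L)
}

# Negative log-likelihood of divergence d given pair counts (vector of 400).
# The pi_a factor is constant in d and dropped.
neg_loglik_d <- function(d, counts, model) {
  P <- model$eig_left %*% (exp(model$eig_values * d) * model$eig_right)
  lp <- log(pmax(t(P), 1e-300))  # counts index is (a-1)*20+b, column-major
  -sum(counts * as.vector(lp))
}

ml_distance_from_counts <- function(counts, model, max_distance, tol) {
  n_sites <- sum(counts)
  diag_idx <- (seq_len(20L) - 1L) * 20L + seq_len(20L)
  if (sum(counts[diag_idx]) == n_sites) {
    return(list(distance = 0, saturated = FALSE, n_sites = n_sites))
  }
  opt <- stats::optimize(neg_loglik_d, interval = c(0, max_distance),
                         counts = counts, model = model, tol = tol)
  d <- opt$minimum
  saturated <- FALSE
  # optimize() never returns the exact endpoint; treat estimates pressed
  # against the cap as saturated and clamp.
  if (d > max_distance * (1 - 1e-4)) {
    d <- max_distance
    saturated <- TRUE
  }
  list(distance = d, saturated = saturated, n_sites = n_sites)
}

#' Proportion of differing sites between two aligned sequences
#'
#' The observed p-distance over comparable sites: positions where either
#' sequence has a gap or an ambiguity code are dropped (pairwise deletion).
#' Serves as a model-free lower bound on the JTT maximum-likelihood distance.
#'
#' @param seq_a,seq_b Aligned sequences of equal length: character vectors of
#'   residues or single strings.
#' @return Fraction of comparable sites that differ, in [0, 1], with
#'   attribute `n_sites` (number of comparable sites).
#' @export
p_distance <- function(seq_a, seq_b) {
  a <- as_residue_vector(seq_a)
  b <- as_residue_vector(seq_b)
  if (length(a) != length(b)) stop("sequences must have equal aligned length")
  ca <- encode_residues(a); cb <- encode_residues(b)
  keep <- !is.na(ca) & !is.na(cb)
  if (!any(keep)) {
    stop("no comparable (both ungapped) sites between the two sequences")
  }
  p <- mean(ca[keep] != cb[keep])
  attr(p, "n_sites") <- sum(keep)
  p
}

as_residue_vector <- function(x) {
  if (is.character(x) && length(x) == 1 && nchar(x) > 1) {
    strsplit(toupper(x), "", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
}

#' Maximum-likelihood pairwise distance under the JTT model
#'
#' Estimates the divergence d (expected substitutions per site) between two
#' aligned protein sequences by maximising the likelihood
#' \eqn{\sum_{sites} \log(\pi_a P_{ab}(d))} under the JTT model with uniform
#' site rates, the quantity MEGA reports as the JTT genetic distance. Sites
#' with a gap or ambiguity code in either sequence are dropped (pairwise
#' deletion). Identical sequences return exactly 0. Estimates pressed against
#' `max_distance` are clamped there and flagged saturated.
#'
#' @inheritParams p_distance
#' @param model A [jtt_model()].
#' @param max_distance Saturation cap in substitutions per site (default 10).
#' @param tol Convergence tolerance of the bounded scalar optimiser.
#' @return The distance estimate with attributes `saturated` (logical) and
#'   `n_sites` (comparable sites used).
#' @examples
#' d <- jtt_pairwise_distance("ACDEFGHIKL", "ACDEFGHIKV")
#' attr(d, "n_sites")
#' @export
jtt_pairwise_distance <- function(seq_a, seq_b, model = jtt_model(),
                                  max_distance = 10, tol = 1e-8) {
  a <- as_residue_vector(seq_a)
  b <- as_residue_vector(seq_b)
  if (length(a) != length(b)) stop("sequences must have equal aligned length")
  counts <- pair_counts(encode_residues(a), encode_residues(b))
  if (is.null(counts)) {
    stop("no comparable (both ungapped) sites between the two sequences")
  }
  fit <- ml_distance_from_counts(counts, model, max_distance, tol)
  structure(fit$distance, saturated = fit$saturated, n_sites = fit$n_sites)
}

#' JTT distance matrix for a protein alignment
#'
#' Applies [jtt_pairwise_distance()] to every unordered pair of sequences.
#'
#' @param aln A [protein_alignment()].
#' @inheritParams jtt_pairwise_distance
#' @return A symmetric numeric matrix (zero diagonal) with taxa in alignment
#'   order, units expected substitutions per site, and attribute `saturated`,
#'   a logical matrix flagging clamped entries. An uncomputable pair (no
#'   shared ungapped sites) raises an error naming the pair.
#' @export
distance_matrix <- function(aln, model = jtt_model(), max_distance = 10,
                            tol = 1e-8) {
  stopifnot(inherits(aln, "protein_alignment"))
  taxa <- rownames(aln)
  n <- length(taxa)
  codes <- matrix(encode_residues(aln), nrow = n)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  sat <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      counts <- pair_counts(codes[i, ], codes[j, ])
      if (is.null(counts)) {
        stop(sprintf("no comparable sites for pair (%s, %s)",
                     taxa[i], taxa[j]))
      }
      fit <- ml_distance_from_counts(counts, model, max_distance, tol)
      D[i, j] <- D[j, i] <- fit$distance
      sat[i, j] <- sat[j, i] <- fit$saturated
    }
  }
  attr(D, "saturated") <- sat
  D
}

#' Column-bootstrap standard errors for JTT distances
#'
#' Resamples alignment columns with replacement `n_replicates` times and
#' recomputes every pairwise JTT distance, reporting the per-pair standard
#' error of the replicate estimates. Replicates in which a pair has no
#' comparable sites are skipped for that pair and counted.
#'
#' @inheritParams distance_matrix
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed; fixed seeds reproduce the resampling.
#' @return A list of class `bootstrap_summary`: `se` (matrix of per-pair
#'   standard errors), `n_replicates`, and `skipped` (matrix of per-pair
#'   skipped-replicate counts).
#' @export
bootstrap_distances <- function(aln, model = jtt_model(),
                                n_replicates = 1000, seed = NULL,
                                max_distance = 10, tol = 1e-8) {
  stopifnot(inherits(aln, "protein_alignment"))
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  taxa <- rownames(aln)
  n <- length(taxa)
  L <- ncol(aln)
  codes <- matrix(encode_residues(aln), nrow = n)
  # per-pair per-column encoded pattern (NA where either member is missing)
  pairs <- utils::combn(n, 2)
  pat <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    p <- (codes[i, ] - 1L) * 20L + codes[j, ]
    p  # NA propagates from either code
  })
  reps <- matrix(NA_real_, nrow = n_replicates, ncol = ncol(pairs))
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      idx <- sample.int(L, L, replace = TRUE)
      for (k in seq_len(ncol(pairs))) {
        v <- pat[[k]][idx]
        v <- v[!is.na(v)]
        if (length(v) == 0) next
        counts <- tabulate(v, nbins = 400L)
        reps[r, k] <- ml_distance_from_counts(counts, model, max_distance,
                                              tol)$distance
      }
    }
  })
  se <- matrix(0, n, n, dimnames = list(taxa, taxa))
  skipped <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    vals <- reps[, k][!is.na(reps[, k])]
    se[i, j] <- se[j, i] <- if (length(vals) >= 2) stats::sd(vals) else 0
    skipped[i, j] <- skipped[j, i] <- n_replicates - length(vals)
  }
  structure(list(se = se, n_replicates = n_replicates, skipped = skipped),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("Bootstrap distance summary: %d replicates, %d taxa\n",
              x$n_replicates, nrow(x$se)))
  cat(sprintf("  standard error range: %.4g .. %.4g\n",
              min(x$se[upper.tri(x$se)]), max(x$se[upper.tri(x$se)])))
  if (any(x$skipped > 0)) {
    cat(sprintf("  replicates skipped (no comparable sites): %d pair-reps\n",
                sum(x$skipped[upper.tri(x$skipped)])))
  }
  invisible(x)
}

#' Read and write distance matrices
#'
#' PHYLIP square format: first line the number of taxa, then one row per
#' taxon (label, then the full row of distances). The tidy TSV form has
#' columns `taxon_a`, `taxon_b`, `distance` and, when available, `se` and
#' `saturated` (upper triangle only).
#'
#' @param dm A labeled symmetric distance matrix.
#' @param file Path.
#' @param se Optional matrix of standard errors (same labels), written into
#'   the tidy TSV.
#' @return `read_phylip` returns the labeled matrix; writers return `file`
#'   invisibly.
#' @name distance_io
NULL

#' @rdname distance_io
#' @export
write_phylip <- function(dm, file) {
  n <- nrow(dm)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  for (i in seq_len(n)) {
    writeLines(paste0(formatC(rownames(dm)[i], width = -10),
                      paste(sprintf("%.8f", dm[i, ]), collapse = "  ")), con)
  }
  invisible(file)
}

#' @rdname distance_io
#' @export
read_phylip <- function(file) {
  lines <- readLines(file)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  taxa <- vapply(rows, `[[`, "", 1)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(vals) <- list(taxa, taxa)
  vals
}

#' @rdname distance_io
#' @export
write_distance_tsv <- function(dm, file, se = NULL) {
  sat <- attr(dm, "saturated")
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  df <- data.frame(
    taxon_a = rownames(dm)[idx[, 1]],
    taxon_b = colnames(dm)[idx[, 2]],
    distance = dm[idx],
    se = if (!is.null(se)) se[idx] else NA_real_,
    saturated = if (!is.null(sat)) sat[idx] else FALSE
  )
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
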