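#' Restrict two distance matrices to their common taxa
#'
#' Both matrices are subset to the intersection of their taxon labels and
#' the rows/columns are sorted alphabetically (C-locale radix order) so that
#' the paired upper-triangle vectors line up entry for entry. At least 4
#' common taxa are required: the Fisher variance 1/(N-3) is degenerate below
#' that.
#'
#' @param dm1,dm2 Labeled symmetric distance matrices.
#' @return A list with the two aligned matrices, `dm1` and `dm2`.
#' @export
common_taxa_align <- function(dm1, dm2) {
  t1 <- rownames(dm1); t2 <- rownames(dm2)
  if (is.null(t1) || is.null(t2)) stop("distance matrices must be labeled")
  common <- sort(intersect(t1, t2), method = "radix")
  if (length(common) < 4) {
    stop(sprintf(
      "insufficient taxon overlap: %d common taxa, need at least 4",
      length(common)))
  }
  list(dm1 = dm1[common, common], dm2 = dm2[common, common])
}

upper_vec <- function(dm) dm[upper.tri(dm)]

#' Mirrortree correlation between two distance matrices
#'
#' The mirrortree statistic: Pearson correlation between the pairwise
#' evolutionary distances of two gene families over their common organisms.
#' The strict upper triangles of the common-taxa-aligned matrices are
#' vectorized in identical order as the paired observations
#' \eqn{(R_i, S_i)}, and
#' \deqn{r = \frac{\sum_i (R_i - \bar R)(S_i - \bar S)}
#'   {\sqrt{\sum_i (R_i - \bar R)^2} \sqrt{\sum_i (S_i - \bar S)^2}}.}
#' A high r indicates that the two families' divergence rates covary across
#' the species tree ("mirror" trees), the signature of shared evolutionary
#' pressure.
#'
#' @param dm1,dm2 Labeled distance matrices (genetic or patristic); taxa
#'   need not match — the common subset is used via [common_taxa_align()].
#' @param gene_pair Optional character vector of length 2 naming the genes.
#' @return An object of class `mirror_cor`: list with `r`, `n_taxa` (common
#'   organisms, the N entering the z test), `n_pairs`, `r_fisher`
#'   ([fisher_transform()] of r) and `gene_pair`.
#' @examples
#' tr <- simulate_species_tree(8, seed = 1)
#' gt <- simulate_coevolving_gene_trees(tr, rho = 1, rate_sd = 0.3, seed = 2)
#' mirrortree_correlation(patristic_matrix(gt$tree1),
#'                        patristic_matrix(gt$tree2))
#' @export
mirrortree_correlation <- function(dm1, dm2, gene_pair = c("gene1", "gene2")) {
  al <- common_taxa_align(dm1, dm2)
  x <- upper_vec(al$dm1)
  y <- upper_vec(al$dm2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: a distance vector has zero variance")
  }
  r <- stats::cor(x, y)
  n_taxa <- nrow(al$dm1)
  # a degenerate r of exactly +/-1 (e.g. identical matrices) transforms to
  # an infinite r'; kept as +/-Inf rather than an error so callers can still
  # report the correlation itself
  rf <- if (abs(r) < 1) fisher_transform(r) else sign(r) * Inf
  structure(list(
    r = r,
    n_taxa = n_taxa,
    n_pairs = n_taxa * (n_taxa - 1) / 2,
    r_fisher = rf,
    gene_pair = gene_pair
  ), class = "mirror_cor")
}

#' @export
print.mirror_cor <- function(x, ...) {
  cat(sprintf("Mirrortree correlation: %s vs %s\n",
              x$gene_pair[1], x$gene_pair[2]))
  cat(sprintf("  r = %.4f  (r' = %.4f), N = %d organisms, %d pairs\n",
              x$r, x$r_fisher, x$n_taxa, x$n_pairs))
  invisible(x)
}

#' Fisher's r-to-z transformation
#'
#' \eqn{r' = \tfrac{1}{2}\ln\left|\frac{1+r}{1-r}\right|}: maps a Pearson
#' correlation to an approximately normal variable with variance 1/(N-3),
#' enabling z tests between correlations. Odd and strictly increasing on
#' (-1, 1); |r| >= 1 is an error (infinite transform).
#'
#' @param r Correlation coefficient(s) in (-1, 1).
#' @return The transformed value(s).
#' @examples
#' fisher_transform(0.8)   # 1.0986...
#' @export
fisher_transform <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("fisher_transform requires |r| < 1")
  }
  0.5 * log(abs((1 + r) / (1 - r)))
}

#' @rdname fisher_transform
#' @param z A Fisher-transformed value.
#' @export
fisher_inverse <- function(z) tanh(z)

#' z test comparing two mirrortree correlations
#'
#' Contrasts two independent correlations through their Fisher transforms:
#' \deqn{z = \frac{r'_1 - r'_2}{\sqrt{1/(N_1-3) + 1/(N_2-3)}}}
#' where \eqn{N_1, N_2} are the numbers of common organisms underlying each
#' correlation. With `sign_convention = "flipped"` the sign is negated so a
#' larger first correlation yields a negative z (some reports use that
#' orientation); the magnitude and p-value are unaffected.
#'
#' @param c1,c2 `mirror_cor` objects (see [mirrortree_correlation()]), or
#'   lists with elements `r_fisher` and `n_taxa`.
#' @param sign_convention `"equation"` (default: z = (r'1 - r'2)/SE) or
#'   `"flipped"`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"` for
#'   the normal tail used for the p-value (applied to the unflipped z).
#' @return An object of class `z_comparison`: list with `z`, `p_value`,
#'   `N1`, `N2`, `pair_1`, `pair_2`, `sign_convention`, `alternative`.
#' @examples
#' c1 <- list(r_fisher = fisher_transform(0.9), n_taxa = 30,
#'            gene_pair = c("a", "b"))
#' c2 <- list(r_fisher = fisher_transform(0.5), n_taxa = 30,
#'            gene_pair = c("a", "c"))
#' compare_correlations(c1, c2)$z   # 3.39
#' @export
compare_correlations <- function(c1, c2,
                                 sign_convention = c("equation", "flipped"),
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  sign_convention <- match.arg(sign_convention)
  alternative <- match.arg(alternative)
  n1 <- c1$n_taxa; n2 <- c2$n_taxa
  if (is.null(n1) || is.null(n2) || n1 < 4 || n2 < 4) {
    stop("both correlations need N >= 4 common organisms ",
         "(Fisher variance 1/(N-3) is degenerate below 4)")
  }
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z <- (c1$r_fisher - c2$r_fisher) / se
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z))
  if (sign_convention == "flipped") z <- -z
  structure(list(
    z = z, p_value = p, N1 = n1, N2 = n2,
    pair_1 = c1$gene_pair, pair_2 = c2$gene_pair,
    sign_convention = sign_convention, alternative = alternative
  ), class = "z_comparison")
}

#' @export
print.z_comparison <- function(x, ...) {
  cat(sprintf("z comparison of correlations: z = %.4f, p = %.4g (N1 = %d, N2 = %d)\n",
              x$z, x$p_value, x$N1, x$N2))
  invisible(x)
}

#' Compare a target correlation against a panel of controls
#'
#' Runs [compare_correlations()] of the target mirrortree correlation
#' against each control correlation and reports one row per control,
#' together with a flag indicating whether the target r exceeds the
#' empirical decision cutoff (default 0.8, the conventional mirrortree
#' threshold for calling a pair coevolving). A failing control row (e.g.
#' too few organisms) is flagged and the run continues.
#'
#' @param target A `mirror_cor` for the pair of interest.
#' @param controls A (optionally named) list of `mirror_cor` objects.
#' @param cutoff Decision threshold on the target r (default 0.8).
#' @param sign_convention Passed to [compare_correlations()].
#' @return A list of class `control_panel`: `table` (data.frame with columns
#'   control, r, r_fisher, n_taxa, z, p_value, ok), `target`, `cutoff` and
#'   `target_above_cutoff`.
#' @export
control_panel_analysis <- function(target, controls, cutoff = 0.8,
                                   sign_convention = "equation") {
  if (length(controls) < 1) stop("need at least one control correlation")
  labels <- names(controls)
  if (is.null(labels)) {
    labels <- vapply(controls, function(cc)
      paste(cc$gene_pair, collapse = "-"), "")
  }
  rows <- lapply(seq_along(controls), function(i) {
    cc <- controls[[i]]
    res <- tryCatch(
      compare_correlations(target, cc, sign_convention = sign_convention),
      error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(control = labels[i], r = cc$r %||% NA_real_,
                 r_fisher = cc$r_fisher %||% NA_real_,
                 n_taxa = cc$n_taxa %||% NA_integer_,
                 z = NA_real_, p_value = NA_real_, ok = FALSE,
                 note = conditionMessage(res))
    } else {
      data.frame(control = labels[i], r = cc$r, r_fisher = cc$r_fisher,
                 n_taxa = cc$n_taxa, z = res$z, p_value = res$p_value,
                 ok = TRUE, note = "")
    }
  })
  structure(list(
    table = do.call(rbind, rows),
    target = target,
    cutoff = cutoff,
    target_above_cutoff = target$r > cutoff
  ), class = "control_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.control_panel <- function(x, ...) {
  cat(sprintf("Control panel analysis (target %s vs %s)\n",
              x$target$gene_pair[1], x$target$gene_pair[2]))
  cat(sprintf("  target r = %.4f; above cutoff %.2f: %s\n",
              x$target$r, x$cutoff, x$target_above_cutoff))
  print(x$table[, c("control", "r", "n_taxa", "z", "p_value", "ok")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Default control gene panels
#'
#' The two conventional control panels used alongside a coevolution target:
#' conserved housekeeping genes and lipid-metabolising enzymes. Shipped as a
#' plain-text fixture in `inst/extdata/control_panels.tsv`.
#'
#' @param panel `"housekeeping"`, `"lipid"`, or `"all"`.
#' @return Character vector of gene labels.
#' @examples
#' control_panels("housekeeping")
#' @export
control_panels <- function(panel = c("all", "housekeeping", "lipid")) {
  panel <- match.arg(panel)
  path <- system.file("extdata", "control_panels.tsv", package = "coevotree")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (panel != "all") df <- df[df$panel == panel, ]
  df$gene
}

#' Presence/absence co-occurrence of two gene families
#'
#' Phylogenetic-profiling score over a shared taxon set: the Jaccard
#' agreement of the presence calls, |A and B| / |A or B|, plus a
#' hypergeometric upper-tail probability for observing at least the seen
#' co-presence count given the two marginal presence counts (drawing
#' |present in 2| taxa from the pool, counting hits in |present in 1|).
#'
#' @param p1,p2 Named binary vectors (0/1 or logical), names = taxa; the
#'   intersection of the taxon sets is used.
#' @return A list of class `cooccurrence`: `jaccard`, `co_presence`,
#'   `n_taxa`, `n_present_1`, `n_present_2`, `p_value`.
#' @examples
#' a <- c(sp1 = 1, sp2 = 1, sp3 = 0, sp4 = 0)
#' b <- c(sp1 = 1, sp2 = 1, sp3 = 0, sp4 = 1)
#' profile_cooccurrence(a, b)
#' @export
profile_cooccurrence <- function(p1, p2) {
  if (is.null(names(p1)) || is.null(names(p2))) {
    stop("profiles must be named by taxon")
  }
  common <- intersect(names(p1), names(p2))
  if (length(common) == 0) stop("profiles share no taxa")
  a <- as.logical(p1[common]); b <- as.logical(p2[common])
  if (any(is.na(a)) || any(is.na(b))) stop("profiles must be binary (0/1)")
  both <- sum(a & b)
  either <- sum(a | b)
  jac <- if (either == 0) NA_real_ else both / either
  # P(X >= both) for X hypergeometric with marginals sum(a), sum(b)
  p <- stats::phyper(both - 1, sum(a), length(common) - sum(a), sum(b),
                     lower.tail = FALSE)
  structure(list(
    jaccard = jac, co_presence = both, n_taxa = length(common),
    n_present_1 = sum(a), n_present_2 = sum(b), p_value = p
  ), class = "cooccurrence")
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat(sprintf(
    "Profile co-occurrence: Jaccard = %.3f, co-presence %d/%d taxa, p = %.3g\n",
    x$jaccard, x$co_presence, x$n_taxa, x$p_value))
  invisible(x)
}

#' Read presence/absence profiles from a long-format TSV
#'
#' Expects columns `taxon`, `gene`, `present` (0/1).
#'
#' @param file Path to the TSV.
#' @return A named list of binary profile vectors, one per gene.
#' @export
read_profiles <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("taxon", "gene", "present")
  if (!all(need %in% names(df))) {
    stop("profile TSV needs columns: ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$gene), function(d) {
    stats::setNames(as.integer(d$present), d$taxon)
  })
}
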