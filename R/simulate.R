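# Deterministic fan-out of one top-level seed into stage-specific child
# seeds, kept within 32-bit integer range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a pure-birth (Yule) species tree
#'
#' Draws a species phylogeny under a constant-rate pure-birth process:
#' exponential waiting times between speciation events and no extinction.
#' Branch lengths are in expected substitutions per site once combined with a
#' substitution model of mean rate 1. Leaves are labeled `t001`, `t002`, ...
#'
#' @param n_taxa Number of leaves, at least 3.
#' @param birth_rate Speciation rate (> 0); larger rates give shorter trees.
#' @param seed Optional integer seed; identical seeds give identical trees.
#' @return An [ape::rphylo()]-style `phylo` tree with `n_taxa` leaves.
#' @examples
#' tr <- simulate_species_tree(5, birth_rate = 1, seed = 1)
#' tr$tip.label
#' @export
simulate_species_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1 || n_taxa < 3 ||
      n_taxa != round(n_taxa)) {
    stop("'n_taxa' must be an integer >= 3")
  }
  if (!is.numeric(birth_rate) || birth_rate <= 0) {
    stop("'birth_rate' must be a positive number")
  }
  tree <- with_seed(seed,
    ape::rphylo(n = n_taxa, birth = birth_rate, death = 0))
  tree$tip.label <- sprintf("t%03d", seq_len(n_taxa))
  tree
}

#' Simulate a pair of coevolving gene trees
#'
#' Both gene trees inherit the species-tree topology; each branch of each
#' gene gets a lognormal rate multiplier. For branch \eqn{b} the two genes'
#' log-rate deviations \eqn{(\epsilon_{1,b}, \epsilon_{2,b})} are bivariate
#' normal with standard deviation `rate_sd` and correlation `rho`, and the
#' branch length becomes \eqn{L_b \exp(\epsilon_{g,b} - \mathrm{rate\_sd}^2/2)}
#' so that the expected branch length equals the species-tree length. `rho`
#' is the coevolution dial: `rho = 1` (shared deviations) makes the gene
#' trees identical, `rho = 0` makes their rate noise independent while both
#' still track the shared species tree.
#'
#' @param species A `phylo` species tree with branch lengths.
#' @param rho Between-gene branch-rate correlation in [0, 1].
#' @param rate_sd Standard deviation of the log branch-rate multipliers
#'   (>= 0); 0 reproduces the species tree exactly in both genes.
#' @param seed Optional integer seed.
#' @return A list with `tree1` and `tree2` (`phylo` objects) and `noise`,
#'   the matrix of per-branch log-rate deviations actually drawn (columns
#'   `eps1`, `eps2`), kept for diagnostics.
#' @examples
#' sp <- simulate_species_tree(6, seed = 1)
#' gt <- simulate_coevolving_gene_trees(sp, rho = 1, rate_sd = 0.5, seed = 2)
#' all.equal(gt$tree1$edge.length, gt$tree2$edge.length)
#' @export
simulate_coevolving_gene_trees <- function(species, rho, rate_sd,
                                           seed = NULL) {
  if (!inherits(species, "phylo") || is.null(species$edge.length)) {
    stop("'species' must be a phylo tree with branch lengths")
  }
  if (!is.numeric(rho) || rho < 0 || rho > 1) stop("'rho' must be in [0, 1]")
  if (!is.numeric(rate_sd) || rate_sd < 0) stop("'rate_sd' must be >= 0")

  n_edge <- length(species$edge.length)
  noise <- with_seed(seed, {
    z1 <- stats::rnorm(n_edge)
    z2 <- stats::rnorm(n_edge)
    eps1 <- rate_sd * z1
    eps2 <- rate_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    cbind(eps1 = eps1, eps2 = eps2)
  })
  shift <- rate_sd^2 / 2
  t1 <- t2 <- species
  t1$edge.length <- species$edge.length * exp(noise[, "eps1"] - shift)
  t2$edge.length <- species$edge.length * exp(noise[, "eps2"] - shift)
  list(tree1 = t1, tree2 = t2, noise = noise)
}

#' Evolve a protein alignment along a tree under the JTT model
#'
#' Ancestral states at the root are drawn from the JTT equilibrium
#' frequencies; along each branch every site evolves independently with
#' transition matrix \eqn{\exp(QL)} where \eqn{L} is the branch length in
#' expected substitutions per site. Site rates are uniform and no indels are
#' generated, so the output is a gap-free alignment.
#'
#' @param tree A `phylo` tree with finite, non-negative branch lengths.
#' @param n_sites Alignment length (>= 1).
#' @param model A [jtt_model()]; the default builds one.
#' @param seed Optional integer seed.
#' @return A [protein_alignment()] with one row per leaf of `tree`.
#' @examples
#' tr <- simulate_species_tree(4, seed = 3)
#' aln <- evolve_alignment(tr, n_sites = 100, seed = 4)
#' dim(aln)
#' @export
evolve_alignment <- function(tree, n_sites, model = jtt_model(),
                             seed = NULL) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
      any(tree$edge.length < 0)) {
    stop("tree branch lengths must all be finite and non-negative")
  }
  if (!is.numeric(n_sites) || n_sites < 1 || n_sites != round(n_sites)) {
    stop("'n_sites' must be a positive integer")
  }
  stopifnot(inherits(model, "jtt_model"))

  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L

  with_seed(seed, {
    states <- matrix(NA_integer_, nrow = n_node, ncol = n_sites)
    states[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                                 prob = model$freqs)
    # preorder: ape edges reordered so parents precede children
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[e, 1]
      child <- ord$edge[e, 2]
      len <- ord$edge.length[e]
      if (len == 0) {
        states[child, ] <- states[parent, ]
        next
      }
      P <- jtt_transition_matrix(model, len)
      ps <- states[parent, ]
      cs <- integer(n_sites)
      for (s in unique(ps)) {
        idx <- which(ps == s)
        cs[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = P[s, ])
      }
      states[child, ] <- cs
    }
    m <- matrix(model$alphabet[states[seq_len(n_tip), , drop = FALSE]],
                nrow = n_tip)
    rownames(m) <- tree$tip.label
    protein_alignment(m)
  })
}

#' Simulate a full coevolution study at the desk scale
#'
#' Convenience wrapper used by the pipeline and the documentation examples:
#' draws a species tree, a coevolving target gene-tree pair at `rho`, a set
#' of independently evolving (`rho = 0`) control gene trees, and (optionally)
#' JTT alignments for every gene. One top-level seed fans out to
#' reproducible stage-specific child seeds.
#'
#' @param n_taxa Number of species (>= 3).
#' @param rho Coevolution parameter for the target pair, in [0, 1].
#' @param rate_sd Log branch-rate standard deviation shared by all genes.
#' @param n_controls Number of control genes evolving independently.
#' @param n_sites Alignment length; if `NULL` no sequences are simulated.
#' @param birth_rate Yule speciation rate for the species tree.
#' @param seed Integer seed for the whole run.
#' @return A list: `species` tree, `trees` (named list of `phylo`: the
#'   targets `target_A`, `target_B`, then `control_01`, ...), `alignments`
#'   (named list of [protein_alignment()] or `NULL`), and `manifest`, a
#'   data.frame recording gene, role, rho, rate_sd and child seed.
#' @export
simulate_coevolution_study <- function(n_taxa = 50, rho = 0.9,
                                       rate_sd = 0.5, n_controls = 8,
                                       n_sites = NULL, birth_rate = 1,
                                       seed = NULL) {
  species <- simulate_species_tree(n_taxa, birth_rate,
                                   seed = derive_seed(seed, "species"))
  pair <- simulate_coevolving_gene_trees(species, rho, rate_sd,
                                         seed = derive_seed(seed, "target"))
  trees <- list(target_A = pair$tree1, target_B = pair$tree2)
  if (n_controls > 0) {
    for (i in seq_len(n_controls)) {
      g <- simulate_coevolving_gene_trees(
        species, rho = 0, rate_sd = rate_sd,
        seed = derive_seed(seed, paste0("control", i)))
      trees[[sprintf("control_%02d", i)]] <- g$tree1
    }
  }
  alignments <- NULL
  if (!is.null(n_sites)) {
    alignments <- lapply(names(trees), function(g) {
      evolve_alignment(trees[[g]], n_sites,
                       seed = derive_seed(seed, paste0("aln_", g)))
    })
    names(alignments) <- names(trees)
  }
  manifest <- data.frame(
    gene = names(trees),
    role = c("target", "target", rep("control", length(trees) - 2)),
    rho = c(rho, rho, rep(0, length(trees) - 2)),
    rate_sd = rate_sd,
    n_taxa = n_taxa,
    seed = if (is.null(seed)) NA_integer_ else seed,
    stringsAsFactors = FALSE
  )
  list(species = species, trees = trees, alignments = alignments,
       manifest = manifest)
}
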