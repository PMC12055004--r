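test_that("pure-birth species trees have the requested shape and are reproducible", {
  tr <- simulate_species_tree(3, birth_rate = 1, seed = 7)
  expect_s3_class(tr, "phylo")
  expect_length(tr$tip.label, 3)
  expect_equal(tr$Nnode, 2L)

  expect_identical(write_newick(simulate_species_tree(3, 1, seed = 7)),
                   write_newick(tr))

  big <- simulate_species_tree(50, birth_rate = 1, seed = 11)
  expect_gt(sum(big$edge.length), 0)
  expect_true(all(big$edge.length >= 0))
  expect_false(anyDuplicated(big$tip.label) > 0)
  expect_identical(big$tip.label, sprintf("t%03d", 1:50))

  expect_error(simulate_species_tree(2), ">= 3")
  expect_error(simulate_species_tree(10, birth_rate = 0), "positive")
})

test_that("coevolving gene trees respect the rho and rate_sd limits", {
  sp <- simulate_species_tree(20, seed = 3)

  # zero noise: both genes reproduce the species tree exactly
  gt0 <- simulate_coevolving_gene_trees(sp, rho = 0.4, rate_sd = 0, seed = 1)
  expect_equal(gt0$tree1$edge.length, sp$edge.length)
  expect_equal(gt0$tree2$edge.length, sp$edge.length)

  # perfectly correlated noise: branch-for-branch identical gene trees
  gt1 <- simulate_coevolving_gene_trees(sp, rho = 1, rate_sd = 0.5, seed = 2)
  expect_equal(gt1$tree1$edge.length, gt1$tree2$edge.length)
  expect_false(isTRUE(all.equal(gt1$tree1$edge.length, sp$edge.length)))

  expect_error(simulate_coevolving_gene_trees(sp, rho = 1.2, rate_sd = 0.5),
               "rho")
  expect_error(simulate_coevolving_gene_trees(sp, rho = 0.5, rate_sd = -1),
               "rate_sd")
})

test_that("independent rate noise is uncorrelated across many branches", {
  # 501 tips -> 1000 edges
  sp <- simulate_species_tree(501, seed = 9)
  gt <- simulate_coevolving_gene_trees(sp, rho = 0, rate_sd = 0.5, seed = 10)
  expect_equal(nrow(gt$noise), 1000L)
  r <- cor(gt$noise[, "eps1"], gt$noise[, "eps2"])
  expect_lt(abs(r), 0.1)
})

test_that("rate multipliers are mean-one lognormal", {
  sp <- simulate_species_tree(501, seed = 12)
  gt <- simulate_coevolving_gene_trees(sp, rho = 0.5, rate_sd = 0.5, seed = 13)
  mult <- gt$tree1$edge.length / sp$edge.length
  expect_true(all(mult > 0))
  # E[exp(eps - sd^2/2)] = 1; MC error with 1000 draws, sd(mult) ~ 0.53
  expect_equal(mean(mult), 1, tolerance = 0.06)
})

test_that("sequence evolution matches the JTT process", {
  m <- jtt_model()

  # zero branch lengths: every leaf equals the root draw
  star <- ape::stree(4, "star")
  star$edge.length <- rep(0, 4)
  aln0 <- evolve_alignment(star, 50, m, seed = 1)
  expect_true(all(aln0[1, ] == aln0[2, ]))
  expect_true(all(aln0[1, ] == aln0[4, ]))

  # observed p-distance at total path 0.5 matches the matrix-exponential
  # expectation
  tr <- coevotree:::two_leaf_tree(0.5)
  aln <- evolve_alignment(tr, 100000, m, seed = 2)
  p_obs <- p_distance(aln["A", ], aln["B", ])
  expect_equal(as.numeric(p_obs), jtt_expected_p_distance(m, 0.5),
               tolerance = 0.01)

  # ergodicity: composition at large depth returns to equilibrium
  deep <- coevotree:::two_leaf_tree(40)
  alnd <- evolve_alignment(deep, 100000, m, seed = 3)
  comp <- table(factor(alnd["A", ], levels = m$alphabet)) / 100000
  expect_lt(max(abs(as.numeric(comp) - m$freqs)), 0.01)

  bad <- tr; bad$edge.length[1] <- NA
  expect_error(evolve_alignment(bad, 10, m), "finite")
})

test_that("identical seeds give byte-identical FASTA and Newick outputs", {
  run <- function() {
    sp <- simulate_species_tree(8, seed = 21)
    aln <- evolve_alignment(sp, 120, seed = 22)
    fa <- tempfile(fileext = ".fasta"); nw <- tempfile(fileext = ".nwk")
    write_alignment(aln, fa)
    write_newick(sp, nw)
    list(fa = readBin(fa, "raw", file.size(fa)),
         nw = readBin(nw, "raw", file.size(nw)))
  }
  a <- run(); b <- run()
  expect_identical(a$fa, b$fa)
  expect_identical(a$nw, b$nw)
})

test_that("alignment FASTA I/O round-trips", {
  sp <- simulate_species_tree(5, seed = 31)
  aln <- evolve_alignment(sp, 80, seed = 32)
  f <- tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  back <- read_alignment(f)
  expect_identical(unclass(back), unclass(aln))
})

test_that("simulate_coevolution_study assembles a consistent bundle", {
  st <- simulate_coevolution_study(n_taxa = 10, rho = 0.8, rate_sd = 0.4,
                                   n_controls = 3, n_sites = 60, seed = 5)
  expect_named(st$trees, c("target_A", "target_B",
                           sprintf("control_%02d", 1:3)))
  expect_equal(nrow(st$manifest), 5)
  expect_equal(st$manifest$rho, c(0.8, 0.8, 0, 0, 0))
  expect_true(all(vapply(st$alignments, ncol, 1L) == 60))
  # reproducible under the same top-level seed
  st2 <- simulate_coevolution_study(n_taxa = 10, rho = 0.8, rate_sd = 0.4,
                                    n_controls = 3, n_sites = 60, seed = 5)
  expect_identical(st$alignments, st2$alignments)
})
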