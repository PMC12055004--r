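test_that("common-taxa alignment intersects and sorts consistently", {
  set.seed(7)
  d1 <- random_distance_matrix(6, labels = c("F", "A", "D", "B", "E", "C"))
  d2 <- random_distance_matrix(6, labels = c("C", "E", "B", "A", "F", "D"))
  al <- common_taxa_align(d1, d2)
  expect_identical(rownames(al$dm1), LETTERS[1:6])
  expect_identical(rownames(al$dm2), LETTERS[1:6])
  expect_equal(al$dm1["B", "E"], d1["B", "E"])

  d3 <- random_distance_matrix(6, labels = c("C", "D", "E", "F", "G", "H"))
  al2 <- common_taxa_align(d1, d3)
  expect_identical(rownames(al2$dm1), c("C", "D", "E", "F"))

  d4 <- random_distance_matrix(4, labels = c("W", "X", "Y", "Z"))
  expect_error(common_taxa_align(d1, d4), "insufficient")
})

test_that("mirrortree correlation matches its defining properties", {
  set.seed(11)
  d1 <- random_distance_matrix(7)
  res <- mirrortree_correlation(d1, d1)
  expect_equal(res$r, 1)
  expect_equal(res$n_taxa, 7)
  expect_equal(res$n_pairs, 21)

  # invariance under positive affine maps of one matrix
  d2 <- 2 * d1 + 0.1; diag(d2) <- 0
  expect_equal(mirrortree_correlation(d1, d2)$r, 1, tolerance = 1e-12)

  # symmetry in the arguments
  d3 <- random_distance_matrix(7)
  expect_equal(mirrortree_correlation(d1, d3)$r,
               mirrortree_correlation(d3, d1)$r, tolerance = 1e-14)

  # invariance under simultaneous taxon permutation
  perm <- sample(rownames(d1))
  expect_equal(mirrortree_correlation(d1[perm, perm], d3[perm, perm])$r,
               mirrortree_correlation(d1, d3)$r, tolerance = 1e-14)

  # zero variance is rejected
  dflat <- matrix(1, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  diag(dflat) <- 0
  dvar <- random_distance_matrix(5, labels = LETTERS[1:5])
  expect_error(mirrortree_correlation(dflat, dvar), "zero variance")
})

test_that("mirrortree r equals brute-force pair enumeration", {
  set.seed(13)
  for (n in 4:8) {
    for (rep in 1:5) {
      d1 <- random_distance_matrix(n)
      d2 <- random_distance_matrix(n)
      expect_equal(mirrortree_correlation(d1, d2)$r,
                   brute_force_mirror_r(d1, d2), tolerance = 1e-12)
    }
  }
})

test_that("the Fisher transform matches its closed form and inverts exactly", {
  expect_equal(fisher_transform(0), 0)
  expect_equal(fisher_transform(0.8), 0.5 * log(1.8 / 0.2), tolerance = 1e-15)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_transform(-r), -fisher_transform(r), tolerance = 1e-15)
  expect_true(all(diff(fisher_transform(r)) > 0))
  expect_equal(fisher_inverse(fisher_transform(r)), r, tolerance = 1e-12)
  expect_error(fisher_transform(1), "< 1")
  expect_error(fisher_transform(-1.2), "< 1")
})

test_that("the z comparison follows the Fisher z equation", {
  mk <- function(r, n) list(r = r, r_fisher = fisher_transform(r), n_taxa = n,
                            gene_pair = c("g", "h"))
  # equal transformed correlations give z = 0 at any N
  z0 <- compare_correlations(mk(0.6, 12), mk(0.6, 40))
  expect_equal(z0$z, 0)
  expect_equal(z0$p_value, 1)

  zc <- compare_correlations(mk(0.9, 30), mk(0.5, 30))
  expect_equal(abs(zc$z), 3.39, tolerance = 0.005)
  expect_equal(zc$p_value, 2 * pnorm(-abs(zc$z)), tolerance = 1e-12)

  # flipped sign convention: higher first correlation becomes negative
  zf <- compare_correlations(mk(0.9, 30), mk(0.5, 30),
                             sign_convention = "flipped")
  expect_equal(zf$z, -zc$z)
  expect_equal(zf$p_value, zc$p_value)

  # more organisms at a fixed r' difference sharpen the test
  zbig <- compare_correlations(mk(0.9, 60), mk(0.5, 60))
  expect_gt(abs(zbig$z), abs(zc$z))

  expect_error(compare_correlations(mk(0.9, 3), mk(0.5, 30)), "N >= 4")
})

test_that("control panel analysis flags the cutoff and tolerates bad rows", {
  mk <- function(r, n, pair) list(r = r, r_fisher = fisher_transform(r),
                                  n_taxa = n, gene_pair = pair)
  target <- mk(0.9, 25, c("geneA", "geneB"))

  pan <- control_panel_analysis(target, list(ctrl1 = mk(0.9, 25, c("geneA", "c1"))))
  expect_true(pan$target_above_cutoff)
  expect_equal(pan$table$z[1], 0)

  low <- control_panel_analysis(mk(0.5, 25, c("geneA", "geneB")),
                                list(ctrl1 = mk(0.2, 25, c("geneA", "c1"))))
  expect_false(low$target_above_cutoff)

  # a control with too few organisms is flagged, the run continues
  mixed <- control_panel_analysis(
    target, list(bad = mk(0.4, 3, c("geneA", "c1")),
                 good = mk(0.4, 25, c("geneA", "c2"))))
  expect_identical(mixed$table$ok, c(FALSE, TRUE))
  expect_true(is.na(mixed$table$z[1]))
  expect_gt(mixed$table$z[2], 0)

  expect_error(control_panel_analysis(target, list()), "at least one")
})

test_that("default control panels ship the conventional gene lists", {
  hk <- control_panels("housekeeping")
  expect_length(hk, 8)
  expect_true(all(c("GAPDH", "PGK1", "ACT1", "RPL5") %in% hk))
  lp <- control_panels("lipid")
  expect_length(lp, 7)
  expect_true("DGA1" %in% lp)
  expect_length(control_panels("all"), 15)
})

test_that("profile co-occurrence scores presence agreement", {
  taxa <- sprintf("sp%02d", 1:12)
  a <- setNames(rep(1, 12), taxa)
  res <- profile_cooccurrence(a, a)
  expect_equal(res$jaccard, 1)
  expect_equal(res$co_presence, 12)

  b <- setNames(c(rep(1, 6), rep(0, 6)), taxa)
  cpl <- setNames(c(rep(0, 6), rep(1, 6)), taxa)
  expect_equal(profile_cooccurrence(b, cpl)$jaccard, 0)

  # one gene absent in exactly one clade where the other is present
  clade_loss <- setNames(c(rep(1, 8), rep(0, 4)), taxa)
  everywhere <- setNames(rep(1, 12), taxa)
  res2 <- profile_cooccurrence(clade_loss, everywhere)
  expect_lt(res2$jaccard, 1)
  expect_equal(res2$co_presence, sum(clade_loss & everywhere))
  expect_equal(res2$jaccard, 8 / 12)

  expect_error(profile_cooccurrence(a, setNames(1, "other")), "share no taxa")
})

test_that("long-format profile TSVs are read into per-gene vectors", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("taxon\tgene\tpresent",
               "sp1\tg1\t1", "sp2\tg1\t0",
               "sp1\tg2\t1", "sp2\tg2\t1"), f)
  pr <- read_profiles(f)
  expect_named(pr, c("g1", "g2"))
  expect_identical(pr$g1, setNames(c(1L, 0L), c("sp1", "sp2")))
})
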