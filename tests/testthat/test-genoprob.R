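test_that("two-gene pair probabilities follow the closed form and sum to 1", {
  expect_equal(pair_probability(c(0.5, 0.5), 0, 1, 1), 0.25)
  expect_equal(pair_probability(c(0.5, 0.5), 1, 1, 1), 0.5)
  expect_equal(pair_probability(c(0.5, 0.5), 0.25, 1, 1), 0.3125)
  expect_error(pair_probability(c(A = 0.5, B = 0.5), 0, "C", "A"), "unknown allele")
  sp <- class_spectrum(p3, 0.37, n_genes = 2)
  expect_equal(sum(sp$prob), 1, tolerance = 1e-12)
})

test_that("three-gene class probabilities match the identity-partition mixture", {
  expect_equal(triplet_probability(c(0.5, 0.5), 0, 0, 0, "iii", 1), 0.125)
  expect_equal(triplet_probability(p3, 1, 1, 1, "iij", c(1, 2)), 0)
  expect_equal(triplet_probability(c(0.5, 0.3, 0.2), 0.2, 0.1, 0.05, "iii", 1),
               0.175)
  expect_error(triplet_probability(c(0.05, 0.95), 0, 0.1, 0.1, "iij", c(1, 2)),
               "inadmissible")
  set.seed(7)
  for (i in 1:20) {
    frg <- rand_FRG()
    sp <- class_spectrum(p4, as.list(frg), 3)
    expect_equal(sum(sp$prob), 1, tolerance = 1e-10)
  }
})

test_that("mode-mixture oracle: closed-form quartet classes equal direct enumeration", {
  # every pure mode x frequency grid, every concrete class, machine precision
  grids <- list(p3, p3b, p4, validate_frequencies(c(0.25, 0.25, 0.5)))
  for (k in 1:9) {
    d <- jacquard(replace(rep(0, 9), k, 1))
    th <- jacquard_to_coefficients(d)
    for (p in grids) {
      sp <- class_spectrum(p, th, n_genes = 4)
      expect_equal(sum(sp$prob), 1, tolerance = 1e-10)
      for (r in seq_len(nrow(sp))) {
        direct <- quartet_delta_probability(c(sp$a1[r], sp$a2[r]),
                                            c(sp$b1[r], sp$b2[r]), d, p)
        expect_equal(sp$prob[r], direct, tolerance = 1e-12,
                     label = sprintf("mode %d class %s", k, sp$pattern[r]))
      }
    }
  }
})

test_that("quartet spectra sum to 1 for random Delta and frequency draws", {
  set.seed(11)
  for (i in 1:150) {
    k <- sample(2:4, 1)
    p <- validate_frequencies(local({ x <- stats::rexp(k); x / sum(x) }))
    d <- rand_delta()
    th <- jacquard_to_coefficients(d)
    for (ng in 2:4) {
      sp <- class_spectrum(p, th, n_genes = ng)
      expect_equal(sum(sp$prob), 1, tolerance = 1e-10)
    }
  }
})

test_that("null quartet spectrum equals multinomial genotype products", {
  sp <- class_spectrum(p3, rel_coefs(), n_genes = 4)
  gprob <- function(a1, a2) if (a1 == a2) p3[[a1]]^2 else 2 * p3[[a1]] * p3[[a2]]
  for (r in seq_len(nrow(sp)))
    expect_equal(sp$prob[r],
                 gprob(sp$a1[r], sp$a2[r]) * gprob(sp$b1[r], sp$b2[r]),
                 tolerance = 1e-14)
})

test_that("Delta2 forces both individuals homozygous", {
  th <- jacquard_to_coefficients(jacquard(c(0, 1, 0, 0, 0, 0, 0, 0, 0)))
  sp <- class_spectrum(p3, th, n_genes = 4)
  hom <- sp$a1 == sp$a2 & sp$b1 == sp$b2
  expect_equal(sum(sp$prob[hom]), 1, tolerance = 1e-12)
})

test_that("full-identity coefficients telescope f_iiii to p_i", {
  th <- jacquard_to_coefficients(jacquard(c(1, rep(0, 8))))
  for (pi in c(0.1, 0.3, 0.5, 0.62, 0.9)) {
    p <- validate_frequencies(c(pi, 1 - pi - 0.05, 0.05))
    expect_equal(quartet_class_probability(p, th, "iiii", c(i = 1)), pi,
                 tolerance = 1e-12)
  }
})

test_that("marginalizing one individual recovers the other's two-gene spectrum", {
  # with only F_A, F_B, R nonzero... requires the four-gene coefficients and
  # G to vanish for the pair structure to factor over the marginal
  th <- rel_coefs(F_A = 0.3, F_B = 0.2, R = 0)
  sp <- class_spectrum(p3, th, n_genes = 4)
  gen <- .genotypes <- unique(sp[c("a1", "a2")])
  margA <- vapply(seq_len(nrow(gen)), function(r)
    sum(sp$prob[sp$a1 == gen$a1[r] & sp$a2 == gen$a2[r]]), 0)
  expected <- vapply(seq_len(nrow(gen)), function(r)
    pair_probability(p3, 0.3, gen$a1[r], gen$a2[r]), 0)
  expect_equal(margA, expected, tolerance = 1e-12)
})

test_that("design matrix columns agree with finite differences and flag degeneracy", {
  DM <- design_matrix(p4)
  expect_false(attr(DM, "singular"))
  expect_gt(abs(det(DM)), 0)
  # finite differencing of the class probabilities wrt each coefficient
  classes <- attr(DM, "classes")
  h <- 1e-7
  base <- rel_coefs()
  spec_classes <- function(th) {
    defs <- list(iiii = c("iiii", 1), ijij = c("ijij", 1, 2),
                 iijj = c("iijj", 1, 2), iiij = c("iiij", 1, 2),
                 ijjj = c("ijjj", 1, 2), iijk = c("iijk", 1, 2, 3),
                 ijkk = c("ijkk", 1, 2, 3), ijik = c("ijik", 1, 2, 3))
    vapply(defs, function(d)
      quartet_class_probability(p4, th, d[1], as.integer(d[-1]), check = FALSE),
      0)
  }
  for (cf in colnames(DM)) {
    thp <- unclass(base); thp[cf] <- h
    fd <- (spec_classes(rel_coefs(as.list(thp))) - spec_classes(base)) / h
    expect_equal(unname(fd), unname(DM[, cf]), tolerance = 1e-6)
  }
  # equal frequencies for the chosen alleles degenerate the class system
  expect_warning(DMs <- design_matrix(c(0.25, 0.25, 0.5)), "singular")
  expect_true(attr(DMs, "singular"))
})

test_that("spectrum serialization is deterministic and complete", {
  sp <- class_spectrum(p3, rel_coefs(H = 0.05, F_AB = 0.1, R_AB = 0.08,
                                     F_A = 0.2, F_B = 0.2, R = 0.15,
                                     G_A = 0.08, G_B = 0.08), n_genes = 4)
  f <- tempfile(fileext = ".tsv")
  write_spectrum(sp, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), nrow(sp))
  expect_equal(sum(tab$prob), 1, tolerance = 1e-10)
  expect_false(is.unsorted(tab$pattern))
})
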