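test_that("sampling is deterministic given the seed", {
  des <- sim_design(rand_delta(), p3, n_pairs = 100, n_loci = 5, seed = 123)
  t1 <- simulate_dataset(des)
  t2 <- simulate_dataset(des)
  expect_identical(t1, t2)
  expect_error(sim_design(delta_null, p3, n_pairs = 10, n_loci = 0), "n_loci")
})

test_that("pure-mode samples respect the mode's identity structure", {
  set.seed(61)
  s1 <- sample_pair(jacquard(c(1, rep(0, 8))), p3)
  expect_true(all(c(s1$a, s1$b) == s1$a[1]))
  s2 <- sample_pair(jacquard(c(0, 1, rep(0, 7))), p3)
  expect_equal(s2$a[1], s2$a[2])
  expect_equal(s2$b[1], s2$b[2])
})

test_that("empirical class frequencies match the probability model for every mode", {
  # simulator and probability model are mutually validating: for each pure
  # mode, empirical four-gene class frequencies at n = 30000 lie within
  # 4 binomial SE (plus a tiny floor) of class_spectrum
  n <- 30000
  for (k in 1:9) {
    d <- jacquard(replace(rep(0, 9), k, 1))
    des <- sim_design(d, p3, n_pairs = n, n_loci = 1, seed = 700 + k)
    tab <- simulate_dataset(des)
    emp <- observed_spectrum(tab, p3, n_genes = 4, locus = "L1")
    th <- jacquard_to_coefficients(d)
    sp <- class_spectrum(p3, th, n_genes = 4)
    expect_equal(emp$a1, sp$a1)
    f_emp <- emp$count / n
    se <- sqrt(pmax(sp$prob * (1 - sp$prob), 1e-12) / n)
    expect_true(all(abs(f_emp - sp$prob) < 4 * se + 5e-4),
                label = sprintf("mode %d", k))
  }
})

test_that("Delta7 sampling reproduces the double-heterozygote probability", {
  d <- jacquard(c(0, 0, 0, 0, 0, 0, 1, 0, 0))
  des <- sim_design(d, p3, n_pairs = 50000, n_loci = 1, seed = 77)
  tab <- simulate_dataset(des)
  both_het_12 <- mean(tab$a1 != tab$a2 & tab$b1 != tab$b2 &
                      pmin(tab$a1, tab$a2) == 1 & pmax(tab$a1, tab$a2) == 2 &
                      pmin(tab$b1, tab$b2) == 1 & pmax(tab$b1, tab$b2) == 2)
  expect_lt(abs(both_het_12 - 0.30), 4 * sqrt(0.3 * 0.7 / 50000) + 1e-3)
})

test_that("mixture with a shared pair component induces identity disequilibrium", {
  mix <- mixture_two_pop(0.3, 0.1)
  des <- sim_design(freqs = c(0.3, 0.7), n_pairs = 60000, n_loci = 2,
                    seed = 83, mixture = mix)
  tabm <- simulate_mixture(des)
  idx <- empirical_identity_disequilibrium(tabm)
  expect_gt(idx$excess[1], 0)
  # brute-force oracle: across-component variance of total homozygosity
  oracle <- mixture_moments(mix)$var_total_homozygosity
  n_ind <- 2 * 60000
  se <- sqrt(1 / n_ind)  # conservative bound for a covariance of Bernoullis
  expect_lt(abs(idx$excess[1] - oracle), 4 * se)
  # a = 0: no disequilibrium
  mix0 <- mixture_two_pop(0.3, 0)
  des0 <- sim_design(freqs = c(0.3, 0.7), n_pairs = 60000, n_loci = 2,
                     seed = 85, mixture = mix0)
  idx0 <- empirical_identity_disequilibrium(simulate_mixture(des0))
  expect_lt(abs(idx0$excess[1]), 4 * se)
})

test_that("single-component mixture matches the plain simulator in distribution", {
  mix <- mixture_model(list(c(0.5, 0.3, 0.2)),
                       delta = jacquard(c(0, 0, 0, 0, 0, 0, 0, 0.4, 0.6)))
  des <- sim_design(freqs = c(0.5, 0.3, 0.2), n_pairs = 30000, n_loci = 1,
                    seed = 87, mixture = mix)
  tab <- simulate_mixture(des)
  emp <- observed_spectrum(tab, p3, n_genes = 4, locus = "L1")
  th <- jacquard_to_coefficients(mix$delta[[1]])
  sp <- class_spectrum(p3, th, n_genes = 4)
  se <- sqrt(pmax(sp$prob * (1 - sp$prob), 1e-12) / 30000)
  expect_true(all(abs(emp$count / 30000 - sp$prob) < 4 * se + 5e-4))
})

test_that("duplicated locus gives identity excess h(1 - h)", {
  des <- sim_design(delta_null, p3, n_pairs = 5000, n_loci = 1, seed = 89)
  tab <- simulate_dataset(des)
  dup <- tab; dup$locus <- "L2"
  both <- rbind(tab, dup)
  idx <- empirical_identity_disequilibrium(both)
  h <- mean(c(tab$a1 == tab$a2, tab$b1 == tab$b2))
  expect_equal(idx$excess[1], h * (1 - h), tolerance = 1e-12)
})

test_that("monomorphic loci are excluded with a warning", {
  tab <- data.frame(pair_id = rep(1:5, 3), locus = rep(c("L1", "L2", "L3"), each = 5),
                    a1 = 1, a2 = 1, b1 = 1, b2 = 1)
  tab[tab$locus != "L2", c("a1", "b2")] <- 2
  expect_warning(idx <- empirical_identity_disequilibrium(tab), "monomorphic")
  expect_equal(nrow(idx), 1)
})
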