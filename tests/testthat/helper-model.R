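# Shared fixtures: random draws on the Delta simplex, admissible
# coefficient sets, and small frequency panels used across test files.

rand_delta <- function() {
  x <- stats::rexp(9)
  jacquard(x / sum(x))
}

# admissible (F, R, G) with G <= min(F, R) and total ibd mass below 1
rand_FRG <- function() {
  repeat {
    F <- stats::runif(1, 0, 0.6)
    R <- stats::runif(1, 0, 0.4)
    G <- stats::runif(1, 0, min(F, R))
    if (1 - F - 2 * R + 2 * G > 0) return(c(F = F, R = R, G = G))
  }
}

p3 <- validate_frequencies(c(0.5, 0.3, 0.2))
p3b <- validate_frequencies(c(0.6, 0.3, 0.1))
p4 <- validate_frequencies(c(0.4, 0.3, 0.2, 0.1))

delta_null <- jacquard(c(0, 0, 0, 0, 0, 0, 0, 0, 1))

# forward expectations of the named quartet classes used by the joint
# closed-form solvers (computed from the class model, independent of the
# solver's internal matrix construction)
joint_class_freqs <- function(p_A, p_a, H = 0, F_AB = 0, R_AB = 0) {
  third <- 1 - p_A - p_a
  p <- validate_frequencies(c(p_A, p_a, third))
  th <- rel_coefs(H = H, F_AB = F_AB, R_AB = R_AB)
  c(AAAA = quartet_class_probability(p, th, "iiii", c(i = 1), check = FALSE),
    AaAa = quartet_class_probability(p, th, "ijij", c(i = 1, j = 2), check = FALSE),
    AAaa = quartet_class_probability(p, th, "iijj", c(i = 1, j = 2), check = FALSE) +
      quartet_class_probability(p, th, "iijj", c(i = 2, j = 1), check = FALSE))
}
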