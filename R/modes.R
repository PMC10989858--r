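# Identity-mode machinery: each condensed mode expands uniformly into the
# detailed ibd partitions of the four gene slots (1,2 = individual A;
# 3,4 = individual B) that are compatible with it. Alleles are then assigned
# one per ibd class, iid from the locus frequencies. This enumeration is the
# generative definition of every genotype-pair probability in the package.

.mode_configs <- list(
  list(list(w = 1,    P = list(c(1, 2, 3, 4)))),                            # D1
  list(list(w = 1,    P = list(c(1, 2), c(3, 4)))),                         # D2
  list(list(w = 0.5,  P = list(c(1, 2, 3), 4)),
       list(w = 0.5,  P = list(c(1, 2, 4), 3))),                            # D3
  list(list(w = 1,    P = list(c(1, 2), 3, 4))),                            # D4
  list(list(w = 0.5,  P = list(c(1, 3, 4), 2)),
       list(w = 0.5,  P = list(c(2, 3, 4), 1))),                            # D5
  list(list(w = 1,    P = list(c(3, 4), 1, 2))),                            # D6
  list(list(w = 0.5,  P = list(c(1, 3), c(2, 4))),
       list(w = 0.5,  P = list(c(1, 4), c(2, 3)))),                         # D7
  list(list(w = 0.25, P = list(c(1, 3), 2, 4)),
       list(w = 0.25, P = list(c(1, 4), 2, 3)),
       list(w = 0.25, P = list(c(2, 3), 1, 4)),
       list(w = 0.25, P = list(c(2, 4), 1, 3))),                            # D8
  list(list(w = 1,    P = list(1, 2, 3, 4)))                                # D9
)

.tuple_prob_partition <- function(tup, part, p) {
  pr <- 1
  for (cl in part) {
    a <- tup[cl]
    if (any(a != a[1L])) return(0)
    pr <- pr * p[a[1L]]
  }
  pr
}

.tuple_prob_mode <- function(tup, k, p) {
  s <- 0
  for (cfg in .mode_configs[[k]]) s <- s + cfg$w * .tuple_prob_partition(tup, cfg$P, p)
  s
}

#' Genotype-pair probability under a single identity mode
#'
#' Probability of observing unordered genotypes `gA` (individual A) and
#' `gB` (individual B) given that the four genes fall in condensed identity
#' mode `k`, with the mode expanded uniformly over its compatible detailed
#' configurations and one allele drawn iid from `p` per ibd class. This is
#' the enumeration oracle against which the closed-form class probabilities
#' of [quartet_class_probability()] are validated.
#'
#' @param gA,gB Length-2 integer vectors of allele indices (unordered).
#' @param k Mode index 1..9.
#' @param p Allele-frequency vector.
#' @return Probability.
#' @export
quartet_mode_probability <- function(gA, gB, k, p) {
  p <- as.numeric(as_freqs(p))
  stopifnot(length(gA) == 2L, length(gB) == 2L, k %in% 1:9,
            all(c(gA, gB) %in% seq_along(p)))
  ordA <- if (gA[1] == gA[2]) list(gA) else list(gA, rev(gA))
  ordB <- if (gB[1] == gB[2]) list(gB) else list(gB, rev(gB))
  s <- 0
  for (a in ordA) for (b in ordB) s <- s + .tuple_prob_mode(c(a, b), k, p)
  s
}

#' Genotype-pair probability under a Jacquard mixture
#'
#' Mixes [quartet_mode_probability()] over the nine modes with weights
#' `delta`.
#'
#' @inheritParams quartet_mode_probability
#' @param delta A [jacquard()] vector.
#' @return Probability.
#' @export
quartet_delta_probability <- function(gA, gB, delta, p) {
  delta <- jacquard(delta)
  s <- 0
  for (k in 1:9) if (delta[[k]] > 0)
    s <- s + delta[[k]] * quartet_mode_probability(gA, gB, k, p)
  s
}

# All unordered genotypes on k alleles, as a 2-column matrix (i <= j).
.genotypes <- function(k) {
  idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  cbind(i = idx[, "row"], j = idx[, "col"])[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
}

# Enumeration of all (gA, gB) observations; returns data.frame a1,a2,b1,b2.
.pair_observations <- function(k) {
  g <- .genotypes(k)
  n <- nrow(g)
  ia <- rep(seq_len(n), each = n)
  ib <- rep(seq_len(n), times = n)
  data.frame(a1 = g[ia, 1], a2 = g[ia, 2], b1 = g[ib, 1], b2 = g[ib, 2])
}

# Mode spectrum matrix: rows = observations of .pair_observations(k alleles),
# columns = modes 1..9.
.mode_spectrum <- function(p) {
  p <- as.numeric(p)
  obs <- .pair_observations(length(p))
  M <- matrix(0, nrow(obs), 9)
  for (r in seq_len(nrow(obs))) for (k in 1:9)
    M[r, k] <- quartet_mode_probability(c(obs$a1[r], obs$a2[r]),
                                        c(obs$b1[r], obs$b2[r]), k, p)
  attr(M, "obs") <- obs
  M
}

# dDelta/dtheta: 9 x 8 Jacobian of the affine inverse coefficient map,
# with Delta9 absorbing the simplex constraint. Column order = coef_names.
.ddelta_dtheta <- local({
  m <- matrix(0, 9, 8, dimnames = list(paste0("D", 1:9), coef_names))
  m["D4", "F_A"] <- 1;  m["D9", "F_A"] <- -1
  m["D6", "F_B"] <- 1;  m["D9", "F_B"] <- -1
  m["D8", "R"] <- 4;    m["D9", "R"] <- -4
  m["D3", "G_A"] <- 2;  m["D4", "G_A"] <- -2; m["D8", "G_A"] <- -4; m["D9", "G_A"] <- 4
  m["D5", "G_B"] <- 2;  m["D6", "G_B"] <- -2; m["D8", "G_B"] <- -4; m["D9", "G_B"] <- 4
  m["D2", "F_AB"] <- 1; m["D4", "F_AB"] <- -1; m["D6", "F_AB"] <- -1; m["D9", "F_AB"] <- 1
  m["D7", "R_AB"] <- 2; m["D8", "R_AB"] <- -4; m["D9", "R_AB"] <- 2
  m[, "H"] <- c(1, -1, -2, 2, -2, 2, -2, 8, -6)
  m
})

# Classify an observed genotype pair into one of the nine four-gene
# identity-by-state patterns, with canonical allele-role assignment.
# Returns list(pattern, alleles = named integer vector of the roles used).
.classify_quartet <- function(gA, gB) {
  gA <- sort(gA); gB <- sort(gB)
  homA <- gA[1] == gA[2]; homB <- gB[1] == gB[2]
  if (homA && homB) {
    if (gA[1] == gB[1]) list(pattern = "iiii", alleles = c(i = gA[1]))
    else list(pattern = "iijj", alleles = c(i = gA[1], j = gB[1]))
  } else if (homA) {
    if (gA[1] %in% gB)
      list(pattern = "iiij", alleles = c(i = gA[1], j = setdiff(gB, gA[1])))
    else
      list(pattern = "iijk", alleles = c(i = gA[1], j = gB[1], k = gB[2]))
  } else if (homB) {
    if (gB[1] %in% gA)
      list(pattern = "ijjj", alleles = c(i = setdiff(gA, gB[1]), j = gB[1]))
    else
      list(pattern = "ijkk", alleles = c(i = gA[1], j = gA[2], k = gB[1]))
  } else {
    shared <- intersect(gA, gB)
    if (length(shared) == 2L) list(pattern = "ijij", alleles = c(i = gA[1], j = gA[2]))
    else if (length(shared) == 1L)
      list(pattern = "ijik",
           alleles = c(i = shared, j = setdiff(gA, shared), k = setdiff(gB, shared)))
    else list(pattern = "ijkl", alleles = c(i = gA[1], j = gA[2], k = gB[1], l = gB[2]))
  }
}
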