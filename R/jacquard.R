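#' Jacquard condensed identity-mode vector
#'
#' The nine condensed identity modes Delta_1..Delta_9 describe every
#' distinguishable identity-by-descent partition of the four genes carried
#' by two diploid individuals A and B at one locus:
#'
#' * Delta1: all four genes ibd
#' * Delta2: A's pair ibd and B's pair ibd, but not to each other
#' * Delta3: A's pair ibd to one gene of B
#' * Delta4: A's pair ibd, B's genes unrelated
#' * Delta5: B's pair ibd to one gene of A
#' * Delta6: B's pair ibd, A's genes unrelated
#' * Delta7: two cross-individual ibd pairs
#' * Delta8: a single cross-individual ibd pair
#' * Delta9: no ibd among the four genes
#'
#' @param delta Numeric vector of nine nonnegative probabilities summing to 1.
#' @param tol Tolerance on the simplex constraint (default `1e-8`).
#' @return Object of class `jacquard` (numeric, length 9, names `D1`..`D9`).
#' @examples
#' jacquard(c(0, 0, 0, 0, 0, 0, 0, 0, 1))  # two unrelated outbred individuals
#' @export
jacquard <- function(delta, tol = 1e-8) {
  delta <- as.numeric(delta)
  if (length(delta) != 9L) stop("a Jacquard vector has exactly 9 components")
  if (anyNA(delta) || any(delta < -tol) || any(delta > 1 + tol))
    stop("each Delta_i must lie in [0, 1]")
  if (abs(sum(delta) - 1) > max(tol, 1e-8))
    stop(sprintf("Delta must sum to 1; got %.10f", sum(delta)))
  delta <- pmin(pmax(delta, 0), 1)
  delta <- delta / sum(delta)
  names(delta) <- paste0("D", 1:9)
  structure(delta, class = "jacquard")
}

coef_names <- c("F_A", "F_B", "R", "G_A", "G_B", "F_AB", "R_AB", "H")

#' Relatedness-coefficient set
#'
#' The eight independent parameters of pairwise relatedness: the two
#' inbreeding coefficients `F_A`, `F_B`; the kinship-scale pairwise
#' coefficient `R` (probability that one gene drawn from each individual is
#' ibd); the three-gene coefficients `G_A`, `G_B` (one individual's pair
#' plus a random gene of the other all ibd); and the three four-gene
#' measures `F_AB` (both within-individual pairs ibd), `R_AB` (a random
#' disjoint cross-pairing ibd as two pairs) and `H` (all four genes ibd).
#' `F_AB` and `R_AB` carry covariance components under population mixtures
#' and therefore may exceed the product bounds that pure probabilities obey.
#'
#' @param F_A,F_B,R,G_A,G_B,F_AB,R_AB,H Numeric scalars. Alternatively pass
#'   a single named vector/list as `F_A`.
#' @return Object of class `rel_coefs` (named numeric, length 8).
#' @seealso [jacquard_to_coefficients()], [coefficient_consistency_report()]
#' @export
rel_coefs <- function(F_A = 0, F_B = 0, R = 0, G_A = 0, G_B = 0,
                      F_AB = 0, R_AB = 0, H = 0) {
  if ((is.list(F_A) || length(F_A) > 1) && missing(F_B)) {
    v <- unlist(F_A)
    if (!all(coef_names %in% names(v)))
      stop("named input must contain: ", paste(coef_names, collapse = ", "))
    v <- v[coef_names]
  } else {
    v <- c(F_A = F_A, F_B = F_B, R = R, G_A = G_A, G_B = G_B,
           F_AB = F_AB, R_AB = R_AB, H = H)
  }
  storage.mode(v) <- "double"
  structure(v, class = "rel_coefs")
}

#' @export
print.rel_coefs <- function(x, ...) {
  cat("Relatedness coefficients:\n")
  print(round(unclass(x), 6), ...)
  invisible(x)
}

#' Map Jacquard identity modes to the eight relatedness coefficients
#'
#' Each coefficient is the probability of an ibd event for randomly sampled
#' genes, obtained by conditioning on the identity mode:
#' \deqn{F_A = \Delta_1+\Delta_2+\Delta_3+\Delta_4,\quad
#'       F_B = \Delta_1+\Delta_2+\Delta_5+\Delta_6,}
#' \deqn{R = \Delta_1 + (\Delta_3+\Delta_5+\Delta_7)/2 + \Delta_8/4,}
#' \deqn{G_A = \Delta_1 + \Delta_3/2,\quad G_B = \Delta_1 + \Delta_5/2,}
#' \deqn{F_{AB} = \Delta_1+\Delta_2,\quad R_{AB} = \Delta_1 + \Delta_7/2,\quad
#'       H = \Delta_1.}
#' The half and quarter weights arise because a randomly sampled gene of the
#' partially-shared individual hits the ibd class with probability 1/2 (one
#' pairing in 4 for the single cross pair of Delta8). This is the unique
#' linear map consistent with the genotype-class probabilities of
#' [quartet_class_probability()]; the map is a linear bijection between the
#' Delta simplex and the coefficient set.
#'
#' @param d A [jacquard()] vector (or coercible numeric of length 9).
#' @return A [rel_coefs()] object.
#' @examples
#' jacquard_to_coefficients(jacquard(c(0,0,0,0,0,0,1,0,0)))  # Delta7 = 1
#' @export
jacquard_to_coefficients <- function(d) {
  if (!inherits(d, "jacquard")) d <- jacquard(d)
  rel_coefs(
    F_A  = d[[1]] + d[[2]] + d[[3]] + d[[4]],
    F_B  = d[[1]] + d[[2]] + d[[5]] + d[[6]],
    R    = d[[1]] + (d[[3]] + d[[5]] + d[[7]]) / 2 + d[[8]] / 4,
    G_A  = d[[1]] + d[[3]] / 2,
    G_B  = d[[1]] + d[[5]] / 2,
    F_AB = d[[1]] + d[[2]],
    R_AB = d[[1]] + d[[7]] / 2,
    H    = d[[1]])
}

#' Invert the coefficient map back to Jacquard modes
#'
#' Inverse of [jacquard_to_coefficients()]. The result is a valid
#' probability vector only for coefficient sets lying in the image of the
#' Delta simplex; for other sets (e.g. mixture-inflated covariances) the
#' returned "Delta" components may be negative, which is reported via
#' `validate = TRUE`.
#'
#' @param coefs A [rel_coefs()] object.
#' @param validate If `TRUE` (default) error when the inverse leaves the
#'   simplex by more than `tol`; if `FALSE` return the raw affine inverse.
#' @param tol Simplex tolerance.
#' @return A [jacquard()] vector (or raw numeric when `validate = FALSE`).
#' @export
coefficients_to_jacquard <- function(coefs, validate = TRUE, tol = 1e-8) {
  v <- unclass(rel_coefs(coefs))
  d <- numeric(9)
  d[1] <- v["H"]
  d[2] <- v["F_AB"] - v["H"]
  d[3] <- 2 * (v["G_A"] - v["H"])
  d[5] <- 2 * (v["G_B"] - v["H"])
  d[7] <- 2 * (v["R_AB"] - v["H"])
  d[4] <- v["F_A"] - v["F_AB"] - d[3]
  d[6] <- v["F_B"] - v["F_AB"] - d[5]
  d[8] <- 4 * (v["R"] + 2 * v["H"] - v["G_A"] - v["G_B"] - v["R_AB"])
  d[9] <- 1 - sum(d[1:8])
  if (!validate) return(d)
  if (any(d < -tol))
    stop("coefficient set has no Jacquard representation (negative mode weight: ",
         paste(sprintf("D%d=%.3g", which(d < -tol), d[d < -tol]), collapse = ", "), ")")
  jacquard(pmax(d, 0) / sum(pmax(d, 0)), tol = tol)
}

#' Check the ordering constraints among relatedness coefficients
#'
#' Any coefficient set derived from a Jacquard vector satisfies
#' `H <= G_A <= F_A`, `H <= G_B <= F_B`, `H <= F_AB <= min(F_A, F_B)` and
#' `H <= R_AB <= R`. Estimated or mixture-derived sets may violate them;
#' this reports every violated constraint (empty character vector if none).
#'
#' @param params A [rel_coefs()] object or named numeric.
#' @param tol Slack allowed before a constraint counts as violated.
#' @return Character vector of violated constraints (possibly empty).
#' @export
coefficient_consistency_report <- function(params, tol = 1e-10) {
  v <- unclass(rel_coefs(params))
  checks <- list(
    c("H <= G_A",  v["H"],    v["G_A"]),
    c("G_A <= F_A", v["G_A"], v["F_A"]),
    c("H <= G_B",  v["H"],    v["G_B"]),
    c("G_B <= F_B", v["G_B"], v["F_B"]),
    c("H <= F_AB", v["H"],    v["F_AB"]),
    c("F_AB <= F_A", v["F_AB"], v["F_A"]),
    c("F_AB <= F_B", v["F_AB"], v["F_B"]),
    c("H <= R_AB", v["H"],    v["R_AB"]),
    c("R_AB <= R", v["R_AB"], v["R"]))
  bad <- vapply(checks, function(ch) as.numeric(ch[2]) > as.numeric(ch[3]) + tol, TRUE)
  vapply(checks[bad], function(ch) paste(ch[1], "violated"), "")
}

#' Effective selfing rate
#'
#' The genetically equivalent selfing rate induced by all forms of
#' biparental inbreeding between mates: `2R - G`, where `R` is the pairwise
#' coefficient between the mates and `G` the three-gene coefficient for the
#' two maternal genes plus the paternal gene. Values outside `[0, 1]` are
#' possible for inconsistent inputs and are flagged, not clamped.
#'
#' @param R,G Coefficients in `[0, 1]`.
#' @return Numeric scalar with attribute `out_of_range` (logical).
#' @examples
#' effective_selfing(0.5, 0)   # full-sib mating scale: s = 1
#' @export
effective_selfing <- function(R, G) {
  stopifnot(is.numeric(R), is.numeric(G), R >= 0, R <= 1, G >= 0, G <= 1)
  s <- 2 * R - G
  attr(s, "out_of_range") <- (s < 0 || s > 1)
  if (attr(s, "out_of_range"))
    warning(sprintf("effective selfing rate %.4f outside [0, 1]", s))
  s
}
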