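# Closed-form identity-by-state class probabilities for two, three and four
# genes at one multiallelic locus, affine in the relatedness coefficients.
# The four-gene forms were derived symbolically from the identity-mode
# mixture (the generative definition in modes.R) and are validated against
# that enumeration in the test suite; several of the corresponding textbook
# expressions circulate with typographic corruption, so the mixture is
# treated as authoritative throughout.

# Per-pattern null probability and gradient wrt the eight coefficients.
# pv: named numeric with the frequencies of the allele roles used.
.quartet_pattern_terms <- function(pattern, pv) {
  g <- stats::setNames(numeric(8), coef_names)
  if (pattern == "iiii") {
    pi <- pv[["i"]]; qi <- 1 - pi
    null <- pi^4
    g["F_A"] <- g["F_B"] <- pi^3 * qi
    g["R"] <- 4 * pi^3 * qi
    g["G_A"] <- g["G_B"] <- 2 * pi^2 * qi * (1 - 2 * pi)
    g["F_AB"] <- pi^2 * qi^2
    g["R_AB"] <- 2 * pi^2 * qi^2
    g["H"] <- pi * qi * (1 - 6 * pi * qi)
  } else if (pattern == "ijij") {
    pi <- pv[["i"]]; pj <- pv[["j"]]
    null <- 4 * pi^2 * pj^2
    g["F_A"] <- g["F_B"] <- -4 * pi^2 * pj^2
    g["R"] <- 4 * pi * pj * (pi + pj - 4 * pi * pj)
    g["G_A"] <- g["G_B"] <- -4 * pi * pj * (pi + pj - 4 * pi * pj)
    g["F_AB"] <- 4 * pi^2 * pj^2
    g["R_AB"] <- 4 * pi * pj * (1 - pi - pj + 2 * pi * pj)
    g["H"] <- -4 * pi * pj * (1 - 2 * pi - 2 * pj + 6 * pi * pj)
  } else if (pattern == "iijj") {
    pi <- pv[["i"]]; pj <- pv[["j"]]; qi <- 1 - pi; qj <- 1 - pj
    null <- pi^2 * pj^2
    g["F_A"] <- pi * pj^2 * qi
    g["F_B"] <- pi^2 * pj * qj
    g["R"] <- -4 * pi^2 * pj^2
    g["G_A"] <- -2 * pi * pj^2 * (1 - 2 * pi)
    g["G_B"] <- -2 * pi^2 * pj * (1 - 2 * pj)
    g["F_AB"] <- pi * pj * qi * qj
    g["R_AB"] <- 2 * pi^2 * pj^2
    g["H"] <- -pi * pj * (1 - 2 * pi - 2 * pj + 6 * pi * pj)
  } else if (pattern == "iiij") {
    pi <- pv[["i"]]; pj <- pv[["j"]]; qi <- 1 - pi
    null <- 2 * pi^3 * pj
    g["F_A"] <- 2 * pi^2 * pj * qi
    g["F_B"] <- -2 * pi^3 * pj
    g["R"] <- 4 * pi^2 * pj * (1 - 2 * pi)
    g["G_A"] <- 2 * pi * pj * (1 - 2 * pi)^2
    g["G_B"] <- -4 * pi^2 * pj * (1 - 2 * pi)
    g["F_AB"] <- -2 * pi^2 * pj * qi
    g["R_AB"] <- -4 * pi^2 * pj * qi
    g["H"] <- -2 * pi * pj * (1 - 6 * pi * qi)
  } else if (pattern == "ijjj") {
    pi <- pv[["i"]]; pj <- pv[["j"]]; qj <- 1 - pj
    null <- 2 * pi * pj^3
    g["F_A"] <- -2 * pi * pj^3
    g["F_B"] <- 2 * pi * pj^2 * qj
    g["R"] <- 4 * pi * pj^2 * (1 - 2 * pj)
    g["G_A"] <- -4 * pi * pj^2 * (1 - 2 * pj)
    g["G_B"] <- 2 * pi * pj * (1 - 2 * pj)^2
    g["F_AB"] <- -2 * pi * pj^2 * qj
    g["R_AB"] <- -4 * pi * pj^2 * qj
    g["H"] <- -2 * pi * pj * (1 - 6 * pj * qj)
  } else if (pattern == "iijk") {
    pi <- pv[["i"]]; pj <- pv[["j"]]; pk <- pv[["k"]]; qi <- 1 - pi
    null <- 2 * pi^2 * pj * pk
    g["F_A"] <- 2 * pi * pj * pk * qi
    g["F_B"] <- -2 * pi^2 * pj * pk
    g["R"] <- -8 * pi^2 * pj * pk
    g["G_A"] <- -4 * pi * pj * pk * (1 - 2 * pi)
    g["G_B"] <- 8 * pi^2 * pj * pk
    g["F_AB"] <- -2 * pi * pj * pk * qi
    g["R_AB"] <- 4 * pi^2 * pj * pk
    g["H"] <- 4 * pi * pj * pk * (1 - 3 * pi)
  } else if (pattern == "ijkk") {
    pi <- pv[["i"]]; pj <- pv[["j"]]; pk <- pv[["k"]]; qk <- 1 - pk
    null <- 2 * pi * pj * pk^2
    g["F_A"] <- -2 * pi * pj * pk^2
    g["F_B"] <- 2 * pi * pj * pk * qk
    g["R"] <- -8 * pi * pj * pk^2
    g["G_A"] <- 8 * pi * pj * pk^2
    g["G_B"] <- -4 * pi * pj * pk * (1 - 2 * pk)
    g["F_AB"] <- -2 * pi * pj * pk * qk
    g["R_AB"] <- 4 * pi * pj * pk^2
    g["H"] <- 4 * pi * pj * pk * (1 - 3 * pk)
  } else if (pattern == "ijik") {
    pi <- pv[["i"]]; pj <- pv[["j"]]; pk <- pv[["k"]]
    null <- 4 * pi^2 * pj * pk
    g["F_A"] <- g["F_B"] <- -4 * pi^2 * pj * pk
    g["R"] <- -4 * pi * pj * pk * (4 * pi - 1)
    g["G_A"] <- g["G_B"] <- 4 * pi * pj * pk * (4 * pi - 1)
    g["F_AB"] <- 4 * pi^2 * pj * pk
    g["R_AB"] <- 4 * pi * pj * pk * (2 * pi - 1)
    g["H"] <- -8 * pi * pj * pk * (3 * pi - 1)
  } else if (pattern == "ijkl") {
    pp <- 4 * pv[["i"]] * pv[["j"]] * pv[["k"]] * pv[["l"]]
    null <- pp
    g["F_A"] <- g["F_B"] <- -pp
    g["R"] <- -4 * pp
    g["G_A"] <- g["G_B"] <- 4 * pp
    g["F_AB"] <- pp
    g["R_AB"] <- 2 * pp
    g["H"] <- -6 * pp
  } else stop("unknown quartet pattern: ", pattern)
  list(null = null, grad = g)
}

.coerce_theta <- function(params) {
  if (inherits(params, "jacquard")) params <- jacquard_to_coefficients(params)
  unclass(rel_coefs(params))
}

#' Two-gene identity-by-state pair probability
#'
#' Probability of observing alleles `i` and `j` on a pair of genes with ibd
#' probability `theta`: `p_i^2 + p_i(1-p_i) theta` for `i = j`, and
#' `2 p_i p_j (1 - theta)` for the unordered heterozygous state. Applies
#' equally to the two genes within one individual (`theta` = inbreeding
#' coefficient F) and to one gene from each of two individuals (`theta` =
#' pairwise coefficient R).
#'
#' @param p Allele frequencies.
#' @param theta Probability the two genes are ibd, in `[0, 1]`.
#' @param i,j Allele indices or labels.
#' @return Probability.
#' @examples
#' pair_probability(c(0.5, 0.5), 0.25, 1, 1)  # 0.3125
#' @export
pair_probability <- function(p, theta, i, j) {
  p <- as_freqs(p)
  stopifnot(theta >= 0, theta <= 1)
  i <- .allele_index(p, i); j <- .allele_index(p, j)
  if (i == j) p[[i]]^2 + p[[i]] * (1 - p[[i]]) * theta
  else 2 * p[[i]] * p[[j]] * (1 - theta)
}

.allele_index <- function(p, a) {
  if (is.character(a)) {
    ix <- match(a, names(p))
    if (is.na(ix)) stop("unknown allele label: ", a)
    ix
  } else {
    if (!a %in% seq_along(p)) stop("allele index out of range: ", a)
    as.integer(a)
  }
}

#' Three-gene identity-by-state class probability
#'
#' Probability of the joint state of one individual's genotype (genes 1, 2)
#' and a single gene of a second individual (gene 3), given the inbreeding
#' coefficient `F` of the first individual, the pairwise coefficient `R`,
#' and the three-gene coefficient `G`. The state is a mixture over
#' three-gene identity partitions with weights `G` (all three ibd),
#' `F - G` (within-pair only), `R - G` for each of the two cross pairs, and
#' `1 - F - 2R + 2G` (no ibd):
#' \deqn{f_{iii} = p_i G + p_i^2 (F + 2R - 3G) + p_i^3 (1 - F - 2R + 2G).}
#'
#' Patterns: `"iii"` (homozygote sharing with the single gene), `"iij"`
#' (homozygote, single gene different), `"iji"` (heterozygote sharing),
#' `"ijk"` (all different). The heterozygous patterns refer to the
#' unordered genotype \{i, j\}.
#'
#' @param p Allele frequencies.
#' @param F,R,G Coefficients (must satisfy `G <= min(F, R)`-type
#'   admissibility for a pure-probability reading; negative class
#'   probabilities raise an error naming the class).
#' @param pattern One of `"iii"`, `"iij"`, `"iji"`, `"ijk"`.
#' @param alleles Integer/character vector naming the allele roles, in
#'   pattern order (e.g. `c(i = 1, j = 2)`).
#' @return Probability.
#' @export
triplet_probability <- function(p, F, R, G, pattern, alleles) {
  p <- as_freqs(p)
  al <- vapply(alleles, function(a) .allele_index(p, a), 1L)
  g0 <- 1 - F - 2 * R + 2 * G
  val <- switch(pattern,
    iii = {
      pi <- p[[al[1]]]
      pi * G + pi^2 * (F + 2 * R - 3 * G) + pi^3 * g0
    },
    iij = {
      pi <- p[[al[1]]]; pj <- p[[al[2]]]
      pi * pj * (F - G) + pi^2 * pj * g0
    },
    iji = {
      pi <- p[[al[1]]]; pj <- p[[al[2]]]
      2 * pi * pj * (R - G) + 2 * pi^2 * pj * g0
    },
    ijk = {
      2 * p[[al[1]]] * p[[al[2]]] * p[[al[3]]] * g0
    },
    stop("unknown triplet pattern: ", pattern))
  if (val < -1e-12)
    stop(sprintf("inadmissible coefficients: class %s has probability %.3g",
                 pattern, val))
  max(val, 0)
}

#' Four-gene genotype-pair class probability
#'
#' Probability of an identity-by-state genotype-pair class at one locus,
#' affine in the eight relatedness coefficients. Patterns (first pair =
#' individual A's unordered genotype, second = B's): `"iiii"`, `"ijij"`,
#' `"iijj"` (A homozygous for i, B for j), `"iiij"`, `"ijjj"`, `"iijk"`,
#' `"ijkk"`, `"ijik"` (heterozygotes sharing allele i; this class already
#' aggregates the within-individual orderings), `"ijkl"`.
#'
#' When `params` derives from a Jacquard vector the value equals, to
#' machine precision, the mixture of pure identity modes computed by
#' [quartet_delta_probability()].
#'
#' @param p Allele frequencies.
#' @param params A [rel_coefs()] set (or [jacquard()] vector).
#' @param pattern Pattern label (see Details).
#' @param alleles Named or positional allele roles in pattern order.
#' @param check If `TRUE` (default) warn when `params` violates the
#'   Jacquard ordering constraints (mixture-derived covariances may do so
#'   legitimately).
#' @return Probability. Negative values (inadmissible parameter sets) raise
#'   an error naming the class.
#' @examples
#' p <- validate_frequencies(c(0.5, 0.3, 0.2))
#' th <- jacquard_to_coefficients(jacquard(c(0,0,0,0,0,0,1,0,0)))
#' quartet_class_probability(p, th, "ijij", c(i = 1, j = 2))  # 2 * 0.5 * 0.3
#' @export
quartet_class_probability <- function(p, params, pattern, alleles, check = TRUE) {
  p <- as_freqs(p)
  theta <- .coerce_theta(params)
  if (check) {
    viol <- coefficient_consistency_report(theta)
    if (length(viol))
      warning("coefficient ordering constraints violated (",
              paste(viol, collapse = "; "),
              "); admissible only as mixture covariances", call. = FALSE)
  }
  al <- vapply(alleles, function(a) .allele_index(p, a), 1L)
  roles <- c("i", "j", "k", "l")[seq_along(al)]
  pv <- stats::setNames(as.numeric(p[al]), roles)
  tm <- .quartet_pattern_terms(pattern, pv)
  val <- tm$null + sum(tm$grad * theta)
  if (val < -1e-12)
    stop(sprintf(
      "negative class probability %.3g for pattern %s at p = (%s); parameter set inadmissible",
      val, pattern, paste(signif(pv, 3), collapse = ", ")))
  max(val, 0)
}

#' Complete class spectrum at one locus
#'
#' Enumerates every concrete identity-by-state class for `n_genes` genes
#' and returns its exact probability. For `n_genes = 2` the unit is a pair
#' of genes (classes `i <= j`); for 3, one individual's unordered genotype
#' plus one gene of the other; for 4, the ordered pair of unordered
#' genotypes (A then B). Spectra sum to 1 by the law of total probability.
#'
#' @param p Allele frequencies.
#' @param params For `n_genes = 2` a single ibd probability (or
#'   [rel_coefs()], in which case `R` is used); for 3 a list/vector with
#'   `F`, `R`, `G` (or [rel_coefs()], using `F_A`, `R`, `G_A`); for 4 a
#'   [rel_coefs()] or [jacquard()] object.
#' @param n_genes 2, 3 or 4.
#' @return A data.frame of class `class_spectrum` with allele columns, a
#'   `pattern` column and a `prob` column; attributes `n_genes` and `p`.
#' @export
class_spectrum <- function(p, params, n_genes = 4) {
  p <- as_freqs(p)
  k <- length(p)
  if (n_genes == 2) {
    theta <- if (inherits(params, "rel_coefs")) params[["R"]] else
      if (inherits(params, "jacquard")) jacquard_to_coefficients(params)[["R"]] else
        as.numeric(params)[1]
    g <- .genotypes(k)
    out <- data.frame(i = g[, 1], j = g[, 2],
                      pattern = ifelse(g[, 1] == g[, 2], "ii", "ij"))
    out$prob <- vapply(seq_len(nrow(out)), function(r)
      pair_probability(p, theta, out$i[r], out$j[r]), 0)
  } else if (n_genes == 3) {
    if (inherits(params, "jacquard")) params <- jacquard_to_coefficients(params)
    if (inherits(params, "rel_coefs"))
      params <- list(F = params[["F_A"]], R = params[["R"]], G = params[["G_A"]])
    pr <- unlist(params)[c("F", "R", "G")]
    g <- .genotypes(k)
    out <- do.call(rbind, lapply(seq_len(nrow(g)), function(ig) {
      data.frame(a1 = unname(g[ig, 1]), a2 = unname(g[ig, 2]), b = seq_len(k))
    }))
    cls <- function(a1, a2, b) {
      if (a1 == a2) { if (b == a1) c("iii", a1, NA, NA) else c("iij", a1, b, NA) }
      else if (b == a1 || b == a2)
        c("iji", b, if (b == a1) a2 else a1, NA)
      else c("ijk", a1, a2, b)
    }
    info <- t(vapply(seq_len(nrow(out)), function(r)
      cls(out$a1[r], out$a2[r], out$b[r]), c("", "", "", "")))
    out$pattern <- info[, 1]
    out$prob <- vapply(seq_len(nrow(out)), function(r)
      triplet_probability(p, pr[["F"]], pr[["R"]], pr[["G"]], info[r, 1],
                          as.integer(stats::na.omit(info[r, 2:4]))), 0)
  } else if (n_genes == 4) {
    theta <- .coerce_theta(params)
    obs <- .pair_observations(k)
    out <- obs
    out$pattern <- NA_character_
    out$prob <- NA_real_
    for (r in seq_len(nrow(obs))) {
      cl <- .classify_quartet(c(obs$a1[r], obs$a2[r]), c(obs$b1[r], obs$b2[r]))
      out$pattern[r] <- cl$pattern
      out$prob[r] <- quartet_class_probability(p, rel_coefs(as.list(theta)),
                                               cl$pattern, cl$alleles,
                                               check = FALSE)
    }
  } else stop("n_genes must be 2, 3 or 4")
  structure(out, class = c("class_spectrum", "data.frame"),
            n_genes = n_genes, p = p)
}

#' Write a class spectrum as TSV
#'
#' Deterministic ordering: lexicographic in pattern label, then allele
#' indices. Columns: `pattern`, `alleles` (comma-joined), `prob`.
#'
#' @param spectrum A [class_spectrum()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  acols <- setdiff(names(spectrum), c("pattern", "prob"))
  tab <- data.frame(
    pattern = spectrum$pattern,
    alleles = apply(spectrum[acols], 1, paste, collapse = ","),
    prob = spectrum$prob)
  tab <- tab[order(tab$pattern, tab$alleles), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Design matrix of the eight-class four-gene system
#'
#' The 8 x 8 matrix of partial derivatives of the chosen class
#' probabilities with respect to the eight relatedness coefficients, for
#' classes `(iiii, ijij, iijj, iiij, ijjj, iijk, ijkk, ijik)` on a chosen
#' allele triple. The determinant is nonzero for generic frequencies; the
#' system degenerates when two chosen alleles share a frequency (the
#' i/j-symmetric classes become linearly dependent), which is flagged via
#' the reciprocal condition number.
#'
#' @param p Allele frequencies (at least 3 alleles).
#' @param allele_choice Integer vector `(i, j, k)` of distinct alleles
#'   (default first three).
#' @param rcond_tol Reciprocal-condition threshold below which the matrix
#'   is flagged singular (default `1e-10`).
#' @return Matrix with attributes `null` (the eight null-model class
#'   probabilities), `classes` (labels), `singular` (logical flag) and
#'   `rcond`.
#' @export
design_matrix <- function(p, allele_choice = 1:3, rcond_tol = 1e-10) {
  p <- as_freqs(p)
  if (length(p) < 3) stop("at least 3 distinct alleles required")
  al <- vapply(allele_choice, function(a) .allele_index(p, a), 1L)
  if (length(al) != 3 || anyDuplicated(al)) stop("allele_choice must be 3 distinct alleles")
  i <- al[1]; j <- al[2]; k <- al[3]
  defs <- list(
    iiii = list("iiii", c(i = i)),
    ijij = list("ijij", c(i = i, j = j)),
    iijj = list("iijj", c(i = i, j = j)),
    iiij = list("iiij", c(i = i, j = j)),
    ijjj = list("ijjj", c(i = i, j = j)),
    iijk = list("iijk", c(i = i, j = j, k = k)),
    ijkk = list("ijkk", c(i = i, j = j, k = k)),
    ijik = list("ijik", c(i = i, j = j, k = k)))
  M <- matrix(0, 8, 8, dimnames = list(names(defs), coef_names))
  null <- numeric(8)
  for (r in seq_along(defs)) {
    pv <- stats::setNames(as.numeric(p[defs[[r]][[2]]]),
                          c("i", "j", "k")[seq_along(defs[[r]][[2]])])
    tm <- .quartet_pattern_terms(defs[[r]][[1]], pv)
    M[r, ] <- tm$grad
    null[r] <- tm$null
  }
  rc <- rcond(M)
  if (rc < rcond_tol)
    warning(sprintf(
      "design matrix numerically singular (rcond %.2e) at p = (%s); equal chosen-allele frequencies degenerate the class system",
      rc, paste(signif(as.numeric(p[al]), 4), collapse = ", ")), call. = FALSE)
  structure(M, null = null, classes = names(defs),
            allele_choice = al, singular = rc < rcond_tol, rcond = rc)
}
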