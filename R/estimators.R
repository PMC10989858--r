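# Method-of-moments and closed-form linear estimators inverting the class
# probability model. All per-pattern inverters are algebraic inversions of
# the forward model of genoprob.R; none is transcribed from secondary
# closed-form displays. Estimates are never truncated to [0, 1]:
# unbiasedness requires unbounded estimators, and out-of-range values are
# informative about sampling noise and model misfit.

new_estimate <- function(method, estimates, components = NULL, weights = NULL,
                         flags = character(), ...) {
  structure(list(method = method, estimates = estimates,
                 components = components, weights = weights,
                 flags = flags, extra = list(...)),
            class = "rq_estimate")
}

#' @export
print.rq_estimate <- function(x, ...) {
  cat("<rq_estimate> method:", x$method, "\n")
  print(round(x$estimates, 6))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize an estimate to JSON
#'
#' @param x An `rq_estimate`.
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
estimate_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "rq_estimate"))
  obj <- list(method = x$method,
              estimates = as.list(x$estimates),
              components = x$components,
              weights = as.list(x$weights),
              flags = x$flags,
              extra = x$extra)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

.spectrum_freq <- function(spectrum) {
  if ("prob" %in% names(spectrum)) f <- spectrum$prob
  else if ("count" %in% names(spectrum)) f <- spectrum$count / sum(spectrum$count)
  else stop("spectrum needs a 'prob' or 'count' column")
  f
}

#' Moment estimator of the pairwise coefficient R
#'
#' Inverts the two-gene model per allele,
#' \eqn{\hat R_{ii} = (f_{ii} - p_i^2) / (p_i(1-p_i))}, and combines the
#' per-allele components with weights summing to one; the default
#' zero-prior weights \eqn{w_i = (1-p_i)/(n-1)} are the constrained
#' minimum-variance weights under the null (see [allele_weights()]).
#'
#' @param spectrum Two-gene class spectrum (data.frame with columns `i`,
#'   `j` and `prob` or `count`) of single genes paired across individuals.
#' @param p Allele frequencies.
#' @param weights Optional weights over alleles (renormalized over the
#'   estimable components); default `(1-p_i)/(n-1)`.
#' @return An `rq_estimate` with estimate `R`, per-allele components and
#'   the weights used.
#' @export
estimate_R <- function(spectrum, p, weights = NULL) {
  p <- as_freqs(p)
  f <- .spectrum_freq(spectrum)
  k <- length(p)
  hom <- spectrum$i == spectrum$j
  f_ii <- numeric(k)
  f_ii[spectrum$i[hom]] <- f[hom]
  usable <- p > 1e-12 & p < 1 - 1e-12
  comp <- rep(NA_real_, k)
  comp[usable] <- (f_ii[usable] - p[usable]^2) / (p[usable] * (1 - p[usable]))
  if (is.null(weights)) weights <- (1 - as.numeric(p)) / (k - 1)
  w <- ifelse(usable, weights, 0)
  if (sum(w) <= 0) stop("no estimable allele components")
  w <- w / sum(w)
  flags <- if (all(usable)) character() else
    paste0("allele ", names(p)[!usable], " excluded (degenerate frequency)")
  new_estimate("moment-R", c(R = sum(w[usable] * comp[usable])),
               components = list(R = stats::setNames(comp, names(p))),
               weights = stats::setNames(w, names(p)), flags = flags)
}

#' Linear estimator of the three-gene coefficient G
#'
#' Given known (or prior-estimated) `F` and `R`, inverts the three-gene
#' model per allele using the triple-homozygous class:
#' \eqn{\hat G_i = (f_{iii} - p_i^3 - p_i^2(1-p_i)(F + 2R)) /
#' (p_i(1-p_i)(1-2p_i))}. The denominator is the order-3 normalization
#' constant, which vanishes at \eqn{p_i = 1/2}: such components are flagged
#' non-estimable and excluded from the weighted combination, never
#' zero-filled.
#'
#' @param spectrum Three-gene class spectrum (columns `a1`, `a2`, `b`,
#'   `prob`/`count`).
#' @param p Allele frequencies.
#' @param F,R Known/prior two-gene coefficients.
#' @param weights Optional weights over alleles (renormalized over the
#'   estimable components); default minimum-variance at the null prior.
#' @param tol Half-frequency tolerance for the singularity flag.
#' @return An `rq_estimate` with estimate `G`.
#' @export
estimate_G <- function(spectrum, p, F, R, weights = NULL, tol = 1e-9) {
  p <- as_freqs(p)
  f <- .spectrum_freq(spectrum)
  k <- length(p)
  f_iii <- numeric(k)
  sel <- spectrum$a1 == spectrum$a2 & spectrum$b == spectrum$a1
  f_iii[spectrum$a1[sel]] <- f[sel]
  pn <- as.numeric(p); qn <- 1 - pn
  denom <- pn * qn * (1 - 2 * pn)
  estimable <- abs(1 - 2 * pn) > tol
  comp <- rep(NA_real_, k)
  comp[estimable] <- (f_iii[estimable] - pn[estimable]^3 -
    pn[estimable]^2 * qn[estimable] * (F + 2 * R)) / denom[estimable]
  flags <- if (all(estimable)) character() else
    sprintf("allele %s non-estimable (p = 1/2 zeroes the order-3 constant)",
            names(p)[!estimable])
  if (!any(estimable)) {
    return(new_estimate("moment-G", c(G = NA_real_),
                        components = list(G = stats::setNames(comp, names(p))),
                        weights = NULL,
                        flags = c(flags, "no estimable component")))
  }
  if (is.null(weights)) {
    weights <- tryCatch(
      allele_weights(p, target = "G")$weights,
      error = function(e) stats::setNames(rep(1 / k, k), names(p)))
  }
  w <- ifelse(estimable, weights, 0)
  w[is.na(w)] <- 0
  w <- w / sum(w)
  new_estimate("moment-G", c(G = sum(w[estimable] * comp[estimable])),
               components = list(G = stats::setNames(comp, names(p))),
               weights = stats::setNames(w, names(p)), flags = flags)
}

# Rows of the joint closed-form systems, from the quartet model:
# class iiii on the focal allele and the two-allele classes on (A, a).
.joint_rows <- function(p, q, classes, cols) {
  third <- 1 - p - q
  if (third < -1e-12) stop("p + q must not exceed 1")
  pv2 <- c(i = p, j = q)
  rows <- lapply(classes, function(cl)
    switch(cl,
      AAAA = .quartet_pattern_terms("iiii", c(i = p)),
      AaAa = .quartet_pattern_terms("ijij", pv2),
      AAaa = {  # both orientations of alternate homozygotes
        t1 <- .quartet_pattern_terms("iijj", c(i = p, j = q))
        t2 <- .quartet_pattern_terms("iijj", c(i = q, j = p))
        list(null = t1$null + t2$null, grad = t1$grad + t2$grad)
      },
      stop("unknown class ", cl)))
  M <- do.call(rbind, lapply(rows, function(r) r$grad[cols]))
  dimnames(M) <- list(classes, cols)
  attr(M, "null") <- vapply(rows, function(r) r$null, 0)
  M
}

#' Joint closed-form estimate of H and F_AB from two classes
#'
#' Solves the 2 x 2 linear system linking the double-homozygote class
#' `f_AAAA` and the double-heterozygote class `f_AaAa` to `(H, F_AB)` at a
#' locus with at least three alleles (`p + q < 1`), the other six
#' coefficients held at zero. The determinant carries the factor
#' `(1 - 2p)(1 - p - q)`: the system is singular at `p = 1/2` and when A
#' and a are the only alleles.
#'
#' @param f_AAAA Observed frequency of both individuals homozygous for A.
#' @param f_AaAa Observed frequency of both individuals heterozygous A/a.
#' @param p,q Frequencies of alleles A and a (`p + q < 1` strictly for
#'   estimability).
#' @param tol Singularity tolerance on the determinant factors.
#' @return An `rq_estimate` with estimates `H` and `F_AB`.
#' @export
estimate_H_Fab <- function(f_AAAA, f_AaAa, p, q, tol = 1e-9) {
  stopifnot(p > 0, q > 0, p + q <= 1 + 1e-12)
  sing <- character()
  if (abs(1 - 2 * p) < tol) sing <- c(sing, "p = 1/2 (order-3 factor vanishes)")
  if (1 - p - q < tol) sing <- c(sing, "p + q = 1 (third allele required)")
  M <- .joint_rows(p, q, c("AAAA", "AaAa"), c("H", "F_AB"))
  if (length(sing) || abs(det(M)) < 1e-14)
    return(new_estimate("joint-H-Fab", c(H = NA_real_, F_AB = NA_real_),
                        flags = c("singular system", sing)))
  sol <- solve(M, c(f_AAAA, f_AaAa) - attr(M, "null"))
  new_estimate("joint-H-Fab", c(H = sol[1], F_AB = sol[2]),
               flags = character(), det = det(M))
}

#' Joint closed-form estimate of H, F_AB and R_AB from three classes
#'
#' Solves the 3 x 3 system linking `(f_AAAA, f_AaAa, f_AAaa)` -- the
#' double homozygote, double heterozygote, and alternate-homozygote
#' (either orientation) classes -- to the three four-gene coefficients
#' `(H, F_AB, R_AB)`. At least three alleles are required in the
#' population, and the determinant carries the factor `(1 - 3p)`: marker
#' frequencies of `p = 1/3` are noninformative.
#'
#' @param f_AAAA,f_AaAa,f_AAaa Observed class frequencies (`f_AAaa` summed
#'   over which individual carries which homozygote).
#' @param p,q Frequencies of alleles A and a.
#' @param tol Singularity tolerance.
#' @return An `rq_estimate` with estimates `H`, `F_AB`, `R_AB`.
#' @export
estimate_H_F_R <- function(f_AAAA, f_AaAa, f_AAaa, p, q, tol = 1e-9) {
  stopifnot(p > 0, q > 0, p + q <= 1 + 1e-12)
  sing <- character()
  if (abs(1 - 3 * p) < tol) sing <- c(sing, "p = 1/3 noninformative")
  if (1 - p - q < tol) sing <- c(sing, "p + q = 1 (third allele required)")
  M <- .joint_rows(p, q, c("AAAA", "AaAa", "AAaa"), c("H", "F_AB", "R_AB"))
  if (length(sing) || abs(det(M)) < 1e-16)
    return(new_estimate("joint-H-F-R",
                        c(H = NA_real_, F_AB = NA_real_, R_AB = NA_real_),
                        flags = c("singular system", sing)))
  sol <- solve(M, c(f_AAAA, f_AaAa, f_AAaa) - attr(M, "null"))
  new_estimate("joint-H-F-R", c(H = sol[1], F_AB = sol[2], R_AB = sol[3]),
               flags = character(), det = det(M))
}

#' Classic identity-disequilibrium estimator of R_AB
#'
#' The double-homozygote contrast
#' \eqn{\hat R_{AB} = (a f_{AAAA} - b f_{AA,aa}) / c} with
#' `a = 6(6pq - 2p - 2q + 1)`, `b = 1 - 6pq`,
#' `c = 6pq(1 - p - q)(1 - 3p)`. Here `f_AAAA` is the observed frequency of
#' double homozygotes and `f_AA,aa` the double-homozygote frequency
#' expected with no zygotic association (callers may supply observed or
#' expected values). The numerator coefficients satisfy `a > b`, but `c`
#' changes sign at `p = 1/3`, where the estimator is singular; the sign of
#' `c` is reported alongside the estimate.
#'
#' @param f_AAAA Observed double-homozygote frequency.
#' @param f_AA_aa Expected double-homozygote frequency under no zygotic
#'   association (product of single-locus homozygote frequencies).
#' @param p,q Allele frequencies of A and a.
#' @param tol Singularity tolerance on `c`.
#' @return An `rq_estimate` with estimate `R_AB`; `extra$abc` holds the
#'   coefficients `a`, `b`, `c`, and `extra$sign_c` the sign of the
#'   denominator.
#' @examples
#' weir_identity_disequilibrium(0, 0, 0.2, 0.3)$extra$abc
#' @export
weir_identity_disequilibrium <- function(f_AAAA, f_AA_aa, p, q, tol = 1e-12) {
  stopifnot(p > 0, q > 0, p + q <= 1 + 1e-12)
  a <- 6 * (6 * p * q - 2 * p - 2 * q + 1)
  b <- 1 - 6 * p * q
  cc <- 6 * p * q * (1 - p - q) * (1 - 3 * p)
  if (abs(cc) < tol)
    return(new_estimate("weir-id", c(R_AB = NA_real_),
                        flags = "singular: c = 0 (p = 1/3 or p + q = 1)",
                        abc = list(a = a, b = b, c = cc), sign_c = sign(cc)))
  new_estimate("weir-id", c(R_AB = (a * f_AAAA - b * f_AA_aa) / cc),
               flags = character(), abc = list(a = a, b = b, c = cc),
               sign_c = sign(cc))
}

#' Joint linear estimate of all eight relatedness coefficients
#'
#' Solves the 8 x 8 residual system: observed frequencies of the eight
#' chosen genotype-pair classes minus their null (unrelated, outbred)
#' expectations, against the [design_matrix()] of partial derivatives.
#' Exact on expected spectra whenever the matrix is nonsingular.
#'
#' @param spectrum Four-gene class spectrum (columns `a1`, `a2`, `b1`,
#'   `b2`, `prob`/`count`) over the full enumeration or at least the eight
#'   chosen classes.
#' @param p Allele frequencies (>= 3 alleles).
#' @param allele_choice Distinct allele triple `(i, j, k)`; default first
#'   three.
#' @return An `rq_estimate` with the eight coefficients, the condition
#'   number of the system, and a singularity flag when the class system
#'   degenerates.
#' @export
estimate_all_eight <- function(spectrum, p, allele_choice = 1:3) {
  p <- as_freqs(p)
  f <- .spectrum_freq(spectrum)
  DM <- withCallingHandlers(design_matrix(p, allele_choice),
                            warning = function(w) invokeRestart("muffleWarning"))
  al <- attr(DM, "allele_choice")
  i <- al[1]; j <- al[2]; k <- al[3]
  want <- list(
    iiii = c(i, i, i, i), ijij = c(min(i, j), max(i, j), min(i, j), max(i, j)),
    iijj = c(i, i, j, j), iiij = c(i, i, min(i, j), max(i, j)),
    ijjj = c(min(i, j), max(i, j), j, j), iijk = c(i, i, min(j, k), max(j, k)),
    ijkk = c(min(i, j), max(i, j), k, k),
    ijik = c(min(i, j), max(i, j), min(i, k), max(i, k)))
  x <- vapply(want, function(wv) {
    sel <- spectrum$a1 == wv[1] & spectrum$a2 == wv[2] &
      spectrum$b1 == wv[3] & spectrum$b2 == wv[4]
    if (!any(sel)) 0 else sum(f[sel])
  }, 0)
  flags <- character()
  if (attr(DM, "singular")) {
    return(new_estimate("linear-8",
                        stats::setNames(rep(NA_real_, 8), coef_names),
                        flags = sprintf(
                          "singular design matrix (rcond %.2e) at chosen frequencies (%s)",
                          attr(DM, "rcond"),
                          paste(signif(as.numeric(p[al]), 4), collapse = ", "))))
  }
  sol <- solve(DM, x - attr(DM, "null"))
  new_estimate("linear-8", stats::setNames(sol, coef_names), flags = flags,
               condition_number = kappa(DM), rcond = attr(DM, "rcond"),
               allele_choice = al)
}

#' Minimum-variance allele weights for per-allele component estimators
#'
#' Finds the weights minimizing `w' V w` subject to `sum(w) = 1`, where `V`
#' is the exact covariance matrix of the per-allele component estimators
#' computed by full enumeration of the observation unit under a prior
#' parameter set. With the zero prior and the two-gene target this
#' reproduces the closed-form weights `w_i = (1 - p_i)/(n - 1)`.
#'
#' @param p Allele frequencies.
#' @param prior Prior [rel_coefs()] (default all zero).
#' @param target Which coefficient's component estimators to weight:
#'   `"R"`, `"F"`, `"G"` or `"H"`.
#' @return List with `weights` (named; `NA` for non-estimable components),
#'   `V` (component covariance matrix) and `target`. Falls back to equal
#'   weights with a warning if `V` is singular.
#' @examples
#' allele_weights(c(0.6, 0.3, 0.1), target = "R")$weights  # 0.2 0.35 0.45
#' @export
allele_weights <- function(p, prior = rel_coefs(), target = c("R", "F", "G", "H")) {
  target <- match.arg(target)
  p <- as_freqs(p)
  k <- length(p)
  pn <- as.numeric(p); qn <- 1 - pn
  theta <- .coerce_theta(prior)
  if (target %in% c("R", "F")) {
    th <- if (target == "R") theta[["R"]] else theta[["F_A"]]
    spec <- class_spectrum(p, th, n_genes = 2)
    denom <- pn * qn
    est <- ok <- rep(TRUE, k)
    vals <- matrix(0, nrow(spec), k)
    for (a in 1:k) {
      ind <- as.numeric(spec$i == a & spec$j == a)
      fexp <- sum(spec$prob[spec$i == a & spec$j == a])
      vals[, a] <- th + (ind - fexp) / denom[a]
    }
  } else if (target == "G") {
    spec <- class_spectrum(p, list(F = theta[["F_A"]], R = theta[["R"]],
                                   G = theta[["G_A"]]), n_genes = 3)
    denom <- pn * qn * (1 - 2 * pn)
    ok <- abs(1 - 2 * pn) > 1e-9
    vals <- matrix(NA_real_, nrow(spec), k)
    for (a in which(ok)) {
      sel <- spec$a1 == a & spec$a2 == a & spec$b == a
      ind <- as.numeric(sel)
      vals[, a] <- theta[["G_A"]] + (ind - sum(spec$prob[sel])) / denom[a]
    }
  } else {
    spec <- class_spectrum(p, rel_coefs(as.list(theta)), n_genes = 4)
    denom <- pn * qn * (1 - 6 * pn * qn)
    ok <- abs(denom) > 1e-9
    vals <- matrix(NA_real_, nrow(spec), k)
    for (a in which(ok)) {
      sel <- spec$a1 == a & spec$a2 == a & spec$b1 == a & spec$b2 == a
      ind <- as.numeric(sel)
      vals[, a] <- theta[["H"]] + (ind - sum(spec$prob[sel])) / denom[a]
    }
  }
  if (target %in% c("R", "F")) ok <- rep(TRUE, k)
  use <- which(ok)
  if (!length(use)) stop("no estimable component for target ", target)
  pr <- spec$prob
  mu <- colSums(pr * vals[, use, drop = FALSE])
  Vc <- crossprod(vals[, use, drop = FALSE], pr * vals[, use, drop = FALSE]) -
    outer(mu, mu)
  w_use <- tryCatch({
    x <- solve(Vc, rep(1, length(use)))
    x / sum(x)
  }, error = function(e) {
    warning("component covariance singular; falling back to equal weights",
            call. = FALSE)
    rep(1 / length(use), length(use))
  })
  w <- rep(NA_real_, k)
  w[use] <- w_use
  V <- matrix(NA_real_, k, k, dimnames = list(names(p), names(p)))
  V[use, use] <- Vc
  list(weights = stats::setNames(w, names(p)), V = V, target = target)
}

#' Observed class spectrum from a genotype table
#'
#' Tabulates the empirical class frequencies of a genotype-pair table (as
#' produced by [simulate_dataset()] or [read_genotype_table()]) at one
#' locus, in the layout of [class_spectrum()]. For `n_genes = 2` each pair
#' contributes its four cross-individual gene pairings with weight 1/4;
#' for `n_genes = 3`, individual A's genotype with each B gene at weight
#' 1/2; for `n_genes = 4`, the genotype pair itself.
#'
#' @param tab Genotype table (`pair_id`, `locus`, `a1`, `a2`, `b1`, `b2`).
#' @param p Allele frequencies of the locus (defines the allele set).
#' @param n_genes 2, 3 or 4.
#' @param locus Optional locus id to subset on.
#' @return Data.frame matching the [class_spectrum()] layout with a
#'   `count` column.
#' @export
observed_spectrum <- function(tab, p, n_genes = 4, locus = NULL) {
  p <- as_freqs(p)
  if (!is.null(locus)) tab <- tab[tab$locus == locus, , drop = FALSE]
  k <- length(p)
  if (n_genes == 2) {
    g <- .genotypes(k)
    cnt <- matrix(0, k, k)
    for (aa in c("a1", "a2")) for (bb in c("b1", "b2")) {
      lo <- pmin(tab[[aa]], tab[[bb]]); hi <- pmax(tab[[aa]], tab[[bb]])
      t0 <- table(factor(lo, 1:k), factor(hi, 1:k))
      cnt <- cnt + t0 / 4
    }
    out <- data.frame(i = g[, 1], j = g[, 2],
                      pattern = ifelse(g[, 1] == g[, 2], "ii", "ij"),
                      count = cnt[g])
  } else if (n_genes == 3) {
    a1 <- pmin(tab$a1, tab$a2); a2 <- pmax(tab$a1, tab$a2)
    key <- expand.grid(b = 1:k, gi = seq_len(nrow(.genotypes(k))))
    g <- .genotypes(k)
    idx <- function(x, y) match(paste(x, y), paste(g[, 1], g[, 2]))
    cnt <- array(0, c(nrow(g), k))
    for (bb in c("b1", "b2")) {
      t0 <- table(factor(idx(a1, a2), seq_len(nrow(g))), factor(tab[[bb]], 1:k))
      cnt <- cnt + t0 / 2
    }
    out <- data.frame(a1 = g[key$gi, 1], a2 = g[key$gi, 2], b = key$b,
                      count = cnt[cbind(key$gi, key$b)])
  } else if (n_genes == 4) {
    obs <- .pair_observations(k)
    a1 <- pmin(tab$a1, tab$a2); a2 <- pmax(tab$a1, tab$a2)
    b1 <- pmin(tab$b1, tab$b2); b2 <- pmax(tab$b1, tab$b2)
    keys <- paste(obs$a1, obs$a2, obs$b1, obs$b2)
    t0 <- table(factor(paste(a1, a2, b1, b2), keys))
    out <- obs
    out$count <- as.numeric(t0)
  } else stop("n_genes must be 2, 3 or 4")
  out
}
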