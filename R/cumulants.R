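#' Normalization constants for identity coefficients
#'
#' The maximum attainable central moment of an allele indicator at
#' frequency `p`, used to convert moment-scale associations into
#' probability-scale coefficients:
#' order 2: `p(1-p)`; order 3: `p(1-p)(1-2p)`; order 4: `p(1-p)(1-6p(1-p))`.
#' The order-3 constant vanishes at `p = 1/2` and the order-4 constant at
#' `p = (3 +- sqrt(3))/6`, the frequencies at which the corresponding
#' single-allele estimators lose information. The order-4 constant equals
#' the fourth cumulant of a Bernoulli(`p`) indicator.
#'
#' @param order 2, 3 or 4.
#' @param p Allele frequency in (0, 1); vectorized.
#' @return Numeric constant(s).
#' @examples
#' normalization_constant(2, 0.2)   # 0.16
#' normalization_constant(4, 0.5)   # -0.125, the Bernoulli(1/2) kurtosis cumulant
#' @export
normalization_constant <- function(order, p) {
  stopifnot(all(p > 0), all(p < 1))
  if (!order %in% c(2, 3, 4)) stop("order must be 2, 3 or 4")
  q <- 1 - p
  switch(as.character(order),
         "2" = p * q,
         "3" = p * q * (1 - 2 * p),
         "4" = p * q * (1 - 6 * p * q))
}

#' Convert central moments to cumulants
#'
#' Cumulants equal central moments through order 3. At order 4 they differ:
#' univariate \eqn{\kappa_4 = \mu_{4c} - 3\kappa_2^2}; four-variate
#' \eqn{\kappa_{1234} = \mu_{1234c} - \sigma_{12}\sigma_{34}
#' - \sigma_{13}\sigma_{24} - \sigma_{14}\sigma_{23}}, i.e. the part of the
#' fourth moment not explained by the three pairwise-covariance pairings.
#' It is this cumulant, normalized by [normalization_constant()] at order 4,
#' that equals the four-gene identity probability `H`.
#'
#' @param mu2 Second central moment (variance), or for the four-variate case
#'   a named list/vector of the six covariances `s12, s13, s14, s23, s24, s34`.
#' @param mu3 Third central moment (univariate case only; optional).
#' @param mu4 Fourth central moment (univariate) or fourth joint central
#'   moment (four-variate).
#' @return Named list with `k2` (or the covariances), `k3` (if supplied) and
#'   `k4` (univariate) or `k1234` (four-variate).
#' @examples
#' central_moments_to_cumulants(mu2 = 0.25, mu4 = 0.0625)  # Bernoulli(1/2): k4 = -0.125
#' @export
central_moments_to_cumulants <- function(mu2, mu3 = NULL, mu4) {
  if (missing(mu4)) stop("fourth central moment required")
  if (length(mu2) == 1L) {
    out <- list(k2 = mu2, k4 = mu4 - 3 * mu2^2)
    if (!is.null(mu3)) out$k3 <- mu3
    return(out[order(names(out))])
  }
  s <- unlist(mu2)
  need <- c("s12", "s13", "s14", "s23", "s24", "s34")
  if (!all(need %in% names(s)))
    stop("four-variate case needs the six named covariances: ",
         paste(need, collapse = ", "))
  list(cov = s,
       k1234 = mu4 - s["s12"] * s["s34"] - s["s13"] * s["s24"] -
         s["s14"] * s["s23"])
}

#' Finite mixture of subpopulations
#'
#' Describes a population composed of `M` subpopulations with mixing
#' weights, per-component allele frequencies, and optional per-component
#' Jacquard vectors. The canonical two-component model has frequencies
#' `p + a` and `p - a` mixed equally; mixing makes per-component cumulants
#' random, which induces covariances between second-order identity
#' measures (identity disequilibrium).
#'
#' @param freqs List of per-component frequency vectors
#'   ([validate_frequencies()] or coercible), all over the same alleles.
#' @param weights Mixing weights (default equal); must sum to 1.
#' @param delta Optional list of per-component [jacquard()] vectors (or one
#'   vector recycled to all components).
#' @return Object of class `mixture_model`.
#' @seealso [mixture_two_pop()] for the canonical `p +- a` construction.
#' @export
mixture_model <- function(freqs, weights = NULL, delta = NULL) {
  freqs <- lapply(freqs, as_freqs)
  M <- length(freqs)
  if (M < 1) stop("at least one component required")
  k <- length(freqs[[1]])
  if (!all(vapply(freqs, length, 1L) == k))
    stop("all components must have the same allele set")
  if (is.null(weights)) weights <- rep(1 / M, M)
  if (length(weights) != M || abs(sum(weights) - 1) > 1e-8 || any(weights < 0))
    stop("weights must be nonnegative and sum to 1")
  if (!is.null(delta)) {
    if (inherits(delta, "jacquard") || (is.numeric(delta) && length(delta) == 9))
      delta <- rep(list(jacquard(delta)), M)
    else delta <- lapply(delta, jacquard)
    if (length(delta) != M) stop("need one Jacquard vector per component")
  }
  structure(list(freqs = freqs, weights = weights / sum(weights), delta = delta),
            class = "mixture_model")
}

#' Canonical symmetric two-population mixture
#'
#' Two components with frequencies `p + a` and `p - a` at the focal allele
#' (the complement allele absorbing the deviation), mixed in equal
#' proportions. The pooled frequency of the focal allele is `p`; the
#' across-component variance of per-component homozygosity `p_m^2` is
#' `a^2 (2p)^2 / ... ` computed exactly by [mixture_moments()].
#'
#' @param p Pooled focal-allele frequency.
#' @param a Symmetric deviation, `0 <= a < min(p, 1-p)`.
#' @param delta Optional Jacquard vector shared by both components.
#' @return A [mixture_model()].
#' @export
mixture_two_pop <- function(p, a, delta = NULL) {
  stopifnot(p > 0, p < 1, a >= 0, a < min(p, 1 - p))
  mixture_model(
    freqs = list(c(A = p + a, a = 1 - p - a), c(A = p - a, a = 1 - p + a)),
    weights = c(0.5, 0.5), delta = delta)
}

#' Exact pooled moments and homozygosity covariances of a mixture
#'
#' Computes, by direct expectation over the mixture components (no
#' closed-form shortcut), the pooled allele frequencies, the pooled central
#' moments of the focal-allele indicator through order 4, the corresponding
#' cumulants, and the across-component variance of per-component
#' homozygosity `p_m^2` -- the quantity that appears as Cov(F_A, F_B)-type
#' identity disequilibrium when pairs are drawn within a random component.
#'
#' @param model A [mixture_model()].
#' @param allele Focal allele (index or label; default first).
#' @return List with `pooled_p` (pooled frequency vector), `mu` (central
#'   moments 2..4 of the focal indicator under the pooled distribution),
#'   `k4` (pooled fourth cumulant), `var_homozygosity` =
#'   Var_m(p_m^2), `cov_indicator` = Var_m(p_m) (the across-component
#'   covariance of two indicators drawn from a shared component), and
#'   `per_component` (component frequencies of the focal allele).
#' @export
mixture_moments <- function(model, allele = 1L) {
  stopifnot(inherits(model, "mixture_model"))
  w <- model$weights
  if (is.character(allele)) allele <- match(allele, names(model$freqs[[1]]))
  pm <- vapply(model$freqs, function(f) f[[allele]], 0)
  k <- length(model$freqs[[1]])
  pooled <- colSums(sweep(do.call(rbind, lapply(model$freqs, as.numeric)), 1, w, `*`))
  names(pooled) <- names(model$freqs[[1]])
  pbar <- pooled[[allele]]
  # pooled central moments of the focal Bernoulli indicator
  mom <- function(r) sum(w * (pm * (1 - pbar)^r + (1 - pm) * (0 - pbar)^r))
  mu <- c(mu2 = mom(2), mu3 = mom(3), mu4 = mom(4))
  k4 <- mu[["mu4"]] - 3 * mu[["mu2"]]^2
  ew <- function(x) sum(w * x)
  # total per-component homozygosity sum_a p_{a,m}^2 -- its across-component
  # variance is the expected identity excess between loci sharing a component
  hm <- vapply(model$freqs, function(f) sum(as.numeric(f)^2), 0)
  list(pooled_p = pooled,
       mu = mu,
       k4 = k4,
       var_homozygosity = ew(pm^4) - ew(pm^2)^2,
       var_total_homozygosity = ew(hm^2) - ew(hm)^2,
       cov_indicator = ew(pm^2) - ew(pm)^2,
       per_component = pm)
}
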