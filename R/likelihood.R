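# Multinomial maximum likelihood across loci. The latent structure of the
# model is the identity mode of each genotype-pair observation, so EM
# operates on the Delta simplex -- a true nine-component mixture with a
# closed-form E-step -- and the fitted Delta is mapped to the eight
# coefficients afterwards. This guarantees admissible estimates and
# monotone log-likelihood, at the cost of the slow convergence typical of
# mixture EM.

#' EM fitting configuration
#'
#' @param tol Convergence tolerance on the log-likelihood change per
#'   iteration (must be > 0; default `1e-8`).
#' @param max_iter Maximum EM iterations per start (default 5000).
#' @param starts Number of starting points (default 3: uniform Delta,
#'   null-heavy Delta9 = 0.9, and a moment-estimate-derived start when one
#'   is computable).
#' @param parameterization Currently `"delta"` (the latent-mode simplex).
#' @param seed Optional seed for reproducible multi-start jitter.
#' @return List of class `fit_config`.
#' @export
fit_config <- function(tol = 1e-8, max_iter = 5000, starts = 3,
                       parameterization = "delta", seed = NULL) {
  stopifnot(tol > 0, max_iter >= 1, starts >= 1,
            parameterization == "delta")
  structure(list(tol = tol, max_iter = max_iter, starts = starts,
                 parameterization = parameterization, seed = seed),
            class = "fit_config")
}

# Per-locus mode matrices restricted to observed classes, with counts.
# The full mode spectrum is cached per distinct frequency vector, since
# multi-locus panels typically share frequency arrays.
.mode_data <- function(tab, freqs) {
  loci <- unique(tab$locus)
  if (!all(loci %in% names(freqs)))
    stop("missing allele frequencies for loci: ",
         paste(setdiff(loci, names(freqs)), collapse = ", "))
  cache <- new.env(parent = emptyenv())
  lapply(loci, function(l) {
    sub <- tab[tab$locus == l, , drop = FALSE]
    p <- as_freqs(freqs[[l]])
    key_p <- paste(format(as.numeric(p), digits = 15), collapse = "|")
    if (is.null(cache[[key_p]])) cache[[key_p]] <- .mode_spectrum(p)
    Mall <- cache[[key_p]]
    obs <- attr(Mall, "obs")
    a1 <- pmin(sub$a1, sub$a2); a2 <- pmax(sub$a1, sub$a2)
    b1 <- pmin(sub$b1, sub$b2); b2 <- pmax(sub$b1, sub$b2)
    tt <- table(paste(a1, a2, b1, b2))
    rows <- match(names(tt), paste(obs$a1, obs$a2, obs$b1, obs$b2))
    if (anyNA(rows)) stop("locus ", l, ": allele codes outside frequency vector")
    list(M = Mall[rows, , drop = FALSE], counts = as.numeric(tt), locus = l)
  })
}

#' Multinomial log-likelihood of genotype-pair data
#'
#' \eqn{\ell = \sum_{loci} \sum_{classes} n_c \log f_c(\theta)} where
#' `f_c` is the class probability under the parameters. Probabilities are
#' floored at `1e-300` (with a warning) to guard minus infinity; a class
#' observed with structurally zero probability is reported, not silently
#' floored.
#'
#' @param tab Genotype-pair table (`pair_id`, `locus`, `a1`, `a2`, `b1`,
#'   `b2`).
#' @param params A [jacquard()] vector or [rel_coefs()] set (shared across
#'   loci).
#' @param freqs Named list of per-locus allele frequencies.
#' @return Log-likelihood (scalar).
#' @export
loglikelihood <- function(tab, params, freqs) {
  if (inherits(params, "rel_coefs")) params <- coefficients_to_jacquard(params)
  delta <- jacquard(params)
  md <- .mode_data(tab, freqs)
  ll <- 0
  for (d in md) {
    pr <- drop(d$M %*% as.numeric(delta))
    zero <- pr <= 0 & d$counts > 0
    if (any(zero)) {
      structural <- rowSums(d$M[zero, , drop = FALSE]) == 0
      if (any(structural))
        warning(sprintf("locus %s: %d observed class(es) with structurally zero probability",
                        d$locus, sum(structural)), call. = FALSE)
      else warning(sprintf("locus %s: probability floored at 1e-300 for %d class(es)",
                           d$locus, sum(zero)), call. = FALSE)
    }
    ll <- ll + sum(d$counts * log(pmax(pr, 1e-300)))
  }
  ll
}

.em_one_start <- function(md, delta0, tol, max_iter) {
  # stack class rows across loci: loci are independent, so the E-step is a
  # single matrix operation on the pooled (class x 9) mode matrix
  M <- do.call(rbind, lapply(md, `[[`, "M"))
  counts <- unlist(lapply(md, `[[`, "counts"))
  delta <- as.numeric(delta0)
  trace <- numeric(max_iter)
  ntot <- sum(counts)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    wk <- M %*% diag(delta)                  # classes x 9
    rs <- .rowSums(wk, nrow(wk), 9L)
    rs[rs <= 0] <- 1e-300
    ll <- sum(counts * log(rs))
    delta_new <- .colSums(counts * wk / rs, nrow(wk), 9L) / ntot
    trace[it] <- ll
    if (it > 1 && abs(ll - ll_old) < tol) {
      return(list(delta = delta_new, loglik = ll, trace = trace[seq_len(it)],
                  iterations = it, converged = TRUE))
    }
    ll_old <- ll
    delta <- delta_new
  }
  list(delta = delta, loglik = ll_old, trace = trace,
       iterations = max_iter, converged = FALSE)
}

#' Maximum-likelihood fit of relatedness coefficients across loci
#'
#' Fits the nine-mode Jacquard vector shared by all genotype pairs in the
#' table by expectation-maximization over the latent identity mode of each
#' observation (E-step: posterior mode membership; M-step: count-weighted
#' mean posterior), then maps the fitted Delta to the eight coefficients
#' with [jacquard_to_coefficients()]. The log-likelihood is non-decreasing
#' at every iteration; the best of several starts is returned.
#'
#' @param tab Genotype-pair table.
#' @param freqs Named list of per-locus allele frequencies.
#' @param config A [fit_config()].
#' @return An `rq_estimate` with the eight coefficients as `estimates`,
#'   and `extra` holding `delta`, `loglik`, `trace`, `iterations`,
#'   `converged`, and `boundary` (modes fitted at the simplex edge).
#' @export
fit_ml <- function(tab, freqs, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"), nrow(tab) >= 1)
  md <- .mode_data(tab, freqs)
  starts <- list(rep(1 / 9, 9),
                 c(rep(0.1 / 8, 8), 0.9))
  if (config$starts >= 3) {
    mom <- tryCatch({
      l1 <- names(freqs)[1]
      p1 <- as_freqs(freqs[[l1]])
      if (length(p1) >= 3) {
        est <- estimate_all_eight(observed_spectrum(tab, p1, 4, locus = l1), p1)
        d <- coefficients_to_jacquard(rel_coefs(as.list(est$estimates)),
                                      validate = FALSE)
        d <- pmax(d, 1e-3); d / sum(d)
      } else NULL
    }, error = function(e) NULL)
    if (!is.null(mom)) starts <- c(starts, list(mom))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  while (length(starts) < config$starts) {
    d <- stats::rexp(9); starts <- c(starts, list(d / sum(d)))
  }
  starts <- starts[seq_len(max(config$starts, 2))]
  fits <- lapply(starts, .em_one_start, md = md,
                 tol = config$tol, max_iter = config$max_iter)
  best <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  if (any(diff(best$trace) < -1e-8))
    warning("log-likelihood decreased during EM; numerical trouble", call. = FALSE)
  delta <- jacquard(pmax(best$delta, 0) / sum(pmax(best$delta, 0)))
  boundary <- which(as.numeric(delta) < 1e-6 | as.numeric(delta) > 1 - 1e-6)
  flags <- character()
  if (!best$converged) flags <- c(flags, "not converged at max_iter")
  if (length(boundary))
    flags <- c(flags, paste0("boundary estimate: ",
                             paste(names(delta)[boundary], collapse = ", ")))
  co <- jacquard_to_coefficients(delta)
  new_estimate("ml-em", unclass(co), flags = flags,
               delta = as.numeric(delta), loglik = best$loglik,
               trace = best$trace, iterations = best$iterations,
               converged = best$converged)
}

#' Write an EM trace as TSV
#'
#' @param fit An `rq_estimate` from [fit_ml()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  stopifnot(inherits(fit, "rq_estimate"), !is.null(fit$extra$trace))
  utils::write.table(
    data.frame(iteration = seq_along(fit$extra$trace),
               loglik = fit$extra$trace),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
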