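# Exact sampling variances of single-locus estimators by full enumeration
# of the observation unit: every genotype (for F), gene pair (for R),
# genotype-plus-gene (for G), or genotype pair (for H) is enumerated,
# weighted by its exact model probability at the stated true coefficients,
# and the estimator applied to each configuration. Means therefore verify
# unbiasedness exactly, and variances are free of Monte-Carlo error.

.component_values <- function(coefficient, p, truth) {
  pn <- as.numeric(p); qn <- 1 - pn; k <- length(pn)
  theta <- .coerce_theta(truth)
  if (coefficient %in% c("F", "F_A", "F_B", "R", "phi_XY")) {
    th <- switch(coefficient, R = , phi_XY = theta[["R"]],
                 F_B = theta[["F_B"]], theta[["F_A"]])
    spec <- class_spectrum(p, th, n_genes = 2)
    denom <- pn * qn
    estimable <- rep(TRUE, k)
    sel <- function(a) spec$i == a & spec$j == a
    truth_c <- th
  } else if (coefficient %in% c("G_A", "G_B")) {
    FF <- if (coefficient == "G_A") theta[["F_A"]] else theta[["F_B"]]
    GG <- if (coefficient == "G_A") theta[["G_A"]] else theta[["G_B"]]
    spec <- class_spectrum(p, list(F = FF, R = theta[["R"]], G = GG), n_genes = 3)
    denom <- pn * qn * (1 - 2 * pn)
    estimable <- abs(1 - 2 * pn) > 1e-9
    sel <- function(a) spec$a1 == a & spec$a2 == a & spec$b == a
    truth_c <- GG
  } else if (coefficient == "H") {
    spec <- class_spectrum(p, rel_coefs(as.list(theta)), n_genes = 4)
    denom <- pn * qn * (1 - 6 * pn * qn)
    estimable <- abs(denom) > 1e-9
    sel <- function(a) spec$a1 == a & spec$a2 == a & spec$b1 == a & spec$b2 == a
    truth_c <- theta[["H"]]
  } else stop("unknown coefficient: ", coefficient)
  vals <- matrix(NA_real_, nrow(spec), k)
  for (a in which(estimable)) {
    s <- sel(a)
    vals[, a] <- truth_c + (as.numeric(s) - sum(spec$prob[s])) / denom[a]
  }
  list(vals = vals, prob = spec$prob, estimable = estimable,
       truth_c = truth_c, n_config = nrow(spec))
}

.variance_weights <- function(V, p, weighting, focal = 1L) {
  k <- length(p)
  est <- !is.na(diag(V))
  w <- rep(0, k)
  if (weighting == "focal") {
    if (!est[focal]) return(NULL)
    w[focal] <- 1
    return(w)
  }
  use <- which(est)
  if (!length(use)) return(NULL)
  w_use <- switch(weighting,
    equal = rep(1 / length(use), length(use)),
    oneminus = {
      x <- 1 - as.numeric(p)[use]; x / sum(x)
    },
    invvar = {
      x <- 1 / diag(V)[use]; x / sum(x)
    },
    minvar = tryCatch({
      x <- solve(V[use, use, drop = FALSE], rep(1, length(use)))
      x / sum(x)
    }, error = function(e) rep(1 / length(use), length(use))),
    stop("unknown weighting: ", weighting))
  w[use] <- w_use
  w
}

#' Exact sampling variance of a single-locus estimator
#'
#' Enumerates every configuration of the estimator's observation unit,
#' weights by the exact model probability at `truth`, applies the
#' per-allele component estimators, and returns their exact means,
#' variances and the variance of the weighted combination. Components
#' whose normalization constant vanishes (order 3 at `p = 1/2`; order 4 at
#' `p(1-p) = 1/6`) are flagged non-estimable and carry no number.
#'
#' @param coefficient One of `"F"` (inbreeding, single-genotype unit),
#'   `"R"`/`"phi_XY"` (pairwise, cross-individual gene-pair unit),
#'   `"G_A"`, `"G_B"` (three-gene unit), `"H"` (genotype-pair unit).
#' @param p Allele frequencies.
#' @param truth True [rel_coefs()] at which the enumeration is taken
#'   (default all zero, the null of the published variance table).
#' @param weighting `"minvar"` (exact constrained minimum-variance,
#'   default), `"equal"`, `"oneminus"` (`(1-p_i)/(n-1)`), `"invvar"`, or
#'   `"focal"` (single focal allele).
#' @param focal Focal allele index for `weighting = "focal"`.
#' @return List of class `rq_variance` with `variance` (combined), `mean`
#'   (equals the true value; unbiasedness), `component_variance` (per
#'   allele), `weights`, `estimable` flags, `n_config` enumeration size.
#' @examples
#' exact_estimator_variance("F", c(0.5, 0.5), weighting = "focal")$component_variance
#' @export
exact_estimator_variance <- function(coefficient, p,
                                     truth = rel_coefs(),
                                     weighting = c("minvar", "equal",
                                                   "oneminus", "invvar", "focal"),
                                     focal = 1L) {
  weighting <- match.arg(weighting)
  p <- as_freqs(p)
  cv <- .component_values(coefficient, p, truth)
  k <- length(p)
  use <- which(cv$estimable)
  V <- matrix(NA_real_, k, k, dimnames = list(names(p), names(p)))
  if (length(use)) {
    vu <- cv$vals[, use, drop = FALSE]
    mu <- colSums(cv$prob * vu)
    V[use, use] <- crossprod(vu, cv$prob * vu) - outer(mu, mu)
  }
  w <- .variance_weights(V, p, weighting, focal)
  combined <- if (is.null(w)) NA_real_ else {
    wu <- w[use]
    drop(t(wu) %*% V[use, use, drop = FALSE] %*% wu)
  }
  mean_est <- if (is.null(w)) NA_real_ else
    sum(w[use] * colSums(cv$prob * cv$vals[, use, drop = FALSE]))
  structure(list(coefficient = coefficient,
                 p = as.numeric(p),
                 variance = combined,
                 mean = mean_est,
                 truth = cv$truth_c,
                 component_variance = stats::setNames(diag(V), names(p)),
                 V = V,
                 weights = if (is.null(w)) NULL else stats::setNames(w, names(p)),
                 estimable = stats::setNames(cv$estimable, names(p)),
                 weighting = weighting,
                 n_config = cv$n_config),
            class = "rq_variance")
}

#' @export
print.rq_variance <- function(x, ...) {
  cat(sprintf("<rq_variance> %s at p = (%s), weighting = %s\n",
              x$coefficient, paste(signif(x$p, 4), collapse = ", "),
              x$weighting))
  cat(sprintf("  variance = %s  (mean = %.3g, truth = %.3g)\n",
              if (is.na(x$variance)) "x (non-estimable)" else
                format(signif(x$variance, 6)), x$mean, x$truth))
  invisible(x)
}

#' Single-locus null variance table
#'
#' Emits, for each frequency array, the exact null sampling variances of
#' the single-locus estimators of F, G_A, G_B, the pairwise coefficient
#' (phi_XY) and H under the chosen weighting, with non-estimable cells
#' marked `NA` (rendered as `"x"` by [write_variance_table()]).
#'
#' @param arrays List of allele-frequency vectors.
#' @param weighting Passed to [exact_estimator_variance()].
#' @param truth True coefficient set (default null).
#' @param focal Focal allele for `weighting = "focal"`.
#' @return Data.frame of class `rq_variance_table` with one row per array
#'   and columns `array`, `F`, `G_A`, `G_B`, `phi_XY`, `H`.
#' @export
variance_table <- function(arrays, weighting = "minvar",
                           truth = rel_coefs(), focal = 1L) {
  rows <- lapply(arrays, function(p) {
    p <- as_freqs(p)
    cell <- function(co) exact_estimator_variance(co, p, truth = truth,
                                                  weighting = weighting,
                                                  focal = focal)$variance
    data.frame(array = paste(signif(as.numeric(p), 6), collapse = ","),
               F = cell("F"), G_A = cell("G_A"), G_B = cell("G_B"),
               phi_XY = cell("phi_XY"), H = cell("H"))
  })
  structure(do.call(rbind, rows),
            class = c("rq_variance_table", "data.frame"),
            weighting = weighting)
}

#' Write a variance table as TSV, marking non-estimable cells "x"
#'
#' @param tab An [variance_table()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variance_table <- function(tab, path) {
  out <- tab
  for (cc in c("F", "G_A", "G_B", "phi_XY", "H"))
    out[[cc]] <- ifelse(is.na(tab[[cc]]), "x", format(signif(tab[[cc]], 6)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
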