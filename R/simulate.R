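# Genotype-pair simulator. A condensed identity mode is drawn from Delta,
# expanded uniformly at random into a detailed configuration compatible
# with the mode (which B gene joins the triple for Delta3/Delta5, which
# cross-pairing for Delta7, which single pair for Delta8), and one allele
# per ibd class is drawn iid from the locus frequencies. The uniform
# expansion is forced by consistency with the half/quarter weights of the
# Delta -> coefficient map and is validated against class_spectrum() in
# the test suite.

# Flat list of (probability-weight-within-mode, partition, mode) configs.
.flat_configs <- local({
  out <- list()
  for (k in 1:9) for (cfg in .mode_configs[[k]])
    out[[length(out) + 1L]] <- list(w = cfg$w, P = cfg$P, mode = k)
  out
})

# Vectorized: n genotype pairs at one locus under delta, p.
.sample_pairs <- function(n, delta, p) {
  delta <- as.numeric(delta)
  pn <- as.numeric(p)
  probs <- vapply(.flat_configs, function(cf) cf$w * delta[cf$mode], 0)
  cfg_id <- sample.int(length(.flat_configs), n, replace = TRUE, prob = probs)
  out <- matrix(0L, n, 4)
  mode <- integer(n)
  for (ci in unique(cfg_id)) {
    rows <- which(cfg_id == ci)
    cf <- .flat_configs[[ci]]
    mode[rows] <- cf$mode
    ncls <- length(cf$P)
    al <- matrix(sample.int(length(pn), length(rows) * ncls, replace = TRUE,
                            prob = pn), ncol = ncls)
    for (ic in seq_len(ncls)) out[rows, cf$P[[ic]]] <- al[, ic]
  }
  colnames(out) <- c("a1", "a2", "b1", "b2")
  attr(out, "mode") <- mode
  out
}

#' Sample one genotype pair under a Jacquard vector
#'
#' @param d A [jacquard()] vector.
#' @param p Allele frequencies.
#' @return List with `a` and `b` (unordered allele index pairs) and the
#'   latent `mode`.
#' @export
sample_pair <- function(d, p) {
  d <- jacquard(d); p <- as_freqs(p)
  m <- .sample_pairs(1L, d, p)
  list(a = as.integer(m[1, 1:2]), b = as.integer(m[1, 3:4]),
       mode = attr(m, "mode"))
}

#' Simulation design
#'
#' @param delta A [jacquard()] vector (ignored when `mixture` is given and
#'   carries per-component Jacquard vectors).
#' @param freqs A single frequency vector (recycled over loci) or a named
#'   list with one vector per locus.
#' @param n_pairs,n_loci Positive integers.
#' @param seed Integer seed recorded in the output metadata.
#' @param mixture Optional [mixture_model()]; see [simulate_mixture()].
#' @param keep_latent Keep latent mode (and component) columns.
#' @return List of class `sim_design`.
#' @export
sim_design <- function(delta = jacquard(c(0, 0, 0, 0, 0, 0, 0, 0, 1)),
                       freqs, n_pairs, n_loci, seed = 1L,
                       mixture = NULL, keep_latent = FALSE) {
  stopifnot(n_pairs >= 1, n_loci >= 1)
  if (inherits(freqs, "allele_freqs") || !is.list(freqs))
    freqs <- stats::setNames(rep(list(as_freqs(freqs)), n_loci),
                             paste0("L", seq_len(n_loci)))
  else {
    freqs <- lapply(freqs, as_freqs)
    if (length(freqs) != n_loci) stop("need one frequency vector per locus")
    if (is.null(names(freqs))) names(freqs) <- paste0("L", seq_len(n_loci))
  }
  structure(list(delta = jacquard(delta), freqs = freqs, n_pairs = n_pairs,
                 n_loci = n_loci, seed = as.integer(seed),
                 mixture = mixture, keep_latent = keep_latent),
            class = "sim_design")
}

#' Simulate a genotype-pair dataset
#'
#' Draws `n_pairs` independent pairs at `n_loci` independent loci under a
#' single Jacquard vector. Reproducible given `design$seed`; the seed and
#' design are attached as metadata.
#'
#' @param design A [sim_design()].
#' @return Data.frame `pair_id`, `locus`, `a1`, `a2`, `b1`, `b2` (plus
#'   `mode` when `keep_latent`), with attribute `meta`.
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  loci <- names(design$freqs)
  rows <- vector("list", design$n_loci)
  for (li in seq_along(loci)) {
    m <- .sample_pairs(design$n_pairs, design$delta, design$freqs[[li]])
    d <- data.frame(pair_id = seq_len(design$n_pairs), locus = loci[li],
                    a1 = m[, 1], a2 = m[, 2], b1 = m[, 3], b2 = m[, 4])
    if (design$keep_latent) d$mode <- attr(m, "mode")
    rows[[li]] <- d
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pair_id, out$locus), ]
  rownames(out) <- NULL
  attr(out, "meta") <- list(seed = design$seed, delta = as.numeric(design$delta),
                            n_pairs = design$n_pairs, n_loci = design$n_loci)
  out
}

#' Simulate genotype pairs from a population mixture
#'
#' Each pair is assigned one mixture component for all of its loci -- the
#' assignment shared across loci is precisely what generates across-locus
#' covariance of homozygosity (identity disequilibrium). Within its
#' component a pair is simulated with that component's allele frequencies
#' (applied at every locus) and Jacquard vector (default: unrelated,
#' outbred).
#'
#' @param design A [sim_design()] whose `mixture` is a [mixture_model()].
#' @return As [simulate_dataset()], with a `component` column when
#'   `keep_latent`.
#' @export
simulate_mixture <- function(design) {
  stopifnot(inherits(design, "sim_design"), inherits(design$mixture, "mixture_model"))
  mix <- design$mixture
  set.seed(design$seed)
  comp <- sample.int(length(mix$weights), design$n_pairs, replace = TRUE,
                     prob = mix$weights)
  null9 <- jacquard(c(0, 0, 0, 0, 0, 0, 0, 0, 1))
  loci <- names(design$freqs)
  rows <- vector("list", design$n_loci * length(mix$weights))
  ri <- 0L
  for (li in seq_along(loci)) {
    for (m in seq_along(mix$weights)) {
      ids <- which(comp == m)
      if (!length(ids)) next
      dlt <- if (!is.null(mix$delta)) mix$delta[[m]] else null9
      g <- .sample_pairs(length(ids), dlt, mix$freqs[[m]])
      d <- data.frame(pair_id = ids, locus = loci[li],
                      a1 = g[, 1], a2 = g[, 2], b1 = g[, 3], b2 = g[, 4])
      if (design$keep_latent) { d$mode <- attr(g, "mode"); d$component <- m }
      ri <- ri + 1L
      rows[[ri]] <- d
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  out <- out[order(out$pair_id, out$locus), ]
  rownames(out) <- NULL
  attr(out, "meta") <- list(seed = design$seed, n_pairs = design$n_pairs,
                            n_loci = design$n_loci,
                            weights = mix$weights,
                            component_freqs = lapply(mix$freqs, as.numeric))
  out
}

#' Empirical identity disequilibrium between locus pairs
#'
#' The classic excess of joint homozygosity over the product of marginal
#' homozygosities, computed per individual across locus pairs:
#' `excess = mean(h1 * h2) - mean(h1) * mean(h2)` where `h` is the
#' homozygosity indicator. Both members of every pair contribute as
#' individuals. Independent Hardy-Weinberg loci give excess ~ 0; mixture
#' data give positive excess; a perfectly duplicated locus gives
#' `h(1 - h)`.
#'
#' @param tab Genotype-pair table.
#' @param loci Optional character vector of loci to use (default all
#'   polymorphic loci in the table).
#' @return Data.frame `locus1`, `locus2`, `joint`, `marginal_product`,
#'   `excess`, plus attribute `mean_excess`.
#' @export
empirical_identity_disequilibrium <- function(tab, loci = NULL) {
  if (is.null(loci)) loci <- unique(tab$locus)
  if (length(loci) < 2) stop("need at least two loci")
  # homozygosity indicators per individual (A and B of each pair)
  H <- sapply(loci, function(l) {
    sub <- tab[tab$locus == l, ]
    sub <- sub[order(sub$pair_id), ]
    c(sub$a1 == sub$a2, sub$b1 == sub$b2)
  })
  mono <- vapply(loci, function(l) {
    sub <- tab[tab$locus == l, ]
    length(unique(c(sub$a1, sub$a2, sub$b1, sub$b2))) < 2L
  }, TRUE)
  if (any(mono)) {
    warning("excluding monomorphic loci: ", paste(loci[mono], collapse = ", "),
            call. = FALSE)
    loci <- loci[!mono]
    H <- H[, !mono, drop = FALSE]
    if (length(loci) < 2) stop("fewer than two polymorphic loci")
  }
  cmb <- utils::combn(seq_along(loci), 2)
  out <- data.frame(
    locus1 = loci[cmb[1, ]], locus2 = loci[cmb[2, ]],
    joint = apply(cmb, 2, function(ix) mean(H[, ix[1]] * H[, ix[2]])),
    marginal_product = apply(cmb, 2, function(ix) mean(H[, ix[1]]) * mean(H[, ix[2]])))
  out$excess <- out$joint - out$marginal_product
  attr(out, "mean_excess") <- mean(out$excess)
  out
}
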