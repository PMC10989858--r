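#' Validated allele-frequency vector
#'
#' Constructs an allele-frequency vector for one locus, the conditioning
#' input of every genotype-class probability in the package. Frequencies
#' must be strictly positive, the locus must be polymorphic (at least two
#' alleles), and the frequencies must sum to one.
#'
#' @param p Numeric vector of allele frequencies, or a list / data.frame of
#'   (label, frequency) pairs.
#' @param alleles Optional character vector of allele labels; defaults to
#'   `names(p)` or `"1","2",...`.
#' @param tol Maximum tolerated deviation of `sum(p)` from 1 before the
#'   input is rejected (default `1e-6`). After validation frequencies are
#'   renormalized so they sum to 1 exactly (to numerical precision).
#'
#' @return An object of class `allele_freqs`: a named numeric vector whose
#'   names are the allele labels, in the order supplied.
#'
#' @examples
#' validate_frequencies(c(A = 0.6, B = 0.3, C = 0.1))
#' @export
validate_frequencies <- function(p, alleles = NULL, tol = 1e-6) {
  if (is.data.frame(p)) {
    stopifnot(ncol(p) >= 2)
    alleles <- as.character(p[[1]])
    p <- as.numeric(p[[2]])
  } else if (is.list(p)) {
    alleles <- vapply(p, function(x) as.character(x[[1]]), "")
    p <- vapply(p, function(x) as.numeric(x[[2]]), 0)
  }
  if (is.null(alleles))
    alleles <- if (!is.null(names(p))) names(p) else as.character(seq_along(p))
  p <- as.numeric(p)
  if (length(p) == 0L) stop("empty allele-frequency vector")
  if (length(p) < 2L)
    stop("monomorphic locus (fewer than two alleles) carries no identity information")
  if (anyNA(p) || any(p <= 0))
    stop("allele frequencies must be strictly positive; got: ",
         paste(signif(p, 4), collapse = ", "))
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("allele frequencies sum to %.8f, not 1 (tolerance %g)", sum(p), tol))
  if (anyDuplicated(alleles)) stop("duplicated allele labels")
  p <- p / sum(p)
  names(p) <- alleles
  structure(p, class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("Allele frequencies (", length(x), " alleles):\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

as_freqs <- function(p) {
  if (inherits(p, "allele_freqs")) p else validate_frequencies(p)
}

#' Read a per-locus allele-frequency table
#'
#' Reads a tab-separated table with columns `locus`, `allele`, `freq` and
#' returns one validated [validate_frequencies()] vector per locus.
#'
#' @param path Path to a TSV file with header `locus`, `allele`, `freq`.
#' @return Named list of `allele_freqs` vectors, one per locus.
#' @export
read_freq_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "allele", "freq")
  if (!all(need %in% names(tab)))
    stop("frequency table must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$locus), function(d)
    validate_frequencies(d$freq, alleles = as.character(d$allele)))
  out[unique(as.character(tab$locus))]
}

#' Write a per-locus allele-frequency table
#'
#' @param freqs Named list of `allele_freqs` vectors (or a single vector).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(freqs, path) {
  if (inherits(freqs, "allele_freqs")) freqs <- list(locus1 = freqs)
  rows <- do.call(rbind, lapply(names(freqs), function(l)
    data.frame(locus = l, allele = names(freqs[[l]]),
               freq = as.numeric(freqs[[l]]), stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
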