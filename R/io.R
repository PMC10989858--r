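# Readers and writers for the package's tab-separated genotype-pair
# format and JSON parameter files, plus VCF ingestion for biallelic and
# triallelic sites.

#' Read a genotype-pair table
#'
#' Tab-separated, header `pair_id`, `locus`, `a1`, `a2`, `b1`, `b2`.
#' Missing genotypes (any allele field `"."`) are dropped with a message
#' reporting the count. Malformed rows raise an error naming the line;
#' unrecognized extra columns are kept with a warning.
#'
#' @param path Input path.
#' @return Data.frame with integer allele columns.
#' @export
read_genotype_table <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("pair_id", "locus", "a1", "a2", "b1", "b2")
  if (!all(need %in% hdr))
    stop("genotype table must have columns: ", paste(need, collapse = ", "))
  extra <- setdiff(hdr, c(need, "mode", "component"))
  if (length(extra))
    warning("unknown columns kept as-is: ", paste(extra, collapse = ", "),
            call. = FALSE)
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(hdr))
  if (length(bad))
    stop(sprintf("malformed row at line %d: %d fields, expected %d",
                 bad[1] + 1L, nf[bad[1]], length(hdr)))
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- hdr
  acols <- c("a1", "a2", "b1", "b2")
  miss <- Reduce(`|`, lapply(acols, function(cc) tab[[cc]] == "."))
  if (any(miss)) {
    message(sum(miss), " rows with missing genotypes dropped")
    tab <- tab[!miss, , drop = FALSE]
  }
  for (cc in acols) {
    v <- suppressWarnings(as.integer(tab[[cc]]))
    if (anyNA(v))
      stop(sprintf("non-integer allele code at line %d, column %s",
                   which(is.na(v))[1] + 1L, cc))
    tab[[cc]] <- v
  }
  rownames(tab) <- NULL
  tab
}

#' Write a genotype-pair table
#'
#' @param tab Genotype table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a parameter file (JSON)
#'
#' Accepts either `{"delta": [9 numbers]}` or
#' `{"coefficients": {"F_A": ..., ..., "H": ...}}`.
#'
#' @param path JSON path.
#' @return A [jacquard()] vector or [rel_coefs()] set.
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!is.null(obj$delta)) return(jacquard(as.numeric(obj$delta)))
  if (!is.null(obj$coefficients)) return(rel_coefs(as.list(obj$coefficients)))
  stop("parameter file must contain 'delta' or 'coefficients'")
}

#' Ingest genotype pairs from a VCF
#'
#' Converts GT fields of named sample pairs into the internal genotype
#' table. Phase separators (`|` vs `/`) are ignored -- genotypes are
#' unordered throughout the package. Sites with missing GT in either
#' member of a pair are dropped for that pair, with a count reported.
#' Allele codes are the VCF allele indices plus one (REF = 1).
#'
#' @param path VCF path (plain text or gzipped; requires the `vcfR`
#'   package).
#' @param pairs Data.frame with columns `pair_id`, `sample_a`, `sample_b`.
#' @return Genotype table (`pair_id`, `locus`, `a1`, `a2`, `b1`, `b2`).
#' @export
read_vcf_pairs <- function(path, pairs) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF ingestion requires the 'vcfR' package")
  stopifnot(all(c("pair_id", "sample_a", "sample_b") %in% names(pairs)))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  missing_samples <- setdiff(unique(c(pairs$sample_a, pairs$sample_b)), samples)
  if (length(missing_samples))
    stop("samples not in VCF: ", paste(missing_samples, collapse = ", "),
         "; available: ", paste(samples, collapse = ", "))
  loci <- paste0(vcfR::getCHROM(vcf), ":", vcfR::getPOS(vcf))
  parse_gt <- function(x) {
    # returns 2-column matrix of allele indices (1-based) or NA
    sp <- strsplit(x, "[/|]")
    t(vapply(sp, function(a) {
      if (length(a) != 2 || any(a == ".") || anyNA(a)) c(NA_integer_, NA_integer_)
      else sort(as.integer(a) + 1L)
    }, integer(2)))
  }
  out <- vector("list", nrow(pairs))
  dropped <- 0L
  for (r in seq_len(nrow(pairs))) {
    ga <- parse_gt(gt[, pairs$sample_a[r]])
    gb <- parse_gt(gt[, pairs$sample_b[r]])
    ok <- !is.na(ga[, 1]) & !is.na(gb[, 1])
    dropped <- dropped + sum(!ok)
    out[[r]] <- data.frame(pair_id = pairs$pair_id[r], locus = loci[ok],
                           a1 = ga[ok, 1], a2 = ga[ok, 2],
                           b1 = gb[ok, 1], b2 = gb[ok, 2])
  }
  if (dropped > 0) message(dropped, " site-pair records dropped for missing GT")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
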