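#' @useDynLib prsbench, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats glm binomial coef vcov pnorm qnorm dnorm pchisq qchisq
#'   rnorm rbinom runif rbeta sd var cor cov setNames binom.test
#' @importFrom utils read.table write.table head
NULL

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Build canonical variant keys
#'
#' A variant key is `chrom:pos:counted:other`; a locus key is `chrom:pos`.
#' Keys are the join columns used throughout the package when matching
#' summary statistics, target genotypes and panel files.
#'
#' @param chrom,pos,a1,a2 vectors describing the variants; `a1` is the
#'   counted/effect allele, `a2` the other allele.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, a1, a2) {
  paste(chrom, pos, toupper(a1), toupper(a2), sep = ":")
}

#' @rdname variant_key
#' @export
locus_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

# unordered-allele key: same variant whichever allele is listed first
pair_key <- function(chrom, pos, a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  paste(chrom, pos, lo, hi, sep = ":")
}

is_snv <- function(a1, a2) {
  a1 %in% names(DNA_COMPLEMENT) & a2 %in% names(DNA_COMPLEMENT)
}

strand_flip <- function(allele) {
  out <- DNA_COMPLEMENT[allele]
  out[is.na(out)] <- allele[is.na(out)]  # indels are never strand-flipped
  unname(out)
}

#' Identify palindromic (strand-ambiguous) variants
#'
#' A/T and C/G single-nucleotide variants cannot be strand-resolved from
#' alleles alone.
#'
#' @param a1,a2 allele vectors.
#' @return logical vector.
#' @export
is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  is_snv(a1, a2) & strand_flip(a1) == a2
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
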