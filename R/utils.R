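#' @importFrom stats rexp rpois runif rgeom rlnorm rbinom binom.test pnorm sd setNames
#' @importFrom utils head tail write.table read.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

.BASES <- c("A", "C", "G", "T")
.PURINES <- c("A", "G")

# integer encoding A=1 C=2 G=3 T=4, NA for anything else
.encode_seq <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], .BASES)
}

.decode_seq <- function(codes) {
  paste(.BASES[codes], collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector; non-ACGT letters are complemented
#' through an identity (N stays N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1),
         USE.NAMES = FALSE)
}

#' Is a ref/alt allele pair a transversion?
#'
#' Transversions are purine-pyrimidine changes (A/C, A/T, G/C, G/T); the
#' transitions A/G and C/T are the classes mimicked by post-mortem
#' deamination and are excluded by the transversion-only filters used
#' throughout the pipeline.
#'
#' @param a,b single-character alleles (vectorised).
#' @return logical vector.
#' @export
is_transversion <- function(a, b) {
  (a %in% .PURINES) != (b %in% .PURINES)
}

#' Random DNA sequence
#'
#' @param length sequence length in bp.
#' @param seed integer seed.
#' @return a single DNA string over A,C,G,T.
#' @export
random_dna <- function(length, seed) {
  stopifnot(length >= 1)
  withr::with_seed(seed, paste(sample(.BASES, length, replace = TRUE), collapse = ""))
}

.check_prob <- function(x, name, upper = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > upper)
    stop(sprintf("`%s` must be a single number in [0, %s]", name, upper), call. = FALSE)
  invisible(x)
}

.check_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("a single integer `seed` is required", call. = FALSE)
  invisible(as.integer(seed))
}
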