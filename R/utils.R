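#' @importFrom stats setNames
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

vk_stop <- function(..., class = "vk_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Reverse complement of a nucleotide string
#'
#' Complements A/C/G/T (and IUPAC ambiguity codes) and reverses the string.
#' Case is preserved.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' IUPAC ambiguity code for a pair of bases
#'
#' @param a,b single upper-case bases in `A`,`C`,`G`,`T`,`N`.
#' @return the single-letter IUPAC code covering both bases (e.g. `R` for
#'   A/G); the base itself when `a == b`.
#' @export
iupac_code <- function(a, b) {
  key <- paste(pmin(a, b), pmax(a, b), sep = "")
  codes <- c(AA = "A", CC = "C", GG = "G", TT = "T", NN = "N",
             AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
             AN = "N", CN = "N", GN = "N", NT = "N")
  out <- codes[key]
  if (anyNA(out)) vk_stop("unknown base pair for IUPAC code: ", key[is.na(out)][1])
  unname(out)
}

## valid single-base genotype alphabet (N = missing/unknown sentinel)
VK_BASES <- c("A", "C", "G", "T", "N")

is_single_base <- function(x) x %in% VK_BASES

assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    vk_stop(what, " must be a non-empty string")
}
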