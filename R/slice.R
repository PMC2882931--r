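#' Genomic slice
#'
#' A contiguous, strand-aware region of a reference sequence. Coordinates are
#' 1-based and fully closed, following the Ensembl convention used throughout
#' the package.
#'
#' @param region_name region (chromosome/contig) identifier.
#' @param start,end 1-based inclusive coordinates, `end >= start >= 1`.
#' @param strand `+1` or `-1` (defaults to `+1`; ignored by overlap tests).
#' @return an object of class `vk_slice`.
#' @examples
#' s <- slice("chr1", 100, 200)
#' slices_overlap(s, slice("chr1", 200, 300))
#' @export
slice <- function(region_name, start, end, strand = 1L) {
  assert_scalar_string(region_name, "region_name")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || start < 1L) vk_stop("slice start must be >= 1")
  if (is.na(end) || end < start) vk_stop("slice end must be >= start")
  if (!strand %in% c(1L, -1L)) vk_stop("strand must be +1 or -1")
  structure(list(region_name = region_name, start = start, end = end,
                 strand = as.integer(strand)),
            class = "vk_slice")
}

#' @export
print.vk_slice <- function(x, ...) {
  cat(sprintf("<slice %s:%d-%d (%s)>\n", x$region_name, x$start, x$end,
              if (x$strand == 1L) "+" else "-"))
  invisible(x)
}

#' Do two slices overlap?
#'
#' Closed-interval intersection on the same region; strand is ignored.
#'
#' @param a,b `vk_slice` objects.
#' @return `TRUE` iff the slices share a region name and at least one base.
#' @export
slices_overlap <- function(a, b) {
  stopifnot(inherits(a, "vk_slice"), inherits(b, "vk_slice"))
  a$region_name == b$region_name && a$start <= b$end && b$start <= a$end
}

## parse "chr:start-end" (CLI convenience)
parse_region <- function(txt) {
  m <- regmatches(txt, regexec("^([^:]+):([0-9]+)-([0-9]+)$", txt))[[1]]
  if (length(m) != 4L) vk_stop("cannot parse region '", txt, "' (expect chr:start-end)")
  slice(m[2], as.integer(m[3]), as.integer(m[4]))
}
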