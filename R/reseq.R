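## Compact resequencing representation: read-coverage intervals per
## individual plus variant differences, from which an individual's sequence
## over any slice can be reconstructed and classified.

#' Add read-coverage intervals
#'
#' Overlapping or adjacent intervals of the same (individual, region, level)
#' are merged and stored sorted.
#'
#' @param ds a `vk_dataset`.
#' @param intervals data frame with columns `individual_name`, `region_name`,
#'   `start`, `end`, `level` (positive integer coverage class).
#' @return the updated dataset; the number of stored (normalised) intervals
#'   added for this input is attached as attribute `"n_normalised"`.
#' @export
add_coverage <- function(ds, intervals) {
  stopifnot(inherits(ds, "vk_dataset"))
  need <- names(vk_schemas()$coverage)
  if (!all(need %in% names(intervals)))
    vk_stop("coverage needs columns: ", paste(need, collapse = ", "))
  intervals <- intervals[, need]
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  intervals$level <- as.integer(intervals$level)
  if (any(intervals$level <= 0L)) vk_stop("coverage level must be positive")
  if (any(intervals$end < intervals$start)) vk_stop("interval end < start")
  for (r in unique(intervals$region_name)) check_region(ds, r)

  all_iv <- rbind(ds$coverage, intervals)
  merged <- do.call(rbind, lapply(
    split(all_iv, paste(all_iv$individual_name, all_iv$region_name, all_iv$level)),
    function(g) {
      g <- g[order(g$start), , drop = FALSE]
      out_s <- g$start[1]; out_e <- g$end[1]
      res <- list()
      for (k in seq_len(nrow(g))[-1]) {
        if (g$start[k] <= out_e + 1L) {         # overlap or adjacency merges
          out_e <- max(out_e, g$end[k])
        } else {
          res[[length(res) + 1L]] <- c(out_s, out_e)
          out_s <- g$start[k]; out_e <- g$end[k]
        }
      }
      res[[length(res) + 1L]] <- c(out_s, out_e)
      m <- do.call(rbind, res)
      data.frame(individual_name = g$individual_name[1],
                 region_name = g$region_name[1],
                 start = m[, 1], end = m[, 2], level = g$level[1],
                 stringsAsFactors = FALSE)
    }))
  merged <- merged[order(merged$individual_name, merged$region_name,
                         merged$level, merged$start), , drop = FALSE]
  rownames(merged) <- NULL
  n_new <- nrow(merged)
  attr(ds, "n_normalised") <- n_new
  ds$coverage <- merged
  ds
}

#' Piecewise maximum coverage over a slice
#'
#' Reports the slice partitioned into maximal sub-intervals of constant
#' maximum coverage level; uncovered stretches appear with level 0.
#'
#' @param ds a `vk_dataset`.
#' @param individual individual name.
#' @param s a `vk_slice`.
#' @return data frame (`start`, `end`, `level`).
#' @export
coverage_at <- function(ds, individual, s) {
  stopifnot(inherits(ds, "vk_dataset"), inherits(s, "vk_slice"))
  check_region(ds, s$region_name)
  len <- s$end - s$start + 1L
  lev <- integer(len)
  cov <- ds$coverage
  sel <- cov$individual_name == individual & cov$region_name == s$region_name &
    cov$start <= s$end & cov$end >= s$start
  for (k in which(sel)) {
    a <- max(cov$start[k], s$start) - s$start + 1L
    b <- min(cov$end[k], s$end) - s$start + 1L
    lev[a:b] <- pmax(lev[a:b], cov$level[k])
  }
  brk <- c(1L, which(diff(lev) != 0L) + 1L)
  data.frame(start = s$start + brk - 1L,
             end = s$start + c(brk[-1] - 1L, len) - 1L,
             level = lev[brk])
}

#' Classify stored genotypes of an individual over a slice
#'
#' Each stored genotype is compared with the reference base: both alleles
#' equal to the reference give `REFERENCE`, equal to each other but not the
#' reference give `HOMOZYGOUS_NONREF`, otherwise `HETEROZYGOUS`. The
#' `covered` flag reports whether the locus has coverage level > 0.
#'
#' @param ds a `vk_dataset`.
#' @param individual individual name.
#' @param s a `vk_slice`.
#' @param cfg a [codec_config()].
#' @return data frame (`position`, `ref_base`, `allele1`, `allele2`,
#'   `status`, `covered`).
#' @export
classify_loci <- function(ds, individual, s, cfg = codec_config()) {
  g <- query_genotypes(ds, s, individuals = individual, cfg = cfg)
  cov <- coverage_at(ds, individual, s)
  covered_at <- function(p) {
    any(cov$start <= p & cov$end >= p & cov$level > 0L)
  }
  ref_base <- vapply(g$position, function(p)
    substr(ds$reference[[s$region_name]], p, p), "")
  status <- ifelse(g$allele1 == ref_base & g$allele2 == ref_base, "REFERENCE",
                   ifelse(g$allele1 == g$allele2, "HOMOZYGOUS_NONREF",
                          "HETEROZYGOUS"))
  data.frame(position = g$position, ref_base = ref_base,
             allele1 = g$allele1, allele2 = g$allele2,
             status = as.character(status),
             covered = vapply(g$position, covered_at, logical(1)),
             stringsAsFactors = FALSE)
}

#' Reconstruct an individual's sequence over a slice
#'
#' Starts from the reference substring, substitutes homozygous non-reference
#' single-base genotypes with their allele and heterozygous ones with the
#' IUPAC ambiguity code of the two alleles, and masks positions without read
#' coverage to lower case. The result always has the slice's length —
#' multi-base genotypes (indels) are rejected and belong in VCF export.
#'
#' @param ds a `vk_dataset`.
#' @param individual individual name.
#' @param s a `vk_slice`.
#' @param cfg a [codec_config()].
#' @return a character string of length `end - start + 1`.
#' @export
individual_sequence <- function(ds, individual, s, cfg = codec_config()) {
  stopifnot(inherits(ds, "vk_dataset"), inherits(s, "vk_slice"))
  check_region(ds, s$region_name)
  if (s$end > nchar(ds$reference[[s$region_name]]))
    vk_stop("slice extends beyond the reference")
  mb <- ds$multi_bp_genotypes
  if (any(mb$individual_name == individual & mb$region_name == s$region_name &
            mb$position >= s$start & mb$position <= s$end))
    vk_stop("slice contains multi-base genotypes; sequence reconstruction is ",
            "length-preserving — export indels via VCF instead")
  chars <- strsplit(substr(ds$reference[[s$region_name]], s$start, s$end),
                    "")[[1]]
  g <- query_genotypes(ds, s, individuals = individual, cfg = cfg)
  for (k in seq_len(nrow(g))) {
    i <- g$position[k] - s$start + 1L
    if (g$allele1[k] == g$allele2[k]) {
      if (g$allele1[k] != chars[i]) chars[i] <- g$allele1[k]
    } else {
      chars[i] <- iupac_code(g$allele1[k], g$allele2[k])
    }
  }
  cov <- coverage_at(ds, individual, s)
  for (k in which(cov$level == 0L)) {
    a <- cov$start[k] - s$start + 1L
    b <- cov$end[k] - s$start + 1L
    chars[a:b] <- tolower(chars[a:b])
  }
  paste(chars, collapse = "")
}
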