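## Flank mapping and variant QC.
##
## A variant arrives with raw 5'/3' flanking sequences and an allele list.
## The composite flank_up + reference_allele + flank_down is searched exactly
## on both strands of the reference (the mapping engine is swappable behind
## map_flanks' contract). QC then fails variants that map nowhere, map more
## than N times (N = 3 by default), or whose declared reference allele does
## not match the genome at a mapped location — unless whitelisted.

#' QC configuration
#'
#' @param max_mappings maximum number of genomic mappings N a variant may
#'   have and still be retained (default 3).
#' @param flank_min_len minimum usable flank length in bp (default 20).
#' @return a `vk_qc_config`.
#' @export
qc_config <- function(max_mappings = 3L, flank_min_len = 20L) {
  max_mappings <- as.integer(max_mappings)
  if (is.na(max_mappings) || max_mappings < 1L) vk_stop("max_mappings must be >= 1")
  structure(list(max_mappings = max_mappings,
                 flank_min_len = as.integer(flank_min_len)),
            class = "vk_qc_config")
}

get_variation <- function(ds, name) {
  i <- match(name, ds$variations$name)
  if (is.na(i)) vk_stop("unknown variation '", name, "'")
  ds$variations[i, , drop = FALSE]
}

## All (overlapping) occurrence start positions of pattern in subject.
find_occurrences <- function(pattern, subject) {
  if (nchar(pattern) == 0L || nchar(pattern) > nchar(subject)) return(integer(0))
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(subject))
  as.integer(Biostrings::start(m))
}

#' Map a variant to the reference via its flanking sequences
#'
#' Searches for the composite 5' flank + reference allele + 3' flank exactly
#' on both strands of every reference region. Hit coordinates delimit the
#' allele itself, not the flanks; for an insertion (reference allele `"-"`)
#' the hit has `start = end + 1`, marking the insertion point. A palindromic
#' composite matching both strands at one locus counts once, on the forward
#' strand. No mapping cap is applied here — that is [apply_qc()]'s job.
#'
#' @param ds a `vk_dataset` holding the variant and the reference.
#' @param name the variation name.
#' @param cfg a [qc_config()] (flank length check).
#' @return data frame of hits (`region_name`, `start`, `end`, `strand`),
#'   sorted by (region, start).
#' @export
map_flanks <- function(ds, name, cfg = qc_config()) {
  stopifnot(inherits(ds, "vk_dataset"))
  v <- get_variation(ds, name)
  up <- v$flank_up_seq; down <- v$flank_down_seq
  if (is.na(up) || is.na(down))
    vk_stop("variation '", name, "' has no raw flanking sequences")
  if (nchar(up) < cfg$flank_min_len || nchar(down) < cfg$flank_min_len)
    vk_stop("flanks of '", name, "' are shorter than flank_min_len = ",
            cfg$flank_min_len)
  ref_allele <- split_alleles(v$alleles)[1]
  allele_seq <- if (ref_allele == "-") "" else ref_allele
  composite <- paste0(up, allele_seq, down)
  alen <- nchar(allele_seq)

  hits <- list()
  for (region in names(ds$reference)) {
    subject <- ds$reference[[region]]
    for (st in c(1L, -1L)) {
      pat <- if (st == 1L) composite else revcomp(composite)
      occ <- find_occurrences(pat, subject)
      for (p in occ) {
        if (st == 1L) {
          a_start <- p + nchar(up)
        } else {
          ## composite reverse-complemented: allele sits after the (RC'd)
          ## 3' flank in forward coordinates
          a_start <- p + nchar(down)
        }
        a_end <- a_start + alen - 1L   # insertion: start = end + 1
        hits[[length(hits) + 1L]] <- data.frame(
          region_name = region, start = a_start, end = a_end, strand = st,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(region_name = character(0), start = integer(0),
                      end = integer(0), strand = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  ## palindromic composite: forward and reverse hits at the same locus are
  ## one physical placement — keep the forward one
  key <- paste(out$region_name, out$start, out$end)
  drop <- out$strand == -1L & key %in% key[out$strand == 1L]
  out <- out[!drop, , drop = FALSE]
  out <- out[order(out$region_name, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

reference_bases_at <- function(ds, region, start, end, strand = 1L) {
  check_region(ds, region)
  seqlen <- nchar(ds$reference[[region]])
  if (start < 1L || end > seqlen) vk_stop("coordinates outside reference")
  if (end < start) return("")
  s <- substr(ds$reference[[region]], start, end)
  if (strand == -1L) revcomp(s) else s
}

#' Apply failed-variation QC to a variant's mapping hits
#'
#' Rules: zero hits fail the variant with `NO_MAPPING`; more than N hits
#' fail it with `TOO_MANY_MAPPINGS`; a hit whose reference bases differ from
#' the declared reference allele fails it with `ALLELE_MISMATCH`. A
#' whitelisted variant is retained regardless; with more than N hits it keeps
#' the N leftmost (by region, start) mapping records while `map_weight`
#' preserves the true hit count. Retained variants get one VariationFeature
#' per kept hit, allele strings expressed on the forward strand
#' (reverse-complemented for reverse-strand hits), with `map_weight` = total
#' number of hits.
#'
#' @param ds a `vk_dataset`.
#' @param name the variation name.
#' @param hits data frame from [map_flanks()] (or externally supplied
#'   mappings with the same columns).
#' @param cfg a [qc_config()].
#' @return the updated dataset; the outcome is attached as attribute
#'   `"qc_outcome"` (a list with `status` = `"retained"`/`"failed"`,
#'   `failed_reason`, `n_features`).
#' @export
apply_qc <- function(ds, name, hits, cfg = qc_config()) {
  stopifnot(inherits(ds, "vk_dataset"))
  v <- get_variation(ds, name)
  i <- match(name, ds$variations$name)
  for (r in unique(hits$region_name)) check_region(ds, r)
  alleles <- split_alleles(v$alleles)
  ref_allele <- alleles[1]

  fail_with <- function(reason) {
    if (v$whitelisted) return(NULL)
    ds$variations$failed_reason[i] <<- reason
    reason
  }

  reason <- NULL
  n_hits <- nrow(hits)
  if (n_hits == 0L) {
    reason <- fail_with("NO_MAPPING")
    if (v$whitelisted) {
      ## whitelisted but unplaceable: retained, simply with no features
      attr(ds, "qc_outcome") <- list(status = "retained", failed_reason = NA_character_,
                                     n_features = 0L)
      return(ds)
    }
  } else {
    if (n_hits > cfg$max_mappings) reason <- fail_with("TOO_MANY_MAPPINGS")
    if (is.null(reason) || v$whitelisted) {
      mismatch <- vapply(seq_len(n_hits), function(k) {
        h <- hits[k, ]
        if (ref_allele == "-") return(FALSE)  # insertion: only flank adjacency
        obs <- reference_bases_at(ds, h$region_name, h$start, h$end, h$strand)
        !identical(obs, ref_allele)
      }, logical(1))
      if (any(mismatch) && is.null(reason)) reason <- fail_with("ALLELE_MISMATCH")
    }
  }

  if (!is.null(reason)) {
    attr(ds, "qc_outcome") <- list(status = "failed", failed_reason = reason,
                                   n_features = 0L)
    return(ds)
  }

  ## retained: whitelisted variants over the cap keep the N leftmost hits
  kept <- hits[order(hits$region_name, hits$start), , drop = FALSE]
  if (nrow(kept) > cfg$max_mappings) kept <- kept[seq_len(cfg$max_mappings), , drop = FALSE]
  feats <- do.call(rbind, lapply(seq_len(nrow(kept)), function(k) {
    h <- kept[k, ]
    al <- if (h$strand == -1L) {
      vapply(alleles, function(a) if (a == "-") "-" else revcomp(a), "",
             USE.NAMES = FALSE)
    } else alleles
    data.frame(variation_name = name, region_name = h$region_name,
               start = h$start, end = h$end, strand = h$strand,
               allele_string = paste(al, collapse = "/"),
               map_weight = n_hits, stringsAsFactors = FALSE)
  }))
  ds$variation_features <- rbind(ds$variation_features, feats)
  rownames(ds$variation_features) <- NULL
  attr(ds, "qc_outcome") <- list(status = "retained", failed_reason = NA_character_,
                                 n_features = nrow(feats))
  ds
}

#' Map and QC every unmapped variant in a dataset
#'
#' Convenience pipeline: [map_flanks()] then [apply_qc()] for each variant
#' without features and without a failed reason, then flank compression
#' ([compress_flanks()]) for retained variants.
#'
#' @param ds a `vk_dataset`.
#' @param cfg a [qc_config()].
#' @param compress also replace matching raw flanks by coordinates.
#' @return the updated dataset.
#' @export
run_mapping_qc <- function(ds, cfg = qc_config(), compress = TRUE) {
  for (name in ds$variations$name) {
    v <- get_variation(ds, name)
    if (!is.na(v$failed_reason)) next
    if (name %in% ds$variation_features$variation_name) next
    hits <- map_flanks(ds, name, cfg)
    ds <- apply_qc(ds, name, hits, cfg)
    out <- attr(ds, "qc_outcome")
    if (compress && out$status == "retained" && out$n_features > 0L)
      ds <- compress_flanks(ds, name)
  }
  ds
}

#' Purge all supplementary data of failed variants
#'
#' Failed variants keep only their name, source and failure reason: mapping
#' features, alleles, flank sequences, population frequencies, phenotype
#' annotations and genotypes (compressed and multi-bp, located via the
#' variant's pre-purge feature coordinates) are deleted. Idempotent.
#'
#' @param ds a `vk_dataset`.
#' @return the updated dataset; removed-record counts are attached as
#'   attribute `"purge_counts"` (features, alleles, frequencies, annotations,
#'   genotypes).
#' @export
purge_failed <- function(ds) {
  stopifnot(inherits(ds, "vk_dataset"))
  failed <- ds$variations$name[!is.na(ds$variations$failed_reason)]
  counts <- c(features = 0L, alleles = 0L, frequencies = 0L,
              annotations = 0L, genotypes = 0L)
  if (length(failed)) {
    ## genotypes first: located through the failed variants' features
    feat <- ds$variation_features
    fsel <- feat$variation_name %in% failed
    for (k in which(fsel)) {
      h <- feat[k, ]
      lo <- min(h$start, h$end); hi <- max(h$start, h$end)
      mb <- ds$multi_bp_genotypes
      drop_mb <- mb$region_name == h$region_name &
        mb$position >= lo & mb$position <= hi
      counts["genotypes"] <- counts["genotypes"] + sum(drop_mb)
      ds$multi_bp_genotypes <- mb[!drop_mb, , drop = FALSE]
      gr <- ds$genotype_rows
      for (ri in which(gr$region_name == h$region_name)) {
        g <- decode_window(gr[ri, ])
        keep <- g$position < lo | g$position > hi
        if (all(keep)) next
        counts["genotypes"] <- counts["genotypes"] + sum(!keep)
        if (!any(keep)) {
          ds$genotype_rows <- ds$genotype_rows[-ri, , drop = FALSE]
        } else {
          enc <- encode_window(g[keep, , drop = FALSE])
          ds$genotype_rows$start[ri] <- enc$start
          ds$genotype_rows$blob[[ri]] <- enc$blob[[1]]
        }
      }
    }
    counts["features"] <- sum(fsel)
    ds$variation_features <- feat[!fsel, , drop = FALSE]

    vi <- ds$variations$name %in% failed
    counts["alleles"] <- sum(lengths(strsplit(ds$variations$alleles[vi], "/")))
    ds$variations$alleles[vi] <- ""
    ds$variations$ancestral_allele[vi] <- NA_character_
    ds$variations$flank_up_seq[vi] <- NA_character_
    ds$variations$flank_down_seq[vi] <- NA_character_
    for (col in c("flank_up_region", "flank_down_region"))
      ds$variations[[col]][vi] <- NA_character_
    for (col in c("flank_up_start", "flank_up_end", "flank_up_strand",
                  "flank_down_start", "flank_down_end", "flank_down_strand"))
      ds$variations[[col]][vi] <- NA_integer_

    dsel <- ds$frequencies$variation_name %in% failed
    counts["frequencies"] <- sum(dsel)
    ds$frequencies <- ds$frequencies[!dsel, , drop = FALSE]
    asel <- ds$annotations$variation_name %in% failed
    counts["annotations"] <- sum(asel)
    ds$annotations <- ds$annotations[!asel, , drop = FALSE]
    rownames(ds$variation_features) <- NULL
    rownames(ds$frequencies) <- NULL
    rownames(ds$annotations) <- NULL
    rownames(ds$multi_bp_genotypes) <- NULL
    rownames(ds$genotype_rows) <- NULL
  }
  attr(ds, "purge_counts") <- counts
  ds
}

## ---- flank coordinate compression -----------------------------------------

#' Compress one flank to coordinates when it matches the reference
#'
#' If the raw flank is exactly the reference sequence adjacent to the
#' variant's mapped location (respecting the mapping strand), the raw
#' sequence is replaced by a coordinate record; otherwise the raw sequence is
#' kept. For a reverse-strand mapping the variant's 5' flank corresponds to
#' the reverse complement of the reference immediately 3' of the feature.
#'
#' @param ds a `vk_dataset`.
#' @param name variation name (retained, with at least one feature).
#' @param which `"up"` or `"down"` flank.
#' @param feature optionally, the one-row feature to compress against
#'   (defaults to the variant's first stored feature).
#' @return a flank record: list with either `raw_seq` or
#'   `region`/`start`/`end`/`strand` set.
#' @seealso [restore_flank()], [compress_flanks()]
#' @export
compress_flank <- function(ds, name, which = c("up", "down"), feature = NULL) {
  which <- match.arg(which)
  v <- get_variation(ds, name)
  if (is.null(feature)) {
    fsel <- ds$variation_features[ds$variation_features$variation_name == name, ,
                                  drop = FALSE]
    if (!nrow(fsel)) vk_stop("variation '", name, "' has no features")
    feature <- fsel[1, ]
  }
  raw_seq <- if (which == "up") v$flank_up_seq else v$flank_down_seq
  if (is.na(raw_seq)) vk_stop("flank already compressed or absent")
  len <- nchar(raw_seq)
  region <- feature$region_name
  seqlen <- nchar(ds$reference[[region]])
  lo <- min(feature$start, feature$end)   # insertion has start = end + 1
  hi <- max(feature$start, feature$end)
  ins <- feature$start > feature$end
  ## which flank sits genomically left of the allele?
  left_side <- (which == "up") == (feature$strand == 1L)
  if (left_side) {
    g_end <- if (ins) feature$end else lo - 1L
    g_start <- g_end - len + 1L
  } else {
    g_start <- if (ins) feature$start else hi + 1L
    g_end <- g_start + len - 1L
  }
  if (g_start < 1L || g_end > seqlen)
    vk_stop("flank coordinates fall outside the reference")
  ref_seq <- reference_bases_at(ds, region, g_start, g_end, feature$strand)
  if (identical(ref_seq, raw_seq)) {
    list(raw_seq = NULL, region = region, start = g_start, end = g_end,
         strand = as.integer(feature$strand))
  } else {
    list(raw_seq = raw_seq, region = NULL, start = NULL, end = NULL,
         strand = NULL)
  }
}

#' Compress both flanks of a retained variant in place
#'
#' @param ds a `vk_dataset`.
#' @param name variation name.
#' @return the updated dataset (flank columns switched from raw sequence to
#'   coordinates where they match the reference).
#' @export
compress_flanks <- function(ds, name) {
  i <- match(name, ds$variations$name)
  for (which in c("up", "down")) {
    fr <- compress_flank(ds, name, which)
    pre <- paste0("flank_", which, "_")
    if (is.null(fr$raw_seq)) {
      ds$variations[[paste0(pre, "seq")]][i] <- NA_character_
      ds$variations[[paste0(pre, "region")]][i] <- fr$region
      ds$variations[[paste0(pre, "start")]][i] <- fr$start
      ds$variations[[paste0(pre, "end")]][i] <- fr$end
      ds$variations[[paste0(pre, "strand")]][i] <- fr$strand
    }
  }
  ds
}

#' Restore a flanking sequence from its record
#'
#' Raw records are returned verbatim; coordinate records are looked up in the
#' reference (reverse-complemented for reverse-strand records) so that
#' `restore(compress(x)) == x` for every compressible flank.
#'
#' @param ds a `vk_dataset`.
#' @param fr a flank record as returned by [compress_flank()], or, with
#'   `name`/`which`, taken from the stored variant.
#' @param name,which alternative to `fr`: restore the stored flank of a
#'   variant (`which` is `"up"` or `"down"`).
#' @return the flanking sequence string.
#' @export
restore_flank <- function(ds, fr = NULL, name = NULL, which = c("up", "down")) {
  if (is.null(fr)) {
    which <- match.arg(which)
    v <- get_variation(ds, name)
    pre <- paste0("flank_", which, "_")
    if (!is.na(v[[paste0(pre, "seq")]]))
      return(v[[paste0(pre, "seq")]])
    fr <- list(region = v[[paste0(pre, "region")]],
               start = v[[paste0(pre, "start")]],
               end = v[[paste0(pre, "end")]],
               strand = v[[paste0(pre, "strand")]])
    if (is.na(fr$region)) vk_stop("variation '", name, "' has no stored ",
                                  which, " flank")
  }
  if (!is.null(fr$raw_seq)) return(fr$raw_seq)
  reference_bases_at(ds, fr$region, fr$start, fr$end, fr$strand)
}
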