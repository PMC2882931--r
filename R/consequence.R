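## Rule-based variant consequence prediction on transcript models.
##
## Each variant allele is classified against each overlapping (or nearby)
## transcript by the change it causes in the reference: coding substitutions
## are translated codon-wise via the standard genetic code, indels are
## checked for frame disruption, and positional rules cover splice sites,
## UTRs, introns, flanking regions, non-coding genes and regulatory regions.

#' Consequence types, most severe first
#'
#' The fixed, totally ordered severity ranking used to pick `most_severe`.
#' @export
CONSEQUENCE_TYPES <- c(
  "STOP_GAINED", "STOP_LOST", "FRAMESHIFT_CODING", "NON_SYNONYMOUS_CODING",
  "ESSENTIAL_SPLICE_SITE", "SPLICE_SITE", "SYNONYMOUS_CODING",
  "5PRIME_UTR", "3PRIME_UTR", "INTRONIC", "UPSTREAM", "DOWNSTREAM",
  "REGULATORY_REGION", "WITHIN_NON_CODING_GENE", "INTERGENIC")

VK_UPDOWNSTREAM_BP <- 5000L   # flanking distance for UPSTREAM/DOWNSTREAM
VK_ESS_SPLICE_BP <- 2L        # intronic bases either side counted essential
VK_SPLICE_INTRON_BP <- 8L     # intronic splice-region window: bases 3..8
VK_SPLICE_EXON_BP <- 3L       # exonic bases at a junction in the splice region

#' Transcript model
#'
#' @param name transcript identifier.
#' @param region_name reference region.
#' @param strand `+1` or `-1`.
#' @param exons data frame with `start`, `end` (genomic, 1-based closed),
#'   non-overlapping; stored sorted in transcript (5' to 3') order.
#' @param cds_start,cds_end genomic CDS bounds (`NULL` for non-coding).
#' @param biotype `"protein_coding"` or `"non_coding"`.
#' @return a `vk_transcript`.
#' @export
transcript_model <- function(name, region_name, strand, exons,
                             cds_start = NULL, cds_end = NULL,
                             biotype = c("protein_coding", "non_coding")) {
  biotype <- match.arg(biotype)
  strand <- as.integer(strand)
  if (!strand %in% c(1L, -1L)) vk_stop("strand must be +1 or -1")
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  if (any(exons$end < exons$start)) vk_stop("exon end < start")
  o <- order(exons$start)
  if (any(exons$start[o][-1] <= exons$end[o][-nrow(exons)]))
    vk_stop("exons overlap")
  ## transcript order: genomic for +, reverse genomic for -
  exons <- if (strand == 1L) exons[o, , drop = FALSE] else exons[rev(o), , drop = FALSE]
  rownames(exons) <- NULL
  if (is.null(cds_start) != is.null(cds_end))
    vk_stop("cds_start and cds_end must be given together")
  if (!is.null(cds_start)) {
    cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
    if (cds_end < cds_start) vk_stop("cds_end < cds_start")
    covered <- any(exons$start <= cds_start & exons$end >= cds_start) &&
      any(exons$start <= cds_end & exons$end >= cds_end)
    if (!covered) vk_stop("CDS bounds must lie inside the exon union")
    if (biotype == "non_coding") vk_stop("non-coding transcripts have no CDS")
  }
  structure(list(name = name, region_name = region_name, strand = strand,
                 exons = exons, cds_start = cds_start, cds_end = cds_end,
                 biotype = biotype),
            class = "vk_transcript")
}

#' Add a transcript model to a dataset
#' @param ds a `vk_dataset`.
#' @param tx a [transcript_model()].
#' @return the updated dataset.
#' @export
add_transcript <- function(ds, tx) {
  stopifnot(inherits(ds, "vk_dataset"), inherits(tx, "vk_transcript"))
  check_region(ds, tx$region_name)
  ds$transcripts <- c(ds$transcripts, list(tx))
  ds
}

tx_span <- function(tx) c(min(tx$exons$start), max(tx$exons$end))

## introns in genomic order: gaps between genomically sorted exons
tx_introns <- function(tx) {
  ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
  if (nrow(ex) < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
}

## genomic positions (transcript 5'->3' order) of the spliced cDNA
tx_cdna_positions <- function(tx) {
  unlist(lapply(seq_len(nrow(tx$exons)), function(i) {
    s <- tx$exons$start[i]; e <- tx$exons$end[i]
    if (tx$strand == 1L) s:e else e:s
  }))
}

tx_cds_positions <- function(tx) {
  if (is.null(tx$cds_start)) return(integer(0))
  pos <- tx_cdna_positions(tx)
  pos[pos >= tx$cds_start & pos <= tx$cds_end]
}

tx_sequence_at <- function(reference, tx, positions) {
  chars <- strsplit(reference[[tx$region_name]], "")[[1]][positions]
  s <- paste(chars, collapse = "")
  if (tx$strand == -1L) chartr("ACGT", "TGCA", s) else s
}

## standard genetic code lookup; stop codons translate to "*"
codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) vk_stop("invalid codon '", codon, "'")
  aa
}

new_call <- function(variation_name, transcript_name, types,
                     codon_change = NA_character_, peptide_change = NA_character_,
                     cdna_position = NA_integer_, protein_position = NA_integer_) {
  types <- CONSEQUENCE_TYPES[CONSEQUENCE_TYPES %in% types]
  structure(list(variation_name = variation_name,
                 transcript_name = transcript_name,
                 types = types, most_severe = types[1],
                 codon_change = codon_change, peptide_change = peptide_change,
                 cdna_position = cdna_position,
                 protein_position = protein_position),
            class = "vk_consequence")
}

#' @export
print.vk_consequence <- function(x, ...) {
  cat(sprintf("<consequence %s on %s: %s%s>\n", x$variation_name,
              x$transcript_name %||% "-", paste(x$types, collapse = ","),
              if (!is.na(x$codon_change))
                sprintf(" (%s, %s)", x$codon_change, x$peptide_change) else ""))
  invisible(x)
}

#' Classify one variant allele against one transcript
#'
#' Applies the consequence rules on the transcript's coding strand. CDS
#' substitutions are translated codon-wise (standard genetic code) into
#' STOP_GAINED / STOP_LOST / SYNONYMOUS_CODING / NON_SYNONYMOUS_CODING;
#' indels whose net length change is not a multiple of 3 are
#' FRAMESHIFT_CODING (in-frame indels count as NON_SYNONYMOUS_CODING).
#' Positional rules add ESSENTIAL_SPLICE_SITE (first/last 2 intronic bp),
#' SPLICE_SITE (intronic bases 3-8 from a junction, or the last 3 exonic
#' bases at a junction), UTRs, INTRONIC, UPSTREAM/DOWNSTREAM (within 5 kb),
#' WITHIN_NON_CODING_GENE and, when a regulatory set is supplied,
#' REGULATORY_REGION. A variant with no transcript context is INTERGENIC.
#'
#' @param ds a `vk_dataset` (reference source).
#' @param region_name,start,end variant location (1-based closed; an
#'   insertion has `start = end + 1`).
#' @param ref_allele reference allele (`"-"` for an insertion).
#' @param alt_allele alternate allele (`"-"` for a deletion).
#' @param tx a [transcript_model()], or `NULL` for no transcript context.
#' @param regulatory optional data frame of regulatory regions
#'   (`region_name`, `start`, `end`).
#' @param variation_name label used in the call (default `"novel"`).
#' @return a `vk_consequence` call.
#' @export
classify <- function(ds, region_name, start, end, ref_allele, alt_allele,
                     tx = NULL, regulatory = NULL, variation_name = "novel") {
  stopifnot(inherits(ds, "vk_dataset"))
  check_region(ds, region_name)
  start <- as.integer(start); end <- as.integer(end)
  seqlen <- nchar(ds$reference[[region_name]])
  lo <- min(start, end); hi <- max(start, end)
  if (lo < 1L || hi > seqlen) vk_stop("variant position outside the reference")
  if (identical(ref_allele, alt_allele)) vk_stop("alt allele equals the reference allele")
  is_ins <- ref_allele == "-"
  is_del <- alt_allele == "-"
  is_snp <- !is_ins && !is_del &&
    nchar(ref_allele) == 1L && nchar(alt_allele) == 1L

  types <- character(0)
  reg_hit <- !is.null(regulatory) && any(
    regulatory$region_name == region_name &
      regulatory$start <= hi & regulatory$end >= lo)

  info <- list(codon_change = NA_character_, peptide_change = NA_character_,
               cdna_position = NA_integer_, protein_position = NA_integer_)

  if (!is.null(tx) && tx$region_name == region_name) {
    span <- tx_span(tx)
    if (hi >= span[1] - VK_UPDOWNSTREAM_BP && lo <= span[2] + VK_UPDOWNSTREAM_BP) {
      if (hi < span[1] || lo > span[2]) {
        before <- hi < span[1]   # genomically left of the transcript
        upstream <- before == (tx$strand == 1L)
        types <- c(types, if (upstream) "UPSTREAM" else "DOWNSTREAM")
      } else {
        vpos <- lo:hi
        exonic_mask <- vapply(vpos, function(p)
          any(tx$exons$start <= p & tx$exons$end >= p), logical(1))
        introns <- tx_introns(tx)

        ess <- spl <- intronic_interior <- FALSE
        if (nrow(introns)) for (k in seq_len(nrow(introns))) {
          is_ <- introns$start[k]; ie <- introns$end[k]
          inp <- vpos[vpos >= is_ & vpos <= ie]
          if (length(inp)) {
            off <- pmin(inp - is_ + 1L, ie - inp + 1L)  # distance into intron
            ess <- ess || any(off <= VK_ESS_SPLICE_BP)
            spl <- spl || any(off >= 3L & off <= VK_SPLICE_INTRON_BP)
            intronic_interior <- intronic_interior || any(off > VK_SPLICE_INTRON_BP)
          }
          ## exonic bases within 3 bp of this junction
          spl <- spl || any(exonic_mask & (abs(vpos - (is_ - 1L)) < VK_SPLICE_EXON_BP |
                                             abs(vpos - (ie + 1L)) < VK_SPLICE_EXON_BP))
        }
        if (ess) types <- c(types, "ESSENTIAL_SPLICE_SITE")
        if (spl) types <- c(types, "SPLICE_SITE")
        if (intronic_interior) types <- c(types, "INTRONIC")

        if (any(exonic_mask)) {
          if (tx$biotype == "non_coding") {
            types <- c(types, "WITHIN_NON_CODING_GENE")
          } else {
            in_cds <- if (is_ins) {
              ## insertion point strictly inside the CDS
              lo >= tx$cds_start && hi <= tx$cds_end && any(exonic_mask)
            } else {
              any(exonic_mask & vpos >= tx$cds_start & vpos <= tx$cds_end)
            }
            if (in_cds) {
              if (is_snp) {
                cres <- classify_coding_snp(ds, tx, start, ref_allele, alt_allele)
                types <- c(types, cres$type)
                info <- cres$info
              } else {
                ref_len <- if (is_ins) 0L else nchar(ref_allele)
                alt_len <- if (is_del) 0L else nchar(alt_allele)
                net <- alt_len - ref_len
                types <- c(types,
                           if (net %% 3L != 0L) "FRAMESHIFT_CODING"
                           else "NON_SYNONYMOUS_CODING")
              }
            }
            utr_mask <- exonic_mask &
              (vpos < tx$cds_start | vpos > tx$cds_end)
            if (any(utr_mask)) {
              left <- vpos[utr_mask] < tx$cds_start
              five <- (left & tx$strand == 1L) | (!left & tx$strand == -1L)
              if (any(five)) types <- c(types, "5PRIME_UTR")
              if (any(!five)) types <- c(types, "3PRIME_UTR")
            }
          }
        }
      }
    }
  }

  if (reg_hit) types <- c(types, "REGULATORY_REGION")
  if (!length(types)) types <- "INTERGENIC"
  do.call(new_call, c(list(variation_name = variation_name,
                           transcript_name = if (is.null(tx)) NA_character_ else tx$name,
                           types = unique(types)), info))
}

## coding SNP: translate the reference and alternate codon
classify_coding_snp <- function(ds, tx, gpos, ref_allele, alt_allele) {
  cds_pos_genomic <- tx_cds_positions(tx)
  idx <- match(gpos, cds_pos_genomic)
  if (is.na(idx)) vk_stop("internal: position not in CDS")
  cds_seq <- tx_sequence_at(ds$reference, tx, cds_pos_genomic)
  codon_i <- (idx - 1L) %/% 3L
  within <- (idx - 1L) %% 3L + 1L
  codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (nchar(codon) < 3L)  # trailing partial codon (degenerate fixture)
    return(list(type = "NON_SYNONYMOUS_CODING",
                info = list(codon_change = NA_character_,
                            peptide_change = NA_character_,
                            cdna_position = NA_integer_,
                            protein_position = NA_integer_)))
  alt_coding <- if (tx$strand == -1L) chartr("ACGT", "TGCA", alt_allele) else alt_allele
  alt_codon <- codon
  substr(alt_codon, within, within) <- alt_coding
  ref_aa <- codon_aa(codon); alt_aa <- codon_aa(alt_codon)
  type <- if (alt_aa == "*" && ref_aa != "*") "STOP_GAINED"
  else if (ref_aa == "*" && alt_aa != "*") "STOP_LOST"
  else if (ref_aa == alt_aa) "SYNONYMOUS_CODING"
  else "NON_SYNONYMOUS_CODING"
  cdna_all <- tx_cdna_positions(tx)
  list(type = type,
       info = list(codon_change = paste0(codon, ">", alt_codon),
                   peptide_change = paste0(ref_aa, "/", alt_aa),
                   cdna_position = match(gpos, cdna_all),
                   protein_position = codon_i + 1L))
}

#' Predict consequences of a (possibly novel) variant
#'
#' Classifies the allele against every transcript whose span lies within
#' 5 kb of the location; the variant need not exist in the dataset. With no
#' transcript in range a single INTERGENIC call is returned.
#'
#' @inheritParams classify
#' @return list of `vk_consequence` calls sorted by severity of
#'   `most_severe`.
#' @export
predict_novel <- function(ds, region_name, start, end, ref_allele, alt_allele,
                          regulatory = NULL, variation_name = "novel") {
  lo <- min(start, end); hi <- max(start, end)
  near <- Filter(function(tx) {
    if (tx$region_name != region_name) return(FALSE)
    span <- tx_span(tx)
    hi >= span[1] - VK_UPDOWNSTREAM_BP && lo <= span[2] + VK_UPDOWNSTREAM_BP
  }, ds$transcripts)
  if (!length(near)) {
    return(list(classify(ds, region_name, start, end, ref_allele, alt_allele,
                         tx = NULL, regulatory = regulatory,
                         variation_name = variation_name)))
  }
  calls <- lapply(near, function(tx)
    classify(ds, region_name, start, end, ref_allele, alt_allele, tx = tx,
             regulatory = regulatory, variation_name = variation_name))
  sev <- vapply(calls, function(cl) match(cl$most_severe, CONSEQUENCE_TYPES),
                integer(1))
  calls[order(sev)]
}

#' Consequence calls for all stored variants
#'
#' Runs [predict_novel()] for each allele of each mapped variant feature.
#'
#' @param ds a `vk_dataset`.
#' @param regulatory optional regulatory regions.
#' @return data frame of calls (one row per variant x transcript x type set).
#' @export
call_consequences <- function(ds, regulatory = NULL) {
  feat <- ds$variation_features
  rows <- list()
  for (k in seq_len(nrow(feat))) {
    f <- feat[k, ]
    alleles <- split_alleles(f$allele_string)
    ref <- alleles[1]
    for (alt in alleles[-1]) {
      calls <- predict_novel(ds, f$region_name, f$start, f$end, ref, alt,
                             regulatory = regulatory,
                             variation_name = f$variation_name)
      for (cl in calls)
        rows[[length(rows) + 1L]] <- data.frame(
          variation_name = cl$variation_name,
          transcript_name = cl$transcript_name %||% NA_character_,
          allele = alt, types = paste(cl$types, collapse = ","),
          most_severe = cl$most_severe,
          codon_change = cl$codon_change, peptide_change = cl$peptide_change,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(variation_name = character(0), transcript_name = character(0),
                      allele = character(0), types = character(0),
                      most_severe = character(0), codon_change = character(0),
                      peptide_change = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
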