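## Standard-format interchange: FASTA references, GFF3/GTF transcript
## models, VCF variants + genotypes, BED regulatory regions.

#' Read a FASTA file into a named reference vector
#'
#' @param path FASTA file.
#' @param keep_softmask keep lower-case (soft-masked) bases; by default
#'   sequences are upper-cased.
#' @return named character vector (region name -> sequence).
#' @export
read_fasta <- function(path, keep_softmask = FALSE) {
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) vk_stop("duplicate FASTA record names")
  seqs <- as.character(set)
  if (!keep_softmask) seqs <- toupper(seqs)
  bad <- grepl("[^ACGTNacgtn]", seqs)
  if (any(bad))
    vk_stop("non-nucleotide characters in FASTA record '", nm[bad][1], "'")
  stats::setNames(seqs, nm)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read transcript models from GFF3/GTF
#'
#' Assembles exon and CDS rows into [transcript_model()]s via their parent
#' (GFF3 `Parent`/`ID`) or `transcript_id` (GTF) links. Transcripts whose
#' exons cannot be assembled are skipped with a warning.
#'
#' @param path GFF3 or GTF file (format chosen by extension; override with
#'   `format`).
#' @param format `"gff3"` or `"gtf"`.
#' @return list of `vk_transcript` objects.
#' @export
read_transcripts <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf")) "gtf" else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  ## parent/transcript linkage differs between GFF3 and GTF
  parent_of <- function(rows) {
    if (!is.null(rows$transcript_id)) return(as.character(rows$transcript_id))
    p <- rows$Parent
    vapply(seq_len(nrow(rows)), function(i) {
      pi <- p[[i]]
      if (length(pi)) as.character(pi[[1]]) else NA_character_
    }, character(1))
  }
  feats <- df[tolower(df$type) %in% c("exon", "cds"), , drop = FALSE]
  if (!nrow(feats)) return(list())
  feats$parent <- parent_of(feats)
  orphans <- is.na(feats$parent)
  if (any(orphans)) {
    warning(sum(orphans), " exon/CDS row(s) without a parent transcript skipped")
    feats <- feats[!orphans, , drop = FALSE]
  }
  ## transcript biotype, if annotated on the mRNA/transcript rows
  tx_rows <- df[tolower(df$type) %in% c("mrna", "transcript"), , drop = FALSE]
  tx_bio <- if (nrow(tx_rows) && !is.null(tx_rows$biotype))
    stats::setNames(as.character(tx_rows$biotype),
                    if (!is.null(tx_rows$ID)) as.character(tx_rows$ID)
                    else as.character(tx_rows$transcript_id))
  else character(0)

  out <- list()
  for (txid in unique(feats$parent)) {
    rows <- feats[feats$parent == txid, , drop = FALSE]
    ex <- rows[tolower(rows$type) == "exon", , drop = FALSE]
    cds <- rows[tolower(rows$type) == "cds", , drop = FALSE]
    if (!nrow(ex)) {
      warning("transcript '", txid, "' has no exon rows; skipped")
      next
    }
    strand <- if (as.character(ex$strand[1]) == "-") -1L else 1L
    biotype <- if (nrow(cds)) "protein_coding"
    else if (identical(unname(tx_bio[txid]), "protein_coding")) "protein_coding"
    else "non_coding"
    tx <- tryCatch(
      transcript_model(txid, as.character(ex$seqnames[1]), strand,
                       data.frame(start = ex$start, end = ex$end),
                       cds_start = if (nrow(cds)) min(cds$start) else NULL,
                       cds_end = if (nrow(cds)) max(cds$end) else NULL,
                       biotype = biotype),
      error = function(e) {
        warning("transcript '", txid, "' malformed (", conditionMessage(e),
                "); skipped")
        NULL
      })
    if (!is.null(tx)) out[[length(out) + 1L]] <- tx
  }
  out
}

#' Read a BED file of regions (e.g. regulatory features)
#'
#' @param path BED file (0-based half-open input; returned 1-based closed).
#' @return data frame (`region_name`, `start`, `end`, `name`).
#' @export
read_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  data.frame(region_name = as.character(bed[[1]]),
             start = as.integer(bed[[2]]) + 1L,
             end = as.integer(bed[[3]]),
             name = if (ncol(bed) >= 4) as.character(bed[[4]]) else NA_character_,
             stringsAsFactors = FALSE)
}

## ---- VCF -------------------------------------------------------------------

#' Import variants and genotypes from VCF
#'
#' REF/ALT become the variant's allele string (reference allele first).
#' Single-base unphased genotypes go to the compressed store; indel and
#' multi-base genotypes go to the uncompressed multi-bp table. Phased GT
#' separators (`|`) are accepted but stored unphased.
#'
#' @param ds a `vk_dataset` (must already hold the reference).
#' @param path VCF 4.x file.
#' @param cfg a [codec_config()].
#' @param source source label for imported variants.
#' @return the updated dataset; counts are attached as attribute
#'   `"import_counts"` (variants, features, genotypes_compressed,
#'   genotypes_multi_bp).
#' @export
import_vcf <- function(ds, path, cfg = codec_config(), source = "vcf") {
  stopifnot(inherits(ds, "vk_dataset"))
  if (!length(ds$reference)) vk_stop("import requires a reference in the dataset")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- if (ncol(vcf@gt) > 1) vcf@gt else NULL
  samples <- if (!is.null(gt)) colnames(gt)[-1] else character(0)
  for (smp in setdiff(samples, ds$individuals$name))
    ds <- add_individual(ds, smp)

  counts <- c(variants = 0L, features = 0L, genotypes_compressed = 0L,
              genotypes_multi_bp = 0L)
  comp <- list(); multi <- list()
  for (k in seq_len(nrow(fix))) {
    region <- fix$CHROM[k]
    check_region(ds, region)
    pos <- as.integer(fix$POS[k])
    ref <- fix$REF[k]
    alts <- strsplit(fix$ALT[k], ",", fixed = TRUE)[[1]]
    alleles <- c(ref, alts)
    name <- fix$ID[k]
    if (is.na(name) || name == ".") name <- sprintf("%s_%d", region, pos)
    vstart <- pos; vend <- pos + nchar(ref) - 1L
    flank_n <- 25L
    up <- substr(ds$reference[[region]], max(1L, vstart - flank_n), vstart - 1L)
    down <- substr(ds$reference[[region]], vend + 1L,
                   min(nchar(ds$reference[[region]]), vend + flank_n))
    ds <- add_variation(ds, name, alleles, flank_up = up, flank_down = down,
                        source = source)
    ds$variation_features <- rbind(
      ds$variation_features,
      data.frame(variation_name = name, region_name = region,
                 start = vstart, end = vend, strand = 1L,
                 allele_string = paste(alleles, collapse = "/"),
                 map_weight = 1L, stringsAsFactors = FALSE))
    counts["variants"] <- counts["variants"] + 1L
    counts["features"] <- counts["features"] + 1L

    if (!is.null(gt)) {
      fmt <- strsplit(gt[k, 1], ":", fixed = TRUE)[[1]]
      gti <- match("GT", fmt)
      if (is.na(gti)) next
      for (smp in samples) {
        cell <- strsplit(gt[k, smp], ":", fixed = TRUE)[[1]][gti]
        if (is.na(cell) || cell %in% c(".", "./.", ".|.")) next
        idx <- strsplit(cell, "[/|]")[[1]]
        if (length(idx) != 2L) vk_stop("non-diploid GT '", cell, "' at ",
                                       region, ":", pos)
        if (any(idx == ".")) next
        al <- alleles[as.integer(idx) + 1L]
        rec <- data.frame(individual_name = smp, region_name = region,
                          position = pos, allele1 = al[1], allele2 = al[2],
                          stringsAsFactors = FALSE)
        if (all(nchar(alleles) == 1L) && all(alleles %in% VK_BASES)) {
          comp[[length(comp) + 1L]] <- rec
        } else {
          multi[[length(multi) + 1L]] <- rec
        }
      }
    }
  }
  if (length(comp)) {
    ds <- store_genotypes(ds, do.call(rbind, comp), cfg)
    counts["genotypes_compressed"] <- length(comp)
  }
  if (length(multi)) {
    ds <- store_genotypes(ds, do.call(rbind, multi), cfg, multi_bp = TRUE)
    counts["genotypes_multi_bp"] <- length(multi)
  }
  attr(ds, "import_counts") <- counts
  ds
}

#' Export variants and genotypes in a slice to VCF
#'
#' Writes one record per variation feature in the slice, with GT columns for
#' every individual that has a stored genotype (always unphased `/`).
#'
#' @param ds a `vk_dataset`.
#' @param s a `vk_slice`, or `NULL` for everything.
#' @param path output file.
#' @param cfg a [codec_config()].
#' @return `path`, invisibly.
#' @export
export_vcf <- function(ds, path, s = NULL, cfg = codec_config()) {
  stopifnot(inherits(ds, "vk_dataset"))
  feat <- ds$variation_features
  if (!is.null(s)) {
    feat <- feat[feat$region_name == s$region_name &
                   feat$start <= s$end & feat$end >= s$start, , drop = FALSE]
  }
  feat <- feat[order(feat$region_name, feat$start), , drop = FALSE]
  samples <- ds$individuals$name
  lines <- c("##fileformat=VCFv4.2",
             "##source=varkit",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", if (length(samples)) c("FORMAT", samples)),
                   collapse = "\t"))
  for (k in seq_len(nrow(feat))) {
    f <- feat[k, ]
    alleles <- split_alleles(f$allele_string)
    ref <- alleles[1]; alts <- alleles[-1]
    if (!length(alts)) alts <- "."
    fields <- c(f$region_name, f$start, f$variation_name, ref,
                paste(alts, collapse = ","), ".", ".", ".")
    if (length(samples)) {
      here <- slice(f$region_name, max(1L, f$start), max(f$start, f$end))
      g <- query_genotypes(ds, here, cfg = cfg)
      g <- g[g$position == f$start, , drop = FALSE]
      mb <- ds$multi_bp_genotypes
      gmb <- mb[mb$region_name == f$region_name & mb$position == f$start, ,
                drop = FALSE]
      g <- rbind(g[, names(vk_schemas()$multi_bp_genotypes)], gmb)
      gts <- vapply(samples, function(smp) {
        row <- g[g$individual_name == smp, , drop = FALSE]
        if (!nrow(row)) return("./.")
        i1 <- match(row$allele1[1], alleles) - 1L
        i2 <- match(row$allele2[1], alleles) - 1L
        if (is.na(i1) || is.na(i2)) return("./.")
        paste0(i1, "/", i2)
      }, character(1))
      fields <- c(fields, "GT", gts)
    }
    lines <- c(lines, paste(fields, collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
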