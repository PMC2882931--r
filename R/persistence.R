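## Dataset persistence: one directory per dataset, one tab-separated file per
## table, a FASTA for the reference, a binary sidecar for genotype blobs
## (referenced by offset + length), and a JSON manifest with a format version.
## Inspectable and diff-able; load(save(ds)) is value-identity, blobs
## bit-for-bit.

VK_STORE_FORMAT <- "varkit-dataset"
VK_STORE_VERSION <- 1L

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = TRUE, na = "NA",
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path, schema) {
  df <- utils::read.delim(path, sep = "\t", quote = "\"", na.strings = "NA",
                          colClasses = unname(schema), check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!identical(names(df), names(schema)))
    vk_stop("table at ", path, " does not match the expected schema",
            class = "vk_load_error")
  rownames(df) <- NULL
  df
}

#' Save a dataset to a directory store
#'
#' Writes each table as a tab-separated text file, the reference as FASTA,
#' compressed genotype blobs into a binary sidecar addressed by offset and
#' length, and a manifest recording the format version.
#'
#' @param ds a `vk_dataset`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @seealso [load_dataset()]
#' @export
save_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "vk_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sch <- vk_schemas()
  for (tb in names(sch))
    write_tsv(ds[[tb]], file.path(path, paste0(tb, ".tsv")))

  ## genotype rows: blob column goes to the sidecar, table stores offsets
  gr <- ds$genotype_rows
  lens <- vapply(gr$blob, length, integer(1))
  offs <- if (nrow(gr)) cumsum(c(0L, lens[-length(lens)])) else integer(0)
  tab <- gr[, c("individual_name", "region_name", "window_index", "start")]
  tab$blob_offset <- offs
  tab$blob_length <- lens
  write_tsv(tab, file.path(path, "genotype_rows.tsv"))
  con <- file(file.path(path, "genotype_blobs.bin"), "wb")
  on.exit(close(con))
  if (nrow(gr)) writeBin(unlist(gr$blob) %||% raw(0), con)

  ## reference + transcripts
  write_fasta(ds$reference, file.path(path, "reference.fa"))
  write_tsv(transcripts_to_table(ds$transcripts), file.path(path, "transcripts.tsv"))

  jsonlite::write_json(
    list(format = VK_STORE_FORMAT, version = VK_STORE_VERSION,
         tables = c(names(sch), "genotype_rows", "transcripts")),
    file.path(path, "manifest.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a dataset from a directory store
#'
#' @param path directory previously written by [save_dataset()].
#' @return a `vk_dataset` value-equal to the one saved.
#' @export
load_dataset <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path))
    vk_stop("not a dataset store (missing manifest): ", path,
            class = "vk_load_error")
  mf <- tryCatch(jsonlite::read_json(mf_path),
                 error = function(e) vk_stop("corrupt manifest at ", mf_path,
                                             class = "vk_load_error"))
  if (!identical(mf$format, VK_STORE_FORMAT) ||
      !identical(as.integer(mf$version), VK_STORE_VERSION))
    vk_stop("dataset store version mismatch (found ",
            mf$format %||% "?", " v", mf$version %||% "?",
            ", expected ", VK_STORE_FORMAT, " v", VK_STORE_VERSION, ")",
            class = "vk_load_error")

  ref <- read_fasta(file.path(path, "reference.fa"))
  ds <- new_dataset(ref)
  sch <- vk_schemas()
  for (tb in names(sch))
    ds[[tb]] <- read_tsv(file.path(path, paste0(tb, ".tsv")), sch[[tb]])

  row_schema <- c(individual_name = "character", region_name = "character",
                  window_index = "integer", start = "integer",
                  blob_offset = "integer", blob_length = "integer")
  tab <- read_tsv(file.path(path, "genotype_rows.tsv"), row_schema)
  blob_path <- file.path(path, "genotype_blobs.bin")
  all_bytes <- readBin(blob_path, "raw", n = file.size(blob_path))
  if (nrow(tab) && length(all_bytes) < max(tab$blob_offset + tab$blob_length))
    vk_stop("genotype blob sidecar is truncated", class = "vk_load_error")
  gr <- tab[, c("individual_name", "region_name", "window_index", "start")]
  gr$blob <- lapply(seq_len(nrow(tab)), function(i)
    all_bytes[seq_len(tab$blob_length[i]) + tab$blob_offset[i]])
  rownames(gr) <- NULL
  ds$genotype_rows <- gr

  ds$transcripts <- transcripts_from_table(
    read_tsv(file.path(path, "transcripts.tsv"), transcript_table_schema()))
  ds
}

transcript_table_schema <- function() {
  c(name = "character", region_name = "character", strand = "integer",
    exons = "character", cds_start = "integer", cds_end = "integer",
    biotype = "character")
}

transcripts_to_table <- function(txs) {
  if (!length(txs)) return(empty_table(transcript_table_schema()))
  do.call(rbind, lapply(txs, function(tx) {
    data.frame(name = tx$name, region_name = tx$region_name,
               strand = tx$strand,
               exons = paste(sprintf("%d-%d", tx$exons$start, tx$exons$end),
                             collapse = ";"),
               cds_start = tx$cds_start %||% NA_integer_,
               cds_end = tx$cds_end %||% NA_integer_,
               biotype = tx$biotype, stringsAsFactors = FALSE)
  }))
}

transcripts_from_table <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i) {
    parts <- strsplit(strsplit(tab$exons[i], ";", fixed = TRUE)[[1]], "-",
                      fixed = TRUE)
    exons <- data.frame(start = as.integer(vapply(parts, `[`, "", 1L)),
                        end = as.integer(vapply(parts, `[`, "", 2L)))
    transcript_model(tab$name[i], tab$region_name[i], tab$strand[i], exons,
                     cds_start = if (is.na(tab$cds_start[i])) NULL else tab$cds_start[i],
                     cds_end = if (is.na(tab$cds_end[i])) NULL else tab$cds_end[i],
                     biotype = tab$biotype[i])
  })
}
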