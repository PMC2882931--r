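## Compressed genotype store.
##
## One row holds all single-base genotypes of one individual inside one
## fixed, genome-anchored window (window k covers [k*W + 1, (k+1)*W], with
## W = 100 kb by default). The row's binary blob is a repeating triplet:
## distance-from-previous-genotype, allele 1, allele 2. The first genotype's
## distance (always 0) is implicit — its absolute position lives in the row's
## start field. Distances are unsigned LEB128; alleles are single ASCII
## bytes over A/C/G/T/N.

#' Codec configuration
#'
#' @param window_size fixed genomic window size in bp (default 100,000).
#' @return a `vk_codec_config`.
#' @export
codec_config <- function(window_size = 100000L) {
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L) vk_stop("window_size must be >= 1")
  structure(list(window_size = window_size), class = "vk_codec_config")
}

window_of <- function(position, w) (as.integer(position) - 1L) %/% as.integer(w)

## Unsigned LEB128: 7 bits per byte, little-endian, high bit = continuation.
uleb128_encode <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) vk_stop("ULEB128 encodes non-negative integers only")
  bytes <- integer(0)
  repeat {
    b <- n %% 128L
    n <- n %/% 128L
    if (n > 0L) bytes <- c(bytes, b + 128L) else { bytes <- c(bytes, b); break }
  }
  as.raw(bytes)
}

## Decode one ULEB128 value starting at offset i (1-based) in raw vector.
## Returns list(value, next_offset); errors name the failing byte offset.
uleb128_decode <- function(bytes, i) {
  value <- 0L
  shift <- 1L
  repeat {
    if (i > length(bytes))
      vk_stop("truncated ULEB128 at byte offset ", i, class = "vk_decode_error")
    b <- as.integer(bytes[i])
    value <- value + (b %% 128L) * shift
    i <- i + 1L
    if (b < 128L) break
    shift <- shift * 128L
    if (shift > .Machine$integer.max)
      vk_stop("ULEB128 overrun at byte offset ", i, class = "vk_decode_error")
  }
  list(value = value, next_offset = i)
}

validate_genotype_df <- function(genotypes) {
  need <- c("individual_name", "region_name", "position", "allele1", "allele2")
  if (!is.data.frame(genotypes) || !all(need %in% names(genotypes)))
    vk_stop("genotypes must be a data frame with columns: ",
            paste(need, collapse = ", "))
  genotypes$position <- as.integer(genotypes$position)
  genotypes
}

#' Encode one individual's genotypes in one window into a compressed row
#'
#' @param genotypes data frame (`individual_name`, `region_name`, `position`,
#'   `allele1`, `allele2`) for a single individual, positions strictly
#'   increasing and all inside one window; alleles single bases (A/C/G/T/N).
#' @param cfg a [codec_config()].
#' @return a one-row data frame matching the dataset's `genotype_rows` table
#'   (with a raw-vector `blob` list column).
#' @seealso [decode_window()]
#' @examples
#' g <- data.frame(individual_name = "NA001", region_name = "chr1",
#'                 position = c(1000L, 1030L), allele1 = c("A", "C"),
#'                 allele2 = c("G", "C"))
#' row <- encode_window(g, codec_config())
#' decode_window(row)
#' @export
encode_window <- function(genotypes, cfg = codec_config()) {
  genotypes <- validate_genotype_df(genotypes)
  n <- nrow(genotypes)
  if (n == 0L) vk_stop("cannot encode an empty genotype set")
  if (length(unique(genotypes$individual_name)) != 1L ||
      length(unique(genotypes$region_name)) != 1L)
    vk_stop("encode_window takes genotypes of one individual in one region")
  pos <- genotypes$position
  if (any(diff(pos) <= 0L))
    vk_stop("positions must be strictly increasing (sorted, no duplicates)")
  a1 <- genotypes$allele1; a2 <- genotypes$allele2
  if (!all(is_single_base(a1)) || !all(is_single_base(a2)))
    vk_stop("only single-base genotypes (A/C/G/T/N) belong in the compressed ",
            "store; route others to the multi-bp genotype table")
  win <- window_of(pos, cfg$window_size)
  if (length(unique(win)) != 1L)
    vk_stop("genotypes span more than one ", cfg$window_size, " bp window")

  parts <- vector("list", 2L * n - 1L)
  parts[[1L]] <- charToRaw(paste0(a1[1L], a2[1L]))
  if (n > 1L) {
    dists <- diff(pos)
    for (k in 2:n) {
      parts[[2L * k - 2L]] <- uleb128_encode(dists[k - 1L])
      parts[[2L * k - 1L]] <- charToRaw(paste0(a1[k], a2[k]))
    }
  }
  row <- data.frame(individual_name = genotypes$individual_name[1L],
                    region_name = genotypes$region_name[1L],
                    window_index = win[1L], start = pos[1L],
                    stringsAsFactors = FALSE)
  row$blob <- list(unlist(parts))
  row
}

#' Decode a compressed genotype row
#'
#' The first genotype sits at the row's start position (its zero distance is
#' implicit, restored during decoding); each later position is the running
#' sum of the stored distances.
#'
#' @param row one row of the `genotype_rows` table (data frame with a raw
#'   `blob` in a list column, or a list with the same fields).
#' @return data frame of genotypes (`individual_name`, `region_name`,
#'   `position`, `allele1`, `allele2`), in position order.
#' @export
decode_window <- function(row) {
  if (is.data.frame(row)) {
    stopifnot(nrow(row) == 1L)
    blob <- row$blob[[1L]]
    meta <- row
  } else {
    blob <- row$blob
    if (is.list(blob)) blob <- blob[[1L]]
    meta <- row
  }
  if (!is.raw(blob)) vk_stop("row blob must be a raw vector")
  read_alleles <- function(i) {
    if (i + 1L > length(blob))
      vk_stop("truncated blob: expected allele pair at byte offset ", i,
              class = "vk_decode_error")
    al <- rawToChar(blob[i:(i + 1L)])
    al <- c(substr(al, 1, 1), substr(al, 2, 2))
    if (!all(is_single_base(al)))
      vk_stop("invalid allele byte at offset ", i, class = "vk_decode_error")
    al
  }
  pos <- integer(0); a1 <- character(0); a2 <- character(0)
  i <- 1L
  cur <- as.integer(meta$start)
  first <- TRUE
  while (i <= length(blob)) {
    if (first) {
      first <- FALSE            # implicit distance 0 for the leading genotype
    } else {
      dec <- uleb128_decode(blob, i)
      if (dec$value == 0L)
        vk_stop("zero distance at byte offset ", i,
                " (duplicate position)", class = "vk_decode_error")
      cur <- cur + dec$value
      i <- dec$next_offset
    }
    al <- read_alleles(i)
    i <- i + 2L
    pos <- c(pos, cur); a1 <- c(a1, al[1]); a2 <- c(a2, al[2])
  }
  data.frame(individual_name = rep(meta$individual_name, length(pos)),
             region_name = rep(meta$region_name, length(pos)),
             position = pos, allele1 = a1, allele2 = a2,
             stringsAsFactors = FALSE)
}

#' Store genotypes into the compressed (and multi-bp) tables
#'
#' Single-base genotypes are partitioned by (individual, region, window) and
#' each non-empty cell is delta-encoded into one compressed row; a cell that
#' already holds a row is decoded, merged and re-encoded. Multi-base
#' genotypes are rejected here — use `multi_bp = TRUE` to route them to the
#' uncompressed multiple-base-pair genotype table instead.
#'
#' @param ds a `vk_dataset`.
#' @param genotypes data frame (`individual_name`, `region_name`, `position`,
#'   `allele1`, `allele2`), any order.
#' @param cfg a [codec_config()].
#' @param multi_bp if `TRUE`, store in the uncompressed multi-bp table.
#' @return the updated dataset; the number of rows written is attached as
#'   attribute `"rows_written"`.
#' @export
store_genotypes <- function(ds, genotypes, cfg = codec_config(),
                            multi_bp = FALSE) {
  stopifnot(inherits(ds, "vk_dataset"))
  genotypes <- validate_genotype_df(genotypes)
  for (r in unique(genotypes$region_name)) check_region(ds, r)
  key <- paste(genotypes$individual_name, genotypes$region_name,
               genotypes$position)
  if (anyDuplicated(key))
    vk_stop("duplicate (individual, region, position) genotype: ",
            key[duplicated(key)][1])

  if (multi_bp) {
    ds$multi_bp_genotypes <- rbind(
      ds$multi_bp_genotypes,
      genotypes[, names(vk_schemas()$multi_bp_genotypes)])
    attr(ds, "rows_written") <- nrow(genotypes)
    return(ds)
  }
  single <- is_single_base(genotypes$allele1) & is_single_base(genotypes$allele2)
  if (!all(single))
    vk_stop("multi-base genotypes cannot enter the compressed store; ",
            "store them with multi_bp = TRUE")

  genotypes$window_index <- window_of(genotypes$position, cfg$window_size)
  cells <- split(genotypes, paste(genotypes$individual_name,
                                  genotypes$region_name,
                                  genotypes$window_index))
  written <- 0L
  for (cell in cells) {
    cell <- cell[order(cell$position), ]
    gr <- ds$genotype_rows
    hit <- which(gr$individual_name == cell$individual_name[1] &
                   gr$region_name == cell$region_name[1] &
                   gr$window_index == cell$window_index[1])
    if (length(hit)) {
      old <- decode_window(gr[hit, ])
      merged <- rbind(old, cell[, names(old)])
      if (anyDuplicated(merged$position))
        vk_stop("duplicate (individual, region, position) genotype at ",
                merged$position[duplicated(merged$position)][1])
      merged <- merged[order(merged$position), ]
      ds$genotype_rows[hit, c("start")] <- merged$position[1]
      ds$genotype_rows$blob[[hit]] <- encode_window(merged, cfg)$blob[[1]]
    } else {
      ds$genotype_rows <- rbind(ds$genotype_rows,
                                encode_window(cell[, names(vk_schemas()$multi_bp_genotypes)], cfg))
    }
    written <- written + 1L
  }
  rownames(ds$genotype_rows) <- NULL
  attr(ds, "rows_written") <- written
  ds
}

#' Query genotypes in a genomic slice
#'
#' Decodes only the compressed rows whose window overlaps the slice, then
#' filters to the exact interval — region queries touch O(rows in window)
#' data rather than the whole table.
#'
#' @param ds a `vk_dataset`.
#' @param s a `vk_slice`.
#' @param individuals optional character vector restricting the individuals.
#' @param cfg a [codec_config()] (must match the one used at store time).
#' @return data frame of genotypes sorted by (individual, position).
#' @export
query_genotypes <- function(ds, s, individuals = NULL, cfg = codec_config()) {
  stopifnot(inherits(ds, "vk_dataset"), inherits(s, "vk_slice"))
  check_region(ds, s$region_name)
  gr <- ds$genotype_rows
  w_lo <- window_of(s$start, cfg$window_size)
  w_hi <- window_of(s$end, cfg$window_size)
  sel <- gr$region_name == s$region_name &
    gr$window_index >= w_lo & gr$window_index <= w_hi
  if (!is.null(individuals)) sel <- sel & gr$individual_name %in% individuals
  rows <- which(sel)
  if (!length(rows))
    return(empty_table(vk_schemas()$multi_bp_genotypes))
  out <- do.call(rbind, lapply(rows, function(i) decode_window(gr[i, ])))
  out <- out[out$position >= s$start & out$position <= s$end, , drop = FALSE]
  out <- out[order(out$individual_name, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
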