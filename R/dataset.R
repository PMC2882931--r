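## Canonical table schemas: column name -> storage type. Single source of
## truth for constructors, persistence and validation.
vk_schemas <- function() {
  list(
    variations = c(name = "character", source = "character",
                   alleles = "character", ancestral_allele = "character",
                   flank_up_seq = "character", flank_up_region = "character",
                   flank_up_start = "integer", flank_up_end = "integer",
                   flank_up_strand = "integer",
                   flank_down_seq = "character", flank_down_region = "character",
                   flank_down_start = "integer", flank_down_end = "integer",
                   flank_down_strand = "integer",
                   whitelisted = "logical", failed_reason = "character"),
    variation_features = c(variation_name = "character", region_name = "character",
                           start = "integer", end = "integer", strand = "integer",
                           allele_string = "character", map_weight = "integer"),
    multi_bp_genotypes = c(individual_name = "character", region_name = "character",
                           position = "integer", allele1 = "character",
                           allele2 = "character"),
    coverage = c(individual_name = "character", region_name = "character",
                 start = "integer", end = "integer", level = "integer"),
    structural_variations = c(name = "character", region_name = "character",
                              outer_start = "integer", inner_start = "integer",
                              inner_end = "integer", outer_end = "integer",
                              sv_class = "character"),
    frequencies = c(population = "character", variation_name = "character",
                    kind = "character", state = "character",
                    frequency = "double", sample_count = "integer"),
    annotations = c(variation_name = "character", phenotype_description = "character",
                    risk_allele = "character", p_value = "double",
                    study_source = "character"),
    individuals = c(name = "character", populations = "character")
  )
}

empty_table <- function(schema) {
  cols <- lapply(schema, function(ty) vector(ty, 0L))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

empty_genotype_rows <- function() {
  df <- data.frame(individual_name = character(0), region_name = character(0),
                   window_index = integer(0), start = integer(0),
                   stringsAsFactors = FALSE)
  df$blob <- list()
  df
}

VK_FAILED_REASONS <- c("NO_MAPPING", "TOO_MANY_MAPPINGS", "ALLELE_MISMATCH")

#' Create an empty variation dataset
#'
#' The dataset is the in-memory analogue of a variation database: a reference
#' sequence set plus tables of variants, mappings, genotypes (compressed and
#' multi-base-pair), read coverage, structural variants, population
#' frequencies, phenotype annotations, individuals and transcript models.
#' All modifier functions are functional: they return an updated copy.
#'
#' @param reference named character vector mapping region names to upper-case
#'   nucleotide sequences (see [read_fasta()]).
#' @return an object of class `vk_dataset`.
#' @examples
#' ds <- new_dataset(c(chr1 = "ACGTACGTAC"))
#' @export
new_dataset <- function(reference = character(0)) {
  if (length(reference) && is.null(names(reference)))
    vk_stop("reference sequences must be named by region")
  sch <- vk_schemas()
  ds <- c(list(reference = reference),
          lapply(sch, empty_table),
          list(genotype_rows = empty_genotype_rows(), transcripts = list()))
  structure(ds, class = "vk_dataset")
}

#' @export
print.vk_dataset <- function(x, ...) {
  cat("<varkit dataset>\n")
  cat(sprintf("  reference:   %d region(s), %s bp\n", length(x$reference),
              format(sum(nchar(x$reference)), big.mark = ",")))
  cat(sprintf("  variations:  %d (%d failed)  features: %d\n",
              nrow(x$variations), sum(!is.na(x$variations$failed_reason)),
              nrow(x$variation_features)))
  cat(sprintf("  genotype rows: %d compressed, %d multi-bp;  coverage: %d;  SVs: %d\n",
              nrow(x$genotype_rows), nrow(x$multi_bp_genotypes),
              nrow(x$coverage), nrow(x$structural_variations)))
  cat(sprintf("  transcripts: %d;  frequencies: %d;  annotations: %d\n",
              length(x$transcripts), nrow(x$frequencies), nrow(x$annotations)))
  invisible(x)
}

check_region <- function(ds, region_name) {
  if (!region_name %in% names(ds$reference))
    vk_stop("unknown region '", region_name, "'")
}

#' Add an individual
#'
#' @param ds a `vk_dataset`.
#' @param name unique individual identifier.
#' @param populations character vector of population names the individual
#'   belongs to.
#' @return the updated dataset.
#' @export
add_individual <- function(ds, name, populations = character(0)) {
  stopifnot(inherits(ds, "vk_dataset"))
  assert_scalar_string(name, "individual name")
  if (name %in% ds$individuals$name) vk_stop("duplicate individual '", name, "'")
  ds$individuals <- rbind(ds$individuals,
                          data.frame(name = name,
                                     populations = paste(populations, collapse = ","),
                                     stringsAsFactors = FALSE))
  ds
}

#' Add a variant defined by its flanking sequences and alleles
#'
#' A variant enters the dataset assembly-independently: identified by name and
#' anchored by its 5' and 3' flanking sequences plus at least one allele.
#' Mapping to the reference ([map_flanks()]) and QC ([apply_qc()]) attach
#' coordinates later.
#'
#' @param ds a `vk_dataset`.
#' @param name unique variant name.
#' @param alleles character vector of alleles (reference allele first;
#'   deletions written `"-"`).
#' @param flank_up,flank_down raw 5' and 3' flanking sequences.
#' @param source free-text provenance.
#' @param ancestral_allele optional ancestral allele.
#' @param whitelisted if `TRUE` the variant is never moved to the failed set
#'   (e.g. clinically significant variants).
#' @return the updated dataset.
#' @export
add_variation <- function(ds, name, alleles, flank_up, flank_down,
                          source = "local", ancestral_allele = NA_character_,
                          whitelisted = FALSE) {
  stopifnot(inherits(ds, "vk_dataset"))
  assert_scalar_string(name, "variation name")
  if (name %in% ds$variations$name) vk_stop("duplicate variation '", name, "'")
  if (length(alleles) < 1L) vk_stop("a variation needs at least one allele")
  row <- empty_table(vk_schemas()$variations)[0, ]
  row[1, ] <- NA
  row$name <- name; row$source <- source
  row$alleles <- paste(alleles, collapse = "/")
  row$ancestral_allele <- ancestral_allele
  row$flank_up_seq <- flank_up; row$flank_down_seq <- flank_down
  row$whitelisted <- isTRUE(whitelisted)
  row$failed_reason <- NA_character_
  ds$variations <- rbind(ds$variations, row)
  ds
}

split_alleles <- function(allele_string) strsplit(allele_string, "/", fixed = TRUE)[[1]]

#' Add a structural variant with bounded coordinates
#'
#' Structural variants (e.g. CNVs) rarely have base-pair-precise breakpoints;
#' start and end are therefore stored as ranges between a minimum (outer) and
#' maximum (inner) value: `outer_start <= inner_start <= inner_end <=
#' outer_end`.
#'
#' @param ds a `vk_dataset`.
#' @param name SV identifier.
#' @param region_name reference region.
#' @param outer_start,inner_start,inner_end,outer_end 1-based bounds.
#' @param sv_class free-text class, e.g. `"CNV"`.
#' @return the updated dataset.
#' @export
add_structural_variation <- function(ds, name, region_name, outer_start,
                                     inner_start, inner_end, outer_end,
                                     sv_class = "CNV") {
  stopifnot(inherits(ds, "vk_dataset"))
  check_region(ds, region_name)
  b <- as.integer(c(outer_start, inner_start, inner_end, outer_end))
  if (anyNA(b) || any(diff(b) < 0L) || b[1] < 1L)
    vk_stop("structural variant bounds must satisfy 1 <= outer_start <= inner_start <= inner_end <= outer_end")
  ds$structural_variations <- rbind(
    ds$structural_variations,
    data.frame(name = name, region_name = region_name,
               outer_start = b[1], inner_start = b[2], inner_end = b[3],
               outer_end = b[4], sv_class = sv_class, stringsAsFactors = FALSE))
  ds
}

#' Add a phenotype annotation for a variant
#'
#' @param ds a `vk_dataset`.
#' @param variation_name annotated variant.
#' @param phenotype_description free-text phenotype.
#' @param risk_allele optional risk allele.
#' @param p_value optional association p-value in (0, 1].
#' @param study_source free-text study identifier.
#' @return the updated dataset.
#' @export
add_annotation <- function(ds, variation_name, phenotype_description,
                           risk_allele = NA_character_, p_value = NA_real_,
                           study_source = "") {
  stopifnot(inherits(ds, "vk_dataset"))
  if (!is.na(p_value) && (p_value <= 0 || p_value > 1))
    vk_stop("p_value must lie in (0, 1]")
  ds$annotations <- rbind(
    ds$annotations,
    data.frame(variation_name = variation_name,
               phenotype_description = phenotype_description,
               risk_allele = risk_allele, p_value = p_value,
               study_source = study_source, stringsAsFactors = FALSE))
  ds
}

#' Add population allele or genotype frequencies
#'
#' @param ds a `vk_dataset`.
#' @param freqs data frame with columns `population`, `variation_name`,
#'   `kind` (`"allele"` or `"genotype"`), `state`, `frequency` and optionally
#'   `sample_count`.
#' @param complete if `TRUE` (default) each (population, variation, kind)
#'   group in `freqs` is taken to be a complete frequency set and must sum to
#'   1 within 1e-6; a violation rejects the whole insert.
#' @return the updated dataset.
#' @export
add_frequencies <- function(ds, freqs, complete = TRUE) {
  stopifnot(inherits(ds, "vk_dataset"))
  need <- c("population", "variation_name", "kind", "state", "frequency")
  if (!all(need %in% names(freqs))) vk_stop("frequency table must have columns: ",
                                            paste(need, collapse = ", "))
  if (is.null(freqs$sample_count)) freqs$sample_count <- NA_integer_
  if (!all(freqs$kind %in% c("allele", "genotype")))
    vk_stop("frequency kind must be 'allele' or 'genotype'")
  if (any(freqs$frequency < 0 | freqs$frequency > 1))
    vk_stop("frequencies must lie in [0, 1]")
  if (complete && nrow(freqs)) {
    sums <- tapply(freqs$frequency,
                   paste(freqs$population, freqs$variation_name, freqs$kind),
                   sum)
    bad <- names(sums)[abs(sums - 1) > 1e-6]
    if (length(bad))
      vk_stop("complete frequency set does not sum to 1: ", bad[1])
  }
  freqs <- freqs[, names(vk_schemas()$frequencies)]
  freqs$sample_count <- as.integer(freqs$sample_count)
  ds$frequencies <- rbind(ds$frequencies, freqs)
  ds
}

#' Structural variants overlapping a slice
#'
#' Overlap is judged on the outer (widest) interval, so a query hitting only
#' the uncertain flank of an SV still returns it.
#'
#' @param ds a `vk_dataset`.
#' @param s a `vk_slice`.
#' @return the matching rows of the structural variation table.
#' @export
query_structural <- function(ds, s) {
  stopifnot(inherits(ds, "vk_dataset"), inherits(s, "vk_slice"))
  check_region(ds, s$region_name)
  sv <- ds$structural_variations
  hit <- sv$region_name == s$region_name &
    sv$outer_start <= s$end & sv$outer_end >= s$start
  out <- sv[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Search phenotype annotations
#'
#' Case-insensitive substring search over phenotype descriptions.
#'
#' @param ds a `vk_dataset`.
#' @param text non-empty query string.
#' @return the matching annotation rows (possibly none).
#' @export
query_phenotype <- function(ds, text) {
  stopifnot(inherits(ds, "vk_dataset"))
  assert_scalar_string(text, "query text")
  hit <- grepl(tolower(text), tolower(ds$annotations$phenotype_description),
               fixed = TRUE)
  out <- ds$annotations[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
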