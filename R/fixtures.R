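## Deterministic fixture generators: toy genomes, planted variants,
## random transcript models, and population genotypes simulated by random
## union of gametes from stated haplotype frequencies. Every generator is a
## pure function of its arguments (including the seed), and each returns the
## truth needed to compute expected downstream answers without re-simulation.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random toy genome
#'
#' Uniform random A/C/G/T, reproducible from the seed.
#'
#' @param lengths named integer vector: region name -> length in bp.
#' @param seed RNG seed.
#' @return named character vector of sequences.
#' @export
make_genome <- function(lengths, seed = 1L) {
  stopifnot(all(lengths >= 1L))
  if (is.null(names(lengths)))
    names(lengths) <- paste0("chr", seq_along(lengths))
  with_seed(seed, {
    vapply(lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
  })
}

#' Plant a variant's composite flank sequence into a genome
#'
#' Embeds `k` non-overlapping copies of a randomly generated
#' `flank_up + reference_allele + flank_down` composite at recorded
#' positions, overwriting the genome there. On request, copies are planted
#' as the reverse complement (placement recorded with strand -1).
#'
#' @param genome named character vector (single or multiple regions; copies
#'   go into the first region).
#' @param flank_len flank length in bp (each side).
#' @param k number of copies to plant.
#' @param alleles allele vector (reference allele first).
#' @param seed RNG seed.
#' @param strands vector of `+1`/`-1`, recycled to length `k`: the strand on
#'   which each copy is planted.
#' @return list with `genome` (modified), `flank_up`, `flank_down`, and
#'   `truth`: data frame (`region_name`, `start`, `end`, `strand`) giving
#'   each planted allele's location.
#' @export
plant_variant <- function(genome, flank_len = 20L, k = 1L,
                          alleles = c("A", "G"), seed = 1L, strands = 1L) {
  region <- names(genome)[1]
  seq <- genome[[region]]
  ref_allele <- alleles[1]
  allele_seq <- if (ref_allele == "-") "" else ref_allele
  strands <- rep_len(as.integer(strands), k)
  with_seed(seed, {
    up <- paste(sample(c("A", "C", "G", "T"), flank_len, replace = TRUE),
                collapse = "")
    down <- paste(sample(c("A", "C", "G", "T"), flank_len, replace = TRUE),
                  collapse = "")
    composite <- paste0(up, allele_seq, down)
    L <- nchar(composite)
    if (nchar(seq) < k * (L + 1L))
      vk_stop("genome too short to plant ", k, " non-overlapping copies")
    ## choose k non-overlapping start positions
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < k) {
      tries <- tries + 1L
      if (tries > 10000L) vk_stop("cannot place ", k, " copies without overlap")
      cand <- sample.int(nchar(seq) - L + 1L, 1L)
      if (!any(abs(cand - starts) < L)) starts <- c(starts, cand)
    }
    starts <- sort(starts)
    truth <- data.frame(region_name = region, start = integer(k),
                        end = integer(k), strand = strands,
                        stringsAsFactors = FALSE)
    for (i in seq_len(k)) {
      p <- starts[i]
      planted <- if (strands[i] == 1L) composite else revcomp(composite)
      substr(seq, p, p + L - 1L) <- planted
      if (strands[i] == 1L) {
        a_start <- p + flank_len
      } else {
        a_start <- p + flank_len  # symmetric flanks: allele centred either way
      }
      truth$start[i] <- a_start
      truth$end[i] <- a_start + nchar(allele_seq) - 1L
    }
    genome[[region]] <- seq
    list(genome = genome, flank_up = up, flank_down = down, truth = truth)
  })
}

#' Generate a random transcript model on a toy genome
#'
#' Builds a protein-coding transcript with `n_exons` non-overlapping exons
#' and a CDS whose length is a multiple of 3, suitable for consequence-rule
#' testing on either strand.
#'
#' @param region_name region the transcript lives on.
#' @param region_length length of that region.
#' @param strand `+1` or `-1`.
#' @param n_exons number of exons.
#' @param seed RNG seed.
#' @param name transcript name.
#' @return a `vk_transcript`.
#' @export
random_transcript <- function(region_name, region_length, strand = 1L,
                              n_exons = 3L, seed = 1L, name = "tx1") {
  with_seed(seed, {
    for (attempt in 1:200) {
      exon_lens <- sample(30:120, n_exons, replace = TRUE)
      intron_lens <- if (n_exons > 1L) sample(25:200, n_exons - 1L, replace = TRUE)
      else integer(0)
      total <- sum(exon_lens) + sum(intron_lens)
      if (total + 20L >= region_length) next
      tx_start <- sample.int(region_length - total - 10L, 1L) + 5L
      starts <- integer(n_exons); ends <- integer(n_exons)
      cur <- tx_start
      for (i in seq_len(n_exons)) {
        starts[i] <- cur
        ends[i] <- cur + exon_lens[i] - 1L
        if (i < n_exons) cur <- ends[i] + intron_lens[i] + 1L
      }
      ## pick CDS bounds inside the exon union with total length %% 3 == 0
      exonic <- unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))
      if (length(exonic) < 24L) next
      lo_i <- sample.int(length(exonic) %/% 3L, 1L)
      hi_i <- length(exonic) - sample.int(length(exonic) %/% 3L, 1L)
      cds_len <- hi_i - lo_i + 1L
      hi_i <- hi_i - (cds_len %% 3L)
      if (hi_i - lo_i + 1L < 6L) next
      tx <- transcript_model(name, region_name, strand,
                             data.frame(start = starts, end = ends),
                             cds_start = exonic[lo_i], cds_end = exonic[hi_i],
                             biotype = "protein_coding")
      return(tx)
    }
    vk_stop("could not generate a transcript for these parameters")
  })
}

#' Simulate unphased population genotypes from known haplotype frequencies
#'
#' Each individual receives two haplotypes drawn i.i.d. from the stated
#' two-locus haplotype frequencies (random union of gametes; Hardy-Weinberg
#' at the haplotype level, matching the EM's likelihood). The unphased
#' genotypes and the truth are both returned.
#'
#' @param n_individuals number of individuals.
#' @param hap_freqs numeric length-4 vector `(p_AB, p_Ab, p_aB, p_ab)`
#'   summing to 1.
#' @param positions length-2 integer vector: genomic positions of the loci.
#' @param alleles1,alleles2 length-2 character vectors `(A, a)` and `(B, b)`:
#'   the allele spellings at each locus.
#' @param region_name region label.
#' @param seed RNG seed.
#' @param individual_prefix prefix for generated individual names.
#' @return list with `genotypes` (data frame ready for [store_genotypes()])
#'   and `truth` (the input frequencies plus realised haplotype counts).
#' @export
simulate_genotypes <- function(n_individuals, hap_freqs = c(.25, .25, .25, .25),
                               positions = c(1000L, 2000L),
                               alleles1 = c("A", "C"), alleles2 = c("G", "T"),
                               region_name = "chr1", seed = 1L,
                               individual_prefix = "ind") {
  if (abs(sum(hap_freqs) - 1) > 1e-9)
    vk_stop("haplotype frequencies must sum to 1")
  haps <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))  # (locus1, locus2) allele index
  with_seed(seed, {
    draws <- sample.int(4L, 2L * n_individuals, replace = TRUE,
                        prob = hap_freqs)
    h1 <- haps[draws[seq_len(n_individuals)], , drop = FALSE]
    h2 <- haps[draws[n_individuals + seq_len(n_individuals)], , drop = FALSE]
    inds <- sprintf("%s%04d", individual_prefix, seq_len(n_individuals))
    genotypes <- rbind(
      data.frame(individual_name = inds, region_name = region_name,
                 position = positions[1],
                 allele1 = alleles1[h1[, 1]], allele2 = alleles1[h2[, 1]],
                 stringsAsFactors = FALSE),
      data.frame(individual_name = inds, region_name = region_name,
                 position = positions[2],
                 allele1 = alleles2[h1[, 2]], allele2 = alleles2[h2[, 2]],
                 stringsAsFactors = FALSE))
    counts <- tabulate(draws, nbins = 4L)
    list(genotypes = genotypes,
         truth = list(hap_freqs = hap_freqs,
                      realised_freqs = counts / (2 * n_individuals),
                      n_individuals = n_individuals,
                      positions = positions))
  })
}

#' Write a full fixture dataset to disk
#'
#' Generates a toy genome, a planted variant, a transcript, simulated
#' genotypes, and writes FASTA + GFF3 + VCF + a truth JSON — the substrate
#' for command-line runs.
#'
#' @param out_dir output directory.
#' @param seed RNG seed controlling everything.
#' @param genome_length toy genome length in bp.
#' @param n_individuals simulated individuals.
#' @return `out_dir`, invisibly; files `reference.fa`, `genes.gff3`,
#'   `variants.vcf`, `truth.json`.
#' @export
write_fixture_set <- function(out_dir, seed = 1L, genome_length = 50000L,
                              n_individuals = 20L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- make_genome(c(chr1 = genome_length), seed = seed)
  tx <- random_transcript("chr1", genome_length, strand = 1L, seed = seed + 1L)
  sim <- simulate_genotypes(n_individuals, hap_freqs = c(.4, .1, .1, .4),
                            positions = c(1000L, 2500L), seed = seed + 2L)
  ## make the loci's reference bases agree with the simulated A/G spellings
  for (i in 1:2)
    substr(genome[["chr1"]], sim$truth$positions[i], sim$truth$positions[i]) <-
      c("A", "G")[i]
  write_fasta(genome, file.path(out_dir, "reference.fa"))

  ## GFF3 for the transcript
  ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
  strand_chr <- if (tx$strand == 1L) "+" else "-"
  gff <- c("##gff-version 3",
           sprintf("chr1\tvarkit\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s",
                   min(ex$start), max(ex$end), strand_chr, tx$name),
           sprintf("chr1\tvarkit\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                   ex$start, ex$end, strand_chr, tx$name),
           sprintf("chr1\tvarkit\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                   tx$cds_start, tx$cds_end, strand_chr, tx$name))
  writeLines(gff, file.path(out_dir, "genes.gff3"))

  ## VCF holding the two simulated loci
  ref_alleles <- c("A", "G"); alt_alleles <- c("C", "T")
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT",
                     unique(sim$genotypes$individual_name)), collapse = "\t"))
  for (i in 1:2) {
    p <- sim$truth$positions[i]
    g <- sim$genotypes[sim$genotypes$position == p, , drop = FALSE]
    gt <- vapply(seq_len(nrow(g)), function(k) {
      idx <- c(match(g$allele1[k], c(ref_alleles[i], alt_alleles[i])),
               match(g$allele2[k], c(ref_alleles[i], alt_alleles[i]))) - 1L
      paste0(idx[1], "/", idx[2])
    }, character(1))
    lines <- c(lines, paste(c("chr1", p, sprintf("rsfix%d", i),
                              ref_alleles[i], alt_alleles[i], ".", ".", ".",
                              "GT", gt), collapse = "\t"))
  }
  writeLines(lines, file.path(out_dir, "variants.vcf"))
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
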