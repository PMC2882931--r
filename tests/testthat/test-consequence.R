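## 30 bp toy chromosome with a forward CDS at 11-19 coding ATG TGG TAA
toy_coding_ds <- function() {
  ref <- paste0(strrep("A", 10), "ATGTGGTAA", strrep("C", 11))
  ds <- new_dataset(c(chr1 = ref))
  tx <- transcript_model("t1", "chr1", 1L, data.frame(start = 5L, end = 25L),
                         cds_start = 11L, cds_end = 19L)
  add_transcript(ds, tx)
}

test_that("coding substitutions translate to the expected consequence classes", {
  ds <- toy_coding_ds()
  tx <- ds$transcripts[[1]]
  stop_gain <- classify(ds, "chr1", 15, 15, "G", "A", tx)
  expect_equal(stop_gain$most_severe, "STOP_GAINED")
  expect_equal(stop_gain$codon_change, "TGG>TAG")
  expect_equal(stop_gain$peptide_change, "W/*")
  expect_equal(stop_gain$protein_position, 2L)

  stop_lost <- classify(ds, "chr1", 18, 18, "A", "C", tx)  # TAA -> TCA
  expect_equal(stop_lost$most_severe, "STOP_LOST")

  syn <- classify(ds, "chr1", 19, 19, "A", "G", tx)        # TAA -> TAG
  expect_equal(syn$most_severe, "SYNONYMOUS_CODING")

  nsyn <- classify(ds, "chr1", 14, 14, "T", "C", tx)       # TGG -> CGG, W/R
  expect_equal(nsyn$most_severe, "NON_SYNONYMOUS_CODING")
  expect_equal(nsyn$peptide_change, "W/R")
})

test_that("indels in the CDS are frameshift unless in frame", {
  ds <- toy_coding_ds()
  tx <- ds$transcripts[[1]]
  expect_equal(classify(ds, "chr1", 14, 14, "T", "-", tx)$most_severe,
               "FRAMESHIFT_CODING")
  ## insertion of one base between 14 and 15 (start = end + 1)
  expect_equal(classify(ds, "chr1", 15, 14, "-", "T", tx)$most_severe,
               "FRAMESHIFT_CODING")
  ## in-frame deletion of a whole codon alters the peptide, not the frame
  expect_equal(classify(ds, "chr1", 14, 16, "GTG", "-", tx)$most_severe,
               "NON_SYNONYMOUS_CODING")
})

test_that("location rules: UTRs, intergenic, up/downstream, non-coding", {
  ds <- toy_coding_ds()
  tx <- ds$transcripts[[1]]
  expect_equal(classify(ds, "chr1", 7, 7, "A", "G", tx)$most_severe, "5PRIME_UTR")
  expect_equal(classify(ds, "chr1", 22, 22, "C", "G", tx)$most_severe, "3PRIME_UTR")
  expect_equal(classify(ds, "chr1", 2, 2, "A", "G", tx)$most_severe, "UPSTREAM")
  expect_equal(classify(ds, "chr1", 28, 28, "C", "G", tx)$most_severe, "DOWNSTREAM")

  ## beyond 5 kb there is no transcript context at all
  big <- new_dataset(c(chr1 = strrep("A", 20000)))
  tx2 <- transcript_model("t2", "chr1", 1L, data.frame(start = 100L, end = 400L),
                          cds_start = 150L, cds_end = 350L)
  big <- add_transcript(big, tx2)
  expect_equal(classify(big, "chr1", 10400, 10400, "A", "G", tx2)$types,
               "INTERGENIC")
  expect_equal(predict_novel(big, "chr1", 10400, 10400, "A", "G")[[1]]$types,
               "INTERGENIC")

  ## a reverse-strand transcript swaps the flanking labels
  rev_tx <- transcript_model("t3", "chr1", -1L,
                             data.frame(start = 100L, end = 400L),
                             cds_start = 150L, cds_end = 350L)
  expect_equal(classify(big, "chr1", 50, 50, "A", "G", rev_tx)$most_severe,
               "DOWNSTREAM")
  expect_equal(classify(big, "chr1", 500, 500, "A", "G", rev_tx)$most_severe,
               "UPSTREAM")

  nc <- transcript_model("nc1", "chr1", 1L, data.frame(start = 100L, end = 400L),
                         biotype = "non_coding")
  expect_equal(classify(big, "chr1", 200, 200, "A", "G", nc)$most_severe,
               "WITHIN_NON_CODING_GENE")
})

test_that("splice-site windows follow the declared intronic/exonic offsets", {
  ds <- new_dataset(c(chr1 = make_genome(c(chr1 = 1000L), seed = 8)[[1]]))
  tx <- transcript_model("t1", "chr1", 1L,
                         data.frame(start = c(101L, 301L), end = c(200L, 400L)),
                         cds_start = 121L, cds_end = 380L)
  ds <- add_transcript(ds, tx)
  ref_at <- function(p) substr(ds$reference[["chr1"]], p, p)
  alt_at <- function(p) setdiff(c("A", "C", "G", "T"), ref_at(p))[1]
  type_at <- function(p) classify(ds, "chr1", p, p, ref_at(p), alt_at(p), tx)$types
  ## intron is 201..300; offsets 1-2 essential, 3-8 splice region
  expect_true("ESSENTIAL_SPLICE_SITE" %in% type_at(201))
  expect_true("ESSENTIAL_SPLICE_SITE" %in% type_at(202))
  expect_true("ESSENTIAL_SPLICE_SITE" %in% type_at(299))
  expect_true("ESSENTIAL_SPLICE_SITE" %in% type_at(300))
  expect_true("SPLICE_SITE" %in% type_at(203))
  expect_true("SPLICE_SITE" %in% type_at(208))
  expect_true("SPLICE_SITE" %in% type_at(293))
  expect_equal(type_at(250), "INTRONIC")
  expect_false("INTRONIC" %in% type_at(205))
  ## exonic 3 bp at the junction keep their coding type alongside SPLICE_SITE
  t198 <- type_at(198)
  expect_true("SPLICE_SITE" %in% t198)
  expect_true(any(c("SYNONYMOUS_CODING", "NON_SYNONYMOUS_CODING",
                    "STOP_GAINED", "STOP_LOST") %in% t198))
  expect_false("SPLICE_SITE" %in% type_at(197))
})

test_that("regulatory overlap adds REGULATORY_REGION", {
  ds <- toy_coding_ds()
  reg <- data.frame(region_name = "chr1", start = 1L, end = 30L)
  cl <- classify(ds, "chr1", 15, 15, "G", "A", ds$transcripts[[1]],
                 regulatory = reg)
  expect_setequal(cl$types, c("STOP_GAINED", "REGULATORY_REGION"))
  expect_equal(cl$most_severe, "STOP_GAINED")
  ## intergenic + regulatory: the regulatory call stands alone
  far <- new_dataset(c(chr1 = strrep("A", 20000)))
  cl2 <- classify(far, "chr1", 10000, 10000, "A", "G", NULL,
                  regulatory = data.frame(region_name = "chr1",
                                          start = 9000L, end = 11000L))
  expect_equal(cl2$types, "REGULATORY_REGION")
})

test_that("novel predictions cover every nearby transcript, sorted by severity", {
  ds <- toy_coding_ds()
  tx2 <- transcript_model("t2", "chr1", 1L, data.frame(start = 10L, end = 28L),
                          biotype = "non_coding")
  ds <- add_transcript(ds, tx2)
  calls <- predict_novel(ds, "chr1", 15, 15, "G", "A")
  expect_length(calls, 2)
  expect_equal(calls[[1]]$transcript_name, "t1")   # STOP_GAINED outranks
  expect_equal(calls[[1]]$most_severe, "STOP_GAINED")
  expect_equal(calls[[2]]$most_severe, "WITHIN_NON_CODING_GENE")

  ## novel and stored paths agree
  stored <- classify(ds, "chr1", 15, 15, "G", "A", ds$transcripts[[1]],
                     variation_name = "rs1")
  expect_equal(calls[[1]]$types, stored$types)
})

test_that("every variant gets >= 1 type and INTERGENIC never co-occurs", {
  set.seed(33)
  genome <- make_genome(c(chr1 = 4000L), seed = 44)
  ds <- new_dataset(genome)
  tx <- random_transcript("chr1", 4000L, strand = 1L, seed = 45)
  ds <- add_transcript(ds, tx)
  for (rep in 1:100) {
    p <- sample.int(4000L, 1)
    ref <- substr(genome[[1]], p, p)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    cl <- classify(ds, "chr1", p, p, ref, alt, tx)
    expect_gte(length(cl$types), 1)
    if ("INTERGENIC" %in% cl$types) expect_length(cl$types, 1)
    expect_equal(cl$most_severe,
                 CONSEQUENCE_TYPES[min(match(cl$types, CONSEQUENCE_TYPES))])
  }
})

test_that("coding calls agree with the translate-and-diff oracle on random SNPs", {
  set.seed(606)
  n_checked <- 0L
  rep <- 0L
  while (n_checked < 250L) {
    rep <- rep + 1L
    strand <- if (rep %% 2 == 0) 1L else -1L
    genome <- make_genome(c(chr1 = 3000L), seed = 7000 + rep)
    tx <- random_transcript("chr1", 3000L, strand = strand,
                            seed = 8000 + rep, n_exons = sample(1:4, 1))
    ds <- new_dataset(genome)
    cds_pos <- varkit:::tx_cds_positions(tx)
    if (length(cds_pos) %% 3 != 0) next
    for (p in sample(cds_pos, min(5, length(cds_pos)))) {
      ref <- substr(genome[[1]], p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      got <- classify(ds, "chr1", p, p, ref, alt, tx)
      coding_types <- intersect(got$types,
                                c("STOP_GAINED", "STOP_LOST",
                                  "SYNONYMOUS_CODING", "NON_SYNONYMOUS_CODING"))
      expect_length(coding_types, 1)
      want <- oracle_coding_snp(ds$reference, tx, p, alt)
      expect_equal(coding_types, want,
                   label = sprintf("pos %d strand %d rep %d", p, strand, rep))
      n_checked <- n_checked + 1L
    }
  }
})

test_that("consequences are invariant under mirroring the genome", {
  ## reverse-complement the genome and all annotations; calls must agree
  set.seed(77)
  L <- 2000L
  genome <- make_genome(c(chr1 = L), seed = 123)
  tx <- random_transcript("chr1", L, strand = 1L, seed = 124, n_exons = 2L)
  ds <- new_dataset(genome)

  mirror_pos <- function(p) L - p + 1L
  genome_m <- c(chr1 = revcomp(genome[[1]]))
  tx_m <- transcript_model(tx$name, "chr1", -1L,
                           data.frame(start = mirror_pos(tx$exons$end),
                                      end = mirror_pos(tx$exons$start)),
                           cds_start = mirror_pos(tx$cds_end),
                           cds_end = mirror_pos(tx$cds_start))
  ds_m <- new_dataset(genome_m)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (rep in 1:60) {
    p <- sample.int(L, 1)
    ref <- substr(genome[[1]], p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    a <- classify(ds, "chr1", p, p, ref, alt, tx)
    b <- classify(ds_m, "chr1", mirror_pos(p), mirror_pos(p),
                  comp[[ref]], comp[[alt]], tx_m)
    expect_setequal(a$types, b$types)
  }
})
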