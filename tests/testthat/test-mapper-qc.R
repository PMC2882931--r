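planted_dataset <- function(k, seed = 1L, alleles = c("A", "G"),
                            strands = 1L, genome_len = 20000L,
                            whitelisted = FALSE) {
  genome <- make_genome(c(chr1 = genome_len), seed = seed)
  pv <- plant_variant(genome, flank_len = 20L, k = k, alleles = alleles,
                      seed = seed + 100L, strands = strands)
  ds <- new_dataset(pv$genome)
  ds <- add_variation(ds, "rs1", alleles, pv$flank_up, pv$flank_down,
                      whitelisted = whitelisted)
  list(ds = ds, truth = pv$truth)
}

test_that("map_flanks finds planted composites at their true positions", {
  px <- planted_dataset(1, seed = 2)
  hits <- map_flanks(px$ds, "rs1")
  expect_equal(hits$start, px$truth$start)
  expect_equal(hits$end, px$truth$end)
  expect_equal(hits$strand, 1L)

  px3 <- planted_dataset(3, seed = 3)
  hits3 <- map_flanks(px3$ds, "rs1")
  expect_equal(nrow(hits3), 3)
  expect_equal(sort(hits3$start), sort(px3$truth$start))
  ## hits are sorted by (region, start)
  expect_equal(hits3$start, sort(hits3$start))
})

test_that("a composite planted only as its reverse complement maps on strand -1", {
  px <- planted_dataset(1, seed = 5, strands = -1L)
  hits <- map_flanks(px$ds, "rs1")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, -1L)
  expect_equal(hits$start, px$truth$start)
  ## oracle: the reverse complement of the composite occurs at the hit
  v <- px$ds$variations[1, ]
  comp <- paste0(v$flank_up_seq, "A", v$flank_down_seq)
  seg <- substr(px$ds$reference[["chr1"]], hits$start - 20L, hits$end + 20L)
  expect_equal(seg, revcomp(comp))
})

test_that("mapping requires flanks and respects the minimum flank length", {
  ds <- new_dataset(c(chr1 = strrep("ACGT", 50)))
  ds <- add_variation(ds, "short", c("A", "G"), "ACGT", "ACGT")
  expect_error(map_flanks(ds, "short"), "flank_min_len")
  expect_silent(map_flanks(ds, "short", qc_config(flank_min_len = 4L)))
})

test_that("QC retains <= N mappings and fails the variant beyond N", {
  ## 3 hits, N = 3: retained, 3 features, each map_weight 3
  px <- planted_dataset(3, seed = 11)
  ds <- apply_qc(px$ds, "rs1", map_flanks(px$ds, "rs1"))
  out <- attr(ds, "qc_outcome")
  expect_equal(out$status, "retained")
  feats <- ds$variation_features
  expect_equal(nrow(feats), 3)
  expect_true(all(feats$map_weight == 3L))

  ## 4 hits, N = 3: failed TOO_MANY_MAPPINGS, no features
  px4 <- planted_dataset(4, seed = 12)
  ds4 <- apply_qc(px4$ds, "rs1", map_flanks(px4$ds, "rs1"))
  expect_equal(attr(ds4, "qc_outcome")$failed_reason, "TOO_MANY_MAPPINGS")
  expect_equal(nrow(ds4$variation_features), 0)
  expect_equal(ds4$variations$failed_reason[1], "TOO_MANY_MAPPINGS")

  ## no hits: NO_MAPPING
  ds0 <- new_dataset(make_genome(c(chr1 = 2000L), seed = 1))
  ds0 <- add_variation(ds0, "ghost", c("A", "G"), strrep("A", 25), strrep("C", 25))
  ds0 <- apply_qc(ds0, "ghost", map_flanks(ds0, "ghost"))
  expect_equal(attr(ds0, "qc_outcome")$failed_reason, "NO_MAPPING")
})

test_that("declared reference allele must match the genome unless whitelisted", {
  ds <- new_dataset(c(chr1 = paste0(strrep("ACGT", 20), "T", strrep("GGCA", 20))))
  ds <- add_variation(ds, "rs1", c("A", "G"), strrep("A", 20), strrep("C", 20))
  hit <- data.frame(region_name = "chr1", start = 81L, end = 81L, strand = 1L)
  ds1 <- apply_qc(ds, "rs1", hit)   # genome has T, declared ref is A
  expect_equal(attr(ds1, "qc_outcome")$failed_reason, "ALLELE_MISMATCH")

  dsw <- new_dataset(ds$reference)
  dsw <- add_variation(dsw, "rs1", c("A", "G"), strrep("A", 20), strrep("C", 20),
                       whitelisted = TRUE)
  dsw <- apply_qc(dsw, "rs1", hit)
  expect_equal(attr(dsw, "qc_outcome")$status, "retained")
  expect_true(is.na(dsw$variations$failed_reason[1]))
})

test_that("whitelisted variants over the cap keep N features but true map_weight", {
  px <- planted_dataset(5, seed = 13, whitelisted = TRUE)
  ds <- apply_qc(px$ds, "rs1", map_flanks(px$ds, "rs1"))
  expect_equal(attr(ds, "qc_outcome")$status, "retained")
  feats <- ds$variation_features
  expect_equal(nrow(feats), 3)                   # N leftmost kept
  expect_true(all(feats$map_weight == 5L))       # truth preserved
  expect_equal(feats$start, sort(px$truth$start)[1:3])
})

test_that("retention matches brute-force occurrence counting for k = 1..5", {
  cfg <- qc_config()
  for (k in 1:5) {
    px <- planted_dataset(k, seed = 20 + k)
    hits <- map_flanks(px$ds, "rs1")
    v <- px$ds$variations[1, ]
    comp <- paste0(v$flank_up_seq, "A", v$flank_down_seq)
    expect_equal(nrow(hits),
                 oracle_count_occurrences(px$ds$reference[["chr1"]], comp))
    ds <- apply_qc(px$ds, "rs1", hits)
    retained <- attr(ds, "qc_outcome")$status == "retained"
    expect_equal(retained, k <= cfg$max_mappings)
    if (retained) {
      expect_equal(nrow(ds$variation_features), k)
      expect_true(all(ds$variation_features$map_weight == k))
    }
  }
})

test_that("reverse-strand features carry forward-strand allele strings", {
  px <- planted_dataset(1, seed = 31, alleles = c("A", "G"), strands = -1L)
  ds <- apply_qc(px$ds, "rs1", map_flanks(px$ds, "rs1"))
  f <- ds$variation_features[1, ]
  expect_equal(f$strand, -1L)
  expect_equal(f$allele_string, "T/C")   # reverse complement of A/G
  ## the genome's forward base at the feature is the forward-strand ref allele
  expect_equal(substr(ds$reference[["chr1"]], f$start, f$end), "T")
})

test_that("purge_failed strips everything but the tombstone and is idempotent", {
  ds <- new_dataset(c(chr1 = strrep("ACGT", 100)))
  ds <- add_individual(ds, "ind1")
  ds <- add_variation(ds, "bad", c("A", "G"), strrep("A", 20), strrep("C", 20))
  ds$variations$failed_reason[1] <- "ALLELE_MISMATCH"
  ds$variation_features <- rbind(ds$variation_features, data.frame(
    variation_name = "bad", region_name = "chr1", start = 50L, end = 50L,
    strand = 1L, allele_string = "A/G", map_weight = 1L))
  ds <- store_genotypes(ds, data.frame(
    individual_name = "ind1", region_name = "chr1", position = 50L,
    allele1 = "A", allele2 = "G"))
  ds <- store_genotypes(ds, data.frame(
    individual_name = "ind1", region_name = "chr1", position = 50L,
    allele1 = "AT", allele2 = "A"), multi_bp = TRUE)
  ds <- add_frequencies(ds, data.frame(population = "P", variation_name = "bad",
                                       kind = "allele", state = c("A", "G"),
                                       frequency = c(.5, .5)))
  ds <- add_annotation(ds, "bad", "some phenotype")

  ds2 <- purge_failed(ds)
  cts <- attr(ds2, "purge_counts")
  expect_equal(unname(cts["features"]), 1L)
  expect_equal(unname(cts["genotypes"]), 2L)
  expect_equal(unname(cts["frequencies"]), 2L)
  expect_equal(unname(cts["annotations"]), 1L)
  ## tombstone: name + source + reason survive, nothing else references it
  expect_equal(ds2$variations$failed_reason[1], "ALLELE_MISMATCH")
  expect_equal(ds2$variations$alleles[1], "")
  expect_false("bad" %in% ds2$variation_features$variation_name)
  expect_false("bad" %in% ds2$frequencies$variation_name)
  expect_false("bad" %in% ds2$annotations$variation_name)
  expect_equal(nrow(ds2$multi_bp_genotypes), 0)
  expect_equal(nrow(ds2$genotype_rows), 0)

  ds3 <- purge_failed(ds2)
  expect_true(all(attr(ds3, "purge_counts") == 0L))

  ## a dataset with no failures purges nothing
  clean <- purge_failed(new_dataset(c(chr1 = "ACGT")))
  expect_true(all(attr(clean, "purge_counts") == 0L))
})

test_that("flanks compress to coordinates only when they match the reference", {
  px <- planted_dataset(1, seed = 41)
  ds <- apply_qc(px$ds, "rs1", map_flanks(px$ds, "rs1"))
  f <- ds$variation_features[1, ]
  fr <- compress_flank(ds, "rs1", "up")
  expect_null(fr$raw_seq)
  expect_equal(fr$start, f$start - 20L)
  expect_equal(fr$end, f$start - 1L)
  expect_equal(fr$strand, 1L)
  expect_equal(restore_flank(ds, fr), ds$variations$flank_up_seq[1])

  ## a flank differing from the reference by one base stays raw
  orig <- ds$variations$flank_up_seq[1]
  other <- setdiff(c("A", "C", "G", "T"), substr(orig, 1, 1))[1]
  substr(ds$variations$flank_up_seq[1], 1, 1) <- other
  fr2 <- compress_flank(ds, "rs1", "up")
  expect_false(is.null(fr2$raw_seq))
  expect_equal(restore_flank(ds, fr2), ds$variations$flank_up_seq[1])
})

test_that("reverse-strand flank compression records strand -1 and round-trips", {
  px <- planted_dataset(1, seed = 43, strands = -1L)
  ds <- apply_qc(px$ds, "rs1", map_flanks(px$ds, "rs1"))
  up_raw <- ds$variations$flank_up_seq[1]
  down_raw <- ds$variations$flank_down_seq[1]
  f <- ds$variation_features[1, ]
  fr_up <- compress_flank(ds, "rs1", "up")
  expect_null(fr_up$raw_seq)
  expect_equal(fr_up$strand, -1L)
  ## the 5' flank of a reverse-strand variant sits genomically 3' of it
  expect_equal(fr_up$start, f$end + 1L)
  expect_equal(restore_flank(ds, fr_up), up_raw)
  fr_down <- compress_flank(ds, "rs1", "down")
  expect_equal(restore_flank(ds, fr_down), down_raw)

  ds <- compress_flanks(ds, "rs1")
  expect_true(is.na(ds$variations$flank_up_seq[1]))
  expect_equal(restore_flank(ds, name = "rs1", which = "up"), up_raw)
  expect_equal(restore_flank(ds, name = "rs1", which = "down"), down_raw)
})

test_that("restore(compress(.)) is the identity on planted variants, both strands", {
  set.seed(99)
  for (rep in 1:40) {
    strand <- sample(c(1L, -1L), 1)
    px <- planted_dataset(1, seed = 500 + rep, strands = strand)
    up <- px$ds$variations$flank_up_seq[1]
    down <- px$ds$variations$flank_down_seq[1]
    ds <- apply_qc(px$ds, "rs1", map_flanks(px$ds, "rs1"))
    ds <- compress_flanks(ds, "rs1")
    expect_true(is.na(ds$variations$flank_up_seq[1]))   # planted => compressible
    expect_identical(restore_flank(ds, name = "rs1", which = "up"), up)
    expect_identical(restore_flank(ds, name = "rs1", which = "down"), down)
  }
})
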