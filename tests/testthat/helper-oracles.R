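## Independent oracles used by the tests. Each is deliberately written
## against the *definition* of the quantity, not the package's code path.

## -- reference ULEB128 reader (big-loop, byte-at-a-time) ---------------------
oracle_read_uleb128_stream <- function(bytes) {
  vals <- integer(0)
  acc <- 0; mult <- 1
  for (b in as.integer(bytes)) {
    acc <- acc + (b %% 128L) * mult
    if (b >= 128L) {
      mult <- mult * 128
    } else {
      vals <- c(vals, acc)
      acc <- 0; mult <- 1
    }
  }
  vals
}

## decode a genotype blob by its published layout, independent of the codec
oracle_decode_blob <- function(blob, start) {
  pos <- integer(0); a1 <- character(0); a2 <- character(0)
  i <- 1L; cur <- start; first <- TRUE
  while (i <= length(blob)) {
    if (!first) {
      d <- 0; mult <- 1
      repeat {
        b <- as.integer(blob[i]); i <- i + 1L
        d <- d + (b %% 128L) * mult
        if (b < 128L) break
        mult <- mult * 128
      }
      cur <- cur + d
    }
    first <- FALSE
    pair <- rawToChar(blob[i:(i + 1L)]); i <- i + 2L
    pos <- c(pos, cur)
    a1 <- c(a1, substr(pair, 1, 1)); a2 <- c(a2, substr(pair, 2, 2))
  }
  data.frame(position = pos, allele1 = a1, allele2 = a2,
             stringsAsFactors = FALSE)
}

## -- two-locus likelihood grid search ---------------------------------------
## log-likelihood of the 3x3 genotype table under haplotype freqs
two_locus_loglik <- function(n, p_AB, p_Ab, p_aB, p_ab) {
  ## clamp float dust at the boundary of the admissible region
  p_AB <- max(p_AB, 0); p_Ab <- max(p_Ab, 0)
  p_aB <- max(p_aB, 0); p_ab <- max(p_ab, 0)
  P <- matrix(0, 3, 3)
  P[3, 3] <- p_AB^2;            P[3, 2] <- 2 * p_AB * p_Ab;  P[3, 1] <- p_Ab^2
  P[2, 3] <- 2 * p_AB * p_aB;   P[1, 3] <- p_aB^2
  P[2, 2] <- 2 * (p_AB * p_ab + p_Ab * p_aB)
  P[2, 1] <- 2 * p_Ab * p_ab;   P[1, 2] <- 2 * p_aB * p_ab;  P[1, 1] <- p_ab^2
  sum(n[n > 0] * log(P[n > 0]))
}

## maximise the likelihood over p_AB on a grid, holding the (sample) allele
## frequencies fixed — the stated independent check on the EM optimum
oracle_grid_p_AB <- function(tab, resolution = 1e-5) {
  n <- tab$n; n_total <- tab$n_total
  i <- 0:2
  p_A <- sum(n * i) / (2 * n_total)
  p_B <- sum(t(n) * i) / (2 * n_total)
  lo <- max(0, p_A + p_B - 1)
  hi <- min(p_A, p_B)
  g <- seq(lo, hi, by = resolution)
  AB <- pmax(g, 0); Ab <- pmax(p_A - g, 0)
  aB <- pmax(p_B - g, 0); ab <- pmax(1 - p_A - p_B + g, 0)
  term <- function(cnt, prob) if (cnt > 0) cnt * log(prob) else 0
  ll <- term(n[3, 3], AB^2) + term(n[3, 2], 2 * AB * Ab) + term(n[3, 1], Ab^2) +
    term(n[2, 3], 2 * AB * aB) + term(n[1, 3], aB^2) +
    term(n[2, 2], 2 * (AB * ab + Ab * aB)) +
    term(n[2, 1], 2 * Ab * ab) + term(n[1, 2], 2 * aB * ab) + term(n[1, 1], ab^2)
  g[which.max(ll)]
}

random_two_locus_table <- function() {
  ## draw genotypes from random haplotype freqs until both loci polymorphic
  repeat {
    f <- as.vector(stats::rgamma(4, 1)); f <- f / sum(f)
    n_ind <- sample(30:150, 1)
    draws <- sample.int(4L, 2L * n_ind, replace = TRUE, prob = f)
    hapA <- c(1L, 1L, 0L, 0L)[draws]  # carries allele A?
    hapB <- c(1L, 0L, 1L, 0L)[draws]
    iA <- hapA[seq_len(n_ind)] + hapA[n_ind + seq_len(n_ind)]
    iB <- hapB[seq_len(n_ind)] + hapB[n_ind + seq_len(n_ind)]
    n <- matrix(0L, 3, 3)
    for (k in seq_len(n_ind)) n[iA[k] + 1L, iB[k] + 1L] <- n[iA[k] + 1L, iB[k] + 1L] + 1L
    pA <- sum(iA) / (2 * n_ind); pB <- sum(iB) / (2 * n_ind)
    if (pA > 0 && pA < 1 && pB > 0 && pB < 1)
      return(structure(list(n = n, n_total = n_ind, allele_A = "A",
                            allele_B = "B"), class = "vk_two_locus"))
  }
}

## -- translate-and-diff consequence oracle ----------------------------------
## Rebuild the full mutant CDS, translate reference and mutant with
## Biostrings, and classify the coding effect from the peptide diff.
oracle_coding_snp <- function(reference, tx, gpos, alt_allele) {
  mut <- reference
  substr(mut[[tx$region_name]], gpos, gpos) <- alt_allele
  extract_cds <- function(ref) {
    ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
    pieces <- vapply(seq_len(nrow(ex)), function(i) {
      s <- max(ex$start[i], tx$cds_start); e <- min(ex$end[i], tx$cds_end)
      if (e < s) "" else substr(ref[[tx$region_name]], s, e)
    }, character(1))
    s <- paste(pieces, collapse = "")
    if (tx$strand == -1L)
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  translate_all <- function(s) {
    n <- (nchar(s) %/% 3) * 3
    as.character(Biostrings::translate(Biostrings::DNAString(substr(s, 1, n)),
                                       no.init.codon = TRUE))
  }
  pep_ref <- translate_all(extract_cds(reference))
  pep_alt <- translate_all(extract_cds(mut))
  if (pep_ref == pep_alt) return("SYNONYMOUS_CODING")
  d <- which(strsplit(pep_ref, "")[[1]] != strsplit(pep_alt, "")[[1]])
  ref_aa <- substr(pep_ref, d[1], d[1]); alt_aa <- substr(pep_alt, d[1], d[1])
  if (alt_aa == "*" && ref_aa != "*") "STOP_GAINED"
  else if (ref_aa == "*" && alt_aa != "*") "STOP_LOST"
  else "NON_SYNONYMOUS_CODING"
}

## -- brute force helpers -----------------------------------------------------
oracle_max_coverage_per_bp <- function(cov, individual, region, start, end) {
  lev <- integer(end - start + 1L)
  sel <- cov[cov$individual_name == individual & cov$region_name == region, ,
             drop = FALSE]
  for (k in seq_len(nrow(sel))) {
    lo <- max(sel$start[k], start); hi <- min(sel$end[k], end)
    if (lo > hi) next
    for (p in lo:hi)
      lev[p - start + 1L] <- max(lev[p - start + 1L], sel$level[k])
  }
  lev
}

oracle_count_occurrences <- function(subject, pattern) {
  ## brute-force overlapping occurrence count on both strands
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
  cnt <- 0L
  L <- nchar(pattern)
  for (p in seq_len(nchar(subject) - L + 1L)) {
    piece <- substr(subject, p, p + L - 1L)
    if (piece == pattern || piece == rc) cnt <- cnt + 1L
  }
  cnt
}

gt_df <- function(inds, a1, a2) {
  data.frame(individual_name = inds, allele1 = a1, allele2 = a2,
             stringsAsFactors = FALSE)
}

random_genotype_set <- function(n, region = "chr1", individual = "ind1",
                                window_start = 0L, window_size = 100000L) {
  pos <- sort(sample.int(window_size, n)) + window_start
  data.frame(individual_name = individual, region_name = region,
             position = pos,
             allele1 = sample(c("A", "C", "G", "T", "N"), n, replace = TRUE),
             allele2 = sample(c("A", "C", "G", "T", "N"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}
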