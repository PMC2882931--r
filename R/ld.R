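## On-the-fly pairwise linkage disequilibrium.
##
## Haplotype frequencies for a pair of biallelic loci are estimated from
## unphased genotypes with the standard EM algorithm: every genotype class
## except the double heterozygote has unambiguous phase; the double
## heterozygote is split between the coupling (AB/ab) and repulsion (Ab/aB)
## configurations in proportion to their current expected frequencies. From
## the converged frequencies the usual summaries D, D' and r^2 follow.

#' Two-locus genotype counts
#'
#' Builds the 3x3 table `n[i+1, j+1]` = number of individuals carrying `i`
#' copies of allele A at locus 1 and `j` copies of allele B at locus 2, where
#' A and B are the first-seen alleles at each locus. Individuals missing a
#' genotype at either locus are excluded pairwise.
#'
#' @param g1,g2 data frames with columns `individual_name`, `allele1`,
#'   `allele2` — the genotypes at locus 1 and locus 2.
#' @return a `vk_two_locus` list: `n` (3x3 integer matrix), `n_total`,
#'   `allele_A`, `allele_B`.
#' @export
count_two_locus <- function(g1, g2) {
  seen_alleles <- function(g) {
    al <- unique(as.vector(rbind(g$allele1, g$allele2)))
    al <- al[al != "N"]
    if (length(al) > 2L)
      vk_stop("more than two alleles at a locus; LD is biallelic only")
    al
  }
  g1 <- g1[g1$allele1 != "N" & g1$allele2 != "N", , drop = FALSE]
  g2 <- g2[g2$allele1 != "N" & g2$allele2 != "N", , drop = FALSE]
  a1 <- seen_alleles(g1); a2 <- seen_alleles(g2)
  if (!length(a1) || !length(a2)) vk_stop("no genotypes at one of the loci")
  A <- a1[1]; B <- a2[1]
  common <- intersect(g1$individual_name, g2$individual_name)
  n <- matrix(0L, 3, 3)
  i1 <- match(common, g1$individual_name)
  i2 <- match(common, g2$individual_name)
  ci <- (g1$allele1[i1] == A) + (g1$allele2[i1] == A)
  cj <- (g2$allele1[i2] == B) + (g2$allele2[i2] == B)
  for (k in seq_along(common))
    n[ci[k] + 1L, cj[k] + 1L] <- n[ci[k] + 1L, cj[k] + 1L] + 1L
  structure(list(n = n, n_total = length(common), allele_A = A, allele_B = B),
            class = "vk_two_locus")
}

two_locus_allele_freqs <- function(t) {
  i <- 0:2
  p_A <- sum(t$n * i) / (2 * t$n_total)          # row copies of A
  p_B <- sum(t(t$n) * i) / (2 * t$n_total)       # column copies of B
  c(p_A = p_A, p_B = p_B)
}

#' EM estimation of two-locus haplotype frequencies
#'
#' Starts from linkage equilibrium (`p_AB = p_A * p_B`) and iterates: the
#' E-step assigns each double heterozygote to the coupling phase with weight
#' `p_AB*p_ab / (p_AB*p_ab + p_Ab*p_aB)`; the M-step renormalises the
#' expected haplotype counts over `2 * n_total`. Iteration stops when the
#' largest frequency change drops below `tol`. Because the equilibrium start
#' is itself a stationary point when every individual is a double
#' heterozygote, that degenerate table converges immediately to D = 0.
#'
#' @param t a `vk_two_locus` table.
#' @param tol convergence tolerance on the haplotype frequencies (default
#'   1e-10).
#' @param max_iter iteration cap (default 1000).
#' @return list with `p_AB`, `p_Ab`, `p_aB`, `p_ab`, `iterations`,
#'   `converged`.
#' @export
em_haplotypes <- function(t, tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(t, "vk_two_locus"))
  if (t$n_total == 0L) vk_stop("empty two-locus table")
  pf <- two_locus_allele_freqs(t)
  p_A <- pf["p_A"]; p_B <- pf["p_B"]
  if (p_A <= 0 || p_A >= 1 || p_B <= 0 || p_B >= 1)
    vk_stop("LD undefined: a locus is monomorphic in the table",
            class = "vk_monomorphic_error")
  n <- t$n
  two_n <- 2 * t$n_total
  ## phase-known haplotype counts (every cell except the double heterozygote)
  base_AB <- 2 * n[3, 3] + n[3, 2] + n[2, 3]
  base_Ab <- 2 * n[3, 1] + n[3, 2] + n[2, 1]
  base_aB <- 2 * n[1, 3] + n[1, 2] + n[2, 3]
  base_ab <- 2 * n[1, 1] + n[1, 2] + n[2, 1]
  n_dh <- n[2, 2]

  p <- c(AB = unname(p_A * p_B), Ab = unname(p_A * (1 - p_B)),
         aB = unname((1 - p_A) * p_B), ab = unname((1 - p_A) * (1 - p_B)))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    coup <- unname(p["AB"] * p["ab"])
    rep_ <- unname(p["Ab"] * p["aB"])
    w <- if (coup + rep_ > 0) coup / (coup + rep_) else 0.5
    new_p <- c(AB = (base_AB + n_dh * w) / two_n,
               Ab = (base_Ab + n_dh * (1 - w)) / two_n,
               aB = (base_aB + n_dh * (1 - w)) / two_n,
               ab = (base_ab + n_dh * w) / two_n)
    delta <- max(abs(new_p - p))
    p <- new_p
    if (delta < tol) { converged <- TRUE; break }
  }
  list(p_AB = unname(p["AB"]), p_Ab = unname(p["Ab"]),
       p_aB = unname(p["aB"]), p_ab = unname(p["ab"]),
       iterations = iter, converged = converged)
}

#' D, D' and r-squared from haplotype frequencies
#'
#' `D = p_AB - p_A p_B`; `D'` is `|D|` scaled by its maximum attainable value
#' given the allele frequencies (0 when D = 0); `r^2 = D^2 / (p_A q_A p_B
#' q_B)`.
#'
#' @param p_AB,p_Ab,p_aB,p_ab haplotype frequencies (must sum to 1).
#' @return list with `p_A`, `p_B`, `D`, `D_prime`, `r2`.
#' @export
ld_stats <- function(p_AB, p_Ab, p_aB, p_ab) {
  tot <- p_AB + p_Ab + p_aB + p_ab
  if (abs(tot - 1) > 1e-6) vk_stop("haplotype frequencies must sum to 1")
  p_A <- p_AB + p_Ab
  p_B <- p_AB + p_aB
  if (p_A <= 0 || p_A >= 1 || p_B <= 0 || p_B >= 1)
    vk_stop("LD undefined for a monomorphic locus",
            class = "vk_monomorphic_error")
  D <- p_AB - p_A * p_B
  D_max <- if (D > 0) min(p_A * (1 - p_B), (1 - p_A) * p_B)
           else min(p_A * p_B, (1 - p_A) * (1 - p_B))
  D_prime <- if (D == 0) 0 else abs(D) / D_max
  r2 <- D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B))
  list(p_A = p_A, p_B = p_B, D = D, D_prime = D_prime, r2 = r2)
}

ld_single_pair <- function(g1, g2, tol = 1e-10, max_iter = 1000L) {
  t <- count_two_locus(g1, g2)
  em <- em_haplotypes(t, tol = tol, max_iter = max_iter)
  st <- ld_stats(em$p_AB, em$p_Ab, em$p_aB, em$p_ab)
  c(list(n_individuals = t$n_total, allele_A = t$allele_A,
         allele_B = t$allele_B), em, st)
}

#' Pairwise LD across a genomic slice
#'
#' Computes EM haplotype frequencies and D/D'/r^2 for every pair of biallelic
#' single-base loci inside the slice that lie within `max_distance` of each
#' other, straight from the compressed genotype store — no precomputed LD
#' table. Monomorphic or otherwise undefined pairs are skipped; the skip
#' reasons are attached as attribute `"skipped"`.
#'
#' @param ds a `vk_dataset`.
#' @param s a `vk_slice`.
#' @param individuals optional individual filter (e.g. one population's
#'   members via [population_members()]).
#' @param population optional population name (overrides `individuals`).
#' @param max_distance maximum pair separation in bp (default `Inf`).
#' @param tol,max_iter EM controls, see [em_haplotypes()].
#' @return data frame with one row per computed pair: `pos1`, `pos2`,
#'   `n_individuals`, `p_AB`, `p_Ab`, `p_aB`, `p_ab`, `p_A`, `p_B`, `D`,
#'   `D_prime`, `r2`, `iterations`, `converged`.
#' @export
pairwise_ld <- function(ds, s, individuals = NULL, population = NULL,
                        max_distance = Inf, tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(ds, "vk_dataset"), inherits(s, "vk_slice"))
  if (!is.null(population)) individuals <- population_members(ds, population)
  g <- query_genotypes(ds, s, individuals)
  loci <- sort(unique(g$position))
  skipped <- list()
  out <- list()
  cols <- c("pos1", "pos2", "n_individuals", "p_AB", "p_Ab", "p_aB", "p_ab",
            "p_A", "p_B", "D", "D_prime", "r2", "iterations", "converged")
  if (length(loci) >= 2L) {
    by_locus <- split(g, g$position)
    for (i in seq_len(length(loci) - 1L)) {
      for (j in seq((i + 1L), length(loci))) {
        if (loci[j] - loci[i] > max_distance) next
        res <- tryCatch(
          ld_single_pair(by_locus[[as.character(loci[i])]],
                         by_locus[[as.character(loci[j])]],
                         tol = tol, max_iter = max_iter),
          vk_monomorphic_error = function(e) e, vk_error = function(e) e)
        if (inherits(res, "condition")) {
          skipped[[length(skipped) + 1L]] <-
            data.frame(pos1 = loci[i], pos2 = loci[j],
                       reason = conditionMessage(res),
                       stringsAsFactors = FALSE)
          next
        }
        out[[length(out) + 1L]] <- data.frame(
          pos1 = loci[i], pos2 = loci[j],
          n_individuals = res$n_individuals,
          p_AB = res$p_AB, p_Ab = res$p_Ab, p_aB = res$p_aB, p_ab = res$p_ab,
          p_A = res$p_A, p_B = res$p_B, D = res$D, D_prime = res$D_prime,
          r2 = res$r2, iterations = res$iterations,
          converged = res$converged, stringsAsFactors = FALSE)
      }
    }
  }
  result <- if (length(out)) do.call(rbind, out) else
    as.data.frame(setNames(lapply(cols, function(x) vector("numeric", 0)), cols))
  rownames(result) <- NULL
  attr(result, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(pos1 = numeric(0), pos2 = numeric(0), reason = character(0))
  result
}

#' Members of a population
#'
#' @param ds a `vk_dataset`.
#' @param population population name.
#' @return character vector of individual names.
#' @export
population_members <- function(ds, population) {
  pops <- strsplit(ds$individuals$populations, ",", fixed = TRUE)
  hit <- vapply(pops, function(p) population %in% p, logical(1))
  if (!any(hit)) vk_stop("unknown population '", population, "'")
  ds$individuals$name[hit]
}
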