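#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Permutation version of the exact HWE test for multi-allelic loci: the
#' observed gene pool is repeatedly re-paired at random (equivalent to
#' drawing genotype arrays conditional on the observed allele counts) and
#' the observed array is compared against the permuted ones. Two test
#' statistics are available:
#' \describe{
#'   \item{`"prob"`}{the conditional probability of the genotype array
#'     given allele counts (Guo-Thompson style); arrays at most as
#'     probable as the observed one count as extreme. Default.}
#'   \item{`"het"`}{the heterozygote count; arrays at least as far from
#'     the conditional expectation as observed count as extreme
#'     (two-sided).}
#' }
#' The p-value uses the add-one rule
#' `(1 + n_extreme) / (1 + n_perm)`, so it is always in `(0, 1]` and at
#' least `1/(1 + n_perm)`.
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional integer seed.
#' @param statistic `"prob"` or `"het"`.
#' @return The Monte-Carlo p-value (numeric scalar).
#' @export
hwe_test_mc <- function(table, locus, n_perm = 1000L, seed = NULL,
                        statistic = c("prob", "het")) {
  stopifnot(inherits(table, "genotype_table"), n_perm >= 100L)
  statistic <- match.arg(statistic)
  l <- match(locus, table$loci)
  if (is.na(l)) stop("unknown locus: ", locus)
  a1 <- table$a1[, l]; a2 <- table$a2[, l]
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]
  n <- length(a1)
  if (n == 0L) stop("locus '", locus, "': all genotypes missing")
  pool <- c(a1, a2)
  alleles <- unique(pool)
  if (length(alleles) < 2L) {
    stop("locus '", locus, "' is monomorphic: HWE test undefined")
  }

  # statistic for one pairing of the pool; smaller = less probable array
  arr_stat <- function(x, y) {
    het <- sum(x != y)
    g <- paste(pmin(x, y), pmax(x, y))
    if (statistic == "prob") {
      # log conditional array probability up to a constant in the allele
      # counts: -sum(log n_g!) + het*log(2)
      -sum(lfactorial(tabulate(factor(g)))) + het * log(2)
    } else {
      het
    }
  }

  # expected heterozygote count drawing 2 genes without replacement
  cnt <- table(pool)
  exp_het <- n * (1 - sum(cnt * (cnt - 1)) / (2 * n * (2 * n - 1)))

  obs <- arr_stat(a1, a2)
  extreme <- function(s) {
    if (statistic == "prob") s <= obs + 1e-12
    else abs(s - exp_het) >= abs(obs - exp_het) - 1e-12
  }
  with_seed(seed, {
    n_ext <- 0L
    for (b in seq_len(n_perm)) {
      perm <- pool[sample.int(2L * n)]
      s <- arr_stat(perm[seq_len(n)], perm[n + seq_len(n)])
      if (extreme(s)) n_ext <- n_ext + 1L
    }
    (1 + n_ext) / (1 + n_perm)
  })
}

#' Bonferroni correction
#'
#' `adjusted = min(1, p * m)` with `m = length(p_values)`; order preserved.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
bonferroni <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value list")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  pmin(1, p_values * length(p_values))
}

#' Per-locus marker QC report
#'
#' Missingness, allele counts, observed heterozygosity and Monte-Carlo HWE
#' p-values (Bonferroni-adjusted across testable loci). Loci typed in fewer
#' than half the individuals are flagged (`low_data`) but never dropped;
#' filtering is left to the caller.
#'
#' @param table a [genotype_table()].
#' @param n_perm HWE permutations per locus.
#' @param seed optional integer seed.
#' @return A data.frame with one row per locus, class `marker_qc`.
#' @export
marker_qc <- function(table, n_perm = 1000L, seed = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  n <- length(table$ids)
  with_seed(seed, {
    rows <- lapply(seq_along(table$loci), function(l) {
      a1 <- table$a1[, l]; a2 <- table$a2[, l]
      typed <- sum(!is.na(a1))
      alle <- unique(c(a1, a2)); alle <- alle[!is.na(alle)]
      het <- sum(!is.na(a1) & a1 != a2)
      p <- if (length(alle) >= 2L) {
        hwe_test_mc(table, table$loci[l], n_perm = n_perm)
      } else NA_real_
      data.frame(locus = table$loci[l], n_typed = typed,
                 prop_missing = 1 - typed / n, n_alleles = length(alle),
                 het_obs = if (typed > 0) het / typed else NA_real_,
                 hwe_p = p, low_data = typed < n / 2)
    })
    out <- do.call(rbind, rows)
    ok <- !is.na(out$hwe_p)
    out$hwe_p_bonferroni <- NA_real_
    if (any(ok)) out$hwe_p_bonferroni[ok] <- bonferroni(out$hwe_p[ok])
    class(out) <- c("marker_qc", "data.frame")
    out
  })
}
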