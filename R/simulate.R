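#' Pedigree relationship categories
#'
#' The four non-inbred dyad categories used throughout: unrelated (UR),
#' half-siblings (HS), full-siblings (FS) and parent-offspring (PO), with
#' their IBD coefficients and expected relatedness `r_e = k1/2 + k2`.
#'
#' @param label one of `"UR"`, `"HS"`, `"FS"`, `"PO"`, or an existing
#'   category object (returned unchanged).
#' @return A list with elements `label`, `k` (length-3 numeric) and
#'   `r_expected`, class `relationship_category`.
#' @examples
#' relationship_category("HS")$r_expected  # 0.25
#' @export
relationship_category <- function(label) {
  if (inherits(label, "relationship_category")) return(label)
  k <- switch(as.character(label),
              UR = c(1, 0, 0),
              HS = c(0.5, 0.5, 0),
              FS = c(0.25, 0.5, 0.25),
              PO = c(0, 1, 0),
              stop("unknown relationship category: ", label,
                   " (expected UR, HS, FS or PO)"))
  structure(list(label = as.character(label), k = k,
                 r_expected = k[2] / 2 + k[3]),
            class = "relationship_category")
}

#' Simulate genotype dyads under a relationship category
#'
#' Generates pairs of multilocus genotypes under the 3-state IBD model:
#' per locus the IBD state is drawn with probabilities `(k0, k1, k2)`, the
#' shared and free genes are drawn from the allele frequencies, and the
#' genotyping-error model then replaces each observed genotype, with
#' probability `error` per locus per individual, by a fresh Hardy-Weinberg
#' draw.
#'
#' @param n number of dyads.
#' @param category a category label or [relationship_category()].
#' @param freqs a [freq_set()].
#' @param error per-locus per-individual error rate in `[0, 1]`.
#' @param seed optional integer seed.
#' @return A `dyad_set`: integer allele-index matrices `A1,B1,A2,B2`
#'   (`n` x n_loci, canonical order within genotype), the allele label
#'   catalogue, and the generating category as attribute.
#' @export
simulate_dyads <- function(n, category, freqs, error = 0, seed = NULL) {
  stopifnot(n >= 1L, inherits(freqs, "freq_set"), error >= 0, error <= 1)
  cat <- relationship_category(category)
  L <- length(freqs)
  with_seed(seed, {
    A1 <- B1 <- A2 <- B2 <- matrix(NA_integer_, n, L)
    for (l in seq_len(L)) {
      p <- as.numeric(freqs[[l]])
      m <- length(p)
      s <- sample.int(3L, n, replace = TRUE, prob = cat$k) - 1L
      x <- sample.int(m, n, TRUE, prob = p)
      y <- sample.int(m, n, TRUE, prob = p)
      z <- sample.int(m, n, TRUE, prob = p)
      w <- sample.int(m, n, TRUE, prob = p)
      g1a <- x; g1b <- y
      g2a <- ifelse(s == 0L, z, x)
      g2b <- ifelse(s == 2L, y, ifelse(s == 1L, z, w))
      if (error > 0) {
        r1 <- stats::runif(n) < error
        r2 <- stats::runif(n) < error
        if (any(r1)) {
          g1a[r1] <- sample.int(m, sum(r1), TRUE, prob = p)
          g1b[r1] <- sample.int(m, sum(r1), TRUE, prob = p)
        }
        if (any(r2)) {
          g2a[r2] <- sample.int(m, sum(r2), TRUE, prob = p)
          g2b[r2] <- sample.int(m, sum(r2), TRUE, prob = p)
        }
      }
      A1[, l] <- pmin(g1a, g1b); B1[, l] <- pmax(g1a, g1b)
      A2[, l] <- pmin(g2a, g2b); B2[, l] <- pmax(g2a, g2b)
    }
    structure(list(loci = names(freqs),
                   alleles = lapply(freqs, names),
                   A1 = A1, B1 = B1, A2 = A2, B2 = B2,
                   id1 = paste0("d", seq_len(n), ".1"),
                   id2 = paste0("d", seq_len(n), ".2"),
                   category = cat$label),
              class = "dyad_set")
  })
}

#' @rdname simulate_dyads
#' @return `simulate_dyad()` returns a single [dyad()] with character
#'   allele labels.
#' @export
simulate_dyad <- function(category, freqs, error = 0, seed = NULL) {
  ds <- simulate_dyads(1L, category, freqs, error = error, seed = seed)
  lab <- function(M) vapply(seq_along(ds$loci),
                            function(l) ds$alleles[[l]][M[1, l]], "")
  g1 <- rbind(lab(ds$A1), lab(ds$B1))
  g2 <- rbind(lab(ds$A2), lab(ds$B2))
  colnames(g1) <- colnames(g2) <- ds$loci
  dyad(g1, g2)
}

#' @export
print.dyad_set <- function(x, ...) {
  cat("Dyad set:", nrow(x$A1), "dyads x", length(x$loci), "loci",
      if (!is.null(x$category)) paste0("(category ", x$category, ")"), "\n")
  invisible(x)
}

#' Extract one dyad from a dyad set
#'
#' @param x a `dyad_set`.
#' @param i dyad index.
#' @return A [dyad()].
#' @export
dyad_at <- function(x, i) {
  stopifnot(inherits(x, "dyad_set"), i >= 1L, i <= nrow(x$A1))
  lab <- function(M, l) {
    v <- M[i, l]
    if (is.na(v)) NA_character_ else x$alleles[[l]][v]
  }
  L <- length(x$loci)
  g1 <- rbind(vapply(seq_len(L), function(l) lab(x$A1, l), ""),
              vapply(seq_len(L), function(l) lab(x$B1, l), ""))
  g2 <- rbind(vapply(seq_len(L), function(l) lab(x$A2, l), ""),
              vapply(seq_len(L), function(l) lab(x$B2, l), ""))
  colnames(g1) <- colnames(g2) <- x$loci
  dyad(g1, g2)
}

# ---- pedigrees -------------------------------------------------------------

#' Simulate a pedigree cohort structure with paternity skew
#'
#' Emulates the breeding structure of a primate group in which the
#' top-dominant male monopolizes most paternities: per birth cohort each of
#' `females_per_cohort` mothers produces one offspring, a fraction
#' `paternity_skew` of which is sired by the cohort's top male, the rest by
#' distinct other males. Top males hold tenure for `cohorts_per_tenure`
#' consecutive cohorts, so full-sibships (same mother, same top male across
#' cohorts) and maternal half-sibships arise alongside the large paternal
#' half-sibships.
#'
#' @param n_cohorts number of birth cohorts.
#' @param females_per_cohort breeding females (also offspring per cohort).
#' @param paternity_skew fraction of each cohort sired by the top male.
#' @param cohorts_per_tenure cohorts a top male stays on top.
#' @param seed optional integer seed.
#' @return A data.frame (class `pedigree`) with columns `id`, `mother`,
#'   `father`, `cohort` (`NA` parents/cohort for founders).
#' @export
gen_pedigree_cohort <- function(n_cohorts, females_per_cohort, paternity_skew,
                                cohorts_per_tenure = 2L, seed = NULL) {
  stopifnot(n_cohorts >= 1L, females_per_cohort >= 1L,
            paternity_skew >= 0, paternity_skew <= 1)
  mothers <- sprintf("F%02d", seq_len(females_per_cohort))
  with_seed(seed, {
    rows <- list()
    extra_i <- 0L
    for (co in seq_len(n_cohorts)) {
      top <- sprintf("T%02d", (co - 1L) %/% cohorts_per_tenure + 1L)
      n_off <- females_per_cohort
      n_top <- round(paternity_skew * n_off)
      sired_by_top <- rep(FALSE, n_off)
      if (n_top > 0L) sired_by_top[sample.int(n_off, n_top)] <- TRUE
      moms <- sample(mothers, n_off)  # without replacement within cohort
      fathers <- character(n_off)
      fathers[sired_by_top] <- top
      if (any(!sired_by_top)) {
        k <- sum(!sired_by_top)
        fathers[!sired_by_top] <- sprintf("M%03d", extra_i + seq_len(k))
        extra_i <- extra_i + k
      }
      rows[[co]] <- data.frame(
        id = sprintf("O%02d%02d", co, seq_len(n_off)),
        mother = moms, father = fathers, cohort = co)
    }
    off <- do.call(rbind, rows)
    founders <- data.frame(id = unique(c(off$mother, off$father)),
                           mother = NA_character_, father = NA_character_,
                           cohort = NA_integer_)
    ped <- rbind(founders, off)
    rownames(ped) <- NULL
    class(ped) <- c("pedigree", "data.frame")
    ped
  })
}

#' True pairwise relationship categories from a pedigree
#'
#' Same mother and father = FS; exactly one shared parent = HS;
#' parent-child = PO; anything else = UR (founders are assumed unrelated;
#' no deeper kinship is traced).
#'
#' @param ped a `pedigree` data.frame.
#' @param ids individuals to pair up; default all non-founders.
#' @return data.frame `id1, id2, category` over all unordered pairs.
#' @export
pedigree_dyad_categories <- function(ped, ids = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(ids)) ids <- ped$id[!is.na(ped$mother)]
  ids <- as.character(ids)
  i <- match(ids, ped$id)
  if (any(is.na(i))) stop("IDs absent from pedigree")
  mo <- ped$mother[i]; fa <- ped$father[i]
  cmb <- utils::combn(seq_along(ids), 2L)
  cat_of <- function(a, b) {
    if ((!is.na(mo[a]) && mo[a] == ids[b]) || (!is.na(fa[a]) && fa[a] == ids[b]) ||
        (!is.na(mo[b]) && mo[b] == ids[a]) || (!is.na(fa[b]) && fa[b] == ids[a])) {
      return("PO")
    }
    sm <- !is.na(mo[a]) && !is.na(mo[b]) && mo[a] == mo[b]
    sf <- !is.na(fa[a]) && !is.na(fa[b]) && fa[a] == fa[b]
    if (sm && sf) "FS" else if (sm || sf) "HS" else "UR"
  }
  data.frame(id1 = ids[cmb[1, ]], id2 = ids[cmb[2, ]],
             category = vapply(seq_len(ncol(cmb)),
                               function(j) cat_of(cmb[1, j], cmb[2, j]), ""))
}

#' Gene-drop genotypes down a pedigree
#'
#' Founders are drawn under Hardy-Weinberg equilibrium from `freqs`;
#' offspring inherit one random allele per parent per locus; the
#' genotyping-error model is applied last (with probability `error` per
#' locus per individual, the genotype is replaced by a fresh HWE draw).
#'
#' @param ped a `pedigree` data.frame (parents listed before offspring).
#' @param freqs a [freq_set()].
#' @param error per-locus per-individual error rate.
#' @param seed optional integer seed.
#' @return A [genotype_table()] over all pedigree members.
#' @export
drop_genotypes <- function(ped, freqs, error = 0, seed = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(freqs, "freq_set"),
            error >= 0, error <= 1)
  n <- nrow(ped); L <- length(freqs)
  ord <- match(ped$mother, ped$id)
  if (any(!is.na(ord) & ord >= seq_len(n)) ||
      any({fo <- match(ped$father, ped$id); !is.na(fo) & fo >= seq_len(n)})) {
    stop("pedigree rows must list parents before offspring (no cycles)")
  }
  with_seed(seed, {
    A1 <- A2 <- matrix(NA_integer_, n, L)
    mo <- match(ped$mother, ped$id); fa <- match(ped$father, ped$id)
    for (l in seq_len(L)) {
      p <- as.numeric(freqs[[l]]); m <- length(p)
      for (i in seq_len(n)) {
        if (is.na(mo[i])) {
          A1[i, l] <- sample.int(m, 1L, prob = p)
          A2[i, l] <- sample.int(m, 1L, prob = p)
        } else {
          A1[i, l] <- if (stats::runif(1) < 0.5) A1[mo[i], l] else A2[mo[i], l]
          A2[i, l] <- if (stats::runif(1) < 0.5) A1[fa[i], l] else A2[fa[i], l]
        }
      }
      if (error > 0) {
        r <- stats::runif(n) < error
        if (any(r)) {
          A1[r, l] <- sample.int(m, sum(r), TRUE, prob = p)
          A2[r, l] <- sample.int(m, sum(r), TRUE, prob = p)
        }
      }
    }
    lab <- function(M) {
      out <- matrix(NA_character_, n, L)
      for (l in seq_len(L)) out[, l] <- names(freqs[[l]])[M[, l]]
      out
    }
    genotype_table(ped$id, names(freqs), lab(A1), lab(A2))
  })
}

# ---- demography ------------------------------------------------------------

#' Simulate male residence and high-rank tenure records
#'
#' The stand-in for longitudinal group-membership records: each male gets a
#' residence spell whose monthly hazard of leaving is
#' `baseline_hazard * kin_hazard_ratio^kin`, right-censored at
#' `censor_month`; kin presence at entry is Bernoulli; high-rank tenure
#' (for males that ever reach rank 1-3) is Gaussian around
#' `tenure_mean_without_kin + tenure_kin_effect * kin`, truncated at one
#' month. Defaults emulate the field conditions of a two-group macaque
#' study: ~2/3 of males with a co-resident relative, a strong protective
#' kin effect on leaving (log-hazard -2.36), and a 146-month observation
#' window.
#'
#' @param n_males number of residence records.
#' @param baseline_hazard monthly leaving hazard without kin (> 0).
#' @param kin_hazard_ratio multiplicative hazard ratio when kin present.
#' @param censor_month administrative censoring time (months).
#' @param p_kin_at_entry probability a relative is present at entry.
#' @param p_kin_window additional probability (among males without kin at
#'   entry) that a relative joins within the 3-month window.
#' @param p_peer_at_entry probability a peer is present at entry.
#' @param tenure_mean_without_kin mean high-rank tenure without kin (months).
#' @param tenure_kin_effect additive kin effect on tenure (months).
#' @param noise_sd Gaussian tenure noise SD (months).
#' @param p_high_rank probability a male ever holds rank 1-3.
#' @param seed optional integer seed.
#' @return data.frame (class `male_residence`) with columns `male_id`,
#'   `group_id`, `entry_month`, `duration_months`, `censored`,
#'   `natal_disperser`, `kin_at_entry`, `kin_3mo`, `peer_at_entry`,
#'   `coresidence_fraction`, `high_rank_tenure_months`, `max_rank`,
#'   `group_n_nonnatal_males`.
#' @export
gen_demography <- function(n_males = 37L,
                           baseline_hazard = 0.04,
                           kin_hazard_ratio = exp(-2.36),
                           censor_month = 146L,
                           p_kin_at_entry = 0.66,
                           p_kin_window = 0.15,
                           p_peer_at_entry = 0.4,
                           tenure_mean_without_kin = 14.2,
                           tenure_kin_effect = 12.7,
                           noise_sd = 11.7,
                           p_high_rank = 0.5,
                           seed = NULL) {
  stopifnot(n_males >= 1L, baseline_hazard > 0, kin_hazard_ratio > 0,
            censor_month >= 0, p_kin_at_entry >= 0, p_kin_at_entry <= 1)
  with_seed(seed, {
    kin <- stats::runif(n_males) < p_kin_at_entry
    kin3 <- kin | (stats::runif(n_males) < p_kin_window)
    peer <- stats::runif(n_males) < p_peer_at_entry
    natal <- stats::runif(n_males) < 0.5
    haz <- baseline_hazard * kin_hazard_ratio^kin
    raw <- stats::rexp(n_males, rate = haz)
    dur <- pmax(1L, ceiling(raw))
    censored <- dur >= censor_month
    dur[censored] <- max(censor_month, 1L)
    group <- sample(c("House", "Antara"), n_males, TRUE)
    cores <- ifelse(kin, stats::rbeta(n_males, 3, 0.68), 0)
    max_rank <- ifelse(stats::runif(n_males) < p_high_rank,
                       sample.int(3L, n_males, TRUE),
                       3L + sample.int(5L, n_males, TRUE))
    tenure <- ifelse(max_rank <= 3L,
                     pmax(1, tenure_mean_without_kin +
                            tenure_kin_effect * kin +
                            stats::rnorm(n_males, 0, noise_sd)),
                     NA_real_)
    out <- data.frame(
      male_id = sprintf("male%03d", seq_len(n_males)),
      group_id = group,
      entry_month = 0L,
      duration_months = as.integer(dur),
      censored = censored,
      natal_disperser = natal,
      kin_at_entry = kin,
      kin_3mo = kin3,
      peer_at_entry = peer,
      coresidence_fraction = cores,
      high_rank_tenure_months = tenure,
      max_rank = as.integer(max_rank),
      group_n_nonnatal_males = sample(3:14, n_males, TRUE))
    class(out) <- c("male_residence", "data.frame")
    out
  })
}
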