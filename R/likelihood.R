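# Per-locus dyad likelihoods under the 3-state IBD model.
#
# A non-inbred dyad shares 0, 1 or 2 genes identical-by-descent at a locus
# with probabilities (k0, k1, k2). Conditional on the state, genotypes are
# generated from the population allele frequencies p:
#   state 2: genes x,y ~ p; both genotypes {x,y}
#   state 1: genes x,y,z ~ p; genotypes {x,y} and {x,z}
#   state 0: four independent genes
# Genotyping error (rate e, per locus per individual) replaces an observed
# genotype with a fresh Hardy-Weinberg draw; since the marginal of each
# genotype under any state is HWE, the error mixture is
#   Q_s = (1-e)^2 P_s + (1 - (1-e)^2) HWE(g1) HWE(g2).

# HWE genotype probability; a, b are allele indices (vectors)
.geno_prob <- function(a, b, p) {
  ifelse(a == b, p[a]^2, 2 * p[a] * p[b])
}

# Pr(genotype {a,b} | one gene is allele x), vectorized over dyads
.share_given <- function(a, b, x, p) {
  ifelse(a == b, (a == x) * p[a], (a == x) * p[b] + (b == x) * p[a])
}

# state-conditional pair probabilities for one locus; all args are
# equal-length integer vectors of allele indices (canonical a <= b)
.state_probs <- function(a1, b1, a2, b2, p) {
  h1 <- .geno_prob(a1, b1, p)
  h2 <- .geno_prob(a2, b2, p)
  P0 <- h1 * h2
  P2 <- h1 * (a1 == a2 & b1 == b2)
  P1 <- 0
  for (x in seq_along(p)) {
    P1 <- P1 + p[x] * .share_given(a1, b1, x, p) * .share_given(a2, b2, x, p)
  }
  list(P0 = P0, P1 = P1, P2 = P2, H = h1 * h2)
}

.error_mix <- function(P, H, e) {
  keep <- (1 - e)^2
  keep * P + (1 - keep) * H
}

#' Per-locus log-likelihood of a genotype pair given IBD coefficients
#'
#' Computes `log Pr(g1, g2 | k, p, e)` under the 3-state IBD generative
#' model with the HWE-redraw error mixture (see Details in the package
#' vignette). A configuration impossible at `e = 0` (e.g. a parent-offspring
#' hypothesis with no shared allele) returns `-Inf` rather than erroring.
#'
#' @param g1,g2 length-2 character vectors of allele labels (unordered).
#' @param locus named numeric vector of allele frequencies for the locus.
#' @param k numeric length-3 `(k0, k1, k2)`, non-negative, summing to 1.
#' @param e per-locus, per-individual genotyping error rate in `[0, 1]`.
#' @return Log-probability (scalar; may be `-Inf`).
#' @examples
#' p <- c(A = 0.5, B = 0.5)
#' locus_pair_loglik(c("A", "A"), c("A", "A"), p, k = c(0, 0, 1))  # log 0.25
#' @export
locus_pair_loglik <- function(g1, g2, locus, k, e = 0) {
  stopifnot(length(g1) == 2L, length(g2) == 2L, length(k) == 3L,
            e >= 0, e <= 1)
  if (any(k < -1e-12) || abs(sum(k) - 1) > 1e-9) {
    stop("k must be non-negative and sum to 1")
  }
  idx <- match(c(g1, g2), names(locus))
  if (any(is.na(idx))) {
    stop("allele(s) not in locus frequency vector: ",
         paste(unique(c(g1, g2)[is.na(idx)]), collapse = ", "))
  }
  cp1 <- sort(idx[1:2]); cp2 <- sort(idx[3:4])
  sp <- .state_probs(cp1[1], cp1[2], cp2[1], cp2[2], as.numeric(locus))
  q <- .error_mix(c(sp$P0, sp$P1, sp$P2), sp$H, e)
  log(sum(pmax(k, 0) * q))
}

# ---- dyad containers -------------------------------------------------------

#' Dyads and dyad sets
#'
#' A `dyad` is one pair of multilocus genotypes; a `dyad_set` is a batch of
#' such pairs stored column-per-locus as integer allele indices (with the
#' label catalogue kept alongside), the unit all estimators operate on.
#'
#' @param g1,g2 2 x n_loci character matrices (as from [genotypes_of()]).
#' @param loci locus names; defaults to `colnames(g1)`.
#' @return `dyad()` returns a `dyad`; `dyad_from_table()` extracts a pair
#'   of individuals from a [genotype_table()].
#' @export
dyad <- function(g1, g2, loci = colnames(g1)) {
  stopifnot(nrow(g1) == 2L, nrow(g2) == 2L, ncol(g1) == ncol(g2))
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(g1)))
  structure(list(loci = as.character(loci),
                 g1a = g1[1, ], g1b = g1[2, ], g2a = g2[1, ], g2b = g2[2, ]),
            class = "dyad")
}

#' @rdname dyad
#' @param table a [genotype_table()].
#' @param id1,id2 individual IDs.
#' @export
dyad_from_table <- function(table, id1, id2) {
  dyad(genotypes_of(table, id1), genotypes_of(table, id2), loci = table$loci)
}

# internal: coerce dyad / genotype-table pairs to the batch representation
# aligned with a freq_set (integer indices into each locus's allele vector)
.as_batch <- function(x, freqs, pairs = NULL) {
  stopifnot(inherits(freqs, "freq_set"))
  if (inherits(x, "dyad_set")) {
    loci <- x$loci
    if (!all(loci %in% names(freqs))) stop("dyad set has loci absent from freqs")
    A1 <- x$A1; B1 <- x$B1; A2 <- x$A2; B2 <- x$B2
    # re-index labels against the supplied frequencies
    for (l in seq_along(loci)) {
      map <- match(x$alleles[[l]], names(freqs[[loci[l]]]))
      if (any(is.na(map))) {
        stop("locus '", loci[l], "': allele(s) absent from freqs")
      }
      A1[, l] <- map[x$A1[, l]]; B1[, l] <- map[x$B1[, l]]
      A2[, l] <- map[x$A2[, l]]; B2[, l] <- map[x$B2[, l]]
    }
    return(list(loci = loci, A1 = A1, B1 = B1, A2 = A2, B2 = B2,
                id1 = x$id1, id2 = x$id2))
  }
  if (inherits(x, "dyad")) {
    loci <- x$loci
    if (!all(loci %in% names(freqs))) stop("dyad has loci absent from freqs")
    idx <- function(lab, l) {
      if (is.na(lab)) return(NA_integer_)
      i <- match(lab, names(freqs[[l]]))
      if (is.na(i)) stop("locus '", l, "': allele '", lab, "' absent from freqs")
      i
    }
    A1 <- matrix(mapply(idx, x$g1a, loci), 1L)
    B1 <- matrix(mapply(idx, x$g1b, loci), 1L)
    A2 <- matrix(mapply(idx, x$g2a, loci), 1L)
    B2 <- matrix(mapply(idx, x$g2b, loci), 1L)
    cp1 <- canon_pair(A1, B1); cp2 <- canon_pair(A2, B2)
    return(list(loci = loci, A1 = cp1$a, B1 = cp1$b, A2 = cp2$a, B2 = cp2$b,
                id1 = "g1", id2 = "g2"))
  }
  if (inherits(x, "genotype_table")) {
    if (is.null(pairs)) {
      cmb <- utils::combn(x$ids, 2L)
      pairs <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ])
    }
    pairs <- as.data.frame(pairs)
    loci <- x$loci
    if (!all(loci %in% names(freqs))) stop("table has loci absent from freqs")
    i1 <- match(as.character(pairs[[1]]), x$ids)
    i2 <- match(as.character(pairs[[2]]), x$ids)
    if (any(is.na(i1)) || any(is.na(i2))) stop("pair IDs absent from table")
    tomat <- function(m, rows) {
      out <- matrix(NA_integer_, length(rows), length(loci))
      for (l in seq_along(loci)) {
        out[, l] <- match(m[rows, l], names(freqs[[loci[l]]]))
        bad <- !is.na(m[rows, l]) & is.na(out[, l])
        if (any(bad)) stop("locus '", loci[l], "': allele(s) absent from freqs")
      }
      out
    }
    A1 <- tomat(x$a1, i1); B1 <- tomat(x$a2, i1)
    A2 <- tomat(x$a1, i2); B2 <- tomat(x$a2, i2)
    cp1 <- canon_pair(A1, B1); cp2 <- canon_pair(A2, B2)
    return(list(loci = loci, A1 = cp1$a, B1 = cp1$b, A2 = cp2$a, B2 = cp2$b,
                id1 = as.character(pairs[[1]]), id2 = as.character(pairs[[2]])))
  }
  stop("cannot interpret 'x' as dyads (expected dyad, dyad_set or genotype_table)")
}

# internal: state-probability arrays Q0/Q1/Q2 (n_dyads x n_loci) for a batch
.batch_Q <- function(batch, freqs, e) {
  n <- nrow(batch$A1); L <- length(batch$loci)
  Q0 <- Q1 <- Q2 <- matrix(NA_real_, n, L)
  for (l in seq_len(L)) {
    p <- as.numeric(freqs[[batch$loci[l]]])
    ok <- !is.na(batch$A1[, l]) & !is.na(batch$A2[, l])
    if (!any(ok)) next
    sp <- .state_probs(batch$A1[ok, l], batch$B1[ok, l],
                       batch$A2[ok, l], batch$B2[ok, l], p)
    Q0[ok, l] <- .error_mix(sp$P0, sp$H, e)
    Q1[ok, l] <- .error_mix(sp$P1, sp$H, e)
    Q2[ok, l] <- .error_mix(sp$P2, sp$H, e)
  }
  list(Q0 = Q0, Q1 = Q1, Q2 = Q2)
}

# internal: per-dyad total log-likelihood at a fixed k (missing loci skipped)
.batch_loglik_at_k <- function(Q, k) {
  v <- k[1] * Q$Q0 + k[2] * Q$Q1 + k[3] * Q$Q2
  lv <- log(v)
  lv[is.na(v)] <- 0
  rowSums(lv)
}
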