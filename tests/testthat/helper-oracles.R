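# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form state probabilities: distributions are built by
# mechanical enumeration of the generative model.

geno_key <- function(g) paste(sort(g), collapse = "/")
pair_key <- function(g1, g2) paste(geno_key(g1), geno_key(g2), sep = "|")

# accumulate weight into a named numeric vector
acc <- function(tab, key, w) {
  if (is.na(tab[key])) tab[key] <- 0
  tab[key] <- tab[key] + w
  tab
}

# HWE genotype distribution by enumeration of two ordered gene draws
enum_hwe_dist <- function(p) {
  al <- names(p)
  tab <- numeric(0)
  for (x in seq_along(p)) for (y in seq_along(p)) {
    tab <- acc(tab, geno_key(al[c(x, y)]), p[x] * p[y])
  }
  tab
}

# full dyad genotype-pair distribution under (k0,k1,k2) and the
# HWE-redraw error model, by enumerating states, genes and error events
enum_pair_dist <- function(p, k, e = 0) {
  al <- names(p)
  m <- length(p)
  true_tab <- numeric(0)
  for (x in 1:m) for (y in 1:m) {
    w2 <- k[3] * p[x] * p[y]
    if (w2 > 0) true_tab <- acc(true_tab, pair_key(al[c(x, y)], al[c(x, y)]), w2)
    for (z in 1:m) {
      w1 <- k[2] * p[x] * p[y] * p[z]
      if (w1 > 0) true_tab <- acc(true_tab, pair_key(al[c(x, y)], al[c(x, z)]), w1)
      for (w in 1:m) {
        w0 <- k[1] * p[x] * p[y] * p[z] * p[w]
        if (w0 > 0) true_tab <- acc(true_tab, pair_key(al[c(x, y)], al[c(z, w)]), w0)
      }
    }
  }
  if (e == 0) return(true_tab)
  hwe <- enum_hwe_dist(p)
  out <- numeric(0)
  for (key in names(true_tab)) {
    gg <- strsplit(key, "|", fixed = TRUE)[[1]]
    wt <- true_tab[key]
    out <- acc(out, key, (1 - e)^2 * wt)                    # no error
    for (h in names(hwe)) {                                  # one genotype redrawn
      out <- acc(out, paste(h, gg[2], sep = "|"), e * (1 - e) * wt * hwe[h])
      out <- acc(out, paste(gg[1], h, sep = "|"), (1 - e) * e * wt * hwe[h])
      for (h2 in names(hwe)) {                               # both redrawn
        out <- acc(out, paste(h, h2, sep = "|"), e^2 * wt * hwe[h] * hwe[h2])
      }
    }
  }
  out
}

# all unordered genotypes over the alleles of p, as list of char pairs
all_genotypes <- function(p) {
  al <- names(p)
  out <- list()
  for (i in seq_along(al)) for (j in i:length(al)) {
    out[[length(out) + 1L]] <- c(al[i], al[j])
  }
  out
}

# log-likelihood ratio statistic for each dyad in a set, built from the
# exported per-locus likelihood only
llr_stats <- function(ds, freqs, k_primary, k_null, e = 0) {
  n <- nrow(ds$A1)
  vapply(seq_len(n), function(i) {
    d <- dyad_at(ds, i)
    s <- 0
    for (l in seq_along(d$loci)) {
      g1 <- c(d$g1a[l], d$g1b[l]); g2 <- c(d$g2a[l], d$g2b[l])
      if (any(is.na(g1)) || any(is.na(g2))) next
      p <- freqs[[d$loci[l]]]
      s <- s + locus_pair_loglik(g1, g2, p, k_primary, e) -
        locus_pair_loglik(g1, g2, p, k_null, e)
    }
    s
  }, 0)
}

# dense simplex grid search of the dyad likelihood (step `by`); the
# per-locus state likelihoods are read off locus_pair_loglik at the three
# vertex hypotheses, so the search is independent of the package optimizer
grid_search_r <- function(d, freqs, e = 0, by = 0.01) {
  L <- length(d$loci)
  Q <- matrix(NA_real_, 3, L)
  for (l in seq_len(L)) {
    g1 <- c(d$g1a[l], d$g1b[l]); g2 <- c(d$g2a[l], d$g2b[l])
    p <- freqs[[d$loci[l]]]
    Q[1, l] <- exp(locus_pair_loglik(g1, g2, p, c(1, 0, 0), e))
    Q[2, l] <- exp(locus_pair_loglik(g1, g2, p, c(0, 1, 0), e))
    Q[3, l] <- exp(locus_pair_loglik(g1, g2, p, c(0, 0, 1), e))
  }
  ks <- seq(0, 1, by = by)
  g <- expand.grid(k1 = ks, k2 = ks)
  g <- g[g$k1 + g$k2 <= 1 + 1e-12, ]
  grid <- cbind(pmax(1 - g$k1 - g$k2, 0), g$k1, g$k2)
  ll <- rowSums(log(grid %*% Q))
  ll[is.nan(ll)] <- -Inf
  best <- grid[which.max(ll), ]
  list(r = best[2] / 2 + best[3], k = best, loglik = max(ll))
}

# convert one side of a dyad to the 2 x L genotype matrix interface
dyad_g1 <- function(d) {
  m <- rbind(d$g1a, d$g1b); colnames(m) <- d$loci; m
}
dyad_g2 <- function(d) {
  m <- rbind(d$g2a, d$g2b); colnames(m) <- d$loci; m
}

# equifrequent reference panel used by simulation-heavy tests
panel_18x8 <- function() gen_frequencies(18, 8, concentration = Inf)

# hand-rolled Breslow partial log-likelihood for a single binary covariate
breslow_partial_loglik <- function(beta, time, event, x) {
  s <- 0
  for (t in sort(unique(time[event]))) {
    d_set <- which(event & time == t)
    risk <- which(time >= t)
    s <- s + beta * sum(x[d_set]) -
      length(d_set) * log(sum(exp(beta * x[risk])))
  }
  s
}

# brute-force interval-overlap flags for kin_presence_flags
brute_flags <- function(related_pairs, res, window = 3) {
  n <- nrow(res)
  ex <- res$entry_month + res$duration_months
  isrel <- function(a, b) {
    any((related_pairs$id1 == a & related_pairs$id2 == b) |
          (related_pairs$id1 == b & related_pairs$id2 == a))
  }
  ke <- kw <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || res$group_id[j] != res$group_id[i] ||
          res$male_id[j] == res$male_id[i]) next
      if (!isrel(res$male_id[i], res$male_id[j])) next
      if (res$entry_month[j] <= res$entry_month[i] && ex[j] >= res$entry_month[i]) {
        ke[i] <- TRUE
      }
      if (res$entry_month[j] <= res$entry_month[i] + window &&
          ex[j] >= res$entry_month[i]) {
        kw[i] <- TRUE
      }
    }
  }
  list(kin_at_entry = ke, kin_3mo = kw)
}
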