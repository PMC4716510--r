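#' Maximum-likelihood dyadic relatedness (DyadML)
#'
#' Fits, for each genotype pair, the IBD coefficients `(k0, k1, k2)` that
#' maximize the product over loci of the 3-state dyad likelihood (see
#' [locus_pair_loglik()]), and reports the relatedness estimate
#' r = k1/2 + k2. The per-dyad log-likelihood is concave in `k` on the
#' simplex (a sum of logarithms of linear functions), so the optimizer is
#' a coarse simplex grid (which contains the four category vertices)
#' followed by a Nelder-Mead polish; `r` lies in `[0, 1]` by construction.
#'
#' Missing loci are skipped and `n_loci_used` recorded; dyads with fewer
#' than `min_loci` usable loci are refused (`NA` estimate plus a warning).
#' The non-inbred feasibility constraint `k1^2 >= 4 k0 k2` is not enforced
#' by default; set `constrain_noninbred = TRUE` to impose it.
#'
#' @param x a [dyad()], a `dyad_set` (see [simulate_dyads()]), or a
#'   [genotype_table()] (all pairs, or the pairs given in `pairs`).
#' @param freqs a [freq_set()]; the reference allele frequencies are always
#'   supplied externally, never re-estimated from the dyad.
#' @param error assumed per-locus per-individual genotyping error rate.
#' @param min_loci minimum usable loci per dyad (default 8).
#' @param pairs optional 2-column data.frame of (id1, id2) when `x` is a
#'   genotype table.
#' @param grid_step simplex grid resolution for the initial search.
#' @param constrain_noninbred if `TRUE`, restrict to `k1^2 >= 4 k0 k2`.
#' @return An object of class `dyadml`: a data.frame with columns `id1`,
#'   `id2`, `r`, `k0`, `k1`, `k2`, `loglik`, `n_loci_used`, with the call
#'   and settings as attributes. Methods: `print`, `summary`, `coef`
#'   (the vector of `r`), `logLik`, `plot`, `simulate`.
#' @examples
#' fs <- gen_frequencies(10, 4, seed = 1)
#' sim <- simulate_dyads(5, "HS", fs, seed = 2)
#' fit <- dyadml(sim, fs)
#' coef(fit)
#' @export
dyadml <- function(x, freqs, error = 0, min_loci = 8L, pairs = NULL,
                   grid_step = 0.02, constrain_noninbred = FALSE) {
  stopifnot(inherits(freqs, "freq_set"), error >= 0, error <= 1,
            min_loci >= 1L, grid_step > 0, grid_step <= 0.5)
  batch <- .as_batch(x, freqs, pairs = pairs)
  Q <- .batch_Q(batch, freqs, error)
  n <- nrow(batch$A1)
  grid <- .simplex_grid(grid_step)
  feas <- function(k) !constrain_noninbred || k[2]^2 >= 4 * k[1] * k[3] - 1e-12
  gridkeep <- if (constrain_noninbred) {
    grid[grid[, 2]^2 >= 4 * grid[, 1] * grid[, 3] - 1e-12, , drop = FALSE]
  } else grid

  res <- matrix(NA_real_, n, 6L,
                dimnames = list(NULL, c("r", "k0", "k1", "k2", "loglik", "n_loci_used")))
  for (i in seq_len(n)) {
    use <- !is.na(Q$Q0[i, ])
    res[i, "n_loci_used"] <- sum(use)
    if (sum(use) < min_loci) next
    qm <- rbind(Q$Q0[i, use], Q$Q1[i, use], Q$Q2[i, use])
    fit <- .fit_k(qm, gridkeep, feas)
    res[i, c("k0", "k1", "k2")] <- fit$k
    res[i, "r"] <- fit$k[2] / 2 + fit$k[3]
    res[i, "loglik"] <- fit$loglik
  }
  refused <- res[, "n_loci_used"] < min_loci
  if (any(refused)) {
    warning(sum(refused), " dyad(s) refused: fewer than ", min_loci,
            " usable loci")
  }
  out <- data.frame(id1 = batch$id1, id2 = batch$id2, res)
  structure(out,
            class = c("dyadml", "data.frame"),
            error = error, min_loci = min_loci,
            loci = batch$loci, freqs = freqs,
            call = match.call())
}

# simplex grid over (k0,k1,k2), includes the 4 category vertices
.simplex_grid <- function(step) {
  ks <- seq(0, 1, by = step)
  g <- expand.grid(k1 = ks, k2 = ks)
  g <- g[g$k1 + g$k2 <= 1 + 1e-12, ]
  k <- cbind(1 - g$k1 - g$k2, g$k1, g$k2)
  k[k < 0] <- 0
  unname(k)
}

# maximize sum(log(k %*% qm)) over the simplex; qm is 3 x L
.fit_k <- function(qm, grid, feas) {
  gv <- grid %*% qm
  ll <- rowSums(log(gv))
  ll[is.nan(ll)] <- -Inf
  best <- which.max(ll)
  k0 <- grid[best, ]
  negll <- function(par) {
    k <- c(1 - par[1] - par[2], par[1], par[2])
    if (any(k < 0) || !feas(k)) return(1e12)
    v <- as.vector(k %*% qm)
    if (any(v <= 0)) return(1e12)
    -sum(log(v))
  }
  # nudge the grid optimum slightly interior so the initial simplex is finite
  st <- c(k0[2], k0[3]) * 0.997 + 0.001
  opt <- stats::optim(st, negll, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500L))
  if (is.finite(opt$value) && -opt$value > ll[best]) {
    k <- c(1 - opt$par[1] - opt$par[2], opt$par[1], opt$par[2])
    k <- pmax(k, 0); k <- k / sum(k)
    list(k = k, loglik = -opt$value)
  } else {
    list(k = k0, loglik = ll[best])
  }
}

#' @export
print.dyadml <- function(x, ...) {
  cat("DyadML relatedness estimates: ", nrow(x), " dyad(s), ",
      length(attr(x, "loci")), " loci, assumed error rate ",
      attr(x, "error"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more)\n", sep = "")
  invisible(x)
}

#' @export
summary.dyadml <- function(object, ...) {
  r <- object$r
  out <- list(n = nrow(object), n_refused = sum(is.na(r)),
              mean_r = mean(r, na.rm = TRUE), var_r = stats::var(r, na.rm = TRUE),
              quantiles = stats::quantile(r, c(0, .05, .25, .5, .75, .95, 1),
                                          na.rm = TRUE))
  class(out) <- "summary.dyadml"
  out
}

#' @export
print.summary.dyadml <- function(x, ...) {
  cat("DyadML fit over", x$n, "dyads (", x$n_refused, "refused )\n")
  cat(sprintf("mean r = %.4f, var r = %.4f\n", x$mean_r, x$var_r))
  print(round(x$quantiles, 4))
  invisible(x)
}

#' @export
coef.dyadml <- function(object, ...) {
  stats::setNames(object$r, paste(object$id1, object$id2, sep = ":"))
}

#' @export
logLik.dyadml <- function(object, ...) {
  ll <- sum(object$loglik, na.rm = TRUE)
  structure(ll, df = 2L * sum(!is.na(object$loglik)), class = "logLik")
}

#' @export
plot.dyadml <- function(x, breaks = 30, ...) {
  graphics::hist(x$r, breaks = breaks, xlab = "relatedness estimate r",
                 main = "DyadML estimates", ...)
}

#' @export
simulate.dyadml <- function(object, nsim = 1, seed = NULL, ...) {
  freqs <- attr(object, "freqs")
  ok <- which(!is.na(object$r))
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      sets <- lapply(ok, function(i) {
        k <- as.numeric(object[i, c("k0", "k1", "k2")])
        cat <- structure(list(label = "fitted", k = k,
                              r_expected = k[2] / 2 + k[3]),
                         class = "relationship_category")
        simulate_dyads(1L, cat, freqs, error = attr(object, "error"))
      })
      .bind_dyad_sets(sets)
    })
  })
}

# rbind a list of dyad_sets sharing one locus panel
.bind_dyad_sets <- function(sets) {
  base <- sets[[1]]
  for (f in c("A1", "B1", "A2", "B2")) {
    base[[f]] <- do.call(rbind, lapply(sets, `[[`, f))
  }
  base$id1 <- paste0("d", seq_len(nrow(base$A1)), ".1")
  base$id2 <- paste0("d", seq_len(nrow(base$A1)), ".2")
  base$category <- NULL
  base
}

# ---- moment estimator ------------------------------------------------------

#' Queller-Goodnight moment estimator of relatedness
#'
#' The symmetrized Queller-Goodnight estimate with numerator and
#' denominator sums pooled over loci and over the two orientations of the
#' dyad. May be negative; unbiased for the expected relatedness under the
#' generative model. Monomorphic-for-the-dyad panels (total denominator
#' zero) raise an error.
#'
#' @inheritParams dyadml
#' @return Numeric vector of estimates (one per dyad); for a single
#'   [dyad()], a scalar.
#' @export
queller_goodnight <- function(x, freqs, min_loci = 8L, pairs = NULL) {
  stopifnot(inherits(freqs, "freq_set"))
  batch <- .as_batch(x, freqs, pairs = pairs)
  n <- nrow(batch$A1)
  num <- den <- rep(0, n)
  nloc <- rep(0L, n)
  for (l in seq_along(batch$loci)) {
    p <- as.numeric(freqs[[batch$loci[l]]])
    a <- batch$A1[, l]; b <- batch$B1[, l]
    c_ <- batch$A2[, l]; d <- batch$B2[, l]
    ok <- !is.na(a) & !is.na(c_)
    if (!any(ok)) next
    S <- 0.5 * ((a == c_) + (a == d) + (b == c_) + (b == d))
    nxy <- S - p[a] - p[b]
    dxy <- 1 + (a == b) - p[a] - p[b]
    nyx <- S - p[c_] - p[d]
    dyx <- 1 + (c_ == d) - p[c_] - p[d]
    num[ok] <- num[ok] + nxy[ok] + nyx[ok]
    den[ok] <- den[ok] + dxy[ok] + dyx[ok]
    nloc[ok] <- nloc[ok] + 1L
  }
  bad <- nloc < min_loci
  zero <- !bad & abs(den) < 1e-12
  if (any(zero)) {
    stop("Queller-Goodnight estimate undefined: zero denominator ",
         "(all loci monomorphic for the dyad)")
  }
  r <- num / den
  if (any(bad)) {
    warning(sum(bad), " dyad(s) refused: fewer than ", min_loci, " usable loci")
    r[bad] <- NA_real_
  }
  r
}

# ---- benchmark -------------------------------------------------------------

#' Benchmark relatedness estimators by simulation
#'
#' Simulates `n_per_category` dyads under each relationship category
#' (UR, HS, FS, PO), applies each estimator, and tabulates the mean,
#' variance and mean squared error of the estimates per category plus the
#' pooled correlation of estimates with the expected relatedness. This is
#' the selection procedure that identifies the best estimator for a given
#' marker panel.
#'
#' @param freqs a [freq_set()].
#' @param n_per_category simulated dyads per category (>= 2).
#' @param estimators subset of `c("dyadml", "qg")`.
#' @param error genotyping error rate used both in simulation and (for
#'   dyadml) in estimation.
#' @param seed optional integer seed.
#' @return A data.frame (class `estimator_benchmark`) with one row per
#'   estimator x category (`mean`, `variance`, `mse`) and the pooled
#'   correlations in `attr(, "correlation")`.
#' @export
benchmark_estimators <- function(freqs, n_per_category = 1000L,
                                 estimators = c("dyadml", "qg"),
                                 error = 0, seed = NULL) {
  stopifnot(n_per_category >= 2L)
  known <- c("dyadml", "qg")
  if (!all(estimators %in% known)) {
    stop("unknown estimator(s): ",
         paste(setdiff(estimators, known), collapse = ", "),
         " (available: ", paste(known, collapse = ", "), ")")
  }
  cats <- c("UR", "HS", "FS", "PO")
  with_seed(seed, {
    sims <- lapply(cats, function(cc)
      simulate_dyads(n_per_category, cc, freqs, error = error))
    names(sims) <- cats
    rows <- list(); cors <- c()
    for (est in estimators) {
      rhat_all <- c(); rexp_all <- c()
      for (cc in cats) {
        rhat <- if (est == "dyadml") {
          dyadml(sims[[cc]], freqs, error = error)$r
        } else {
          queller_goodnight(sims[[cc]], freqs)
        }
        re <- relationship_category(cc)$r_expected
        rhat_all <- c(rhat_all, rhat)
        rexp_all <- c(rexp_all, rep(re, length(rhat)))
        mu <- mean(rhat, na.rm = TRUE)
        v <- stats::var(rhat, na.rm = TRUE) * (1 - 1 / sum(!is.na(rhat)))
        rows[[paste(est, cc)]] <- data.frame(
          estimator = est, category = cc, r_expected = re,
          mean = mu, variance = v, mse = mean((rhat - re)^2, na.rm = TRUE))
      }
      cors[est] <- stats::cor(rhat_all, rexp_all, use = "complete.obs")
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, class = c("estimator_benchmark", "data.frame"),
              correlation = cors, n_per_category = n_per_category)
  })
}

#' @export
print.estimator_benchmark <- function(x, ...) {
  cat("Estimator benchmark,", attr(x, "n_per_category"), "dyads per category\n")
  print.data.frame(x, digits = 4)
  cat("pooled correlation with expected r:\n")
  print(round(attr(x, "correlation"), 4))
  invisible(x)
}
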