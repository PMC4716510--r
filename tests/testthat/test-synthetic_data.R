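test_that("generated allele frequencies are valid and honour the equifrequent convention", {
  fs <- gen_frequencies(4, 2, concentration = Inf)
  for (l in seq_along(fs)) expect_equal(unname(fs[[l]]), c(0.5, 0.5))

  fs2 <- gen_frequencies(20, 6, concentration = 0.5, seed = 3)
  for (l in seq_along(fs2)) {
    expect_equal(sum(fs2[[l]]), 1, tolerance = 1e-9)
    expect_true(all(fs2[[l]] > 0))
  }

  # symmetric Dirichlet: mean frequency of allele 1 across many loci = 1/m
  fs3 <- gen_frequencies(4000, 5, concentration = 1, seed = 4)
  m1 <- mean(vapply(fs3, `[`, 0, 1))
  expect_lt(abs(m1 - 0.2), 0.015)  # Dirichlet moment, MC SE ~ 0.0025
})

test_that("simulated dyads obey the category's IBD sharing structure", {
  fs <- gen_frequencies(12, 6, seed = 1)
  po <- simulate_dyads(300, "PO", fs, seed = 2)
  shares <- (po$A1 == po$A2) | (po$A1 == po$B2) |
    (po$B1 == po$A2) | (po$B1 == po$B2)
  expect_true(all(shares))  # k1 = 1 forces a shared allele at every locus

  mono <- freq_set(list(M = c(a = 1)))
  ur <- simulate_dyads(50, "UR", mono, seed = 3)
  expect_true(all(ur$A1 == 1 & ur$B1 == 1 & ur$A2 == 1 & ur$B2 == 1))
})

test_that("FS genotype-pair frequencies match exhaustive enumeration of the generative model", {
  p <- c(A = 0.5, B = 0.5)
  fs <- freq_set(list(L1 = p))
  dist <- enum_pair_dist(p, c(0.25, 0.5, 0.25))
  n <- 20000L
  sim <- simulate_dyads(n, "FS", fs, seed = 9)
  lab <- function(i) names(p)[i]
  keys <- vapply(seq_len(n), function(i) {
    pair_key(c(lab(sim$A1[i, 1]), lab(sim$B1[i, 1])),
             c(lab(sim$A2[i, 1]), lab(sim$B2[i, 1])))
  }, "")
  for (key in names(dist)) {
    obs <- mean(keys == key)
    tol <- 3 * sqrt(dist[key] * (1 - dist[key]) / n)
    expect_lt(abs(obs - dist[key]), tol + 1e-9)
  }
})

test_that("UR dyads are two independent HWE draws (chi-square GOF)", {
  p <- c(A = 0.6, B = 0.4)
  fs <- freq_set(list(L1 = p))
  n <- 10000L
  sim <- simulate_dyads(n, "UR", fs, seed = 21)
  keys <- vapply(seq_len(n), function(i) {
    pair_key(names(p)[c(sim$A1[i, 1], sim$B1[i, 1])],
             names(p)[c(sim$A2[i, 1], sim$B2[i, 1])])
  }, "")
  dist <- enum_pair_dist(p, c(1, 0, 0))
  obs <- table(factor(keys, levels = names(dist)))
  gof <- suppressWarnings(stats::chisq.test(obs, p = dist / sum(dist)))
  expect_gt(gof$p.value, 0.001)
})

test_that("IBD-state-2 sharing fraction matches k2 on a hyper-diverse locus", {
  # with 50 equifrequent alleles, identical heterozygous genotypes almost
  # surely reflect IBD state 2
  fs <- gen_frequencies(1, 50, concentration = Inf)
  for (cc in c("UR", "HS", "FS", "PO")) {
    k2 <- relationship_category(cc)$k[3]
    n <- 3000L
    sim <- simulate_dyads(n, cc, fs, seed = 31)
    both <- mean(sim$A1[, 1] == sim$A2[, 1] & sim$B1[, 1] == sim$B2[, 1])
    tol <- 3 * sqrt(max(k2 * (1 - k2), 0.001) / n) + 0.05  # + chance identity
    expect_lt(abs(both - k2), tol)
  }
})

test_that("genotyping error perturbs the configured fraction of genotypes", {
  fs <- gen_frequencies(1, 40, concentration = Inf)
  a <- simulate_dyads(5000, "PO", fs, error = 0.2, seed = 12)
  shares <- (a$A1 == a$A2) | (a$A1 == a$B2) | (a$B1 == a$A2) | (a$B1 == a$B2)
  # PO sharing is broken when either genotype is redrawn (minus chance share)
  expect_lt(mean(shares), 1)
  expect_gt(mean(shares), 0.5)
})

test_that("pedigree cohorts implement paternity skew and derivable categories", {
  ped <- gen_pedigree_cohort(1, 6, paternity_skew = 1, seed = 1)
  cats <- pedigree_dyad_categories(ped)
  expect_true(all(cats$category == "HS"))  # same top father, distinct mothers

  ped0 <- gen_pedigree_cohort(1, 6, paternity_skew = 0, seed = 2)
  cats0 <- pedigree_dyad_categories(ped0)
  expect_true(all(cats0$category == "UR"))

  # combinatorial count oracle at skew 0.8, one cohort of 10
  ped8 <- gen_pedigree_cohort(1, 10, paternity_skew = 0.8, seed = 3)
  off <- ped8[!is.na(ped8$mother), ]
  expected_hs <- sum(choose(table(off$father), 2))
  cats8 <- pedigree_dyad_categories(ped8)
  expect_equal(sum(cats8$category == "HS"), expected_hs)

  # PO detection against parents
  child <- off$id[1]
  mum <- off$mother[1]
  po <- pedigree_dyad_categories(ped8, ids = c(child, mum))
  expect_equal(po$category, "PO")
})

test_that("gene-dropped genotypes are Mendelian and recover HS relatedness", {
  fs <- panel_18x8()
  ped <- gen_pedigree_cohort(4, 8, paternity_skew = 1, seed = 5)
  tab <- drop_genotypes(ped, fs, error = 0, seed = 6)
  off <- ped$id[!is.na(ped$mother)]
  for (id in off[1:10]) {
    mo <- ped$mother[ped$id == id]
    chk <- mendelian_check(genotypes_of(tab, id), genotypes_of(tab, mo),
                           max_mismatch = 0)
    expect_true(chk$compatible)
  }

  # deterministic inheritance: AA x BB parents give AB offspring
  ped2 <- structure(data.frame(id = c("m", "f", "o"),
                               mother = c(NA, NA, "m"),
                               father = c(NA, NA, "f"),
                               cohort = c(NA, NA, 1)),
                    class = c("pedigree", "data.frame"))
  fs1 <- freq_set(list(L1 = c(A = 0.999, B = 0.001)))
  # force parent genotypes by monomorphic-like loci: use direct check instead
  tab2 <- drop_genotypes(ped2, fs1, seed = 7)
  g_o <- genotypes_of(tab2, "o")
  g_m <- genotypes_of(tab2, "m")
  expect_true(g_o[1, 1] %in% g_m | g_o[2, 1] %in% g_m)
})

test_that("gene-dropping and direct dyad simulation agree on HS relatedness", {
  fs <- panel_18x8()
  ped <- gen_pedigree_cohort(10, 15, paternity_skew = 1,
                             cohorts_per_tenure = 1, seed = 8)
  tab <- drop_genotypes(ped, fs, seed = 9)
  cats <- pedigree_dyad_categories(ped)
  hs <- cats[cats$category == "HS", ]
  set.seed(10)
  hs <- hs[sample(nrow(hs), 1000), ]
  fit_ped <- dyadml(tab, fs, pairs = hs[, c("id1", "id2")])
  fit_sim <- dyadml(simulate_dyads(1000, "HS", fs, seed = 11), fs)
  expect_lt(abs(mean(fit_ped$r) - mean(fit_sim$r)), 0.02)
})

test_that("demographic records honour censoring and the null kin model", {
  d0 <- gen_demography(n_males = 30, censor_month = 0, seed = 1)
  expect_true(all(d0$censored))

  d1 <- gen_demography(n_males = 800, kin_hazard_ratio = 1,
                       censor_month = 1e6, seed = 2)
  ks <- suppressWarnings(
    stats::ks.test(d1$duration_months[d1$kin_at_entry],
                   d1$duration_months[!d1$kin_at_entry]))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(d1$duration_months >= 1))
  expect_true(all(is.na(d1$high_rank_tenure_months) | d1$max_rank <= 3))
  expect_true(all(d1$coresidence_fraction >= 0 & d1$coresidence_fraction <= 1))
})

test_that("demography generator supports Cox parameter recovery", {
  d <- gen_demography(n_males = 500, kin_hazard_ratio = 0.1,
                      baseline_hazard = 0.05, censor_month = 400, seed = 3)
  fit <- cox_fit(d, "kin_at_entry")
  b <- fit$coefficients$beta[1]
  se <- fit$coefficients$se[1]
  expect_lt(abs(b - log(0.1)), 2 * se)
})
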