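test_that("A1 cutoff retains the top fraction of the known-related distribution", {
  x <- 1:100
  rule <- a1_cutoff(x, retain_fraction = 0.85)
  expect_equal(rule$related_threshold,
               unname(quantile(x, 0.15, type = 7)))
  expect_equal(mean(x >= rule$related_threshold), 0.85, tolerance = 0.01)

  allc <- rep(0.3, 20)
  expect_equal(a1_cutoff(allc)$related_threshold, 0.3)
  expect_error(a1_cutoff(1:5), ">= 10")
  expect_error(a1_cutoff(1:20, retain_fraction = 1), "retain_fraction")
})

test_that("A2 cutoffs sit at the stated tail quantiles with a sane exclusion zone", {
  rel <- seq(0.2, 0.6, length.out = 200)
  unr <- seq(0, 0.05, length.out = 200)
  rule <- a2_cutoffs(rel, unr, tail = 0.05)
  expect_equal(rule$related_threshold, unname(quantile(rel, 0.05, type = 7)))
  expect_equal(rule$unrelated_threshold, unname(quantile(unr, 0.95, type = 7)))
  expect_gt(rule$related_threshold, rule$unrelated_threshold)

  expect_warning(a2_cutoffs(unr, unr), "inverted|empty")
  expect_error(a2_cutoffs(rel[1:50], unr), ">= 100")
})

test_that("classification boundaries follow the A1-inclusive / A2-exclusive convention", {
  a2 <- structure(list(kind = "A2", related_threshold = 0.1843,
                       unrelated_threshold = 0.0730, tail = 0.05),
                  class = "cutoff_rule")
  expect_equal(as.character(classify(c(0.20, 0.05, 0.10), a2)),
               c("related", "unrelated", "unassigned"))
  # exclusive boundaries: the thresholds themselves are unassigned
  expect_equal(as.character(classify(c(0.1843, 0.0730), a2)),
               c("unassigned", "unassigned"))

  a1 <- structure(list(kind = "A1", related_threshold = 0.14,
                       retain_fraction = 0.85),
                  class = "cutoff_rule")
  expect_equal(as.character(classify(c(0.14, 0.139), a1)),
               c("related", "unrelated"))  # inclusive boundary, never unassigned
})

test_that("classify is monotone in r", {
  rule <- a2_cutoffs(runif(200, 0.2, 0.5), runif(200, 0, 0.08))
  r <- sort(runif(300, -0.1, 0.9))
  lab <- classify(r, rule)
  ord <- c(unrelated = 1, unassigned = 2, related = 3)
  expect_true(all(diff(ord[as.character(lab)]) >= 0))
})

test_that("validation report reproduces the worked percentage arithmetic", {
  labels <- c(rep("related", 60), "unrelated", rep("unassigned", 18))
  rep79 <- validate_classification(labels)
  expect_equal(rep79$n_total, 79)
  expect_equal(rep79$pct_correct, 75.95)
  expect_equal(rep79$pct_incorrect, 1.27)
  expect_equal(rep79$pct_unassigned, 22.78)
  expect_equal(rep79$n_correct + rep79$n_incorrect + rep79$n_unassigned, 79)
  expect_lt(abs(rep79$pct_correct + rep79$pct_incorrect +
                  rep79$pct_unassigned - 100), 0.02)

  expect_equal(validate_classification(rep("related", 5))$pct_correct, 100)
  three <- validate_classification(c("related", "unrelated", "unassigned"))
  expect_equal(three$pct_correct, 33.33)
})

test_that("A2 error guarantees hold on fresh simulated dyads", {
  fs <- panel_18x8()
  rel_sim <- dyadml(simulate_dyads(1000, "HS", fs, seed = 1), fs)$r
  unr_sim <- dyadml(simulate_dyads(1000, "UR", fs, seed = 2), fs)$r
  # at this panel the HS and UR estimate distributions overlap enough that
  # the exclusion zone is inverted; the constructor must warn about it
  expect_warning(rule <- a2_cutoffs(rel_sim, unr_sim), "inverted|empty")

  # by construction, at most the tail mass of the UR training sample can
  # ever be labelled related (they lie above their own 95th percentile)
  mis_train <- mean(classify(unr_sim, rule) == "related")
  tie_mass <- mean(unr_sim == rule$unrelated_threshold)
  expect_lte(mis_train, 0.05 + tie_mass + 1 / length(unr_sim))

  # HS mislabelled "unrelated" is bounded by the HS mass below the
  # unrelated threshold (checked by direct simulation)
  fresh_hs <- dyadml(simulate_dyads(1000, "HS", fs, seed = 4), fs)$r
  miss_rate <- mean(classify(fresh_hs, rule) == "unrelated")
  mass_below <- mean(fresh_hs < rule$unrelated_threshold)
  expect_lte(miss_rate, mass_below)
  expect_lte(miss_rate, 0.10)
})

test_that("A1 and A2 pipelines agree outside the exclusion zone", {
  fs <- panel_18x8()
  known_hs <- dyadml(simulate_dyads(300, "HS", fs, seed = 5), fs)$r
  a1 <- a1_cutoff(known_hs, 0.85)
  a2 <- suppressWarnings(
    a2_cutoffs(dyadml(simulate_dyads(1000, "HS", fs, seed = 6), fs)$r,
               dyadml(simulate_dyads(1000, "UR", fs, seed = 7), fs)$r))
  mixed <- c(dyadml(simulate_dyads(300, "HS", fs, seed = 8), fs)$r,
             dyadml(simulate_dyads(300, "UR", fs, seed = 9), fs)$r)
  l1 <- classify(mixed, a1)
  l2 <- classify(mixed, a2)
  outside <- l2 != "unassigned"
  expect_gte(mean(l1[outside] == l2[outside]), 0.90)
})

test_that("Mendelian compatibility counts mismatching loci", {
  mo <- rbind(c("A", "A"), c("B", "A")); colnames(mo) <- c("L1", "L2")
  of <- rbind(c("B", "A"), c("C", "B")); colnames(of) <- c("L1", "L2")
  chk <- mendelian_check(of, mo)
  expect_equal(chk$n_mismatch, 0)
  expect_true(chk$compatible)

  of2 <- rbind(c("B", "B"), c("C", "C")); colnames(of2) <- c("L1", "L2")
  mo2 <- rbind(c("A", "B"), c("A", "B")); colnames(mo2) <- c("L1", "L2")
  chk2 <- mendelian_check(of2, mo2)
  expect_equal(chk2$n_mismatch, 1)
  expect_equal(chk2$mismatch_loci, "L1")
  expect_true(chk2$compatible)  # max_mismatch = 1 by default
  expect_false(mendelian_check(of2, mo2, max_mismatch = 0)$compatible)

  mo3 <- rbind(c(NA, NA), c(NA, NA))
  expect_error(mendelian_check(of2, mo3), "no shared")
})

test_that("random unrelated pairs are nearly always Mendelian-incompatible", {
  fs <- panel_18x8()
  sim <- simulate_dyads(400, "UR", fs, seed = 10)
  incompat <- vapply(seq_len(400), function(i) {
    d <- dyad_at(sim, i)
    !mendelian_check(dyad_g1(d), dyad_g2(d), max_mismatch = 1)$compatible
  }, TRUE)
  expect_gte(mean(incompat), 0.95)
})

test_that("kin and peer presence flags match interval logic and a brute-force oracle", {
  rel <- data.frame(id1 = "m1", id2 = "m2", label = "related")
  res <- data.frame(male_id = c("m1", "m2", "m3"),
                    group_id = "G",
                    entry_month = c(10, 0, 0),
                    duration_months = c(20, 40, 5),
                    natal_group = c("N1", "N1", "N2"),
                    birth_cohort = c(1980, 1981, 1980))
  out <- kin_presence_flags(rel, res)
  expect_true(out$kin_at_entry[1])   # relative resident months 0-40 at entry 10
  expect_false(out$kin_at_entry[3])
  expect_false(out$peer_at_entry[3]) # different natal group
  expect_true(out$peer_at_entry[1])  # m2: same natal group, 1 year apart, resident
  expect_false(out$peer_at_entry[2]) # m1 had not yet entered at month 0

  # window logic: relative arrives 2 months after focal male
  res2 <- data.frame(male_id = c("m1", "m2"), group_id = "G",
                     entry_month = c(10, 12), duration_months = c(20, 20))
  out2 <- kin_presence_flags(rel, res2, window_months = 3)
  expect_false(out2$kin_at_entry[1])
  expect_true(out2$kin_3mo[1])

  # m2's spell 12-32 overlaps m1's 10-30 for 18 of 20 months
  expect_equal(out2$coresidence_fraction[2], 0.9)

  # random roster against the brute-force overlap oracle
  set.seed(11)
  ids <- paste0("m", 1:12)
  pairs <- t(combn(ids, 2))
  relr <- data.frame(id1 = pairs[, 1], id2 = pairs[, 2],
                     label = sample(c("related", "unrelated"), nrow(pairs),
                                    TRUE))
  resr <- data.frame(male_id = ids,
                     group_id = sample(c("G1", "G2"), 12, TRUE),
                     entry_month = sample(0:50, 12, TRUE),
                     duration_months = sample(1:60, 12, TRUE))
  got <- kin_presence_flags(relr, resr)
  want <- brute_flags(relr[relr$label == "related", ], resr)
  expect_equal(got$kin_at_entry, want$kin_at_entry)
  expect_equal(got$kin_3mo, want$kin_3mo)

  # overlapping spells for one male in one group are malformed
  bad <- data.frame(male_id = c("m1", "m1"), group_id = "G",
                    entry_month = c(0, 5), duration_months = c(10, 10))
  expect_error(kin_presence_flags(rel, bad), "overlap")
})
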