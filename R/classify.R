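#' Classification cutoffs from known half-siblings (rule A1)
#'
#' Derives a single "related" threshold from the empirical distribution of
#' relatedness estimates of known (pedigree- or paternity-confirmed)
#' half-sibling dyads: the threshold is the empirical `(1 - retain_fraction)`
#' quantile, so that the top `retain_fraction` of the known-related
#' distribution is retained as "related". Quantiles use linear
#' interpolation between order statistics (R type 7).
#'
#' @param known_related_r numeric vector of r-values of known related
#'   dyads (length >= 10).
#' @param retain_fraction fraction of the known-related distribution to
#'   retain (default 0.85).
#' @return A `cutoff_rule` (kind `"A1"`).
#' @export
a1_cutoff <- function(known_related_r, retain_fraction = 0.85) {
  if (length(known_related_r) < 10L) {
    stop("need >= 10 known related r-values to set an A1 cutoff")
  }
  if (!(retain_fraction > 0 && retain_fraction < 1)) {
    stop("retain_fraction must lie in (0, 1)")
  }
  thr <- unname(stats::quantile(known_related_r, 1 - retain_fraction,
                                type = 7, names = FALSE))
  structure(list(kind = "A1", related_threshold = thr,
                 retain_fraction = retain_fraction),
            class = "cutoff_rule")
}

#' Dual classification cutoffs from simulated dyads (rule A2)
#'
#' Uses the simulated r-value distributions of related (half-sibling) and
#' unrelated dyads: "related" above the lower `tail`-quantile of the
#' related simulations, "unrelated" below the upper `(1 - tail)`-quantile
#' of the unrelated simulations, and an exclusion zone (unassigned) in
#' between. If the two thresholds invert (related threshold below the
#' unrelated one) a warning is emitted: the exclusion zone is empty and
#' the "related" test takes precedence in [classify()].
#'
#' @param sim_related_r,sim_unrelated_r numeric vectors of simulated
#'   r-values (each length >= 100).
#' @param tail tail mass in `(0, 0.5)` (default 0.05).
#' @return A `cutoff_rule` (kind `"A2"`) with `related_threshold` and
#'   `unrelated_threshold`.
#' @export
a2_cutoffs <- function(sim_related_r, sim_unrelated_r, tail = 0.05) {
  if (length(sim_related_r) < 100L || length(sim_unrelated_r) < 100L) {
    stop("need >= 100 simulated r-values per distribution for A2 cutoffs")
  }
  if (!(tail > 0 && tail < 0.5)) stop("tail must lie in (0, 0.5)")
  rel <- unname(stats::quantile(sim_related_r, tail, type = 7))
  unr <- unname(stats::quantile(sim_unrelated_r, 1 - tail, type = 7))
  if (rel <= unr) {
    warning("A2 exclusion zone empty or inverted (related threshold ",
            format(rel), " <= unrelated threshold ", format(unr), ")")
  }
  structure(list(kind = "A2", related_threshold = rel,
                 unrelated_threshold = unr, tail = tail),
            class = "cutoff_rule")
}

#' @export
print.cutoff_rule <- function(x, ...) {
  if (x$kind == "A1") {
    cat(sprintf("A1 rule: related iff r >= %.4f (retain top %.0f%% of known related)\n",
                x$related_threshold, 100 * x$retain_fraction))
  } else if (x$related_threshold > x$unrelated_threshold) {
    cat(sprintf("A2 rule: related iff r > %.4f; unrelated iff r < %.4f (tail %.2f)\n",
                x$related_threshold, x$unrelated_threshold, x$tail))
  } else {
    cat(sprintf(
      "A2 rule (inverted zone): related iff r >= %.4f; unrelated iff r <= %.4f; ambiguous band unassigned (tail %.2f)\n",
      x$unrelated_threshold, x$related_threshold, x$tail))
  }
  invisible(x)
}

#' Classify dyads as related / unrelated / unassigned
#'
#' A1 rules are binary with an inclusive boundary (related iff the
#' estimate is at or above the threshold; never unassigned). A2 rules use
#' exclusive boundaries: related strictly above `related_threshold`,
#' unrelated strictly below `unrelated_threshold`, otherwise unassigned.
#' When the exclusion zone is inverted (overlapping related/unrelated
#' bands), a value satisfying both tests is ambiguous evidence and is
#' labelled unassigned; this reduces to the plain rule whenever the zone
#' is proper and keeps the false-related rate at the construction tail by
#' design.
#'
#' @param r numeric vector of relatedness estimates.
#' @param rule a `cutoff_rule` from [a1_cutoff()] or [a2_cutoffs()].
#' @return Factor with levels `related`, `unrelated`, `unassigned`.
#' @export
classify <- function(r, rule) {
  stopifnot(inherits(rule, "cutoff_rule"))
  lv <- c("related", "unrelated", "unassigned")
  out <- if (rule$kind == "A1") {
    ifelse(r >= rule$related_threshold, "related", "unrelated")
  } else {
    looks_rel <- r > rule$related_threshold
    looks_unr <- r < rule$unrelated_threshold
    ifelse(looks_rel & !looks_unr, "related",
           ifelse(looks_unr & !looks_rel, "unrelated", "unassigned"))
  }
  out[is.na(r)] <- NA
  factor(out, levels = lv)
}

#' Validation report for a classification of known-related dyads
#'
#' Given labels produced on dyads that are all truly related, counts
#' correct ("related"), incorrect ("unrelated") and unassigned calls and
#' reports percentage rates rounded half-up to 2 decimals.
#'
#' @param labels factor/character vector of classification labels.
#' @return A `validation_report` list: counts `n_total`, `n_correct`,
#'   `n_incorrect`, `n_unassigned` and matching percentage rates.
#' @export
validate_classification <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("need at least one label")
  if (!all(labels %in% c("related", "unrelated", "unassigned"))) {
    stop("labels must be related / unrelated / unassigned")
  }
  n <- length(labels)
  nc <- sum(labels == "related")
  ni <- sum(labels == "unrelated")
  nu <- sum(labels == "unassigned")
  structure(list(n_total = n, n_correct = nc, n_incorrect = ni,
                 n_unassigned = nu,
                 pct_correct = round_half_up(100 * nc / n, 2L),
                 pct_incorrect = round_half_up(100 * ni / n, 2L),
                 pct_unassigned = round_half_up(100 * nu / n, 2L)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Validation of %d known-related pairs: %d correct (%.2f%%), %d incorrect (%.2f%%), %d unassigned (%.2f%%)\n",
    x$n_total, x$n_correct, x$pct_correct, x$n_incorrect, x$pct_incorrect,
    x$n_unassigned, x$pct_unassigned))
  invisible(x)
}

#' Mendelian compatibility of an offspring-parent pair
#'
#' At each locus typed in both individuals, a mismatch means the offspring
#' shares no allele with the putative mother. The pair is compatible if
#' the mismatch count does not exceed `max_mismatch` (default 1, allowing
#' one genotyping error or null allele).
#'
#' @param offspring,mother 2 x n_loci genotype matrices (see
#'   [genotypes_of()]); column names must agree where both are non-missing.
#' @param max_mismatch maximum tolerated mismatching loci.
#' @return List with `compatible` (flag), `n_mismatch`, `n_loci_compared`
#'   and the mismatching locus names.
#' @export
mendelian_check <- function(offspring, mother, max_mismatch = 1L) {
  stopifnot(nrow(offspring) == 2L, nrow(mother) == 2L,
            ncol(offspring) == ncol(mother))
  ok <- !is.na(offspring[1, ]) & !is.na(mother[1, ])
  if (!any(ok)) stop("no shared non-missing loci to compare")
  shares <- offspring[1, ok] == mother[1, ok] | offspring[1, ok] == mother[2, ok] |
    offspring[2, ok] == mother[1, ok] | offspring[2, ok] == mother[2, ok]
  mm <- sum(!shares)
  loci <- colnames(offspring)[ok] %||% as.character(which(ok))
  list(compatible = mm <= max_mismatch, n_mismatch = mm,
       n_loci_compared = sum(ok), mismatch_loci = loci[!shares])
}

#' Attach kin- and peer-presence flags to residence records
#'
#' For each residence spell, determines from the full roster and a table
#' of classified dyads whether a related male was present at entry,
#' whether one was co-resident within `window_months` after entry, what
#' fraction of the spell was spent with at least one related male
#' co-resident, and (when `natal_group` and `birth_cohort` columns are
#' present) whether a peer — a male from the same natal group born within
#' 2 years — was present at entry.
#'
#' @param classified_dyads data.frame with columns `id1`, `id2`, `label`
#'   (only rows labelled `"related"` matter).
#' @param residence data.frame with columns `male_id`, `group_id`,
#'   `entry_month`, `duration_months` (and optionally `natal_group`,
#'   `birth_cohort`).
#' @param window_months co-residence window after entry (default 3).
#' @param peer_max_cohort_diff maximum birth-cohort difference for peers.
#' @return `residence` with columns `kin_at_entry`, `kin_3mo`,
#'   `peer_at_entry`, `coresidence_fraction` added (recomputed).
#' @export
kin_presence_flags <- function(classified_dyads, residence, window_months = 3L,
                               peer_max_cohort_diff = 2L) {
  need <- c("male_id", "group_id", "entry_month", "duration_months")
  if (!all(need %in% names(residence))) {
    stop("residence records need columns: ", paste(need, collapse = ", "))
  }
  if (any(residence$duration_months < 0)) stop("negative spell duration")
  res <- residence
  res$.exit <- res$entry_month + res$duration_months
  # overlapping spells of the same male in the same group are malformed
  for (key in unique(paste(res$male_id, res$group_id))) {
    rows <- res[paste(res$male_id, res$group_id) == key, ]
    if (nrow(rows) > 1L) {
      o <- order(rows$entry_month)
      if (any(rows$.exit[o][-nrow(rows)] > rows$entry_month[o][-1L])) {
        stop("overlapping spells for male ", rows$male_id[1],
             " in group ", rows$group_id[1])
      }
    }
  }
  rel <- classified_dyads[as.character(classified_dyads$label) == "related", ,
                          drop = FALSE]
  related_to <- function(a, b) {
    any((rel$id1 == a & rel$id2 == b) | (rel$id1 == b & rel$id2 == a))
  }
  has_peer_cols <- all(c("natal_group", "birth_cohort") %in% names(res))
  n <- nrow(res)
  kin_entry <- kin_win <- peer_entry <- logical(n)
  cofrac <- numeric(n)
  for (i in seq_len(n)) {
    others <- which(res$group_id == res$group_id[i] &
                      res$male_id != res$male_id[i])
    ent <- res$entry_month[i]; ext <- res$.exit[i]
    rel_others <- others[vapply(others, function(j)
      related_to(res$male_id[i], res$male_id[j]), TRUE)]
    kin_entry[i] <- any(res$entry_month[rel_others] <= ent &
                          res$.exit[rel_others] >= ent)
    kin_win[i] <- any(res$entry_month[rel_others] <= ent + window_months &
                        res$.exit[rel_others] >= ent)
    if (length(rel_others) && ext > ent) {
      lo <- pmax(res$entry_month[rel_others], ent)
      hi <- pmin(res$.exit[rel_others], ext)
      iv <- cbind(lo, hi)[hi > lo, , drop = FALSE]
      if (nrow(iv)) {
        iv <- iv[order(iv[, 1]), , drop = FALSE]
        tot <- 0; cur_lo <- iv[1, 1]; cur_hi <- iv[1, 2]
        for (j in seq_len(nrow(iv))[-1]) {
          if (iv[j, 1] <= cur_hi) cur_hi <- max(cur_hi, iv[j, 2])
          else { tot <- tot + cur_hi - cur_lo; cur_lo <- iv[j, 1]; cur_hi <- iv[j, 2] }
        }
        tot <- tot + cur_hi - cur_lo
        cofrac[i] <- tot / (ext - ent)
      }
    }
    if (has_peer_cols) {
      peers <- others[!is.na(res$natal_group[others]) &
                        res$natal_group[others] == res$natal_group[i] &
                        abs(res$birth_cohort[others] - res$birth_cohort[i]) <=
                          peer_max_cohort_diff]
      peer_entry[i] <- any(res$entry_month[peers] <= ent &
                             res$.exit[peers] >= ent)
    }
  }
  residence$kin_at_entry <- kin_entry
  residence$kin_3mo <- kin_win
  if (has_peer_cols) residence$peer_at_entry <- peer_entry
  residence$coresidence_fraction <- cofrac
  residence
}
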