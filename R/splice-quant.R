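## Psi estimation, Bayes factors, monotonicity Z, regulated-event calling,
## homolog agreement, direction bias and rescue correlation.

#' Estimate percent spliced in (Psi) from junction counts
#'
#' Junction read counts are normalised by the number of junctions
#' supporting each isoform before forming the inclusion fraction, so that a
#' skipped exon's two inclusion junctions do not inflate Psi.  Credible
#' intervals come from the Beta posterior with a Jeffreys prior on the
#' normalised counts.
#'
#' @param inclusion,exclusion Non-negative junction read counts
#'   (vectorised).
#' @param nIncJunctions,nExcJunctions Number of junctions supporting the
#'   inclusion / exclusion isoform (>= 1); defaults are the skipped-exon
#'   weights 2 and 1.
#' @param conf Credible-interval mass (default 0.95).
#' @return Data frame with columns `psi`, `ci_low`, `ci_high`,
#'   `no_coverage`.  Events with zero reads on both isoforms get `NA` Psi
#'   and `no_coverage = TRUE`.
#' @examples
#' estimatePsi(20, 10, 2, 1)   # psi = 0.5
#' estimatePsi(30, 10, 2, 1)   # psi = 0.6, CI from Beta(15.5, 10.5)
#' @export
estimatePsi <- function(inclusion, exclusion, nIncJunctions = 2,
                        nExcJunctions = 1, conf = 0.95) {
  stopifnot(all(inclusion >= 0), all(exclusion >= 0),
            all(nIncJunctions >= 1), all(nExcJunctions >= 1))
  n <- max(length(inclusion), length(exclusion))
  inclusion <- rep_len(inclusion, n); exclusion <- rep_len(exclusion, n)
  nIncJunctions <- rep_len(nIncJunctions, n)
  nExcJunctions <- rep_len(nExcJunctions, n)
  ni <- inclusion / nIncJunctions
  ne <- exclusion / nExcJunctions
  noCov <- (inclusion + exclusion) == 0
  psi <- ifelse(noCov, NA_real_, ni / (ni + ne))
  a <- ni + 0.5; b <- ne + 0.5
  lo <- (1 - conf) / 2
  ci_low <- ifelse(noCov, NA_real_, qbeta(lo, a, b))
  ci_high <- ifelse(noCov, NA_real_, qbeta(1 - lo, a, b))
  data.frame(psi = psi, ci_low = ci_low, ci_high = ci_high,
             no_coverage = noCov)
}

#' Psi from gel band intensities
#'
#' Background-corrected inclusion product divided by total
#' background-corrected splice product, as in a reporter splicing assay.
#'
#' @param inclusion_intensity,exclusion_intensity Band intensities
#'   (>= `background`).
#' @param background Background intensity to subtract from each band.
#' @return Fraction in `[0, 1]`; `NA` when both corrected intensities are 0.
#' @examples
#' gelPsi(77, 43, 10)   # 67/100 = 0.67
#' @export
gelPsi <- function(inclusion_intensity, exclusion_intensity, background = 0) {
  if (any(inclusion_intensity < background) ||
      any(exclusion_intensity < background))
    stop("intensities must be >= background")
  inc <- inclusion_intensity - background
  exc <- exclusion_intensity - background
  ifelse(inc + exc == 0, NA_real_, inc / (inc + exc))
}

#' Splicing activity relative to human MBNL1
#'
#' `(psi_homolog - psi_mock) / (psi_hsmbnl1 - psi_mock)`: 1 means activity
#' equal to HsMBNL1, 0 means no activity, negative values mean regulation
#' in the opposite direction.
#'
#' @param psi_homolog Psi with the homolog expressed.
#' @param psi_mock Psi with the mock (GFP) control.
#' @param psi_hsmbnl1 Psi with human MBNL1 expressed.
#' @return Numeric; `NA` when the denominator is zero.
#' @examples
#' relativeActivity(0.44, 0.67, 0.19)  # CeMBL on the MBNL1 exon 5 reporter
#' @export
relativeActivity <- function(psi_homolog, psi_mock, psi_hsmbnl1) {
  den <- psi_hsmbnl1 - psi_mock
  ifelse(den == 0, NA_real_, (psi_homolog - psi_mock) / den)
}

#' Two-sample Bayes factor for a Psi difference
#'
#' Conjugate beta-binomial marginal-likelihood ratio: the null integrates a
#' single shared Psi with a Uniform(0,1) prior over both binomial
#' likelihoods; the alternative integrates an independent Psi per sample.
#' Counts are junction-normalised and rounded half-up before the
#' closed-form Beta-function computation.
#'
#' @param inc1,exc1,inc2,exc2 Raw junction read counts (vectorised).
#' @param nIncJunctions,nExcJunctions Junction weights (see
#'   [estimatePsi()]).
#' @return Numeric Bayes factors (alternative over null).  All-zero count
#'   quadruples give BF = 1 and are flagged in the `"noInformation"`
#'   attribute.
#' @examples
#' bayesFactorTwoSample(10, 10, 10, 10, 1, 1)  # identical counts: BF < 1
#' bayesFactorTwoSample(18, 2, 2, 18, 1, 1)    # strong difference: BF >> 5
#' @export
bayesFactorTwoSample <- function(inc1, exc1, inc2, exc2,
                                 nIncJunctions = 2, nExcJunctions = 1) {
  norm <- function(x, w) floor(x / w + 0.5)
  i1 <- norm(inc1, nIncJunctions); e1 <- norm(exc1, nExcJunctions)
  i2 <- norm(inc2, nIncJunctions); e2 <- norm(exc2, nExcJunctions)
  noInfo <- (i1 + e1 + i2 + e2) == 0
  bf <- exp(lbeta(i1 + 1, e1 + 1) + lbeta(i2 + 1, e2 + 1) -
            lbeta(i1 + i2 + 1, e1 + e2 + 1))
  bf[noInfo] <- 1
  attr(bf, "noInformation") <- noInfo
  bf
}

#' Monotonicity Z-score between two replicate groups
#'
#' Welch-type Z on replicate Psi values,
#' `(mean_a - mean_b) / sqrt(max(var_a, eps)/n_a + max(var_b, eps)/n_b)`,
#' with a per-group variance floor `eps` that keeps the statistic finite
#' for degenerate replicate sets.  The sign follows `mean_a - mean_b`.
#'
#' @param group_a_psis,group_b_psis Numeric vectors of replicate Psi values
#'   (at least 2 finite values each).
#' @param varFloor Variance floor (default `1e-4`).
#' @return Signed Z; `NA` when either group has fewer than 2 finite values.
#' @export
monotonicityZ <- function(group_a_psis, group_b_psis, varFloor = 1e-4) {
  a <- group_a_psis[is.finite(group_a_psis)]
  b <- group_b_psis[is.finite(group_b_psis)]
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  num <- mean(a) - mean(b)
  if (num == 0) return(0)
  den <- sqrt(max(var(a), varFloor) / length(a) +
              max(var(b), varFloor) / length(b))
  num / den
}

#' Default regulated-event thresholds
#'
#' Bayes factor > 5, |delta Psi| > 0.1 and monotonicity |Z| > 1.5.
#'
#' @return Named list with `bf_min`, `dpsi_min`, `z_min`.
#' @export
defaultThresholds <- function() list(bf_min = 5, dpsi_min = 0.1, z_min = 1.5)

#' Call regulated splicing events
#'
#' An event is `activated` when `delta_psi > dpsi_min`, `bf > bf_min` and
#' `z > z_min` (Z signed, same direction as delta Psi); `repressed`
#' symmetrically with `delta_psi < -dpsi_min` and `z < -z_min`; otherwise
#' `unaffected`.  When `z` is `NULL` the Z gate is skipped (single-sample
#' homolog comparisons use the two-condition BF + delta-Psi filter).
#' Undefined delta Psi or Z yields `unaffected` with `low_coverage = TRUE`.
#'
#' @param delta_psi Group-mean Psi differences (vectorised).
#' @param bf Bayes factors.
#' @param z Monotonicity Z-scores, or `NULL` to skip the Z gate.
#' @param thresholds List with `bf_min`, `dpsi_min`, `z_min`
#'   (see [defaultThresholds()]); all must be positive.
#' @return Data frame with columns `delta_psi`, `z`, `bf`, `direction`
#'   (factor: activated/repressed/unaffected), `significant`,
#'   `low_coverage`.
#' @export
callRegulation <- function(delta_psi, bf, z = NULL,
                           thresholds = defaultThresholds()) {
  stopifnot(thresholds$bf_min > 0, thresholds$dpsi_min > 0,
            thresholds$z_min > 0)
  n <- length(delta_psi)
  useZ <- !is.null(z)
  if (!useZ) z <- rep(NA_real_, n)
  lowCov <- !is.finite(delta_psi) | (useZ & !is.finite(z))
  zUp <- if (useZ) z > thresholds$z_min else rep(TRUE, n)
  zDn <- if (useZ) z < -thresholds$z_min else rep(TRUE, n)
  act <- !lowCov & delta_psi > thresholds$dpsi_min &
    bf > thresholds$bf_min & zUp
  rep_ <- !lowCov & delta_psi < -thresholds$dpsi_min &
    bf > thresholds$bf_min & zDn
  direction <- rep("unaffected", n)
  direction[act] <- "activated"
  direction[rep_] <- "repressed"
  data.frame(delta_psi = delta_psi, z = z, bf = bf,
             direction = factor(direction,
                                levels = c("activated", "repressed",
                                           "unaffected")),
             significant = act | rep_, low_coverage = lowCov)
}

#' Per-event Psi estimates for a SpliceCounts object
#'
#' @param sc A [SpliceCounts-class] object.
#' @param conf Credible-interval mass.
#' @return Long-format data frame: `event_id`, `sample_id`, `group`,
#'   `psi`, `ci_low`, `ci_high`, `no_coverage`, plus raw counts.
#' @export
quantifyPsi <- function(sc, conf = 0.95) {
  stopifnot(is(sc, "SpliceCounts"))
  inc <- assay(sc, "inclusion"); exc <- assay(sc, "exclusion")
  rd <- rowData(sc)
  events <- rep(rownames(sc), times = ncol(sc))
  samples <- rep(colnames(sc), each = nrow(sc))
  est <- estimatePsi(as.vector(inc), as.vector(exc),
                     rep(rd$n_inc_junctions, times = ncol(sc)),
                     rep(rd$n_exc_junctions, times = ncol(sc)), conf)
  data.frame(event_id = events, sample_id = samples,
             group = colData(sc)$group[match(samples, colnames(sc))],
             est,
             inclusion_reads = as.vector(inc),
             exclusion_reads = as.vector(exc),
             stringsAsFactors = FALSE)
}

#' Compare two sample groups and call regulation per event
#'
#' Delta Psi is the difference of group-mean Psi (`groupA - groupB`).  The
#' Bayes factor is computed on group-pooled junction counts.  The
#' monotonicity Z gate applies only when both groups have >= 2 replicates;
#' single-sample comparisons (homolog lines) are gated on BF and delta Psi
#' alone.
#'
#' @param sc A [SpliceCounts-class] object.
#' @param groupA,groupB Group labels present in `colData(sc)$group`.
#' @param thresholds See [callRegulation()].
#' @return Data frame with one row per event: `event_id`, `comparison`,
#'   plus the [callRegulation()] columns.
#' @export
compareGroups <- function(sc, groupA, groupB,
                          thresholds = defaultThresholds()) {
  stopifnot(is(sc, "SpliceCounts"))
  grp <- colData(sc)$group
  ia <- which(grp == groupA); ib <- which(grp == groupB)
  if (!length(ia) || !length(ib))
    stop("group(s) not found: ",
         paste(c(groupA, groupB)[c(!length(ia), !length(ib))],
               collapse = ", "))
  inc <- assay(sc, "inclusion"); exc <- assay(sc, "exclusion")
  rd <- rowData(sc)
  psiOf <- function(idx) {
    m <- matrix(NA_real_, nrow(sc), length(idx))
    for (j in seq_along(idx)) {
      m[, j] <- estimatePsi(inc[, idx[j]], exc[, idx[j]],
                            rd$n_inc_junctions, rd$n_exc_junctions)$psi
    }
    m
  }
  pa <- psiOf(ia); pb <- psiOf(ib)
  dpsi <- rowMeans(pa, na.rm = TRUE) - rowMeans(pb, na.rm = TRUE)
  dpsi[!is.finite(dpsi)] <- NA_real_
  bf <- bayesFactorTwoSample(rowSums(inc[, ia, drop = FALSE]),
                             rowSums(exc[, ia, drop = FALSE]),
                             rowSums(inc[, ib, drop = FALSE]),
                             rowSums(exc[, ib, drop = FALSE]),
                             rd$n_inc_junctions, rd$n_exc_junctions)
  useZ <- length(ia) >= 2L && length(ib) >= 2L
  z <- if (useZ) {
    vapply(seq_len(nrow(sc)), function(i) monotonicityZ(pa[i, ], pb[i, ]),
           numeric(1))
  } else NULL
  calls <- callRegulation(dpsi, as.numeric(bf), z, thresholds)
  cbind(data.frame(event_id = rownames(sc),
                   comparison = paste0(groupA, "-vs-", groupB),
                   stringsAsFactors = FALSE),
        calls)
}

#' Homolog agreement for one event
#'
#' Counts how many homolog comparisons call the event significant, and
#' whether each significant call shares the direction (sign of delta Psi)
#' of the reference WT-vs-DKO call.
#'
#' @param reference_call One-row data frame (or list) with `delta_psi` for
#'   the WT-vs-DKO comparison of this event.
#' @param homolog_calls Data frame of homolog-vs-control calls for the same
#'   event, with columns `delta_psi` and `significant`.
#' @return List with `n_homologs_regulating`, `consistent_direction`
#'   (TRUE when all significant homolog calls share the reference sign)
#'   and `consistency_fraction`.
#' @export
homologAgreement <- function(reference_call, homolog_calls) {
  sig <- homolog_calls$significant
  n <- sum(sig)
  if (n == 0L)
    return(list(n_homologs_regulating = 0L, consistent_direction = NA,
                consistency_fraction = NA_real_))
  refSign <- sign(reference_call$delta_psi)
  same <- sign(homolog_calls$delta_psi[sig]) == refSign
  list(n_homologs_regulating = as.integer(n),
       consistent_direction = all(same),
       consistency_fraction = mean(same))
}

#' Agreement summary across all events
#'
#' @param referenceCalls [compareGroups()] output for the reference
#'   comparison (WT vs DKO).
#' @param homologCallList Named list of [compareGroups()] outputs, one per
#'   homolog comparison.
#' @return Data frame: `event_id`, `n_homologs_regulating`,
#'   `consistent_direction`, `consistency_fraction`.
#' @export
agreementSummary <- function(referenceCalls, homologCallList) {
  ev <- referenceCalls$event_id
  out <- lapply(seq_along(ev), function(i) {
    hc <- do.call(rbind, lapply(homologCallList, function(h)
      h[h$event_id == ev[i], c("delta_psi", "significant")]))
    a <- homologAgreement(referenceCalls[i, ], hc)
    data.frame(event_id = ev[i],
               n_homologs_regulating = a$n_homologs_regulating,
               consistent_direction = a$consistent_direction,
               consistency_fraction = a$consistency_fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Exact binomial test for activation/repression bias
#'
#' Two-sided exact binomial test of the activated count against an equal
#' split of activated and repressed events.
#'
#' @param n_activated,n_repressed Non-negative event counts (sum >= 1).
#' @return Two-sided p-value.
#' @export
directionBiasTest <- function(n_activated, n_repressed) {
  stopifnot(n_activated >= 0, n_repressed >= 0,
            n_activated + n_repressed >= 1)
  binom.test(n_activated, n_activated + n_repressed, p = 0.5,
             alternative = "two.sided")$p.value
}

#' Squared correlation of rescue delta-Psi values
#'
#' Squared Pearson correlation of paired delta-Psi vectors over the union
#' of significantly regulated events.
#'
#' @param delta_ref_by_event,delta_homolog_by_event Paired numeric vectors
#'   (>= 3 finite pairs).
#' @param comparison Label for the comparison.
#' @return List with `comparison`, `r_squared`, `n_events`; `r_squared` is
#'   `NA` when either vector has zero variance.
#' @export
rescueCorrelation <- function(delta_ref_by_event, delta_homolog_by_event,
                              comparison = "rescue") {
  ok <- is.finite(delta_ref_by_event) & is.finite(delta_homolog_by_event)
  x <- delta_ref_by_event[ok]; y <- delta_homolog_by_event[ok]
  if (length(x) < 3L)
    stop("need at least 3 paired finite delta-Psi values")
  r2 <- if (var(x) == 0 || var(y) == 0) NA_real_ else cor(x, y)^2
  list(comparison = comparison, r_squared = r2, n_events = length(x))
}
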