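#' Nine torsion permutations from three basal and three apical measurements
#'
#' All ordered combinations of the three basal and three apical acquisitions
#' (one each at the subject's minimum, middle and maximum end-expiratory
#' window positions) yield nine torsion values.
#'
#' @param basal,apical either numeric vectors of 3 peak twist angles
#'   (degrees) or lists of 3 `twist_curve` objects.
#' @param d basal-apical distance in cm (required for numeric input; taken
#'   from plane metadata for `twist_curve` input).
#' @return numeric vector of 9 peak torsions (deg/cm), named
#'   `"<basal>.<apical>"` by position index.
#' @export
nine_permutations <- function(basal, apical, d = NULL) {
  if (length(basal) != 3 || length(apical) != 3)
    stop("exactly 3 basal and 3 apical measurements are required")
  if (is.list(basal)) {
    out <- numeric(9)
    nm <- character(9)
    k <- 0
    for (i in 1:3) for (j in 1:3) {
      k <- k + 1
      out[k] <- torsion_curve(basal[[i]], apical[[j]])$peak_torsion
      nm[k] <- paste0("b", i, ".a", j)
    }
    names(out) <- nm
    out
  } else {
    if (is.null(d) || d <= 0) stop("d (cm) required for numeric twist input")
    g <- expand.grid(a = apical, b = basal)  # varies apical fastest
    out <- (g$a - g$b) / d
    names(out) <- paste0("b", rep(1:3, each = 3), ".a", rep(1:3, 3))
    out
  }
}

#' Duplicate-pair RMSE of the consistent-position reference scans
#'
#' For a duplicate measurement pair, the mean squared error about the truth
#' is estimated by `(x1 - x2)^2 / 2`, giving RMSE `|x1 - x2| / sqrt(2)`.
#'
#' @param ref_pair numeric vector of the two repeated middle-window torsions.
#' @return RMSE in deg/cm.
#' @export
rmse_consistent <- function(ref_pair) {
  stopifnot(length(ref_pair) == 2)
  abs(ref_pair[1] - ref_pair[2]) / sqrt(2)
}

#' RMSE of the nine permutations against the reference pair
#'
#' The mean squared error of the nine permutation torsions is computed
#' separately with respect to each of the two middle-window reference scans;
#' the two MSEs are averaged and the square root taken.
#'
#' @param nine numeric vector of 9 permutation torsions.
#' @param ref_pair numeric vector of the two reference torsions.
#' @return RMSE in deg/cm.
#' @export
rmse_permutations <- function(nine, ref_pair) {
  stopifnot(length(nine) == 9, length(ref_pair) == 2)
  mse1 <- mean((nine - ref_pair[1])^2)
  mse2 <- mean((nine - ref_pair[2])^2)
  sqrt((mse1 + mse2) / 2)
}

#' 95% limits-of-agreement half-width
#'
#' @param differences numeric vector (>= 2) of paired measurement
#'   differences.
#' @return `1.96 * sd(differences)` (n-1 denominator).
#' @export
limits_of_agreement <- function(differences) {
  if (length(differences) < 2) stop("need at least 2 differences")
  1.96 * stats::sd(differences)
}

#' Exact binomial test of coverage by the 95% limits of agreement
#'
#' Counts how many values fall within `halfwidth` of their reference center
#' and tests, one-sided, whether coverage is significantly below the nominal
#' 95%: `p = P(X <= k)` for `X ~ Binomial(N, 0.95)`.
#'
#' @param values pooled torsion values (e.g. all subjects' permutations).
#' @param centers reference center per value (recycled; e.g. each subject's
#'   mean of the two middle-window scans).
#' @param halfwidth limits-of-agreement half-width.
#' @return list with `k`, `n`, and the one-sided `p_value`.
#' @export
binomial_within_limits <- function(values, centers, halfwidth) {
  if (length(values) < 1) stop("need at least one value")
  stopifnot(halfwidth >= 0)
  centers <- rep_len(centers, length(values))
  k <- sum(abs(values - centers) <= halfwidth)
  n <- length(values)
  list(k = k, n = n, p_value = stats::pbinom(k, n, 0.95))
}

#' Consecutive basal-apical pairing rule
#'
#' Acquisitions alternate basal, apical, basal, apical in temporal order
#' (basal at slots 1, 3, ..., apical at slots 2, 4, ...). Each basal
#' measurement is paired with its two temporally nearest apical
#' measurements: basal k pairs with apicals k-1 and k (the first basal,
#' having no earlier apical, pairs with apicals 1 and 2). This turns n
#' basal/apical pairs into 2n torsion measurements.
#'
#' @param n number of basal (= apical) acquisitions.
#' @return data.frame with columns `basal` and `apical` (1-based acquisition
#'   numbers within each slice series), `2n` rows, ordered by basal then
#'   temporal slot of the apical.
#' @export
consecutive_pairing <- function(n) {
  stopifnot(n >= 2, n == round(n))
  basal <- rep(seq_len(n), each = 2)
  apical <- as.vector(vapply(seq_len(n), function(k) {
    if (k == 1) c(1L, 2L) else c(k - 1L, k)
  }, integer(2)))
  data.frame(basal = basal, apical = apical)
}

#' Torsion series from interleaved basal/apical twist curves
#'
#' Applies [consecutive_pairing()] to a temporally ordered, alternating
#' acquisition series and computes the torsion of each pairing.
#'
#' @param twists list of `2n` `twist_curve` objects in temporal order,
#'   alternating basal, apical (checked via their `slice_label` and
#'   `acquisition_index` fields).
#' @return data.frame with `basal`, `apical` (series numbers), `slot_basal`,
#'   `slot_apical` (temporal slots) and `peak_torsion`.
#' @export
pair_torsions <- function(twists) {
  n2 <- length(twists)
  if (n2 < 4 || n2 %% 2 != 0) stop("need an even number (>= 4) of twist curves")
  labs <- vapply(twists, function(t) t$slice_label, character(1))
  idx <- vapply(twists, function(t) as.integer(t$acquisition_index), integer(1))
  if (is.unsorted(idx, strictly = TRUE) ||
      !all(labs == rep(c("basal", "apical"), n2 / 2)))
    stop("twist curves must alternate basal, apical in temporal order")
  n <- n2 / 2
  pr <- consecutive_pairing(n)
  pr$slot_basal <- 2L * pr$basal - 1L
  pr$slot_apical <- 2L * pr$apical
  pr$peak_torsion <- vapply(seq_len(nrow(pr)), function(i) {
    torsion_curve(twists[[pr$slot_basal[i]]], twists[[pr$slot_apical[i]]])$peak_torsion
  }, numeric(1))
  pr
}

#' Paired comparison of per-subject torsion variability between protocols
#'
#' Two-sided paired Student's t-test on per-subject standard deviations of
#' the torsion measurements from two protocols. A degenerate test (zero
#' variance of the paired differences) returns p = 1 with a warning.
#'
#' @param sd_a,sd_b per-subject SDs (equal-length, same subject order).
#' @return list with `estimate` (mean difference a - b), `t`, `df`,
#'   `p_value`.
#' @export
protocol_sd_comparison <- function(sd_a, sd_b) {
  if (length(sd_a) != length(sd_b))
    stop("protocols must cover the same subjects")
  d <- sd_a - sd_b
  if (stats::sd(d) == 0 || length(d) < 2) {
    warning("zero variance of paired differences; returning p = 1")
    return(list(estimate = mean(d), t = NA_real_,
                df = length(d) - 1, p_value = 1))
  }
  ht <- stats::t.test(sd_a, sd_b, paired = TRUE)
  list(estimate = unname(ht$estimate), t = unname(ht$statistic),
       df = unname(ht$parameter), p_value = ht$p.value)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y equal-length numeric vectors (n >= 3, non-degenerate).
#' @return list with `r` and `p_value`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value)
}

#' Enforced-variability (experiment 1) analysis
#'
#' Per subject: the nine min/mid/max permutation torsions, the two
#' middle-window reference torsions, the duplicate-pair RMSE and the
#' permutation RMSE. Across subjects: 95% limits of agreement of the
#' reference-pair differences, the pooled binomial coverage test of the
#' permutations (center = each subject's reference-pair mean), the paired
#' comparison of the two RMSEs, and (if scout ranges are supplied) the
#' correlation of permutation RMSE with the end-expiratory range.
#'
#' @param per_subject list, one element per subject, each a list with
#'   `nine` (9 permutation torsions), `ref_pair` (2 reference torsions) and
#'   optionally `scout_range` (mm).
#' @return an object of class `variability_report`.
#' @export
analyze_experiment1 <- function(per_subject) {
  stopifnot(length(per_subject) >= 1)
  tab <- do.call(rbind, lapply(seq_along(per_subject), function(i) {
    s <- per_subject[[i]]
    data.frame(
      subject = names(per_subject)[i] %||% paste0("S", i),
      rmse_consistent = rmse_consistent(s$ref_pair),
      rmse_permutations = rmse_permutations(s$nine, s$ref_pair),
      ref_diff = s$ref_pair[1] - s$ref_pair[2],
      ref_center = mean(s$ref_pair),
      mean_torsion = mean(c(s$nine, s$ref_pair)),
      scout_range = s$scout_range %||% NA_real_
    )
  }))
  loa <- if (nrow(tab) >= 2) limits_of_agreement(tab$ref_diff) else NA_real_
  all_perm <- unlist(lapply(per_subject, `[[`, "nine"))
  centers <- rep(tab$ref_center, each = 9)
  binom <- if (is.finite(loa))
    binomial_within_limits(all_perm, centers, loa) else NULL
  ttest <- if (nrow(tab) >= 2)
    tryCatch(protocol_sd_comparison(tab$rmse_permutations, tab$rmse_consistent),
             warning = function(w) list(estimate = 0, t = NA, df = NA, p_value = 1))
    else NULL
  corr <- if (sum(is.finite(tab$scout_range)) >= 3 &&
              stats::sd(tab$scout_range) > 0 && stats::sd(tab$rmse_permutations) > 0)
    correlate(tab$scout_range, tab$rmse_permutations) else NULL
  structure(list(
    experiment = 1L,
    per_subject = tab,
    rmse_consistent_mean = mean(tab$rmse_consistent),
    rmse_consistent_sd = stats::sd(tab$rmse_consistent),
    rmse_permutations_mean = mean(tab$rmse_permutations),
    rmse_permutations_sd = stats::sd(tab$rmse_permutations),
    pct_reduction = 100 * (mean(tab$rmse_permutations) - mean(tab$rmse_consistent)) /
      mean(tab$rmse_permutations),
    loa_halfwidth = loa,
    binomial = binom,
    rmse_ttest = ttest,
    range_correlation = corr,
    mean_torsion = mean(tab$mean_torsion)
  ), class = "variability_report")
}

#' Natural-variability (experiment 2) analysis
#'
#' Per subject and protocol, the 2n consecutive-pairing torsions give a
#' per-subject SD; protocols are compared with a paired t-test. 95% limits
#' of agreement per protocol come from the SD of differences between
#' consecutive torsion measurements in temporal order (optionally disjoint
#' consecutive pairs). If navigator logs are supplied, the per-subject
#' torsion SD is correlated with the per-subject SD of measured
#' end-expiratory position, pooling both protocols.
#'
#' @param torsions data.frame with columns `subject`, `protocol`
#'   (`"breath_hold"`/`"navigator"`), `order` (temporal order of the
#'   pairing) and `peak_torsion`.
#' @param position_sd optional data.frame with `subject`, `protocol`,
#'   `position_sd` (mm) of the measured end-expiratory positions.
#' @param loa_flavor `"consecutive"` (successive differences, 2n-1 per
#'   subject; default) or `"disjoint"` (non-overlapping pairs, n per
#'   subject).
#' @return an object of class `variability_report`.
#' @export
analyze_experiment2 <- function(torsions, position_sd = NULL,
                                loa_flavor = c("consecutive", "disjoint")) {
  loa_flavor <- match.arg(loa_flavor)
  stopifnot(all(c("subject", "protocol", "order", "peak_torsion") %in% names(torsions)))
  split_sp <- split(torsions, list(torsions$protocol, torsions$subject), drop = TRUE)
  per <- do.call(rbind, lapply(split_sp, function(df) {
    df <- df[order(df$order), ]
    data.frame(subject = df$subject[1], protocol = df$protocol[1],
               sd_torsion = stats::sd(df$peak_torsion),
               mean_torsion = mean(df$peak_torsion))
  }))
  rownames(per) <- NULL
  diffs_by_protocol <- function(proto) {
    unlist(lapply(split(torsions[torsions$protocol == proto, ],
                        torsions$subject[torsions$protocol == proto]),
      function(df) {
        v <- df$peak_torsion[order(df$order)]
        if (loa_flavor == "consecutive") diff(v)
        else v[seq(2, length(v), by = 2)] - v[seq(1, length(v) - 1, by = 2)]
      }))
  }
  protos <- unique(torsions$protocol)
  loa <- vapply(protos, function(p) limits_of_agreement(diffs_by_protocol(p)),
                numeric(1))
  names(loa) <- protos
  sd_wide <- NULL
  ttest <- NULL
  if (all(c("breath_hold", "navigator") %in% protos)) {
    bh <- per[per$protocol == "breath_hold", ]
    nv <- per[per$protocol == "navigator", ]
    common <- intersect(bh$subject, nv$subject)
    if (length(setdiff(union(bh$subject, nv$subject), common)) > 0)
      stop("protocols cover different subject sets")
    bh <- bh[match(common, bh$subject), ]
    nv <- nv[match(common, nv$subject), ]
    sd_wide <- data.frame(subject = common, sd_breath_hold = bh$sd_torsion,
                          sd_navigator = nv$sd_torsion)
    ttest <- protocol_sd_comparison(bh$sd_torsion, nv$sd_torsion)
  }
  corr <- NULL
  if (!is.null(position_sd)) {
    m <- merge(per, position_sd, by = c("subject", "protocol"))
    if (nrow(m) >= 3 && stats::sd(m$position_sd) > 0 && stats::sd(m$sd_torsion) > 0)
      corr <- correlate(m$position_sd, m$sd_torsion)
  }
  structure(list(
    experiment = 2L,
    per_subject = per,
    per_subject_wide = sd_wide,
    sd_breathhold_mean = if (!is.null(sd_wide)) mean(sd_wide$sd_breath_hold) else NA_real_,
    sd_breathhold_sd = if (!is.null(sd_wide)) stats::sd(sd_wide$sd_breath_hold) else NA_real_,
    sd_navigator_mean = if (!is.null(sd_wide)) mean(sd_wide$sd_navigator) else NA_real_,
    sd_navigator_sd = if (!is.null(sd_wide)) stats::sd(sd_wide$sd_navigator) else NA_real_,
    loa_halfwidth = loa,
    loa_flavor = loa_flavor,
    sd_ttest = ttest,
    position_correlation = corr,
    mean_torsion = mean(per$mean_torsion)
  ), class = "variability_report")
}

#' @export
print.variability_report <- function(x, ...) {
  cat(sprintf("<variability_report> experiment %d, %d subject rows\n",
              x$experiment, nrow(x$per_subject)))
  if (x$experiment == 1L) {
    cat(sprintf("  RMSE permutations: %.3f +/- %.3f deg/cm\n",
                x$rmse_permutations_mean, x$rmse_permutations_sd))
    cat(sprintf("  RMSE consistent:   %.3f +/- %.3f deg/cm (%.0f%% lower)\n",
                x$rmse_consistent_mean, x$rmse_consistent_sd, x$pct_reduction))
    if (is.finite(x$loa_halfwidth))
      cat(sprintf("  LoA (consistent): +/-%.2f deg/cm\n", x$loa_halfwidth))
    if (!is.null(x$binomial))
      cat(sprintf("  binomial coverage: %d/%d within limits, p = %.3g\n",
                  x$binomial$k, x$binomial$n, x$binomial$p_value))
  } else {
    cat(sprintf("  SD breath-hold: %.3f +/- %.3f deg/cm\n",
                x$sd_breathhold_mean, x$sd_breathhold_sd))
    cat(sprintf("  SD navigator:   %.3f +/- %.3f deg/cm (t-test p = %.3g)\n",
                x$sd_navigator_mean, x$sd_navigator_sd,
                if (!is.null(x$sd_ttest)) x$sd_ttest$p_value else NA))
    for (p in names(x$loa_halfwidth))
      cat(sprintf("  LoA %s: +/-%.2f deg/cm\n", p, x$loa_halfwidth[[p]]))
  }
  invisible(x)
}
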