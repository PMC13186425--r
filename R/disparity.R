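# Quartile aggregation and Q1-vs-Q4 disparity statistics.
#
# The unit of analysis is the tract: tract-level park means (or size
# metrics) are the observations entering quartile means and the Welch
# t-test contrasting the least (Q1) and most (Q4) privileged quartiles.

#' Per-quartile means
#'
#' @param values numeric vector, one per tract (NA = undefined, excluded)
#' @param quartiles integer vector in 1..4, parallel to `values`
#' @return data.frame: quartile, mean (NA for an empty quartile), n
#' @export
quartile_means <- function(values, quartiles) {
  stopifnot(length(values) == length(quartiles))
  ok <- !is.na(values) & !is.na(quartiles)
  out <- data.frame(quartile = 1:4, mean = NA_real_, n = 0L)
  for (q in 1:4) {
    v <- values[ok & quartiles == q]
    out$n[q] <- length(v)
    if (length(v) > 0L) out$mean[q] <- mean(v)
  }
  out
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch--Satterthwaite degrees of
#' freedom and a two-sided p-value. The statistic is computed directly from
#' the group moments; see the test suite for the cross-check against a
#' reference implementation.
#'
#' @param a,b numeric vectors (each n >= 2, not both zero-variance)
#' @return list(t, df, p)
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("degenerate groups: each needs >= 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va <= 0 && vb <= 0) stop("degenerate groups: zero variance in both")
  se2a <- va / na; se2b <- vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 /
    (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Percent difference between Q1 and Q4 means
#'
#' 100 * (q1 - q4) / q4: positive values mean the least privileged quartile
#' is higher.
#'
#' @param q1_mean,q4_mean quartile means
#' @return percent; `NA` when `q4_mean` is 0
#' @export
percent_diff_q1_q4 <- function(q1_mean, q4_mean) {
  if (is.na(q4_mean) || q4_mean == 0) return(NA_real_)
  100 * (q1_mean - q4_mean) / q4_mean
}

significance_tier <- function(p) {
  if (is.na(p)) return("none")
  if (p < 0.001) return("***")
  if (p < 0.01) return("**")
  if (p < 0.05) return("*")
  "none"
}

#' Full disparity contrast for one urban area and one variable
#'
#' @param values tract-level values (park means or size metric)
#' @param quartiles quartile labels, 1 = least privileged
#' @param urban_mean_value urban-area mean of the variable (for the
#'   difference-from-urban-mean column); NA to skip
#' @param urban_area_id,variable,variant identifiers stamped on the row
#' @return one-row data.frame with quartile means and counts, q1_minus_q4,
#'   percent_diff, Welch t/df/p, significance tier, and per-quartile
#'   differences from the urban mean
#' @export
disparity_row <- function(values, quartiles, urban_mean_value = NA_real_,
                          urban_area_id = "city", variable = "value",
                          variant = "combined") {
  qm <- quartile_means(values, quartiles)
  q1 <- values[!is.na(values) & quartiles == 1L]
  q4 <- values[!is.na(values) & quartiles == 4L]
  tt <- tryCatch(welch_t(q1, q4),
                 error = function(e) list(t = NA_real_, df = NA_real_,
                                          p = NA_real_))
  d14 <- qm$mean[1] - qm$mean[4]
  out <- data.frame(
    urban_area_id = urban_area_id, variant = variant, variable = variable,
    q1_mean = qm$mean[1], q2_mean = qm$mean[2], q3_mean = qm$mean[3],
    q4_mean = qm$mean[4],
    n_q1 = qm$n[1], n_q2 = qm$n[2], n_q3 = qm$n[3], n_q4 = qm$n[4],
    q1_minus_q4 = d14,
    percent_diff_q1_q4 = percent_diff_q1_q4(qm$mean[1], qm$mean[4]),
    t_stat = tt$t, df = tt$df, p_value = tt$p,
    significance = significance_tier(tt$p),
    urban_mean = urban_mean_value,
    stringsAsFactors = FALSE)
  for (q in 1:4) {
    out[[sprintf("q%d_diff_urban", q)]] <-
      if (is.na(urban_mean_value)) NA_real_ else qm$mean[q] - urban_mean_value
  }
  out
}

#' Per-quartile differences from the urban mean across urban areas
#'
#' For each quartile, the distribution over urban areas of (quartile park
#' mean - urban mean), summarised by its median and interquartile range.
#'
#' @param disparity data.frame of [disparity_row()]s (one per urban area)
#' @return data.frame: variable, quartile, median_diff, q25, q75, n_areas
#' @export
diff_from_urban_mean <- function(disparity) {
  out <- list(); k <- 0L
  for (var in unique(disparity$variable)) {
    d <- disparity[disparity$variable == var, , drop = FALSE]
    for (q in 1:4) {
      diffs <- d[[sprintf("q%d_diff_urban", q)]]
      diffs <- diffs[!is.na(diffs)]
      k <- k + 1L
      out[[k]] <- data.frame(
        variable = var, quartile = q,
        median_diff = if (length(diffs)) stats::median(diffs) else NA_real_,
        q25 = if (length(diffs)) unname(stats::quantile(diffs, 0.25)) else NA_real_,
        q75 = if (length(diffs)) unname(stats::quantile(diffs, 0.75)) else NA_real_,
        n_areas = length(diffs), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-city summary of Q1-vs-Q4 differences
#'
#' @param disparity data.frame of [disparity_row()]s across urban areas
#' @param alpha significance level for the per-city counts (default 0.05)
#' @return data.frame per variable: mean absolute Q1-Q4 difference, its
#'   range across urban areas, and counts of urban areas with significant
#'   differences favouring Q4 (q1 > q4, i.e. worse conditions in the least
#'   privileged) and favouring Q1
#' @export
cross_city_summary <- function(disparity, alpha = 0.05) {
  out <- list(); k <- 0L
  for (var in unique(disparity$variable)) {
    d <- disparity[disparity$variable == var, , drop = FALSE]
    diffs <- d$q1_minus_q4
    sig <- !is.na(d$p_value) & d$p_value < alpha
    k <- k + 1L
    out[[k]] <- data.frame(
      variable = var,
      mean_abs_q1_q4 = mean(abs(diffs), na.rm = TRUE),
      min_diff = min(diffs, na.rm = TRUE),
      max_diff = max(diffs, na.rm = TRUE),
      n_sig_q1_higher = sum(sig & diffs > 0, na.rm = TRUE),
      n_sig_q4_higher = sum(sig & diffs < 0, na.rm = TRUE),
      n_areas = nrow(d), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
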