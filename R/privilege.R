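# Neighborhood privilege: the Index of Concentration at the Extremes (ICE).
#
# ICE = (most privileged - least privileged) / total for a small area and
# ranges from -1 (entirely the least advantaged extreme) to +1 (entirely the
# most advantaged). The combined race+income variant counts white-alone
# non-Hispanic householders in the top income brackets as "most privileged"
# and Black householders in the bottom brackets as "least privileged", over
# all householders; the income-only variant uses the all-race bracket table
# at both extremes; the race/ethnicity-only variant uses population counts.
#
# Demographic tables are one row per tract with columns
#   tract_id, urban_area_id,
#   hh_all_b01..hh_all_bNN      all-race householder counts by income bracket
#   hh_black_b01..              Black householder counts, same bracket order
#   hh_white_nh_b01..           white-alone non-Hispanic householders
#   pop_total, pop_white_nh, pop_black
# Brackets are ordered from lowest (b01) to highest income.

bracket_cols <- function(demog, stratum) {
  cols <- grep(paste0("^hh_", stratum, "_b[0-9]+$"), names(demog), value = TRUE)
  cols[order(as.integer(sub(".*_b", "", cols)))]
}

#' Select income-bracket cutpoints for the ICE extremes
#'
#' Walks a running cumulative sum of householder counts from the bottom and
#' from the top of the income-bracket ordering and returns the contiguous
#' bracket sets whose cumulative population share is closest to
#' `target_share` (ties include the extra bracket, tolerating overshoot).
#'
#' @param demog demographic table (see file header for schema)
#' @param target_share target population share at each extreme, default 0.20
#' @param scope "pooled" computes one cutpoint set over all urban areas;
#'   "per_urban_area" computes one per urban area
#' @return an `ice_cutpoints` object: for pooled scope a list with
#'   `low_brackets`, `high_brackets` (integer bracket indices),
#'   `achieved_low_share`, `achieved_high_share`; for per-urban-area scope a
#'   named list of such sets under `$by_area`
#' @export
select_income_cutpoints <- function(demog, target_share = 0.20,
                                    scope = c("pooled", "per_urban_area")) {
  scope <- match.arg(scope)
  stopifnot(target_share > 0, target_share < 0.5)
  cols <- bracket_cols(demog, "all")
  if (length(cols) == 0L) stop("no income bracket columns (hh_all_b*) found")
  one <- function(counts) {
    total <- sum(counts)
    if (total <= 0) stop("no population")
    k <- length(counts)
    lo_shares <- cumsum(counts) / total
    hi_shares <- rev(cumsum(rev(counts))) / total  # share of suffix j..k
    pick <- function(shares) {
      d <- abs(shares - target_share)
      best <- min(d)
      # ties at the minimum: include the extra bracket (larger set)
      max(which(d <= best + 1e-12))
    }
    jlo <- pick(lo_shares)
    jhi_size <- pick(rev(hi_shares))          # size of the suffix
    jhi <- k - jhi_size + 1L
    if (jlo >= jhi) stop("cutpoint extremes overlap; target_share too large for table")
    structure(list(low_brackets = seq_len(jlo),
                   high_brackets = seq.int(jhi, k),
                   achieved_low_share = unname(lo_shares[jlo]),
                   achieved_high_share = unname(hi_shares[jhi]),
                   scope = scope, n_brackets = k),
              class = "ice_cutpoints")
  }
  if (scope == "pooled") {
    one(colSums(demog[, cols, drop = FALSE]))
  } else {
    areas <- split(demog, demog$urban_area_id)
    out <- lapply(areas, function(d) one(colSums(d[, cols, drop = FALSE])))
    structure(list(by_area = out, scope = scope), class = "ice_cutpoints")
  }
}

#' @export
print.ice_cutpoints <- function(x, ...) {
  if (!is.null(x$by_area)) {
    cat("<ice_cutpoints> per urban area:\n")
    for (nm in names(x$by_area)) {
      y <- x$by_area[[nm]]
      cat(sprintf("  %s: low {%s} (%.1f%%), high {%s} (%.1f%%)\n", nm,
                  paste(y$low_brackets, collapse = ","),
                  100 * y$achieved_low_share,
                  paste(y$high_brackets, collapse = ","),
                  100 * y$achieved_high_share))
    }
  } else {
    cat(sprintf("<ice_cutpoints> pooled: low brackets {%s} (share %.1f%%), high brackets {%s} (share %.1f%%)\n",
                paste(x$low_brackets, collapse = ","),
                100 * x$achieved_low_share,
                paste(x$high_brackets, collapse = ","),
                100 * x$achieved_high_share))
  }
  invisible(x)
}

#' Index of Concentration at the Extremes
#'
#' @param most count in the most privileged extreme
#' @param least count in the least privileged extreme
#' @param total total population (denominator)
#' @return (most - least) / total in [-1, 1]; `NA` where `total` is 0.
#'   Vectorised.
#' @export
compute_ice <- function(most, least, total) {
  if (any(most < 0 | least < 0 | total < 0)) stop("counts must be non-negative")
  if (any(total > 0 & most + least > total)) {
    stop("most + least exceeds total")
  }
  ifelse(total > 0, (most - least) / total, NA_real_)
}

#' Compute ICE for every tract
#'
#' @param demog demographic table
#' @param cutpoints an `ice_cutpoints` object (ignored for the race variant)
#' @param variant "combined" (race + income), "income", or "race"
#' @return data.frame: tract_id, urban_area_id, variant, most, least, total,
#'   ice (`NA` where the denominator is zero)
#' @export
compute_ice_table <- function(demog, cutpoints = NULL,
                              variant = c("combined", "income", "race")) {
  variant <- match.arg(variant)
  cp_for <- function(area) {
    if (variant == "race") return(NULL)
    if (is.null(cutpoints)) stop("cutpoints required for variant ", variant)
    if (!is.null(cutpoints$by_area)) {
      cp <- cutpoints$by_area[[as.character(area)]]
      if (is.null(cp)) stop("no cutpoints for urban area ", area)
      cp
    } else cutpoints
  }
  rows <- lapply(split(demog, demog$urban_area_id), function(d) {
    cp <- cp_for(d$urban_area_id[1])
    if (variant == "race") {
      need <- c("pop_white_nh", "pop_black", "pop_total")
      if (!all(need %in% names(d))) stop("missing population columns for race variant")
      most <- d$pop_white_nh; least <- d$pop_black; total <- d$pop_total
    } else {
      all_cols <- bracket_cols(d, "all")
      hi <- all_cols[cp$high_brackets]; lo <- all_cols[cp$low_brackets]
      total <- rowSums(d[, all_cols, drop = FALSE])
      if (variant == "income") {
        most <- rowSums(d[, hi, drop = FALSE])
        least <- rowSums(d[, lo, drop = FALSE])
      } else {
        wcols <- bracket_cols(d, "white_nh"); bcols <- bracket_cols(d, "black")
        if (length(wcols) == 0L || length(bcols) == 0L) {
          stop("combined variant needs hh_white_nh_b* and hh_black_b* columns")
        }
        most <- rowSums(d[, wcols[cp$high_brackets], drop = FALSE])
        least <- rowSums(d[, bcols[cp$low_brackets], drop = FALSE])
      }
    }
    data.frame(tract_id = d$tract_id, urban_area_id = d$urban_area_id,
               variant = variant, most = most, least = least, total = total,
               ice = compute_ice(most, least, total),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign privilege quartiles within urban areas
#'
#' Tracts are ranked by ICE within each urban area (ties broken by stable
#' tract-id order) and split into four groups: quartile 1 is the least
#' privileged, 4 the most. Group sizes are floor(n/4) with the remainder
#' distributed to the lowest quartiles first, so sizes differ by at most
#' one. Tracts with undefined ICE are excluded and reported via the
#' "excluded" attribute.
#'
#' @param ice_df output of [compute_ice_table()] (one variant)
#' @return the defined-ICE rows with a `quartile` column appended
#' @export
assign_quartiles <- function(ice_df) {
  excluded <- ice_df$tract_id[is.na(ice_df$ice)]
  keep <- ice_df[!is.na(ice_df$ice), , drop = FALSE]
  out <- lapply(split(keep, keep$urban_area_id), function(d) {
    n <- nrow(d)
    if (n < 4L) stop("too few tracts with defined ICE in urban area ",
                     d$urban_area_id[1], " (", n, " < 4)")
    if (length(unique(d$ice)) == 1L) {
      warning("all ICE values equal in urban area ", d$urban_area_id[1],
              "; quartiles assigned by stable tract order")
    }
    ord <- order(d$ice, d$tract_id)
    sizes <- rep(n %/% 4L, 4L)
    rem <- n %% 4L
    if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    q <- rep.int(1:4, sizes)
    d$quartile <- NA_integer_
    d$quartile[ord] <- q
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
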