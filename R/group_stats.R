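#' Bootstrap confidence interval for a mean
#'
#' Resamples the data with replacement `B` times (default 6000) and reports
#' the 5th and 95th percentiles of the resampled means (linear interpolation
#' between order statistics), together with the sample mean. Deterministic
#' for a fixed seed.
#'
#' @param values numeric data (>= 1 value).
#' @param B number of bootstrap resamples.
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @return Object of class `bootstrap_ci`: list with `estimate`, `lo`, `hi`,
#'   `n`, `B`, `seed`.
#' @export
bootstrap_ci <- function(values, B = 6000, seed = NULL) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) stop("need at least one value")
  if (!is.null(seed)) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
  }
  if (length(unique(values)) == 1L) {
    lo <- hi <- mean(values)
  } else {
    means <- colMeans(matrix(values[sample.int(n, n * B, replace = TRUE)],
                             nrow = n, ncol = B))
    q <- stats::quantile(means, c(0.05, 0.95), names = FALSE, type = 7)
    lo <- q[1]; hi <- q[2]
  }
  structure(list(estimate = mean(values), lo = lo, hi = hi, n = n, B = B,
                 seed = seed),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("mean %.4g, 90%% bootstrap CI [%.4g, %.4g] (n = %d, B = %d)\n",
              x$estimate, x$lo, x$hi, x$n, x$B))
  invisible(x)
}

#' Burstiness percentile groups for electrodes
#'
#' Assigns electrodes to the groups used to relate morphology to bursting:
#' `nonbursting` (no bursts detected at all), `top5` (at or above the 95th
#' percentile of burstiness among bursting electrodes; ties at the boundary
#' all included), `p1_3` (between the 1st and 3rd percentiles, inclusive)
#' and `other`.
#'
#' @param burstiness_values numeric per-electrode burstiness.
#' @param n_bursts integer per-electrode burst counts (defines
#'   `nonbursting`); defaults to treating zero burstiness as nonbursting.
#' @return Factor with levels `top5`, `p1_3`, `nonbursting`, `other`.
#' @export
burstiness_groups <- function(burstiness_values,
                              n_bursts = as.integer(burstiness_values > 0)) {
  stopifnot(length(n_bursts) == length(burstiness_values))
  grp <- rep("other", length(burstiness_values))
  nonb <- n_bursts == 0
  grp[nonb] <- "nonbursting"
  b <- burstiness_values[!nonb]
  if (length(b)) {
    q95 <- stats::quantile(b, 0.95, names = FALSE, type = 7)
    q1 <- stats::quantile(b, 0.01, names = FALSE, type = 7)
    q3 <- stats::quantile(b, 0.03, names = FALSE, type = 7)
    g <- rep("other", length(b))
    g[b >= q1 & b <= q3] <- "p1_3"
    g[b >= q95] <- "top5"
    grp[!nonb] <- g
  }
  factor(grp, levels = c("top5", "p1_3", "nonbursting", "other"))
}

# quantile-group sizes: n into k groups, remainder spread from the first
.group_sizes <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + as.integer(seq_len(k) <= extra)
}

#' Stratify MEAs into quantile groups per recording date
#'
#' Divides the MEAs of each recording date into `n_groups` quantile groups
#' of a summary key (e.g. tertiles of mean network-burst duration, or a
#' median split of the mean correlation coefficient). Group 1 holds the
#' lowest values. Sizes are as equal as possible, with the remainder going
#' to the first groups (7 MEAs in tertiles -> 3/2/2); ties are broken by MEA
#' id so the partition is deterministic. Dates with fewer MEAs than groups
#' are skipped with a message.
#'
#' @param df data frame with columns `mea_id`, `date` and the key column.
#' @param key name of the key column.
#' @param n_groups number of quantile groups.
#' @return `df` with an added integer `group` column (`NA` for skipped
#'   dates).
#' @export
stratify_meas <- function(df, key, n_groups = 3) {
  stopifnot(all(c("mea_id", "date", key) %in% names(df)))
  df$group <- NA_integer_
  for (d in unique(df$date)) {
    sel <- which(df$date == d & !is.na(df[[key]]))
    if (length(sel) < n_groups) {
      message("date ", d, ": only ", length(sel), " MEA(s), skipped")
      next
    }
    ord <- sel[order(df[[key]][sel], df$mea_id[sel])]
    sizes <- .group_sizes(length(ord), n_groups)
    df$group[ord] <- rep(seq_len(n_groups), times = sizes)
  }
  df
}

#' Join morphology and activity into analysis tables
#'
#' Builds the two tables behind the morphology-activity comparisons: a
#' per-electrode table (clusterness score with burstiness group) and a
#' per-MEA table (cluster ratio with network-burst-duration tertile and
#' correlation median-split), each with bootstrap CIs per group. Recording
#' and image entries are matched by `mea_id` and `date`; unmatched entries
#' are skipped with a message.
#'
#' @param electro data frame with columns `mea_id`, `date`, `electrode_id`,
#'   `burstiness`, `n_bursts`, plus per-MEA summaries `nb_duration` and
#'   `mean_correlation` in `mea_summary`.
#' @param mea_summary data frame with columns `mea_id`, `date`,
#'   `nb_duration`, `mean_correlation`.
#' @param images data frame with columns `mea_id`, `date`, `electrode_id`,
#'   `clusterness`, `cluster_ratio`.
#' @param B,seed bootstrap parameters.
#' @return List with `per_electrode`, `per_mea` (joined rows) and
#'   `group_cis` (bootstrap CI per burstiness group of clusterness).
#' @export
morphology_activity_table <- function(electro, mea_summary, images,
                                      B = 6000, seed = 1) {
  per_electrode <- merge(electro, images,
                         by = c("mea_id", "date", "electrode_id"))
  dropped <- nrow(electro) - nrow(per_electrode)
  if (dropped > 0)
    message(dropped, " electrode row(s) without a matching image, skipped")
  if (nrow(per_electrode)) {
    per_electrode$burst_group <-
      burstiness_groups(per_electrode$burstiness, per_electrode$n_bursts)
  }
  img_mea <- unique(images[, c("mea_id", "date", "cluster_ratio")])
  per_mea <- merge(mea_summary, img_mea, by = c("mea_id", "date"))
  if (nrow(per_mea)) {
    per_mea <- stratify_meas(per_mea, "nb_duration", 3)
    names(per_mea)[names(per_mea) == "group"] <- "nb_duration_tertile"
    per_mea <- stratify_meas(per_mea, "mean_correlation", 2)
    names(per_mea)[names(per_mea) == "group"] <- "correlation_half"
  }
  group_cis <- NULL
  if (nrow(per_electrode)) {
    group_cis <- lapply(split(per_electrode$clusterness,
                              per_electrode$burst_group),
                        function(v) if (length(v[!is.na(v)]))
                          bootstrap_ci(v, B = B, seed = seed) else NULL)
  }
  list(per_electrode = per_electrode, per_mea = per_mea,
       group_cis = group_cis)
}
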