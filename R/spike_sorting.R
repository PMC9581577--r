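#' Project spike waveforms onto their top two principal components
#'
#' Waveforms are mean-centred and projected onto the first two principal
#' axes of their covariance. Two components suffice to separate units whose
#' action-potential shapes differ (e.g. in dominant polarity or width).
#'
#' @param waveforms events x samples numeric matrix.
#' @return events x 2 matrix of PC scores (columns `PC1`, `PC2`).
#' @export
waveform_pca <- function(waveforms) {
  waveforms <- as.matrix(waveforms)
  if (nrow(waveforms) < 2) stop("need >= 2 events for PCA")
  pr <- stats::prcomp(waveforms, center = TRUE, scale. = FALSE)
  sc <- pr$x[, seq_len(min(2L, ncol(pr$x))), drop = FALSE]
  if (ncol(sc) < 2L) sc <- cbind(sc, 0)
  colnames(sc) <- c("PC1", "PC2")
  sc
}

# k-means++ seeding: spread initial centres with distance-proportional sampling
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        centers[j, ] <- x[sample.int(n, 1L), ]
      } else {
        centers[j, ] <- x[sample.int(n, 1L, prob = d2), ]
      }
      dj <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, dj)
    }
  }
  centers
}

# best-of-restarts k-means with k-means++ seeding; returns stats::kmeans fit
.kmeans_restart <- function(x, k, n_restarts) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cent <- .kmeanspp_centers(x, k)
    cent <- cent[!duplicated(cent), , drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = cent, iter.max = 100)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss))
      best <- fit
  }
  best
}

# mean within-cluster radius: mean distance of points to their centroid,
# membership-weighted (equivalently the grand mean over all points)
.mean_cluster_radius <- function(x, labels, centers) {
  d <- sqrt(rowSums((x - centers[labels, , drop = FALSE])^2))
  mean(d)
}

#' Estimate the number of units on an electrode ("knee" of scanning k-means)
#'
#' Runs k-means for k = 1..`k_max` on the PC scores and records the mean
#' within-cluster radius r(k). Splitting a single homogeneous cloud makes
#' log r(k) fall roughly linearly in log k; a genuine multi-unit structure
#' makes r(k) drop below that line at the true unit count. The chosen k is
#' the one with the largest negative residual from the least-squares fit of
#' log r(k) on log k, accepted only if that residual is materially below
#' the fit (at least `min_resid` log units; k-means restart noise and the
#' mild anisotropy of a single waveform cloud produce residuals an order of
#' magnitude smaller) and the relative radius drop from k-1 to k exceeds
#' `min_drop`; otherwise one unit is reported.
#'
#' @param pc_scores events x 2 matrix of PC scores.
#' @param k_max largest candidate unit count (lowered to the number of
#'   distinct points when there are fewer).
#' @param n_restarts k-means restarts per k (k-means++ seeding).
#' @param min_drop minimum relative drop in r(k) to accept a knee.
#' @param min_resid minimum depth (log units) below the log-log fit.
#' @param seed RNG seed for reproducible restarts.
#' @return List with `chosen_k`, `radius_curve` (r(k) for k = 1..k_max) and
#'   `fits` (k-means fits per k, for labelling).
#' @export
estimate_unit_count <- function(pc_scores, k_max = 6, n_restarts = 10,
                                min_drop = 0.2, min_resid = 0.15, seed = 1) {
  x <- as.matrix(pc_scores)
  n_distinct <- nrow(unique(x))
  k_max <- max(1L, min(k_max, n_distinct, nrow(x)))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  r <- numeric(k_max)
  fits <- vector("list", k_max)
  center1 <- matrix(colMeans(x), 1)
  r[1] <- .mean_cluster_radius(x, rep(1L, nrow(x)), center1)
  fits[[1]] <- list(cluster = rep(1L, nrow(x)), centers = center1)
  if (k_max >= 2) for (k in 2:k_max) {
    fit <- .kmeans_restart(x, k, n_restarts)
    if (is.null(fit)) { k_max <- k - 1L; r <- r[1:k_max]; fits <- fits[1:k_max]; break }
    fits[[k]] <- fit
    r[k] <- .mean_cluster_radius(x, fit$cluster, fit$centers)
  }
  chosen <- 1L
  if (k_max >= 2 && r[1] > 0) {
    eps <- max(r) * 1e-12 + 1e-300
    lr <- log(pmax(r, eps))
    lk <- log(seq_len(k_max))
    fit_lm <- stats::lm.fit(cbind(1, lk), lr)
    resid <- fit_lm$residuals
    drop_ok <- c(FALSE, (r[-k_max] - r[-1]) / pmax(r[-k_max], eps) > min_drop)
    cand <- which(resid < -min_resid & drop_ok)
    if (length(cand)) chosen <- cand[which.min(resid[cand])]
  }
  list(chosen_k = as.integer(chosen), radius_curve = r, fits = fits)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Sort the spike events of one electrode into units
#'
#' PCA of the event waveforms followed by scanning k-means with automatic
#' unit-count selection ([estimate_unit_count()]). With fewer than two
#' events sorting is skipped and all events are assigned to unit 1. Units
#' are numbered in order of their first spike.
#'
#' @param events a `spike_events` object from [detect_spikes()].
#' @param k_max,n_restarts,min_drop,min_resid,seed passed to
#'   [estimate_unit_count()].
#' @return List with `sorting` (class `sorting_result`: `electrode_id`,
#'   `chosen_k`, `labels`, `radius_curve`, `pc_scores`) and `units` (list of
#'   [mea_unit()]).
#' @export
sort_electrode <- function(events, k_max = 6, n_restarts = 10,
                           min_drop = 0.2, min_resid = 0.15, seed = 1) {
  stopifnot(inherits(events, "spike_events"))
  n <- length(events$peak_time)
  el <- events$electrode_id
  if (n == 0)
    return(list(sorting = structure(list(electrode_id = el, chosen_k = 0L,
                                         labels = integer(0),
                                         radius_curve = numeric(0),
                                         pc_scores = NULL),
                                    class = "sorting_result"),
                units = list()))
  if (n < 2) {
    labels <- rep(1L, n)
    est <- list(chosen_k = 1L, radius_curve = 0)
    scores <- matrix(0, n, 2, dimnames = list(NULL, c("PC1", "PC2")))
  } else {
    scores <- waveform_pca(events$waveforms)
    est <- estimate_unit_count(scores, k_max = k_max, n_restarts = n_restarts,
                               min_drop = min_drop, min_resid = min_resid,
                               seed = seed)
    labels <- if (est$chosen_k == 1L) rep(1L, n)
              else as.integer(est$fits[[est$chosen_k]]$cluster)
  }
  # renumber units by time of first spike
  first <- tapply(events$peak_time, labels, min)
  remap <- match(labels, as.integer(names(sort(first))))
  units <- lapply(sort(unique(remap)), function(u) {
    sel <- which(remap == u)
    ord <- sel[order(events$peak_time[sel])]
    # spike times are unique per electrode (dead time), so strictly ascending
    mea_unit(unit_id = sprintf("%s_u%d", el, u),
             electrode_id = el,
             spike_times = events$peak_time[ord],
             mean_waveform = colMeans(events$waveforms[sel, , drop = FALSE]))
  })
  list(sorting = structure(list(electrode_id = el,
                                chosen_k = length(units),
                                labels = as.integer(remap),
                                radius_curve = est$radius_curve,
                                pc_scores = scores),
                           class = "sorting_result"),
       units = units)
}

#' @export
print.sorting_result <- function(x, ...) {
  cat(sprintf("<sorting_result> electrode %s: %d unit(s) from %d events\n",
              x$electrode_id, x$chosen_k, length(x$labels)))
  invisible(x)
}
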