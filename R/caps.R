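# Co-activation pattern (CAP) analysis on parcel-level BOLD: k-means
# template extraction on pooled volumes, a cluster-count selection index
# based on inter-group occurrence-rate similarity, volume-wise
# synchronization from parcel analytic phases, and a permutation test of
# per-class CAP occurrence rates.

#' Extract co-activation patterns by k-means
#'
#' Clusters volumes (pooled across conditions and subjects) by Euclidean
#' distance in parcel space with multiple restarts, keeping the best
#' within-cluster sum of squares; deterministic under `seed`.
#'
#' @param volumes n_volumes x n_parcels matrix.
#' @param k cluster count (>= 2, <= n_volumes).
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @param iter_max k-means iteration cap.
#' @return list with `templates` (k x n_parcels centroid matrix), `labels`
#'   (per-volume template index), `withinss`.
#' @export
extract_caps <- function(volumes, k, seed, nstart = 10L, iter_max = 100L) {
  stopifnot(is.matrix(volumes))
  k <- check_count(k, "k", min = 2L)
  if (k > nrow(volumes)) stop("k exceeds the number of volumes")
  set.seed(check_count(seed, "seed", min = 0L))
  km <- kmeans(volumes, centers = k, nstart = nstart, iter.max = iter_max)
  list(templates = unname(km$centers), labels = unname(km$cluster),
       withinss = sum(km$withinss))
}

#' Cluster-count selection index from inter-group similarity
#'
#' For each candidate `k`: cluster the pooled volumes, compute each group's
#' CAP occurrence-rate distribution, and measure the ratio
#' `(CC + UU) / (2 * CU)` of mean inter-group similarities (inverse
#' Euclidean distance between rate vectors) within conscious-like pairs
#' (CC), within unresponsive-like pairs (UU), and across (CU). The
#' recommended `k` maximizes the index; identical groups give an index
#' of 1.
#'
#' @param volumes_by_group named list of n_i x n_parcels matrices.
#' @param side character vector (`"conscious"`/`"unresponsive"`), one per
#'   group; at least two groups per side.
#' @param k_range candidate cluster counts (default 2:30).
#' @param seed integer seed for the clustering restarts.
#' @return data.frame with `k` and `k_index`; attribute `best_k`.
#' @export
select_k <- function(volumes_by_group, side, k_range = 2:30, seed = 1L) {
  stopifnot(is.list(volumes_by_group),
            length(side) == length(volumes_by_group))
  side <- match.arg(side, c("conscious", "unresponsive"),
                    several.ok = TRUE)
  if (sum(side == "conscious") < 2L || sum(side == "unresponsive") < 2L)
    stop("need at least 2 groups on each side")
  pooled <- do.call(rbind, volumes_by_group)
  grp <- rep(seq_along(volumes_by_group),
             vapply(volumes_by_group, nrow, integer(1)))
  eps <- 1e-12
  idx <- vapply(k_range, function(k) {
    caps <- extract_caps(pooled, k, seed = seed)
    rates <- t(vapply(seq_along(volumes_by_group), function(g) {
      tabulate(caps$labels[grp == g], nbins = k) / sum(grp == g)
    }, numeric(k)))
    simil <- function(a, b) 1 / (sqrt(sum((rates[a, ] - rates[b, ])^2)) + eps)
    pair_mean <- function(ga, gb) {
      s <- 0
      cnt <- 0L
      for (a in ga) for (b in gb) if (a < b || !identical(ga, gb)) {
        s <- s + simil(a, b)
        cnt <- cnt + 1L
      }
      s / cnt
    }
    cons <- which(side == "conscious")
    unre <- which(side == "unresponsive")
    CC <- pair_mean(cons, cons)
    UU <- pair_mean(unre, unre)
    CU <- pair_mean(cons, unre)
    (CC + UU) / (2 * CU)
  }, numeric(1))
  out <- data.frame(k = k_range, k_index = idx)
  attr(out, "best_k") <- k_range[which.max(idx)]
  out
}

#' Volume-wise synchronization of parcel BOLD
#'
#' Linearly detrends each parcel's time course, takes its analytic-signal
#' phase, and evaluates the order parameter across parcels at each volume.
#' Constant parcel series (no phase) are flagged and excluded.
#'
#' @param volumes n_volumes x n_parcels matrix (rows are time points).
#' @return list with `r` (per-volume order parameter), `n_parcels_used`,
#'   `constant_parcels` (indices excluded).
#' @export
volume_sync <- function(volumes) {
  stopifnot(is.matrix(volumes), ncol(volumes) >= 2L, nrow(volumes) >= 4L)
  tt <- seq_len(nrow(volumes))
  const <- which(apply(volumes, 2L, function(v) sd(v) == 0))
  use <- setdiff(seq_len(ncol(volumes)), const)
  if (length(use) < 2L) stop("fewer than 2 non-constant parcels")
  detr <- apply(volumes[, use, drop = FALSE], 2L, function(v)
    stats::residuals(stats::lm.fit(cbind(1, tt), v)))
  phases <- t(apply(detr, 2L, function(v) Arg(analytic_signal(v))))
  list(r = order_parameter(phases)$r, n_parcels_used = length(use),
       constant_parcels = const)
}

#' Permutation test of CAP occurrence rates per synchronization class
#'
#' For each class (`low`, `high`), compares the observed per-template
#' occurrence rate at that class's time points with a null built by
#' permuting the CAP label time series uniformly in time (preserving the
#' label multiset) and re-reading the rates at the same time points.
#' Templates whose observed rate exceeds the upper `1 - alpha` null
#' quantile are flagged dominant (one-sided). Volumes classified `neither`
#' take part in the permutations (the label pool) but are tested in
#' neither class.
#'
#' @param labels per-volume template indices (1..k).
#' @param sync_class per-volume factor/character with levels
#'   `low`/`neither`/`high`.
#' @param n_perm number of permutations (>= 1000; 20000 is the reference
#'   setting).
#' @param alpha one-sided significance level (default 0.005, i.e. the
#'   99.5% null percentile).
#' @param seed integer seed.
#' @return object of class `cap_test`: list with `occurrence` (class x
#'   template observed rates), `null_lower`/`null_upper` (alpha and
#'   1-alpha null quantiles), `significant` (class x template logical),
#'   `n_class` (volumes per class), `alpha`, `n_perm`.
#' @export
occurrence_permutation_test <- function(labels, sync_class, n_perm = 20000L,
                                        alpha = 0.005, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm", min = 1000L)
  check_fraction(alpha, "alpha")
  stopifnot(length(labels) == length(sync_class))
  labels <- as.integer(labels)
  k <- max(labels)
  sync_class <- as.character(sync_class)
  set.seed(check_count(seed, "seed", min = 0L))
  n <- length(labels)

  classes <- c("low", "high")
  occurrence <- matrix(NA_real_, 2L, k,
                       dimnames = list(classes, paste0("cap", seq_len(k))))
  null_lower <- null_upper <- occurrence
  significant <- matrix(FALSE, 2L, k,
                        dimnames = dimnames(occurrence))
  n_class <- c(low = sum(sync_class == "low"),
               high = sum(sync_class == "high"))
  for (cl in classes) {
    idx <- which(sync_class == cl)
    if (length(idx) == 0L) next  # empty class: flagged by NA rates
    occurrence[cl, ] <- tabulate(labels[idx], nbins = k) / length(idx)
    null_rates <- matrix(0, n_perm, k)
    for (p in seq_len(n_perm)) {
      perm <- labels[sample.int(n)]
      null_rates[p, ] <- tabulate(perm[idx], nbins = k) / length(idx)
    }
    null_lower[cl, ] <- apply(null_rates, 2L, quantile, probs = alpha)
    null_upper[cl, ] <- apply(null_rates, 2L, quantile, probs = 1 - alpha)
    significant[cl, ] <- occurrence[cl, ] > null_upper[cl, ]
  }
  structure(list(occurrence = occurrence, null_lower = null_lower,
                 null_upper = null_upper, significant = significant,
                 n_class = n_class, alpha = alpha, n_perm = n_perm),
            class = "cap_test")
}

#' @export
print.cap_test <- function(x, ...) {
  cat(sprintf("CAP occurrence permutation test (%d permutations, alpha = %g)\n",
              x$n_perm, x$alpha))
  cat(sprintf("  volumes: low = %d, high = %d\n",
              x$n_class["low"], x$n_class["high"]))
  for (cl in rownames(x$occurrence)) {
    sig <- which(x$significant[cl, ])
    cat(sprintf("  %s-sync dominant CAPs: %s\n", cl,
                if (length(sig)) paste(sig, collapse = ", ") else "none"))
  }
  invisible(x)
}
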