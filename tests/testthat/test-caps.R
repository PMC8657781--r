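# Co-activation pattern pipeline: template recovery, cluster-count
# selection, volume-wise synchronization, and the occurrence permutation
# test.

test_that("k-means recovers planted templates deterministically", {
  pb <- generate_parcel_bold(90, 600, noise_sd = 0.2, seed = 5)
  caps <- extract_caps(pb$volumes, 3, seed = 1)
  expect_gt(mclust::adjustedRandIndex(caps$labels, pb$template_labels), 0.9)
  again <- extract_caps(pb$volumes, 3, seed = 1)
  expect_identical(caps$labels, again$labels)
  expect_error(extract_caps(pb$volumes, 1, seed = 1), "k")
  expect_error(extract_caps(pb$volumes[1:4, ], 10, seed = 1), "exceeds")
})

test_that("the cluster-count index peaks at the planted k", {
  # two conscious-like groups share one occupancy profile, two
  # unresponsive-like groups another; similarity contrast peaks at k = 3
  occ_c <- matrix(c(1 / 3, 1 / 3, 1 / 3, 0.6, 0.2, 0.2), 2, 3, byrow = TRUE)
  occ_u <- matrix(c(0.1, 0.1, 0.8, 0.1, 0.8, 0.1), 2, 3, byrow = TRUE)
  tm <- cap_templates(3, 60, seed = 2)
  # a small per-group parcel offset emulates subject-level variability,
  # which is what keeps overfit cluster counts from scoring as well as the
  # planted one
  mk <- function(occ, seed) {
    v <- generate_parcel_bold(60, 300, templates = tm,
                              occupancy_by_class = occ, noise_sd = 0.15,
                              seed = seed)$volumes
    set.seed(seed + 1000)
    sweep(v, 2, rnorm(60, 0, 0.2), "+")
  }
  groups <- list(c1 = mk(occ_c, 11), c2 = mk(occ_c, 12),
                 u1 = mk(occ_u, 13), u2 = mk(occ_u, 14))
  side <- c("conscious", "conscious", "unresponsive", "unresponsive")
  res <- select_k(groups, side, k_range = 2:6, seed = 3)
  expect_identical(attr(res, "best_k"), 3L)
  expect_gt(res$k_index[res$k == 3], res$k_index[res$k == 2])
  # degenerate equality: identical groups on both sides give index 1
  same <- list(a = groups$c1, b = groups$c1, c = groups$c1, d = groups$c1)
  res_same <- select_k(same, side, k_range = 3, seed = 3)
  expect_equal(res_same$k_index, 1, tolerance = 1e-6)
  expect_identical(nrow(select_k(groups, side, k_range = 2, seed = 1)), 1L)
  expect_error(select_k(groups[1:3], side[1:3], 2:3), "2 groups")
})

test_that("volume-wise synchronization reflects parcel phase alignment", {
  tt <- seq_len(200)
  # all parcels share one time course: full coherence
  shared <- matrix(rep(sin(2 * pi * tt / 20), 6), 200, 6)
  expect_true(all(volume_sync(shared)$r > 0.999))
  # evenly spread constant phase offsets: cancellation
  spread <- sapply(0:5, function(p) sin(2 * pi * tt / 20 + p * pi / 3))
  expect_lt(mean(volume_sync(spread)$r), 0.1)
  # planted high-sync blocks carry higher r than low-sync blocks
  pb <- generate_parcel_bold(90, 600, noise_sd = 0.2, seed = 5)
  vs <- volume_sync(pb$volumes)
  expect_gt(mean(vs$r[pb$class_labels == "high"]),
            mean(vs$r[pb$class_labels == "low"]) + 0.1)
  # constant parcels are flagged and excluded
  withconst <- cbind(shared, 0.7)
  expect_identical(volume_sync(withconst)$constant_parcels, 7L)
})

test_that("the permutation test flags planted dominance at the null level", {
  occ <- matrix(c(1 / 3, 1 / 3, 1 / 3, 0.6, 0.2, 0.2), 2, 3, byrow = TRUE)
  pb <- generate_parcel_bold(90, 600, occupancy_by_class = occ,
                             noise_sd = 0.2, seed = 6)
  caps <- extract_caps(pb$volumes, 3, seed = 1)
  lab <- align_labels(caps$labels, pb$template_labels)
  vs <- volume_sync(pb$volumes)
  cls <- classify_windows(vs$r, "pooled",
                          pooled_stats = c(mean(vs$r), sd(vs$r)))
  tst <- occurrence_permutation_test(lab, cls, n_perm = 2000, seed = 9)
  expect_true(tst$significant["high", 1])
  expect_false(any(tst$significant["high", 2:3]))
  # occurrence rates are proper distributions per class
  expect_equal(rowSums(tst$occurrence), c(low = 1, high = 1),
               tolerance = 1e-12)
  expect_error(occurrence_permutation_test(lab, cls, n_perm = 100),
               "n_perm")
})

test_that("uniform labels are flagged at about the nominal rate", {
  set.seed(10)
  pb <- generate_parcel_bold(30, 600, noise_sd = 0.2, seed = 11)
  vs <- volume_sync(pb$volumes)
  cls <- classify_windows(vs$r, "pooled",
                          pooled_stats = c(mean(vs$r), sd(vs$r)))
  flags <- unlist(lapply(1:25, function(rep) {
    lab <- sample.int(3, 600, replace = TRUE)
    tst <- occurrence_permutation_test(lab, cls, n_perm = 2000,
                                       alpha = 0.005, seed = 100 + rep)
    tst$significant
  }))
  expect_lt(mean(flags), 0.02)  # nominal 0.005, one-sided
})
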