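test_that("hourly counts respect bins, anchors and event conservation", {
  r <- ed_record(c(0.5, 0.5, 23.9), sleep_onset_clock = 23,
                 sleep_offset_clock = 7)
  cnt <- hourly_counts(r)
  expect_equal(cnt[1], 2L)
  expect_equal(cnt[24], 1L)
  expect_equal(sum(cnt), 3L)

  # alignment identity: one event exactly at sleep onset lands in bin 0
  r1 <- ed_record(23, 23, 7)
  expect_equal(hourly_counts(r1, anchor = "sleep_onset")[1], 1L)

  # 45-min bins tile 24 h exactly: 32 equal bins, counts conserved
  set.seed(1)
  r2 <- ed_record(runif(100, 0, 24), 23, 7)
  c45 <- hourly_counts(r2, bin_width_min = 45)
  expect_length(c45, 32)
  expect_false(attr(c45, "short_last_bin"))
  expect_equal(sum(c45), 100L)
  # 50-min bins do not: 29 bins, the last one short (40 min)
  c50 <- hourly_counts(r2, bin_width_min = 50)
  expect_length(c50, 29)
  expect_true(attr(c50, "short_last_bin"))
  expect_equal(sum(c50), 100L)

  # conservation across anchors and widths
  for (a in c("clock", "sleep_onset", "sleep_offset"))
    for (bw in c(45, 60, 90))
      expect_equal(sum(hourly_counts(r2, bw, a)), 100L)

  # empty record is a zero vector, not an error
  expect_equal(sum(hourly_counts(ed_record(numeric(0), 23, 7))), 0L)
  expect_error(hourly_counts(r, anchor = "lunch"))
})

test_that("rate normalisation gives unit-sum rows and cohort curve", {
  cnt <- c(2, 2, rep(0, 22))
  nr <- normalize_rates(rbind(cnt))
  expect_equal(as.numeric(nr$rates[1, 1:3]), c(0.5, 0.5, 0))

  # two identical subjects: cohort curve equals either row
  nr2 <- normalize_rates(rbind(cnt, cnt))
  expect_equal(as.numeric(nr2$cohort_curve), as.numeric(nr2$rates[1, ]))

  # hand-computed cohort curve for two disjoint singletons
  a <- c(1, rep(0, 23)); b <- c(0, 1, rep(0, 22))
  nr3 <- normalize_rates(rbind(a, b))
  expect_equal(as.numeric(nr3$cohort_curve[1:3]), c(0.5, 0.5, 0))

  expect_error(normalize_rates(rbind(rep(0, 24))), "zero events")
  expect_message(normalize_rates(rbind(a, rep(0, 24))), "excluding")
})

test_that("correlation matrix matches a direct-formula Pearson oracle", {
  set.seed(2)
  X <- matrix(runif(8 * 24), 8)
  X <- X / rowSums(X)
  C <- correlation_matrix(X)
  expect_equal(diag(unclass(C)), rep(1, 8), ignore_attr = TRUE)
  expect_equal(unclass(C), t(unclass(C)), ignore_attr = TRUE)
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(C[i, j], pearson_direct(X[i, ], X[j, ]), tolerance = 1e-12)

  # identical rows correlate at 1; a row and its reflection about the mean
  # correlate at -1
  Y <- rbind(X[1, ], X[1, ], 2 * mean(X[1, ]) - X[1, ])
  CY <- correlation_matrix(Y)
  expect_equal(CY[1, 2], 1)
  expect_equal(CY[1, 3], -1)

  # constant profile handled as zero similarity
  Z <- rbind(X[1, ], rep(1 / 24, 24))
  expect_message(CZ <- correlation_matrix(Z), "constant")
  expect_equal(CZ[1, 2], 0)
  expect_error(correlation_matrix(X[1, , drop = FALSE]), "2 subjects")
})

test_that("clustering recovers planted phenotypes and respects k_range", {
  coh <- gen_ed_cohort(n_group1 = 25, n_group2 = 25, seed = 3)
  C <- correlation_matrix(normalize_rates(coh))
  cl <- cluster_subjects(C, seed = 4)
  expect_equal(cl$k_optimal, 2)
  truth <- vapply(coh, `[[`, 1L, "group_label")
  tab <- table(cl$labels, truth)
  expect_gte(sum(apply(tab, 2, max)) / sum(tab), 0.95)
  expect_true(all(names(cl$criterion_curve) == 2:10))

  # two exact blocks of identical rows: infinite criterion handled,
  # perfect recovery
  B <- rbind(matrix(rep(c(1, 0, 0, 1), each = 3), 3, byrow = FALSE),
             matrix(rep(c(0, 1, 1, 0), each = 3), 3, byrow = FALSE))
  clB <- cluster_subjects(correlation_matrix(B), k_range = 2:4, seed = 5)
  expect_equal(clB$k_optimal, 2)
  expect_equal(length(unique(clB$labels[1:3])), 1L)

  # bounds respected on a minimal cohort
  set.seed(6)
  S <- matrix(runif(4 * 24), 4)
  clS <- cluster_subjects(correlation_matrix(S), k_range = 2:3, seed = 7)
  expect_true(clS$k_optimal %in% 2:3)
  expect_error(cluster_subjects(correlation_matrix(S), k_range = 2:4),
               "k_range")
  expect_error(cluster_subjects(matrix(0.5, 5, 5), k_range = 2:3, seed = 1),
               "no cluster structure")
})

test_that("clustering is invariant to subject ordering", {
  coh <- gen_ed_cohort(n_group1 = 15, n_group2 = 15, seed = 8)
  C <- correlation_matrix(normalize_rates(coh))
  cl1 <- cluster_subjects(C, seed = 9)
  perm <- sample(seq_len(nrow(C)))
  cl2 <- cluster_subjects(unclass(C)[perm, perm], seed = 9)
  # same partition up to label permutation
  agree <- table(cl1$labels[perm], cl2$labels)
  expect_equal(sum(apply(agree, 2, max)), nrow(C))
})

test_that("sleep fraction is the mean per-subject in-sleep proportion", {
  # per-subject fractions 0.5 and 1.0 average to 0.75
  rA <- ed_record(c(0, 12), 23, 7)            # 0 in window, 12 out -> 0.5
  rB <- ed_record(c(1, 2), 23, 7)             # both inside -> 1.0
  F <- sleep_fraction(list(rA, rB), groups = c(1, 1))
  expect_equal(as.numeric(F), 0.75)

  allin <- list(ed_record(c(23.2, 0.5), 23, 7))
  expect_equal(as.numeric(sleep_fraction(allin)), 1)
  noneins <- list(ed_record(c(12, 13), 23, 7))
  expect_equal(as.numeric(sleep_fraction(noneins)), 0)

  # the boundary is half-open: an event exactly at offset is outside
  F2 <- sleep_fraction(list(ed_record(c(7), 23, 7)))
  expect_equal(as.numeric(F2), 0)

  expect_warning(sleep_fraction(list(rA, ed_record(numeric(0), 23, 7)),
                                groups = c(1, 1)),
                 "zero events")
})

test_that("density peaks find modes and ignore flat samples", {
  set.seed(10)
  tight <- rnorm(200, 3, 0.2) %% 24
  pk <- density_peaks(tight, bandwidth_h = 0.5)
  expect_equal(pk$location[1], 3, tolerance = 0.3)

  unif <- runif(1000, 0, 24)
  expect_equal(nrow(density_peaks(unif, bandwidth_h = 1)), 0)

  expect_error(density_peaks(tight, bandwidth_h = 0), "bandwidth")
  expect_error(density_peaks(1:5), "10 events")
})
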