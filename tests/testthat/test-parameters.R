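# build a segmentation object directly from a label vector
seg_from <- function(labels, fs = 250, epochs = cbind(0L, length(labels)),
                     K = 4L, subject = "s1", group = "g1") {
  seg <- list(labels = as.integer(labels),
              segments = microstatr:::segments_from_labels(
                as.integer(labels), epochs),
              fs_hz = fs, epochs = epochs,
              class_labels = LETTERS[seq_len(K)],
              subject_id = subject, group = group, migraine = NA,
              peaks = integer(0), peak_class = integer(0))
  class(seg) <- "segmentation"
  seg
}
flat_gfp <- function(n, v = 1) {
  structure(list(values = rep(v, n), peak_indices = integer(0)),
            class = "gfp_series")
}

test_that("duration, occurrence and coverage follow their definitions", {
  # one epoch: 10 A, 15 B, 10 A, 15 C, 10 A  (60 samples total)
  labels <- rep(c(1L, 2L, 1L, 3L, 1L), c(10, 15, 10, 15, 10))
  seg <- seg_from(labels)
  p <- compute_parameters(seg, flat_gfp(60))
  # class B: one interior 15-sample segment -> 60 ms at 250 Hz
  expect_equal(p$duration_ms[p$class == "B"], 60)
  expect_equal(p$duration_ms[p$class == "C"], 60)
  # class A: first and last segments truncated; one interior 10-sample
  expect_equal(p$duration_ms[p$class == "A"], 40)
  # occurrence (default policy counts truncated): A 3 segments in 0.24 s
  expect_equal(p$occurrence_per_s[p$class == "A"], 3 / 0.24)
  expect_equal(p$occurrence_per_s[p$class == "D"], 0)
  # coverage percentages
  expect_equal(p$coverage_pct, c(50, 25, 25, 0), tolerance = 1e-12)
  expect_equal(sum(p$coverage_pct), 100)
  # class with zero qualifying segments -> NA duration, not zero
  expect_true(is.na(p$duration_ms[p$class == "D"]))
  # strict policy drops truncated segments from occurrence
  ps <- compute_parameters(seg, flat_gfp(60), truncation_policy = "strict")
  expect_equal(ps$occurrence_per_s[ps$class == "A"], 1 / 0.24)
})

test_that("six segments of one class in 3 s give occurrence 2 per second", {
  labels <- rep(rep(c(1L, 2L), 6), rep(c(63L, 62L), 6))  # 750 samples = 3 s
  seg <- seg_from(labels, epochs = cbind(0L, 750L))
  p <- compute_parameters(seg, flat_gfp(750))
  expect_equal(p$occurrence_per_s[p$class == "A"], 6 / 3)
})

test_that("mean GFP per class averages the class's samples", {
  labels <- rep(c(1L, 2L), each = 5)
  g <- structure(list(values = c(rep(2, 5), rep(4, 5)),
                      peak_indices = integer(0)), class = "gfp_series")
  p <- compute_parameters(seg_from(labels, epochs = cbind(0L, 10L)), g)
  expect_equal(p$mean_gfp_uv[1:2], c(2, 4))
})

test_that("transition tables count distinct consecutive pairs per epoch", {
  # classes A,B,A,C in one epoch
  labels <- rep(c(1L, 2L, 1L, 3L), each = 10)
  tt <- transition_table(seg_from(labels, epochs = cbind(0L, 40L)))
  expect_equal(tt$counts["A", "B"], 1L)
  expect_equal(tt$counts["A", "C"], 1L)
  expect_equal(tt$counts["B", "A"], 1L)
  expect_equal(tt$n_transitions, 3L)
  expect_equal(tt$percentages["A", c("B", "C")], c(B = 50, C = 50))
  expect_equal(tt$percentages["B", "A"], 100)
  expect_true(all(is.nan(tt$percentages["C", ])))
  expect_true(all(diag(tt$counts) == 0L))
  # single segment: no transitions
  t1 <- transition_table(seg_from(rep(1L, 20), epochs = cbind(0L, 20L)))
  expect_equal(t1$n_transitions, 0L)
  # no counting across epoch boundaries
  t2 <- transition_table(seg_from(rep(c(1L, 2L), each = 10),
                                  epochs = rbind(c(0L, 10L), c(10L, 20L))))
  expect_equal(t2$n_transitions, 0L)
})

test_that("transition counts match an independent pair-scan oracle", {
  set.seed(91)
  for (rep in 1:5) {
    labels <- sample(1:4, 300, replace = TRUE)
    # collapse immediate repeats into runs implicitly via segments
    epochs <- rbind(c(0L, 150L), c(150L, 300L))
    seg <- seg_from(labels, epochs = epochs)
    tt <- transition_table(seg)
    # oracle: scan the label sequence, counting changes within epochs
    cnt <- matrix(0L, 4, 4)
    for (e in 1:2) {
      idx <- (epochs[e, 1] + 1):epochs[e, 2]
      x <- labels[idx]
      for (i in seq_len(length(x) - 1)) {
        if (x[i] != x[i + 1]) cnt[x[i], x[i + 1]] <- cnt[x[i], x[i + 1]] + 1L
      }
    }
    expect_equal(unname(tt$counts), cnt)
  }
})

test_that("the outlier screen excludes subjects beyond group mean + 3 SD", {
  # 21 subjects: twenty at ~70 ms, one at 136 ms
  set.seed(5)
  dur <- c(rnorm(20, 70, 2), 136)
  tab <- data.frame(subject_id = sprintf("s%02d", 1:21), group = "g1",
                    migraine = NA, class = "A", duration_ms = dur)
  expect_lt(mean(dur) + 3 * sd(dur), 136)
  scr <- exclude_outliers(tab, "duration_ms")
  expect_equal(scr$excluded, "s21")
  expect_false("s21" %in% scr$table$subject_id)
  # all-equal values: nobody excluded (SD = 0)
  tab2 <- tab; tab2$duration_ms <- 70
  expect_length(exclude_outliers(tab2, "duration_ms")$excluded, 0L)
  # single pass: a value extreme only after removal stays in
  dur3 <- c(rnorm(19, 70, 0.5), 80, 136)
  tab3 <- tab; tab3$duration_ms <- dur3
  scr3 <- exclude_outliers(tab3, "duration_ms")
  first_pass <- abs(dur3 - mean(dur3)) > 3 * sd(dur3)
  expect_setequal(scr3$excluded, tab3$subject_id[first_pass])
})

test_that("overall value is the unweighted mean of the four class values", {
  tab <- data.frame(subject_id = "s1", group = "g1", migraine = NA,
                    class = c("A", "B", "C", "D"),
                    duration_ms = c(70.07, 65.38, 62.30, 59.40))
  ov <- aggregate_overall(tab, "duration_ms")
  expect_equal(round(ov$overall, 2), 64.29)
  tab$duration_ms <- c(73.78, 70.83, 69.58, 67.16)
  expect_equal(round(aggregate_overall(tab, "duration_ms")$overall, 2),
               70.34)
  tab$duration_ms <- rep(5, 4)
  expect_equal(aggregate_overall(tab, "duration_ms")$overall, 5)
  tab$duration_ms[2] <- NA
  expect_true(is.na(aggregate_overall(tab, "duration_ms")$overall))
})
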