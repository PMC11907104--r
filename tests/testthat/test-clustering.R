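test_that("spatial correlation behaves as a polarity-invariant similarity", {
  u <- c(1, -1, 0, 0); v <- c(0, 0, 1, -1)
  expect_equal(spatial_correlation(u, u), 1)
  expect_equal(spatial_correlation(u, -u), 1)
  expect_equal(spatial_correlation(u, -u, polarity_invariant = FALSE), -1)
  expect_equal(spatial_correlation(u, v), 0)
  expect_error(spatial_correlation(u, c(1, 1, 1, 1)), "zero-variance")
})

test_that("GEV equals 1 for perfect fits and 0 for orthogonal templates", {
  tm <- random_maps(10, 2, seed = 3)
  tm <- qr.Q(qr(tm)); tm <- sweep(tm, 2, colMeans(tm))
  tm <- sweep(tm, 2, sqrt(colSums(tm^2)), "/")
  ts <- template_set(tm, labels = c("A", "B"), level = "norms")
  # maps are scalar multiples of their assigned template
  maps <- cbind(3 * tm[, 1], -2 * tm[, 1], 0.5 * tm[, 2])
  g <- gev(maps, gfp = c(1, 2, 3), ts, assignment = c(1L, 1L, 2L))
  expect_equal(g$total, 1, tolerance = 1e-12)
  # every map exactly orthogonal (and mean-zero) to its assigned template
  u <- c(1, -1, 0, 0); v <- c(0, 0, 1, -1)
  ts2 <- template_set(cbind(A = u / sqrt(2), B = v / sqrt(2)),
                      level = "norms")
  g0 <- gev(cbind(u, v), c(1, 1), ts2, assignment = c(2L, 1L))
  expect_equal(g0$total, 0, tolerance = 1e-12)
  expect_error(gev(maps, c(0, 0, 0), ts, c(1L, 1L, 2L)), "all-zero")
})

test_that("GEV matches an independent direct-summation oracle", {
  # brute force: explicit per-map Pearson correlation and summation
  gev_oracle <- function(maps, gfp, templates, assignment) {
    denom <- sum(gfp^2)
    per <- numeric(ncol(templates))
    for (t in seq_along(assignment)) {
      k <- assignment[t]
      r <- stats::cor(maps[, t], templates[, k])
      per[k] <- per[k] + (gfp[t] * r)^2 / denom
    }
    per
  }
  set.seed(30)
  for (rep in 1:10) {
    E <- sample(5:25, 1)
    n <- sample(5:15, 1)
    maps <- random_maps(E, n, seed = 100 + rep) *
      rep(runif(n, 0.5, 3), each = E)
    tmpl <- random_maps(E, 3, seed = 200 + rep)
    ts <- template_set(tmpl, labels = c("A", "B", "C"), level = "norms")
    w <- runif(n, 0.1, 5)
    a <- sample(1:3, n, replace = TRUE)
    g <- gev(maps, w, ts, a)
    expect_equal(unname(g$per_class), gev_oracle(maps, w, ts$maps, a),
                 tolerance = 1e-12)
    expect_equal(g$total, sum(gev_oracle(maps, w, ts$maps, a)),
                 tolerance = 1e-12)
  }
})

test_that("AAHC recovers exact duplicate pairs and degenerate K", {
  base <- random_maps(10, 3, seed = 4)
  maps <- cbind(base[, 1], -base[, 1], base[, 2], -base[, 2],
                base[, 3], base[, 3])
  fit <- aahc(maps, gfp = rep(1, 6), K_target = 3)
  expect_equal(fit$gev$total, 1, tolerance = 1e-9)
  cc <- abs(crossprod(fit$templates$maps, base))
  expect_equal(sort(apply(cc, 2, max)), rep(1, 3), tolerance = 1e-9)
  # K_target = map count: every map its own cluster
  fit_all <- aahc(maps[, 1:4], rep(1, 4), 4)
  expect_equal(fit_all$gev$total, 1, tolerance = 1e-9)
  expect_error(aahc(maps, rep(1, 6), 0), "K_target")
  expect_error(aahc(maps, rep(1, 6), 7), "K_target")
})

test_that("AAHC GEV is monotone in K and invariant to input sign flips", {
  inst <- three_class_instance(seed = 9)
  gevs <- vapply(1:6, function(k)
    aahc(inst$maps, inst$gfp, k)$gev$total, 0)
  expect_true(all(diff(gevs) >= -1e-12))
  fit <- aahc(inst$maps, inst$gfp, 3)
  set.seed(10)
  flipped <- sweep(inst$maps, 2L,
                   sample(c(-1, 1), ncol(inst$maps), TRUE), "*")
  fit2 <- aahc(flipped, inst$gfp, 3)
  expect_equal(fit2$gev$total, fit$gev$total, tolerance = 1e-9)
  expect_equal(unname(abs(diag(crossprod(fit2$templates$maps,
                                         fit$templates$maps)))),
               rep(1, 3), tolerance = 1e-6)
})

test_that("AAHC reaches the exhaustive-partition optimum on a small instance", {
  inst <- three_class_instance(seed = 15)
  opt <- exhaustive_partition_gev(inst$maps, inst$gfp, 3)
  fit <- aahc(inst$maps, inst$gfp, 3)
  expect_gte(fit$gev$total, 0.95 * opt)
})

test_that("individual fits recover generative templates", {
  qs <- quick_subject(seed = 51)
  ts <- fit_individual_microstates(qs$rec, qs$gfp, 4)
  cc <- abs(crossprod(ts$maps, qs$config$templates$maps))
  best <- apply(cc, 2, max)
  expect_true(all(best >= 0.95))
  expect_gt(ts$gev, 0.8)
  # noiseless subject: near-exact recovery
  cfgN <- sim_config(snr = 1e9, n_epochs = 1L, epoch_s = 10)
  trN <- sample_label_sequence(cfgN, seed = 52L)
  recN <- synthesize_recording(trN, seed = 53L)
  gN <- detect_gfp_peaks(compute_gfp(recN))
  tsN <- fit_individual_microstates(recN, gN, 4)
  ccN <- abs(crossprod(tsN$maps, cfgN$templates$maps))
  expect_true(all(apply(ccN, 2, max) >= 0.999))
})

test_that("sorting recovers permutations and sign flips exactly", {
  ref <- make_canonical_templates()
  expect_equal(sort_templates(ref, ref)$maps, ref$maps)
  perm <- c(3L, 1L, 4L, 2L)
  signs <- c(-1, 1, -1, 1)
  shuffled <- template_set(sweep(ref$maps[, perm], 2L, signs, "*"),
                           labels = c("w", "x", "y", "z"),
                           level = "individual")
  sorted <- sort_templates(shuffled, ref)
  expect_equal(sorted$maps, ref$maps, tolerance = 1e-12)
  expect_equal(sorted$labels, ref$labels)
  expect_equal(attr(sorted, "mean_corr"), 1, tolerance = 1e-12)
})

test_that("sorting matches an independently coded exhaustive search", {
  set.seed(60)
  for (rep in 1:5) {
    a <- template_set(random_maps(8, 4, seed = 300 + rep),
                      level = "individual")
    b <- template_set(random_maps(8, 4, seed = 400 + rep),
                      level = "norms")
    sorted <- sort_templates(a, b)
    # brute force over all 24 permutations with nested loops
    best <- -Inf
    for (p1 in 1:4) for (p2 in 1:4) for (p3 in 1:4) for (p4 in 1:4) {
      p <- c(p1, p2, p3, p4)
      if (length(unique(p)) != 4) next
      s <- sum(vapply(1:4, function(k)
        abs(stats::cor(b$maps[, k], a$maps[, p[k]])), 0))
      if (s > best) best <- s
    }
    expect_equal(attr(sorted, "mean_corr") * 4, best, tolerance = 1e-10)
  }
})

test_that("grand means align classes and polarity before averaging", {
  ref <- make_canonical_templates()
  sets <- list(ref, ref, ref)
  gm <- grand_mean(sets, level = "grand_mean")
  expect_equal(gm$maps, ref$maps, tolerance = 1e-12)
  # permuted, sign-flipped copy still averages to the common set
  perm <- c(2L, 4L, 1L, 3L)
  copy <- template_set(sweep(ref$maps[, perm], 2L, c(-1, -1, 1, 1), "*"),
                       labels = ref$labels, level = "individual")
  gm2 <- grand_mean(list(ref, copy), level = "grand_mean")
  expect_equal(abs(diag(crossprod(gm2$maps, ref$maps))), rep(1, 4),
               tolerance = 1e-9, ignore_attr = TRUE)
  # the aligned mean fits the inputs at least as well as any single input
  set.seed(70)
  rsets <- lapply(1:4, function(i)
    template_set(random_maps(10, 3, seed = 500 + i), level = "individual"))
  gm3 <- grand_mean(rsets, level = "grand_mean")
  fit_of <- function(cand) mean(vapply(rsets, function(s)
    attr(sort_templates(s, cand), "mean_corr"), 0))
  expect_gte(fit_of(gm3) + 1e-9, max(vapply(rsets, fit_of, 0)))
})
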