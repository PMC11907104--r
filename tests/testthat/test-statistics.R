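# balanced split-plot sums-of-squares oracle, coded from the textbook
# decomposition (equal group sizes, complete within factor)
split_plot_oracle <- function(d) {
  g <- levels(d$group); k <- levels(d$class)
  n <- length(unique(d$subject[d$group == g[1]]))
  GM <- mean(d$value)
  ss_group <- length(k) * n * sum((tapply(d$value, d$group, mean) - GM)^2)
  subj_means <- tapply(d$value, d$subject, mean)
  subj_group <- tapply(as.character(d$group), d$subject, `[`, 1)
  ss_subj <- length(k) * sum((subj_means -
                                tapply(d$value, d$group, mean)[subj_group])^2)
  ss_class <- 2 * n * sum((tapply(d$value, d$class, mean) - GM)^2)
  cell <- tapply(d$value, list(d$group, d$class), mean)
  gm_g <- tapply(d$value, d$group, mean)
  gm_k <- tapply(d$value, d$class, mean)
  ss_int <- n * sum((sweep(sweep(cell, 1, gm_g), 2, gm_k) + GM)^2)
  ss_tot <- sum((d$value - GM)^2)
  ss_errw <- ss_tot - ss_group - ss_subj - ss_class - ss_int
  list(F_group = (ss_group / (length(g) - 1)) /
         (ss_subj / (length(g) * (n - 1))),
       F_class = (ss_class / (length(k) - 1)) /
         (ss_errw / (length(g) * (n - 1) * (length(k) - 1))),
       F_int = (ss_int / ((length(g) - 1) * (length(k) - 1))) /
         (ss_errw / (length(g) * (n - 1) * (length(k) - 1))))
}

make_long <- function(n, k = 4, gshift = 0, seed = 1) {
  set.seed(seed)
  d <- expand.grid(subject = sprintf("s%02d", 1:(2 * n)),
                   class = LETTERS[1:k])
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= n, "g1", "g2")
  d$value <- rnorm(nrow(d)) + ifelse(d$group == "g2", gshift, 0)
  d$group <- factor(d$group); d$class <- factor(d$class)
  d
}

test_that("mixed ANOVA F values match a hand-coded SS decomposition", {
  for (seed in 1:3) {
    d <- make_long(5, k = 2, gshift = 0.5, seed = seed)
    res <- mixed_anova(d, value = "value", subject = "subject")
    orc <- split_plot_oracle(d)
    expect_equal(res$F[res$effect == "group"], orc$F_group,
                 tolerance = 1e-10)
    expect_equal(res$F[res$effect == "class"], orc$F_class,
                 tolerance = 1e-10)
    expect_equal(res$F[res$effect == "group:class"], orc$F_int,
                 tolerance = 1e-10)
  }
})

test_that("mixed ANOVA handles degenerate and invalid input", {
  d <- make_long(4)
  d$value <- 7
  res <- mixed_anova(d, subject = "subject")
  expect_equal(res$F, c(0, 0, 0))
  expect_equal(res$p, c(1, 1, 1))
  d2 <- make_long(4)[-1, ]
  expect_error(mixed_anova(d2, subject = "subject"), "unbalanced")
})

test_that("Greenhouse-Geisser correction engages under non-sphericity", {
  # strongly correlated classes with heterogeneous variances violate
  # sphericity; epsilon < 1 and within dfs shrink
  set.seed(8)
  n <- 12
  base <- rnorm(2 * n)
  d <- expand.grid(subject = sprintf("s%02d", 1:(2 * n)),
                   class = LETTERS[1:4])
  d$group <- factor(ifelse(as.integer(sub("s", "", d$subject)) <= n,
                           "g1", "g2"))
  sd_of <- c(A = 0.1, B = 0.1, C = 3, D = 6)
  d$value <- base[as.integer(sub("s", "", d$subject))] *
    c(A = 1, B = 1, C = 8, D = 1)[as.character(d$class)] +
    rnorm(nrow(d), 0, sd_of[as.character(d$class)])
  res <- mixed_anova(d, subject = "subject")
  expect_lt(res$mauchly_p[1], 0.05)
  expect_true(all(res$gg_applied))
  expect_lt(res$gg_epsilon[1], 1)
  expect_gte(res$gg_epsilon[1], 1 / 3)
  expect_equal(res$df1[res$effect == "class"], res$gg_epsilon[1] * 3)
  # p consistent with the corrected dfs
  rc <- res[res$effect == "class", ]
  expect_equal(rc$p, pf(rc$F, rc$df1, rc$df2, lower.tail = FALSE))
})

test_that("Welch t and Cohen's d match independent formulas", {
  set.seed(21)
  for (rep in 1:5) {
    a <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1), sd = runif(1, .5, 2))
    b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1), sd = runif(1, .5, 2))
    w <- welch_t(a, b)
    se2a <- var(a) / length(a); se2b <- var(b) / length(b)
    t_ref <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
    df_ref <- (se2a + se2b)^2 /
      (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
    p_ref <- 2 * pt(abs(t_ref), df_ref, lower.tail = FALSE)
    expect_equal(w$t, t_ref, tolerance = 1e-12)
    expect_equal(w$df, df_ref, tolerance = 1e-12)
    expect_equal(w$p, p_ref, tolerance = 1e-12)
    d_ref <- (mean(a) - mean(b)) /
      sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
             (length(a) + length(b) - 2))
    expect_equal(cohens_d(a, b), d_ref, tolerance = 1e-12)
  }
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_lt(welch_t(c(1, 2, 3), c(11, 12.01, 12.99))$p, 0.001)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # means one pooled SD apart -> d = 1
  a <- c(1, 2, 3); b <- a - 1
  expect_equal(cohens_d(a, b), 1)
  expect_error(cohens_d(rep(1, 3), rep(1, 3)), "zero pooled")
})

test_that("transition comparisons are Bonferroni-corrected over 12 pairs", {
  mk <- function(m) {
    pct <- 100 * m / rowSums(m); diag(pct) <- 0
    list(counts = m, percentages = pct, n_transitions = sum(m))
  }
  set.seed(31)
  tabs <- replicate(6, {
    m <- matrix(rpois(16, 20), 4, 4,
                dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    diag(m) <- 0L
    mk(m)
  }, simplify = FALSE)
  res <- compare_transitions(tabs, tabs)
  expect_equal(nrow(res), 12L)
  expect_equal(res$t, rep(0, 12))
  expect_equal(res$p_bonf, rep(1, 12))
  # correction is min(1, 12 p) and never below the raw p
  tabs2 <- replicate(6, {
    m <- matrix(rpois(16, 20), 4, 4,
                dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    diag(m) <- 0L
    mk(m)
  }, simplify = FALSE)
  res2 <- compare_transitions(tabs, tabs2)
  expect_equal(res2$p_bonf, pmin(1, 12 * res2$p))
  expect_true(all(res2$p_bonf >= res2$p))
})

test_that("TANOVA is exact on identical groups and detects separation", {
  maps <- random_maps(25, 8, seed = 41)
  res <- tanova(maps, maps, n_permutations = 200, seed = 3)
  expect_equal(res$observed_effect, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  # symmetry: swapping group labels leaves p unchanged
  A <- random_maps(25, 8, seed = 42); B <- random_maps(25, 8, seed = 43)
  expect_equal(tanova(A, B, 500, seed = 9)$p,
               tanova(B, A, 500, seed = 9)$p, tolerance = 0.05)
  # orthogonal template families separate decisively
  can <- make_canonical_templates()$maps
  mk <- function(k, seed) {
    set.seed(seed)
    can[, rep(k, 10)] + matrix(rnorm(250, sd = 0.05), 25, 10)
  }
  res2 <- tanova(mk(1, 44), mk(2, 45), n_permutations = 1000, seed = 10)
  expect_lte(res2$p, 0.01)
  # reproducible given seed
  expect_identical(tanova(A, B, 300, seed = 5),
                   tanova(A, B, 300, seed = 5))
  Z <- A; Z[, 1] <- 5  # constant map has zero GFP
  colnames(Z) <- paste0("sub", 1:8)
  expect_error(tanova(Z, B, 200, seed = 1), "sub1")
})
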