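#' Mixed (split-plot) ANOVA with Greenhouse-Geisser correction
#'
#' Two-way mixed analysis of variance with one between-participants factor
#' (group) and one within-participants factor (microstate class).  Sums of
#' squares come from the classical split-plot decomposition
#' (`aov` with a subject error stratum); partial eta squared is computed
#' against each effect's own error stratum.  Mauchly's test of sphericity
#' is run on the pooled within-group covariance of the class values and,
#' when sphericity is rejected at alpha = 0.05, the Greenhouse-Geisser
#' epsilon rescales the degrees of freedom of the within effects (class
#' and interaction) before the p-values are evaluated.
#'
#' @param data data frame with one row per subject x class.
#' @param value,group,class,subject column names (strings).
#' @param sphericity_alpha alpha for the Mauchly pre-test.
#' @return A data frame with one row per effect (`group`, `class`,
#'   `group:class`): `F`, `df1`, `df2` (possibly fractional after
#'   correction), `p`, `peta2`, plus the common `mauchly_W`, `mauchly_p`,
#'   `gg_epsilon` and logical `gg_applied` columns.
#' @export
mixed_anova <- function(data, value = "value", group = "group",
                        class = "class", subject = "subject",
                        sphericity_alpha = 0.05) {
  d <- data.frame(value = data[[value]],
                  group = factor(data[[group]]),
                  class = factor(data[[class]]),
                  subject = factor(data[[subject]]))
  if (any(!is.finite(d$value))) stop("non-finite values in ANOVA input")
  tab <- table(d$subject, d$class)
  if (any(tab != 1L)) {
    bad <- rownames(tab)[rowSums(tab != 1L) > 0]
    stop("unbalanced within-subject cells for subject(s): ",
         paste(bad, collapse = ", "))
  }
  k <- nlevels(d$class)
  g <- nlevels(d$group)
  N <- nlevels(d$subject)
  if (N - g < 1L) stop("need at least 2 subjects per group")

  fit <- stats::aov(value ~ group * class + Error(subject), data = d)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject"]][[1L]])
  within <- as.data.frame(sm[["Error: Within"]][[1L]])
  ss <- function(tab, row) tab[trimws(rownames(tab)) == row, "Sum Sq"]
  df <- function(tab, row) tab[trimws(rownames(tab)) == row, "Df"]
  ss_g <- ss(between, "group");      df_g <- df(between, "group")
  ss_eb <- ss(between, "Residuals"); df_eb <- df(between, "Residuals")
  ss_c <- ss(within, "class");       df_c <- df(within, "class")
  ss_i <- ss(within, "group:class"); df_i <- df(within, "group:class")
  ss_ew <- ss(within, "Residuals");  df_ew <- df(within, "Residuals")

  # pooled within-group covariance of the subject-by-class matrix
  wide <- stats::reshape(d[order(d$subject, d$class), ],
                         direction = "wide", idvar = "subject",
                         timevar = "class", v.names = "value",
                         drop = "group")
  m <- as.matrix(wide[, -1L, drop = FALSE])
  grp_of <- d$group[match(wide$subject, d$subject)]
  centred <- m
  for (gl in levels(grp_of))
    centred[grp_of == gl, ] <- scale(m[grp_of == gl, , drop = FALSE],
                                     scale = FALSE)
  S <- crossprod(centred) / (N - g)

  # Greenhouse-Geisser epsilon from the double-centred covariance
  Sstar <- S - outer(rowMeans(S), rep(1, k)) -
    outer(rep(1, k), colMeans(S)) + mean(S)
  eps <- sum(diag(Sstar))^2 / ((k - 1) * sum(Sstar^2))
  if (!is.finite(eps)) eps <- 1        # degenerate (zero) covariance
  eps <- min(1, max(1 / (k - 1), eps))

  # Mauchly's W on an orthonormal contrast basis
  Ct <- contrast_basis(k)
  A <- Ct %*% S %*% t(Ct)
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (any(lam <= 0)) {
    mauchly_W <- 0; mauchly_p <- 0
  } else {
    mauchly_W <- prod(lam) / (mean(lam))^(k - 1)
    nd <- N - g
    fstat <- -(nd - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1))) *
      log(mauchly_W)
    mauchly_p <- stats::pchisq(fstat, k * (k - 1) / 2 - 1,
                               lower.tail = FALSE)
  }
  gg_applied <- is.finite(mauchly_p) && mauchly_p < sphericity_alpha

  # SS at numerical-noise level (e.g. perfectly constant data) count as 0
  ss_tol <- 1e-12 * max(sum(d$value^2), .Machine$double.eps)
  f_of <- function(ss_e, df_e, ss_err, df_err) {
    if (ss_e < ss_tol) return(0)
    (ss_e / df_e) / (ss_err / df_err)
  }
  p_of <- function(F, df1, df2) {
    if (F == 0) return(1)
    stats::pf(F, df1, df2, lower.tail = FALSE)
  }
  peta <- function(ss_e, ss_err)
    if (ss_e + ss_err == 0) 0 else ss_e / (ss_e + ss_err)

  e <- if (gg_applied) eps else 1
  F_g <- f_of(ss_g, df_g, ss_eb, df_eb)
  F_c <- f_of(ss_c, df_c, ss_ew, df_ew)
  F_i <- f_of(ss_i, df_i, ss_ew, df_ew)
  res <- data.frame(
    effect = c("group", "class", "group:class"),
    F = c(F_g, F_c, F_i),
    df1 = c(df_g, e * df_c, e * df_i),
    df2 = c(df_eb, e * df_ew, e * df_ew),
    peta2 = c(peta(ss_g, ss_eb), peta(ss_c, ss_ew), peta(ss_i, ss_ew)))
  res$p <- c(p_of(F_g, df_g, df_eb),
             p_of(F_c, e * df_c, e * df_ew),
             p_of(F_i, e * df_i, e * df_ew))
  res$mauchly_W <- mauchly_W
  res$mauchly_p <- mauchly_p
  res$gg_epsilon <- eps
  res$gg_applied <- gg_applied
  res
}

# (k-1) x k orthonormal basis orthogonal to the unit vector (Helmert)
contrast_basis <- function(k) {
  H <- stats::contr.helmert(k)
  t(H) / sqrt(colSums(H^2))
}

#' Welch's unequal-variance t test
#'
#' Two-sample t statistic with the Welch-Satterthwaite (fractional)
#' degrees of freedom and a two-tailed p-value.
#'
#' @param a,b numeric samples (each of size >= 2).
#' @return A data frame row: `t`, `df`, `p`, `mean_a`, `mean_b`, `d`
#'   (Cohen's d, [cohens_d()]).
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 finite values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(data.frame(t = 0, df = length(a) + length(b) - 2, p = 1,
                        mean_a = mean(a), mean_b = mean(b), d = 0))
    stop("zero variance in both samples")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, mean_a = mean(a), mean_b = mean(b),
             d = tryCatch(cohens_d(a, b), error = function(e) NA_real_))
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(a) - mean(b)) / s_pooled`, pooling the two sample variances with
#' n - 1 weights.
#'
#' @param a,b numeric samples (each of size >= 2).
#' @return A scalar effect size.
#' @export
cohens_d <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each sample needs at least 2 finite values")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  (mean(a) - mean(b)) / sp
}

#' Compare transition percentages between groups
#'
#' Welch t tests on the per-subject relative transition percentages for
#' every ordered class pair (i != j), Bonferroni-corrected over the
#' K*(K-1) tests (12 pairs for K = 4).  Subjects whose row has no
#' transitions (undefined percentage) are dropped from that pair's test.
#'
#' @param tablesA,tablesB lists of per-subject [transition_table()]
#'   results (one list element per subject).
#' @return A data frame with one row per ordered pair: `from`, `to`, `t`,
#'   `df`, `p`, `p_bonf`, `d`, `mean_a`, `mean_b`, `n_dropped`.
#' @export
compare_transitions <- function(tablesA, tablesB) {
  labs <- rownames(tablesA[[1L]]$counts)
  K <- length(labs)
  m <- K * (K - 1L)
  res <- vector("list", m)
  r <- 0L
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    va <- vapply(tablesA, function(tt) tt$percentages[i, j], 0)
    vb <- vapply(tablesB, function(tt) tt$percentages[i, j], 0)
    dropped <- sum(!is.finite(va)) + sum(!is.finite(vb))
    ht <- tryCatch(welch_t(va[is.finite(va)], vb[is.finite(vb)]),
                   error = function(e)
                     data.frame(t = NA_real_, df = NA_real_, p = NA_real_,
                                mean_a = mean(va[is.finite(va)]),
                                mean_b = mean(vb[is.finite(vb)]),
                                d = NA_real_))
    r <- r + 1L
    res[[r]] <- data.frame(from = labs[i], to = labs[j], t = ht$t,
                           df = ht$df, p = ht$p,
                           p_bonf = pmin(1, m * ht$p), d = ht$d,
                           mean_a = ht$mean_a, mean_b = ht$mean_b,
                           n_dropped = dropped)
  }
  do.call(rbind, res)
}

#' Randomization TANOVA on scalp topographies
#'
#' Topographic analysis of variance: each subject's map is first
#' strength-normalized to unit GFP, the observed effect is the GFP of the
#' difference between the two group-mean maps, and its null distribution
#' is obtained by reshuffling subjects between the groups (preserving
#' group sizes).  The p-value uses the add-one estimator
#' `(1 + #\{permuted >= observed\}) / (1 + n_permutations)`, which cannot
#' return zero.
#'
#' @param mapsA,mapsB numeric E x n matrices, one column per subject
#'   (column names identify subjects in error messages).
#' @param n_permutations number of random reassignments (>= 100).
#' @param seed RNG seed; the result is reproducible given the seed.
#' @return A list: `observed_effect` (GFP of the normalized group-mean
#'   difference), `p`, `n_permutations`, `seed`.
#' @export
tanova <- function(mapsA, mapsB, n_permutations = 5000L, seed = 1L) {
  mapsA <- as.matrix(mapsA); mapsB <- as.matrix(mapsB)
  if (nrow(mapsA) != nrow(mapsB)) stop("map montages differ")
  if (n_permutations < 100L) stop("need at least 100 permutations")
  norm1 <- function(M, tag) {
    g <- apply(M, 2L, pop_sd)
    if (any(g == 0)) {
      who <- colnames(M)[g == 0]
      if (is.null(who)) who <- paste0(tag, which(g == 0))
      stop("zero-GFP subject map: ", paste(who, collapse = ", "))
    }
    sweep(M, 2L, g, "/")
  }
  A <- norm1(mapsA, "A"); B <- norm1(mapsB, "B")
  nA <- ncol(A); nB <- ncol(B); n <- nA + nB
  X <- cbind(A, B)
  effect <- function(ia) {
    d <- rowMeans(X[, ia, drop = FALSE]) -
      rowMeans(X[, -ia, drop = FALSE])
    pop_sd(d)
  }
  observed <- effect(seq_len(nA))
  set.seed(seed)
  # weight matrix: one permutation per column
  W <- matrix(-1 / nB, n, n_permutations)
  for (p in seq_len(n_permutations))
    W[sample.int(n, nA), p] <- 1 / nA
  diffs <- X %*% W
  perm_eff <- sqrt(colMeans(diffs^2) - colMeans(diffs)^2)
  p <- (1 + sum(perm_eff >= observed)) / (1 + n_permutations)
  list(observed_effect = observed, p = p,
       n_permutations = n_permutations, seed = seed)
}

# population (1/E) standard deviation — the GFP of a map
pop_sd <- function(v) sqrt(mean(v^2) - mean(v)^2)
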