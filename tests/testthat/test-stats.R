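test_that("arm summary matches hand computation and the box convention", {
  s <- summarize_arm(c(1, 2, 3, 4, 5), arm = "a", region = "CA1")
  expect_equal(s$mean, 3)
  expect_equal(s$se, sqrt(2.5 / 5))
  expect_equal(s$ci_lower, 3 - qt(0.975, 4) * s$se, tolerance = 1e-12)
  expect_equal(s$ci_upper, 4.9632, tolerance = 1e-4)
  expect_equal(s$box_upper - s$box_lower, 2 * 1.96 * s$se)

  const <- summarize_arm(rep(2, 6))
  expect_equal(const$ci_upper - const$ci_lower, 0)
  expect_error(summarize_arm(3), "at least 2")
})

test_that("one-way ANOVA equals the brute-force sums-of-squares oracle
           and the two-group t^2 identity", {
  set.seed(31)
  groups <- lapply(1:4, function(i) rnorm(6, mean = i * 0.3))
  names(groups) <- paste0("g", 1:4)
  res <- one_way_anova(groups)

  # oracle: explicit SS decomposition
  v <- unlist(groups)
  gm <- mean(v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  sst <- sum((v - gm)^2)
  expect_equal(ssb + ssw, sst, tolerance = 1e-9)
  k <- 4; n <- length(v)
  f_oracle <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(res$f, f_oracle, tolerance = 1e-9)
  expect_equal(res$p, pf(f_oracle, k - 1, n - k, lower.tail = FALSE),
               tolerance = 1e-9)

  # two groups: F is the square of the pooled-variance t statistic
  two <- groups[1:2]
  tt <- t.test(two[[1]], two[[2]], var.equal = TRUE)
  expect_equal(one_way_anova(two)$f, unname(tt$statistic)^2,
               tolerance = 1e-9)

  # identical groups with internal variance: F = 0, p = 1
  same <- replicate(4, c(-1, 0, 1), simplify = FALSE)
  res0 <- one_way_anova(same)
  expect_equal(res0$f, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1, tolerance = 1e-12)

  expect_error(one_way_anova(list(a = rep(1, 3), b = rep(1, 3))),
               "degenerate")
})

test_that("Tukey HSD: 6 pairs, sane p-values, never anti-conservative,
           and close to a permutation max-T reference", {
  set.seed(12)
  groups <- list(a = rnorm(5, 0), b = rnorm(5, 0.2),
                 c = rnorm(5, 2.5), d = rnorm(5, 0.1))
  tk <- tukey_hsd(groups)
  expect_equal(nrow(tk), 6)
  expect_true(all(tk$p_adjusted >= 0 & tk$p_adjusted <= 1))

  # the well-separated group has the smallest adjusted p against all
  c_rows <- tk$group_i == "c" | tk$group_j == "c"
  expect_lt(max(tk$p_adjusted[c_rows]), min(tk$p_adjusted[!c_rows]))

  # adjustment never below the unadjusted p of the pooled-variance t
  # (same MSE and df the range statistic is studentized with)
  mse <- mean(vapply(groups, var, numeric(1)))
  for (i in seq_len(nrow(tk))) {
    t_unadj <- abs(tk$diff[i]) / sqrt(mse * 2 / 5)
    p_unadj <- 2 * pt(-t_unadj, df = 16)
    expect_gte(tk$p_adjusted[i] + 1e-12, p_unadj)
  }

  # permutation max-T oracle on the same 4 x 5 dataset
  v <- unlist(groups, use.names = FALSE)
  lab <- rep(1:4, each = 5)
  # studentized range of the permuted data: max pairwise mean difference
  # over the pooled within-group SE, as Tukey's q
  max_q <- function(x, g) {
    ms <- tapply(x, g, mean)
    mse <- mean(tapply(x, g, var))
    (max(ms) - min(ms)) / sqrt(mse / 5)
  }
  set.seed(99)
  n_perm <- 100000
  null_max <- vapply(seq_len(n_perm), function(k) {
    max_q(v, sample(lab))
  }, numeric(1))
  mse_obs <- mean(vapply(groups, var, numeric(1)))
  for (i in seq_len(nrow(tk))) {
    q_obs <- abs(tk$diff[i]) / sqrt(mse_obs / 5)
    p_perm <- mean(null_max >= q_obs)
    expect_lt(abs(tk$p_adjusted[i] - p_perm), 0.01)
  }

  # four identical groups: all adjusted p near 1
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3),
               d = c(1, 2, 3))
  expect_true(all(tukey_hsd(same)$p_adjusted > 0.999))
})

test_that("sample size: closed form gives 16 for the design parameters", {
  expect_equal(sample_size(0.20, 0.20, 0.05, 0.80), 16L)
  expect_equal(sample_size(0.40, 0.20, 0.05, 0.80), 4L)
  # n scales with (sd / delta)^2
  n1 <- sample_size(0.2, 0.1)
  n4 <- sample_size(0.2, 0.4)
  expect_equal(n4 / n1, 16, tolerance = 0.1)
  expect_error(sample_size(0.2, 0.2, alpha = 1.2), "alpha")
  expect_error(sample_size(-0.1, 0.2), "positive")
})
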