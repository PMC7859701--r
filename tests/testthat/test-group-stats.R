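test_that("the Shapiro-Wilk gate flags non-normal groups", {
  set.seed(202)
  normal <- list(a = rnorm(50), b = rnorm(40, 5), c = rnorm(30, -2, 3))
  gate <- shapiro_gate(normal)
  expect_true(gate$parametric)
  expect_equal(unname(gate$p_values["a"]),
               shapiro.test(normal$a)$p.value)

  bimodal <- list(a = c(rnorm(50, 0, 0.2), rnorm(50, 10, 0.2)),
                  b = rnorm(50))
  gate2 <- shapiro_gate(bimodal)
  expect_lt(gate2$p_values["a"], 0.05)
  expect_false(gate2$parametric)

  expect_error(shapiro_gate(list(ok = rnorm(10), tiny = c(1, 2))), "tiny")
})

test_that("identical groups give F = 0 and p = 1 with all pairs at 1", {
  g <- list(a = 1:5, b = 1:5, c = 1:5)
  res <- anova_tukey(g)
  expect_equal(unname(res$statistic), 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  expect_true(all(res$pairwise$p_adj == 1))
  expect_false(any(res$pairwise$significant))
  expect_error(anova_tukey(list(a = c(2, 2), b = c(2, 2))),
               "degenerate variance")
})

test_that("ANOVA omnibus and Tukey p agree with closed-form oracles", {
  set.seed(11)
  g <- list(a = rnorm(20), b = rnorm(20, 10))
  res <- anova_tukey(g)
  # closed-form one-way F
  gm <- mean(unlist(g))
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, 0))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  f_oracle <- (ssb / 1) / (ssw / 38)
  expect_equal(unname(res$statistic), f_oracle, tolerance = 1e-10)
  expect_equal(res$p_value, pf(f_oracle, 1, 38, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(all(res$pairwise$p_adj < 1e-6))

  # studentized-range oracle for the Tukey adjusted p (unequal n)
  set.seed(12)
  g3 <- list(a = rnorm(12), b = rnorm(17, 1), c = rnorm(9, 0.5))
  res3 <- anova_tukey(g3)
  mse <- sum(vapply(g3, function(v) sum((v - mean(v))^2), 0)) /
    (sum(lengths(g3)) - 3)
  for (k in seq_len(nrow(res3$pairwise))) {
    va <- g3[[res3$pairwise$group_a[k]]]
    vb <- g3[[res3$pairwise$group_b[k]]]
    se <- sqrt(mse / 2 * (1 / length(va) + 1 / length(vb)))
    q <- abs(mean(va) - mean(vb)) / se
    p_or <- ptukey(q, 3, sum(lengths(g3)) - 3, lower.tail = FALSE)
    expect_equal(res3$pairwise$p_adj[k], p_or, tolerance = 1e-8)
  }
})

test_that("Kruskal-Wallis H matches the direct rank oracle", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  res <- kruskal_dunn(g)
  expect_equal(unname(res$statistic), oracle_kw_h(g), tolerance = 1e-12)
  expect_equal(unname(res$statistic), 7.2)

  # ties: still matches the tie-corrected oracle and kruskal.test
  gt <- list(a = c(1, 1, 2, 3), b = c(2, 2, 3, 5), c = c(5, 6, 6, 7))
  rest <- kruskal_dunn(gt)
  expect_equal(unname(rest$statistic), oracle_kw_h(gt), tolerance = 1e-12)

  expect_error(kruskal_dunn(list(a = c(3, 3), b = c(3, 3))), "identical")
})

test_that("the observed H sits at its permutation quantile", {
  set.seed(13)
  g <- list(a = rnorm(12), b = rnorm(12, 0.8), c = rnorm(12))
  res <- kruskal_dunn(g)
  pooled <- unlist(g)
  sizes <- lengths(g)
  perm_h <- replicate(2000, {
    sh <- sample(pooled)
    oracle_kw_h(split(sh, rep(seq_along(sizes), sizes)))
  })
  p_perm <- mean(perm_h >= unname(res$statistic))
  expect_equal(p_perm, res$p_value, tolerance = 0.03)
})

test_that("Dunn pairs are symmetric and two same-population groups pass", {
  set.seed(14)
  g <- list(a = rexp(200), b = rexp(200))
  res <- kruskal_dunn(g)
  expect_gt(res$p_value, 0.05)
  expect_true(all(res$pairwise$p_adj >= 0 & res$pairwise$p_adj <= 1))
  # reversing group order flips the z sign but not the adjusted p
  res_rev <- kruskal_dunn(rev(g))
  expect_equal(sort(res$pairwise$p_adj), sort(res_rev$pairwise$p_adj))
  expect_equal(abs(res$pairwise$estimate), abs(res_rev$pairwise$estimate))
})

test_that("compare_groups gates on normality and honours overrides", {
  set.seed(15)
  normal <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  expect_identical(compare_groups(normal)$test_used, "anova_tukey")

  skewed <- list(a = rlnorm(60, sdlog = 1.5), b = rlnorm(60, sdlog = 1.5))
  expect_identical(compare_groups(skewed)$test_used, "kruskal_dunn")

  forced <- compare_groups(normal, force_test = "kruskal_dunn")
  expect_identical(forced$test_used, "kruskal_dunn")
  expect_true(forced$forced)
  expect_true(forced$normality$parametric)  # gate verdict still attached

  # data.frame interface
  df <- data.frame(value = unlist(normal),
                   group = rep(names(normal), each = 30))
  expect_identical(compare_groups(df)$test_used, "anova_tukey")
})

test_that("a 75% intensity reduction at n = 44 is detected essentially always", {
  # the simulated severe-variant contrast at measurement CV 0.3
  hits <- 0
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    coh <- simulate_het_cohort(competition_model(1, 3, 100), n = 44,
                               noise_cv = 0.3, seed = 2000 + i)
    res <- compare_groups(list(WT = coh$homo, G155S = coh$het))
    hits <- hits + all(res$pairwise$p_adj < 0.05)
  }
  expect_gte(hits / n_rep, 0.95)
})
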