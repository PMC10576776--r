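test_that("a single defected boundary on either side scores the embryo defected", {
  left <- matrix(0L, 1, 20); left[1, 5] <- 1L
  tab <- make_boundary_table(left, matrix(0L, 1, 20))
  pen <- classify_embryos(tab)
  expect_equal(pen$n_defected, 1L)
  expect_equal(pen$fraction_defected, 1)

  tab_wt <- make_boundary_table(matrix(0L, 3, 20))
  pen_wt <- classify_embryos(tab_wt)
  expect_equal(pen_wt$n_defected, 0L)
  expect_equal(pen_wt$fraction_defected, 0)
})

test_that("penetrance fraction is plain count arithmetic", {
  left <- matrix(0L, 100, 20)
  left[seq_len(85), 1] <- 1L           # 85 of 100 embryos carry a defect
  pen <- classify_embryos(make_boundary_table(left, matrix(0L, 100, 20)))
  expect_equal(pen$n_embryos, 100L)
  expect_equal(pen$fraction_defected, 0.85)
})

test_that("all-NA embryos are excluded from penetrance with a warning", {
  left <- matrix(0L, 2, 20)
  left[2, ] <- NA_integer_
  tab <- make_boundary_table(left, left)
  expect_warning(pen <- classify_embryos(tab), "all-NA")
  expect_equal(pen$n_embryos, 1L)
})

test_that("defect counts hit the range endpoints and respect NA exclusion", {
  tab <- make_boundary_table(matrix(1L, 1, 20), matrix(0L, 1, 20))
  cnt <- defect_counts(tab)$counts
  expect_equal(cnt$n_defected[cnt$side == "L"], 20L)
  expect_equal(cnt$n_defected[cnt$side == "R"], 0L)

  left_na <- matrix(1L, 1, 20); left_na[1, 3] <- NA_integer_
  expect_warning(cnt2 <- defect_counts(make_boundary_table(left_na))$counts,
                 "unscorable")
  expect_equal(cnt2$n_defected[cnt2$side == "L"], 19L)
  expect_equal(cnt2$n_na[cnt2$side == "L"], 1L)
})

test_that("simulated defect-count median falls in the exact binomial IQR envelope", {
  # per-side count ~ Binomial(20, 0.25); quartiles by direct enumeration
  cdf <- cumsum(stats::dbinom(0:20, 20, 0.25))
  q1 <- min(which(cdf >= 0.25)) - 1L
  q3 <- min(which(cdf >= 0.75)) - 1L
  sim <- bernoulli_sim(78, 0.25, seed = 5)   # 156 sides
  med <- defect_counts(sim$boundary_table)$summary$median
  expect_gte(med, q1)
  expect_lte(med, q3)
})

test_that("consecutive correlation matches the product-moment formula", {
  expect_equal(consecutive_correlation(rep(c(0, 1), 10)), -1)
  expect_true(is.na(consecutive_correlation(rep(0, 20))))
  v <- c(1, 0, 0, 1, 0, 1, 1, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 1, 1, 0)
  oracle <- pearson_by_formula(v[1:19], v[2:20])
  expect_equal(consecutive_correlation(v), oracle, tolerance = 1e-12)
  expect_error(consecutive_correlation(c(0, 1, 0)), "at least 4")
  expect_error(consecutive_correlation(c(v[1:17], NA, NA, NA)), "unscorable")
})

test_that("left-right correlation matches the formula and is symmetric", {
  l <- c(1, 0, 0, 1, 0, 1, 1, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 1, 1, 0)
  r <- c(0, 0, 1, 1, 0, 0, 1, 1, 0, 1, 1, 0, 0, 1, 1, 0, 0, 0, 1, 0)
  expect_equal(left_right_correlation(l, l), 1)
  expect_equal(left_right_correlation(l, 1 - l), -1)
  expect_equal(left_right_correlation(l, r), pearson_by_formula(l, r),
               tolerance = 1e-12)
  expect_equal(left_right_correlation(l, r), left_right_correlation(r, l))
  expect_true(is.na(left_right_correlation(l, rep(1, 20))))
})

test_that("correlation summary bins at 0.1 with a closed rightmost bin", {
  s <- summarize_correlations(c(0.05, 0.05))
  expect_equal(s$mean_r, 0.05)
  hit <- s$histogram[s$histogram$frequency > 0, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$bin_lower, 0)

  s1 <- summarize_correlations(1.0)
  hit1 <- s1$histogram[s1$histogram$frequency > 0, ]
  expect_equal(hit1$bin_lower, 0.9)   # r = 1 lands in the closed top bin

  s2 <- summarize_correlations(c(0.05, NA, 0.15))
  expect_equal(s2$n_excluded, 1L)
  expect_equal(sum(s2$histogram$frequency), 1)
  expect_error(summarize_correlations(c(NA_real_, NA_real_)), "no defined")
})

test_that("independence null keeps the mean consecutive r near zero", {
  sim <- bernoulli_sim(111, 0.45, seed = 17)   # 222 sides
  r <- consecutive_correlations(sim$boundary_table)
  m <- mean(r, na.rm = TRUE)
  se <- stats::sd(r, na.rm = TRUE) / sqrt(sum(!is.na(r)))
  expect_lt(abs(m), 4 * se)
  # the pooled-pairs alternative is nearly unbiased under independence
  r_pool <- consecutive_correlations(sim$boundary_table, pooled = TRUE)
  expect_lt(abs(r_pool), 0.05)
})

test_that("percent change reproduces the printed temperature and hypoxia effects", {
  expect_equal(expressivity_change(8, 13)$percent_raw, 62.5)
  expect_equal(expressivity_change(8, 13)$percent, 63)
  expect_equal(expressivity_change(8.9, 11.5)$percent, 29)
  expect_equal(expressivity_change(4, 4)$percent, 0)
  expect_error(expressivity_change(0, 5), "zero")
})

test_that("two-sided exact 2x2 test matches hypergeometric enumeration", {
  even <- matrix(c(10L, 10L, 10L, 10L), 2)
  expect_equal(compare_conditions(even)$p.value, 1)

  tab <- matrix(c(10L, 0L, 0L, 10L), 2)
  # enumerate all tables with these margins; two-sided p sums those no more
  # probable than the observed table
  probs <- stats::dhyper(0:10, 10, 10, 10)
  p_oracle <- sum(probs[probs <= probs[11] * (1 + 1e-7)])
  expect_equal(compare_conditions(tab)$p.value, p_oracle, tolerance = 1e-10)
})

test_that("rank-sum separates non-overlapping groups decisively", {
  set.seed(2)
  a <- runif(30, 0, 1); b <- runif(30, 2, 3)
  res <- compare_conditions(c(a, b), rep(c("lo", "hi"), each = 30))
  expect_match(res$method, "Mann-Whitney")
  expect_lt(res$p.value, 0.001)
})

test_that("three groups trigger the rank-based omnibus test with pairwise table", {
  set.seed(3)
  x <- c(rnorm(12), rnorm(12, 2), rnorm(12, 4))
  g <- rep(c("a", "b", "c"), each = 12)
  res <- compare_conditions(x, g)
  expect_match(res$method, "Kruskal")
  expect_equal(nrow(res$pairwise), 3L)
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_unadjusted - 1e-12))
  # the extreme pair separates most clearly
  ac <- res$pairwise$p_adjusted[res$pairwise$group_a == "a" &
                                  res$pairwise$group_b == "c"]
  expect_lt(ac, 0.01)
})

test_that("summaries are invariant to embryo ordering within the range", {
  sim <- bernoulli_sim(40, 0.3, seed = 31)
  tab <- sim$boundary_table
  set.seed(1)
  shuf <- tab[sample.int(nrow(tab)), ]
  class(shuf) <- class(tab)
  expect_equal(classify_embryos(shuf)$fraction_defected,
               classify_embryos(tab)$fraction_defected)
  r_tab <- consecutive_correlations(tab)
  expect_equal(consecutive_correlations(shuf)[names(r_tab)], r_tab)
  expect_equal(defect_counts(shuf)$summary, defect_counts(tab)$summary)
})

test_that("all defined correlations stay inside [-1, 1]", {
  sim <- bernoulli_sim(60, 0.45, seed = 13)
  r <- c(consecutive_correlations(sim$boundary_table),
         left_right_correlations(sim$boundary_table))
  r <- r[!is.na(r)]
  expect_true(all(r >= -1 & r <= 1))
})
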