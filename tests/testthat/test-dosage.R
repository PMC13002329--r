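# Dosage-balance statistics: regressions, high/low split, receptor
# correlation, ploidy contrasts and expression comparison.

test_that("noiseless proportional tables give exact slopes", {
  total <- seq(10, 100, 10)
  tab <- data.frame(asmt = 0.3 * total, comt = 0.7 * total, total = total)
  reg <- subfamily_regression(tab)
  expect_equal(reg$slope_asmt, 0.3, tolerance = 1e-12)
  expect_equal(reg$slope_comt, 0.7, tolerance = 1e-12)
  expect_equal(reg$slope_ratio, 0.3 / 0.7, tolerance = 1e-12)
  expect_error(subfamily_regression(data.frame(asmt = 1:5, comt = 1:5,
                                               total = rep(4, 5))),
               "all equal")
})

test_that("subfamily slopes sum to one on arbitrary tables", {
  for (seed in 1:25) {
    tab <- simulate_copy_number_table(60, asmt_share = stats::runif(1, 0.1, 0.9),
                                      seed = seed)
    reg <- subfamily_regression(tab)
    expect_equal(reg$slope_asmt + reg$slope_comt, 1, tolerance = 1e-10)
  }
})

test_that("binomial simulation recovers the low-share slope ratio", {
  ratios <- vapply(1:20, function(seed) {
    tab <- simulate_copy_number_table(1052, asmt_share = 0.11, seed = seed)
    subfamily_regression(tab)$slope_ratio
  }, 0)
  expect_equal(mean(ratios), 0.11 / 0.89, tolerance = 0.05)
})

test_that("1-D k-means split is a deterministic threshold rule", {
  totals <- c(10, 12, 14, 80, 85, 90)
  sp <- split_high_low(totals)
  expect_equal(sp$assignment, c("low", "low", "low", "high", "high", "high"))
  expect_equal(unname(sp$boundary), c(14, 80))

  # threshold property on random data: sorted totals split at one cut
  for (seed in 1:10) {
    set.seed(seed)
    t2 <- sample(1:200, 50, replace = TRUE)
    sp2 <- split_high_low(t2)
    expect_lt(max(t2[sp2$assignment == "low"]),
              min(t2[sp2$assignment == "high"]))
  }
  expect_error(split_high_low(rep(7, 10)), "identical")
})

test_that("group tests behave under exchangeable groups", {
  set.seed(71)
  totals <- c(rep(10, 20), rep(100, 20))
  stat <- stats::rnorm(40)  # statistic unrelated to the split
  sp <- split_high_low(totals, statistic = stat)
  expect_gt(sp$t_test$p.value, 0.001)
  # identical samples across groups: t statistic exactly 0
  stat_eq <- rep(c(1, 2, 3, 4, 5), 8)
  sp_eq <- split_high_low(totals, statistic = stat_eq)
  expect_equal(unname(sp_eq$t_test$statistic), 0)
})

test_that("group-test power matches a Monte-Carlo oracle", {
  alpha <- 0.05
  n_low <- 160; n_high <- 40
  run_once <- function(seed, use_package) {
    set.seed(seed)
    totals <- c(stats::rpois(n_low, 12), stats::rpois(n_high, 90))
    prop <- c(stats::rnorm(n_low, 0.40, 0.08),
              stats::rnorm(n_high, 0.46, 0.08))  # planted shift 0.06
    if (use_package) {
      sp <- split_high_low(totals, statistic = prop)
      sp$t_test$p.value < alpha
    } else {
      # oracle: known group memberships, direct Welch test
      stats::t.test(prop[seq_len(n_low)],
                    prop[n_low + seq_len(n_high)])$p.value < alpha
    }
  }
  reps <- 150
  pkg_rate <- mean(vapply(1:reps, run_once, TRUE, use_package = TRUE))
  orc_rate <- mean(vapply(1:reps, run_once, TRUE, use_package = FALSE))
  se <- sqrt(orc_rate * (1 - orc_rate) / reps +
               pkg_rate * (1 - pkg_rate) / reps)
  expect_lt(abs(pkg_rate - orc_rate), 3 * se + 0.02)
})

test_that("receptor correlation recovers copula truth and flags constants", {
  tab <- simulate_copy_number_table(200, 0.5, seed = 1, receptor_rho = 0.9)
  tab$receptor <- tab$total
  expect_equal(receptor_correlation(tab)$rho, 1)

  tab$receptor <- 2L
  out <- receptor_correlation(tab)
  expect_true(is.na(out$rho))
  expect_equal(out$reason, "constant_receptor")

  # population Spearman of the copula generator, by a large-sample oracle
  big <- simulate_copy_number_table(200000, 0.5, seed = 99,
                                    receptor_rho = 0.3)
  rho_pop <- suppressWarnings(
    stats::cor(big$receptor, big$total, method = "spearman"))
  covered <- vapply(1:20, function(seed) {
    tb <- simulate_copy_number_table(1052, 0.5, seed = seed,
                                     receptor_rho = 0.3)
    est <- receptor_correlation(tb)$rho
    z <- atanh(est)
    ci <- tanh(z + c(-1, 1) * 1.96 / sqrt(nrow(tb) - 3))
    rho_pop >= ci[1] && rho_pop <= ci[2]
  }, TRUE)
  expect_gte(mean(covered), 0.9)
})

test_that("ploidy contrast reproduces fold changes and nulls", {
  # means pinned to 144.06 and 54.00
  a_tot <- rep(c(144L, 145L), c(94, 6))
  b_tot <- rep(54L, 40)
  mk <- function(tot, share) data.frame(asmt = round(share * tot),
                                        comt = tot - round(share * tot),
                                        total = tot)
  cmp <- ploidy_comparison(mk(a_tot, 0.78), mk(b_tot, 0.72))
  expect_equal(unname(cmp$mean_total), c(144.06, 54.00))
  expect_equal(round(cmp$fold_change, 2), 2.67)
  expect_lt(cmp$total_t$p.value, 1e-10)

  set.seed(72)
  same <- simulate_copy_number_table(50, 0.5, seed = 5)
  cmp2 <- ploidy_comparison(same, same)
  expect_equal(cmp2$fold_change, 1)
  expect_gt(cmp2$total_t$p.value, 0.99)
})

test_that("expression comparison filters, removes outliers and tests", {
  low <- matrix(0.5, 4, 3, dimnames = list(paste0("g", 1:4), NULL))
  expect_error(expression_compare(low, c("ASMT", "ASMT", "COMT", "COMT")),
               "no values left")

  dirs <- vapply(1:20, function(seed) {
    sim <- simulate_expression_matrix(25, 25, 10, comt_shift = 1,
                                      seed = seed)
    expression_compare(sim$fpkm, sim$subfamily)$comt_higher
  }, TRUE)
  expect_true(all(dirs))

  # outlier removal shrinks the pool
  sim <- simulate_expression_matrix(40, 40, 10, comt_shift = 0, seed = 3)
  with_out <- expression_compare(sim$fpkm, sim$subfamily, outlier_k = Inf)
  no_out <- expression_compare(sim$fpkm, sim$subfamily, outlier_k = 1.5)
  expect_lte(no_out$asmt["n"], with_out$asmt["n"])
})

test_that("statistics are invariant to row order and monotone transforms", {
  tab <- simulate_copy_number_table(120, 0.6, seed = 14, receptor_rho = 0.3)
  perm <- sample(nrow(tab))
  reg1 <- subfamily_regression(tab)
  reg2 <- subfamily_regression(tab[perm, ])
  expect_equal(reg1$slope_ratio, reg2$slope_ratio)
  expect_equal(receptor_correlation(tab)$rho,
               receptor_correlation(tab[perm, ])$rho)

  # Mann-Whitney is rank-based: a monotone transform leaves U unchanged
  set.seed(15)
  totals <- c(rep(5, 15), rep(60, 15))
  stat <- stats::rlnorm(30)
  u1 <- split_high_low(totals, statistic = stat)$mann_whitney
  u2 <- split_high_low(totals, statistic = log(stat))$mann_whitney
  expect_equal(u1$statistic, u2$statistic)
  expect_equal(u1$p.value, u2$p.value)
})
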