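# Greedy clustering, PAV matrices, occupancy classes, openness curves and
# power-law fits.

test_that("greedy clustering merges identical and splits unrelated", {
  set.seed(41)
  s <- random_protein_string(100)
  one <- greedy_cluster(c(a = s, b = s))
  expect_equal(length(one), 1)
  expect_equal(sort(one[[1]]$members), c("a", "b"))

  two <- greedy_cluster(c(a = random_protein_string(100),
                          b = random_protein_string(100)))
  expect_equal(length(two), 2)

  expect_error(greedy_cluster(c(a = s, a = s)), "unique")
})

test_that("clustering recovers planted OGGs and keeps invariants", {
  sim <- simulate_pangenome(5, n_core = 4, n_dispensable = 4,
                            occupancy = 0.6,
                            within_identity = 0.98,
                            between_identity = 0.60,
                            seq_length = 110, seed = 17)
  oggs <- greedy_cluster(sim$sequences)
  expect_equal(length(oggs), nrow(sim$truth$pav))

  lens <- Biostrings::width(sim$sequences)
  names(lens) <- names(sim$sequences)
  for (cl in oggs) {
    # representative is a maximal-length member
    expect_equal(unname(lens[cl$representative_id]),
                 max(unname(lens[cl$members])))
    # every member matches its representative at >= identity_min
    rep_seq <- as.character(sim$sequences[[cl$representative_id]])
    for (m in cl$members) {
      st <- pandosage:::.align_stats(
        Biostrings::AAString(as.character(sim$sequences[[m]])),
        Biostrings::AAString(rep_seq))
      expect_gte(st$identity, 0.95)
    }
  }
  # every input sequence lands in exactly one cluster
  all_members <- unlist(lapply(oggs, `[[`, "members"))
  expect_setequal(all_members, names(sim$sequences))
  expect_equal(anyDuplicated(all_members), 0L)

  # PAV round trip against planted truth
  pav <- build_pav_matrix(oggs, stats::setNames(sim$mapping$variety,
                                                sim$mapping$gene))
  truth <- sim$truth$pav
  # map clusters to planted OGGs through any member gene
  ogg_of <- stats::setNames(sim$mapping$ogg, sim$mapping$gene)
  row_map <- vapply(oggs, function(cl) ogg_of[cl$members[1]], "")
  expect_equal(unname(pav[, colnames(truth)]),
               unname(truth[row_map, colnames(truth)]))
})

test_that("PAV construction flags unmapped members", {
  set.seed(42)
  s <- random_protein_string(80)
  oggs <- greedy_cluster(c(x = s, y = s))
  expect_error(build_pav_matrix(oggs, c(x = "v1")), "unmapped")
  pav <- build_pav_matrix(oggs, c(x = "v1", y = "v1"))
  expect_equal(dim(pav), c(1L, 1L))
  expect_true(all(pav))
})

test_that("occupancy classes follow the quoted thresholds and partition", {
  pav <- matrix(FALSE, 4, 20)
  pav[1, ] <- TRUE                 # 100% -> Core
  pav[2, 1:19] <- TRUE             # 95%  -> Shell
  pav[3, 1:10] <- TRUE             # 50%  -> SoftCore
  pav[4, 1] <- TRUE                # 5%   -> Cloud
  occ <- classify_occupancy(pav)
  expect_equal(as.character(occ$class),
               c("Core", "Shell", "SoftCore", "Cloud"))
  expect_equal(occ$dispensable, c(FALSE, TRUE, TRUE, TRUE))

  # boundary cases: exactly 90% -> Shell, exactly 10% -> SoftCore
  pavb <- rbind(c(rep(TRUE, 9), FALSE), c(TRUE, rep(FALSE, 9)))
  occb <- classify_occupancy(pavb)
  expect_equal(as.character(occb$class), c("Shell", "SoftCore"))

  # random matrix: classes equal an independent recount and partition
  set.seed(43)
  pr <- matrix(stats::runif(200 * 12) < 0.5, 200, 12)
  pr <- pr[rowSums(pr) > 0, ]
  oc <- classify_occupancy(pr)
  counts <- table(oc$class)
  recount <- c(Core = 0, Shell = 0, SoftCore = 0, Cloud = 0)
  for (i in seq_len(nrow(pr))) {
    f <- sum(pr[i, ]) / ncol(pr)
    lab <- if (f == 1) "Core" else if (f >= 0.9) "Shell"
           else if (f >= 0.1) "SoftCore" else "Cloud"
    recount[lab] <- recount[lab] + 1
  }
  expect_equal(as.numeric(counts), as.numeric(recount))
  expect_equal(sum(counts), nrow(pr))
  expect_equal(sum(oc$class == "Core") + sum(oc$dispensable), nrow(pr))
})

test_that("openness curve matches the exhaustive permutation average", {
  set.seed(44)
  pav <- matrix(stats::runif(8 * 3) < 0.6, 8, 3)
  pav <- pav[rowSums(pav) > 0, ]
  colnames(pav) <- paste0("v", 1:3)
  exact <- oracle_openness_exact(pav)
  curve <- openness_curve(pav, n_iter = 4000, seed = 1)
  expect_lt(max(abs(curve$new_mean - exact)), 0.15)

  # conservation: one permutation's counts sum to the OGG total
  one <- openness_curve(pav, n_iter = 1, seed = 7)
  expect_equal(sum(one$new_mean), nrow(pav))

  # closed pan-genome: all new OGGs arrive with the first variety
  closed <- matrix(TRUE, 6, 4)
  cc <- openness_curve(closed, n_iter = 10, seed = 1)
  expect_equal(cc$new_mean, c(6, 0, 0, 0))
})

test_that("expected openness curve is nonincreasing for exchangeable varieties", {
  set.seed(45)
  pav <- matrix(stats::runif(60 * 8) < 0.4, 60, 8)
  pav <- pav[rowSums(pav) > 0, ]
  curve <- openness_curve(pav, n_iter = 200, seed = 2)
  expect_true(all(diff(curve$new_mean) <= 1))
})

test_that("power-law fit round-trips noiseless parameters", {
  N <- 1:48
  fit <- fit_power_law(N, 31.42 * N^(-0.29))
  expect_equal(fit$k, 31.42, tolerance = 1e-6)
  expect_equal(fit$a, 0.29, tolerance = 1e-6)
  expect_gt(fit$r2, 0.999999)
  expect_equal(unname(coef(fit)["a"]), fit$a)
  expect_equal(predict(fit, 1), fit$k, tolerance = 1e-6)

  # constant curve: exponent ~ 0
  cfit <- fit_power_law(1:10, rep(5, 10) + c(1e-9, rep(0, 9)))
  expect_lt(abs(cfit$a), 1e-3)

  expect_error(fit_power_law(1:2, c(3, 2)), "at least 3")
  expect_warning(fit_power_law(1:5, c(10, 5, 2, 0, 1)), "nonpositive")
})

test_that("power-law fit agrees with a coarse grid-search oracle", {
  set.seed(46)
  N <- 1:30
  n <- 20 * N^(-0.7) * exp(stats::rnorm(30, 0, 0.05))
  fit <- fit_power_law(N, n)
  # oracle: exhaustive grid over (k, a)
  grid_k <- seq(10, 30, 0.1)
  grid_a <- seq(0.3, 1.1, 0.005)
  sse <- outer(grid_k, grid_a, function(k, a) {
    vapply(seq_along(k), function(i) {
      sum((n - k[i] * N^(-a[i]))^2)
    }, 0)
  })
  best <- arrayInd(which.min(sse), dim(sse))
  expect_equal(fit$k, grid_k[best[1]], tolerance = 0.02)
  expect_equal(fit$a, grid_a[best[2]], tolerance = 0.02)
  expect_lte(sum((n - predict(fit))^2), min(sse) + 1e-8)
})
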