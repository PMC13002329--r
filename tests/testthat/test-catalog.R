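# Hit filtering, subfamily assignment, copy tabulation and divergence-column
# ranking.

make_hits <- function(n, seed) {
  set.seed(seed)
  data.frame(
    query_id = sprintf("g%03d", sample.int(n %/% 2, n, replace = TRUE)),
    source = sample(c("domain_scan", "similarity"), n, replace = TRUE),
    evalue = 10^stats::runif(n, -30, 0),
    bitscore = stats::runif(n, 30, 500),
    subject_id = "ref",
    stringsAsFactors = FALSE
  )
}

test_that("candidate filtering applies E-value and length bounds", {
  lens <- c(g1 = 199, g2 = 200, g3 = 600, g4 = 601, g5 = 300)
  hits <- data.frame(query_id = c("g1", "g2", "g3", "g4", "g5"),
                     source = "similarity",
                     evalue = c(1e-10, 1e-10, 1e-10, 1e-10, 1e-4))
  out <- filter_candidates(hits, lens)
  expect_identical(out, c("g2", "g3"))  # 200 and 600 inclusive; 1e-4 fails

  # union vs intersection of evidence sources
  hits2 <- data.frame(query_id = c("a", "a", "b"),
                      source = c("domain_scan", "similarity", "similarity"),
                      evalue = 1e-9)
  lens2 <- c(a = 300, b = 300)
  expect_identical(filter_candidates(hits2, lens2), c("a", "b"))
  expect_identical(filter_candidates(hits2, lens2, require_both = TRUE), "a")
})

test_that("filtering matches a brute-force oracle and is idempotent", {
  hits <- make_hits(500, seed = 21)
  genes <- unique(hits$query_id)
  set.seed(22)
  lens <- stats::setNames(sample(150:700, length(genes), replace = TRUE),
                          genes)
  out <- filter_candidates(hits, lens)
  # oracle: direct per-gene recount
  oracle <- sort(Filter(function(g) {
    any(hits$evalue[hits$query_id == g] <= 1e-5) &&
      lens[g] >= 200 && lens[g] <= 600
  }, genes))
  expect_identical(out, oracle)
  # idempotence: re-filtering the survivors changes nothing
  hits_surv <- hits[hits$query_id %in% out, , drop = FALSE]
  expect_identical(filter_candidates(hits_surv, lens), out)
})

test_that("missing lengths drop genes with a warning", {
  hits <- data.frame(query_id = c("g1", "g2"), source = "similarity",
                     evalue = 1e-9)
  expect_warning(out <- filter_candidates(hits, c(g1 = 300)), "g2")
  expect_identical(out, "g1")
})

test_that("subfamily assignment picks the best reference with stated ties", {
  set.seed(31)
  ref_a <- random_protein_string(120)
  ref_c <- random_protein_string(120)
  refs <- c(asmt_ref = ref_a, comt_ref = ref_c)
  labels <- c(asmt_ref = "ASMT", comt_ref = "COMT")
  out <- assign_subfamily(c(q1 = ref_a), refs, labels)
  expect_equal(out$subfamily, "ASMT")
  expect_equal(out$identity, 1)

  # exact tie on score and identity: lexicographically smaller ref id wins
  refs_tie <- c(zz_ref = ref_a, aa_ref = ref_a)
  labels_tie <- c(zz_ref = "COMT", aa_ref = "ASMT")
  out_tie <- assign_subfamily(c(q1 = ref_a), refs_tie, labels_tie)
  expect_equal(out_tie$best_ref, "aa_ref")
  expect_equal(out_tie$subfamily, "ASMT")

  # invariance to reference input order
  out_rev <- assign_subfamily(c(q1 = ref_a), rev(refs_tie), labels_tie)
  expect_identical(out_tie, out_rev)
  expect_error(assign_subfamily(c(q1 = ref_a), refs[0], labels), "empty")
})

test_that("assignment recovers two-ancestor family truth", {
  agree <- 0L
  total <- 0L
  for (seed in 1:20) {
    sim <- simulate_pangenome(5, n_core = 2, n_dispensable = 0,
                              within_identity = 0.95,
                              between_identity = 0.60,
                              seq_length = 120, seed = seed)
    seqs <- as.character(sim$sequences)
    truth <- ifelse(sim$mapping$ogg == "ogg001", "ASMT", "COMT")
    # first copy of each ancestor serves as the reference
    ref_idx <- c(match("ogg001", sim$mapping$ogg),
                 match("ogg002", sim$mapping$ogg))
    refs <- stats::setNames(seqs[ref_idx], c("refA", "refC"))
    qi <- setdiff(seq_along(seqs), ref_idx)
    out <- assign_subfamily(stats::setNames(seqs[qi], sim$mapping$gene[qi]),
                            refs, c(refA = "ASMT", refC = "COMT"))
    agree <- agree + sum(out$subfamily == truth[qi])
    total <- total + length(qi)
  }
  expect_gte(agree / total, 0.99)
})

test_that("copy tabulation handles rosters, zeros and round trips", {
  empty <- data.frame(gene_id = character(), species_id = character(),
                      subfamily = character())
  tab <- tabulate_copy_numbers(empty, roster = c("s1", "s2", "s3"))
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$total == 0))

  # round trip: expand a simulated table into genes and re-tabulate
  src <- simulate_copy_number_table(40, asmt_share = 0.55, seed = 12)
  genes <- do.call(rbind, lapply(seq_len(nrow(src)), function(i) {
    data.frame(
      gene_id = sprintf("%s_g%03d", src$species[i], seq_len(src$total[i])),
      species_id = src$species[i],
      subfamily = rep(c("ASMT", "COMT"), c(src$asmt[i], src$comt[i])),
      stringsAsFactors = FALSE
    )
  }))
  out <- tabulate_copy_numbers(genes)
  expect_equal(out[, c("species", "asmt", "comt", "total")],
               src[, c("species", "asmt", "comt", "total")])

  genes$subfamily[1] <- "unassigned"
  expect_error(tabulate_copy_numbers(genes), "unassigned")
  expect_silent(tabulate_copy_numbers(genes, allow_unassigned = TRUE))
})

test_that("column MI is maximal for perfect columns and zero for constants", {
  sim <- simulate_labeled_alignment(15, 40, diagnostic_columns = 5,
                                    leakage = 0, seed = 3)
  msa <- sim$msa
  msa[, 10] <- "A"  # force a constant column
  scores <- rank_divergence_columns(msa, sim$labels, n_permutations = 30,
                                    seed = 1)
  expect_equal(scores$column[1], 5)
  expect_equal(scores$mi[1], 1)                    # H(label) = 1 bit
  expect_equal(scores$mi[scores$column == 10], 0)
  expect_true(all(scores$mi >= 0 & scores$mi <= 1))
})

test_that("column MI is invariant to symbol relabelling and label swap", {
  sim <- simulate_labeled_alignment(10, 20, diagnostic_columns = c(2, 9),
                                    leakage = 0.1, seed = 7)
  base <- rank_divergence_columns(sim$msa, sim$labels,
                                  n_permutations = 10, seed = 1)
  # bijective residue relabelling
  perm <- stats::setNames(sample(LETTERS[1:20]), pandosage:::.AA20)
  msa2 <- matrix(perm[sim$msa], nrow = nrow(sim$msa))
  rel <- rank_divergence_columns(msa2, sim$labels,
                                 n_permutations = 10, seed = 1)
  expect_equal(rel$mi, base$mi)
  # class-label swap
  swapped <- factor(ifelse(sim$labels == "ASMT", "COMT", "ASMT"))
  swp <- rank_divergence_columns(sim$msa, swapped,
                                 n_permutations = 10, seed = 1)
  expect_equal(swp$mi, base$mi)
})

test_that("planted diagnostic columns are recovered in the top 13", {
  recovered <- vapply(1:10, function(seed) {
    sim <- simulate_labeled_alignment(30, 400,
                                      diagnostic_columns = seq(20, 260, 20),
                                      leakage = 0.05, seed = seed)
    scores <- rank_divergence_columns(sim$msa, sim$labels,
                                      n_permutations = 20, top_k = 13,
                                      seed = seed)
    sum(scores$column[scores$top_k] %in%
          attr(sim, "truth")$diagnostic_columns)
  }, 0)
  expect_true(all(recovered >= 12))
})
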