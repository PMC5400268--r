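test_that("posterior-predictive genotype likelihoods match closed forms", {
  # k=2, counts {A:3, B:1}, query AB: 2 * 3.5 * 1.5 / (5 * 6) = 0.35
  expect_equal(rm_genotype_likelihood(c(A = 3, B = 1), "A", "B", k = 2),
               0.35)
  # empty reference, k=2, query AA: prior-only predictive 0.375
  expect_equal(rm_genotype_likelihood(c(A = 0, B = 0), "A", "A", k = 2),
               0.375)
  # unseen allele still gets positive mass
  expect_gt(rm_genotype_likelihood(c(A = 10), "Z", "Z", k = 3), 0)
})

test_that("genotype likelihoods normalize over all unordered genotypes", {
  for (seed in 1:4) {
    cfg <- withr::with_seed(seed, list(
      k = sample(2:5, 1),
      counts = stats::rpois(sample(2:5, 1), 4)))
    k <- cfg$k
    counts <- stats::setNames(rep(0, k), paste0("a", 1:k))
    counts[seq_along(cfg$counts)[seq_len(min(k, length(cfg$counts)))]] <-
      cfg$counts[seq_len(min(k, length(cfg$counts)))]
    tot <- 0
    for (i in 1:k) for (j in i:k)
      tot <- tot + rm_genotype_likelihood(counts, paste0("a", i),
                                          paste0("a", j), k)
    expect_equal(tot, 1)
  }
})

test_that("maximally diverged populations self-assign perfectly", {
  md <- two_pop_metadata()
  x <- make_table(list(c(rep("1/1", 20), rep("2/2", 20)),
                       c(rep("3/3", 20), rep("4/4", 20))),
                  pop = rep(c(1L, 2L), each = 20), md)
  sa <- self_assign(x, min_pop_size = 16)
  expect_true(all(sa$results$correct_pop))
  expect_equal(sa$region_rates$correct_region, c(1, 1))
})

test_that("twin populations split assignments but keep the region", {
  # one generating population duplicated under two labels in one region,
  # plus a diverged population in the other region
  md <- data.frame(code = 1:3, name = c("twinA", "twinB", "far"),
                   region = c("Western", "Western", "Eastern"),
                   stringsAsFactors = FALSE)
  n <- 60
  g <- withr::with_seed(31, {
    p <- c(0.3, 0.25, 0.2, 0.15, 0.1)
    lapply(1:6, function(j)
      paste(sample(1:5, 3 * n, TRUE, p), sample(1:5, 3 * n, TRUE, p),
            sep = "/"))
  })
  g <- lapply(g, function(col) {
    far <- paste(sample(6:9, n, TRUE), sample(6:9, n, TRUE), sep = "/")
    c(col[1:(2 * n)], far)
  })
  x <- make_table(g, pop = rep(1:3, each = n), md)
  sa <- self_assign(x, min_pop_size = 16)
  twin <- sa$results[sa$results$pop %in% 1:2, ]
  expect_gt(mean(twin$correct_pop), 0.3)
  expect_lt(mean(twin$correct_pop), 0.7)   # ~50% between the twins
  expect_gt(mean(twin$correct_region), 0.95)
  expect_true(all(sa$results$correct_pop[sa$results$pop == 3L]))
})

test_that("leave-one-out is less optimistic than resubstitution", {
  sim <- simulate_str_dataset(str_sim_config(seed = 41))
  keep <- sim$table$pop %in% c(1L, 2L, 4L, 25L, 26L)
  x <- timberid:::.subset_genotypes(sim$table, keep)
  loo <- self_assign(x, min_pop_size = 10, leave_one_out = TRUE)
  res <- self_assign(x, min_pop_size = 10, leave_one_out = FALSE)
  expect_gte(mean(res$results$correct_pop), mean(loo$results$correct_pop))
})

test_that("assignment is invariant to locus and individual order", {
  sim <- simulate_str_dataset(str_sim_config(seed = 41))
  keep <- sim$table$pop %in% c(9L, 10L, 25L)
  x <- timberid:::.subset_genotypes(sim$table, keep)
  sa1 <- self_assign(x, min_pop_size = 10)
  permL <- withr::with_seed(2, sample(15))
  permI <- withr::with_seed(3, sample(length(x$ids)))
  y <- str_genotypes(x$ids[permI], x$pop[permI],
                     x$a1[permI, permL], x$a2[permI, permL],
                     x$loci[permL], x$metadata)
  sa2 <- self_assign(y, min_pop_size = 10)
  m <- match(sa1$results$id, sa2$results$id)
  expect_equal(sa1$results$best_pop, sa2$results$best_pop[m])
  expect_equal(sa1$results$score, sa2$results$score[m])
})

test_that("query assignment applies the confidence threshold", {
  sim <- simulate_str_dataset(str_sim_config(seed = 41))
  fx <- frim_fixture(str_truth = sim$truth, seed = 41)
  res <- assign_query(sim$table, fx$queries, score_threshold = 80)
  expect_equal(nrow(res), 40L)
  # scores sum to 100 over candidates
  expect_equal(unname(rowSums(attr(res, "scores"))), rep(100, 40),
               tolerance = 1e-6)
  # assigned queries mostly land in the true source populations' region
  expect_gt(mean(res$best_region == "Western"), 0.8)
  # threshold above 100 leaves every query unassigned
  res101 <- assign_query(sim$table, fx$queries, score_threshold = 101)
  expect_false(any(res101$assigned))
  expect_true(all(res101$call == "unassigned (below threshold)"))
  # a query with no genotyped loci errors
  q <- fx$queries
  q$a1[1, ] <- NA; q$a2[1, ] <- NA
  expect_error(assign_query(sim$table, q), "no genotyped loci")
  # locus mismatch errors
  q2 <- fx$queries
  q2$loci[1] <- "nonexistent"
  expect_error(assign_query(sim$table, q2), "absent from reference")
})
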