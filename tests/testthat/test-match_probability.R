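test_that("genotype frequencies hit the model's closed-form limits", {
  # HWE limit at theta = f = 0
  expect_equal(genotype_frequency(0.5, theta = 0, f = 0), 0.25)
  expect_equal(genotype_frequency(0.5, 0.5, theta = 0, f = 0, hom = FALSE),
               0.5)
  # Balding-Nichols heterozygote at f = 0, frozen independent evaluation
  expect_equal(genotype_frequency(0.1, 0.2, theta = 0.05, f = 0,
                                  hom = FALSE),
               2 * (0.145 / 1.05) * (0.24 / 1.10))
  expect_equal(genotype_frequency(0.1, 0.2, theta = 0.05, f = 0,
                                  hom = FALSE), 0.06025974, tolerance = 1e-7)
  # inbreeding-HWE homozygote at theta = 0: p^2 + f p (1-p)
  expect_equal(genotype_frequency(0.5, theta = 0, f = 0.1), 0.275)
  # domain checks
  expect_error(genotype_frequency(0, theta = 0, f = 0), "frequencies")
  expect_error(genotype_frequency(0.5, theta = 1, f = 0), "theta")
})

test_that("unconditional genotype frequencies are a distribution", {
  # brute-force enumeration over all unordered genotypes from an allele set
  for (seed in 1:5) {
    p <- withr::with_seed(seed, {
      k <- sample(2:6, 1)
      g <- stats::rgamma(k, 1); g / sum(g)
    })
    f <- c(0, 0.13, 0.4)[seed %% 3 + 1]
    tot <- 0
    for (i in seq_along(p)) for (j in i:length(p))
      tot <- tot + genotype_frequency(p[i], p[j], theta = 0.3, f = f,
                                      hom = (i == j),
                                      mode = "unconditional")
    expect_equal(tot, 1)
  }
})

test_that("match-mode frequencies dominate and increase with theta", {
  grid <- expand.grid(p = c(0.01, 0.1, 0.5, 0.9),
                      theta = c(0, 0.05, 0.2), f = c(0, 0.05, 0.3))
  hom_match <- with(grid, genotype_frequency(p, p, theta, f, hom = TRUE))
  hom_unc <- with(grid, genotype_frequency(p, p, theta, f, hom = TRUE,
                                           mode = "unconditional"))
  expect_true(all(hom_match >= hom_unc - 1e-12))
  # strictly increasing in theta for p < 1
  for (p in c(0.05, 0.5, 0.95)) for (f in c(0, 0.2)) {
    v <- vapply(seq(0, 0.45, by = 0.05), function(th)
      genotype_frequency(p, p, th, f, hom = TRUE), numeric(1))
    expect_true(all(diff(v) > 0))
  }
  # at f = 0 match mode equals Balding-Nichols for heterozygotes too
  bn_het <- function(pi, pj, th)
    2 * (th + (1 - th) * pi) * (th + (1 - th) * pj) /
    ((1 + th) * (1 + 2 * th))
  expect_equal(genotype_frequency(0.3, 0.2, 0.1, 0, hom = FALSE),
               bn_het(0.3, 0.2, 0.1))
})

test_that("profile frequencies multiply per-locus terms", {
  md <- one_pop_metadata()
  # single-locus homozygote, p = 0.5, theta = f = 0 -> 0.25
  x <- make_table(list(c("1/1", "1/2", "2/2", "1/2")), rep(1L, 4), md)
  afd <- allele_frequencies(x, "Malaysia", apply_floor = FALSE)
  pf <- profile_frequency(x, "ind1", afd, theta = 0, f = 0)
  expect_equal(pf$profile_frequency, 0.25)
  expect_equal(pf$rmp_reciprocal, 4)
  # 15-locus all-heterozygote profile with p = 0.1 everywhere: (0.02)^15
  freqs <- structure(list(
    freq = stats::setNames(rep(list(c(`1` = 0.1, `2` = 0.1, `3` = 0.8)),
                               15), paste0("L", 1:15)),
    floor = 0.001, n_individuals = 2500, pool_label = "synthetic",
    floored = TRUE, loci = paste0("L", 1:15)), class = "allele_freq_db")
  y <- make_table(rep(list("1/2"), 15), 1L, md)
  pfy <- profile_frequency(y, "ind1", freqs, theta = 0, f = 0)
  expect_equal(pfy$profile_frequency, 0.02^15)
  expect_equal(pfy$profile_frequency, 3.2768e-26)
  # locus-order invariance on heterogeneous loci
  sim <- simulate_str_dataset(str_sim_config(seed = 12))
  afd <- allele_frequencies(sim$table, "Malaysia")
  id <- sim$table$ids[complete_profiles(sim$table)][1L]
  ref <- profile_frequency(sim$table, id, afd, 0.06, 0.07)
  perm <- withr::with_seed(1, sample(15))
  xp <- sim$table
  xp$a1 <- xp$a1[, perm, drop = FALSE]
  xp$a2 <- xp$a2[, perm, drop = FALSE]
  xp$loci <- xp$loci[perm]
  afdp <- allele_frequencies(xp, "Malaysia")
  expect_equal(profile_frequency(xp, id, afdp, 0.06, 0.07)$profile_frequency,
               ref$profile_frequency)
  # missing call -> explicit rejection
  z <- make_table(list(c("1/1"), c("5/5")), 1L, md)
  z$a1[1, 2] <- NA; z$a2[1, 2] <- NA
  expect_error(profile_frequency(z, "ind1", afd, 0, 0),
               "rejected.*missing")
})

test_that("alleles absent from the database score at the floor", {
  md <- one_pop_metadata()
  x <- make_table(list(c("1/1", "1/2", "2/2", "2/2")), rep(1L, 4), md)
  afd <- allele_frequencies(x, "Malaysia")
  q <- make_table(list("7/7"), 1L, md)   # allele 7 never observed
  pf <- profile_frequency(q, "ind1", afd, theta = 0, f = 0)
  expect_equal(pf$per_locus$frequency, afd$floor^2)
})

test_that("simulated national profile frequencies sit at forensic scale", {
  sim <- simulate_str_dataset(str_sim_config(seed = 12))
  afd <- allele_frequencies(sim$table, "Malaysia")
  fit <- estimate_theta_f(sim$table, "Malaysia")
  pf <- profile_frequencies(sim$table, afd, fit$theta, fit$f)
  m <- mean(pf$log10_pf)
  expect_gt(m, -18); expect_lt(m, -12)
})
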