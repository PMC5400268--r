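test_that("simulators are deterministic under a fixed seed", {
  s1 <- simulate_str_dataset(str_sim_config(seed = 17))
  s2 <- simulate_str_dataset(str_sim_config(seed = 17))
  expect_identical(s1$table$a1, s2$table$a1)
  expect_identical(s1$truth$pop_freq, s2$truth$pop_freq)
  s3 <- simulate_str_dataset(str_sim_config(seed = 18))
  expect_false(identical(s1$table$a1, s3$table$a1))
  c1 <- simulate_cpdna_dataset(cp_sim_config(seed = 17))
  c2 <- simulate_cpdna_dataset(cp_sim_config(seed = 17))
  expect_identical(c1$alignments[[3]]$seqs, c2$alignments[[3]]$seqs)
  expect_error(str_sim_config(), "seed")
  expect_error(cp_sim_config(), "seed")
})

test_that("STR generator honors its degenerate limits", {
  md <- one_pop_metadata()
  loci <- data.frame(locus = "L1", n_alleles = 2, stringsAsFactors = FALSE)
  big <- md; big$n_ind <- 10000L; big$n_pop <- 8L
  # f = 0.5, one biallelic locus: Ho = 2pq(1-f)
  cfg <- str_sim_config(metadata = big, loci = loci,
                        theta_region = c(Western = 0, Eastern = 0),
                        f_region = c(Western = 0.5, Eastern = 0.5),
                        theta_between = 0, missing_rate = 0,
                        ancestral_alpha = 100, seed = 23)
  sim <- simulate_str_dataset(cfg)
  p <- sim$truth$pop_freq[["L1"]][1, 1]
  ho <- mean(sim$table$a1[, 1] != sim$table$a2[, 1])
  expect_equal(ho, 2 * p * (1 - p) * 0.5, tolerance = 0.05)
  # theta = 0 copies ancestral frequencies exactly
  expect_equal(sim$truth$pop_freq[["L1"]][, 1],
               sim$truth$ancestral[["L1"]])
})

test_that("generated allele counts never exceed the configured maximum", {
  sim <- simulate_str_dataset(str_sim_config(seed = 29))
  loci <- shorea_loci()
  for (j in seq_len(15)) {
    seen <- length(unique(stats::na.omit(c(sim$table$a1[, j],
                                           sim$table$a2[, j]))))
    expect_lte(seen, loci$n_alleles[j])
  }
})

test_that("cpDNA generator reproduces the designed haplotype geography", {
  cp <- simulate_cpdna_dataset(cp_sim_config(seed = 31))
  expect_length(cp$alignments, 7L)
  expect_equal(vapply(cp$alignments, `[[`, 0L, "length"),
               c(`trnT-trnL` = 314L, `trnS-trnG` = 277L,
                 `atpB-rbcL` = 531L, `petG-trnP` = 449L,
                 `trnG-atpA` = 362L, `psbM-trnD` = 559L,
                 `trnG-rps14` = 400L))
  vs <- extract_variable_sites(cp$alignments)
  expect_equal(nrow(vs$sites), 39L)
  expect_equal(sum(vs$sites$kind == "substitution"), 31L)
  expect_equal(sum(vs$sites$kind == "indel"), 8L)
  db <- collapse_haplotypes(vs, cp$sample_pops)
  expect_length(db$haplotypes, 29L)
  # 16 haplotypes in single individuals; 2 shared between regions
  expect_equal(sum(db$counts == 1L), 16L)
  expect_equal(sum(db$region_status == "shared"), 2L)
  # dominant haplotype: Western-confined, ~57.5% of samples, in every
  # Western population
  expect_equal(unname(db$region_status["H1"]), "confined:Western")
  expect_equal(unname(db$counts["H1"]), 123L)
  md <- shorea_populations()
  wpops <- as.character(md$code[md$region == "Western"])
  expect_true(all(db$occurrence["H1", wpops] > 0L))
})

test_that("confinement-free and degenerate configurations work", {
  cp <- simulate_cpdna_dataset(cp_sim_config(shared_haplotypes = 0,
                                             seed = 33))
  vs <- extract_variable_sites(cp$alignments)
  db <- collapse_haplotypes(vs, cp$sample_pops)
  expect_false(any(db$region_status == "shared"))
  calls <- classify_haplotype(db, vs$states)
  s <- summarize_region_origin(calls)
  expect_equal(s[["unattributed"]], 0)
  expect_equal(s[["Western"]] + s[["Eastern"]], 100)
  # single-haplotype world: no variable sites, classification degenerate
  cp1 <- simulate_cpdna_dataset(cp_sim_config(n_haplotypes = 1,
                                              seed = 34))
  vs1 <- extract_variable_sites(cp1$alignments)
  expect_equal(nrow(vs1$sites), 0L)
  db1 <- collapse_haplotypes(vs1, cp1$sample_pops)
  expect_length(db1$haplotypes, 1L)
})

test_that("regional theta ordering holds across simulator seeds", {
  ord <- vapply(1:10, function(s) {
    sim <- simulate_str_dataset(str_sim_config(seed = 200 + s))
    estimate_theta_f(sim$table, "Eastern")$theta >
      estimate_theta_f(sim$table, "Western")$theta
  }, logical(1))
  expect_true(mean(ord) >= 0.9)
})

test_that("the planted-stand fixture carries the printed composition", {
  fx <- frim_fixture(with_queries = FALSE)
  expect_equal(nrow(fx$calls), 40L)
  expect_equal(sum(fx$calls$haplotype == "NOVEL"), 6L)
  expect_equal(as.vector(table(fx$calls$haplotype)[c("H1", "H2", "H3", "H5")]),
               c(27L, 4L, 2L, 1L))
  s <- summarize_region_origin(fx$calls)
  expect_equal(s[["Western"]], 75.0)
  expect_equal(s[["unattributed"]], 25.0)
  fxq <- frim_fixture(seed = 99)
  expect_length(fxq$queries$ids, 40L)
  expect_true(all(is.na(fxq$queries$pop)))
})
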