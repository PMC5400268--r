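test_that("substitutions and indel events are coded as single sites", {
  al <- make_alignments(c("AACGTAAGCT", "AAGGTAAGCT"))
  vs <- extract_variable_sites(al)
  expect_equal(nrow(vs$sites), 1L)
  expect_equal(vs$sites$kind, "substitution")
  # a two-column gap run is one indel event, not two sites
  al <- make_alignments(c("ACGTA", "AC--A"))
  vs <- extract_variable_sites(al)
  expect_equal(nrow(vs$sites), 1L)
  expect_equal(vs$sites$kind, "indel")
  expect_equal(unname(vs$states[, 1L]), c("1", "0"))
  # N gives an unknown state but the site is kept
  al <- make_alignments(c("ACGTA", "AGGTA", "ANGTA"))
  vs <- extract_variable_sites(al)
  expect_equal(nrow(vs$sites), 1L)
  expect_true(is.na(vs$states[3L, 1L]))
})

test_that("sample-set mismatch across spacers is rejected", {
  al <- make_alignments(c("ACGTA", "ACGTT"), c("GGGG", "GGGC"))
  rownames(al[[2L]]$seqs) <- c("s1", "zz")
  expect_error(extract_variable_sites(al), "sample-set mismatch")
})

test_that("haplotype collapse numbers by descending frequency", {
  al <- make_alignments(c("ACGTA", "ACGTA", "AGGTC"))
  vs <- extract_variable_sites(al)
  db <- collapse_haplotypes(vs, c(s1 = 1L, s2 = 1L, s3 = 2L),
                            two_pop_metadata())
  expect_length(db$haplotypes, 2L)
  expect_equal(unname(db$counts), c(2L, 1L))
  expect_equal(names(db$counts), c("H1", "H2"))
  expect_equal(unname(db$region_status),
               c("confined:Western", "confined:Eastern"))
  expect_equal(sum(db$counts), 3L)
})

test_that("identical samples collapse to one shared haplotype", {
  al <- make_alignments(c("ACGTA", "ACGTA"))
  vs <- extract_variable_sites(al)   # zero variable sites
  db <- collapse_haplotypes(vs, c(s1 = 1L, s2 = 2L), two_pop_metadata())
  expect_length(db$haplotypes, 1L)
  expect_equal(unname(db$region_status), "shared")
})

test_that("classification infers regions from confinement", {
  cp <- simulate_cpdna_dataset(cp_sim_config(seed = 2))
  vs <- extract_variable_sites(cp$alignments)
  db <- collapse_haplotypes(vs, cp$sample_pops)
  # H1 is the dominant Western-confined haplotype
  call <- classify_haplotype(db, db$states["H1", ])
  expect_equal(call$haplotype, "H1")
  expect_equal(call$inferred_region, "Western")
  # a shared haplotype is ambiguous
  shared <- names(db$region_status)[db$region_status == "shared"][1L]
  call <- classify_haplotype(db, db$states[shared, ])
  expect_equal(call$inferred_region, "ambiguous")
  # an unmatched vector is NOVEL with region none
  novel <- db$states["H1", ]
  flip <- which(db$sites$kind == "substitution")[1L]
  novel[flip] <- setdiff(c("A", "C", "G", "T"), novel[flip])[1L]
  call <- classify_haplotype(db, novel)
  expect_equal(call$haplotype, "NOVEL")
  expect_equal(call$inferred_region, "none")
  # length mismatch errors
  expect_error(classify_haplotype(db, novel[-1]), "sites")
})

test_that("unknown states use strict unique-completion matching", {
  al <- make_alignments(c("ACGTA", "AGGTC", "ACGTC"))
  vs <- extract_variable_sites(al)
  db <- collapse_haplotypes(vs, c(s1 = 1L, s2 = 1L, s3 = 1L),
                            one_pop_metadata())
  # sites: column 2 (C/G) and column 5 (A/C); states per sample:
  # s1 = (C, A), s2 = (G, C), s3 = (C, C)
  expect_equal(nrow(db$sites), 2L)
  h_of_s1 <- db$sample_haplotypes[["s1"]]
  # default k = 0: any unknown state means NOVEL
  expect_equal(classify_haplotype(db, c(NA, "A"))$haplotype, "NOVEL")
  # unique completion: only s1's vector has "A" at the second site
  expect_equal(classify_haplotype(db, c(NA, "A"),
                                  max_unknown = 1)$haplotype, h_of_s1)
  # ambiguous completion (two haplotypes end in "C") stays NOVEL
  expect_equal(classify_haplotype(db, c(NA, "C"),
                                  max_unknown = 1)$haplotype, "NOVEL")
})

test_that("collapse satisfies its structural invariants", {
  cp <- simulate_cpdna_dataset(cp_sim_config(seed = 7))
  vs <- extract_variable_sites(cp$alignments)
  db <- collapse_haplotypes(vs, cp$sample_pops)
  # occurrence counts sum to the number of samples
  expect_equal(sum(db$occurrence), nrow(vs$states))
  # confined haplotypes only occur in populations of that region
  md <- shorea_populations()
  pop_region <- md$region[match(as.integer(colnames(db$occurrence)),
                                md$code)]
  for (h in names(db$region_status)) {
    st <- db$region_status[[h]]
    if (st != "shared") {
      rg <- sub("confined:", "", st)
      expect_true(all(pop_region[db$occurrence[h, ] > 0L] == rg))
    }
  }
  # self-consistency: every training vector classifies to its own haplotype
  calls <- classify_haplotype(db, vs$states)
  expect_identical(calls$haplotype,
                   unname(db$sample_haplotypes[calls$sample]))
  # permutation invariance up to tie-breaking: the partition of samples is
  # unchanged, and haplotypes with a unique count keep their ID
  perm <- withr::with_seed(3, sample(nrow(vs$states)))
  vsp <- vs
  vsp$states <- vs$states[perm, , drop = FALSE]
  dbp <- collapse_haplotypes(vsp, cp$sample_pops)
  expect_equal(sort(unname(db$counts)), sort(unname(dbp$counts)))
  uniq <- names(db$counts)[!(db$counts %in%
                               db$counts[duplicated(db$counts)])]
  for (h in uniq) {
    carriers <- sort(names(db$sample_haplotypes)[db$sample_haplotypes == h])
    expect_identical(
      carriers,
      sort(names(dbp$sample_haplotypes)[dbp$sample_haplotypes == h]))
  }
  expect_gte(length(uniq), 3L)   # the check is not vacuous
})

test_that("regional attribution percentages follow the confinement rule", {
  calls <- data.frame(inferred_region = c(rep("Eastern", 10)))
  expect_equal(summarize_region_origin(calls)[["Eastern"]], 100)
  calls <- data.frame(inferred_region = rep("none", 5))
  s <- summarize_region_origin(calls)
  expect_equal(s[["Western"]], 0)
  expect_equal(s[["Eastern"]], 0)
  expect_equal(s[["unattributed"]], 100)
  expect_error(summarize_region_origin(data.frame()), "no haplotype calls")
})
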