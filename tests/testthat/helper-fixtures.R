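# Shared fixtures: tiny metadata and quick genotype-table builders.

two_pop_metadata <- function() {
  data.frame(code = c(1L, 2L), name = c("west_pop", "east_pop"),
             region = c("Western", "Eastern"), stringsAsFactors = FALSE)
}

one_pop_metadata <- function() {
  data.frame(code = 1L, name = "only", region = "Western",
             stringsAsFactors = FALSE)
}

# Build an str_genotypes table from per-locus lists of "a/b" genotype
# strings; alleles are small integers.
make_table <- function(genotypes, pop, metadata, loci = NULL) {
  n <- length(genotypes[[1L]])
  if (is.null(loci)) loci <- paste0("L", seq_along(genotypes))
  a1 <- vapply(genotypes, function(g)
    as.integer(sub("/.*", "", g)), integer(n))
  a2 <- vapply(genotypes, function(g)
    as.integer(sub(".*/", "", g)), integer(n))
  str_genotypes(paste0("ind", seq_len(n)), pop,
                matrix(a1, nrow = n), matrix(a2, nrow = n), loci, metadata)
}

# A single-population table of n HWE genotypes at one locus with allele
# frequencies p (named by allele label).
hwe_locus_table <- function(n, p, seed, n_loci = 1L) {
  md <- one_pop_metadata()
  labels <- as.integer(names(p))
  withr::with_seed(seed, {
    a1 <- matrix(sample(labels, n * n_loci, TRUE, p), n, n_loci)
    a2 <- matrix(sample(labels, n * n_loci, TRUE, p), n, n_loci)
    str_genotypes(paste0("i", seq_len(n)), rep(1L, n), a1, a2,
                  paste0("L", seq_len(n_loci)), md)
  })
}

# Tiny two-spacer alignment set from explicit sequence strings.
make_alignments <- function(...) {
  specs <- list(...)
  lapply(seq_along(specs), function(k) {
    seqs <- do.call(rbind, strsplit(specs[[k]], ""))
    rownames(seqs) <- paste0("s", seq_along(specs[[k]]))
    cp_alignment(paste0("spacer", k), seqs)
  })
}
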