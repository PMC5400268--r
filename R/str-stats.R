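#' Allele frequency database with 5/(2N) minimum-frequency floor
#'
#' Computes per-locus allele frequencies for a reference pool from observed
#' allele counts (complete-case per locus: individuals missing at a locus
#' are dropped from that locus's denominator only). With `apply_floor`,
#' frequencies below 5/(2N) — the level at which an allele is effectively
#' observed at least five times — are raised to the floor *without*
#' renormalizing the remaining frequencies (the conservative convention;
#' renormalization is available behind `renormalize`).
#'
#' @param x An [str_genotypes] table.
#' @param pool Pool selector: `"Malaysia"` (all individuals), `"Western"`,
#'   `"Eastern"`, or a vector of population codes.
#' @param apply_floor Apply the 5/(2N) floor (default `TRUE`).
#' @param renormalize After flooring, rescale so frequencies sum to 1
#'   (default `FALSE`).
#' @return Object of class `allele_freq_db`: list with `freq` (per-locus
#'   named numeric vectors), `raw` (unfloored), `n_individuals`, `floor`,
#'   `pool_label`, `loci`.
#' @examples
#' sim <- simulate_str_dataset(str_sim_config(seed = 1))
#' afd <- allele_frequencies(sim$table, "Malaysia")
#' afd$floor   # 5 / (2 * 1032)
#' @export
allele_frequencies <- function(x, pool = "Malaysia", apply_floor = TRUE,
                               renormalize = FALSE) {
  keep <- .pool_index(x, pool)
  if (!any(keep)) stop("empty pool: ", paste(pool, collapse = ","))
  n_ind <- sum(keep)
  floor_val <- 5 / (2 * n_ind)
  a1 <- x$a1[keep, , drop = FALSE]; a2 <- x$a2[keep, , drop = FALSE]
  raw <- stats::setNames(vector("list", length(x$loci)), x$loci)
  frq <- raw
  for (j in seq_along(x$loci)) {
    al <- c(a1[, j], a2[, j])
    al <- al[!is.na(al)]
    if (length(al) == 0L) stop("no genotypes at locus ", x$loci[j],
                               " in pool ", paste(pool, collapse = ","))
    tab <- table(al)
    p <- as.numeric(tab) / sum(tab)
    names(p) <- names(tab)
    raw[[j]] <- p
    if (apply_floor) {
      p <- pmax(p, floor_val)
      if (renormalize) p <- p / sum(p)
    }
    frq[[j]] <- p
  }
  structure(list(freq = frq, raw = raw, n_individuals = n_ind,
                 floor = floor_val,
                 pool_label = paste(pool, collapse = ","),
                 floored = apply_floor, loci = x$loci),
            class = "allele_freq_db")
}

#' @export
print.allele_freq_db <- function(x, ...) {
  cat("allele frequency database [", x$pool_label, "]: ",
      length(x$loci), " loci, N = ", x$n_individuals,
      ", floor 5/(2N) = ", format(round(x$floor, 4), nsmall = 4),
      if (x$floored) " (applied)" else " (not applied)", "\n", sep = "")
  invisible(x)
}

# Forensic summary statistics from a raw allele frequency vector / genotypes.
.pic <- function(p) {
  s2 <- sum(p^2)
  1 - s2 - (s2^2 - sum(p^4))
}

.unbiased_he <- function(p, n) {
  (2 * n / (2 * n - 1)) * (1 - sum(p^2))
}

#' Per-locus diversity and forensic parameters
#'
#' For each locus in the pool (complete-case per locus): number of alleles
#' `A`, observed heterozygosity `Ho`, Nei's unbiased expected
#' heterozygosity `He = (2n/(2n-1))(1 - sum p_i^2)`, polymorphic
#' information content `PIC`, matching probability `MP` (sum of squared
#' observed genotype proportions) and power of discrimination `PD = 1 - MP`.
#' A monomorphic locus returns `A=1, Ho=He=PIC=0, MP=1, PD=0`.
#'
#' @inheritParams allele_frequencies
#' @return A `data.frame` with one row per locus: `locus`, `n`, `A`, `Ho`,
#'   `He`, `PIC`, `MP`, `PD`.
#' @export
locus_summary <- function(x, pool = "Malaysia") {
  keep <- .pool_index(x, pool)
  out <- lapply(seq_along(x$loci), function(j) {
    a1 <- x$a1[keep, j]; a2 <- x$a2[keep, j]
    ok <- !is.na(a1)
    a1 <- a1[ok]; a2 <- a2[ok]
    n <- length(a1)
    if (n < 2L) stop("fewer than 2 complete genotypes at locus ", x$loci[j])
    tab <- table(c(a1, a2))
    p <- as.numeric(tab) / sum(tab)
    A <- length(p)
    Ho <- mean(a1 != a2)
    He <- if (A == 1L) 0 else .unbiased_he(p, n)
    PIC <- if (A == 1L) 0 else .pic(p)
    gt <- paste(a1, a2, sep = "/")
    gp <- as.numeric(table(gt)) / n
    MP <- sum(gp^2)
    data.frame(locus = x$loci[j], n = n, A = A, Ho = Ho, He = He,
               PIC = PIC, MP = MP, PD = 1 - MP, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Run fn with a private RNG stream; global .Random.seed is untouched.
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

# log conditional probability of a genotype array given its allele counts
# (Guo & Thompson exact-test statistic).
.log_genotype_array_prob <- function(a1, a2) {
  n <- length(a1)
  h <- sum(a1 != a2)
  gt <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  ng <- as.numeric(table(gt))
  na <- as.numeric(table(c(a1, a2)))
  lgamma(n + 1) - sum(lgamma(ng + 1)) + h * log(2) +
    sum(lgamma(na + 1)) - lgamma(2 * n + 1)
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Permutation version of the exact test: the `2n` observed alleles are
#' repeatedly re-paired at random into diploid genotypes and the
#' conditional probability of each permuted genotype array (the
#' Guo-Thompson statistic) is compared with the observed one. The p-value
#' is the proportion of permutations with probability less than or equal to
#' the observed, with the +1 correction in numerator and denominator.
#'
#' @inheritParams allele_frequencies
#' @param locus Locus name.
#' @param reps Number of Monte-Carlo permutations (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return The Monte-Carlo p-value (1.0 for a monomorphic locus).
#' @export
hwe_exact_test <- function(x, pool = "Malaysia", locus, reps = 10000,
                           seed = NULL) {
  if (reps < 1000) stop("reps must be >= 1000 for a stable exact p-value")
  j <- match(locus, x$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  keep <- .pool_index(x, pool)
  a1 <- x$a1[keep, j]; a2 <- x$a2[keep, j]
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  alleles <- c(a1, a2)
  if (length(unique(alleles)) < 2L) return(1.0)
  n <- length(a1)
  # integer-coded alleles; only the permutation-variant part of the
  # Guo-Thompson statistic (h*log2 - sum lgamma(n_g + 1)) is recomputed
  code <- as.integer(factor(alleles))
  k <- max(code)
  part_stat <- function(c1, c2) {
    lo <- pmin(c1, c2); hi <- pmax(c1, c2)
    ng <- tabulate((lo - 1L) * k + hi, nbins = k * k)
    ng <- ng[ng > 0L]
    sum(lo != hi) * log(2) - sum(lgamma(ng + 1))
  }
  obs <- part_stat(code[1:n], code[(n + 1):(2 * n)])
  .with_seed(seed, function() {
    cnt <- 0L
    for (r in seq_len(reps)) {
      perm <- sample(code)
      if (part_stat(perm[1:n], perm[(n + 1):(2 * n)]) <= obs + 1e-9)
        cnt <- cnt + 1L
    }
    (1 + cnt) / (reps + 1)
  })
}

# G statistic (log-likelihood ratio) of a two-way contingency table.
.g_stat <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  nz <- tab > 0
  2 * sum(tab[nz] * log(tab[nz] / e[nz]))
}

#' Monte-Carlo exact test of linkage (genotypic) equilibrium
#'
#' Permutation test of independence between the genotype columns of two
#' loci: one locus's genotypes are shuffled among individuals and the
#' log-likelihood-ratio (G) statistic of the two-locus genotype contingency
#' table is recomputed. The p-value carries the +1 correction.
#'
#' @inheritParams hwe_exact_test
#' @param loci Character vector of two locus names.
#' @return The Monte-Carlo p-value (1.0 if either locus is monomorphic).
#' @export
le_exact_test <- function(x, pool = "Malaysia", loci, reps = 10000,
                          seed = NULL) {
  if (reps < 1000) stop("reps must be >= 1000 for a stable exact p-value")
  if (length(loci) != 2L) stop("'loci' must name exactly two loci")
  jj <- match(loci, x$loci)
  if (anyNA(jj)) stop("unknown locus: ", paste(loci[is.na(jj)], collapse = ","))
  keep <- .pool_index(x, pool)
  ok <- !is.na(x$a1[keep, jj[1L]]) & !is.na(x$a1[keep, jj[2L]])
  g1 <- paste(x$a1[keep, jj[1L]][ok], x$a2[keep, jj[1L]][ok], sep = "/")
  g2 <- paste(x$a1[keep, jj[2L]][ok], x$a2[keep, jj[2L]][ok], sep = "/")
  if (length(unique(g1)) < 2L || length(unique(g2)) < 2L) return(1.0)
  # integer-coded genotypes; expected counts depend only on the (invariant)
  # margins, so they are precomputed once
  f1 <- as.integer(factor(g1)); f2 <- as.integer(factor(g2))
  r1 <- max(f1); r2 <- max(f2); n <- length(f1)
  e <- as.vector(outer(tabulate(f1, r1), tabulate(f2, r2))) / n
  gfun <- function(ff2) {
    tab <- tabulate((ff2 - 1L) * r1 + f1, nbins = r1 * r2)
    nz <- tab > 0L
    2 * sum(tab[nz] * log(tab[nz] / e[nz]))
  }
  obs <- gfun(f2)
  .with_seed(seed, function() {
    cnt <- 0L
    for (r in seq_len(reps)) {
      if (gfun(sample(f2)) >= obs - 1e-9) cnt <- cnt + 1L
    }
    (1 + cnt) / (reps + 1)
  })
}

#' Run HWE exact tests across a locus panel
#'
#' @inheritParams hwe_exact_test
#' @return `data.frame` with `locus` and `p`.
#' @export
hwe_tests <- function(x, pool = "Malaysia", reps = 10000, seed = NULL) {
  seeds <- if (is.null(seed)) vector("list", length(x$loci)) else
    as.list(seed + seq_along(x$loci))
  data.frame(locus = x$loci,
             p = vapply(seq_along(x$loci), function(j)
               hwe_exact_test(x, pool, x$loci[j], reps, seeds[[j]]),
               numeric(1)),
             stringsAsFactors = FALSE)
}

#' Run linkage-equilibrium exact tests for every locus pair
#'
#' Emits one test per unordered locus pair: `choose(L, 2)` rows (105 for a
#' 15-locus panel).
#'
#' @inheritParams hwe_exact_test
#' @return `data.frame` with `locus1`, `locus2`, `p`.
#' @export
le_tests <- function(x, pool = "Malaysia", reps = 10000, seed = NULL) {
  pairs <- utils::combn(x$loci, 2L)
  seeds <- if (is.null(seed)) vector("list", ncol(pairs)) else
    as.list(seed + seq_len(ncol(pairs)))
  data.frame(locus1 = pairs[1L, ], locus2 = pairs[2L, ],
             p = vapply(seq_len(ncol(pairs)), function(k)
               le_exact_test(x, pool, pairs[, k], reps, seeds[[k]]),
               numeric(1)),
             stringsAsFactors = FALSE)
}

#' Multiple-testing correction decisions
#'
#' Plain Bonferroni (reject when `p < alpha/m`) or sequential Bonferroni
#' (Holm: sort ascending, reject while `p_(i) < alpha/(m - i + 1)`, stop at
#' the first failure).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @param method `"bonferroni"` or `"sequential"`.
#' @return List with `reject` (logical, original order), `m`, `alpha`,
#'   `method`, and (Bonferroni) `threshold = alpha/m`.
#' @export
multiple_testing <- function(pvals, alpha = 0.05,
                             method = c("bonferroni", "sequential")) {
  method <- match.arg(method)
  if (length(pvals) == 0L) stop("empty p-value list")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  if (method == "bonferroni") {
    thr <- alpha / m
    reject <- pvals < thr
    list(reject = reject, m = m, alpha = alpha, method = method,
         threshold = thr)
  } else {
    o <- order(pvals)
    rej_sorted <- logical(m)
    for (i in seq_len(m)) {
      if (pvals[o[i]] < alpha / (m - i + 1)) rej_sorted[i] <- TRUE
      else break
    }
    reject <- logical(m)
    reject[o] <- rej_sorted
    list(reject = reject, m = m, alpha = alpha, method = method)
  }
}
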