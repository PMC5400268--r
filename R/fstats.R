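#' Weir-Cockerham variance components per locus and allele
#'
#' Computes the among-population (`a`), among-individual-within-population
#' (`b`) and within-individual (`c`) variance components of Weir &
#' Cockerham's (1984) method-of-moments estimator, per locus and allele,
#' using observed heterozygote frequencies and the `n_bar`/`n_c`
#' sample-size weights. Individuals missing at a locus are dropped from
#' that locus only (complete-case per locus).
#'
#' @inheritParams allele_frequencies
#' @param allow_single Allow a single-population pool: the among-population
#'   component is then 0 by construction and only `b`, `c` (hence `f`) are
#'   meaningful. Default `FALSE` (error with one population).
#' @return `data.frame` with `locus`, `allele`, `a`, `b`, `c`.
#' @export
variance_components <- function(x, pool = "Malaysia", allow_single = FALSE) {
  keep <- .pool_index(x, pool)
  out <- lapply(seq_along(x$loci), function(j) {
    a1 <- x$a1[keep, j]; a2 <- x$a2[keep, j]; popv <- x$pop[keep]
    ok <- !is.na(a1)
    a1 <- a1[ok]; a2 <- a2[ok]; popv <- popv[ok]
    pops <- sort(unique(popv))
    r <- length(pops)
    if (r < 2L && !allow_single)
      stop("pool has a single population at locus ", x$loci[j],
           "; among-population components are undefined")
    ni <- as.numeric(table(factor(popv, levels = pops)))
    nbar <- mean(ni)
    nc <- if (r >= 2L) (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1) else nbar
    alleles <- sort(unique(c(a1, a2)))
    res <- lapply(alleles, function(al) {
      # per-population frequency of the allele and of heterozygotes carrying it
      cnt <- (a1 == al) + (a2 == al)
      het <- (a1 != a2) & (a1 == al | a2 == al)
      pi <- tapply(cnt, factor(popv, levels = pops), sum) / (2 * ni)
      hi <- tapply(het, factor(popv, levels = pops), mean)
      pbar <- sum(ni * pi) / sum(ni)
      hbar <- sum(ni * hi) / sum(ni)
      s2 <- if (r >= 2L) sum(ni * (pi - pbar)^2) / ((r - 1) * nbar) else 0
      rr <- if (r >= 2L) (r - 1) / r else 0
      a <- if (r >= 2L)
        (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                         (pbar * (1 - pbar) - rr * s2 - hbar / 4)) else 0
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - rr * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      c_ <- hbar / 2
      data.frame(locus = x$loci[j], allele = al, a = a, b = b, c = c_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  do.call(rbind, out)
}

#' Estimate coancestry (theta) and inbreeding (f) coefficients
#'
#' Ratio-of-sums Weir-Cockerham estimates across all alleles and loci:
#' `theta = sum(a) / sum(a + b + c)` and `f = 1 - sum(c) / sum(b + c)`.
#'
#' @inheritParams variance_components
#' @param level Label for the hierarchical level (defaults to the pool).
#' @param f_only Estimate only `f` (permits a single-population pool;
#'   `theta` is `NA`).
#' @return Object of class `fstat`: list with `level`, `theta`, `f`,
#'   `ci_theta`, `ci_f` (NULL until [bootstrap_ci()]), `reps`, and
#'   per-locus component sums used by the bootstrap.
#' @examples
#' sim <- simulate_str_dataset(str_sim_config(seed = 1))
#' estimate_theta_f(sim$table, "Western")
#' @export
estimate_theta_f <- function(x, pool = "Malaysia", level = NULL,
                             f_only = FALSE) {
  comp <- variance_components(x, pool, allow_single = f_only)
  sums <- do.call(rbind, lapply(split(comp, comp$locus), function(d)
    data.frame(locus = d$locus[1L], a = sum(d$a), b = sum(d$b),
               c = sum(d$c), stringsAsFactors = FALSE)))
  sums <- sums[match(intersect(x$loci, sums$locus), sums$locus), ]
  if (sum(sums$a + sums$b + sums$c) == 0)
    stop("all loci monomorphic in pool ", paste(pool, collapse = ","))
  theta <- if (f_only) NA_real_ else
    sum(sums$a) / sum(sums$a + sums$b + sums$c)
  # under total fixation there are no within-population pairs: f undefined
  f <- if (sum(sums$b + sums$c) > 0)
    1 - sum(sums$c) / sum(sums$b + sums$c) else NA_real_
  if (f_only && is.na(f))
    stop("inbreeding coefficient undefined: no within-population variation")
  structure(list(level = if (is.null(level)) paste(pool, collapse = ",")
                 else level,
                 theta = theta, f = f, ci_theta = NULL, ci_f = NULL,
                 reps = 0L, locus_sums = sums),
            class = "fstat")
}

#' Bootstrap confidence intervals for theta and f
#'
#' Percentile bootstrap across loci: loci are resampled with replacement
#' and the ratio-of-sums estimates recomputed; the 2.5% and 97.5%
#' percentiles bound the 95% interval.
#'
#' @inheritParams estimate_theta_f
#' @param reps Bootstrap replicates (default 1000; fewer than 100 rejected
#'   unless `force = TRUE`).
#' @param seed Optional integer seed.
#' @param force Allow `reps < 100`.
#' @return An `fstat` object with `ci_theta`, `ci_f` and `reps` filled in.
#' @export
bootstrap_ci <- function(x, pool = "Malaysia", reps = 1000, seed = NULL,
                         level = NULL, f_only = FALSE, force = FALSE) {
  if (reps < 100 && !force)
    stop("reps < 100 gives unstable percentile bounds; use force = TRUE")
  fit <- estimate_theta_f(x, pool, level = level, f_only = f_only)
  sums <- fit$locus_sums
  L <- nrow(sums)
  if (L < 2L) stop("bootstrap across loci needs >= 2 loci")
  bt <- .with_seed(seed, function() {
    idx <- matrix(sample.int(L, L * reps, replace = TRUE), nrow = reps)
    t(apply(idx, 1L, function(ii) {
      a <- sum(sums$a[ii]); b <- sum(sums$b[ii]); cc <- sum(sums$c[ii])
      c(theta = a / (a + b + cc), f = 1 - cc / (b + cc))
    }))
  })
  fit$ci_theta <- if (f_only) NULL else
    unname(stats::quantile(bt[, "theta"], c(0.025, 0.975), na.rm = TRUE))
  fit$ci_f <- unname(stats::quantile(bt[, "f"], c(0.025, 0.975),
                                     na.rm = TRUE))
  fit$reps <- reps
  fit
}

#' @export
print.fstat <- function(x, ...) {
  cat("Weir-Cockerham F-statistics - level:", x$level, "\n")
  fmt <- function(v) formatC(v, digits = 4, format = "f")
  cat("  theta =", fmt(x$theta))
  if (!is.null(x$ci_theta))
    cat("  95% CI [", fmt(x$ci_theta[1]), ",", fmt(x$ci_theta[2]), "]")
  cat("\n  f     =", fmt(x$f))
  if (!is.null(x$ci_f))
    cat("  95% CI [", fmt(x$ci_f[1]), ",", fmt(x$ci_f[2]), "]")
  if (x$reps > 0) cat("\n  (", x$reps, "bootstrap replicates across loci )")
  cat("\n")
  invisible(x)
}

#' Hierarchical F-statistics table
#'
#' Point estimates and bootstrap intervals for the national pool and each
#' region, in the conventional three-row layout.
#'
#' @inheritParams bootstrap_ci
#' @return `data.frame` with `level`, `n`, `theta`, `theta_2.5`,
#'   `theta_97.5`, `f`, `f_2.5`, `f_97.5`.
#' @export
fstat_table <- function(x, reps = 1000, seed = NULL) {
  levels <- c("Malaysia", "Western", "Eastern")
  rows <- lapply(seq_along(levels), function(i) {
    lv <- levels[i]
    fit <- bootstrap_ci(x, lv, reps = reps,
                        seed = if (is.null(seed)) NULL else seed + i)
    data.frame(level = lv, n = sum(.pool_index(x, lv)),
               theta = fit$theta, theta_2.5 = fit$ci_theta[1],
               theta_97.5 = fit$ci_theta[2], f = fit$f,
               f_2.5 = fit$ci_f[1], f_97.5 = fit$ci_f[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
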