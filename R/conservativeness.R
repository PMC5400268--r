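#' Conservativeness test of the pooled national database
#'
#' For every eligible individual (complete multilocus profile, population
#' of size at least `min_pop_size`), computes the profile frequency against
#' its own region's database with region-specific parameters
#' (`P_origin`) and against the pooled national database with the combined
#' parameters (`P_combined`), and the difference
#' `d = log10(P_origin / P_combined)`. The pooled database is conservative
#' for a profile when `d < 0`, i.e. the national database does not
#' understate the profile's frequency.
#'
#' @param x An [str_genotypes] table (the full national database; regional
#'   and national allele-frequency databases are built from it with the
#'   5/(2N) floor).
#' @param theta_combined,f_combined Parameters for the national
#'   `P_combined` computation.
#' @param theta_regional,f_regional Named numeric vectors
#'   (`c(Western=, Eastern=)`) of region-specific parameters for
#'   `P_origin`. Default `NULL`: estimated from `x` by [estimate_theta_f()].
#' @param min_pop_size Populations below this size are excluded from
#'   testing (their individuals still contribute to the databases).
#' @return Object of class `conservativeness`: list with `profiles`
#'   (`data.frame`: id, pop, region, log10_Po, log10_Pc, d), `summary`
#'   (per region: n_tests, mean_d, prop_negative, mean log10 profile
#'   frequencies), `params`.
#' @export
conservativeness_test <- function(x, theta_combined, f_combined,
                                  theta_regional = NULL, f_regional = NULL,
                                  min_pop_size = 16) {
  if (is.null(theta_regional) || is.null(f_regional)) {
    fits <- lapply(c(Western = "Western", Eastern = "Eastern"),
                   function(rg) estimate_theta_f(x, rg))
    if (is.null(theta_regional))
      theta_regional <- vapply(fits, `[[`, numeric(1), "theta")
    if (is.null(f_regional))
      f_regional <- vapply(fits, `[[`, numeric(1), "f")
  }
  elig <- .eligible_profiles(x, min_pop_size)
  national <- allele_frequencies(x, "Malaysia")
  prof <- list()
  for (rg in c("Western", "Eastern")) {
    idx <- elig & !is.na(x$region) & x$region == rg
    if (!any(idx)) stop("region ", rg, " has zero eligible profiles")
    regional <- allele_frequencies(x, rg)
    po <- rowSums(log10(.profile_locus_matrix(
      x, idx, regional, theta_regional[[rg]], f_regional[[rg]])))
    pc <- rowSums(log10(.profile_locus_matrix(
      x, idx, national, theta_combined, f_combined)))
    prof[[rg]] <- data.frame(id = x$ids[idx], pop = x$pop[idx], region = rg,
                             log10_Po = po, log10_Pc = pc, d = po - pc,
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  profiles <- do.call(rbind, prof)
  rownames(profiles) <- NULL
  summary <- do.call(rbind, lapply(split(profiles, profiles$region),
                                   function(d)
    data.frame(region = d$region[1L], n_tests = nrow(d),
               mean_d = mean(d$d), prop_negative = mean(d$d < 0),
               mean_log10_Po = mean(d$log10_Po),
               mean_log10_Pc = mean(d$log10_Pc),
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(profiles = profiles, summary = summary,
                 params = list(theta_combined = theta_combined,
                               f_combined = f_combined,
                               theta_regional = theta_regional,
                               f_regional = f_regional,
                               min_pop_size = min_pop_size)),
            class = "conservativeness")
}

.eligible_profiles <- function(x, min_pop_size) {
  pop_n <- table(x$pop)
  big <- as.integer(names(pop_n)[pop_n >= min_pop_size])
  complete_profiles(x) & !is.na(x$pop) & x$pop %in% big
}

#' @export
print.conservativeness <- function(x, ...) {
  cat("database conservativeness test (theta_combined =",
      format(x$params$theta_combined, digits = 4), ")\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Coancestry adjustment sweep for database conservativeness
#'
#' Increases the combined-database coancestry value along a grid
#' (`theta_start`, `theta_start + step`, ...): at each grid value only
#' `P_combined` is recomputed while every profile's `P_origin` stays fixed.
#' For each region the sweep reports the first grid value at which all
#' tests are conservative (100% negative `d`), or a flagged failure at
#' `theta_max`.
#'
#' @inheritParams conservativeness_test
#' @param theta_start First grid value (conventionally the estimated
#'   national coancestry).
#' @param step Grid increment (default 0.01).
#' @param theta_max Upper end of the grid (default 0.5).
#' @return Object of class `theta_sweep`: list with `adjusted_theta` (named
#'   vector, `NA` when not achieved by `theta_max`), `achieved` (logical),
#'   `trace` (`data.frame`: theta, region, mean_d, prop_negative,
#'   mean_profile_frequency of the combined database), `params`.
#' @export
theta_sweep <- function(x, theta_start, f_combined,
                        theta_regional = NULL, f_regional = NULL,
                        step = 0.01, theta_max = 0.5, min_pop_size = 16) {
  if (step <= 0) stop("step must be > 0")
  base <- conservativeness_test(x, theta_start, f_combined,
                                theta_regional, f_regional, min_pop_size)
  profiles <- base$profiles
  elig <- .eligible_profiles(x, min_pop_size)
  national <- allele_frequencies(x, "Malaysia")
  grid <- seq(theta_start, theta_max, by = step)
  regions <- c("Western", "Eastern")
  adjusted <- stats::setNames(rep(NA_real_, 2L), regions)
  trace <- list()
  for (th in grid) {
    pc <- rowSums(log10(.profile_locus_matrix(
      x, elig, national, th, f_combined)))
    pc <- pc[match(profiles$id, x$ids[elig])]
    d <- profiles$log10_Po - pc
    for (rg in regions) {
      sel <- profiles$region == rg
      trace[[length(trace) + 1L]] <-
        data.frame(theta = th, region = rg, mean_d = mean(d[sel]),
                   prop_negative = mean(d[sel] < 0),
                   mean_profile_frequency = mean(10^pc[sel]),
                   stringsAsFactors = FALSE)
      if (is.na(adjusted[rg]) && all(d[sel] < 0)) adjusted[rg] <- th
    }
    if (!anyNA(adjusted)) break
  }
  structure(list(adjusted_theta = adjusted, achieved = !is.na(adjusted),
                 trace = do.call(rbind, trace),
                 params = c(base$params,
                            list(theta_start = theta_start, step = step,
                                 theta_max = theta_max))),
            class = "theta_sweep")
}

#' @export
print.theta_sweep <- function(x, ...) {
  cat("coancestry adjustment sweep (start",
      format(x$params$theta_start, digits = 4), ", step",
      format(x$params$step, digits = 4), ")\n")
  for (rg in names(x$adjusted_theta)) {
    if (x$achieved[rg])
      cat(sprintf("  %s: fully conservative at theta = %.4f\n",
                  rg, x$adjusted_theta[rg]))
    else
      cat(sprintf("  %s: not conservative by theta_max = %.2f\n",
                  rg, x$params$theta_max))
  }
  invisible(x)
}
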