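#' Dirichlet posterior-predictive genotype likelihood
#'
#' The Rannala-Mountain building block of the Bayesian assignment method:
#' with a symmetric Dirichlet(1/k, ..., 1/k) prior over the `k` alleles
#' observed at a locus across the whole reference, the posterior-predictive
#' probability that an unordered diploid genotype is drawn from a candidate
#' population with reference allele counts `n_i` (total `n`) is
#' `2 (n_i + 1/k)(n_j + 1/k) / ((n+1)(n+2))` for a heterozygote and
#' `(n_i + 1/k)(n_i + 1 + 1/k) / ((n+1)(n+2))` for a homozygote. Alleles
#' never seen in the reference are handled by the prior mass, so the
#' likelihood is always positive.
#'
#' @param counts Named numeric vector of the candidate population's allele
#'   counts at the locus (names are allele labels; alleles absent from the
#'   vector count 0).
#' @param allele1,allele2 The query genotype's allele labels.
#' @param k Number of distinct alleles observed at the locus across the
#'   whole reference.
#' @return The genotype probability.
#' @examples
#' rm_genotype_likelihood(c(A = 3, B = 1), "A", "B", k = 2)  # 0.35
#' @export
rm_genotype_likelihood <- function(counts, allele1, allele2, k) {
  if (k < 1) stop("k must be >= 1")
  if (any(counts < 0)) stop("allele counts must be non-negative")
  n <- sum(counts)
  gi <- function(al) {
    v <- counts[as.character(al)]
    if (is.na(v)) 0 else unname(v)
  }
  ni <- gi(allele1); nj <- gi(allele2)
  if (identical(as.character(allele1), as.character(allele2)))
    (ni + 1 / k) * (ni + 1 + 1 / k) / ((n + 1) * (n + 2))
  else
    2 * (ni + 1 / k) * (nj + 1 / k) / ((n + 1) * (n + 2))
}

# Per-locus allele-count matrices (allele x population) for a reference
# table, plus k (distinct alleles per locus across the whole reference).
.reference_counts <- function(ref, candidates) {
  lapply(seq_along(ref$loci), function(j) {
    al <- c(ref$a1[, j], ref$a2[, j])
    alleles <- sort(unique(al[!is.na(al)]))
    cm <- vapply(candidates, function(p) {
      sel <- !is.na(ref$pop) & ref$pop == p & !is.na(ref$a1[, j])
      tabulate(match(c(ref$a1[sel, j], ref$a2[sel, j]), alleles),
               nbins = length(alleles))
    }, numeric(length(alleles)))
    cm <- matrix(cm, nrow = length(alleles),
                 dimnames = list(as.character(alleles),
                                 as.character(candidates)))
    cm
  })
}

# Multilocus log-likelihood of one individual's genotype for every
# candidate population (vectorized over candidates). counts_list comes from
# .reference_counts; loo_pop (if not NA) has the individual's own alleles
# removed from that population's column.
.assign_loglik <- function(x, i, counts_list, candidates, loo_pop = NA) {
  ll <- numeric(length(candidates))
  used <- FALSE
  for (j in seq_along(x$loci)) {
    a1 <- x$a1[i, j]; a2 <- x$a2[i, j]
    if (is.na(a1)) next
    used <- TRUE
    cm <- counts_list[[j]]
    k <- nrow(cm)
    if (!is.na(loo_pop)) {
      col <- as.character(loo_pop)
      cm[, col] <- cm[, col] -
        tabulate(match(c(a1, a2), as.integer(rownames(cm))), nbins = k)
    }
    n <- colSums(cm)
    r1 <- match(as.character(a1), rownames(cm))
    r2 <- match(as.character(a2), rownames(cm))
    ni <- if (is.na(r1)) rep(0, ncol(cm)) else cm[r1, ]
    nj <- if (is.na(r2)) rep(0, ncol(cm)) else cm[r2, ]
    if (a1 == a2)
      ll <- ll + log((ni + 1 / k) * (ni + 1 + 1 / k)) -
        log((n + 1) * (n + 2))
    else
      ll <- ll + log(2 * (ni + 1 / k) * (nj + 1 / k)) -
        log((n + 1) * (n + 2))
  }
  if (!used) return(NULL)
  ll
}

.scores_from_loglik <- function(ll) {
  m <- max(ll)
  w <- exp(ll - m)
  100 * w / sum(w)
}

#' Leave-one-out Bayesian self-assignment
#'
#' Classifies every reference individual to the candidate population with
#' the highest multilocus Dirichlet posterior-predictive likelihood.
#' With `leave_one_out = TRUE` (default) the individual's own two alleles
#' per locus are removed from its population's counts before scoring, so
#' the self-assignment rates are not trivially optimistic. Populations
#' smaller than `min_pop_size` are excluded (both as test individuals and
#' as candidates). The region-level rate is the fraction of individuals
#' whose best population lies in their true region.
#'
#' @param x An [str_genotypes] reference table.
#' @param min_pop_size Minimum population size for inclusion (default 16).
#' @param leave_one_out Remove each individual's alleles from its own
#'   population's counts (default `TRUE`).
#' @return Object of class `assignment`: list with `results`
#'   (per individual: best population/region, normalized score, correct
#'   flags), `pop_rates`, `region_rates`, `candidates`, `leave_one_out`.
#' @export
self_assign <- function(x, min_pop_size = 16, leave_one_out = TRUE) {
  pop_n <- table(x$pop)
  candidates <- as.integer(names(pop_n)[pop_n >= min_pop_size])
  if (length(candidates) < 2L)
    stop("fewer than 2 candidate populations after size exclusion")
  keep <- which(!is.na(x$pop) & x$pop %in% candidates)
  counts_list <- .reference_counts(x, candidates)
  cand_region <- x$metadata$region[match(candidates, x$metadata$code)]
  res <- vector("list", length(keep))
  for (u in seq_along(keep)) {
    i <- keep[u]
    ll <- .assign_loglik(x, i, counts_list, candidates,
                         loo_pop = if (leave_one_out) x$pop[i] else NA)
    if (is.null(ll)) stop("individual ", x$ids[i], " has no genotyped loci")
    sc <- .scores_from_loglik(ll)
    best <- which.max(ll)
    if (sum(ll == ll[best]) > 1L)
      warning("likelihood tie for ", x$ids[i],
              "; first candidate in order kept")
    res[[u]] <- data.frame(
      id = x$ids[i], pop = x$pop[i], region = x$region[i],
      best_pop = candidates[best], best_region = cand_region[best],
      score = sc[best],
      correct_pop = candidates[best] == x$pop[i],
      correct_region = cand_region[best] == x$region[i],
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  pop_rates <- do.call(rbind, lapply(split(results, results$pop), function(d)
    data.frame(pop = d$pop[1L], region = d$region[1L], n = nrow(d),
               correct_pop = mean(d$correct_pop),
               stringsAsFactors = FALSE)))
  pop_rates <- pop_rates[order(pop_rates$pop), ]
  rownames(pop_rates) <- NULL
  region_rates <- do.call(rbind, lapply(split(results, results$region),
                                        function(d)
    data.frame(region = d$region[1L], n = nrow(d),
               correct_pop = mean(d$correct_pop),
               correct_region = mean(d$correct_region),
               stringsAsFactors = FALSE)))
  rownames(region_rates) <- NULL
  structure(list(results = results, pop_rates = pop_rates,
                 region_rates = region_rates, candidates = candidates,
                 leave_one_out = leave_one_out),
            class = "assignment")
}

#' @export
print.assignment <- function(x, ...) {
  cat("Bayesian self-assignment (",
      if (x$leave_one_out) "leave-one-out" else "resubstitution",
      "), ", length(x$candidates), " candidate populations\n", sep = "")
  for (i in seq_len(nrow(x$region_rates)))
    cat(sprintf("  %s: %.2f%% by population, %.2f%% by region (n = %d)\n",
                x$region_rates$region[i],
                100 * x$region_rates$correct_pop[i],
                100 * x$region_rates$correct_region[i],
                x$region_rates$n[i]))
  invisible(x)
}

#' Assign query profiles against a reference database
#'
#' Scores query individuals (no leave-one-out) against every candidate
#' population; a query whose top normalized score falls below
#' `score_threshold` is reported as unassigned.
#'
#' @param reference An [str_genotypes] reference table.
#' @param queries An [str_genotypes] table of query profiles (population
#'   codes may be `NA`); query loci must all be present in the reference.
#' @param score_threshold Minimum normalized confidence score (0-100) for
#'   an assignment (default 80).
#' @param min_pop_size Minimum reference population size for candidacy.
#' @return `data.frame` with `id`, `best_pop`, `best_region`, `score`,
#'   `assigned` (`FALSE` rows read "unassigned (below threshold)" in
#'   `call`); attribute `"scores"` holds the full score matrix
#'   (queries x candidates).
#' @export
assign_query <- function(reference, queries, score_threshold = 80,
                         min_pop_size = 16) {
  if (!all(queries$loci %in% reference$loci))
    stop("query loci absent from reference: ",
         paste(setdiff(queries$loci, reference$loci), collapse = ", "))
  pop_n <- table(reference$pop)
  candidates <- as.integer(names(pop_n)[pop_n >= min_pop_size])
  counts_list <- .reference_counts(reference, candidates)
  cand_region <- reference$metadata$region[
    match(candidates, reference$metadata$code)]
  # align query columns with reference locus order
  jmap <- match(reference$loci, queries$loci)
  qa1 <- matrix(NA_integer_, length(queries$ids), length(reference$loci))
  qa2 <- qa1
  qa1[, !is.na(jmap)] <- queries$a1[, jmap[!is.na(jmap)], drop = FALSE]
  qa2[, !is.na(jmap)] <- queries$a2[, jmap[!is.na(jmap)], drop = FALSE]
  qx <- list(ids = queries$ids, loci = reference$loci, a1 = qa1, a2 = qa2)
  scores <- matrix(NA_real_, length(queries$ids), length(candidates),
                   dimnames = list(queries$ids, as.character(candidates)))
  rows <- vector("list", length(queries$ids))
  for (i in seq_along(queries$ids)) {
    ll <- .assign_loglik(qx, i, counts_list, candidates, loo_pop = NA)
    if (is.null(ll))
      stop("query ", queries$ids[i], " has no genotyped loci")
    sc <- .scores_from_loglik(ll)
    scores[i, ] <- sc
    best <- which.max(ll)
    ok <- sc[best] >= score_threshold
    rows[[i]] <- data.frame(
      id = queries$ids[i], best_pop = candidates[best],
      best_region = cand_region[best], score = sc[best], assigned = ok,
      call = if (ok) paste0("population ", candidates[best]) else
        "unassigned (below threshold)",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "scores") <- scores
  out
}
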