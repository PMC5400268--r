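#' Single-locus genotype frequency under the subpopulation-cum-inbreeding model
#'
#' The default `mode = "match"` gives the conditional (match-probability)
#' genotype frequency: the Balding-Nichols sampling formula for a
#' subdivided population with coancestry `theta`, extended with
#' within-population inbreeding `f` entering as an identity-by-descent
#' mixture at the second allele draw:
#' \deqn{P_{hom} = \frac{2\theta + (1-\theta)p}{1+\theta}\left(f + (1-f)\,
#'   \frac{3\theta + (1-\theta)p}{1+2\theta}\right)}
#' \deqn{P_{het} = 2(1-f)\,\frac{\theta + (1-\theta)p_i}{1+\theta}\,
#'   \frac{\theta + (1-\theta)p_j}{1+2\theta}}
#' `mode = "unconditional"` gives the population genotype proportions
#' `p^2 + f p (1-p)` (homozygote) and `2 p_i p_j (1-f)` (heterozygote).
#' At `f = 0` the match mode reduces to Balding-Nichols; at
#' `theta = f = 0` both modes reduce to Hardy-Weinberg proportions.
#'
#' @param p_i,p_j Allele frequencies (floored database frequencies for
#'   match-probability use); a homozygote has `p_i == p_j` — equality of the
#'   allele labels is declared via `hom`.
#' @param theta Coancestry coefficient, `0 <= theta < 1`.
#' @param f Within-population inbreeding coefficient, `0 <= f < 1`.
#' @param hom Logical: is the genotype homozygous? Defaults to `TRUE` when
#'   `p_j` is missing.
#' @param mode `"match"` (default) or `"unconditional"`.
#' @return Genotype frequency/probability (vectorized over `p_i`, `p_j`,
#'   `hom`).
#' @examples
#' genotype_frequency(0.5, theta = 0, f = 0)                   # 0.25
#' genotype_frequency(0.1, 0.2, theta = 0.05, f = 0, hom = FALSE)
#' @export
genotype_frequency <- function(p_i, p_j = p_i, theta = 0, f = 0,
                               hom = missing(p_j),
                               mode = c("match", "unconditional")) {
  mode <- match.arg(mode)
  if (any(p_i <= 0 | p_i > 1) || any(p_j <= 0 | p_j > 1))
    stop("allele frequencies must lie in (0, 1]")
  if (any(theta < 0 | theta >= 1) || any(f < 0 | f >= 1))
    stop("theta and f must lie in [0, 1)")
  if (mode == "match") {
    hom_p <- (2 * theta + (1 - theta) * p_i) / (1 + theta) *
      (f + (1 - f) * (3 * theta + (1 - theta) * p_i) / (1 + 2 * theta))
    het_p <- 2 * (1 - f) *
      (theta + (1 - theta) * p_i) / (1 + theta) *
      (theta + (1 - theta) * p_j) / (1 + 2 * theta)
  } else {
    hom_p <- p_i^2 + f * p_i * (1 - p_i)
    het_p <- 2 * p_i * p_j * (1 - f)
  }
  ifelse(hom, hom_p, het_p)
}

# Per-locus match-mode genotype frequencies for a set of individuals.
# Returns a matrix (individuals x loci); alleles absent from the database
# contribute at the floor. Rows with any missing call get NA.
.profile_locus_matrix <- function(x, idx, freqs, theta, f) {
  n <- sum(idx)
  out <- matrix(NA_real_, n, length(x$loci),
                dimnames = list(x$ids[idx], x$loci))
  for (j in seq_along(x$loci)) {
    fj <- freqs$freq[[x$loci[j]]]
    a1 <- x$a1[idx, j]; a2 <- x$a2[idx, j]
    p1 <- fj[as.character(a1)]
    p2 <- fj[as.character(a2)]
    p1[is.na(p1) & !is.na(a1)] <- freqs$floor
    p2[is.na(p2) & !is.na(a2)] <- freqs$floor
    out[, j] <- genotype_frequency(p1, p2, theta, f, hom = (a1 == a2))
  }
  out
}

#' Multilocus profile frequency and random match probability
#'
#' The profile frequency of one individual's complete multilocus STR
#' genotype: the product of per-locus match-mode genotype frequencies
#' computed from floored database frequencies under the
#' subpopulation-cum-inbreeding model. The random match probability is
#' reported as its reciprocal ("1 in X").
#'
#' @param x An [str_genotypes] table.
#' @param id Individual ID (must have a complete profile).
#' @param freqs An [allele_frequencies()] database (floored).
#' @param theta,f Model parameters for the reference pool.
#' @return Object of class `profile_frequency`: list with `id`,
#'   `per_locus` (`data.frame` of locus, alleles, frequency),
#'   `profile_frequency`, `rmp_reciprocal`, `theta`, `f`, `pool_label`.
#' @export
profile_frequency <- function(x, id, freqs, theta = 0, f = 0) {
  i <- match(id, x$ids)
  if (is.na(i)) stop("unknown individual: ", id)
  if (any(is.na(x$a1[i, ])))
    stop("profile rejected: individual ", id, " has missing calls at ",
         paste(x$loci[is.na(x$a1[i, ])], collapse = ", "))
  idx <- seq_along(x$ids) == i
  gm <- .profile_locus_matrix(x, idx, freqs, theta, f)
  per_locus <- data.frame(locus = x$loci, a1 = x$a1[i, ], a2 = x$a2[i, ],
                          frequency = gm[1L, ], row.names = NULL,
                          stringsAsFactors = FALSE)
  pf <- prod(gm[1L, ])
  structure(list(id = id, per_locus = per_locus, profile_frequency = pf,
                 rmp_reciprocal = 1 / pf, theta = theta, f = f,
                 pool_label = freqs$pool_label),
            class = "profile_frequency")
}

#' @export
print.profile_frequency <- function(x, ...) {
  cat("profile frequency for", x$id, "against", x$pool_label,
      sprintf("(theta = %.4f, f = %.4f)\n", x$theta, x$f))
  cat(sprintf("  P(profile) = %.4e   RMP: 1 in %.4e\n",
              x$profile_frequency, x$rmp_reciprocal))
  invisible(x)
}

#' Profile frequencies for many individuals
#'
#' Vectorized counterpart of [profile_frequency()]: computes the multilocus
#' profile frequency for every selected individual with a complete profile.
#'
#' @inheritParams profile_frequency
#' @param ids Individuals to score (default: all with complete profiles).
#' @return `data.frame` with `id`, `pop`, `region`, `profile_frequency`,
#'   `log10_pf`.
#' @export
profile_frequencies <- function(x, freqs, theta = 0, f = 0, ids = NULL) {
  idx <- complete_profiles(x)
  if (!is.null(ids)) idx <- idx & x$ids %in% ids
  if (!any(idx)) stop("no complete profiles to score")
  gm <- .profile_locus_matrix(x, idx, freqs, theta, f)
  lg <- rowSums(log10(gm))
  data.frame(id = x$ids[idx], pop = x$pop[idx], region = x$region[idx],
             profile_frequency = 10^lg, log10_pf = lg,
             stringsAsFactors = FALSE, row.names = NULL)
}
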