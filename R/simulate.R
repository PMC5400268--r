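#' Configuration for the hierarchical STR simulator
#'
#' Defaults encode the reference study design: 27 populations in two
#' regions with the [shorea_populations()] sample sizes, the 15-locus panel
#' with the [shorea_loci()] allele counts, region-level coancestry
#' `theta = 0.0333` (Western) / `0.1064` (Eastern), inbreeding
#' `f = 0.0358` / `0.1248`, an extra between-region Dirichlet layer
#' (`theta_between = 0.03`) so the national coancestry exceeds the
#' within-region values, and a 0.2% per-locus missing-call rate.
#'
#' @param metadata Population metadata (`code`, `region`, `n_ind` used).
#' @param loci `data.frame` with `locus` and `n_alleles`.
#' @param theta_region,f_region Named vectors (`Western`, `Eastern`) of the
#'   within-region coancestry and inbreeding parameters, each in `[0, 1)`.
#' @param theta_between Between-region coancestry layer, in `[0, 1)`.
#' @param ancestral_alpha Concentration of the symmetric Dirichlet from
#'   which each locus's national ancestral frequencies are drawn. The
#'   default 0.2 yields the skewed allele-frequency spectra typical of STR
#'   panels (locus expected heterozygosity mostly 0.6-0.9 rather than the
#'   near-uniform spectra a flat Dirichlet would give).
#' @param missing_rate Per-genotype missing probability.
#' @param seed Integer seed (mandatory).
#' @return A list of class `str_sim_config`.
#' @export
str_sim_config <- function(metadata = shorea_populations(),
                           loci = shorea_loci(),
                           theta_region = c(Western = 0.0333,
                                            Eastern = 0.1064),
                           f_region = c(Western = 0.0358, Eastern = 0.1248),
                           theta_between = 0.03, ancestral_alpha = 0.2,
                           missing_rate = 0.002, seed) {
  if (missing(seed)) stop("a seed is mandatory for the simulator")
  stopifnot(all(theta_region >= 0 & theta_region < 1),
            all(f_region >= 0 & f_region < 1),
            theta_between >= 0 && theta_between < 1,
            ancestral_alpha > 0,
            all(metadata$n_ind >= 1), all(loci$n_alleles >= 1))
  structure(list(metadata = metadata, loci = loci,
                 theta_region = theta_region, f_region = f_region,
                 theta_between = theta_between,
                 ancestral_alpha = ancestral_alpha,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "str_sim_config")
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1   # degenerate guard
  g / sum(g)
}

# Balding-Nichols daughter frequencies: Dirichlet(p * (1-theta)/theta);
# theta = 0 copies the parent exactly.
.bn_draw <- function(p, theta) {
  if (theta == 0) return(p)
  .rdirichlet(p * (1 - theta) / theta)
}

#' Simulate an STR genotype dataset under the hierarchical island model
#'
#' Per locus, a national ancestral frequency vector is drawn from a
#' symmetric Dirichlet over the configured allele set; each region's
#' ancestral vector diverges from it by a Balding-Nichols Dirichlet layer
#' with `theta_between`; each population's vector diverges from its
#' region's by the region's `theta`. Genotypes are drawn with
#' identity-by-descent probability `f` (one allele draw copied) and calls
#' are masked at `missing_rate`. This is exactly the model under which the
#' theta/f-corrected match probabilities are derived, so parameter-recovery
#' checks are a fair test of the estimators.
#'
#' @param config An [str_sim_config()].
#' @return List with `table` (an [str_genotypes]) and `truth` (latent
#'   ancestral/regional/population frequency vectors and the config).
#' @export
simulate_str_dataset <- function(config) {
  stopifnot(inherits(config, "str_sim_config"))
  md <- config$metadata
  loci <- config$loci
  .with_seed(config$seed, function() {
    ancestral <- list(); region_freq <- list(); pop_freq <- list()
    regions <- c("Western", "Eastern")
    for (j in seq_len(nrow(loci))) {
      A <- loci$n_alleles[j]
      labels <- as.character(150L + 2L * (0:(A - 1L)))  # even fragment sizes
      anc <- stats::setNames(.rdirichlet(rep(config$ancestral_alpha, A)),
                             labels)
      reg <- lapply(stats::setNames(regions, regions), function(rg)
        stats::setNames(.bn_draw(anc, config$theta_between), labels))
      pf <- vapply(seq_len(nrow(md)), function(i)
        .bn_draw(reg[[md$region[i]]], config$theta_region[[md$region[i]]]),
        numeric(A))
      dimnames(pf) <- list(labels, as.character(md$code))
      ancestral[[loci$locus[j]]] <- anc
      region_freq[[loci$locus[j]]] <- reg
      pop_freq[[loci$locus[j]]] <- pf
    }
    n_tot <- sum(md$n_ind)
    ids <- unlist(lapply(seq_len(nrow(md)), function(i)
      sprintf("P%02d_%03d", md$code[i], seq_len(md$n_ind[i]))))
    pop <- rep(md$code, md$n_ind)
    a1 <- matrix(NA_integer_, n_tot, nrow(loci))
    a2 <- a1
    for (j in seq_len(nrow(loci))) {
      pf <- pop_freq[[loci$locus[j]]]
      labels <- as.integer(rownames(pf))
      row0 <- 0L
      for (i in seq_len(nrow(md))) {
        n <- md$n_ind[i]
        p <- pf[, as.character(md$code[i])]
        f <- config$f_region[[md$region[i]]]
        x1 <- sample(labels, n, replace = TRUE, prob = p)
        x2 <- sample(labels, n, replace = TRUE, prob = p)
        ibd <- stats::runif(n) < f
        x2[ibd] <- x1[ibd]
        a1[row0 + seq_len(n), j] <- x1
        a2[row0 + seq_len(n), j] <- x2
        row0 <- row0 + n
      }
      miss <- stats::runif(n_tot) < config$missing_rate
      a1[miss, j] <- NA_integer_
      a2[miss, j] <- NA_integer_
    }
    list(table = str_genotypes(ids, pop, a1, a2, loci$locus, md),
         truth = list(config = config, ancestral = ancestral,
                      region_freq = region_freq, pop_freq = pop_freq))
  })
}

#' Configuration for the chloroplast haplotype simulator
#'
#' Defaults emulate the reference study's haplotype geography: 214 samples
#' (per-population chloroplast sample sizes from `metadata$n_pop`), 39
#' variable sites (31 substitutions + 8 indel events) spread over the seven
#' intergenic spacers at their published aligned lengths, 29 distinct
#' haplotypes of which one widespread haplotype is confined to Western
#' Malaysia and carried by 57.5% of samples (present in every Western
#' population), two haplotypes are shared between regions (13.1% and 1.4%
#' of samples), and 16 haplotypes occur in single individuals.
#'
#' @param metadata Population metadata (`code`, `region`, `n_pop` used).
#' @param n_substitutions,n_indels Numbers of substitution sites and indel
#'   events (their sum is the total variable-site count).
#' @param n_haplotypes Number of distinct haplotypes.
#' @param widespread_western_fraction Fraction of all samples carrying the
#'   dominant Western-confined haplotype.
#' @param shared_haplotypes Number of haplotypes present in both regions
#'   (0, 1 or 2).
#' @param shared_fractions Sample fractions for the shared haplotypes.
#' @param n_singletons Number of single-individual haplotypes.
#' @param east_singletons How many of the singletons are Eastern.
#' @param east_confined_extra Number of non-singleton Eastern-confined
#'   haplotypes.
#' @param seed Integer seed (mandatory).
#' @return A list of class `cp_sim_config`.
#' @export
cp_sim_config <- function(metadata = shorea_populations(),
                          n_substitutions = 31, n_indels = 8,
                          n_haplotypes = 29,
                          widespread_western_fraction = 0.575,
                          shared_haplotypes = 2,
                          shared_fractions = c(0.131, 0.014),
                          n_singletons = 16, east_singletons = 5,
                          east_confined_extra = 3, seed) {
  if (missing(seed)) stop("a seed is mandatory for the simulator")
  n_sites <- n_substitutions + n_indels
  if (n_haplotypes > 2^n_sites)
    stop("infeasible configuration: more haplotypes than distinct ",
         "state vectors (2^n_sites)")
  structure(list(metadata = metadata, n_substitutions = n_substitutions,
                 n_indels = n_indels, n_haplotypes = n_haplotypes,
                 widespread_western_fraction = widespread_western_fraction,
                 shared_haplotypes = shared_haplotypes,
                 shared_fractions = shared_fractions,
                 n_singletons = n_singletons,
                 east_singletons = east_singletons,
                 east_confined_extra = east_confined_extra,
                 seed = as.integer(seed)),
            class = "cp_sim_config")
}

# split total into k near-equal positive integer parts, decreasing
.partition <- function(total, k) {
  if (k == 0L) return(integer(0))
  if (total < k) stop("infeasible configuration: cannot place ", k,
                      " haplotypes into ", total, " samples")
  base <- total %/% k
  out <- rep(base, k)
  extra <- total - base * k
  if (extra > 0) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  sort(out, decreasing = TRUE)
}

#' Simulate a chloroplast haplotype dataset
#'
#' Builds distinct haplotype state vectors, allocates them to populations
#' respecting region confinement (the dominant haplotype appears in every
#' Western population; singleton haplotypes occupy a single individual),
#' and embeds the states into seven spacer alignments at the configured
#' aligned lengths. Indel events occupy a two-column gap run, so simple
#' indel coding recovers each as one site.
#'
#' @param config A [cp_sim_config()].
#' @return List with `alignments` (list of [cp_alignment]), `sample_pops`
#'   (named population codes), and `truth` (haplotype of every sample, the
#'   haplotype state vectors, target counts and region labels, site table).
#' @export
simulate_cpdna_dataset <- function(config) {
  stopifnot(inherits(config, "cp_sim_config"))
  md <- config$metadata
  H <- config$n_haplotypes
  n_sites <- config$n_substitutions + config$n_indels
  wpops <- md$code[md$region == "Western"]
  epops <- md$code[md$region == "Eastern"]
  capW <- sum(md$n_pop[md$region == "Western"])
  capE <- sum(md$n_pop[md$region == "Eastern"])
  N <- capW + capE

  # ---- target counts per haplotype and region labels -----------------
  if (H == 1L) {
    hap_count <- N; hap_region <- "both"
    counts <- stats::setNames(N, "T01")
    region_of <- stats::setNames("shared", "T01")
    eastern_part <- stats::setNames(capE, "T01")
  } else {
    n_shared <- config$shared_haplotypes
    n_sing <- config$n_singletons
    e_sing <- if (n_sing > 0) min(config$east_singletons, n_sing) else 0L
    w_sing <- n_sing - e_sing
    n_rest <- H - 1L - n_shared - n_sing
    if (n_rest < 0)
      stop("infeasible configuration: fewer haplotypes than shared + ",
           "singleton slots")
    e_rest <- min(config$east_confined_extra, n_rest)
    w_rest <- n_rest - e_rest
    c1 <- round(config$widespread_western_fraction * N)
    if (c1 < length(wpops))
      stop("infeasible configuration: dominant haplotype count below the ",
           "number of Western populations")
    sh_cnt <- if (n_shared > 0)
      pmax(2L, round(config$shared_fractions[seq_len(n_shared)] * N)) else
        integer(0)
    sh_east <- if (n_shared > 0)
      pmax(1L, round(sh_cnt * capE / N)) else integer(0)
    sh_west <- sh_cnt - sh_east
    if (any(sh_west < 1L))
      stop("infeasible configuration: shared haplotype absent from Western")
    e_budget <- capE - sum(sh_east) - e_sing
    w_budget <- capW - c1 - sum(sh_west) - w_sing
    e_cnt <- .partition(e_budget, e_rest)
    w_cnt <- .partition(w_budget, w_rest)
    ids <- sprintf("T%02d", seq_len(H))
    counts <- c(c1, sh_cnt, w_cnt, e_cnt, rep(1L, w_sing), rep(1L, e_sing))
    region_of <- c("W", rep("shared", n_shared), rep("W", w_rest),
                   rep("E", e_rest), rep("W", w_sing), rep("E", e_sing))
    names(counts) <- names(region_of) <- ids
    eastern_part <- stats::setNames(rep(0L, H), ids)
    eastern_part[region_of == "E"] <- counts[region_of == "E"]
    if (n_shared > 0) eastern_part[1L + seq_len(n_shared)] <- sh_east
  }
  if (sum(counts) != N) stop("internal allocation error: counts != N")

  .with_seed(config$seed, function() {
    # ---- distinct state vectors over the sites -----------------------
    kinds <- rep("substitution", n_sites)
    if (config$n_indels > 0)
      kinds[unique(round(seq(2, max(2, n_sites - 1),
                             length.out = config$n_indels)))] <- "indel"
    if (sum(kinds == "indel") != config$n_indels)
      kinds <- rep(c("indel", "substitution"),
                   c(config$n_indels, config$n_substitutions))
    for (try in 1:100) {
      hmat <- matrix("0", H, n_sites)
      if (H > 1L) {
        for (s in seq_len(n_sites)) {
          ncarry <- sample(seq_len(H - 1L), 1L)
          hmat[sample.int(H, ncarry), s] <- "1"
        }
      }
      if (!anyDuplicated(apply(hmat, 1L, paste, collapse = ""))) break
      if (try == 100) stop("failed to draw distinct haplotype vectors")
    }

    # ---- allocate haplotypes to populations --------------------------
    hap_ids <- names(counts)
    slot_hap <- character(0); slot_pop <- integer(0)
    for (rg in c("W", "E")) {
      pops <- if (rg == "W") wpops else epops
      cap <- stats::setNames(md$n_pop[match(pops, md$code)],
                             as.character(pops))
      copies <- character(0)
      for (h in hap_ids) {
        nh <- if (region_of[[h]] == "shared") {
          if (rg == "E") eastern_part[[h]] else counts[[h]] - eastern_part[[h]]
        } else if ((region_of[[h]] == "W") == (rg == "W")) counts[[h]] else 0L
        if (h == hap_ids[1L] && rg == "W" && region_of[[h]] == "W") {
          # dominant haplotype: one copy in every Western population first
          for (p in names(cap)) {
            slot_hap <- c(slot_hap, h); slot_pop <- c(slot_pop, as.integer(p))
            cap[p] <- cap[p] - 1L
          }
          nh <- nh - length(cap)
        }
        copies <- c(copies, rep(h, nh))
      }
      if (length(copies) != sum(cap))
        stop("internal allocation error in region ", rg)
      # contiguous fill: keeps each haplotype's copies geographically
      # clustered and every singleton in a single population
      pop_slots <- rep(as.integer(names(cap)), cap)
      slot_hap <- c(slot_hap, copies)
      slot_pop <- c(slot_pop, pop_slots)
    }

    sample_ids <- unlist(lapply(sort(unique(slot_pop)), function(p)
      sprintf("C%02d_%02d", p, seq_len(sum(slot_pop == p)))))
    o <- order(slot_pop)
    sample_pops <- stats::setNames(slot_pop[o], sample_ids)
    sample_haps <- stats::setNames(slot_hap[o], sample_ids)

    # ---- embed into spacer alignments --------------------------------
    sp <- .cp_spacers()
    site_per_spacer <- .spread_counts(n_sites, sp$n_sites)
    site_spacer <- rep(sp$spacer, site_per_spacer)
    alignments <- list()
    site_cols <- integer(n_sites)
    s0 <- 0L
    hap_row <- match(sample_haps, hap_ids)
    for (q in seq_len(nrow(sp))) {
      k <- site_per_spacer[q]
      L <- sp$length[q]
      backbone <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      seqs <- matrix(rep(backbone, each = length(sample_ids)),
                     nrow = length(sample_ids),
                     dimnames = list(sample_ids, NULL))
      if (k > 0) {
        pos <- round(seq(10, L - 10, length.out = k))
        for (t in seq_len(k)) {
          s <- s0 + t
          site_cols[s] <- pos[t]
          derived <- hmat[hap_row, s] == "1"
          if (kinds[s] == "indel") {
            seqs[derived, pos[t]:(pos[t] + 1L)] <- "-"
          } else {
            alt <- setdiff(c("A", "C", "G", "T"), backbone[pos[t]])[1L]
            seqs[derived, pos[t]] <- alt
          }
        }
      }
      alignments[[sp$spacer[q]]] <- cp_alignment(sp$spacer[q], seqs)
      s0 <- s0 + k
    }
    truth <- list(config = config,
                  sample_haplotypes = sample_haps,
                  hap_states = hmat, hap_counts = counts,
                  hap_region = region_of,
                  sites = data.frame(region_name = site_spacer,
                                     column = site_cols, kind = kinds,
                                     stringsAsFactors = FALSE))
    list(alignments = alignments, sample_pops = sample_pops, truth = truth)
  })
}

# proportionally rescale default per-spacer site counts to a new total
.spread_counts <- function(total, template) {
  if (total == sum(template)) return(template)
  raw <- template / sum(template) * total
  out <- floor(raw)
  rem <- total - sum(out)
  if (rem > 0) {
    o <- order(raw - out, decreasing = TRUE)
    out[o[seq_len(rem)]] <- out[o[seq_len(rem)]] + 1L
  }
  as.integer(out)
}

#' Worked-example fixture: a 40-sample planted stand
#'
#' Emits the demonstration query set used throughout the documentation: 40
#' haplotype calls (27 carrying the dominant Western-confined haplotype H1,
#' 4 the shared H2, 2 the Western-confined H3, 1 the Western-confined H5,
#' and 6 previously unseen haplotypes), plus, optionally, simulated STR
#' query profiles drawn from four northwestern Western populations
#' (Temenggor, Bintang Hijau, Bukit Larut, Bukit Kinta) for the assignment
#' demonstration.
#'
#' @param with_queries Also simulate STR query profiles (default `TRUE`).
#' @param str_truth Optionally, the `truth` component of an existing
#'   [simulate_str_dataset()] run to draw query genotypes from; when `NULL`
#'   a default simulation is generated.
#' @param n_queries Number of STR query individuals.
#' @param seed Integer seed (required when `with_queries = TRUE`).
#' @return List with `calls` (`data.frame`: sample, haplotype,
#'   inferred_region), `queries` (an [str_genotypes] with `NA` population
#'   codes, or `NULL`), `source_pops`.
#' @export
frim_fixture <- function(with_queries = TRUE, str_truth = NULL,
                         n_queries = 40, seed = NULL) {
  hap <- c(rep("H1", 27), rep("H2", 4), rep("H3", 2), "H5",
           rep("NOVEL", 6))
  region_of <- c(H1 = "Western", H2 = "ambiguous", H3 = "Western",
                 H5 = "Western")
  calls <- data.frame(
    sample = sprintf("FRIM%02d", seq_along(hap)),
    haplotype = hap,
    inferred_region = ifelse(hap == "NOVEL", "none", region_of[hap]),
    stringsAsFactors = FALSE)
  queries <- NULL
  source_pops <- c(10L, 12L, 13L, 15L)
  if (with_queries) {
    if (is.null(seed) && is.null(str_truth))
      stop("a seed is required to simulate STR queries")
    if (is.null(str_truth))
      str_truth <- simulate_str_dataset(str_sim_config(seed = seed))$truth
    md <- str_truth$config$metadata
    loci <- str_truth$config$loci
    queries <- .with_seed(if (is.null(seed)) 1L else seed + 1L, function() {
      pops <- rep_len(source_pops, n_queries)
      a1 <- matrix(NA_integer_, n_queries, nrow(loci))
      a2 <- a1
      for (j in seq_len(nrow(loci))) {
        pf <- str_truth$pop_freq[[loci$locus[j]]]
        labels <- as.integer(rownames(pf))
        for (i in seq_len(n_queries)) {
          p <- pf[, as.character(pops[i])]
          f <- str_truth$config$f_region[[
            md$region[match(pops[i], md$code)]]]
          x1 <- sample(labels, 1L, prob = p)
          x2 <- if (stats::runif(1) < f) x1 else sample(labels, 1L, prob = p)
          a1[i, j] <- x1; a2[i, j] <- x2
        }
      }
      str_genotypes(sprintf("FRIM%02d", seq_len(n_queries)),
                    rep(NA_integer_, n_queries), a1, a2, loci$locus, md)
    })
  }
  list(calls = calls, queries = queries, source_pops = source_pops)
}
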