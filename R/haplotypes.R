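#' Extract variable sites from a set of chloroplast alignments
#'
#' Scans one alignment per intergenic spacer (all sharing the same sample
#' IDs) and builds the variable-site matrix that defines haplotypes:
#' nucleotide substitution sites plus indel events under simple indel
#' coding, where a maximal run of consecutive gap-containing columns is one
#' binary presence/absence character regardless of its length. Columns
#' belonging to a gap run are scored only for the indel event. Ambiguous
#' bases (`N`) give an unknown (`NA`) state for that sample at that site.
#'
#' @param alignments A list of [cp_alignment] objects, in spacer order.
#' @return An object of class `variable_sites`: list with
#'   \describe{
#'     \item{sites}{`data.frame` with `region_name`, `column` (first column
#'       of the site in its spacer), `kind` (`substitution`/`indel`).}
#'     \item{states}{character matrix, samples x sites; indel states are
#'       `"1"` (bases present) / `"0"` (deleted).}
#'   }
#' @export
extract_variable_sites <- function(alignments) {
  if (inherits(alignments, "cp_alignment")) alignments <- list(alignments)
  ids <- rownames(alignments[[1L]]$seqs)
  for (al in alignments)
    if (!identical(sort(rownames(al$seqs)), sort(ids)))
      stop("sample-set mismatch between spacer alignments (",
           al$region_name, ")")
  site_tab <- list(); state_cols <- list()
  for (al in alignments) {
    seqs <- al$seqs[ids, , drop = FALSE]
    gapcol <- apply(seqs == "-", 2L, any)
    # indel events: maximal runs of gap-containing columns
    if (any(gapcol)) {
      runs <- rle(gapcol)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (k in which(runs$values)) {
        cols <- starts[k]:ends[k]
        sub <- seqs[, cols, drop = FALSE]
        st <- ifelse(rowSums(sub == "-") > 0L, "0", "1")
        st[rowSums(sub == "N") > 0L & st == "1"] <- NA_character_
        if (length(unique(stats::na.omit(st))) >= 2L) {
          site_tab[[length(site_tab) + 1L]] <-
            data.frame(region_name = al$region_name, column = cols[1L],
                       kind = "indel", stringsAsFactors = FALSE)
          state_cols[[length(state_cols) + 1L]] <- st
        }
      }
    }
    # substitution sites: gap-free polymorphic columns
    for (j in which(!gapcol)) {
      st <- seqs[, j]
      st[st == "N"] <- NA_character_
      if (length(unique(stats::na.omit(st))) >= 2L) {
        site_tab[[length(site_tab) + 1L]] <-
          data.frame(region_name = al$region_name, column = j,
                     kind = "substitution", stringsAsFactors = FALSE)
        state_cols[[length(state_cols) + 1L]] <- st
      }
    }
  }
  sites <- if (length(site_tab)) do.call(rbind, site_tab) else
    data.frame(region_name = character(), column = integer(),
               kind = character(), stringsAsFactors = FALSE)
  # order: spacer order as supplied, then column
  spacer_rank <- match(sites$region_name,
                       vapply(alignments, `[[`, "", "region_name"))
  o <- order(spacer_rank, sites$column)
  states <- if (length(state_cols))
    do.call(cbind, state_cols)[, o, drop = FALSE] else
      matrix(character(), nrow = length(ids), ncol = 0L,
             dimnames = list(ids, NULL))
  rownames(states) <- ids
  structure(list(sites = sites[o, , drop = FALSE], states = states),
            class = "variable_sites")
}

#' @export
print.variable_sites <- function(x, ...) {
  cat("variable-site matrix:", nrow(x$states), "samples x",
      nrow(x$sites), "sites (",
      sum(x$sites$kind == "substitution"), "substitutions,",
      sum(x$sites$kind == "indel"), "indels )\n")
  invisible(x)
}

.hap_key <- function(states) {
  if (ncol(states) == 0L) return(rep("", nrow(states)))
  s <- states; s[is.na(s)] <- "?"
  apply(s, 1L, paste, collapse = "")
}

#' Collapse the variable-site matrix into a haplotype database
#'
#' Samples with identical state vectors share a haplotype. Haplotypes are
#' numbered `H1, H2, ...` by descending total count (ties broken by first
#' sample occurrence; numbering is presentation-only). Per-population
#' occurrence, region status (confined to one region vs shared) and the
#' unique flag (found in a single population) are recorded.
#'
#' @param vs A `variable_sites` object from [extract_variable_sites()].
#' @param sample_pops Integer vector (named by sample ID, or in row order of
#'   `vs$states`) of population codes.
#' @param metadata Population metadata (see [str_genotypes()]).
#' @param max_unknown Maximum tolerated fraction of unknown states per
#'   sample (default 0.5); samples above it are rejected.
#' @return An object of class `haplotype_db`: list with `haplotypes` (ID ->
#'   state-vector key), `states` (matrix haplotype x site), `counts`,
#'   `occurrence` (matrix haplotype x population), `region_status`
#'   (`confined:Western` / `confined:Eastern` / `shared`), `unique_flag`,
#'   `sites`, `metadata`.
#' @export
collapse_haplotypes <- function(vs, sample_pops, metadata = shorea_populations(),
                                max_unknown = 0.5) {
  states <- vs$states
  if (nrow(states) == 0L) stop("empty variable-site matrix: no samples")
  if (!is.null(names(sample_pops)))
    sample_pops <- sample_pops[rownames(states)]
  sample_pops <- as.integer(sample_pops)
  if (length(sample_pops) != nrow(states))
    stop("'sample_pops' must give one population code per sample")
  if (ncol(states) > 0L) {
    unk <- rowMeans(is.na(states))
    if (any(unk > max_unknown))
      stop("sample(s) with unknown state at >", 100 * max_unknown,
           "% of sites: ",
           paste(rownames(states)[unk > max_unknown], collapse = ", "))
  }
  key <- .hap_key(states)
  first <- !duplicated(key)
  ukey <- key[first]
  counts <- as.vector(table(key)[ukey])
  o <- order(-counts, which(first))
  ukey <- ukey[o]; counts <- counts[o]
  ids <- paste0("H", seq_along(ukey))
  hap_of_sample <- ids[match(key, ukey)]
  pops <- sort(unique(sample_pops))
  occurrence <- table(factor(hap_of_sample, levels = ids),
                      factor(sample_pops, levels = pops))
  occurrence <- matrix(as.integer(occurrence), nrow = length(ids),
                       dimnames = list(ids, as.character(pops)))
  pop_region <- metadata$region[match(pops, metadata$code)]
  region_status <- apply(occurrence, 1L, function(cnt) {
    regs <- unique(pop_region[cnt > 0L])
    if (length(regs) == 1L) paste0("confined:", regs) else "shared"
  })
  unique_flag <- rowSums(occurrence > 0L) == 1L
  hap_states <- states[match(ukey, key), , drop = FALSE]
  rownames(hap_states) <- ids
  structure(list(haplotypes = stats::setNames(ukey, ids),
                 states = hap_states, counts = stats::setNames(counts, ids),
                 occurrence = occurrence,
                 region_status = stats::setNames(region_status, ids),
                 unique_flag = stats::setNames(unique_flag, ids),
                 sites = vs$sites, metadata = metadata,
                 sample_haplotypes = stats::setNames(hap_of_sample,
                                                     rownames(states))),
            class = "haplotype_db")
}

#' @export
print.haplotype_db <- function(x, ...) {
  cat("haplotype database:", length(x$haplotypes), "haplotypes over",
      nrow(x$sites), "variable sites;", sum(x$counts), "samples\n")
  st <- table(x$region_status)
  cat("  region status:", paste(names(st), st, sep = "=", collapse = ", "),
      "\n  unique (single-population) haplotypes:", sum(x$unique_flag), "\n")
  invisible(x)
}

#' Classify a query state vector against the haplotype database
#'
#' Exact-match lookup of a chloroplast state vector. A matched haplotype
#' inherits its region status: a confined haplotype infers that region, a
#' shared haplotype is `ambiguous`, and an unmatched vector is `NOVEL` with
#' region `none`. Up to `max_unknown` unknown (`NA`) states are tolerated if
#' exactly one database haplotype completes them (forensic default: 0).
#'
#' @param db A `haplotype_db`.
#' @param states A character vector (one sample) or matrix (samples x sites)
#'   of site states.
#' @param max_unknown Maximum number of unknown states allowed for
#'   unique-completion matching.
#' @return A `data.frame` with `sample`, `haplotype` (ID or `"NOVEL"`),
#'   `inferred_region` (`Western`/`Eastern`/`ambiguous`/`none`), and
#'   `candidate_populations` (comma-separated codes where the haplotype was
#'   observed; never a point assignment).
#' @export
classify_haplotype <- function(db, states, max_unknown = 0) {
  if (is.null(dim(states)))
    states <- matrix(states, nrow = 1L,
                     dimnames = list("query", NULL))
  if (ncol(states) != nrow(db$sites))
    stop("state vector has ", ncol(states), " sites; database has ",
         nrow(db$sites))
  res <- lapply(seq_len(nrow(states)), function(i) {
    st <- states[i, ]
    nunk <- sum(is.na(st))
    hap <- "NOVEL"
    if (nunk == 0L) {
      m <- match(paste(st, collapse = ""), db$haplotypes)
      if (!is.na(m)) hap <- names(db$haplotypes)[m]
    } else if (nunk <= max_unknown) {
      ok <- which(apply(db$states, 1L, function(h)
        all(h[!is.na(st)] == st[!is.na(st)])))
      if (length(ok) == 1L) hap <- rownames(db$states)[ok]
    }
    if (hap == "NOVEL") {
      region <- "none"; cand <- ""
    } else {
      status <- db$region_status[[hap]]
      region <- if (status == "shared") "ambiguous" else
        sub("confined:", "", status, fixed = TRUE)
      cand <- paste(colnames(db$occurrence)[db$occurrence[hap, ] > 0L],
                    collapse = ",")
    }
    data.frame(sample = rownames(states)[i], haplotype = hap,
               inferred_region = region, candidate_populations = cand,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Summarize regional attribution of a set of haplotype calls
#'
#' The percentage of query samples attributable to each region by the
#' region-confinement rule: a sample counts toward a region only when its
#' haplotype is confined to that region. Shared-haplotype (`ambiguous`) and
#' `NOVEL` (`none`) calls are unattributed.
#'
#' @param calls A `data.frame` of calls with column `inferred_region`
#'   (as from [classify_haplotype()]).
#' @return Named numeric vector of percentages: `Western`, `Eastern`,
#'   `unattributed`; sums to 100.
#' @export
summarize_region_origin <- function(calls) {
  if (NROW(calls) == 0L) stop("no haplotype calls supplied")
  r <- calls$inferred_region
  n <- length(r)
  c(Western = 100 * sum(r == "Western") / n,
    Eastern = 100 * sum(r == "Eastern") / n,
    unattributed = 100 * sum(r %in% c("ambiguous", "none")) / n)
}
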