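#' Construct a diploid STR genotype table
#'
#' The central container for the individual-identification tier: one row per
#' individual, two integer allele calls per locus (unordered; stored sorted
#' so that `a1 <= a2`), a population code per individual and the population
#' metadata giving the population-to-region mapping.
#'
#' @param ids Character vector of unique individual identifiers.
#' @param pop Integer vector of population codes, one per individual. `NA`
#'   is allowed for query individuals of unknown origin.
#' @param a1,a2 Integer matrices (individuals x loci) of allele calls
#'   (fragment sizes in base pairs); `NA` marks a missing call. If one
#'   allele of a pair is missing the whole genotype is treated as missing.
#' @param loci Character vector of locus names (columns of `a1`/`a2`).
#' @param metadata Population metadata as returned by
#'   [shorea_populations()] or [read_population_table()]; must contain
#'   columns `code` and `region` covering every non-`NA` population code.
#' @return An object of class `str_genotypes`: a list with elements `ids`,
#'   `pop`, `region`, `loci`, `a1`, `a2`, `metadata`.
#' @examples
#' md <- shorea_populations()
#' g <- str_genotypes(ids = c("a", "b"), pop = c(1L, 25L),
#'                    a1 = matrix(c(100L, 102L), 2, 1),
#'                    a2 = matrix(c(104L, 102L), 2, 1),
#'                    loci = "Spl003", metadata = md)
#' g$region
#' @export
str_genotypes <- function(ids, pop, a1, a2, loci, metadata) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate individual IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(ids)
  if (nrow(a1) != n || nrow(a2) != n || ncol(a1) != length(loci) ||
      ncol(a2) != length(loci))
    stop("allele matrices must be individuals x loci")
  if (any(!is.na(a1) & a1 <= 0L) || any(!is.na(a2) & a2 <= 0L))
    stop("allele labels must be positive integers")
  # a missing half-call voids the genotype
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) { a1[half] <- NA_integer_; a2[half] <- NA_integer_ }
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) { tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp }
  pop <- as.integer(pop)
  if (length(pop) != n) stop("'pop' must have one code per individual")
  known <- !is.na(pop)
  if (any(known) && !all(pop[known] %in% metadata$code))
    stop("unknown population codes: ",
         paste(sort(unique(pop[known][!pop[known] %in% metadata$code])),
               collapse = ", "))
  region <- metadata$region[match(pop, metadata$code)]
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(ids = ids, pop = pop, region = region,
                 loci = as.character(loci), a1 = a1, a2 = a2,
                 metadata = metadata),
            class = "str_genotypes")
}

#' @export
print.str_genotypes <- function(x, ...) {
  cat("STR genotype table:", length(x$ids), "individuals x",
      length(x$loci), "loci\n")
  tab <- table(x$region, useNA = "ifany")
  cat("  populations:", length(unique(x$pop[!is.na(x$pop)])),
      " regions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.str_genotypes <- function(object, ...) {
  data.frame(
    locus = object$loci,
    n = colSums(!is.na(object$a1)),
    n_alleles = vapply(seq_along(object$loci), function(j)
      length(unique(c(object$a1[, j], object$a2[, j])) |> stats::na.omit()),
      integer(1)),
    row.names = NULL
  )
}

# Logical index of individuals belonging to a pool selector:
# "Malaysia" (all), a region name, or a vector of population codes.
.pool_index <- function(x, pool) {
  if (is.character(pool) && length(pool) == 1L) {
    if (pool == "Malaysia") return(rep(TRUE, length(x$ids)))
    if (pool %in% c("Western", "Eastern"))
      return(!is.na(x$region) & x$region == pool)
  }
  codes <- suppressWarnings(as.integer(pool))
  if (any(is.na(codes))) stop("unknown pool selector: ", paste(pool, collapse = ","))
  !is.na(x$pop) & x$pop %in% codes
}

.subset_genotypes <- function(x, keep) {
  str_genotypes(x$ids[keep], x$pop[keep],
                x$a1[keep, , drop = FALSE], x$a2[keep, , drop = FALSE],
                x$loci, x$metadata)
}

#' Individuals with a complete multilocus profile
#'
#' @param x An [str_genotypes] table.
#' @return Logical vector: `TRUE` where no locus has a missing call.
#' @export
complete_profiles <- function(x) {
  rowSums(is.na(x$a1)) == 0L
}

#' Read a delimited STR genotype table
#'
#' Reads a GenAlEx-like delimited text layout: a header line
#' `ID<sep>Pop<sep>` followed by each locus name repeated twice (one column
#' per allele), then one line per individual. Allele calls are integer
#' fragment sizes; the missing-data code (default `"0"`) becomes `NA`.
#'
#' @param path Path to the file.
#' @param metadata Population metadata (see [str_genotypes()]).
#' @param missing_code Character allele code denoting a missing call.
#' @param sep Field separator.
#' @return An [str_genotypes] table.
#' @seealso [write_genotype_table()] for the paired writer; a
#'   write-then-read round trip is lossless.
#' @export
read_genotype_table <- function(path, metadata = shorea_populations(),
                                missing_code = "0", sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("genotype table needs a header and >=1 row")
  fields <- strsplit(lines, sep, fixed = TRUE)
  hdr <- fields[[1L]]
  if (length(hdr) < 4L || hdr[1L] != "ID" || hdr[2L] != "Pop")
    stop("header must start with 'ID", sep, "Pop' followed by locus column pairs")
  locus_cols <- hdr[-(1:2)]
  if (length(locus_cols) %% 2L != 0L)
    stop("locus '", locus_cols[length(locus_cols)],
         "' has a single allele column; two are required per locus")
  first <- locus_cols[seq(1L, length(locus_cols), by = 2L)]
  second <- locus_cols[seq(2L, length(locus_cols), by = 2L)]
  if (any(first != second))
    stop("locus '", first[which(first != second)[1L]],
         "' has a single allele column; two are required per locus")
  loci <- first
  ncol_expect <- length(hdr)
  body <- fields[-1L]
  nf <- lengths(body)
  if (any(nf != ncol_expect))
    stop("line ", which(nf != ncol_expect)[1L] + 1L, ": expected ",
         ncol_expect, " fields, found ", nf[nf != ncol_expect][1L])
  m <- do.call(rbind, body)
  ids <- m[, 1L]
  pop <- suppressWarnings(as.integer(m[, 2L]))
  if (any(is.na(pop)))
    stop("line ", which(is.na(pop))[1L] + 1L, ": non-integer population code")
  al <- m[, -(1:2), drop = FALSE]
  al[al == missing_code] <- NA_character_
  alv <- suppressWarnings(as.integer(al))
  bad <- is.na(alv) & !is.na(al)
  if (any(bad))
    stop("line ", (which(bad) - 1L) %% nrow(al) + 2L,
         ": non-numeric allele label '", al[bad][1L], "'")
  alm <- matrix(alv, nrow = nrow(al))
  a1 <- alm[, seq(1L, ncol(alm), by = 2L), drop = FALSE]
  a2 <- alm[, seq(2L, ncol(alm), by = 2L), drop = FALSE]
  x <- str_genotypes(ids, pop, a1, a2, loci, metadata)
  message(sprintf("read %d individuals x %d loci from %s",
                  length(x$ids), length(x$loci), path))
  x
}

#' Write an STR genotype table
#'
#' Writes the delimited layout read by [read_genotype_table()]. Output is
#' deterministic; writing the same table twice yields byte-identical files.
#'
#' @param x An [str_genotypes] table.
#' @param path Output path.
#' @inheritParams read_genotype_table
#' @export
write_genotype_table <- function(x, path, missing_code = "0", sep = "\t") {
  L <- length(x$loci)
  hdr <- c("ID", "Pop", rep(x$loci, each = 2L))
  al <- matrix(NA_integer_, length(x$ids), 2L * L)
  al[, seq(1L, 2L * L, by = 2L)] <- x$a1
  al[, seq(2L, 2L * L, by = 2L)] <- x$a2
  alc <- matrix(as.character(al), nrow = nrow(al))
  alc[is.na(alc)] <- missing_code
  rows <- apply(cbind(x$ids, as.character(x$pop), alc), 1L, paste,
                collapse = sep)
  writeLines(c(paste(hdr, collapse = sep), rows), path)
  invisible(path)
}

#' Read a population metadata table
#'
#' Tab-delimited with header; requires columns `code`, `name`, `region`
#' (values `Western`/`Eastern`); `latitude`/`longitude` optional and, when
#' present, checked against Malaysia's bounding box.
#'
#' @param path Path to the file.
#' @return A `data.frame` usable as `metadata` in [str_genotypes()].
#' @export
read_population_table <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("code", "name", "region")
  if (!all(need %in% names(md)))
    stop("population table must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(md$code)) stop("duplicate population codes")
  if (!all(md$region %in% c("Western", "Eastern")))
    stop("region must be 'Western' or 'Eastern'")
  if (all(c("latitude", "longitude") %in% names(md))) {
    off <- md$latitude < 0.5 | md$latitude > 7.5 |
      md$longitude < 99 | md$longitude > 120
    if (any(off, na.rm = TRUE))
      warning("coordinates outside Malaysia's bounding box for population(s): ",
              paste(md$code[which(off)], collapse = ", "))
  }
  md$code <- as.integer(md$code)
  md
}
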