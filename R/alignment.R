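#' Read an aligned chloroplast spacer from FASTA
#'
#' Reads one intergenic-spacer alignment (gap character `-`, ambiguity `N`
#' allowed) and validates that all records have equal length and unique IDs.
#'
#' @param path Path to a FASTA file.
#' @param region_name Name of the intergenic spacer the alignment covers
#'   (defaults to the file name without extension).
#' @return An object of class `cp_alignment`: list with `region_name`,
#'   `seqs` (character matrix, records x columns, uppercase), `length`.
#' @export
read_alignment <- function(path, region_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no FASTA records in ", path)
  if (is.null(region_name))
    region_name <- sub("\\.[^.]*$", "", basename(path))
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop("unequal sequence lengths in ", path, "; offending IDs: ",
         paste(names(dna)[lens != lens[1L]], collapse = ", "))
  if (anyDuplicated(names(dna)))
    stop("duplicate record IDs in ", path)
  seqs <- toupper(do.call(rbind, as.character(dna)))
  rownames(seqs) <- names(dna)
  cp_alignment(region_name, seqs)
}

#' Construct a chloroplast alignment object
#'
#' @param region_name Spacer name.
#' @param seqs Character matrix (records x columns) over `A,C,G,T,-,N`.
#' @return A `cp_alignment` object.
#' @export
cp_alignment <- function(region_name, seqs) {
  seqs <- as.matrix(seqs)
  if (is.null(rownames(seqs))) stop("sequence records must be named")
  bad <- !(seqs %in% c("A", "C", "G", "T", "-", "N"))
  if (any(bad))
    stop("invalid characters in alignment: ",
         paste(unique(seqs[bad]), collapse = ", "))
  structure(list(region_name = region_name, seqs = seqs,
                 length = ncol(seqs)),
            class = "cp_alignment")
}

#' @export
print.cp_alignment <- function(x, ...) {
  cat("chloroplast alignment", x$region_name, ":", nrow(x$seqs),
      "records x", x$length, "bp\n")
  invisible(x)
}

#' Write a chloroplast alignment to FASTA
#'
#' @param x A `cp_alignment`.
#' @param path Output path.
#' @export
write_alignment <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x$seqs)))
    writeLines(c(paste0(">", rownames(x$seqs)[i]),
                 paste(x$seqs[i, ], collapse = "")), con)
  invisible(path)
}

#' Write a stage result as TSV or JSON
#'
#' Serializes a result (a `data.frame` or any list of scalars/vectors) with
#' deterministic field order and fixed numeric precision, so repeated writes
#' of the same object are byte-identical.
#'
#' @param result A `data.frame` (TSV or JSON) or list (JSON).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param digits Significant digits for numeric fields (default 6).
#' @export
write_report <- function(result, path, format = c("tsv", "json"),
                         digits = 6) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(result))
      result <- as.data.frame(result, stringsAsFactors = FALSE)
    num <- vapply(result, is.numeric, logical(1))
    result[num] <- lapply(result[num], signif, digits = digits)
    utils::write.table(result, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(.signif_rec(unclass(result), digits), path,
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

.signif_rec <- function(x, digits) {
  if (is.list(x)) lapply(x, .signif_rec, digits = digits)
  else if (is.numeric(x)) signif(x, digits)
  else x
}
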