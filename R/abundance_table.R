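#' Construct an abundance table
#'
#' An abundance table is a non-negative numeric matrix of microbial features
#' (species relative abundances, gene RPKM, or raw counts) in rows and samples
#' in columns, the layout conventional in shotgun-metagenomics profiling.
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#'   Row names are feature identifiers, column names are sample identifiers;
#'   both must be present and unique.
#' @param kind One of `"relative_abundance"`, `"rpkm"`, `"counts"`.
#' @return An object of class `abundance_table`: a list with elements
#'   `values` (the matrix), `kind`, and accessor-friendly `feature_ids` /
#'   `sample_ids`.
#' @examples
#' m <- matrix(c(2, 1, 0, 1, 1, 2), nrow = 3,
#'             dimnames = list(paste0("sp", 1:3), c("A", "B")))
#' abundance_table(m, "counts")
#' @export
abundance_table <- function(values,
                            kind = c("relative_abundance", "rpkm", "counts")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (features x samples)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry feature row names and sample column names",
         call. = FALSE)
  }
  tab <- structure(
    list(values = values, kind = kind,
         feature_ids = rownames(values), sample_ids = colnames(values)),
    class = "abundance_table"
  )
  validate_abundance_table(tab)
  tab
}

validate_abundance_table <- function(tab) {
  v <- tab$values
  dup_f <- unique(rownames(v)[duplicated(rownames(v))])
  dup_s <- unique(colnames(v)[duplicated(colnames(v))])
  if (length(dup_f)) {
    stop("duplicate feature identifiers: ", paste(dup_f, collapse = ", "),
         call. = FALSE)
  }
  if (length(dup_s)) {
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(v)) {
    bad <- which(is.na(v), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing value at feature '%s', sample '%s'",
                 rownames(v)[bad[1]], colnames(v)[bad[2]]), call. = FALSE)
  }
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at feature '%s', sample '%s'",
                 rownames(v)[bad[1]], colnames(v)[bad[2]]), call. = FALSE)
  }
  invisible(tab)
}

#' @exportS3Method base::print
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d features x %d samples, kind = %s\n",
              nrow(x$values), ncol(x$values), x$kind))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Read an abundance table from TSV
#'
#' The expected layout is the microbiome convention: a header row of sample
#' identifiers whose first cell is `feature_id`, one row per feature, numeric
#' body. Input order of features and samples is preserved.
#'
#' @param path Path to a tab-separated file.
#' @param kind Abundance kind; see [abundance_table()].
#' @return An `abundance_table`.
#' @export
read_abundance_table <- function(path,
                                 kind = c("relative_abundance", "rpkm",
                                          "counts")) {
  kind <- match.arg(kind)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) {
    stop("abundance TSV needs a feature_id column plus at least one sample",
         call. = FALSE)
  }
  feature_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num) && !anyNA(body)) {
    bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s' in %s",
                 body[bad[1], bad[2]], feature_ids[bad[1]],
                 sample_ids[bad[2]], path), call. = FALSE)
  }
  dimnames(num) <- list(feature_ids, sample_ids)
  abundance_table(num, kind)
}

#' Write an abundance table to TSV
#'
#' Values are written with full double precision so that a write/read
#' round-trip reproduces the matrix within 1e-12.
#'
#' @param tab An `abundance_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(tab, path) {
  stopifnot(inherits(tab, "abundance_table"))
  v <- tab$values
  lines <- c(
    paste(c("feature_id", colnames(v)), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(i) {
      paste(c(rownames(v)[i], format_repr(v[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Convert an abundance table to relative abundances
#'
#' Divides each sample column by its sum (compositional closure). Applying it
#' to an already-relative table is a no-op up to floating point.
#'
#' @param tab An `abundance_table`.
#' @return An `abundance_table` with `kind = "relative_abundance"` whose
#'   columns each sum to 1.
#' @export
to_relative <- function(tab) {
  stopifnot(inherits(tab, "abundance_table"))
  cs <- colSums(tab$values)
  zero <- which(cs <= 0)
  if (length(zero)) {
    stop("sample(s) with no positive abundance: ",
         paste(colnames(tab$values)[zero], collapse = ", "), call. = FALSE)
  }
  abundance_table(sweep(tab$values, 2, cs, "/"), "relative_abundance")
}
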