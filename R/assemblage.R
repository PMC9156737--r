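#' Assemblage tables
#'
#' An `assemblage` is the compositional core of both calibration and fossil
#' pollen data: a samples x taxa abundance matrix, optionally carrying sample
#' ages (calendar years BP, larger = older), together with a tag recording
#' what the values are: raw `"counts"`, row-normalised `"proportions"` (on
#' \[0, 1\], not percentages) or `"sqrt_proportions"` (the square-root
#' transformed proportions that the transfer function is fitted on).
#'
#' Invariants enforced by the constructor: all values finite and
#' non-negative; taxon names unique and non-empty; sample ids unique; rows of
#' a proportion table sum to 1 within 1e-9; ages, when present, finite, and
#' the table is stored sorted by increasing age.
#'
#' @param values numeric matrix, samples in rows, taxa in columns. Row and
#'   column names supply sample ids and taxon names unless given explicitly.
#' @param sample_id character vector of unique sample labels.
#' @param ages optional numeric vector of ages in calendar years BP.
#' @param kind one of `"counts"`, `"proportions"`, `"sqrt_proportions"`.
#' @return An object of class `assemblage`: a list with elements `values`
#'   (named matrix), `ages` (numeric or `NULL`) and `kind`.
#' @examples
#' m <- matrix(c(5, 7, 2, 1, 0, 3), nrow = 3,
#'             dimnames = list(c("s1", "s2", "s3"), c("Pinus", "Quercus")))
#' a <- assemblage(m)
#' to_proportions(a)
#' @export
assemblage <- function(values, sample_id = rownames(values), ages = NULL,
                       kind = c("counts", "proportions", "sqrt_proportions")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_id))
    sample_id <- paste0("sample", seq_len(nrow(values)))
  sample_id <- as.character(sample_id)
  taxa <- colnames(values)
  if (is.null(taxa) || anyNA(taxa) || any(!nzchar(taxa)))
    stop("all taxa must be named")
  if (anyDuplicated(taxa))
    stop("duplicate taxon name(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (length(sample_id) != nrow(values))
    stop("sample_id length does not match the number of rows")
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("invalid abundance at sample '%s', taxon '%s'",
                 sample_id[bad[1L, 1L]], taxa[bad[1L, 2L]]))
  rownames(values) <- sample_id
  if (!is.null(ages)) {
    ages <- as.numeric(ages)
    if (length(ages) != nrow(values) || anyNA(ages) || any(!is.finite(ages)))
      stop("ages must be finite and one per sample")
    ord <- order(ages)
    values <- values[ord, , drop = FALSE]
    ages <- ages[ord]
    if (any(diff(ages) <= 0))
      stop("ages must be strictly increasing after sorting (duplicated age?)")
  }
  if (kind == "proportions") {
    rs <- rowSums(values)
    off <- which(abs(rs - 1) > 1e-9)
    if (length(off) > 0L)
      stop(sprintf("proportion row '%s' sums to %.12g, not 1",
                   rownames(values)[off[1L]], rs[off[1L]]))
  }
  structure(list(values = values, ages = ages, kind = kind),
            class = "assemblage")
}

#' @export
print.assemblage <- function(x, ...) {
  cat(sprintf("Assemblage table: %d samples x %d taxa (%s)%s\n",
              nrow(x$values), ncol(x$values), x$kind,
              if (is.null(x$ages)) "" else
                sprintf(", ages %.6g-%.6g yr BP",
                        min(x$ages), max(x$ages))))
  invisible(x)
}

#' @export
dim.assemblage <- function(x) dim(x$values)

#' Taxon names of an assemblage
#' @param x an `assemblage`.
#' @return character vector of taxon names.
#' @export
taxa <- function(x) {
  stopifnot(inherits(x, "assemblage"))
  colnames(x$values)
}

#' Read an assemblage table from CSV
#'
#' The interchange dialect is fixed: UTF-8, comma separated, `.` decimal,
#' one header row of taxon names, one row per sample. The first column is
#' `sample_id`; with `has_ages = TRUE` the second column is `age` in
#' calendar years BP. Remaining columns are taxon abundances (counts).
#'
#' @param path path to a CSV file.
#' @param has_ages whether the second column holds ages.
#' @return An [assemblage] with `kind = "counts"`.
#' @export
read_assemblage <- function(path, has_ages = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        stringsAsFactors = FALSE)
  if (ncol(df) < (2L + has_ages))
    stop("assemblage CSV needs sample_id", if (has_ages) ", age",
         " and at least one taxon column")
  sample_id <- as.character(df[[1L]])
  ages <- NULL
  first_taxon <- 2L
  if (has_ages) {
    ages <- suppressWarnings(as.numeric(df[[2L]]))
    if (anyNA(ages)) stop("non-numeric age value in column 2")
    first_taxon <- 3L
  }
  vals <- df[, first_taxon:ncol(df), drop = FALSE]
  # data-frame subsetting deduplicates names; keep the raw header
  names(vals) <- names(df)[first_taxon:ncol(df)]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v) && !anyNA(vals[[j]]))
      stop(sprintf("non-numeric cell in taxon column '%s'", names(vals)[j]))
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  colnames(m) <- names(vals)
  assemblage(m, sample_id = sample_id, ages = ages, kind = "counts")
}

#' Write an assemblage table to CSV
#'
#' Values are written with 12 significant digits so that a
#' read/write/read round trip reproduces the table exactly for values
#' representable at that precision.
#'
#' @param x an [assemblage].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assemblage <- function(x, path) {
  stopifnot(inherits(x, "assemblage"))
  vals <- apply(x$values, 2L, function(col) sprintf("%.12g", col))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L,
                                         dimnames = list(NULL, taxa(x)))
  df <- data.frame(sample_id = rownames(x$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(x$ages)) df$age <- sprintf("%.12g", x$ages)
  df <- cbind(df, as.data.frame(vals, check.names = FALSE,
                                stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a climate matrix from CSV
#'
#' One row per modern sample: a `sample_id` column followed by named climate
#' variables (e.g. mean annual / winter / summer precipitation in mm/yr).
#'
#' @param path path to a CSV file.
#' @return data frame with row names set to `sample_id`.
#' @export
read_climate <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample_id in climate table")
  out <- df[, -1L, drop = FALSE]
  for (j in seq_along(out)) {
    v <- suppressWarnings(as.numeric(out[[j]]))
    if (anyNA(v)) stop(sprintf("non-numeric value in climate column '%s'",
                               names(out)[j]))
    out[[j]] <- v
  }
  if (any(!is.finite(as.matrix(out)))) stop("climate values must be finite")
  rownames(out) <- ids
  out
}
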