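#' Taxon harmonization maps
#'
#' A harmonization map folds minor taxa into the major taxon, genus or
#' family they belong to (child -> parent pairs) and lists taxa to exclude
#' outright, e.g. aquatics and cultivars whose distribution is not driven by
#' climate. Harmonization is single-pass: chains (a parent that is itself a
#' child elsewhere) are rejected, so maps requiring them must be
#' pre-flattened.
#'
#' @param child,parent character vectors of equal length: each `child[i]`
#'   taxon is folded into `parent[i]`.
#' @param exclude character vector of taxon names dropped after merging.
#' @return An object of class `harmonization_map`.
#' @export
harmonization_map <- function(child = character(), parent = character(),
                              exclude = character()) {
  child <- as.character(child); parent <- as.character(parent)
  exclude <- as.character(exclude)
  if (length(child) != length(parent))
    stop("child and parent must have equal length")
  if (anyDuplicated(child))
    stop("each child taxon may appear only once")
  if (any(child == parent))
    stop("a taxon cannot be its own parent")
  chained <- intersect(parent, child)
  if (length(chained) > 0L)
    stop("harmonization chains not allowed; pre-flatten: ",
         paste(chained, collapse = ", "))
  bad <- intersect(exclude, parent)
  if (length(bad) > 0L)
    stop("excluded taxa cannot also be parents: ", paste(bad, collapse = ", "))
  structure(list(child = child, parent = parent, exclude = unique(exclude)),
            class = "harmonization_map")
}

#' @export
print.harmonization_map <- function(x, ...) {
  cat(sprintf("Harmonization map: %d child->parent pairs, %d exclusions\n",
              length(x$child), length(x$exclude)))
  invisible(x)
}

#' Read a harmonization map from CSV
#'
#' @param map_path CSV with columns `child,parent`; may be `NULL` for an
#'   exclusion-only map.
#' @param exclude_path optional plain-text file, one taxon name per line.
#' @return A [harmonization_map].
#' @export
read_harmonization <- function(map_path = NULL, exclude_path = NULL) {
  child <- parent <- character()
  if (!is.null(map_path)) {
    df <- utils::read.csv(map_path, check.names = FALSE,
                          fileEncoding = "UTF-8", stringsAsFactors = FALSE)
    if (!all(c("child", "parent") %in% names(df)))
      stop("harmonization CSV must have columns 'child' and 'parent'")
    child <- as.character(df$child); parent <- as.character(df$parent)
  }
  exclude <- character()
  if (!is.null(exclude_path)) {
    exclude <- readLines(exclude_path, encoding = "UTF-8", warn = FALSE)
    exclude <- trimws(exclude)
    exclude <- exclude[nzchar(exclude)]
  }
  harmonization_map(child, parent, exclude)
}

#' Harmonize an assemblage table
#'
#' Adds every child column into its parent column (creating the parent if it
#' is not already present), drops the child columns, then drops excluded
#' taxa. The per-sample total abundance of non-excluded taxa is conserved
#' exactly. Applied to counts, before any compositional transform.
#'
#' @param x an [assemblage] with `kind = "counts"`.
#' @param map a [harmonization_map].
#' @return A harmonized [assemblage] (counts).
#' @export
harmonize <- function(x, map) {
  stopifnot(inherits(x, "assemblage"), inherits(map, "harmonization_map"))
  if (x$kind != "counts")
    stop("harmonization operates on counts, got ", x$kind)
  vals <- x$values
  present <- map$child %in% colnames(vals)
  for (i in which(present)) {
    ch <- map$child[i]; pa <- map$parent[i]
    if (!pa %in% colnames(vals)) {
      vals <- cbind(vals, 0)
      colnames(vals)[ncol(vals)] <- pa
    }
    vals[, pa] <- vals[, pa] + vals[, ch]
  }
  vals <- vals[, !(colnames(vals) %in% map$child[present]), drop = FALSE]
  dropped <- intersect(map$exclude, colnames(vals))
  vals <- vals[, !(colnames(vals) %in% dropped), drop = FALSE]
  if (ncol(vals) == 0L)
    stop("harmonization removed every taxon")
  if (length(dropped) > 0L)
    message(sprintf("harmonize: excluded %d taxa (%s)", length(dropped),
                    paste(dropped, collapse = ", ")))
  assemblage(vals, sample_id = rownames(x$values), ages = x$ages,
             kind = "counts")
}

#' Convert counts to proportions
#'
#' Each row is divided by its total, giving closed compositions on \[0, 1\].
#'
#' @param x an [assemblage] with `kind = "counts"`.
#' @return An [assemblage] with `kind = "proportions"`.
#' @export
to_proportions <- function(x) {
  stopifnot(inherits(x, "assemblage"))
  if (x$kind != "counts")
    stop("to_proportions expects counts, got ", x$kind)
  rs <- rowSums(x$values)
  if (any(rs == 0))
    stop("all-zero row(s): ",
         paste(rownames(x$values)[rs == 0], collapse = ", "))
  assemblage(x$values / rs, sample_id = rownames(x$values), ages = x$ages,
             kind = "proportions")
}

#' Square-root transform of a proportion table
#'
#' The square-root (Hellinger-style) transformation damps the dominance of
#' abundant taxa and stabilises the count variance; the transfer function is
#' fitted on this scale.
#'
#' @param x an [assemblage] with `kind = "proportions"`.
#' @return An [assemblage] with `kind = "sqrt_proportions"`.
#' @export
sqrt_transform <- function(x) {
  stopifnot(inherits(x, "assemblage"))
  if (x$kind != "proportions")
    stop("sqrt_transform expects proportions, got ", x$kind)
  out <- assemblage(sqrt(x$values), sample_id = rownames(x$values),
                    ages = x$ages, kind = "counts")
  out$kind <- "sqrt_proportions"
  out
}
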