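#' @include AllClasses.R
NULL

#' Construct an LD matrix
#'
#' @param r square numeric matrix of pairwise correlations.
#' @param variantIds character vector labelling the rows/columns (defaults
#'   to the matrix dimnames).
#' @return an \linkS4class{LDMatrix}.
#' @export
LDMatrix <- function(r, variantIds = rownames(r)) {
  if (is.null(variantIds)) stop("variantIds required (or set matrix dimnames)")
  r <- as.matrix(r)
  dimnames(r) <- list(variantIds, variantIds)
  new("LDMatrix", variantIds = as.character(variantIds), r = r)
}

#' Read an LD matrix from plain text
#'
#' Format: first line holds whitespace-separated variant ids; each
#' subsequent line one matrix row of decimal correlations.
#'
#' @param path file path.
#' @return an \linkS4class{LDMatrix}.
#' @export
readLDMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  m <- length(ids)
  if (length(lines) < m + 1L)
    stop("LD matrix file has fewer rows than variant ids")
  vals <- lapply(lines[2:(m + 1L)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(lengths(vals) != m)) stop("ragged LD matrix row")
  LDMatrix(do.call(rbind, vals), ids)
}

#' Write an LD matrix as plain text
#'
#' @param x an \linkS4class{LDMatrix}.
#' @param path output path.
#' @param digits significant digits for the correlations.
#' @return invisibly, the path.
#' @export
writeLDMatrix <- function(x, path, digits = 10) {
  stopifnot(is(x, "LDMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(x@variantIds, collapse = " "), con)
  apply(signif(x@r, digits), 1L, function(row)
    writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

## Subset an LDMatrix to (and in the order of) the given variant ids.
.ld_subset <- function(ld, ids) {
  idx <- match(ids, ld@variantIds)
  if (anyNA(idx))
    stop("variant(s) missing from LD matrix: ",
         paste(ids[is.na(idx)], collapse = ", "))
  new("LDMatrix", variantIds = ids, r = ld@r[idx, idx, drop = FALSE])
}
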