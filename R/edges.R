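# Edge vectorization: row-major upper triangle, i < j.
# For 68 regions this gives the canonical 2278-edge vector
# (1,2),(1,3),...,(1,68),(2,3),...,(67,68). The ordering is fixed and used
# everywhere: generators, IO, selection, strengths, serialized models.

.edge_cache <- new.env(parent = emptyenv())

#' Edge index table for an n-region connectome
#'
#' Enumerates the region pairs (i, j), i < j, in row-major upper-triangle
#' order. This ordering defines the edge vectorization used throughout the
#' package (2278 edges for the default 68 regions).
#'
#' @param n_regions Number of regions (nodes).
#' @return Integer matrix with columns `i`, `j` and one row per edge.
#' @export
#' @examples
#' head(edge_index(68))
edge_index <- function(n_regions) {
  stopifnot(is.numeric(n_regions), length(n_regions) == 1L, n_regions >= 2)
  n_regions <- as.integer(n_regions)
  key <- as.character(n_regions)
  if (!is.null(.edge_cache[[key]])) return(.edge_cache[[key]])
  idx <- which(upper.tri(matrix(0, n_regions, n_regions)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  .edge_cache[[key]] <- idx
  idx
}

#' Number of edges for n regions
#' @param n_regions Number of regions.
#' @return `n_regions * (n_regions - 1) / 2`.
#' @export
n_edges <- function(n_regions) as.integer(n_regions * (n_regions - 1) / 2)

#' Vectorize a symmetric connectivity matrix
#'
#' @param mat Square symmetric matrix.
#' @return Numeric vector of upper-triangle entries in row-major edge order.
#' @export
vectorize_connectome <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  idx <- edge_index(nrow(mat))
  mat[idx]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_connectome()]: zero diagonal, symmetric off-diagonal.
#'
#' @param edges Edge vector of length `n_regions * (n_regions - 1) / 2`.
#' @param n_regions Number of regions.
#' @return `n_regions` x `n_regions` symmetric matrix.
#' @export
connectome_from_edges <- function(edges, n_regions) {
  m <- n_edges(n_regions)
  if (length(edges) != m) {
    stop("expected ", m, " edges for ", n_regions, " regions, got ",
         length(edges))
  }
  idx <- edge_index(n_regions)
  mat <- matrix(0, n_regions, n_regions)
  mat[idx] <- edges
  mat[idx[, c(2L, 1L)]] <- edges
  mat
}

#' Stack per-subject connectomes into a subjects x edges matrix
#'
#' @param connectomes List of square symmetric matrices (or `cpm_connectome`
#'   objects), one per subject.
#' @return Numeric matrix, one row per subject, `n_edges` columns; row names
#'   taken from `subject_id` attributes when present.
#' @export
stack_connectomes <- function(connectomes) {
  stopifnot(is.list(connectomes), length(connectomes) > 0L)
  vecs <- lapply(connectomes, function(m) vectorize_connectome(unclass(m)))
  lens <- lengths(vecs)
  if (length(unique(lens)) != 1L) stop("connectomes differ in size")
  out <- do.call(rbind, vecs)
  ids <- vapply(connectomes, function(m) {
    id <- attr(m, "subject_id")
    if (is.null(id)) NA_character_ else as.character(id)
  }, character(1))
  if (!anyNA(ids)) rownames(out) <- ids
  out
}
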