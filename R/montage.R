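#' Electrode montage
#'
#' An electrode montage is the physical layout of an EEG cap projected onto
#' the 2-D head circle: electrode labels (10-20/10-10 system), projected
#' coordinates, and the list of neighbour pairs used to build the spatial
#' adjacency graph. Edges are unordered label pairs; self-connections are
#' never listed because the adjacency rule adds the diagonal itself.
#'
#' @param names Character vector of unique electrode labels.
#' @param positions Numeric matrix (electrodes x 2) of projected coordinates,
#'   rows in the order of `names`.
#' @param edges Two-column character matrix (or data frame) of unordered
#'   label pairs.
#' @return An object of class `electrode_montage`.
#' @export
electrode_montage <- function(names, positions, edges) {
  names <- as.character(names)
  if (length(names) < 1L) stop("montage needs at least one electrode")
  if (anyDuplicated(names)) stop("electrode labels must be unique")
  positions <- as.matrix(positions)
  if (nrow(positions) != length(names) || ncol(positions) != 2L)
    stop("positions must be an (electrodes x 2) matrix")
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(0), 0L, 2L)
  } else if (ncol(edges) != 2L) {
    stop("edges must have two columns")
  }
  storage.mode(edges) <- "character"
  bad <- setdiff(unique(c(edges)), names)
  if (length(bad) > 0L)
    stop(sprintf("edge refers to unknown electrode label(s): %s",
                 paste(bad, collapse = ", ")))
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-pairs are not allowed in the edge list")
  rownames(positions) <- names
  structure(list(names = names, positions = positions, edges = edges),
            class = "electrode_montage")
}

#' @export
print.electrode_montage <- function(x, ...) {
  cat(sprintf("<electrode_montage> %d electrodes, %d edges\n",
              length(x$names), nrow(x$edges)))
  cat(" ", paste(x$names, collapse = " "), "\n")
  invisible(x)
}

#' Read a montage from plain-text tables
#'
#' Positions are a whitespace/tab table with header `label x y`; edges are a
#' headerless two-column table of label pairs (one edge per line).
#'
#' @param positions_file Path to the positions table.
#' @param edges_file Path to the edge list.
#' @return An [electrode_montage()].
#' @export
read_montage <- function(positions_file, edges_file) {
  pos <- utils::read.delim(positions_file, header = TRUE,
                           stringsAsFactors = FALSE)
  ed <- tryCatch(
    utils::read.delim(edges_file, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) data.frame(V1 = character(0), V2 = character(0)))
  electrode_montage(pos$label, cbind(pos$x, pos$y), as.matrix(ed))
}

#' Bundled montages
#'
#' `montage_2a()` is the 22-electrode 10-10 motor cortex layout of the
#' four-class cued motor-imagery paradigm (Fz through POz); its edge list was
#' generated once by Delaunay triangulation of the azimuthal-equidistant
#' projected electrode positions, giving a deterministic, physiologically
#' local neighbourhood graph. `montage_2b()` is the three-electrode bipolar
#' C3/Cz/C4 chain used for two-class left/right-hand imagery.
#'
#' @return An [electrode_montage()].
#' @export
montage_2a <- function() {
  read_montage(system.file("extdata", "montage_2a_positions.tsv",
                           package = "gahtnet", mustWork = TRUE),
               system.file("extdata", "montage_2a_edges.tsv",
                           package = "gahtnet", mustWork = TRUE))
}

#' @rdname montage_2a
#' @export
montage_2b <- function() {
  read_montage(system.file("extdata", "montage_2b_positions.tsv",
                           package = "gahtnet", mustWork = TRUE),
               system.file("extdata", "montage_2b_edges.tsv",
                           package = "gahtnet", mustWork = TRUE))
}

#' Build the binary electrode adjacency matrix
#'
#' A_ij = 1 iff i = j or \{i, j\} is a montage edge; 0 otherwise. The unit
#' diagonal is part of the adjacency definition (each electrode is its own
#' neighbour); symmetric normalisation later adds the identity once more,
#' so the self-weight entering the degree computation is 2.
#'
#' @param montage An [electrode_montage()].
#' @return A `spatial_graph` object holding only `A` (use
#'   [normalize_adjacency()] and [chebyshev_basis()] to complete it, or
#'   [spatial_graph()] for the one-call path).
#' @export
build_adjacency <- function(montage) {
  stopifnot(inherits(montage, "electrode_montage"))
  C <- length(montage$names)
  A <- diag(1, C)
  dimnames(A) <- list(montage$names, montage$names)
  if (nrow(montage$edges) > 0L) {
    i <- match(montage$edges[, 1L], montage$names)
    j <- match(montage$edges[, 2L], montage$names)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  structure(list(A = A, A_hat = NULL, cheb_basis = NULL, K = NULL,
                 names = montage$names),
            class = "spatial_graph")
}

#' Symmetrically normalise an adjacency matrix
#'
#' Computes `A_hat = D^{-1/2} (A + I) D^{-1/2}` where `D` is the degree
#' matrix of `A + I`, taken literally: since `A` already carries a unit
#' diagonal, the self-weight inside the normalisation is 2. The result is
#' symmetric with spectrum in (-1, 1] and largest eigenvalue exactly 1
#' (eigenvector `D^{1/2} 1`).
#'
#' @param A Symmetric binary adjacency matrix with unit diagonal.
#' @return The normalised operator, same dimension as `A`.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (!isSymmetric(unname(A), tol = 0)) stop("adjacency matrix must be symmetric")
  if (any(diag(A) != 1)) stop("adjacency matrix must have a unit diagonal")
  Ai <- A + diag(nrow(A))
  d <- rowSums(Ai)
  dm <- 1 / sqrt(d)
  Ah <- Ai * (dm %o% dm)
  (Ah + t(Ah)) / 2  # enforce exact symmetry against rounding
}

#' Chebyshev polynomial basis of a graph operator
#'
#' Returns `T_0, ..., T_{K-1}` of the Chebyshev recursion
#' `T_0 = I`, `T_1 = A_hat`, `T_k = 2 A_hat T_{k-1} - T_{k-2}`, evaluated at
#' the normalised operator itself. Because the spectrum of `A_hat` lies in
#' (-1, 1], every basis matrix has entries of bounded spectral norm.
#'
#' @param A_hat Normalised graph operator.
#' @param K Polynomial order (number of basis matrices, >= 1).
#' @return List of `K` matrices.
#' @export
chebyshev_basis <- function(A_hat, K) {
  if (!is.numeric(K) || length(K) != 1L || K < 1) stop("K must be >= 1")
  K <- as.integer(K)
  A_hat <- as.matrix(A_hat)
  basis <- vector("list", K)
  basis[[1L]] <- diag(nrow(A_hat))
  if (K >= 2L) basis[[2L]] <- A_hat
  if (K >= 3L) {
    for (k in 3:K) {
      basis[[k]] <- 2 * A_hat %*% basis[[k - 1L]] - basis[[k - 2L]]
    }
  }
  basis
}

#' Spatial graph of an electrode montage
#'
#' One-call constructor: adjacency, symmetric normalisation, and the
#' Chebyshev basis used by the graph convolution.
#'
#' @param montage An [electrode_montage()].
#' @param K Chebyshev order (default 3, the order used throughout).
#' @return A `spatial_graph` with fields `A`, `A_hat`, `cheb_basis`, `K`.
#' @export
spatial_graph <- function(montage, K = 3L) {
  g <- build_adjacency(montage)
  g$A_hat <- normalize_adjacency(g$A)
  g$cheb_basis <- chebyshev_basis(g$A_hat, K)
  g$K <- as.integer(K)
  g
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d electrodes, %d edges%s\n",
              nrow(x$A), (sum(x$A) - nrow(x$A)) / 2,
              if (is.null(x$K)) " (adjacency only)"
              else sprintf(", Chebyshev order %d", x$K)))
  invisible(x)
}

n_electrodes <- function(graph) nrow(graph$A)
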