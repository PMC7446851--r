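#' @include AllClasses.R
NULL

.sort_barcode <- function(bars) {
  bars <- bars[order(bars$dim, bars$birth, bars$death), , drop = FALSE]
  rownames(bars) <- NULL
  bars
}

.check_cloud <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L)
    stop("point cloud must be an n x 3 numeric matrix")
  if (nrow(points) < 1L) stop("point cloud must contain at least one point")
  if (!all(is.finite(points))) stop("point cloud coordinates must be finite")
  points
}

#' Euclidean distance matrix of a point cloud
#'
#' @param points n x 3 numeric matrix of coordinates (Angstrom).
#' @return symmetric n x n matrix with zero diagonal.
#' @export
pairwiseDistances <- function(points) {
  points <- .check_cloud(points)
  as.matrix(stats::dist(points))
}

#' Vietoris-Rips persistence barcodes of a 3-D point cloud
#'
#' Builds the Vietoris-Rips filtration with edge value equal to Euclidean
#' distance, truncated at \code{maxFiltration}, and returns its persistence
#' barcodes over Z/2 for homology dimensions 0..\code{maxDim}. Classes still
#' alive at the truncation value carry \code{death = Inf}; the dimension-0
#' barcode has exactly one infinite bar per connected component of the
#' distance graph at \code{maxFiltration} and one bar per point in total.
#' Zero-persistence bars in dimensions >= 1 (features that fill the moment
#' they form, e.g. an equilateral triangle's loop) are omitted.
#'
#' @param points n x 3 numeric matrix (Angstrom).
#' @param maxFiltration filtration upper bound F > 0 (Angstrom).
#' @param maxDim largest homology dimension, 0, 1 or 2 (simplices are built
#'   one dimension higher). Larger values are rejected: the complex size
#'   grows too quickly for the dense reduction used here.
#' @return data.frame with columns \code{dim}, \code{birth}, \code{death}
#'   (Angstrom; \code{Inf} for essential classes), sorted by
#'   (dim, birth, death).
#' @seealso \code{\link{bruteForcePersistence}} for the independent oracle.
#' @export
ripsPersistence <- function(points, maxFiltration, maxDim = 1L) {
  points <- .check_cloud(points)
  if (!is.finite(maxFiltration) || maxFiltration <= 0)
    stop("maxFiltration must be a positive number")
  maxDim <- as.integer(maxDim)
  if (maxDim < 0L || maxDim > 2L)
    stop("unsupported homology dimension: maxDim must be 0, 1 or 2")
  .sort_barcode(.rips_cpp(points, maxFiltration, maxDim))
}

# symmetric difference of two sorted integer index vectors (Z/2 addition)
.symdiff <- function(a, b) sort(c(setdiff(a, b), setdiff(b, a)))

#' Brute-force persistence by full boundary-matrix reduction
#'
#' Independent oracle for \code{\link{ripsPersistence}}: enumerates every
#' simplex up to dimension \code{maxDim + 1} whose diameter is at most
#' \code{maxFiltration}, orders them by (filtration value, dimension,
#' lexicographic vertex order), and performs the textbook column reduction of
#' the full boundary matrix over Z/2, reading bars off the pivot pairs. The
#' output contract is identical to \code{\link{ripsPersistence}}; the two
#' implementations share no code beyond the distance computation.
#'
#' @param points n x 3 numeric matrix with at most 12 points (the full
#'   simplex enumeration is exponential).
#' @inheritParams ripsPersistence
#' @return data.frame with columns \code{dim}, \code{birth}, \code{death},
#'   sorted by (dim, birth, death).
#' @export
bruteForcePersistence <- function(points, maxFiltration, maxDim = 1L) {
  points <- .check_cloud(points)
  n <- nrow(points)
  if (n > 12L) stop("brute-force oracle is limited to 12 points")
  if (!is.finite(maxFiltration) || maxFiltration <= 0)
    stop("maxFiltration must be a positive number")
  maxDim <- as.integer(maxDim)
  if (maxDim < 0L || maxDim > 2L)
    stop("unsupported homology dimension: maxDim must be 0, 1 or 2")
  D <- as.matrix(stats::dist(points))

  maxSize <- min(maxDim + 2L, n)
  verts <- list(); filts <- numeric(0); dims <- integer(0)
  for (k in seq_len(maxSize)) {
    cmb <- utils::combn(n, k)
    for (c in seq_len(ncol(cmb))) {
      v <- cmb[, c]
      f <- if (k == 1L) 0 else max(D[v, v])
      if (f <= maxFiltration) {
        verts[[length(verts) + 1L]] <- v
        filts <- c(filts, f)
        dims <- c(dims, k - 1L)
      }
    }
  }
  S <- length(verts)
  # global order: filtration, then dimension, then lexicographic vertices
  pad <- matrix(0L, nrow = S, ncol = maxSize)
  for (s in seq_len(S)) pad[s, seq_along(verts[[s]])] <- verts[[s]]
  ord <- do.call(order, c(list(filts, dims),
                          lapply(seq_len(maxSize), function(j) pad[, j])))
  verts <- verts[ord]; filts <- filts[ord]; dims <- dims[ord]
  key <- vapply(verts, paste, character(1), collapse = "-")
  idx <- seq_len(S); names(idx) <- key

  stored <- vector("list", S)
  pivotOwner <- integer(S)           # 0 = unclaimed
  pairDeath <- rep(NA_real_, S)      # death filtration of the killed simplex
  for (j in seq_len(S)) {
    v <- verts[[j]]
    col <- integer(0)
    if (length(v) > 1L) {
      faces <- vapply(seq_along(v),
                      function(drop) paste(v[-drop], collapse = "-"),
                      character(1))
      col <- sort(unname(idx[faces]))
    }
    while (length(col)) {
      piv <- col[length(col)]
      if (pivotOwner[piv] == 0L) {
        pivotOwner[piv] <- j
        pairDeath[piv] <- filts[j]
        break
      }
      col <- .symdiff(col, stored[[pivotOwner[piv]]])
    }
    stored[[j]] <- col
  }

  barDim <- integer(0); barBirth <- numeric(0); barDeath <- numeric(0)
  for (i in seq_len(S)) {
    if (length(stored[[i]])) next          # negative simplex: creates no class
    d <- dims[i]
    if (d > maxDim) next
    death <- if (pivotOwner[i] == 0L) Inf else pairDeath[i]
    if (d >= 1L && death <= filts[i]) next # zero-persistence, dims >= 1
    barDim <- c(barDim, d)
    barBirth <- c(barBirth, filts[i])
    barDeath <- c(barDeath, death)
  }
  .sort_barcode(data.frame(dim = barDim, birth = barBirth, death = barDeath))
}

#' Write barcodes to a columnar CSV
#'
#' @param bars data.frame with columns \code{sample_id}, \code{element},
#'   \code{dim}, \code{birth}, \code{death} (may be \code{Inf}).
#' @param path output file; infinite deaths are serialized as \code{+inf}.
#' @return \code{path}, invisibly.
#' @export
writeBarcodes <- function(bars, path) {
  stopifnot(all(c("sample_id", "element", "dim", "birth", "death") %in%
                names(bars)))
  out <- bars
  out$death <- ifelse(is.infinite(out$death), "+inf",
                      format(out$death, digits = 17, scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read barcodes written by \code{\link{writeBarcodes}}
#' @param path CSV path.
#' @return data.frame with numeric \code{death} (\code{Inf} restored).
#' @export
readBarcodes <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$death <- ifelse(trimws(out$death) == "+inf", Inf,
                      as.numeric(out$death))
  out
}
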