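#' Build a regular grid lattice with rook or queen contiguity
#'
#' Constructs the areal lattice used throughout the package: a set of
#' non-overlapping areas together with a binary neighbourhood matrix `W`.
#' Regular grids stand in for real small-area geographies (e.g. UK LSOAs),
#' whose polygon contiguity is out of scope here.
#'
#' @param rows,cols Grid dimensions; `rows * cols` areas are created.
#' @param contiguity `"queen"` (edge or corner shared, interior degree 8) or
#'   `"rook"` (edge shared, interior degree 4). Queen is the default used by
#'   the synthetic studies.
#' @param area_ids Optional character vector of area identifiers in
#'   row-major order; defaults to `"A001"`, `"A002"`, ...
#'
#' @return An object of class `area_lattice`: a list with `area_ids`
#'   (character, length N), `W` (N x N symmetric 0/1 matrix with zero
#'   diagonal), and the grid coordinates `coords` (tibble with `area_id`,
#'   `row`, `col`).
#' @examples
#' lat <- build_grid_lattice(3, 3, "rook")
#' rowSums(lat$W) # corner areas have 2 neighbours, the centre has 4
#' @export
build_grid_lattice <- function(rows, cols, contiguity = c("queen", "rook"),
                               area_ids = NULL) {
  contiguity <- match.arg(contiguity)
  stopifnot(rows >= 1, cols >= 1)
  n <- rows * cols
  if (n < 2) {
    stop("invalid lattice: need at least 2 areas (rows * cols >= 2)",
         call. = FALSE)
  }
  if (is.null(area_ids)) {
    area_ids <- sprintf("A%03d", seq_len(n))
  }
  stopifnot(length(area_ids) == n, !anyDuplicated(area_ids))

  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  grid <- grid[order(grid$row, grid$col), c("row", "col")]
  W <- matrix(0L, n, n, dimnames = list(area_ids, area_ids))
  dr <- abs(outer(grid$row, grid$row, "-"))
  dc <- abs(outer(grid$col, grid$col, "-"))
  adj <- if (contiguity == "rook") {
    (dr + dc) == 1L
  } else {
    dr <= 1L & dc <= 1L & (dr + dc) > 0L
  }
  W[adj] <- 1L

  new_area_lattice(area_ids, W,
                   coords = tibble::tibble(area_id = area_ids,
                                           row = grid$row, col = grid$col))
}

new_area_lattice <- function(area_ids, W, coords = NULL) {
  validate_lattice(W)
  structure(list(area_ids = area_ids, W = W, coords = coords),
            class = "area_lattice")
}

validate_lattice <- function(W) {
  if (!isSymmetric(unname(W))) stop("W must be symmetric", call. = FALSE)
  if (any(diag(W) != 0)) stop("W must have a zero diagonal", call. = FALSE)
  if (!all(W %in% c(0, 1))) stop("W entries must be 0 or 1", call. = FALSE)
  if (any(rowSums(W) == 0)) {
    stop("every area must have at least one neighbour", call. = FALSE)
  }
  invisible(W)
}

#' @export
print.area_lattice <- function(x, ...) {
  cat(sprintf("<area_lattice> %d areas, %d undirected edges\n",
              length(x$area_ids), sum(x$W) / 2))
  invisible(x)
}

n_areas <- function(lattice) length(lattice$area_ids)

#' Leroux precision matrix
#'
#' Computes the Leroux conditional autoregressive precision matrix
#' \deqn{Q(\rho_S, W) = \rho_S (\mathrm{diag}(W 1) - W) + (1 - \rho_S) I,}
#' which interpolates between independence (`rho_s = 0`, identity) and the
#' intrinsic CAR model (`rho_s = 1`, graph Laplacian, singular).
#'
#' @param lattice An [`area_lattice`][build_grid_lattice].
#' @param rho_s Spatial dependency parameter in `[0, 1]`. The matrix is
#'   positive definite if and only if `rho_s < 1`.
#' @return A sparse symmetric `Matrix::dsCMatrix` of dimension N x N.
#' @examples
#' lat <- build_grid_lattice(2, 2)
#' leroux_precision(lat, 0)    # identity
#' leroux_precision(lat, 0.5)
#' @export
leroux_precision <- function(lattice, rho_s) {
  if (!is.numeric(rho_s) || length(rho_s) != 1 || is.na(rho_s) ||
      rho_s < 0 || rho_s > 1) {
    stop("rho_s must be a single number in [0, 1]", call. = FALSE)
  }
  W <- Matrix::Matrix(lattice$W, sparse = TRUE)
  Q <- rho_s * (Matrix::Diagonal(x = Matrix::rowSums(W)) - W) +
    (1 - rho_s) * Matrix::Diagonal(nrow(W))
  methods::as(Matrix::forceSymmetric(Q), "CsparseMatrix")
}

#' Read and write adjacency structures as plain-text files
#'
#' The on-disk interchange formats are a three-column edge list
#' (`area_i, area_j, weight`, one row per undirected edge) paired with an
#' `area_ids` file fixing the area order, or a dense CSV matrix with area
#' identifiers as the header and first column.
#'
#' @param lattice An `area_lattice`.
#' @param edges_path,ids_path,path File paths.
#' @return `read_lattice_edges()` and `read_lattice_matrix()` return an
#'   `area_lattice`; the writers return the input invisibly.
#' @name lattice_io
NULL

#' @rdname lattice_io
#' @export
write_lattice_edges <- function(lattice, edges_path, ids_path) {
  W <- lattice$W
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  edges <- tibble::tibble(area_i = lattice$area_ids[idx[, 1]],
                          area_j = lattice$area_ids[idx[, 2]],
                          weight = W[idx])
  readr::write_csv(edges, edges_path)
  readr::write_csv(tibble::tibble(area_id = lattice$area_ids), ids_path)
  invisible(lattice)
}

#' @rdname lattice_io
#' @export
read_lattice_edges <- function(edges_path, ids_path) {
  ids <- readr::read_csv(ids_path, show_col_types = FALSE)$area_id
  edges <- readr::read_csv(edges_path, show_col_types = FALSE)
  n <- length(ids)
  W <- matrix(0L, n, n, dimnames = list(ids, ids))
  i <- match(edges$area_i, ids)
  j <- match(edges$area_j, ids)
  if (anyNA(i) || anyNA(j)) {
    stop("edge list refers to areas absent from the area_ids file",
         call. = FALSE)
  }
  W[cbind(i, j)] <- as.integer(edges$weight)
  W[cbind(j, i)] <- as.integer(edges$weight)
  new_area_lattice(ids, W)
}

#' @rdname lattice_io
#' @export
write_lattice_matrix <- function(lattice, path) {
  df <- tibble::as_tibble(as.data.frame(lattice$W), rownames = "area_id")
  readr::write_csv(df, path)
  invisible(lattice)
}

#' @rdname lattice_io
#' @export
read_lattice_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  ids <- df$area_id
  W <- as.matrix(df[, -1])
  rownames(W) <- ids
  storage.mode(W) <- "integer"
  new_area_lattice(ids, W[, ids, drop = FALSE])
}
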