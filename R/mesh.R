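#' Construct a triangulated surface mesh
#'
#' A `surface_mesh` is the 2-D manifold on which all per-vertex fields live:
#' an `n x 3` matrix of vertex coordinates (mm) and an `m x 3` integer matrix
#' of triangles indexing vertices (1-based in memory; all on-disk formats use
#' 0-based indices, converted at the I/O boundary).
#'
#' @param vertices numeric matrix, one row per vertex, 3 columns (x, y, z).
#' @param triangles integer matrix, one row per triangle, 3 vertex indices
#'   (1-based).
#' @return an object of class `surface_mesh` with elements `vertices`,
#'   `triangles` and `n_vertices`.
#' @examples
#' m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                   rbind(c(1L, 2L, 3L)))
#' m$n_vertices
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3L)
    stop("`vertices` must have 3 columns (x, y, z)", call. = FALSE)
  if (ncol(triangles) != 3L)
    stop("`triangles` must have 3 columns", call. = FALSE)
  n <- nrow(vertices)
  if (nrow(triangles) > 0L) {
    if (any(triangles < 1L) || any(triangles > n))
      stop("triangle indices out of range [1, ", n, "]", call. = FALSE)
    degen <- triangles[, 1L] == triangles[, 2L] |
      triangles[, 1L] == triangles[, 3L] |
      triangles[, 2L] == triangles[, 3L]
    if (any(degen))
      stop("degenerate triangles (repeated vertex) at rows: ",
           paste(which(degen), collapse = ", "), call. = FALSE)
  }
  structure(
    list(vertices = vertices, triangles = triangles, n_vertices = n),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", x$n_vertices, "vertices,",
      nrow(x$triangles), "triangles\n")
  invisible(x)
}

#' Vertex adjacency of a surface mesh
#'
#' Two vertices are adjacent iff they share a triangle edge. Emits a warning
#' if the edge graph is disconnected (permitted; downstream operations work
#' per component).
#'
#' @param mesh a [surface_mesh()].
#' @return sparse symmetric 0/1 `dgCMatrix` with zero diagonal.
#' @export
build_vertex_adjacency <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  tri <- mesh$triangles
  n <- mesh$n_vertices
  i <- c(tri[, 1L], tri[, 2L], tri[, 3L])
  j <- c(tri[, 2L], tri[, 3L], tri[, 1L])
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(n, n))
  A <- methods::as(A > 0, "dMatrix") * 1
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  nc <- n_components(A)
  if (nc > 1L)
    warning("mesh edge graph has ", nc, " connected components",
            call. = FALSE)
  A
}

# number of connected components of a sparse 0/1 adjacency
n_components <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = NULL, diag = FALSE)
  igraph::count_components(g)
}

#' Linked-distance neighborhoods
#'
#' For every vertex `s`, the neighborhood `N(s)` contains all vertices
#' (including `s` itself) within `D` mesh-edge hops of `s`, found by
#' breadth-first expansion. Linked distance is combinatorial (edge hops),
#' not geodesic millimetres.
#'
#' @param mesh a [surface_mesh()].
#' @param D non-negative integer hop count. `D = 0` gives `N(s) = {s}`.
#' @return object of class `neighborhood_table`: a list of integer vectors
#'   (sorted, 1-based), with attribute `D`.
#' @export
linked_neighborhoods <- function(mesh, D = 11L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  D <- as.integer(D)
  if (is.na(D) || D < 0L) stop("`D` must be a non-negative integer",
                               call. = FALSE)
  n <- mesh$n_vertices
  if (D == 0L) {
    nbrs <- as.list(seq_len(n))
  } else {
    A <- suppressWarnings(build_vertex_adjacency(mesh))
    # boolean closure (A + I)^D applied to identity, kept sparse
    step <- A + Matrix::Diagonal(n)
    reach <- methods::as(Matrix::Diagonal(n), "CsparseMatrix")
    for (k in seq_len(D)) {
      reach <- methods::as(reach %*% step, "CsparseMatrix")
      reach@x[] <- 1  # keep 0/1 to avoid count blow-up
    }
    cols <- rep.int(seq_len(n), diff(reach@p))
    nbrs <- unname(split(reach@i + 1L, factor(cols, levels = seq_len(n))))
    nbrs <- lapply(nbrs, sort)
  }
  structure(nbrs, D = D, class = "neighborhood_table")
}

#' @export
print.neighborhood_table <- function(x, ...) {
  sizes <- lengths(x)
  cat("neighborhood_table: ", length(x), " vertices, D = ", attr(x, "D"),
      ", |N(s)| in [", min(sizes), ", ", max(sizes), "]\n", sep = "")
  invisible(x)
}

#' Laplace-Beltrami eigenbasis of a surface mesh
#'
#' Discretizes the Laplace-Beltrami operator with the cotangent stiffness
#' matrix and lumped (diagonal barycentric) mass matrix, and solves the
#' generalized symmetric eigenproblem `K phi = lambda M phi` for the
#' `n_modes` smallest eigenpairs. Eigenfunctions are orthonormal under the
#' mass-weighted inner product `<f, g> = f' M g`. On a connected mesh the
#' first eigenvalue is ~0 with a constant eigenfunction (free/Neumann
#' boundary behaviour on open meshes).
#'
#' @param mesh a [surface_mesh()].
#' @param n_modes number of eigenpairs to retain; default
#'   `min(500, n_vertices)`.
#' @return object of class `lb_eigenbasis`: list with `values` (ascending),
#'   `functions` (n_vertices x n_modes, M-orthonormal), `mass` (lumped mass
#'   vector), `n_modes`, `lumped_mass = TRUE`.
#' @export
lb_eigenbasis <- function(mesh, n_modes = min(500L, mesh$n_vertices)) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- mesh$n_vertices
  n_modes <- as.integer(n_modes)
  if (n_modes < 1L || n_modes > n)
    stop("`n_modes` must be in [1, n_vertices]", call. = FALSE)
  if (n > 4000L)
    warning("dense eigendecomposition on ", n,
            " vertices may be slow", call. = FALSE)
  KM <- cotan_laplacian(mesh)
  Msqi <- as.vector(1 / sqrt(KM$mass))
  # symmetrized operator M^{-1/2} K M^{-1/2}
  S <- as.matrix(KM$stiffness)
  S <- S * tcrossprod(Msqi)
  S <- (S + t(S)) / 2
  ee <- eigen(S, symmetric = TRUE)
  if (any(!is.finite(ee$values)))
    stop("eigensolver returned non-finite eigenvalues", call. = FALSE)
  idx <- order(ee$values)[seq_len(n_modes)]
  vals <- pmax(ee$values[idx], 0)
  funs <- ee$vectors[, idx, drop = FALSE] * Msqi
  structure(
    list(values = vals, functions = funs, mass = KM$mass,
         n_modes = n_modes, lumped_mass = TRUE),
    class = "lb_eigenbasis"
  )
}

# Cotangent stiffness + lumped barycentric mass of a triangle mesh.
# Standard FEM discretization: K[u,v] = -(cot a + cot b)/2 for edge (u,v)
# shared by angles a, b opposite the edge; M[u,u] = sum of adjacent triangle
# areas / 3.
cotan_laplacian <- function(mesh) {
  V <- mesh$vertices
  Tm <- mesh$triangles
  n <- mesh$n_vertices
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  mass <- numeric(n)
  p1 <- V[Tm[, 1L], , drop = FALSE]
  p2 <- V[Tm[, 2L], , drop = FALSE]
  p3 <- V[Tm[, 3L], , drop = FALSE]
  cross3 <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  cr <- cross3(p2 - p1, p3 - p1)
  area <- 0.5 * sqrt(rowSums(cr^2))
  if (any(area <= 0))
    stop("zero-area triangle encountered", call. = FALSE)
  for (k in 1:3) {
    mass_k <- area / 3
    idx <- Tm[, k]
    mass <- mass + as.vector(tapply(mass_k, factor(idx, levels = seq_len(n)),
                                    sum, default = 0))
  }
  # cotangent of the angle at each corner; corner k is opposite edge (k+1,k+2)
  corners <- list(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
  for (cc in corners) {
    a <- V[Tm[, cc[1L]], , drop = FALSE]
    b <- V[Tm[, cc[2L]], , drop = FALSE]
    c3 <- V[Tm[, cc[3L]], , drop = FALSE]
    u <- b - a; w <- c3 - a
    cot <- rowSums(u * w) / sqrt(pmax(rowSums(cross3(u, w)^2), 1e-300))
    half <- cot / 2
    ii <- c(ii, Tm[, cc[2L]], Tm[, cc[3L]])
    jj <- c(jj, Tm[, cc[3L]], Tm[, cc[2L]])
    xx <- c(xx, -half, -half)
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::diag(K) <- -Matrix::rowSums(K)
  list(stiffness = K, mass = mass)
}

#' @export
print.lb_eigenbasis <- function(x, ...) {
  cat("lb_eigenbasis:", x$n_modes, "modes over", nrow(x$functions),
      "vertices; lambda in [", format(min(x$values), digits = 3), ",",
      format(max(x$values), digits = 3), "]\n")
  invisible(x)
}

#' Boundary triangles of a parcellation
#'
#' A triangle is a boundary triangle iff its three vertices carry two or
#' more distinct parcel labels. The map is invariant under relabeling.
#'
#' @param mesh a [surface_mesh()].
#' @param parcellation a [parcellation()] (or bare integer vector of
#'   per-vertex labels) covering all mesh vertices.
#' @return integer 0/1 vector, one entry per triangle.
#' @export
boundary_triangles <- function(mesh, parcellation) {
  stopifnot(inherits(mesh, "surface_mesh"))
  labels <- parcel_labels(parcellation)
  if (length(labels) != mesh$n_vertices)
    stop("parcellation covers ", length(labels), " vertices but mesh has ",
         mesh$n_vertices, call. = FALSE)
  tri <- mesh$triangles
  l1 <- labels[tri[, 1L]]; l2 <- labels[tri[, 2L]]; l3 <- labels[tri[, 3L]]
  as.integer(l1 != l2 | l1 != l3 | l2 != l3)
}
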