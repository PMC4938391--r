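#' Regular triangulated grid mesh
#'
#' An `n x n` vertex grid in the z = 0 plane with unit spacing; every cell
#' is split into two triangles along the fixed lower-left to upper-right
#' diagonal, so interior vertices have exactly 6 neighbors and neighbor
#' counts are deterministic. Stand-in for a square cortical surface patch.
#'
#' @param n vertices per side, `n >= 2`.
#' @return a [surface_mesh()] with `n^2` vertices and `2 (n-1)^2`
#'   positively oriented triangles. Vertex `(i, j)` (0-based grid
#'   coordinates, x = i, y = j) has 1-based index `j * n + i + 1`.
#' @export
make_grid_mesh <- function(n) {
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be >= 2", call. = FALSE)
  ij <- expand.grid(i = 0:(n - 1L), j = 0:(n - 1L))
  vertices <- cbind(ij$i, ij$j, 0)
  vid <- function(i, j) j * n + i + 1L
  cells <- expand.grid(i = 0:(n - 2L), j = 0:(n - 2L))
  v00 <- vid(cells$i, cells$j)
  v10 <- vid(cells$i + 1L, cells$j)
  v01 <- vid(cells$i, cells$j + 1L)
  v11 <- vid(cells$i + 1L, cells$j + 1L)
  triangles <- rbind(cbind(v00, v10, v11),  # lower-right triangle
                     cbind(v00, v11, v01))  # upper-left triangle
  surface_mesh(vertices, triangles)
}

#' Quadrant membership of grid-mesh vertices
#'
#' Quadrants of the square patch, numbered 1 = lower-left, 2 = lower-right,
#' 3 = upper-left, 4 = upper-right (split at `n/2` in grid coordinates).
#'
#' @param mesh a [make_grid_mesh()] result.
#' @return integer vector of quadrant labels per vertex.
#' @export
grid_quadrants <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  x <- mesh$vertices[, 1L]; y <- mesh$vertices[, 2L]
  n <- round(sqrt(mesh$n_vertices))
  half <- n / 2
  1L + (x >= half) + 2L * (y >= half)
}

#' Simulation design for the four-quadrant patch
#'
#' Describes a square patch whose quadrants carry internally correlated,
#' mutually decorrelated (or anti-correlated) time series — the structure
#' of four functionally distinct cortical regions. Optionally a quadrant is
#' subdivided into horizontal sub-block strips, each with its own latent
#' signal, planting finer functional structure.
#'
#' Latent signals are AR(1) processes (`phi = 0.9` by default, mimicking
#' BOLD autocorrelation) with unit stationary variance; latents of
#' different quadrants correlate at `cross_corr`, latents of sub-blocks
#' within one quadrant at `within_corr`.
#'
#' @param n grid side (even, `>= 4`).
#' @param T_len number of time samples.
#' @param sub_blocks integer vector of length 4: number of latent
#'   sub-blocks per quadrant (1 = homogeneous quadrant).
#' @param cross_corr target correlation between latents of different
#'   quadrants, in `[-1, 1]`.
#' @param within_corr target correlation between sub-block latents of the
#'   same quadrant.
#' @param noise_sd standard deviation of i.i.d. vertex noise added to the
#'   unit-variance latent (noise_sd = 1 gives SNR 1).
#' @param ar_phi AR(1) coefficient of the latents.
#' @param seed integer seed; the simulation is fully determined by it.
#' @return object of class `quadrant_sim_spec`.
#' @export
quadrant_sim_spec <- function(n = 20L, T_len = 300L,
                              sub_blocks = c(1L, 1L, 1L, 1L),
                              cross_corr = 0, within_corr = 0.4,
                              noise_sd = 1, ar_phi = 0.9, seed = 1L) {
  n <- as.integer(n); T_len <- as.integer(T_len)
  sub_blocks <- as.integer(sub_blocks)
  if (n < 4L || n %% 2L != 0L) stop("`n` must be even and >= 4",
                                    call. = FALSE)
  if (length(sub_blocks) != 4L || any(sub_blocks < 1L))
    stop("`sub_blocks` must be 4 positive counts", call. = FALSE)
  if (abs(cross_corr) > 1 || abs(within_corr) > 1)
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (T_len < 2L * sum(sub_blocks))
    stop("T_len = ", T_len, " too small for ", sum(sub_blocks),
         " latent components", call. = FALSE)
  structure(
    list(n = n, T_len = T_len, sub_blocks = sub_blocks,
         cross_corr = cross_corr, within_corr = within_corr,
         noise_sd = noise_sd, ar_phi = ar_phi, seed = as.integer(seed)),
    class = "quadrant_sim_spec"
  )
}

# region (sub-block) id per vertex: quadrants ordered 1..4, sub-blocks are
# horizontal strips (by y) within a quadrant
region_labels <- function(mesh, spec) {
  quad <- grid_quadrants(mesh)
  y <- mesh$vertices[, 2L]
  n <- spec$n; half <- n / 2
  region <- integer(mesh$n_vertices)
  offset <- 0L
  for (q in 1:4) {
    nb <- spec$sub_blocks[q]
    idx <- quad == q
    y0 <- ifelse(q <= 2L, 0, half)  # quadrant's y range start
    strip <- pmin(floor((y[idx] - y0) / (half / nb)), nb - 1L)
    region[idx] <- offset + strip + 1L
    offset <- offset + nb
  }
  list(region = region, quadrant = quad)
}

# correlated AR(1) latents: z_t = phi z_{t-1} + sqrt(1-phi^2) C e_t with
# C C' = R, so the stationary cross-correlation matrix is R
simulate_latents <- function(T_len, R, phi) {
  L <- nrow(R)
  Cf <- chol_psd(R)
  E <- matrix(stats::rnorm(T_len * L), T_len, L) %*% t(Cf)
  Z <- matrix(0, T_len, L)
  Z[1L, ] <- E[1L, ]
  a <- sqrt(1 - phi^2)
  for (t in 2:T_len) Z[t, ] <- phi * Z[t - 1L, ] + a * E[t, ]
  Z
}

chol_psd <- function(R) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(ch)) return(t(ch))
  ee <- eigen(R, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  ee$vectors %*% diag(sqrt(vals), nrow = length(vals))
}

#' Simulate a four-quadrant time-series field with planted regions
#'
#' Each vertex receives its region's latent AR(1) signal plus independent
#' Gaussian noise, then the field is standardized. Ground-truth quadrant
#' and region (sub-block) labels are returned alongside.
#'
#' @param mesh a [make_grid_mesh()] with side `spec$n`.
#' @param spec a [quadrant_sim_spec()].
#' @return list with elements `field` (standardized [ts_field()]),
#'   `quadrant` ([parcellation()] of the 4 quadrants), `region`
#'   ([parcellation()] of the sub-block regions; equals `quadrant` when no
#'   sub-blocks), and `spec`.
#' @export
simulate_quadrant_field <- function(mesh, spec) {
  stopifnot(inherits(mesh, "surface_mesh"),
            inherits(spec, "quadrant_sim_spec"))
  if (mesh$n_vertices != spec$n^2)
    stop("mesh has ", mesh$n_vertices, " vertices; spec expects ",
         spec$n^2, call. = FALSE)
  lab <- region_labels(mesh, spec)
  L <- sum(spec$sub_blocks)
  # latent correlation: within_corr inside a quadrant, cross_corr across
  quad_of_region <- rep(1:4, spec$sub_blocks)
  R <- matrix(spec$cross_corr, L, L)
  same_q <- outer(quad_of_region, quad_of_region, `==`)
  R[same_q] <- spec$within_corr
  diag(R) <- 1
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  Z <- simulate_latents(spec$T_len, R, spec$ar_phi)
  X <- t(Z)[lab$region, , drop = FALSE]
  if (spec$noise_sd > 0)
    X <- X + spec$noise_sd *
      matrix(stats::rnorm(length(X)), nrow(X), ncol(X))
  field <- standardize(ts_field(X))
  list(
    field = field,
    quadrant = parcellation(lab$quadrant, K = 4L, method = "truth",
                            params = list(kind = "quadrant"),
                            seed = spec$seed),
    region = parcellation(lab$region, K = L, method = "truth",
                          params = list(kind = "region"),
                          seed = spec$seed),
    spec = spec
  )
}

#' Simulate a test-retest session pair
#'
#' Two independent realizations (latents and noise) of the same planted
#' design, sharing ground-truth labels — the desk-scale analogue of two
#' resting-state sessions of one subject, for concordance experiments.
#'
#' @param spec a [quadrant_sim_spec()] (its own `seed` is ignored).
#' @param seed_a,seed_b seeds for the two sessions.
#' @return list with `a`, `b` (each a [simulate_quadrant_field()] result on
#'   a shared mesh), `mesh`, `quadrant`, `region`.
#' @export
simulate_session_pair <- function(spec, seed_a, seed_b) {
  stopifnot(inherits(spec, "quadrant_sim_spec"))
  mesh <- make_grid_mesh(spec$n)
  spec_a <- spec; spec_a$seed <- as.integer(seed_a)
  spec_b <- spec; spec_b$seed <- as.integer(seed_b)
  a <- simulate_quadrant_field(mesh, spec_a)
  b <- simulate_quadrant_field(mesh, spec_b)
  list(a = a, b = b, mesh = mesh, quadrant = a$quadrant, region = a$region)
}
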