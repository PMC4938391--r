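#' Construct a parcellation
#'
#' A parcellation assigns every vertex to exactly one of `K` disjoint
#' classes (functional networks). Labels are integers `1..K` in memory;
#' on-disk formats use 0-based labels.
#'
#' @param labels integer vector, one label per vertex.
#' @param K number of classes; defaults to the number of distinct labels.
#' @param method,params,seed provenance metadata.
#' @return object of class `parcellation`.
#' @export
parcellation <- function(labels, K = length(unique(labels)),
                         method = "manual", params = list(), seed = NA) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels must not contain NA", call. = FALSE)
  structure(
    list(labels = labels, K = as.integer(K), method = method,
         params = params, seed = seed),
    class = "parcellation"
  )
}

# accept a parcellation object or a bare label vector
parcel_labels <- function(p) {
  if (inherits(p, "parcellation")) p$labels
  else if (is.numeric(p)) as.integer(p)
  else stop("expected a parcellation or an integer label vector",
            call. = FALSE)
}

#' @export
print.parcellation <- function(x, ...) {
  cat("parcellation:", length(x$labels), "vertices in", x$K,
      "classes (method:", x$method, ")\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a parcellation into a vertex/label table
#'
#' @param x a [parcellation()].
#' @param ... unused.
#' @return tibble with columns `vertex` (1-based) and `label`.
#' @method tidy parcellation
#' @export
tidy.parcellation <- function(x, ...) {
  tibble::tibble(vertex = seq_along(x$labels), label = x$labels)
}

#' One-row summary of a parcellation
#'
#' @param x a [parcellation()].
#' @param graph optional [affinity_matrix()] on the same vertices; when
#'   given, the normalized-association score is included.
#' @param ... unused.
#' @method glance parcellation
#' @export
glance.parcellation <- function(x, graph = NULL, ...) {
  tibble::tibble(
    n_vertices = length(x$labels),
    K = x$K,
    n_nonempty = length(unique(x$labels)),
    min_size = min(tabulate(x$labels, nbins = max(x$labels))[unique(x$labels)]),
    nassoc = if (is.null(graph)) NA_real_ else nassoc_score(graph, x),
    method = x$method
  )
}

#' Correlation-affinity graph over all vertex pairs
#'
#' Builds the fully connected graph `G = (V, A)` whose edge strength between
#' vertices `u` and `v` is `A(u, v) = exp(d(u)'d(v) / T)`; for standardized
#' series this is `exp(corr(u, v))`, so entries lie in
#' `[exp(-1), exp(1)]` with diagonal `exp(1)`. No sparsification and no
#' spatial edges: all pairwise functional similarity enters the graph.
#'
#' @param field standardized [ts_field()].
#' @return object of class `affinity_graph`: dense symmetric matrix with
#'   attribute `n`.
#' @export
affinity_matrix <- function(field) {
  stopifnot(inherits(field, "ts_field"))
  if (!field$standardized)
    stop("`field` must be standardized", call. = FALSE)
  n <- field$n_vertices
  if (n > 15000L)
    warning("dense affinity over ", n, " vertices needs ~",
            round(8 * n^2 / 2^30, 1), " GiB", call. = FALSE)
  if (any(field$zero_var))
    warning(sum(field$zero_var),
            " zero-variance vertices enter with corr 0 (edge strength 1)",
            call. = FALSE)
  C <- tcrossprod(field$data) / field$n_time
  C[field$zero_var, ] <- 0
  C[, field$zero_var] <- 0
  diag(C) <- 1
  A <- exp(C)
  A <- (A + t(A)) / 2
  class(A) <- c("affinity_graph", class(A))
  A
}

#' Normalized association score of a partition
#'
#' The N-cuts objective: `Nassoc = (1/K) * sum_i [assoc(V_i, V_i) /
#' assoc(V_i, V)]`, where `assoc(X, Y)` sums edge strengths `A(u, v)` over
#' `u in X, v in Y` (self-loops included). Lies in `(0, 1]`; equals 1 only
#' when there is no between-class affinity.
#'
#' @param graph an [affinity_matrix()] (any symmetric matrix accepted).
#' @param parcellation a [parcellation()] or label vector covering all
#'   graph vertices.
#' @return scalar score.
#' @export
nassoc_score <- function(graph, parcellation) {
  A <- unclass(graph)
  labels <- parcel_labels(parcellation)
  n <- nrow(A)
  if (length(labels) != n)
    stop("labels cover ", length(labels), " vertices but graph has ", n,
         call. = FALSE)
  classes <- sort(unique(labels))
  K <- if (inherits(parcellation, "parcellation")) parcellation$K
       else length(classes)
  if (length(classes) < K)
    stop("degenerate partition: ", K - length(classes), " empty class(es)",
         call. = FALSE)
  rs <- rowSums(A)
  total <- 0
  for (cl in classes) {
    idx <- labels == cl
    within <- sum(A[idx, idx])
    denom <- sum(rs[idx])
    total <- total + within / denom
  }
  total / K
}

#' Normalized-cuts spectral partitioning
#'
#' Multiclass spectral clustering in the Yu-Shi style: the top-`K`
#' eigenvectors of the symmetrically normalized affinity
#' `D^{-1/2} A D^{-1/2}` give a continuous relaxation of the indicator
#' matrix, which is discretized to labels two ways — iterative rotation
#' (alternating argmax assignment and orthogonal Procrustes alignment) and
#' seeded k-means on the row-normalized embedding — keeping whichever
#' scores higher on the normalized-association objective. Deterministic
#' given `seed`.
#'
#' A constant-affinity graph carries no partition information; in that
#' degenerate case contiguous index blocks are returned with a
#' non-identifiability warning.
#'
#' @param graph an [affinity_matrix()].
#' @param K number of classes, `2 <= K <= n`.
#' @param seed integer seed controlling the discretization initialization.
#' @return a [parcellation()] with attribute-level provenance and element
#'   `nassoc` in `params` (the achieved normalized-association score).
#' @export
ncuts_partition <- function(graph, K, seed = 1L) {
  A <- unclass(graph)
  n <- nrow(A)
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  if (K > n) stop("K = ", K, " exceeds n = ", n, call. = FALSE)
  if (max(A) - min(A) < 1e-12 * max(abs(A))) {
    warning("constant affinity: partition is non-identifiable; ",
            "returning contiguous index blocks", call. = FALSE)
    labels <- cut(seq_len(n), breaks = K, labels = FALSE)
    p <- parcellation(labels, K = K, method = "ncuts-degenerate",
                      seed = seed)
    p$params$nassoc <- nassoc_score(A, p)
    return(p)
  }
  d <- rowSums(A)
  dis <- 1 / sqrt(d)
  S <- A * tcrossprod(dis)
  S <- (S + t(S)) / 2
  ee <- eigen(S, symmetric = TRUE)
  U <- ee$vectors[, seq_len(K), drop = FALSE]
  # row-normalized embedding
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  Xh <- U / rn
  # two discretizations behind the same seed; keep the one that scores
  # higher on the objective being maximized
  cand <- list(ncuts_discretize(Xh, K, seed),
               ncuts_kmeans_fallback(Xh, K, seed))
  cand <- Filter(function(l) length(unique(l)) == K, cand)
  if (length(cand) == 0L)
    stop("N-cuts discretization failed to produce ", K,
         " non-empty classes", call. = FALSE)
  scores <- vapply(cand, function(l) nassoc_score(A, l), 0)
  labels <- cand[[which.max(scores)]]
  p <- parcellation(labels, K = K, method = "ncuts",
                    params = list(nassoc = max(scores)), seed = seed)
  p
}

# Yu-Shi rotation-based discretization of the spectral embedding.
# Alternates hard assignment (argmax of X R) with the orthogonal Procrustes
# solution for R until the assignment objective stabilizes.
ncuts_discretize <- function(Xh, K, seed, max_iter = 200L) {
  n <- nrow(Xh)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  # farthest-first initialization of the rotation columns
  R <- matrix(0, K, K)
  first <- sample.int(n, 1L)
  R[, 1L] <- Xh[first, ]
  cost <- rep(0, n)
  for (j in seq_len(K - 1L)) {
    cost <- cost + abs(Xh %*% R[, j, drop = FALSE])[, 1L]
    R[, j + 1L] <- Xh[which.min(cost), ]
  }
  last_obj <- -Inf
  labels <- NULL
  for (it in seq_len(max_iter)) {
    XR <- Xh %*% R
    labels <- max.col(XR, ties.method = "first")
    Ind <- matrix(0, n, K)
    Ind[cbind(seq_len(n), labels)] <- 1
    sv <- svd(crossprod(Ind, Xh))
    obj <- sum(sv$d)
    R <- t(sv$u %*% t(sv$v))
    if (abs(obj - last_obj) < 1e-10) break
    last_obj <- obj
  }
  labels
}

ncuts_kmeans_fallback <- function(Xh, K, seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer((seed + 1L) %% .Machine$integer.max))
  km <- stats::kmeans(Xh, centers = K, nstart = 20L, iter.max = 100L)
  km$cluster
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
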