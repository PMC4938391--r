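# Independent oracles used across tests. These are deliberately naive
# (loops, enumeration, dense matrix exponentials) and share no code with
# the implementation paths they check.

# direct double-summation of the normalized-association objective
brute_nassoc <- function(A, labels) {
  classes <- unique(labels)
  total <- 0
  for (cl in classes) {
    num <- 0
    den <- 0
    for (u in which(labels == cl)) {
      for (v in which(labels == cl)) num <- num + A[u, v]
      for (v in seq_len(nrow(A))) den <- den + A[u, v]
    }
    total <- total + num / den
  }
  total / length(classes)
}

# all 2-partitions of n nodes (both classes non-empty), as 1/2 label rows
all_2partitions <- function(n) {
  masks <- 1:(2^(n - 1L) - 1L)  # fix node n in class 1 to kill the symmetry
  t(vapply(masks, function(m)
    c(as.integer(bitwAnd(m, 2^(0:(n - 2L))) > 0), 0L) + 1L,
    integer(n)))
}

# exhaustive optimum of the normalized association over 2-partitions
exhaustive_nassoc_opt <- function(A) {
  parts <- all_2partitions(nrow(A))
  best <- -Inf
  for (i in seq_len(nrow(parts))) {
    v <- brute_nassoc(A, parts[i, ])
    if (v > best) best <- v
  }
  best
}

# planted 2-block affinity on n nodes: exp(within_corr) inside blocks,
# exp(between_corr) across, exp(1) diagonal
planted_block_graph <- function(n, within = 0.9, between = -0.5) {
  half <- n %/% 2L
  labels <- rep(1:2, c(half, n - half))
  A <- exp(ifelse(outer(labels, labels, `==`), within, between))
  diag(A) <- exp(1)
  list(A = A, labels = labels)
}

# dense heat-kernel smoothing oracle: expm(-t M^{-1} K) f per column
expm_heat_oracle <- function(mesh, X, t) {
  KM <- tnlm:::cotan_laplacian(mesh)
  L <- diag(1 / as.vector(KM$mass)) %*% as.matrix(KM$stiffness)
  as.matrix(Matrix::expm(-t * L) %*% X)
}

# standardized random series (population variance 1)
rand_standardized <- function(T_len) {
  x <- stats::rnorm(T_len)
  (x - mean(x)) / sqrt(mean((x - mean(x))^2))
}

# hand-built neighborhood table (list of 1-based index vectors)
manual_nbrs <- function(lst, D = 1L) {
  structure(lapply(lst, as.integer), D = D, class = "neighborhood_table")
}

# a 2-triangle strip mesh: vertices 1-2-3-4, triangles (1,2,3), (1,3,4)
strip_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
}

# check Gale-Shapley stability: no pair (a, b) not matched together where
# both prefer each other (by overlap, ties to smaller ID) over partners
has_blocking_pair <- function(match, ov) {
  la <- as.integer(rownames(ov)); lb <- as.integer(colnames(ov))
  map <- match$mapping
  partner_of_a <- stats::setNames(map$label_b, map$label_a)
  partner_of_b <- stats::setNames(map$label_a, map$label_b)
  pref <- function(ovec, ids, cand, cur) {
    # does the owner of ovec prefer cand over cur (NA cur = unmatched)?
    if (is.na(cur)) return(TRUE)
    oc <- ovec[match(cand, ids)]; ou <- ovec[match(cur, ids)]
    oc > ou || (oc == ou && cand < cur)
  }
  for (a in la) {
    for (b in lb) {
      pa <- unname(partner_of_a[as.character(a)])
      pb <- unname(partner_of_b[as.character(b)])
      if (!is.na(pa) && pa == b) next
      a_wants <- pref(ov[as.character(a), ], lb, b,
                      if (is.na(pa)) NA else pa)
      b_wants <- pref(ov[, as.character(b)], la, a,
                      if (is.na(pb)) NA else pb)
      if (a_wants && b_wants) return(TRUE)
    }
  }
  FALSE
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# quadrant seam hop-distances on a grid mesh (oracle via igraph BFS)
seam_hop_distance <- function(mesh) {
  quad <- grid_quadrants(mesh)
  A <- suppressWarnings(build_vertex_adjacency(mesh))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  seam <- which(vapply(seq_len(mesh$n_vertices), function(v)
    any(quad[igraph::neighbors(g, v)] != quad[v]), TRUE))
  apply(igraph::distances(g, to = seam), 1L, min)
}
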