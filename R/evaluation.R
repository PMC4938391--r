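#' Overlap (contingency) table between two parcellations
#'
#' @param parcA,parcB [parcellation()]s (or label vectors) on the same
#'   vertex set.
#' @return integer matrix, rows = labels of A, columns = labels of B,
#'   entries = shared vertex counts; dimnames carry the label IDs.
#' @export
overlap_table <- function(parcA, parcB) {
  a <- parcel_labels(parcA); b <- parcel_labels(parcB)
  if (length(a) != length(b))
    stop("parcellations cover different vertex sets (", length(a), " vs ",
         length(b), " vertices)", call. = FALSE)
  tab <- table(factor(a, levels = sort(unique(a))),
               factor(b, levels = sort(unique(b))))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Gale-Shapley stable matching of parcellation labels
#'
#' Establishes a one-to-one correspondence between the labels of two
#' parcellations. Each side ranks the other side's labels by raw overlap
#' vertex count (descending), ties broken toward the smaller label ID; side
#' A proposes. The result is stable: no unmatched-together pair prefers
#' each other over their assigned partners. When label counts differ, the
#' excess labels stay unmatched. Deterministic.
#'
#' @param parcA,parcB [parcellation()]s or label vectors on the same
#'   vertex set; A is the proposing (reference) side.
#' @return object of class `match_result`: tibble `mapping` with columns
#'   `label_a`, `label_b`, `overlap`; plus `unmatched_a`, `unmatched_b`.
#' @export
stable_match <- function(parcA, parcB) {
  ov <- overlap_table(parcA, parcB)
  la <- as.integer(rownames(ov)); lb <- as.integer(colnames(ov))
  nA <- length(la); nB <- length(lb)
  # preference orders: overlap desc, then smaller counterpart label ID
  prefA <- lapply(seq_len(nA), function(i) order(-ov[i, ], lb))
  rankB <- lapply(seq_len(nB), function(j) {
    o <- order(-ov[, j], la)   # B j's preference over A labels
    r <- integer(nA); r[o] <- seq_len(nA); r
  })
  partnerA <- rep(NA_integer_, nA)  # index into lb
  partnerB <- rep(NA_integer_, nB)  # index into la
  next_prop <- rep(1L, nA)
  free <- seq_len(nA)
  while (length(free) > 0L) {
    i <- free[1L]
    if (next_prop[i] > nB) { free <- free[-1L]; next }  # exhausted: unmatched
    j <- prefA[[i]][next_prop[i]]
    next_prop[i] <- next_prop[i] + 1L
    cur <- partnerB[j]
    if (is.na(cur)) {
      partnerB[j] <- i; partnerA[i] <- j
      free <- free[-1L]
    } else if (rankB[[j]][i] < rankB[[j]][cur]) {
      partnerB[j] <- i; partnerA[i] <- j
      partnerA[cur] <- NA_integer_
      free <- c(free[-1L], cur)
    }
  }
  matched <- which(!is.na(partnerA))
  mapping <- tibble::tibble(
    label_a = la[matched],
    label_b = lb[partnerA[matched]],
    overlap = ov[cbind(matched, partnerA[matched])]
  )
  mapping <- mapping[order(mapping$label_a), , drop = FALSE]
  structure(
    list(mapping = mapping,
         unmatched_a = la[is.na(partnerA)],
         unmatched_b = lb[is.na(partnerB)],
         overlap = ov),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat("match_result:", nrow(x$mapping), "matched label pairs")
  if (length(x$unmatched_a)) cat(";", length(x$unmatched_a), "unmatched in A")
  if (length(x$unmatched_b)) cat(";", length(x$unmatched_b), "unmatched in B")
  cat("\n")
  print(x$mapping)
  invisible(x)
}

#' @method tidy match_result
#' @export
tidy.match_result <- function(x, ...) x$mapping

#' Concordance between two parcellations
#'
#' Fraction of vertices whose labels agree after the one-to-one
#' [stable_match()] relabeling (the first-listed parcellation proposes).
#' Vertices of unmatched labels count as disagreements.
#'
#' @param parcA,parcB [parcellation()]s or label vectors on the same
#'   vertex set.
#' @param both_directions when `TRUE`, also return the B-proposing value
#'   (the two can differ slightly through tie-breaking).
#' @return scalar in `[0, 1]`, or a named vector of both directions.
#' @export
concordance <- function(parcA, parcB, both_directions = FALSE) {
  ab <- concordance_one(parcA, parcB)
  if (!both_directions) return(ab)
  c(a_proposes = ab, b_proposes = concordance_one(parcB, parcA))
}

concordance_one <- function(parcA, parcB) {
  a <- parcel_labels(parcA); b <- parcel_labels(parcB)
  m <- stable_match(a, b)
  map <- m$mapping
  # relabel B into A's label space; unmatched B labels -> NA (disagree)
  lookup <- stats::setNames(map$label_a, map$label_b)
  b_as_a <- lookup[as.character(b)]
  mean(!is.na(b_as_a) & b_as_a == a)
}

#' Build a task label map from Z-score activation maps
#'
#' Thresholds each per-vertex Z map at `z_thresh`, merges into one labeled
#' map by assigning each supra-threshold vertex the label of its most
#' significant map (argmax of Z), then removes isolated labeled patches
#' (connected components of same-label vertices under mesh-edge adjacency)
#' of `min_patch` vertices or fewer. Label 0 means unlabeled. Idempotent.
#'
#' @param zmaps numeric matrix, vertices x maps (or list of vectors).
#' @param mesh a [surface_mesh()] supplying vertex connectivity.
#' @param z_thresh Z threshold; the default 3.0 corresponds to a one-tailed
#'   uncorrected p of about 0.00135.
#' @param min_patch patches of this many vertices *or fewer* are removed.
#' @return object of class `task_label_map`: integer labels (0 = none),
#'   with attributes `z_thresh`, `min_patch`, `n_maps`.
#' @export
build_task_label_map <- function(zmaps, mesh, z_thresh = 3.0,
                                 min_patch = 40L) {
  if (is.list(zmaps) && !is.data.frame(zmaps))
    zmaps <- do.call(cbind, zmaps)
  zmaps <- as.matrix(zmaps)
  if (ncol(zmaps) == 0L || nrow(zmaps) == 0L)
    stop("`zmaps` is empty", call. = FALSE)
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(zmaps) != mesh$n_vertices)
    stop("zmaps cover ", nrow(zmaps), " vertices but mesh has ",
         mesh$n_vertices, call. = FALSE)
  best <- max.col(zmaps, ties.method = "first")
  bestz <- zmaps[cbind(seq_len(nrow(zmaps)), best)]
  labels <- ifelse(bestz >= z_thresh, best, 0L)
  labels <- remove_small_patches(labels, mesh, min_patch)
  structure(as.integer(labels), z_thresh = z_thresh,
            min_patch = as.integer(min_patch), n_maps = ncol(zmaps),
            class = "task_label_map")
}

# drop connected same-label components of size <= min_patch (label -> 0)
remove_small_patches <- function(labels, mesh, min_patch) {
  A <- suppressWarnings(build_vertex_adjacency(mesh))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  for (lab in setdiff(unique(labels), 0L)) {
    idx <- which(labels == lab)
    sub <- igraph::induced_subgraph(g, idx)
    comp <- igraph::components(sub)
    small <- which(comp$csize <= min_patch)
    if (length(small))
      labels[idx[comp$membership %in% small]] <- 0L
  }
  labels
}

#' @export
print.task_label_map <- function(x, ...) {
  cat("task_label_map:", length(x), "vertices;",
      sum(x > 0), "labeled across", length(setdiff(unique(x), 0L)),
      "task labels (Z >=", attr(x, "z_thresh"),
      ", min patch >", attr(x, "min_patch"), ")\n")
  invisible(x)
}

#' Task-label agreement fraction
#'
#' For each task label `l`, matched by [stable_match()] (task side
#' proposing) to resting-state parcel `p`: the fraction of `l`'s vertices
#' lying in `p`. The fraction is of the task label, not of the parcel, so a
#' small task region fully inside a large parcel scores 1.
#'
#' @param task a [build_task_label_map()] result (or labeled vector, 0 =
#'   unlabeled).
#' @param parcellation a [parcellation()] on the same vertices.
#' @return tibble with columns `task_label`, `parcel`, `n_vertices`,
#'   `agreement`.
#' @export
agreement_fraction <- function(task, parcellation) {
  tl <- as.integer(task)
  pl <- parcel_labels(parcellation)
  if (length(tl) != length(pl))
    stop("task map and parcellation cover different vertex sets",
         call. = FALSE)
  keep <- tl > 0L
  if (!any(keep)) {
    warning("no labeled task vertices", call. = FALSE)
    return(tibble::tibble(task_label = integer(), parcel = integer(),
                          n_vertices = integer(), agreement = numeric()))
  }
  m <- stable_match(tl[keep], pl[keep])
  map <- m$mapping
  out <- lapply(seq_len(nrow(map)), function(i) {
    l <- map$label_a[i]; p <- map$label_b[i]
    in_l <- tl == l
    tibble::tibble(task_label = l, parcel = p,
                   n_vertices = sum(in_l),
                   agreement = sum(in_l & pl == p) / sum(in_l))
  })
  do.call(rbind, out)
}

#' Cumulative boundary map across parcellations
#'
#' Sums per-triangle boundary indicators ([boundary_triangles()]) across a
#' list of parcellations (e.g. the N-cuts results for
#' K = 2,...,10,15,30,40,50,60,80), giving, for each triangle, the number
#' of parcellations in which it sat on a parcel boundary.
#'
#' @param parcellations non-empty list of [parcellation()]s / label vectors.
#' @param mesh the common [surface_mesh()].
#' @return object of class `boundary_count_map`: integer vector per
#'   triangle with attribute `n_parcellations`.
#' @export
cumulative_boundary_map <- function(parcellations, mesh) {
  if (length(parcellations) == 0L)
    stop("`parcellations` is empty", call. = FALSE)
  counts <- Reduce(`+`, lapply(parcellations, boundary_triangles,
                               mesh = mesh))
  structure(as.integer(counts),
            n_parcellations = length(parcellations),
            class = "boundary_count_map")
}

#' @export
print.boundary_count_map <- function(x, ...) {
  cat("boundary_count_map:", length(x), "triangles, counts in [0,",
      attr(x, "n_parcellations"), "]; ", sum(x > 0),
      "ever-boundary triangles\n")
  invisible(x)
}

#' @method tidy boundary_count_map
#' @export
tidy.boundary_count_map <- function(x, ...) {
  tibble::tibble(triangle = seq_along(x), count = as.integer(x))
}
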