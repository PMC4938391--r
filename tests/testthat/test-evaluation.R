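test_that("stable matching recovers label permutations perfectly", {
  set.seed(505)
  a <- sample(1:4, 60, replace = TRUE)
  perm <- c(3L, 4L, 2L, 1L)
  m <- stable_match(a, perm[a])
  expect_equal(nrow(m$mapping), 4)
  expect_equal(m$mapping$label_b, perm[m$mapping$label_a])
  sizes <- as.integer(table(a))
  expect_equal(m$mapping$overlap, sizes[m$mapping$label_a])
  expect_length(m$unmatched_a, 0)
})

test_that("cardinality gaps leave labels unmatched", {
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 3, 3)
  m <- stable_match(a, b)
  expect_equal(nrow(m$mapping), 2)
  expect_length(m$unmatched_b, 1)
  expect_length(m$unmatched_a, 0)
})

test_that("matching equals optimal assignment under mutual preferences", {
  # 6-vertex hand example: overlaps make preferences mutual and unambiguous
  a <- c(1, 1, 1, 2, 2, 3)
  b <- c(1, 1, 2, 2, 2, 3)
  m <- stable_match(a, b)
  # overlap table: a1:{b1=2,b2=1}, a2:{b2=2}, a3:{b3=1} -> identity match
  expect_equal(m$mapping$label_a, c(1L, 2L, 3L))
  expect_equal(m$mapping$label_b, c(1L, 2L, 3L))
  expect_equal(m$mapping$overlap, c(2L, 2L, 1L))
  # brute force over all injective matchings: identity maximizes total
  # overlap (2+2+1=5); any other assignment totals at most 3
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  ov <- overlap_table(a, b)
  totals <- apply(perms, 1, function(p) sum(ov[cbind(1:3, p)]))
  expect_equal(unname(which.max(totals)), 1L)
})

test_that("returned matchings admit no blocking pair", {
  set.seed(606)
  for (rep in 1:20) {
    nA <- sample(2:6, 1); nB <- sample(2:6, 1)
    a <- sample(seq_len(nA), 40, replace = TRUE)
    b <- sample(seq_len(nB), 40, replace = TRUE)
    a[seq_len(nA)] <- seq_len(nA)  # ensure every label occurs
    b[seq_len(nB)] <- seq_len(nB)
    m <- stable_match(a, b)
    expect_false(has_blocking_pair(m, overlap_table(a, b)))
  }
})

test_that("concordance handles identity, permutation, and hand counts", {
  set.seed(707)
  a <- sample(1:3, 50, replace = TRUE)
  expect_equal(concordance(a, a), 1)
  expect_equal(concordance(a, c(2L, 3L, 1L)[a]), 1)

  # 10 vertices, 3 disagreements after optimal relabel -> 0.7
  pa <- c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2)
  pb <- c(1, 1, 1, 2, 2, 1, 2, 2, 2, 2)  # identity match: 3 + 4 agree
  expect_equal(concordance(pa, pb), 0.7)

  both <- concordance(pa, pb, both_directions = TRUE)
  expect_lt(abs(both[1] - both[2]), 0.1 + 1e-12)
  expect_error(concordance(a, a[-1]), "different vertex sets")
})

test_that("task label maps threshold, take argmax, and prune small patches", {
  n <- 12
  m <- make_grid_mesh(n)  # 144 vertices
  # patch A: 41 connected vertices (rows y=0..2 plus 5 of row y=3)
  patchA <- which(m$vertices[, 2] <= 2 |
                    (m$vertices[, 2] == 3 & m$vertices[, 1] <= 4))
  expect_length(patchA, 41)
  z1 <- rep(0, 144); z1[patchA] <- 5
  tl <- build_task_label_map(cbind(z1), m, z_thresh = 3, min_patch = 40)
  expect_equal(sum(tl > 0), 41)  # 41-vertex patch survives

  # exactly 40 vertices: removed ("40 vertices or less")
  patchB <- patchA[1:40]
  z2 <- rep(0, 144); z2[patchB] <- 5
  tl2 <- build_task_label_map(cbind(z2), m, z_thresh = 3, min_patch = 40)
  expect_equal(sum(tl2 > 0), 0)

  # argmax rule: most significant map wins
  z_a <- rep(3.2, 144); z_b <- rep(4.0, 144)
  tl3 <- build_task_label_map(cbind(z_a, z_b), m)
  expect_true(all(tl3 == 2L))
  # sub-threshold everywhere -> unlabeled
  tl4 <- build_task_label_map(cbind(rep(2.9, 144)), m)
  expect_true(all(tl4 == 0L))
  expect_error(build_task_label_map(matrix(0, 0, 0), m), "empty")
})

test_that("task label map construction is idempotent", {
  set.seed(808)
  m <- make_grid_mesh(10)
  z <- matrix(rnorm(100 * 3, mean = 2), 100, 3)
  tl <- build_task_label_map(z, m, z_thresh = 3, min_patch = 5)
  # re-running on a Z encoding of its own output changes nothing
  z2 <- matrix(0, 100, 3)
  for (lab in 1:3) z2[tl == lab, lab] <- 5
  tl2 <- build_task_label_map(z2, m, z_thresh = 3, min_patch = 5)
  expect_equal(as.integer(tl2), as.integer(tl))
})

test_that("agreement fraction measures task-label capture", {
  # identical maps -> 1 per label
  task <- c(rep(1L, 10), rep(2L, 10))
  expect_true(all(agreement_fraction(task, task)$agreement == 1))

  # task label fully inside a parcel twice its size -> 1.0
  task2 <- c(rep(1L, 5), rep(0L, 15))
  parc2 <- c(rep(1L, 10), rep(2L, 10))
  af2 <- agreement_fraction(task2, parc2)
  expect_equal(af2$agreement, 1)

  # 20-vertex case with 15/20 overlap -> 0.75
  task3 <- rep(1L, 20)
  parc3 <- c(rep(1L, 15), rep(2L, 5))
  af3 <- agreement_fraction(task3, parc3)
  expect_equal(af3$agreement, 0.75)
  expect_equal(af3$n_vertices, 20L)

  expect_warning(agreement_fraction(rep(0L, 10), rep(1L, 10)), "no labeled")
})

test_that("cumulative boundary maps sum boundary indicators", {
  m <- make_grid_mesh(8)
  quad <- grid_quadrants(m)
  halves <- 1L + (m$vertices[, 2] >= 4)  # horizontal split only
  bq <- boundary_triangles(m, quad)
  expect_equal(as.integer(cumulative_boundary_map(list(quad), m)), bq)

  five <- cumulative_boundary_map(rep(list(quad), 5), m)
  expect_true(all(five %in% c(0L, 5L)))
  expect_equal(as.integer(five), 5L * bq)

  # nested quadrant/half splits: the shared horizontal seam counts 2
  both <- cumulative_boundary_map(list(quad, halves), m)
  bh <- boundary_triangles(m, halves)
  expect_equal(as.integer(both), bq + bh)
  expect_true(any(both == 2))
  expect_error(cumulative_boundary_map(list(), m), "empty")
})
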