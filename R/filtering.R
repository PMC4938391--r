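#' Construct a per-vertex time-series field
#'
#' Holds the BOLD signal `d(s, tau)` as a `vertices x T` matrix together
#' with standardization metadata. Most operations expect a standardized
#' field (see [standardize()]).
#'
#' @param data numeric matrix, vertices in rows, time samples in columns.
#' @param standardized logical; `TRUE` when each row has zero mean, unit
#'   population variance.
#' @param zero_var logical vector flagging vertices whose raw series had
#'   zero variance (their standardized series are all-zero).
#' @param tr repetition time in seconds (metadata only).
#' @return object of class `ts_field`.
#' @export
ts_field <- function(data, standardized = FALSE, zero_var = NULL, tr = NA_real_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(zero_var)) zero_var <- rep(FALSE, nrow(data))
  stopifnot(length(zero_var) == nrow(data))
  structure(
    list(data = data, standardized = isTRUE(standardized),
         zero_var = zero_var, tr = tr,
         n_vertices = nrow(data), n_time = ncol(data)),
    class = "ts_field"
  )
}

#' @export
print.ts_field <- function(x, ...) {
  cat("ts_field:", x$n_vertices, "vertices x", x$n_time, "time samples;",
      if (x$standardized) "standardized" else "raw",
      if (any(x$zero_var)) sprintf("(%d zero-variance)", sum(x$zero_var))
      else "", "\n")
  invisible(x)
}

#' Standardize each vertex time series to zero mean, unit variance
#'
#' Uses the population variance (denominator `T`, not `T - 1`): with this
#' normalization the squared distance between two standardized series obeys
#' the exact identity `(1/T) * ||d(s) - d(r)||^2 = 2 - 2 * corr(d(s), d(r))`
#' on which the tNLM weights rely. Vertices with zero variance are mapped to
#' all-zero series and flagged in `zero_var`.
#'
#' @param field a [ts_field()] (or bare matrix).
#' @return standardized `ts_field`.
#' @export
standardize <- function(field) {
  if (is.matrix(field)) field <- ts_field(field)
  stopifnot(inherits(field, "ts_field"))
  X <- field$data
  Tn <- ncol(X)
  if (Tn < 2L) stop("need at least 2 time samples to standardize",
                    call. = FALSE)
  mu <- rowMeans(X)
  Xc <- X - mu
  sd_pop <- sqrt(rowMeans(Xc^2))
  zv <- sd_pop < .Machine$double.eps * 10 * pmax(abs(mu), 1)
  sd_pop[zv] <- 1
  Xs <- Xc / sd_pop
  Xs[zv, ] <- 0
  ts_field(Xs, standardized = TRUE, zero_var = zv, tr = field$tr)
}

#' tNLM weight between two standardized series
#'
#' `w(s, r) = exp(-(1/T) * ||d(s) - d(r)||^2 / h^2)`. For standardized
#' series the exponent equals `-(2 - 2 * corr) / h^2`, so `w` is a strictly
#' increasing function of the Pearson correlation, ranging from
#' `exp(-4/h^2)` (corr = -1) to 1 (corr = 1).
#'
#' @param ds,dr standardized numeric vectors of equal length `T`.
#' @param h positive decay parameter.
#' @return scalar weight in `(0, 1]`.
#' @export
tnlm_weight <- function(ds, dr, h = 0.72) {
  stopifnot(length(ds) == length(dr), h > 0)
  check_standardized_series(ds)
  check_standardized_series(dr)
  Tn <- length(ds)
  exp(-sum((ds - dr)^2) / Tn / h^2)
}

check_standardized_series <- function(x) {
  Tn <- length(x)
  m <- mean(x); v <- sum((x - m)^2) / Tn
  all_zero <- all(x == 0)
  if (!all_zero && (abs(m) > 1e-8 || abs(v - 1) > 1e-6))
    stop("series is not standardized (mean ", format(m),
         ", population variance ", format(v), ")", call. = FALSE)
  invisible(TRUE)
}

#' Temporal non-local means filtering
#'
#' Replaces each vertex series by a weighted average over its linked-distance
#' neighborhood, `f(s, tau) = sum_r d(r, tau) w(s, r) / sum_r w(s, r)` with
#' `r` ranging over `N(s)`. The weights come from full time-series similarity
#' ([tnlm_weight()]), are computed once per vertex pair, and are applied
#' identically at every time point (time-invariant kernel), so edges between
#' functionally distinct regions are preserved rather than blurred.
#'
#' Zero-variance vertices pass through as zeros and do not serve as
#' neighbors of other vertices (their correlation is undefined; an
#' artificial weight would bias the average).
#'
#' @param field standardized [ts_field()].
#' @param nbrs a [linked_neighborhoods()] table built on the same mesh.
#' @param h positive decay parameter; smaller `h` preserves edges harder.
#' @return filtered `ts_field` (not re-standardized).
#' @export
tnlm_filter <- function(field, nbrs, h = 0.72) {
  stopifnot(inherits(field, "ts_field"), inherits(nbrs, "neighborhood_table"))
  if (!field$standardized)
    stop("`field` must be standardized (see standardize())", call. = FALSE)
  if (length(nbrs) != field$n_vertices)
    stop("neighborhood table covers ", length(nbrs),
         " vertices but field has ", field$n_vertices, call. = FALSE)
  stopifnot(h > 0)
  X <- field$data
  n <- nrow(X); Tn <- ncol(X)
  zv <- field$zero_var
  if (any(zv))
    warning(sum(zv), " zero-variance vertices pass through unfiltered",
            call. = FALSE)
  # corr(s, r) = (1/T) d(s).d(r) for standardized rows
  C <- tcrossprod(X) / Tn
  W <- exp(-(2 - 2 * C) / h^2)
  out <- X
  for (s in which(!zv)) {
    r <- nbrs[[s]]
    r <- r[!zv[r] | r == s]
    w <- W[s, r]
    w <- pmax(w, .Machine$double.xmin)
    out[s, ] <- crossprod(X[r, , drop = FALSE], w)[, 1L] / sum(w)
  }
  ts_field(out, standardized = FALSE, zero_var = zv, tr = field$tr)
}

#' Laplace-Beltrami heat-kernel smoothing
#'
#' Linear isotropic smoothing on the surface: each time frame is expanded in
#' the truncated LB eigenbasis, mode `i` is attenuated by `exp(-lambda_i t)`,
#' and the frame is resynthesized. This generalizes Gaussian smoothing to a
#' curved surface; a single diffusion-time parameter `t` controls the degree
#' of smoothing. Applied independently per time point.
#'
#' @param field a [ts_field()] (standardization not required).
#' @param basis an [lb_eigenbasis()] from the same mesh.
#' @param t non-negative diffusion time. `t = 0` projects onto the basis
#'   span (identity when the basis is complete); large `t` drives every
#'   frame to its surface mean.
#' @return smoothed `ts_field`.
#' @export
lb_filter <- function(field, basis, t = 4) {
  if (is.matrix(field)) field <- ts_field(field)
  stopifnot(inherits(field, "ts_field"), inherits(basis, "lb_eigenbasis"),
            t >= 0)
  if (nrow(basis$functions) != field$n_vertices)
    stop("basis has ", nrow(basis$functions), " vertices but field has ",
         field$n_vertices, call. = FALSE)
  Phi <- basis$functions
  # mass-weighted analysis: coef = Phi' M X
  coef <- crossprod(Phi, basis$mass * field$data)
  coef <- coef * exp(-basis$values * t)
  out <- Phi %*% coef
  ts_field(out, standardized = FALSE, zero_var = field$zero_var,
           tr = field$tr)
}
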