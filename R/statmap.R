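# Cluster-based permutation statistics over time courses and 2-D maps
# (delay x time, frequency x time), with paired contrasts and
# double-subtraction interaction tests.

as_subject_maps <- function(x) {
  # accepts subjects x cells matrix, or a list of per-subject vectors /
  # matrices (2-D grids); returns list(mat = subjects x cells, dims)
  if (is.list(x) && !is.data.frame(x)) {
    dims <- dim(x[[1L]]) %||% length(x[[1L]])
    mat <- t(vapply(x, function(m) {
      d <- dim(m) %||% length(m)
      if (!identical(d, dims)) stop("subject grids differ", call. = FALSE)
      as.numeric(m)
    }, numeric(prod(dims))))
    list(mat = mat, dims = dims)
  } else {
    x <- as.matrix(x)
    list(mat = x, dims = ncol(x))
  }
}

#' Paired t map
#'
#' Per grid point, the dependent-samples t statistic and two-sided p value
#' across subjects for condition A minus condition B.  Points with zero
#' within-subject variance but nonzero mean are degenerate; their t is
#' `+/-Inf` (treated as maximal by downstream clustering).
#'
#' @param setA,setB Subjects x cells matrices (or lists of per-subject
#'   grids) with identical subject order and grid.
#' @return List with `t`, `p`, `df`, `dims`.
#' @export
paired_t_map <- function(setA, setB) {
  a <- as_subject_maps(setA)
  b <- as_subject_maps(setB)
  if (!identical(dim(a$mat), dim(b$mat)) || !identical(a$dims, b$dims)) {
    stop("conditions must share subjects and grid", call. = FALSE)
  }
  n <- nrow(a$mat)
  if (n < 5L) stop("need at least 5 subjects", call. = FALSE)
  d <- a$mat - b$mat
  m <- colMeans(d)
  s <- sqrt((colSums(d^2) - n * m^2) / (n - 1))
  t <- m / (s / sqrt(n))
  t[s == 0 & m != 0] <- sign(m[s == 0 & m != 0]) * Inf
  t[s == 0 & m == 0] <- 0
  p <- 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE)
  list(t = t, p = p, df = n - 1L, dims = a$dims)
}

# connected components of a logical mask over a 1-D or 2-D grid
# (1-D: neighbours; 2-D: 4-connectivity).  Returns a list of index vectors.
grid_clusters <- function(mask, dims) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  if (length(dims) == 1L) {
    breaks <- c(0L, which(diff(idx) != 1L), length(idx))
    return(lapply(seq_len(length(breaks) - 1L),
                  function(k) idx[(breaks[k] + 1L):breaks[k + 1L]]))
  }
  nr <- dims[1L]
  lab <- integer(length(mask))
  out <- list()
  for (seed in idx) {
    if (lab[seed]) next
    comp <- integer(0)
    stack <- seed
    lab[seed] <- 1L
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, i)
      r <- ((i - 1L) %% nr) + 1L
      nb <- c(if (r > 1L) i - 1L, if (r < nr) i + 1L, i - nr, i + nr)
      nb <- nb[nb >= 1L & nb <= length(mask)]
      nb <- nb[mask[nb] & !lab[nb]]
      lab[nb] <- 1L
      stack <- c(stack, nb)
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

# shared engine: one-sample (sign-flip) cluster permutation test on the
# subject x cells difference matrix D.  NA cells (e.g. missing delay-time
# combinations) are excluded from clustering and from the null.
cluster_engine <- function(D, dims, point_alpha, n_perm, seed) {
  n <- nrow(D)
  valid <- !col_any_na(D)
  tcrit <- stats::qt(1 - point_alpha / 2, df = n - 1)

  tmap_of <- function(signs) {
    m <- as.numeric(signs %*% D) / n
    s <- sqrt(pmax(ss - n * m^2, 0) / (n - 1))
    t <- m / (s / sqrt(n))
    t[s == 0 & m != 0] <- sign(m[s == 0 & m != 0]) * Inf
    t[s == 0 & m == 0] <- 0
    t
  }
  Dz <- D
  Dz[, !valid] <- 0
  ss <- colSums(Dz^2)
  ss[!valid] <- NA_real_

  obs_t <- tmap_of(matrix(1, 1L, n))
  obs_t[!valid] <- NA_real_

  collect <- function(t) {
    pos <- grid_clusters(!is.na(t) & t > tcrit, dims)
    neg <- grid_clusters(!is.na(t) & t < -tcrit, dims)
    list(pos = pos, neg = neg)
  }
  obs <- collect(obs_t)
  clusters <- c(
    lapply(obs$pos, function(ix) list(cells = ix, stat = sum(obs_t[ix]),
                                      sign = "positive")),
    lapply(obs$neg, function(ix) list(cells = ix, stat = sum(obs_t[ix]),
                                      sign = "negative")))

  null_max <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    vapply(seq_len(n_perm), function(k) {
      t <- tmap_of(signs[k, , drop = FALSE])
      t[!valid] <- NA_real_
      cl <- collect(t)
      mx <- 0
      for (ix in cl$pos) mx <- max(mx, abs(sum(t[ix])))
      for (ix in cl$neg) mx <- max(mx, abs(sum(t[ix])))
      mx
    }, numeric(1))
  })
  for (k in seq_along(clusters)) {
    clusters[[k]]$p <- (1 + sum(null_max >= abs(clusters[[k]]$stat))) /
      (n_perm + 1)
  }
  ord <- order(vapply(clusters, function(cl) -abs(cl$stat), numeric(1)))
  structure(list(clusters = clusters[ord], t_map = obs_t, dims = dims,
                 null_max = null_max,
                 parameters = list(point_alpha = point_alpha,
                                   n_perm = n_perm, df = n - 1L)),
            class = "cluster_result")
}

col_any_na <- function(M) apply(M, 2L, function(col) any(is.na(col)))

#' Cluster-based permutation test for a paired contrast
#'
#' Grid points whose paired t exceeds the `point_alpha` two-sided
#' threshold are clustered (1-D: neighbouring points; 2-D: 4-connectivity)
#' and each cluster's statistic is the sum of its t values.  The null
#' distribution records, for each of `n_perm` random subject-wise
#' condition-label exchanges (equivalently sign flips of the paired
#' differences), the largest absolute cluster statistic; Monte-Carlo
#' p = `(1 + #permutations >= observed) / (n_perm + 1)`.  Positive and
#' negative clusters are formed separately and compared against the common
#' max-statistic null, which controls the two-sided family-wise error.
#'
#' @param setA,setB Subjects x cells matrices or lists of per-subject
#'   grids (see [paired_t_map()]).
#' @param point_alpha Point-wise threshold for cluster formation.
#' @param n_perm Number of permutations (>= 100 recommended; fewer warns).
#' @param dims Grid dimensions; inferred from list input, required only to
#'   reinterpret a matrix input as a 2-D grid.
#' @param seed Optional seed for the permutation draw.
#' @return A `cluster_result` with `clusters` (cells, summed t, sign,
#'   Monte-Carlo p), the observed `t_map` and the `null_max` distribution.
#' @export
cluster_permutation <- function(setA, setB, point_alpha = 0.01, n_perm = 1000,
                                dims = NULL, seed = NULL) {
  a <- as_subject_maps(setA)
  b <- as_subject_maps(setB)
  if (!identical(dim(a$mat), dim(b$mat))) {
    stop("conditions must share subjects and grid", call. = FALSE)
  }
  if (n_perm < 100) warning("fewer than 100 permutations: p values are coarse")
  use_dims <- dims %||% a$dims
  if (prod(use_dims) != ncol(a$mat)) {
    stop("`dims` incompatible with the number of grid cells", call. = FALSE)
  }
  cluster_engine(a$mat - b$mat, use_dims, point_alpha, n_perm, seed)
}

#' One-sample cluster permutation test against zero
#'
#' @param set Subjects x cells matrix or list of per-subject grids of
#'   values tested against 0 (e.g. per-subject difference maps).
#' @inheritParams cluster_permutation
#' @return A `cluster_result`.
#' @export
cluster_permutation_onesample <- function(set, point_alpha = 0.01,
                                          n_perm = 1000, dims = NULL,
                                          seed = NULL) {
  a <- as_subject_maps(set)
  if (nrow(a$mat) < 5L) stop("need at least 5 subjects", call. = FALSE)
  if (n_perm < 100) warning("fewer than 100 permutations: p values are coarse")
  use_dims <- dims %||% a$dims
  if (prod(use_dims) != ncol(a$mat)) {
    stop("`dims` incompatible with the number of grid cells", call. = FALSE)
  }
  cluster_engine(a$mat, use_dims, point_alpha, n_perm, seed)
}

#' Double-subtraction interaction contrast
#'
#' Per subject computes `(A1 - A2) - (B1 - B2)` and tests it against zero
#' with the sign-flip cluster permutation test — e.g. (to INT - to DIF) in
#' the feedback direction minus the same subtraction in the feedforward
#' direction.
#'
#' @param setA1,setA2,setB1,setB2 Subjects x cells inputs sharing subjects
#'   and grid.
#' @inheritParams cluster_permutation
#' @return A `cluster_result`; the per-subject interaction maps are
#'   attached as attribute `"interaction_maps"`.
#' @export
interaction_contrast <- function(setA1, setA2, setB1, setB2,
                                 point_alpha = 0.01, n_perm = 1000,
                                 dims = NULL, seed = NULL) {
  m <- lapply(list(setA1, setA2, setB1, setB2), as_subject_maps)
  dd <- vapply(m, function(x) dim(x$mat), integer(2))
  if (any(dd[1, ] != dd[1, 1]) || any(dd[2, ] != dd[2, 1])) {
    stop("all four sets must share subjects and grid", call. = FALSE)
  }
  D <- (m[[1]]$mat - m[[2]]$mat) - (m[[3]]$mat - m[[4]]$mat)
  use_dims <- dims %||% m[[1]]$dims
  res <- cluster_engine(D, use_dims, point_alpha, n_perm, seed)
  attr(res, "interaction_maps") <- D
  res
}

#' Minimum cluster p value of a result (1 if no clusters formed)
#' @param result A `cluster_result`.
#' @export
min_cluster_p <- function(result) {
  if (!length(result$clusters)) return(1)
  min(vapply(result$clusters, `[[`, numeric(1), "p"))
}

#' Export cluster results as JSON
#'
#' Writes cluster extents (cell indices plus, when axis vectors are given,
#' extents in axis units), summed t statistics, signs and Monte-Carlo p
#' values.
#'
#' @param result A `cluster_result`.
#' @param path Output path.
#' @param axes Optional named list of axis value vectors (e.g.
#'   `list(delay_ms = delays, time_ms = times)`) matching `result$dims`.
#' @export
write_cluster_json <- function(result, path, axes = NULL) {
  dims <- result$dims
  describe <- function(cl) {
    out <- list(stat = cl$stat, p = cl$p, sign = cl$sign,
                n_cells = length(cl$cells), cells = cl$cells)
    if (!is.null(axes) && length(dims) == 2L && length(axes) == 2L) {
      r <- ((cl$cells - 1L) %% dims[1L]) + 1L
      c <- ((cl$cells - 1L) %/% dims[1L]) + 1L
      out[[paste0(names(axes)[1L], "_range")]] <- range(axes[[1L]][r])
      out[[paste0(names(axes)[2L], "_range")]] <- range(axes[[2L]][c])
    } else if (!is.null(axes) && length(axes) == 1L) {
      out[[paste0(names(axes)[1L], "_range")]] <- range(axes[[1L]][cl$cells])
    }
    out
  }
  payload <- list(parameters = result$parameters,
                  clusters = lapply(result$clusters, describe))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations, point alpha %g\n",
              length(x$clusters), x$parameters$n_perm,
              x$parameters$point_alpha))
  for (cl in x$clusters) {
    cat(sprintf("  %s: %d cells, sum t = %.2f, p = %.4g\n",
                cl$sign, length(cl$cells), cl$stat, cl$p))
  }
  invisible(x)
}
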