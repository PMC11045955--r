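#' Pointwise distance matrix between two sequences
#'
#' Entry `(i, j)` is the Euclidean norm of the difference between sample
#' `i` of `x` and sample `j` of `y` taken across channels (the absolute
#' difference for single-channel input).
#'
#' @param x,y Numeric matrices (channels x samples) with identical channel
#'   count and ordering, or plain numeric vectors (treated as one channel).
#' @return An `m x n` nonnegative matrix, `m = ncol(x)`, `n = ncol(y)`.
#' @export
dtw_distance_matrix <- function(x, y) {
  x <- as_dtw_matrix(x)
  y <- as_dtw_matrix(y)
  check_dtw_channels(x, y)
  # ||xi - yj||^2 = ||xi||^2 + ||yj||^2 - 2 xi.yj, clipped at 0 before sqrt
  sq <- outer(colSums(x^2), colSums(y^2), "+") - 2 * crossprod(x, y)
  sq[sq < 0] <- 0
  sqrt(sq)
}

as_dtw_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
}

check_dtw_channels <- function(x, y) {
  if (nrow(x) != nrow(y)) {
    stop("sequences have different channel counts", call. = FALSE)
  }
  rx <- rownames(x); ry <- rownames(y)
  if (!is.null(rx) && !is.null(ry) && !identical(rx, ry)) {
    stop("sequences have different channel ordering", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("sequences contain NA", call. = FALSE)
  invisible(TRUE)
}

#' Cumulative DTW cost matrix
#'
#' Dynamic program over a nonnegative pointwise distance matrix `D`:
#' `C[1,1] = D[1,1]`, the first row and column are prefix sums, and each
#' interior cell adds `D[i,j]` to the cheapest of the three admissible
#' predecessors (up, left, diagonal). `C[m,n]` is the optimal alignment
#' cost.
#'
#' @param D Nonnegative numeric matrix from [dtw_distance_matrix()].
#' @return Matrix of the same shape.
#' @export
dtw_cumulative <- function(D) {
  stopifnot(is.matrix(D), all(D >= 0))
  .dtw_cumulative_cpp(D)
}

#' Backtrack the optimal warping path
#'
#' Walks from `(m, n)` back to `(1, 1)` through the cumulative matrix,
#' always moving to the predecessor with the smallest cumulative cost.
#' Ties are broken deterministically: diagonal first, then vertical
#' (`i - 1`), then horizontal (`j - 1`). The returned path is reversed to
#' start at `(1, 1)`.
#'
#' @param C Cumulative matrix from [dtw_cumulative()].
#' @return Two-column integer matrix of 1-based index pairs `(i, j)`.
#' @export
dtw_backtrack <- function(C) {
  stopifnot(is.matrix(C))
  i <- nrow(C)
  j <- ncol(C)
  path <- matrix(NA_integer_, nrow = i + j - 1L, ncol = 2L)
  k <- nrow(path)
  path[k, ] <- c(i, j)
  while (i > 1L || j > 1L) {
    if (i == 1L) {
      j <- j - 1L
    } else if (j == 1L) {
      i <- i - 1L
    } else {
      diag <- C[i - 1L, j - 1L]
      up <- C[i - 1L, j]
      left <- C[i, j - 1L]
      best <- min(diag, up, left)
      if (diag <= best) {
        i <- i - 1L; j <- j - 1L
      } else if (up <= best) {
        i <- i - 1L
      } else {
        j <- j - 1L
      }
    }
    k <- k - 1L
    path[k, ] <- c(i, j)
  }
  path[k:nrow(path), , drop = FALSE]
}

#' Multidimensional DTW distance
#'
#' Aligns two multichannel sequences by dynamic time warping. The
#' `"dependent"` strategy (default) warps all channels along one shared
#' path with vector Euclidean pointwise cost; the `"independent"` strategy
#' runs scalar DTW per channel and sums the distances. For single-channel
#' input the two strategies coincide with scalar DTW. The distance is the
#' raw optimal alignment cost `C[m, n]` (no path-length normalization) and
#' no warping window is applied unless `window` is set.
#'
#' @param x,y Channels-x-samples matrices (or numeric vectors) with the
#'   same channel ordering.
#' @param strategy `"dependent"` or `"independent"`.
#' @param window Optional Sakoe-Chiba band half-width in samples
#'   (`NULL` = unconstrained). Applies to the fast distance-only path.
#' @param keep_matrices Also return the cumulative matrix and warping
#'   path(s) in a `"dtw_result"` object; when `FALSE` only the numeric
#'   distance is returned (the classifier's fast path).
#' @return A numeric distance, or a `"dtw_result"` list with `distance`,
#'   `cumulative` and `path` (for `"independent"`, per-channel lists).
#' @examples
#' mdtw_distance(c(1, 2, 3), c(2, 2, 2, 3, 3))
#' r <- mdtw_distance(rbind(1:4, 4:1), rbind(1:4, 4:1), keep_matrices = TRUE)
#' r$distance
#' @export
mdtw_distance <- function(x, y, strategy = c("dependent", "independent"),
                          window = NULL, keep_matrices = FALSE) {
  strategy <- match.arg(strategy)
  x <- as_dtw_matrix(x)
  y <- as_dtw_matrix(y)
  check_dtw_channels(x, y)
  win <- if (is.null(window)) -1L else as.integer(window)
  if (!keep_matrices) {
    if (strategy == "dependent") {
      return(.mdtw_dist_cpp(x, y, win))
    }
    return(sum(vapply(seq_len(nrow(x)), function(k) {
      .mdtw_dist_cpp(x[k, , drop = FALSE], y[k, , drop = FALSE], win)
    }, 0.0)))
  }
  if (strategy == "dependent") {
    D <- dtw_distance_matrix(x, y)
    C <- dtw_cumulative(D)
    structure(list(distance = C[nrow(C), ncol(C)], cumulative = C,
                   path = dtw_backtrack(C), strategy = strategy),
              class = "dtw_result")
  } else {
    per <- lapply(seq_len(nrow(x)), function(k) {
      D <- dtw_distance_matrix(x[k, , drop = FALSE], y[k, , drop = FALSE])
      C <- dtw_cumulative(D)
      list(distance = C[nrow(C), ncol(C)], cumulative = C,
           path = dtw_backtrack(C))
    })
    names(per) <- rownames(x)
    structure(list(distance = sum(vapply(per, `[[`, 0.0, "distance")),
                   per_channel = per, strategy = strategy),
              class = "dtw_result")
  }
}

#' @export
print.dtw_result <- function(x, ...) {
  cat("<dtw_result>", x$strategy, "distance:", format(x$distance), "\n")
  invisible(x)
}
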