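# Exhaustive DTW oracle: minimum cost over every admissible monotone
# warping path, by plain recursion over path continuations. No dynamic
# programming, no memoisation — independent of the package's DP.
dtw_oracle <- function(x, y) {
  D <- abs(outer(x, y, "-"))
  m <- nrow(D)
  n <- ncol(D)
  rec <- function(i, j) {
    if (i == m && j == n) return(D[m, n])
    best <- Inf
    if (i < m) best <- min(best, rec(i + 1L, j))
    if (j < n) best <- min(best, rec(i, j + 1L))
    if (i < m && j < n) best <- min(best, rec(i + 1L, j + 1L))
    D[i, j] + best
  }
  rec(1L, 1L)
}

# all sequences of lengths 1..max_len over the given alphabet
all_sequences <- function(max_len, alphabet = 0:2) {
  out <- list()
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    for (r in seq_len(nrow(grid))) {
      out[[length(out) + 1L]] <- as.numeric(grid[r, ])
    }
  }
  out
}
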