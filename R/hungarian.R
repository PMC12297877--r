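# Hungarian (Kuhn-Munkres) solver for the rectangular linear sum assignment
# problem, via shortest augmenting paths with dual potentials: O(n^2 m).
# Returns, for each row of `cost`, the assigned column index or NA. Requires
# finite costs; infeasibility is handled upstream with a large sentinel.
hungarian_solve <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  transposed <- n > m
  if (transposed) { cost <- t(cost); tmp <- n; n <- m; m <- tmp }

  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)      # p[j+1]: row assigned to column j (0 = none)
  way <- integer(m + 1)

  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }

  assign_row <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assign_row[p[j + 1L]] <- j
  if (transposed) {
    out <- rep(NA_integer_, m)  # m is the original row count here
    for (i in seq_along(assign_row)) if (!is.na(assign_row[i])) out[assign_row[i]] <- i
    out
  } else {
    assign_row
  }
}
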