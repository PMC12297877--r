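# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# --- linear Kalman filter ---------------------------------------------------

lkf_predict <- function(mean, cov, model) {
  list(mean = drop(model$F %*% mean),
       cov = model$F %*% cov %*% t(model$F) + model$Q)
}

lkf_update <- function(mean, cov, z, model) {
  S <- model$H %*% cov %*% t(model$H) + model$R
  K <- cov %*% t(model$H) %*% solve(S)
  innov <- z - drop(model$H %*% mean)
  list(mean = drop(mean + K %*% innov),
       cov = cov - K %*% S %*% t(K))
}

# random valid track state: positive aspect/height (and velocities that keep
# them positive one step ahead, inside the tracker's physical regime),
# PSD covariance
random_state <- function() {
  mean <- c(runif(1, 50, 500), runif(1, 50, 500), runif(1, 0.5, 2.5),
            runif(1, 10, 60), rnorm(2, 0, 2), rnorm(1, 0, 0.1), rnorm(1, 0, 1))
  A <- matrix(rnorm(64), 8, 8)
  cov <- crossprod(A) + diag(8) * 0.5
  list(mean = mean, cov = cov)
}

# relative error in the max norm: ||a - b|| / ||b||
max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(abs(b))
}

# --- brute-force assignment -------------------------------------------------

# exhaustive minimum-cost one-to-one assignment; infeasible entries are
# simply unavailable. Returns the minimal total cost over all partial
# matchings of size min-cost-optimal cardinality-first (maximum feasible
# cardinality, then minimum cost), matching the sentinel semantics of the
# solver: with a large finite sentinel, any extra feasible pair is cheaper
# than leaving it unmatched.
brute_force_assignment <- function(costs, infeasible = NULL) {
  n <- nrow(costs); m <- ncol(costs)
  if (is.null(infeasible)) infeasible <- matrix(FALSE, n, m)
  best <- list(size = -1L, cost = Inf)
  recurse <- function(i, used_cols, size, cost) {
    if (i > n) {
      if (size > best$size || (size == best$size && cost < best$cost)) {
        best <<- list(size = size, cost = cost)
      }
      return(invisible())
    }
    recurse(i + 1L, used_cols, size, cost)  # row i unmatched
    for (j in seq_len(m)) {
      if (!used_cols[j] && !infeasible[i, j]) {
        used_cols[j] <- TRUE
        recurse(i + 1L, used_cols, size + 1L, cost + costs[i, j])
        used_cols[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(m), 0L, 0)
  best
}

# --- misc fixtures ----------------------------------------------------------

random_boxes <- function(n, max_xy = 500, max_wh = 60) {
  data.frame(x = runif(n, 0, max_xy), y = runif(n, 0, max_xy),
             w = runif(n, 1, max_wh), h = runif(n, 1, max_wh))
}

expect_one_to_one <- function(res) {
  expect_false(any(duplicated(res$matches$track)))
  expect_false(any(duplicated(res$matches$detection)))
  expect_length(intersect(res$matches$track, res$unmatched_tracks), 0)
  expect_length(intersect(res$matches$detection, res$unmatched_detections), 0)
}
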