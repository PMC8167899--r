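# Dense square linear assignment by shortest augmenting paths
# (Jonker-Volgenant style potentials). Minimizes sum(cost[i, p(i)]).
# Infeasible entries should be encoded as a large finite cost.
# Returns list(assignment = integer vector p with p[i] = column of row i,
#              cost = total cost).
solve_lap <- function(cost) {
  n <- nrow(cost)
  if (n == 0) return(list(assignment = integer(0), cost = 0))
  stopifnot(ncol(cost) == n)
  u <- numeric(n)           # row potentials
  v <- numeric(n + 1)       # column potentials, index 1 = virtual column 0
  p <- integer(n + 1)       # p[j + 1] = row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free <- which(!used[-1])
      cur <- cost[i0, free] - u[i0] - v[free + 1]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      uc <- used[-1]
      u[p[c(TRUE, uc)]] <- u[p[c(TRUE, uc)]] + delta
      v[c(TRUE, uc)] <- v[c(TRUE, uc)] - delta
      minv[!uc] <- minv[!uc] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  assignment[p[-1]] <- seq_len(n)
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}

# big-but-finite stand-in for a forbidden link
.lap_big <- 1e9

# Gated frame-to-frame assignment between two detection point sets.
# Costs are squared distances; links beyond max_dist are forbidden; each
# unmatched point (death in A, birth in B) costs max_dist^2 via the standard
# augmented square matrix with a zero dummy-dummy block.
# Returns list(links = 2-column matrix (i in A, j in B), cost = total gated
# objective: sum of linked squared distances + max_dist^2 per unmatched).
assign_frame_pair <- function(pos_a, pos_b, max_dist) {
  n <- nrow(pos_a); m <- nrow(pos_b)
  if (n == 0 || m == 0) {
    return(list(links = matrix(integer(0), 0, 2),
                cost = (n + m) * max_dist^2))
  }
  d2 <- outer(rowSums(pos_a^2), rowSums(pos_b^2), "+") -
    2 * pos_a %*% t(pos_b)
  d2[d2 < 0] <- 0
  link_cost <- ifelse(d2 <= max_dist^2, d2, .lap_big)
  size <- n + m
  cost <- matrix(.lap_big, size, size)
  cost[seq_len(n), seq_len(m)] <- link_cost
  for (i in seq_len(n)) cost[i, m + i] <- max_dist^2      # death
  for (j in seq_len(m)) cost[n + j, j] <- max_dist^2      # birth
  cost[(n + 1):size, (m + 1):size] <- 0                   # dummy-dummy
  sol <- solve_lap(cost)
  ass <- sol$assignment
  links <- cbind(seq_len(n), ass[seq_len(n)])
  links <- links[links[, 2] <= m, , drop = FALSE]
  links <- links[link_cost[links] < .lap_big, , drop = FALSE]
  n_linked <- nrow(links)
  total <- sum(d2[links]) + max_dist^2 * ((n - n_linked) + (m - n_linked))
  list(links = links, cost = total)
}
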