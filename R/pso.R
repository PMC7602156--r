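# Global-best particle swarm optimiser over a box.
#
# A deliberately small, deterministic (given the R RNG state)
# implementation of the standard inertia-weighted swarm: positions are
# initialised uniformly within the bounds (no user initial guess),
# velocities are clamped to the box range, particles leaving the box are
# clamped to the boundary with their velocity zeroed. The search stops
# once the relative improvement of the best cost stays below `tol` for
# `stall_iters` consecutive iterations, mirroring the "large cost
# function tolerance" role of the global stage.
#
# `fn` must accept a matrix with one particle per row and return a
# vector of costs; all model costs in this package are vectorised that
# way so a whole swarm is evaluated with a couple of matrix exps.
pso_minimise <- function(fn, lower, upper,
                         swarm_size = 100L, max_iters = 1000L,
                         tol = 1e-3, stall_iters = 20L,
                         inertia = 0.7298, cognitive = 1.49618,
                         social = 1.49618) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  lo <- matrix(lower, swarm_size, d, byrow = TRUE)
  hi <- matrix(upper, swarm_size, d, byrow = TRUE)
  span <- hi - lo

  pos <- lo + matrix(stats::runif(swarm_size * d), swarm_size, d) * span
  vel <- matrix(stats::runif(swarm_size * d, -1, 1), swarm_size, d) * span

  cost <- fn(pos)
  pbest <- pos
  pbest_cost <- cost
  g <- which.min(cost)
  gbest <- pos[g, ]
  gbest_cost <- cost[g]

  stall <- 0L
  iters <- 0L
  for (it in seq_len(max_iters)) {
    iters <- it
    r1 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
    r2 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
    gmat <- matrix(gbest, swarm_size, d, byrow = TRUE)
    vel <- inertia * vel + cognitive * r1 * (pbest - pos) +
      social * r2 * (gmat - pos)
    vel <- pmin(pmax(vel, -span), span)
    pos <- pos + vel
    below <- pos < lo
    above <- pos > hi
    pos[below] <- lo[below]
    pos[above] <- hi[above]
    vel[below | above] <- 0

    cost <- fn(pos)
    improved <- cost < pbest_cost
    if (any(improved)) {
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pbest_cost[improved] <- cost[improved]
    }
    m <- which.min(pbest_cost)
    new_best <- pbest_cost[m]
    gain <- gbest_cost - new_best
    if (new_best < gbest_cost) {
      gbest <- pbest[m, ]
      gbest_cost <- new_best
    }
    # stall when the improvement is negligible relative to the cost scale
    if (gain <= tol * max(abs(gbest_cost), tol)) {
      stall <- stall + 1L
    } else {
      stall <- 0L
    }
    if (stall >= stall_iters) break
  }
  list(par = as.numeric(gbest), value = as.numeric(gbest_cost),
       iters = iters, stalled = stall >= stall_iters)
}
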