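# Small fixture builders used across the suite. Everything is generated in
# code; no stored data.

# a bare scenario with particles at explicit positions (um) on the default
# 32 x 32 / 15 um grid unless overridden
make_scenario <- function(starts, goals, types = NULL, obstacle_pos = NULL,
                          type_names = NULL, goal_types = NULL,
                          obstacle_type = "bead10", ws = workspace(),
                          seed = 42L, diffusion = 0,
                          sim = sim_config(seed = 7L)) {
  starts <- rbind(starts)
  goals_m <- rbind(goals)
  n <- nrow(starts)
  if (is.null(type_names)) type_names <- rep("cell", n)
  used <- unique(c(type_names,
                   if (!is.null(obstacle_pos)) obstacle_type,
                   stats::na.omit(goal_types)))
  if (is.null(types)) {
    types <- stats::setNames(lapply(used, preset_type), used)
  }
  n_obs <- if (is.null(obstacle_pos)) 0L else nrow(rbind(obstacle_pos))
  particles <- data.frame(
    id = seq_len(n + n_obs),
    type = c(type_names, rep(obstacle_type, n_obs)),
    x = c(starts[, 1], if (n_obs) rbind(obstacle_pos)[, 1]),
    y = c(starts[, 2], if (n_obs) rbind(obstacle_pos)[, 2]),
    status = c(rep("trapped", n), rep("free-obstacle", n_obs)),
    goal_id = NA_integer_)
  gdf <- data.frame(id = seq_len(nrow(goals_m)),
                    x = goals_m[, 1], y = goals_m[, 2],
                    required_type = goal_types %||%
                      rep(NA_character_, nrow(goals_m)))
  scenario(ws, medium(diffusion_coefficient = diffusion), particles, gdf,
           types, seed = seed, sim = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic run configuration: no slip, no diffusion, exact observation
exact_config <- function(...) {
  utils::modifyList(list(slip_prob = 0, obs_sigma = 0), list(...))
}

# brute-force minimum assignment cost by exhausting all permutations
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    tot <- sum(cost[cbind(seq_len(n), p)])
    if (tot < best) best <- tot
  }
  best
}

# independent dense value-iteration oracle (matrix form, no package internals)
oracle_value_iteration <- function(P_list, V0, clamped, eta, tol = 1e-10,
                                   iters = 10000) {
  V <- V0
  nA <- length(P_list)
  for (it in seq_len(iters)) {
    Q <- sapply(P_list, function(P) eta * as.numeric(P %*% V))
    Vn <- apply(Q, 1, max)
    Vn[clamped] <- V0[clamped]
    if (max(abs(Vn - V)) < tol) return(Vn)
    V <- Vn
  }
  V
}
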