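#' The planner's action set
#'
#' Nine single-step actions: unit moves to the 8 adjacent cells plus the
#' zero "stay" vector. The order is fixed and documented — N, NE, E, SE, S,
#' SW, W, NW, stay (stay last) — and is the tie-break order for the policy.
#' y increases downward, so N is (0, -1).
#'
#' @return A 9 x 2 integer matrix of (dcol, drow) displacements with row
#'   names.
#' @export
action_set <- function() {
  m <- rbind(N = c(0L, -1L), NE = c(1L, -1L), E = c(1L, 0L), SE = c(1L, 1L),
             S = c(0L, 1L), SW = c(-1L, 1L), W = c(-1L, 0L), NW = c(-1L, -1L),
             stay = c(0L, 0L))
  colnames(m) <- c("dcol", "drow")
  m
}

#' Build the grid transition model
#'
#' The response of a particle to the moving electrode is not perfectly
#' predictable, so the intended move succeeds with probability
#' `1 - slip_prob` and the remaining mass is split equally between the two
#' lateral neighbours of the intended direction (the moves 45 degrees to
#' either side). "Stay" is deterministic. Any component that would leave
#' the grid is redirected to the current cell.
#'
#' @param ws an `oet_workspace`.
#' @param slip_prob probability mass diverted to lateral neighbours,
#'   in `[0, 1)`.
#' @return An object of class `oet_transition_model`: list with index
#'   matrices `T1`, `T2`, `T3` (n_states x 9, 1-based destinations) and
#'   probability vector `p = c(1 - slip, slip/2, slip/2)`.
#' @export
build_transition_model <- function(ws, slip_prob = 0.1) {
  stopifnot(slip_prob >= 0, slip_prob < 1)
  acts <- action_set()
  n <- n_states(ws)
  cr <- state_colrow(seq_len(n), ws)
  dest <- function(dcol, drow) {
    col <- cr[, 1] + dcol; row <- cr[, 2] + drow
    off <- col < 0 | col >= ws$nx | row < 0 | row >= ws$ny
    s <- row * ws$nx + col + 1L
    s[off] <- seq_len(n)[off]        # off-grid moves redirect to stay
    as.integer(s)
  }
  k <- nrow(acts)
  T1 <- T2 <- T3 <- matrix(0L, n, k, dimnames = list(NULL, rownames(acts)))
  for (a in seq_len(k)) {
    T1[, a] <- dest(acts[a, 1], acts[a, 2])
    if (a <= 8L) {
      lat1 <- ((a - 2L) %% 8L) + 1L   # 45 degrees counter-clockwise
      lat2 <- (a %% 8L) + 1L          # 45 degrees clockwise
      T2[, a] <- dest(acts[lat1, 1], acts[lat1, 2])
      T3[, a] <- dest(acts[lat2, 1], acts[lat2, 2])
    } else {
      T2[, a] <- T1[, a]; T3[, a] <- T1[, a]
    }
  }
  structure(list(T1 = T1, T2 = T2, T3 = T3,
                 p = c(1 - slip_prob, slip_prob / 2, slip_prob / 2),
                 slip_prob = slip_prob, workspace = ws),
            class = "oet_transition_model")
}

#' Dense transition probabilities for one state-action pair
#' @param tm an `oet_transition_model`.
#' @param s state index; `a` action index (1-9).
#' @param a action index.
#' @return Numeric vector over all states summing to 1.
#' @export
transition_row <- function(tm, s, a) {
  n <- nrow(tm$T1)
  out <- numeric(n)
  idx <- c(tm$T1[s, a], tm$T2[s, a], tm$T3[s, a])
  for (i in 1:3) out[idx[i]] <- out[idx[i]] + tm$p[i]
  out
}

#' Initialise the value function for one particle's planning problem
#'
#' The goal cell is set to 100 and held fixed (clamped) throughout value
#' iteration; every cell carrying obstacle belief is clamped at -50 times
#' its belief weight (a certain obstacle is -50, a cell believed occupied
#' with probability 0.5 is -25). All other cells start at 0 and are updated
#' by the Bellman recursion, so goal attraction propagates through
#' discounting alone.
#'
#' @param ws an `oet_workspace`.
#' @param goal_states integer vector of goal cell indices.
#' @param obstacle_belief numeric vector over states (weights in `[0, 1]`),
#'   or `NULL` for none.
#' @param goal_value clamp value at the goal (default 100).
#' @param obstacle_base clamp base for a certain obstacle (default -50).
#' @return List with `V` (numeric over states) and `clamped` (logical).
#'   A goal coinciding with a certain obstacle is an error.
#' @export
init_value_function <- function(ws, goal_states, obstacle_belief = NULL,
                                goal_value = 100, obstacle_base = -50) {
  n <- n_states(ws)
  V <- numeric(n)
  clamped <- logical(n)
  goal_states <- as.integer(goal_states)
  stopifnot(all(goal_states >= 1L & goal_states <= n))
  if (!is.null(obstacle_belief)) {
    stopifnot(length(obstacle_belief) == n, all(obstacle_belief >= 0))
    if (any(obstacle_belief[goal_states] >= 1 - 1e-12)) {
      stop("goal state coincides with a certain obstacle")
    }
    occ <- obstacle_belief > 0
    V[occ] <- obstacle_base * obstacle_belief[occ]
    clamped[occ] <- TRUE
  }
  V[goal_states] <- goal_value
  clamped[goal_states] <- TRUE
  list(V = V, clamped = clamped)
}

#' Value iteration to convergence
#'
#' Bellman updates
#' `V(s) <- max_a [ r(s, a) + eta * sum_{s'} V(s') p(s' | s, a) ]`
#' over all unclamped states, Jacobi-style, until the sup-norm change drops
#' below `tol`. Returns both the value function and the Q function; the Q
#' rows of clamped states are computed too, so a policy is defined
#' everywhere.
#'
#' @param init list from [init_value_function()] (fields `V`, `clamped`),
#'   or a numeric `V0` (then nothing is clamped).
#' @param tm an `oet_transition_model`.
#' @param eta discount rate, strictly inside (0, 1).
#' @param reward optional n_states x 9 immediate-reward matrix (default 0).
#' @param tol sup-norm convergence tolerance.
#' @param max_iter iteration cap; default `10 * (nx + ny)` sweeps.
#'   Non-convergence within the cap is an error reporting the residual.
#' @param warm_start optional numeric V to start from (e.g. the previous
#'   control period's solution); clamped cells are re-imposed.
#' @return List of class `oet_value_function`: `V`, `Q` (n x 9), `clamped`,
#'   `iterations`, `residual`, `deltas` (per-sweep sup-norm changes).
#' @export
value_iteration <- function(init, tm, eta = 0.95, reward = NULL,
                            tol = 1e-6, max_iter = NULL, warm_start = NULL) {
  stopifnot(eta > 0, eta < 1)
  if (is.numeric(init)) init <- list(V = init, clamped = logical(length(init)))
  ws <- tm$workspace
  if (is.null(max_iter)) max_iter <- 10L * (ws$nx + ws$ny)
  V0 <- init$V
  start <- V0
  if (!is.null(warm_start)) {
    start <- warm_start
    start[init$clamped] <- V0[init$clamped]
  }
  res <- .vi_core(start, init$clamped, tm$T1, tm$T2, tm$T3, tm$p,
                  eta, reward, tol, as.integer(max_iter))
  # clamp targets are defined by V0, which .vi_core re-imposes each sweep
  # only when starting from V0; re-imposing here covers the warm start
  res$V[init$clamped] <- V0[init$clamped]
  if (!res$converged) {
    stop(sprintf("value iteration did not converge in %d sweeps (residual %.3g)",
                 max_iter, res$residual))
  }
  structure(list(V = res$V, Q = res$Q, clamped = init$clamped,
                 iterations = res$iterations, residual = res$residual,
                 deltas = res$deltas),
            class = "oet_value_function")
}

#' Construct a belief distribution
#'
#' @param ws an `oet_workspace`.
#' @param weights numeric over states (renormalised), or a single state
#'   index via `at =` for a point mass.
#' @param at state index for a point-mass belief.
#' @return Numeric vector over states summing to 1, class `oet_belief`.
#' @export
belief <- function(ws, weights = NULL, at = NULL) {
  n <- n_states(ws)
  if (!is.null(at)) {
    weights <- numeric(n)
    weights[as.integer(at)] <- 1
  }
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  structure(weights / sum(weights), class = "oet_belief")
}

#' QMDP policy: best action under a belief
#'
#' The QMDP rule scores each action by its belief-averaged Q value,
#' `argmax_a sum_s b(s) Q(s, a)`, and so accounts for position uncertainty
#' without solving the full POMDP. Exact ties go to the earlier action in
#' the fixed action order (stay last).
#'
#' @param b belief vector over states (must have non-empty support).
#' @param vf an `oet_value_function` (or any list with a `Q` matrix).
#' @return List `action` (index 1-9), `name`, `scores` (length 9).
#' @export
qmdp_action <- function(b, vf) {
  if (sum(b) <= 0) stop("belief has empty support")
  scores <- as.numeric(crossprod(vf$Q, as.numeric(b)))
  names(scores) <- colnames(vf$Q) %||% rownames(action_set())
  a <- unname(which.max(scores))    # first max wins: fixed-order tie-break
  list(action = a, name = rownames(action_set())[a], scores = scores)
}

#' Discretized Gaussian observation model
#'
#' Observation likelihood of the true state given a detected position:
#' symmetric Gaussian over cells, standard deviation `sigma` (cell units),
#' truncated at `truncate` cells.
#'
#' @param sigma standard deviation in cell units (default 0.5).
#' @param truncate truncation radius in cells (default 2).
#' @return An object of class `oet_observation_model`.
#' @export
observation_model <- function(sigma = 0.5, truncate = 2) {
  stopifnot(sigma > 0, truncate > 0)
  structure(list(sigma = sigma, truncate = truncate),
            class = "oet_observation_model")
}

observation_likelihood <- function(obs_pos, ws, om) {
  n <- n_states(ws)
  ctr <- state_center(seq_len(n), ws)
  d2 <- ((ctr[, 1] - obs_pos[1])^2 + (ctr[, 2] - obs_pos[2])^2) / ws$cell_size^2
  lik <- exp(-d2 / (2 * om$sigma^2))
  lik[d2 > om$truncate^2] <- 0
  lik
}

#' Bayes-filter belief update
#'
#' Predict the belief through the transition model under the executed
#' action, then (when an observation is available) multiply by the
#' observation likelihood and renormalise. With no observation the
#' prediction alone is returned. An observation wholly inconsistent with
#' the predicted belief (zero total likelihood) reinitialises the belief
#' around the observation with a warning.
#'
#' @param b belief vector over states.
#' @param action action index (1-9) that was executed.
#' @param observation observed position in um (length-2), or `NULL`.
#' @param tm an `oet_transition_model`.
#' @param om an `oet_observation_model`.
#' @return Updated belief vector (sums to 1).
#' @export
update_belief <- function(b, action, observation = NULL, tm, om = observation_model()) {
  n <- nrow(tm$T1)
  stopifnot(length(b) == n)
  pred <- numeric(n)
  sup <- which(b > 0)
  for (s in sup) {
    pred[tm$T1[s, action]] <- pred[tm$T1[s, action]] + tm$p[1] * b[s]
    pred[tm$T2[s, action]] <- pred[tm$T2[s, action]] + tm$p[2] * b[s]
    pred[tm$T3[s, action]] <- pred[tm$T3[s, action]] + tm$p[3] * b[s]
  }
  if (is.null(observation)) {
    return(structure(pred / sum(pred), class = "oet_belief"))
  }
  lik <- observation_likelihood(observation, tm$workspace, om)
  post <- pred * lik
  if (sum(post) <= 0) {
    warning("observation inconsistent with belief; reinitializing around it")
    post <- lik
    if (sum(post) <= 0) {
      post[grid_state_of(observation, tm$workspace)] <- 1
    }
  }
  structure(post / sum(post), class = "oet_belief")
}

#' Export a per-state function as a grid data frame
#'
#' Reshapes a state-indexed vector (value function, belief, obstacle
#' weights) into an ny x nx grid for CSV export or inspection.
#'
#' @param v numeric vector over states.
#' @param ws an `oet_workspace`.
#' @return ny x nx matrix (rows = grid rows from the top).
#' @export
state_grid <- function(v, ws) {
  stopifnot(length(v) == n_states(ws))
  matrix(v, nrow = ws$ny, ncol = ws$nx, byrow = TRUE)
}
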