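#' Extra path length for detouring around one obstacle
#'
#' An obstacle at perpendicular offset `L` from the straight start-goal
#' segment forces a circular detour of radius `r_sys`. The exact
#' arc-minus-chord length of that detour is
#' `2 * (r_sys * acos(L / r_sys) - sqrt(r_sys^2 - L^2))`, which is
#' non-negative, decreasing in `L`, and vanishes at `L = r_sys`. Only
#' obstacles whose perpendicular foot falls within the segment contribute:
#' an obstacle beyond either endpoint forces no detour.
#'
#' @param start,goal segment endpoints, um (length-2).
#' @param obstacles n x 2 matrix of obstacle positions, um (may be empty).
#' @param lambda influence factor of the detour penalty (>= 0).
#' @param r_sys estimated detour radius, um (> 0).
#' @return Penalty in the same length unit as the inputs (`lambda` times the
#'   summed extra distances).
#' @export
obstacle_detour_term <- function(start, goal, obstacles, lambda = 1, r_sys) {
  if (any(r_sys <= 0)) stop("r_sys must be positive")
  stopifnot(lambda >= 0)
  obstacles <- rbind(obstacles)
  if (is.null(obstacles) || nrow(obstacles) == 0L) return(0)
  d <- goal - start
  len2 <- sum(d^2)
  if (len2 == 0) return(0)
  rel <- sweep(obstacles, 2, start)
  t <- (rel[, 1] * d[1] + rel[, 2] * d[2]) / len2
  perp <- sqrt(pmax(0, rel[, 1]^2 + rel[, 2]^2 - t^2 * len2))
  r <- rep(r_sys, length.out = nrow(obstacles))
  active <- t > 0 & t < 1 & perp < r
  if (!any(active)) return(0)
  L <- perp[active]; r <- r[active]
  extra <- 2 * (r * acos(pmin(1, L / r)) - sqrt(pmax(0, r^2 - L^2)))
  lambda * sum(extra)
}

#' Mutual-avoidance factor between two planned transport segments
#'
#' Dimensionless weight gamma in `[0, 1]` scaling the estimated extra
#' distance `gamma * r_sys * (pi - 1)` a particle must travel to avoid a
#' fellow target whose own start-goal segment crosses its path. The default
#' rule uses the two stated influencing factors — the angle between the
#' segments and the distances from both starts to their intersection:
#' `gamma = (1 - theta/pi)` when the segments properly intersect and the
#' two starts reach the intersection within `r_sys` of each other (so the
#' particles actually meet there), and 0 otherwise. Gamma is defined to be
#' 0 for every pair on the first cost-matrix construction, before any
#' matching exists.
#'
#' @param seg_i,seg_w 2 x 2 matrices, rows = (start, goal) of each segment,
#'   um.
#' @param r_sys detour radius, um.
#' @return gamma in `[0, 1]`. Degenerate zero-length segments give 0 with a
#'   warning.
#' @export
interaction_gamma <- function(seg_i, seg_w, r_sys) {
  a <- seg_i[1, ]; b <- seg_i[2, ]
  c_ <- seg_w[1, ]; d <- seg_w[2, ]
  u <- b - a; v <- d - c_
  if (sum(u^2) == 0 || sum(v^2) == 0) {
    warning("degenerate zero-length segment; gamma = 0")
    return(0)
  }
  den <- u[1] * v[2] - u[2] * v[1]
  if (abs(den) < 1e-12) return(0)            # parallel
  w <- c_ - a
  t <- (w[1] * v[2] - w[2] * v[1]) / den
  s <- (w[1] * u[2] - w[2] * u[1]) / den
  if (t <= 0 || t >= 1 || s <= 0 || s >= 1) return(0)  # no proper crossing
  di <- t * sqrt(sum(u^2))
  dw <- s * sqrt(sum(v^2))
  if (abs(di - dw) >= r_sys) return(0)       # they reach the crossing apart
  theta <- acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  1 - theta / pi
}

pair_r_sys <- function(sc, type_a, type_b) {
  max(electrode_outer_radius(sc$types[[type_a]]),
      electrode_outer_radius(sc$types[[type_b]])) + sc$safety_margin
}

#' Build the goal-assignment cost matrix
#'
#' Entry (i, j) estimates the transport cost, in cell units, from target i's
#' start to goal j: the Manhattan grid distance, plus the obstacle-detour
#' penalty for free obstacles near the straight segment, plus — once a
#' provisional matching exists — the mutual-avoidance terms
#' `gamma * r_sys * (pi - 1)` against every other target travelling to its
#' currently-matched goal. Goals restricted to a different particle type get
#' a large sentinel cost (forbidden pairing).
#'
#' @param sc an `oet_scenario`.
#' @param matching `NULL` on the first construction (all gamma terms 0), or
#'   an `oet_matching` giving the other targets' default goals.
#' @param lambda detour influence factor.
#' @return An object of class `oet_cost_matrix`: numeric matrix (rows =
#'   targets, cols = goals, dimnames = ids) with attributes `lambda` and
#'   `sentinel`.
#' @export
build_cost_matrix <- function(sc, matching = NULL, lambda = 1) {
  ti <- target_indices(sc)
  oi <- obstacle_indices(sc)
  goals <- sc$goals
  if (length(ti) == 0L || nrow(goals) == 0L) {
    stop("scenario must have at least one target and one goal")
  }
  p <- sc$particles
  ws <- sc$workspace
  sentinel <- 1e6
  n <- length(ti); m <- nrow(goals)
  E <- matrix(0, n, m,
              dimnames = list(p$id[ti], goals$id))
  obst_pos <- cbind(p$x[oi], p$y[oi])
  for (a in seq_len(n)) {
    i <- ti[a]
    start <- c(p$x[i], p$y[i])
    for (b in seq_len(m)) {
      if (!is.na(goals$required_type[b]) &&
          goals$required_type[b] != p$type[i]) {
        E[a, b] <- sentinel
        next
      }
      gpos <- c(goals$x[b], goals$y[b])
      cost <- manhattan_distance(start, gpos, ws)
      if (length(oi)) {
        r <- vapply(oi, function(k) pair_r_sys(sc, p$type[i], p$type[k]),
                    numeric(1))
        det <- obstacle_detour_term(start, gpos, obst_pos, lambda = lambda,
                                    r_sys = r)
        cost <- cost + det / ws$cell_size
      }
      if (!is.null(matching)) {
        seg_i <- rbind(start, gpos)
        for (w in seq_len(n)) {
          if (w == a) next
          gw <- matching$pairs[as.character(p$id[ti[w]])]
          if (is.na(gw)) next
          gwrow <- match(gw, goals$id)
          seg_w <- rbind(c(p$x[ti[w]], p$y[ti[w]]),
                         c(goals$x[gwrow], goals$y[gwrow]))
          r_sys <- pair_r_sys(sc, p$type[i], p$type[ti[w]])
          g <- interaction_gamma(seg_i, seg_w, r_sys)
          cost <- cost + g * r_sys * (pi - 1) / ws$cell_size
        }
      }
      E[a, b] <- cost
    }
  }
  structure(E, lambda = lambda, sentinel = sentinel,
            class = c("oet_cost_matrix", "matrix", "array"))
}

# O(n^3) Kuhn-Munkres (shortest augmenting path with potentials).
# `a` is a square cost matrix; returns 1-based column assignment per row.
hungarian_core <- function(a) {
  n <- nrow(a)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)          # p[j+1] = row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- a[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
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
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0L) ans[p[j + 1]] <- j
  ans
}

#' Minimum-cost assignment of targets to goals
#'
#' Solves the square (padded) cost matrix with a Kuhn-Munkres solver
#' (shortest augmenting paths over a bipartite graph). Among cost-ties the
#' result is deterministic: the lowest particle index keeps the
#' lexicographically smallest goal index, enforced by a sequential
#' re-solve that fixes rows in order to the smallest goal column still
#' compatible with the optimal total.
#'
#' @param cost an `oet_cost_matrix` or plain numeric matrix (rows =
#'   particles, cols = goals). Rectangular inputs are padded to square with
#'   a large dummy cost; dummy pairings are dropped from the result.
#' @return An object of class `oet_matching`: list with `pairs` (named
#'   integer vector, particle id -> goal id), `total_cost`, `converged`.
#' @export
solve_assignment <- function(cost) {
  a <- unclass(cost)
  if (!all(is.finite(a))) stop("cost matrix entries must be finite")
  if (any(a < 0)) stop("cost matrix entries must be non-negative")
  n0 <- nrow(a); m0 <- ncol(a)
  rn <- rownames(a) %||% as.character(seq_len(n0))
  cn <- colnames(a) %||% as.character(seq_len(m0))
  n <- max(n0, m0)
  pad <- 1e6
  sq <- matrix(pad, n, n)
  sq[seq_len(n0), seq_len(m0)] <- a

  assign0 <- hungarian_core(sq)
  best <- sum(sq[cbind(seq_len(n), assign0)])
  tol <- 1e-7 * max(1, abs(best))

  # lexicographic refinement among optimal matchings
  fixed <- integer(0)                       # fixed[i] = column for row i
  rows_left <- seq_len(n)
  cols_left <- seq_len(n)
  fixed_cost <- 0
  assign <- integer(n)
  for (i in seq_len(n)) {
    found <- FALSE
    for (j in sort(cols_left)) {
      rest_r <- setdiff(rows_left, i)
      rest_c <- setdiff(cols_left, j)
      sub_cost <- if (length(rest_r)) {
        sub <- sq[rest_r, rest_c, drop = FALSE]
        s_assign <- hungarian_core(sub)
        sum(sub[cbind(seq_along(rest_r), s_assign)])
      } else 0
      if (fixed_cost + sq[i, j] + sub_cost <= best + tol) {
        assign[i] <- j
        fixed_cost <- fixed_cost + sq[i, j]
        rows_left <- setdiff(rows_left, i)
        cols_left <- setdiff(cols_left, j)
        found <- TRUE
        break
      }
    }
    if (!found) stop("internal error: no optimal completion found")
  }

  keep <- seq_len(n0)
  pairs <- setNames(rep(NA_integer_, n0), rn)
  total <- 0
  for (i in keep) {
    j <- assign[i]
    if (j <= m0 && a[i, j] < attr(cost, "sentinel") %||% 1e6) {
      pairs[rn[i]] <- as.integer(cn[j])
      total <- total + a[i, j]
    }
  }
  structure(list(pairs = pairs, total_cost = total, converged = TRUE),
            class = "oet_matching")
}

#' @export
print.oet_matching <- function(x, ...) {
  cat(sprintf("<oet_matching> %d pairs, total cost %.4g%s\n",
              sum(!is.na(x$pairs)), x$total_cost,
              if (isTRUE(x$converged)) "" else " (fixed point not reached)"))
  for (id in names(x$pairs)) {
    if (!is.na(x$pairs[[id]])) {
      cat(sprintf("  particle %s -> goal %d\n", id, x$pairs[[id]]))
    }
  }
  invisible(x)
}

#' Goal assignment by iterated matching
#'
#' Runs once at the start of a task: alternates cost-matrix construction
#' (with the latest provisional matching supplying the other targets'
#' default goals) and Kuhn-Munkres matching, until two consecutive rounds
#' agree or the round cap is hit. The converged matching minimises the total
#' estimated transport distance over all targets, including mutual-avoidance
#' detours.
#'
#' @param sc an `oet_scenario`.
#' @param lambda detour influence factor.
#' @param max_rounds fixed-point cap (default 10).
#' @return An `oet_matching`; `converged` is `FALSE` if the cap was hit.
#' @export
assign_goals <- function(sc, lambda = 1, max_rounds = 10L) {
  matching <- solve_assignment(build_cost_matrix(sc, NULL, lambda))
  for (round in seq_len(max_rounds)) {
    nxt <- solve_assignment(build_cost_matrix(sc, matching, lambda))
    if (identical(nxt$pairs, matching$pairs)) {
      nxt$converged <- TRUE
      return(nxt)
    }
    matching <- nxt
  }
  matching$converged <- FALSE
  matching
}

#' Attach a matching to a scenario
#' @param sc an `oet_scenario`.
#' @param matching an `oet_matching`.
#' @return The scenario with `goal_id` filled in on the matched particles.
#' @export
apply_matching <- function(sc, matching) {
  idx <- match(names(matching$pairs), as.character(sc$particles$id))
  sc$particles$goal_id[idx] <- unname(matching$pairs)
  sc
}
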