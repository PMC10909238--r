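#' Dipper-throated optimization configuration
#'
#' DTO models a flock of foraging birds with positions `P` and velocities
#' `V`. Each individual's candidate moves are an exploitation jump around its
#' personal best (`X = P_best - K1 * |K2 * P_best - P|`) and a velocity-driven
#' move (`Y = P + V'` with
#' `V' = K3 V + K4 r1 (P_best - P) + K5 r2 (P_Gbest - P)`); a uniform draw
#' `r3 < 0.5` selects the jump, otherwise the velocity move.
#'
#' @param m Swarm size (>= 2).
#' @param T Iteration budget (>= 1).
#' @param K4,K5 Velocity coefficients (defaults 1.7 and 1.8).
#' @param k_range Interval from which `K1`, `K2`, `K3` are redrawn uniformly
#'   for every individual at every iteration (default `c(0, 2)`).
#' @param seed Integer seed used by [swarm_optimize()].
#' @return An object of class `dto_config`.
#' @export
dto_config <- function(m = 20, T = 100, K4 = 1.7, K5 = 1.8,
                       k_range = c(0, 2), seed = 1) {
  if (m < 2) stop_config("swarm size m must be >= 2")
  if (T < 1) stop_config("iteration budget T must be >= 1")
  if (K4 <= 0 || K5 <= 0) stop_config("K4, K5 must be positive")
  if (length(k_range) != 2 || k_range[1] < 0 || k_range[2] > 2 ||
      k_range[1] >= k_range[2]) {
    stop_config("k_range must be an interval within [0, 2]")
  }
  structure(list(m = as.integer(m), T = as.integer(T), K4 = K4, K5 = K5,
                 k_range = k_range, seed = as.integer(seed)),
            class = "dto_config")
}

#' Modified sine-cosine algorithm configuration
#'
#' SCA moves each coordinate toward the destination (global best) by
#' `X' = X + r1 * sin(r2) * |r3 * best - X|` (or the cosine twin, chosen by
#' `r4 < 0.5`), with amplitude `r1 = a (1 - t/T)` decaying linearly. The
#' modified variant (MSCA) hybridizes in the firefly attraction move: after
#' `activation_fraction` of the budget, each solution with a uniform draw
#' `phi > phi_threshold` instead moves by
#' `x + beta0 exp(-gamma r^2) (x_j - x) + alpha_t (kappa - 0.5)`.
#'
#' @param m Population size (>= 2).
#' @param T Iteration budget (>= 1).
#' @param a Amplitude schedule constant (default 2).
#' @param beta0 Firefly attraction at distance zero (default 1).
#' @param gamma Light absorption coefficient (default 1).
#' @param alpha0 Initial firefly noise amplitude (default 0.2).
#' @param alpha_decay Per-iteration multiplicative decay of the noise
#'   amplitude (default 0.97).
#' @param phi_threshold Switch level for the firefly branch (default 0.5).
#' @param activation_fraction Fraction of the budget before which the firefly
#'   branch stays disabled (default 1/3).
#' @param pairwise If `TRUE`, firefly moves attract each solution to every
#'   brighter (fitter) one in turn; default `FALSE` moves toward the global
#'   best only.
#' @param seed Integer seed used by [swarm_optimize()].
#' @return An object of class `msca_config`.
#' @export
msca_config <- function(m = 20, T = 100, a = 2, beta0 = 1, gamma = 1,
                        alpha0 = 0.2, alpha_decay = 0.97,
                        phi_threshold = 0.5, activation_fraction = 1 / 3,
                        pairwise = FALSE, seed = 1) {
  if (m < 2) stop_config("population size m must be >= 2")
  if (T < 1) stop_config("iteration budget T must be >= 1")
  vals <- c(a = a, beta0 = beta0, gamma = gamma, alpha0 = alpha0,
            alpha_decay = alpha_decay)
  if (any(vals < 0)) stop_config("MSCA constants must be non-negative")
  if (!is.finite(phi_threshold) || phi_threshold < 0 || phi_threshold > 1) {
    stop_config("phi_threshold must lie in [0, 1]")
  }
  if (activation_fraction < 0 || activation_fraction >= 1) {
    stop_config("activation_fraction must lie in [0, 1)")
  }
  structure(list(m = as.integer(m), T = as.integer(T), a = a, beta0 = beta0,
                 gamma = gamma, alpha0 = alpha0, alpha_decay = alpha_decay,
                 phi_threshold = phi_threshold,
                 activation_fraction = activation_fraction,
                 pairwise = pairwise, seed = as.integer(seed)),
            class = "msca_config")
}

# Swarm state shared by all three algorithms: positions P (m x d),
# velocities V, fitness f, per-individual bests, global best.
new_swarm <- function(P, V, f) {
  best <- which.min(f)
  structure(list(P = P, V = V, f = f, P_best = P, f_best = f,
                 P_Gbest = P[best, ], f_Gbest = f[best]),
            class = "swarm")
}

update_bests <- function(swarm) {
  imp <- swarm$f < swarm$f_best
  swarm$P_best[imp, ] <- swarm$P[imp, , drop = FALSE]
  swarm$f_best[imp] <- swarm$f[imp]
  b <- which.min(swarm$f_best)
  if (swarm$f_best[b] < swarm$f_Gbest) {        # strict improvement: elitist
    swarm$f_Gbest <- swarm$f_best[b]
    swarm$P_Gbest <- swarm$P_best[b, ]
  }
  swarm
}

#' One DTO iteration
#'
#' For each individual, draws `r1, r2, r3 ~ U(0,1)` and `K1, K2, K3` uniform
#' on `cfg$k_range`, then applies the exploitation jump or the velocity move
#' (selected by `r3 < 0.5`), clips to the box, and returns the moved swarm
#' with updated velocities. Fitness is not re-evaluated here; the caller
#' evaluates and then updates bests.
#'
#' @param swarm A swarm state (list with `P`, `V`, `f`, `P_best`, `P_Gbest`).
#' @param cfg A [dto_config()].
#' @param lower,upper Box bounds.
#' @param draws Optional list pinning the random draws (`r1`, `r2`, `r3`
#'   length-m vectors; `K1`, `K2`, `K3` length-m vectors), used by tests;
#'   by default all are drawn from the current RNG stream.
#' @return The swarm with updated `P` and `V`.
#' @export
dto_step <- function(swarm, cfg, lower, upper, draws = NULL) {
  m <- nrow(swarm$P); d <- ncol(swarm$P)
  if (is.null(draws)) {
    draws <- list(r1 = stats::runif(m), r2 = stats::runif(m),
                  r3 = stats::runif(m),
                  K1 = stats::runif(m, cfg$k_range[1], cfg$k_range[2]),
                  K2 = stats::runif(m, cfg$k_range[1], cfg$k_range[2]),
                  K3 = stats::runif(m, cfg$k_range[1], cfg$k_range[2]))
  }
  P <- swarm$P; V <- swarm$V
  newP <- P; newV <- V
  for (i in seq_len(m)) {
    X <- swarm$P_best[i, ] - draws$K1[i] * abs(draws$K2[i] * swarm$P_best[i, ] - P[i, ])
    Vn <- draws$K3[i] * V[i, ] +
      cfg$K4 * draws$r1[i] * (swarm$P_best[i, ] - P[i, ]) +
      cfg$K5 * draws$r2[i] * (swarm$P_Gbest - P[i, ])
    Y <- P[i, ] + Vn
    newV[i, ] <- Vn
    newP[i, ] <- if (draws$r3[i] < 0.5) X else Y
  }
  swarm$P <- clip_box(newP, lower, upper)
  swarm$V <- newV
  swarm
}

#' One sine-cosine iteration over a position matrix
#'
#' Per coordinate of every row, draws `r2 ~ U(0, 2*pi)`, `r3 ~ U(0, 2)`,
#' `r4 ~ U(0, 1)`; with amplitude `r1 = a (1 - t/T)`, applies the sine branch
#' when `r4 < 0.5` and the cosine branch otherwise, then clips to the box.
#'
#' @param P Position matrix (m x d).
#' @param best Destination position (global best), length d.
#' @param t Iteration index (0-based; `t = T` gives `r1 = 0`).
#' @param cfg An [msca_config()].
#' @param lower,upper Box bounds.
#' @param draws Optional list with matrices `r2`, `r3`, `r4` (m x d), for
#'   tests.
#' @param rows Optional integer vector: update only these rows.
#' @return The updated position matrix.
#' @export
sca_step <- function(P, best, t, cfg, lower, upper, draws = NULL, rows = NULL) {
  if (cfg$T == 0) stop_config("iteration budget T must be positive")
  m <- nrow(P); d <- ncol(P)
  if (is.null(rows)) rows <- seq_len(m)
  if (is.null(draws)) {
    draws <- list(r2 = matrix(stats::runif(m * d, 0, 2 * pi), m, d),
                  r3 = matrix(stats::runif(m * d, 0, 2), m, d),
                  r4 = matrix(stats::runif(m * d), m, d))
  }
  r1 <- cfg$a * (1 - t / cfg$T)
  B <- matrix(best, m, d, byrow = TRUE)
  sine <- P + r1 * sin(draws$r2) * abs(draws$r3 * B - P)
  cosi <- P + r1 * cos(draws$r2) * abs(draws$r3 * B - P)
  newP <- ifelse(draws$r4 < 0.5, sine, cosi)
  P[rows, ] <- newP[rows, , drop = FALSE]
  clip_box(P, lower, upper)
}

#' Firefly attraction move
#'
#' Moves `xi` toward a brighter solution `xj` with exponentially
#' distance-damped attraction plus decaying Gaussian jitter:
#' `xi + beta0 * exp(-gamma * r^2) * (xj - xi) + alpha_t * (kappa - 0.5)`
#' where `r` is the Euclidean distance between the two solutions,
#' `alpha_t = alpha0 * alpha_decay^t`, and `kappa` is a standard-Gaussian
#' draw per coordinate.
#'
#' @param xi Solution to move.
#' @param xj Attracting (fitter) solution, same length.
#' @param t Iteration index (0-based), for the noise decay.
#' @param cfg An [msca_config()].
#' @param kappa Optional pinned Gaussian draw vector (tests).
#' @return The moved vector (unclipped; callers clip to their box).
#' @export
firefly_move <- function(xi, xj, t, cfg, kappa = NULL) {
  if (length(xi) != length(xj)) stop_config("xi and xj must have equal length")
  if (is.null(kappa)) kappa <- stats::rnorm(length(xi))
  r2 <- sum((xi - xj)^2)
  alpha_t <- cfg$alpha0 * cfg$alpha_decay^t
  xi + cfg$beta0 * exp(-cfg$gamma * r2) * (xj - xi) + alpha_t * (kappa - 0.5)
}

#' One modified sine-cosine (MSCA) iteration
#'
#' Draws `phi ~ U(0,1)` per solution. Once `t >= activation_fraction * T`,
#' solutions with `phi > phi_threshold` take the firefly move toward the
#' global best (or toward each brighter solution in turn when
#' `cfg$pairwise`); all others take the sine-cosine update. Before the
#' activation point the whole population follows plain SCA.
#'
#' @inheritParams sca_step
#' @param f Current fitness vector (needed for `pairwise` brightness order).
#' @param draws Optional pinned draws: `phi` (length m), plus `r2`, `r3`,
#'   `r4` matrices and `kappa` matrix for the two branches.
#' @return The updated position matrix.
#' @export
msca_step <- function(P, best, f, t, cfg, lower, upper, draws = NULL) {
  m <- nrow(P); d <- ncol(P)
  phi <- if (!is.null(draws$phi)) draws$phi else stats::runif(m)
  active <- t >= cfg$activation_fraction * cfg$T
  fa_rows <- if (active) which(phi > cfg$phi_threshold) else integer(0)
  sca_rows <- setdiff(seq_len(m), fa_rows)
  sca_draws <- if (!is.null(draws)) draws[c("r2", "r3", "r4")] else NULL
  if (length(sca_rows) > 0 || is.null(draws)) {
    # draw the SCA matrices even if unused so pinned/unpinned streams align
    P <- sca_step(P, best, t, cfg, lower, upper, draws = sca_draws,
                  rows = sca_rows)
  }
  for (i in fa_rows) {
    kap <- if (!is.null(draws$kappa)) draws$kappa[i, ] else NULL
    if (cfg$pairwise) {
      for (j in order(f)) {
        if (f[j] < f[i]) P[i, ] <- firefly_move(P[i, ], P[j, ], t, cfg, kappa = kap)
      }
    } else {
      P[i, ] <- firefly_move(P[i, ], best, t, cfg, kappa = kap)
    }
  }
  clip_box(P, lower, upper)
}

#' Run a swarm optimizer over a bounded box
#'
#' Minimizes `objective` over `space` with DTO, SCA or MSCA. The initial
#' population is uniform over the box (velocities zero); each of the `T`
#' iterations moves the population with the chosen algorithm, re-evaluates
#' it, and updates personal/global bests by strict improvement, so the
#' recorded global-best fitness history is non-increasing. Non-finite
#' objective values are re-evaluated once, then replaced by `+Inf` and the
#' individual reset to a random in-bounds position at the next move.
#' Exactly `m * (T + 1)` objective evaluations are performed, plus any
#' re-evaluations of non-finite values.
#'
#' @param objective Function mapping a length-d numeric vector to a scalar.
#' @param space A [search_space()].
#' @param algo One of `"dto"`, `"sca"`, `"msca"`.
#' @param cfg A [dto_config()] (for `"dto"`) or [msca_config()] (for the
#'   other two); defaults to the algorithm's default configuration.
#' @param seed Overrides `cfg$seed` when given.
#' @return List with `best` (position), `value` (best fitness), `history`
#'   (length `T + 1` vector of global-best fitness after 0..T iterations),
#'   `evaluations` (objective call count), and `algo`.
#' @examples
#' sp <- search_space(rep(-5, 2), rep(5, 2))
#' res <- swarm_optimize(function(x) sum(x^2), sp, "msca",
#'                       msca_config(m = 10, T = 30), seed = 1)
#' res$value
#' @export
swarm_optimize <- function(objective, space, algo = c("dto", "sca", "msca"),
                           cfg = NULL, seed = NULL) {
  algo <- match.arg(algo)
  if (!inherits(space, "search_space")) stop_config("space must be a search_space")
  if (is.null(cfg)) cfg <- if (algo == "dto") dto_config() else msca_config()
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  d <- length(space$lower)
  lower <- space$lower; upper <- space$upper
  n_eval <- 0L
  eval_pop <- function(P) {
    f <- numeric(nrow(P))
    for (i in seq_len(nrow(P))) {
      v <- objective(P[i, ])
      n_eval <<- n_eval + 1L
      if (!is.finite(v)) {                      # one retry, then +Inf penalty
        v <- objective(P[i, ])
        n_eval <<- n_eval + 1L
        if (!is.finite(v)) v <- Inf
      }
      f[i] <- v
    }
    f
  }
  with_local_seed(cfg$seed, {
    P <- matrix(stats::runif(cfg$m * d, lower, upper), cfg$m, d, byrow = TRUE)
    V <- matrix(0, cfg$m, d)
    sw <- new_swarm(P, V, eval_pop(P))
    sw <- update_bests(sw)
    history <- numeric(cfg$T + 1L)
    history[1L] <- sw$f_Gbest
    for (t in seq_len(cfg$T)) {
      bad <- !is.finite(sw$f)
      if (any(bad)) {                           # reset flagged individuals
        sw$P[bad, ] <- matrix(stats::runif(sum(bad) * d, lower, upper),
                              sum(bad), d, byrow = TRUE)
      }
      if (algo == "dto") {
        sw <- dto_step(sw, cfg, lower, upper)
      } else if (algo == "sca") {
        # routed through msca_step with the firefly branch unreachable so a
        # shared seed gives stream-aligned SCA and MSCA trajectories
        cfg_sca <- cfg
        cfg_sca$phi_threshold <- 2
        sw$P <- msca_step(sw$P, sw$P_Gbest, sw$f, t - 1L, cfg_sca, lower, upper)
      } else {
        sw$P <- msca_step(sw$P, sw$P_Gbest, sw$f, t - 1L, cfg, lower, upper)
      }
      sw$f <- eval_pop(sw$P)
      sw <- update_bests(sw)
      history[t + 1L] <- sw$f_Gbest
    }
    list(best = sw$P_Gbest, value = sw$f_Gbest, history = history,
         evaluations = n_eval, algo = algo)
  })
}

#' Write an optimization history as CSV
#'
#' Layout `iteration,f_gbest`, one row per recorded iteration (0-based).
#'
#' @param result A [swarm_optimize()] result.
#' @param path Output CSV path.
#' @export
write_history <- function(result, path) {
  utils::write.csv(
    data.frame(iteration = seq_along(result$history) - 1L,
               f_gbest = result$history),
    path, row.names = FALSE)
  invisible(path)
}
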