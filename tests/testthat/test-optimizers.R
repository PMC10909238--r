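make_swarm <- function(P, V = NULL, f = NULL) {
  if (is.null(V)) V <- matrix(0, nrow(P), ncol(P))
  if (is.null(f)) f <- rep(Inf, nrow(P))
  sw <- dtocrop:::new_swarm(P, V, f)
  sw
}

test_that("DTO hand examples reproduce the update equations", {
  # fixed point of the velocity branch: P = P_best = P_Gbest = 0, V = 0
  sw <- make_swarm(matrix(0, 2, 1), f = c(1, 2))
  draws <- list(r1 = c(0.3, 0.3), r2 = c(0.6, 0.6), r3 = c(0.9, 0.9),
                K1 = c(1, 1), K2 = c(1, 1), K3 = c(0.5, 0.5))
  out <- dto_step(sw, dto_config(m = 2, T = 5), lower = -5, upper = 5,
                  draws = draws)
  expect_equal(out$P, matrix(0, 2, 1))

  # hand-evaluated velocity move: P=2, P_best=P_Gbest=4, V=0, K3=0.5,
  # r1=r2=1, r3=0.9 -> V' = 1.7*2 + 1.8*2 = 7, Y = 9
  sw <- make_swarm(matrix(c(2, 0), 2, 1), f = c(1, 2))
  sw$P_best <- matrix(c(4, 0), 2, 1)
  sw$P_Gbest <- 4
  draws <- list(r1 = c(1, 0), r2 = c(1, 0), r3 = c(0.9, 0.9),
                K1 = c(1, 1), K2 = c(1, 1), K3 = c(0.5, 0.5))
  out <- dto_step(sw, dto_config(m = 2, T = 5), lower = -50, upper = 50,
                  draws = draws)
  expect_equal(out$V[1, 1], 7.0, tolerance = 1e-12)
  expect_equal(out$P[1, 1], 9.0, tolerance = 1e-12)

  # default coefficients
  cfg <- dto_config()
  expect_equal(cfg$K4, 1.7)
  expect_equal(cfg$K5, 1.8)
  expect_equal(cfg$k_range, c(0, 2))
})

test_that("SCA hand examples reproduce the sine/cosine branches", {
  cfg <- msca_config(m = 2, T = 10)
  # r1 = 0 at t = T: positions unchanged whatever the branch
  P <- matrix(c(1, -2), 2, 1)
  draws <- list(r2 = matrix(c(1, 2), 2, 1), r3 = matrix(1, 2, 1),
                r4 = matrix(c(0.1, 0.9), 2, 1))
  out <- sca_step(P, best = 3, t = cfg$T, cfg, lower = -5, upper = 5,
                  draws = draws)
  expect_equal(out, P)

  # sine branch: X=1, best=3, r1=1 (t = T/2), r2=pi/2, r3=1, r4=0 -> X'=3
  cfg2 <- msca_config(m = 2, T = 2)
  draws <- list(r2 = matrix(pi / 2), r3 = matrix(1), r4 = matrix(0))
  out <- sca_step(matrix(1), best = 3, t = 1, cfg2, lower = -5, upper = 5,
                  draws = draws)
  expect_equal(out[1, 1], 3, tolerance = 1e-12)

  # sin(0) = 0 leaves the position unchanged
  draws$r2 <- matrix(0)
  out <- sca_step(matrix(1), best = 3, t = 1, cfg2, lower = -5, upper = 5,
                  draws = draws)
  expect_equal(out[1, 1], 1, tolerance = 1e-12)
})

test_that("firefly move matches its closed form", {
  cfg <- msca_config(m = 2, T = 10, beta0 = 1, gamma = 0.25, alpha0 = 0)
  # xi = xj with no noise: unchanged
  expect_equal(firefly_move(c(1, 2), c(1, 2), t = 0, cfg), c(1, 2))
  # gamma = 0, beta0 = 1: full attraction onto xj
  cfg0 <- msca_config(m = 2, T = 10, gamma = 0, alpha0 = 0)
  expect_equal(firefly_move(c(0, 5), c(2, -1), t = 3, cfg0), c(2, -1))
  # closed form: 0 + exp(-0.25 * 4) * 2 = 2 e^{-1}
  out <- firefly_move(0, 2, t = 0, cfg)
  expect_equal(out, 2 * exp(-1), tolerance = 1e-12)
  expect_error(firefly_move(c(1, 2), 1, 0, cfg), "equal length")
})

test_that("one full step of each algorithm matches the scalar oracle", {
  set.seed(99)
  m <- 3; d <- 2
  lower <- rep(-4, d); upper <- rep(4, d)
  P <- matrix(runif(m * d, -4, 4), m, d)
  V <- matrix(runif(m * d, -1, 1), m, d)
  f <- c(3, 1, 2)
  draws <- make_step_draws(m, d, seed = 123)

  # DTO
  sw <- dtocrop:::new_swarm(P, V, f)
  cfg <- dto_config(m = m, T = 5)
  got <- dto_step(sw, cfg, lower, upper,
                  draws = draws[c("r1", "r2", "r3", "K1", "K2", "K3")])
  want <- oracle_dto_step(P, V, sw$P_best, sw$P_Gbest, cfg$K4, cfg$K5,
                          draws, lower, upper)
  expect_equal(got$P, want$P, tolerance = 1e-12)
  expect_equal(got$V, want$V, tolerance = 1e-12)

  # SCA
  mcfg <- msca_config(m = m, T = 9)
  best <- P[2, ]
  sca_draws <- list(r2 = draws$r2m, r3 = draws$r3m, r4 = draws$r4m)
  got <- sca_step(P, best, t = 4, mcfg, lower, upper, draws = sca_draws)
  want <- oracle_sca_step(P, best, t = 4, a = mcfg$a, T = mcfg$T,
                          draws = list(r2 = draws$r2m, r3 = draws$r3m,
                                       r4 = draws$r4m), lower, upper)
  expect_equal(got, want, tolerance = 1e-12)

  # MSCA in the active phase (t >= T/3) with a mix of phi outcomes
  msca_draws <- list(phi = c(0.9, 0.2, 0.7), r2 = draws$r2m, r3 = draws$r3m,
                     r4 = draws$r4m, kappa = draws$kappa)
  got <- msca_step(P, best, f, t = 4, mcfg, lower, upper, draws = msca_draws)
  want <- oracle_msca_step(P, best, t = 4, mcfg, msca_draws, lower, upper)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("the phi switch honours the activation rule and thresholds", {
  sp <- search_space(rep(-5, 3), rep(5, 3))
  sphere <- function(x) sum(x^2)

  # phi_threshold = 1: MSCA is bitwise pure SCA for all t
  r_sca <- swarm_optimize(sphere, sp, "sca", msca_config(m = 8, T = 30), seed = 5)
  r_msca1 <- swarm_optimize(sphere, sp, "msca",
                            msca_config(m = 8, T = 30, phi_threshold = 1), seed = 5)
  expect_identical(r_sca$history, r_msca1$history)
  expect_identical(r_sca$best, r_msca1$best)

  # before the activation point the trajectories coincide; with an
  # always-on firefly branch they then diverge
  r_msca0 <- swarm_optimize(sphere, sp, "msca",
                            msca_config(m = 8, T = 30, phi_threshold = 0), seed = 5)
  act <- ceiling(30 / 3)
  expect_identical(r_sca$history[1:act], r_msca0$history[1:act])
  expect_false(identical(r_sca$history, r_msca0$history))

  # phi_threshold = 0 in the active phase: every row takes the firefly move
  set.seed(7)
  P <- matrix(runif(6, -4, 4), 3, 2)
  f <- c(2, 1, 3)
  cfg <- msca_config(m = 3, T = 9, phi_threshold = 0)
  draws <- make_step_draws(3, 2, seed = 11)
  msca_draws <- list(phi = c(0.4, 0.6, 0.9), r2 = draws$r2m, r3 = draws$r3m,
                     r4 = draws$r4m, kappa = draws$kappa)
  best <- P[2, ]
  got <- msca_step(P, best, f, t = 5, cfg, rep(-9, 2), rep(9, 2),
                   draws = msca_draws)
  for (i in 1:3) {
    want <- oracle_firefly(P[i, ], best, 5, cfg$beta0, cfg$gamma,
                           cfg$alpha0, cfg$alpha_decay, draws$kappa[i, ])
    expect_equal(got[i, ], pmin(pmax(want, -9), 9), tolerance = 1e-12)
  }
})

test_that("swarm_optimize keeps its bookkeeping contracts", {
  sp <- search_space(rep(-5, 5), rep(5, 5))
  sphere <- function(x) sum(x^2)
  for (algo in c("dto", "sca", "msca")) {
    cfg <- if (algo == "dto") dto_config(m = 10, T = 25) else msca_config(m = 10, T = 25)
    r <- swarm_optimize(sphere, sp, algo, cfg, seed = 3)
    expect_length(r$history, 26)
    expect_true(all(diff(r$history) <= 0))            # monotone record
    expect_true(all(r$best >= -5 & r$best <= 5))      # feasibility
    expect_equal(r$evaluations, 10 * 26)              # exact budget
    r2 <- swarm_optimize(sphere, sp, algo, cfg, seed = 3)
    expect_identical(r$history, r2$history)           # seed determinism
  }

  # constant objective: gbest equals the constant at every iteration
  r <- swarm_optimize(function(x) 4.2, sp, "dto", dto_config(m = 5, T = 10), seed = 1)
  expect_true(all(r$history == 4.2))

  # collapsed-but-valid tiny box still returns a point inside it
  tiny <- search_space(c(1, 1), c(1 + 1e-9, 1 + 1e-9))
  r <- swarm_optimize(sphere, tiny, "msca", msca_config(m = 3, T = 3), seed = 1)
  expect_equal(r$best, c(1, 1), tolerance = 1e-6)
  expect_error(search_space(numeric(0), numeric(0)), "at least one")
})

test_that("non-finite objective values are penalized, not fatal", {
  sp <- search_space(rep(-2, 2), rep(2, 2))
  bad <- function(x) if (x[1] > 0) NaN else sum(x^2)
  r <- swarm_optimize(bad, sp, "msca", msca_config(m = 6, T = 10), seed = 2)
  expect_true(is.finite(r$value))
  expect_true(all(diff(r$history) <= 0))
})

test_that("MSCA is at least competitive with SCA on the sphere (soft check)", {
  sp <- search_space(rep(-5, 5), rep(5, 5))
  sphere <- function(x) sum(x^2)
  finals <- vapply(1:10, function(s) {
    c(msca = swarm_optimize(sphere, sp, "msca", msca_config(m = 15, T = 60), seed = s)$value,
      sca = swarm_optimize(sphere, sp, "sca", msca_config(m = 15, T = 60), seed = s)$value)
  }, numeric(2))
  if (median(finals["msca", ]) > median(finals["sca", ])) {
    warning(sprintf("MSCA median %.3g exceeded SCA median %.3g on the sphere",
                    median(finals["msca", ]), median(finals["sca", ])))
  }
  succeed()
})
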