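# Independent straight-line oracles for the optimizer update rules, the ELM
# solve and the metric formulas. These deliberately re-derive every quantity
# with scalar loops / textbook algebra, sharing no code with the package
# internals they check.

# One DTO iteration, scalar transcription: per individual i,
#   X = P_best[i] - K1 |K2 P_best[i] - P[i]|
#   V' = K3 V[i] + K4 r1 (P_best[i] - P[i]) + K5 r2 (P_Gbest - P[i])
#   Y = P[i] + V'
#   P'[i] = X if r3 < 0.5 else Y, clipped to the box.
oracle_dto_step <- function(P, V, P_best, P_Gbest, K4, K5, draws, lower, upper) {
  m <- nrow(P); d <- ncol(P)
  newP <- matrix(0, m, d); newV <- matrix(0, m, d)
  for (i in 1:m) {
    for (j in 1:d) {
      X <- P_best[i, j] - draws$K1[i] * abs(draws$K2[i] * P_best[i, j] - P[i, j])
      Vn <- draws$K3[i] * V[i, j] +
        K4 * draws$r1[i] * (P_best[i, j] - P[i, j]) +
        K5 * draws$r2[i] * (P_Gbest[j] - P[i, j])
      Y <- P[i, j] + Vn
      newV[i, j] <- Vn
      p <- if (draws$r3[i] < 0.5) X else Y
      newP[i, j] <- min(max(p, lower[j]), upper[j])
    }
  }
  list(P = newP, V = newV)
}

# One SCA iteration, scalar transcription of the sine/cosine branches with
# amplitude r1 = a (1 - t/T).
oracle_sca_step <- function(P, best, t, a, T, draws, lower, upper) {
  m <- nrow(P); d <- ncol(P)
  r1 <- a * (1 - t / T)
  newP <- matrix(0, m, d)
  for (i in 1:m) {
    for (j in 1:d) {
      step <- if (draws$r4[i, j] < 0.5) {
        r1 * sin(draws$r2[i, j]) * abs(draws$r3[i, j] * best[j] - P[i, j])
      } else {
        r1 * cos(draws$r2[i, j]) * abs(draws$r3[i, j] * best[j] - P[i, j])
      }
      p <- P[i, j] + step
      newP[i, j] <- min(max(p, lower[j]), upper[j])
    }
  }
  newP
}

# Firefly attraction, scalar transcription.
oracle_firefly <- function(xi, xj, t, beta0, gamma, alpha0, alpha_decay, kappa) {
  r2 <- sum((xi - xj)^2)
  out <- numeric(length(xi))
  for (j in seq_along(xi)) {
    out[j] <- xi[j] + beta0 * exp(-gamma * r2) * (xj[j] - xi[j]) +
      alpha0 * alpha_decay^t * (kappa[j] - 0.5)
  }
  out
}

# One MSCA iteration: phi switch per solution, firefly toward the global
# best when active, SCA row update otherwise.
oracle_msca_step <- function(P, best, t, cfg, draws, lower, upper) {
  m <- nrow(P); d <- ncol(P)
  active <- t >= cfg$activation_fraction * cfg$T
  newP <- oracle_sca_step(P, best, t, cfg$a, cfg$T, draws, lower, upper)
  for (i in 1:m) {
    if (active && draws$phi[i] > cfg$phi_threshold) {
      moved <- oracle_firefly(P[i, ], best, t, cfg$beta0, cfg$gamma,
                              cfg$alpha0, cfg$alpha_decay, draws$kappa[i, ])
      newP[i, ] <- pmin(pmax(moved, lower), upper)
    }
  }
  newP
}

# Normal-equations least-squares solve of H beta = Y (full column rank).
oracle_normal_equations <- function(H, Y) {
  solve(t(H) %*% H, t(H) %*% Y)
}

# Element-by-element hidden matrix.
oracle_hidden_matrix <- function(X, w, b, g) {
  N <- nrow(X); L <- nrow(w)
  H <- matrix(0, N, L)
  for (j in 1:N) for (i in 1:L) {
    a <- sum(w[i, ] * X[j, ]) + b[i]
    H[j, i] <- switch(g, sigmoid = 1 / (1 + exp(-a)), relu = max(a, 0),
                      tanh = tanh(a))
  }
  H
}

# Dictionary-counting confusion matrix.
oracle_confusion <- function(y_true, y_pred, C) {
  counts <- new.env()
  for (i in seq_along(y_true)) {
    key <- paste(y_true[i], y_pred[i])
    counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
  }
  cm <- matrix(0L, C, C)
  for (key in ls(counts)) {
    ij <- as.integer(strsplit(key, " ")[[1]])
    cm[ij[1] + 1L, ij[2] + 1L] <- counts[[key]]
  }
  cm
}

# Brute-force nearest-centroid classifier: fit centroids on train rows,
# predict by minimum Euclidean distance.
nearest_centroid_error <- function(X_train, y_train, X_test, y_test) {
  classes <- sort(unique(y_train))
  centroids <- t(vapply(classes, function(k) {
    colMeans(X_train[y_train == k, , drop = FALSE])
  }, numeric(ncol(X_train))))
  pred <- apply(X_test, 1, function(x) {
    classes[which.min(colSums((t(centroids) - x)^2))]
  })
  mean(pred != y_test)
}

# Fixed draws for one optimizer step on an m x d problem.
make_step_draws <- function(m, d, seed, k_range = c(0, 2)) {
  set.seed(seed)
  list(r1 = runif(m), r2m = matrix(runif(m * d, 0, 2 * pi), m, d),
       r2 = runif(m), r3 = runif(m),
       K1 = runif(m, k_range[1], k_range[2]),
       K2 = runif(m, k_range[1], k_range[2]),
       K3 = runif(m, k_range[1], k_range[2]),
       r3m = matrix(runif(m * d, 0, 2), m, d),
       r4m = matrix(runif(m * d), m, d),
       phi = runif(m), kappa = matrix(rnorm(m * d), m, d))
}

# A four-configuration extractor family over a 1-D search space: exactly one
# decoded configuration (index `good`) returns class-informative features
# (per-band patch means); the others return features decoupled from the
# labels (deterministically shuffled rows or constants). Used to check that
# stage-1 tuning recovers the one separable configuration.
planted_family <- function(good = 2L) {
  force(good)
  function(images, hp, seed) {
    idx <- hp$config_idx
    d <- dim(images$patches)
    means <- t(apply(images$patches, 1, function(p) {
      apply(array(p, dim = d[2:4]), 1, mean)
    }))
    n <- d[1]
    X <- if (idx == good) {
      means
    } else if (idx %% 2L == 0L) {
      matrix(0.5, n, d[2])                       # constant features
    } else {
      means[((seq_len(n) + n %/% 2L - 1L) %% n) + 1L, , drop = FALSE]  # label-decoupled
    }
    feature_table(X, images$labels)
  }
}

planted_space <- function() search_space(0, 3.999, names = "config_idx")

decode_planted <- function(position) {
  structure(list(config_idx = as.integer(floor(min(max(position, 0), 3.999)))),
            class = "extractor_hyperparams")
}
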