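# Inference engines for the Gaussian hierarchical model
#
#   y = M c + e,  e ~ N(0, sigma2 I),  c ~ N(0, D(theta)^-1)
#
# where M = [X | A_1 | ... | A_B] stacks fixed-effect columns and the
# (reparameterized) random-effect blocks, and D is diagonal: beta_precision
# for fixed effects and tau_b * lambda_bj for block b coordinate j.  Given
# the precisions the coefficient posterior is exactly Gaussian with
# precision P = MtM/sigma2 + D; both engines exploit that conjugacy through
# one sparse Cholesky factorization per precision setting (CHOLMOD, with the
# symbolic factorization reused across updates).  Sum-to-zero constraints on
# iid blocks are imposed by conditioning-by-kriging on means and draws.

engine_prep <- function(design, priors) {
  M <- design$M
  p <- ncol(M)
  n <- design$n
  MtM <- Matrix::forceSymmetric(Matrix::crossprod(M))
  Mty <- as.vector(Matrix::crossprod(M, design$y))
  yty <- sum(design$y^2)

  lam <- rep(priors$beta_precision, p)   # template; block entries scaled by tau
  for (b in design$blocks) lam[b$cols] <- b$lambda

  taus <- paste0("tau_", names(design$blocks))
  fixed <- priors$fixed
  free <- c(if (is.null(fixed$sigma2)) "sigma2", setdiff(taus, names(fixed)))
  # constraint matrix (k x p), one row per constrained block
  con <- Filter(function(b) !is.null(b$constraint), design$blocks)
  Acon <- if (length(con)) {
    rows <- lapply(seq_along(con), function(k)
      cbind(k, con[[k]]$cols, con[[k]]$constraint))
    ijx <- do.call(rbind, rows)
    Matrix::sparseMatrix(i = ijx[, 1], j = ijx[, 2], x = ijx[, 3],
                         dims = c(length(con), p))
  } else NULL
  ncon <- vapply(design$blocks, function(b) length(b$constraint) > 0, logical(1))

  # template for fast posterior-precision rebuilds: P = MtM * tau_e + diag(d).
  # Adding an explicit identity guarantees every diagonal entry is stored
  # (a level unobserved in a subset fit gives an empty indicator column);
  # dsCMatrix stores the upper triangle column-wise, so the diagonal entry
  # of column j is its last stored element.
  Pt <- methods::as(Matrix::forceSymmetric(MtM + Matrix::Diagonal(p)),
                    "CsparseMatrix")
  diag_pos <- Pt@p[-1L]
  stopifnot(all(Pt@i[diag_pos] == seq_len(p) - 1L))
  base_x <- Pt@x
  base_x[diag_pos] <- base_x[diag_pos] - 1   # pure MtM values on the pattern

  list(M = M, MtM = MtM, Mty = Mty, yty = yty, n = n, p = p,
       lambda_template = lam, tau_names = taus, free = free, fixed = fixed,
       Acon = Acon, has_constraint = ncon, P_template = Pt,
       P_x = base_x, diag_pos = diag_pos)
}

# diagonal of the prior precision for a named precision vector
prior_diag <- function(prep, design, tau) {
  d <- prep$lambda_template
  for (i in seq_along(design$blocks)) {
    b <- design$blocks[[i]]
    d[b$cols] <- d[b$cols] * tau[[prep$tau_names[i]]]
  }
  d
}

# moment-based initial values for the precisions
init_hypers <- function(prep, design) {
  vy <- stats::var(design$y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  vals <- c(sigma2 = vy / 2,
            stats::setNames(rep(1 / (0.1 * vy), length(prep$tau_names)),
                            prep$tau_names))
  vals
}

eng_laplace <- function(design, priors, control) {
  prep <- engine_prep(design, priors)
  n <- prep$n; p <- prep$p
  shape <- priors$tau_shape; rate <- priors$tau_rate

  init <- init_hypers(prep, design)
  for (nm in names(control$init_hypers %||% list()))
    if (nm %in% names(init)) init[[nm]] <- control$init_hypers[[nm]]
  for (nm in names(prep$fixed)) init[[nm]] <- prep$fixed[[nm]]
  free <- prep$free

  Ch <- NULL
  make_P <- function(vals) {
    tau_e <- 1 / vals[["sigma2"]]
    d <- prior_diag(prep, design, vals)
    x <- prep$P_x * tau_e
    x[prep$diag_pos] <- x[prep$diag_pos] + d
    P <- prep$P_template
    P@x <- x
    list(P = P, tau_e = tau_e, d = d)
  }
  neg_log_post <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 34)) return(1e10)
    vals <- init
    vals[free] <- exp(theta)
    parts <- make_P(vals)
    Ch <<- if (is.null(Ch)) Matrix::Cholesky(parts$P, LDL = FALSE, perm = TRUE)
           else Matrix::update(Ch, parts$P)
    b <- parts$tau_e * prep$Mty
    m <- as.vector(Matrix::solve(Ch, b, system = "A"))
    logdetP <- 2 * as.numeric(Matrix::determinant(Ch, logarithm = TRUE, sqrt = TRUE)$modulus)
    quad <- parts$tau_e * prep$yty - sum(b * m)
    ll <- 0.5 * sum(log(parts$d)) - 0.5 * logdetP +
      0.5 * n * log(parts$tau_e) - 0.5 * quad - 0.5 * n * log(2 * pi)
    # Gamma hyperpriors on every free precision (sigma2 enters as 1/sigma2),
    # with the log-scale Jacobian
    prec <- 1 / vals[["sigma2"]]
    lp <- ll
    if ("sigma2" %in% free)
      lp <- lp + stats::dgamma(prec, shape, rate, log = TRUE) + log(prec)
    for (nm in setdiff(free, "sigma2"))
      lp <- lp + stats::dgamma(vals[[nm]], shape, rate, log = TRUE) + log(vals[[nm]])
    if (!is.finite(lp)) return(1e10)
    -lp
  }

  conv <- 0L
  theta_hat <- numeric(0)
  if (length(free)) {
    theta0 <- log(init[free])
    if (length(free) == 1L) {
      opt <- stats::optimize(function(t) neg_log_post(t), c(-30, 30), tol = 1e-7)
      theta_hat <- opt$minimum
    } else {
      opt <- stats::optim(theta0, neg_log_post, method = "Nelder-Mead",
                          control = list(maxit = control$maxit, reltol = 1e-8))
      theta_hat <- opt$par
      conv <- opt$convergence
    }
    init[free] <- exp(theta_hat)
  }
  vals_hat <- init

  # solve one precision setting: conditional mean, constrained draws
  solve_component <- function(vals, ndraw, want_sigma = FALSE) {
    parts <- make_P(vals)
    Ch <<- if (is.null(Ch)) Matrix::Cholesky(parts$P, LDL = FALSE, perm = TRUE)
           else Matrix::update(Ch, parts$P)
    b <- parts$tau_e * prep$Mty
    m <- as.vector(Matrix::solve(Ch, b, system = "A"))
    Z <- matrix(stats::rnorm(p * ndraw), p, ndraw)
    dr <- Matrix::solve(Ch, Z, system = "Lt")
    dr <- as.matrix(Matrix::solve(Ch, dr, system = "Pt")) + m
    Sigma <- if (want_sigma)
      as.matrix(Matrix::solve(Ch, Matrix::Diagonal(p), system = "A")) else NULL
    if (!is.null(prep$Acon)) {   # conditioning-by-kriging on the constraints
      V <- as.matrix(Matrix::solve(Ch, Matrix::t(prep$Acon), system = "A"))
      Sk <- as.matrix(prep$Acon %*% V)
      W <- V %*% solve(Sk)
      m <- as.vector(m - W %*% as.vector(prep$Acon %*% m))
      dr <- dr - W %*% as.matrix(prep$Acon %*% dr)
      if (want_sigma) Sigma <- Sigma - W %*% t(V)
    }
    list(m = m, draws = dr, Sigma = Sigma)
  }

  # hyperparameter uncertainty: Gaussian approximation to p(log theta | y) at
  # the mode, sampled; the coefficient posterior is the equal-weight mixture
  # of the conditional Gaussians.  K = 1 (or no free hypers) degenerates to
  # empirical Bayes at the mode.
  S <- control$draws
  K <- if (length(free)) max(1L, min(control$hyper_draws %||% 20L, S)) else 1L
  theta_mat <- matrix(theta_hat, nrow = 1L)
  if (K > 1L) {
    H <- stats::optimHess(theta_hat, neg_log_post)
    eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
    evals <- pmax(eg$values, 1e-2)   # cap hyper-posterior sd at 10 (log scale)
    Sig_half <- eg$vectors %*% diag(1 / sqrt(evals), length(evals))
    theta_mat <- matrix(theta_hat, K, length(free), byrow = TRUE) +
      matrix(stats::rnorm(K * length(free)), K) %*% t(Sig_half)
    theta_mat <- pmin(pmax(theta_mat, -33), 33)
  }

  per <- ceiling(S / K)
  comp_means <- matrix(NA_real_, p, K)
  dr <- matrix(NA_real_, p, K * per)
  sigma2_comp <- numeric(K)
  Sigma_hat <- NULL
  for (kk in seq_len(K)) {
    vals <- vals_hat
    if (length(free)) vals[free] <- exp(theta_mat[kk, ])
    cs <- solve_component(vals, per, want_sigma = (kk == 1L && all(theta_mat[1L, ] == theta_hat)))
    comp_means[, kk] <- cs$m
    dr[, (kk - 1L) * per + seq_len(per)] <- cs$draws
    sigma2_comp[kk] <- vals[["sigma2"]]
    if (!is.null(cs$Sigma)) Sigma_hat <- cs$Sigma
  }
  if (is.null(Sigma_hat)) {
    cs <- solve_component(vals_hat, 1L, want_sigma = TRUE)
    Sigma_hat <- cs$Sigma
    m_hat <- cs$m
  } else m_hat <- comp_means[, 1L]

  m <- rowMeans(comp_means)
  if (K > 1L) {
    sds <- apply(dr, 1L, stats::sd)
    qs <- apply(dr, 1L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
    q025 <- qs[1L, ]; q975 <- qs[2L, ]
  } else {
    sds <- sqrt(pmax(diag(Sigma_hat), 0))
    q025 <- m + stats::qnorm(0.025) * sds
    q975 <- m + stats::qnorm(0.975) * sds
  }

  sigma2 <- vals_hat[["sigma2"]]
  tau <- vals_hat[prep$tau_names]

  fitted <- as.vector(prep$M %*% m)
  # DIC at the hyperparameter mode (modal conditional mean and curvature)
  rss_hat <- sum((design$y - as.vector(prep$M %*% m_hat))^2)
  d_hat <- n * log(2 * pi * sigma2) + rss_hat / sigma2
  p_d <- sum(as.matrix(prep$MtM) * Sigma_hat) / sigma2
  dic <- list(dbar = d_hat + p_d, p_d = p_d, dic = d_hat + 2 * p_d)

  list(engine = "laplace", mean = m, sd = sds, Sigma = Sigma_hat,
       q025 = q025, q975 = q975,
       draws = dr, sigma2 = sigma2, tau = tau,
       hyper_draws = if (K > 1L) {
         hm <- t(exp(theta_mat)); rownames(hm) <- free; hm
       } else NULL,
       fitted = fitted, dic = dic,
       diagnostics = list(converged = conv == 0L, optim_code = conv,
                          free_hypers = free, hyper_components = K))
}

eng_gibbs <- function(design, priors, control) {
  prep <- engine_prep(design, priors)
  n <- prep$n; p <- prep$p
  shape <- priors$tau_shape; rate <- priors$tau_rate
  chains <- control$chains
  keep_per <- ceiling(control$draws / chains)
  iters <- control$warmup + keep_per

  init <- init_hypers(prep, design)
  for (nm in names(control$init_hypers %||% list()))
    if (nm %in% names(init)) init[[nm]] <- control$init_hypers[[nm]]
  for (nm in names(prep$fixed)) init[[nm]] <- prep$fixed[[nm]]
  free <- prep$free
  nblocks <- length(design$blocks)

  all_draws <- vector("list", chains)
  all_hyp <- vector("list", chains)
  Ch <- NULL

  for (ch_i in seq_len(chains)) {
    vals <- init
    if (length(free)) vals[free] <- vals[free] * exp(stats::runif(length(free), -0.5, 0.5))
    keep <- matrix(NA_real_, p, keep_per)
    hyp <- matrix(NA_real_, 1L + nblocks, keep_per,
                  dimnames = list(c("sigma2", prep$tau_names), NULL))
    for (it in seq_len(iters)) {
      tau_e <- 1 / vals[["sigma2"]]
      d <- prior_diag(prep, design, vals)
      px <- prep$P_x * tau_e
      px[prep$diag_pos] <- px[prep$diag_pos] + d
      P <- prep$P_template
      P@x <- px
      Ch <- if (is.null(Ch)) Matrix::Cholesky(P, LDL = FALSE, perm = TRUE)
            else Matrix::update(Ch, P)
      b <- tau_e * prep$Mty
      m <- as.vector(Matrix::solve(Ch, b, system = "A"))
      z <- stats::rnorm(p)
      cc <- as.vector(Matrix::solve(Ch, Matrix::solve(Ch, z, system = "Lt"),
                                    system = "Pt")) + m
      if (!is.null(prep$Acon)) {
        V <- as.matrix(Matrix::solve(Ch, Matrix::t(prep$Acon), system = "A"))
        Sk <- as.matrix(prep$Acon %*% V)
        W <- V %*% solve(Sk)
        cc <- cc - as.vector(W %*% as.vector(prep$Acon %*% cc))
      }
      for (i in seq_len(nblocks)) {
        nm <- prep$tau_names[i]
        if (nm %in% free) {
          bl <- design$blocks[[i]]
          w <- cc[bl$cols]
          df_b <- length(bl$cols) - (if (is.null(bl$constraint)) 0L else 1L)
          vals[[nm]] <- stats::rgamma(1, shape + df_b / 2,
                                      rate + 0.5 * sum(bl$lambda * w^2))
        }
      }
      if ("sigma2" %in% free) {
        rss <- sum((design$y - as.vector(prep$M %*% cc))^2)
        vals[["sigma2"]] <- 1 / stats::rgamma(1, shape + n / 2, rate + rss / 2)
      }
      if (it > control$warmup) {
        keep[, it - control$warmup] <- cc
        hyp[, it - control$warmup] <- c(vals[["sigma2"]], unlist(vals[prep$tau_names]))
      }
    }
    all_draws[[ch_i]] <- keep
    all_hyp[[ch_i]] <- hyp
  }

  dr <- do.call(cbind, all_draws)
  hyp <- do.call(cbind, all_hyp)
  m <- rowMeans(dr)
  sds <- apply(dr, 1L, stats::sd)
  qs <- apply(dr, 1L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)

  rhat <- if (chains >= 2L) {
    cm <- vapply(all_draws, rowMeans, numeric(p))
    cv <- vapply(all_draws, function(d) apply(d, 1, stats::var), numeric(p))
    Bv <- keep_per * apply(cm, 1, stats::var)
    Wv <- rowMeans(cv)
    sqrt(pmax((keep_per - 1) / keep_per + Bv / (keep_per * pmax(Wv, 1e-300)), 0))
  } else rep(NA_real_, p)

  sigma2_draws <- hyp["sigma2", ]
  sigma2 <- mean(sigma2_draws)
  tau <- rowMeans(hyp)[prep$tau_names]

  fitted <- as.vector(prep$M %*% m)
  # DIC from the sampled deviances
  dev <- vapply(seq_len(ncol(dr)), function(s) {
    rss <- sum((design$y - as.vector(prep$M %*% dr[, s]))^2)
    n * log(2 * pi * sigma2_draws[s]) + rss / sigma2_draws[s]
  }, numeric(1))
  dbar <- mean(dev)
  d_hat <- n * log(2 * pi * sigma2) + sum((design$y - fitted)^2) / sigma2
  dic <- list(dbar = dbar, p_d = dbar - d_hat, dic = 2 * dbar - d_hat)

  list(engine = "mcmc", mean = m, sd = sds, Sigma = NULL,
       q025 = qs[1L, ], q975 = qs[2L, ], draws = dr,
       sigma2 = sigma2, tau = as.list(tau),
       hyper_draws = hyp, fitted = fitted, dic = dic,
       diagnostics = list(converged = all(is.na(rhat)) || max(rhat, na.rm = TRUE) < 1.1,
                          max_rhat = suppressWarnings(max(rhat, na.rm = TRUE)),
                          chains = chains, kept = ncol(dr)))
}
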