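# A compact no-U-turn sampler (NUTS) with dual-averaging step-size
# adaptation and diagonal mass-matrix estimation, plus split-Rhat and
# effective-sample-size diagnostics. Self-contained: no external MCMC
# backend is assumed.
#
# The target is supplied as lp_grad(theta) -> list(lp = scalar log density,
# grad = gradient vector), on an unconstrained parameter space.

find_reasonable_epsilon <- function(lp_grad, theta, v) {
  eps <- 1
  p <- stats::rnorm(length(theta), 0, 1 / sqrt(v))
  cur <- lp_grad(theta)
  joint0 <- cur$lp - 0.5 * sum(p^2 * v)
  step <- leapfrog(lp_grad, theta, p, eps, v, cur$grad)
  joint1 <- step$lp - 0.5 * sum(step$p^2 * v)
  if (!is.finite(joint1)) joint1 <- -Inf
  a <- if (joint1 - joint0 > log(0.5)) 1 else -1
  for (k in 1:50) {
    eps <- eps * 2^a
    step <- leapfrog(lp_grad, theta, p, eps, v, cur$grad)
    joint1 <- step$lp - 0.5 * sum(step$p^2 * v)
    if (!is.finite(joint1)) joint1 <- -Inf
    if (a * (joint1 - joint0) <= a * log(0.5)) break
  }
  eps
}

leapfrog <- function(lp_grad, theta, p, eps, v, grad) {
  p <- p + 0.5 * eps * grad
  theta <- theta + eps * v * p
  cur <- lp_grad(theta)
  if (!is.finite(cur$lp) || any(!is.finite(cur$grad))) {
    return(list(theta = theta, p = p, lp = -Inf, grad = grad * 0))
  }
  p <- p + 0.5 * eps * cur$grad
  list(theta = theta, p = p, lp = cur$lp, grad = cur$grad)
}

build_tree <- function(lp_grad, theta, p, grad, lp, logu, dir, depth, eps, v,
                       joint0) {
  if (depth == 0) {
    st <- leapfrog(lp_grad, theta, dir * p, eps, v, grad)
    st$p <- dir * st$p
    joint <- st$lp - 0.5 * sum(st$p^2 * v)
    if (!is.finite(joint)) joint <- -Inf
    divergent <- (logu - joint) > 1000
    n_prime <- as.integer(joint >= logu)
    alpha <- min(1, exp(joint - joint0))
    if (!is.finite(alpha)) alpha <- 0
    return(list(theta_minus = st$theta, p_minus = st$p, grad_minus = st$grad,
                lp_minus = st$lp,
                theta_plus = st$theta, p_plus = st$p, grad_plus = st$grad,
                lp_plus = st$lp,
                theta_prime = st$theta, lp_prime = st$lp, grad_prime = st$grad,
                n_prime = n_prime, s_prime = !divergent,
                alpha = alpha, n_alpha = 1L, divergent = divergent))
  }
  t1 <- build_tree(lp_grad, theta, p, grad, lp, logu, dir, depth - 1, eps, v,
                   joint0)
  if (!t1$s_prime) return(t1)
  if (dir == -1) {
    t2 <- build_tree(lp_grad, t1$theta_minus, t1$p_minus, t1$grad_minus,
                     t1$lp_minus, logu, dir, depth - 1, eps, v, joint0)
    t1$theta_minus <- t2$theta_minus; t1$p_minus <- t2$p_minus
    t1$grad_minus <- t2$grad_minus; t1$lp_minus <- t2$lp_minus
  } else {
    t2 <- build_tree(lp_grad, t1$theta_plus, t1$p_plus, t1$grad_plus,
                     t1$lp_plus, logu, dir, depth - 1, eps, v, joint0)
    t1$theta_plus <- t2$theta_plus; t1$p_plus <- t2$p_plus
    t1$grad_plus <- t2$grad_plus; t1$lp_plus <- t2$lp_plus
  }
  ntot <- t1$n_prime + t2$n_prime
  if (t2$n_prime > 0 && stats::runif(1) < t2$n_prime / max(ntot, 1L)) {
    t1$theta_prime <- t2$theta_prime
    t1$lp_prime <- t2$lp_prime
    t1$grad_prime <- t2$grad_prime
  }
  dtheta <- t1$theta_plus - t1$theta_minus
  no_uturn <- (sum(dtheta * (v * t1$p_minus)) >= 0) &&
    (sum(dtheta * (v * t1$p_plus)) >= 0)
  t1$n_prime <- ntot
  t1$s_prime <- t2$s_prime && no_uturn
  t1$alpha <- t1$alpha + t2$alpha
  t1$n_alpha <- t1$n_alpha + t2$n_alpha
  t1$divergent <- t1$divergent || t2$divergent
  t1
}

nuts_chain <- function(lp_grad, init, iter, warmup, max_treedepth, adapt_delta,
                       v_init = NULL) {
  n_par <- length(init)
  v <- v_init %||% rep(1, n_par)
  theta <- init
  cur <- lp_grad(theta)
  if (!is.finite(cur$lp)) stop_replistat("invalid initial point",
                                         "replistat_sampler_error")
  eps <- find_reasonable_epsilon(lp_grad, theta, v)
  # dual averaging state
  mu <- log(10 * eps); eps_bar <- 1; h_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75; da_count <- 0
  # mass adaptation windows (Stan-like: initial buffer, doubling windows,
  # terminal buffer)
  init_buf <- min(75, floor(warmup * 0.15))
  term_buf <- min(50, floor(warmup * 0.1))
  win_ends <- integer(0)
  if (warmup - init_buf - term_buf > 40) {
    w <- 25; pos <- init_buf
    while (pos + w < warmup - term_buf) {
      pos <- pos + w
      win_ends <- c(win_ends, pos)
      w <- w * 2
    }
    win_ends[length(win_ends)] <- warmup - term_buf
    win_ends <- unique(win_ends)
  }
  win_start <- init_buf + 1

  draws <- matrix(NA_real_, nrow = iter, ncol = n_par)
  lps <- numeric(iter)
  divergences <- 0L
  treedepths <- integer(iter)
  acc_window <- list()

  total <- warmup + iter
  for (it in seq_len(total)) {
    p0 <- stats::rnorm(n_par, 0, 1 / sqrt(v))
    joint0 <- cur$lp - 0.5 * sum(p0^2 * v)
    logu <- joint0 - stats::rexp(1)
    tm <- theta; tp <- theta; pm <- p0; pp <- p0
    gm <- cur$grad; gp <- cur$grad; lm <- cur$lp; lpp <- cur$lp
    depth <- 0L; n_acc <- 1L; s <- TRUE
    alpha_sum <- 0; n_alpha <- 0L; div_it <- FALSE
    theta_new <- theta; lp_new <- cur$lp; grad_new <- cur$grad
    while (s && depth < max_treedepth) {
      dir <- if (stats::runif(1) < 0.5) -1 else 1
      if (dir == -1) {
        tr <- build_tree(lp_grad, tm, pm, gm, lm, logu, dir, depth, eps, v,
                         joint0)
        tm <- tr$theta_minus; pm <- tr$p_minus; gm <- tr$grad_minus
        lm <- tr$lp_minus
      } else {
        tr <- build_tree(lp_grad, tp, pp, gp, lpp, logu, dir, depth, eps, v,
                         joint0)
        tp <- tr$theta_plus; pp <- tr$p_plus; gp <- tr$grad_plus
        lpp <- tr$lp_plus
      }
      if (tr$s_prime && tr$n_prime > 0 &&
          stats::runif(1) < tr$n_prime / max(n_acc, 1L)) {
        theta_new <- tr$theta_prime; lp_new <- tr$lp_prime
        grad_new <- tr$grad_prime
      }
      n_acc <- n_acc + tr$n_prime
      alpha_sum <- alpha_sum + tr$alpha; n_alpha <- n_alpha + tr$n_alpha
      div_it <- div_it || tr$divergent
      dtheta <- tp - tm
      s <- tr$s_prime && (sum(dtheta * (v * pm)) >= 0) &&
        (sum(dtheta * (v * pp)) >= 0)
      depth <- depth + 1L
    }
    theta <- theta_new
    cur <- list(lp = lp_new, grad = grad_new)
    a_stat <- if (n_alpha > 0) alpha_sum / n_alpha else 0

    if (it <= warmup) {
      da_count <- da_count + 1
      frac <- 1 / (da_count + t0)
      h_bar <- (1 - frac) * h_bar + frac * (adapt_delta - a_stat)
      log_eps <- mu - sqrt(da_count) / gamma * h_bar
      w_da <- da_count^(-kappa)
      eps_bar <- exp(w_da * log_eps + (1 - w_da) * log(eps_bar))
      eps <- exp(log_eps)
      if (it >= win_start && length(win_ends) > 0) {
        acc_window[[length(acc_window) + 1L]] <- theta
        if (it == win_ends[1]) {
          m <- do.call(rbind, acc_window)
          nw <- nrow(m)
          if (nw >= 10) {
            var_est <- apply(m, 2, stats::var)
            v <- (nw / (nw + 5)) * var_est + 1e-3 * (5 / (nw + 5))
            v[!is.finite(v) | v <= 0] <- 1e-3
          }
          acc_window <- list()
          win_ends <- win_ends[-1]
          eps <- find_reasonable_epsilon(lp_grad, theta, v)
          mu <- log(10 * eps); eps_bar <- 1; h_bar <- 0; da_count <- 0
        }
      }
      if (it == warmup) eps <- eps_bar
    } else {
      idx <- it - warmup
      draws[idx, ] <- theta
      lps[idx] <- lp_new
      treedepths[idx] <- depth
      if (div_it) divergences <- divergences + 1L
    }
  }
  list(draws = draws, lp = lps, divergences = divergences,
       eps = eps, inv_mass = v, treedepth = treedepths)
}

#' Sample from a log posterior with the built-in no-U-turn sampler
#'
#' @param lp_grad Function of the unconstrained parameter vector returning
#'   `list(lp =, grad =)`.
#' @param n_par Number of parameters.
#' @param chains,iter,warmup Sampler controls (post-warmup draws per chain).
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param init Either a function `(chain_id) -> numeric(n_par)` or a matrix
#'   of chain inits; default small random values.
#' @param max_treedepth,adapt_delta NUTS tuning.
#' @return List with `draws` (iter x chains x n_par array), `divergences`,
#'   per-chain step sizes and mass estimates.
#' @keywords internal
#' @export
nuts_sample <- function(lp_grad, n_par, chains = 4, iter = 400, warmup = 400,
                        seed = 1, init = NULL, max_treedepth = 9,
                        adapt_delta = 0.8) {
  draws <- array(NA_real_, dim = c(iter, chains, n_par))
  divs <- integer(chains); epss <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch)
    th0 <- if (is.function(init)) init(ch)
           else if (is.matrix(init)) init[ch, ]
           else stats::runif(n_par, -0.5, 0.5)
    res <- nuts_chain(lp_grad, th0, iter, warmup, max_treedepth, adapt_delta)
    draws[, ch, ] <- res$draws
    divs[ch] <- res$divergences
    epss[ch] <- res$eps
  }
  list(draws = draws, divergences = sum(divs), step_sizes = epss)
}

#' Split-chain potential scale reduction factor (Rhat)
#'
#' @param x Matrix of draws, iterations x chains.
#' @return Scalar split-Rhat.
#' @keywords internal
#' @export
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  w <- mean(vars)
  b <- nn * stats::var(means)
  if (w == 0) return(1)
  sqrt((nn - 1) / nn + b / (w * nn))
}

#' Effective sample size across chains
#'
#' Combined-chain ESS using per-chain autocovariances and Geyer's initial
#' monotone positive sequence.
#'
#' @param x Matrix of draws, iterations x chains.
#' @return Scalar ESS estimate.
#' @keywords internal
#' @export
ess_mean <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (stats::sd(as.vector(x)) == 0) return(n * m)
  lag_max <- min(n - 2, 400)
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = lag_max, type = "covariance",
                    plot = FALSE, demean = TRUE)
    as.vector(a$acf)
  })
  mean_acov <- rowMeans(acov)
  w <- mean(apply(x, 2, stats::var))
  b_term <- if (m > 1) stats::var(colMeans(x)) else 0
  var_plus <- w * (n - 1) / n + b_term
  rho <- 1 - (w - mean_acov) / var_plus
  rho[1] <- 1
  # Geyer initial monotone positive sequence on paired sums
  tau <- 0
  k <- 1
  prev_pair <- Inf
  while (k + 1 <= length(rho)) {
    pair <- rho[k + 1] + (if (k + 2 <= length(rho)) rho[k + 2] else 0)
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    tau <- tau + pair
    k <- k + 2
  }
  ess <- n * m / (1 + 2 * tau)
  max(min(ess, n * m), 1)
}
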