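#' Stationary distribution of a Markov chain
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalised to
#' a probability vector, computed by eigen-decomposition and validated
#' against `pi T = pi`.
#'
#' @param T row-stochastic transition matrix.
#' @return stationary probability vector.
#' @export
stationary_distribution <- function(T) {
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  pi <- v / sum(v)
  if (any(pi <= 0))
    stop("chain does not appear irreducible: stationary weights <= 0")
  if (max(abs(as.numeric(pi %*% T) - pi)) > 1e-10)
    stop("failed to compute stationary distribution to 1e-10")
  pi
}

#' Latent Markov-chain environment
#'
#' Describes a stationary environment in which both the dendritic input
#' (per-state PSP values, matrix `B` of states x synapses) and the somatic
#' input rate `r_I = phi(U*)` depend on the state of a latent,
#' irreducible Markov chain with transition matrix `T`. `gamma` is the
#' per-step discount of the low-pass PSP trace and `delta` the duration of
#' one chain step.
#'
#' @param T row-stochastic transition matrix.
#' @param B per-state x per-synapse PSP matrix.
#' @param r_I per-state somatic input rate (kHz).
#' @param lam nudging factor, scalar or per-state vector.
#' @param gamma per-step discount in `[0, 1)`.
#' @param delta step duration (ms).
#' @param pi optional stationary distribution; computed and validated when
#'   missing.
#' @return An object of class `markov_environment`.
#' @export
markov_environment <- function(T, B, r_I, lam, gamma, delta = 1, pi = NULL) {
  T <- as.matrix(T)
  n <- nrow(T)
  stopifnot(ncol(T) == n, all(T >= 0))
  if (max(abs(rowSums(T) - 1)) > 1e-10)
    stop("rows of T must sum to 1")
  stopifnot(gamma >= 0, gamma < 1, delta > 0)
  B <- as.matrix(B)
  stopifnot(nrow(B) == n, length(r_I) == n)
  lam <- rep_len(lam, n)  # 0 = full clamping, 1 = no somatic input
  stopifnot(all(lam >= 0), all(lam <= 1))
  if (is.null(pi)) pi <- stationary_distribution(T)
  else if (max(abs(as.numeric(pi %*% T) - pi)) > 1e-10)
    stop("supplied pi is not stationary for T")
  structure(list(n_states = n, T = T, pi = pi, B = B,
                 r_I = as.numeric(r_I), lam = lam,
                 gamma = gamma, delta = delta),
            class = "markov_environment")
}

#' @export
print.markov_environment <- function(x, ...) {
  cat(sprintf("Markov environment: %d states, %d synapses, gamma = %g, delta = %g ms\n",
              x$n_states, ncol(x$B), x$gamma, x$delta))
  invisible(x)
}

#' Discounting operator of the chain
#'
#' `A = alpha sum_t gamma^t T^t = alpha (I - gamma T)^{-1}`, computed by
#' linear solve (`method = "solve"`) or, as a cross-check oracle, by
#' truncated series summation (`method = "series"`, truncated where
#' `gamma^t < 1e-12`). Every row of `A` sums to `alpha / (1 - gamma)`.
#'
#' @param env a [markov_environment()].
#' @param alpha potentiation factor.
#' @param method computation route.
#' @return the matrix `A`.
#' @export
discount_operator <- function(env, alpha, method = c("solve", "series")) {
  method <- match.arg(method)
  T <- env$T; gamma <- env$gamma; n <- env$n_states
  if (method == "solve")
    return(alpha * solve(diag(n) - gamma * T))
  A <- diag(n); Tk <- diag(n); gk <- 1
  t_max <- if (gamma == 0) 0 else ceiling(log(1e-12) / log(gamma))
  for (t in seq_len(t_max)) {
    Tk <- Tk %*% T
    gk <- gk * gamma
    A <- A + gk * Tk
  }
  alpha * A
}

#' Effective discount factor of the learned code
#'
#' `gamma_eff = gamma / (1 - lam alpha)`, the stretched per-step discount
#' implied by the bootstrapping effect; approaches 1 as
#' `alpha -> (1 - gamma)/lam`.
#'
#' @param env a [markov_environment()] (scalar nudging assumed).
#' @param alpha potentiation factor.
#' @return `gamma_eff`.
#' @export
effective_discount <- function(env, alpha) {
  lam <- env$lam[1]
  if (lam * alpha >= 1 - env$gamma)
    stop("convergence condition lam * alpha < 1 - gamma violated")
  env$gamma / (1 - lam * alpha)
}

#' Stationary dendritic rate on a Markov chain
#'
#' Fixed point of the mean learning dynamics for linear transfer:
#' `r_V = (I - A Lambda)^{-1} A r_I`, which for scalar nudging equals the
#' `gamma_eff`-discounted expectation
#' `(alpha/(1 - lam alpha)) sum_t gamma_eff^t T^t r_I`
#' (`method = "series"`, an independent summation oracle). Requires the
#' convergence condition `lam alpha < 1 - gamma`.
#'
#' @param env a [markov_environment()].
#' @param alpha potentiation factor.
#' @param method computation route.
#' @return per-state stationary dendritic rate `r_V`.
#' @export
markov_fixed_point <- function(env, alpha, method = c("solve", "series")) {
  method <- match.arg(method)
  lam <- env$lam
  if (max(lam) * alpha >= 1 - env$gamma)
    stop("convergence condition lam * alpha < 1 - gamma violated")
  A <- discount_operator(env, alpha)
  n <- env$n_states
  if (method == "solve")
    return(as.numeric(solve(diag(n) - A %*% diag(lam, n), A %*% env$r_I)))
  # series route assumes scalar nudging
  g_eff <- effective_discount(env, alpha)
  pref <- alpha / (1 - lam[1] * alpha)
  rv <- numeric(n); x <- env$r_I; gk <- 1
  t_max <- ceiling(log(1e-12) / log(g_eff))
  for (t in 0:t_max) {
    rv <- rv + gk * x
    x <- as.numeric(env$T %*% x)
    gk <- gk * g_eff
  }
  pref * rv
}

#' Mean-ODE weight dynamics with Lyapunov certificate
#'
#' Euler iteration of the averaged weight dynamics
#' `dw/dt = eta B' Pi (A (Lambda r_V + r_I) - r_V)` with
#' `r_V = phi_slope B w`, together with the Lyapunov values
#' `L(w) = 0.5 ||w - w*||^2` against the orthogonal projection `w*` of the
#' initial point onto the fixed-point set. `L` is non-increasing along the
#' trajectory; at convergence `phi_slope B w` matches
#' [markov_fixed_point()] whenever `B Pi` has trivial kernel.
#'
#' @param env a [markov_environment()].
#' @param alpha potentiation factor.
#' @param eta learning rate.
#' @param w0 initial weight vector (default zeros).
#' @param n_steps number of Euler steps.
#' @param phi_slope slope of the linear transfer function.
#' @param step Euler step size; defaults to `0.5 / max |eigenvalue|` of the
#'   linear update map, keeping the discrete map contractive.
#' @return list with the weight trajectory (`n_steps + 1` rows), Lyapunov
#'   values `L`, projected fixed point `w_star`, final dendritic rate `r_V`
#'   and the step size used.
#' @export
mean_ode_trajectory <- function(env, alpha, eta, w0 = NULL, n_steps = 1000,
                                phi_slope = 1, step = NULL) {
  B <- env$B; n <- env$n_states; S <- ncol(B)
  if (is.null(w0)) w0 <- numeric(S)
  stopifnot(length(w0) == S)
  A <- discount_operator(env, alpha)
  Pi <- diag(env$pi, n)
  Lam <- diag(env$lam, n)
  X <- eta * phi_slope * t(B) %*% Pi %*% (A %*% Lam - diag(n)) %*% B
  cvec <- eta * as.numeric(t(B) %*% Pi %*% A %*% env$r_I)
  ev <- eigen(X, only.values = TRUE)$values
  if (is.null(step)) step <- 0.5 / max(abs(ev))
  # projection of w0 onto the affine fixed-point set {w : X w = -c}
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-12
  Xplus <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  w_star <- as.numeric(-Xplus %*% cvec +
                         (diag(S) - Xplus %*% X) %*% w0)
  W <- matrix(NA_real_, n_steps + 1, S)
  L <- numeric(n_steps + 1)
  w <- w0
  for (k in 0:n_steps) {
    W[k + 1, ] <- w
    L[k + 1] <- 0.5 * sum((w - w_star)^2)
    if (k < n_steps) w <- w + step * as.numeric(X %*% w + cvec)
  }
  list(weights = W, L = L, w_star = w_star,
       r_V = phi_slope * as.numeric(B %*% w), step = step)
}

#' TD learning parameters
#'
#' @param gamma_TD discount factor in (0, 1).
#' @param lambda_TD eligibility-trace parameter in `[0, 1]`.
#' @param eta learning rate.
#' @return An object of class `td_params`.
#' @export
td_params <- function(gamma_TD, lambda_TD = 1, eta = 0.01) {
  stopifnot(gamma_TD > 0, gamma_TD < 1, lambda_TD >= 0, lambda_TD <= 1,
            eta >= 0)
  structure(list(gamma_TD = gamma_TD, lambda_TD = lambda_TD, eta = eta),
            class = "td_params")
}

#' Value function of the somatic input on the chain
#'
#' `V(x) = (alpha/(1 - alpha lam)) sum_t gamma_TD^t E[phi(U*)(X_t) | X_0 = x]`,
#' computed by matrix solve. Equals [markov_fixed_point()] when
#' `gamma_TD = gamma_eff`.
#'
#' @param env a [markov_environment()] (scalar nudging assumed).
#' @param alpha potentiation factor.
#' @param td a [td_params()].
#' @return per-state value vector.
#' @export
value_function <- function(env, alpha, td) {
  lam <- env$lam[1]
  stopifnot(alpha * lam < 1)
  pref <- alpha / (1 - alpha * lam)
  n <- env$n_states
  pref * as.numeric(solve(diag(n) - td$gamma_TD * env$T, env$r_I))
}

# Sample a state path of length n_steps + 1 from the chain, started from pi.
sample_chain <- function(env, n_steps) {
  n <- env$n_states
  x <- numeric(n_steps + 1)
  x[1] <- sample.int(n, 1, prob = env$pi)
  for (t in seq_len(n_steps))
    x[t + 1] <- sample.int(n, 1, prob = env$T[x[t], ])
  x
}

#' TD(lambda) with linear function approximation on the chain
#'
#' Simulates the chain from its stationary distribution and applies the
#' classical TD(lambda) update `dw = eta delta_t PSPhat_t` with eligibility
#' trace `PSPhat_t = lambda_TD gamma_TD PSPhat_{t-1} + PSP(X_t)` and delta
#' error
#' `delta_t = (alpha/(1-alpha lam)) phi(U*)(X_t) + gamma_TD vhat(X_{t+1}) -
#' vhat(X_t)` for the linear approximation `vhat(x) = phi_slope (B w)(x)`.
#' When `lambda_TD gamma_TD = gamma`, the eligibility trace coincides with
#' the plasticity rule's low-pass PSP trace.
#'
#' @param env a [markov_environment()].
#' @param alpha potentiation factor.
#' @param td a [td_params()].
#' @param seed integer seed for the chain realisation.
#' @param n_steps number of transitions.
#' @param w0 initial weights (default zeros).
#' @param phi_slope slope of the linear transfer.
#' @return list with final weights `w`, per-state estimate `v_hat`, mean
#'   delta error over the run, and the visited states.
#' @export
td_lambda_learn <- function(env, alpha, td, seed, n_steps, w0 = NULL,
                            phi_slope = 1) {
  B <- env$B; S <- ncol(B); lam <- env$lam[1]
  if (is.null(w0)) w0 <- numeric(S)
  pref <- alpha / (1 - alpha * lam)
  with_seed(seed, {
    x <- sample_chain(env, n_steps)
    w <- w0
    trace <- numeric(S)
    deltas <- numeric(n_steps)
    for (t in seq_len(n_steps)) {
      trace <- td$lambda_TD * td$gamma_TD * trace + B[x[t], ]
      v_now <- phi_slope * sum(B[x[t], ] * w)
      v_next <- phi_slope * sum(B[x[t + 1], ] * w)
      delta <- pref * env$r_I[x[t]] + td$gamma_TD * v_next - v_now
      deltas[t] <- delta
      w <- w + td$eta * delta * trace
    }
    list(w = w, v_hat = phi_slope * as.numeric(B %*% w),
         mean_delta = mean(deltas), sd_delta = stats::sd(deltas),
         states = x)
  })
}

#' Trajectory equivalence of the rule and TD(1) in the dendrite
#'
#' Runs the discrete-time prospective plasticity rule
#' `dw_i = eta (alpha phi(U(X_t)) PSPtilde_t,i - phi(V*(X_t)) PSP_i(X_t))`
#' and the TD(1) rule with dendritic delta error
#' `delta_t = alpha phi(U(X_t)) + gamma phi(V*(X_{t+1})) - phi(V*(X_t))`
#' side by side on one chain realisation (`U = lam V* + U*`, linear
#' transfer). Expanding the TD update shows the two differ only by a
#' telescoping boundary pair; the raw trajectory discrepancy is therefore
#' O(eta) and vanishes linearly in the learning rate, and subtracting the
#' analytic boundary terms leaves a higher-order residual.
#'
#' @param env a [markov_environment()] (scalar nudging).
#' @param alpha potentiation factor.
#' @param eta shared learning rate.
#' @param seed integer seed for the chain realisation.
#' @param n_steps number of transitions.
#' @param phi_slope slope of the linear transfer.
#' @param w0 shared initial weights; from exactly zero weights every
#'   potential is itself O(eta), so the linear-in-eta scaling of the
#'   boundary term shows from a nonzero starting point.
#' @return list with `max_discrepancy` (max over steps of the sup-norm
#'   weight difference), `max_residual` (after subtracting the boundary
#'   terms), and the two final weight vectors.
#' @export
td1_equivalence_check <- function(env, alpha, eta, seed, n_steps,
                                  phi_slope = 1, w0 = NULL) {
  B <- env$B; S <- ncol(B)
  gamma <- env$gamma; lam <- env$lam[1]
  if (is.null(w0)) w0 <- numeric(S)
  with_seed(seed, {
    x <- sample_chain(env, n_steps)
    w_rule <- w0
    w_td <- w0
    trace <- B[x[1], ]  # PSPtilde_0, shared by both rules (lambda_TD = 1)
    v0 <- phi_slope * sum(B[x[1], ] * w0)  # phi(V*) at the start
    p0 <- B[x[1], ]
    tr0 <- trace
    max_disc <- 0
    max_resid <- 0
    for (t in seq_len(n_steps)) {
      v_now_r <- phi_slope * sum(B[x[t], ] * w_rule)
      u_now_r <- lam * v_now_r + env$r_I[x[t]]
      w_rule_new <- w_rule +
        eta * (alpha * u_now_r * trace - v_now_r * B[x[t], ])
      v_now_t <- phi_slope * sum(B[x[t], ] * w_td)
      v_next_t <- phi_slope * sum(B[x[t + 1], ] * w_td)
      u_now_t <- lam * v_now_t + env$r_I[x[t]]
      delta <- alpha * u_now_t + gamma * v_next_t - v_now_t
      w_td <- w_td + eta * delta * trace
      w_rule <- w_rule_new
      trace <- gamma * trace + B[x[t + 1], ]
      # analytic telescoping boundary at the current weights
      v_t <- phi_slope * sum(B[x[t + 1], ] * w_rule)
      boundary <- eta * (v0 * p0 - v_t * B[x[t + 1], ] +
                           v_t * trace - v0 * tr0)
      max_disc <- max(max_disc, max(abs(w_td - w_rule)))
      max_resid <- max(max_resid, max(abs(w_td - w_rule - boundary)))
    }
    list(max_discrepancy = max_disc, max_residual = max_resid,
         w_rule = w_rule, w_td = w_td)
  })
}
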