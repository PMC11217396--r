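#' Multiplicative gradient-descent dynamics
#'
#' The continuous counterpart of product-rule mutation:
#' `dA_ij^(l)/dt = eta * A_ij^(l) * dF/dA_ij^(l)` with
#' `F = -||A - G||_F^2`.  The per-link learning rate proportional to the
#' link's current value makes zeros absorbing and amplifies initial
#' differences multiplicatively — the mechanism behind the transient
#' bow-tie.
#'
#' @name ode_model
NULL

#' Derivative stack of the multiplicative gradient flow
#'
#' For layer l the gradient is
#' `dF/dA^(l) = -2 (A^(L)...A^(l+1))^T (A - G) (A^(l-1)...A^(1))^T`
#' (empty products are identities) and the flow multiplies it elementwise
#' by `eta * A^(l)`.  For L = 2 this reduces to the two-layer Hadamard
#' form.
#'
#' @param net a [layered_network].
#' @param G a [goal_matrix] (or plain matrix).
#' @param eta learning rate (default 1e-4).
#' @return list of L derivative matrices.
#' @export
multiplicative_gradient <- function(net, G, eta = 1e-4) {
  stopifnot(inherits(net, "layered_network"))
  Gm <- if (inherits(G, "goal_matrix")) G$entries else G
  if (nrow(Gm) != net$M) stop("goal and network dimensions disagree")
  M <- net$M
  L <- net$L
  pre <- vector("list", L + 1) # pre[[k+1]] = A^(k) ... A^(1)
  pre[[1]] <- diag(M)
  for (k in seq_len(L)) pre[[k + 1]] <- net$matrices[[k]] %*% pre[[k]]
  suf <- vector("list", L + 1) # suf[[k]] = A^(L) ... A^(k)
  suf[[L + 1]] <- diag(M)
  for (k in L:1) suf[[k]] <- suf[[k + 1]] %*% net$matrices[[k]]
  E <- pre[[L + 1]] - Gm
  lapply(seq_len(L), function(l) {
    -2 * eta * (t(suf[[l + 1]]) %*% E %*% t(pre[[l]])) * net$matrices[[l]]
  })
}

#' Integrate the full multiplicative gradient flow (fixed-step RK4)
#'
#' Advances the link-matrix stack with classical fourth-order Runge-Kutta,
#' recording fitness and waist statistics at a sampling stride.  The
#' integration stops early when the composed matrix reaches the goal
#' (`fitness >= conv_fitness`), when any entry exceeds `entry_cap`
#' (divergence guard), or when a non-finite value appears; all three are
#' reported through `status`, never as an error.
#'
#' @param net a [layered_network] (initial condition, nonnegative entries).
#' @param G a [goal_matrix].
#' @param eta learning rate (default 1e-4).
#' @param dt time step; the default keeps `eta * dt * ||G||_F^2` well below
#'   one for the 6 x 6 norm-60 protocol.
#' @param t_end integration horizon.
#' @param entry_cap divergence guard on single entries (default 1e6).
#' @param record_stride record every this many steps.
#' @param conv_fitness fitness threshold for early convergence stop.
#' @param stop_at_convergence stop when the threshold is reached.
#' @param active_def,active_threshold active-node bookkeeping as in
#'   [node_importance].
#' @return object of class `ode_trajectory`: `records` (data.frame with t,
#'   fitness, active counts, waist), `final_network`, `t`, `status`.
#' @export
integrate_ode <- function(net, G, eta = 1e-4, dt = 0.1, t_end = 1e5,
                          entry_cap = 1e6, record_stride = 100,
                          conv_fitness = -0.01, stop_at_convergence = TRUE,
                          active_def = 1, active_threshold = 0.001) {
  stopifnot(inherits(net, "layered_network"))
  Gm <- if (inherits(G, "goal_matrix")) G$entries else G
  res <- cpp_ode_rk4(as_link_array(net), Gm, eta, dt, t_end, entry_cap,
                     as.integer(record_stride), conv_fitness,
                     stop_at_convergence, as.integer(active_def),
                     active_threshold)
  rec <- as.data.frame(res$records)
  names(rec) <- c("t", "fitness", paste0("active_", seq_len(net$L - 1) + 1),
                  "waist")
  structure(list(records = rec, final_network = array_to_network(res$final),
                 t = res$t, status = res$status),
            class = "ode_trajectory")
}

#' @export
print.ode_trajectory <- function(x, ...) {
  cat(sprintf("ODE trajectory: %d samples to t = %.4g, status %s\n",
              nrow(x$records), x$t, x$status))
  invisible(x)
}

#' Reduced two-node flow of the summed input/output intensities
#'
#' In the early phase (`A` much smaller than `G`) of the two-layer, two-node
#' model with the uniform rank-1 goal (all elements `g`), the summed input
#' (`I_k`) and output (`R_k`) intensities of middle node k obey
#' `dI/dt = dR/dt = 2 eta g R I`, so `R - I` is conserved.  Integration
#' uses fixed-step RK4 (`deSolve`).
#'
#' @param I0,R0 positive initial values.
#' @param g goal element (`> 0`).
#' @param eta learning rate.
#' @param t_end end time.
#' @param n_steps number of RK4 steps (default 20000).
#' @return data.frame with columns `t`, `I`, `R`, and attribute
#'   `"conserved"` = `R0 - I0`.
#' @export
reduced_dynamics <- function(I0, R0, g, eta = 1e-4, t_end,
                             n_steps = 20000) {
  stopifnot(I0 > 0, R0 > 0, g > 0, eta > 0, t_end > 0)
  times <- seq(0, t_end, length.out = n_steps + 1)
  deriv <- function(t, y, parms) {
    rate <- 2 * parms$eta * parms$g * y[["R"]] * y[["I"]]
    list(c(I = rate, R = rate))
  }
  out <- deSolve::ode(c(I = I0, R = R0), times, deriv,
                      list(eta = eta, g = g), method = "rk4")
  df <- as.data.frame(out)
  names(df) <- c("t", "I", "R")
  attr(df, "conserved") <- R0 - I0
  df
}

#' Closed-form solution of the reduced output intensity
#'
#' `R(t) = R0 (R0 - I0) / (R0 - I0 exp(2 eta g (R0 - I0) t))`; when
#' `R0 = I0` the analytic limit `R0 / (1 - 2 eta g R0 t)` is used.  The
#' solution blows up at the finite divergence time ([divergence_time]); for
#' `t` at or beyond it the function returns `Inf` rather than the
#' sign-flipped branch.
#'
#' @param R0,I0 positive initial values.
#' @param g goal element.
#' @param eta learning rate.
#' @param t time (vectorized).
#' @return `R(t)`; `Inf` at or beyond the divergence time.
#' @export
closed_form_R <- function(R0, I0, g, eta, t) {
  stopifnot(R0 > 0, I0 > 0, g > 0, eta > 0)
  td <- divergence_time(R0, I0, g, eta)
  r <- if (identical(R0, I0)) {
    R0 / (1 - 2 * eta * g * R0 * t)
  } else {
    d <- R0 - I0
    R0 * d / (R0 - I0 * exp(2 * eta * g * d * t))
  }
  r[t >= td] <- Inf
  r
}

#' Finite divergence time of the reduced flow
#'
#' `t* = (1 / (2 eta g)) (ln R0 - ln I0) / (R0 - I0)`, with the limit
#' `1 / (2 eta g R0)` when `R0 = I0`.
#'
#' @inheritParams closed_form_R
#' @export
divergence_time <- function(R0, I0, g, eta) {
  stopifnot(R0 > 0, I0 > 0, g > 0, eta > 0)
  if (identical(R0, I0)) {
    1 / (2 * eta * g * R0)
  } else {
    (log(R0) - log(I0)) / (2 * eta * g * (R0 - I0))
  }
}

#' Numerically measured blow-up time of the reduced flow
#'
#' Steps the reduced equations with RK4 until `R` exceeds `cap` (or turns
#' non-finite), returning the first crossing time.  Used to confirm the
#' analytic divergence time.
#'
#' @inheritParams reduced_dynamics
#' @param cap blow-up threshold (default 1e6).
#' @param dt step size.
#' @param t_max search horizon.
#' @return time of the first cap crossing (`NA` if none before `t_max`).
#' @export
reduced_blowup_time <- function(I0, R0, g, eta = 1e-4, cap = 1e6,
                                dt = 0.05, t_max = 1e6) {
  y <- c(I = I0, R = R0)
  f <- function(y) {
    rate <- 2 * eta * g * y[["R"]] * y[["I"]]
    c(rate, rate)
  }
  t <- 0
  while (t < t_max) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y2 <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    if (!all(is.finite(y2)) || y2[["R"]] >= cap) return(t)
    y <- y2
  }
  NA_real_
}

#' Column independence of the early-phase two-layer flow
#'
#' Under the early-phase approximation (`A^(2) A^(1) - G ~ -G`) the
#' derivatives of column k of `A^(2)` together with row k of `A^(1)` do not
#' depend on the other column group.  This check perturbs column group 2
#' and verifies numerically that column-group-1 derivatives are unchanged.
#' Without the approximation (exact flow) the groups couple through the
#' residual, so the check generally fails — a documented negative control.
#'
#' @param net a two-layer [layered_network].
#' @param G goal matrix.
#' @param eta learning rate.
#' @param approx use the early-phase approximation (default `TRUE`).
#' @param delta perturbation size.
#' @param tol tolerance on the derivative change.
#' @return `TRUE` when column-group-1 derivatives are unaffected.
#' @export
column_independence_check <- function(net, G, eta = 1e-4, approx = TRUE,
                                      delta = 1e-3, tol = 1e-12) {
  stopifnot(inherits(net, "layered_network"))
  if (net$L != 2) stop("defined for two-layer networks")
  Gm <- if (inherits(G, "goal_matrix")) G$entries else G
  deriv <- function(m) {
    A1 <- m[[1]]
    A2 <- m[[2]]
    E <- if (approx) -Gm else A2 %*% A1 - Gm
    list(-2 * eta * (t(A2) %*% E) * A1, -2 * eta * (E %*% t(A1)) * A2)
  }
  group1 <- function(d) c(d[[2]][, 1], d[[1]][1, ])
  base <- deriv(net$matrices)
  m2 <- net$matrices
  m2[[2]][, 2] <- m2[[2]][, 2] + delta # column 2 of A^(2)
  m2[[1]][2, ] <- m2[[1]][2, ] + delta # row 2 of A^(1)
  pert <- deriv(m2)
  max(abs(group1(pert) - group1(base))) <= tol
}
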