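# Rectified Adam (RAdam).  Moment estimates as in Adam; the adaptive step is
# variance-rectified and only engages once the approximated SMA length
# rho_t exceeds 5, before which the update falls back to bias-corrected
# momentum SGD.

radam_state <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = beta1, beta2 = beta2, eps = eps,
       rho_inf = 2 / (1 - beta2) - 1)
}

radam_step <- function(state, params, grads, lr) {
  b1 <- state$beta1; b2 <- state$beta2
  t <- state$t + 1L
  rho_t <- state$rho_inf - 2 * t * b2^t / (1 - b2^t)
  rect <- rho_t > 5
  r_t <- if (rect)
    sqrt(((rho_t - 4) * (rho_t - 2) * state$rho_inf) /
           ((state$rho_inf - 4) * (state$rho_inf - 2) * rho_t)) else NA_real_
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / (1 - b1^t)
    if (rect) {
      vhat <- sqrt(state$v[[nm]] / (1 - b2^t))
      params[[nm]] <- params[[nm]] - lr * r_t * mhat / (vhat + state$eps)
    } else {
      params[[nm]] <- params[[nm]] - lr * mhat
    }
  }
  state$t <- t
  list(params = params, state = state)
}
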