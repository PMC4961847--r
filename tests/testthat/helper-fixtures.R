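# shared fixtures, built in code at test time

default_truth <- function() list("PD-L2" = kinetic_truth(1e6, 1e-4))

# small layout for fast fits: one binder bait + one control, in duplicate
small_layout <- function(n_channels = 4L) {
  chip_layout(
    bait_map = c("PD-L2", "PD-L2", "BSA", "BSA"),
    role_map = c("PD-L2" = "probe", "BSA" = "negative_control"),
    n_channels = n_channels,
    dilution_fractions = c(1, 0.75, 0.5, 0.25)[seq_len(n_channels)]
  )
}

noiseless <- function(seed = 1L) noise_model(sigma_rel = 0, amp_cv = 0,
                                             seed = seed)

# independent ODE oracle for the Langmuir rate equation
ode_theta <- function(times, C, kon, koff, t0 = 0) {
  rhs <- function(t, y, p) list(kon * C * (1 - y[1]) - koff * y[1])
  post <- times[times >= t0]
  ts <- if (isTRUE(all.equal(post[1], t0))) post else c(t0, post)
  sol <- deSolve::ode(y = c(theta = 0), times = ts, func = rhs, parms = NULL,
                      rtol = 1e-12, atol = 1e-14)
  th <- utils::tail(sol[, "theta"], length(post))
  out <- numeric(length(times))
  out[times >= t0] <- th
  out
}
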