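# Closed-form periodic solution of C dP/dt = Q - P/R for the
# sinusoidal-systole / null-diastole flow Q(t) = Qp sin(w t) on [0, Ts],
# derived symbolically: particular solution Qp*R/(1+(w*tau)^2) *
# (sin - w*tau*cos) plus exponential homogeneous decay; pure decay in
# diastole; periodic initial value from the affine period map.
wk2_closed_form <- function(Qp, Ts, Tp, R, C) {
  w <- pi / Ts
  tau <- R * C
  k <- Qp * R / (1 + (w * tau)^2)
  Pp <- function(t) k * (sin(w * t) - w * tau * cos(w * t))
  Pp0 <- Pp(0)
  sys <- function(t, P0) (P0 - Pp0) * exp(-t / tau) + Pp(t)
  a <- exp(-Tp / tau)
  PTs_from0 <- sys(Ts, 0)          # affine map pieces
  PTs_from1 <- sys(Ts, 1)
  # P(T) = (P(Ts; P0)) * exp(-(T-Ts)/tau)
  b <- PTs_from0 * exp(-(Tp - Ts) / tau)
  slope <- (PTs_from1 - PTs_from0) * exp(-(Tp - Ts) / tau)  # = a
  P0 <- b / (1 - slope)
  eval_at <- function(t) {
    t <- t %% Tp
    ifelse(t <= Ts, sys(t, P0),
           sys(Ts, P0) * exp(-(t - Ts) / tau))
  }
  # analytic mean over one period (Pa): integral of systolic part + decay
  # int Pp = k*(-cos/w - tau*sin)| ; int hom = -(P0-Pp0)*tau*(e^{-Ts/tau}-1)
  int_sys <- (P0 - Pp0) * tau * (1 - exp(-Ts / tau)) +
    k * ((1 - cos(w * Ts)) / w - tau * sin(w * Ts))
  PTs <- sys(Ts, P0)
  int_dia <- PTs * tau * (1 - exp(-(Tp - Ts) / tau))
  list(P = eval_at, P0 = P0, mean = (int_sys + int_dia) / Tp,
       tau = tau, PTs = PTs)
}

# reference flow waveform used throughout: 60 bpm, 0.3 s sinusoidal systole,
# descending fraction 0.85 of Q_peak = 4e-4 m^3/s; densely sampled so the
# spline represents the ideal sine to well below the oracle tolerances
std_flow <- function() {
  flowrate_waveform(synth_waveform(2.7, 0.3, 1.0, n = 1000), 0.85, 4e-4)
}

# least-squares slope of log(err) vs log(h)
loglog_slope <- function(h, err) {
  unname(coef(lm(log(err) ~ log(h)))[2])
}
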