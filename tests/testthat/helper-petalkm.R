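# Independent oracle for the two-flux equations: integrate the coupled ODEs
#   dI/dx = -(K + S) I + S J   (downward flux)
#   dJ/dx =  (K + S) J - S I   (upward flux)
# on x in [0, 1] with boundary conditions I(0) = 1, J(1) = 0, by superposition
# shooting (the system is linear, so two initial-value solves suffice).
# Returns r = J(0), t = I(1).  Never calls the package's closed forms.
two_flux_ode_rt <- function(K_star, S_star) {
  rhs <- function(x, y, parms) {
    K <- parms[1]; S <- parms[2]
    list(c(-(K + S) * y[1] + S * y[2],
           (K + S) * y[2] - S * y[1]))
  }
  solve1 <- function(y0) {
    out <- deSolve::lsoda(y0, c(0, 1), rhs, c(K_star, S_star),
                          rtol = 1e-11, atol = 1e-13)
    out[2, 2:3]
  }
  ya <- solve1(c(1, 0))   # I(0)=1, J(0)=0
  yb <- solve1(c(0, 1))   # I(0)=0, J(0)=1
  alpha <- -ya[2] / yb[2] # choose J(0) so that J(1) = 0
  list(r = unname(alpha), t = unname(ya[1] + alpha * yb[1]))
}

# random physically valid symmetric plate(s)
random_plate <- function(n = 1) {
  r <- stats::runif(n, 0, 0.9)
  t <- stats::runif(n, 0.01, 1) * (1 - r)
  plate_rt(r, t)
}

expect_plate_equal <- function(a, b, tol = 1e-10) {
  for (f in c("r_top", "t_down", "r_bottom", "t_up"))
    expect_lt(max(abs(a[[f]] - b[[f]])), tol)
}
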