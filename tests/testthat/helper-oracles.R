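# Finite-difference oracle for the shell reaction-diffusion problem:
# (1/r^2)(r^2 c')' = (rho/R)^2 c, c(R) = c_b, c'(R_n) = 0, solved on a fine
# grid with a tridiagonal system. Independent of the closed form.
fd_shell_profile_once <- function(r_eval, R, R_n, rho, c_b, n) {
  r <- seq(R_n, R, length.out = n)
  h <- r[2] - r[1]
  q2 <- (rho / R)^2
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  for (i in 1:(n - 1)) {
    rp <- r[i] + h / 2
    rm <- max(r[i] - h / 2, R_n)
    vol <- q2 * (rp^3 - rm^3) / 3
    if (i > 1) {
      A[i, i - 1] <- rm^2 / h
      A[i, i] <- -(rp^2 + rm^2) / h - vol
    } else {
      A[i, i] <- -rp^2 / h - vol   # zero flux through the inner face
    }
    A[i, i + 1] <- rp^2 / h
  }
  A[n, n] <- 1; rhs[n] <- c_b
  sol <- solve(A, rhs)
  stats::approx(r, sol, xout = r_eval)$y
}

# second-order finite-volume solve plus Richardson extrapolation in h
fd_shell_profile <- function(r_eval, R, R_n, rho, c_b, n = 2001) {
  f1 <- fd_shell_profile_once(r_eval, R, R_n, rho, c_b, n)
  f2 <- fd_shell_profile_once(r_eval, R, R_n, rho, c_b, 2 * n - 1)
  (4 * f2 - f1) / 3
}
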