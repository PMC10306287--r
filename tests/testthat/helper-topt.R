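# shared test helpers: independent oracles and small utilities

R_KCAL <- 1.987204e-3

trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

# independent hinge-regression oracle: brute-force SSE over a candidate grid,
# fitting y = b0 + b1 x + b2 (x - x0)+ by ordinary normal equations
hinge_sse_grid <- function(T_K, y, w, candidates_K) {
  x <- 1 / T_K
  vapply(candidates_K, function(tb) {
    z <- pmax(x - 1 / tb, 0)
    X <- cbind(1, x, z)
    W <- diag(w)
    beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
    sum(w * (y - X %*% beta)^2)
  }, numeric(1))
}

# Horn's quaternion method for the optimal rotation (independent of the
# SVD-based implementation under test): returns R minimising |P R - Q|
horn_rotation <- function(P, Q) {
  M <- crossprod(P, Q)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  # row-vector convention (P %*% R ~ Q), validated against a known rotation
  t(matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE))
}

# local maxima of a density estimate (interior sign changes of the slope)
density_peaks <- function(dens) {
  y <- dens$density
  i <- which(diff(sign(diff(y))) == -2) + 1
  dens$grid_A[i]
}
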