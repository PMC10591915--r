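# Independent oracles used by module and acceptance tests. These follow
# different solution routes than the package implementations on purpose.

# Competitive-equilibrium oracle: nested bisection over the free-ligand
# concentrations (the implementation solves a single equation in free
# protein instead).
oracle_equilibrium <- function(spec, iters = 200) {
  Pt <- spec$protein_total; Lt <- spec$retinol_total
  It <- spec$inhibitor_total
  Kd <- spec$kd_retinol; Ki <- spec$ki_inhibitor
  pf_given <- function(Lf, If) Pt / (1 + Lf / Kd + If / Ki)
  # residual of the retinol mass balance for fixed If, as a function of Lf
  l_resid <- function(Lf, If) Lf * (1 + pf_given(Lf, If) / Kd) - Lt
  solve_l <- function(If) {
    lo <- 0; hi <- max(Lt, 1e-30)
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (l_resid(mid, If) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  i_resid <- function(If) {
    Lf <- solve_l(If)
    If * (1 + pf_given(Lf, If) / Ki) - It
  }
  lo <- 0; hi <- max(It, 1e-30)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (i_resid(mid) > 0) hi <- mid else lo <- mid
  }
  If <- (lo + hi) / 2
  Lf <- solve_l(If)
  Pf <- pf_given(Lf, If)
  list(protein_free = Pf, retinol_free = Lf, inhibitor_free = If,
       protein_retinol = Pf * Lf / Kd, protein_inhibitor = Pf * If / Ki)
}

# Superposition oracle: direct numerical minimization of RMSD over the
# rotation group (z-y-z Euler angles, optimal translation by centroids),
# multi-start BFGS. Independent of the SVD route.
oracle_superpose_rmsd <- function(mobile, reference, n_starts = 20) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rotmat <- function(a) {
    cz1 <- cos(a[1]); sz1 <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cz2 <- cos(a[3]); sz2 <- sin(a[3])
    Rz1 <- matrix(c(cz1, sz1, 0, -sz1, cz1, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz2 <- matrix(c(cz2, sz2, 0, -sz2, cz2, 0, 0, 0, 1), 3, 3)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(a) sqrt(mean(rowSums((P %*% rotmat(a) - Q)^2)))
  starts <- rbind(c(0, 0, 0),
                  matrix(stats::runif(3 * (n_starts - 1), 0, 2 * pi),
                         ncol = 3))
  vals <- apply(starts, 1, function(s) {
    stats::optim(s, obj, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500))$value
  })
  min(vals)
}

# Simple OLS R^2 by explicit sums (cross-check for correlate()).
oracle_r_squared <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
}
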