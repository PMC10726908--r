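# Independent reference implementations used as oracles.
# Deliberately written in a different style from the package internals:
# complex-valued EPG with explicit textbook operator matrices and dense
# state vectors, exhaustive active-set NNLS, exact permutation Spearman.

# Complex EPG oracle for a CPMG train (90deg excitation about y, refocusing
# about x). States stored as a 3 x (K+1) complex matrix Omega with rows
# (F+_k, conj(F_{-k}), Z_k). Echo amplitude = |F+_0| at the echo time.
epg_oracle <- function(t2, alpha_deg, n_echoes, esp, t1) {
  K <- n_echoes + 2L
  omega <- matrix(0 + 0i, 3L, K + 1L)
  # textbook pulse operator for flip alpha (rad), phase phi (rad, from +x)
  pulse_T <- function(alpha, phi) {
    ca2 <- cos(alpha / 2)^2
    sa2 <- sin(alpha / 2)^2
    sa <- sin(alpha)
    matrix(c(
      ca2,                    exp(2i * phi) * sa2,  -1i * exp(1i * phi) * sa,
      exp(-2i * phi) * sa2,   ca2,                   1i * exp(-1i * phi) * sa,
      -0.5i * exp(-1i * phi) * sa, 0.5i * exp(1i * phi) * sa, cos(alpha)),
      nrow = 3L, byrow = TRUE)
  }
  # thermal equilibrium, then ideal 90y excitation
  omega[3L, 1L] <- 1 + 0i
  omega <- pulse_T(pi / 2, pi / 2) %*% omega
  Tref <- pulse_T(alpha_deg * pi / 180, 0)
  tau <- esp / 2
  relax <- diag(c(exp(-tau / t2), exp(-tau / t2), exp(-tau / t1)))
  shift <- function(om) {
    Fp <- om[1L, ]; Fmc <- om[2L, ]
    new_Fp <- c(Conj(Fmc[2L]), Fp[seq_len(K)])
    new_Fmc <- c(Fmc[-1L], 0 + 0i)
    new_Fmc[1L] <- Conj(new_Fp[1L])
    rbind(new_Fp, new_Fmc, om[3L, ], deparse.level = 0)
  }
  echoes <- numeric(n_echoes)
  for (e in seq_len(n_echoes)) {
    omega <- shift(relax %*% omega)
    omega <- Tref %*% omega
    omega <- shift(relax %*% omega)
    echoes[e] <- Mod(omega[1L, 1L])
  }
  echoes
}

epg_oracle_basis <- function(t2_values, alpha_deg, params) {
  vapply(t2_values, epg_oracle, numeric(params$n_echoes),
         alpha_deg = alpha_deg, n_echoes = params$n_echoes,
         esp = params$echo_spacing, t1 = params$t1_assumed)
}

# Exhaustive NNLS: enumerate every support set, keep the unconstrained
# least-squares solutions that are feasible (non-negative), return the one
# with the smallest residual. Exact for small column counts.
nnls_bruteforce <- function(A, b) {
  p <- ncol(A)
  stopifnot(p <= 12L)
  best_x <- numeric(p)
  best_obj <- sum(b^2)
  for (code in seq_len(2^p) - 1L) {
    sel <- which(bitwAnd(code, 2^(seq_len(p) - 1L)) > 0L)
    if (length(sel) == 0L) next
    As <- A[, sel, drop = FALSE]
    if (qr(As)$rank < length(sel)) next
    xs <- qr.solve(As, b)
    if (any(xs < -1e-12)) next
    obj <- sum((As %*% xs - b)^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best_x <- numeric(p)
      best_x[sel] <- xs
    }
  }
  best_x
}

# KKT certificate for min ||Ax-b||^2, x >= 0
nnls_kkt_ok <- function(A, b, x, tol = 1e-8) {
  g <- as.numeric(crossprod(A, A %*% x - b))  # gradient/2
  scale <- max(abs(crossprod(A, b)), 1)
  pos <- x > 1e-12
  all(x >= 0) &&
    all(abs(g[pos]) <= tol * scale) &&
    all(g[!pos] >= -tol * scale)
}

# Spearman r by the midrank product-moment formula with exact permutation p
spearman_perm_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  perms <- all_perms(length(y))
  robs <- abs(r)
  count <- 0L
  for (i in seq_len(nrow(perms))) {
    if (abs(stats::cor(rx, ry[perms[i, ]])) >= robs - 1e-12)
      count <- count + 1L
  }
  list(r = r, p = count / nrow(perms))
}

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(seq_len(n)[-k][sub], nrow(sub)))
  }))
}
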