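# Shared fixtures: coarse wavelength grids keep the PARAFAC problems small
# enough for quick tests while preserving the six-component structure.

test_ex <- seq(240, 650, 10)
test_em <- seq(300, 600, 5)

test_campaign <- function(seed = 7, treatments = "PB", n_rep = 1,
                          noise_mult = 0.005, noise_add = 1e-4, ...) {
  reps <- c(PB = n_rep, "MD0.2" = 1, "MD0.7" = 1, "MD3.0" = 1, "PB3.0" = 1)
  campaign_config(treatments = treatments,
                  replicates = reps,
                  noise_multiplicative = noise_mult, noise_additive = noise_add,
                  ex_grid = test_ex, em_grid = test_em, seed = seed, ...)
}

# small exact trilinear tensor wrapped as an eem_dataset
toy_dataset <- function(A, B, C, em = NULL, ex = NULL, mask = NULL) {
  I <- nrow(A); J <- nrow(B); K <- nrow(C)
  X <- array(0, c(I, J, K))
  for (f in seq_len(ncol(A))) X <- X + A[, f] %o% B[, f] %o% C[, f]
  if (is.null(em)) em <- seq(300, by = 5, length.out = J)
  if (is.null(ex)) ex <- seq(240, by = 10, length.out = K)
  if (is.null(mask)) mask <- matrix(FALSE, J, K)
  X_masked <- X
  for (i in seq_len(I)) { sl <- X_masked[i, , ]; sl[mask] <- NA; X_masked[i, , ] <- sl }
  structure(list(tensor = X_masked, ex = ex, em = em, mask = mask,
                 manifest = data.frame(sample_id = paste0("S", seq_len(I)),
                                       station = seq_len(I), salinity_psu = NA_real_,
                                       treatment = NA_character_, timepoint_days = NA_real_,
                                       replicate = NA)),
            class = "eem_dataset")
}

# Independent oracle: unconstrained CP by classical ALS with exact
# least-squares mode updates (pseudo-inverse of the Khatri-Rao design).
# Shares no code with the package fitter.
oracle_cp_als <- function(X, F_, n_iter = 20000, seed = 1, tol = 1e-14) {
  d <- dim(X)
  set.seed(seed)
  A <- matrix(rnorm(d[1] * F_), d[1]); B <- matrix(rnorm(d[2] * F_), d[2])
  C <- matrix(rnorm(d[3] * F_), d[3])
  kr <- function(U, V) {
    out <- matrix(0, nrow(U) * nrow(V), ncol(U))
    for (f in seq_len(ncol(U))) out[, f] <- as.vector(V[, f] %o% U[, f])
    out
  }
  X1 <- matrix(X, d[1], d[2] * d[3])                       # i x (j,k)
  X2 <- matrix(aperm(X, c(2, 1, 3)), d[2], d[1] * d[3])    # j x (i,k)
  X3 <- matrix(aperm(X, c(3, 1, 2)), d[3], d[1] * d[2])    # k x (i,j)
  tss <- sum(X1^2)
  rel_prev <- Inf
  for (it in seq_len(n_iter)) {
    A <- t(qr.coef(qr(kr(C, B)), t(X1)))
    B <- t(qr.coef(qr(kr(C, A)), t(X2)))
    C <- t(qr.coef(qr(kr(B, A)), t(X3)))
    if (it %% 25 == 0) {
      rel <- sqrt(sum((X1 - t(kr(C, B) %*% t(A)))^2) / tss)
      if (abs(rel_prev - rel) < tol) break
      rel_prev <- rel
    }
  }
  M <- t(kr(C, B) %*% t(A))
  sqrt(sum((X1 - M)^2) / sum(X1^2))   # relative reconstruction error
}
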