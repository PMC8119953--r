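## Non-negative trilinear PARAFAC for EEM datasets.
##
## The fit is a hierarchical (component-wise) non-negative alternating least
## squares on the sample x emission x excitation tensor, with masked cells
## handled by expectation-maximisation style imputation from the current
## model. Magnitude is carried by the sample scores; spectral loadings are
## unit Euclidean norm. Components are ordered by descending emission peak.

# mode-n unfoldings; X is I x J x K stored as the I x (J*K) matrix X1
unfold2 <- function(X1, I, J, K) matrix(aperm(array(X1, c(I, J, K)), c(2, 1, 3)), J, I * K)
unfold3 <- function(X1, I, J, K) matrix(aperm(array(X1, c(I, J, K)), c(3, 1, 2)), K, I * J)

# Khatri-Rao product with columns vec(u_f %o% v_f)
khatri_rao <- function(U, V) {
  F_ <- ncol(U)
  out <- matrix(0, nrow(U) * nrow(V), F_)
  for (f in seq_len(F_)) out[, f] <- as.vector(U[, f] %o% V[, f])
  out
}

# component-wise nonnegative block solve for factor A given
# P = X_(n) %*% KR and G = hadamard of the other two grams; inner sweeps
# are cheap (F x F Gram), so iterate them to near-exactness
hals_update <- function(A, P, G, n_inner = 25, inner_tol = 1e-10) {
  for (s in seq_len(n_inner)) {
    delta <- 0; size <- 0
    for (f in seq_len(ncol(A))) {
      d <- G[f, f]
      if (d < 1e-12) next
      new <- pmax(0, A[, f] + (P[, f] - A %*% G[, f]) / d)
      delta <- delta + sum((new - A[, f])^2)
      size <- size + sum(new^2)
      A[, f] <- new
    }
    if (delta <= inner_tol * max(size, 1e-300)) break
  }
  A
}

normalize_model <- function(A, B, C) {
  for (f in seq_len(ncol(A))) {
    nb <- sqrt(sum(B[, f]^2)); nc <- sqrt(sum(C[, f]^2))
    if (nb > 0) B[, f] <- B[, f] / nb
    if (nc > 0) C[, f] <- C[, f] / nc
    A[, f] <- A[, f] * nb * nc
  }
  list(A = A, B = B, C = C)
}

parafac_single_fit <- function(X1, I, J, K, F_, obs_cols_idx, masked_idx,
                               tol, max_iter, init, seed, warm = NULL) {
  tss <- sum(X1[, obs_cols_idx]^2)
  Xw <- X1
  start_fill <- mean(Xw[, obs_cols_idx])
  if (length(masked_idx)) Xw[, masked_idx] <- start_fill
  if (!is.null(warm)) {
    A <- warm$A; B <- warm$B; C <- warm$C
  } else if (init == "svd") {
    B <- abs(svd(unfold2(Xw, I, J, K), nu = F_, nv = 0)$u[, seq_len(F_), drop = FALSE])
    C <- abs(svd(unfold3(Xw, I, J, K), nu = F_, nv = 0)$u[, seq_len(F_), drop = FALSE])
    A <- matrix(1, I, F_)
  } else {
    ini <- with_seed(seed, list(A = matrix(stats::runif(I * F_), I, F_),
                                B = matrix(stats::runif(J * F_), J, F_),
                                C = matrix(stats::runif(K * F_), K, F_)))
    A <- ini$A; B <- ini$B; C <- ini$C
  }
  rss_of <- function(A_, B_, C_) {
    M <- tcrossprod(A_, khatri_rao(B_, C_))
    list(M = M, rss = sum((Xw[, obs_cols_idx] - M[, obs_cols_idx])^2))
  }
  rss_prev <- Inf; rss <- Inf; converged <- FALSE; it <- 0L
  beta <- 1; A_old <- A; B_old <- B; C_old <- C
  for (it in seq_len(max_iter)) {
    A_old <- A; B_old <- B; C_old <- C
    # component-wise nonnegative sweeps, one per mode
    A <- hals_update(A, Xw %*% khatri_rao(B, C), crossprod(B) * crossprod(C))
    B <- hals_update(B, unfold2(Xw, I, J, K) %*% khatri_rao(A, C),
                     crossprod(A) * crossprod(C))
    C <- hals_update(C, unfold3(Xw, I, J, K) %*% khatri_rao(A, B),
                     crossprod(A) * crossprod(B))
    nm <- normalize_model(A, B, C); A <- nm$A; B <- nm$B; C <- nm$C
    cur <- rss_of(A, B, C)
    # extrapolation acceleration (line search along the last step)
    if (it > 2) {
      Ae <- A + beta * (A - A_old); Ae[Ae < 0] <- 0
      Be <- B + beta * (B - B_old); Be[Be < 0] <- 0
      Ce <- C + beta * (C - C_old); Ce[Ce < 0] <- 0
      nm <- normalize_model(Ae, Be, Ce)
      ext <- rss_of(nm$A, nm$B, nm$C)
      if (ext$rss < cur$rss) {
        A <- nm$A; B <- nm$B; C <- nm$C; cur <- ext
        beta <- min(beta * 1.15, 8)
      } else beta <- max(beta * 0.6, 0.5)
    }
    if (length(masked_idx)) Xw[, masked_idx] <- cur$M[, masked_idx]
    rss <- cur$rss
    if (is.finite(rss_prev) && abs(rss_prev - rss) <= tol * tss) {
      converged <- TRUE
      break
    }
    rss_prev <- rss
  }
  list(A = A, B = B, C = C, rss = rss, n_iterations = it, converged = converged)
}

#' Fit a non-negative PARAFAC model to an EEM dataset
#'
#' Decomposes the sample x emission x excitation fluorescence tensor into
#' `ncomp` trilinear components with non-negativity constraints on all three
#' modes. Masked (scatter) cells are excluded from the loss by
#' expectation-maximisation imputation from the current model. The solver is
#' component-wise non-negative alternating least squares (hierarchical ALS),
#' run from `n_starts` random initialisations plus one SVD-based
#' initialisation; the solution with the lowest final residual sum of
#' squares is kept. All magnitude is carried by the sample scores; emission
#' and excitation loadings have unit Euclidean norm. Components are ordered
#' by descending emission-peak wavelength (ties by descending excitation
#' peak). Results are deterministic given `seed`.
#'
#' @param ds an [assemble_dataset()] result.
#' @param ncomp number of components (F >= 1).
#' @param n_starts number of random starts (an SVD start is always added).
#' @param tol convergence tolerance: iteration stops when the residual sum
#'   of squares changes by less than `tol` times the total sum of squares,
#'   i.e. when the unexplained-variance fraction moves by less than `tol`
#'   per iteration (default 1e-8).
#' @param max_iter iteration cap per start (default 2500).
#' @param seed integer seed controlling the random starts.
#' @return An object of class `"parafac"`: list with `scores` (sample x F,
#'   Raman units), `em_loadings` (em x F, unit norm), `ex_loadings`
#'   (ex x F, unit norm), `ncomp`, `explained_variance` (percent), `rss`,
#'   `tss`, `n_iterations`, `converged`, `start_seed`, the grids, `mask`
#'   and the dataset `manifest`.
#' @references Bro, R. (1997) PARAFAC. Tutorial and applications.
#'   Chemometrics and Intelligent Laboratory Systems 38, 149-171.
#' @export
parafac <- function(ds, ncomp, n_starts = 10, tol = 1e-8, max_iter = 2500, seed = 1L) {
  stopifnot(inherits(ds, "eem_dataset"))
  I <- dim(ds$tensor)[1]; J <- dim(ds$tensor)[2]; K <- dim(ds$tensor)[3]
  if (ncomp < 1) stop("ncomp must be >= 1", call. = FALSE)
  if (ncomp > min(J, K)) stop("ncomp exceeds a spectral dimension of the tensor", call. = FALSE)
  if (I < 2 * ncomp)
    stop(sprintf("dataset has %d samples; at least %d (2 x ncomp) required", I, 2 * ncomp),
         call. = FALSE)
  X1 <- matrix(ds$tensor, I, J * K)
  masked_idx <- which(as.vector(ds$mask))
  obs_cols_idx <- which(!as.vector(ds$mask))
  if (!length(obs_cols_idx)) stop("all cells masked", call. = FALSE)
  X1[, masked_idx] <- NA_real_
  tss <- sum(X1[, obs_cols_idx]^2)
  if (tss == 0) stop("total sum of squares is zero", call. = FALSE)

  # multi-start economy: short pilot runs from every start, then the best
  # pilot is refined to full tolerance
  start_seeds <- derive_seeds(seed, max(n_starts, 1L))
  pilot_iter <- min(max_iter, 300L)
  fits <- vector("list", n_starts + 1L)
  for (s in seq_len(n_starts))
    fits[[s]] <- parafac_single_fit(X1, I, J, K, ncomp, obs_cols_idx, masked_idx,
                                    tol, pilot_iter, "random", start_seeds[s])
  fits[[n_starts + 1L]] <- parafac_single_fit(X1, I, J, K, ncomp, obs_cols_idx, masked_idx,
                                              tol, pilot_iter, "svd", seed)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  if (!best$converged)
    best <- parafac_single_fit(X1, I, J, K, ncomp, obs_cols_idx, masked_idx,
                               tol, max_iter, "warm", seed, warm = best)
  if (!best$converged)
    warning("fit did not converge within max_iter; returning best available solution")

  A <- best$A; B <- best$B; C <- best$C
  # order components: descending emission peak, ties by descending excitation peak
  em_pk <- apply(B, 2L, function(v) if (all(v == 0)) -Inf else ds$em[which.max(v)])
  ex_pk <- apply(C, 2L, function(v) if (all(v == 0)) -Inf else ds$ex[which.max(v)])
  ord <- order(-em_pk, -ex_pk)
  A <- A[, ord, drop = FALSE]; B <- B[, ord, drop = FALSE]; C <- C[, ord, drop = FALSE]
  cn <- paste0("C", seq_len(ncomp))
  colnames(A) <- colnames(B) <- colnames(C) <- cn
  rownames(A) <- ds$manifest$sample_id

  structure(list(scores = A, em_loadings = B, ex_loadings = C, ncomp = ncomp,
                 explained_variance = 100 * (1 - best$rss / tss),
                 rss = best$rss, tss = tss,
                 n_iterations = best$n_iterations, converged = best$converged,
                 start_seed = as.integer(seed), ex = ds$ex, em = ds$em,
                 mask = ds$mask, manifest = ds$manifest),
            class = "parafac")
}

#' @export
print.parafac <- function(x, ...) {
  cat(sprintf("<parafac> %d components, %d samples; %.4f%% of variation explained (%d iterations%s)\n",
              x$ncomp, nrow(x$scores), x$explained_variance, x$n_iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' @export
summary.parafac <- function(object, ...) {
  pk <- data.frame(
    component = colnames(object$scores),
    peak_ex_nm = apply(object$ex_loadings, 2L, function(v) object$ex[which.max(v)]),
    peak_em_nm = apply(object$em_loadings, 2L, function(v) object$em[which.max(v)]),
    mean_score = colMeans(object$scores))
  structure(list(ncomp = object$ncomp, n_samples = nrow(object$scores),
                 explained_variance = object$explained_variance,
                 converged = object$converged, n_iterations = object$n_iterations,
                 components = pk), class = "summary.parafac")
}

#' @export
print.summary.parafac <- function(x, ...) {
  cat(sprintf("Non-negative PARAFAC model: %d components, %d samples\n",
              x$ncomp, x$n_samples))
  cat(sprintf("Explained variation: %.4f%%  (converged: %s, %d iterations)\n",
              x$explained_variance, x$converged, x$n_iterations))
  print(x$components, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.parafac <- function(object, ...) {
  list(scores = object$scores, em_loadings = object$em_loadings,
       ex_loadings = object$ex_loadings)
}

#' @export
fitted.parafac <- function(object, ...) {
  I <- nrow(object$scores); J <- nrow(object$em_loadings); K <- nrow(object$ex_loadings)
  array(tcrossprod(object$scores, khatri_rao(object$em_loadings, object$ex_loadings)),
        c(I, J, K))
}

#' @export
residuals.parafac <- function(object, ds = NULL, ...) {
  if (is.null(ds)) stop("supply the fitted eem_dataset via the 'ds' argument", call. = FALSE)
  ds$tensor - fitted(object)
}

#' @export
plot.parafac <- function(x, which = seq_len(x$ncomp), ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::matplot(x$em, x$em_loadings[, which, drop = FALSE], type = "l", lty = 1,
                    xlab = "emission (nm)", ylab = "loading", main = "emission loadings", ...)
  graphics::legend("topright", colnames(x$scores)[which], col = seq_along(which),
                   lty = 1, cex = 0.7, bty = "n")
  graphics::matplot(x$ex, x$ex_loadings[, which, drop = FALSE], type = "l", lty = 1,
                    xlab = "excitation (nm)", ylab = "loading", main = "excitation loadings", ...)
  invisible(x)
}

# nonnegative least squares for a score vector given fixed spectral loadings
nnls_scores <- function(Y_obs, KR_obs, G, max_iter = 500, tol = 1e-12) {
  s <- pmax(0, qr.coef(qr(KR_obs), Y_obs))
  s[is.na(s)] <- 0
  p <- crossprod(KR_obs, Y_obs)
  for (i in seq_len(max_iter)) {
    s_old <- s
    for (f in seq_along(s)) {
      d <- G[f, f]
      if (d < 1e-12) next
      s[f] <- max(0, s[f] + (p[f] - sum(G[f, ] * s)) / d)
    }
    if (sum((s - s_old)^2) <= tol * max(sum(s_old^2), 1e-300)) break
  }
  s
}

#' Project new EEMs onto a fitted PARAFAC model
#'
#' Estimates non-negative scores for new samples with the model's emission
#' and excitation loadings held fixed (a non-negative least-squares
#' projection over unmasked cells).
#'
#' @param object a fitted [parafac()] model.
#' @param newdata an `eem` or `eem_dataset` on the model's grids.
#' @param ... unused.
#' @return A sample x component score matrix (R.U.).
#' @export
predict.parafac <- function(object, newdata, ...) {
  if (inherits(newdata, "eem"))
    newdata <- assemble_dataset(list(newdata), require_state = newdata$state)
  stopifnot(inherits(newdata, "eem_dataset"))
  if (!isTRUE(all.equal(newdata$em, object$em)) || !isTRUE(all.equal(newdata$ex, object$ex)))
    stop("newdata grids differ from the model grids", call. = FALSE)
  KR <- khatri_rao(object$em_loadings, object$ex_loadings)
  I <- dim(newdata$tensor)[1]
  X1 <- matrix(newdata$tensor, I, length(object$em) * length(object$ex))
  out <- matrix(0, I, object$ncomp, dimnames = list(newdata$manifest$sample_id,
                                                    colnames(object$scores)))
  for (i in seq_len(I)) {
    obs <- which(!is.na(X1[i, ]))
    KRo <- KR[obs, , drop = FALSE]
    out[i, ] <- nnls_scores(X1[i, obs], KRo, crossprod(KRo))
  }
  out
}

#' Percent of total variation explained by a PARAFAC model
#'
#' Computes 100 * (1 - RSS / TSS) over the unmasked cells of the dataset,
#' where TSS is the uncentred total sum of squares.
#'
#' @param model a fitted [parafac()] model.
#' @param ds the `eem_dataset` the model was fitted on (same grids).
#' @return Percentage in `[0, 100]` (can be negative for a pathological model).
#' @export
explained_variance <- function(model, ds) {
  stopifnot(inherits(model, "parafac"), inherits(ds, "eem_dataset"))
  if (!isTRUE(all.equal(ds$em, model$em)) || !isTRUE(all.equal(ds$ex, model$ex)))
    stop("dataset grids differ from the model grids", call. = FALSE)
  obs <- !is.na(ds$tensor)
  tss <- sum(ds$tensor[obs]^2)
  if (tss == 0) stop("total sum of squares is zero", call. = FALSE)
  rss <- sum((ds$tensor[obs] - fitted(model)[obs])^2)
  100 * (1 - rss / tss)
}

#' Tucker congruence coefficient
#'
#' Cosine similarity between two loading vectors,
#' sum(u v) / sqrt(sum(u^2) sum(v^2)); the standard statistic for matching
#' fluorescence components across models and against spectral databases.
#'
#' @param u,v numeric vectors of equal length; neither may be all zero.
#' @return Scalar in `[-1, 1]`.
#' @export
tucker_congruence <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length", call. = FALSE)
  nu <- sum(u^2); nv <- sum(v^2)
  if (nu == 0 || nv == 0) stop("congruence undefined for a zero vector", call. = FALSE)
  sum(u * v) / sqrt(nu * nv)
}

# congruence that tolerates dead components (returns 0)
safe_congruence <- function(u, v) {
  nu <- sum(u^2); nv <- sum(v^2)
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / sqrt(nu * nv)
}

# greedy injective assignment between two models maximizing the per-pair
# min(emission, excitation) congruence; returns data.frame of pairs
match_loadings <- function(emA, exA, emB, exB) {
  FA <- ncol(emA); FB <- ncol(emB)
  score <- matrix(0, FA, FB)
  cem <- matrix(0, FA, FB); cex <- matrix(0, FA, FB)
  for (i in seq_len(FA)) for (j in seq_len(FB)) {
    cem[i, j] <- safe_congruence(emA[, i], emB[, j])
    cex[i, j] <- safe_congruence(exA[, i], exB[, j])
    score[i, j] <- min(cem[i, j], cex[i, j])
  }
  n <- min(FA, FB)
  pairs <- data.frame(a = integer(n), b = integer(n),
                      congruence_em = numeric(n), congruence_ex = numeric(n))
  sc <- score
  for (r in seq_len(n)) {
    idx <- which.max(sc)
    i <- (idx - 1L) %% FA + 1L; j <- (idx - 1L) %/% FA + 1L
    pairs$a[r] <- i; pairs$b[r] <- j
    pairs$congruence_em[r] <- cem[i, j]
    pairs$congruence_ex[r] <- cex[i, j]
    sc[i, ] <- -Inf; sc[, j] <- -Inf
  }
  pairs
}

#' Split-half validation of a PARAFAC model
#'
#' Splits the dataset into four quarters (round-robin over manifest order,
#' robust to ordered manifests), combines them into the three canonical
#' half-pairs (Q1+Q2 vs Q3+Q4, Q1+Q3 vs Q2+Q4, Q1+Q4 vs Q2+Q3), fits an
#' independent model on each half, and matches components between halves by
#' maximal Tucker congruence. The model is validated when every matched
#' component exceeds `threshold` in both emission and excitation modes for
#' all three half-pairs.
#'
#' @param ds an `eem_dataset` with at least `4 * ncomp` samples.
#' @param ncomp number of components to validate.
#' @param threshold per-mode congruence threshold (default 0.95).
#' @param n_starts,tol,max_iter,seed passed to the half fits.
#' @return An object of class `"parafac_validation"`: list with `scheme`,
#'   `per_component_congruence` (data.frame: half_pair, component pair,
#'   per-mode congruences), `min_congruence`, `threshold`, `validated`.
#' @export
split_half_validate <- function(ds, ncomp, threshold = 0.95, n_starts = 3,
                                tol = 1e-8, max_iter = 2500, seed = 1L) {
  stopifnot(inherits(ds, "eem_dataset"))
  n <- dim(ds$tensor)[1]
  if (n < 4 * ncomp)
    stop(sprintf("split-half needs at least %d samples for %d components", 4 * ncomp, ncomp),
         call. = FALSE)
  quarter <- ((seq_len(n) - 1L) %% 4L) + 1L
  pairs <- list(c(1, 2), c(1, 3), c(1, 4))
  seeds <- derive_seeds(seed, 6L)
  rows <- list(); si <- 0L
  for (p in seq_along(pairs)) {
    h1 <- which(quarter %in% pairs[[p]])
    h2 <- which(!quarter %in% pairs[[p]])
    m1 <- parafac(subset_dataset(ds, h1), ncomp, n_starts = n_starts, tol = tol,
                  max_iter = max_iter, seed = seeds[si <- si + 1L])
    m2 <- parafac(subset_dataset(ds, h2), ncomp, n_starts = n_starts, tol = tol,
                  max_iter = max_iter, seed = seeds[si <- si + 1L])
    mt <- match_loadings(m1$em_loadings, m1$ex_loadings, m2$em_loadings, m2$ex_loadings)
    mt$half_pair <- paste0("Q", pairs[[p]][1], pairs[[p]][2], "_vs_rest")
    rows[[p]] <- mt
  }
  tab <- do.call(rbind, rows)
  min_c <- min(tab$congruence_em, tab$congruence_ex)
  structure(list(scheme = "four quarters, three half-pairs",
                 per_component_congruence = tab,
                 min_congruence = min_c, threshold = threshold,
                 validated = min_c >= threshold),
            class = "parafac_validation")
}

#' @export
print.parafac_validation <- function(x, ...) {
  cat(sprintf("<parafac_validation> %s\n  min congruence %.4f (threshold %.2f): %s\n",
              x$scheme, x$min_congruence, x$threshold,
              if (x$validated) "VALIDATED" else "not validated"))
  invisible(x)
}

#' Sample-mode leverage outlier screening
#'
#' Computes hat-matrix leverages from the model's sample scores,
#' h = diag(S (S'S)^-1 S'); leverages lie in `[0, 1]` and sum to the number
#' of components. Samples above `leverage_cut` (default three times the
#' average leverage, F/n) are flagged for removal and refitting.
#'
#' @param ds the fitted `eem_dataset` (for sample ids).
#' @param model a fitted [parafac()] model.
#' @param leverage_cut flagging threshold; default `min(3 * ncomp / n, 0.95)`.
#' @return An object of class `"parafac_outliers"`: list with `leverages`
#'   (named), `flagged` (sample ids), `criterion`, `refit_recommended`.
#' @export
detect_outliers <- function(ds, model, leverage_cut = NULL) {
  stopifnot(inherits(model, "parafac"))
  S <- model$scores
  n <- nrow(S)
  if (is.null(leverage_cut)) leverage_cut <- min(3 * model$ncomp / n, 0.95)
  G <- crossprod(S)
  Gi <- tryCatch(solve(G), error = function(e) solve(G + diag(1e-10 * mean(diag(G)), ncol(G))))
  lev <- rowSums((S %*% Gi) * S)
  names(lev) <- rownames(S)
  flagged <- names(lev)[lev > leverage_cut]
  structure(list(leverages = lev, flagged = flagged,
                 criterion = sprintf("leverage > %.4g", leverage_cut),
                 refit_recommended = length(flagged) > 0),
            class = "parafac_outliers")
}

#' @export
print.parafac_outliers <- function(x, ...) {
  cat(sprintf("<parafac_outliers> %s; %d sample(s) flagged\n",
              x$criterion, length(x$flagged)))
  if (length(x$flagged)) cat(" ", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Match model components against a spectral library
#'
#' For each fitted component, reports library entries whose excitation and
#' emission loadings both exceed `threshold` in Tucker congruence (the
#' matching statistic used by online fluorescence component databases).
#' Library loadings are linearly interpolated onto the model grids.
#'
#' @param model a fitted [parafac()] model.
#' @param library a [make_component_library()] result (or compatible list).
#' @param threshold minimum per-mode congruence (default 0.95).
#' @return data.frame with columns `component`, `library_entry`,
#'   `congruence_em`, `congruence_ex`, `congruence_min`, sorted within
#'   component by descending `congruence_min`.
#' @export
match_components <- function(model, library, threshold = 0.95) {
  stopifnot(inherits(model, "parafac"))
  if (!length(library)) stop("empty component library", call. = FALSE)
  rows <- list()
  for (f in seq_len(model$ncomp)) for (l in seq_along(library)) {
    lib <- library[[l]]
    em_l <- interp_onto(lib$em_grid, lib$emission_loading, model$em)
    ex_l <- interp_onto(lib$ex_grid, lib$excitation_loading, model$ex)
    cem <- safe_congruence(model$em_loadings[, f], em_l)
    cex <- safe_congruence(model$ex_loadings[, f], ex_l)
    if (min(cem, cex) >= threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        component = colnames(model$scores)[f], library_entry = lib$name,
        congruence_em = cem, congruence_ex = cex, congruence_min = min(cem, cex),
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(component = character(), library_entry = character(),
                      congruence_em = numeric(), congruence_ex = numeric(),
                      congruence_min = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$component, -out$congruence_min), , drop = FALSE]
}

# tensor-times-matrix along mode 1 of an F-led array
ttm1 <- function(Y, M) {
  d <- dim(Y)
  array(M %*% matrix(Y, d[1], prod(d[-1])), c(nrow(M), d[-1]))
}

pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Core consistency diagnostic
#'
#' Fits an unconstrained Tucker core to the data with the PARAFAC factors
#' held fixed and measures how close it is to the superdiagonal identity the
#' trilinear model assumes: 100 * (1 - sum((G - T)^2) / F). Values near 100
#' support the trilinear structure; low or negative values indicate
#' over-factoring. Masked cells are imputed from the model. This is an
#' auxiliary diagnostic; split-half congruence is the validation gate.
#'
#' @param model a fitted [parafac()] model.
#' @param ds the fitted `eem_dataset`.
#' @return Core consistency percentage (can be negative).
#' @export
core_consistency <- function(model, ds) {
  stopifnot(inherits(model, "parafac"), inherits(ds, "eem_dataset"))
  X <- ds$tensor
  fit <- fitted(model)
  X[is.na(X)] <- fit[is.na(X)]
  F_ <- model$ncomp
  G <- ttm1(X, pinv(model$scores))                 # F x J x K
  G <- aperm(ttm1(aperm(G, c(2, 1, 3)), pinv(model$em_loadings)), c(2, 1, 3))
  G <- aperm(ttm1(aperm(G, c(3, 1, 2)), pinv(model$ex_loadings)), c(2, 3, 1))
  T_ <- array(0, c(F_, F_, F_))
  for (f in seq_len(F_)) T_[f, f, f] <- 1
  100 * (1 - sum((G - T_)^2) / F_)
}

#' Choose the number of PARAFAC components
#'
#' Fits each candidate component count, records explained variance, core
#' consistency and split-half validation, and returns the largest validated
#' candidate. When no candidate validates, the selected count is `NA`
#' ("no validated model") and the diagnostics table is still returned.
#'
#' @param ds an `eem_dataset`.
#' @param candidates integer vector of component counts to try.
#' @param threshold split-half congruence threshold.
#' @param n_starts,tol,max_iter,seed fitting controls.
#' @return An object of class `"parafac_selection"`: list with `ncomp`
#'   (selected, or `NA`), `diagnostics` (data.frame), `models` (fitted
#'   models, named by component count).
#' @export
select_n_components <- function(ds, candidates, threshold = 0.95, n_starts = 5,
                                tol = 1e-8, max_iter = 2500, seed = 1L) {
  if (!length(candidates)) stop("no candidate component counts", call. = FALSE)
  candidates <- sort(unique(as.integer(candidates)))
  seeds <- derive_seeds(seed, 2L * length(candidates))
  diag_rows <- list(); models <- list()
  for (i in seq_along(candidates)) {
    F_ <- candidates[i]
    m <- parafac(ds, F_, n_starts = n_starts, tol = tol, max_iter = max_iter,
                 seed = seeds[2L * i - 1L])
    v <- tryCatch(split_half_validate(ds, F_, threshold = threshold, n_starts = max(2, n_starts %/% 2),
                                      tol = tol, max_iter = max_iter, seed = seeds[2L * i]),
                  error = function(e) NULL)
    diag_rows[[i]] <- data.frame(
      ncomp = F_, explained_variance = m$explained_variance,
      core_consistency = core_consistency(m, ds),
      min_congruence = if (is.null(v)) NA_real_ else v$min_congruence,
      validated = if (is.null(v)) FALSE else v$validated)
    models[[as.character(F_)]] <- m
  }
  diagnostics <- do.call(rbind, diag_rows)
  ok <- diagnostics$ncomp[diagnostics$validated]
  structure(list(ncomp = if (length(ok)) max(ok) else NA_integer_,
                 diagnostics = diagnostics, models = models),
            class = "parafac_selection")
}

#' @export
print.parafac_selection <- function(x, ...) {
  if (is.na(x$ncomp)) cat("<parafac_selection> no validated model\n")
  else cat(sprintf("<parafac_selection> selected %d components\n", x$ncomp))
  print(x$diagnostics, row.names = FALSE, digits = 4)
  invisible(x)
}
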