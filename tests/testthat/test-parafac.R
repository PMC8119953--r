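test_that("a rank-1 tensor is recovered exactly by a one-component model", {
  set.seed(4)
  A <- matrix(runif(8, 0.5, 2), 8, 1)
  B <- matrix(gauss <- exp(-(seq(300, 400, 5) - 350)^2 / 500), ncol = 1)
  C <- matrix(exp(-(seq(240, 340, 10) - 280)^2 / 400), ncol = 1)
  ds <- toy_dataset(A, B, C, em = seq(300, 400, 5), ex = seq(240, 340, 10))
  m <- parafac(ds, 1, n_starts = 2, seed = 1)
  expect_gt(m$explained_variance, 100 - 1e-8)
  expect_gt(abs(tucker_congruence(m$em_loadings[, 1], B[, 1])), 1 - 1e-6)
  expect_gt(abs(tucker_congruence(m$ex_loadings[, 1], C[, 1])), 1 - 1e-6)
})

test_that("loadings stay nonnegative, unit norm and emission-ordered", {
  cfg <- test_campaign(seed = 21, treatments = "PB",
                       timepoints_days = list(PB = c(0, 3, 24)))
  camp <- simulate_campaign(cfg)
  ds <- assemble_dataset(camp$eems)
  m <- parafac(ds, 4, n_starts = 2, seed = 5)
  expect_true(all(m$scores >= 0))
  expect_true(all(m$em_loadings >= 0) && all(m$ex_loadings >= 0))
  expect_equal(colSums(m$em_loadings^2), rep(1, 4), ignore_attr = TRUE)
  expect_equal(colSums(m$ex_loadings^2), rep(1, 4), ignore_attr = TRUE)
  peaks <- apply(m$em_loadings, 2, function(v) m$em[which.max(v)])
  expect_true(all(diff(peaks) <= 0))
})

test_that("the same seed reproduces the model and different seeds agree after alignment", {
  cfg <- test_campaign(seed = 31, treatments = "PB",
                       timepoints_days = list(PB = c(0, 7, 24)))
  camp <- simulate_campaign(cfg)
  ds <- assemble_dataset(camp$eems)
  m1 <- parafac(ds, 6, n_starts = 2, seed = 9)
  m2 <- parafac(ds, 6, n_starts = 2, seed = 9)
  expect_identical(m1$scores, m2$scores)
  expect_identical(m1$em_loadings, m2$em_loadings)
  m3 <- parafac(ds, 6, n_starts = 2, seed = 77)
  mt <- fluordom:::match_loadings(m1$em_loadings, m1$ex_loadings,
                                  m3$em_loadings, m3$ex_loadings)
  expect_true(all(pmin(mt$congruence_em, mt$congruence_ex) >= 0.999))
})

test_that("noiseless campaign data are explained essentially completely", {
  cfg <- test_campaign(seed = 41, noise_mult = 0, noise_add = 0,
                       timepoints_days = list(PB = c(0, 1, 3, 7, 14, 24)))
  camp <- simulate_campaign(cfg)
  ds <- assemble_dataset(camp$eems)
  m <- parafac(ds, 6, n_starts = 2, tol = 1e-10, max_iter = 6000, seed = 1)
  expect_gt(m$explained_variance, 100 * (1 - 1e-6))
})

test_that("explained variance is 100 for perfect fits, 0 for a null model, and nested in F", {
  set.seed(8)
  A <- matrix(runif(12, 0.2, 1), 12, 3)
  B <- matrix(runif(45), 15, 3); C <- matrix(runif(36), 12, 3)
  ds <- toy_dataset(A, B, C)
  m3 <- parafac(ds, 3, n_starts = 3, seed = 2)
  expect_equal(explained_variance(m3, ds), m3$explained_variance, tolerance = 1e-9)
  expect_gt(explained_variance(m3, ds), 100 - 1e-5)
  null_model <- m3; null_model$scores[] <- 0
  expect_equal(explained_variance(null_model, ds), 0)
  evs <- vapply(1:3, function(F_)
    parafac(ds, F_, n_starts = 3, seed = 2)$explained_variance, numeric(1))
  expect_true(all(diff(evs) > -1e-8))
})

test_that("Tucker congruence has its defining properties", {
  u <- c(0.2, 0.5, 0.8)
  expect_equal(tucker_congruence(u, u), 1)
  expect_equal(tucker_congruence(u, 2 * u), 1)
  expect_equal(tucker_congruence(c(1, 0, 0), c(0, 0, 1)), 0)
  expect_error(tucker_congruence(u, rep(0, 3)), "zero vector")
  expect_error(tucker_congruence(u, c(1, 2)), "equal length")
})

test_that("sample leverages obey the hat-matrix identities and flag gross outliers", {
  lib <- make_component_library(test_ex, test_em)
  sc <- matrix(rep(c(1, 0.6, 0.9, 0.7, 0.2, 0.1), each = 12), 12, byrow = FALSE)
  set.seed(6); sc <- sc * matrix(runif(72, 0.8, 1.2), 12)
  eems <- lapply(seq_len(12), function(i) simulate_eem(sc[i, ], lib, 0.002, 1e-5, i,
                                                       meta = list(sample_id = paste0("S", i))))
  ds <- assemble_dataset(eems)
  m <- parafac(ds, 3, n_starts = 2, seed = 3)
  out <- detect_outliers(ds, m)
  expect_equal(sum(out$leverages), m$ncomp, tolerance = 1e-6)
  expect_true(all(out$leverages >= 0 & out$leverages <= 1 + 1e-12))
  # identical samples share leverage and none are flagged
  eems_same <- lapply(seq_len(8), function(i)
    simulate_eem(c(1, 0.6, 0.9, 0.7, 0.2, 0.1), lib, 0, 0, 1,
                 meta = list(sample_id = paste0("S", i))))
  ds_same <- assemble_dataset(eems_same)
  m_same <- parafac(ds_same, 2, n_starts = 2, seed = 3)
  o_same <- detect_outliers(ds_same, m_same)
  expect_lt(diff(range(o_same$leverages)), 1e-9)
  expect_length(o_same$flagged, 0)
  # one sample scaled x100 dominates the leverage
  eems_out <- eems
  eems_out[[5]] <- simulate_eem(100 * sc[5, ], lib, 0.002, 1e-5, 5,
                                meta = list(sample_id = "S5"))
  ds_out <- assemble_dataset(eems_out)
  m_out <- parafac(ds_out, 3, n_starts = 2, seed = 3)
  o_out <- detect_outliers(ds_out, m_out)
  expect_equal(names(which.max(o_out$leverages)), "S5")
  expect_true("S5" %in% o_out$flagged)
})

test_that("masked cells have no influence on the fit", {
  set.seed(12)
  A <- matrix(runif(16, 0.2, 1), 16, 2)
  B <- matrix(runif(30), 15, 2); C <- matrix(runif(24), 12, 2)
  mask <- matrix(FALSE, 15, 12); mask[3:5, 4:6] <- TRUE
  ds <- toy_dataset(A, B, C, mask = mask)
  poisoned <- ds
  for (i in seq_len(16)) {
    sl <- poisoned$tensor[i, , ]
    sl[mask] <- 1e6   # then re-mask: the stored tensor keeps NA at masked cells
    sl[mask] <- NA
    poisoned$tensor[i, , ] <- sl
  }
  m1 <- parafac(ds, 2, n_starts = 2, seed = 4)
  m2 <- parafac(poisoned, 2, n_starts = 2, seed = 4)
  expect_identical(m1$scores, m2$scores)
  expect_gt(m1$explained_variance, 100 - 1e-6)
})

test_that("split-half validation is exact for duplicated data and rejects overfactoring", {
  lib <- make_component_library(test_ex, test_em)
  base <- lapply(1:4, function(i) {
    # three-component truth on well-separated fluorophores (C2, C4, C6)
    set.seed(i); v <- rep(0, 6); v[c(2, 4, 6)] <- runif(3, 0.1, 1); v
  })
  eems <- lapply(seq_len(16), function(i)
    simulate_eem(base[[(i - 1) %% 4 + 1]], lib, 0, 0, 1,
                 meta = list(sample_id = paste0("S", i))))
  ds <- assemble_dataset(eems)
  # quarters are identical by construction: congruence 1 between halves
  v <- split_half_validate(ds, 3, n_starts = 2, seed = 5)
  expect_true(v$validated)
  expect_gt(v$min_congruence, 1 - 1e-6)
  expect_error(split_half_validate(ds, 5, seed = 1), "at least")
})

test_that("masked nonnegative ALS matches an independent trilinear reference on small tensors", {
  for (seed in 1:3) {
    set.seed(seed)
    A <- matrix(runif(8 * 3, 0.2, 1), 8, 3)
    B <- matrix(runif(20 * 3), 20, 3)
    C <- matrix(runif(20 * 3), 20, 3)
    X <- array(0, c(8, 20, 20))
    for (f in 1:3) X <- X + A[, f] %o% B[, f] %o% C[, f]
    ds <- toy_dataset(A, B, C, em = seq(300, 395, 5), ex = seq(240, 430, 10))
    m <- parafac(ds, 3, n_starts = 3, tol = 1e-15, max_iter = 30000, seed = seed)
    rel_pkg <- sqrt(m$rss / m$tss)
    rel_oracle <- oracle_cp_als(X, 3, seed = seed)
    expect_lt(abs(rel_pkg - rel_oracle), 1e-6)
  }
})

test_that("component counts are selected by validation, and pure noise validates nothing", {
  lib <- make_component_library(test_ex, test_em)
  set.seed(19)
  scores <- matrix(runif(24 * 6, 0.1, 1), 24, 6)
  scores[, 4:6] <- 0   # a three-component truth embedded in the library
  eems <- lapply(seq_len(24), function(i)
    simulate_eem(scores[i, ], lib, 0.005, 1e-4, i,
                 meta = list(sample_id = paste0("S", i))))
  ds <- assemble_dataset(eems)
  sel <- select_n_components(ds, c(2, 3, 4), n_starts = 2, seed = 8)
  expect_equal(sel$ncomp, 3L)
  expect_true(sel$diagnostics$validated[sel$diagnostics$ncomp == 3])
  expect_false(sel$diagnostics$validated[sel$diagnostics$ncomp == 4])
  # unstructured noise: no candidate validates
  noise <- lapply(seq_len(24), function(i) {
    set.seed(100 + i)
    eem(test_ex, test_em,
        matrix(abs(rnorm(length(test_em) * length(test_ex), 0, 1)),
               length(test_em), length(test_ex)),
        state = fluordom:::.eem_steps, meta = list(sample_id = paste0("N", i)))
  })
  ds_n <- assemble_dataset(noise)
  sel_n <- select_n_components(ds_n, c(2, 3), n_starts = 2, seed = 8)
  expect_true(is.na(sel_n$ncomp))
})

test_that("library matching finds self-matches and respects the threshold bound", {
  lib <- make_component_library(test_ex, test_em)
  eems <- lapply(seq_len(14), function(i) {
    set.seed(i); simulate_eem(runif(6, 0.1, 1), lib, 0.005, 1e-4, i,
                              meta = list(sample_id = paste0("S", i)))
  })
  ds <- assemble_dataset(eems)
  m <- parafac(ds, 6, n_starts = 3, seed = 2)
  mt <- match_components(m, lib, threshold = 0.95)
  expect_equal(nrow(mt), 6L)           # every fitted component matches its source
  expect_setequal(mt$library_entry, names(lib))
  expect_true(all(mt$congruence_min >= 0.95))
  expect_equal(nrow(match_components(m, lib, threshold = 1.01)), 0L)
  expect_error(match_components(m, list()), "empty")
})

test_that("new samples project onto fixed loadings with nonnegative scores", {
  lib <- make_component_library(test_ex, test_em)
  eems <- lapply(seq_len(14), function(i) {
    set.seed(i); simulate_eem(runif(6, 0.1, 1), lib, 0.002, 1e-5, i,
                              meta = list(sample_id = paste0("S", i)))
  })
  ds <- assemble_dataset(eems)
  m <- parafac(ds, 6, n_starts = 3, seed = 2)
  truth <- c(0.8, 0.3, 0.5, 0.4, 0.1, 0.05)
  new_eem <- simulate_eem(truth, lib, 0, 0, 1, meta = list(sample_id = "new"))
  sc <- predict(m, new_eem)
  expect_true(all(sc >= 0))
  # scores carry Fmax-scale magnitude: reconstruction matches the new sample
  recon <- m$em_loadings %*% diag(as.numeric(sc)) %*% t(m$ex_loadings)
  expect_lt(sqrt(sum((recon - new_eem$intensity)^2) / sum(new_eem$intensity^2)), 0.02)
})
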