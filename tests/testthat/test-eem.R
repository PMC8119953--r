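make_flat_eem <- function(val = 1, ex = test_ex, em = test_em, state = character()) {
  eem(ex, em, matrix(val, length(em), length(ex)), state = state,
      meta = list(sample_id = "x"))
}

test_that("blank subtraction is exact and single-shot", {
  s <- make_flat_eem(2); b <- make_flat_eem(2)
  z <- subtract_blank(s, b)
  expect_true(all(z$intensity == 0))
  expect_equal(z$state, "blank_subtracted")
  ident <- subtract_blank(make_flat_eem(3), make_flat_eem(0))
  expect_true(all(ident$intensity == 3))
  expect_error(subtract_blank(z, b), "already applied")
  small <- eem(test_ex[-1], test_em, matrix(1, length(test_em), length(test_ex) - 1))
  expect_error(subtract_blank(s, small), "grids differ")
})

test_that("inner-filter correction applies the absorbance-based multiplier", {
  wl <- 220:750
  # decadal absorbance 0.1 per cm across the band
  abs01 <- absorbance_spectrum(wl, rep(0.1 * 5, length(wl)), pathlength = 0.05)
  s <- make_flat_eem(1, state = "blank_subtracted")
  cor <- inner_filter_correct(s, abs01)
  expect_equal(cor$intensity[1, 1], 10^0.1, tolerance = 1e-12)
  expect_true(all(cor$intensity >= s$intensity))
  zero <- absorbance_spectrum(wl, rep(0, length(wl)))
  s2 <- make_flat_eem(1, state = "blank_subtracted")
  expect_equal(inner_filter_correct(s2, zero)$intensity, s2$intensity)
  # strongly absorbing sample flagged as unreliable
  dark <- absorbance_spectrum(wl, rep(0.8 * 5, length(wl)), pathlength = 0.05)
  expect_warning(inner_filter_correct(make_flat_eem(1, state = "blank_subtracted"), dark),
                 "unreliable")
})

test_that("correction order is enforced", {
  s <- make_flat_eem(1)
  ref <- structure(list(raman_area = 2), class = "raman_reference")
  expect_error(raman_normalize(s, ref), "requires prior")
  expect_error(mask_scatter(s), "requires prior")
  expect_error(inner_filter_correct(s, absorbance_spectrum(220:750, rep(0, 531))),
               "requires prior")
})

test_that("Raman peak integration matches closed forms", {
  em <- 300:500; ex <- seq(240, 650, 5)
  # constant intensity c over the integration window: trapezoid = width * c
  blank_const <- eem(ex, em, matrix(0.5, length(em), length(ex)))
  ref <- compute_raman_area(blank_const, ex_line = 350, em_range = c(371, 428))
  expect_equal(ref$raman_area, 0.5 * (428 - 371))
  # Gaussian band: analytic integral amp * sd * sqrt(2*pi) within 1%
  band <- 0.3 * exp(-(em - 399)^2 / (2 * 8^2))
  blank_g <- eem(ex, em, matrix(band, length(em), length(ex)))
  ref_g <- compute_raman_area(blank_g, ex_line = 350, em_range = c(371, 428))
  expect_equal(ref_g$raman_area, 0.3 * 8 * sqrt(2 * pi), tolerance = 0.01)
  expect_error(compute_raman_area(eem(ex, em, matrix(0, length(em), length(ex)))),
               "not positive")
})

test_that("Raman normalization cancels instrument gain", {
  em <- 300:500; ex <- seq(240, 650, 5)
  true_signal <- outer(exp(-(em - 420)^2 / 2000), exp(-(ex - 330)^2 / 1500))
  raman_band <- 0.1 * exp(-(em - 399)^2 / (2 * 8^2))
  run_instrument <- function(gain) {
    blank <- eem(ex, em, gain * matrix(raman_band, length(em), length(ex)))
    sample <- eem(ex, em, gain * true_signal,
                  state = c("blank_subtracted", "ife_corrected"))
    raman_normalize(sample, compute_raman_area(blank))
  }
  r1 <- run_instrument(1); r7 <- run_instrument(7.3)
  expect_equal(r1$intensity, r7$intensity, tolerance = 1e-12)
  ref1 <- structure(list(raman_area = 1), class = "raman_reference")
  s <- make_flat_eem(2, state = c("blank_subtracted", "ife_corrected"))
  expect_equal(raman_normalize(s, ref1)$intensity, s$intensity)
})

test_that("scatter masking hits exactly the configured bands", {
  st3 <- c("blank_subtracted", "ife_corrected", "raman_normalized")
  s <- make_flat_eem(1, state = st3)
  ident <- mask_scatter(s, widths = c(rayleigh1 = 0, raman1 = 0, rayleigh2 = 0, raman2 = 0),
                        zero_below = FALSE)
  expect_equal(ident$intensity, s$intensity)
  # spike on the first-order Rayleigh line is masked
  sp <- make_flat_eem(0, state = st3)
  sp$intensity[which.min(abs(sp$em - 350)), which.min(abs(sp$ex - 350))] <- 100
  masked <- mask_scatter(sp, widths = c(rayleigh1 = 10, raman1 = 0, rayleigh2 = 0, raman2 = 0),
                         zero_below = FALSE)
  expect_true(is.na(masked$intensity[which.min(abs(masked$em - 350)),
                                     which.min(abs(masked$ex - 350))]))
  # reported mask fraction equals a direct cell count
  w <- c(rayleigh1 = 10, raman1 = 5, rayleigh2 = 10, raman2 = 10)
  m2 <- mask_scatter(make_flat_eem(1, state = st3), widths = w, zero_below = FALSE)
  raman_line <- 1 / (1 / test_ex - 3382e-7)
  cnt <- 0L
  for (k in seq_along(test_ex)) for (j in seq_along(test_em)) {
    em_ <- test_em[j]; ex_ <- test_ex[k]
    if (abs(em_ - ex_) <= 10 || abs(em_ - raman_line[k]) <= 5 ||
        abs(em_ - 2 * ex_) <= 10 || abs(em_ - 2 * raman_line[k]) <= 10) cnt <- cnt + 1L
  }
  expect_equal(attr(m2, "mask_fraction"), cnt / (length(test_em) * length(test_ex)))
  expect_equal(sum(is.na(m2$intensity)), cnt)
  expect_error(mask_scatter(make_flat_eem(1, state = st3), widths = c(rayleigh1 = -1)),
               "nonnegative")
})

test_that("dataset assembly requires homogeneous grids and states", {
  lib <- make_component_library(test_ex, test_em)
  eems <- lapply(1:4, function(i) simulate_eem(i * (1:6) / 10, lib, seed = i,
                                               meta = list(sample_id = paste0("S", i))))
  ds <- assemble_dataset(eems)
  expect_equal(dim(ds$tensor), c(4L, length(test_em), length(test_ex)))
  expect_equal(ds$manifest$sample_id, paste0("S", 1:4))
  broken <- eems
  broken[[2]]$state <- setdiff(broken[[2]]$state, "raman_normalized")
  expect_error(assemble_dataset(broken), "raman_normalized")
})

test_that("EEM wide CSV round-trips losslessly and rejects bad dialects", {
  lib <- make_component_library(test_ex, test_em)
  e <- simulate_eem(c(0.5, 1, 0.2, 0.3, 0.05, 0.02), lib, noise_mult = 0.01, seed = 3)
  e$intensity[5, 7] <- NA  # masked cell survives the trip
  f <- withr::local_tempfile(fileext = ".csv")
  write_eem_csv(e, f)
  back <- read_eem_csv(f, state = e$state)
  expect_identical(back$intensity, e$intensity)
  expect_identical(back$ex, e$ex)
  expect_identical(back$em, e$em)
  # malformed header
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wrong,240,250", "300,1,2"), bad)
  expect_error(read_eem_csv(bad), "emission_nm")
  # locale comma decimals break the cell grid and are rejected naming the line
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("emission_nm,240,250", "300,1,5,2"), bad2)
  expect_error(read_eem_csv(bad2), "line 2")
  # non-numeric cells are named, with a decimal-separator hint for commas
  bad2b <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("emission_nm,240,250", "300,abc,2"), bad2b)
  expect_error(read_eem_csv(bad2b), "non-numeric")
  # non-monotone excitation grid
  bad3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("emission_nm,250,240", "300,1,2"), bad3)
  expect_error(read_eem_csv(bad3), "increasing")
})
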