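test_that("component library is nonnegative, unit norm and identifiable", {
  lib <- make_component_library(test_ex, test_em)
  expect_length(lib, 6L)
  for (cc in lib) {
    expect_true(all(cc$excitation_loading >= 0))
    expect_true(all(cc$emission_loading >= 0))
    expect_equal(sum(cc$excitation_loading^2), 1)
    expect_equal(sum(cc$emission_loading^2), 1)
    expect_gt(cc$peak_em, cc$peak_ex)
  }
  # pairwise congruence of combined spectra below the identifiability bound
  for (i in seq_along(lib)) for (j in seq_len(i - 1)) {
    cc <- tucker_congruence(lib[[i]]$excitation_loading, lib[[j]]$excitation_loading) *
      tucker_congruence(lib[[i]]$emission_loading, lib[[j]]$emission_loading)
    expect_lt(cc, 0.9)
  }
  # the tyrosine-like component emits blue of every humic component
  humic_em <- vapply(lib[c("C1", "C2", "C3", "C4")], `[[`, numeric(1), "peak_em")
  expect_true(all(lib$C6$peak_em < humic_em))
})

test_that("grids too coarse to separate peaks raise an identifiability error", {
  expect_error(make_component_library(seq(240, 650, 205), seq(300, 600, 150)),
               "not identifiable")
})

test_that("kinetic laws obey their closed forms and constraints", {
  expect_equal(eval_kinetics(kinetics_spec("single_exp_decay", k = 0.2), 0), 1)
  expect_equal(eval_kinetics(kinetics_spec("single_exp_decay", k = 0.2), 5), exp(-1))
  d <- kinetics_spec("double_exp_decay", f1 = 0.6, k1 = 0.5, k2 = 0.05)
  expect_equal(eval_kinetics(d, 0), 1)
  expect_equal(eval_kinetics(d, 2), 0.6 * exp(-1) + 0.4 * exp(-0.1))
  rf <- kinetics_spec("rise_then_fall", a = 0.35, k_rise = 0.6, k_decay = 0.017)
  expect_gt(eval_kinetics(rf, 3), eval_kinetics(rf, 0))
  expect_lt(eval_kinetics(rf, 24), eval_kinetics(rf, 3))
  sr <- kinetics_spec("saturating_rise", A = 1.81, k = 0.12)
  y <- eval_kinetics(sr, 0:24)
  expect_true(all(diff(y) > 0))
  expect_true(all(y <= 1 + 1.81))
  expect_error(kinetics_spec("single_exp_decay", k = -1), "nonnegative")
  expect_error(kinetics_spec("double_exp_decay", f1 = 1.2, k1 = 1, k2 = 0.1), "sum to 1")
})

test_that("simulated scores follow the kinetic sign structure", {
  cfg <- test_campaign(seed = 5, treatments = c("PB", "MD3.0"))
  sc <- simulate_scores(cfg)
  m <- sc$manifest
  for (st in unique(m$station)) {
    pb <- which(m$station == st & m$treatment == "PB" & m$replicate == 1)
    pb <- pb[order(m$timepoint_days[pb])]
    for (comp in c("C1", "C2", "C3", "C4"))
      expect_true(all(diff(sc$scores[pb, comp]) < 0))
    # dark humic changes at day 24 are at most a fifth of the PB change
    dk <- which(m$station == st & m$treatment == "MD3.0" & m$replicate == 1)
    d0 <- dk[m$timepoint_days[dk] == 0]; d24 <- dk[m$timepoint_days[dk] == 24]
    p0 <- pb[m$timepoint_days[pb] == 0]; p24 <- pb[m$timepoint_days[pb] == 24]
    for (comp in c("C1", "C2", "C3", "C4")) {
      dark_mag <- abs(sc$scores[d24, comp] / sc$scores[d0, comp] - 1)
      pb_mag <- abs(sc$scores[p24, comp] / sc$scores[p0, comp] - 1)
      expect_lt(dark_mag, pb_mag / 5)
    }
  }
})

test_that("synthetic absorbance recovers its generating slope analytically", {
  for (S in c(0.0140, 0.0175, 0.0358)) {
    sp <- simulate_absorbance(S, a350 = 5)
    a <- absorbance_to_absorption(sp)
    expect_lt(abs(fit_spectral_slope(a, c(275, 295))$S - S), 1e-6)
    expect_lt(abs(fit_spectral_slope(a, c(350, 400))$S - S), 1e-6)
  }
  expect_error(simulate_absorbance(0.018, a350 = 0), "positive")
  # amplitude scaling leaves the slope unchanged
  a1 <- absorbance_to_absorption(simulate_absorbance(0.02, 3))
  a2 <- absorbance_to_absorption(simulate_absorbance(0.02, 6))
  expect_equal(fit_spectral_slope(a1, c(275, 295))$S,
               fit_spectral_slope(a2, c(275, 295))$S, tolerance = 1e-9)
})

test_that("simulated EEMs are exact trilinear mixtures plus seeded noise", {
  lib <- make_component_library(test_ex, test_em)
  e1 <- simulate_eem(c(1, 0, 0, 0, 0, 0), lib, seed = 1)
  expect_equal(e1$intensity, lib$C1$emission_loading %o% lib$C1$excitation_loading)
  e0 <- simulate_eem(rep(0, 6), lib, seed = 1)
  expect_true(all(e0$intensity == 0))
  n1 <- simulate_eem(1:6, lib, noise_mult = 0.01, noise_add = 1e-4, seed = 42)
  n2 <- simulate_eem(1:6, lib, noise_mult = 0.01, noise_add = 1e-4, seed = 42)
  expect_identical(n1$intensity, n2$intensity)
  expect_true(all(n1$intensity >= 0))
})

test_that("campaign layout, duplicates and determinism match the design", {
  cfg <- test_campaign(seed = 11, treatments = c("PB", "MD0.7"), n_rep = 2)
  camp <- simulate_campaign(cfg)
  m <- camp$manifest
  pb <- m[m$treatment == "PB", ]
  counts <- table(pb$station, pb$timepoint_days)
  expect_true(all(counts == 2))     # duplicate bottles at every PB timepoint
  expect_setequal(unique(pb$timepoint_days), c(0, 1, 3, 7, 14, 24))
  expect_setequal(unique(m$timepoint_days[m$treatment == "MD0.7"]), c(0, 3, 10, 24))
  camp2 <- simulate_campaign(cfg)
  expect_identical(camp$manifest, camp2$manifest)
  expect_identical(camp$eems[[1]]$intensity, camp2$eems[[1]]$intensity)
  expect_identical(camp$doc, camp2$doc)
  expect_error(campaign_config(treatments = character()), "empty")
  expect_error(campaign_config(timepoints_days = list(PB = c(0, 2))), "subset")
})

test_that("a day-0-only schedule yields a degenerate campaign with no kinetics", {
  cfg <- test_campaign(seed = 2, treatments = "PB",
                       timepoints_days = list(PB = 0))
  camp <- simulate_campaign(cfg)
  expect_true(all(camp$manifest$timepoint_days == 0))
  fm <- data.frame(camp$manifest, camp$truth$true_scores, check.names = FALSE)
  ch <- component_changes(fm, grubbs = FALSE)
  expect_equal(nrow(ch), 0L)
})

test_that("photobleached spectra lose most absorption in the UV window", {
  cfg <- test_campaign(seed = 3)
  camp <- simulate_campaign(cfg)
  m <- camp$manifest
  pb <- which(m$treatment == "PB")
  for (st in unique(m$station[pb])) {
    i0 <- pb[m$station[pb] == st & m$timepoint_days[pb] == 0][1]
    for (tp in c(3, 24)) {
      it <- pb[m$station[pb] == st & m$timepoint_days[pb] == tp][1]
      pk <- peak_loss_wavelength(absorbance_to_absorption(camp$absorbance[[i0]]),
                                 absorbance_to_absorption(camp$absorbance[[it]]))
      expect_true(pk >= 290 && pk <= 305)
    }
  }
})

test_that("ground-truth sidecar serializes and carries the seed", {
  cfg <- test_campaign(seed = 13, treatments = "PB",
                       timepoints_days = list(PB = c(0, 24)))
  camp <- simulate_campaign(cfg)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_ground_truth(camp, f)
  y <- yaml::read_yaml(f)
  expect_equal(y$seed, 13)
  expect_length(y$components, 6L)
  expect_equal(y$kinetics$PB$C1$law, "single_exp_decay")
})
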