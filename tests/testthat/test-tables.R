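test_that("stations classify into river, plume and ocean by salinity", {
  expect_equal(classify_station(0.1), "river")
  expect_equal(classify_station(13.9), "plume")
  expect_equal(classify_station(2.7), "plume")
  expect_equal(classify_station(27.8), "plume")
  expect_equal(classify_station(31.2), "ocean")
  expect_equal(classify_station(c(0, 15, 35)), c("river", "plume", "ocean"))
  expect_error(classify_station(-1), "nonnegative")
  # boundaries are configurable
  rules <- list(river = c(-Inf, 5), plume = c(5, 25), ocean = c(25, Inf))
  expect_equal(classify_station(2.7, rules), "river")
})

make_changes <- function(stations, salinities, deltas, treatment = "PB",
                         parameter = "DOC", replicate = 1, kind = "percent") {
  data.frame(station = stations, salinity_psu = salinities, treatment = treatment,
             replicate = replicate, parameter = parameter, timepoint_days = 24,
             delta = deltas, kind = kind, retained = TRUE, stringsAsFactors = FALSE)
}

test_that("summary cells average between stations for river/plume groups", {
  ch <- make_changes(1:3, 0.1, c(-15, -20, -25))
  s <- summarize_changes(ch)
  expect_equal(s$mean, -20)
  expect_equal(s$sd, 5)
  expect_equal(s$n, 3L)
  expect_equal(s$basis, "between_stations")
  # replicate bottles are averaged within station before the spread is taken
  ch2 <- make_changes(c(1, 1, 2, 2, 3, 3), 0.1, c(-14, -16, -19, -21, -24, -26),
                      replicate = rep(1:2, 3))
  s2 <- summarize_changes(ch2)
  expect_equal(s2$mean, -20)
  expect_equal(s2$sd, 5)
  expect_equal(s2$n, 3L)
})

test_that("ocean-group spread is computed between replicate bottles", {
  ch <- make_changes(c(9, 9), 31.2, c(-26, -28), replicate = 1:2)
  s <- summarize_changes(ch)
  expect_equal(s$mean, -27)
  expect_equal(s$sd, sd(c(-26, -28)))
  expect_equal(s$basis, "between_replicates")
  expect_equal(s$n, 2L)
  # all-equal inputs: the spread is exactly zero
  s0 <- summarize_changes(make_changes(c(9, 9), 31.2, c(-27, -27), replicate = 1:2))
  expect_equal(s0$sd, 0)
  # single bottle: spread omitted
  s1 <- summarize_changes(make_changes(9, 31.2, -7.7))
  expect_true(is.na(s1$sd))
})

test_that("slope changes are audited to be absolute, and units propagate", {
  ch <- make_changes(1:3, 0.1, c(0.0099, 0.0101, 0.0100), parameter = "S275:295",
                     kind = "absolute_per_nm")
  s <- summarize_changes(ch)
  expect_equal(s$units, "1/nm")
  expect_equal(s$mean, 0.01)
  bad <- ch; bad$kind <- "percent"
  expect_error(summarize_changes(bad), "absolute")
})

test_that("the wide layout pivots treatments into columns", {
  ch <- rbind(make_changes(1:3, 0.1, c(-15, -20, -25), treatment = "PB"),
              make_changes(1:3, 0.1, c(-1, -2, -3), treatment = "MD0.2"))
  w <- table1_layout(summarize_changes(ch))
  expect_setequal(names(w), c("parameter", "loc", "PB", "MD0.2"))
  expect_match(w$PB, "-20 ± 5", fixed = TRUE)
})

test_that("DOC pairs where carbon increases are excluded, with a log", {
  pairs <- data.frame(sample_id = c("a", "b", "c"),
                      doc_t0 = c(8.0, 8.0, 6.5), doc_t24 = c(8.5, 7.0, 6.5))
  out <- exclude_doc_anomalies(pairs)
  expect_equal(out$retained$sample_id, c("b", "c"))
  expect_equal(out$excluded$sample_id, "a")
  expect_match(out$log, "excluded a")
  # all increasing: empty result, full log
  inc <- data.frame(sample_id = c("x", "y"), doc_t0 = c(5, 6), doc_t24 = c(5.5, 6.2))
  out2 <- exclude_doc_anomalies(inc)
  expect_equal(nrow(out2$retained), 0L)
  expect_length(out2$log, 2L)
  # a tolerance admits small analytical noise
  out3 <- exclude_doc_anomalies(pairs, tolerance = 0.1)
  expect_equal(nrow(out3$retained), 3L)
})

test_that("campaign summaries reproduce configured group means within the spread", {
  cfg <- test_campaign(seed = 23, treatments = "PB", n_rep = 2,
                       timepoints_days = list(PB = c(0, 24)))
  camp <- simulate_campaign(cfg)
  docx <- exclude_doc_anomalies(camp$doc)
  ch <- fluordom:::doc_changes(docx$retained)
  s <- summarize_changes(ch)
  riv <- s[s$loc == "river", ]
  # generator draws PB DOC losses around -20% with 5% station spread
  expect_lt(abs(riv$mean - (-20)), 2 * 5)
  expect_true(all(s$units == "%"))
})
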