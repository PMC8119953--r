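## Component fluorescence metrics: Fmax, percent contribution,
## percent change, Grubbs outlier filtering.

#' Component fluorescence maxima (Fmax)
#'
#' The fluorescence maximum of a component in a sample is its score times
#' the peak value of each unit-norm spectral loading:
#' Fmax(sample, f) = score * max(em_loading_f) * max(ex_loading_f), in
#' Raman units. It is the component's concentration proxy.
#'
#' @param model a fitted [parafac()] model.
#' @return data.frame with `sample_id`, one `Fmax` column per component, and
#'   the manifest metadata joined.
#' @export
fmax <- function(model) {
  stopifnot(inherits(model, "parafac"))
  peak <- apply(model$em_loadings, 2L, max) * apply(model$ex_loadings, 2L, max)
  Fm <- sweep(model$scores, 2L, peak, "*")
  out <- data.frame(sample_id = rownames(model$scores), Fm,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(model$manifest))
    out <- merge(out, model$manifest, by = "sample_id", sort = FALSE)
  out
}

#' Percent contribution of each component to total fluorescence
#'
#' Ci% = 100 * Fmax_i / sum_f(Fmax_f) for one sample; the contributions sum
#' to 100.
#'
#' @param fmax_row nonnegative numeric vector of per-component Fmax values
#'   (one sample), with at least one positive entry.
#' @return Percent vector of the same length, summing to 100.
#' @export
percent_contribution <- function(fmax_row) {
  fmax_row <- as.numeric(fmax_row)
  tot <- sum(fmax_row)
  if (tot <= 0) stop("all component maxima are zero; contribution undefined", call. = FALSE)
  100 * fmax_row / tot
}

#' Percent change of a quantity relative to its day-0 baseline
#'
#' Delta = 100 * (C_t - C_0) / C_0, a pure ratio independent of the units of
#' C; used for both absorption coefficients and component maxima.
#'
#' @param c0 baseline value(s) at day 0; must be positive.
#' @param ct value(s) at time t.
#' @return Percent change(s).
#' @export
percent_change <- function(c0, ct) {
  if (any(c0 <= 0)) stop("baseline value must be positive", call. = FALSE)
  100 * (ct - c0) / c0
}

grubbs_critical <- function(n, alpha) {
  tq <- stats::qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

#' Iterative two-sided Grubbs outlier filter
#'
#' Applies Grubbs' test for a single outlier repeatedly, removing the most
#' extreme value whenever its test statistic G = max|x - mean| / sd exceeds
#' the two-sided critical value at level `alpha`, until no value is
#' rejected. Intended for populations of percent changes that are
#' approximately normal.
#'
#' @param x numeric vector (n >= 3; shorter vectors pass through with a
#'   warning).
#' @param alpha significance level per iteration (default 0.05).
#' @return list with `retained`, `removed`, and `tests` (data.frame of each
#'   iteration's value, G statistic and critical value).
#' @export
grubbs_filter <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  tests <- data.frame(value = numeric(), G = numeric(), critical = numeric(),
                      removed = logical())
  if (length(x) < 3L) {
    warning("fewer than 3 values; Grubbs filter passes data through")
    return(list(retained = x, removed = numeric(), tests = tests))
  }
  removed <- numeric()
  repeat {
    n <- length(x)
    if (n < 3L) break
    s <- stats::sd(x)
    if (s == 0) break   # zero-variance guard: identical values, nothing to test
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    G <- dev[i] / s
    crit <- grubbs_critical(n, alpha)
    rej <- G > crit
    tests <- rbind(tests, data.frame(value = x[i], G = G, critical = crit, removed = rej))
    if (!rej) break
    removed <- c(removed, x[i])
    x <- x[-i]
  }
  list(retained = x, removed = removed, tests = tests)
}

#' Component contributions ordered by salinity
#'
#' Computes per-sample percent contributions from an Fmax table and returns
#' them sorted by ascending salinity, as used to display the evolution of
#' the fluorescent DOM pool along a river-to-ocean gradient.
#'
#' @param fmax_table a [fmax()] result (must carry `salinity_psu`).
#' @param components component column names; default all `C*` columns.
#' @return data.frame sorted by ascending salinity; contribution columns
#'   (percent) sum to 100 in every row.
#' @export
contribution_by_salinity <- function(fmax_table, components = NULL) {
  if (is.null(fmax_table$salinity_psu) || all(is.na(fmax_table$salinity_psu)))
    stop("salinity_psu missing from the Fmax table", call. = FALSE)
  if (is.null(components))
    components <- grep("^C[0-9]+$", names(fmax_table), value = TRUE)
  contrib <- t(apply(fmax_table[, components, drop = FALSE], 1L, percent_contribution))
  colnames(contrib) <- components
  out <- cbind(fmax_table[, setdiff(names(fmax_table), components), drop = FALSE], contrib)
  out[order(out$salinity_psu), , drop = FALSE]
}

#' Percent changes of component maxima across incubation timepoints
#'
#' Joins an Fmax table with its manifest, computes per-bottle percent change
#' of every component at each timepoint relative to that bottle's day-0
#' value, and (optionally) Grubbs-filters each component x treatment x
#' timepoint change population.
#'
#' @param fmax_table a [fmax()] result carrying `station`, `treatment`,
#'   `timepoint_days`, `replicate`.
#' @param components component columns; default all `C*` columns.
#' @param grubbs logical; apply [grubbs_filter()] per component x treatment
#'   x timepoint (default TRUE).
#' @param alpha Grubbs level.
#' @return data.frame of change records: `station`, `salinity_psu`,
#'   `treatment`, `replicate`, `parameter`, `timepoint_days`, `delta`
#'   (percent), `retained` (logical, FALSE when Grubbs-removed).
#' @export
component_changes <- function(fmax_table, components = NULL, grubbs = TRUE, alpha = 0.05) {
  if (is.null(components))
    components <- grep("^C[0-9]+$", names(fmax_table), value = TRUE)
  need <- c("station", "treatment", "timepoint_days", "replicate")
  if (!all(need %in% names(fmax_table)))
    stop("Fmax table must carry station/treatment/timepoint_days/replicate", call. = FALSE)
  rows <- list()
  key <- interaction(fmax_table$station, fmax_table$treatment, fmax_table$replicate, drop = TRUE)
  for (g in split(fmax_table, key)) {
    base <- g[g$timepoint_days == 0, , drop = FALSE]
    if (nrow(base) != 1L) next
    for (comp in components) {
      c0 <- base[[comp]]
      if (c0 <= 0) next
      later <- g[g$timepoint_days > 0, , drop = FALSE]
      if (!nrow(later)) next
      rows[[length(rows) + 1L]] <- data.frame(
        station = later$station, salinity_psu = later$salinity_psu %||% NA_real_,
        treatment = later$treatment, replicate = later$replicate,
        parameter = comp, timepoint_days = later$timepoint_days,
        delta = percent_change(c0, later[[comp]]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(station = integer(), salinity_psu = numeric(), treatment = character(),
                      replicate = integer(), parameter = character(),
                      timepoint_days = numeric(), delta = numeric(), retained = logical()))
  out <- do.call(rbind, rows)
  out$retained <- TRUE
  if (grubbs) {
    key2 <- interaction(out$parameter, out$treatment, out$timepoint_days, drop = TRUE)
    for (lev in levels(key2)) {
      idx <- which(key2 == lev)
      if (length(idx) < 3L) next
      gf <- grubbs_filter(out$delta[idx], alpha = alpha)
      if (length(gf$removed))
        out$retained[idx][out$delta[idx] %in% gf$removed] <- FALSE
    }
  }
  rownames(out) <- NULL
  out
}
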