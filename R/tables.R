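## Station classification and campaign summary tables.

#' Default river/plume/ocean salinity rules
#'
#' Half-open salinity intervals `[lo, hi)` in psu: river below 1, plume
#' 1--30, ocean 30 and above. Boundaries are configurable; classes must be
#' disjoint and exhaustive.
#'
#' @return named list of length-2 numeric intervals.
#' @export
station_class_rules <- function() {
  list(river = c(-Inf, 1), plume = c(1, 30), ocean = c(30, Inf))
}

#' Classify a station by salinity
#'
#' @param salinity salinity in psu (nonnegative); vectorised.
#' @param rules named list of `[lo, hi)` intervals, see
#'   [station_class_rules()].
#' @return character vector of class labels.
#' @export
classify_station <- function(salinity, rules = station_class_rules()) {
  if (any(salinity < 0)) stop("salinity must be nonnegative", call. = FALSE)
  out <- rep(NA_character_, length(salinity))
  for (lab in names(rules)) {
    iv <- rules[[lab]]
    out[salinity >= iv[1] & salinity < iv[2]] <- lab
  }
  if (anyNA(out)) stop("salinity rules are not exhaustive", call. = FALSE)
  out
}

#' Summarize day-0-to-final changes per parameter, class and treatment
#'
#' Builds the campaign summary in the layout of an incubation change table:
#' mean and standard deviation of the change in each parameter for each
#' station class x treatment. For river and plume classes the spread is
#' computed between stations (replicate bottles are first averaged within
#' station); for the ocean class (typically a single station) it is
#' computed between replicate bottles. Percent-change parameters are
#' reported in percent; spectral-slope parameters must be supplied as
#' absolute changes in 1/nm (`kind = "absolute_per_nm"`) and are audited:
#' a slope parameter tagged as percent is an error.
#'
#' @param changes data.frame with columns `station`, `salinity_psu`,
#'   `treatment`, `replicate`, `parameter`, `timepoint_days`, `delta`,
#'   optional `retained` (Grubbs flag) and `kind` (`"percent"` default, or
#'   `"absolute_per_nm"`).
#' @param rules salinity class rules; see [classify_station()].
#' @param timepoint the final timepoint summarised (default day 24).
#' @param replicate_sd_classes classes whose spread is computed between
#'   replicates rather than stations (default `"ocean"`).
#' @return data.frame with `parameter`, `loc`, `treatment`, `mean`, `sd`,
#'   `n`, `basis`, `units`. `sd` is `NA` when `n = 1`. Empty cells are
#'   omitted.
#' @export
summarize_changes <- function(changes, rules = station_class_rules(), timepoint = 24,
                              replicate_sd_classes = "ocean") {
  need <- c("station", "salinity_psu", "treatment", "replicate", "parameter",
            "timepoint_days", "delta")
  if (!all(need %in% names(changes)))
    stop("changes table is missing required columns", call. = FALSE)
  if (is.null(changes$kind)) changes$kind <- "percent"
  if (any(grepl("^S[0-9]", changes$parameter) & changes$kind == "percent"))
    stop("spectral slope changes must be absolute (1/nm), not percent", call. = FALSE)
  x <- changes[changes$timepoint_days == timepoint, , drop = FALSE]
  if (!is.null(x$retained)) x <- x[x$retained, , drop = FALSE]
  if (!nrow(x)) return(data.frame())
  x$loc <- classify_station(x$salinity_psu, rules)
  rows <- list()
  for (g in split(x, interaction(x$parameter, x$loc, x$treatment, drop = TRUE))) {
    if (!nrow(g)) next
    loc <- g$loc[1]
    if (loc %in% replicate_sd_classes) {
      vals <- g$delta
      basis <- "between_replicates"
    } else {
      vals <- tapply(g$delta, g$station, mean)  # bottle means within station
      basis <- "between_stations"
    }
    n <- length(vals)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = g$parameter[1], loc = loc, treatment = g$treatment[1],
      mean = mean(vals), sd = if (n > 1) stats::sd(vals) else NA_real_,
      n = n, basis = basis,
      units = if (g$kind[1] == "percent") "%" else "1/nm",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$parameter, out$loc, out$treatment), , drop = FALSE]
}

#' Pivot a change summary into the wide campaign-table layout
#'
#' One row per parameter x location, one "mean +/- sd" column per treatment.
#'
#' @param summary a [summarize_changes()] result.
#' @param digits digits for formatting.
#' @return data.frame with columns `parameter`, `loc`, then one column per
#'   treatment.
#' @export
table1_layout <- function(summary, digits = 3) {
  if (!nrow(summary)) return(data.frame())
  g <- function(x) sprintf("%.*g", digits, x)
  fmt <- function(m, s) ifelse(is.na(s), g(m), paste0(g(m), " ± ", g(s)))
  summary$cell <- fmt(summary$mean, summary$sd)
  wide <- stats::reshape(summary[, c("parameter", "loc", "treatment", "cell")],
                         idvar = c("parameter", "loc"), timevar = "treatment",
                         direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Exclude implausible DOC pairs
#'
#' Incubations cannot create dissolved organic carbon; paired observations
#' where the final DOC exceeds the initial value indicate contamination or
#' analytical error and are excluded (strict inequality, optionally with a
#' tolerance for noisy synthetic data).
#'
#' @param doc_pairs data.frame with columns `doc_t0` and `doc_t24` (plus any
#'   key columns, carried through).
#' @param tolerance allow `doc_t24 <= doc_t0 * (1 + tolerance)` (default 0,
#'   the strict rule).
#' @return list with `retained` (data.frame), `excluded` (data.frame) and
#'   `log` (character descriptions of exclusions).
#' @export
exclude_doc_anomalies <- function(doc_pairs, tolerance = 0) {
  stopifnot(all(c("doc_t0", "doc_t24") %in% names(doc_pairs)))
  bad <- doc_pairs$doc_t24 > doc_pairs$doc_t0 * (1 + tolerance)
  log <- character()
  if (any(bad)) {
    ids <- if (!is.null(doc_pairs$sample_id)) doc_pairs$sample_id[bad]
    else if (all(c("station", "treatment") %in% names(doc_pairs)))
      paste0("st", doc_pairs$station[bad], "_", doc_pairs$treatment[bad],
             "_r", doc_pairs$replicate[bad] %||% "")
    else which(bad)
    log <- sprintf("excluded %s: DOC(t24) %.4g > DOC(t0) %.4g", ids,
                   doc_pairs$doc_t24[bad], doc_pairs$doc_t0[bad])
  }
  list(retained = doc_pairs[!bad, , drop = FALSE],
       excluded = doc_pairs[bad, , drop = FALSE],
       log = log)
}
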