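## Plain-text interchange: EEM wide CSV, absorbance CSV, manifest CSV,
## loading export and model reports.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write an EEM to wide CSV
#'
#' Dialect: header row `emission_nm` then the excitation wavelengths;
#' one row per emission wavelength; `NA` for masked cells; `.` decimal
#' separator. The round trip through [read_eem_csv()] is lossless.
#'
#' @param x an `eem`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eem_csv <- function(x, path) {
  stopifnot(inherits(x, "eem"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("emission_nm", fmt_num(x$ex)), collapse = ","), con)
  for (j in seq_along(x$em)) {
    row <- x$intensity[j, ]
    cells <- ifelse(is.na(row), "NA", fmt_num(row))
    writeLines(paste(c(fmt_num(x$em[j]), cells), collapse = ","), con)
  }
  invisible(path)
}

parse_num_strict <- function(s, where) {
  s[s == "NA"] <- NA
  out <- suppressWarnings(as.numeric(s))
  bad <- is.na(out) & !is.na(s)
  if (any(bad)) {
    offender <- s[bad][1]
    hint <- if (grepl(",", offender)) " (comma decimal separators are not accepted; use '.')" else ""
    stop(sprintf("non-numeric value '%s' in %s%s", offender, where, hint), call. = FALSE)
  }
  out
}

#' Read an EEM from wide CSV
#'
#' Strictly parses the dialect written by [write_eem_csv()]: malformed
#' headers, non-monotone grids and locale comma decimals are rejected with
#' a message naming the offending line.
#'
#' @param path input path.
#' @param state,meta passed to [eem()].
#' @return An `eem`.
#' @export
read_eem_csv <- function(path, state = character(), meta = list()) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty EEM file", call. = FALSE)
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (hdr[1] != "emission_nm")
    stop(sprintf("line 1: header must start with 'emission_nm', found '%s'", hdr[1]),
         call. = FALSE)
  ex <- parse_num_strict(hdr[-1], "line 1 (excitation header)")
  if (anyNA(ex) || length(ex) < 2 || any(diff(ex) <= 0))
    stop("line 1: excitation grid must be strictly increasing", call. = FALSE)
  body <- lapply(seq_along(lines[-1]), function(i) {
    cells <- strsplit(lines[i + 1], ",", fixed = TRUE)[[1]]
    if (length(cells) != length(ex) + 1L)
      stop(sprintf("line %d: expected %d cells, found %d", i + 1, length(ex) + 1, length(cells)),
           call. = FALSE)
    parse_num_strict(cells, sprintf("line %d", i + 1))
  })
  M <- do.call(rbind, body)
  em <- M[, 1]
  if (anyNA(em) || any(diff(em) <= 0))
    stop("emission grid (first column) must be strictly increasing", call. = FALSE)
  eem(ex, em, M[, -1, drop = FALSE], state = state, meta = meta)
}

#' Write / read absorbance spectra as long CSV
#'
#' Columns `sample_id`, `wavelength_nm`, `absorbance`; several samples may
#' share one file. Pathlength travels in the manifest, not the CSV.
#'
#' @param spectra named list of `absorbance_spectrum` objects.
#' @param path file path.
#' @return `path` invisibly (write); named list of spectra (read).
#' @export
write_absorbance_csv <- function(spectra, path) {
  rows <- do.call(rbind, lapply(names(spectra), function(id) {
    s <- spectra[[id]]
    data.frame(sample_id = id, wavelength_nm = s$wavelengths,
               absorbance = s$absorbance, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_absorbance_csv
#' @param pathlength pathlength (m) assigned to every spectrum on read.
#' @export
read_absorbance_csv <- function(path, pathlength = 0.05) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "wavelength_nm", "absorbance") %in% names(d)))
    stop("absorbance CSV must have columns sample_id, wavelength_nm, absorbance", call. = FALSE)
  out <- lapply(split(d, d$sample_id), function(g) {
    g <- g[order(g$wavelength_nm), ]
    absorbance_spectrum(g$wavelength_nm, g$absorbance, pathlength = pathlength)
  })
  out
}

#' Export PARAFAC spectral loadings
#'
#' Writes a CSV in the layout used for spectral-database submission: one
#' block of excitation rows and one of emission rows, columns `mode`,
#' `wavelength_nm`, then one column per component.
#'
#' @param model a fitted [parafac()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_loadings <- function(model, path) {
  stopifnot(inherits(model, "parafac"))
  exb <- data.frame(mode = "ex", wavelength_nm = model$ex, model$ex_loadings)
  emb <- data.frame(mode = "em", wavelength_nm = model$em, model$em_loadings)
  utils::write.csv(rbind(exb, emb), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a PARAFAC diagnostics report
#'
#' JSON report of fit statistics, component peaks, and (optionally)
#' split-half validation and outlier screening results.
#'
#' @param model a fitted [parafac()] model.
#' @param path output path.
#' @param validation optional [split_half_validate()] result.
#' @param outliers optional [detect_outliers()] result.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(model, path, validation = NULL, outliers = NULL) {
  stopifnot(inherits(model, "parafac"))
  rep_ <- list(
    n_components = model$ncomp,
    n_samples = nrow(model$scores),
    explained_variance_pct = model$explained_variance,
    converged = model$converged,
    n_iterations = model$n_iterations,
    start_seed = model$start_seed,
    component_peaks = data.frame(
      component = colnames(model$scores),
      peak_ex_nm = apply(model$ex_loadings, 2L, function(v) model$ex[which.max(v)]),
      peak_em_nm = apply(model$em_loadings, 2L, function(v) model$em[which.max(v)])))
  if (!is.null(validation))
    rep_$validation <- list(scheme = validation$scheme,
                            min_congruence = validation$min_congruence,
                            threshold = validation$threshold,
                            validated = validation$validated)
  if (!is.null(outliers))
    rep_$outliers <- list(criterion = outliers$criterion, flagged = outliers$flagged)
  jsonlite::write_json(rep_, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
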