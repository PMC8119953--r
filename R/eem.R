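## Excitation-emission matrices: container and correction chain.
## Correction order is enforced: blank -> inner-filter -> Raman -> scatter.

.eem_steps <- c("blank_subtracted", "ife_corrected", "raman_normalized", "scatter_masked")

#' Construct an excitation-emission matrix (EEM)
#'
#' Fluorescence intensity over an excitation x emission wavelength grid.
#' Intensities are stored with emission along rows and excitation along
#' columns (the same orientation as the wide CSV interchange format).
#'
#' @param ex excitation wavelengths (nm), strictly increasing
#'   (instrument default 240--650 nm at 5-nm steps).
#' @param em emission wavelengths (nm), strictly increasing.
#' @param intensity numeric matrix, `length(em)` rows x `length(ex)` columns.
#'   `NA` marks masked cells.
#' @param state character vector of correction steps already applied, in
#'   order; subset of `blank_subtracted`, `ife_corrected`,
#'   `raman_normalized`, `scatter_masked`.
#' @param meta named list of sample metadata (sample_id, station,
#'   salinity_psu, treatment, timepoint_days, replicate, ...).
#' @return An object of class `"eem"`.
#' @export
eem <- function(ex, em, intensity, state = character(), meta = list()) {
  stop_if_not_increasing(ex, "ex")
  stop_if_not_increasing(em, "em")
  intensity <- as.matrix(intensity)
  if (!all(dim(intensity) == c(length(em), length(ex))))
    stop("intensity must be length(em) x length(ex)", call. = FALSE)
  if (!all(state %in% .eem_steps)) stop("unknown state step", call. = FALSE)
  if (anyDuplicated(state)) stop("state steps may be applied at most once", call. = FALSE)
  structure(list(ex = as.numeric(ex), em = as.numeric(em),
                 intensity = intensity, state = state, meta = meta),
            class = "eem")
}

#' @export
print.eem <- function(x, ...) {
  st <- if (length(x$state)) paste(x$state, collapse = " > ") else "raw"
  id <- if (!is.null(x$meta$sample_id)) paste0(" '", x$meta$sample_id, "'") else ""
  cat(sprintf("<eem>%s %d em x %d ex (em %g-%g, ex %g-%g nm) [%s]\n", id,
              length(x$em), length(x$ex), min(x$em), max(x$em),
              min(x$ex), max(x$ex), st))
  invisible(x)
}

#' @export
plot.eem <- function(x, n_levels = 30, ...) {
  z <- t(x$intensity)  # image() wants x = rows
  graphics::image(x$ex, x$em, z, col = grDevices::hcl.colors(n_levels, "YlGnBu", rev = TRUE),
                  xlab = "excitation (nm)", ylab = "emission (nm)", ...)
  invisible(x)
}

# state machine: each step requires its predecessors and must be new
check_step <- function(x, step) {
  need <- .eem_steps[seq_len(match(step, .eem_steps) - 1L)]
  if (step %in% x$state)
    stop(sprintf("step '%s' already applied", step), call. = FALSE)
  missing <- setdiff(need, x$state)
  if (length(missing))
    stop(sprintf("step '%s' requires prior step(s): %s", step,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

same_grids <- function(a, b) {
  isTRUE(all.equal(a$ex, b$ex)) && isTRUE(all.equal(a$em, b$em))
}

#' Subtract a blank-water EEM from a sample EEM
#'
#' Element-wise subtraction of a pure-water blank run on the same day.
#' Negative residual intensities are retained (they carry noise information
#' and are handled later by the non-negativity of the PARAFAC model).
#'
#' @param sample,blank `eem` objects on identical grids.
#' @return The corrected `eem`, with `blank_subtracted` appended to its state.
#' @export
subtract_blank <- function(sample, blank) {
  stopifnot(inherits(sample, "eem"), inherits(blank, "eem"))
  check_step(sample, "blank_subtracted")
  if (!same_grids(sample, blank)) stop("sample and blank grids differ", call. = FALSE)
  sample$intensity <- sample$intensity - blank$intensity
  sample$state <- c(sample$state, "blank_subtracted")
  sample
}

#' Inner-filter effect correction (absorbance-based)
#'
#' Corrects for attenuation of excitation and emission light by the sample's
#' own absorbance using the absorbance-based (ABA) method for a 1-cm
#' fluorescence cell: F_corr(ex, em) = F_obs * 10^((A(ex) + A(em)) / 2),
#' where A is decadal absorbance per cm at the respective wavelengths.
#' Pairs with total absorbance A(ex) + A(em) > `flag_above` are unreliable
#' for this correction; if any occur a warning is raised and the offending
#' fraction recorded in attribute `ife_flagged_fraction`.
#'
#' @param sample an `eem`, blank-subtracted.
#' @param abs_spec an [absorbance_spectrum()] covering all excitation and
#'   emission wavelengths (its absorbance is rescaled to a 1-cm path).
#' @param flag_above total-absorbance threshold for the reliability flag.
#' @return The corrected `eem` with `ife_corrected` appended.
#' @export
inner_filter_correct <- function(sample, abs_spec, flag_above = 1.5) {
  stopifnot(inherits(sample, "eem"), inherits(abs_spec, "absorbance_spectrum"))
  check_step(sample, "ife_corrected")
  wl <- abs_spec$wavelengths
  if (min(sample$ex) < min(wl) || max(sample$em) > max(wl))
    stop("absorbance spectrum does not cover the EEM wavelengths", call. = FALSE)
  A_per_cm <- abs_spec$absorbance / (abs_spec$pathlength * 100)
  A_ex <- interp_onto(wl, A_per_cm, sample$ex)
  A_em <- interp_onto(wl, A_per_cm, sample$em)
  total <- outer(A_em, A_ex, "+")           # em x ex
  frac <- mean(total > flag_above)
  if (frac > 0)
    warning(sprintf("inner-filter correction unreliable for %.1f%% of cells (total absorbance > %.2g)",
                    100 * frac, flag_above))
  sample$intensity <- sample$intensity * 10^(total / 2)
  sample$state <- c(sample$state, "ife_corrected")
  attr(sample, "ife_flagged_fraction") <- frac
  sample
}

#' Integrate the water Raman peak of a blank EEM
#'
#' Trapezoidal integral of the blank's emission scan at the Raman excitation
#' line (default 350 nm) over the Raman emission band (default 371--428 nm).
#' The resulting area is the Raman-unit calibration factor for that run day.
#'
#' @param blank a blank-water `eem`.
#' @param ex_line excitation wavelength of the Raman scan (nm).
#' @param em_range numeric length-2 emission integration window (nm).
#' @param date optional run-day label.
#' @return An object of class `"raman_reference"` with the integrated
#'   `raman_area` (intensity units x nm).
#' @export
compute_raman_area <- function(blank, ex_line = 350, em_range = c(371, 428), date = NA_character_) {
  stopifnot(inherits(blank, "eem"))
  if (ex_line < min(blank$ex) || ex_line > max(blank$ex))
    stop("ex_line outside the blank's excitation grid", call. = FALSE)
  if (em_range[1] < min(blank$em) || em_range[2] > max(blank$em))
    stop("em_range outside the blank's emission grid", call. = FALSE)
  # emission scan at the Raman line (interpolate between ex columns if needed)
  scan <- apply(blank$intensity, 1L, function(row) interp_onto(blank$ex, row, ex_line))
  idx <- blank$em >= em_range[1] & blank$em <= em_range[2]
  em <- blank$em[idx]; y <- scan[idx]
  if (length(em) < 2L) stop("integration window covers fewer than 2 emission points", call. = FALSE)
  area <- sum(diff(em) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  if (!is.finite(area) || area <= 0)
    stop("Raman peak area is not positive; blank unusable", call. = FALSE)
  structure(list(date = date, raman_area = area, integration_em_range = em_range,
                 ex_line = ex_line), class = "raman_reference")
}

#' @export
print.raman_reference <- function(x, ...) {
  cat(sprintf("<raman_reference> area %.5g (ex %g nm, em %g-%g nm)\n",
              x$raman_area, x$ex_line, x$integration_em_range[1], x$integration_em_range[2]))
  invisible(x)
}

#' Normalize an EEM to Raman units
#'
#' Divides intensity by the integrated water Raman peak area of the same-day
#' blank, converting arbitrary instrument units to Raman units (R.U.).
#' Because sample and blank share the instrument gain, the gain cancels.
#'
#' @param sample an `eem`, inner-filter corrected.
#' @param ref a [compute_raman_area()] reference from the same run day.
#' @return The normalized `eem` with `raman_normalized` appended.
#' @export
raman_normalize <- function(sample, ref) {
  stopifnot(inherits(sample, "eem"), inherits(ref, "raman_reference"))
  check_step(sample, "raman_normalized")
  if (ref$raman_area <= 0) stop("raman_area must be positive", call. = FALSE)
  sample$intensity <- sample$intensity / ref$raman_area
  sample$state <- c(sample$state, "raman_normalized")
  sample
}

#' Mask Rayleigh and Raman scatter bands
#'
#' Sets to `NA` the cells within configured half-widths of the first- and
#' second-order Rayleigh lines (em = ex, em = 2 ex) and first- and
#' second-order water Raman lines (the 3382 1/cm Stokes shift of the
#' excitation line and its second order). Optionally zeroes the physically
#' signal-free region below the Rayleigh diagonal (em <= ex + `below_cut`),
#' which anchors the PARAFAC model without inventing data inside the bands.
#'
#' @param sample an `eem`, Raman-normalized.
#' @param widths named numeric vector of half-widths in nm:
#'   `rayleigh1`, `raman1`, `rayleigh2`, `raman2`.
#' @param zero_below logical; zero the region em <= ex + `below_cut`.
#' @param below_cut nm offset for the below-diagonal zeroing (default 5).
#' @return The masked `eem` with `scatter_masked` appended and attribute
#'   `mask_fraction` (fraction of cells set to `NA`).
#' @export
mask_scatter <- function(sample,
                         widths = c(rayleigh1 = 10, raman1 = 5, rayleigh2 = 10, raman2 = 10),
                         zero_below = TRUE, below_cut = 5) {
  stopifnot(inherits(sample, "eem"))
  check_step(sample, "scatter_masked")
  if (any(widths < 0)) stop("scatter half-widths must be nonnegative", call. = FALSE)
  w <- c(rayleigh1 = 0, raman1 = 0, rayleigh2 = 0, raman2 = 0)
  w[names(widths)] <- widths
  ex <- sample$ex; em <- sample$em
  # Raman emission line for excitation lambda: 1/em = 1/ex - 3382e-7 (nm^-1)
  raman_line <- 1 / (1 / ex - 3382e-7)
  EM <- matrix(em, length(em), length(ex))
  centers <- list(rayleigh1 = matrix(ex, length(em), length(ex), byrow = TRUE),
                  raman1 = matrix(raman_line, length(em), length(ex), byrow = TRUE),
                  rayleigh2 = matrix(2 * ex, length(em), length(ex), byrow = TRUE),
                  raman2 = matrix(2 * raman_line, length(em), length(ex), byrow = TRUE))
  mask <- matrix(FALSE, length(em), length(ex))
  for (band in names(centers))
    if (w[[band]] > 0) mask <- mask | abs(EM - centers[[band]]) <= w[[band]]
  sample$intensity[mask] <- NA_real_
  if (zero_below) {
    below <- EM <= centers$rayleigh1 + below_cut
    sample$intensity[below & !mask] <- 0
  }
  sample$state <- c(sample$state, "scatter_masked")
  attr(sample, "mask_fraction") <- mean(mask)
  sample
}

#' Assemble corrected EEMs into a dataset tensor
#'
#' Stacks fully corrected samples (identical grids and identical correction
#' states) into a sample x emission x excitation array with a shared
#' missing-cell mask, plus a manifest of per-sample metadata. This is the
#' input object for [parafac()].
#'
#' @param samples list of `eem` objects.
#' @param require_state character vector of steps every sample must have
#'   (default: all four corrections).
#' @return An object of class `"eem_dataset"`: list with `tensor`
#'   (n x em x ex, `NA` = masked), `ex`, `em`, `mask` (em x ex logical,
#'   TRUE = masked), `manifest` (data.frame).
#' @export
assemble_dataset <- function(samples, require_state = .eem_steps) {
  if (!length(samples)) stop("no samples", call. = FALSE)
  ref <- samples[[1L]]
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (!inherits(s, "eem")) stop("all elements must be eem objects", call. = FALSE)
    if (!same_grids(s, ref)) stop(sprintf("sample %d grid differs from sample 1", i), call. = FALSE)
    missing <- setdiff(require_state, s$state)
    if (length(missing))
      stop(sprintf("sample %d is missing processing step(s): %s", i,
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  n <- length(samples)
  tens <- array(NA_real_, c(n, length(ref$em), length(ref$ex)))
  for (i in seq_len(n)) tens[i, , ] <- samples[[i]]$intensity
  # shared mask: a cell is masked when missing in any sample
  mask <- apply(tens, c(2, 3), function(v) any(is.na(v)))
  for (i in seq_len(n)) { m <- tens[i, , ]; m[mask] <- NA_real_; tens[i, , ] <- m }
  meta_rows <- lapply(seq_len(n), function(i) {
    m <- samples[[i]]$meta
    base <- list(sample_id = if (is.null(m$sample_id)) paste0("S", i) else m$sample_id,
                 station = m$station %||% NA, salinity_psu = m$salinity_psu %||% NA_real_,
                 treatment = m$treatment %||% NA_character_,
                 timepoint_days = m$timepoint_days %||% NA_real_,
                 replicate = m$replicate %||% NA)
    as.data.frame(base, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, meta_rows)
  structure(list(tensor = tens, ex = ref$ex, em = ref$em, mask = mask,
                 manifest = manifest, state = ref$state),
            class = "eem_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eem_dataset <- function(x, ...) {
  cat(sprintf("<eem_dataset> %d samples, %d em x %d ex, %.1f%% cells masked\n",
              dim(x$tensor)[1], length(x$em), length(x$ex), 100 * mean(x$mask)))
  invisible(x)
}

#' Subset an EEM dataset by sample
#'
#' @param ds an `eem_dataset`.
#' @param idx integer or logical sample index.
#' @return The subsetted `eem_dataset`.
#' @export
subset_dataset <- function(ds, idx) {
  stopifnot(inherits(ds, "eem_dataset"))
  ds$tensor <- ds$tensor[idx, , , drop = FALSE]
  ds$manifest <- ds$manifest[idx, , drop = FALSE]
  rownames(ds$manifest) <- NULL
  ds
}
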