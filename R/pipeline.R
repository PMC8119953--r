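## End-to-end orchestration: simulate or ingest -> preprocess -> PARAFAC ->
## metrics -> kinetics -> summary tables, with reproducible per-stage seeds
## and a checksummed run manifest.

#' Configure a pipeline run
#'
#' Schema-checked configuration for [run_pipeline()]. One global `seed` is
#' split hierarchically into independent per-stage seeds (generator, PARAFAC
#' starts, kinetics), so stages are individually reproducible.
#'
#' @param input `"synthetic"` (generate a campaign) or `"files"` (read EEM,
#'   absorbance and manifest CSVs).
#' @param campaign a [campaign_config()] (synthetic mode); its seed is
#'   overridden by the pipeline's generator stage seed.
#' @param raw synthetic mode: generate raw instrument-like EEMs and run the
#'   full correction chain (default TRUE); `FALSE` generates analysis-ready
#'   EEMs and skips preprocessing.
#' @param paths files mode: named list with `manifest`, `eem_dir`,
#'   `absorbance`, `blank`, and optionally `pathlength`.
#' @param raman list: `ex_line` (nm) and `em_range` (nm, length 2) for the
#'   Raman-unit calibration.
#' @param scatter list passed to [mask_scatter()]: `widths`, `zero_below`,
#'   `below_cut`.
#' @param parafac list: `candidates` (component counts; a single value fits
#'   directly, several triggers [select_n_components()]), `n_starts`, `tol`,
#'   `max_iter`, `threshold`.
#' @param kinetics list: `lambda` (absorption wavelength for decay series,
#'   nm) and `alpha` (F-test level).
#' @param grouping salinity class rules, see [station_class_rules()].
#' @param seed global integer seed.
#' @param output_dir directory for all artifacts (created if needed).
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = c("synthetic", "files"),
                            campaign = campaign_config(),
                            raw = TRUE,
                            paths = list(),
                            raman = list(ex_line = 350, em_range = c(371, 428)),
                            scatter = list(widths = c(rayleigh1 = 10, raman1 = 5,
                                                      rayleigh2 = 10, raman2 = 10),
                                           zero_below = TRUE, below_cut = 5),
                            parafac = list(candidates = 6, n_starts = 10, tol = 1e-8,
                                           max_iter = 2500, threshold = 0.95),
                            kinetics = list(lambda = 300, alpha = 0.01),
                            grouping = station_class_rules(),
                            seed = 1L,
                            output_dir = tempfile("fluordom_run_")) {
  input <- match.arg(input)
  chk_names <- function(x, allowed, what) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop(sprintf("unknown %s option(s): %s", what, paste(extra, collapse = ", ")),
           call. = FALSE)
  }
  chk_names(raman, c("ex_line", "em_range"), "raman")
  chk_names(scatter, c("widths", "zero_below", "below_cut"), "scatter")
  chk_names(parafac, c("candidates", "n_starts", "tol", "max_iter", "threshold"), "parafac")
  chk_names(kinetics, c("lambda", "alpha"), "kinetics")
  if (input == "files") chk_names(paths, c("manifest", "eem_dir", "absorbance", "blank",
                                           "pathlength"), "paths")
  defaults <- list(parafac = list(candidates = 6, n_starts = 10, tol = 1e-8,
                                  max_iter = 2500, threshold = 0.95),
                   kinetics = list(lambda = 300, alpha = 0.01),
                   raman = list(ex_line = 350, em_range = c(371, 428)),
                   scatter = list(widths = c(rayleigh1 = 10, raman1 = 5,
                                             rayleigh2 = 10, raman2 = 10),
                                  zero_below = TRUE, below_cut = 5))
  fill <- function(x, d) utils::modifyList(d, x)
  raman <- fill(raman, defaults$raman)
  raman$em_range <- as.numeric(unlist(raman$em_range))
  scatter <- fill(scatter, defaults$scatter)
  scatter$widths <- unlist(scatter$widths)
  structure(list(input = input, campaign = campaign, raw = isTRUE(raw), paths = paths,
                 raman = raman,
                 scatter = scatter,
                 parafac = fill(parafac, defaults$parafac),
                 kinetics = fill(kinetics, defaults$kinetics),
                 grouping = grouping, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown top-level or nested keys are rejected.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  extra <- setdiff(names(y), allowed)
  if (length(extra))
    stop(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")), call. = FALSE)
  if (!is.null(y$campaign)) {
    c_allowed <- names(formals(campaign_config))
    c_extra <- setdiff(names(y$campaign), c_allowed)
    if (length(c_extra))
      stop(sprintf("unknown campaign key(s): %s", paste(c_extra, collapse = ", ")), call. = FALSE)
    y$campaign <- do.call(campaign_config, y$campaign)
  }
  do.call(pipeline_config, y)
}

# write a csv whose first line records the config hash
write_csv_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_hashed <- function(path) utils::read.csv(path, comment.char = "#",
                                                  stringsAsFactors = FALSE)

preprocess_samples <- function(eems, blank, absorbance, config) {
  ref <- compute_raman_area(blank, ex_line = config$raman$ex_line,
                            em_range = config$raman$em_range)
  lapply(eems, function(s) {
    id <- s$meta$sample_id
    s <- subtract_blank(s, blank)
    s <- inner_filter_correct(s, absorbance[[id]])
    s <- raman_normalize(s, ref)
    mask_scatter(s, widths = config$scatter$widths,
                 zero_below = config$scatter$zero_below,
                 below_cut = config$scatter$below_cut)
  })
}

# per-sample absorption summaries: a(350), a(lambda_kinetics), S275:295, S350:400
absorption_summary <- function(absorbance, lambda = 300) {
  rows <- lapply(names(absorbance), function(id) {
    a <- absorbance_to_absorption(absorbance[[id]])
    data.frame(sample_id = id,
               a350 = absorption_at(a, 350),
               a_kin = absorption_at(a, lambda),
               S275 = fit_spectral_slope(a, c(275, 295))$S,
               S350 = fit_spectral_slope(a, c(350, 400))$S,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# change records for absorption metrics and DOC, in summarize_changes layout
optical_changes <- function(manifest, absum) {
  m <- merge(manifest, absum, by = "sample_id", sort = FALSE)
  rows <- list()
  key <- interaction(m$station, m$treatment, m$replicate, drop = TRUE)
  for (g in split(m, key)) {
    b <- g[g$timepoint_days == 0, , drop = FALSE]
    if (nrow(b) != 1L) next
    later <- g[g$timepoint_days > 0, , drop = FALSE]
    if (!nrow(later)) next
    add <- function(par, delta, kind) data.frame(
      station = later$station, salinity_psu = later$salinity_psu,
      treatment = later$treatment, replicate = later$replicate,
      parameter = par, timepoint_days = later$timepoint_days,
      delta = delta, kind = kind, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- add("aCDOM350", percent_change(b$a350, later$a350), "percent")
    rows[[length(rows) + 1L]] <- add("S275:295", later$S275 - b$S275, "absolute_per_nm")
    rows[[length(rows) + 1L]] <- add("S350:400", later$S350 - b$S350, "absolute_per_nm")
  }
  out <- do.call(rbind, rows)
  out$retained <- TRUE
  out
}

doc_changes <- function(doc) {
  data.frame(station = doc$station, salinity_psu = doc$salinity_psu,
             treatment = doc$treatment, replicate = doc$replicate,
             parameter = "DOC", timepoint_days = 24,
             delta = percent_change(doc$doc_t0, doc$doc_t24),
             kind = "percent", retained = TRUE, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes, in fixed order: input (simulate or ingest), preprocessing
#' (blank, inner-filter, Raman, scatter), dataset assembly, PARAFAC fit
#' with split-half validation and outlier screening, component metrics
#' (Fmax, contributions, Grubbs-filtered changes), photobleaching decay
#' kinetics of CDOM absorption, and the river/plume/ocean change summary.
#' Any stage failure aborts with an error naming the stage. All tables are
#' written to `config$output_dir` with the configuration hash in a header
#' comment, and a run manifest with per-file checksums is returned; a rerun
#' with the same configuration reproduces identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `"run_manifest"`: list with `config_hash`,
#'   `version`, `outputs` (file checksums), `stages` (log), `output_dir`,
#'   and the fitted `model`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage_log <- character()
  run_stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    stage_log <<- c(stage_log, name)
    res
  }
  seeds <- derive_seeds(config$seed, 3L, c("generator", "parafac", "kinetics"))

  # ---- input -----------------------------------------------------------
  inp <- run_stage("input", {
    if (config$input == "synthetic") {
      camp_cfg <- config$campaign
      camp_cfg$seed <- seeds[["generator"]]
      camp <- simulate_campaign(camp_cfg, raw = config$raw)
      list(eems = camp$eems, manifest = camp$manifest, absorbance = camp$absorbance,
           doc = camp$doc, blank = camp$blank, pathlength = camp_cfg$pathlength,
           campaign = camp)
    } else {
      p <- config$paths
      manifest <- utils::read.csv(p$manifest, stringsAsFactors = FALSE)
      pl <- p$pathlength %||% 0.05
      absorbance <- read_absorbance_csv(p$absorbance, pathlength = pl)
      blank <- read_eem_csv(p$blank, meta = list(sample_id = "blank"))
      eems <- lapply(seq_len(nrow(manifest)), function(i) {
        id <- manifest$sample_id[i]
        read_eem_csv(file.path(p$eem_dir, paste0(id, ".csv")),
                     meta = as.list(manifest[i, ]))
      })
      names(eems) <- manifest$sample_id
      list(eems = eems, manifest = manifest, absorbance = absorbance,
           doc = NULL, blank = blank, pathlength = pl, campaign = NULL)
    }
  })

  # ---- preprocess + assemble -------------------------------------------
  ds <- run_stage("preprocess", {
    needs_corrections <- !length(inp$eems[[1]]$state)
    eems <- if (needs_corrections)
      preprocess_samples(inp$eems, inp$blank, inp$absorbance, config)
    else inp$eems
    assemble_dataset(eems)
  })

  # ---- PARAFAC ---------------------------------------------------------
  pf <- config$parafac
  fitres <- run_stage("parafac", {
    if (length(pf$candidates) > 1L) {
      sel <- select_n_components(ds, pf$candidates, threshold = pf$threshold,
                                 n_starts = pf$n_starts, tol = pf$tol,
                                 max_iter = pf$max_iter, seed = seeds[["parafac"]])
      if (is.na(sel$ncomp)) stop("no candidate component count validated")
      list(model = sel$models[[as.character(sel$ncomp)]], selection = sel,
           validation = NULL)
    } else {
      m <- parafac(ds, pf$candidates, n_starts = pf$n_starts, tol = pf$tol,
                   max_iter = pf$max_iter, seed = seeds[["parafac"]])
      v <- tryCatch(split_half_validate(ds, pf$candidates, threshold = pf$threshold,
                                        n_starts = max(2, pf$n_starts %/% 2),
                                        tol = pf$tol, max_iter = pf$max_iter,
                                        seed = seeds[["parafac"]]),
                    error = function(e) NULL)
      list(model = m, selection = NULL, validation = v)
    }
  })
  model <- fitres$model
  outl <- detect_outliers(ds, model)

  # ---- metrics ---------------------------------------------------------
  metrics <- run_stage("metrics", {
    fm <- fmax(model)
    contrib <- contribution_by_salinity(fm)
    changes <- component_changes(fm)
    list(fmax = fm, contributions = contrib, changes = changes)
  })

  # ---- kinetics --------------------------------------------------------
  absum <- absorption_summary(inp$absorbance, lambda = config$kinetics$lambda)
  kin <- run_stage("kinetics", {
    m <- merge(inp$manifest, absum, by = "sample_id", sort = FALSE)
    pbm <- m[m$treatment == "PB", , drop = FALSE]
    rows <- list()
    if (nrow(pbm)) for (st in unique(pbm$station)) {
      g <- pbm[pbm$station == st, , drop = FALSE]
      ser <- tapply(g$a_kin, g$timepoint_days, mean)  # mean across bottles
      t <- as.numeric(names(ser)); y <- as.numeric(ser)
      if (length(t) < 3) next
      fit <- fit_decay(t, y / y[t == 0], alpha = config$kinetics$alpha)
      p <- fit$params
      rows[[length(rows) + 1L]] <- data.frame(
        series = sprintf("st%02d_aCDOM%d", st, config$kinetics$lambda),
        station = st, model = fit$model,
        a = unname(p["a"]),
        f1 = if (fit$model == "double") unname(p["f1"]) else NA_real_,
        k1 = unname(if (fit$model == "double") p["k1"] else p["k"]),
        k2 = if (fit$model == "double") unname(p["k2"]) else NA_real_,
        rss = fit$rss,
        aicc_single = fit$selection$aicc_single,
        aicc_double = fit$selection$aicc_double,
        F_statistic = fit$selection$F_statistic %||% NA_real_,
        p_value = fit$selection$p_value %||% NA_real_,
        stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else data.frame()
  })

  # ---- tables ----------------------------------------------------------
  tables <- run_stage("tables", {
    ch <- optical_changes(inp$manifest, absum)
    comp_ch <- metrics$changes
    if (nrow(comp_ch)) {
      comp_ch$kind <- "percent"
      ch <- rbind(ch, comp_ch[, names(ch)])
    }
    doc_log <- character()
    if (!is.null(inp$doc)) {
      docx <- exclude_doc_anomalies(inp$doc)
      doc_log <- docx$log
      if (nrow(docx$retained)) ch <- rbind(ch, doc_changes(docx$retained))
    }
    summ <- summarize_changes(ch, rules = config$grouping)
    list(changes = ch, summary = summ, wide = table1_layout(summ), doc_log = doc_log)
  })

  # ---- write artifacts -------------------------------------------------
  cfg_path <- file.path(config$output_dir, "config.yaml")
  cfg_serial <- config
  cfg_serial$output_dir <- NULL  # hash covers the analysis settings, not the destination
  yaml::write_yaml(unclass_deep(cfg_serial), cfg_path)
  hash <- unname(tools::md5sum(cfg_path))

  out_files <- c(config = cfg_path)
  wr <- function(df, name) {
    p <- file.path(config$output_dir, name)
    write_csv_hashed(df, p, hash)
    out_files[[name]] <<- p
  }
  wr(inp$manifest, "manifest.csv")
  wr(metrics$fmax, "fmax.csv")
  wr(metrics$contributions, "contributions.csv")
  wr(tables$changes, "changes.csv")
  if (nrow(kin)) wr(kin, "kinetics.csv")
  wr(tables$summary, "table1.csv")
  wr(tables$wide, "table1_wide.csv")
  lp <- file.path(config$output_dir, "loadings.csv")
  export_loadings(model, lp); out_files[["loadings.csv"]] <- lp
  rp <- file.path(config$output_dir, "model_report.json")
  write_model_report(model, rp, validation = fitres$validation, outliers = outl)
  out_files[["model_report.json"]] <- rp

  checksums <- vapply(out_files, function(p) unname(tools::md5sum(p)), character(1))
  structure(list(config_hash = hash,
                 version = as.character(utils::packageVersion("fluordom")),
                 outputs = checksums, stages = stage_log,
                 output_dir = config$output_dir, model = model,
                 doc_exclusions = tables$doc_log),
            class = "run_manifest")
}

# strip S3 classes recursively so yaml serializes plain lists
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> config %s, %d stage(s): %s\n  outputs in %s\n",
              substr(x$config_hash, 1, 8), length(x$stages),
              paste(x$stages, collapse = " > "), x$output_dir))
  invisible(x)
}
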