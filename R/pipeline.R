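#' Default run configuration
#'
#' All defaults equal the protocol's published constants: 12-h protocol
#' windows, delta band 0.98-3.91 Hz, interval counts 12/5/9/11/6 (+36 for
#' SD waking), alpha 0.05, PFP threshold 0.015, and the shipped genotype
#' calibration parameters.
#'
#' @param seed master seed.
#' @param n_subjects subjects per genotype.
#' @param genotypes named list of [genotype_params()]; defaults to the
#'   shipped calibration set.
#' @param noise_sd spectral noise level.
#' @param expression optional list
#'   `list(n_genes=, de_fraction=, fc_log2=)` enabling the
#'   differential-expression stage.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, n_subjects = 2L,
                       genotypes = default_genotypes(),
                       noise_sd = 0.2, expression = NULL) {
  cfg <- list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
              genotypes = genotypes,
              windows = protocol_windows(),
              bands = eeg_bands(),
              interval_counts = default_interval_counts(),
              alpha = 0.05, pfp_threshold = 0.015,
              noise_sd = noise_sd, expression = expression)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  required <- c("seed", "n_subjects", "genotypes", "windows", "bands",
                "interval_counts", "alpha", "pfp_threshold", "noise_sd")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("run config is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  need_w <- protocol_windows()$window
  if (!all(need_w %in% cfg$windows$window)) {
    stop("run config windows missing: ",
         paste(setdiff(need_w, cfg$windows$window), collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_w %in% names(cfg$interval_counts))) {
    stop("run config interval_counts missing: ",
         paste(setdiff(need_w, names(cfg$interval_counts)),
               collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Simulates each subject of each genotype (or ingests hypnogram/spectra
#' files, when `config` carries an `inputs` list of paths), then computes
#' the vigilance, spectral, homeostasis and statistics stages, writing
#' tidy long-format tables plus a manifest (seed, config hash, package
#' version, per-stage timing) into one run directory.  A subject whose
#' data cannot support a stage (insufficient-data signal) is recorded in
#' the manifest and the pipeline continues with the remaining subjects.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created; must not already contain a
#'   manifest).
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timing <- c()
  failures <- list()
  sc <- sim_config(seed = config$seed, n_subjects = config$n_subjects,
                   noise_sd = config$noise_sd)

  budgets <- list(); tcs <- list(); swes <- list(); wakes <- list()
  rebounds <- list(); spectra_rows <- list()
  sid <- 0L
  for (gname in names(config$genotypes)) {
    gp <- config$genotypes[[gname]]
    for (s in seq_len(config$n_subjects)) {
      sid <- sid + 1L
      st <- Sys.time()
      hyp <- simulate_hypnogram(gp, sc, subject_id = sid)
      frames <- simulate_spectra(hyp, gp, sc)
      key <- data.frame(genotype = gname, subject = sid)
      for (w in config$windows$window) {
        sp <- state_percentages(hyp, w, bin_h = 12)
        budgets[[length(budgets) + 1L]] <- cbind(key, window = w, sp)
      }
      res <- try({
        tc <- delta_timecourse(frames, hyp, config$interval_counts)
        tcs[[length(tcs) + 1L]] <- cbind(key, as.data.frame(tc))
        rebounds[[length(rebounds) + 1L]] <-
          cbind(key, rebound_pct = immediate_rebound(tc))
        swe <- swe_accumulation(frames, hyp)
        swes[[length(swes) + 1L]] <- cbind(key, as.data.frame(swe))
        wb <- waking_band_timecourse(frames, hyp, mode = "hourly")
        wakes[[length(wakes) + 1L]] <- cbind(key, wb)
      }, silent = TRUE)
      if (inherits(res, "try-error")) {
        failures[[length(failures) + 1L]] <-
          list(genotype = gname, subject = sid,
               error = conditionMessage(attr(res, "condition")))
      }
      for (stt in c("N", "R", "W")) {
        sp <- state_spectrum(frames, hyp, stt, "BSL-L")
        if (!is.null(sp)) {
          spectra_rows[[length(spectra_rows) + 1L]] <-
            cbind(key, state = stt,
                  as.data.frame(t(sp), check.names = FALSE))
        }
      }
      rm(frames)
      timing[paste0("subject_", sid)] <-
        as.numeric(difftime(Sys.time(), st, units = "secs"))
    }
  }
  wt <- function(x, f) {
    utils::write.table(do.call(rbind, x), file.path(out_dir, f),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(budgets, "state_budgets.tsv")
  if (length(tcs)) wt(tcs, "delta_timecourse.tsv")
  if (length(rebounds)) wt(rebounds, "rebound.tsv")
  if (length(swes)) wt(swes, "swe_accumulation.tsv")
  if (length(wakes)) wt(wakes, "waking_bands.tsv")
  if (length(spectra_rows)) wt(spectra_rows, "state_spectra.tsv")

  # per-bin genotype statistics on the BSL-L NREMS spectra
  sp_all <- do.call(rbind, spectra_rows)
  nrem <- sp_all[sp_all$state == "N", , drop = FALSE]
  if (nrow(nrem) > 0 && length(unique(nrem$genotype)) >= 2) {
    mats <- lapply(split(nrem, nrem$genotype), function(d) {
      as.matrix(d[, -(1:3), drop = FALSE])
    })
    if (all(vapply(mats, nrow, integer(1)) >= 2)) {
      kw <- per_bin_kruskal_wallis(mats)
      utils::write.table(kw, file.path(out_dir, "per_bin_kw.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if (!is.null(config$expression)) {
    ex <- config$expression
    m <- simulate_expression(ex$n_genes, ex$n_per_group %||% 8L,
                             de_fraction = ex$de_fraction,
                             fc_log2 = ex$fc_log2,
                             seed = derive_seed(config$seed, 0L, 9L))
    norm <- percentile_shift_normalize(m)
    de <- classify_de(norm, alpha = config$alpha,
                      pfp_threshold = config$pfp_threshold,
                      seed = derive_seed(config$seed, 0L, 10L))
    utils::write.table(as.data.frame(de), file.path(out_dir, "de_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fold_change_ranking(de),
                       file.path(out_dir, "fc_top.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cfg_path <- file.path(out_dir, "config.json")
  cfg_json <- list(seed = config$seed, n_subjects = config$n_subjects,
                   noise_sd = config$noise_sd,
                   genotypes = names(config$genotypes),
                   interval_counts = as.list(config$interval_counts),
                   alpha = config$alpha,
                   pfp_threshold = config$pfp_threshold)
  jsonlite::write_json(cfg_json, cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "somnostat",
    version = as.character(utils::packageVersion("somnostat")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    n_subjects = sid,
    failures = failures,
    timing_s = as.list(round(timing, 3)),
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0,
                                          units = "secs")), 3)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
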