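#' Read a pipeline configuration
#'
#' The configuration is a YAML file with either a `data:` block (paths to
#' modern, climate, fossil and optional harmonization CSVs) or a
#' `synthetic:` block (taxon count, gradient, sample sizes, depth, events),
#' plus optional `wapls:` (`ncomp`, `select`), `analogue:`, `snsizer:`
#' (`n_scales`, `grid_n`, `alpha`, `ess_min`) and a master `seed`.
#'
#' @param path YAML file path.
#' @return A named list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_pipeline_config(cfg)
}

as_pipeline_config <- function(cfg) {
  has_data <- !is.null(cfg$data); has_syn <- !is.null(cfg$synthetic)
  if (has_data == has_syn)
    stop("config must contain exactly one of 'data' or 'synthetic'")
  if (has_data && is.null(cfg$data$fossil))
    stop("config 'data' block is missing the fossil source")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "pipeline_config")
}

#' Run the full reconstruction pipeline
#'
#' Executes the stages in order: harmonize -> compositional transform ->
#' WA-PLS fit and leave-one-out cross-validation -> reconstruction of the
#' fossil record -> analogue quality control -> SnSiZer significance map
#' -> interval extraction at the highlighted smoothing levels. All
#' artifacts are written to `outdir` as CSV (plus an optional PNG of the
#' map), stamped with the configuration hash and master seed; per-stage
#' seeds are derived deterministically from the master seed, so a rerun
#' with the same configuration is byte-identical. A failure in any stage
#' leaves the partial outputs in place next to a `FAILED` marker naming
#' the stage.
#'
#' @param config a `pipeline_config` (see [read_pipeline_config()]) or a
#'   plain list with the same structure.
#' @param outdir output directory, created if needed.
#' @param png also render the significance map to `snsizer_map.png`.
#' @return Invisibly, a list with the fitted model, CV report, the
#'   reconstruction (`signal_series`), analogue report, `snsizer` map and
#'   interval table.
#' @export
run_pipeline <- function(config, outdir, png = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- as_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  cfg_hash <- sum(utf8ToInt(paste(deparse(unclass(config)), collapse = "")) *
                    (seq_along(utf8ToInt(paste(deparse(unclass(config)),
                                               collapse = ""))) %% 97 + 1))
  logf <- file.path(outdir, "pipeline.log")
  logcon <- file(logf, "w", encoding = "UTF-8")
  say <- function(...) writeLines(sprintf(...), logcon)
  say("pipeline config_hash=%d seed=%d", cfg_hash, seed)
  stage <- "config"
  on.exit({
    close(logcon)
  })
  result <- tryCatch({
    stage <- "inputs"
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      resp <- make_taxon_responses(syn$m %||% 30,
                                   as.numeric(syn$gradient %||% c(200, 800)),
                                   seed = derive_seed(seed, "responses"))
      xmod <- seq(resp_attr(resp)[1L], resp_attr(resp)[2L],
                  length.out = syn$n_modern %||% 300)
      mod <- simulate_modern_trainingset(resp, xmod,
                                         depth = syn$depth %||% 400,
                                         seed = derive_seed(seed, "modern"))
      modern <- mod$assemblage; climate <- mod$climate
      ev <- if (is.null(syn$events)) NULL else
        do.call(rbind, lapply(syn$events, as.data.frame))
      sched <- history_schedule(
        range_kyr = as.numeric(syn$range %||% c(0, 197000)),
        baseline = syn$baseline %||% 400,
        events = ev, noise_sd = syn$noise_sd %||% 30,
        n_samples = syn$n_fossil %||% 438)
      history <- simulate_climate_history(sched,
                                          seed = derive_seed(seed, "history"))
      fossil <- simulate_fossil_record(resp, history,
                                       depth = syn$depth %||% 400,
                                       seed = derive_seed(seed, "fossil"))
      say("synthetic inputs: %d modern, %d fossil, %d taxa",
          nrow(modern$values), nrow(fossil$values), ncol(modern$values))
      write_assemblage(modern, file.path(outdir, "modern_counts.csv"))
      write_assemblage(fossil, file.path(outdir, "fossil_counts.csv"))
      utils::write.csv(data.frame(sample_id = rownames(climate), climate),
                       file.path(outdir, "climate.csv"), row.names = FALSE)
    } else {
      modern <- read_assemblage(config$data$modern)
      climate <- read_climate(config$data$climate)
      fossil <- read_assemblage(config$data$fossil, has_ages = TRUE)
      history <- NULL
      if (!is.null(config$data$harmonization) ||
          !is.null(config$data$exclude)) {
        stage <- "harmonize"
        map <- read_harmonization(config$data$harmonization,
                                  config$data$exclude)
        n0 <- ncol(modern$values)
        modern <- harmonize(modern, map)
        fossil <- harmonize(fossil, map)
        say("harmonize: modern taxa %d -> %d", n0, ncol(modern$values))
      }
    }

    stage <- "transform"
    mod_prop <- to_proportions(modern)
    fos_prop <- to_proportions(fossil)
    mod_sqrt <- sqrt_transform(mod_prop)
    fos_sqrt <- sqrt_transform(fos_prop)
    xvar <- config$wapls$variable %||% colnames(climate)[1L]
    x <- climate[rownames(modern$values), xvar]

    stage <- "fit"
    ncomp <- config$wapls$ncomp %||% 5
    select <- config$wapls$select %||% 2
    fit <- wapls(mod_sqrt, x, ncomp = ncomp)
    write_wapls(fit, file.path(outdir, "wapls_model.csv"))

    stage <- "crossvalidate"
    cv <- wapls_loo(mod_sqrt, x, ncomp = ncomp, select = select)
    best <- which.min(cv$stats[, "rmsep"])
    if (best != cv$selected)
      say("warning: selected c=%d but CV-optimal RMSEP at c=%d",
          cv$selected, best)
    utils::write.csv(data.frame(component = rownames(cv$stats),
                                round(cv$stats, 6)),
                     file.path(outdir, "cv_report.csv"), row.names = FALSE)

    stage <- "reconstruct"
    pred <- withCallingHandlers(
      predict(fit, fos_sqrt, ncomp = cv$selected),
      message = function(m) {
        say("reconstruct: %s", conditionMessage(m)); invokeRestart("muffleMessage")
      })
    recon <- structure(list(t = fossil$ages, y = as.numeric(pred),
                            truth = if (!is.null(history)) history$truth
                            else NULL),
                       class = "signal_series")
    utils::write.csv(data.frame(sample_id = rownames(fossil$values),
                                age = fossil$ages,
                                prediction = sprintf("%.10g", pred)),
                     file.path(outdir, "reconstruction.csv"),
                     row.names = FALSE)

    stage <- "analogue"
    rep <- classify_analogues(fos_prop, mod_prop)
    write_analogue_report(rep, file.path(outdir, "analogue_report.csv"))
    say("analogue: good %.2f%% fair %.2f%% none %.2f%%",
        rep$proportions["good"], rep$proportions["fair"],
        rep$proportions["none"])

    stage <- "snsizer"
    sz_cfg <- config$snsizer
    sz <- snsizer(recon$t, recon$y,
                  n_scales = sz_cfg$n_scales %||% 50,
                  grid_n = sz_cfg$grid_n %||% 401,
                  alpha = sz_cfg$alpha %||% 0.05,
                  ess_min = sz_cfg$ess_min %||% 5)
    write_snsizer(sz, outdir)
    if (png) {
      grDevices::png(file.path(outdir, "snsizer_map.png"), 1200, 600)
      plot(sz)
      grDevices::dev.off()
    }

    stage <- "intervals"
    intervals <- do.call(rbind, lapply(sz$highlight, function(h)
      extract_intervals(sz, h)))
    say("intervals: %d across %d highlighted levels", nrow(intervals),
        length(sz$highlight))

    meta <- c(sprintf("config_hash: %d", cfg_hash),
              sprintf("seed: %d", seed),
              sprintf("selected_components: %d", cv$selected),
              sprintf("alpha: %g", sz$alpha),
              sprintf("ess_min: %g", sz$ess_min),
              sprintf("analogue_reference: %s", rep$reference),
              sprintf("highlight: %s",
                      paste(sprintf("%.8g", sz$highlight), collapse = ";")))
    writeLines(meta, file.path(outdir, "metadata.txt"))
    list(model = fit, cv = cv, reconstruction = recon, analogue = rep,
         snsizer = sz, intervals = intervals)
  }, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage,
                       conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

resp_attr <- function(responses) attr(responses, "gradient")
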