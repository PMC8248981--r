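#' Run the simulate - quantify - gate - analyse pipeline from one config
#'
#' Executes the requested stages in order against one output directory and
#' records every file written in a manifest (with MD5 content hashes and a
#' snapshot of the configuration), so a run can be audited and reproduced:
#' the same config and seed give identical hashes.
#'
#' Stages (any subset, executed in this order):
#' * `simulate` — population table (+ ground truth columns), lineage
#'   traces, and optionally rendered images (`render_n` cells);
#' * `quantify` — [quantify_image()] on every rendered image, written as a
#'   records table;
#' * `gate` — [gate_records()] flags on the quantified (or simulated)
#'   records;
#' * `doseresponse` — [fit_sigmoid()] of activity vs level per genotype on
#'   the simulated population;
#' * `thresholds` — [threshold_level()] per genotype;
#' * `bistability` — [bistability_profile()] per genotype;
#' * `lineage` — event detection and skipped-division classification on
#'   the simulated traces.
#'
#' @param config Either a named list or a path to a YAML file with fields
#'   `seed`, `stages` (character vector), `out_dir`, optional `sim`
#'   (arguments for [sim_config()]), and per-stage parameter blocks
#'   (`simulate$n_lineages`, `simulate$duration_min`, `simulate$render_n`,
#'   `gate`, `thresholds`, `bistability`).
#' @return The manifest: tibble with `stage`, `file`, `md5`. Written to
#'   `manifest.json` in `out_dir` together with the config snapshot.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("simulate", "gate", "doseresponse",
                                 "thresholds", "bistability", "lineage")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_args <- config$sim %||% list()
  sim_args$seed <- config$seed %||% sim_args$seed %||% 1L
  cfg <- do.call(sim_config, sim_args)

  manifest <- tibble(stage = character(), file = character(),
                     md5 = character())
  note <- function(stage, file) {
    hash <- unname(tools::md5sum(file))
    manifest <<- bind_rows(manifest,
                           tibble(stage = stage, file = basename(file),
                                  md5 = hash))
  }
  state <- new.env(parent = emptyenv())
  # analysis stages need genotype/level/activity columns; quantified image
  # tables carry no genotype, so fall back to the simulated population
  analysis_records <- function() {
    for (cand in list(state$gated, state$quantified, state$pop)) {
      if (!is.null(cand) &&
          all(c("genotype", "cdk_level_au", "activity_nc") %in% names(cand))) {
        return(cand)
      }
    }
    abort("no records with genotype/level/activity available")
  }

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)),
            class = "cdkflow_pipeline_error")
    })
  }

  for (stage in stages) {
    switch(stage,
      simulate = run_stage("simulate", function() {
        pop <- simulate_population(cfg)
        f <- file.path(out_dir, "population.csv")
        write_records(pop, f); note("simulate", f)
        state$pop <- pop
        sim_p <- config$simulate %||% list()
        tr <- simulate_lineages(cfg, sim_p$n_lineages %||% 100,
                                sim_p$duration_min %||% 300)
        ft <- file.path(out_dir, "lineages.csv")
        write_lineage_traces(tr, ft)
        note("simulate", ft); note("simulate", paste0(ft, ".events.json"))
        state$traces <- tr
        render_n <- sim_p$render_n %||% 0
        if (render_n > 0) {
          img_dir <- file.path(out_dir, "images")
          dir.create(img_dir, showWarnings = FALSE)
          for (i in seq_len(min(render_n, nrow(pop)))) {
            fi <- file.path(img_dir, paste0(pop$cell_id[i], ".tif"))
            write_cell_image(render_cell_image(pop[i, ], cfg), fi)
            note("simulate", fi)
          }
          state$img_dir <- img_dir
        }
      }),
      quantify = run_stage("quantify", function() {
        if (is.null(state$img_dir)) {
          abort("quantify stage needs rendered images (simulate$render_n)")
        }
        imgs <- read_cell_images(state$img_dir)
        recs <- purrr::imap_dfr(imgs, function(img, id) {
          mutate(quantify_image(img), cell_id = id, .before = 1)
        })
        f <- file.path(out_dir, "quantified.csv")
        write_records(recs, f); note("quantify", f)
        state$quantified <- recs
      }),
      gate = run_stage("gate", function() {
        recs <- state$quantified %||% state$pop
        if (is.null(recs)) abort("gate stage needs records")
        if (!"focus_grad_rms" %in% names(recs)) {
          recs$focus_grad_rms <- Inf  # simulated tables carry no image focus
        }
        if (!"aspect_ratio" %in% names(recs)) {
          recs$aspect_ratio <- recs$length_um / (2 * recs$radius_um)
        }
        gated <- gate_records(recs, config$gate %||% list())
        f <- file.path(out_dir, "gated.csv")
        write_records(gated, f); note("gate", f)
        state$gated <- gated
      }),
      doseresponse = run_stage("doseresponse", function() {
        recs <- analysis_records()
        if ("gated" %in% names(recs)) recs <- filter(recs, .data$gated)
        fits <- recs %>%
          group_by(.data$genotype) %>%
          dplyr::group_modify(function(df, key) {
            fit <- fit_sigmoid(df$cdk_level_au, df$activity_nc)
            tibble(ec50 = fit$ic50, slope = fit$hill_coef, top = fit$top,
                   bottom = fit$bottom, rss = fit$rss,
                   converged = fit$converged, n = nrow(df))
          }) %>% ungroup()
        f <- file.path(out_dir, "sigmoid_fits.csv")
        write_records(fits, f); note("doseresponse", f)
      }),
      thresholds = run_stage("thresholds", function() {
        recs <- analysis_records()
        p <- config$thresholds %||% list()
        curves <- recs %>%
          group_by(.data$genotype) %>%
          dplyr::group_modify(function(df, key) {
            threshold_level(df,
                            size_bin_width = p$size_bin_width %||% 1,
                            activity_cut = p$activity_cut %||% 5,
                            fraction = p$fraction %||% 0.5)
          }) %>% ungroup()
        f <- file.path(out_dir, "threshold_curves.csv")
        write_records(curves, f); note("thresholds", f)
      }),
      bistability = run_stage("bistability", function() {
        recs <- analysis_records()
        p <- config$bistability %||% list()
        rows <- recs %>%
          group_by(.data$genotype) %>%
          dplyr::group_modify(function(df, key) {
            bp <- bistability_profile(
              df, size_bin_width = p$size_bin_width %||% 1,
              level_bin_width = p$level_bin_width %||% 100,
              min_n = p$min_n %||% 50)
            out <- bp$by_bin
            out$nonlinearity_score <-
              bp$regression$nonlinearity_score %||% NA_real_
            out
          }) %>% ungroup()
        f <- file.path(out_dir, "bistability.csv")
        write_records(rows, f); note("bistability", f)
      }),
      lineage = run_stage("lineage", function() {
        if (is.null(state$traces)) abort("lineage stage needs traces")
        cls <- classify_skipped_divisions(state$traces)
        f <- file.path(out_dir, "lineage_events.csv")
        write_records(cls$events, f); note("lineage", f)
        fj <- file.path(out_dir, "skip_fraction.json")
        jsonlite::write_json(list(fraction = cls$fraction,
                                  n_events = cls$n_events, ci = cls$ci),
                             fj, auto_unbox = TRUE, digits = NA)
        note("lineage", fj)
      }),
      abort(sprintf("unknown pipeline stage '%s'", stage),
            class = "cdkflow_pipeline_error")
    )
  }
  jsonlite::write_json(list(config = config, manifest = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
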