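## End-to-end orchestration: simulate truth sets, emulate callers,
## benchmark over the design grid, fit/cross-validate/select performance
## models, and report predictions — the non-interactive counterpart of a
## hosted performance calculator. Every figure's underlying numbers are
## also written as TSV; plots are views, never the only record.

#' Pipeline run configuration
#'
#' @param grid a \code{\link{design_grid}}.
#' @param truth_spec a \code{\link{truth_set_spec}}.
#' @param profiles named list of \code{\link{caller_profile}} objects.
#' @param mask a \code{\link{genome_mask}}.
#' @param responses responses to model.
#' @param model_ids candidate model forms to cross-validate.
#' @param seed integer base seed for every stochastic stage.
#' @param out_dir output directory.
#' @param plots write prediction-curve figures (default FALSE).
#' @return object of class \code{svperf_config}.
#' @export
run_config <- function(grid, truth_spec = truth_set_spec(),
                       profiles = builtin_profiles(),
                       mask = miniature_genome(),
                       responses = c("sensitivity", "precision", "f1"),
                       model_ids = 1:8, seed = 1L, out_dir = "svperf_out",
                       plots = FALSE) {
  stopifnot(inherits(grid, "svperf_grid"),
            inherits(truth_spec, "svperf_truth_spec"))
  structure(list(grid = grid, truth_spec = truth_spec, profiles = profiles,
                 mask = mask, responses = responses, model_ids = model_ids,
                 seed = as.integer(seed), out_dir = out_dir, plots = plots),
            class = "svperf_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: \code{normal_covs, tumour_covs, vafs, t_thresholds},
#' \code{somatic_per_type, germline_per_type, length_range},
#' \code{profiles} (names of bundled profiles), \code{responses},
#' \code{model_ids}, \code{seed}, \code{out_dir}, \code{plots}.
#'
#' @param path YAML file.
#' @return a \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  grid <- design_grid(y$normal_covs, y$tumour_covs, y$vafs, y$t_thresholds)
  spec <- truth_set_spec(
    somatic_per_type = y$somatic_per_type %||% 200,
    germline_per_type = y$germline_per_type %||% 2000,
    length_range = unlist(y$length_range %||% c(50, 5000)))
  profs <- builtin_profiles()
  if (!is.null(y$profiles)) {
    unknown <- setdiff(y$profiles, names(profs))
    if (length(unknown) > 0L)
      stop("unknown profiles in config: ", paste(unknown, collapse = ", "))
    profs <- profs[y$profiles]
  }
  run_config(grid, spec, profs,
             responses = y$responses %||% c("sensitivity", "precision", "f1"),
             model_ids = y$model_ids %||% 1:8,
             seed = y$seed %||% 1L,
             out_dir = y$out_dir %||% "svperf_out",
             plots = isTRUE(y$plots))
}

#' Run the full performance-calculator pipeline
#'
#' simulate -> emulate -> benchmark -> fit/cross-validate/select, writing
#' truth sets (TSV), the evaluation table (TSV), the CV report (TSV),
#' selected models (JSON) and a manifest (JSON) recording package
#' version, seeds and selected model ids. Reruns with the same
#' configuration are byte-identical except for the manifest timestamp.
#'
#' @param config a \code{\link{run_config}}.
#' @return (invisibly) list with the evaluation table, CV results, fitted
#'   selected models and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "svperf_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- stage("simulate", simulate_truth_sets(config$truth_spec,
                                                 config$mask, config$seed))
  write_callset(truth$somatic,
                file.path(config$out_dir, "truth_somatic.tsv"))
  write_callset(truth$germline,
                file.path(config$out_dir, "truth_germline.tsv"))
  tab <- stage("benchmark",
               build_evaluation_table(config$grid, truth, config$profiles,
                                      config$mask, seed = config$seed))
  write_eval_table(tab, file.path(config$out_dir, "eval_table.tsv"))

  cv_rows <- list(); fits <- list(); selected <- list()
  for (prof in names(config$profiles)) {
    slice <- tab[tab$callset == prof & tab$sv_type_scope == "ALL", ]
    for (resp in config$responses) {
      if (all(is.na(slice[[resp]]))) next
      cv <- stage(paste0("cv:", prof, ":", resp),
                  cross_validate(slice, resp, config$model_ids))
      id <- select_model(cv)
      fit <- stage(paste0("fit:", prof, ":", resp),
                   fit_perf_model(slice, perf_model_spec(id, resp)))
      fit <- prune_insignificant_terms(fit, table = slice)
      key <- paste(prof, resp, sep = ".")
      cv_rows[[key]] <- cbind(callset = prof, response = resp,
                              as.data.frame(cv))
      fits[[key]] <- fit
      selected[[key]] <- list(callset = prof, response = resp,
                              model_id = id,
                              pruned = fit$pruned %||% character())
    }
  }
  cv_report <- do.call(rbind, cv_rows)
  utils::write.table(cv_report, file.path(config$out_dir, "cv_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(selected,
                       file.path(config$out_dir, "selected_models.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(
    package = "svperf",
    version = as.character(utils::packageVersion("svperf")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    grid = unclass(config$grid),
    truth_records = c(somatic = nrow(truth$somatic),
                      germline = nrow(truth$germline)),
    selected_models = lapply(selected, function(s)
      list(callset = s$callset, response = s$response,
           model_id = s$model_id, pruned = s$pruned))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (isTRUE(config$plots) && length(fits) > 0L) {
    tryCatch({
      sens_fits <- fits[vapply(fits, function(f)
        f$response == "sensitivity", logical(1L))]
      if (length(sens_fits) > 0L) {
        pc <- plot_performance_curves(
          sens_fits, x_var = "vaf",
          fixed = list(tumour_cov = stats::median(config$grid$tumour_covs),
                       normal_cov = stats::median(config$grid$normal_covs),
                       t_threshold = max(config$grid$t_thresholds)))
        utils::write.table(pc$data,
                           file.path(config$out_dir, "curve_sensitivity.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        ggplot2::ggsave(file.path(config$out_dir, "curve_sensitivity.png"),
                        pc$plot, width = 7, height = 5, dpi = 150)
      }
    }, error = function(e)
      warning("figure stage skipped: ", conditionMessage(e)))
  }
  invisible(list(truth = truth, eval_table = tab, cv = cv_report,
                 fits = fits, selected = selected, manifest = manifest))
}

#' Prediction curves with confidence ribbons
#'
#' Line plots of predicted performance against one predictor, one line
#' per fitted model (callset), optionally overlaid at up to three values
#' of a second predictor (line type), with CI ribbons and horizontal
#' reference lines at user targets. Returns both the plot and its
#' underlying numbers.
#'
#' @param fits named list of \code{\link{fit_perf_model}} results (one
#'   per callset).
#' @param x_var predictor on the x axis.
#' @param fixed named list fixing the remaining predictors.
#' @param overlay_var optional second predictor varied across
#'   \code{overlay_values} (at most 3).
#' @param overlay_values values of \code{overlay_var}.
#' @param targets optional numeric vector of target performance levels
#'   drawn as horizontal reference lines.
#' @param ci_level confidence level for ribbons.
#' @param n_points curve resolution.
#' @return list with elements \code{plot} (ggplot) and \code{data}
#'   (data frame of plotted values).
#' @export
plot_performance_curves <- function(fits, x_var, fixed,
                                    overlay_var = NULL,
                                    overlay_values = NULL,
                                    targets = NULL, ci_level = 0.95,
                                    n_points = 50L) {
  stopifnot(length(fits) > 0L, x_var %in% PREDICTOR_VARS)
  if (!is.null(overlay_var)) {
    stopifnot(overlay_var %in% PREDICTOR_VARS, overlay_var != x_var,
              length(overlay_values) >= 1L, length(overlay_values) <= 3L)
  }
  if (is.null(names(fits)))
    names(fits) <- paste0("callset_", seq_along(fits))
  rows <- list()
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    r <- fit$ranges[[x_var]]
    xs <- seq(r[1], r[2], length.out = n_points)
    ovs <- if (is.null(overlay_var)) NA else overlay_values
    for (ov in ovs) {
      pts <- data.frame(x = xs)
      names(pts) <- x_var
      for (v in setdiff(PREDICTOR_VARS, c(x_var, overlay_var)))
        pts[[v]] <- fixed[[v]]
      if (!is.null(overlay_var)) pts[[overlay_var]] <- ov
      pr <- predict_performance(fit, pts, ci_level)
      pr$callset <- nm
      pr$overlay <- if (is.null(overlay_var)) NA_real_ else ov
      rows[[length(rows) + 1L]] <- pr
    }
  }
  d <- do.call(rbind, rows)
  aes_args <- list(x = as.name(x_var), y = quote(estimate),
                   colour = quote(callset))
  p <- ggplot2::ggplot(d, do.call(ggplot2::aes, aes_args)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper,
                                      fill = callset,
                                      group = interaction(callset, overlay)),
                         alpha = 0.2, colour = NA)
  if (!is.null(overlay_var)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(linetype = factor(overlay)),
                                linewidth = 0.8) +
      ggplot2::labs(linetype = overlay_var)
  } else {
    p <- p + ggplot2::geom_line(linewidth = 0.8)
  }
  if (!is.null(targets))
    p <- p + ggplot2::geom_hline(yintercept = targets, linetype = "dashed",
                                 colour = "grey40")
  p <- p + ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = x_var, y = fits[[1L]]$response) +
    ggplot2::theme_minimal()
  list(plot = p, data = d)
}
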