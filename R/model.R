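## Performance-surface modelling: eight candidate smooth additive model
## forms over (VAF, tumour coverage, normal coverage, breakpoint precision
## threshold), fitted by beta regression with logistic link and
## tensor-product penalized smooths (thin-plate marginal bases, smoothing
## parameters by REML) via mgcv; model choice by leave-one-level-out
## cross-validation with a simplest-among-tied rule.

PREDICTOR_VARS <- c("vaf", "tumour_cov", "normal_cov", "t_threshold")

## term catalogue for the eight candidate forms: smooths are tensor
## products of predictor pairs, remaining predictors enter linearly
MODEL_CATALOGUE <- list(
  `1` = list(smooths = list(c("vaf", "tumour_cov"), c("vaf", "t_threshold"),
                            c("vaf", "normal_cov"),
                            c("tumour_cov", "t_threshold")),
             linear = character()),
  `2` = list(smooths = list(c("vaf", "tumour_cov"), c("vaf", "t_threshold"),
                            c("vaf", "normal_cov")),
             linear = character()),
  `3` = list(smooths = list(c("vaf", "tumour_cov"), c("vaf", "t_threshold"),
                            c("tumour_cov", "t_threshold")),
             linear = "normal_cov"),
  `4` = list(smooths = list(c("vaf", "tumour_cov"), c("vaf", "t_threshold")),
             linear = "normal_cov"),
  `5` = list(smooths = list(c("vaf", "tumour_cov"),
                            c("tumour_cov", "t_threshold")),
             linear = "normal_cov"),
  `6` = list(smooths = list(c("vaf", "tumour_cov")),
             linear = c("t_threshold", "normal_cov")),
  `7` = list(smooths = list(c("vaf", "t_threshold")),
             linear = c("tumour_cov", "normal_cov")),
  `8` = list(smooths = list(),
             linear = c("vaf", "t_threshold", "tumour_cov", "normal_cov"))
)

#' Candidate performance-model specification
#'
#' The eight candidate forms combine tensor-product smooths of predictor
#' pairs with linear terms: form 1 has four smooths
#' (VAF x tumour coverage, VAF x T, VAF x normal coverage,
#' tumour coverage x T), forms 2--7 progressively fewer, and form 8 is
#' linear in all four predictors.
#'
#' @param model_id integer 1..8.
#' @param response one of \code{"sensitivity"}, \code{"precision"},
#'   \code{"f1"}.
#' @param drop_linear optional character vector of linear terms to omit
#'   (used by \code{\link{prune_insignificant_terms}}).
#' @return object of class \code{svperf_model_spec}.
#' @export
perf_model_spec <- function(model_id,
                            response = c("sensitivity", "precision", "f1"),
                            drop_linear = character()) {
  response <- match.arg(response)
  stopifnot(model_id %in% 1:8)
  terms <- MODEL_CATALOGUE[[as.character(model_id)]]
  structure(list(model_id = as.integer(model_id), response = response,
                 smooth_terms = terms$smooths,
                 linear_terms = setdiff(terms$linear, drop_linear)),
            class = "svperf_model_spec")
}

## complexity order: (number of smooth terms, total variables inside
## smooths, -model_id); lower is simpler
model_complexity <- function(model_id) {
  terms <- MODEL_CATALOGUE[[as.character(model_id)]]
  c(n_smooth = length(terms$smooths),
    n_smooth_vars = length(unlist(terms$smooths)),
    neg_id = -as.integer(model_id))
}

## beta-likelihood boundary shrinkage: exact 0/1 responses are pulled into
## the open interval, y' = (y (n - 1) + 0.5) / n with n the slice size
shrink_boundary <- function(y) {
  n <- length(y)
  at_boundary <- y %in% c(0, 1)
  y[at_boundary] <- (y[at_boundary] * (n - 1) + 0.5) / n
  y
}

build_formula <- function(spec, data, k_max = 5L) {
  k_for <- function(v) min(k_max, length(unique(data[[v]])))
  smooth_str <- vapply(spec$smooth_terms, function(vars) {
    ks <- vapply(vars, k_for, integer(1L))
    if (any(ks < 2L))
      stop("predictor with a single distinct value in smooth term ",
           paste(vars, collapse = ":"))
    sprintf("te(%s, bs = \"tp\", k = c(%s))",
            paste(vars, collapse = ", "), paste(ks, collapse = ", "))
  }, character(1L))
  rhs <- c(smooth_str, spec$linear_terms)
  if (length(rhs) == 0L) rhs <- "1"
  stats::as.formula(paste(".response ~", paste(rhs, collapse = " + ")))
}

#' Fit a performance-surface model
#'
#' Maximizes the penalized beta log-likelihood with logit link
#' (\code{mgcv::gam}, \code{family = betar}), with tensor-product
#' penalized smooths on thin-plate marginal bases and smoothing
#' parameters selected by REML. Responses exactly at 0 or 1 are shrunk
#' into the open interval before fitting. Marginal basis dimension is the
#' mgcv default (5), reduced where a predictor has fewer distinct values.
#'
#' @param table an \code{\link{eval_table}} (or data frame) slice for one
#'   callset; rows with missing response are dropped.
#' @param spec a \code{\link{perf_model_spec}}, or a bare model id 1..8.
#' @param response response column; defaults to the spec's.
#' @return object of class \code{svperf_fit} wrapping the \code{gam} fit,
#'   the spec, and the training ranges of the predictors.
#' @export
fit_perf_model <- function(table, spec, response = NULL) {
  if (is.numeric(spec)) spec <- perf_model_spec(spec, response %||%
                                                  "sensitivity")
  stopifnot(inherits(spec, "svperf_model_spec"))
  response <- response %||% spec$response
  d <- as.data.frame(table)
  if (!response %in% names(d)) stop("no response column: ", response)
  d <- d[!is.na(d[[response]]), c(PREDICTOR_VARS, response)]
  y <- d[[response]]
  if (any(y < 0 | y > 1)) stop("response values outside [0, 1]")
  d$.response <- shrink_boundary(y)
  form <- build_formula(spec, d)
  theta_fallback <- FALSE
  fit <- tryCatch(
    mgcv::gam(form, family = mgcv::betar(link = "logit"), method = "REML",
              data = d),
    error = function(e) e)
  if (inherits(fit, "error")) {
    ## degenerate (near-constant) slices break the precision-parameter
    ## estimation; refit with the precision fixed, which leaves the mean
    ## surface intact
    theta_fallback <- TRUE
    fit <- tryCatch(
      suppressWarnings(
        mgcv::gam(form, family = mgcv::betar(theta = 100, link = "logit"),
                  method = "REML", data = d)),
      error = function(e) stop("model ", spec$model_id, " fit failed: ",
                               conditionMessage(e)))
  }
  ranges <- lapply(d[PREDICTOR_VARS], range)
  structure(list(gam = fit, spec = spec, response = response,
                 ranges = ranges, n = nrow(d),
                 theta_fallback = theta_fallback),
            class = "svperf_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.svperf_fit <- function(x, ...) {
  cat(sprintf(paste0("<svperf_fit> model %d for %s (n = %d): %d smooth ",
                     "term(s), linear: %s\n"),
              x$spec$model_id, x$response, x$n,
              length(x$spec$smooth_terms),
              if (length(x$spec$linear_terms) > 0L)
                paste(x$spec$linear_terms, collapse = ", ") else "none"))
  invisible(x)
}

#' Predict detection performance with uncertainty
#'
#' Estimates are the inverse-logit of the linear predictor; standard
#' errors on the response scale follow from the delta method; confidence
#' intervals are computed on the link scale and back-transformed, so they
#' always lie inside (0, 1). Points outside the training range are
#' flagged as extrapolation.
#'
#' @param fitted a \code{\link{fit_perf_model}} result.
#' @param points data frame with columns \code{vaf, tumour_cov,
#'   normal_cov, t_threshold}.
#' @param ci_level confidence level (default 0.95).
#' @return \code{points} plus columns \code{estimate, se, lower, upper,
#'   extrapolated}.
#' @export
predict_performance <- function(fitted, points, ci_level = 0.95) {
  stopifnot(inherits(fitted, "svperf_fit"), ci_level > 0, ci_level < 1)
  points <- as.data.frame(points)
  missing_vars <- setdiff(PREDICTOR_VARS, names(points))
  if (length(missing_vars) > 0L)
    stop("prediction points lack: ", paste(missing_vars, collapse = ", "))
  p <- mgcv::predict.gam(fitted$gam, newdata = points, type = "link",
                         se.fit = TRUE)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  est <- stats::plogis(as.numeric(p$fit))
  extrap <- Reduce(`|`, lapply(PREDICTOR_VARS, function(v) {
    r <- fitted$ranges[[v]]
    points[[v]] < r[1] | points[[v]] > r[2]
  }))
  cbind(points,
        data.frame(estimate = est,
                   se = as.numeric(p$se.fit) * est * (1 - est),
                   lower = stats::plogis(as.numeric(p$fit) -
                                           z * as.numeric(p$se.fit)),
                   upper = stats::plogis(as.numeric(p$fit) +
                                           z * as.numeric(p$se.fit)),
                   extrapolated = extrap))
}

#' Leave-one-level-out cross-validation of candidate models
#'
#' Folds: for each of the four predictors and each of its distinct
#' simulated values, hold out every row at that value, fit on the rest
#' and score held-out RMSE and MAE on the response scale. The fold count
#' is the sum of distinct levels over the four predictors. Folds whose
#' training slice cannot identify a model are skipped with a warning and
#' recorded.
#'
#' @param table evaluation-table slice for one callset.
#' @param response response column.
#' @param model_ids candidate form ids (default 1:8).
#' @return object of class \code{svperf_cv}: a data frame with columns
#'   \code{model_id, rmse, mae, n_folds}, with the per-fold table in
#'   attribute \code{"folds"}.
#' @export
cross_validate <- function(table, response = "sensitivity",
                           model_ids = 1:8) {
  d <- as.data.frame(table)
  d <- d[!is.na(d[[response]]), ]
  folds <- do.call(rbind, lapply(PREDICTOR_VARS, function(v) {
    lv <- sort(unique(d[[v]]))
    if (length(lv) < 2L)
      stop("cross-validation needs >= 2 distinct levels of ", v)
    data.frame(var = v, level = lv, stringsAsFactors = FALSE)
  }))
  fold_rows <- list()
  for (id in model_ids) {
    spec <- perf_model_spec(id, response)
    for (k in seq_len(nrow(folds))) {
      held <- d[[folds$var[k]]] == folds$level[k]
      fit <- tryCatch(
        fit_perf_model(d[!held, , drop = FALSE], spec, response),
        error = function(e) NULL)
      if (is.null(fit)) {
        warning(sprintf("fold %s=%g skipped for model %d (unidentifiable)",
                        folds$var[k], folds$level[k], id))
        fold_rows[[length(fold_rows) + 1L]] <-
          data.frame(model_id = id, var = folds$var[k],
                     level = folds$level[k], rmse = NA_real_,
                     mae = NA_real_, n_test = sum(held))
        next
      }
      pred <- predict_performance(fit, d[held, , drop = FALSE])$estimate
      err <- pred - d[[response]][held]
      fold_rows[[length(fold_rows) + 1L]] <-
        data.frame(model_id = id, var = folds$var[k], level = folds$level[k],
                   rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
                   n_test = sum(held))
    }
  }
  fold_df <- do.call(rbind, fold_rows)
  agg <- do.call(rbind, lapply(model_ids, function(id) {
    f <- fold_df[fold_df$model_id == id & !is.na(fold_df$rmse), ]
    data.frame(model_id = id,
               rmse = if (nrow(f) > 0L) mean(f$rmse) else NA_real_,
               mae = if (nrow(f) > 0L) mean(f$mae) else NA_real_,
               n_folds = nrow(f))
  }))
  structure(agg, folds = fold_df, response = response,
            class = c("svperf_cv", "data.frame"))
}

#' Select the simplest among similarly accurate candidate models
#'
#' Models whose average RMSE (and MAE, when available) are within
#' \code{tolerance} of the respective minima form the tie set; within it
#' the model with the fewest smooth terms wins, remaining ties broken by
#' fewer variables inside smooths, then by the higher model id (the more
#' constrained form). A unique error minimum wins regardless of
#' complexity.
#'
#' @param cv a \code{\link{cross_validate}} result, or any data frame with
#'   columns \code{model_id}, \code{rmse} and optionally \code{mae}.
#' @param tolerance slack defining "similarly low" (default 0.0005,
#'   i.e. equality at three printed decimals).
#' @return the selected model id (integer).
#' @export
select_model <- function(cv, tolerance = 5e-4) {
  cv <- as.data.frame(cv)
  stopifnot(all(c("model_id", "rmse") %in% names(cv)), nrow(cv) > 0L)
  cv <- cv[order(cv$model_id), ]
  cv <- cv[is.finite(cv$rmse), ]  # models with no scored fold drop out
  if (nrow(cv) == 0L) stop("no candidate model could be scored")
  tie <- cv$rmse <= min(cv$rmse) + tolerance
  if ("mae" %in% names(cv) && !anyNA(cv$mae))
    tie <- tie & cv$mae <= min(cv$mae) + tolerance
  cand <- cv$model_id[tie]
  cx <- t(vapply(cand, model_complexity, numeric(3L)))
  cand[order(cx[, 1L], cx[, 2L], cx[, 3L])][1L]
}

#' Drop linear terms with no significant effect
#'
#' Refits without linear terms whose Wald p-value is at or above
#' \code{alpha} (smooth terms are never pruned); returns the original fit
#' when nothing is pruned.
#'
#' @param fitted a \code{\link{fit_perf_model}} result.
#' @param alpha significance level (default 0.05).
#' @param table the training table (defaults to the data stored in the
#'   gam fit).
#' @return a \code{svperf_fit}, refitted if any term was dropped.
#' @export
prune_insignificant_terms <- function(fitted, alpha = 0.05, table = NULL) {
  stopifnot(inherits(fitted, "svperf_fit"))
  lin <- fitted$spec$linear_terms
  if (length(lin) == 0L) return(fitted)
  pt <- summary(fitted$gam)$p.table
  pv <- stats::setNames(pt[, 4L], rownames(pt))
  pv <- pv[names(pv) %in% lin]
  drop <- names(pv)[pv >= alpha]
  if (length(drop) == 0L) return(fitted)
  spec <- fitted$spec
  spec$linear_terms <- setdiff(spec$linear_terms, drop)
  d <- table %||% fitted$gam$model
  if (".response" %in% names(d) && !fitted$response %in% names(d))
    d[[fitted$response]] <- d$.response
  refit <- fit_perf_model(d, spec, fitted$response)
  refit$pruned <- drop
  refit
}

#' Minimum predictor value achieving a target performance
#'
#' Grid-searches the free predictor (step 1x for coverages, 0.01 for VAF,
#' 1 bp for the threshold) over the training range, the other three held
#' fixed, and returns the smallest value whose predicted response meets
#' the target, or NA when the target is unachievable within the range.
#'
#' @param fitted a \code{\link{fit_perf_model}} result.
#' @param target required performance level in [0, 1].
#' @param free_var one of \code{"vaf"}, \code{"tumour_cov"},
#'   \code{"normal_cov"}, \code{"t_threshold"}.
#' @param fixed named list/one-row data frame fixing the other three
#'   predictors.
#' @param step search step; defaults to 1 for coverages and the
#'   threshold, 0.01 for VAF.
#' @return list with \code{value} (numeric or NA), \code{achievable}
#'   (logical) and \code{predicted} (the response at \code{value}).
#' @export
minimum_requirement <- function(fitted, target, free_var, fixed,
                                step = NULL) {
  stopifnot(inherits(fitted, "svperf_fit"),
            free_var %in% PREDICTOR_VARS, target >= 0, target <= 1)
  fixed <- as.list(fixed)
  others <- setdiff(PREDICTOR_VARS, free_var)
  missing_vars <- setdiff(others, names(fixed))
  if (length(missing_vars) > 0L)
    stop("fixed must specify: ", paste(missing_vars, collapse = ", "))
  if (is.null(step)) step <- if (free_var == "vaf") 0.01 else 1
  r <- fitted$ranges[[free_var]]
  grid_vals <- seq(r[1], r[2], by = step)
  points <- data.frame(v = grid_vals)
  names(points) <- free_var
  for (v in others) points[[v]] <- fixed[[v]]
  pred <- predict_performance(fitted, points)$estimate
  hit <- which(pred >= target)
  if (length(hit) == 0L)
    return(list(value = NA_real_, achievable = FALSE,
                predicted = NA_real_))
  list(value = grid_vals[hit[1L]], achievable = TRUE,
       predicted = pred[hit[1L]])
}
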