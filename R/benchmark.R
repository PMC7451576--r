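## Benchmarking engine: classify calls against a truth set under the
## two-part true-positive criterion — (i) reported type acceptable for the
## truth type, (ii) every breakend of the event within T bp of its assigned
## truth breakend — and compute sensitivity / precision / F1 overall and
## per SV type, plus breakpoint-resolution profiles.

## |pos - pos'| on the same chromosome, Inf across chromosomes
breakend_dist <- function(chrom_a, pos_a, chrom_b, pos_b) {
  d <- abs(outer(pos_a, pos_b, "-"))
  d[outer(chrom_a, chrom_b, "!=")] <- Inf
  d
}

## Assignment distance between call records and truth records: each call
## breakend is assigned to a truth breakend by the pairing minimizing the
## maximum per-breakend distance (both orderings tried for two-breakend
## events). A single-breakend call (unmated BND) is matched on its one
## breakend against the nearer truth breakend. Returns a calls x truth
## matrix of distances.
assignment_dist <- function(calls, truth) {
  d11 <- breakend_dist(calls$chrom1, calls$pos1, truth$chrom1, truth$pos1)
  d12 <- breakend_dist(calls$chrom1, calls$pos1, truth$chrom2, truth$pos2)
  ## single-breakend calls: unmated BNDs, and point events (e.g. an
  ## insertion reported as one position) — matched on the nearer truth
  ## breakend
  unmated <- is.na(calls$chrom2) |
    (calls$chrom1 == calls$chrom2 & calls$pos1 == calls$pos2)
  unmated[is.na(unmated)] <- TRUE
  if (all(unmated)) return(pmin(d11, d12))
  c2 <- ifelse(unmated, calls$chrom1, calls$chrom2)
  p2 <- ifelse(unmated, calls$pos1, calls$pos2)
  d21 <- breakend_dist(c2, p2, truth$chrom1, truth$pos1)
  d22 <- breakend_dist(c2, p2, truth$chrom2, truth$pos2)
  d <- pmin(pmax(d11, d22), pmax(d12, d21))
  if (any(unmated)) d[unmated, ] <- pmin(d11, d12)[unmated, , drop = FALSE]
  d
}

## T-independent nearest-truth assignment: for every call, the compatible
## truth record minimizing the assignment distance. Compatibility: the
## call's reported type is acceptable for the truth type under the profile.
## Returns list(call_best = data.frame(truth_idx, distance),
##              truth_best = per-truth min distance over assigned calls).
## single-breakend records get the breakend duplicated so they can stand
## on the "truth" side of assignment_dist
fill_single_breakends <- function(x) {
  nm <- is.na(x$chrom2)
  if (any(nm)) {
    x$chrom2[nm] <- x$chrom1[nm]
    x$pos2[nm] <- x$pos1[nm]
  }
  x
}

sv_match_assignment <- function(truth, calls, profile) {
  n_c <- nrow(calls); n_t <- nrow(truth)
  truth <- fill_single_breakends(truth)
  best_idx <- rep(NA_integer_, n_c)
  best_d <- rep(Inf, n_c)
  if (n_c > 0L && n_t > 0L) {
    for (rt in unique(calls$sv_type)) {
      ci <- which(calls$sv_type == rt)
      compat_tt <- names(Filter(function(acc) rt %in% acc,
                                profile$type_equivalences))
      ti <- which(truth$sv_type %in% compat_tt)
      if (length(ti) == 0L) next
      d <- assignment_dist(calls[ci, , drop = FALSE],
                           truth[ti, , drop = FALSE])
      j <- max.col(-d, ties.method = "first")
      dm <- d[cbind(seq_along(ci), j)]
      hit <- is.finite(dm)
      best_idx[ci[hit]] <- ti[j[hit]]
      best_d[ci[hit]] <- dm[hit]
    }
  }
  truth_best <- rep(Inf, n_t)
  if (n_t > 0L && any(!is.na(best_idx))) {
    agg <- tapply(best_d[!is.na(best_idx)], best_idx[!is.na(best_idx)], min)
    truth_best[as.integer(names(agg))] <- agg
  }
  list(call_idx = best_idx, call_dist = best_d, truth_best = truth_best)
}

#' Classify calls against a truth set at a breakpoint-precision threshold
#'
#' A call is a true positive iff (i) its reported SV type is acceptable for
#' the truth record's type under the profile's type equivalences and
#' (ii) all of its breakend positions are within \code{t_threshold} bp of
#' the assigned truth breakends (breakends are assigned by the pairing
#' minimizing the maximum per-breakend distance; breakends on different
#' chromosomes are infinitely distant). Every non-TP call is a false
#' positive. A truth record is detected iff at least one call pairs to it;
#' a truth event may absorb multiple TP calls but counts once for
#' sensitivity.
#'
#' @param truth,calls \code{\link{sv_callset}} objects.
#' @param t_threshold breakpoint precision threshold T in bp (>= 0).
#' @param profile a \code{\link{caller_profile}}; defaults to strict type
#'   identity plus the DINS/FINS -> INS equivalence.
#' @return object of class \code{svperf_match} with per-call labels
#'   (TP/FP), per-truth labels (DETECTED/MISSED), the call -> truth pairing
#'   and the matching distances.
#' @export
classify_calls <- function(truth, calls, t_threshold,
                           profile = identity_profile()) {
  stopifnot(is_sv_callset(truth), is_sv_callset(calls), t_threshold >= 0)
  a <- sv_match_assignment(truth, calls, profile)
  tp <- !is.na(a$call_idx) & a$call_dist <= t_threshold
  call_df <- data.frame(
    id = calls$id, reported_type = calls$sv_type,
    label = ifelse(tp, "TP", "FP"),
    truth_id = ifelse(tp, truth$id[a$call_idx], NA_character_),
    distance = ifelse(is.finite(a$call_dist), a$call_dist, NA_real_),
    stringsAsFactors = FALSE)
  truth_df <- data.frame(
    id = truth$id, sv_type = truth$sv_type,
    label = ifelse(a$truth_best <= t_threshold, "DETECTED", "MISSED"),
    best_distance = ifelse(is.finite(a$truth_best), a$truth_best, NA_real_),
    stringsAsFactors = FALSE)
  structure(list(calls = call_df, truth = truth_df,
                 t_threshold = t_threshold,
                 n_truth = nrow(truth), n_calls = nrow(calls),
                 profile = profile$name),
            class = "svperf_match")
}

#' @export
print.svperf_match <- function(x, ...) {
  cat(sprintf(paste0("<svperf_match> T=%g bp: %d/%d truth detected, ",
                     "%d TP / %d FP calls\n"),
              x$t_threshold, sum(x$truth$label == "DETECTED"), x$n_truth,
              sum(x$calls$label == "TP"), sum(x$calls$label == "FP")))
  invisible(x)
}

metrics_from_counts <- function(tp_event, fn, tp_call, fp, n_truth, n_calls) {
  sens <- if (n_truth > 0L) tp_event / n_truth else NA_real_
  prec <- if (n_calls > 0L) tp_call / n_calls else NA_real_
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
    2 * sens * prec / (sens + prec) else NA_real_
  data.frame(tp_event = tp_event, tp_call = tp_call, fp = fp, fn = fn,
             sensitivity = sens, precision = prec, f1 = f1)
}

#' Compute sensitivity, precision and F1 from a match result
#'
#' sensitivity = detected truth / total truth, precision = TP calls / total
#' calls, F1 = 2sp/(s+p). Precision is missing (NA) for an empty callset;
#' F1 is missing when either input is missing or both are zero.
#'
#' @param match result of \code{\link{classify_calls}}.
#' @return one-row data frame with counts and metrics
#'   (\code{sv_type_scope = "ALL"}).
#' @export
compute_metrics <- function(match) {
  stopifnot(inherits(match, "svperf_match"))
  tp_event <- sum(match$truth$label == "DETECTED")
  tp_call <- sum(match$calls$label == "TP")
  cbind(sv_type_scope = "ALL",
        metrics_from_counts(tp_event, match$n_truth - tp_event, tp_call,
                            match$n_calls - tp_call, match$n_truth,
                            match$n_calls),
        stringsAsFactors = FALSE)
}

## the pooled precision group a truth type belongs to under a profile, or
## NA when the type is not reportable
precision_group_of <- function(profile, truth_type) {
  acc <- profile$type_equivalences[[truth_type]]
  if (length(acc) == 0L) return(NA_character_)
  for (g in names(profile$precision_groups))
    if (any(acc %in% profile$precision_groups[[g]])) return(g)
  NA_character_
}

#' Per-SV-type benchmark metrics
#'
#' Sensitivity is reported per truth type (DEL, DUP, INV, DINS, FINS,
#' TRA). Precision is reported for the pooled reported-type group the
#' truth type maps to: domestic and foreign insertions pool as generic
#' INS, and a profile that cannot distinguish DUP from INS pools DUP/INS.
#' Per-type F1 combines the type's sensitivity with the pooled precision.
#' Types the profile cannot report get missing precision and F1.
#'
#' @inheritParams classify_calls
#' @return data frame with one row per truth type plus an "ALL" row;
#'   columns as in \code{\link{compute_metrics}} plus
#'   \code{precision_group}.
#' @export
per_type_metrics <- function(truth, calls, t_threshold,
                             profile = identity_profile()) {
  match <- classify_calls(truth, calls, t_threshold, profile)
  group_stats <- function(g) {
    in_g <- match$calls$reported_type %in% profile$precision_groups[[g]]
    c(n = sum(in_g), tp = sum(in_g & match$calls$label == "TP"))
  }
  rows <- lapply(TRUTH_SV_TYPES, function(tt) {
    in_t <- match$truth$sv_type == tt
    n_t <- sum(in_t)
    det <- sum(in_t & match$truth$label == "DETECTED")
    g <- precision_group_of(profile, tt)
    if (!is.na(g)) {
      gs <- group_stats(g)
      m <- metrics_from_counts(det, n_t - det, gs[["tp"]],
                               gs[["n"]] - gs[["tp"]], n_t, gs[["n"]])
    } else {
      m <- metrics_from_counts(det, n_t - det, 0L, 0L, n_t, 0L)
    }
    cbind(sv_type_scope = tt, m, precision_group = if (is.na(g)) NA_character_
          else g, stringsAsFactors = FALSE)
  })
  all_row <- cbind(compute_metrics(match), precision_group = "ALL",
                   stringsAsFactors = FALSE)
  out <- rbind(all_row, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Breakpoint-resolution profile
#'
#' Cumulative count of detected truth events at every integer breakpoint
#' precision threshold 0..\code{t_max}: the value at T equals the
#' detected-truth count \code{\link{classify_calls}} would report at that
#' T, and is non-decreasing in T.
#'
#' @inheritParams classify_calls
#' @param t_max largest threshold (bp).
#' @return data frame with columns \code{t_threshold} and \code{tp_events}.
#' @export
resolution_profile <- function(truth, calls, t_max,
                               profile = identity_profile()) {
  stopifnot(is_sv_callset(truth), is_sv_callset(calls), t_max >= 0)
  a <- sv_match_assignment(truth, calls, profile)
  bd <- sort(a$truth_best[is.finite(a$truth_best)])
  tt <- 0:t_max
  data.frame(t_threshold = tt, tp_events = findInterval(tt, bd))
}
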