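## Synthetic study design: the simulation parameter grid, a miniature
## masked genome, truth-set generation, and a caller emulator with known
## detection / breakpoint-jitter / false-positive behaviour. The emulator
## stands in for the read-simulation + alignment + caller stage so the
## benchmark and modelling layers can run end-to-end with no external
## data; the modelling layer only ever consumes evaluation tables.

#' Design grid of simulation parameter values
#'
#' @param normal_covs,tumour_covs numeric vectors of fold coverages (> 0).
#' @param vafs numeric vector of variant allele fractions in (0, 1].
#' @param t_thresholds numeric vector of breakpoint precision thresholds
#'   (bp, >= 0).
#' @return object of class \code{svperf_grid}.
#' @export
design_grid <- function(normal_covs, tumour_covs, vafs, t_thresholds) {
  for (v in list(normal_covs, tumour_covs, vafs, t_thresholds))
    if (length(v) == 0L) stop("design grid lists must be non-empty")
  stopifnot(all(normal_covs > 0), all(tumour_covs > 0),
            all(vafs > 0), all(vafs <= 1), all(t_thresholds >= 0))
  structure(list(normal_covs = normal_covs, tumour_covs = tumour_covs,
                 vafs = vafs, t_thresholds = t_thresholds),
            class = "svperf_grid")
}

#' The published simulation grid
#'
#' Normal and tumour coverages 20x--100x in steps of 10, VAF 0.05 and
#' 0.1--1.0 in steps of 0.1, and twelve breakpoint precision thresholds
#' (2, 10, 20, ..., 200 bp): 891 tumour/normal coverage-VAF
#' configurations and 10,692 predictor permutations in all.
#'
#' @return a \code{\link{design_grid}}.
#' @export
published_design_grid <- function() {
  design_grid(normal_covs = seq(20, 100, by = 10),
              tumour_covs = seq(20, 100, by = 10),
              vafs = c(0.05, seq(0.1, 1.0, by = 0.1)),
              t_thresholds = c(2, 10, seq(20, 200, by = 20)))
}

#' Enumerate all parameter combinations of a design grid
#'
#' Cartesian product in deterministic lexicographic order (VAF varies
#' slowest, then tumour coverage, normal coverage, threshold).
#'
#' @param grid a \code{\link{design_grid}}.
#' @param include_threshold include the breakpoint precision threshold as
#'   a fourth column (default TRUE); with \code{FALSE} the enumeration is
#'   over (VAF, tumour, normal) configurations only.
#' @return data frame with columns \code{vaf, tumour_cov, normal_cov} and
#'   (optionally) \code{t_threshold}.
#' @export
enumerate_grid <- function(grid, include_threshold = TRUE) {
  stopifnot(inherits(grid, "svperf_grid"))
  if (include_threshold) {
    d <- expand.grid(t_threshold = grid$t_thresholds,
                     normal_cov = grid$normal_covs,
                     tumour_cov = grid$tumour_covs,
                     vaf = grid$vafs, KEEP.OUT.ATTRS = FALSE)
    d[, c("vaf", "tumour_cov", "normal_cov", "t_threshold")]
  } else {
    d <- expand.grid(normal_cov = grid$normal_covs,
                     tumour_cov = grid$tumour_covs,
                     vaf = grid$vafs, KEEP.OUT.ATTRS = FALSE)
    d[, c("vaf", "tumour_cov", "normal_cov")]
  }
}

#' Genome mask: allowed placement intervals per chromosome
#'
#' The allowed space is each chromosome minus N-gap and centromere
#' intervals and minus a telomeric flank at both ends. Interval arithmetic
#' is 1-based inclusive.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param masked optional data frame of masked intervals with columns
#'   \code{chrom, start, end} (1-based inclusive), e.g. N-gaps and
#'   centromeres.
#' @param telomere_flank width (bp) masked at both ends of every
#'   chromosome.
#' @return object of class \code{svperf_mask} with element \code{allowed},
#'   a data frame of disjoint intervals \code{chrom, start, end}.
#' @export
genome_mask <- function(chrom_lengths, masked = NULL, telomere_flank = 0) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0),
            telomere_flank >= 0)
  allowed <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    span <- IRanges::IRanges(start = 1L + telomere_flank,
                             end = len - telomere_flank)
    if (IRanges::width(span) <= 0)
      return(NULL)
    bad <- if (!is.null(masked)) masked[masked$chrom == ch, , drop = FALSE]
           else NULL
    if (!is.null(bad) && nrow(bad) > 0L) {
      span <- IRanges::setdiff(
        span, IRanges::reduce(IRanges::IRanges(start = bad$start,
                                               end = bad$end)))
    }
    if (length(span) == 0L) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(span),
               end = IRanges::end(span), stringsAsFactors = FALSE)
  }))
  structure(list(chrom_lengths = chrom_lengths, allowed = allowed),
            class = "svperf_mask")
}

#' Read mask intervals from BED files
#'
#' BED is 0-based half-open; intervals are converted to 1-based inclusive.
#'
#' @param paths character vector of BED file paths (e.g. N-gaps and
#'   centromeres).
#' @return data frame \code{chrom, start, end} suitable for
#'   \code{\link{genome_mask}}.
#' @export
read_mask_bed <- function(paths) {
  do.call(rbind, lapply(paths, function(p) {
    gr <- rtracklayer::import(p, format = "BED")
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),  # import() already 1-based
               end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  }))
}

#' Default miniature masked genome
#'
#' Two 25-Mbp chromosomes with a 1-Mbp planted N-gap, a 2-Mbp central
#' centromere block and 1-Mbp telomeric flanks. A scaled-down stand-in for
#' a masked reference assembly: large enough to hold full published-scale truth-set
#' counts, small enough for desk-scale runs.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param telomere_flank telomere mask width (bp).
#' @return a \code{\link{genome_mask}}.
#' @export
miniature_genome <- function(n_chrom = 2, chrom_length = 25e6,
                             telomere_flank = 1e6) {
  lens <- stats::setNames(rep(chrom_length, n_chrom),
                          paste0("chr", seq_len(n_chrom)))
  cen_half <- round(chrom_length * 0.04)
  masked <- do.call(rbind, lapply(names(lens), function(ch) {
    mid <- round(chrom_length / 2)
    rbind(
      data.frame(chrom = ch, start = mid - cen_half, end = mid + cen_half),
      data.frame(chrom = ch, start = round(chrom_length * 0.2),
                 end = round(chrom_length * 0.2) + 1e6)  # planted N-gap
    )
  }))
  genome_mask(lens, masked = masked, telomere_flank = telomere_flank)
}

#' Truth-set composition specification
#'
#' @param somatic_per_type,germline_per_type records per SV type (the
#'   published design simulates 200 somatic and 2,000 germline of each of
#'   six types: 1,200 + 12,000 records).
#' @param types truth SV types to simulate.
#' @param length_range SV length range (bp); must lie within
#'   [50, 1,000,000]. Lengths are drawn log-uniformly. The default upper
#'   bound is scaled to the miniature genome.
#' @return object of class \code{svperf_truth_spec}.
#' @export
truth_set_spec <- function(somatic_per_type = 200, germline_per_type = 2000,
                           types = TRUTH_SV_TYPES,
                           length_range = c(50, 5000)) {
  stopifnot(somatic_per_type >= 0, germline_per_type >= 0,
            length_range[1] >= 50, length_range[2] <= 1e6,
            length_range[1] <= length_range[2],
            all(types %in% TRUTH_SV_TYPES))
  structure(list(somatic_per_type = somatic_per_type,
                 germline_per_type = germline_per_type,
                 types = types, length_range = length_range),
            class = "svperf_truth_spec")
}

## log-uniform SV lengths
draw_lengths <- function(n, range) {
  if (n == 0L) return(integer())
  pmax(as.integer(round(exp(stats::runif(n, log(range[1]), log(range[2]))))),
       as.integer(range[1]))
}

## Place n non-overlapping segments of the given footprints uniformly in
## the allowed intervals: capacity-weighted assignment of segments to
## intervals with bounded retries, then the sorted-uniform-offset
## construction within each interval (exact uniform placement of
## non-overlapping segments, no rejection loop).
place_segments <- function(footprints, mask, max_tries = 50L) {
  n <- length(footprints)
  iv <- mask$allowed
  w <- iv$end - iv$start + 1
  if (sum(footprints) > sum(w))
    stop("mask capacity insufficient: need ", sum(footprints),
         " bp, have ", sum(w))
  for (try in seq_len(max_tries)) {
    assign <- sample.int(nrow(iv), n, replace = TRUE, prob = w)
    load <- tapply(footprints, factor(assign, levels = seq_len(nrow(iv))),
                   sum, default = 0)
    if (all(load <= w)) {
      start <- integer(n)
      for (k in which(load > 0)) {
        idx <- which(assign == k)
        l <- footprints[idx]
        free <- w[k] - sum(l)
        off <- sort(stats::runif(length(idx), 0, free))
        start[idx] <- as.integer(iv$start[k] + floor(off) +
                                   c(0, cumsum(l))[seq_along(l)])
      }
      return(data.frame(chrom = iv$chrom[assign], start = start,
                        footprint = footprints, stringsAsFactors = FALSE))
    }
  }
  stop("mask capacity insufficient after ", max_tries,
       " placement attempts (intervals too fragmented for the requested ",
       "counts and lengths)")
}

## build breakend records for one truth set
build_truth_records <- function(types, lengths, mask, prefix) {
  n <- length(types)
  if (n == 0L) return(sv_callset(NULL, source = prefix))
  ## placement items: main segment per record; DINS/TRA add an insertion
  ## site point; FINS occupies only its insertion site
  main_fp <- ifelse(types == "FINS", 1L, lengths + 1L)
  two_locus <- types %in% c("DINS", "TRA")
  fp <- c(main_fp, rep(1L, sum(two_locus)))
  placed <- place_segments(fp, mask)
  main <- placed[seq_len(n), ]
  site <- placed[-seq_len(n), , drop = FALSE]
  chrom1 <- main$chrom; pos1 <- main$start
  chrom2 <- main$chrom; pos2 <- main$start + lengths
  ## FINS: two identical-position breakends at the insertion site
  fins <- types == "FINS"
  pos2[fins] <- pos1[fins]
  ## DINS/TRA: breakend 1 is the insertion/fusion site, breakend 2 the
  ## source fragment start
  if (any(two_locus)) {
    k <- cumsum(two_locus)
    chrom2[two_locus] <- chrom1[two_locus]
    pos2[two_locus] <- pos1[two_locus]
    chrom1[two_locus] <- site$chrom[k[two_locus]]
    pos1[two_locus] <- site$start[k[two_locus]]
  }
  sv_callset(data.frame(
    chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2, pos2 = pos2,
    sv_type = types, sv_length = lengths,
    id = sprintf("%s_%s_%05d", prefix, types,
                 stats::ave(seq_len(n), types, FUN = seq_along)),
    stringsAsFactors = FALSE), source = prefix)
}

#' Simulate somatic and germline truth SV sets on a masked genome
#'
#' Per-type counts follow the specification exactly; breakends fall only
#' inside allowed intervals; lengths are log-uniform over the specified
#' range; records do not overlap within a set; output is deterministic
#' for a fixed seed.
#'
#' @param spec a \code{\link{truth_set_spec}}.
#' @param mask a \code{\link{genome_mask}}.
#' @param seed integer RNG seed.
#' @return list with elements \code{somatic} and \code{germline}, both
#'   \code{\link{sv_callset}} objects.
#' @export
simulate_truth_sets <- function(spec, mask = miniature_genome(), seed = 1L) {
  stopifnot(inherits(spec, "svperf_truth_spec"),
            inherits(mask, "svperf_mask"))
  withr::with_seed(seed, {
    one_set <- function(per_type, prefix) {
      types <- rep(spec$types, each = per_type)
      lens <- draw_lengths(length(types), spec$length_range)
      build_truth_records(types, lens, mask, prefix)
    }
    list(somatic = one_set(spec$somatic_per_type, "som"),
         germline = one_set(spec$germline_per_type, "grm"))
  })
}

## closed-form emulator detection probability at a parameter point
emulator_detection_p <- function(emu, vaf, tumour_cov, normal_cov) {
  stats::plogis(emu$beta0 + emu$beta1 * log(vaf * tumour_cov) +
                  emu$beta2 * vaf + emu$beta3 / normal_cov)
}

## P(|two-sided geometric jitter| <= t) for one breakend
jitter_within_p <- function(scale, t) {
  if (scale <= 0) return(rep(1, length(t)))
  prob <- 1 / (1 + scale)
  stats::pgeom(t, prob)
}

#' Closed-form expected sensitivity of the emulator
#'
#' Detection probability times the chance the jittered breakends stay
#' within T, averaged over the truth-type mix: two-breakend events need
#' both jitters within T (probability q^2), point-reported insertions
#' (DINS/FINS reported as generic INS) need one (q), and types the
#' profile cannot report contribute zero. Used as the independent truth
#' surface when checking model recovery.
#'
#' @param profile a \code{\link{caller_profile}}.
#' @param vaf,tumour_cov,normal_cov,t_threshold parameter point
#'   (vectorized).
#' @param types the truth-type mix (equal counts assumed).
#' @return expected sensitivity.
#' @export
emulator_expected_sensitivity <- function(profile, vaf, tumour_cov,
                                          normal_cov, t_threshold,
                                          types = TRUTH_SV_TYPES) {
  emu <- profile$emulator
  q <- jitter_within_p(emu$jitter_scale, t_threshold)
  per_type <- vapply(types, function(tt) {
    r <- profile$report_map[[tt]]
    if (is.null(r)) return(rep(0, length(q)))
    if (r == "INS") q else q^2
  }, numeric(length(q)))
  emulator_detection_p(emu, vaf, tumour_cov, normal_cov) *
    rowMeans(matrix(per_type, nrow = length(q)))
}

two_sided_geom <- function(n, scale) {
  if (scale <= 0 || n == 0L) return(integer(n))
  mag <- stats::rgeom(n, 1 / (1 + scale))
  sign <- sample(c(-1L, 1L), n, replace = TRUE)
  as.integer(mag * sign)
}

#' Emulate a caller's output at one design point
#'
#' Each somatic truth record is emitted independently with the profile's
#' logistic detection probability; emitted breakends are jittered by
#' two-sided geometric displacements with the profile's jitter scale
#' (larger scale = lower breakpoint resolution); reported types follow the
#' profile's reporting map (e.g. domestic/foreign insertions reported as
#' generic INS, or not at all). False positives are added as
#' Poisson(rate * (1 + c / tumour coverage)) random records in allowed
#' space, and germline records leak through with a small probability to
#' emulate imperfect somatic filtering. Deterministic for a fixed seed.
#'
#' @param somatic,germline truth \code{\link{sv_callset}} objects.
#' @param point one-row data frame (or list) with \code{vaf, tumour_cov,
#'   normal_cov}.
#' @param profile a \code{\link{caller_profile}} with emulator parameters.
#' @param mask the \code{\link{genome_mask}} used for FP placement.
#' @param seed integer RNG seed.
#' @return an \code{\link{sv_callset}} of emulated calls.
#' @export
emulate_caller <- function(somatic, germline, point, profile,
                           mask = miniature_genome(), seed = 1L) {
  emu <- profile$emulator
  if (is.null(emu)) stop("profile ", profile$name, " has no emulator_params")
  withr::with_seed(seed, {
    emit_from_truth <- function(truth, p) {
      reported <- vapply(truth$sv_type, function(tt) {
        r <- profile$report_map[[tt]]
        if (is.null(r)) NA_character_ else r
      }, character(1L), USE.NAMES = FALSE)
      keep <- !is.na(reported) & stats::runif(nrow(truth)) < p
      rec <- as.data.frame(truth)[keep, , drop = FALSE]
      if (nrow(rec) == 0L) return(rec[0L, ])
      rec$sv_type <- reported[keep]
      rec$pos1 <- pmax(1L, rec$pos1 + two_sided_geom(nrow(rec),
                                                     emu$jitter_scale))
      rec$pos2 <- pmax(1L, rec$pos2 + two_sided_geom(nrow(rec),
                                                     emu$jitter_scale))
      ## an insertion call is a single reported position (the insertion
      ## site, breakend 1 of the truth record)
      pt <- rec$sv_type == "INS"
      rec$chrom2[pt] <- rec$chrom1[pt]
      rec$pos2[pt] <- rec$pos1[pt]
      rec
    }
    p_det <- emulator_detection_p(emu, point$vaf, point$tumour_cov,
                                  point$normal_cov)
    som <- emit_from_truth(somatic, p_det)
    leak <- emit_from_truth(germline, emu$germline_leak)
    n_fp <- stats::rpois(1L, emu$fp_rate *
                           (1 + emu$fp_cov_coef / point$tumour_cov))
    fp <- if (n_fp > 0L) {
      lens <- draw_lengths(n_fp, c(50, 2000))
      placed <- place_segments(lens + 1L, mask)
      rep_types <- unique(unlist(profile$report_map))
      data.frame(chrom1 = placed$chrom, pos1 = placed$start,
                 chrom2 = placed$chrom, pos2 = placed$start + lens,
                 sv_type = sample(rep_types, n_fp, replace = TRUE),
                 sv_length = lens, id = sprintf("fp_%05d", seq_len(n_fp)),
                 stringsAsFactors = FALSE)
    } else NULL
    rec <- rbind(som, leak, fp)
    if (!is.null(rec) && nrow(rec) > 0L)
      rec$id <- sprintf("call_%05d", seq_len(nrow(rec)))
    sv_callset(rec, source = profile$name)
  })
}

#' Build an evaluation table over a design grid
#'
#' For every profile and every (VAF, tumour, normal) configuration the
#' caller is emulated once; the same emulated callset is then benchmarked
#' at each breakpoint precision threshold of the grid (matching the study
#' design, where thresholds are applied to a fixed callset). Rows are
#' reproducible for fixed seeds.
#'
#' @param grid a \code{\link{design_grid}}.
#' @param truth list with \code{somatic} and \code{germline} callsets, as
#'   returned by \code{\link{simulate_truth_sets}}.
#' @param profiles named list of \code{\link{caller_profile}} objects.
#' @param mask the \code{\link{genome_mask}}.
#' @param seed integer base seed; per-point seeds are derived from it.
#' @param per_type also emit per-SV-type rows (default FALSE).
#' @return an \code{\link{eval_table}}.
#' @export
build_evaluation_table <- function(grid, truth, profiles,
                                   mask = miniature_genome(), seed = 1L,
                                   per_type = FALSE) {
  stopifnot(inherits(grid, "svperf_grid"))
  pairs <- enumerate_grid(grid, include_threshold = FALSE)
  rows <- list()
  for (pn in seq_along(profiles)) {
    profile <- profiles[[pn]]
    for (i in seq_len(nrow(pairs))) {
      point <- pairs[i, ]
      point_seed <- (seed + 7919L * (pn - 1L) + i) %% .Machine$integer.max
      calls <- emulate_caller(truth$somatic, truth$germline, point, profile,
                              mask, seed = point_seed)
      a <- if (!per_type) sv_match_assignment(truth$somatic, calls, profile)
      for (t in grid$t_thresholds) {
        m <- if (per_type) {
          per_type_metrics(truth$somatic, calls, t, profile)
        } else {
          ## reuse the T-independent assignment across thresholds
          tp_event <- sum(a$truth_best <= t)
          tp_call <- sum(a$call_dist <= t)
          cbind(sv_type_scope = "ALL",
                metrics_from_counts(tp_event, nrow(truth$somatic) - tp_event,
                                    tp_call, nrow(calls) - tp_call,
                                    nrow(truth$somatic), nrow(calls)),
                stringsAsFactors = FALSE)
        }
        m$precision_group <- NULL
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(callset = profile$name, vaf = point$vaf,
                     tumour_cov = point$tumour_cov,
                     normal_cov = point$normal_cov, t_threshold = t,
                     stringsAsFactors = FALSE),
          m)
      }
    }
  }
  out <- do.call(rbind, rows)
  eval_table(out[, c("callset", "vaf", "tumour_cov", "normal_cov",
                     "t_threshold", "sv_type_scope", "tp_event", "tp_call",
                     "fp", "fn", "sensitivity", "precision", "f1")])
}
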