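## Caller capability profiles: which truth types a caller can report, how it
## labels them, how precision is pooled across reported types, and the
## parameters driving the synthetic caller emulator.

#' Construct a caller profile
#'
#' A profile captures (i) a caller's capability map — which truth SV types
#' it reports and under which labels (e.g. domestic/foreign insertions both
#' reported as generic \code{INS}), (ii) how per-type precision is pooled
#' (insertion precision is computed for generic \code{INS}; a caller that
#' cannot distinguish duplications from insertions pools \code{DUP/INS}),
#' and (iii) emulator parameters: a logistic detection surface over
#' (VAF, tumour coverage, normal coverage), a geometric breakpoint-jitter
#' scale, a false-positive intensity, and a germline leak-through rate.
#'
#' The detection surface is
#' \deqn{p = logit^{-1}(\beta_0 + \beta_1 \log(VAF \cdot C_t) + \beta_2 VAF
#'   + \beta_3 / C_n)}
#' with \eqn{C_t, C_n} the tumour and normal coverages.
#'
#' @param name profile label.
#' @param type_equivalences named list: truth type -> character vector of
#'   acceptable reported types (empty vector = not reportable).
#' @param report_map named list: truth type -> the single label the
#'   emulator emits for it (\code{NULL} entries = not reportable).
#' @param precision_groups named list: pooled precision group label ->
#'   reported types counted in that group.
#' @param emulator list with elements \code{beta0, beta1, beta2, beta3,
#'   jitter_scale} (bp), \code{fp_rate} (Poisson intensity),
#'   \code{fp_cov_coef} (coverage dependence of the FP intensity) and
#'   \code{germline_leak} (per-record leak probability).
#' @return object of class \code{svperf_profile}.
#' @export
caller_profile <- function(name,
                           type_equivalences = default_type_equivalences(),
                           report_map = default_report_map(),
                           precision_groups = default_precision_groups(),
                           emulator = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  missing_types <- setdiff(TRUTH_SV_TYPES, names(type_equivalences))
  if (length(missing_types) > 0L)
    stop("type_equivalences must cover every truth type; missing: ",
         paste(missing_types, collapse = ", "))
  structure(list(name = name,
                 type_equivalences = type_equivalences,
                 report_map = report_map,
                 precision_groups = precision_groups,
                 emulator = emulator),
            class = "svperf_profile")
}

#' @export
print.svperf_profile <- function(x, ...) {
  reportable <- names(Filter(function(v) length(v) > 0L, x$type_equivalences))
  cat(sprintf("<svperf_profile> %s\n  reportable truth types: %s\n",
              x$name, paste(reportable, collapse = ", ")))
  cat("  precision groups:",
      paste(names(x$precision_groups), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname caller_profile
#' @export
default_type_equivalences <- function() {
  list(DEL = "DEL", DUP = "DUP", INV = "INV",
       DINS = "INS", FINS = "INS", TRA = c("TRA", "BND"))
}

#' @rdname caller_profile
#' @export
default_report_map <- function() {
  list(DEL = "DEL", DUP = "DUP", INV = "INV",
       DINS = "INS", FINS = "INS", TRA = "TRA")
}

#' @rdname caller_profile
#' @export
default_precision_groups <- function() {
  list(DEL = "DEL", DUP = "DUP", INV = "INV", INS = "INS",
       TRA = c("TRA", "BND"))
}

#' Bundled emulator profiles
#'
#' Five fixture profiles whose capability maps follow the published
#' behaviour of widely used somatic SV callers (an assembler-style caller
#' with coarse breakpoints that cannot distinguish DUP from INS, a
#' read-pair/split-read caller that does not report insertions, etc.) and
#' whose detection surfaces rise steeply over VAF 0.05--0.3 and saturate
#' thereafter. The emulator coefficients are fixture parameters for
#' exercising the pipeline, not measurements of the real tools.
#'
#' @return named list of \code{\link{caller_profile}} objects.
#' @export
builtin_profiles <- function() {
  base_emu <- function(beta0, beta1, beta2, beta3, jitter, fp, fpc = 20,
                       leak = 0.002) {
    list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
         jitter_scale = jitter, fp_rate = fp, fp_cov_coef = fpc,
         germline_leak = leak)
  }
  list(
    ## precise assembler, mild normal-coverage effect
    manta_like = caller_profile(
      "manta_like",
      emulator = base_emu(-2.6, 1.0, 3.2, -6.0, jitter = 1, fp = 8)),
    ## read-pair/split-read caller, no insertion calls
    lumpy_like = caller_profile(
      "lumpy_like",
      type_equivalences = utils::modifyList(default_type_equivalences(),
                                            list(DINS = character(),
                                                 FINS = character())),
      report_map = utils::modifyList(default_report_map(),
                                     list(DINS = NULL, FINS = NULL)),
      precision_groups = list(DEL = "DEL", DUP = "DUP", INV = "INV",
                              TRA = c("TRA", "BND")),
      emulator = base_emu(-2.2, 0.9, 2.6, 0.0, jitter = 2, fp = 10)),
    ## breakend assembler, slightly noisier
    gridss_like = caller_profile(
      "gridss_like",
      emulator = base_emu(-2.9, 1.1, 3.0, -3.0, jitter = 1, fp = 14)),
    ## assembler that reports DUP and INS indistinguishably, coarse
    ## breakpoints (lowest breakpoint resolution of the five)
    svaba_like = caller_profile(
      "svaba_like",
      type_equivalences = utils::modifyList(default_type_equivalences(),
                                            list(DUP = c("DUP", "INS"),
                                                 DINS = c("DUP", "INS"),
                                                 FINS = c("DUP", "INS"))),
      precision_groups = list(DEL = "DEL", `DUP/INS` = c("DUP", "INS"),
                              INV = "INV", TRA = c("TRA", "BND")),
      emulator = base_emu(-3.0, 1.0, 2.8, 0.0, jitter = 8, fp = 12)),
    ## read-pair caller with separate refinement, least sensitive at low VAF
    delly_like = caller_profile(
      "delly_like",
      emulator = base_emu(-3.2, 1.0, 2.4, 0.0, jitter = 2, fp = 10))
  )
}

## A permissive profile for benchmarking arbitrary callsets when no
## capability map is known: strict identity matching plus the generic
## DINS/FINS -> INS equivalence.
identity_profile <- function(name = "identity") caller_profile(name)

## acceptable reported types for a vector of truth types
acceptable_types <- function(profile, truth_types) {
  profile$type_equivalences[truth_types]
}
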