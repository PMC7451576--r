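#' svperf: somatic SV detection performance benchmarking and prediction
#'
#' Tools to benchmark somatic structural-variant (SV) callsets against truth
#' sets under a breakpoint-precision threshold, derive pairwise
#' union/intersection callsets under the dominant-caller convention, emulate
#' caller outputs on synthetic truth sets, fit smooth additive performance
#' surfaces (beta regression with tensor-product penalized smooths) over
#' VAF x coverage x threshold design grids, select among candidate model
#' forms by leave-one-level-out cross-validation, and predict detection
#' performance (with uncertainty and minimum-requirement tables) for
#' proposed study designs.
#'
#' @keywords internal
"_PACKAGE"

## Truth-set SV types. DINS (domestic insertion) and TRA carry a second
## locus (the source fragment); FINS (foreign insertion) has only an
## insertion site. Callers additionally report the generic INS and BND.
TRUTH_SV_TYPES <- c("DEL", "DUP", "INV", "DINS", "FINS", "TRA")
ALL_SV_TYPES <- c(TRUTH_SV_TYPES, "INS", "BND")

## Types whose breakends must share one chromosome.
INTRA_SV_TYPES <- c("DEL", "DUP", "INV", "INS", "FINS")

#' Construct a structural-variant callset
#'
#' A callset is a data frame with one row per SV record and columns
#' \code{chrom1, pos1, chrom2, pos2, sv_type, sv_length, id}. Each record
#' carries exactly two breakends; insertions carry two identical-position
#' breakends so the matching engine sees a uniform contract, and an unmated
#' single breakend is encoded with \code{chrom2 = NA}. Coordinates are
#' 1-based inclusive (VCF convention) throughout.
#'
#' @param records data frame with the columns above (zero rows allowed).
#' @param source label for the producing caller or derived callset.
#' @return an object of class \code{svperf_callset}.
#' @export
sv_callset <- function(records = NULL, source = "unknown") {
  cols <- c("chrom1", "pos1", "chrom2", "pos2", "sv_type", "sv_length", "id")
  if (is.null(records) || nrow(records) == 0L) {
    records <- data.frame(chrom1 = character(), pos1 = integer(),
                          chrom2 = character(), pos2 = integer(),
                          sv_type = character(), sv_length = integer(),
                          id = character(), stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0L)
    stop("callset records lack columns: ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records)[, cols]
  records$chrom1 <- as.character(records$chrom1)
  records$chrom2 <- as.character(records$chrom2)
  records$pos1 <- as.integer(records$pos1)
  records$pos2 <- as.integer(records$pos2)
  records$sv_type <- as.character(records$sv_type)
  records$sv_length <- as.integer(records$sv_length)
  records$id <- as.character(records$id)
  rownames(records) <- NULL
  obj <- structure(records, source = source,
                   class = c("svperf_callset", "data.frame"))
  validate_callset(obj)
  obj
}

validate_callset <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  if (anyNA(x$chrom1) || any(!nzchar(x$chrom1)))
    stop("breakend 1 chromosome missing or empty")
  if (anyNA(x$pos1) || any(x$pos1 < 1L))
    stop("breakend positions must be >= 1")
  mated <- !is.na(x$chrom2)
  if (any(!is.na(x$pos2[mated]) & x$pos2[mated] < 1L))
    stop("breakend positions must be >= 1")
  if (anyDuplicated(x$id))
    stop("record ids must be unique within a callset: ",
         x$id[duplicated(x$id)][1L])
  bad <- x$sv_type %in% INTRA_SV_TYPES & mated & x$chrom1 != x$chrom2
  if (any(bad))
    stop("intra-chromosomal SV type with breakends on two chromosomes: ",
         x$id[bad][1L])
  invisible(x)
}

#' @export
print.svperf_callset <- function(x, ...) {
  cat(sprintf("<svperf_callset> source=%s, %d records\n",
              attr(x, "source"), nrow(x)))
  if (nrow(x) > 0L) {
    tab <- table(x$sv_type)
    cat("  types:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
    print(utils::head(as.data.frame(x), 6L))
    if (nrow(x) > 6L) cat("  ...\n")
  }
  invisible(x)
}

#' @rdname sv_callset
#' @param x object to test.
#' @export
is_sv_callset <- function(x) inherits(x, "svperf_callset")

callset_source <- function(x) attr(x, "source")

#' Construct an evaluation table
#'
#' Long-format table of benchmark metrics, one row per
#' (callset, VAF, tumour coverage, normal coverage, threshold, type scope).
#' \code{sv_type_scope} is \code{"ALL"} for overall metrics or an SV type /
#' pooled precision group label. Metric columns may be \code{NA} (e.g.
#' precision of an empty callset).
#'
#' @param rows data frame with columns \code{callset, vaf, tumour_cov,
#'   normal_cov, t_threshold, sv_type_scope, tp_event, tp_call, fp, fn,
#'   sensitivity, precision, f1}.
#' @return object of class \code{svperf_eval_table}.
#' @export
eval_table <- function(rows) {
  cols <- c("callset", "vaf", "tumour_cov", "normal_cov", "t_threshold",
            "sv_type_scope", "tp_event", "tp_call", "fp", "fn",
            "sensitivity", "precision", "f1")
  missing_cols <- setdiff(cols, names(rows))
  if (length(missing_cols) > 0L)
    stop("evaluation table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  rows <- as.data.frame(rows)[, cols]
  key <- do.call(paste, c(rows[c("callset", "vaf", "tumour_cov",
                                 "normal_cov", "t_threshold",
                                 "sv_type_scope")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate evaluation-table key at row ", which(duplicated(key))[1L])
  for (m in c("sensitivity", "precision", "f1")) {
    v <- rows[[m]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(m, " outside [0, 1]")
  }
  rownames(rows) <- NULL
  structure(rows, class = c("svperf_eval_table", "data.frame"))
}

#' @export
print.svperf_eval_table <- function(x, ...) {
  cat(sprintf("<svperf_eval_table> %d rows, %d callsets\n",
              nrow(x), length(unique(x$callset))))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}
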