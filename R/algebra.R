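## Pairwise callset algebra: union and intersection of two callsets under
## the dominant-caller convention. Two calls are "the same" when their
## types match and their breakends lie within the concordance window of
## each other (default 5 bp), using the same breakend-assignment rule as
## the benchmark. Pairing is one-to-one greedy on ascending distance so
## the cardinality identities |A| <= |union| <= |A|+|B| etc. hold.

#' Concordance policy for callset algebra
#'
#' @param window breakpoint distance (bp) within which two calls of
#'   matching type are considered the same call (default 5).
#' @param require_type_match require reported SV types to be equal
#'   (default TRUE). When FALSE any pair of types may be concordant.
#' @param type_map optional named list mapping a type to the set of types
#'   it is considered equivalent to (applied symmetrically), for callers
#'   whose labels are known interchangeable (e.g. DUP and INS).
#' @return object of class \code{svperf_policy}.
#' @export
concordance_policy <- function(window = 5, require_type_match = TRUE,
                               type_map = NULL) {
  stopifnot(window >= 0)
  structure(list(window = window, require_type_match = require_type_match,
                 type_map = type_map), class = "svperf_policy")
}

type_concordant <- function(ta, tb, policy) {
  if (!policy$require_type_match) return(rep(TRUE, length(ta)))
  ok <- ta == tb
  if (!is.null(policy$type_map)) {
    extra <- mapply(function(a, b) {
      (a %in% names(policy$type_map) && b %in% policy$type_map[[a]]) ||
        (b %in% names(policy$type_map) && a %in% policy$type_map[[b]])
    }, ta, tb)
    ok <- ok | extra
  }
  ok
}

#' Are two SV records concordant?
#'
#' @param a,b one-row data frames (or single-record callsets) with the
#'   callset columns.
#' @param policy a \code{\link{concordance_policy}}.
#' @return logical.
#' @export
concordant <- function(a, b, policy = concordance_policy()) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  if (!type_concordant(a$sv_type, b$sv_type, policy)) return(FALSE)
  assignment_dist(a, fill_single_breakends(b))[1L, 1L] <= policy$window
}

## all concordant (i, j, distance) pairs between two callsets, then a
## greedy one-to-one matching on ascending distance
concordant_pairs <- function(a, b, policy) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  d <- assignment_dist(a, fill_single_breakends(b))  # |a| x |b|
  tc <- outer(a$sv_type, b$sv_type,
              function(x, y) type_concordant(x, y, policy))
  d[!tc] <- Inf
  hit <- which(d <= policy$window, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  pairs <- data.frame(i = hit[, 1L], j = hit[, 2L], d = d[hit])
  pairs <- pairs[order(pairs$d, pairs$i, pairs$j), ]
  used_i <- logical(nrow(a)); used_j <- logical(nrow(b))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if (!used_i[pairs$i[k]] && !used_j[pairs$j[k]]) {
      keep[k] <- TRUE
      used_i[pairs$i[k]] <- TRUE
      used_j[pairs$j[k]] <- TRUE
    }
  }
  pairs[keep, , drop = FALSE]
}

#' Union of two callsets under the dominant-caller convention
#'
#' Contains every record of the dominant callset plus every record of the
#' other callset with no concordant partner in the dominant one.
#' Overlapping pairs contribute the dominant record's coordinates and
#' type verbatim.
#'
#' @param dominant,other \code{\link{sv_callset}} objects.
#' @param policy a \code{\link{concordance_policy}}.
#' @return an \code{\link{sv_callset}} labelled
#'   \code{"<dominant>.union.<other>"}.
#' @export
union_callset <- function(dominant, other, policy = concordance_policy()) {
  stopifnot(is_sv_callset(dominant), is_sv_callset(other))
  pairs <- concordant_pairs(dominant, other, policy)
  extra <- setdiff(seq_len(nrow(other)), pairs$j)
  rec <- rbind(as.data.frame(dominant),
               as.data.frame(other)[extra, , drop = FALSE])
  if (anyDuplicated(rec$id))  # same id in both sources: qualify the other's
    rec$id[-seq_len(nrow(dominant))] <-
      paste0(callset_source(other), ":", rec$id[-seq_len(nrow(dominant))])
  sv_callset(rec, source = paste0(callset_source(dominant), ".union.",
                                  callset_source(other)))
}

#' Intersection of two callsets under the dominant-caller convention
#'
#' Dominant records having at least one concordant partner in the other
#' callset, kept verbatim from the dominant caller.
#'
#' @inheritParams union_callset
#' @return an \code{\link{sv_callset}} labelled
#'   \code{"<dominant>.intersect.<other>"}.
#' @export
intersect_callset <- function(dominant, other,
                              policy = concordance_policy()) {
  stopifnot(is_sv_callset(dominant), is_sv_callset(other))
  pairs <- concordant_pairs(dominant, other, policy)
  sv_callset(as.data.frame(dominant)[sort(pairs$i), , drop = FALSE],
             source = paste0(callset_source(dominant), ".intersect.",
                             callset_source(other)))
}

#' Derive all pairwise union and intersection callsets
#'
#' For every ordered pair (dominant, other) of the supplied callsets, one
#' union and one intersection callset: n callers yield 2 n (n - 1) derived
#' callsets (five callers yield 40).
#'
#' @param callsets list of at least two \code{\link{sv_callset}} objects.
#' @param policy a \code{\link{concordance_policy}}.
#' @return named list of derived callsets.
#' @export
derive_all_pairs <- function(callsets, policy = concordance_policy()) {
  stopifnot(length(callsets) >= 2L)
  out <- list()
  for (i in seq_along(callsets)) for (j in seq_along(callsets)) {
    if (i == j) next
    u <- union_callset(callsets[[i]], callsets[[j]], policy)
    x <- intersect_callset(callsets[[i]], callsets[[j]], policy)
    out[[callset_source(u)]] <- u
    out[[callset_source(x)]] <- x
  }
  out
}
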