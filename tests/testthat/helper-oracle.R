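# Independent brute-force oracles and random fixture generators shared
# across the suite. The oracle enumerates every call x truth x
# breakend-assignment combination with plain loops; it never calls the
# package's matching engine.

# distance between one call record and one truth record under the
# minimax breakend-assignment rule (Inf across chromosomes); a
# single-breakend / point call matches the nearer truth breakend
oracle_record_dist <- function(call, truth) {
  bd <- function(ca, pa, cb, pb) {
    if (is.na(ca) || is.na(cb) || ca != cb) Inf else abs(pa - pb)
  }
  point <- is.na(call$chrom2) ||
    (call$chrom1 == call$chrom2 && call$pos1 == call$pos2)
  if (point) {
    min(bd(call$chrom1, call$pos1, truth$chrom1, truth$pos1),
        bd(call$chrom1, call$pos1, truth$chrom2, truth$pos2))
  } else {
    min(max(bd(call$chrom1, call$pos1, truth$chrom1, truth$pos1),
            bd(call$chrom2, call$pos2, truth$chrom2, truth$pos2)),
        max(bd(call$chrom1, call$pos1, truth$chrom2, truth$pos2),
            bd(call$chrom2, call$pos2, truth$chrom1, truth$pos1)))
  }
}

# full classification by exhaustive enumeration: per-call TP/FP labels,
# pairing to the nearest compatible truth (first index on ties), and
# per-truth DETECTED/MISSED labels
oracle_classify <- function(truth, calls, t_threshold, profile) {
  truth <- as.data.frame(truth); calls <- as.data.frame(calls)
  n_c <- nrow(calls); n_t <- nrow(truth)
  best_d <- rep(Inf, n_c); best_j <- rep(NA_integer_, n_c)
  for (i in seq_len(n_c)) {
    for (j in seq_len(n_t)) {
      acceptable <- profile$type_equivalences[[truth$sv_type[j]]]
      if (!(calls$sv_type[i] %in% acceptable)) next
      d <- oracle_record_dist(calls[i, ], truth[j, ])
      if (d < best_d[i]) {
        best_d[i] <- d
        best_j[i] <- j
      }
    }
  }
  tp <- best_d <= t_threshold
  detected <- rep(FALSE, n_t)
  for (i in which(tp)) detected[best_j[i]] <- TRUE
  list(call_label = ifelse(tp, "TP", "FP"),
       call_truth = ifelse(tp, truth$id[best_j], NA_character_),
       truth_label = ifelse(detected, "DETECTED", "MISSED"))
}

# all concordant pairs between two callsets by exhaustive enumeration,
# then greedy one-to-one matching on ascending distance
oracle_concordant_pairs <- function(a, b, policy) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  pairs <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (policy$require_type_match && a$sv_type[i] != b$sv_type[j]) next
    d <- oracle_record_dist(b[j, ], a[i, ])
    if (d <= policy$window)
      pairs <- rbind(pairs, data.frame(i = i, j = j, d = d))
  }
  if (is.null(pairs)) return(data.frame(i = integer(), j = integer()))
  pairs <- pairs[order(pairs$d, pairs$i, pairs$j), ]
  used_i <- logical(nrow(a)); used_j <- logical(nrow(b)); keep <- c()
  for (k in seq_len(nrow(pairs))) {
    if (!used_i[pairs$i[k]] && !used_j[pairs$j[k]]) {
      keep <- c(keep, k)
      used_i[pairs$i[k]] <- TRUE
      used_j[pairs$j[k]] <- TRUE
    }
  }
  pairs[keep, , drop = FALSE]
}

# random truth set on two small chromosomes
random_truth <- function(n, span = 1e5, types = c("DEL", "DUP", "INV",
                                                  "DINS", "FINS", "TRA")) {
  tt <- sample(types, n, replace = TRUE)
  chrom1 <- sample(c("chr1", "chr2"), n, replace = TRUE)
  pos1 <- sample.int(span, n, replace = TRUE)
  len <- sample(50:5000, n, replace = TRUE)
  chrom2 <- chrom1
  pos2 <- pos1 + len
  inter <- tt %in% c("DINS", "TRA")
  chrom2[inter] <- sample(c("chr1", "chr2"), sum(inter), replace = TRUE)
  pos2[inter] <- sample.int(span, sum(inter), replace = TRUE)
  point <- tt == "FINS"
  chrom2[point] <- chrom1[point]
  pos2[point] <- pos1[point]
  sv_callset(data.frame(chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2,
                        pos2 = pos2, sv_type = tt, sv_length = len,
                        id = sprintf("t%04d", seq_len(n)),
                        stringsAsFactors = FALSE), source = "truth")
}

# random callset: a mix of jittered truth copies (type mapped through the
# profile's reporting map) and uniformly random records
random_calls <- function(truth, n, profile, jitter_sd = 10, span = 1e5) {
  truth <- as.data.frame(truth)
  rows <- lapply(seq_len(n), function(i) {
    if (nrow(truth) > 0L && stats::runif(1) < 0.6) {
      j <- sample.int(nrow(truth), 1L)
      r <- truth[j, ]
      rep_type <- profile$report_map[[r$sv_type]]
      if (is.null(rep_type)) rep_type <- r$sv_type  # emit anyway: it's noise
      r$sv_type <- rep_type
      r$pos1 <- max(1L, r$pos1 + as.integer(round(stats::rnorm(1, 0,
                                                               jitter_sd))))
      r$pos2 <- max(1L, r$pos2 + as.integer(round(stats::rnorm(1, 0,
                                                               jitter_sd))))
      if (rep_type == "INS") {
        r$chrom2 <- r$chrom1
        r$pos2 <- r$pos1
      }
      r
    } else {
      tt <- sample(c("DEL", "DUP", "INV", "INS", "TRA"), 1L)
      c1 <- sample(c("chr1", "chr2"), 1L)
      p1 <- sample.int(span, 1L)
      len <- sample(50:5000, 1L)
      data.frame(chrom1 = c1, pos1 = p1,
                 chrom2 = if (tt == "TRA") sample(c("chr1", "chr2"), 1L)
                          else c1,
                 pos2 = if (tt == "INS") p1
                        else if (tt == "TRA") sample.int(span, 1L)
                        else p1 + len,
                 sv_type = tt, sv_length = len, id = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  d <- do.call(rbind, rows)
  d$id <- sprintf("c%04d", seq_len(nrow(d)))
  sv_callset(d, source = "calls")
}

# small callset built from explicit breakend coordinates
make_callset <- function(..., source = "x") {
  rows <- list(...)
  el <- function(r, k, default) if (length(r) >= k) r[[k]] else default
  d <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(chrom1 = r[[1]], pos1 = as.integer(r[[2]]),
               chrom2 = r[[3]], pos2 = as.integer(r[[4]]),
               sv_type = r[[5]],
               sv_length = as.integer(el(r, 6, abs(as.integer(r[[4]]) -
                                                     as.integer(r[[2]])))),
               id = el(r, 7, sprintf("%s%03d", source, i)),
               stringsAsFactors = FALSE)
  }))
  sv_callset(d, source = source)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
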