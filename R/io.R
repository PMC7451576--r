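## Readers/writers for callsets (VCF / BEDPE / TSV), evaluation tables and
## genome masks. Coordinates are kept 1-based inclusive internally; BEDPE
## (0-based half-open) is converted on read and on write.

#' Read a callset from VCF, BEDPE or the flat TSV dialect
#'
#' VCF 4.2 symbolic records (\code{SVTYPE}/\code{END}) map directly to
#' two-breakend records; paired \code{BND} records are joined into one
#' record by \code{MATEID} or, failing that, coordinate reciprocity between
#' the record position and the mate coordinate embedded in the ALT. An
#' unmated BND is kept as a single-breakend record with a warning. The TSV
#' truth dialect is \code{chrom1 pos1 chrom2 pos2 sv_type sv_length id}
#' with a header line.
#'
#' @param path file path.
#' @param fmt \code{"auto"} (by extension), \code{"vcf"}, \code{"bedpe"} or
#'   \code{"tsv"}.
#' @param source callset label; defaults to the file name.
#' @return an \code{\link{sv_callset}}.
#' @export
read_callset <- function(path, fmt = c("auto", "vcf", "bedpe", "tsv"),
                         source = NULL) {
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    fmt <- switch(tolower(tools::file_ext(path)),
                  vcf = "vcf", bedpe = "bedpe", tsv = "tsv", txt = "tsv",
                  stop("cannot infer callset format from extension: ", path))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(source)) source <- basename(path)
  switch(fmt,
         vcf = read_callset_vcf(path, source),
         bedpe = read_callset_bedpe(path, source),
         tsv = read_callset_tsv(path, source))
}

read_callset_tsv <- function(path, source) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom1 = "character",
                                        chrom2 = "character",
                                        id = "character"))
  sv_callset(d, source = source)
}

read_callset_bedpe <- function(path, source) {
  d <- tryCatch(
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#"),
    error = function(e) stop("unparseable BEDPE: ", path, ": ",
                             conditionMessage(e)))
  if (nrow(d) == 0L) return(sv_callset(NULL, source = source))
  if (ncol(d) < 6L) stop("BEDPE needs >= 6 columns: ", path)
  ## cols 1-6 standard; 7 name, 11 sv_type, 12 sv_length are optional
  type <- if (ncol(d) >= 11L) as.character(d[[11L]]) else
    ifelse(as.character(d[[1L]]) == as.character(d[[4L]]), "BND", "TRA")
  len <- if (ncol(d) >= 12L) as.integer(d[[12L]]) else
    ifelse(as.character(d[[1L]]) == as.character(d[[4L]]),
           abs(as.integer(d[[5L]]) - as.integer(d[[2L]])), NA_integer_)
  id <- if (ncol(d) >= 7L) as.character(d[[7L]]) else
    sprintf("bedpe_%05d", seq_len(nrow(d)))
  sv_callset(data.frame(
    chrom1 = as.character(d[[1L]]), pos1 = as.integer(d[[2L]]) + 1L,
    chrom2 = as.character(d[[4L]]), pos2 = as.integer(d[[5L]]) + 1L,
    sv_type = type, sv_length = len, id = id,
    stringsAsFactors = FALSE), source = source)
}

## mate coordinate embedded in a BND ALT, e.g. N]chr2:321682] or ]13:123]T
parse_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec("[\\[\\]]([^\\[\\]:]+):([0-9]+)[\\[\\]]",
                               alt, perl = TRUE))
  t(vapply(m, function(g) {
    if (length(g) == 3L) c(g[2L], g[3L]) else c(NA_character_, NA_character_)
  }, character(2L)))
}

read_callset_vcf <- function(path, source) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("unparseable VCF: ", path, ": ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single record comes back as vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(sv_callset(NULL, source = source))
  info_field <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else as.character(val)
  }
  svtype <- info_field("SVTYPE")
  endpos <- suppressWarnings(as.integer(info_field("END")))
  svlen <- suppressWarnings(as.integer(info_field("SVLEN")))
  chr2 <- info_field("CHR2")
  mateid <- info_field("MATEID")
  pos <- suppressWarnings(as.integer(fix$POS))
  id <- fix$ID
  id[is.na(id) | id == "."] <- sprintf("vcf_%05d", which(is.na(id) | id == "."))
  if (anyNA(pos))
    stop("unparseable VCF record at data line ", which(is.na(pos))[1L],
         " of ", path)
  if (anyNA(svtype))
    stop("VCF record without SVTYPE at data line ", which(is.na(svtype))[1L],
         " of ", path)

  is_bnd <- svtype == "BND"
  out <- vector("list", nrow(fix))

  ## symbolic (non-BND) records
  for (i in which(!is_bnd)) {
    st <- svtype[i]
    c2 <- if (!is.na(chr2[i])) chr2[i] else fix$CHROM[i]
    p2 <- if (st %in% c("INS", "DINS", "FINS") && is.na(endpos[i])) pos[i]
          else endpos[i]
    if (is.na(p2))
      stop("SV record without END at data line ", i, " of ", path)
    ln <- if (!is.na(svlen[i])) abs(svlen[i]) else
      if (c2 == fix$CHROM[i]) abs(p2 - pos[i]) else NA_integer_
    out[[i]] <- data.frame(chrom1 = fix$CHROM[i], pos1 = pos[i],
                           chrom2 = c2, pos2 = p2, sv_type = st,
                           sv_length = ln, id = id[i],
                           stringsAsFactors = FALSE)
  }

  ## BND records: pair mates into one record each
  if (any(is_bnd)) {
    bidx <- which(is_bnd)
    mate_coord <- parse_bnd_alt(fix$ALT[bidx])
    mate_chrom <- mate_coord[, 1L]
    mate_pos <- suppressWarnings(as.integer(mate_coord[, 2L]))
    used <- logical(length(bidx))
    key <- paste(fix$CHROM[bidx], pos[bidx])
    mkey <- paste(mate_chrom, mate_pos)
    for (k in seq_along(bidx)) {
      if (used[k]) next
      i <- bidx[k]
      partner <- NA_integer_
      if (!is.na(mateid[i])) {
        hit <- which(id[bidx] == mateid[i] & !used)
        if (length(hit) > 0L) partner <- hit[1L]
      }
      if (is.na(partner) && !is.na(mkey[k])) {
        hit <- which(key == mkey[k] & mkey == key[k] & !used &
                       seq_along(bidx) != k)
        if (length(hit) > 0L) partner <- hit[1L]
      }
      used[k] <- TRUE
      if (!is.na(partner)) {
        used[partner] <- TRUE
        j <- bidx[partner]
        st <- if (fix$CHROM[i] == fix$CHROM[j]) "BND" else "TRA"
        out[[i]] <- data.frame(chrom1 = fix$CHROM[i], pos1 = pos[i],
                               chrom2 = fix$CHROM[j], pos2 = pos[j],
                               sv_type = st, sv_length = svlen_or_na(svlen[i]),
                               id = id[i], stringsAsFactors = FALSE)
      } else if (!is.na(mate_chrom[k])) {
        ## mate record absent but coordinate known from ALT
        st <- if (fix$CHROM[i] == mate_chrom[k]) "BND" else "TRA"
        warning("unmated BND record ", id[i], " (mate record missing); ",
                "using ALT mate coordinate")
        out[[i]] <- data.frame(chrom1 = fix$CHROM[i], pos1 = pos[i],
                               chrom2 = mate_chrom[k], pos2 = mate_pos[k],
                               sv_type = st, sv_length = svlen_or_na(svlen[i]),
                               id = id[i], stringsAsFactors = FALSE)
      } else {
        warning("unmated BND record ", id[i], " kept with a single breakend")
        out[[i]] <- data.frame(chrom1 = fix$CHROM[i], pos1 = pos[i],
                               chrom2 = NA_character_, pos2 = NA_integer_,
                               sv_type = "BND",
                               sv_length = svlen_or_na(svlen[i]),
                               id = id[i], stringsAsFactors = FALSE)
      }
    }
  }
  sv_callset(do.call(rbind, out[!vapply(out, is.null, logical(1L))]),
             source = source)
}

svlen_or_na <- function(x) if (is.na(x)) NA_integer_ else abs(x)

#' Write a callset to TSV, VCF or BEDPE
#'
#' The TSV dialect round-trips losslessly through \code{\link{read_callset}}.
#' VCF output writes one symbolic record per SV with \code{SVTYPE},
#' \code{END}, \code{SVLEN} and (for inter-chromosomal records)
#' \code{CHR2} INFO keys.
#'
#' @param callset an \code{\link{sv_callset}}.
#' @param path output file path.
#' @param fmt \code{"tsv"}, \code{"vcf"} or \code{"bedpe"}.
#' @export
write_callset <- function(callset, path, fmt = c("tsv", "vcf", "bedpe")) {
  fmt <- match.arg(fmt)
  stopifnot(is_sv_callset(callset))
  if (fmt == "tsv") {
    utils::write.table(as.data.frame(callset), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  } else if (fmt == "bedpe") {
    d <- as.data.frame(callset)
    out <- data.frame(d$chrom1, d$pos1 - 1L, d$pos1, d$chrom2, d$pos2 - 1L,
                      d$pos2, d$id, 0L, "+", "+", d$sv_type, d$sv_length)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, na = ".")
  } else {
    d <- as.data.frame(callset)
    hdr <- c("##fileformat=VCFv4.2",
             "##source=svperf",
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
             "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
             "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
             "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Chromosome of second breakend\">",
             paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                                 "FILTER", "INFO"), collapse = "\t")))
    info <- sprintf("SVTYPE=%s;END=%d", d$sv_type, d$pos2)
    info <- ifelse(is.na(d$sv_length), info,
                   sprintf("%s;SVLEN=%d", info, d$sv_length))
    inter <- !is.na(d$chrom2) & d$chrom2 != d$chrom1
    info[inter] <- sprintf("%s;CHR2=%s", info[inter], d$chrom2[inter])
    body <- sprintf("%s\t%d\t%s\tN\t<%s>\t.\t.\t%s",
                    d$chrom1, d$pos1, d$id, d$sv_type, info)
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Write / read an evaluation table as long-format TSV
#'
#' @param table an \code{\link{eval_table}}.
#' @param path file path.
#' @return \code{read_eval_table} returns an \code{\link{eval_table}};
#'   \code{write_eval_table} returns \code{path} invisibly.
#' @export
write_eval_table <- function(table, path) {
  stopifnot(inherits(table, "svperf_eval_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_eval_table
#' @export
read_eval_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(callset = "character",
                                        sv_type_scope = "character"))
  eval_table(d)
}
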