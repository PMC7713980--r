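# Mapping-efficiency evaluation: alignment filters, breadth/depth metrics,
# SAM text I/O, and the built-in toy mapper.
#
# The metric definitions follow the evaluation protocol: alignments pass iff
# mapped, MAPQ >= 20, and none of the not-primary (0x100), vendor-failed
# (0x200) or supplementary (0x800) flags are set (duplicates, 0x400, are NOT
# filtered).  Breadth is the percentage of non-missing (non-N) reference
# positions with depth >= 1, and mean depth is likewise computed over
# non-missing positions only.  Depth counts the reference-consuming CIGAR
# operations M, =, X and D.

#' Map read pairs with the built-in toy mapper
#'
#' Exact k-mer seeds at fixed offsets on both strands, Hamming-distance
#' extension over the full read, unique best hit gets MAPQ 60, tied best hits
#' MAPQ 0, no hit within the mismatch budget is reported unmapped.
#' Deterministic.
#'
#' @param pairs a `read_pairs` object
#' @param reference a `genome`
#' @param seed_len exact-seed length (default 12, must be <= 15; lengths up to 12 use a direct-addressed index)
#' @param seed_step offset between successive seeds (default 7)
#' @param max_mismatch mismatch budget; default 30% of the read length
#' @return a `data.table` of SAM-like records (qname, flag, rname, pos, mapq,
#'   cigar, seq, mismatches) with attribute `header` carrying reference
#'   names/lengths and `total_reads` = 2 * number of pairs
#' @export
toy_map <- function(pairs, reference, seed_len = 12L, seed_step = 7L,
                    max_mismatch = NULL) {
  if (is.null(max_mismatch)) {
    rl <- if (nrow(pairs)) nchar(pairs$read1[1]) else 100L
    max_mismatch <- as.integer(0.3 * rl)
  }
  res <- toy_map_cpp(names(reference), unclass(reference), pairs$name,
                     pairs$read1, pairs$read2, as.integer(seed_len),
                     as.integer(seed_step), as.integer(max_mismatch))
  dt <- data.table::as.data.table(res)
  dt[, rname := names(reference)[rname]]
  data.table::setattr(dt, "header",
                      data.frame(sn = names(reference),
                                 ln = nchar(unclass(reference)),
                                 stringsAsFactors = FALSE))
  data.table::setattr(dt, "total_reads", 2L * nrow(pairs))
  dt[]
}

#' Write SAM-like records to a SAM text file
#' @param records a record table from [toy_map()] or [read_sam()]
#' @param path output path
#' @param header data.frame(sn, ln); defaults to the records' header attribute
#' @export
write_sam <- function(records, path, header = attr(records, "header")) {
  if (is.null(header)) stop("no header available")
  hd <- c("@HD\tVN:1.6\tSO:unsorted",
          sprintf("@SQ\tSN:%s\tLN:%d", header$sn, as.integer(header$ln)))
  rn <- ifelse(is.na(records$rname), "*", records$rname)
  pos <- ifelse(is.na(records$rname), 0L, records$pos)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  records$qname, records$flag, rn, pos, records$mapq,
                  records$cigar, records$seq)
  writeLines(c(hd, body), path)
  invisible(path)
}

#' Read a SAM text file
#'
#' Plain-text SAM only; the first 11 mandatory fields are parsed.
#'
#' @param path SAM path
#' @return a `data.table` (qname, flag, rname, pos, mapq, cigar, seq) with a
#'   `header` attribute (data.frame of SN/LN); errors if the file has no
#'   header
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hd <- startsWith(lines, "@")
  if (!any(is_hd)) stop("SAM file has no header: ", path)
  sq <- lines[startsWith(lines, "@SQ")]
  header <- data.frame(
    sn = sub(".*\tSN:([^\t]+).*", "\\1", sq),
    ln = as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq)),
    stringsAsFactors = FALSE)
  body <- lines[!is_hd]
  if (!length(body)) {
    dt <- data.table::data.table(qname = character(0), flag = integer(0),
                                 rname = character(0), pos = integer(0),
                                 mapq = integer(0), cigar = character(0),
                                 seq = character(0))
  } else {
    f <- data.table::tstrsplit(body, "\t", fixed = TRUE, keep = 1:11)
    dt <- data.table::data.table(qname = f[[1]], flag = as.integer(f[[2]]),
                                 rname = ifelse(f[[3]] == "*", NA_character_, f[[3]]),
                                 pos = as.integer(f[[4]]),
                                 mapq = as.integer(f[[5]]), cigar = f[[6]],
                                 seq = f[[10]])
  }
  data.table::setattr(dt, "header", header)
  dt[]
}

#' Filter alignment records with the evaluation criteria
#'
#' A record passes iff it is mapped, MAPQ >= `min_mapq`, and the flags
#' not-primary (0x100), vendor-failed (0x200) and supplementary (0x800) are
#' all clear.  Duplicates (0x400) are not filtered.
#'
#' @param records a record table from [toy_map()] or [read_sam()]
#' @param min_mapq minimum mapping quality (default 20; a record with MAPQ
#'   exactly 20 passes)
#' @return the passing records
#' @export
filter_alignments <- function(records, min_mapq = 20L) {
  bad <- bitwAnd(records$flag, bitwOr(bitwOr(0x4L, 0x100L),
                                      bitwOr(0x200L, 0x800L))) != 0L
  records[!bad & records$mapq >= min_mapq & !is.na(records$rname), ]
}

# Reference-consuming spans of a CIGAR string: M, =, X, D (and N, which
# advances the reference without contributing depth).  Returns a data.frame
# with start (1-based) and width for the depth-contributing ops.
.cigar_ref_spans <- function(cigar, pos) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  o <- sub("^[0-9]+", "", ops)
  starts <- integer(0); widths <- integer(0)
  at <- pos
  for (i in seq_along(o)) {
    if (o[i] %in% c("M", "=", "X", "D")) {
      starts <- c(starts, at); widths <- c(widths, n[i]); at <- at + n[i]
    } else if (o[i] == "N") {
      at <- at + n[i]
    }
    # I, S, H, P consume no reference
  }
  data.frame(start = starts, width = widths)
}

#' Compute mapping-efficiency metrics
#'
#' Applies [filter_alignments()] and reports the percentage of total reads
#' passing, the breadth of coverage at depth >= 1 over non-missing reference
#' positions, and the mean depth over non-missing positions, together with
#' reference length accounting.
#'
#' @param records a record table from [toy_map()] or [read_sam()]
#' @param reference a `genome` (lengths are checked against the records'
#'   header when present)
#' @param total_reads denominator for the mapped percentage (each mate counts
#'   as one read); defaults to the records' `total_reads` attribute
#' @param min_mapq MAPQ threshold (default 20)
#' @return a `mapping_metrics` list: total_reads, mapped_pct, breadth_pct,
#'   mean_depth, ref_total_length, ref_missing, n_passing
#' @export
compute_metrics <- function(records, reference, total_reads = NULL,
                            min_mapq = 20L) {
  header <- attr(records, "header")
  if (!is.null(header)) {
    m <- match(header$sn, names(reference))
    if (anyNA(m) || any(header$ln != nchar(unclass(reference))[m]))
      stop("reference does not match SAM header (names or lengths differ)")
  }
  if (is.null(total_reads)) total_reads <- attr(records, "total_reads")
  if (is.null(total_reads)) stop("total_reads not given and not recorded on records")

  pass <- filter_alignments(records, min_mapq)
  lens <- nchar(unclass(reference))

  # per-contig coverage from reference-consuming spans
  cov_by_contig <- setNames(vector("list", length(reference)), names(reference))
  if (nrow(pass)) {
    simple <- grepl("^[0-9]+M$", pass$cigar)
    width <- rep(NA_integer_, nrow(pass))
    width[simple] <- as.integer(sub("M$", "", pass$cigar[simple]))
    spans <- data.table::data.table(rname = pass$rname, start = pass$pos,
                                    width = width)
    if (any(!simple)) {
      extra <- lapply(which(!simple), function(i) {
        sp <- .cigar_ref_spans(pass$cigar[i], pass$pos[i])
        data.table::data.table(rname = pass$rname[i], start = sp$start,
                               width = sp$width)
      })
      spans <- data.table::rbindlist(c(list(spans[simple]), extra))
    }
    for (nm in unique(spans$rname)) {
      s <- spans[spans$rname == nm]
      cov_by_contig[[nm]] <- IRanges::coverage(
        IRanges::IRanges(start = s$start, width = s$width), width = lens[[nm]])
    }
  }

  non_missing <- 0; covered <- 0; depth_sum <- 0
  for (nm in names(reference)) {
    mask <- S4Vectors::Rle(genome_missing_mask(reference, nm))
    ok <- !mask
    non_missing <- non_missing + sum(ok)
    cov <- cov_by_contig[[nm]]
    if (is.null(cov)) next
    covered <- covered + sum(cov > 0 & ok)
    depth_sum <- depth_sum + sum(as.numeric(S4Vectors::runValue(cov)) *
                                   .run_overlap(cov, ok))
  }

  structure(list(
    total_reads = total_reads,
    mapped_pct = 100 * nrow(pass) / total_reads,
    breadth_pct = if (non_missing > 0) 100 * covered / non_missing else 0,
    mean_depth = if (non_missing > 0) depth_sum / non_missing else 0,
    ref_total_length = sum(lens),
    ref_missing = genome_missing(reference),
    n_passing = nrow(pass)), class = "mapping_metrics")
}

# For each run of the coverage Rle, the number of its positions that are
# non-missing according to the logical Rle `ok`.
.run_overlap <- function(cov, ok) {
  ends <- cumsum(S4Vectors::runLength(cov))
  starts <- c(1, head(ends, -1) + 1)
  csum <- c(0, cumsum(as.integer(as.vector(ok))))
  csum[ends + 1] - csum[starts]
}

#' @export
print.mapping_metrics <- function(x, ...) {
  cat(sprintf(
    "mapping metrics: %.2f%% mapped (%d/%d), breadth >=1X %.2f%%, mean depth %.3fX\n  reference %d bp (%d N)\n",
    x$mapped_pct, x$n_passing, x$total_reads, x$breadth_pct, x$mean_depth,
    x$ref_total_length, x$ref_missing))
  invisible(x)
}
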