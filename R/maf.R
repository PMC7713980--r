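# MAF (Multiple Alignment Format, UCSC dialect) reading, validation,
# filtering and writing.
#
# A block is a list with elements:
#   score     alignment score (NA if absent from the "a" line)
#   rows      data.frame(species, seq_name, start, size, strand, src_size, text)
#   n_columns number of alignment columns
# The first row is the anchor species.  Coordinates follow the MAF standard:
# 0-based, strand-relative (a minus-strand start counts from the
# reverse-complemented source).  `maf_anchor_interval()` converts to
# forward-strand 0-based half-open coordinates for interval arithmetic.

.new_maf_block <- function(rows, score = NA_real_) {
  structure(list(score = score, rows = rows, n_columns = nchar(rows$text[1])),
            class = "maf_block")
}

#' @export
print.maf_block <- function(x, ...) {
  cat("MAF block:", nrow(x$rows), "rows,", x$n_columns, "columns, score",
      x$score, "\n  anchor:", x$rows$species[1], x$rows$seq_name[1],
      paste0("[", x$rows$start[1], ",", x$rows$start[1] + x$rows$size[1], ")"), "\n")
  invisible(x)
}

# Forward-strand 0-based half-open interval of a block row.
.row_fwd_interval <- function(row) {
  if (row$strand == "+") c(row$start, row$start + row$size)
  else c(row$src_size - row$start - row$size, row$src_size - row$start)
}

#' Forward-strand anchor interval of a MAF block
#' @param block a MAF block
#' @return numeric `c(start, end)`, 0-based half-open on the anchor sequence
#' @export
maf_anchor_interval <- function(block) .row_fwd_interval(block$rows[1, ])

#' Read a MAF file
#'
#' Parses "a" (optionally with `score=`) and "s" lines; "#" comments and
#' auxiliary i/e/q lines are ignored.  Lowercase bases are uppercased and
#' characters outside \{A,C,G,T,N,-\} are mapped to N.  Malformed blocks
#' (unequal row widths, or a `size` field disagreeing with the number of
#' non-gap characters) raise an error naming the offending line.
#'
#' @param path path to a MAF file, or a character vector of MAF lines
#' @return a list of MAF blocks (class `maf`), in file order
#' @export
read_maf <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path))
    readLines(path) else unlist(strsplit(path, "\n"))
  blocks <- list()
  cur <- NULL      # list of s-line fields for the open block
  cur_score <- NA_real_
  cur_lines <- integer()

  close_block <- function() {
    if (is.null(cur) || !length(cur)) return()
    rows <- data.frame(
      species = vapply(cur, `[[`, "", "species"),
      seq_name = vapply(cur, `[[`, "", "seq_name"),
      start = vapply(cur, `[[`, 0, "start"),
      size = vapply(cur, `[[`, 0, "size"),
      strand = vapply(cur, `[[`, "", "strand"),
      src_size = vapply(cur, `[[`, 0, "src_size"),
      text = vapply(cur, `[[`, "", "text"),
      stringsAsFactors = FALSE)
    w <- nchar(rows$text)
    if (length(unique(w)) != 1L)
      stop("ragged MAF block ending at line ", cur_lines[length(cur_lines)],
           ": row widths ", paste(w, collapse = ", "))
    if (anyDuplicated(rows$species))
      stop("MAF block ending at line ", cur_lines[length(cur_lines)],
           " has more than one row for species ",
           rows$species[duplicated(rows$species)][1])
    blocks[[length(blocks) + 1L]] <<- .new_maf_block(rows, cur_score)
    cur <<- NULL; cur_score <<- NA_real_; cur_lines <<- integer()
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) { close_block(); next }
    first <- substr(trimws(ln), 1L, 1L)
    if (first == "#") next
    if (first == "a") {
      close_block()
      cur <- list()
      m <- regmatches(ln, regexpr("score=[-0-9.eE+]+", ln))
      cur_score <- if (length(m)) as.numeric(sub("score=", "", m)) else NA_real_
      next
    }
    if (first == "s") {
      if (is.null(cur))
        stop("MAF 's' line outside a block at line ", i)
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) != 7L)
        stop("malformed MAF 's' line at line ", i, " (expected 7 fields)")
      text <- .sanitize_seq(f[7])
      size <- as.numeric(f[4])
      ngap <- nchar(gsub("-", "", text, fixed = TRUE))
      if (ngap != size)
        stop("MAF 's' line at line ", i, ": size field is ", size,
             " but text has ", ngap, " non-gap characters")
      src <- f[2]
      dot <- regexpr(".", src, fixed = TRUE)
      species <- if (dot > 0) substr(src, 1L, dot - 1L) else src
      seq_name <- if (dot > 0) substr(src, dot + 1L, nchar(src)) else src
      start <- as.numeric(f[3]); src_size <- as.numeric(f[6])
      if (start + size > src_size)
        stop("MAF 's' line at line ", i, ": start + size exceeds srcSize")
      if (!f[5] %in% c("+", "-"))
        stop("MAF 's' line at line ", i, ": bad strand '", f[5], "'")
      cur[[length(cur) + 1L]] <- list(species = species, seq_name = seq_name,
                                      start = start, size = size, strand = f[5],
                                      src_size = src_size, text = text)
      cur_lines <- c(cur_lines, i)
      next
    }
    # i/e/q and other auxiliary lines: ignored
  }
  close_block()
  structure(blocks, class = "maf")
}

#' Write MAF blocks
#'
#' @param blocks a list of MAF blocks
#' @param path output path (or "" for stdout)
#' @export
write_maf <- function(blocks, path = "") {
  out <- character(0)
  chunks <- lapply(blocks, function(b) {
    a <- if (is.na(b$score)) "a" else sprintf("a score=%s", format(b$score, scientific = FALSE))
    src <- ifelse(b$rows$seq_name == b$rows$species, b$rows$species,
                  paste0(b$rows$species, ".", b$rows$seq_name))
    s <- sprintf("s %s %d %d %s %d %s", src, as.integer(b$rows$start),
                 as.integer(b$rows$size), b$rows$strand,
                 as.integer(b$rows$src_size), b$rows$text)
    c(a, s, "")
  })
  out <- c("##maf version=1", "", unlist(chunks))
  writeLines(out, path)
  invisible(path)
}

#' Drop alignment blocks narrower than a minimum number of columns
#'
#' Mirrors `mafFilter -factor -minCol=100`: blocks with at least `min_col`
#' columns are retained (the boundary is inclusive), in input order.
#'
#' @param blocks list of MAF blocks
#' @param min_col minimum number of alignment columns (default 100)
#' @return filtered list of blocks
#' @export
filter_min_columns <- function(blocks, min_col = 100L) {
  stopifnot(min_col >= 1L)
  keep <- vapply(blocks, function(b) b$n_columns >= min_col, logical(1))
  structure(blocks[keep], class = "maf")
}

#' Resolve overlapping blocks, keeping the best hit
#'
#' For any pair of blocks whose anchor intervals overlap on the same anchor
#' sequence, only the higher-scoring block is retained (ties broken by input
#' order; blocks without a score are scored by column count).  Output anchor
#' intervals are pairwise disjoint and sorted by anchor coordinate.
#'
#' @param blocks list of MAF blocks
#' @return deduplicated list of blocks sorted by anchor position
#' @export
dedupe_best_hit <- function(blocks) {
  n <- length(blocks)
  if (n == 0L) return(structure(list(), class = "maf"))
  score <- vapply(blocks, function(b) if (is.na(b$score)) b$n_columns else b$score,
                  numeric(1))
  seqn <- vapply(blocks, function(b) b$rows$seq_name[1], character(1))
  iv <- t(vapply(blocks, maf_anchor_interval, numeric(2)))
  ord <- order(-score, seq_len(n))          # best first, ties by input order
  keep <- logical(n)
  kept_by_seq <- split(integer(0), character(0))
  for (i in ord) {
    ks <- kept_by_seq[[seqn[i]]]
    clash <- FALSE
    if (length(ks)) {
      clash <- any(iv[ks, 1] < iv[i, 2] & iv[i, 1] < iv[ks, 2])
    }
    if (!clash) {
      keep[i] <- TRUE
      kept_by_seq[[seqn[i]]] <- c(ks, i)
    }
  }
  out <- blocks[keep]
  oiv <- iv[keep, , drop = FALSE]
  out <- out[order(seqn[keep], oiv[, 1])]
  structure(out, class = "maf")
}
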