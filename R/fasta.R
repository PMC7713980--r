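# Genome container and FASTA input/output.
#
# A genome is a named character vector of uppercase sequences over
# {A,C,G,T,N}, wrapped in the "genome" S3 class.  Missing data are N bases;
# per-position masks are derived on demand rather than stored.

#' Construct a genome object
#'
#' @param sequences named character vector of sequences.  Lowercase input is
#'   uppercased; IUPAC ambiguity codes other than N are collapsed to N (the
#'   downstream substitution model is 4-state).
#' @return an object of class `genome`: a named character vector.
#' @export
genome <- function(sequences) {
  if (length(sequences) && (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")))
    stop("all genome sequences must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate sequence names: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", "))
  sequences <- vapply(sequences, .sanitize_seq, character(1))
  structure(sequences, class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x), "sequence(s),", sum(nchar(x)), "bp total,",
      genome_missing(x), "N\n")
  invisible(x)
}

#' Total number of missing (N) bases in a genome
#' @param g a `genome`
#' @return integer count of N bases
#' @export
genome_missing <- function(g) {
  sum(vapply(unclass(g), function(s) {
    sum(as.integer(charToRaw(s)) == 78L)
  }, numeric(1)))
}

#' Per-position missing-data mask
#'
#' @param g a `genome`
#' @param seq_name sequence to extract the mask for (default: all, as a list)
#' @return logical vector (or named list of them), TRUE where the base is N
#' @export
genome_missing_mask <- function(g, seq_name = NULL) {
  f <- function(s) as.integer(charToRaw(s)) == 78L
  if (!is.null(seq_name)) {
    if (!seq_name %in% names(g)) stop("no sequence named ", seq_name)
    return(f(g[[seq_name]]))
  }
  lapply(unclass(g), f)
}

#' Read a FASTA file into a genome
#'
#' @param path path to an (uncompressed or gzipped) FASTA file
#' @return a `genome`
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nm))
    stop("duplicate FASTA names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- as.character(dss)
  names(seqs) <- nm
  genome(seqs)
}

#' Write a genome to FASTA
#'
#' @param g a `genome`
#' @param path output path
#' @param width line-wrap width (default 60)
#' @export
write_fasta <- function(g, path, width = 60L) {
  dss <- Biostrings::BStringSet(unclass(g))
  Biostrings::writeXStringSet(dss, path, width = as.integer(width))
  invisible(path)
}
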