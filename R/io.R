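#' Write fingerprints in the plain-text bands dialect
#'
#' One record per clone: a header line `>{owner_id} {band_count}` followed by
#' one integer band value per line; records concatenated, UTF-8, LF line
#' endings.
#'
#' @param fps Named list of sorted integer band vectors.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bands <- function(fps, path) {
  stopifnot(!is.null(names(fps)), !anyDuplicated(names(fps)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (id in names(fps)) {
    b <- fps[[id]]
    writeLines(c(sprintf(">%s %d", id, length(b)), format(b, scientific = FALSE,
                                                          trim = TRUE)),
               con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read a bands file
#'
#' Reads the dialect written by [write_bands()]. Blank lines between records
#' are tolerated and CRLF input is accepted. Malformed records are rejected
#' with the offending line number or clone id: non-integer band values,
#' duplicate clone ids, and header counts that disagree with the number of
#' listed bands are all errors.
#'
#' @param path Input file.
#' @return Named list of sorted integer band vectors.
#' @export
read_bands <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  fps <- list()
  cur_id <- NULL; cur_n <- 0L; cur <- integer(0)
  flush_rec <- function() {
    if (is.null(cur_id)) return()
    if (length(cur) != cur_n)
      stop("band count mismatch for clone ", cur_id, ": header says ",
           cur_n, ", found ", length(cur))
    if (!is.null(fps[[cur_id]]))
      stop("duplicate clone id: ", cur_id)
    fps[[cur_id]] <<- cur
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      flush_rec()
      parts <- strsplit(sub("^>", "", ln), "[ \t]+")[[1]]
      if (length(parts) != 2 || is.na(suppressWarnings(as.integer(parts[2]))))
        stop("malformed header at line ", i, ": ", ln)
      cur_id <- parts[1]; cur_n <- as.integer(parts[2]); cur <- integer(0)
    } else {
      if (is.null(cur_id)) stop("band value before any header at line ", i)
      v <- suppressWarnings(as.numeric(ln))
      if (is.na(v) || v != as.integer(v))
        stop("non-integer band value at line ", i, ": ", ln)
      cur <- c(cur, as.integer(v))
    }
  }
  flush_rec()
  fps
}

#' Write sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path Input file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub(" .*$", "", names(x))
  out
}

#' Write repeat annotations as BED (0-based, half-open)
#' @param annotations data.frame `start/end/class`.
#' @param chrom_name Chromosome name for the first BED column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(annotations, chrom_name, path) {
  df <- data.frame(chrom = rep(chrom_name, nrow(annotations)),
                   start = annotations$start,
                   end = annotations$end, name = annotations$class)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write/read a TSV table with a header row
#' @param df data.frame.
#' @param path File path.
#' @return `path` (write) or a data.frame (read).
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
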