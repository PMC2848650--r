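#' Sequence database constructor
#'
#' Builds the in-memory database object used throughout the package: an
#' ordered set of named DNA sequences over the strict alphabet \{A,C,G,T\}.
#' Sequences are uppercased and every non-ACGT character (any IUPAC ambiguity
#' or "universal" character, not only \code{N}) is replaced by \code{A} before
#' storage, the same blanket preprocessing applied to EST libraries before
#' signature discovery.
#'
#' @param seqs named character vector of DNA sequences. Names must be unique.
#' @return An object of class \code{sig_db}: a list with elements
#'   \code{names} (character), \code{seqs} (character, cleaned), and
#'   \code{total_bases} (integer).
#' @export
sig_db <- function(seqs) {
  if (length(seqs) == 0L)
    stop("empty database")
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("all records must be named")
  if (anyDuplicated(nm))
    stop("duplicate record names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  cleaned <- gsub("[^ACGT]", "A", toupper(as.character(seqs)))
  structure(
    list(names = unname(nm), seqs = unname(cleaned),
         total_bases = sum(nchar(cleaned))),
    class = "sig_db")
}

#' @export
print.sig_db <- function(x, ...) {
  cat(sprintf("DNA signature database: %d record(s), %d bases\n",
              length(x$seqs), x$total_bases))
  n_show <- min(5L, length(x$seqs))
  for (i in seq_len(n_show)) {
    s <- x$seqs[i]
    cat(sprintf("  %s (%d bp) %s%s\n", x$names[i], nchar(s),
                substr(s, 1L, 40L), if (nchar(s) > 40L) "..." else ""))
  }
  if (length(x$seqs) > n_show)
    cat(sprintf("  ... and %d more\n", length(x$seqs) - n_show))
  invisible(x)
}

#' Read and preprocess a FASTA database
#'
#' Reads a (plain or gzipped) FASTA file, uppercases the sequences, replaces
#' every character outside \{A,C,G,T\} with \code{A}, and drops records
#' shorter than \code{min_len} bases. Record names are the first
#' whitespace-delimited token of each header; descriptions are ignored.
#'
#' @param path path to a FASTA file (may be gzip-compressed).
#' @param min_len minimum record length kept, in bases. Defaults to 36, the
#'   conventional preprocessing cut-off for EST libraries.
#' @return A \code{\link{sig_db}}.
#' @export
read_fasta <- function(path, min_len = 36L) {
  if (!file.exists(path))
    stop("cannot read FASTA file: ", path)
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  keep <- nchar(seqs) >= min_len
  if (!any(keep))
    stop("empty database: no record of length >= ", min_len, " in ", path)
  names(seqs) <- nm
  sig_db(seqs[keep])
}

#' Enumerate all fixed-length pattern occurrences
#'
#' Slides a window of \code{l} bases over every record and returns one row per
#' position (overlaps included), in record order then left-to-right.
#' Coordinates are 0-based half-open internally; reports written to disk use
#' 1-based inclusive coordinates.
#'
#' @param db a \code{\link{sig_db}}.
#' @param l pattern length in bases (l >= 1).
#' @return data.frame with columns \code{seq_index} (0-based record index),
#'   \code{offset} (0-based start), \code{length}.
#' @export
extract_occurrences <- function(db, l) {
  stopifnot(inherits(db, "sig_db"))
  l <- as.integer(l)
  if (is.na(l) || l < 1L)
    stop("pattern length l must be a positive integer")
  lens <- nchar(db$seqs)
  n_per <- pmax(lens - l + 1L, 0L)
  data.frame(
    seq_index = rep.int(seq_along(db$seqs) - 1L, n_per),
    offset    = unlist(lapply(n_per, function(k) seq_len(k) - 1L), use.names = FALSE),
    length    = rep.int(l, sum(n_per)))
}

# Strings of a set of occurrences, in row order.
occ_strings <- function(db, occ) {
  substring(db$seqs[occ$seq_index + 1L], occ$offset + 1L, occ$offset + occ$length)
}

# Integer-coded pattern matrix (one row per occurrence) for fast hamming work.
occ_matrix <- function(db, occ) {
  s <- occ_strings(db, occ)
  if (length(s) == 0L) return(matrix(integer(0), 0L, 0L))
  matrix(utf8ToInt(paste(s, collapse = "")), nrow = length(s),
         ncol = occ$length[1L], byrow = TRUE)
}

#' Write a signature set to disk
#'
#' TSV output has columns \code{sequence_name}, \code{start} (1-based),
#' \code{length}, \code{l}, \code{d}, \code{signature_string}, sorted by
#' record and position. FASTA output names each record
#' \code{"{seq_name}:{start}-{end}"} with 1-based inclusive coordinates.
#'
#' @param sigs a \code{\link{signature_set}}.
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"fasta"}.
#' @return Invisibly, \code{path}.
#' @export
write_signatures <- function(sigs, path, format = c("tsv", "fasta")) {
  stopifnot(inherits(sigs, "signature_set"))
  format <- match.arg(format)
  m <- sigs$members
  m <- m[order(m$seq_index, m$offset), , drop = FALSE]
  if (format == "tsv") {
    out <- data.frame(
      sequence_name   = m$seq_name,
      start           = m$offset + 1L,
      length          = rep.int(sigs$l, nrow(m)),
      l               = rep.int(sigs$l, nrow(m)),
      d               = rep.int(sigs$d, nrow(m)),
      signature_string = m$string)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (nrow(m) == 0L) {
      file.create(path)
    } else {
      recs <- Biostrings::DNAStringSet(m$string)
      names(recs) <- sprintf("%s:%d-%d", m$seq_name, m$offset + 1L, m$offset + sigs$l)
      Biostrings::writeXStringSet(recs, path)
    }
  }
  invisible(path)
}

#' Write a database as FASTA
#'
#' @param db a \code{\link{sig_db}}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_db_fasta <- function(db, path) {
  stopifnot(inherits(db, "sig_db"))
  recs <- Biostrings::DNAStringSet(db$seqs)
  names(recs) <- db$names
  Biostrings::writeXStringSet(recs, path)
  invisible(path)
}
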