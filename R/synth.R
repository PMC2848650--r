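# Run code under a private RNG stream seeded from `seed`, restoring the
# caller's RNG state afterwards. One integer seed determines all randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a seeded synthetic DNA database
#'
#' Uniform-random ACGT records, fully determined by the seed. Records are
#' named \code{synth_0001}, \code{synth_0002}, ...
#'
#' @param n_records number of records.
#' @param record_length length of each record in bases.
#' @param seed integer seed; the single source of randomness.
#' @return A \code{\link{sig_db}}.
#' @export
generate_db <- function(n_records, record_length, seed) {
  n_records <- as.integer(n_records); record_length <- as.integer(record_length)
  stopifnot(n_records >= 1L, record_length >= 1L)
  seqs <- with_seed(seed, {
    vapply(seq_len(n_records), function(i)
      paste(sample(c("A", "C", "G", "T"), record_length, replace = TRUE),
            collapse = ""),
      character(1))
  })
  names(seqs) <- sprintf("synth_%04d", seq_len(n_records))
  sig_db(seqs)
}

#' Plant near-duplicate patterns into a database
#'
#' Overwrites \code{copies} disjoint length-l windows with copies of one
#' random l-mer: the first copy is the original verbatim, each further copy
#' is mutated at exactly \code{mismatches} positions (substituted bases are
#' forced to differ, so the realized hamming distance to the original is
#' exactly \code{mismatches}). Every planted copy is therefore within
#' \code{mismatches} of the original occurrence, making all planted
#' occurrences non-unique at any tolerance d >= mismatches, while at
#' d < mismatches a long random background leaves them unique with high
#' probability.
#'
#' Windows are chosen among non-overlapping l-base tiles of the records, so
#' planted copies never overlap each other.
#'
#' @param db a \code{\link{sig_db}}.
#' @param l planted pattern length.
#' @param copies number of copies planted (>= 2).
#' @param mismatches hamming distance of copies 2..k from the original
#'   (0 <= mismatches < l).
#' @param seed integer seed.
#' @return list with \code{db} (modified database) and \code{plants}
#'   (data.frame seq_index, offset, length, copy, dist_to_original).
#' @export
plant_near_duplicates <- function(db, l, copies, mismatches, seed) {
  stopifnot(inherits(db, "sig_db"))
  l <- as.integer(l); copies <- as.integer(copies)
  mismatches <- as.integer(mismatches)
  if (copies < 2L) stop("need at least 2 copies")
  if (mismatches >= l || mismatches < 0L) stop("need 0 <= mismatches < l")
  bases <- c("A", "C", "G", "T")
  lens <- nchar(db$seqs)
  tiles <- do.call(rbind, lapply(seq_along(lens), function(i) {
    k <- lens[i] %/% l
    if (k == 0L) return(NULL)
    data.frame(seq_index = i - 1L, offset = (seq_len(k) - 1L) * l)
  }))
  if (is.null(tiles) || nrow(tiles) < copies)
    stop("insufficient space: ", copies, " disjoint windows of ", l,
         " bases do not fit")
  res <- with_seed(seed, {
    motif <- sample(bases, l, replace = TRUE)
    sel <- tiles[sample.int(nrow(tiles), copies), , drop = FALSE]
    seqs <- db$seqs
    dists <- integer(copies)
    for (ci in seq_len(copies)) {
      copy <- motif
      if (ci > 1L && mismatches > 0L) {
        pos <- sample.int(l, mismatches)
        for (p in pos) copy[p] <- sample(setdiff(bases, motif[p]), 1L)
        dists[ci] <- mismatches
      }
      i <- sel$seq_index[ci] + 1L
      substr(seqs[i], sel$offset[ci] + 1L, sel$offset[ci] + l) <-
        paste(copy, collapse = "")
    }
    list(seqs = seqs, sel = sel, dists = dists)
  })
  names(res$seqs) <- db$names
  list(db = sig_db(res$seqs),
       plants = data.frame(seq_index = res$sel$seq_index,
                           offset = res$sel$offset, length = l,
                           copy = seq_len(copies),
                           dist_to_original = res$dists))
}
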