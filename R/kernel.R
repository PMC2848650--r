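#' Hamming distance between equal-length patterns
#'
#' @param a,b strings of equal length.
#' @return integer mismatch count.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("hamming distance requires equal-length strings")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Comparison counter
#'
#' A mutable counter recording the work of a discovery run: the number of
#' full pattern-to-pattern string comparisons and the characters they
#' touched. Every full comparison costs l' characters (the key region is not
#' skipped), so counts are an upper bound on the key-skipping variant and
#' are asserted only as monotone.
#'
#' @return An object of class \code{comparison_counter} (an environment with
#'   fields \code{char_comparisons} and \code{string_comparisons}).
#' @export
new_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$char_comparisons <- 0
  e$string_comparisons <- 0
  class(e) <- "comparison_counter"
  e
}

#' @export
print.comparison_counter <- function(x, ...) {
  cat(sprintf("comparison counter: %g string comparisons, %g character comparisons\n",
              x$string_comparisons, x$char_comparisons))
  invisible(x)
}

# Core check of one indexed occurrence (by row in index$occ) at one slot:
# returns TRUE if some OTHER occurrence within the slot's similar entries is
# within d' mismatches.
slot_hit <- function(index, i, slot, counter = NULL) {
  cond <- index$condition
  sch <- index$scheme
  key <- substring(index$db$seqs[index$occ$seq_index[i] + 1L],
                   index$occ$offset[i] + sch$start[slot + 1L] + 1L,
                   index$occ$offset[i] + sch$start[slot + 1L] + sch$length[slot + 1L])
  ents <- similar_entries(index, key, slot)
  if (length(ents) == 0L) return(FALSE)
  others <- setdiff(unlist(lapply(ents, `[[`, "occ_idx"), use.names = FALSE), i)
  if (length(others) == 0L) return(FALSE)
  if (!is.null(counter)) {
    counter$string_comparisons <- counter$string_comparisons + length(others)
    counter$char_comparisons <- counter$char_comparisons + length(others) * cond$l
  }
  dists <- colSums(t(index$mat[others, , drop = FALSE]) != index$mat[i, ])
  any(dists <= cond$d)
}

#' Uniqueness of one candidate occurrence
#'
#' A pattern occurrence is unique when no occurrence at any other database
#' position is within hamming distance d' of it. The search space is the
#' union over partition slots of the similar entries of the pattern's keys;
#' pigeonhole filtration guarantees this union contains every near match.
#'
#' @param p a one-row data.frame occurrence (seq_index, offset, length).
#' @param index a \code{\link{build_index}} result.
#' @param counter optional \code{\link{new_counter}} to accumulate work.
#' @return logical.
#' @export
is_unique <- function(p, index, counter = NULL) {
  stopifnot(inherits(index, "pattern_index"))
  i <- which(index$occ$seq_index == p$seq_index[1L] &
             index$occ$offset == p$offset[1L])
  if (length(i) != 1L)
    stop("occurrence not present in index")
  for (slot in seq_len(nrow(index$scheme)) - 1L)
    if (slot_hit(index, i, slot, counter)) return(FALSE)
  TRUE
}

# Assemble a signature_set from surviving occurrence rows (deduplicated by
# string, first position kept), sorted by position.
as_signature_set <- function(db, occ, l, d) {
  if (nrow(occ) > 0L) {
    occ <- occ[order(occ$seq_index, occ$offset), , drop = FALSE]
    s <- occ_strings(db, occ)
    keep <- !duplicated(s)
    occ <- occ[keep, , drop = FALSE]
    s <- s[keep]
  } else s <- character(0)
  structure(
    list(l = as.integer(l), d = as.integer(d),
         members = data.frame(
           seq_index = occ$seq_index, offset = occ$offset,
           seq_name = db$names[occ$seq_index + 1L], string = s,
           stringsAsFactors = FALSE)),
    class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature set Omega_(%d,%d): %d unique signature(s)\n",
              x$l, x$d, nrow(x$members)))
  n_show <- min(10L, nrow(x$members))
  if (n_show > 0L)
    print(utils::head(x$members, n_show), row.names = FALSE)
  if (nrow(x$members) > n_show)
    cat(sprintf("  ... and %d more\n", nrow(x$members) - n_show))
  invisible(x)
}

#' @exportS3Method base::summary
summary.signature_set <- function(object, ...) {
  cat(sprintf("Omega_(%d,%d): %d signature(s) across %d record(s)\n",
              object$l, object$d, nrow(object$members),
              length(unique(object$members$seq_index))))
  invisible(object)
}

#' @exportS3Method base::as.data.frame
as.data.frame.signature_set <- function(x, ...) x$members

#' @export
length.signature_set <- function(x) nrow(x$members)

#' Incremental parallel signature discovery (PISD)
#'
#' Verifies a candidate set against every pattern of the database under one
#' discovery condition, keeping exactly the candidates with no other
#' occurrence within hamming distance d'. Candidates normally come from a
#' previously discovered signature set under a looser condition
#' (\code{\link{derive_candidates}}); passing all occurrences reproduces the
#' stand-alone UO / IMUS algorithms (\code{\link{full_discover}}).
#'
#' The index entries form the task list. With \code{scheduler = "pel"} and
#' \code{workers > 1} the list is reordered (heavy entries first, the
#' heaviest split into per-worker parts) by \code{\link{pel_schedule}}.
#' Tasks are executed sequentially in schedule order inside one R process;
#' each task eliminates candidates independently and the result is the
#' intersection of survivors, so the signature set is byte-identical for any
#' worker count and any task order. \code{workers} affects only the schedule
#' and the simulated dispatch available via \code{\link{greedy_dispatch}}.
#'
#' @param db a \code{\link{sig_db}}.
#' @param cond a \code{\link{discovery_condition}}.
#' @param candidates data.frame of l'-occurrences to verify.
#' @param workers number of workers the schedule is built for (>= 1).
#' @param scheduler \code{"pel"} or \code{"none"} (natural entry order).
#' @param counter optional \code{\link{new_counter}}.
#' @return A \code{signature_set}.
#' @export
pisd_discover <- function(db, cond, candidates, workers = 1L,
                          scheduler = c("pel", "none"), counter = NULL) {
  stopifnot(inherits(db, "sig_db"), inherits(cond, "discovery_condition"))
  scheduler <- match.arg(scheduler)
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L)
    stop("workers must be >= 1")
  if (nrow(candidates) == 0L)
    return(as_signature_set(db, candidates, cond$l, cond$d))
  index <- build_index(db, cond, candidates)
  tasks <- index_tasks(index)
  if (scheduler == "pel" && workers > 1L && nrow(tasks) > 0L)
    tasks <- pel_schedule(tasks, workers)
  killed <- logical(nrow(index$occ))
  for (t in seq_len(nrow(tasks))) {
    # all candidates of a task share the entry key, so the similar-entry
    # pool is looked up once per task
    ents <- similar_entries(index, tasks$key[t], tasks$slot[t])
    pool <- unlist(lapply(ents, `[[`, "occ_idx"), use.names = FALSE)
    for (i in task_candidates(index, tasks, t)) {
      if (killed[i]) next
      others <- pool[pool != i]
      if (length(others) == 0L) next
      if (!is.null(counter)) {
        counter$string_comparisons <- counter$string_comparisons + length(others)
        counter$char_comparisons <- counter$char_comparisons + length(others) * cond$l
      }
      dists <- colSums(t(index$mat[others, , drop = FALSE]) != index$mat[i, ])
      if (any(dists <= cond$d)) killed[i] <- TRUE
    }
  }
  surv <- which(index$is_candidate & !killed)
  as_signature_set(db, index$occ[surv, , drop = FALSE], cond$l, cond$d)
}

# Task list of an index: one task per entry holding >= 1 candidate.
index_tasks <- function(index) {
  sizes <- index_entry_sizes(index)
  sizes <- sizes[sizes$n_candidates > 0L, , drop = FALSE]
  if (nrow(sizes) == 0L)
    return(data.frame(id = character(0), key = character(0),
                      slot = integer(0), count = integer(0),
                      part = integer(0), n_parts = integer(0)))
  data.frame(id = paste0(sizes$slot, "|", sizes$key), key = sizes$key,
             slot = sizes$slot, count = sizes$n_candidates,
             part = 1L, n_parts = 1L, stringsAsFactors = FALSE)
}

# Candidate occ rows a task must verify (the leading candidate block of its
# entry, restricted to the task's split part when the entry was divided).
task_candidates <- function(index, tasks, t) {
  e <- index_entry(index, tasks$key[t], tasks$slot[t])
  cand <- e$occ_idx[seq_len(e$candidate_end)]
  np <- tasks$n_parts[t]
  if (np == 1L) return(cand)
  sizes <- split_counts(length(cand), np)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  p <- tasks$part[t]
  if (sizes[p] == 0L) integer(0) else cand[starts[p]:ends[p]]
}

#' Full (stand-alone) discovery under one condition
#'
#' Runs \code{\link{pisd_discover}} with every l'-occurrence as a candidate:
#' the UO algorithm for \code{kernel = "UO"}, the IMUS algorithm (without its
#' optional frequency pre-filter) for \code{kernel = "IMUS"}.
#'
#' @inheritParams pisd_discover
#' @return A \code{signature_set}.
#' @export
full_discover <- function(db, cond, workers = 1L,
                          scheduler = c("pel", "none"), counter = NULL) {
  pisd_discover(db, cond, extract_occurrences(db, cond$l),
                workers = workers, scheduler = scheduler, counter = counter)
}

#' Brute-force discovery oracle
#'
#' All-pairs hamming comparison over every occurrence pair; quadratic in the
#' number of occurrences, intended for validation on small inputs.
#'
#' @param db a \code{\link{sig_db}}.
#' @param l signature length.
#' @param d mismatch tolerance.
#' @return A \code{signature_set} with the identical contract to
#'   \code{\link{full_discover}}.
#' @export
brute_force_discover <- function(db, l, d) {
  stopifnot(inherits(db, "sig_db"))
  occ <- extract_occurrences(db, l)
  n <- nrow(occ)
  if (n == 0L) return(as_signature_set(db, occ, l, d))
  m <- occ_matrix(db, occ)
  dist <- matrix(0L, n, n)
  for (j in seq_len(ncol(m)))
    dist <- dist + outer(m[, j], m[, j], "!=")
  diag(dist) <- l + 1L  # an occurrence never disqualifies itself
  uniq <- apply(dist, 1L, function(r) all(r > d))
  as_signature_set(db, occ[uniq, , drop = FALSE], l, d)
}
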