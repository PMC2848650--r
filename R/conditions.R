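#' Discovery condition
#'
#' A discovery condition is the pair (l', d') -- signature length and mismatch
#' tolerance -- together with the filtration kernel. The kernel fixes the
#' pigeonhole partition scheme used to index patterns:
#' \describe{
#'   \item{UO}{lambda = floor(d'/2) + 1 partitions, key tolerance beta = 1.}
#'   \item{IMUS}{lambda = 2 partitions (halves), beta = floor(d'/2).}
#' }
#' Both choices guarantee that if two l'-patterns are within hamming distance
#' d', at least one aligned partition pair is within beta mismatches, so the
#' key neighborhood of an index entry covers every near match.
#'
#' @param l signature length l' (bases).
#' @param d mismatch tolerance d' (1 <= d < l).
#' @param kernel \code{"UO"} or \code{"IMUS"}.
#' @return An object of class \code{discovery_condition} with fields
#'   \code{l}, \code{d}, \code{kernel}, \code{lambda}, \code{beta}.
#' @export
discovery_condition <- function(l, d, kernel = c("UO", "IMUS")) {
  kernel <- match.arg(toupper(kernel), c("UO", "IMUS"))
  l <- as.integer(l); d <- as.integer(d)
  if (is.na(l) || is.na(d) || d < 1L || d >= l)
    stop("need 1 <= d < l; got l=", l, ", d=", d)
  lambda <- if (kernel == "UO") d %/% 2L + 1L else 2L
  beta   <- if (kernel == "UO") 1L else d %/% 2L
  structure(list(l = l, d = d, kernel = kernel, lambda = lambda, beta = beta),
            class = "discovery_condition")
}

#' @export
print.discovery_condition <- function(x, ...) {
  cat(sprintf("discovery condition (l'=%d, d'=%d), kernel %s: lambda=%d partitions, key tolerance beta=%d\n",
              x$l, x$d, x$kernel, x$lambda, x$beta))
  invisible(x)
}

#' Partition scheme of a condition
#'
#' Tiles [0, l') into lambda contiguous parts as equal as possible. When
#' lambda does not divide l', part lengths differ by one with the longer
#' parts first; the pigeonhole bound still holds (if every part exceeded
#' beta mismatches, the total would exceed d').
#'
#' @param cond a \code{\link{discovery_condition}}.
#' @return data.frame with columns \code{start} (0-based) and \code{length},
#'   one row per partition slot.
#' @export
make_scheme <- function(cond) {
  stopifnot(inherits(cond, "discovery_condition"))
  lambda <- cond$lambda
  if (lambda > cond$l)
    stop("partition count ", lambda, " exceeds pattern length ", cond$l,
         " (index keys would be empty)")
  base <- cond$l %/% lambda
  extra <- cond$l %% lambda
  lens <- rep.int(base, lambda) + as.integer(seq_len(lambda) <= extra)
  data.frame(start = cumsum(c(0L, lens[-lambda])), length = lens)
}

#' Hamming-ball key neighborhood
#'
#' All DNA strings of the same length within hamming distance \code{beta}
#' of \code{key}, including \code{key} itself. For beta = 1 this is the key
#' plus its 3*alpha single-base permutations.
#'
#' @param key a string over \{A,C,G,T\}.
#' @param beta maximum key mismatch count (>= 0).
#' @return character vector of neighbor keys (unique, key first).
#' @export
neighbor_keys <- function(key, beta) {
  beta <- as.integer(beta)
  stopifnot(beta >= 0L)
  alpha <- nchar(key)
  bases <- c("A", "C", "G", "T")
  code <- match(strsplit(key, "", fixed = TRUE)[[1L]], bases)
  if (anyNA(code)) stop("key must be over {A,C,G,T}")
  b <- min(beta, alpha)
  blocks <- list(matrix(code, 1L, alpha))
  for (m in seq_len(b)) {
    pos <- utils::combn(alpha, m)
    subs <- as.matrix(expand.grid(rep(list(1:3), m)))  # 3^m substitution combos
    for (j in seq_len(ncol(pos))) {
      p <- pos[, j]
      block <- matrix(code, nrow(subs), alpha, byrow = TRUE)
      for (t in seq_len(m)) {
        alt <- (1:4)[-code[p[t]]]    # substituted base always differs
        block[, p[t]] <- alt[subs[, t]]
      }
      blocks[[length(blocks) + 1L]] <- block
    }
  }
  M <- do.call(rbind, blocks)
  do.call(paste0, lapply(seq_len(alpha), function(j) bases[M[, j]]))
}

#' Build the slot-annotated pattern index
#'
#' Every l'-occurrence of the database is listed once per partition slot,
#' under the key equal to its slot substring. Within each entry the candidate
#' occurrences come first and \code{candidate_end} counts them, so uniqueness
#' checking touches only the leading block.
#'
#' @param db a \code{\link{sig_db}}.
#' @param cond a \code{\link{discovery_condition}}.
#' @param candidates data.frame of l'-occurrences (seq_index, offset, length)
#'   to be verified; every other occurrence is compared against but never
#'   verified itself.
#' @return An object of class \code{pattern_index}.
#' @export
build_index <- function(db, cond, candidates) {
  stopifnot(inherits(db, "sig_db"), inherits(cond, "discovery_condition"))
  occ <- extract_occurrences(db, cond$l)
  if (nrow(candidates) > 0 && any(candidates$length != cond$l))
    stop("candidate occurrences must have length l' = ", cond$l)
  scheme <- make_scheme(cond)
  occ_key <- paste(occ$seq_index, occ$offset)
  cand_key <- paste(candidates$seq_index, candidates$offset)
  if (!all(cand_key %in% occ_key))
    stop("candidate occurrences must be l'-occurrences of the database")
  is_cand <- occ_key %in% cand_key

  mat <- occ_matrix(db, occ)
  # order candidates first, stable, so every entry lists candidates before
  # non-candidates by construction
  ord <- order(!is_cand)
  occ <- occ[ord, , drop = FALSE]
  mat <- mat[ord, , drop = FALSE]
  is_cand <- is_cand[ord]

  entries <- new.env(parent = emptyenv(), hash = TRUE)
  rec <- db$seqs[occ$seq_index + 1L]
  for (s in seq_len(nrow(scheme))) {
    keys <- substring(rec, occ$offset + scheme$start[s] + 1L,
                      occ$offset + scheme$start[s] + scheme$length[s])
    by_key <- split(seq_len(nrow(occ)), keys)
    for (k in names(by_key)) {
      idx <- by_key[[k]]                      # already candidate-first
      assign(paste0(s - 1L, "|", k),
             list(occ_idx = idx, candidate_end = sum(is_cand[idx])),
             envir = entries)
    }
  }
  structure(
    list(condition = cond, scheme = scheme, entries = entries,
         occ = occ, mat = mat, is_candidate = is_cand, db = db),
    class = "pattern_index")
}

#' @export
print.pattern_index <- function(x, ...) {
  cat(sprintf("pattern index: %d occurrences x %d slots, %d entries, %d candidates\n",
              nrow(x$occ), nrow(x$scheme), length(ls(x$entries)),
              sum(x$is_candidate)))
  print(x$condition)
  invisible(x)
}

# Fetch one entry (occ indices + candidate_end) or NULL.
index_entry <- function(index, key, slot) {
  nm <- paste0(slot, "|", key)
  if (exists(nm, envir = index$entries, inherits = FALSE))
    get(nm, envir = index$entries, inherits = FALSE)
  else NULL
}

#' Similar entries of an index key
#'
#' The entries of the same partition slot whose keys are within the kernel's
#' key tolerance beta of \code{key}. By the pigeonhole observations these
#' entries contain every pattern within hamming distance d' of any pattern
#' stored under \code{key}.
#'
#' @param index a \code{\link{build_index}} result.
#' @param key an alpha-mer key string.
#' @param slot 0-based partition slot index.
#' @return list of entries, each a list with \code{occ_idx} and
#'   \code{candidate_end}.
#' @export
similar_entries <- function(index, key, slot) {
  stopifnot(inherits(index, "pattern_index"))
  slot <- as.integer(slot)
  if (slot < 0L || slot >= nrow(index$scheme))
    stop("slot out of range")
  nbr <- neighbor_keys(key, index$condition$beta)
  res <- mget(paste0(slot, "|", nbr), envir = index$entries,
              ifnotfound = list(NULL))
  res <- res[!vapply(res, is.null, logical(1))]
  names(res) <- sub("^[0-9]+\\|", "", names(res))
  res
}

#' Dump entry sizes for debugging
#'
#' @param index a \code{pattern_index}.
#' @return data.frame (key, slot, n_candidates, n_total), one row per entry.
#' @export
index_entry_sizes <- function(index) {
  stopifnot(inherits(index, "pattern_index"))
  nms <- ls(index$entries)
  parts <- strsplit(nms, "|", fixed = TRUE)
  ents <- lapply(nms, get, envir = index$entries)
  data.frame(
    key = vapply(parts, `[`, character(1), 2L),
    slot = as.integer(vapply(parts, `[`, character(1), 1L)),
    n_candidates = vapply(ents, `[[`, integer(1), "candidate_end"),
    n_total = vapply(ents, function(e) length(e$occ_idx), integer(1)),
    stringsAsFactors = FALSE)
}
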