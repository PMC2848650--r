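#' Derive candidate occurrences for a stricter condition
#'
#' A signature under (l', d') with l' <= x and d' >= y must be a substring of
#' some signature under the looser condition (x, y). This expands a source
#' signature set into the complete candidate set for a stricter target:
#' the source occurrences themselves when lengths match, otherwise every
#' length-l' sub-occurrence of every source member (x - l' + 1 windows each),
#' deduplicated by position.
#'
#' @param source a \code{\link{signature_set}} at the looser condition (x, y).
#' @param l_target target signature length l' (<= x).
#' @param d_target target tolerance d' (>= y).
#' @return data.frame of occurrences (seq_index, offset, length).
#' @export
derive_candidates <- function(source, l_target, d_target) {
  stopifnot(inherits(source, "signature_set"))
  l_target <- as.integer(l_target); d_target <- as.integer(d_target)
  if (l_target > source$l || d_target < source$d)
    stop("source condition (", source$l, ",", source$d,
         ") is not looser than target (", l_target, ",", d_target, ")")
  m <- source$members
  if (nrow(m) == 0L)
    return(data.frame(seq_index = integer(0), offset = integer(0),
                      length = integer(0)))
  shift <- 0L:(source$l - l_target)
  out <- data.frame(
    seq_index = rep(m$seq_index, each = length(shift)),
    offset    = rep(m$offset, each = length(shift)) + shift,
    length    = l_target)
  out <- out[!duplicated(paste(out$seq_index, out$offset)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate the implicit-signature condition grid
#'
#' @param l,d the user's discovery condition (grid corner).
#' @param l_min lower bound on signature length.
#' @param d_max upper bound on mismatch tolerance.
#' @return data.frame of (l, d) rows, ordered l descending then d ascending;
#'   each row satisfies d < l.
#' @export
condition_grid <- function(l, d, l_min, d_max) {
  stopifnot(l_min >= 1L, l_min <= l, d_max >= d)
  grid <- expand.grid(d = seq.int(d, d_max), l = seq.int(l, l_min))
  grid <- grid[grid$d < grid$l, c("l", "d"), drop = FALSE]
  if (nrow(grid) == 0L) stop("impossible grid: no condition satisfies d < l")
  rownames(grid) <- NULL
  grid
}

#' Consecutive multiple discovery (CMD)
#'
#' Discovers every implicit signature of the condition (l, d): all unique
#' signatures of length l' <= l and tolerance d' >= d within the bounds
#' [l_min, l] x [d, d_max]. The seed condition (l, d) is computed by full
#' stand-alone discovery; every other grid condition is verified
#' incrementally from the tightest previously computed superset:
#' Omega(l', d'-1) along the tolerance axis, substring-derived candidates
#' from Omega(l'+1, d) along the length axis. Grid conditions whose kernel
#' partition scheme degenerates (more partitions than bases) are skipped
#' with a warning.
#'
#' @param db a \code{\link{sig_db}}.
#' @param l,d discovery condition (seed corner of the grid).
#' @param l_min smallest signature length enumerated (default
#'   \code{max(12, 2*lambda)} where lambda is the partition count at d_max).
#' @param d_max largest tolerance enumerated (default \code{d + 2}).
#' @param kernel \code{"UO"} or \code{"IMUS"}.
#' @param workers scheduling worker count passed to the kernel.
#' @param scheduler \code{"pel"} or \code{"none"}.
#' @return An object of class \code{cmd_result}: list with \code{grid},
#'   \code{sets} (named list of \code{signature_set}, names "l<l'>_d<d'>"),
#'   \code{provenance} (named character: "full" for the seed, otherwise the
#'   source condition name), and \code{skipped}.
#' @export
cmd_discover <- function(db, l, d, l_min = NULL, d_max = NULL,
                         kernel = c("UO", "IMUS"), workers = 1L,
                         scheduler = c("pel", "none")) {
  stopifnot(inherits(db, "sig_db"))
  kernel <- match.arg(toupper(kernel), c("UO", "IMUS"))
  scheduler <- match.arg(scheduler)
  l <- as.integer(l); d <- as.integer(d)
  if (is.null(d_max)) d_max <- d + 2L
  d_max <- min(as.integer(d_max), l - 1L)
  lambda_max <- if (kernel == "UO") d_max %/% 2L + 1L else 2L
  if (is.null(l_min)) l_min <- min(l, max(12L, 2L * lambda_max))
  l_min <- as.integer(l_min)
  grid <- condition_grid(l, d, l_min, d_max)

  cond_name <- function(li, di) sprintf("l%d_d%d", li, di)
  sets <- list(); provenance <- character(0); skipped <- character(0)
  for (i in seq_len(nrow(grid))) {
    li <- grid$l[i]; di <- grid$d[i]
    nm <- cond_name(li, di)
    cond <- discovery_condition(li, di, kernel)
    if (cond$lambda > li) {
      warning("skipping degenerate condition (", li, ",", di,
              "): partition count exceeds length")
      skipped <- c(skipped, nm)
      next
    }
    if (li == l && di == d) {
      sets[[nm]] <- full_discover(db, cond, workers = workers,
                                  scheduler = scheduler)
      provenance[nm] <- "full"
    } else {
      src_nm <- if (di > d) cond_name(li, di - 1L) else cond_name(li + 1L, d)
      if (is.null(sets[[src_nm]])) {
        # source itself was skipped; fall back to full discovery
        sets[[nm]] <- full_discover(db, cond, workers = workers,
                                    scheduler = scheduler)
        provenance[nm] <- "full"
      } else {
        cands <- derive_candidates(sets[[src_nm]], li, di)
        sets[[nm]] <- pisd_discover(db, cond, cands, workers = workers,
                                    scheduler = scheduler)
        provenance[nm] <- src_nm
      }
    }
  }
  structure(
    list(l = l, d = d, l_min = l_min, d_max = d_max, kernel = kernel,
         grid = grid, sets = sets, provenance = provenance,
         skipped = skipped),
    class = "cmd_result")
}

#' @export
print.cmd_result <- function(x, ...) {
  cat(sprintf("CMD implicit-signature discovery, kernel %s, grid l in [%d,%d], d in [%d,%d]\n",
              x$kernel, x$l_min, x$l, x$d, x$d_max))
  for (nm in names(x$sets))
    cat(sprintf("  %s: %d signature(s)  [candidates from %s]\n",
                nm, nrow(x$sets[[nm]]$members), x$provenance[nm]))
  if (length(x$skipped))
    cat("  skipped degenerate conditions:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.cmd_result <- function(object, ...) {
  counts <- vapply(object$sets, function(s) nrow(s$members), integer(1))
  cat(sprintf("%d condition(s), %d signature(s) in total\n",
              length(object$sets), sum(counts)))
  invisible(data.frame(condition = names(counts), n_signatures = counts,
                       provenance = object$provenance[names(counts)],
                       row.names = NULL))
}

#' Write CMD outputs and a run manifest
#'
#' One TSV per grid condition plus a JSON manifest recording the database
#' summary, grid, kernel, worker count, per-condition file names, signature
#' counts and candidate provenance, so a run is reproducible from the
#' manifest alone.
#'
#' @param res a \code{cmd_result}.
#' @param out_dir output directory (created if missing).
#' @param db_path input database path recorded in the manifest (optional).
#' @param extra named list merged into the manifest (e.g. the merged run
#'   configuration).
#' @return Invisibly, the manifest path.
#' @export
write_cmd_result <- function(res, out_dir, db_path = NA_character_,
                             extra = list()) {
  stopifnot(inherits(res, "cmd_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(res$sets)) {
    f <- file.path(out_dir, paste0("signatures_", nm, ".tsv"))
    write_signatures(res$sets[[nm]], f, "tsv")
    files[nm] <- basename(f)
  }
  manifest <- c(list(
    db_path = db_path, kernel = res$kernel,
    l = res$l, d = res$d, l_min = res$l_min, d_max = res$d_max,
    conditions = names(res$sets),
    n_signatures = vapply(res$sets, function(s) nrow(s$members), integer(1)),
    provenance = as.list(res$provenance),
    skipped = res$skipped, files = as.list(files)), extra)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}
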