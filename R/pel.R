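# Split a count into n near-equal parts, floor(c/n) first, remainders
# distributed to the later parts (e.g. 143 over 2 workers -> 71, 72).
split_counts <- function(count, n) {
  sizes <- rep.int(count %/% n, n)
  rem <- count %% n
  if (rem > 0L)
    sizes[(n - rem + 1L):n] <- sizes[(n - rem + 1L):n] + 1L
  sizes
}

#' Parallel entry list (PEL) scheduling heuristic
#'
#' Reorders a task list so that heavy tasks (more candidate patterns) come
#' first, then splits the heaviest surviving tasks into one part per worker.
#' The heuristic is an iterative partial partition, similar in spirit to one
#' side of quicksort but linear-time: each iteration computes the floored
#' mean g of the current working region, swaps the leftmost count <= g with
#' the rightmost count > g until the scans cross, and shrinks the region to
#' the crossing point w. Iterations continue while w exceeds the worker
#' count n; the final first w tasks are each divided into n near-equal parts
#' which are prepended to the list.
#'
#' If at some iteration no task in the region exceeds g (all counts equal),
#' the list is returned as scanned so far with no splits.
#'
#' @param tasks data.frame with at least columns \code{id} and \code{count}
#'   (candidate patterns per task; the cost proxy). Extra columns are
#'   carried through; \code{part}/\code{n_parts} columns are added/updated
#'   for split parts.
#' @param n number of workers (>= 1).
#' @return The reordered (and possibly split) task data.frame, with
#'   attributes \code{trace} (data.frame: iteration, g, w after the
#'   iteration) and \code{visits} (elements inspected across all partition
#'   scans; O(N)).
#' @export
pel_schedule <- function(tasks, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("worker count n must be >= 1")
  if (nrow(tasks) == 0L) stop("task list is empty")
  if (is.null(tasks$part)) tasks$part <- 1L
  if (is.null(tasks$n_parts)) tasks$n_parts <- 1L
  cnt <- as.numeric(tasks$count)
  ord <- seq_len(nrow(tasks))
  w <- length(ord)
  visits <- 0L
  trace <- list()
  it <- 0L
  split_w <- 0L
  repeat {
    it <- it + 1L
    g <- floor(sum(cnt[ord[seq_len(w)]]) / w)
    k <- 1L; r <- w
    repeat {
      while (k <= w && { visits <- visits + 1L; cnt[ord[k]] > g }) k <- k + 1L
      while (r >= 1L && { visits <- visits + 1L; cnt[ord[r]] <= g }) r <- r - 1L
      if (r < k) break
      tmp <- ord[k]; ord[k] <- ord[r]; ord[r] <- tmp
      k <- k + 1L; r <- r - 1L
    }
    trace[[it]] <- data.frame(iteration = it, g = g, w = max(r, 0L))
    if (r < 1L) { split_w <- 0L; break }   # nothing exceeds g: degenerate region
    w <- r
    if (w <= n) { split_w <- w; break }
  }
  out <- tasks[ord, , drop = FALSE]
  if (split_w > 0L && n > 1L) {
    head_tasks <- out[seq_len(split_w), , drop = FALSE]
    rest <- out[-seq_len(split_w), , drop = FALSE]
    parts <- do.call(rbind, lapply(seq_len(split_w), function(i) {
      p <- head_tasks[rep(i, n), , drop = FALSE]
      p$count <- split_counts(head_tasks$count[i], n)
      p$part <- seq_len(n)
      p$n_parts <- rep.int(n, n)
      p
    }))
    out <- rbind(parts, rest)
  }
  rownames(out) <- NULL
  attr(out, "trace") <- do.call(rbind, trace)
  attr(out, "visits") <- visits
  out
}

#' Greedy earliest-available dispatch
#'
#' Simulates workers claiming tasks from the ordered list: each task goes to
#' the worker that becomes free first (ties broken by lower worker id), with
#' task time equal to its candidate count. Returns the per-worker
#' assignments, loads t_i and the makespan T_n = max(t_i).
#'
#' @param tasks ordered task data.frame (columns \code{id}, \code{count}).
#' @param n number of workers (>= 1).
#' @return An object of class \code{dispatch_result}: list with
#'   \code{assignment} (per-worker list of task row indices),
#'   \code{task_ids} (per-worker id vectors), \code{loads}, \code{makespan}.
#' @export
greedy_dispatch <- function(tasks, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("worker count n must be >= 1")
  avail <- numeric(n)
  assignment <- rep(list(integer(0)), n)
  for (t in seq_len(nrow(tasks))) {
    wkr <- which.min(avail)          # ties -> lowest worker id
    assignment[[wkr]] <- c(assignment[[wkr]], t)
    avail[wkr] <- avail[wkr] + tasks$count[t]
  }
  structure(
    list(assignment = assignment,
         task_ids = lapply(assignment, function(ix) tasks$id[ix]),
         loads = avail, makespan = max(avail)),
    class = "dispatch_result")
}

#' @export
print.dispatch_result <- function(x, ...) {
  cat(sprintf("greedy dispatch over %d worker(s), makespan T_n = %g\n",
              length(x$loads), x$makespan))
  for (i in seq_along(x$loads))
    cat(sprintf("  worker %d (load %g): %s\n", i, x$loads[i],
                paste(x$task_ids[[i]], collapse = ", ")))
  invisible(x)
}

#' Dump a schedule with simulated worker assignment
#'
#' @param tasks ordered task data.frame.
#' @param n worker count.
#' @param path optional TSV output path; when NULL the data.frame is
#'   returned only.
#' @return data.frame (id, count, worker) in schedule order.
#' @export
schedule_dump <- function(tasks, n, path = NULL) {
  disp <- greedy_dispatch(tasks, n)
  worker <- integer(nrow(tasks))
  for (i in seq_along(disp$assignment))
    worker[disp$assignment[[i]]] <- i
  out <- data.frame(id = tasks$id, count = tasks$count, worker = worker)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
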