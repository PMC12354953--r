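# Task construction, meta-train/meta-test splitting, and dynamic episodic
# sampling of class-balanced support sets with disjoint query sets.

#' Build per-property tasks from a property matrix
#'
#' Each property column becomes one binary task holding only the molecules
#' whose label is defined for it.
#'
#' @param pm a [property_matrix()].
#' @return a named list of tasks, each `list(name, molecule_ids, labels)`.
#' @export
tasks_from_matrix <- function(pm) {
  out <- lapply(seq_along(pm$task_names), function(j) {
    ids <- which(!is.na(pm$labels[, j]))
    list(name = pm$task_names[j],
         molecule_ids = ids,
         labels = as.integer(pm$labels[ids, j]))
  })
  names(out) <- pm$task_names
  out
}

#' Split tasks into meta-training and meta-testing pools
#'
#' Schemes: `"last_n"` holds out the final `n` property columns (the split
#' convention for most benchmark matrices); `"first_and_last"` holds out the
#' first 5 and last 5 columns; `"explicit"` takes the names in `test_tasks`;
#' `"provider_prefix"` groups tasks by the name prefix before the first
#' underscore and holds out the last `n` tasks of every group.
#'
#' @param pm a [property_matrix()] (or a task list from
#'   [tasks_from_matrix()]).
#' @param scheme one of `"last_n"`, `"first_and_last"`, `"explicit"`,
#'   `"provider_prefix"`.
#' @param n number of held-out tasks for `"last_n"` / per-group for
#'   `"provider_prefix"`.
#' @param test_tasks character vector of task names for `"explicit"`.
#' @return a `task_pool`: `list(meta_train, meta_test)` of task lists.
#' @export
split_tasks <- function(pm, scheme = c("last_n", "first_and_last",
                                       "explicit", "provider_prefix"),
                        n = NULL, test_tasks = NULL) {
  scheme <- match.arg(scheme)
  tasks <- if (inherits(pm, "property_matrix")) tasks_from_matrix(pm) else pm
  nm <- names(tasks)
  nt <- length(tasks)
  test_idx <- switch(scheme,
    last_n = {
      if (is.null(n)) stop("split_tasks: scheme 'last_n' needs n")
      if (n >= nt) stop("split error: n must be smaller than the task count")
      seq.int(nt - n + 1L, nt)
    },
    first_and_last = {
      if (nt <= 5) stop("split error: need more than 5 tasks")
      unique(c(1:5, seq.int(max(nt - 4L, 1L), nt)))
    },
    explicit = {
      if (is.null(test_tasks)) stop("split_tasks: scheme 'explicit' needs test_tasks")
      idx <- match(test_tasks, nm)
      if (anyNA(idx)) {
        stop("lookup error: unknown task name(s): ",
             paste(test_tasks[is.na(idx)], collapse = ", "))
      }
      idx
    },
    provider_prefix = {
      if (is.null(n)) n <- 1L
      prefix <- sub("_.*$", "", nm)
      unlist(lapply(split(seq_len(nt), prefix), function(ix) {
        if (n >= length(ix)) stop("split error: group smaller than n")
        ix[seq.int(length(ix) - n + 1L, length(ix))]
      }), use.names = FALSE)
    }
  )
  if (length(test_idx) >= nt) stop("split error: no tasks left for meta-training")
  structure(list(meta_train = tasks[-test_idx], meta_test = tasks[test_idx]),
            class = "task_pool")
}

#' @export
print.task_pool <- function(x, ...) {
  cat(sprintf("<task_pool> %d meta-train / %d meta-test tasks\n",
              length(x$meta_train), length(x$meta_test)))
  invisible(x)
}

# A task is eligible for K-shot sampling iff it has at least K+1 examples of
# each class (K for the support plus at least one query example).
task_eligible <- function(task, K) {
  n1 <- sum(task$labels == 1)
  n0 <- sum(task$labels == 0)
  n1 >= K + 1 && n0 >= K + 1
}

# Draw a balanced K+/K- support and a disjoint query set from one task.
draw_support_query <- function(task, K, query_per_class = Inf) {
  pos <- which(task$labels == 1)
  neg <- which(task$labels == 0)
  sp <- sample(pos, K)
  sn <- sample(neg, K)
  qp <- setdiff(pos, sp)
  qn <- setdiff(neg, sn)
  if (is.finite(query_per_class)) {
    if (length(qp) > query_per_class) qp <- sample(qp, query_per_class)
    if (length(qn) > query_per_class) qn <- sample(qn, query_per_class)
  }
  si <- c(sp, sn)
  qi <- c(qp, qn)
  list(
    support = list(molecule_ids = task$molecule_ids[si],
                   labels = task$labels[si]),
    query = list(molecule_ids = task$molecule_ids[qi],
                 labels = task$labels[qi])
  )
}

#' Sample one meta-training episode
#'
#' Draws `Ns` distinct eligible tasks uniformly without replacement from the
#' meta-training pool; for each task draws a class-balanced support set of
#' `K` positives and `K` negatives without replacement, then up to
#' `query_per_class` examples per class from the remaining molecules as the
#' query set. Every call uses fresh randomness (dynamic resampling).
#'
#' @param pool a `task_pool` from [split_tasks()].
#' @param Ns number of tasks per episode.
#' @param K shots per class.
#' @param query_per_class query examples per class (truncated to
#'   availability).
#' @return an `episode`: list of per-task `list(name, support, query)`.
#' @export
sample_episode <- function(pool, Ns, K, query_per_class = 16) {
  elig <- Filter(function(t) task_eligible(t, K), pool$meta_train)
  if (length(elig) < Ns) {
    bad <- Filter(function(t) !task_eligible(t, K), pool$meta_train)
    counts <- vapply(bad, function(t) {
      sprintf("%s (%d+/%d-)", t$name, sum(t$labels == 1), sum(t$labels == 0))
    }, character(1))
    stop(sprintf(
      "sampling error: only %d of %d meta-train tasks are eligible for %d-shot episodes (need %d). Ineligible: %s",
      length(elig), length(pool$meta_train), K, Ns,
      paste(counts, collapse = ", ")))
  }
  chosen <- sample(seq_along(elig), Ns)
  ep <- lapply(chosen, function(i) {
    sq <- draw_support_query(elig[[i]], K, query_per_class)
    c(list(name = elig[[i]]$name), sq)
  })
  structure(ep, class = "episode")
}

#' Split one task for test-time adaptation
#'
#' Draws a balanced `K`-shot support set; the query set is all remaining
#' labeled molecules of the task.
#'
#' @param task one task (`list(name, molecule_ids, labels)`).
#' @param K shots per class.
#' @return `list(support, query)`, each with `molecule_ids` and `labels`.
#' @export
make_adaptation_split <- function(task, K) {
  if (!task_eligible(task, K)) {
    stop(sprintf(
      "sampling error: task '%s' has %d positives / %d negatives; %d-shot adaptation needs at least %d of each",
      task$name, sum(task$labels == 1), sum(task$labels == 0), K, K + 1))
  }
  draw_support_query(task, K, query_per_class = Inf)
}
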