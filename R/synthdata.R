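# Synthetic task pools with the statistical structure the meta-learner
# assumes: a shared set of random molecular-like graphs, and binary tasks
# whose labels are driven by hidden structural motifs (typed paths) drawn
# from a library shared across tasks, plus label noise and missingness.
# Molecules are serialized to genuine SMILES (via OpenBabel) so the full
# parsing/standardization path is exercised end to end.

SYNTH_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br")
SYNTH_VALENCE  <- c(4L, 3L, 2L, 2L, 3L, 1L, 1L, 1L)
# polyvalent elements are favored so graphs have internal structure
SYNTH_TYPE_WEIGHTS <- c(0.30, 0.15, 0.15, 0.10, 0.10, 0.08, 0.07, 0.05)

#' Specify a synthetic task pool
#'
#' @param n_tasks number of binary property tasks.
#' @param molecules_per_task size of the shared molecule set every task
#'   labels (minus blanked cells).
#' @param n_node_types number of element types used (first `n` of C, N, O, S,
#'   P, F, Cl, Br).
#' @param motif_library_size number of distinct label-driving motifs shared
#'   across tasks.
#' @param motif_size nodes per motif (a typed simple path).
#' @param label_noise probability of independently flipping each label.
#' @param missing_rate fraction of matrix cells blanked to missing.
#' @param positive_fraction target fraction of positive labels per task;
#'   motifs whose occurrence rate strays more than 0.3 from it are rejected.
#' @param graph_size_range integer `(min, max)` heavy-atom count per
#'   molecule.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_tasks = 30, molecules_per_task = 150,
                       n_node_types = 8, motif_library_size = 8,
                       motif_size = 3, label_noise = 0.05,
                       missing_rate = 0.1, positive_fraction = 0.5,
                       graph_size_range = c(8, 16), seed = 1) {
  stopifnot(
    n_tasks >= 1, molecules_per_task >= 4,
    n_node_types >= 2, n_node_types <= length(SYNTH_ELEMENTS),
    motif_library_size >= 1, motif_size >= 1,
    label_noise >= 0, label_noise < 0.5,
    missing_rate >= 0, missing_rate < 1,
    positive_fraction > 0, positive_fraction < 1,
    length(graph_size_range) == 2,
    graph_size_range[1] <= graph_size_range[2],
    motif_size <= graph_size_range[1]
  )
  structure(as.list(environment()), class = "synth_spec")
}

# Random connected typed graph respecting element valences: a random
# attachment tree, occasional ring-closure edges, and double-bond upgrades
# where both endpoints have spare valence.
random_typed_graph <- function(n, n_types, p_ring = 0.4, p_double = 0.25) {
  w <- SYNTH_TYPE_WEIGHTS[seq_len(n_types)]
  for (attempt in 1:50) {
    types <- sample.int(n_types, n, replace = TRUE, prob = w)
    cap <- SYNTH_VALENCE[types]
    from <- integer(0); to <- integer(0)
    used <- integer(n)
    ok <- TRUE
    for (i in seq_len(n)[-1]) {
      cand <- which(used[1:(i - 1)] < cap[1:(i - 1)])
      if (length(cand) == 0) { ok <- FALSE; break }
      j <- if (length(cand) == 1) cand else sample(cand, 1)
      from <- c(from, j); to <- c(to, i)
      used[j] <- used[j] + 1L; used[i] <- used[i] + 1L
    }
    if (!ok) next
    order_ <- rep(1L, length(from))
    # ring closure between non-adjacent nodes with spare valence
    if (n >= 4 && stats::runif(1) < p_ring) {
      spare <- which(used < cap)
      if (length(spare) >= 2) {
        pick <- sample(spare, 2)
        a <- pick[1]; b <- pick[2]
        adjacent <- any((from == a & to == b) | (from == b & to == a))
        if (!adjacent) {
          from <- c(from, a); to <- c(to, b); order_ <- c(order_, 1L)
          used[a] <- used[a] + 1L; used[b] <- used[b] + 1L
        }
      }
    }
    # double-bond upgrades
    for (e in seq_along(from)) {
      a <- from[e]; b <- to[e]
      if (used[a] < cap[a] && used[b] < cap[b] && stats::runif(1) < p_double) {
        order_[e] <- 2L
        used[a] <- used[a] + 1L; used[b] <- used[b] + 1L
      }
    }
    return(list(types = types, from = from, to = to, order = order_))
  }
  stop("generation error: could not build a valence-consistent graph; widen graph_size_range or reduce n_node_types")
}

# V2000 MOL block for a typed graph (no coordinates needed).
graph_to_molblock <- function(g) {
  n <- length(g$types)
  m <- length(g$from)
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, SYNTH_ELEMENTS[g$types])
  bond_lines <- if (m > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", g$from, g$to, g$order)
  } else character(0)
  paste(c("", " synthetic", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m),
          atom_lines, bond_lines, "M  END", "$$$$"),
        collapse = "\n")
}

# Canonical SMILES for a typed graph via OpenBabel.
graph_to_smiles <- function(g) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SDF", "SMI", source = graph_to_molblock(g)),
    error = function(e) "")
  out <- sub("[\t\n ].*$", "", out)
  if (!nzchar(out)) return(NA_character_)
  out
}

#' Exhaustive motif-occurrence oracle
#'
#' Tests whether a typed path motif occurs as a simple path in a molecule
#' graph, by exhaustive depth-first search over simple paths. Independent of
#' the generator's bookkeeping; used to audit generated labels.
#'
#' @param graph a [molecule_graph()] or a generator graph
#'   (`list(types, from, to)`).
#' @param motif integer vector of node types along the path.
#' @param type_of optional function mapping the graph's node codes to motif
#'   type indices; defaults to identity for generator graphs and to the
#'   synthetic element mapping for [molecule_graph()]s.
#' @return 1 if the motif occurs, 0 otherwise.
#' @export
oracle_labels <- function(graph, motif, type_of = NULL) {
  if (inherits(graph, "molecule_graph")) {
    z <- graph$node_atom_type
    types <- match(z, element_to_index(SYNTH_ELEMENTS))
    from <- graph$edge_index[, 1]
    to <- graph$edge_index[, 2]
    # directed edges already contain both directions
    adj <- split(to, factor(from, levels = seq_len(graph$n_nodes)))
  } else {
    types <- graph$types
    n <- length(types)
    from <- c(graph$from, graph$to)
    to <- c(graph$to, graph$from)
    adj <- split(to, factor(from, levels = seq_len(n)))
  }
  m <- length(motif)
  if (m > length(types)) return(0L)
  visit <- function(v, pos, visited) {
    if (is.na(types[v]) || types[v] != motif[pos]) return(FALSE)
    if (pos == m) return(TRUE)
    for (u in adj[[v]]) {
      if (!visited[u]) {
        visited[u] <- TRUE
        if (visit(u, pos + 1L, visited)) return(TRUE)
        visited[u] <- FALSE
      }
    }
    FALSE
  }
  visited <- logical(length(types))
  for (v in seq_along(types)) {
    if (!is.na(types[v]) && types[v] == motif[1]) {
      visited[] <- FALSE
      visited[v] <- TRUE
      if (visit(v, 1L, visited)) return(1L)
    }
  }
  0L
}

#' Generate a synthetic task pool
#'
#' Builds a shared set of random connected typed graphs, enumerates the
#' typed-path motif candidates (deduplicated up to reversal, which defines
#' identical labels), selects a library uniformly among those whose
#' occurrence rate over the molecule set is within 0.3 of
#' `positive_fraction`, assigns each task a motif from the library
#' (motifs recur across tasks, giving meta-test tasks the relatedness
#' meta-learning exploits), sets `label(mol, task) = 1` iff the motif occurs,
#' flips labels independently with probability `label_noise`, and blanks
#' cells at `missing_rate`. Molecules are serialized to valid SMILES.
#'
#' @param spec a [synth_spec()].
#' @return a list of class `synth_pool` with elements `matrix` (a
#'   [property_matrix()] with parsed graphs attached), `motifs` (the motif
#'   library), `task_motif` (library index per task), and `clean_labels`
#'   (the noise-free motif-presence matrix).
#' @export
generate_pool <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n_mol <- spec$molecules_per_task

  draw_molecules <- function() {
    mols <- vector("list", n_mol)
    smiles <- character(n_mol)
    for (i in seq_len(n_mol)) {
      for (attempt in 1:50) {
        n <- sample(spec$graph_size_range[1]:spec$graph_size_range[2], 1)
        g <- random_typed_graph(n, spec$n_node_types)
        s <- graph_to_smiles(g)
        if (!is.na(s)) {
          pg <- tryCatch(parse_and_standardize(s), error = function(e) NULL)
          if (!is.null(pg) && pg$n_nodes == length(g$types)) {
            mols[[i]] <- g; smiles[i] <- s
            break
          }
        }
        if (attempt == 50) {
          stop("generation error: failed to serialize a molecule to parseable SMILES")
        }
      }
    }
    list(mols = mols, smiles = smiles)
  }

  # Candidate motifs: typed paths with polyvalent interior positions. A path
  # and its reverse define identical labels, so candidates are deduplicated
  # up to reversal.
  middle_ok <- which(SYNTH_VALENCE[seq_len(spec$n_node_types)] >= 2L)
  pos_choices <- lapply(seq_len(spec$motif_size), function(j) {
    if (j == 1 || j == spec$motif_size) seq_len(spec$n_node_types)
    else middle_ok
  })
  grid <- as.matrix(expand.grid(pos_choices))
  if (nrow(grid) > 1e5) {
    stop("generation error: motif candidate space too large; reduce motif_size or n_node_types")
  }
  canon <- vapply(seq_len(nrow(grid)), function(r) {
    f <- paste(grid[r, ], collapse = "-")
    b <- paste(rev(grid[r, ]), collapse = "-")
    min(f, b)
  }, character(1))
  candidates <- grid[!duplicated(canon), , drop = FALSE]

  # Up to 3 molecule sets are drawn; each is screened for a full library of
  # motifs whose occurrence rate is within 0.3 of positive_fraction.
  n_qualified <- integer(0)
  for (attempt in 1:3) {
    dm <- draw_molecules()
    mols <- dm$mols; smiles <- dm$smiles
    presence <- vapply(seq_len(nrow(candidates)), function(r) {
      vapply(mols, oracle_labels, integer(1), motif = candidates[r, ])
    }, integer(n_mol))
    frac <- colMeans(presence)
    ok <- which(abs(frac - spec$positive_fraction) <= 0.3)
    n_qualified <- c(n_qualified, length(ok))
    if (length(ok) >= spec$motif_library_size) {
      pick <- if (length(ok) == spec$motif_library_size) ok else
        sample(ok, spec$motif_library_size)
      motifs <- lapply(pick, function(r) unname(candidates[r, ]))
      presence_cols <- lapply(pick, function(r) presence[, r])
      break
    }
    if (attempt == 3) {
      stop(sprintf(
        "generation error: only %s motifs had occurrence within 0.3 of positive_fraction=%.2f (library size %d) over 3 molecule sets; adjust positive_fraction, motif_library_size, motif_size or graph_size_range",
        paste(n_qualified, collapse = "/"), spec$positive_fraction,
        spec$motif_library_size))
    }
  }
  # cyclic assignment: every motif recurs across the task sequence, so any
  # contiguous meta-test block shares its motifs with the meta-train tasks
  # (the relatedness meta-learning exploits)
  task_motif <- rep_len(seq_along(motifs), spec$n_tasks)
  clean <- do.call(cbind, presence_cols)[, task_motif, drop = FALSE]
  labels <- clean
  if (spec$label_noise > 0) {
    flip <- matrix(stats::runif(length(labels)) < spec$label_noise,
                   nrow(labels), ncol(labels))
    labels <- abs(labels - flip)
  }
  if (spec$missing_rate > 0) {
    blank <- matrix(stats::runif(length(labels)) < spec$missing_rate,
                    nrow(labels), ncol(labels))
    labels[blank] <- NA_real_
  }
  task_names <- sprintf("task_%02d", seq_len(spec$n_tasks))
  colnames(clean) <- task_names
  pm <- property_matrix(smiles, task_names, labels)
  attr(pm, "graphs") <- lapply(smiles, parse_and_standardize)
  structure(list(matrix = pm, motifs = motifs, task_motif = task_motif,
                 clean_labels = clean, spec = spec),
            class = "synth_pool")
}

#' @export
print.synth_pool <- function(x, ...) {
  cat(sprintf("<synth_pool> %d molecules x %d tasks, %d motifs, noise=%.2f, missing=%.2f\n",
              length(x$matrix$smiles), length(x$matrix$task_names),
              length(x$motifs), x$spec$label_noise, x$spec$missing_rate))
  invisible(x)
}

#' Write a synthetic pool to disk
#'
#' Emits the molecule-property matrix as the standard CSV dialect plus a
#' JSON ground-truth sidecar (spec, motif library, task-motif assignment).
#'
#' @param pool a `synth_pool` from [generate_pool()].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_pool <- function(pool, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_property_matrix(pool$matrix, file.path(dir, "pool.csv"))
  truth <- list(spec = unclass(pool$spec), motifs = pool$motifs,
                task_motif = pool$task_motif,
                elements = SYNTH_ELEMENTS[seq_len(pool$spec$n_node_types)])
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
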