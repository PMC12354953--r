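# Molecule parsing, standardization and graph featurization.

#' Construct a molecule graph
#'
#' Low-level constructor for the typed atom-bond graph consumed by the
#' encoder. Every chemical bond is stored as two directed edges. Use
#' [parse_and_standardize()] to build one from a SMILES string.
#'
#' @param node_atom_type integer vector, atom-vocabulary index per node
#'   (atomic number, out-of-range bucket at 119).
#' @param node_chirality integer vector, index into the chirality vocabulary
#'   (`unspecified`, `tetrahedral_cw`, `tetrahedral_ccw`, `other`).
#' @param edge_index integer matrix with 2 columns `(from, to)`, one row per
#'   directed edge; zero-row matrix for bond-free molecules.
#' @param edge_bond_type integer vector, bond-type index per directed edge
#'   (`single`, `double`, `triple`, `aromatic`).
#' @param edge_bond_dir integer vector, bond-direction index per directed edge
#'   (`none`, `end_up_right`, `end_down_right`).
#' @param source_smiles optional SMILES string the graph was derived from.
#' @return an object of class `molecule_graph`.
#' @export
molecule_graph <- function(node_atom_type, node_chirality,
                           edge_index, edge_bond_type, edge_bond_dir,
                           source_smiles = NA_character_) {
  n <- length(node_atom_type)
  stopifnot(length(node_chirality) == n)
  edge_index <- matrix(as.integer(edge_index), ncol = 2)
  m <- nrow(edge_index)
  stopifnot(length(edge_bond_type) == m, length(edge_bond_dir) == m)
  if (m > 0) {
    if (any(edge_index < 1L) || any(edge_index > n)) {
      stop("molecule_graph: edge indices out of [1, n_nodes]")
    }
    if (any(edge_index[, 1] == edge_index[, 2])) {
      stop("molecule_graph: self-loops are not allowed")
    }
  }
  structure(
    list(
      node_atom_type = as.integer(node_atom_type),
      node_chirality = as.integer(node_chirality),
      edge_index = edge_index,
      edge_bond_type = as.integer(edge_bond_type),
      edge_bond_dir = as.integer(edge_bond_dir),
      n_nodes = n,
      source_smiles = source_smiles
    ),
    class = "molecule_graph"
  )
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("<molecule_graph> %d nodes, %d directed edges (%d bonds)\n",
              x$n_nodes, nrow(x$edge_index), nrow(x$edge_index) %/% 2L))
  if (!is.na(x$source_smiles)) cat("  source:", x$source_smiles, "\n")
  invisible(x)
}

# Undirected bond table -> symmetric directed edge fields.
bonds_to_directed <- function(from, to, btype, bdir_fwd = NULL, bdir_rev = NULL) {
  m <- length(from)
  if (m == 0) {
    return(list(edge_index = matrix(integer(0), ncol = 2),
                edge_bond_type = integer(0), edge_bond_dir = integer(0)))
  }
  if (is.null(bdir_fwd)) bdir_fwd <- rep(1L, m)
  if (is.null(bdir_rev)) bdir_rev <- rep(1L, m)
  list(
    edge_index = cbind(c(from, to), c(to, from)),
    edge_bond_type = as.integer(c(btype, btype)),
    edge_bond_dir = as.integer(c(bdir_fwd, bdir_rev))
  )
}

# Parse the atom lines of a V2000 MOL block (used only for bond-free
# molecules, which ChemmineR cannot represent).
v2000_atoms <- function(lines, n_atoms) {
  atom_lines <- lines[5:(4 + n_atoms)]
  sym <- trimws(substr(atom_lines, 32, 34))
  parity <- suppressWarnings(as.integer(trimws(substr(atom_lines, 40, 42))))
  parity[is.na(parity)] <- 0L
  list(symbol = sym, parity = parity)
}

# MDL atom parity: 0 = non-stereo, 1 = odd, 2 = even, 3 = either
# (a stereocenter whose configuration the input left unspecified).
parity_to_chirality <- function(parity) {
  chir <- rep(1L, length(parity))
  chir[parity == 1L] <- 2L
  chir[parity == 2L] <- 3L
  chir
}

#' Parse a SMILES string into a standardized molecule graph
#'
#' Parses a SMILES string (via OpenBabel through ChemmineOB), applies Kekule
#' conversion so aromatic rings are rewritten as alternating single/double
#' bonds, and featurizes the heavy atoms into a typed graph. Hydrogens remain
#' implicit. Node order follows the parser's atom order for the input string.
#'
#' @param smiles a single non-empty SMILES string.
#' @return a [molecule_graph()].
#' @examples
#' g <- parse_and_standardize("O=C(C)Oc1ccccc1C(=O)O") # aspirin
#' g$n_nodes                                           # 13
#' @export
parse_and_standardize <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop("parse_and_standardize: 'smiles' must be a single non-empty string")
  }
  raw <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = smiles),
    error = function(e) ""
  )
  if (!nzchar(trimws(raw))) {
    stop(sprintf("parse error: could not parse SMILES '%s'", smiles))
  }
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) {
    stop(sprintf("parse error: could not parse SMILES '%s'", smiles))
  }
  n_atoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(n_atoms) || n_atoms < 1) {
    stop(sprintf("parse error: no atoms in SMILES '%s'", smiles))
  }

  if (is.na(n_bonds) || n_bonds == 0) {
    at <- v2000_atoms(lines, n_atoms)
    eb <- bonds_to_directed(integer(0), integer(0), integer(0))
    return(molecule_graph(
      node_atom_type = element_to_index(at$symbol),
      node_chirality = parity_to_chirality(at$parity),
      edge_index = eb$edge_index,
      edge_bond_type = eb$edge_bond_type,
      edge_bond_dir = eb$edge_bond_dir,
      source_smiles = smiles
    ))
  }

  sdf <- suppressWarnings(ChemmineR::read.SDFset(lines))
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  sym <- sub("_\\d+$", "", rownames(ab))
  parity <- if ("C7" %in% colnames(ab)) as.integer(ab[, "C7"]) else
    rep(0L, nrow(ab))
  btype <- as.integer(bb[, 3])
  if (any(btype == AROMATIC_BOND)) {
    stop(sprintf(
      "standardization error: SMILES '%s' could not be kekulized (aromatic bonds remain)",
      smiles))
  }
  if (any(!btype %in% 1:3)) {
    stop(sprintf("standardization error: SMILES '%s' has unsupported bond order",
                 smiles))
  }
  eb <- bonds_to_directed(as.integer(bb[, 1]), as.integer(bb[, 2]), btype)
  molecule_graph(
    node_atom_type = element_to_index(sym),
    node_chirality = parity_to_chirality(parity),
    edge_index = eb$edge_index,
    edge_bond_type = eb$edge_bond_type,
    edge_bond_dir = eb$edge_bond_dir,
    source_smiles = smiles
  )
}

#' Construct a molecule-property matrix
#'
#' @param smiles character vector of SMILES strings, one per molecule.
#' @param task_names character vector of unique task (property) names.
#' @param labels numeric matrix, molecules x tasks, entries in `{0, 1, NA}`.
#' @return an object of class `property_matrix`.
#' @export
property_matrix <- function(smiles, task_names, labels) {
  labels <- as.matrix(labels)
  stopifnot(nrow(labels) == length(smiles),
            ncol(labels) == length(task_names))
  if (anyDuplicated(task_names)) stop("property_matrix: task names must be unique")
  bad <- !(labels %in% c(0, 1) | is.na(labels))
  if (any(bad)) stop("property_matrix: labels must be 0, 1 or NA")
  defined <- colSums(!is.na(labels))
  if (any(defined == 0)) {
    stop("property_matrix: task(s) with no defined labels: ",
         paste(task_names[defined == 0], collapse = ", "))
  }
  dimnames(labels) <- list(NULL, task_names)
  structure(list(smiles = smiles, task_names = task_names, labels = labels),
            class = "property_matrix")
}

#' @export
print.property_matrix <- function(x, ...) {
  cat(sprintf("<property_matrix> %d molecules x %d tasks (%.1f%% labels defined)\n",
              length(x$smiles), length(x$task_names),
              100 * mean(!is.na(x$labels))))
  invisible(x)
}

#' Fraction of defined labels in a property matrix
#'
#' @param pm a [property_matrix()].
#' @param per_task if `TRUE`, return one availability per task.
#' @return fraction(s) of non-missing entries in `[0, 1]`.
#' @export
label_availability <- function(pm, per_task = FALSE) {
  if (per_task) colMeans(!is.na(pm$labels)) else mean(!is.na(pm$labels))
}

#' Read a molecule-property matrix from CSV or SDF
#'
#' CSV files need a header with a SMILES column (default name `"smiles"`);
#' every remaining column is a binary task whose entries are 0, 1 or missing
#' (empty string, `NA`, `NaN`). SDF files carry task labels as property tags.
#' Rows whose SMILES fail [parse_and_standardize()] are dropped with a
#' warning reporting the count.
#'
#' @param path file path.
#' @param format `"csv"` or `"sdf"`.
#' @param smiles_col name of the SMILES column (CSV only).
#' @return a [property_matrix()]. Parsed graphs are attached as attribute
#'   `"graphs"` so downstream featurization does not re-parse.
#' @examples
#' path <- system.file("extdata", "example_matrix.csv",
#'                     package = "molfewshot")
#' pm <- read_property_matrix(path)
#' label_availability(pm)
#' @export
read_property_matrix <- function(path, format = c("csv", "sdf"),
                                 smiles_col = "smiles") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_property_matrix: no such file: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "NaN"))
    if (!smiles_col %in% names(df)) {
      stop(sprintf("format error: CSV has no '%s' column", smiles_col))
    }
    smiles <- as.character(df[[smiles_col]])
    task_names <- setdiff(names(df), smiles_col)
    lab <- as.matrix(df[task_names])
    storage.mode(lab) <- "double"
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    blocks <- ChemmineR::datablock(sdf)
    raw <- paste(readLines(path), collapse = "\n")
    smi_text <- ChemmineOB::convertFormat("SDF", "SMI", source = raw)
    smiles <- vapply(strsplit(trimws(smi_text), "\n")[[1]],
                     function(x) sub("\\s.*$", "", x), character(1),
                     USE.NAMES = FALSE)
    if (length(smiles) != length(blocks)) {
      stop("format error: could not recover one SMILES per SDF record in ",
           path)
    }
    task_names <- unique(unlist(lapply(blocks, names)))
    lab <- matrix(NA_real_, length(smiles), length(task_names),
                  dimnames = list(NULL, task_names))
    for (i in seq_along(blocks)) {
      v <- blocks[[i]]
      lab[i, names(v)] <- suppressWarnings(as.numeric(v))
    }
  }
  graphs <- vector("list", length(smiles))
  ok <- rep(TRUE, length(smiles))
  for (i in seq_along(smiles)) {
    g <- tryCatch(parse_and_standardize(smiles[i]), error = function(e) NULL)
    if (is.null(g)) ok[i] <- FALSE else graphs[[i]] <- g
  }
  if (!any(ok)) stop("empty-input error: no valid molecules in ", path)
  if (any(!ok)) {
    warning(sprintf("read_property_matrix: dropped %d molecule(s) that failed parsing/standardization",
                    sum(!ok)))
  }
  pm <- property_matrix(smiles[ok], task_names,
                        lab[ok, , drop = FALSE])
  attr(pm, "graphs") <- graphs[ok]
  pm
}

#' Write a property matrix as CSV
#'
#' Inverse of [read_property_matrix()] for the CSV dialect: a `smiles`
#' column followed by one column per task; missing labels become empty cells.
#'
#' @param pm a [property_matrix()].
#' @param path output file path.
#' @param smiles_col name for the SMILES column.
#' @return `path`, invisibly.
#' @export
write_property_matrix <- function(pm, path, smiles_col = "smiles") {
  df <- data.frame(pm$smiles, pm$labels, check.names = FALSE)
  names(df)[1] <- smiles_col
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# Featurize all molecules of a property matrix once; reuses graphs cached by
# read_property_matrix when present.
featurize_matrix <- function(pm) {
  g <- attr(pm, "graphs")
  if (!is.null(g)) return(g)
  lapply(pm$smiles, parse_and_standardize)
}
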