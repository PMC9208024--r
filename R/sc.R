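#' Construct a structural connectome
#'
#' Pairs a symmetric fractional anisotropy (FA) matrix — mean FA within
#' each reconstructed white-matter tract, 0 where no tract exists — with
#' the matching tract-length matrix in millimetres. Matrices are kept
#' unthresholded; structural presence is `fa > 0` (configurable downstream).
#'
#' @param fa Symmetric node x node matrix, values in `[0, 1]`, zero
#'   diagonal.
#' @param lengths Symmetric node x node matrix of tract lengths (mm),
#'   positive wherever `fa > 0`.
#' @param node_labels Node names; default taken from `fa` dimnames.
#' @return An object of class `structural_connectome`.
#' @export
structural_connectome <- function(fa, lengths, node_labels = NULL) {
  fa <- check_square_symmetric(fa, "fa")
  lengths <- check_square_symmetric(lengths, "lengths")
  if (!all(dim(fa) == dim(lengths))) stop("`fa` and `lengths` must have identical dimensions.", call. = FALSE)
  labels <- node_labels %||% rownames(fa) %||% paste0("node_", seq_len(nrow(fa)))
  if (length(labels) != nrow(fa)) stop("`node_labels` length must match matrix dimension.", call. = FALSE)
  diag(fa) <- 0
  diag(lengths) <- 0
  bad <- which(fa < 0 | fa > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("FA outside [0, 1] at cell (%d, %d): %g.",
                 bad[1, 1], bad[1, 2], fa[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  if (any(lengths < 0)) stop("Negative tract lengths found.", call. = FALSE)
  missing_len <- which(fa > 0 & lengths <= 0, arr.ind = TRUE)
  if (nrow(missing_len) > 0) {
    stop(sprintf("Tract present (fa > 0) but non-positive length at cell (%d, %d).",
                 missing_len[1, 1], missing_len[1, 2]), call. = FALSE)
  }
  dimnames(fa) <- dimnames(lengths) <- list(labels, labels)
  structure(list(fa = fa, lengths = lengths, node_labels = labels),
            class = "structural_connectome")
}

#' @export
print.structural_connectome <- function(x, ...) {
  cat(sprintf("<structural_connectome> %d nodes, %d present / %d possible edges (sparsity %.3f)\n",
              length(x$node_labels), sum(edge_vector(x$fa) > 0),
              n_edges_of(length(x$node_labels)), sparsity(x)))
  invisible(x)
}

#' Read a structural connectome from delimited text
#'
#' Both files must be square tab-delimited matrices with a header row of
#' node labels (as written by [write_connectome()]); labels must agree
#' between the FA and length files.
#'
#' @param fa_path,lengths_path File paths.
#' @return A [structural_connectome()].
#' @export
read_connectome <- function(fa_path, lengths_path) {
  read_square <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    m <- as.matrix(df)
    if (nrow(m) != ncol(m)) stop(sprintf("Matrix in '%s' is not square (%d x %d).", path, nrow(m), ncol(m)), call. = FALSE)
    rownames(m) <- colnames(m)
    m
  }
  fa <- read_square(fa_path)
  lengths <- read_square(lengths_path)
  if (!identical(colnames(fa), colnames(lengths))) {
    stop("Node labels differ between the FA and tract-length files.", call. = FALSE)
  }
  structural_connectome(fa, lengths)
}

#' Write a structural connectome to delimited text
#'
#' @param sc A [structural_connectome()].
#' @param fa_path,lengths_path Destination paths.
#' @return `sc`, invisibly.
#' @export
write_connectome <- function(sc, fa_path, lengths_path) {
  stopifnot(inherits(sc, "structural_connectome"))
  write_square <- function(m, path) {
    utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  }
  write_square(sc$fa, fa_path)
  write_square(sc$lengths, lengths_path)
  invisible(sc)
}

#' Sparsity of a structural connectome
#'
#' Proportion of possible edges (upper triangle) with no reconstructed
#' tract (`fa = 0`).
#'
#' @param sc A [structural_connectome()].
#' @param presence_floor Edges with `fa > presence_floor` count as present.
#' @return Fraction in `[0, 1]`.
#' @export
sparsity <- function(sc, presence_floor = 0) {
  stopifnot(inherits(sc, "structural_connectome"))
  mean(edge_vector(sc$fa) <= presence_floor)
}

#' Whole-brain structural connectivity
#'
#' Mean FA over edges. With `present_only = TRUE` (default) absent tracts
#' are excluded rather than counted as zeros, consistent with FA being a
#' per-tract average; set `FALSE` to average over all possible edges.
#'
#' @param sc A [structural_connectome()].
#' @param present_only Exclude absent edges from the mean.
#' @param presence_floor Presence threshold on FA.
#' @return Scalar mean FA.
#' @export
whole_brain_sc <- function(sc, present_only = TRUE, presence_floor = 0) {
  stopifnot(inherits(sc, "structural_connectome"))
  fa <- edge_vector(sc$fa)
  if (present_only) {
    fa <- fa[fa > presence_floor]
    if (length(fa) == 0) stop("No present edges: whole-brain SC undefined.", call. = FALSE)
  }
  mean(fa)
}

#' Tract-length range thresholds
#'
#' A pair of tract-length cutoffs (mm): edges strictly below `q1` are
#' short-range, strictly above `q3` long-range.
#'
#' @param q1,q3 Cutoffs in mm, `q1 < q3`.
#' @return An object of class `range_thresholds`.
#' @export
range_thresholds <- function(q1, q3) {
  if (!is.numeric(q1) || !is.numeric(q3) || q3 < q1) {
    stop("Need numeric thresholds with q1 <= q3.", call. = FALSE)
  }
  structure(list(q1 = as.numeric(q1), q3 = as.numeric(q3)), class = "range_thresholds")
}

#' @export
print.range_thresholds <- function(x, ...) {
  cat(sprintf("<range_thresholds> short < %.3f mm, long > %.3f mm\n", x$q1, x$q3))
  invisible(x)
}

#' Quartile thresholds from healthy-control tract lengths
#'
#' Pools the tract lengths of all present edges across the supplied
#' healthy-control connectomes and returns the 25th and 75th percentiles
#' (linear interpolation between order statistics, position
#' `(n - 1) p + 1`). These group-level cutoffs define short- and
#' long-range edge classes for every subject.
#'
#' @param hc_connectomes List of [structural_connectome()] objects.
#' @param presence_floor Presence threshold on FA.
#' @return A [range_thresholds()].
#' @export
quartile_thresholds <- function(hc_connectomes, presence_floor = 0) {
  if (inherits(hc_connectomes, "structural_connectome")) hc_connectomes <- list(hc_connectomes)
  stopifnot(length(hc_connectomes) >= 1)
  pooled <- unlist(lapply(hc_connectomes, function(sc) {
    len <- edge_vector(sc$lengths)
    len[edge_vector(sc$fa) > presence_floor]
  }), use.names = FALSE)
  if (length(pooled) < 4) stop("Fewer than 4 present edges pooled: quartiles undefined.", call. = FALSE)
  q <- stats::quantile(pooled, c(0.25, 0.75), names = FALSE, type = 7)
  range_thresholds(q[1], q[2])
}

#' Classify edges into short- and long-range
#'
#' Present edges (per-subject presence, group-level length thresholds)
#' with length strictly below `thr$q1` are short-range, strictly above
#' `thr$q3` long-range; lengths at exactly a threshold, and the middle
#' quartiles, stay unclassified. Absent edges belong to neither class.
#'
#' @param sc A [structural_connectome()].
#' @param thr A [range_thresholds()].
#' @param presence_floor Presence threshold on FA.
#' @return An `edge_class_mask`: logical edge vectors `present`, `short`,
#'   `long` in row-major upper-triangle order, plus node labels and the
#'   thresholds used.
#' @export
classify_edges <- function(sc, thr, presence_floor = 0) {
  stopifnot(inherits(sc, "structural_connectome"), inherits(thr, "range_thresholds"))
  fa <- edge_vector(sc$fa)
  len <- edge_vector(sc$lengths)
  present <- fa > presence_floor
  structure(list(
    present = present,
    short = present & len < thr$q1,
    long = present & len > thr$q3,
    node_labels = sc$node_labels,
    thresholds = thr
  ), class = "edge_class_mask")
}

#' @export
print.edge_class_mask <- function(x, ...) {
  cat(sprintf("<edge_class_mask> %d nodes: %d present, %d short, %d long\n",
              length(x$node_labels), sum(x$present), sum(x$short), sum(x$long)))
  invisible(x)
}

#' Count short- and long-range connections
#'
#' @param mask An `edge_class_mask` from [classify_edges()].
#' @return Named integer vector `c(n_short, n_long)`.
#' @export
count_range_connections <- function(mask) {
  stopifnot(inherits(mask, "edge_class_mask"))
  c(n_short = sum(mask$short), n_long = sum(mask$long))
}

#' Edge class mask as an edge list
#'
#' @param mask An `edge_class_mask`.
#' @return Tibble with one row per present edge: `node_i`, `node_j`,
#'   `length_class` (short / long / mid).
#' @export
edge_class_table <- function(mask) {
  stopifnot(inherits(mask, "edge_class_mask"))
  idx <- edge_index(length(mask$node_labels))
  cls <- rep("mid", length(mask$present))
  cls[mask$short] <- "short"
  cls[mask$long] <- "long"
  tibble::tibble(
    node_i = mask$node_labels[idx[, "i"]][mask$present],
    node_j = mask$node_labels[idx[, "j"]][mask$present],
    length_class = cls[mask$present]
  )
}

#' Extract FC (or SC) values on a structural edge class
#'
#' Returns the edge values of a matrix restricted to the requested class
#' of structurally present edges, in the fixed row-major upper-triangle
#' ordering — only functional connections with a direct underlying
#' structural connection are taken into account.
#'
#' @param fc An `fc_matrix`, or any square symmetric matrix over the same
#'   nodes (e.g. an FA matrix, to extract the matching SC vector).
#' @param mask An `edge_class_mask`.
#' @param which `"short"`, `"long"`, or `"whole"` (all present edges).
#' @return Numeric vector of edge values.
#' @export
mask_fc_by_structure <- function(fc, mask, which = c("whole", "short", "long")) {
  which <- match.arg(which)
  stopifnot(inherits(mask, "edge_class_mask"))
  values <- if (inherits(fc, "fc_matrix")) unclass(fc) else fc
  values <- check_square_symmetric(values, "fc")
  if (nrow(values) != length(mask$node_labels)) {
    stop("Matrix and mask are over different node sets.", call. = FALSE)
  }
  sel <- switch(which, whole = mask$present, short = mask$short, long = mask$long)
  if (!any(sel)) {
    stop(sprintf("No edges in class '%s': downstream correlation undefined.", which), call. = FALSE)
  }
  edge_vector(values)[sel]
}
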