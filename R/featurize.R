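# Time-ordered feature matrices: lesion-partner pairwise distances and
# mean-centering ahead of TICA.

#' Time-ordered feature series
#'
#' A `T x d` real matrix of features with frame spacing and segment
#' boundaries. Segments mark independent trajectories concatenated row-wise;
#' no time-lagged pair of frames may straddle a segment boundary.
#'
#' @param values Numeric matrix, one row per frame (no missing values,
#'   at least 2 rows).
#' @param dt Time between rows.
#' @param labels Column labels (default from `colnames`).
#' @param boundaries 1-based, strictly increasing segment start rows,
#'   first = 1.
#' @return A `feature_series`.
#' @export
feature_series <- function(values, dt = 1, labels = colnames(values),
                           boundaries = 1L) {
  values <- as.matrix(values)
  .stop_if(anyNA(values), "feature series contains missing values")
  .stop_if(nrow(values) < 2, "feature series needs at least 2 frames")
  boundaries <- as.integer(boundaries)
  .stop_if(boundaries[1] != 1L ||
             (length(boundaries) > 1 && is.unsorted(boundaries, strictly = TRUE)),
           "boundaries must be strictly increasing and start at 1")
  .stop_if(any(boundaries > nrow(values)), "boundary beyond last frame")
  if (is.null(labels)) labels <- paste0("f", seq_len(ncol(values)))
  colnames(values) <- labels
  structure(list(values = values, dt = dt, labels = labels,
                 boundaries = boundaries),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("feature_series: %d frames x %d features, %d segment(s), dt = %g\n",
              nrow(x$values), ncol(x$values), length(x$boundaries), x$dt))
  invisible(x)
}

# rows of each segment as a list of index vectors
.segment_rows <- function(T, boundaries) {
  ends <- c(boundaries[-1] - 1L, T)
  mapply(function(a, b) seq.int(a, b), boundaries, ends, SIMPLIFY = FALSE)
}

#' Pairwise interatomic distance features
#'
#' One column per (i, j) atom pair of two disjoint groups, row-major over
#' (group_a, group_b); the classic lesion-vs-partner distance set for flipping studies.
#'
#' @param traj An [md_trajectory()].
#' @param group_a,group_b Disjoint [atom_selection()]s (or index vectors).
#' @return A [feature_series()] with `|a| * |b|` columns named
#'   `d<ai>_<bj>`, inheriting the trajectory's dt and boundaries.
#' @export
pairwise_distance_features <- function(traj, group_a, group_b) {
  ia <- if (inherits(group_a, "atom_selection")) group_a$indices else as.integer(group_a)
  ib <- if (inherits(group_b, "atom_selection")) group_b$indices else as.integer(group_b)
  .stop_if(length(ia) == 0 || length(ib) == 0, "feature groups must be non-empty")
  .stop_if(length(intersect(ia, ib)) > 0, "feature groups must be disjoint")
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nf, length(ia) * length(ib))
  labs <- character(ncol(out))
  col <- 0L
  for (i in ia) for (j in ib) {
    col <- col + 1L
    d <- traj$coords[, i, , drop = FALSE] - traj$coords[, j, , drop = FALSE]
    out[, col] <- sqrt(rowSums(matrix(d, nrow = nf)^2))
    labs[col] <- sprintf("d%d_%d", i, j)
  }
  feature_series(out, dt = traj$dt, labels = labs, boundaries = traj$boundaries)
}

#' Remove column means (mean-free data)
#'
#' Centers every feature column on its global mean across all segments; the
#' removed means are stored in attribute `"means"` for the inverse
#' transform. Centering is idempotent.
#'
#' @param fs A [feature_series()].
#' @return A centered `feature_series`.
#' @export
mean_free <- function(fs) {
  stopifnot(inherits(fs, "feature_series"))
  mu <- colMeans(fs$values)
  out <- feature_series(sweep(fs$values, 2, mu), dt = fs$dt,
                        labels = fs$labels, boundaries = fs$boundaries)
  prev <- attr(fs, "means")
  attr(out, "means") <- if (is.null(prev)) mu else prev + mu
  out
}

#' Write / read delimited feature tables
#'
#' Plain tab-separated text with a header row naming each feature column.
#' Segment boundaries are stored in a `# boundaries:` comment line.
#'
#' @param fs A [feature_series()].
#' @param file Path.
#' @return `write_features`: `file` invisibly; `read_features`: a
#'   [feature_series()].
#' @export
write_features <- function(fs, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# boundaries: %s", paste(fs$boundaries, collapse = ",")), con)
  writeLines(sprintf("# dt: %g", fs$dt), con)
  write.table(fs$values, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_features
#' @export
read_features <- function(file) {
  hdr <- readLines(file, n = 2)
  bnd <- as.integer(strsplit(sub("# boundaries: ", "", hdr[1]), ",")[[1]])
  dt <- as.numeric(sub("# dt: ", "", hdr[2]))
  vals <- as.matrix(read.table(file, header = TRUE, sep = "\t", skip = 2,
                               check.names = FALSE))
  feature_series(vals, dt = dt, boundaries = bnd)
}
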