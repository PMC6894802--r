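#' Read a regional volume table from delimited text
#'
#' Accepts either (a) a CSV with a header whose first column holds subject
#' IDs and remaining columns are named regions (the format written by
#' [write_volume_table()]), or (b) a headerless rectangular numeric matrix —
#' the shape of toolbox export files — with region names supplied separately
#' as a one-column text file in atlas order via `region_names_path`.
#'
#' @param path CSV file.
#' @param region_names_path optional one-name-per-line text file; its
#'   presence switches to headerless-matrix mode.
#' @param group_label group label to attach (defaults to the file stem).
#' @param sep field separator (`","`; use `"\t"` for TSV).
#' @return a [volume_table()].
#' @export
read_volume_table <- function(path, region_names_path = NULL,
                              group_label = NULL, sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(group_label))
    group_label <- sub("\\.[^.]*$", "", basename(path))
  if (!is.null(region_names_path)) {
    regions <- trimws(readLines(region_names_path))
    regions <- regions[nzchar(regions)]
    raw <- read.csv(path, header = FALSE, sep = sep, strip.white = TRUE)
    M <- as.matrix(raw)
    if (!is.numeric(M))
      stop("headerless matrix mode: file contains non-numeric cells", call. = FALSE)
    if (ncol(M) != length(regions))
      stop(sprintf("matrix has %d columns but region file lists %d regions",
                   ncol(M), length(regions)), call. = FALSE)
    tb <- volume_table(M, region_names = regions, group_label = group_label)
  } else {
    raw <- read.csv(path, header = TRUE, sep = sep, check.names = FALSE,
                    strip.white = TRUE)
    if (ncol(raw) < 2)
      stop("expected a subject-ID column plus at least one region column",
           call. = FALSE)
    ids <- as.character(raw[[1]])
    M <- as.matrix(raw[, -1, drop = FALSE])
    if (!is.numeric(M))
      stop("non-numeric cells in the volume body", call. = FALSE)
    tb <- volume_table(M, region_names = colnames(raw)[-1], subject_ids = ids,
                       group_label = group_label)
  }
  message(sprintf("read_volume_table: %d subjects x %d regions (group '%s')",
                  nrow(tb$volumes), ncol(tb$volumes), tb$group_label))
  tb
}

#' Write a regional volume table as CSV
#'
#' First column `subject_id`, remaining columns the named regions, one row
#' per subject.
#'
#' @param table a [volume_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_volume_table <- function(table, path) {
  stopifnot(inherits(table, "volume_table"))
  df <- data.frame(subject_id = table$subject_ids, table$volumes,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an association matrix (or any network matrix) as CSV
#'
#' @param assoc an `assoc_matrix` or `binary_network`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(assoc, path) {
  M <- if (inherits(assoc, "assoc_matrix")) assoc$r
       else if (inherits(assoc, "binary_network")) assoc$adjacency
       else as.matrix(assoc)
  rn <- if (inherits(assoc, "assoc_matrix") || inherits(assoc, "binary_network"))
    assoc$region_names else rownames(M)
  dimnames(M) <- list(rn, rn)
  write.csv(M, path, row.names = TRUE)
  invisible(path)
}

#' Write a network as an edge list
#'
#' Columns `region_i`, `region_j`, `weight` (the correlation for an
#' association matrix; 1 for a binary network).
#'
#' @param x an `assoc_matrix` or `binary_network`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  if (inherits(x, "assoc_matrix")) {
    idx <- which(upper.tri(x$r), arr.ind = TRUE)
    df <- data.frame(region_i = x$region_names[idx[, 1]],
                     region_j = x$region_names[idx[, 2]],
                     weight = x$r[idx])
  } else if (inherits(x, "binary_network")) {
    df <- data.frame(region_i = x$region_names[x$edges[, 1]],
                     region_j = x$region_names[x$edges[, 2]],
                     weight = 1)
  } else stop("unsupported object", call. = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' AAL-style region names
#'
#' Generic placeholder names for a parcellation of `n` regions, alternating
#' left/right hemisphere labels the way the 90-region AAL atlas does. Used by
#' the synthetic-data generator; real analyses should pass the atlas's own
#' names.
#'
#' @param n number of regions (default 90).
#' @return character vector of length `n`.
#' @export
aal_region_names <- function(n = 90) {
  base <- sprintf("roi_%02d", ceiling(seq_len(n) / 2))
  side <- rep(c("L", "R"), length.out = n)
  paste(base, side, sep = "_")
}
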