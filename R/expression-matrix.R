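#' Expression matrix container
#'
#' An `expression_matrix` holds a samples x probes real-valued matrix with
#' unique sample and probe identifiers. Missing (undefined) cells are stored
#' as `NA`; [em_missing_mask()] exposes them as a logical mask. Values are in
#' whatever dimensionless units the source deposited (log2 ratios,
#' normalized intensities, ...).
#'
#' @param values numeric matrix, rows = samples, columns = probes. `NA`
#'   entries are treated as missing.
#' @param sample_ids,probe_ids character vectors of unique identifiers; if
#'   omitted, taken from `dimnames(values)`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              probe_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(probe_ids)) probe_ids <- paste0("P", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  probe_ids <- as.character(probe_ids)
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) must equal nrow(values)")
  if (length(probe_ids) != ncol(values))
    stop("length(probe_ids) must equal ncol(values)")
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup))
    stop("duplicate probe ids: ", paste(dup, collapse = ", "))
  dimnames(values) <- list(sample_ids, probe_ids)
  structure(list(values = values), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d probes (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param x an `expression_matrix`.
#' @export
em_values <- function(x) x$values

#' @rdname expression_matrix
#' @export
em_sample_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
em_probe_ids <- function(x) colnames(x$values)

#' @rdname expression_matrix
#' @export
em_missing_mask <- function(x) is.na(x$values)

#' Read a delimited expression matrix
#'
#' Reads a tab- or comma-delimited matrix with one header row of column
#' identifiers and a leading column of row identifiers, either in samples x
#' probes orientation (`orientation = "samples"`, the internal layout) or
#' probes x samples (`orientation = "probes"`, the usual deposition layout),
#' in which case the result is transposed. Empty or non-numeric cells become
#' missing. Also accepts a minimal GEO series-matrix dialect: when the file
#' contains a `!series_matrix_table_begin` line, only the table between that
#' marker and `!series_matrix_table_end` is read (probes-in-rows).
#'
#' @param path path to the file.
#' @param orientation `"samples"` if rows are samples, `"probes"` if rows are
#'   probes.
#' @param sep field separator; `NULL` (default) autodetects tab vs comma from
#'   the header line.
#' @return An [expression_matrix] in samples x probes orientation, ID order
#'   preserved from the file.
#' @export
read_expression_matrix <- function(path, orientation = c("samples", "probes"),
                                   sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  if (length(begin)) {
    end <- grep("^!series_matrix_table_end", lines)
    if (!length(end)) stop("series matrix table not terminated in ", path)
    offset <- begin[1]
    lines <- lines[(begin[1] + 1L):(end[1] - 1L)]
    orientation <- "probes"
  } else {
    offset <- 0L
    lines <- lines[nzchar(lines)]
  }
  if (length(lines) < 2L) stop("no data rows in ", path)
  if (is.null(sep))
    sep <- if (grepl("\t", lines[1])) "\t" else ","
  # append one separator so trailing empty (missing) cells survive strsplit
  cells <- strsplit(paste0(lines, sep), sep, fixed = TRUE)
  width <- length(cells[[1]])
  ragged <- which(vapply(cells, length, 1L) != width)
  if (length(ragged))
    stop(sprintf("ragged row at line %d of %s (expected %d fields)",
                 ragged[1] + offset, path, width))
  header <- gsub('^"|"$', "", cells[[1]][-1])
  body <- cells[-1]
  row_ids <- gsub('^"|"$', "", vapply(body, `[[`, "", 1L))
  vals <- vapply(body, function(r) {
    suppressWarnings(as.numeric(r[-1]))
  }, numeric(width - 1L))
  vals <- if (width == 2L) matrix(vals, ncol = 1L) else t(vals)
  if (orientation == "probes") {
    expression_matrix(t(vals), sample_ids = header, probe_ids = row_ids)
  } else {
    expression_matrix(vals, sample_ids = row_ids, probe_ids = header)
  }
}

#' Write an expression matrix as TSV
#'
#' Samples in rows, probes in columns; missing cells written empty. A
#' read-back with [read_expression_matrix()] reproduces the object.
#'
#' @param x an [expression_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  v <- em_values(x)
  out <- cbind(sample_id = rownames(v),
               matrix(ifelse(is.na(v), "",
                             formatC(v, digits = 17, format = "g")),
                      nrow = nrow(v), dimnames = dimnames(v)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Phase tensor: one expression matrix per clinical phase
#'
#' Stacks the case cohort over the three clinical phases (Acute, Subacute,
#' Convalescent) into a single structure sharing one sample and one probe
#' universe. Sample and probe sets are intersected across phases (each
#' patient must have exactly one observation per phase for the downstream
#' label matrix), reordered to the Acute phase's order, and dropped IDs are
#' reported.
#'
#' @param matrices named list of three [expression_matrix] objects; names
#'   must be `"A"`, `"SA"`, `"C"` in any order.
#' @return A `phase_tensor`: list with `phases` (always `c("A","SA","C")`),
#'   `matrices` (in that order), and `dropped` (list of sample/probe IDs
#'   removed by the intersection).
#' @export
assemble_phase_tensor <- function(matrices) {
  if (!is.list(matrices) || length(matrices) != 3L)
    stop("exactly three phase matrices (A, SA, C) are required")
  if (!setequal(names(matrices), c("A", "SA", "C")))
    stop("phase matrices must be named A, SA and C")
  matrices <- matrices[c("A", "SA", "C")]
  samp <- Reduce(intersect, lapply(matrices, em_sample_ids))
  prob <- Reduce(intersect, lapply(matrices, em_probe_ids))
  if (!length(samp)) stop("empty sample intersection across phases")
  if (!length(prob)) stop("empty probe intersection across phases")
  # keep the A phase's ordering for the shared universe
  samp <- em_sample_ids(matrices$A)[em_sample_ids(matrices$A) %in% samp]
  prob <- em_probe_ids(matrices$A)[em_probe_ids(matrices$A) %in% prob]
  dropped <- list(
    samples = sort(unique(unlist(lapply(matrices, function(m)
      setdiff(em_sample_ids(m), samp))))),
    probes = sort(unique(unlist(lapply(matrices, function(m)
      setdiff(em_probe_ids(m), prob))))))
  aligned <- lapply(matrices, function(m)
    expression_matrix(em_values(m)[samp, prob, drop = FALSE]))
  structure(list(phases = c("A", "SA", "C"), matrices = aligned,
                 dropped = dropped),
            class = "phase_tensor")
}

#' @export
print.phase_tensor <- function(x, ...) {
  d <- dim(x$matrices[[1]])
  cat(sprintf("phase_tensor: %d patients x %d probes x %d phases (%s)\n",
              d[1], d[2], length(x$phases), paste(x$phases, collapse = ", ")))
  invisible(x)
}

#' Read a probe-to-gene annotation map
#'
#' Two-column delimited file (`probe_id<TAB>gene_id`, header optional, `#`
#' comments allowed). Many probes may map to one gene; a probe mapped to two
#' different genes is an error. Probes absent from the map are retained
#' downstream under their probe id.
#'
#' @param path path to the file.
#' @return A `probe_annotation`: named character vector, names = probe ids,
#'   values = gene ids.
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !grepl("^#", lines)
  idx <- which(keep)
  cells <- strsplit(lines[keep], "[\t,]")
  bad <- which(vapply(cells, length, 1L) != 2L)
  if (length(bad))
    stop("malformed annotation row at line ", idx[bad[1]], " of ", path)
  probes <- vapply(cells, `[[`, "", 1L)
  genes <- vapply(cells, `[[`, "", 2L)
  if (identical(tolower(probes[1]), "probe_id")) {
    probes <- probes[-1]; genes <- genes[-1]
  }
  pair <- !duplicated(paste(probes, genes, sep = "\r"))
  probes <- probes[pair]; genes <- genes[pair]
  conflict <- unique(probes[duplicated(probes)])
  if (length(conflict))
    stop("probe(s) mapped to conflicting genes: ",
         paste(conflict, collapse = ", "))
  structure(stats::setNames(genes, probes), class = "probe_annotation")
}

#' @rdname read_probe_annotation
#' @param map named character vector (probe id -> gene id).
#' @export
probe_annotation <- function(map) {
  map <- stats::setNames(as.character(map), names(map))
  if (anyDuplicated(names(map))) stop("duplicate probe ids in annotation")
  structure(map, class = "probe_annotation")
}
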