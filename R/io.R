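#' Read an expression matrix
#'
#' Dense formats expect a header row of feature ids and a first column of
#' cell ids.  MatrixMarket input follows the common single-cell layout —
#' genes as rows, cells as columns — with sibling plain-text id files (one
#' id per line) and is transposed on load to the package-wide cells x
#' genes convention.
#'
#' @param path file path.
#' @param format one of `"dense_tsv"`, `"dense_csv"`, `"mtx"`.
#' @param features_path,barcodes_path id files for `mtx` input; default to
#'   `features.txt` / `barcodes.txt` next to the matrix.
#' @param max_entries densification guard for `mtx`: error when
#'   cells x genes exceeds this budget (default 5e7).
#' @return list with `matrix` (cells x genes, numeric), `cell_ids`,
#'   `feature_ids`.
#' @export
read_expression <- function(path,
                            format = c("dense_tsv", "dense_csv", "mtx"),
                            features_path = NULL, barcodes_path = NULL,
                            max_entries = 5e7) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "mtx") {
    return(read_expression_mtx(path, features_path, barcodes_path, max_entries))
  }
  sep <- if (format == "dense_tsv") "\t" else ","
  nf <- utils::count.fields(path, sep = sep, quote = "")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged row in ", path, ": line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1])
  }
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  if (ncol(tab) < 2L) stop("expected a cell-id column plus >= 1 feature column")
  cell_ids <- tab[[1]]
  feature_ids <- colnames(tab)[-1]
  m <- matrix(NA_real_, nrow(tab), length(feature_ids))
  for (j in seq_along(feature_ids)) {
    v <- suppressWarnings(as.numeric(tab[[j + 1]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("non-numeric entry in ", path, ": line ", bad + 1L,
           " (cell '", cell_ids[bad], "'), column '", feature_ids[j], "'")
    }
    m[, j] <- v
  }
  list(matrix = m, cell_ids = cell_ids, feature_ids = feature_ids)
}

read_expression_mtx <- function(path, features_path, barcodes_path, max_entries) {
  dir <- dirname(path)
  if (is.null(features_path)) features_path <- file.path(dir, "features.txt")
  if (is.null(barcodes_path)) barcodes_path <- file.path(dir, "barcodes.txt")
  for (p in c(features_path, barcodes_path)) {
    if (!file.exists(p)) stop("missing id file for mtx input: ", p)
  }
  m <- Matrix::readMM(path)
  feature_ids <- readLines(features_path)
  cell_ids <- readLines(barcodes_path)
  if (nrow(m) != length(feature_ids)) {
    stop("mtx has ", nrow(m), " rows but ", length(feature_ids),
         " feature ids in ", features_path)
  }
  if (ncol(m) != length(cell_ids)) {
    stop("mtx has ", ncol(m), " columns but ", length(cell_ids),
         " barcodes in ", barcodes_path)
  }
  if (as.double(nrow(m)) * ncol(m) > max_entries) {
    stop("mtx densification guard: ", nrow(m), " x ", ncol(m),
         " exceeds max_entries = ", max_entries)
  }
  list(matrix = t(as.matrix(m)), cell_ids = cell_ids,
       feature_ids = feature_ids)
}

#' Write a dense TSV expression matrix
#'
#' Inverse of [read_expression()] for the `dense_tsv` format: header of
#' feature ids, first column of cell ids, full double precision.
#'
#' @param path output path.
#' @param matrix cells x genes numeric matrix.
#' @param cell_ids,feature_ids identifier vectors.
#' @export
write_expression <- function(path, matrix, cell_ids, feature_ids) {
  matrix <- as.matrix(matrix)
  stopifnot(length(cell_ids) == nrow(matrix),
            length(feature_ids) == ncol(matrix))
  header <- paste(c("cell_id", feature_ids), collapse = "\t")
  rows <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(cell_ids[i], sprintf("%.17g", matrix[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read per-cell stage labels
#'
#' TSV with columns `cell_id` and `stage_time` (numeric experimental
#' time).  Rows are joined to `cell_ids` by id, never by file order;
#' stage indices are the 1-based ranks of the sorted unique times.
#'
#' @param path label file path.
#' @param cell_ids the expression matrix's cell ids, in matrix order.
#' @return list with `stage_time` (raw times, matrix order),
#'   `stage_time_normalized`, `stage_index`.
#' @export
read_stage_labels <- function(path, cell_ids) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  need <- c("cell_id", "stage_time")
  if (!all(need %in% colnames(tab))) {
    stop("label file must have columns 'cell_id' and 'stage_time'; found: ",
         paste(colnames(tab), collapse = ", "))
  }
  dup <- tab$cell_id[duplicated(tab$cell_id)]
  if (length(dup)) {
    stop("duplicate cell ids in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  idx <- match(cell_ids, tab$cell_id)
  if (anyNA(idx)) {
    stop("cell ids missing from ", path, ": ",
         paste(cell_ids[is.na(idx)], collapse = ", "))
  }
  times <- suppressWarnings(as.numeric(tab$stage_time[idx]))
  if (anyNA(times)) {
    stop("non-numeric stage_time for cells: ",
         paste(cell_ids[is.na(times)], collapse = ", "))
  }
  list(
    stage_time = times,
    stage_time_normalized = normalize_times(times),
    stage_index = match(times, sort(unique(times)))
  )
}

#' Write an embedding with its run manifest
#'
#' TSV with columns `cell_id`, `dim_1..dim_d`, `stage_time`,
#' `stage_index`, at full double precision, plus a sibling
#' `<path>.manifest.json` capturing everything needed to re-run the fit
#' bit-identically (configuration snapshot, resolved sigma, package
#' version, seed, timestamp).
#'
#' @param path output TSV path.
#' @param result an `embedding_result` from [fit_tsee()].
#' @param dataset optional [time_series_dataset()]; defaults to the stage
#'   annotation stored in the result.
#' @param input_paths optional named character vector recorded in the
#'   manifest.
#' @return `path`, invisibly; the manifest path is attribute
#'   `"manifest"`.
#' @export
write_embedding <- function(path, result, dataset = NULL, input_paths = NULL) {
  stopifnot(inherits(result, "embedding_result"))
  X <- result$coordinates
  d <- ncol(X)
  cell_ids <- if (!is.null(dataset)) dataset$cell_ids else result$cell_ids
  stage_time <- if (!is.null(dataset)) dataset$stage_time else result$stage_time
  stage_index <- if (!is.null(dataset)) dataset$stage_index else result$stage_index
  header <- paste(c("cell_id", paste0("dim_", seq_len(d)),
                    "stage_time", "stage_index"), collapse = "\t")
  rows <- vapply(seq_len(nrow(X)), function(i) {
    paste(c(cell_ids[i], sprintf("%.17g", X[i, ]),
            sprintf("%.17g", stage_time[i]), stage_index[i]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)

  manifest <- list(
    tool = "tsee",
    version = as.character(utils::packageVersion("tsee")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_paths = as.list(input_paths),
    config = unclass(result$config_used),
    resolved_sigma = result$sigma,
    n_iterations = result$n_iterations,
    converged = result$converged,
    final_energy = result$energy_trace[length(result$energy_trace)]
  )
  manifest_path <- paste0(path, ".manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(path, "manifest") <- manifest_path
  invisible(path)
}

#' Read an embedding written by [write_embedding()]
#'
#' @param path embedding TSV path.
#' @return list with `coordinates`, `cell_ids`, `stage_time`,
#'   `stage_index`.
#' @export
read_embedding <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "")
  dim_cols <- grep("^dim_", colnames(tab))
  if (!length(dim_cols)) stop("no dim_* columns in ", path)
  list(
    coordinates = as.matrix(tab[, dim_cols, drop = FALSE]),
    cell_ids = as.character(tab$cell_id),
    stage_time = as.numeric(tab$stage_time),
    stage_index = as.integer(tab$stage_index)
  )
}

#' Write per-cell stage labels
#'
#' @param path output TSV path.
#' @param cell_ids cell identifiers.
#' @param stage_time numeric experimental times.
#' @export
write_stage_labels <- function(path, cell_ids, stage_time) {
  stopifnot(length(cell_ids) == length(stage_time))
  writeLines(c(
    "cell_id\tstage_time",
    paste(cell_ids, sprintf("%.17g", stage_time), sep = "\t")
  ), path)
  invisible(path)
}

#' Write a metric report as TSV and JSON
#'
#' @param path_prefix output prefix; writes `<prefix>.tsv` (flat
#'   key/value rows) and `<prefix>.json`.
#' @param report a [metric_report()].
#' @return character vector of the two paths, invisibly.
#' @export
write_metric_report <- function(path_prefix, report) {
  stopifnot(inherits(report, "metric_report"))
  rows <- c(
    sprintf("weighted_mean_igp\t%.17g", report$weighted_mean_igp),
    sprintf("igp_stage_%s\t%.17g", names(report$igp_per_group),
            report$igp_per_group),
    sprintf("igp2_stage_%s\t%.17g", names(report$igp2_per_group),
            report$igp2_per_group),
    sprintf("n_misplaced\t%d", sum(report$misplaced_mask)),
    sprintf("n_cells\t%d", length(report$misplaced_mask))
  )
  if (!is.na(report$pcc_time)) {
    rows <- c(rows, sprintf("pcc_time\t%.17g", report$pcc_time))
  }
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  writeLines(c("metric\tvalue", rows), tsv)
  out <- list(
    weighted_mean_igp = report$weighted_mean_igp,
    igp_per_group = as.list(report$igp_per_group),
    igp2_per_group = as.list(report$igp2_per_group),
    pcc_time = if (is.na(report$pcc_time)) NULL else report$pcc_time,
    misplaced_mask = report$misplaced_mask,
    group_sizes = as.list(report$group_sizes)
  )
  jsonlite::write_json(out, json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}
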