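# Delimited-text interchange: the expression matrix, pixel coordinates and
# label files are plain CSV/TSV so that runs are reproducible from files
# alone.  Separator is autodetected from the extension (.csv -> comma,
# anything else -> whitespace/tab).

.sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
}

# Reads a numeric table, tolerating an optional header row and an optional
# leading column of non-numeric row identifiers.
.read_numeric_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sep_for(path)
  first <- utils::read.table(path, sep = sep, header = FALSE, nrows = 1,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  is_num <- function(v) !is.na(suppressWarnings(as.numeric(v)))
  header <- !all(vapply(unlist(first), is_num, logical(1)))
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  rown <- NULL
  if (ncol(df) > 1L && !is.numeric(df[[1L]]) &&
      !all(vapply(as.character(df[[1L]]), is_num, logical(1)))) {
    rown <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric cells in ", path, " (columns ",
         paste(which(bad), collapse = ", "), ")")
  M <- as.matrix(df)
  rownames(M) <- rown
  M
}

#' Read an expression matrix and its pixel coordinates
#'
#' The matrix file holds n rows by p columns of numbers, optionally with a
#' header row and a leading column of row identifiers (e.g. m/z labels).
#' The coordinates file has two numeric columns (x, y), one row per pixel,
#' in the column order of the matrix.  Decimal separator is always the dot.
#'
#' @param matrix_path,coords_path paths to delimited text files (.csv for
#'   comma-separated, otherwise whitespace/tab).
#' @return list with elements \code{X} (numeric matrix), \code{coords}
#'   (p x 2 matrix), \code{n}, \code{p}.
#' @export
read_dataset <- function(matrix_path, coords_path) {
  X <- .read_numeric_table(matrix_path)
  coords <- .read_numeric_table(coords_path)
  if (ncol(coords) != 2L)
    stop("coordinates file must have exactly two numeric columns (x, y)")
  colnames(coords) <- c("x", "y")
  if (nrow(coords) != ncol(X))
    stop("shape mismatch: matrix has ", ncol(X), " columns but ",
         nrow(coords), " coordinate rows")
  if (anyDuplicated(coords))
    warning("duplicated pixel coordinates; kernel factorization will fall ",
            "back on diagonal jitter")
  list(X = X, coords = coords, n = nrow(X), p = ncol(X))
}

#' Log-transform raw abundances
#'
#' Entrywise \eqn{\log(Y + 1)}, mapping nonnegative raw abundances to the
#' real line before fitting; monotone and zero-preserving.
#'
#' @param Y nonnegative numeric matrix of raw abundances.
#' @export
log_transform <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0, na.rm = TRUE))
    stop("`Y` has negative entries; the log(Y + 1) transform is meant for ",
         "raw abundances")
  log1p(Y)
}

#' Write fit outputs to a directory
#'
#' Writes delimited-text artifacts of a fit: row labels
#' (\code{row_labels.csv}), column labels with coordinates
#' (\code{col_labels.csv}, the segmentation table), the centroid matrix
#' (\code{centroids.csv}) with per-block row/column counts
#' (\code{block_counts.csv}), the loss trace (\code{loss_trace.csv}) and a
#' structured run summary with a config echo (\code{summary.json}).
#'
#' @param fit an \code{"spnmtf"} object.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_result <- function(fit, out_dir) {
  stopifnot(inherits(fit, "spnmtf"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)

  utils::write.csv(data.frame(row = seq_len(fit$n), cluster = fit$F),
                   fp("row_labels.csv"), row.names = FALSE)
  cl <- data.frame(col = seq_len(fit$p))
  if (!is.null(fit$coords)) { cl$x <- fit$coords[, 1]; cl$y <- fit$coords[, 2] }
  cl$cluster <- fit$G
  utils::write.csv(cl, fp("col_labels.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(fit$mu), fp("centroids.csv"),
                   row.names = FALSE)
  counts <- data.frame(
    cluster = seq_len(max(fit$K, fit$R)),
    n_rows = c(tabulate(fit$F, fit$K), rep(NA, max(0, fit$R - fit$K))),
    n_cols = c(tabulate(fit$G, fit$R), rep(NA, max(0, fit$K - fit$R)))
  )
  utils::write.csv(counts, fp("block_counts.csv"), row.names = FALSE)
  utils::write.csv(fit$trace, fp("loss_trace.csv"), row.names = FALSE)

  summary <- list(
    variant = fit$variant, K = fit$K, R = fit$R, phi = fit$phi,
    tau = fit$tau, loss = fit$loss, penalized_loss = fit$penalized_loss,
    n_iter = fit$n_iter, converged = fit$converged,
    degenerate = fit$degenerate,
    nonempty_row = fit$nonempty_row, nonempty_col = fit$nonempty_col,
    n = fit$n, p = fit$p,
    n_restarts = length(fit$restart_losses),
    restart_losses = fit$restart_losses,
    rel_tol = fit$rel_tol, patience = fit$patience, max_iter = fit$max_iter,
    seed = fit$seed, runtime = fit$runtime
  )
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c("row_labels.csv", "col_labels.csv", "centroids.csv",
              "block_counts.csv", "loss_trace.csv", "summary.json"))
}

# Writes a simulated dataset the same way, plus truth labels and config echo.
.write_sim <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  utils::write.csv(as.data.frame(sim$X), fp("X.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(sim$coords), fp("coords.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(row = seq_len(sim$n), cluster = sim$F),
                   fp("true_row_labels.csv"), row.names = FALSE)
  utils::write.csv(data.frame(col = seq_len(sim$p), cluster = sim$G),
                   fp("true_col_labels.csv"), row.names = FALSE)
  cfg <- sim[c("n", "p", "K", "R", "tau", "phi", "spatial", "min_size",
               "centroid_sd", "noise_sd", "seed")]
  cfg$mean_matrix <- sim$mean_matrix
  jsonlite::write_json(cfg, fp("sim_config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", matrix = "rowmajor")
  invisible(out_dir)
}

# Reads a label file as written above (last column holds the labels), or a
# bare single-column file.
.read_labels <- function(path) {
  M <- .read_numeric_table(path)
  as.integer(M[, ncol(M)])
}
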