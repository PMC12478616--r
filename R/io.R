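#' Read a Q-matrix from CSV
#'
#' Expects a header row `A1..AK` and one 0/1 row per item.  Non-binary cells
#' are reported with their (row, column) location; items requiring no
#' attribute (all-zero rows) are rejected.
#'
#' @param path path to the CSV file.
#' @return A validated J x K integer Q-matrix.
#' @export
read_q_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  M <- .parse_binary_cells(df, path, what = "Q-matrix")
  validate_q(M)
}

#' Read a binary response matrix from CSV
#'
#' One row per examinee, one 0/1 column per item; an optional `id` column is
#' used for row names.  Malformed cells are reported with their location.
#'
#' @param path path to the CSV file.
#' @param J optional expected item count (e.g. `nrow(Q)`).
#' @return A validated N x J integer response matrix.
#' @export
read_responses <- function(path, J = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- NULL
  if ("id" %in% names(df)) {
    ids <- as.character(df[["id"]])
    df <- df[setdiff(names(df), "id")]
  }
  M <- .parse_binary_cells(df, path, what = "response matrix")
  if (!is.null(ids)) rownames(M) <- ids
  validate_responses(M, J)
}

.parse_binary_cells <- function(df, path, what) {
  M <- suppressWarnings(as.matrix(as.data.frame(lapply(df, as.numeric))))
  bad <- which(is.na(M) | !(M %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(M)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(M)) + 1L
    stop("malformed ", what, " in '", path, "': cell '", as.matrix(df)[bad[1L]],
         "' at row ", i, ", column ", j, " is not 0/1", call. = FALSE)
  }
  colnames(M) <- names(df)
  M
}

#' Write a Q-matrix or response matrix to CSV
#'
#' Inverse of [read_q_matrix()] / [read_responses()]: `write_q_matrix()`
#' writes the `A1..AK` header, `write_responses()` optionally prepends an
#' `id` column from the row names.  A write followed by a read restores the
#' matrix exactly.
#'
#' @param Q,X the matrix to write.
#' @param path destination CSV path.
#' @param id include an `id` column from the row names (responses only).
#' @return The path, invisibly.
#' @export
write_q_matrix <- function(Q, path) {
  Q <- validate_q(Q)
  utils::write.csv(as.data.frame(Q), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_q_matrix
#' @export
write_responses <- function(X, path, id = !is.null(rownames(X))) {
  X <- validate_responses(X)
  df <- as.data.frame(X)
  if (id) df <- cbind(id = rownames(X) %||% seq_len(nrow(X)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the outputs of a generalized Bayesian fit to a directory
#'
#' Exports the attribute mastery probabilities (N x K), the pattern
#' probabilities (N x \eqn{2^K}, columns labelled by pattern strings), the
#' mastery classifications, the posterior-mean mixing proportions and (for
#' the squared-Euclidean loss) weights as CSV files, plus a JSON run
#' manifest recording the configuration, seed, MH acceptance rate and
#' half-split stability correlations -- enough to re-run the fit
#' bit-identically.
#'
#' @param fit a [gbdcm()] object.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_gbdcm <- function(fit, dir) {
  stopifnot(inherits(fit, "gbdcm"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(fit$attr_prob),
                   file.path(dir, "attribute_probabilities.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(fit$pattern_prob),
                   file.path(dir, "pattern_probabilities.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(fit$classification),
                   file.path(dir, "classification.csv"), row.names = FALSE)
  utils::write.csv(data.frame(pattern = names(fit$pi), pi = fit$pi),
                   file.path(dir, "mixing.csv"), row.names = FALSE)
  if (!is.null(fit$W))
    utils::write.csv(as.data.frame(fit$W), file.path(dir, "weights.csv"),
                     row.names = FALSE)
  manifest <- list(
    package = "gbdcm",
    version = as.character(utils::packageVersion("gbdcm")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    loss = fit$loss, init = fit$init, config = fit$config,
    n_examinees = fit$N, n_items = nrow(fit$Q), n_attributes = ncol(fit$Q),
    acceptance_rate = fit$acceptance_rate,
    half_split = as.list(fit$half_split))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
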