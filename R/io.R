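#' Write a subject time series to delimited text
#'
#' One CSV per series, columns = nodes, preceded by a comment header line
#' recording the sampling interval, e.g. `# tr=0.8`.
#'
#' @param y T x n numeric matrix
#' @param path output file
#' @param tr sampling interval in seconds
#' @export
write_series <- function(y, path, tr) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr=%.10g", tr), con)
  utils::write.csv(as.data.frame(y), con, row.names = FALSE)
  invisible(path)
}

#' Read a subject time series written by [write_series()]
#'
#' @param path CSV file with a `# tr=` header line
#' @return T x n matrix with attribute `tr`
#' @export
read_series <- function(path) {
  first <- readLines(path, n = 1)
  tr <- NA_real_
  skip <- 0L
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("tr=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2) tr <- as.numeric(m[2])
    skip <- 1L
  }
  y <- as.matrix(utils::read.csv(path, skip = skip))
  storage.mode(y) <- "double"
  attr(y, "tr") <- tr
  y
}

#' Write a simulated dataset to a directory
#'
#' Subject series go to `subject01.csv`, ... with a `# tr=` header; ground
#' truth (state paths, A matrices, transition matrix, seed, configuration
#' scalars) goes to a JSON sidecar `dataset.json`.
#'
#' @param ds `statedcm_dataset`
#' @param dir output directory (created if missing)
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "statedcm_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (j in seq_along(ds$bold)) {
    write_series(ds$bold[[j]], file.path(dir, sprintf("subject%02d.csv", j)), ds$tr)
  }
  side <- list(
    tr = ds$tr, seed = ds$seed,
    n_subjects = length(ds$bold),
    dwell_samples = ds$truth_path[[1]]$dwell_samples,
    truth_path = lapply(ds$truth_path, function(p) p$labels),
    truth_A = lapply(ds$truth_A, function(A) unclass(A)),
    tm = unclass(ds$tm)
  )
  jsonlite::write_json(side, file.path(dir, "dataset.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory containing `subject*.csv` and optionally `dataset.json`
#' @return `statedcm_dataset` (truth fields NULL when no sidecar present)
#' @export
read_dataset <- function(dir) {
  files <- sort(list.files(dir, pattern = "^subject[0-9]+\\.csv$", full.names = TRUE))
  if (!length(files)) stop("no subject*.csv series found in ", dir)
  bold <- lapply(files, read_series)
  tr <- attr(bold[[1]], "tr")
  side_path <- file.path(dir, "dataset.json")
  truth_path <- truth_A <- tm <- NULL
  seed <- NA_integer_
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    tr <- side$tr
    seed <- side$seed
    dwell <- side$dwell_samples
    truth_path <- lapply(seq_len(nrow(side$truth_path) %||% length(side$truth_path)),
                         function(i) NULL)
    labs <- side$truth_path
    if (is.matrix(labs)) labs <- lapply(seq_len(nrow(labs)), function(i) labs[i, ])
    truth_path <- lapply(labs, function(l)
      structure(list(labels = as.integer(l), dwell_samples = dwell, tr = tr,
                     K = max(as.integer(l))), class = "statedcm_path"))
    tA <- side$truth_A
    if (is.array(tA) && length(dim(tA)) == 3) {
      truth_A <- lapply(seq_len(dim(tA)[1]), function(i) ec_matrix(tA[i, , ]))
    } else {
      truth_A <- lapply(tA, ec_matrix)
    }
    tm <- transition_matrix(side$tm)
  }
  structure(list(bold = bold, truth_path = truth_path, truth_A = truth_A,
                 tm = tm, tr = tr, seed = seed, config = NULL),
            class = "statedcm_dataset")
}
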