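# Shared reader: tab-separated with header, strict column checking.
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss)) stop(path, " lacks column(s): ", paste(miss, collapse = ", "))
  x
}

#' Read a choice log
#'
#' Tab-separated table with header columns `subject_id`, `immediate_amount`,
#' `delayed_amount`, `delay_days`, `chose_delayed` (0/1).
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_choice_log <- function(path) {
  x <- read_tsv_checked(path, c(
    "subject_id", "immediate_amount", "delayed_amount",
    "delay_days", "chose_delayed"
  ))
  num <- c("immediate_amount", "delayed_amount", "delay_days", "chose_delayed")
  for (cl in num) {
    v <- suppressWarnings(as.numeric(x[[cl]]))
    if (anyNA(v)) {
      stop("non-numeric or missing value in `", cl, "` at row(s): ",
        paste(utils::head(which(is.na(v)), 5), collapse = ", "))
    }
    x[[cl]] <- v
  }
  if (!all(x$chose_delayed %in% c(0, 1))) stop("`chose_delayed` must be 0/1")
  x
}

#' Read a subject-by-region volume table with its covariates
#'
#' The volume table is tab-separated with `subject_id` as the first column
#' and one column per region; the covariate table is keyed by `subject_id`.
#' Subjects are matched by id, and duplicates, missing cells or non-numeric
#' cells are rejected with their coordinates.
#'
#' @param volumes_path,covariates_path File paths.
#' @param group Optional label vector or a two-column (`subject_id`,
#'   `group`) table path.
#' @return A [morph_table()].
#' @export
read_morphometry <- function(volumes_path, covariates_path, group = NULL) {
  vt <- read_tsv_checked(volumes_path, "subject_id")
  cv <- read_tsv_checked(covariates_path, "subject_id")
  ids <- as.character(vt$subject_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicated subject_id: ", paste(dup, collapse = ", "))
  vol <- as.matrix(vt[, setdiff(names(vt), "subject_id"), drop = FALSE])
  suppressWarnings(storage.mode(vol) <- "double")
  if (anyNA(vol)) {
    idx <- which(is.na(vol), arr.ind = TRUE)
    stop(
      "missing or non-numeric volume cell(s) at (row, region): ",
      paste(sprintf("(%s, %s)", ids[idx[, 1]], colnames(vol)[idx[, 2]]), collapse = " ")
    )
  }
  rownames(vol) <- ids
  cv <- cv[match(ids, as.character(cv$subject_id)), , drop = FALSE]
  if (anyNA(cv$subject_id)) stop("covariates missing for some subjects")
  if (is.character(group) && length(group) == 1 && file.exists(group)) {
    gt <- read_tsv_checked(group, c("subject_id", "group"))
    group <- gt$group[match(ids, as.character(gt$subject_id))]
  }
  morph_table(vol, cv, group = group)
}

#' Write a morphometry table to disk
#'
#' Writes the volume matrix, covariates and (when present) group labels as
#' three tab-separated files that [read_morphometry()] reads back
#' identically.
#'
#' @param table A [morph_table()].
#' @param volumes_path,covariates_path,group_path Output paths (`group_path`
#'   optional).
#' @return Invisibly, the paths written.
#' @export
write_morphometry <- function(table, volumes_path, covariates_path, group_path = NULL) {
  stopifnot(inherits(table, "morph_table"))
  vt <- data.frame(subject_id = table$subjects, table$volumes, check.names = FALSE)
  utils::write.table(vt, volumes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$covariates, covariates_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  paths <- c(volumes_path, covariates_path)
  if (!is.null(group_path)) {
    utils::write.table(
      data.frame(subject_id = table$subjects, group = table$group),
      group_path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    paths <- c(paths, group_path)
  }
  invisible(paths)
}

#' Write a covariance network
#'
#' Square matrix (weights, or adjacency when binarized) as tab-separated
#' text with a region-label header, plus an edge-list variant
#' (`region_a`, `region_b`, `weight`, `retained`).
#'
#' @param network A `cov_network`.
#' @param matrix_path,edges_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, matrix_path = NULL, edges_path = NULL) {
  stopifnot(inherits(network, "cov_network"))
  out <- character()
  if (!is.null(matrix_path)) {
    m <- if (is.null(network$adjacency)) network$weights else network$adjacency
    utils::write.table(
      data.frame(region = network$labels, m, check.names = FALSE),
      matrix_path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    out <- c(out, matrix_path)
  }
  if (!is.null(edges_path)) {
    ij <- which(upper.tri(network$weights), arr.ind = TRUE)
    el <- data.frame(
      region_a = network$labels[ij[, 1]],
      region_b = network$labels[ij[, 2]],
      weight = network$weights[ij],
      retained = if (is.null(network$adjacency)) NA else network$adjacency[ij] == 1
    )
    utils::write.table(el, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, edges_path)
  }
  invisible(out)
}
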