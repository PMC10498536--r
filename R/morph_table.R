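#' Assemble a subject-by-region morphometry table
#'
#' Container for regional gray-matter volumes plus the per-subject covariates
#' used for correction (age, sex, education, total intracranial volume) and a
#' group label. Validation is strict: every downstream stage assumes
#' complete numeric volumes and unique subject ids.
#'
#' @param volumes Numeric matrix, subjects in rows, regions in columns.
#'   Row names (or `covariates$subject_id`) identify subjects; column names
#'   are region labels (default [aal90_labels()] when 90 columns and unnamed).
#' @param covariates Data frame with `subject_id` plus covariate columns
#'   (typically `age`, `sex`, `education`, `tiv`), one row per subject in the
#'   row order of `volumes`.
#' @param group Character vector of group labels per subject (`"high"`,
#'   `"low"`, or `"none"`). Defaults to `"none"`.
#' @return List of class `morph_table` with elements `volumes`, `covariates`,
#'   `group`, `regions`, `subjects` and a `residualized` flag.
#' @export
morph_table <- function(volumes, covariates, group = NULL) {
  volumes <- as.matrix(volumes)
  if (!is.numeric(volumes)) {
    bad <- which(!apply(volumes, 2, function(x) all(!is.na(suppressWarnings(as.numeric(x))))))
    stop("non-numeric volume cells in column(s): ", paste(bad, collapse = ", "))
  }
  if (anyNA(volumes)) {
    idx <- which(is.na(volumes), arr.ind = TRUE)
    stop(
      "missing volume cell(s) at row/column: ",
      paste(sprintf("(%d,%d)", idx[, 1], idx[, 2]), collapse = " ")
    )
  }
  if (is.null(covariates$subject_id)) stop("covariates lack a `subject_id` column")
  if (nrow(covariates) != nrow(volumes)) {
    stop("covariate rows (", nrow(covariates), ") != volume rows (", nrow(volumes), ")")
  }
  ids <- as.character(covariates$subject_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicated subject_id: ", paste(dup, collapse = ", "))
  if (anyNA(covariates)) stop("missing covariate values")
  rownames(volumes) <- ids
  if (is.null(colnames(volumes))) {
    colnames(volumes) <- if (ncol(volumes) == 90) aal90_labels() else paste0("R", seq_len(ncol(volumes)))
  }
  if (is.null(group)) group <- rep("none", nrow(volumes))
  if (length(group) != nrow(volumes)) stop("`group` length != subject count")
  structure(
    list(
      volumes = volumes,
      covariates = as.data.frame(covariates),
      group = as.character(group),
      regions = colnames(volumes),
      subjects = ids,
      residualized = FALSE
    ),
    class = "morph_table"
  )
}

#' @export
print.morph_table <- function(x, ...) {
  cat(
    "morph_table:", length(x$subjects), "subjects x", length(x$regions), "regions;",
    "groups:", paste(names(table(x$group)), table(x$group), collapse = ", "),
    if (x$residualized) "(residualized)" else "(raw)", "\n"
  )
  invisible(x)
}

#' Attach group labels from a median split
#'
#' @param table A [morph_table()].
#' @param assignment A `group_assignment` from [median_split()]. Subjects in
#'   the `excluded` set are dropped from the table.
#' @return The table with `group` set to `"high"`/`"low"` and excluded
#'   subjects removed.
#' @export
assign_groups <- function(table, assignment) {
  stopifnot(inherits(table, "morph_table"), inherits(assignment, "group_assignment"))
  ids <- table$subjects
  unknown <- setdiff(c(assignment$high, assignment$low), ids)
  if (length(unknown)) stop("assignment names unknown subjects: ", paste(unknown, collapse = ", "))
  keep <- ids %in% c(assignment$high, assignment$low)
  table$volumes <- table$volumes[keep, , drop = FALSE]
  table$covariates <- table$covariates[keep, , drop = FALSE]
  table$subjects <- ids[keep]
  table$group <- ifelse(table$subjects %in% assignment$high, "high", "low")
  table
}
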