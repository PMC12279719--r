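#' Canonical names of the nine executive-function tasks
#'
#' Three inhibition tasks, three shifting tasks, three updating tasks, in
#' the fixed order used throughout the package.
#' @return Character vector of length 9.
#' @export
ef_task_names <- function() {
  c("antisaccade", "number_stroop", "stop_signal",
    "category_switch", "color_shape", "number_letter",
    "digit_span", "keep_track", "spatial_2back")
}

#' Assemble a cohort dataset
#'
#' @param subjects data.frame with at least \code{subject_id}, \code{age},
#'   \code{sex} (0/1), \code{education}, and either the nine task-score
#'   columns (\code{\link{ef_task_names}}) or a \code{common_ef} column.
#' @param connectomes Named list of \code{\link{connectome}} objects keyed
#'   by subject id (may be \code{NULL} for behaviour-only datasets).
#' @param atlas The shared \code{node_atlas}.
#' @param age_range Plausible age bounds; ages outside are an error.
#' @return An object of class \code{cohort_dataset}.
#' @export
cohort_dataset <- function(subjects, connectomes, atlas,
                           age_range = c(18, 110)) {
  req <- c("subject_id", "age", "sex", "education")
  if (!all(req %in% names(subjects))) {
    stop("missing required subject column(s): ",
         paste(setdiff(req, names(subjects)), collapse = ", "))
  }
  has_tasks <- all(ef_task_names() %in% names(subjects))
  if (!has_tasks && !("common_ef" %in% names(subjects))) {
    stop("subjects need either the nine task-score columns or common_ef")
  }
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject id(s): ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
               collapse = ", "))
  }
  if (any(subjects$age < age_range[1] | subjects$age > age_range[2])) {
    stop("age outside plausible range [", age_range[1], ", ",
         age_range[2], "]")
  }
  if (!all(subjects$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  if (has_tasks) {
    ts <- as.matrix(subjects[, ef_task_names()])
    if (anyNA(ts) || any(!is.finite(ts))) stop("task scores must be finite")
  }
  if (!is.null(connectomes)) {
    missing_cn <- setdiff(subjects$subject_id, names(connectomes))
    if (length(missing_cn)) {
      stop("no connectome for subject(s): ",
           paste(missing_cn, collapse = ", "))
    }
    connectomes <- connectomes[as.character(subjects$subject_id)]
    n_atlas <- nrow(validate_atlas(atlas))
    ok <- vapply(connectomes, function(cn) {
      inherits(cn, "connectome") && nrow(cn$weights) == n_atlas
    }, logical(1))
    if (!all(ok)) stop("connectome/atlas mismatch for subject(s): ",
                       paste(names(connectomes)[!ok], collapse = ", "))
  }
  structure(list(subjects = subjects, connectomes = connectomes,
                 atlas = validate_atlas(atlas)),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset> ", nrow(x$subjects), " subjects, ",
      if (is.null(x$connectomes)) "no" else length(x$connectomes),
      " connectomes, age ", signif(min(x$subjects$age), 4), "-",
      signif(max(x$subjects$age), 4), "\n", sep = "")
  invisible(x)
}

#' Load a cohort from a manifest and a directory of matrices
#'
#' The manifest is a CSV with columns \code{subject_id}, \code{age},
#' \code{sex}, \code{education}, \code{matrix_file}, and either the nine
#' task-score columns or \code{common_ef}. Sex may be given as 0/1 or as
#' strings mapped through \code{sex_map}.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param matrix_dir Directory containing the per-subject matrix files.
#' @param atlas A \code{node_atlas}.
#' @param strict If \code{TRUE} (default) an unreadable matrix aborts the
#'   load, naming the subject; if \code{FALSE} such subjects are dropped
#'   with a warning listing their ids.
#' @param sex_map Named numeric vector mapping string sex codes to 0/1.
#' @param age_range Plausible age bounds.
#' @return A \code{\link{cohort_dataset}}.
#' @export
load_cohort <- function(manifest_path, matrix_dir, atlas, strict = TRUE,
                        sex_map = c(female = 0, male = 1),
                        age_range = c(18, 110)) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  req <- c("subject_id", "age", "sex", "education", "matrix_file")
  if (!all(req %in% names(man))) {
    stop("manifest is missing required column(s): ",
         paste(setdiff(req, names(man)), collapse = ", "))
  }
  if (is.character(man$sex)) {
    key <- tolower(man$sex)
    if (!all(key %in% names(sex_map))) {
      stop("unmapped sex value(s): ",
           paste(setdiff(unique(key), names(sex_map)), collapse = ", "))
    }
    man$sex <- unname(sex_map[key])
  }
  atlas <- validate_atlas(atlas)
  cns <- list()
  failed <- character()
  for (i in seq_len(nrow(man))) {
    sid <- as.character(man$subject_id[i])
    fp <- file.path(matrix_dir, man$matrix_file[i])
    cn <- tryCatch(read_connectome(fp, atlas, subject_id = sid),
                   error = function(e) e)
    if (inherits(cn, "error")) {
      if (strict) {
        stop("failed to read matrix for subject ", sid, ": ",
             conditionMessage(cn))
      }
      failed <- c(failed, sid)
    } else {
      cns[[sid]] <- cn
    }
  }
  if (length(failed)) {
    warning("dropped subject(s) with unreadable matrices: ",
            paste(failed, collapse = ", "))
    man <- man[!(as.character(man$subject_id) %in% failed), , drop = FALSE]
  }
  cohort_dataset(man, cns, atlas, age_range = age_range)
}

#' Write a cohort to disk as manifest + matrix files
#'
#' Inverse of \code{\link{load_cohort}}: writes \code{manifest.csv} and one
#' TSV matrix per subject into \code{dir}. Optionally writes a ground-truth
#' JSON (used by the synthetic generator).
#'
#' @param cohort A \code{cohort_dataset}.
#' @param dir Output directory (created if needed).
#' @param truth Optional list serialized to \code{ground_truth.json}.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$subjects
  man$matrix_file <- paste0("sub-", man$subject_id, ".tsv")
  for (i in seq_len(nrow(man))) {
    sid <- as.character(man$subject_id[i])
    write_connectome(cohort$connectomes[[sid]],
                     file.path(dir, man$matrix_file[i]))
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
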