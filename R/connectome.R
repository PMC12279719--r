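#' Construct and validate a connectome
#'
#' A connectome is one subject's nonnegative, symmetric, weighted
#' connectivity matrix on a fixed node atlas, with a zero diagonal
#' (intra-regional strengths are not meaningful). Asymmetry within the
#' relative tolerance is silently symmetrized to \code{(W + t(W)) / 2};
#' larger asymmetry is an error.
#'
#' @param weights Square numeric matrix of nonnegative connection strengths.
#' @param atlas A \code{node_atlas}; \code{nrow(atlas)} must equal
#'   \code{nrow(weights)}.
#' @param subject_id Subject identifier.
#' @param tol Relative asymmetry tolerance (default \code{1e-8}).
#' @return An object of class \code{connectome}: a list with elements
#'   \code{weights}, \code{atlas}, \code{subject_id}.
#' @examples
#' at <- default_atlas()
#' w <- matrix(0, 84, 84); w[1, 2] <- w[2, 1] <- 3
#' cn <- connectome(w, at, "s1")
#' @export
connectome <- function(weights, atlas, subject_id = "subject", tol = 1e-8) {
  atlas <- validate_atlas(atlas)
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("weights must be a numeric matrix")
  }
  if (nrow(weights) != ncol(weights)) {
    stop("connectome matrix must be square (got ",
         nrow(weights), " x ", ncol(weights), ")")
  }
  if (nrow(weights) != nrow(atlas)) {
    stop("matrix size (", nrow(weights), ") does not match atlas size (",
         nrow(atlas), ")")
  }
  if (anyNA(weights) || any(!is.finite(weights))) {
    stop("weights must be finite")
  }
  if (any(weights < 0)) stop("negative weight in connectivity matrix")
  scale <- max(abs(weights), 1e-300)
  asym <- max(abs(weights - t(weights))) / scale
  if (asym > tol) {
    stop("matrix asymmetry (relative ", signif(asym, 3),
         ") exceeds tolerance ", tol)
  }
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) {
    warning("nonzero diagonal entries set to zero for subject ", subject_id)
    diag(weights) <- 0
  }
  dimnames(weights) <- list(node_names(atlas), node_names(atlas))
  structure(list(weights = weights, atlas = atlas,
                 subject_id = as.character(subject_id)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  w <- x$weights
  cat("<connectome> subject ", x$subject_id, ": ", nrow(w), " nodes, ",
      sum(w[upper.tri(w)] > 0), " edges, total strength ",
      signif(sum(w) / 2, 4), "\n", sep = "")
  invisible(x)
}

# Infer field separator from a file extension.
matrix_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a connectivity matrix from TSV/CSV
#'
#' Accepts a plain square numeric matrix, with an optional single header row
#' of node names which, when present, must match the atlas order exactly.
#'
#' @param path File path (\code{.tsv}/\code{.txt} tab-separated, \code{.csv}
#'   comma-separated).
#' @param atlas A \code{node_atlas}.
#' @param subject_id Subject identifier (defaults to the file stem).
#' @param tol Relative asymmetry tolerance.
#' @return A validated \code{\link{connectome}}.
#' @export
read_connectome <- function(path, atlas,
                            subject_id = sub("\\.[^.]*$", "", basename(path)),
                            tol = 1e-8) {
  if (!file.exists(path)) stop("connectome file not found: ", path)
  sep <- matrix_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  first <- gsub('^"|"$', "", first)
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  if (has_header) {
    expected <- node_names(validate_atlas(atlas))
    if (length(first) != length(expected) || any(first != expected)) {
      stop("header of ", path, " does not match atlas node order")
    }
  }
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                   skip = as.integer(has_header),
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  connectome(m, atlas, subject_id = subject_id, tol = tol)
}

#' Write a connectivity matrix to TSV/CSV
#'
#' Values are printed with 17 significant digits so that
#' \code{read_connectome(write_connectome(c))} reproduces the weights
#' bit-comparably.
#'
#' @param c A \code{connectome}.
#' @param path Output path; extension selects the separator.
#' @param header Write a header row of node names (default \code{FALSE}).
#' @return \code{path}, invisibly.
#' @export
write_connectome <- function(c, path, header = FALSE) {
  stopifnot(inherits(c, "connectome"))
  sep <- matrix_sep(path)
  w <- c$weights
  lines <- apply(w, 1L, function(row) {
    paste(formatC(row, digits = 17, format = "g"), collapse = sep)
  })
  if (header) lines <- c(paste(node_names(c$atlas), collapse = sep), lines)
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write connectome to ", path)
  invisible(path)
}
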