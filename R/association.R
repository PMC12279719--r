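# Covariate-adjusted Pearson association and FDR-controlled node screens.

# Residualize v on [intercept, X] by least squares (X may be NULL).
residualize <- function(v, X) {
  design <- cbind(`(Intercept)` = rep(1, length(v)), X)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) stop("rank-deficient covariate matrix")
  stats::residuals(stats::lm.fit(design, v))
}

#' Partial Pearson correlation with nuisance covariates
#'
#' Residualizes \code{x} and \code{y} on an intercept plus the covariates
#' by least squares, correlates the residuals, and tests
#' \eqn{t = r \sqrt{df / (1 - r^2)}} with \eqn{df = n - 2 - k} (two-sided).
#' With no covariates this is the plain Pearson correlation and test.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional data.frame/matrix of k nuisance covariates.
#' @return List with \code{r}, \code{p}, \code{df}, \code{n}.
#' @examples
#' set.seed(1)
#' a <- rnorm(40); b <- 0.5 * a + rnorm(40); z <- rnorm(40)
#' partial_pearson(a, b, data.frame(z))$r
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  X <- NULL
  k <- 0L
  if (!is.null(covariates)) {
    X <- as.matrix(as.data.frame(covariates))
    if (nrow(X) != n) stop("covariates must have one row per observation")
    k <- ncol(X)
  }
  if (n <= k + 2) stop("need n > k + 2 observations")
  if (anyNA(c(x, y, X)) || any(!is.finite(c(x, y, X)))) {
    stop("inputs must be finite")
  }
  rx <- residualize(x, X)
  ry <- residualize(y, X)
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
    stop("zero residual variance after covariate adjustment")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  r_clamped <- max(min(r, 1 - 1e-15), -1 + 1e-15)
  tval <- r_clamped * sqrt(df / (1 - r_clamped^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, df = df, n = n)
}

#' Benjamini-Hochberg false-discovery-rate step-up procedure
#'
#' Rejects all hypotheses with \eqn{p \le p_{(k^*)}} where
#' \eqn{k^* = \max\{k : p_{(k)} \le k q / m\}}. The critical p is the
#' largest rejected p-value (0 when nothing is rejected).
#'
#' @param pvals Vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return List with logical \code{rejected} (in input order),
#'   \code{critical_p}, \code{m}.
#' @examples
#' bh_fdr(c(0.01, 0.2, 0.02, 0.04))$critical_p
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  pvals <- as.numeric(pvals)
  m <- length(pvals)
  if (m == 0) stop("empty p-value vector")
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  ord <- order(pvals)
  sorted <- pvals[ord]
  passes <- which(sorted <= seq_len(m) * q / m)
  if (length(passes) == 0) {
    return(list(rejected = rep(FALSE, m), critical_p = 0, m = m))
  }
  crit <- sorted[max(passes)]
  list(rejected = pvals <= crit, critical_p = crit, m = m)
}

#' FDR-controlled regional association screen
#'
#' Partial Pearson correlation of every node's regional efficiency against
#' a target variable (controlling for the covariates), with
#' Benjamini-Hochberg correction across all nodes as one family. The
#' report lists significant rows sorted by hemisphere, lobe, and ascending
#' p-value, the convention used for regional screening tables.
#'
#' @param metric_table data.frame of per-subject node metrics; one column
#'   per node named as \code{\link{node_names}} of the atlas (the
#'   \code{e_reg} columns of \code{\link{cohort_profiles}} qualify).
#' @param target Numeric vector (e.g. age or Common-EF score), aligned
#'   with the rows of \code{metric_table}.
#' @param covariates Optional covariate data.frame (e.g. sex, education).
#' @param atlas The \code{node_atlas} naming the columns.
#' @param q FDR level (default 0.05).
#' @param direction Keep \code{"both"} (default), only \code{"positive"},
#'   or only \code{"negative"} significant rows in the report.
#' @return An object of class \code{screen_report}: \code{rows}
#'   (significant only), \code{all_rows}, \code{m_tests},
#'   \code{fdr_critical_p}, \code{q}, \code{direction}.
#' @export
node_screen <- function(metric_table, target, covariates = NULL, atlas,
                        q = 0.05, direction = c("both", "positive", "negative")) {
  direction <- match.arg(direction)
  atlas <- validate_atlas(atlas)
  cols <- node_names(atlas)
  missing_cols <- setdiff(cols, names(metric_table))
  if (length(missing_cols)) {
    stop("metric table lacks node column(s), e.g. ", missing_cols[1])
  }
  res <- lapply(cols, function(cl) {
    partial_pearson(metric_table[[cl]], target, covariates)
  })
  r <- vapply(res, `[[`, numeric(1), "r")
  p <- vapply(res, `[[`, numeric(1), "p")
  fdr <- bh_fdr(p, q = q)
  rows <- data.frame(region = atlas$label,
                     hemisphere = atlas$hemisphere,
                     lobe = atlas$group,
                     r = r, p = p,
                     significant = fdr$rejected,
                     stringsAsFactors = FALSE)
  hemi_rank <- match(rows$hemisphere, c("left", "right", "midline"))
  lobe_rank <- match(rows$lobe, atlas_groups())
  ord <- order(hemi_rank, lobe_rank, rows$p)
  rows <- rows[ord, ]
  rownames(rows) <- NULL
  sig <- rows[rows$significant, , drop = FALSE]
  if (direction == "positive") sig <- sig[sig$r > 0, , drop = FALSE]
  if (direction == "negative") sig <- sig[sig$r < 0, , drop = FALSE]
  rownames(sig) <- NULL
  structure(list(rows = sig, all_rows = rows, m_tests = fdr$m,
                 fdr_critical_p = fdr$critical_p, q = q,
                 direction = direction),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> ", nrow(x$rows), " of ", x$m_tests,
      " nodes significant (q = ", x$q, ", critical p = ",
      signif(x$fdr_critical_p, 3), ", direction = ", x$direction, ")\n",
      sep = "")
  if (nrow(x$rows)) print(utils::head(x$rows, 10))
  invisible(x)
}

#' Write a screen report (TSV table + JSON header)
#' @param report A \code{screen_report}.
#' @param path Output TSV path; a \code{.json} sidecar records m, q and
#'   the critical p.
#' @return \code{path}, invisibly.
#' @export
write_screen <- function(report, path) {
  utils::write.table(report$rows, path, sep = "\t", row.names = FALSE,
                     quote = TRUE)
  jsonlite::write_json(list(m = report$m_tests, q = report$q,
                            fdr_critical_p = report$fdr_critical_p,
                            direction = report$direction),
                       paste0(sub("\\.tsv$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Region + hemisphere keys of significant screen rows, normalized for
# matching across label conventions.
screen_keys <- function(report) {
  paste(report$rows$hemisphere, normalize_region(report$rows$region))
}

#' Intersection of two regional screens
#'
#' The candidate set for regional mediation: regions (matched by
#' hemisphere plus normalized region name) significant in both screens.
#'
#' @param screen_a,screen_b \code{screen_report} objects (or data.frames
#'   with \code{hemisphere} and \code{region} columns).
#' @return data.frame with \code{hemisphere} and \code{region} of the
#'   intersection, in the order of \code{screen_a}.
#' @export
screen_intersection <- function(screen_a, screen_b) {
  rows_of <- function(s) if (inherits(s, "screen_report")) s$rows else s
  a <- rows_of(screen_a); b <- rows_of(screen_b)
  key <- function(d) paste(d$hemisphere, normalize_region(d$region))
  keep <- key(a) %in% key(b)
  out <- a[keep, c("hemisphere", "region"), drop = FALSE]
  rownames(out) <- NULL
  out
}
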