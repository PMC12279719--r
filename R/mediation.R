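# Standardized three-path mediation with bias-corrected bootstrap CIs.
#
# The simple mediation model separates the total effect of the independent
# variable (IV, here age) on the dependent variable (DV, here Common EF)
# into an indirect path through the mediator M (a network metric) and a
# direct path:
#   M  ~ a * IV  (+ covariates)
#   DV ~ b * M + c' * IV (+ covariates)
#   DV ~ c * IV (+ covariates)
# With identical covariate sets, OLS guarantees c = c' + a*b exactly.
# IV, M and DV are z-scored on the analysis sample before all fits so the
# paths are standardized coefficients; covariates enter on their raw
# scale by default (a config switch standardizes them too).

# Standardize the three focal variables and assemble design matrices.
mediation_design <- function(iv, m, dv, covariates, standardize_covariates) {
  n <- length(iv)
  if (length(m) != n || length(dv) != n) {
    stop("iv, m and dv must have equal length")
  }
  X <- NULL
  if (!is.null(covariates)) {
    X <- as.matrix(as.data.frame(covariates))
    if (nrow(X) != n) stop("covariates must have one row per observation")
    if (standardize_covariates) X <- scale(X)
  }
  k <- if (is.null(X)) 0L else ncol(X)
  if (n <= k + 3) stop("need n > #covariates + 3 observations")
  vals <- cbind(iv, m, dv)
  if (anyNA(vals) || any(!is.finite(vals))) stop("inputs must be finite")
  if (any(apply(vals, 2, stats::sd) < 1e-12)) {
    stop("zero variance in iv, m or dv")
  }
  list(iv = as.numeric(scale(iv)), m = as.numeric(scale(m)),
       dv = as.numeric(scale(dv)), X = X, n = n, k = k)
}

# Point estimates of all paths from standardized data.
mediation_paths <- function(d) {
  Xm <- cbind(1, d$iv, d$X)
  Xy <- cbind(1, d$iv, d$m, d$X)
  fa <- stats::lm.fit(Xm, d$m)
  fb <- stats::lm.fit(Xy, d$dv)
  fc <- stats::lm.fit(Xm, d$dv)
  if (fa$rank < ncol(Xm) || fb$rank < ncol(Xy)) {
    stop("rank-deficient design in mediation fit")
  }
  covariate_coefs <- NULL
  if (!is.null(d$X)) {
    cn <- colnames(d$X)
    if (is.null(cn)) cn <- paste0("cov", seq_len(ncol(d$X)))
    covariate_coefs <- stats::setNames(fb$coefficients[-(1:3)], cn)
  }
  list(a = unname(fa$coefficients[2]),
       b = unname(fb$coefficients[3]),
       c_prime = unname(fb$coefficients[2]),
       c = unname(fc$coefficients[2]),
       covariate_coefs = covariate_coefs)
}

#' Fit a three-path mediation model (point estimates)
#'
#' @param iv Independent variable (e.g. age).
#' @param m Mediator (e.g. local efficiency).
#' @param dv Dependent variable (e.g. Common-EF score).
#' @param covariates Optional nuisance covariates (e.g. sex, education).
#' @param standardize_covariates Standardize covariates too (default
#'   \code{FALSE}: binary sex stays 0/1, education stays in years).
#' @return An object of class \code{mediation_result} with standardized
#'   \code{beta_a}, \code{beta_b}, \code{beta_c}, \code{beta_c_prime},
#'   \code{beta_ab} and \code{covariate_coefs}; CI fields are \code{NA}
#'   until \code{\link{bootstrap_ci}} completes them.
#' @examples
#' set.seed(1)
#' iv <- rnorm(100); m <- -0.5 * iv + rnorm(100)
#' dv <- 0.4 * m - 0.2 * iv + rnorm(100)
#' fit_mediation(iv, m, dv)
#' @export
fit_mediation <- function(iv, m, dv, covariates = NULL,
                          standardize_covariates = FALSE) {
  d <- mediation_design(iv, m, dv, covariates, standardize_covariates)
  p <- mediation_paths(d)
  structure(list(beta_a = p$a, beta_b = p$b, beta_c = p$c,
                 beta_c_prime = p$c_prime, beta_ab = p$a * p$b,
                 covariate_coefs = p$covariate_coefs,
                 boot_se = NA_real_, ci_lower = NA_real_,
                 ci_upper = NA_real_, level = NA_real_,
                 n_boot = 0L, seed = NA_integer_, n = d$n,
                 significant = NA, redraws = 0L),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("<mediation_result> n =", x$n, "\n")
  cat(sprintf("  a = %.3f  b = %.3f  c = %.3f  c' = %.3f  ab = %.3f\n",
              x$beta_a, x$beta_b, x$beta_c, x$beta_c_prime, x$beta_ab))
  if (x$n_boot > 0) {
    cat(sprintf("  %d%% BC bootstrap CI for ab: [%.3f, %.3f] (%s; %d resamples)\n",
                round(100 * x$level), x$ci_lower, x$ci_upper,
                if (isTRUE(x$significant)) "significant" else "n.s.",
                x$n_boot))
  }
  invisible(x)
}

#' Bias-corrected bootstrap CI for the indirect effect
#'
#' Case resampling: subjects (rows of iv, m, dv, covariates) are resampled
#' with replacement \code{n_boot} times and \code{ab} recomputed each time.
#' The bias-corrected percentile interval shifts the quantile levels by
#' \eqn{z_0 = \Phi^{-1}(\mathrm{prop})}, where prop is the proportion of
#' bootstrap ab values strictly below the point estimate (ties excluded,
#' proportion clamped to \eqn{[1/(B+1), B/(B+1)]}). Resamples in which
#' iv, m or dv degenerates to zero variance are redrawn (count reported).
#'
#' @inheritParams fit_mediation
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed; same seed gives bit-identical intervals.
#' @return A completed \code{mediation_result} with \code{boot_se},
#'   \code{ci_lower}, \code{ci_upper} and the \code{significant} flag
#'   (CI excludes zero).
#' @export
bootstrap_ci <- function(iv, m, dv, covariates = NULL, n_boot = 5000L,
                         level = 0.95, seed = 1L,
                         standardize_covariates = FALSE) {
  res <- fit_mediation(iv, m, dv, covariates,
                       standardize_covariates = standardize_covariates)
  d <- mediation_design(iv, m, dv, covariates, standardize_covariates)
  Xm <- cbind(1, d$iv, d$X)
  Xy <- cbind(1, d$iv, d$m, d$X)
  n <- d$n
  pm <- ncol(Xm); py <- ncol(Xy)
  ab <- numeric(n_boot)
  redraws <- 0L
  max_attempts <- 100 * n_boot
  with_seed(seed, {
    b <- 1L
    attempts <- 0L
    while (b <= n_boot) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("too many degenerate bootstrap resamples")
      }
      idx <- sample.int(n, n, replace = TRUE)
      ivb <- d$iv[idx]
      mb <- d$m[idx]
      dvb <- d$dv[idx]
      if (stats::var(ivb) < 1e-12 || stats::var(mb) < 1e-12 ||
          stats::var(dvb) < 1e-12) {
        redraws <- redraws + 1L
        next
      }
      fa <- .lm.fit(Xm[idx, , drop = FALSE], mb)
      fb <- .lm.fit(Xy[idx, , drop = FALSE], dvb)
      if (fa$rank < pm || fb$rank < py) {
        redraws <- redraws + 1L
        next
      }
      ab[b] <- fa$coefficients[2] * fb$coefficients[3]
      b <- b + 1L
    }
  })
  ci <- bc_interval(ab, res$beta_ab, level)
  res$boot_se <- stats::sd(ab)
  res$ci_lower <- ci[1]
  res$ci_upper <- ci[2]
  res$level <- level
  res$n_boot <- as.integer(n_boot)
  res$seed <- as.integer(seed)
  res$redraws <- redraws
  res$significant <- (res$ci_lower > 0) || (res$ci_upper < 0)
  res
}

# Bias-corrected percentile bounds for a bootstrap distribution.
bc_interval <- function(boot, estimate, level) {
  b_eff <- length(boot)
  n_below <- sum(boot < estimate)
  n_ties <- sum(boot == estimate)
  denom <- max(b_eff - n_ties, 1L)
  prop <- n_below / denom
  prop <- min(max(prop, 1 / (b_eff + 1)), b_eff / (b_eff + 1))
  z0 <- stats::qnorm(prop)
  za <- stats::qnorm((1 + level) / 2)
  lo <- stats::pnorm(2 * z0 - za)
  hi <- stats::pnorm(2 * z0 + za)
  unname(stats::quantile(boot, probs = c(lo, hi), type = 7))
}

#' Regional mediation over a screened candidate set
#'
#' Restricts the mediation analysis to the regions whose regional
#' efficiency was significantly associated with both the IV screen (age)
#' and the DV screen (Common EF): the intersection, matched by hemisphere
#' plus region. One bias-corrected bootstrap mediation is fitted per
#' candidate node, with that node's regional efficiency as mediator. No
#' multiplicity correction is applied across the per-region CIs; a region
#' mediates when its CI excludes zero.
#'
#' @param ereg_table data.frame of per-subject regional efficiencies, one
#'   column per node named as \code{\link{node_names}} (e.g. from
#'   \code{\link{cohort_profiles}}).
#' @param iv,dv Aligned IV (age) and DV (Common EF) vectors.
#' @param age_screen,ef_screen \code{screen_report}s defining the
#'   candidate intersection.
#' @param atlas The \code{node_atlas}.
#' @param covariates Optional nuisance covariates.
#' @param n_boot,level,seed Bootstrap settings (see
#'   \code{\link{bootstrap_ci}}); seeds for successive regions are
#'   \code{seed + 0:(n-1)}.
#' @return data.frame of class \code{regional_mediation_table}, one row
#'   per candidate (region, hemisphere, lobe, standardized paths,
#'   bootstrap SE and CI, significance flag), ordered by hemisphere then
#'   lobe. Empty intersection gives an empty table.
#' @export
regional_mediation <- function(ereg_table, iv, dv, age_screen, ef_screen,
                               atlas, covariates = NULL, n_boot = 5000L,
                               level = 0.95, seed = 1L) {
  atlas <- validate_atlas(atlas)
  cand <- screen_intersection(age_screen, ef_screen)
  cols <- character(0)
  if (nrow(cand)) {
    atlas_key <- paste(atlas$hemisphere, normalize_region(atlas$label))
    idx <- match(paste(cand$hemisphere, normalize_region(cand$region)),
                 atlas_key)
    if (anyNA(idx)) {
      stop("screen region not found in atlas: ",
           cand$region[which(is.na(idx))[1]])
    }
    cols <- node_names(atlas)[idx]
  }
  rows <- lapply(seq_along(cols), function(j) {
    res <- bootstrap_ci(iv, ereg_table[[cols[j]]], dv, covariates,
                        n_boot = n_boot, level = level,
                        seed = seed + j - 1L)
    i <- match(cols[j], node_names(atlas))
    data.frame(region = atlas$label[i], hemisphere = atlas$hemisphere[i],
               lobe = atlas$group[i],
               beta_c = res$beta_c, beta_c_prime = res$beta_c_prime,
               beta_ab = res$beta_ab, boot_se = res$boot_se,
               ci_lower = res$ci_lower, ci_upper = res$ci_upper,
               beta_a = res$beta_a, beta_b = res$beta_b,
               significant = res$significant,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = character(0), hemisphere = character(0),
               lobe = character(0), beta_c = numeric(0),
               beta_c_prime = numeric(0), beta_ab = numeric(0),
               boot_se = numeric(0), ci_lower = numeric(0),
               ci_upper = numeric(0), beta_a = numeric(0),
               beta_b = numeric(0), significant = logical(0),
               stringsAsFactors = FALSE)
  if (nrow(out)) {
    ord <- order(match(out$hemisphere, c("left", "right", "midline")),
                 match(out$lobe, atlas_groups()))
    out <- out[ord, ]
    rownames(out) <- NULL
  }
  attr(out, "n_boot") <- as.integer(n_boot)
  attr(out, "level") <- level
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("regional_mediation_table", "data.frame")
  out
}

#' Write a regional mediation table (TSV + JSON sidecar)
#' @param tab A \code{regional_mediation_table}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_mediation_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t",
                     row.names = FALSE, quote = TRUE)
  jsonlite::write_json(list(n_boot = attr(tab, "n_boot"),
                            level = attr(tab, "level"),
                            seed = attr(tab, "seed")),
                       paste0(sub("\\.tsv$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
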