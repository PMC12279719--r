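# Synthetic ageing-cohort generator with planted age -> efficiency -> EF
# structure, so every pipeline stage is testable by parameter recovery.
#
# The generative model mirrors the study conditions: ages truncated-normal
# on 60-85 (mean 68.06, sd 4.74), 52/84 female, education 18.06 (2.66)
# years. A modular template connectome (higher edge probability and weight
# within lobe blocks) is scaled per subject on the log scale: age acts
# multiplicatively on the weights, plus subject-level variability sized so
# the standardized age -> efficiency path equals the configured path_a.
# The EF-generating equation uses the efficiency actually computed from
# the generated matrix by the graph code, so mediation recovery exercises
# the full chain. Task scores follow the bifactor loading convention of
# the latent-EF module.

#' Simulation parameters for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions: demographics as above,
#' template global efficiency scaled to 0.026 (the cohort-mean scale of
#' SIFT2-weighted 84-node connectomes), planted standardized paths
#' a = -0.44, b = 0.18, c' = -0.45 (the local-efficiency mediation row),
#' and bifactor loadings 0.6 (common) / 0.5 (specifics).
#'
#' @param n_subjects Cohort size.
#' @param age_range,age_mean,age_sd Truncated-normal age model (years).
#' @param sex_p_female Probability of female (coded 0; male = 1).
#' @param edu_mean,edu_sd Education years.
#' @param template_density Fraction of possible edges in the template.
#' @param template_eglob Global-efficiency scale of the template.
#' @param effect_age_on_weights Per-year multiplicative slope on
#'   log-weights (negative = efficiency declines with age).
#' @param path_a,path_b,path_c_prime Planted standardized paths.
#' @param noise_sd_ef Residual sd of the EF equation.
#' @param sex_effect,edu_effect Nuisance effects on EF (raw-sex /
#'   z-education scale).
#' @param edge_noise_sd Per-edge log-normal measurement noise sd.
#' @param target_node Optional node index: age then scales only that
#'   node's connections and the planted mediator is that node's regional
#'   efficiency (instead of local efficiency).
#' @param loadings_common,loadings_shifting,loadings_updating Bifactor
#'   loadings for task-score generation.
#' @param seed RNG seed.
#' @return A validated list of class \code{simulation_params}.
#' @export
simulation_params <- function(n_subjects = 84L,
                              age_range = c(60, 85),
                              age_mean = 68.06, age_sd = 4.74,
                              sex_p_female = 52 / 84,
                              edu_mean = 18.06, edu_sd = 2.66,
                              template_density = 0.35,
                              template_eglob = 0.026,
                              effect_age_on_weights = -0.01,
                              path_a = -0.44, path_b = 0.18,
                              path_c_prime = -0.45,
                              noise_sd_ef = 0.83,
                              sex_effect = -0.19, edu_effect = 0.09,
                              edge_noise_sd = 0.05,
                              target_node = NULL,
                              loadings_common = rep(0.6, 9),
                              loadings_shifting = rep(0.5, 3),
                              loadings_updating = rep(0.5, 3),
                              seed = 1L) {
  p <- list(n_subjects = as.integer(n_subjects), age_range = age_range,
            age_mean = age_mean, age_sd = age_sd,
            sex_p_female = sex_p_female, edu_mean = edu_mean,
            edu_sd = edu_sd, template_density = template_density,
            template_eglob = template_eglob,
            effect_age_on_weights = effect_age_on_weights,
            path_a = path_a, path_b = path_b,
            path_c_prime = path_c_prime, noise_sd_ef = noise_sd_ef,
            sex_effect = sex_effect, edu_effect = edu_effect,
            edge_noise_sd = edge_noise_sd, target_node = target_node,
            loadings_common = loadings_common,
            loadings_shifting = loadings_shifting,
            loadings_updating = loadings_updating,
            seed = as.integer(seed))
  if (p$n_subjects < 1) stop("n_subjects must be positive")
  if (p$sex_p_female < 0 || p$sex_p_female > 1) {
    stop("sex_p_female must be in [0, 1]")
  }
  if (p$template_density <= 0 || p$template_density > 1) {
    stop("template_density must be in (0, 1]")
  }
  if (p$age_sd <= 0 || p$edu_sd <= 0 || p$noise_sd_ef <= 0) {
    stop("scale parameters must be positive")
  }
  if (p$edge_noise_sd < 0) stop("edge_noise_sd must be nonnegative")
  if (abs(p$path_a) >= 1) stop("path_a must lie in (-1, 1)")
  if (length(p$loadings_common) != 9 || length(p$loadings_shifting) != 3 ||
      length(p$loadings_updating) != 3) {
    stop("loadings must have lengths 9 / 3 / 3")
  }
  class(p) <- "simulation_params"
  p
}

# Truncated-normal sampling by rejection.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Modular template connectome
#'
#' Symmetric nonnegative 84 x 84 template with zero diagonal. Edge
#' existence is biased toward within-lobe blocks (segregated structure)
#' while matching the requested overall density; weights are log-normal
#' with a within-block premium. Optionally rescaled so its global
#' efficiency equals \code{target_eglob} (efficiency is homogeneous of
#' degree 1 in the weights, so one scalar suffices).
#'
#' @param atlas A \code{node_atlas}.
#' @param density Overall edge density in (0, 1].
#' @param seed RNG seed; same seed gives an identical template.
#' @param target_eglob Optional global-efficiency scale.
#' @return A \code{\link{connectome}} with subject id
#'   \code{"template"}.
#' @export
make_template_connectome <- function(atlas, density = 0.35, seed = 1L,
                                     target_eglob = NULL) {
  atlas <- validate_atlas(atlas)
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  n <- nrow(atlas)
  grp <- atlas$group
  same <- outer(grp, grp, "==")
  ut <- upper.tri(same)
  f_within <- mean(same[ut])
  p_within <- min(1, 1.6 * density)
  p_between <- (density - f_within * p_within) / (1 - f_within)
  p_between <- min(1, max(0, p_between))
  w <- matrix(0, n, n)
  with_seed(seed, {
    pe <- ifelse(same[ut], p_within, p_between)
    present <- stats::runif(sum(ut)) < pe
    wt <- exp(stats::rnorm(sum(ut), mean = 0, sd = 0.5))
    wt <- wt * ifelse(same[ut], 1.5, 1.0)
    w[ut] <- ifelse(present, wt, 0)
  })
  w <- w + t(w)
  cn <- connectome(w, atlas, subject_id = "template")
  if (!is.null(target_eglob)) {
    e <- global_efficiency(cn)
    if (e <= 0) stop("template is too sparse to rescale")
    cn <- connectome(cn$weights * (target_eglob / e), atlas,
                     subject_id = "template")
  }
  cn
}

# Regional efficiency of a single node (same formula as
# regional_efficiency, computed for one index).
regional_efficiency_node <- function(w, i) {
  nb <- which(w[i, ] > 0)
  k <- length(nb)
  if (k < 2) return(0)
  len3 <- ifelse(w[nb, nb] > 0, (1 / w[nb, nb])^(1 / 3), Inf)
  diag(len3) <- 0
  dinv <- 1 / dist_on_lengths(len3)
  diag(dinv) <- 0
  sw <- w[i, nb]^(1 / 3)
  sum(tcrossprod(sw) * dinv) / (k * (k - 1))
}

#' Simulate a cohort with planted mediation structure
#'
#' @param params A \code{\link{simulation_params}}.
#' @param atlas Node atlas (default the bundled 84-node atlas).
#' @param store \code{"matrices"} (default) materializes one connectome
#'   per subject; \code{"none"} skips them (only valid without edge noise
#'   and without a target node, where per-subject efficiency follows from
#'   homogeneity of the metrics) for large-n behavioural simulations.
#' @return List with \code{cohort} (a \code{\link{cohort_dataset}}) and
#'   \code{truth} (per-subject true factors and mediators plus the
#'   planted standardized paths).
#' @export
simulate_cohort <- function(params, atlas = default_atlas(),
                            store = c("matrices", "none")) {
  store <- match.arg(store)
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  if (store == "none" && (p$edge_noise_sd > 0 || !is.null(p$target_node))) {
    stop("store = \"none\" requires edge_noise_sd = 0 and no target node")
  }
  atlas <- validate_atlas(atlas)
  template <- make_template_connectome(atlas, p$template_density,
                                       seed = p$seed + 1L,
                                       target_eglob = p$template_eglob)
  wt <- template$weights
  n <- p$n_subjects
  slope <- p$effect_age_on_weights
  # subject-level log-scale variability sized so cor(age, log mediator)
  # equals path_a (derived, not tuned): sd = |slope| sd_age sqrt(1/a^2 - 1)
  sigma_zeta <- if (slope == 0 || p$path_a == 0) 0.05 else
    abs(slope) * p$age_sd * sqrt(1 / p$path_a^2 - 1)

  out <- with_seed(p$seed, {
    age <- rtruncnorm(n, p$age_mean, p$age_sd, p$age_range[1], p$age_range[2])
    sex <- stats::rbinom(n, 1, 1 - p$sex_p_female)  # female = 0, male = 1
    edu <- stats::rnorm(n, p$edu_mean, p$edu_sd)
    zeta <- stats::rnorm(n, 0, sigma_zeta)
    log_scale <- slope * (age - 70) + zeta

    mediator <- numeric(n)
    true_mediator <- numeric(n)
    cns <- if (store == "matrices") vector("list", n) else NULL
    ids <- sprintf("S%04d", seq_len(n))

    if (store == "none") {
      base_eloc <- local_efficiency(template)
      mediator <- base_eloc * exp(log_scale)
      true_mediator <- base_eloc * exp(slope * (age - 70))
    } else {
      base <- wt
      # noise-free truth follows from homogeneity: scaling all weights by f
      # scales e_loc by f; scaling only node i's incident edges scales
      # e_reg(i) by f^(2/3) (numerator ~ f^(2/3), neighbour paths unchanged)
      if (is.null(p$target_node)) {
        base_val <- local_efficiency(base)
        true_mediator <- base_val * exp(slope * (age - 70))
      } else {
        base_val <- regional_efficiency_node(base, p$target_node)
        true_mediator <- base_val * exp(slope * (age - 70))^(2 / 3)
      }
      for (s in seq_len(n)) {
        f <- exp(log_scale[s])
        if (is.null(p$target_node)) {
          ws <- base * f
        } else {
          ws <- base
          ws[p$target_node, ] <- ws[p$target_node, ] * f
          ws[, p$target_node] <- ws[, p$target_node] * f
        }
        if (p$edge_noise_sd > 0) {
          nn <- nrow(ws)
          en <- matrix(0, nn, nn)
          en[upper.tri(en)] <- stats::rnorm(nn * (nn - 1) / 2, 0,
                                            p$edge_noise_sd)
          en <- en + t(en)
          ws <- ws * exp(en)
        }
        cns[[s]] <- connectome(ws, atlas, subject_id = ids[s])
        mediator[s] <- if (p$edge_noise_sd > 0) {
          if (is.null(p$target_node)) local_efficiency(ws) else
            regional_efficiency_node(ws, p$target_node)
        } else if (is.null(p$target_node)) {
          base_val * f
        } else {
          base_val * f^(2 / 3)
        }
      }
      if (!is.null(cns)) names(cns) <- ids
    }

    zmed <- as.numeric(scale(log(pmax(mediator, 1e-300))))
    zage <- as.numeric(scale(age))
    zedu <- as.numeric(scale(edu))
    common <- p$path_b * zmed + p$path_c_prime * zage +
      p$sex_effect * sex + p$edu_effect * zedu +
      stats::rnorm(n, 0, p$noise_sd_ef)

    shifting <- stats::rnorm(n)
    updating <- stats::rnorm(n)
    tasks <- matrix(0, n, 9, dimnames = list(NULL, ef_task_names()))
    lam <- bifactor_lambda(p$loadings_common, p$loadings_shifting,
                           p$loadings_updating)
    fac <- cbind(common = as.numeric(scale(common)),
                 shifting = shifting, updating = updating)
    uniq_sd <- sqrt(pmax(0.05, 1 - rowSums(lam^2)))
    for (t in seq_len(9)) {
      tasks[, t] <- fac %*% lam[t, ] + stats::rnorm(n, 0, uniq_sd[t])
    }

    subjects <- data.frame(subject_id = ids, age = age, sex = sex,
                           education = edu, stringsAsFactors = FALSE)
    subjects <- cbind(subjects, as.data.frame(tasks))
    list(subjects = subjects, cns = cns,
         truth = list(common_factor = common,
                      mediator = mediator,
                      true_mediator = true_mediator,
                      shifting_factor = shifting,
                      updating_factor = updating,
                      path_a = p$path_a, path_b = p$path_b,
                      path_c_prime = p$path_c_prime,
                      path_ab = p$path_a * p$path_b,
                      target_node = p$target_node,
                      seed = p$seed))
  })

  cohort <- cohort_dataset(out$subjects, out$cns, atlas)
  list(cohort = cohort, truth = out$truth)
}

#' Simulate task scores from known bifactor loadings
#'
#' Convenience generator for factor-model recovery studies: latent
#' common, shifting and updating factors are independent standard
#' normals; task scores follow the bifactor loading structure with
#' independent unique noise.
#'
#' @param n Number of subjects.
#' @param loadings_common,loadings_shifting,loadings_updating Loadings.
#' @param seed RNG seed.
#' @return List with \code{scores} (n x 9 data.frame) and \code{factors}
#'   (n x 3 matrix of the true factor values).
#' @export
simulate_task_scores <- function(n,
                                 loadings_common = rep(0.6, 9),
                                 loadings_shifting = rep(0.5, 3),
                                 loadings_updating = rep(0.5, 3),
                                 seed = 1L) {
  lam <- bifactor_lambda(loadings_common, loadings_shifting,
                         loadings_updating)
  with_seed(seed, {
    fac <- matrix(stats::rnorm(n * 3), n, 3,
                  dimnames = list(NULL, c("common", "shifting", "updating")))
    uniq_sd <- sqrt(pmax(0.05, 1 - rowSums(lam^2)))
    scores <- fac %*% t(lam) +
      matrix(stats::rnorm(n * 9), n, 9) %*% diag(uniq_sd)
    colnames(scores) <- ef_task_names()
    list(scores = as.data.frame(scores), factors = fac)
  })
}

#' Simulate a planted-path mediation dataset
#'
#' Direct trivariate generator on the standardized scale:
#' \code{m = a*iv + e}, \code{dv = b*m + c'*iv + e'}, all variables with
#' (population) unit variance, so the fitted standardized paths estimate
#' a, b and c' directly.
#'
#' @param n Sample size.
#' @param a,b,c_prime Planted standardized paths.
#' @param seed RNG seed.
#' @return data.frame with \code{iv}, \code{m}, \code{dv}.
#' @export
simulate_mediation_data <- function(n, a = -0.44, b = 0.18,
                                    c_prime = -0.45, seed = 1L) {
  if (abs(a) >= 1) stop("a must lie in (-1, 1)")
  sig2 <- 1 - (b^2 + c_prime^2 + 2 * a * b * c_prime)
  sig <- sqrt(max(sig2, 0.1))
  with_seed(seed, {
    iv <- stats::rnorm(n)
    m <- a * iv + sqrt(1 - a^2) * stats::rnorm(n)
    dv <- b * m + c_prime * iv + sig * stats::rnorm(n)
    data.frame(iv = iv, m = m, dv = dv)
  })
}

#' Parameter-recovery report for the mediation chain
#'
#' Repeatedly simulates cohorts with the planted paths of \code{params},
#' runs the mediation estimator with bias-corrected bootstrap CIs, and
#' summarizes bias, RMSE, CI coverage of the true indirect effect, and
#' the CI-excludes-zero rate. \code{mode = "paths"} (default) simulates
#' the mediation triple directly (scales to hundreds of replicates);
#' \code{mode = "full"} runs the whole connectome chain (template,
#' per-subject matrices, graph metrics, task scores, CFA scoring) per
#' replicate and is intended for small replicate counts.
#'
#' @param params A \code{\link{simulation_params}}.
#' @param n_replicates Number of simulated cohorts.
#' @param seed Master seed; replicate r uses \code{seed + r}.
#' @param n_boot Bootstrap resamples per replicate.
#' @param level CI level.
#' @param mode \code{"paths"} or \code{"full"}.
#' @return One-row data.frame: planted values, mean estimates, bias,
#'   RMSE, coverage, rejection rate, replicate count and sample size.
#' @export
recovery_report <- function(params, n_replicates = 100L, seed = 1L,
                            n_boot = 1000L, level = 0.95,
                            mode = c("paths", "full")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "simulation_params"))
  n <- params$n_subjects
  truth_ab <- params$path_a * params$path_b
  est <- matrix(NA_real_, n_replicates, 4,
                dimnames = list(NULL, c("a", "b", "ab", "covered")))
  reject <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_seed <- seed + r
    if (mode == "paths") {
      dat <- simulate_mediation_data(n, params$path_a, params$path_b,
                                     params$path_c_prime, seed = rep_seed)
      iv <- dat$iv; m <- dat$m; dv <- dat$dv
      covs <- NULL
    } else {
      p_r <- params
      p_r$seed <- rep_seed
      sim <- simulate_cohort(p_r)
      prof <- cohort_profiles(sim$cohort, seed = rep_seed)
      fit <- fit_bifactor_cfa(sim$cohort$subjects[, ef_task_names()],
                              seed = rep_seed)
      ef <- factor_scores(fit, sim$cohort$subjects[, ef_task_names()])
      iv <- sim$cohort$subjects$age
      m <- if (is.null(params$target_node)) prof$e_loc else
        prof[[node_names(sim$cohort$atlas)[params$target_node]]]
      dv <- ef$common_ef
      covs <- sim$cohort$subjects[, c("sex", "education")]
    }
    res <- bootstrap_ci(iv, m, dv, covs, n_boot = n_boot, level = level,
                        seed = rep_seed)
    est[r, "a"] <- res$beta_a
    est[r, "b"] <- res$beta_b
    est[r, "ab"] <- res$beta_ab
    est[r, "covered"] <- (res$ci_lower <= truth_ab) &&
      (truth_ab <= res$ci_upper)
    reject[r] <- res$significant
  }
  data.frame(mode = mode, n = n, n_replicates = n_replicates,
             true_a = params$path_a, true_b = params$path_b,
             true_ab = truth_ab,
             mean_a = mean(est[, "a"]), mean_b = mean(est[, "b"]),
             mean_ab = mean(est[, "ab"]),
             bias_ab = mean(est[, "ab"]) - truth_ab,
             rmse_ab = sqrt(mean((est[, "ab"] - truth_ab)^2)),
             coverage = mean(est[, "covered"]),
             rejection_rate = mean(reject),
             stringsAsFactors = FALSE)
}
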