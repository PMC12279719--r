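# Full-analysis orchestration: metrics -> EF scores -> screens ->
# mediation, from one validated configuration.

#' Analysis configuration
#'
#' @param manifest,matrix_dir Paths for \code{\link{load_cohort}} (may be
#'   \code{NULL} when a cohort object is passed to
#'   \code{\link{run_full_analysis}} directly).
#' @param out_dir Output directory for tables and the run manifest.
#' @param covariates Nuisance covariate column names (default sex and
#'   education).
#' @param q FDR level for the node screens.
#' @param n_boot Bootstrap resamples for mediation (>= 1000 for reported
#'   runs; smaller values are allowed but warned about).
#' @param level CI level.
#' @param seed Master seed for all stochastic stages.
#' @param atlas_path Optional user atlas CSV overriding the bundled one.
#' @param stages Stages to run, in pipeline order.
#' @return A validated list of class \code{analysis_config}.
#' @export
analysis_config <- function(manifest = NULL, matrix_dir = NULL,
                            out_dir = NULL,
                            covariates = c("sex", "education"),
                            q = 0.05, n_boot = 5000L, level = 0.95,
                            seed = 1L, atlas_path = NULL,
                            stages = c("metrics", "efscores",
                                       "correlations", "screens",
                                       "mediation", "regional")) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    stop("q must be a single number in (0, 1)")
  }
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("level must lie in (0, 1)")
  }
  n_boot <- as.integer(n_boot)
  if (n_boot < 100) stop("n_boot must be at least 100")
  if (n_boot < 1000) {
    warning("n_boot < 1000: acceptable for exploration, not for ",
            "reported runs")
  }
  bad <- setdiff(stages, c("metrics", "efscores", "correlations",
                           "screens", "mediation", "regional"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(manifest = manifest, matrix_dir = matrix_dir,
                 out_dir = out_dir, covariates = covariates, q = q,
                 n_boot = n_boot, level = level, seed = as.integer(seed),
                 atlas_path = atlas_path, stages = stages),
            class = "analysis_config")
}

run_stage <- function(name, expr) {
  message("[efmediate] stage ", name, " ...")
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Computes (1) the per-subject efficiency profile table, (2) global
#' partial correlations (age and Common EF vs global/local efficiency,
#' controlling for the covariates), (3) FDR-controlled regional screens
#' against age and Common EF, (4) global- and local-efficiency mediation
#' models, and (5) regional mediation on the screen intersection. All
#' tables are returned and, when \code{out_dir} is set, written as TSV
#' plus a JSON run manifest recording seeds and parameters.
#'
#' @param config An \code{\link{analysis_config}}.
#' @param cohort Optional pre-loaded \code{\link{cohort_dataset}}
#'   (otherwise loaded from the config paths).
#' @return Invisibly, a list with \code{profiles}, \code{cfa_fit},
#'   \code{ef_scores}, \code{global_correlations}, \code{age_screen},
#'   \code{ef_screen}, \code{mediation_global}, \code{mediation_local},
#'   \code{mediation_regional}, and \code{manifest}.
#' @export
run_full_analysis <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  atlas <- default_atlas(config$atlas_path)
  if (is.null(cohort)) {
    if (is.null(config$manifest) || is.null(config$matrix_dir)) {
      stop("config needs manifest and matrix_dir when no cohort is given")
    }
    cohort <- run_stage("load", load_cohort(config$manifest,
                                            config$matrix_dir, atlas))
  }
  atlas <- cohort$atlas
  subj <- cohort$subjects
  covs <- if (length(config$covariates)) {
    subj[, config$covariates, drop = FALSE]
  } else NULL
  want <- function(s) s %in% config$stages
  out <- list(manifest = list(
    package_version = as.character(utils::packageVersion("efmediate")),
    n_subjects = nrow(subj), q = config$q, n_boot = config$n_boot,
    level = config$level, seed = config$seed,
    covariates = config$covariates, stages = config$stages))

  profiles <- NULL
  if (want("metrics")) {
    profiles <- run_stage("metrics",
                          cohort_profiles(cohort, seed = config$seed))
    out$profiles <- profiles
  }

  ef <- NULL
  if (want("efscores")) {
    ef <- run_stage("efscores", {
      if (all(ef_task_names() %in% names(subj))) {
        fit <- fit_bifactor_cfa(subj[, ef_task_names()],
                                seed = config$seed)
        scores <- factor_scores(fit, subj[, ef_task_names()])
        out$cfa_fit <- fit
        scores$common_ef
      } else if ("common_ef" %in% names(subj)) {
        subj$common_ef
      } else {
        stop("no task scores and no precomputed common_ef column")
      }
    })
    out$ef_scores <- ef
  }

  if (want("correlations")) {
    out$global_correlations <- run_stage("correlations", {
      stopifnot(!is.null(profiles), !is.null(ef))
      pairs <- list(c("age", "e_glob"), c("age", "e_loc"),
                    c("common_ef", "e_glob"), c("common_ef", "e_loc"))
      do.call(rbind, lapply(pairs, function(pr) {
        x <- if (pr[1] == "age") subj$age else ef
        pp <- partial_pearson(x, profiles[[pr[2]]], covs)
        data.frame(x = pr[1], y = pr[2], r = pp$r, p = pp$p,
                   stringsAsFactors = FALSE)
      }))
    })
  }

  age_screen <- ef_screen <- NULL
  if (want("screens")) {
    run_stage("screens", {
      stopifnot(!is.null(profiles), !is.null(ef))
      age_screen <- node_screen(profiles, subj$age, covs, atlas,
                                 q = config$q)
      ef_screen <- node_screen(profiles, ef, covs, atlas, q = config$q)
    })
    out$age_screen <- age_screen
    out$ef_screen <- ef_screen
  }

  if (want("mediation")) {
    run_stage("mediation", {
      stopifnot(!is.null(profiles), !is.null(ef))
      out$mediation_global <- bootstrap_ci(subj$age, profiles$e_glob, ef,
                                            covs, n_boot = config$n_boot,
                                            level = config$level,
                                            seed = config$seed)
      out$mediation_local <- bootstrap_ci(subj$age, profiles$e_loc, ef,
                                           covs, n_boot = config$n_boot,
                                           level = config$level,
                                           seed = config$seed + 1L)
    })
  }

  if (want("regional")) {
    out$mediation_regional <- run_stage("regional", {
      stopifnot(!is.null(age_screen), !is.null(ef_screen))
      regional_mediation(profiles, subj$age, ef, age_screen, ef_screen,
                         atlas, covariates = covs,
                         n_boot = config$n_boot, level = config$level,
                         seed = config$seed + 100L)
    })
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$out_dir
    if (!is.null(out$profiles)) {
      write_profiles(out$profiles, file.path(od, "efficiency_profiles.tsv"))
    }
    if (!is.null(out$cfa_fit)) {
      write_cfa_fit(out$cfa_fit, file.path(od, "cfa_fit.json"))
    }
    if (!is.null(out$ef_scores)) {
      utils::write.table(data.frame(subject_id = subj$subject_id,
                                    common_ef = out$ef_scores),
                         file.path(od, "ef_scores.tsv"), sep = "\t",
                         row.names = FALSE, quote = TRUE)
    }
    if (!is.null(out$global_correlations)) {
      utils::write.table(out$global_correlations,
                         file.path(od, "global_correlations.tsv"),
                         sep = "\t", row.names = FALSE, quote = TRUE)
    }
    if (!is.null(out$age_screen)) {
      write_screen(out$age_screen, file.path(od, "age_screen.tsv"))
      write_screen(out$ef_screen, file.path(od, "ef_screen.tsv"))
    }
    if (!is.null(out$mediation_regional)) {
      write_mediation_table(out$mediation_regional,
                            file.path(od, "regional_mediation.tsv"))
    }
    med_sum <- function(m) if (is.null(m)) NULL else
      m[c("beta_a", "beta_b", "beta_c", "beta_c_prime", "beta_ab",
          "boot_se", "ci_lower", "ci_upper", "n_boot", "seed",
          "significant")]
    jsonlite::write_json(c(out$manifest,
                           list(mediation_global = med_sum(out$mediation_global),
                                mediation_local = med_sum(out$mediation_local))),
                         file.path(od, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
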