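# Orchestration of the fully crossed Monte-Carlo experiment: 2 factor-score
# distributions x 3 factor correlations x 6 sample sizes x 6 estimation
# methods, with per-cell/per-replication child seeds so any cell can be
# reproduced in isolation and results do not depend on execution order.

LS_METHODS <- c("RML", "RDWLS", "RULS", "WLS")
BAYES_METHODS <- c("bayes_inf", "bayes_lessinf")

#' Define a study design
#'
#' Defaults are the full crossed design; the replication count and Bayesian
#' chain configuration default to a desk-scale profile. \code{profile =
#' "full"} selects the full-scale configuration (500 replications,
#' 10,000 burn-in / 2,000 retained / 3 chains).
#'
#' @param distributions subset of \code{c("normal", "mild_skew")}
#' @param xi_values generating factor correlations
#' @param sample_sizes sample sizes
#' @param methods estimation methods (least-squares: WLS, RDWLS, RULS, RML;
#'   Bayesian: bayes_inf, bayes_lessinf)
#' @param replications Monte-Carlo replications per cell
#' @param master_seed master seed; all cell/replication seeds derive from it
#' @param n_burn,n_keep,n_chains Bayesian chain configuration
#' @param level interval level
#' @param workers parallel workers for cells (requires the parallel package;
#'   results are identical for any worker count)
#' @param profile \code{"desk"} or \code{"full"}
#' @return object of class \code{study_design}
#' @export
study_design <- function(distributions = c("normal", "mild_skew"),
                         xi_values = c(0.2, 0.5, 0.8),
                         sample_sizes = c(42, 63, 84, 105, 210, 315),
                         methods = c(BAYES_METHODS, LS_METHODS),
                         replications = NULL,
                         master_seed = 1L,
                         n_burn = NULL, n_keep = NULL, n_chains = NULL,
                         level = 0.95,
                         workers = 1L,
                         profile = c("desk", "full")) {
  profile <- match.arg(profile)
  defaults <- if (profile == "full")
    list(replications = 500L, n_burn = 10000L, n_keep = 2000L, n_chains = 3L)
  else
    list(replications = 100L, n_burn = 2000L, n_keep = 1000L, n_chains = 2L)
  methods <- match.arg(methods, c(BAYES_METHODS, LS_METHODS),
                       several.ok = TRUE)
  structure(
    list(distributions = distributions, xi_values = xi_values,
         sample_sizes = sample_sizes, methods = methods,
         replications = replications %||% defaults$replications,
         master_seed = master_seed,
         n_burn = n_burn %||% defaults$n_burn,
         n_keep = n_keep %||% defaults$n_keep,
         n_chains = n_chains %||% defaults$n_chains,
         level = level, workers = workers, profile = profile),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design (%s profile): %d x %d x %d cells, R = %d\n",
              x$profile, length(x$distributions), length(x$xi_values),
              length(x$sample_sizes), x$replications))
  cat("  methods:", paste(x$methods, collapse = ", "), "\n")
  if (any(x$methods %in% BAYES_METHODS))
    cat(sprintf("  chains: %d x (%d burn + %d kept)\n",
                x$n_chains, x$n_burn, x$n_keep))
  invisible(x)
}

empty_record <- function(dist, xi, n, method, rep) {
  data.frame(dist = dist, xi_true = xi, n = n, method = method, rep = rep,
             est = NA_real_, se = NA_real_, lower = NA_real_,
             upper = NA_real_, converged = FALSE, admissible = FALSE,
             stringsAsFactors = FALSE)
}

ls_record <- function(fit, dist, xi, n, rep) {
  r <- empty_record(dist, xi, n, fit$method, rep)
  r$converged <- fit$converged
  r$admissible <- fit$admissible
  if (fit$converged) {
    r$est <- fit$xi
    if (fit$admissible) {
      r$se <- fit$se_xi
      r$lower <- fit$ci[["lower"]]
      r$upper <- fit$ci[["upper"]]
    }
  }
  r
}

bayes_record <- function(bf, method, dist, xi, n, rep, mpsrf_bound = 1.2) {
  r <- empty_record(dist, xi, n, method, rep)
  r$est <- bf$eap
  r$se <- bf$post_sd
  r$lower <- bf$ci[["lower"]]
  r$upper <- bf$ci[["upper"]]
  r$converged <- is.na(bf$mpsrf) || bf$mpsrf < mpsrf_bound
  r$admissible <- TRUE
  r$mpsrf <- bf$mpsrf
  r
}

#' Run one design cell
#'
#' For each replication: draw loadings, generate one dataset, and apply ALL
#' requested methods to that same dataset (shared-data design, so method
#' comparisons are paired). Failures are recorded, never fatal.
#'
#' @param design a \code{\link{study_design}}
#' @param dist factor-score distribution of this cell
#' @param xi generating factor correlation
#' @param n sample size
#' @param cell_index integer index used for seed derivation
#' @return records data frame (one row per replication x method; Bayesian
#'   rows carry an \code{mpsrf} column)
#' @export
run_cell <- function(design, dist, xi, n, cell_index = 1L) {
  ls_m <- intersect(design$methods, LS_METHODS)
  ba_m <- intersect(design$methods, BAYES_METHODS)
  out <- vector("list", design$replications)
  for (rep in seq_len(design$replications)) {
    seed <- child_seed(design$master_seed, cell_index, rep)
    set.seed(seed)
    recs <- list()
    dataset <- tryCatch({
      spec <- model_spec(draw_loadings(), xi, dist_shape = dist)
      generate_dataset(spec, n)
    }, error = function(e) NULL)
    if (is.null(dataset)) {
      for (m in c(ls_m, ba_m))
        recs[[m]] <- empty_record(dist, xi, n, m, rep)
    } else {
      if (length(ls_m)) {
        pc <- tryCatch(polychoric(dataset), error = function(e) NULL)
        for (m in ls_m) {
          ft <- if (is.null(pc)) NULL else
            tryCatch(cfa_fit(pc, n, m, level = design$level),
                     error = function(e) NULL)
          recs[[m]] <- if (is.null(ft)) empty_record(dist, xi, n, m, rep)
          else ls_record(ft, dist, xi, n, rep)
        }
      }
      for (m in ba_m) {
        prior <- prior_spec(if (m == "bayes_inf") "inf" else "lessinf")
        bf <- tryCatch(
          bayes_fit(dataset, prior, n_chains = design$n_chains,
                    n_burn = design$n_burn, n_keep = design$n_keep,
                    seed = child_seed(seed, match(m, BAYES_METHODS)),
                    level = design$level),
          error = function(e) NULL)
        recs[[m]] <- if (is.null(bf)) empty_record(dist, xi, n, m, rep)
        else bayes_record(bf, m, dist, xi, n, rep)
      }
    }
    for (i in seq_along(recs))
      if (!"mpsrf" %in% names(recs[[i]])) recs[[i]]$mpsrf <- NA_real_
    out[[rep]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full study
#'
#' Executes every cell of the design (optionally in parallel over cells),
#' assembles the per-replication records, the per-cell summaries, and the
#' eta-squared tables, and optionally writes everything (plus a manifest)
#' to a directory as CSV/JSON.
#'
#' @param design a \code{\link{study_design}}
#' @param out_dir optional output directory
#' @return list with \code{records}, \code{summaries}, \code{eta_sq} (list
#'   of per-outcome effect tables), and \code{design}
#' @export
run_study <- function(design, out_dir = NULL) {
  cells <- expand.grid(dist = design$distributions, xi = design$xi_values,
                       n = design$sample_sizes, stringsAsFactors = FALSE)
  run_one <- function(ci) run_cell(design, cells$dist[ci], cells$xi[ci],
                                   cells$n[ci], cell_index = ci)
  idx <- seq_len(nrow(cells))
  records <- if (design$workers > 1L &&
                 requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(idx, run_one, mc.cores = design$workers)
  } else {
    lapply(idx, run_one)
  }
  records <- do.call(rbind, records)

  summaries <- do.call(rbind, lapply(
    split(records, list(records$dist, records$xi_true, records$n,
                        records$method), drop = TRUE),
    function(r) cell_summary(r, r$xi_true[1])))
  rownames(summaries) <- NULL
  summaries <- summaries[order(summaries$dist, summaries$n,
                               summaries$xi_true, summaries$method), ]

  eta <- list()
  for (outc in c("coverage", "mean_width", "pos_bias_pct", "neg_bias_pct",
                 "rmse", "bias")) {
    eta[[outc]] <- tryCatch(eta_squared(summaries, outc),
                            error = function(e) NULL)
  }

  out <- list(records = records, summaries = summaries, eta_sq = eta,
              design = design)
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

#' Write study outputs as CSV plus a JSON manifest
#'
#' @param study result of \code{\link{run_study}}
#' @param out_dir output directory (created if needed)
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(study$summaries, file.path(out_dir, "cell_summaries.csv"),
                   row.names = FALSE)
  for (nm in names(study$eta_sq))
    if (!is.null(study$eta_sq[[nm]]))
      utils::write.csv(study$eta_sq[[nm]],
                       file.path(out_dir, paste0("eta_sq_", nm, ".csv")),
                       row.names = FALSE)
  d <- study$design
  jsonlite::write_json(
    list(distributions = d$distributions, xi_values = d$xi_values,
         sample_sizes = d$sample_sizes, methods = d$methods,
         replications = d$replications, master_seed = d$master_seed,
         n_burn = d$n_burn, n_keep = d$n_keep, n_chains = d$n_chains,
         level = d$level, profile = d$profile,
         package_version = tryCatch(
           as.character(utils::packageVersion("ordcfa")),
           error = function(e) NA_character_),
         r_version = R.version.string),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
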