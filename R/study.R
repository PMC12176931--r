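default_missing_levels <- function() {
  c("Complete",
    "Concen-S-30%", "Constant-30%", "Concen-E-30%",
    "Concen-S-70%", "Constant-70%", "Concen-E-70%")
}

default_prior_names <- function() {
  c("DIF", "I-ATK", "WI-ATK", "I-PRK", "WI-PRK", "I-PSK", "WI-PSK")
}

#' Map a missing-level label to its missingness specification
#'
#' Translates the study labels (\code{"Complete"}, \code{"Concen-S-30\%"},
#' \code{"Constant-30\%"}, \code{"Concen-E-30\%"} and the 70\% variants)
#' into \code{\link{missingness_spec}} objects.
#'
#' @param label Missing-level label.
#' @param grid Time grid (default 0..6).
#' @param monotone Carry dropout forward (see
#'   \code{\link{missingness_spec}}).
#' @return A \code{\link{missingness_spec}}.
#' @export
missing_level_spec <- function(label, grid = time_grid(),
                               monotone = FALSE) {
  if (label == "Complete") {
    return(missingness_spec("complete", grid = grid))
  }
  m <- regmatches(label,
                  regexec("^(Concen-S|Constant|Concen-E)-(30|70)%$", label))[[1]]
  if (length(m) == 0L) {
    stop("unknown missing level '", label, "'", call. = FALSE)
  }
  pattern <- c("Concen-S" = "concen_s", "Constant" = "constant",
               "Concen-E" = "concen_e")[[m[2]]]
  missingness_spec(pattern, terminal_prop = as.numeric(m[3]) / 100,
                   grid = grid, monotone = monotone)
}

#' Factorial simulation design
#'
#' The fully crossed Monte Carlo design: sample sizes x missing-data
#' levels x knot-prior presets, with a fixed number of replications per
#' cell. The defaults reproduce the 3 x 7 x 7 = 147-cell design with 500
#' replications per cell.
#'
#' @param sample_sizes Integer vector (default 50, 150, 500).
#' @param missing_levels Character vector of missing-level labels.
#' @param prior_names Character vector of knot-prior preset names.
#' @param replications Replications per cell (default 500).
#' @param mcmc An \code{\link{mcmc_config}}. The default is the reduced
#'   desk-scale preset; pass \code{mcmc_config()} for the full-scale
#'   4 x 25,000 protocol.
#' @param population Data-generating \code{\link{pgm_parameters}}.
#' @param seed Master seed; every replication seed is derived from
#'   (seed, cell index, replication index), so results are a pure
#'   function of the design and independent of scheduling.
#' @return An object of class \code{study_design}.
#' @export
study_design <- function(sample_sizes = c(50L, 150L, 500L),
                         missing_levels = default_missing_levels(),
                         prior_names = default_prior_names(),
                         replications = 500L,
                         mcmc = mcmc_config_reduced(),
                         population = default_population(),
                         seed = 1L) {
  stopifnot(inherits(mcmc, "mcmc_config"),
            inherits(population, "pgm_parameters"))
  if (length(sample_sizes) == 0L || length(missing_levels) == 0L ||
      length(prior_names) == 0L) {
    stop("all factor lists must be nonempty", call. = FALSE)
  }
  for (fac in list(sample_sizes, missing_levels, prior_names)) {
    if (anyDuplicated(fac)) {
      stop("duplicate factor levels in the design", call. = FALSE)
    }
  }
  if (replications < 1L) stop("replications must be >= 1", call. = FALSE)
  structure(list(sample_sizes = as.integer(sample_sizes),
                 missing_levels = missing_levels,
                 prior_names = prior_names,
                 replications = as.integer(replications),
                 mcmc = mcmc, population = population,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  k <- length(x$sample_sizes) * length(x$missing_levels) *
    length(x$prior_names)
  cat("<study_design>", k, "cells x", x$replications,
      "replications (seed", paste0(x$seed, ")\n"))
  invisible(x)
}

#' Enumerate the design cells
#'
#' Deterministic ordering: sample size is the outermost (slowest) factor,
#' missing level the middle, prior the innermost.
#'
#' @param design A \code{\link{study_design}}.
#' @return Data frame with columns \code{cell}, \code{sample_size},
#'   \code{missing_level}, \code{prior_name}; one row per cell.
#' @examples
#' nrow(enumerate_design(study_design()))  # 147
#' @export
enumerate_design <- function(design) {
  stopifnot(inherits(design, "study_design"))
  grid <- expand.grid(prior_name = design$prior_names,
                      missing_level = design$missing_levels,
                      sample_size = design$sample_sizes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(cell = seq_len(nrow(grid)),
             sample_size = grid$sample_size,
             missing_level = grid$missing_level,
             prior_name = grid$prior_name,
             stringsAsFactors = FALSE)
}

# replication seed derived from (master, cell, rep); < 2^31 and positive,
# independent of execution order
derive_seed <- function(master, cell, rep) {
  s <- (as.double(master %% 100000L) * 20011 + as.double(cell) * 104729 +
          as.double(rep) * 7919) %% 2147483629
  as.integer(s) + 1L
}

run_one_replication <- function(n, mspec, priors, design, seed_r,
                                rep_index) {
  set.seed(seed_r)
  dat <- generate_complete(design$population, n)
  dat <- apply_mar(dat, mspec)
  fit <- fit_pgm(dat, priors, design$mcmc)
  g <- fit$summaries[fit$summaries$parameter == "gamma", ]
  data.frame(replication = rep_index, estimate = g$mean,
             ci_lower = g$ci_lower, ci_upper = g$ci_upper,
             converged = fit$converged,
             knot_acceptance = fit$knot_acceptance, seed = seed_r)
}

#' Run one design cell
#'
#' For each replication: generate complete data from the population,
#' impose the cell's MAR pattern, fit the model under the cell's knot
#' prior with the diffuse nuisance priors, and record the knot posterior
#' mean, 95\% credible interval and convergence flag. Sampler failures in
#' a replication are logged and counted as nonconverged; they never abort
#' the cell.
#'
#' @param cell Either a cell index into \code{\link{enumerate_design}} or
#'   a one-row data frame from it.
#' @param design A \code{\link{study_design}}.
#' @param verbose Emit one structured log line per replication.
#' @return A \code{\link{cell_metrics}} object; the per-replication
#'   records are attached as \code{attr(, "records")}.
#' @export
run_cell <- function(cell, design, verbose = FALSE) {
  stopifnot(inherits(design, "study_design"))
  cells <- enumerate_design(design)
  if (is.numeric(cell)) cell <- cells[cells$cell == cell, , drop = FALSE]
  if (nrow(cell) != 1L) stop("cell must identify one design cell",
                             call. = FALSE)
  grid <- design$population$grid
  mspec <- missing_level_spec(cell$missing_level, grid)
  priors <- default_nuisance_priors(knot_prior_preset(cell$prior_name,
                                                      grid))
  recs <- vector("list", design$replications)
  for (r in seq_len(design$replications)) {
    seed_r <- derive_seed(design$seed, cell$cell, r)
    recs[[r]] <- tryCatch(
      run_one_replication(cell$sample_size, mspec, priors, design, seed_r,
                          r),
      error = function(e) {
        warning("replication ", r, " in cell ", cell$cell, " failed: ",
                conditionMessage(e), call. = FALSE)
        data.frame(replication = r, estimate = NA_real_,
                   ci_lower = NA_real_, ci_upper = NA_real_,
                   converged = FALSE, knot_acceptance = NA_real_,
                   seed = seed_r)
      })
    if (verbose) {
      rec <- recs[[r]]
      cat(sprintf("cell=%d rep=%d converged=%s knot_mean=%.3f acc=%.2f\n",
                  cell$cell, r, rec$converged, rec$estimate,
                  rec$knot_acceptance))
    }
  }
  records <- do.call(rbind, recs)
  out <- cell_metrics(records, truth = design$population$gamma)
  attr(out, "records") <- records
  attr(out, "cell") <- cell
  out
}

#' Run the full factorial study
#'
#' Executes every cell of the design and assembles the result tables:
#' long-format convergence, coverage and RMSE tables (one row per cell,
#' keyed by sample size, missing level and prior), a tidy file of
#' per-replication knot posterior means (the data behind ridgeline plots
#' of the estimate distributions), and a bias summary per cell.
#'
#' @param design A \code{\link{study_design}}.
#' @param out_dir Optional directory; when given, the four tables are
#'   written as \code{convergence.csv}, \code{coverage.csv},
#'   \code{rmse.csv}, \code{bias.csv}, \code{posterior_means.csv}, plus a
#'   \code{run_log.csv} of per-cell completion status.
#' @param verbose Per-replication logging.
#' @return List with data frames \code{convergence}, \code{coverage},
#'   \code{rmse}, \code{bias}, \code{posterior_means} and \code{run_log}.
#' @export
run_study <- function(design, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(design, "study_design"))
  cells <- enumerate_design(design)
  key <- cells[, c("sample_size", "missing_level", "prior_name")]
  metrics <- vector("list", nrow(cells))
  reps <- vector("list", nrow(cells))
  status <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cm <- run_cell(cells[i, ], design, verbose = verbose)
    metrics[[i]] <- cm
    rec <- attr(cm, "records")
    reps[[i]] <- cbind(key[rep(i, nrow(rec)), , drop = FALSE], rec,
                       row.names = NULL)
    status[i] <- if (anyNA(rec$estimate)) "partial" else "ok"
  }
  pull <- function(field) {
    cbind(key, value = vapply(metrics, `[[`, numeric(1), field),
          row.names = NULL)
  }
  out <- list(convergence = pull("convergence_rate"),
              coverage = pull("coverage"),
              rmse = pull("rmse"),
              bias = pull("avg_bias"),
              posterior_means = do.call(rbind, reps),
              run_log = cbind(key, status = status, row.names = NULL))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  out
}

#' Fit a wide-format CSV under each knot-prior preset
#'
#' The applied single-dataset workflow: reads a wide longitudinal CSV
#' (one row per subject, empty cells missing), rescales the knot-prior
#' presets to the dataset's time grid, fits the model once per preset and
#' returns one summary row per prior for the knot location.
#'
#' @param path CSV path.
#' @param time_codes Optional time codes (otherwise parsed from the
#'   header).
#' @param prior_names Preset names to fit (default: all seven).
#' @param mcmc An \code{\link{mcmc_config}}; when it carries a seed, each
#'   preset's fit is seeded deterministically from it.
#' @return Data frame with columns \code{prior}, \code{mean},
#'   \code{median}, \code{sd}, \code{ci_lower}, \code{ci_upper},
#'   \code{max_rhat}, \code{converged}.
#' @export
fit_from_csv <- function(path, time_codes = NULL,
                         prior_names = default_prior_names(),
                         mcmc = mcmc_config()) {
  data <- read_longitudinal_csv(path, time_codes)
  rows <- lapply(seq_along(prior_names), function(i) {
    cfg <- mcmc
    if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + i - 1L
    priors <- default_nuisance_priors(
      knot_prior_preset(prior_names[i], data$grid))
    fit <- fit_pgm(data, priors, cfg)
    g <- fit$summaries[fit$summaries$parameter == "gamma", ]
    data.frame(prior = prior_names[i], mean = g$mean, median = g$median,
               sd = g$sd, ci_lower = g$ci_lower, ci_upper = g$ci_upper,
               max_rhat = max(fit$rhat), converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
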