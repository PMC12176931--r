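#' Default simulation population
#'
#' The documented population values used by the packaged Monte Carlo
#' design: a linear-linear piecewise growth model on seven equidistant
#' occasions with the knot at the fourth occasion (coded 3), growth-factor
#' means \code{(50, 1, 2.5)}, factor covariance
#' \code{diag(25, 0.5, 0.5)}, and residual variance 60 at every
#' occasion.
#'
#' @details The post-knot slope mean exceeds the pre-knot mean by 1.5,
#' a standardized slope-change effect of \eqn{1.5/\sqrt{0.5 + 0.5} = 1.5}
#' — a large change by conventional benchmarks, so the knot is detectable
#' in principle. The residual variance is calibrated so that a single
#' dataset of n = 50 carries weak information about the knot (the regime
#' in which knot estimates are dictated by their priors at small n) while
#' the no-knot boundary pseudo-mode of the posterior is suppressed by
#' n = 500; see the methods vignette for the derivation. All values can
#' be overridden by constructing \code{\link{pgm_parameters}} directly.
#'
#' @param grid Time grid (default 0..6).
#' @return A \code{\link{pgm_parameters}} object.
#' @export
default_population <- function(grid = time_grid()) {
  pgm_parameters(alpha = c(50, 1, 2.5),
                 omega_eta = diag(c(25, 0.5, 0.5)),
                 sigma2_eps = 60,
                 gamma = 3,
                 grid = grid)
}

#' Target marginal missingness schedules
#'
#' Evaluates the attrition schedules that fix the marginal percentage of
#' missing values at each occasion on the default 0..6 grid. With terminal
#' percentage P at the last occasion, the three patterns are, in percent:
#' decelerated increase (missing concentrated at the start,
#' \code{concen_s}) \eqn{-(P/36)(t_j-6)^2 + P}; constant increase
#' \eqn{(P/6) t_j}; accelerated increase (concentrated at the end,
#' \code{concen_e}) \eqn{(P/36) t_j^2}. At the printed levels these reduce
#' to \eqn{-\frac{5}{6}(t_j-6)^2+30}, \eqn{5t_j}, \eqn{\frac{5}{6}t_j^2}
#' (30\%) and \eqn{-\frac{35}{18}(t_j-6)^2+70}, \eqn{\frac{35}{3}t_j},
#' \eqn{\frac{35}{18}t_j^2} (70\%).
#'
#' @param pattern One of \code{"concen_s"}, \code{"constant"},
#'   \code{"concen_e"}.
#' @param terminal_prop Fraction missing at the final occasion (e.g. 0.30).
#' @param grid Must be the default 0..6 grid; other grids need an explicit
#'   user-supplied schedule in \code{\link{missingness_spec}}.
#' @return Length-J vector of missing fractions; the first entry is 0.
#' @examples
#' missing_schedule("constant", 0.30)  # 0, .05, .10, .15, .20, .25, .30
#' @export
missing_schedule <- function(pattern = c("concen_s", "constant", "concen_e"),
                             terminal_prop, grid = time_grid()) {
  pattern <- match.arg(pattern)
  stopifnot(inherits(grid, "time_grid"))
  if (!is_default_grid(grid)) {
    stop("schedule formulas are defined on the default 0..6 grid; ",
         "supply an explicit schedule for other grids", call. = FALSE)
  }
  if (!is.numeric(terminal_prop) || terminal_prop < 0 || terminal_prop >= 1) {
    stop("terminal_prop must be a fraction in [0, 1)", call. = FALSE)
  }
  t <- grid$codes
  P <- 100 * terminal_prop
  pct <- switch(pattern,
    concen_s = -(P / 36) * (t - 6)^2 + P,
    constant = (P / 6) * t,
    concen_e = (P / 36) * t^2
  )
  pct / 100
}

#' Solve logistic-dropout intercepts for target marginal missingness
#'
#' For each occasion's target missing fraction \eqn{p_j}, finds the
#' intercept \eqn{b_{0,j}} such that the missingness probability
#' \eqn{\mathrm{logit}^{-1}(b_{0,j} + b_1 z)} averaged over a standard
#' normal predictor \eqn{z} equals \eqn{p_j}. The average is computed by
#' adaptive quadrature and the intercept by 1-D root finding to a
#' tolerance of 1e-8.
#'
#' @param schedule Vector of target fractions in [0, 1).
#' @param b1 Logistic slope on the standardized first-occasion outcome
#'   (default 1.48, a strong association between the cause of missingness
#'   and dropout).
#' @return Numeric vector of intercepts; entries where \eqn{p_j = 0} are
#'   \code{NA} ("no missingness" sentinel, no \code{-Inf} arithmetic).
#' @examples
#' solve_logit_intercepts(c(0, 0.5), b1 = 1.48)  # NA, 0
#' @export
solve_logit_intercepts <- function(schedule, b1 = 1.48) {
  if (any(schedule < 0 | schedule >= 1)) {
    stop("schedule entries must lie in [0, 1)", call. = FALSE)
  }
  if (!is.finite(b1)) stop("b1 must be finite", call. = FALSE)
  marg <- function(b0) {
    stats::integrate(function(z) stats::plogis(b0 + b1 * z) * stats::dnorm(z),
                     -Inf, Inf, rel.tol = 1e-10)$value
  }
  vapply(schedule, function(p) {
    if (p == 0) return(NA_real_)
    stats::uniroot(function(b0) marg(b0) - p, interval = c(-40, 40),
                   tol = 1e-8)$root
  }, numeric(1))
}

#' Missingness specification for MAR attrition generation
#'
#' Bundles an attrition pattern, its target schedule and the solved
#' logistic intercepts. Missingness at occasions 2..J is driven by the
#' standardized first-occasion outcome (which therefore stays fully
#' observed), satisfying the missing-at-random mechanism by construction.
#'
#' @param pattern \code{"complete"} (no missingness), \code{"concen_s"},
#'   \code{"constant"} or \code{"concen_e"}.
#' @param terminal_prop Fraction missing at the final occasion.
#' @param b1 Logistic slope (default 1.48).
#' @param schedule Optional explicit J-vector of target fractions
#'   (required for non-default grids); first entry must be 0.
#' @param monotone If \code{TRUE}, dropout is carried forward so the mask
#'   is a per-row staircase (strict attrition). The default \code{FALSE}
#'   generates independent per-occasion indicators, which reproduces the
#'   target marginal proportions exactly.
#' @param grid Time grid.
#' @return An object of class \code{missingness_spec}.
#' @export
missingness_spec <- function(pattern = c("complete", "concen_s", "constant",
                                         "concen_e"),
                             terminal_prop = 0, b1 = 1.48, schedule = NULL,
                             monotone = FALSE, grid = time_grid()) {
  pattern <- match.arg(pattern)
  stopifnot(inherits(grid, "time_grid"))
  if (pattern == "complete") {
    schedule <- rep(0, grid$J)
    terminal_prop <- 0
  } else if (is.null(schedule)) {
    schedule <- missing_schedule(pattern, terminal_prop, grid)
  } else {
    schedule <- as.numeric(schedule)
    if (length(schedule) != grid$J) {
      stop("schedule must have length J = ", grid$J, call. = FALSE)
    }
    if (schedule[1L] != 0) {
      stop("the first occasion must be fully observed (schedule[1] = 0)",
           call. = FALSE)
    }
    terminal_prop <- schedule[grid$J]
  }
  if (is.unsorted(schedule)) {
    stop("attrition schedules must be non-decreasing over occasions",
         call. = FALSE)
  }
  intercepts <- if (pattern == "complete") rep(NA_real_, grid$J) else
    solve_logit_intercepts(schedule, b1)
  structure(list(pattern = pattern, terminal_prop = terminal_prop, b1 = b1,
                 schedule = schedule, intercepts = intercepts,
                 monotone = monotone, grid = grid),
            class = "missingness_spec")
}

#' @export
print.missingness_spec <- function(x, ...) {
  cat("<missingness_spec>", x$pattern,
      sprintf("(%.0f%% at final occasion, b1 = %.2f%s)\n",
              100 * x$terminal_prop, x$b1,
              if (x$monotone) ", monotone" else ""))
  cat("  schedule:", paste(sprintf("%.3f", x$schedule), collapse = " "),
      "\n")
  invisible(x)
}

#' Generate complete data from a piecewise growth population
#'
#' Draws growth factors \eqn{\eta_i \sim N(\alpha, \Omega_\eta)} and
#' residuals \eqn{\epsilon_i \sim N(0, \mathrm{diag}(\sigma^2_\epsilon))},
#' and returns \eqn{y_i = \Lambda(\gamma)\eta_i + \epsilon_i} with every
#' cell observed.
#'
#' @param params A \code{\link{pgm_parameters}} object.
#' @param n Number of subjects (>= 1).
#' @param grid Time grid; defaults to the grid in \code{params}.
#' @param seed Optional integer seed; when supplied the draw is
#'   reproducible and the caller's RNG state is untouched.
#' @return A fully observed \code{\link{longitudinal_dataset}}.
#' @export
generate_complete <- function(params, n, grid = params$grid, seed = NULL) {
  stopifnot(inherits(params, "pgm_parameters"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  L <- build_loading_matrix(grid, params$gamma)
  Ceta <- chol(params$omega_eta + diag(1e-12, 3))
  eta <- matrix(stats::rnorm(n * 3L), n, 3L) %*% Ceta
  eta <- sweep(eta, 2L, params$alpha, `+`)
  eps <- matrix(stats::rnorm(n * grid$J), n, grid$J)
  eps <- sweep(eps, 2L, sqrt(params$sigma2_eps), `*`)
  y <- eta %*% t(L) + eps
  longitudinal_dataset(y, matrix(TRUE, n, grid$J), grid)
}

#' Impose MAR attrition-style missingness
#'
#' Standardizes the first-occasion outcome with its sample mean and SD,
#' computes per-subject missingness probabilities
#' \eqn{\mathrm{logit}^{-1}(b_{0,j} + b_1 z_{i1})} for occasions 2..J, and
#' deletes values where independent Bernoulli indicators come up 1. With
#' \code{spec$monotone} set, missingness is additionally carried forward
#' from a subject's first missing occasion.
#'
#' @param data A fully observed (column 1 at minimum)
#'   \code{\link{longitudinal_dataset}}.
#' @param spec A \code{\link{missingness_spec}}; a \code{"complete"} spec
#'   returns the input unchanged.
#' @param seed Optional integer seed (restores the caller's RNG state).
#' @return A \code{\link{longitudinal_dataset}} with updated mask.
#' @export
apply_mar <- function(data, spec, seed = NULL) {
  stopifnot(inherits(data, "longitudinal_dataset"),
            inherits(spec, "missingness_spec"))
  if (spec$pattern == "complete") return(data)
  if (data$grid$J != spec$grid$J ||
      !isTRUE(all.equal(data$grid$codes, spec$grid$codes))) {
    stop("data and missingness spec are on different grids", call. = FALSE)
  }
  if (!all(data$mask[, 1L])) {
    stop("the first occasion must be fully observed before applying MAR",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  J <- data$grid$J
  n <- data$n
  y1 <- data$values[, 1L]
  z <- (y1 - mean(y1)) / stats::sd(y1)
  mask <- data$mask
  for (j in 2L:J) {
    b0 <- spec$intercepts[j]
    if (is.na(b0)) next  # p_j = 0: nothing to delete at this occasion
    p <- stats::plogis(b0 + spec$b1 * z)
    miss <- stats::rbinom(n, 1L, p) == 1L
    mask[miss, j] <- FALSE
  }
  if (spec$monotone) {
    # once missing, always missing: cumulative carry-forward per row
    for (j in 3L:J) mask[, j] <- mask[, j] & mask[, j - 1L]
  }
  vals <- data$values
  vals[!mask] <- NA_real_
  longitudinal_dataset(vals, mask, data$grid)
}

#' Write / read wide-format longitudinal CSV
#'
#' The on-disk interchange format: a header row of time codes, one row per
#' subject, one column per occasion, empty cells for missing values.
#'
#' @param data A \code{\link{longitudinal_dataset}}.
#' @param path File path.
#' @return \code{write_longitudinal_csv} returns \code{path} invisibly;
#'   \code{read_longitudinal_csv} returns a
#'   \code{\link{longitudinal_dataset}}.
#' @export
write_longitudinal_csv <- function(data, path) {
  stopifnot(inherits(data, "longitudinal_dataset"))
  df <- as.data.frame(data$values)
  names(df) <- paste0("t", data$grid$codes)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @param time_codes Time codes for the columns; if \code{NULL} they are
#'   parsed from header names of the form \code{t<code>}.
#' @rdname write_longitudinal_csv
#' @export
read_longitudinal_csv <- function(path, time_codes = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", na.strings = "")
  m <- as.matrix(df)
  suppressWarnings(vals <- matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which(is.na(vals) & !is.na(m) & nzchar(trimws(m)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-numeric cells at row ", bad[1L, 1L], ", column ", bad[1L, 2L],
         call. = FALSE)
  }
  if (is.null(time_codes)) {
    time_codes <- suppressWarnings(as.numeric(sub("^t", "", colnames(df))))
    if (anyNA(time_codes)) {
      stop("cannot parse time codes from the header; pass time_codes",
           call. = FALSE)
    }
  }
  empty <- which(rowSums(!is.na(vals)) == 0L)
  if (length(empty) > 0L) {
    stop("subjects with zero observations at rows: ",
         paste(utils::head(empty, 10), collapse = ", "), call. = FALSE)
  }
  longitudinal_dataset(vals, !is.na(vals), time_grid(time_codes))
}
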