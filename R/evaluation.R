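#' Outcome measures for knot recovery
#'
#' Replication-level results are aggregated into the study's four outcome
#' measures. All measures except the convergence rate are computed over
#' converged replications only. \code{records} is a data frame with one
#' row per replication and columns \code{estimate} (posterior mean of the
#' knot), \code{ci_lower}, \code{ci_upper} (95\% credible bounds) and
#' \code{converged} (logical).
#'
#' \describe{
#'   \item{coverage_rate}{\eqn{\frac{1}{R_c}\sum_s 1\{\theta_\gamma \in
#'     [L_s, U_s]\}}, the fraction of converged replications whose 95\%
#'     credible interval contains the true knot.}
#'   \item{average_bias}{\eqn{\frac{1}{R_c}\sum_s (\hat\theta_{\gamma s} -
#'     \theta_\gamma)}.}
#'   \item{rmse}{\eqn{\sqrt{\frac{1}{R_c}\sum_s (\hat\theta_{\gamma s} -
#'     \theta_\gamma)^2}}.}
#'   \item{convergence_rate}{fraction of all replications flagged
#'     converged.}
#' }
#'
#' @param records Replication records (see Details).
#' @param truth True knot location \eqn{\theta_\gamma}; defaults to 3, the
#'   coded fourth occasion of the default population.
#' @return A single number. With zero converged replications the
#'   interval/bias/error measures return \code{NA_real_} (an
#'   undefined-result sentinel, not 0).
#' @name outcome_measures
NULL

check_records <- function(records) {
  need <- c("estimate", "ci_lower", "ci_upper", "converged")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("records lack columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) stop("need at least one record", call. = FALSE)
  ok <- records$converged & !is.na(records$ci_lower)
  if (any(records$ci_lower[ok] > records$ci_upper[ok])) {
    stop("ci_lower exceeds ci_upper in some records", call. = FALSE)
  }
  invisible(records)
}

#' @rdname outcome_measures
#' @export
coverage_rate <- function(records, truth = 3) {
  check_records(records)
  conv <- records[records$converged, , drop = FALSE]
  if (nrow(conv) == 0L) return(NA_real_)
  mean(truth >= conv$ci_lower & truth <= conv$ci_upper)
}

#' @rdname outcome_measures
#' @export
average_bias <- function(records, truth = 3) {
  check_records(records)
  conv <- records[records$converged, , drop = FALSE]
  if (nrow(conv) == 0L) return(NA_real_)
  mean(conv$estimate - truth)
}

#' @rdname outcome_measures
#' @export
rmse <- function(records, truth = 3) {
  check_records(records)
  conv <- records[records$converged, , drop = FALSE]
  if (nrow(conv) == 0L) return(NA_real_)
  sqrt(mean((conv$estimate - truth)^2))
}

#' @rdname outcome_measures
#' @export
convergence_rate <- function(records) {
  check_records(records)
  mean(records$converged)
}

#' Aggregate replication records into cell metrics
#'
#' @param records Replication records (see \link{outcome_measures}).
#' @param truth True knot location.
#' @return An object of class \code{cell_metrics}: convergence rate,
#'   coverage, average bias, RMSE, and the converged/total counts.
#' @export
cell_metrics <- function(records, truth = 3) {
  check_records(records)
  structure(list(convergence_rate = convergence_rate(records),
                 coverage = coverage_rate(records, truth),
                 avg_bias = average_bias(records, truth),
                 rmse = rmse(records, truth),
                 n_converged = sum(records$converged),
                 n_total = nrow(records)),
            class = "cell_metrics")
}

#' @export
print.cell_metrics <- function(x, ...) {
  cat(sprintf(paste0("<cell_metrics> %d/%d converged (%.3f); coverage ",
                     "%.3f, bias %+.3f, RMSE %.3f\n"),
              x$n_converged, x$n_total, x$convergence_rate, x$coverage,
              x$avg_bias, x$rmse))
  invisible(x)
}
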