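#' Measurement-occasion time grid
#'
#' Constructs the ordered vector of time codes \eqn{t_1, \dots, t_J} on
#' which a piecewise growth model is defined. A linear-linear piecewise
#' model with a free knot needs at least five occasions to be identified,
#' so shorter grids are rejected.
#'
#' @param codes Numeric vector of strictly increasing time codes. The
#'   default is the seven equidistant occasions \code{0:6} used throughout
#'   the simulation design, where the knot at the fourth occasion is coded
#'   as 3.
#' @return An object of class \code{time_grid}: a list with elements
#'   \code{codes} and \code{J}.
#' @examples
#' time_grid()            # 0,1,...,6
#' time_grid(c(0, 0.5, 1, 1.5, 3.5, 5.5, 8.5))
#' @export
time_grid <- function(codes = 0:6) {
  codes <- as.numeric(codes)
  if (anyNA(codes) || any(!is.finite(codes))) {
    stop("time codes must be finite numbers", call. = FALSE)
  }
  if (length(codes) < 5L) {
    stop("a linear-linear piecewise growth model needs at least 5 occasions",
         call. = FALSE)
  }
  if (any(diff(codes) <= 0)) {
    stop("time codes must be strictly increasing", call. = FALSE)
  }
  structure(list(codes = codes, J = length(codes)), class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat("<time_grid> J =", x$J, "occasions:", paste(x$codes, collapse = ", "),
      "\n")
  invisible(x)
}

is_default_grid <- function(grid) {
  grid$J == 7L && isTRUE(all.equal(grid$codes, as.numeric(0:6)))
}

#' Population parameters of a linear-linear piecewise growth model
#'
#' Bundles the growth-factor means \eqn{\alpha} (intercept, pre-knot slope,
#' post-knot slope), the 3x3 factor covariance \eqn{\Omega_\eta}, the
#' occasion-specific residual variances (the diagonal of \eqn{\Omega_y}),
#' and the knot location \eqn{\gamma} on the time-code scale.
#'
#' @param alpha Numeric length-3 vector of growth-factor means.
#' @param omega_eta Symmetric positive-semidefinite 3x3 factor covariance.
#' @param sigma2_eps Positive residual variances; either one value recycled
#'   to all occasions or a length-\code{J} vector.
#' @param gamma Knot location, strictly inside the time-grid range when the
#'   parameters describe a data-generating population.
#' @param grid A \code{\link{time_grid}}.
#' @return An object of class \code{pgm_parameters}.
#' @seealso \code{\link{default_population}} for the package's documented
#'   simulation defaults.
#' @export
pgm_parameters <- function(alpha, omega_eta, sigma2_eps, gamma,
                           grid = time_grid()) {
  stopifnot(inherits(grid, "time_grid"))
  alpha <- as.numeric(alpha)
  if (length(alpha) != 3L) stop("alpha must have length 3", call. = FALSE)
  omega_eta <- as.matrix(omega_eta)
  if (!isTRUE(all.equal(dim(omega_eta), c(3L, 3L))) ||
      !isTRUE(all.equal(omega_eta, t(omega_eta), tolerance = 1e-8))) {
    stop("omega_eta must be a symmetric 3x3 matrix", call. = FALSE)
  }
  ev <- eigen(omega_eta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("omega_eta must be positive semidefinite", call. = FALSE)
  }
  sigma2_eps <- as.numeric(sigma2_eps)
  if (length(sigma2_eps) == 1L) sigma2_eps <- rep(sigma2_eps, grid$J)
  if (length(sigma2_eps) != grid$J || any(sigma2_eps <= 0)) {
    stop("sigma2_eps must be ", grid$J, " positive variances", call. = FALSE)
  }
  gamma <- as.numeric(gamma)
  rng <- range(grid$codes)
  if (length(gamma) != 1L || gamma <= rng[1] || gamma >= rng[2]) {
    stop("gamma must lie strictly between min and max of the time codes",
         call. = FALSE)
  }
  structure(list(alpha = alpha, omega_eta = omega_eta,
                 sigma2_eps = sigma2_eps, gamma = gamma, grid = grid),
            class = "pgm_parameters")
}

#' @export
print.pgm_parameters <- function(x, ...) {
  cat("<pgm_parameters> linear-linear piecewise growth population\n")
  cat("  alpha      :", paste(signif(x$alpha, 4), collapse = ", "), "\n")
  cat("  gamma      :", x$gamma, "(knot, time-code scale)\n")
  cat("  omega_eta  : diag", paste(signif(diag(x$omega_eta), 4),
                                   collapse = ", "), "\n")
  cat("  sigma2_eps :", paste(signif(x$sigma2_eps, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Wide-format longitudinal dataset with missingness mask
#'
#' @param values n x J numeric matrix of outcomes; cells may hold anything
#'   where the mask is \code{FALSE} (they are ignored), but must be finite
#'   where observed.
#' @param mask Logical n x J matrix, \code{TRUE} = observed. Defaults to
#'   everything observed.
#' @param grid A \code{\link{time_grid}} with \code{J} occasions.
#' @return An object of class \code{longitudinal_dataset} with elements
#'   \code{values}, \code{mask}, \code{grid}, \code{n}.
#' @details Every subject must have at least one observed occasion;
#'   datasets produced by the MAR generator additionally keep the first
#'   occasion fully observed because dropout is modeled from the second
#'   occasion onwards. An \code{n = 0} dataset is permitted (used by the
#'   no-data sampler path in which the posterior reduces to the prior).
#' @export
longitudinal_dataset <- function(values, mask = NULL, grid = time_grid()) {
  stopifnot(inherits(grid, "time_grid"))
  values <- as.matrix(values)
  if (ncol(values) != grid$J) {
    stop("values must have J = ", grid$J, " columns", call. = FALSE)
  }
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!identical(dim(mask), dim(values))) {
    stop("mask and values dimensions differ", call. = FALSE)
  }
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  if (any(mask & !is.finite(values))) {
    stop("observed cells must hold finite values", call. = FALSE)
  }
  n <- nrow(values)
  if (n > 0L && any(rowSums(mask) == 0L)) {
    bad <- which(rowSums(mask) == 0L)
    stop("subjects with zero observed occasions: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, grid = grid, n = n),
            class = "longitudinal_dataset")
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  pmiss <- if (x$n > 0) mean(!x$mask) else 0
  cat("<longitudinal_dataset> n =", x$n, "subjects, J =", x$grid$J,
      sprintf("occasions, %.1f%% missing overall\n", 100 * pmiss))
  invisible(x)
}

#' Knot-dependent factor loading matrix
#'
#' Builds the J x 3 loading matrix of a linear-linear piecewise growth
#' model, whose j-th row is \eqn{[1,\ \min(t_j, \gamma),\ \max(t_j -
#' \gamma, 0)]}: a constant intercept loading, a pre-knot slope loading
#' that saturates at the knot, and a post-knot slope loading that switches
#' on after the knot.
#'
#' @param grid A \code{\link{time_grid}}.
#' @param gamma Knot location; must lie in the closed range of the time
#'   codes (the boundary is permitted here because truncated knot priors
#'   place support up to the endpoints).
#' @return A numeric \code{J x 3} matrix.
#' @examples
#' build_loading_matrix(time_grid(), gamma = 3)
#' @export
build_loading_matrix <- function(grid, gamma) {
  stopifnot(inherits(grid, "time_grid"))
  gamma <- as.numeric(gamma)
  rng <- range(grid$codes)
  if (length(gamma) != 1L || !is.finite(gamma) ||
      gamma < rng[1] || gamma > rng[2]) {
    stop("gamma must lie within [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  }
  t <- grid$codes
  cbind(1, pmin(t, gamma), pmax(t - gamma, 0))
}

#' Model-implied mean vector and covariance matrix
#'
#' Under the common-factor form \eqn{y_i = \Lambda(\gamma)\eta_i +
#' \epsilon_i} with \eqn{\eta_i \sim N(\alpha, \Omega_\eta)} and
#' independent occasion-specific residuals, the marginal moments of
#' \eqn{y_i} are \eqn{\mu = \Lambda\alpha} and \eqn{\Sigma = \Lambda
#' \Omega_\eta \Lambda' + \mathrm{diag}(\sigma^2_\epsilon)}.
#'
#' @param params A \code{\link{pgm_parameters}} object.
#' @param grid Time grid; defaults to the grid stored in \code{params}.
#' @return List with \code{mean} (length J) and \code{cov} (J x J).
#' @export
implied_moments <- function(params, grid = params$grid) {
  stopifnot(inherits(params, "pgm_parameters"), inherits(grid, "time_grid"))
  L <- build_loading_matrix(grid, params$gamma)
  mu <- drop(L %*% params$alpha)
  S <- L %*% params$omega_eta %*% t(L) + diag(params$sigma2_eps, grid$J)
  S <- (S + t(S)) / 2
  list(mean = mu, cov = S)
}

#' Observed-data log-likelihood of a piecewise growth model
#'
#' Marginal multivariate-normal log-likelihood of the observed entries:
#' each subject contributes the log density of their observed subvector
#' under the implied moments restricted to the observed occasions. Used
#' for testing the sampler and for comparing parameter values; it plays no
#' role in the Gibbs updates themselves.
#'
#' @param data A \code{\link{longitudinal_dataset}}.
#' @param params A \code{\link{pgm_parameters}} on the same grid.
#' @return A single number, the summed log density.
#' @export
observed_data_loglik <- function(data, params) {
  stopifnot(inherits(data, "longitudinal_dataset"),
            inherits(params, "pgm_parameters"))
  if (data$grid$J != params$grid$J ||
      !isTRUE(all.equal(data$grid$codes, params$grid$codes))) {
    stop("data and params are on different time grids", call. = FALSE)
  }
  if (data$n == 0L) return(0)
  mom <- implied_moments(params, data$grid)
  # subjects sharing a missingness pattern share one Cholesky factor
  pat <- apply(data$mask, 1L, function(m) paste(as.integer(m), collapse = ""))
  total <- 0
  for (p in unique(pat)) {
    rows <- which(pat == p)
    obs <- data$mask[rows[1L], ]
    k <- sum(obs)
    S <- mom$cov[obs, obs, drop = FALSE]
    R <- chol(S)
    Y <- data$values[rows, obs, drop = FALSE]
    D <- sweep(Y, 2L, mom$mean[obs])
    Z <- t(backsolve(R, t(D), transpose = TRUE))
    q <- rowSums(Z^2)
    logdet <- 2 * sum(log(diag(R)))
    total <- total + sum(-0.5 * (k * log(2 * pi) + logdet + q))
  }
  total
}
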