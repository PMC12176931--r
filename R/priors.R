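#' Prior distribution for the knot location
#'
#' Either a uniform distribution over the study window or a normal
#' distribution truncated to it. The truncation bounds are always the
#' first and last time codes, so a knot draw can never leave the observed
#' time range.
#'
#' @param family \code{"uniform"} or \code{"truncated_normal"}.
#' @param lower,upper Truncation bounds (time-code units).
#' @param mu_gamma Center (truncated normal only).
#' @param sigma2_gamma Variance (> 0, truncated normal only).
#' @param name Optional preset label.
#' @return An object of class \code{knot_prior}.
#' @seealso \code{\link{knot_prior_preset}} for the seven named presets.
#' @export
knot_prior <- function(family = c("uniform", "truncated_normal"),
                       lower, upper, mu_gamma = NULL, sigma2_gamma = NULL,
                       name = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(lower), is.numeric(upper), upper > lower)
  if (family == "truncated_normal") {
    if (is.null(mu_gamma) || is.null(sigma2_gamma) || sigma2_gamma <= 0) {
      stop("truncated_normal needs mu_gamma and sigma2_gamma > 0",
           call. = FALSE)
    }
  } else {
    mu_gamma <- NA_real_
    sigma2_gamma <- NA_real_
  }
  structure(list(family = family, lower = lower, upper = upper,
                 mu_gamma = mu_gamma, sigma2_gamma = sigma2_gamma,
                 name = if (is.null(name)) family else name),
            class = "knot_prior")
}

#' @export
print.knot_prior <- function(x, ...) {
  if (x$family == "uniform") {
    cat(sprintf("<knot_prior> %s: gamma ~ U(%g, %g)\n", x$name, x$lower,
                x$upper))
  } else {
    cat(sprintf("<knot_prior> %s: gamma ~ N(%g, %g) T(%g, %g)\n", x$name,
                x$mu_gamma, x$sigma2_gamma, x$lower, x$upper))
  }
  invisible(x)
}

#' The seven knot-prior presets
#'
#' Named prior regimes for the knot location, spanning a diffuse uniform
#' (DIF) and truncated normals that cross informativeness (informative
#' \code{I-} vs weakly informative \code{WI-}, the latter with 5x the
#' variance) with placement (at the presumed true knot \code{ATK}, before
#' it \code{PRK}, after it \code{PSK}).
#'
#' On the default 0..6 grid the presets are exactly: DIF = U(0, 6);
#' I-ATK = N(3, 0.146) T(0, 6); WI-ATK = N(3, 0.730) T(0, 6);
#' I-PRK = N(1.5, 0.146); WI-PRK = N(1.5, 0.730); I-PSK = N(4.5, 0.146);
#' WI-PSK = N(4.5, 0.730), all truncated to (0, 6).
#'
#' On any other grid the hyperparameters are rescaled: the ATK center is
#' the grid midpoint, the PRK/PSK centers are the midpoints between an
#' endpoint and the ATK center, the informative variance solves the 10\%
#' overlap condition \eqn{2\Phi(-d/(2\sigma)) = 0.10} between adjacent
#' informative priors (spacing \eqn{d} = a quarter of the grid range), and
#' the weakly informative variance is 5x the informative one. On the
#' 0..8.5 grid this yields N(4.25, 0.417), N(2.125, 0.417),
#' N(6.375, 0.417) and the 2.085 weakly informative variants.
#'
#' @param name One of \code{"DIF"}, \code{"I-ATK"}, \code{"WI-ATK"},
#'   \code{"I-PRK"}, \code{"WI-PRK"}, \code{"I-PSK"}, \code{"WI-PSK"}.
#' @param grid A \code{\link{time_grid}}.
#' @return A \code{\link{knot_prior}}.
#' @examples
#' knot_prior_preset("I-ATK")
#' knot_prior_preset("WI-ATK", time_grid(c(0, 0.5, 1, 1.5, 3.5, 5.5, 8.5)))
#' @export
knot_prior_preset <- function(name, grid = time_grid()) {
  stopifnot(inherits(grid, "time_grid"))
  presets <- c("DIF", "I-ATK", "WI-ATK", "I-PRK", "WI-PRK", "I-PSK",
               "WI-PSK")
  if (!name %in% presets) {
    stop("unknown preset '", name, "'; choose one of: ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  lo <- min(grid$codes)
  hi <- max(grid$codes)
  if (name == "DIF") {
    return(knot_prior("uniform", lo, hi, name = "DIF"))
  }
  mid <- (lo + hi) / 2
  centers <- c(ATK = mid, PRK = (lo + mid) / 2, PSK = (mid + hi) / 2)
  if (is_default_grid(grid)) {
    # the printed simulation hyperparameters, used verbatim
    v_inf <- 0.146
  } else {
    # 10% overlap between adjacent informative priors at spacing range/4
    d <- (hi - lo) / 4
    sigma <- d / (2 * stats::qnorm(0.95))
    v_inf <- round(sigma^2, 3)
  }
  weak <- startsWith(name, "WI")
  v <- if (weak) 5 * v_inf else v_inf
  loc <- sub("^(WI|I)-", "", name)
  knot_prior("truncated_normal", lo, hi, mu_gamma = centers[[loc]],
             sigma2_gamma = v, name = name)
}

#' Log prior density of a knot location
#'
#' Uniform: \code{log(1/(upper - lower))} on the support. Truncated
#' normal: the normal log density minus the log normal mass on
#' \code{(lower, upper)}. Outside the support the value is \code{-Inf}
#' (a value, not an error).
#'
#' @param spec A \code{\link{knot_prior}}.
#' @param gamma Knot location(s); vectorized.
#' @return Log density, same length as \code{gamma}.
#' @export
knot_log_density <- function(spec, gamma) {
  stopifnot(inherits(spec, "knot_prior"))
  gamma <- as.numeric(gamma)
  out <- rep(-Inf, length(gamma))
  inside <- gamma > spec$lower & gamma < spec$upper
  if (spec$family == "uniform") {
    out[inside] <- -log(spec$upper - spec$lower)
  } else {
    s <- sqrt(spec$sigma2_gamma)
    lmass <- log(stats::pnorm(spec$upper, spec$mu_gamma, s) -
                   stats::pnorm(spec$lower, spec$mu_gamma, s))
    out[inside] <- stats::dnorm(gamma[inside], spec$mu_gamma, s,
                                log = TRUE) - lmass
  }
  out
}

# quantile of the knot prior; used to disperse chain starting values
knot_prior_quantile <- function(spec, p) {
  if (spec$family == "uniform") {
    spec$lower + p * (spec$upper - spec$lower)
  } else {
    s <- sqrt(spec$sigma2_gamma)
    plo <- stats::pnorm(spec$lower, spec$mu_gamma, s)
    phi <- stats::pnorm(spec$upper, spec$mu_gamma, s)
    stats::qnorm(plo + p * (phi - plo), spec$mu_gamma, s)
  }
}

#' Full prior specification of a piecewise growth model
#'
#' The nuisance-parameter priors with their printed diffuse defaults —
#' growth-factor means \eqn{\alpha_m \sim N(0, 10^6)}, factor covariance
#' \eqn{\Omega_\eta \sim IW(I_{3\times 3}, 3)}, residual variances
#' \eqn{\sigma^2_{\epsilon j} \sim IG(0.001, 0.001)} — together with a
#' knot prior.
#'
#' The inverse gamma is parameterized with density proportional to
#' \eqn{x^{-a-1} e^{-b/x}} and the inverse Wishart with density
#' proportional to \eqn{|\Omega|^{-(\nu+p+1)/2}
#' e^{-\mathrm{tr}(\Psi\Omega^{-1})/2}}, the JAGS conventions.
#'
#' @param knot A \code{\link{knot_prior}} (default: the DIF preset on the
#'   default grid).
#' @param mu_alpha Mean hyperparameter for the growth-factor means.
#' @param sigma2_alpha Variance hyperparameter (> 0).
#' @param Psi Inverse-Wishart scale matrix (3x3 positive definite).
#' @param nu Inverse-Wishart degrees of freedom (>= 3).
#' @param a,b Inverse-gamma shape and scale (> 0).
#' @return An object of class \code{model_priors}.
#' @export
model_priors <- function(knot = knot_prior_preset("DIF"),
                         mu_alpha = 0, sigma2_alpha = 1e6,
                         Psi = diag(3), nu = 3, a = 0.001, b = 0.001) {
  stopifnot(inherits(knot, "knot_prior"))
  Psi <- as.matrix(Psi)
  if (!isTRUE(all.equal(dim(Psi), c(3L, 3L))) ||
      min(eigen(Psi, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("Psi must be 3x3 positive definite", call. = FALSE)
  }
  if (nu < 3) stop("nu must be >= 3 (the dimension of Psi)", call. = FALSE)
  if (a <= 0 || b <= 0) stop("a and b must be > 0", call. = FALSE)
  if (sigma2_alpha <= 0) stop("sigma2_alpha must be > 0", call. = FALSE)
  structure(list(knot = knot, mu_alpha = mu_alpha,
                 sigma2_alpha = sigma2_alpha, Psi = Psi, nu = nu,
                 a = a, b = b),
            class = "model_priors")
}

#' @rdname model_priors
#' @export
default_nuisance_priors <- function(knot = knot_prior_preset("DIF")) {
  model_priors(knot = knot)
}

#' @export
print.model_priors <- function(x, ...) {
  cat("<model_priors>\n")
  cat(sprintf("  alpha     ~ N(%g, %g)\n", x$mu_alpha, x$sigma2_alpha))
  cat(sprintf("  omega_eta ~ IW(Psi, nu = %g)\n", x$nu))
  cat(sprintf("  sigma2    ~ IG(%g, %g)\n", x$a, x$b))
  cat("  knot      : ")
  print(x$knot)
  invisible(x)
}
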