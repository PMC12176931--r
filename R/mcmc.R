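#' @useDynLib pgmknot, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' MCMC configuration
#'
#' @param n_chains Number of chains (>= 2 so that R-hat is defined).
#' @param n_iter Post-burn-in iterations per chain.
#' @param burn_in Discarded initial iterations per chain.
#' @param thin Keep every \code{thin}-th post-burn-in draw.
#' @param seed Optional integer seed; chains are run sequentially from one
#'   RNG stream, so a fixed seed makes the whole fit reproducible.
#' @param rhat_threshold Convergence cutoff; a fit is flagged converged
#'   when every monitored R-hat is strictly below it.
#' @param knot_proposal_sd Initial SD of the Gaussian random-walk proposal
#'   for the knot.
#' @param adapt Adapt the proposal SD during burn-in (targeting 25--45\%
#'   acceptance, frozen afterwards so the post-burn-in kernel is a valid
#'   fixed Metropolis kernel).
#' @param rhat_method \code{"rank"} (split-chain, rank-normalized, folded)
#'   or \code{"classic"} Gelman--Rubin.
#' @return An object of class \code{mcmc_config}.
#' @details \code{mcmc_config()} defaults to the full-scale protocol
#'   (4 chains x 25,000 post-burn-in after 5,000 burn-in, thinned by 10).
#'   \code{mcmc_config_reduced()} is the desk-scale preset used by the
#'   packaged simulation study (2 chains x 4,000 after 1,000 burn-in,
#'   unthinned); \code{mcmc_config_illustrative()} mirrors the
#'   single-dataset protocol (4 chains x 50,000 after 50,000, unthinned).
#' @export
mcmc_config <- function(n_chains = 4L, n_iter = 25000L, burn_in = 5000L,
                        thin = 10L, seed = NULL, rhat_threshold = 1.1,
                        knot_proposal_sd = 0.2, adapt = TRUE,
                        rhat_method = c("rank", "classic")) {
  rhat_method <- match.arg(rhat_method)
  if (n_chains < 2L) stop("need at least 2 chains for R-hat", call. = FALSE)
  if (thin < 1L) stop("thin must be >= 1", call. = FALSE)
  if (burn_in < 0L) stop("burn_in must be >= 0", call. = FALSE)
  if (n_iter < thin) stop("n_iter must be >= thin", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed, rhat_threshold = rhat_threshold,
                 knot_proposal_sd = knot_proposal_sd, adapt = adapt,
                 rhat_method = rhat_method),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @param ... Overrides passed on to \code{mcmc_config}.
#' @export
mcmc_config_reduced <- function(...) {
  args <- list(n_chains = 2L, n_iter = 4000L, burn_in = 1000L, thin = 1L)
  do.call(mcmc_config, utils::modifyList(args, list(...)))
}

#' @rdname mcmc_config
#' @export
mcmc_config_illustrative <- function(...) {
  args <- list(n_chains = 4L, n_iter = 50000L, burn_in = 50000L, thin = 1L)
  do.call(mcmc_config, utils::modifyList(args, list(...)))
}

param_names <- function(J) {
  c(paste0("alpha[", 1:3, "]"),
    "omega[1,1]", "omega[2,1]", "omega[3,1]", "omega[2,2]", "omega[3,2]",
    "omega[3,3]",
    paste0("sigma2[", seq_len(J), "]"),
    "gamma")
}

# dispersed starting values for one chain, drawn from the current RNG
chain_inits <- function(data, priors, grid) {
  gamma0 <- knot_prior_quantile(priors$knot,
                                stats::runif(1, 0.1, 0.9))
  J <- grid$J
  if (data$n == 0L) {
    return(list(alpha = stats::rnorm(3, priors$mu_alpha, 1),
                omega = diag(3), sigma2 = rep(1, J), gamma = gamma0))
  }
  cmeans <- vapply(seq_len(J), function(j) {
    mean(data$values[data$mask[, j], j])
  }, numeric(1))
  cvars <- vapply(seq_len(J), function(j) {
    v <- stats::var(data$values[data$mask[, j], j])
    if (!is.finite(v) || v < 1e-3) 1e-3 else v
  }, numeric(1))
  L0 <- build_loading_matrix(grid, gamma0)
  alpha0 <- tryCatch(qr.solve(L0, cmeans), error = function(e) c(cmeans[1], 0, 0))
  alpha0 <- alpha0 + stats::rnorm(3, 0, 0.1 * pmax(abs(alpha0), 1))
  jit <- exp(stats::runif(2, -0.4, 0.4))
  list(alpha = alpha0,
       omega = diag(c(max(0.5 * cvars[1], 0.5), 0.5, 0.5)) * jit[1],
       sigma2 = pmax(0.5 * cvars, 1e-2) * jit[2],
       gamma = gamma0)
}

#' Fit a Bayesian piecewise growth model by MCMC
#'
#' Runs a Gibbs sampler with, per iteration: (1) data augmentation of the
#' missing outcomes from their normal full conditionals, (2) the
#' multivariate-normal full conditional of each subject's growth factors,
#' (3) the normal full conditional of the growth-factor means, (4) the
#' inverse-Wishart full conditional of the factor covariance, (5) the
#' inverse-gamma full conditionals of the occasion residual variances, and
#' (6) a random-walk Metropolis update of the knot location using the
#' complete-data likelihood times the knot prior (proposals outside the
#' truncated support are rejected).
#'
#' @param data A \code{\link{longitudinal_dataset}}. Subjects must have at
#'   least one observed occasion; an \code{n = 0} dataset is allowed, in
#'   which case the posterior reproduces the prior (a testing path).
#' @param priors A \code{\link{model_priors}} object.
#' @param config An \code{\link{mcmc_config}}.
#' @return An object of class \code{pgm_fit} with per-chain thinned draws,
#'   a pooled summary table, per-parameter R-hat, a convergence flag and
#'   the knot Metropolis acceptance fraction.
#' @examples
#' \donttest{
#' pop <- default_population()
#' d <- generate_complete(pop, n = 50, seed = 1)
#' pr <- default_nuisance_priors(knot_prior_preset("I-ATK"))
#' fit <- fit_pgm(d, pr, mcmc_config_reduced(n_iter = 1000, seed = 1))
#' summary(fit)
#' }
#' @export
fit_pgm <- function(data, priors = default_nuisance_priors(),
                    config = mcmc_config()) {
  stopifnot(inherits(data, "longitudinal_dataset"),
            inherits(priors, "model_priors"),
            inherits(config, "mcmc_config"))
  grid <- data$grid
  rng <- range(grid$codes)
  if (priors$knot$lower > rng[1] || priors$knot$upper < rng[2]) {
    warning("knot prior support is narrower than the time grid")
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  J <- grid$J
  obs <- matrix(0L, max(data$n, 0L), J)
  obs[data$mask] <- 1L
  Y <- data$values
  Y[!data$mask] <- 0
  fam <- if (priors$knot$family == "uniform") 0L else 1L
  kmu <- if (fam == 1L) priors$knot$mu_gamma else 0
  ks2 <- if (fam == 1L) priors$knot$sigma2_gamma else 1

  chains <- vector("list", config$n_chains)
  acc <- numeric(config$n_chains)
  for (c in seq_len(config$n_chains)) {
    ini <- chain_inits(data, priors, grid)
    res <- cpp_gibbs_chain(Y, obs, grid$codes, ini$alpha, ini$omega,
                           ini$sigma2, ini$gamma, fam, priors$knot$lower,
                           priors$knot$upper, kmu, ks2, priors$mu_alpha,
                           priors$sigma2_alpha, priors$Psi, priors$nu,
                           priors$a, priors$b, config$n_iter,
                           config$burn_in, config$thin,
                           config$knot_proposal_sd, config$adapt)
    colnames(res$draws) <- param_names(J)
    chains[[c]] <- res$draws
    acc[c] <- res$acceptance
  }

  pooled <- do.call(rbind, chains)
  rhat <- vapply(colnames(pooled), function(pn) {
    m <- vapply(chains, function(ch) ch[, pn], numeric(nrow(chains[[1]])))
    suppressWarnings(compute_rhat(m, method = config$rhat_method))
  }, numeric(1))
  summaries <- data.frame(
    parameter = colnames(pooled),
    mean = colMeans(pooled),
    median = apply(pooled, 2L, stats::median),
    sd = apply(pooled, 2L, stats::sd),
    ci_lower = apply(pooled, 2L, stats::quantile, probs = 0.025,
                     names = FALSE),
    ci_upper = apply(pooled, 2L, stats::quantile, probs = 0.975,
                     names = FALSE),
    rhat = unname(rhat),
    row.names = NULL
  )
  structure(list(chains = chains, summaries = summaries, rhat = rhat,
                 converged = all(rhat < config$rhat_threshold),
                 knot_acceptance = mean(acc), config = config,
                 priors = priors, n = data$n, grid = grid),
            class = "pgm_fit")
}

#' @export
print.pgm_fit <- function(x, ...) {
  cat("<pgm_fit>", x$config$n_chains, "chains x",
      nrow(x$chains[[1]]), "retained draws, n =", x$n, "subjects\n")
  g <- x$summaries[x$summaries$parameter == "gamma", ]
  cat(sprintf("  knot: mean %.3f, 95%% CI [%.3f, %.3f], R-hat %.3f\n",
              g$mean, g$ci_lower, g$ci_upper, g$rhat))
  cat(sprintf("  converged: %s (max R-hat %.3f < %.2f), knot acceptance %.2f\n",
              x$converged, max(x$rhat), x$config$rhat_threshold,
              x$knot_acceptance))
  invisible(x)
}

#' Posterior summary table
#'
#' Per-parameter posterior mean, median, SD and equal-tailed 95\% credible
#' interval (2.5th and 97.5th percentiles) over the pooled post-burn-in
#' thinned draws, plus R-hat.
#'
#' @param object A \code{\link{fit_pgm}} result.
#' @param ... Unused.
#' @return A data frame, one row per monitored parameter.
#' @export
summary.pgm_fit <- function(object, ...) {
  object$summaries
}

#' Tidy export of posterior draws
#'
#' @param x A \code{pgm_fit}.
#' @param ... Unused.
#' @return Long data frame with columns \code{chain}, \code{iteration},
#'   \code{parameter}, \code{value}.
#' @export
as.data.frame.pgm_fit <- function(x, ...) {
  out <- lapply(seq_along(x$chains), function(c) {
    ch <- x$chains[[c]]
    data.frame(chain = c,
               iteration = rep(seq_len(nrow(ch)), times = ncol(ch)),
               parameter = rep(colnames(ch), each = nrow(ch)),
               value = as.vector(ch))
  })
  do.call(rbind, out)
}

#' Potential scale reduction factor (R-hat)
#'
#' Split-chain R-hat: each chain is halved, and the between- to
#' within-chain variance ratio is computed on the split chains. The
#' default \code{"rank"} method rank-normalizes the pooled draws first and
#' takes the maximum of the bulk statistic and the same statistic on
#' folded draws (absolute deviations from the median), which is sensitive
#' to both location and scale differences between chains. The
#' \code{"classic"} method is the plain Gelman--Rubin statistic on the
#' split chains.
#'
#' @param draws Matrix of draws, iterations x chains (or a list of
#'   equal-length numeric vectors, one per chain).
#' @param method \code{"rank"} or \code{"classic"}.
#' @return R-hat; approximately 1 at convergence. If the draws have zero
#'   total variance, 1 is returned by convention with a warning.
#' @export
compute_rhat <- function(draws, method = c("rank", "classic")) {
  method <- match.arg(method)
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) stop("need at least 2 chains", call. = FALSE)
  if (nrow(draws) < 4L) stop("need at least 4 draws per chain",
                             call. = FALSE)
  if (stats::var(as.vector(draws)) == 0) {
    warning("zero total variance; R-hat set to 1 by convention")
    return(1)
  }
  half <- floor(nrow(draws) / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[half + seq_len(half), , drop = FALSE])
  if (method == "classic") return(gelman_rubin(split))
  bulk <- gelman_rubin(rank_normalize(split))
  folded <- gelman_rubin(rank_normalize(abs(split - stats::median(split))))
  max(bulk, folded)
}

rank_normalize <- function(m) {
  z <- stats::qnorm((rank(as.vector(m)) - 3 / 8) / (length(m) + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

gelman_rubin <- function(m) {
  n <- nrow(m)
  W <- mean(apply(m, 2L, stats::var))
  B <- n * stats::var(colMeans(m))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence check against an R-hat threshold
#'
#' @param result A \code{pgm_fit}.
#' @param threshold Cutoff; the fit converged iff every monitored
#'   parameter's R-hat is strictly below it.
#' @return Logical flag.
#' @export
check_convergence <- function(result, threshold = 1.1) {
  stopifnot(inherits(result, "pgm_fit"))
  all(result$rhat < threshold)
}
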