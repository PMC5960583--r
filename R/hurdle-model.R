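## Bayesian hierarchical hurdle-exponential model for per-netting-wall
## revenue (Euros) or discard biomass (kg).
##
## Occurrence: w_i ~ Bernoulli(p[type_i]) with w fully observed, so p has an
## exact conjugate Beta(1 + sum w, 1 + sum(1 - w)) conditional.
## Positive part: x_i | w_i = 1 ~ Exponential with mean
##   m_i = mu[type_i] + b_boat[boat_i] + b_net[net_i],
## boat and net deviations normal with zero mean and unknown scales.

#' Assemble a hurdle dataset
#'
#' Bundles the per-wall response with the gear type and the boat/net
#' hierarchy, checking the hurdle invariant (`w = 1` iff `x > 0`) and that
#' every net belongs to exactly one boat.
#'
#' @param x nonnegative per-wall response (Euros or kg).
#' @param type gear type per wall (character or factor).
#' @param boat,net boat and net identifiers per wall.
#' @param wall_id optional wall identifiers.
#' @return a data frame of class `hurdle_data` with columns `x`, `w`,
#'   `type`, `boat`, `net`.
#' @export
hurdle_data <- function(x, type, boat, net, wall_id = NULL) {
  n <- length(x)
  if (n == 0L) stopf("empty hurdle dataset")
  if (length(type) != n || length(boat) != n || length(net) != n)
    stopf("x, type, boat and net must have equal length")
  if (any(!is.finite(x)) || any(x < 0)) stopf("x must be nonnegative")
  net_boat <- unique(data.frame(net = as.character(net),
                                boat = as.character(boat)))
  if (anyDuplicated(net_boat$net))
    stopf("net '%s' maps to more than one boat",
          net_boat$net[duplicated(net_boat$net)][1])
  out <- data.frame(x = as.numeric(x), w = as.integer(x > 0),
                    type = factor(as.character(type)),
                    boat = factor(as.character(boat)),
                    net = factor(as.character(net)),
                    stringsAsFactors = FALSE)
  if (!is.null(wall_id)) out$wall_id <- wall_id
  class(out) <- c("hurdle_data", "data.frame")
  out
}

#' Hurdle-exponential log-likelihood
#'
#' Sum over walls of the Bernoulli log-probability of the occurrence
#' indicator plus, for occupied walls, the exponential log-density of the
#' positive amount with mean `mu[type] + b_boat + b_net`.  Returns `-Inf`
#' when any occupied wall has a nonpositive mean (the sampler uses this to
#' reject such proposals).
#'
#' @param params list with elements `p` and `mu` (named by gear type),
#'   `b_boat`, `b_net` (named by boat/net; missing names default to 0) and
#'   optionally `sigma_boat`, `sigma_net` (unused by the likelihood).
#' @param data a [hurdle_data()] object.
#' @return the log-likelihood (possibly `-Inf`).
#' @export
hurdle_loglik <- function(params, data) {
  p <- params$p[as.character(data$type)]
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stopf("params$p must supply a probability for every gear type")
  ll <- sum(stats::dbinom(data$w, 1, p, log = TRUE))
  pos <- data$w == 1L
  if (any(pos)) {
    b_boat <- params$b_boat %||% numeric(0)
    b_net <- params$b_net %||% numeric(0)
    bb <- ifelse(as.character(data$boat[pos]) %in% names(b_boat),
                 b_boat[as.character(data$boat[pos])], 0)
    bn <- ifelse(as.character(data$net[pos]) %in% names(b_net),
                 b_net[as.character(data$net[pos])], 0)
    m <- params$mu[as.character(data$type[pos])] + bb + bn
    if (anyNA(m)) stopf("params$mu must supply a mean for every gear type")
    if (any(m <= 0)) return(-Inf)
    ll <- ll + sum(stats::dexp(data$x[pos], rate = 1 / m, log = TRUE))
  }
  ll
}

#' Sampler settings for the hurdle model
#'
#' The `"paper"` profile mirrors the survey protocol (3 chains, 10,000
#' burn-in, thinning 1/10, 30,000 retained in total); the `"fast"` profile
#' (3 chains, 1,000 burn-in, thinning 1/5, 3,000 retained) is intended for
#' tests and exploratory runs.
#'
#' @param profile `"paper"` or `"fast"`; sets the chain protocol defaults.
#' @param chains number of chains (at least 2 for diagnostics).
#' @param burn_in burn-in iterations per chain.
#' @param thin thinning interval.
#' @param retained total retained draws across chains.
#' @param mu_upper upper bound of the uniform prior on the gear-type means;
#'   default 100 times the mean positive response.
#' @param sigma_upper upper bound of the uniform priors on the random-effect
#'   scales; default 10 times the SD of the positive response.
#' @param fix_sigma_boat,fix_sigma_net set to a value (usually 0) to fix a
#'   random-effect scale instead of sampling it.
#' @return a list of class `hurdle_control`.
#' @export
hurdle_control <- function(profile = c("paper", "fast"), chains = 3,
                           burn_in = NULL, thin = NULL, retained = NULL,
                           mu_upper = NULL, sigma_upper = NULL,
                           fix_sigma_boat = NULL, fix_sigma_net = NULL) {
  profile <- match.arg(profile)
  def <- if (profile == "paper") list(burn_in = 10000, thin = 10,
                                      retained = 30000)
         else list(burn_in = 1000, thin = 5, retained = 3000)
  ctl <- list(profile = profile, chains = chains,
              burn_in = burn_in %||% def$burn_in, thin = thin %||% def$thin,
              retained = retained %||% def$retained, mu_upper = mu_upper,
              sigma_upper = sigma_upper, fix_sigma_boat = fix_sigma_boat,
              fix_sigma_net = fix_sigma_net)
  if (ctl$chains < 1 || ctl$retained %% ctl$chains != 0)
    stopf("retained draws must divide evenly across chains")
  class(ctl) <- "hurdle_control"
  ctl
}

#' Fit the hierarchical hurdle model
#'
#' Occurrence probabilities are drawn exactly from their conjugate Beta
#' conditional (flat Beta(1,1) prior; the indicators are observed data).
#' Gear-type means, boat/net deviations and their scales are updated by
#' Gaussian random-walk Metropolis within Gibbs, with step sizes adapted
#' during burn-in only.  Priors: `mu ~ U(0, mu_upper)`,
#' `b ~ N(0, sigma^2)`, `sigma ~ U(0, sigma_upper)`; proposals driving the
#' mean of any occupied wall nonpositive are rejected.
#'
#' @param data a [hurdle_data()] object.
#' @param control a [hurdle_control()] object.
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @return an object of class `hurdle_fit` holding a draws array
#'   (`draw` x `parameter` x `chain`) plus the sampler settings.
#' @export
fit_hurdle <- function(data, control = hurdle_control(), seed = 1L) {
  stopifnot(inherits(data, "hurdle_data"))
  types <- levels(data$type)
  boats <- levels(data$boat)
  nets <- levels(data$net)
  pos <- data$w == 1L
  xpos <- data$x[pos]

  if (length(xpos) > 0L) {
    mu_upper <- control$mu_upper %||% (100 * mean(xpos))
    sd_pos <- if (length(xpos) > 1L) stats::sd(xpos) else mean(xpos)
    sigma_upper <- control$sigma_upper %||% (10 * sd_pos)
  } else {
    warnf("no positive observations: gear-type means returned as prior draws")
    mu_upper <- control$mu_upper %||% 100
    sigma_upper <- control$sigma_upper %||% 10
  }

  n_keep <- control$retained %/% control$chains
  par_names <- c(paste0("p[", types, "]"), paste0("mu[", types, "]"),
                 paste0("b_boat[", boats, "]"), paste0("b_net[", nets, "]"),
                 "sigma_boat", "sigma_net")
  draws <- array(NA_real_,
                 dim = c(n_keep, length(par_names), control$chains),
                 dimnames = list(NULL, par_names, paste0("chain", seq_len(control$chains))))

  succ <- tapply(data$w, data$type, sum)
  fail <- tapply(1L - data$w, data$type, sum)
  pos_by_type <- tapply(pos, data$type, sum)
  empty_types <- names(pos_by_type)[pos_by_type == 0]
  if (length(empty_types) > 0L && length(xpos) > 0L)
    warnf("gear type(s) %s have no positive walls; their means are prior draws",
          paste(sQuote(empty_types), collapse = ", "))

  ## initial values from the positive-part data
  mu_init <- vapply(types, function(t) {
    xt <- data$x[pos & data$type == t]
    if (length(xt) > 0) mean(xt) else mu_upper / 2
  }, numeric(1))
  sigma_init <- pmin(pmax(0.1 * mean(mu_init), 1e-3), 0.9 * sigma_upper)
  step_mu <- pmax(0.3 * mu_init, 1e-3)

  fsb <- control$fix_sigma_boat
  fsn <- control$fix_sigma_net

  for (ch in seq_len(control$chains)) {
    set.seed(seed + ch - 1L)
    core <- run_hurdle_chain(
      x = xpos,
      type = as.integer(data$type[pos]) - 1L,
      boat = as.integer(data$boat[pos]) - 1L,
      net = as.integer(data$net[pos]) - 1L,
      n_type = length(types), n_boat = length(boats), n_net = length(nets),
      mu0 = mu_init * stats::runif(length(types), 0.5, 1.5),
      b_boat0 = rep(0, length(boats)), b_net0 = rep(0, length(nets)),
      sigma_boat0 = fsb %||% sigma_init, sigma_net0 = fsn %||% sigma_init,
      mu_upper = mu_upper, sigma_boat_upper = sigma_upper,
      sigma_net_upper = sigma_upper,
      update_sigma_boat = is.null(fsb), update_sigma_net = is.null(fsn),
      step = c(step_mu, rep(pmax(0.2 * mean(mu_init), 1e-3),
                            length(boats) + length(nets)),
               rep(pmax(0.1 * sigma_init, 1e-3), 2)),
      burn = control$burn_in, thin = control$thin, n_keep = n_keep)
    for (ti in seq_along(types)) {
      draws[, ti, ch] <- stats::rbeta(n_keep, 1 + succ[[types[ti]]],
                                      1 + fail[[types[ti]]])
      if (types[ti] %in% empty_types)
        core[, ti] <- stats::runif(n_keep, 0, mu_upper)
    }
    draws[, -seq_along(types), ch] <- core
  }

  structure(list(draws = draws, types = types, boats = boats, nets = nets,
                 control = control, seed = seed, n_walls = nrow(data),
                 mu_upper = mu_upper, sigma_upper = sigma_upper),
            class = "hurdle_fit")
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat("Hierarchical hurdle-exponential fit\n")
  cat(sprintf("  walls: %d   gear types: %s\n", x$n_walls,
              paste(x$types, collapse = ", ")))
  cat(sprintf("  chains: %d   retained: %d   burn-in: %d   thin: %d\n",
              dim(x$draws)[3], dim(x$draws)[1] * dim(x$draws)[3],
              x$control$burn_in, x$control$thin))
  invisible(x)
}

#' Extract pooled draws of one parameter
#'
#' @param fit a `hurdle_fit`.
#' @param parameter parameter name, e.g. `"p[PMF]"` or `"mu[MMF]"`.
#' @return numeric vector of draws pooled across chains.
#' @export
posterior_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "hurdle_fit"))
  if (!parameter %in% dimnames(fit$draws)[[2]])
    stopf("unknown parameter '%s'", parameter)
  as.numeric(fit$draws[, parameter, ])
}

#' Posterior summary table
#'
#' Mean, SD, central 95% credibility interval and the Gelman-Rubin
#' statistic for every parameter.  Parameters held constant (e.g. a scale
#' fixed at zero) get an `NA` diagnostic.
#'
#' @param object a `hurdle_fit`.
#' @param ... unused.
#' @return data frame with one row per parameter.
#' @export
summary.hurdle_fit <- function(object, ...) {
  pars <- dimnames(object$draws)[[2]]
  rows <- lapply(pars, function(p) {
    mat <- object$draws[, p, , drop = TRUE]
    if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
    v <- as.numeric(mat)
    rhat <- if (stats::var(v) == 0 || ncol(mat) < 2) NA_real_ else
      gelman_rubin(mat)
    ci <- central_interval(v)
    data.frame(parameter = p, mean = mean(v), sd = stats::sd(v),
               cri_low = ci[1], cri_high = ci[2], rhat = rhat,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Long-format posterior draws
#'
#' @param x a `hurdle_fit`.
#' @param ... unused.
#' @return data frame with columns `chain`, `draw`, `parameter`, `value`,
#'   suitable for delimited export.
#' @export
as.data.frame.hurdle_fit <- function(x, ...) {
  d <- dim(x$draws)
  data.frame(chain = rep(seq_len(d[3]), each = d[1] * d[2]),
             draw = rep(rep(seq_len(d[1]), times = d[2]), times = d[3]),
             parameter = rep(rep(dimnames(x$draws)[[2]], each = d[1]),
                             times = d[3]),
             value = as.numeric(x$draws), stringsAsFactors = FALSE)
}

#' Gelman-Rubin potential scale reduction
#'
#' `sqrt(((n - 1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B = n * var(chain means)`.  Values near 1 indicate
#' convergence; the conventional acceptance threshold used here is 1.1.
#'
#' @param chains a matrix (iterations x chains) or a list of equal-length
#'   numeric vectors, one per chain.
#' @return the statistic (NaN with a warning if the within-chain variance
#'   is zero).
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    if (length(unique(lengths(chains))) != 1L)
      stopf("chains must have equal length")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stopf("at least 2 chains are required")
  n <- nrow(chains)
  if (n < 2L) stopf("chains must contain at least 2 iterations")
  W <- mean(apply(chains, 2, stats::var))
  B <- n * stats::var(colMeans(chains))
  if (W == 0) {
    warnf("within-chain variance is zero; diagnostic undefined")
    return(NaN)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Expected catch value of an average net
#'
#' For each posterior draw, the expected per-net total is
#' `n_walls * p * mu`: the random effects integrate out at their zero
#' mean, so an average net of `n_walls` walls contributes `p * mu` per
#' wall.
#'
#' @param object a `hurdle_fit` or a numeric vector of occurrence draws.
#' @param ... passed to methods.
#' @return a list of class `net_expectation` with the draw-wise sequence,
#'   its mean and central 95% credibility interval.
#' @export
net_expectation <- function(object, ...) UseMethod("net_expectation")

#' @rdname net_expectation
#' @param type gear type to evaluate.
#' @param n_walls number of netting walls of the average net (default 22).
#' @export
net_expectation.hurdle_fit <- function(object, type, n_walls = 22, ...) {
  if (!type %in% object$types) stopf("unknown gear type '%s'", type)
  net_expectation(posterior_draws(object, paste0("p[", type, "]")),
                  mu = posterior_draws(object, paste0("mu[", type, "]")),
                  n_walls = n_walls)
}

#' @rdname net_expectation
#' @param mu positive-part mean draws paired with the occurrence draws.
#' @export
net_expectation.default <- function(object, mu, n_walls = 22, ...) {
  if (length(object) != length(mu))
    stopf("p and mu draw sequences must have equal length")
  draws <- n_walls * object * mu
  structure(list(draws = draws, mean = mean(draws),
                 cri = central_interval(draws), n_walls = n_walls),
            class = "net_expectation")
}

#' @export
print.net_expectation <- function(x, ...) {
  cat(sprintf("Expected total for an average net of %d walls: %.2f (95%% CrI %.2f-%.2f)\n",
              x$n_walls, x$mean, x$cri[1], x$cri[2]))
  invisible(x)
}

#' Credibility-interval relevance decision
#'
#' Computes the central 95% credibility interval of the draw-wise
#' difference `a - b` and labels the contrast `RELEVANT` when the reference
#' value 0 falls outside the interval, `NOT_RELEVANT` otherwise (the
#' Bayesian analogue of a significance call).
#'
#' @param samples_a posterior draws.
#' @param samples_b posterior draws paired with `samples_a`, or a single
#'   reference value.
#' @param quantity label for the contrast.
#' @param level credibility level (default 0.95).
#' @return a list of class `relevance` with `quantity`, `cri_low`,
#'   `cri_high`, `reference` and `label`.
#' @export
relevance <- function(samples_a, samples_b = 0, quantity = "difference",
                      level = 0.95) {
  if (length(samples_a) < 100L)
    stopf("at least 100 draws are required for a relevance decision")
  if (length(samples_b) > 1L && length(samples_b) != length(samples_a))
    stopf("paired draw sequences must have equal length")
  d <- samples_a - samples_b
  ci <- central_interval(d, level)
  label <- if (ci[1] <= 0 && 0 <= ci[2]) "NOT_RELEVANT" else "RELEVANT"
  structure(list(quantity = quantity, cri_low = ci[1], cri_high = ci[2],
                 reference = 0, label = label), class = "relevance")
}

#' @export
print.relevance <- function(x, ...) {
  cat(sprintf("%s: 95%% CrI [%.3f, %.3f] vs %g -> %s\n", x$quantity,
              x$cri_low, x$cri_high, x$reference, x$label))
  invisible(x)
}

#' Net-level log-biomass comparison
#'
#' One-way least-squares decomposition of log-transformed per-net totals by
#' fiber type (ordinary `lm`/ANOVA); used for the pooled net-level discard
#' comparison after removing mixed-material nets.
#'
#' @param net_log_totals log-transformed per-net values.
#' @param types gear label per net.
#' @return list of class `net_anova`: `ss_effect`, `ss_residual`, `df1`,
#'   `df2`, `statistic` (F) and `p_value`.
#' @export
compare_net_level <- function(net_log_totals, types) {
  g <- factor(as.character(types))
  if (nlevels(g) < 2L) stopf("at least 2 gear types are required")
  if (length(net_log_totals) - nlevels(g) < 1L)
    stopf("no residual degrees of freedom")
  fit <- stats::lm(net_log_totals ~ g)
  an <- stats::anova(fit)
  structure(list(ss_effect = an$`Sum Sq`[1], ss_residual = an$`Sum Sq`[2],
                 df1 = an$Df[1], df2 = an$Df[2], statistic = an$`F value`[1],
                 p_value = an$`Pr(>F)`[1]), class = "net_anova")
}

#' @export
print.net_anova <- function(x, ...) {
  cat(sprintf("Net-level comparison: df = %d,%d  SS = %.3f (effect), %.3f (residual)  F = %.3f  p = %.4g\n",
              x$df1, x$df2, x$ss_effect, x$ss_residual, x$statistic,
              x$p_value))
  invisible(x)
}
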