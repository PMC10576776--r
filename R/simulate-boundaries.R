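#' Parameters for the stochastic amplitude-threshold clock simulator
#'
#' The generative model behind variable segmentation phenotypes: each clock
#' cycle draws an oscillation amplitude \eqn{A_c = s \cdot e^{\mu + \sigma Z}}
#' (log-normal, \eqn{Z} standard normal), and the corresponding somite boundary
#' forms intact iff \eqn{A_c \ge \theta}. The environment acts multiplicatively
#' through `env_scale` (s < 1 models an unfavorable environment such as low
#' temperature or hypoxia), so lowering `s` proportionally lowers the number of
#' supra-threshold cycles. Left and right sides of an embryo draw independent
#' amplitude series.
#'
#' @param n_cycles Clock cycles per side; cycle `c` maps to boundary `10 + c`,
#'   so the default 20 covers boundaries 11--30.
#' @param mu Log-scale location of the per-cycle amplitude distribution.
#' @param sigma Log-scale spread; must be positive.
#' @param theta Amplitude threshold, in the same (arbitrary) units as the
#'   amplitudes. `theta <= 0` makes every boundary intact.
#' @param env_scale Multiplicative environment factor `s > 0`; 1 = favorable.
#' @param n_embryos Number of embryos to simulate.
#' @param seed Root RNG seed; per-embryo child seeds are derived from it so
#'   each embryo's draws are stable under reordering.
#' @param condition Free-text condition label copied into the boundary table.
#' @return A `clock_sim_params` list.
#' @seealso [simulate_boundary_outcomes()], [analytic_defect_probability()]
#' @export
clock_sim_params <- function(n_cycles = 20L, mu = 0, sigma = 0.5, theta = 1,
                             env_scale = 1, n_embryos = 50L, seed = 1L,
                             condition = "sim") {
  stopifnot(is.numeric(n_cycles), length(n_cycles) == 1L,
            is.numeric(n_embryos), length(n_embryos) == 1L,
            is.numeric(seed), length(seed) == 1L)
  n_cycles <- as.integer(n_cycles)
  n_embryos <- as.integer(n_embryos)
  if (n_cycles < 1L) stop("n_cycles must be >= 1")
  if (n_embryos < 0L) stop("n_embryos must be >= 0")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is.numeric(env_scale) || env_scale <= 0) stop("env_scale must be > 0")
  if (!is.numeric(mu) || !is.numeric(theta)) stop("mu and theta must be numeric")
  structure(list(n_cycles = n_cycles, mu = mu, sigma = sigma, theta = theta,
                 env_scale = env_scale, n_embryos = n_embryos,
                 seed = as.integer(seed), condition = as.character(condition)),
            class = "clock_sim_params")
}

#' Closed-form per-cycle defect probability
#'
#' Under the log-normal amplitude law the probability that one cycle fails the
#' threshold is \eqn{P(A < \theta) = \Phi((\ln\theta - \ln s - \mu)/\sigma)},
#' with \eqn{\Phi} the standard normal CDF. Serves as the analytic oracle for
#' the Monte-Carlo simulator.
#'
#' @param params A [clock_sim_params()] object.
#' @return The defect probability; 0 when `theta <= 0` (amplitudes have
#'   positive support).
#' @export
analytic_defect_probability <- function(params) {
  stopifnot(inherits(params, "clock_sim_params"))
  if (params$theta <= 0) return(0)
  stats::pnorm((log(params$theta) - log(params$env_scale) - params$mu) /
                 params$sigma)
}

#' Threshold giving a target defect probability
#'
#' Inverse of [analytic_defect_probability()]: the threshold at which a cycle
#' fails with probability `p` under the given amplitude law. Convenient for
#' simulating i.i.d. Bernoulli(p) boundary outcomes through the amplitude
#' model.
#'
#' @param p Target per-cycle defect probability in (0, 1).
#' @param mu,sigma,env_scale Amplitude-law parameters as in
#'   [clock_sim_params()].
#' @return Threshold value `theta`.
#' @export
threshold_for_defect_probability <- function(p, mu = 0, sigma = 0.5,
                                             env_scale = 1) {
  stopifnot(is.numeric(p), length(p) == 1L, p > 0, p < 1)
  env_scale * exp(mu + sigma * stats::qnorm(p))
}

# deterministic per-embryo child seeds from the root seed
.child_seeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate per-boundary segmentation outcomes
#'
#' Draws, for every embryo and side, `n_cycles` independent log-normal
#' amplitudes and scores the boundary fed by cycle `c` (boundary `10 + c`) as
#' defected iff the amplitude falls below the threshold. Returns both the
#' amplitude truth table and the derived binary boundary-phenotype table.
#'
#' @param params A [clock_sim_params()] object.
#' @return A `clock_sim` list with elements
#'   \describe{
#'     \item{truth}{data frame `embryo_id, side, cycle, boundary_index,
#'       amplitude, phenotype` (0 intact, 1 defected).}
#'     \item{boundary_table}{[boundary_table] with columns `embryo_id, side,
#'       boundary_index, phenotype, condition`.}
#'     \item{params}{the input parameters.}
#'   }
#' @examples
#' sim <- simulate_boundary_outcomes(clock_sim_params(n_embryos = 5, seed = 7))
#' head(sim$boundary_table)
#' @export
simulate_boundary_outcomes <- function(params) {
  stopifnot(inherits(params, "clock_sim_params"))
  n_e <- params$n_embryos
  n_c <- params$n_cycles
  seeds <- .child_seeds(params$seed, n_e)
  sides <- c("L", "R")
  rows <- vector("list", n_e)
  for (e in seq_len(n_e)) {
    set.seed(seeds[e])
    # left drawn first, then right; the two series are mutually independent
    z <- stats::rnorm(2L * n_c)
    amp <- params$env_scale * exp(params$mu + params$sigma * z)
    rows[[e]] <- data.frame(
      embryo_id = sprintf("E%03d", e),
      side = rep(sides, each = n_c),
      cycle = rep(seq_len(n_c), times = 2L),
      amplitude = amp,
      stringsAsFactors = FALSE
    )
  }
  truth <- if (n_e > 0L) do.call(rbind, rows) else
    data.frame(embryo_id = character(0), side = character(0),
               cycle = integer(0), amplitude = numeric(0))
  truth$boundary_index <- truth$cycle + 10L
  truth$phenotype <- as.integer(truth$amplitude < params$theta)
  truth <- truth[, c("embryo_id", "side", "cycle", "boundary_index",
                     "amplitude", "phenotype")]
  tab <- boundary_table(truth[, c("embryo_id", "side", "boundary_index",
                                  "phenotype")],
                        condition = params$condition)
  structure(list(truth = truth, boundary_table = tab, params = params),
            class = "clock_sim")
}

#' @export
print.clock_sim <- function(x, ...) {
  p <- x$params
  cat("Stochastic amplitude-threshold clock simulation\n")
  cat(sprintf("  %d embryos x 2 sides x %d cycles (boundaries 11-%d)\n",
              p$n_embryos, p$n_cycles, 10L + p$n_cycles))
  cat(sprintf("  amplitude ~ %.3g * lognormal(mu = %.3g, sigma = %.3g), theta = %.3g\n",
              p$env_scale, p$mu, p$sigma, p$theta))
  cat(sprintf("  analytic defect probability: %.4f; empirical: %.4f\n",
              analytic_defect_probability(p),
              if (nrow(x$truth)) mean(x$truth$phenotype) else NA_real_))
  invisible(x)
}
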