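#' MCMC search configuration
#'
#' Settings for the Metropolis search over tip descriptors. The search is
#' used as a global minimizer of the map-wide fitting-error objective (with
#' annealing and best-so-far tracking), not as a posterior sampler.
#'
#' @param n_iter number of iterations (default 1000, one proposal each).
#' @param scales named numeric proposal standard deviations for
#'   `r, a, b, c`; default 10% of the initial value with absolute floors
#'   (2 nm for `r`, 5 nm for `a` and `b`, 5e-3 for `c`; their angle-space
#'   analogues for the conical model).
#' @param seed integer seed; the chain is fully reproducible.
#' @param objective `"variance"` (variance across pixels of per-curve
#'   fitting error, the default feedback quantity) or `"sum"` (accumulated
#'   squared residual).
#' @param bounds list of length-2 numeric ranges for `r`, `a`, `b`, `c`;
#'   `NULL` (default) resolves at optimization time to radius-space bounds
#'   (`r` in (0, 10 um], `a`, `b` in +/- 5 um per unit slope, `c` in
#'   +/- 10) or angle-space bounds for the conical model (`theta0` in
#'   (0, pi/2), `a`, `b` in +/- 1 rad per unit slope, `c` in +/- 2e6
#'   rad/m).
#' @param temp0_frac initial Metropolis temperature as a fraction of the
#'   initial objective value. The fitting-error landscape has a long,
#'   shallow valley (the constant radius term trades off against the depth
#'   coupling), so the default is cold: the chain behaves like stochastic
#'   descent with occasional small uphill moves.
#' @param anneal_to temperature and proposal scales are annealed linearly
#'   (reaching this fraction of their starting values at 80% of the run,
#'   then held) so late iterations refine rather than explore.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 1000L, scales = NULL, seed = 1L,
                        objective = c("variance", "sum"), bounds = NULL,
                        temp0_frac = 1e-4, anneal_to = 0.02) {
  objective <- match.arg(objective)
  if (n_iter < 1L) stop("mcmc_config: n_iter must be >= 1", call. = FALSE)
  if (!is.null(scales) && any(scales <= 0))
    stop("mcmc_config: proposal scales must be > 0", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), scales = scales, seed = seed,
                 objective = objective, bounds = bounds,
                 temp0_frac = temp0_frac, anneal_to = anneal_to),
            class = "mcmc_config")
}

default_scales <- function(init_td) {
  floors <- c(r = 2e-9, a = 5e-9, b = 5e-9, c = 5e-3)
  if (init_td$kind == "angle") floors <- c(r = 5e-3, a = 5e-3, b = 5e-3,
                                           c = 1e4)
  v <- abs(td_vector(init_td))
  pmax(0.10 * v, floors)
}

#' Optimize tip descriptors by Markov-chain Monte Carlo
#'
#' Metropolis search over the tip descriptors `(r, a, b, c)` minimizing the
#' map-wide fitting-error objective. Proposals are independent Gaussian
#' steps per parameter; a proposal is accepted with probability
#' `min(1, exp(-(L' - L) / Tmp))` where the temperature `Tmp` starts at
#' `temp0_frac` times the initial objective; both `Tmp` and the proposal
#' scales are annealed linearly to `anneal_to` of their starting values.
#' Proposals outside the bounds, or producing tip-geometry violations on
#' more than 1% of the used samples, receive an infinite objective. The
#' best descriptors seen anywhere along the chain are tracked and returned
#' (the search is a minimizer, not a posterior sampler).
#'
#' @param img a [spectrum_image()].
#' @param model model id.
#' @param init_td initial [tip_descriptors()] (typically the nominal tip
#'   radius with `a = b = c = 0`).
#' @param cfg an [mcmc_config()].
#' @param config a [model_config()].
#' @param split optional [split_train_test()]; when given, the objective is
#'   evaluated on training samples only.
#' @param depth_window optional depth window (m) applied before fitting.
#' @param grads optional precomputed gradients.
#' @return An object of class `mcmc_trace`: data frame `$trace` with one row
#'   per iteration (`iteration, r, a, b, c, objective, accepted`), plus
#'   `$best_td`, `$best_objective`, `$best_iteration`, `$acceptance_rate`.
#' @export
mcmc_optimize <- function(img, model, init_td, cfg = mcmc_config(),
                          config = model_config(model), split = NULL,
                          depth_window = NULL, grads = NULL) {
  cm <- curve_matrix(img, grads)
  base_mask <- !is.na(cm$D) & !is.na(cm$F)
  if (!is.null(depth_window)) base_mask <- base_mask & cm$D <= depth_window
  if (!is.null(split)) base_mask <- base_mask & !split_test_mask(split, cm)
  bounds <- cfg$bounds
  if (is.null(bounds)) {
    bounds <- if (init_td$kind == "angle")
      list(r = c(1e-3, pi / 2 - 1e-3), a = c(-1, 1), b = c(-1, 1),
           c = c(-2e6, 2e6))
    else
      list(r = c(1e-12, 10e-6), a = c(-5e-6, 5e-6), b = c(-5e-6, 5e-6),
           c = c(-10, 10))
  }
  obj_fun <- function(tdv) {
    bb <- bounds
    if (tdv[1] < bb$r[1] || tdv[1] > bb$r[2] ||
        tdv[2] < bb$a[1] || tdv[2] > bb$a[2] ||
        tdv[3] < bb$b[1] || tdv[3] > bb$b[2] ||
        tdv[4] < bb$c[1] || tdv[4] > bb$c[2]) return(Inf)
    td <- tip_descriptors(tdv[1], tdv[2], tdv[3], tdv[4], kind = init_td$kind)
    fit <- cm_fit(cm, model, td, poisson = config$poisson,
                  r_cell = config$r_cell, use_mask = base_mask)
    if (fit$viol_frac > 0.01) return(Inf)
    cm_objective(fit, cfg$objective)
  }
  scales <- if (is.null(cfg$scales)) default_scales(init_td) else cfg$scales
  x <- td_vector(init_td)
  L <- obj_fun(x)
  if (!is.finite(L))
    stop("mcmc_optimize: initial descriptors give an infinite objective; ",
         "revise the initialization or bounds", call. = FALSE)
  n <- cfg$n_iter
  tr <- matrix(NA_real_, n, 7L)
  best_x <- x; best_L <- L; best_i <- 0L
  temp0 <- cfg$temp0_frac * L
  n_acc <- 0L
  run_with_seed(cfg$seed, {
    for (i in seq_len(n)) {
      fr <- max(1 - (i - 1) / (0.8 * max(n - 1, 1)), cfg$anneal_to)
      prop <- x + stats::rnorm(4L, 0, scales * fr)
      Lp <- obj_fun(prop)
      tmp <- temp0 * fr
      accept <- if (!is.finite(Lp)) FALSE
        else if (Lp <= L) TRUE
        else if (tmp <= 0) FALSE
        else stats::runif(1) < exp(-(Lp - L) / tmp)
      if (accept) { x <- prop; L <- Lp; n_acc <- n_acc + 1L }
      if (L < best_L) { best_L <- L; best_x <- x; best_i <- i }
      tr[i, ] <- c(i, x, L, accept)
    }
  })
  if (!is.finite(best_L))
    stop("mcmc_optimize: no finite-objective iteration; revise bounds/init",
         call. = FALSE)
  trace <- data.frame(iteration = as.integer(tr[, 1]), r = tr[, 2],
                      a = tr[, 3], b = tr[, 4], c = tr[, 5],
                      objective = tr[, 6], accepted = tr[, 7] > 0)
  structure(list(trace = trace,
                 best_td = tip_descriptors(best_x[1], best_x[2], best_x[3],
                                           best_x[4], kind = init_td$kind),
                 best_objective = best_L, best_iteration = best_i,
                 acceptance_rate = n_acc / n, model = model, cfg = cfg),
            class = "mcmc_trace")
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat(sprintf(
    "<mcmc_trace> model %s: %d iterations, best objective %.4g at iteration %d (acceptance %.0f%%)\n",
    x$model, nrow(x$trace), x$best_objective, x$best_iteration,
    100 * x$acceptance_rate))
  print(x$best_td)
  invisible(x)
}

#' Export an MCMC trace as CSV
#' @param trace an [mcmc_optimize()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mcmc_trace <- function(trace, path) {
  utils::write.csv(format(trace$trace, digits = 17, trim = TRUE,
                          scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_init_td <- function(model, nominal_radius = 1.5e-7,
                            nominal_angle = pi / 9) {
  if (model == "sneddon") tip_descriptors(nominal_angle, 0, 0, 0, "angle")
  else tip_descriptors(nominal_radius, 0, 0, 0, "radius")
}

#' Compare contact models by held-out prediction error
#'
#' For each candidate model: optimize its tip descriptors by
#' [mcmc_optimize()] on the training samples, then evaluate
#' [prediction_error()] on the held-out test samples; rank models by
#' ascending prediction error. Descriptors are optimized independently per
#' model (the conical model's live in angle space). A model whose
#' optimization fails is ranked last with the failure reason recorded.
#'
#' @param img a [spectrum_image()].
#' @param models character vector of model ids (>= 1).
#' @param cfg an [mcmc_config()].
#' @param config a [model_config()] (model field ignored).
#' @param seed seed for the train/test split.
#' @param fraction_test held-out fraction (default 1/8).
#' @param init named list of initial [tip_descriptors()] per model, or
#'   `NULL` for defaults.
#' @param nominal_radius,nominal_angle defaults for the initial descriptors.
#' @return An object of class `model_comparison`: data frame `$table` with
#'   columns `model, prediction_error, objective, rank, reason`, ordered by
#'   rank, plus `$fits` (per-model list with `best_td` and the trace) and
#'   `$split`.
#' @export
compare_models <- function(img, models = c("hs", "hertz", "sneddon", "cslc"),
                           cfg = mcmc_config(), config = model_config("hs"),
                           seed = 1L, fraction_test = 1 / 8, init = NULL,
                           nominal_radius = 1.5e-7, nominal_angle = pi / 9) {
  stopifnot(length(models) >= 1L)
  split <- split_train_test(img, fraction_test, seed = seed)
  grads <- topography_gradients(img)
  rows <- list(); fits <- list()
  for (mdl in models) {
    td0 <- if (!is.null(init) && !is.null(init[[mdl]])) init[[mdl]]
           else default_init_td(mdl, nominal_radius, nominal_angle)
    mc <- config; mc$model <- mdl
    res <- tryCatch({
      opt <- mcmc_optimize(img, mdl, td0, cfg = cfg, config = mc,
                           split = split, grads = grads)
      pe <- prediction_error(img, mdl, opt$best_td, split, config = mc,
                             grads = grads)
      fits[[mdl]] <- list(best_td = opt$best_td, trace = opt, pe = pe)
      data.frame(model = mdl, prediction_error = pe$rms,
                 objective = opt$best_objective, reason = "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(model = mdl, prediction_error = Inf, objective = Inf,
                 reason = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[mdl]] <- res
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$prediction_error), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, split = split),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  tab <- x$table
  tab$prediction_error_nN <- 1e9 * tab$prediction_error
  print(tab[, c("rank", "model", "prediction_error_nN", "objective")],
        row.names = FALSE)
  invisible(x)
}
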