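#' Sum-of-squares objective for a parameter set
#'
#' `SSE = sum_x (prediction[x] - target[x])^2` over the axis positions of
#' the profile table. Deterministic given its inputs. When the same
#' sequence/PWM/profile bundle is evaluated repeatedly (as during
#' annealing), pass `sites` pre-computed with [scan_sites()] so scanning is
#' not repeated — the called sites do not depend on the fitted parameters.
#'
#' @param params a [param_set()].
#' @param seq locus sequence.
#' @param pwms list of [pwm_record()]s.
#' @param profiles profile tibble.
#' @param target numeric vector of observed levels, one per position.
#' @param mask optional [accessibility_mask()].
#' @param mode `"competition"` or `"no_competition"`.
#' @param sites optional pre-computed site tibble.
#' @return Numeric scalar SSE.
#' @export
sse_objective <- function(params, seq, pwms, profiles, target,
                          mask = NULL, mode = "competition", sites = NULL) {
  if (length(target) != nrow(profiles)) {
    stop("target length does not match the number of axis positions")
  }
  out <- predict_locus(seq, pwms, params, profiles, mask = mask, mode = mode,
                       sites = sites, details = FALSE)
  sum((out$prediction$rate - target)^2)
}

#' Annealing configuration
#'
#' @param kappa accuracy knob: smaller values buy a longer, slower cooling
#'   schedule (the default move budget is `round(0.8 / kappa)` when
#'   `max_moves` is not given).
#' @param seed integer seed; the whole run is reproducible from it.
#' @param max_moves total proposal count per restart.
#' @param restarts number of independent random-start runs.
#' @param t_end_frac final temperature as a fraction of the initial one.
#' @param polish run a bounded quasi-Newton polish from the best state.
#' @param polish_maxit iteration cap for the polish stage.
#' @return A list with class `"anneal_config"`.
#' @export
anneal_config <- function(kappa = 4e-4, seed = 1, max_moves = NULL,
                          restarts = 1, t_end_frac = 1e-10, polish = TRUE,
                          polish_maxit = 100) {
  stopifnot(kappa > 0)
  if (is.null(max_moves)) max_moves <- round(0.8 / kappa)
  structure(list(kappa = kappa, seed = as.integer(seed),
                 max_moves = as.integer(max_moves),
                 restarts = as.integer(restarts),
                 t_end_frac = t_end_frac, polish = polish,
                 polish_maxit = as.integer(polish_maxit)),
            class = "anneal_config")
}

# one coordinate proposal; log-scale coordinates move multiplicatively,
# and every proposal is reflected back into its bounds
.propose <- function(x, j, bounds, sd_frac) {
  lo <- bounds$lower[j]; hi <- bounds$upper[j]
  if (bounds$scale[j] == "log") {
    llo <- log(lo); lhi <- log(hi)
    v <- log(x[j]) + stats::rnorm(1, 0, sd_frac * (lhi - llo))
    v <- .reflect(v, llo, lhi)
    x[j] <- exp(v)
  } else {
    v <- x[j] + stats::rnorm(1, 0, sd_frac * (hi - lo))
    x[j] <- .reflect(v, lo, hi)
  }
  x
}

.reflect <- function(v, lo, hi) {
  span <- hi - lo
  if (span <= 0) return(lo)
  v <- (v - lo) %% (2 * span)
  lo + ifelse(v > span, 2 * span - v, v)
}

# bounded local polish: L-BFGS-B on internally log-transformed log-scale
# coordinates, with fine finite-difference steps so the numeric gradient
# stays informative close to the optimum; optionally followed by a
# derivative-free Nelder-Mead sweep (projected back into bounds)
.polish <- function(objective, x, bounds, maxit = 60, nm_maxit = 0,
                    fine = FALSE) {
  scale <- bounds$scale == "log"
  to_int <- function(v) ifelse(scale, log(v), v)
  to_ext <- function(v) stats::setNames(ifelse(scale, exp(v), v), bounds$name)
  best <- list(par = x, value = objective(x))
  ctl <- if (fine) {
    list(maxit = maxit, factr = 1e2, ndeps = rep(1e-6, nrow(bounds)))
  } else {
    list(maxit = maxit)
  }
  po <- tryCatch(
    stats::optim(to_int(x), function(v) objective(to_ext(v)),
                 method = "L-BFGS-B",
                 lower = to_int(bounds$lower), upper = to_int(bounds$upper),
                 control = ctl),
    error = function(e) NULL)
  if (!is.null(po) && po$value < best$value) {
    best <- list(par = to_ext(po$par), value = po$value)
  }
  if (nm_maxit > 0) {
    clamp <- function(v) pmin(pmax(v, to_int(bounds$lower)),
                              to_int(bounds$upper))
    nm <- tryCatch(
      stats::optim(to_int(best$par),
                   function(v) objective(to_ext(clamp(v))),
                   method = "Nelder-Mead",
                   control = list(maxit = nm_maxit, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(nm) && nm$value < best$value) {
      best <- list(par = to_ext(clamp(nm$par)), value = nm$value)
    }
  }
  best
}

# random start drawn uniformly (log-uniformly for log-scale coordinates)
.random_start <- function(bounds) {
  v <- numeric(nrow(bounds))
  for (j in seq_len(nrow(bounds))) {
    if (bounds$scale[j] == "log") {
      v[j] <- exp(stats::runif(1, log(bounds$lower[j]), log(bounds$upper[j])))
    } else {
      v[j] <- stats::runif(1, bounds$lower[j], bounds$upper[j])
    }
  }
  stats::setNames(v, bounds$name)
}

#' Minimise an objective by simulated annealing within bounds
#'
#' Seeded geometric-cooling annealer over a named, bounded parameter
#' vector. Proposals perturb one coordinate at a time (multiplicatively for
#' log-scale coordinates), are reflected into the bounds, and are accepted
#' by the Metropolis rule under a temperature that decays geometrically
#' from an initial scale estimated on a short random walk. The best state
#' seen is optionally polished with bounded L-BFGS-B. Identical seeds give
#' identical results; non-convergence is a result, not an error.
#'
#' @param objective function taking a named numeric vector, returning a
#'   scalar to minimise.
#' @param bounds tibble with `name`, `lower`, `upper`, `scale` (see
#'   [param_bounds()]).
#' @param cfg an [anneal_config()].
#' @param init optional named start vector (defaults to a random one).
#' @return An object of class `"fit_result"`: `par` (best vector), `value`
#'   (its objective), `trace` tibble (`move`, `value`, `best`),
#'   `accept_rate`, `seed`.
#' @export
anneal <- function(objective, bounds, cfg = anneal_config(), init = NULL) {
  stopifnot(all(is.finite(bounds$lower)), all(is.finite(bounds$upper)))
  .with_seed(cfg$seed, {
    x <- init %||% .random_start(bounds)
    x <- x[bounds$name]
    e <- objective(x)
    nj <- nrow(bounds)

    # temperature scale from a short exploratory walk
    deltas <- numeric(24)
    xx <- x
    ee <- e
    for (i in seq_along(deltas)) {
      xp <- .propose(xx, ((i - 1) %% nj) + 1, bounds, 0.25)
      ep <- objective(xp)
      deltas[i] <- abs(ep - ee)
      if (ep < ee) { xx <- xp; ee <- ep }
    }
    t0 <- max(stats::median(deltas), 1e-12)
    if (ee < e) { x <- xx; e <- ee }

    best_x <- x
    best_e <- e
    n_acc <- 0
    cool <- cfg$t_end_frac^(1 / max(cfg$max_moves, 1))
    sd0 <- 0.35
    sd_end <- 0.003
    sd_cool <- (sd_end / sd0)^(1 / max(cfg$max_moves, 1))
    every <- max(1L, cfg$max_moves %/% 200L)
    trace <- list()
    temp <- t0
    sd_frac <- sd0
    for (m in seq_len(cfg$max_moves)) {
      j <- sample.int(nj, 1)
      xp <- .propose(x, j, bounds, sd_frac)
      ep <- objective(xp)
      if (ep <= e || stats::runif(1) < exp((e - ep) / temp)) {
        x <- xp; e <- ep; n_acc <- n_acc + 1
        if (e < best_e) { best_e <- e; best_x <- x }
      }
      temp <- temp * cool
      sd_frac <- sd_frac * sd_cool
      if (m %% every == 0) {
        trace[[length(trace) + 1]] <- c(move = m, value = e, best = best_e)
      }
    }

    if (cfg$polish && is.finite(best_e)) {
      pol <- .polish(objective, best_x, bounds,
                     maxit = cfg$polish_maxit %||% 60)
      if (pol$value < best_e) {
        best_e <- pol$value
        best_x <- pol$par
      }
    }

    structure(list(par = best_x, value = best_e,
                   trace = tibble::as_tibble(do.call(rbind, trace)),
                   accept_rate = n_acc / max(cfg$max_moves, 1),
                   seed = cfg$seed),
              class = "fit_result")
  })
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> value = ", format(x$value, digits = 6),
      "; acceptance ", round(100 * x$accept_rate), "%\n", sep = "")
  invisible(x)
}

#' Fit model parameters to an expression profile
#'
#' Minimises the SSE between the model prediction and the target profile
#' over a chosen set of free parameters, by multi-start simulated annealing
#' under the search-space bounds. Binding sites are scanned once up front.
#'
#' @param params a [param_set()] providing structure, bounds and the values
#'   of the non-free parameters.
#' @param seq,pwms,profiles,target,mask,mode as in [sse_objective()].
#' @param free character vector of free parameter names (see
#'   [flatten_params()]); defaults to all.
#' @param cfg an [anneal_config()]; `cfg$restarts` independent runs are
#'   performed and the best kept.
#' @return An object of class `"cis_fit"`: `params` (fitted [param_set()]),
#'   `sse`, `free`, `fits` (per-restart `fit_result`s), `best_restart`.
#' @export
fit_locus <- function(params, seq, pwms, profiles, target, mask = NULL,
                      mode = "competition", free = NULL,
                      cfg = anneal_config()) {
  seq <- .as_locus(seq)
  sites <- scan_sites(pwms, seq, threshold = params$config$threshold)
  if (!is.null(mask)) {
    sites <- apply_mask(sites, mask, rule = params$config$mask_rule)
  }
  free <- free %||% .param_names(params)
  bounds <- param_bounds(params, free)
  obj <- function(x) {
    sse_objective(unflatten_params(params, x), seq, pwms, profiles, target,
                  mode = mode, sites = sites)
  }
  fits <- lapply(seq_len(cfg$restarts), function(r) {
    rc <- cfg
    rc$seed <- as.integer(.child_seed(cfg$seed, 100 + r))
    anneal(obj, bounds, rc)
  })
  best <- which.min(vapply(fits, function(f) f$value, numeric(1)))
  best_par <- fits[[best]]$par
  best_sse <- fits[[best]]$value
  if (cfg$polish) {
    # deep-polish the winning restart only
    pol <- .polish(obj, best_par, bounds, maxit = 200, nm_maxit = 400,
                   fine = TRUE)
    if (pol$value < best_sse) {
      best_par <- pol$par
      best_sse <- pol$value
    }
  }
  structure(list(params = unflatten_params(params, best_par),
                 sse = best_sse, free = free, fits = fits,
                 best_restart = best, n_positions = nrow(profiles)),
            class = "cis_fit")
}

#' @export
print.cis_fit <- function(x, ...) {
  cat("<cis_fit> SSE = ", format(x$sse, digits = 6), " (best of ",
      length(x$fits), " restart(s)); ", length(x$free),
      " free parameters\n", sep = "")
  invisible(x)
}

#' Tidy the fitted parameters
#'
#' @param x a `"cis_fit"`.
#' @param ... unused.
#' @return Tibble with one row per free parameter.
#' @export
tidy.cis_fit <- function(x, ...) {
  dplyr::filter(tidy(x$params), .data$name %in% x$free)
}

#' One-row summary of a fit
#'
#' @param x a `"cis_fit"`.
#' @param ... unused.
#' @return Tibble with `sse`, `n_free`, `n_positions`, `restarts`,
#'   `best_restart`.
#' @export
glance.cis_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n_free = length(x$free),
                 n_positions = x$n_positions, restarts = length(x$fits),
                 best_restart = x$best_restart)
}

#' Fit-known-optimum control
#'
#' Replaces the data with the model's own output under `true_params`, so
#' the refit has a known global minimum at zero, then refits the free
#' parameters from random starts and reports the Spearman rank correlation
#' between the true and recovered parameter vectors.
#'
#' @param true_params generating [param_set()].
#' @param seq,pwms,profiles,mask,mode as in [sse_objective()].
#' @param free free parameter names.
#' @param cfg an [anneal_config()].
#' @return List with `fit` (a `"cis_fit"`), `spearman_rho`, `true` and
#'   `recovered` flat vectors, and `target`.
#' @export
fit_known_optimum_control <- function(true_params, seq, pwms, profiles,
                                      mask = NULL, mode = "competition",
                                      free = NULL, cfg = anneal_config()) {
  out <- predict_locus(seq, pwms, true_params, profiles, mask = mask,
                       mode = mode)
  target <- out$prediction$rate
  fit <- fit_locus(true_params, seq, pwms, profiles, target, mask = mask,
                   mode = mode, free = free, cfg = cfg)
  true_v <- flatten_params(true_params, fit$free)
  rec_v <- flatten_params(fit$params, fit$free)
  rho <- stats::cor(true_v, rec_v, method = "spearman")
  list(fit = fit, spearman_rho = rho, true = true_v, recovered = rec_v,
       target = target)
}

#' Permute non-coding sequence and refit
#'
#' Shuffles the locus bases outside any excluded (e.g. coding) intervals —
#' preserving base composition exactly — and refits the model to the same
#' target on each permuted sequence. Much worse permuted scores indicate
#' the fit uses genuine sequence information rather than overfitting.
#'
#' @param seq locus sequence.
#' @param pwms,params,profiles,target,mask,mode,free,cfg as in
#'   [fit_locus()].
#' @param n_permutations number of permuted replicates.
#' @param exclude optional tibble of 0-based half-open intervals
#'   (`start`, `end`) whose bases are left in place.
#' @return Tibble with one row per permutation (`permutation`, `sse`) and
#'   the fits as an attribute `"fits"`.
#' @export
permutation_control <- function(seq, pwms, params, profiles, target,
                                n_permutations = 3, exclude = NULL,
                                mask = NULL, mode = "competition",
                                free = NULL, cfg = anneal_config()) {
  seq <- .as_locus(seq)
  fits <- list()
  sses <- numeric(n_permutations)
  for (p in seq_len(n_permutations)) {
    pseq <- permute_noncoding(seq, exclude,
                              seed = .child_seed(cfg$seed, 500 + p))
    rc <- cfg
    rc$seed <- as.integer(.child_seed(cfg$seed, 700 + p))
    fit <- fit_locus(params, pseq, pwms, profiles, target, mask = mask,
                     mode = mode, free = free, cfg = rc)
    fits[[p]] <- fit
    sses[p] <- fit$sse
  }
  out <- tibble::tibble(permutation = seq_len(n_permutations), sse = sses)
  attr(out, "fits") <- fits
  out
}

#' Permute a locus outside excluded intervals
#'
#' @param seq locus sequence.
#' @param exclude tibble of 0-based half-open intervals left untouched.
#' @param seed integer seed.
#' @return A [locus_sequence()] with the same base composition.
#' @export
permute_noncoding <- function(seq, exclude = NULL, seed = 1) {
  seq <- .as_locus(seq)
  b <- strsplit(seq$bases, "")[[1]]
  keep <- rep(FALSE, length(b))
  if (!is.null(exclude) && nrow(exclude) > 0) {
    for (i in seq_len(nrow(exclude))) {
      keep[(exclude$start[i] + 1):exclude$end[i]] <- TRUE
    }
  }
  idx <- which(!keep)
  .with_seed(seed, {
    b[idx] <- b[sample(idx)]
  })
  locus_sequence(paste(b, collapse = ""), name = paste0(seq$name, "_permuted"))
}
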