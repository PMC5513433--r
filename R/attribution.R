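#' Numerical derivative of the transcription rate in one factor's level
#'
#' Estimates `dR/d[A]` at one axis position by perturbing that factor's
#' concentration at that position and re-running the model. Where the
#' concentration is positive a symmetric difference quotient
#' `(f(c + h) - f(c - h)) / (2h)` is used (with `h` clipped to `c` so the
#' perturbed level stays non-negative); at zero concentration the forward
#' (Newton) quotient is used.
#'
#' @param params a [param_set()].
#' @param seq,pwms,profiles,mask,mode as in [predict_locus()].
#' @param tf factor name.
#' @param position index (1-based) of the axis position.
#' @param h concentration step, in profile fluorescence units.
#' @param sites optional pre-computed site tibble.
#' @return Numeric scalar derivative estimate.
#' @export
rate_derivative <- function(params, seq, pwms, profiles, tf, position,
                            h = 1e-3, mask = NULL, mode = "competition",
                            sites = NULL) {
  stopifnot(h > 0, tf %in% names(profiles))
  conc <- profiles[[tf]][position]
  rate_at <- function(level) {
    pf <- profiles
    pf[[tf]][position] <- level
    out <- predict_locus(seq, pwms, params, pf, mask = mask, mode = mode,
                         sites = sites, details = FALSE)
    out$prediction$rate[position]
  }
  if (conc > 0) {
    hh <- min(h, conc)
    (rate_at(conc + hh) - rate_at(conc - hh)) / (2 * hh)
  } else {
    (rate_at(conc + h) - rate_at(conc)) / h
  }
}

#' Sweep the derivative step size to check convergence
#'
#' @inheritParams rate_derivative
#' @param h_values vector of step sizes.
#' @return Tibble with `h` and `derivative`.
#' @export
derivative_convergence <- function(params, seq, pwms, profiles, tf, position,
                                   h_values = 10^seq(1, -11, by = -1),
                                   mask = NULL, mode = "competition") {
  seq <- .as_locus(seq)
  sites <- scan_sites(pwms, seq, threshold = params$config$threshold)
  if (!is.null(mask)) sites <- apply_mask(sites, mask,
                                          rule = params$config$mask_rule)
  tibble::tibble(
    h = h_values,
    derivative = vapply(h_values, function(h) {
      rate_derivative(params, seq, pwms, profiles, tf, position, h,
                      mask = mask, mode = mode, sites = sites)
    }, numeric(1))
  )
}

#' Decompose stripe borders into per-factor contributions
#'
#' At every axis position, multiplies the marginal rate derivative
#' `dR/d[A]` of each factor by how much that factor's level is changing
#' there, `delta[A]_i`. Factors whose product is positive build anterior
#' (rising) borders, negative products build posterior (falling) borders,
#' and the per-position column sums approximate the first-order change in
#' predicted output between adjacent positions.
#'
#' @param params a [param_set()].
#' @param seq,pwms,profiles,mask,mode as in [predict_locus()].
#' @param h derivative step in concentration units. The default small step
#'   measures the local gradient; `h = NULL` instead uses each factor's
#'   own concentration change over the adjacent positions (a secant
#'   variant kept for sensitivity analysis).
#' @param delta_method `"central"` uses `([A]_{i+1} - [A]_{i-1}) / 2`, the
#'   change in level at position `i`; `"literal_average"` uses
#'   `([A]_{i-1} + [A]_{i+1}) / 2` (an alternative reading kept for
#'   auditability).
#' @param tfs factors to decompose (defaults to every profile column).
#' @return Tibble with `tf`, `position`, `derivative`, `delta`,
#'   `contribution`.
#' @export
border_contributions <- function(params, seq, pwms, profiles, h = 1e-3,
                                 delta_method = c("central", "literal_average"),
                                 tfs = NULL, mask = NULL,
                                 mode = "competition") {
  delta_method <- match.arg(delta_method)
  if (nrow(profiles) < 3) stop("need at least 3 axis positions")
  seq <- .as_locus(seq)
  sites <- scan_sites(pwms, seq, threshold = params$config$threshold)
  if (!is.null(mask)) sites <- apply_mask(sites, mask,
                                          rule = params$config$mask_rule)
  tfs <- tfs %||% intersect(params$tf$tf, names(profiles))
  P <- nrow(profiles)
  out <- list()
  for (tf in tfs) {
    conc <- profiles[[tf]]
    change <- numeric(P)
    change[2:(P - 1)] <- (conc[3:P] - conc[1:(P - 2)]) / 2
    change[1] <- conc[2] - conc[1]
    change[P] <- conc[P] - conc[P - 1]
    delta <- change
    if (delta_method == "literal_average") {
      delta[2:(P - 1)] <- (conc[1:(P - 2)] + conc[3:P]) / 2
      delta[1] <- conc[2]
      delta[P] <- conc[P - 1]
    }
    hh <- if (is.null(h)) pmax(abs(change), 1e-3) else rep(h, P)
    deriv <- vapply(seq_len(P), function(i) {
      rate_derivative(params, seq, pwms, profiles, tf, i, hh[i], mask = mask,
                      mode = mode, sites = sites)
    }, numeric(1))
    out[[tf]] <- tibble::tibble(tf = tf, position = profiles$position,
                                derivative = deriv, delta = delta,
                                contribution = deriv * delta)
  }
  dplyr::bind_rows(out)
}

#' Per-factor share of promoter activation
#'
#' Splits the adaptor counts of every window by the factor recruiting them
#' and weights by the window's promoter time fraction:
#' `N_a[x] = sum_m N_m,a[x] * T_m[x]`. The decomposition is exact
#' (`sum_a N_a = sum_m N_m * T_m`), and shares are reported as
#' `100 * N_a / max_a N_a` per position.
#'
#' @param params a [param_set()].
#' @param seq,pwms,profiles,mask as in [predict_locus()].
#' @param sites optional pre-computed site tibble.
#' @return Tibble with `tf`, `position`, `N_a`, `percent`.
#' @export
activation_shares <- function(params, seq, pwms, profiles, mask = NULL,
                              sites = NULL) {
  seq <- .as_locus(seq)
  out <- predict_locus(seq, pwms, params, profiles, mask = mask,
                       mode = "competition", sites = sites)
  if (is.null(out$N)) stop("no sites; activation shares are undefined")
  T_frac <- window_time(out$N, params$global$beta)
  ea <- out$activation
  st <- out$sites
  res <- list()
  for (tf in unique(st$tf)) {
    sel <- st$tf == tf
    ea_tf <- ea
    ea_tf$F <- ea$F * ifelse(sel, 1, 0)
    N_tf <- window_adaptors(ea_tf, st, params, l = .as_locus(seq)$length)
    res[[tf]] <- tibble::tibble(tf = tf, position = profiles$position,
                                N_a = colSums(N_tf * T_frac))
  }
  res <- dplyr::bind_rows(res)
  dplyr::mutate(dplyr::group_by(res, .data$position),
                percent = 100 * (.data$N_a / max(max(.data$N_a), 1e-300))) |>
    dplyr::ungroup()
}

#' In-silico fragment (reporter) assay
#'
#' Runs the trained model on a DNA fragment alone — the computational
#' analogue of placing it upstream of a reporter — and standardises the
#' output so its maximum is 1.
#'
#' @param params a [param_set()].
#' @param fragment a [locus_sequence()] or character scalar.
#' @param pwms,profiles,mask,mode as in [predict_locus()].
#' @return A `"model_output"` whose `prediction` tibble gains a
#'   `standardized` column (`rate / max(rate)`; zero if the fragment is
#'   silent).
#' @export
fragment_assay <- function(params, fragment, pwms, profiles, mask = NULL,
                           mode = "competition") {
  out <- predict_locus(fragment, pwms, params, profiles, mask = mask,
                       mode = mode)
  mx <- max(out$prediction$rate)
  out$prediction$standardized <-
    if (mx > 0) out$prediction$rate / mx else rep(0, nrow(out$prediction))
  out
}

#' Edit the trans environment (concentration profiles)
#'
#' Applies a sequence of edits to named factor columns and returns the
#' edited copy; the input is untouched. Supported operations:
#' `set_uniform` (replace the column with a constant), `scale` (multiply
#' by a factor), `zero`.
#'
#' @param profiles profile tibble.
#' @param edits list of edits, each `list(tf =, op =, value =)`.
#' @return The edited profile tibble.
#' @export
perturb_trans <- function(profiles, edits) {
  if (!is.null(edits$tf)) edits <- list(edits)
  for (e in edits) {
    if (!e$tf %in% names(profiles)) stop("unknown factor: ", e$tf)
    profiles[[e$tf]] <- switch(match.arg(e$op, c("set_uniform", "scale", "zero")),
      set_uniform = rep(e$value, nrow(profiles)),
      scale = profiles[[e$tf]] * e$value,
      zero = rep(0, nrow(profiles))
    )
  }
  profiles
}
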