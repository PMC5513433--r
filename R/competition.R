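#' Sliding-window adaptor counts
#'
#' For every window `[m, m + alpha)` of the locus (window starts run from
#' `-alpha` to `l - 1` in 0-based coordinates, i.e. `l + alpha` windows in
#' single-nucleotide increments, including edge windows extending past the
#' locus ends) the number of transcriptional adaptors recruited is the sum
#' of `F_k * E_A(a_k)` over sites whose footprint midpoint lies inside the
#' window. Computed by sliding prefix sums in `O(l + n)` per position.
#'
#' @param ea an `"effective_activation"` with `F` filled (see
#'   [effective_activation()]).
#' @param sites site tibble.
#' @param params a [param_set()].
#' @param alpha window size in bp (defaults to the one in `params`).
#' @param l locus length in bp.
#' @return Numeric matrix, `l + alpha` windows x positions; row `w`
#'   corresponds to window start `w - alpha - 1` in 0-based locus
#'   coordinates (attribute `window_start`).
#' @export
window_adaptors <- function(ea, sites, params, l, alpha = NULL) {
  alpha <- alpha %||% params$global$alpha
  P <- ncol(ea$F)
  E_A <- params$tf$E_A[match(sites$tf, params$tf$tf)]
  contrib <- ea$F * E_A                      # sites x positions
  mid <- floor((sites$start + sites$end) / 2)

  # per-base adaptor totals, then windowed sums over alpha consecutive bases
  base_tot <- matrix(0, l, P)
  if (nrow(sites) > 0) {
    for (k in seq_len(nrow(sites))) {
      base_tot[mid[k] + 1L, ] <- base_tot[mid[k] + 1L, ] + contrib[k, ]
    }
  }
  cs <- apply(rbind(0, base_tot), 2, cumsum)  # (l+1) x P, cs[i+1]=sum to base i-1
  starts <- seq(-alpha, l - 1)                # 0-based window starts
  hi <- pmin(starts + alpha, l)               # exclusive upper base bound
  lo <- pmax(starts, 0)
  N <- cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
  attr(N, "window_start") <- starts
  colnames(N) <- colnames(ea$F)
  N
}

#' Window transcription rate (Arrhenius law)
#'
#' `R = Rmax / (1 + exp(theta - N))`, elementwise: each bound adaptor
#' lowers the energy barrier `theta` by one unit; with no activation the
#' promoter leaks at `Rmax / (1 + exp(theta))`.
#'
#' @param N adaptor count matrix from [window_adaptors()] (any numeric).
#' @param theta energy barrier.
#' @param Rmax maximal rate.
#' @return Matrix (or vector) of rates, same shape as `N`.
#' @export
window_rate <- function(N, theta, Rmax) {
  Rmax / (1 + exp(theta - N))
}

#' Window promoter-interaction time fractions
#'
#' `T[m] = beta * N[m] / (1 + sum_n beta * N[n])`, per axis position: the
#' fraction of time window `m` engages the promoter. Time fractions sum to
#' `S / (1 + S) < 1` where `S = sum(beta * N)`; the remainder is promoter
#' idle time.
#'
#' @param N adaptor count matrix, windows x positions.
#' @param beta per-adaptor interaction weight.
#' @return Matrix of time fractions, same shape as `N`.
#' @export
window_time <- function(N, beta) {
  bN <- beta * N
  sweep(bN, 2, 1 + colSums(bN), "/")
}

#' Competition-weighted total transcription rate
#'
#' `R_total[x] = sum_m R[m, x] * T[m, x]`: the frequency-weighted sum of
#' the rates driven by every window. The predicted mRNA level equals
#' `R_total` (mRNA turnover is fast on the patterning timescale, so level
#' is proportional to rate; the proportionality constant is absorbed into
#' `Rmax`).
#'
#' @param R rate matrix from [window_rate()].
#' @param T_frac time-fraction matrix from [window_time()].
#' @param positions optional axis positions for the output tibble.
#' @return An object of class `"model_output"`: `prediction` tibble
#'   (`position`, `rate`, `mRNA`), `contribution` matrix (windows x
#'   positions of `R * T`), `window_start` attribute carried through.
#' @export
locus_rate <- function(R, T_frac, positions = NULL) {
  if (!all(dim(R) == dim(T_frac))) stop("R and T have different shapes")
  contribution <- R * T_frac
  r_tot <- unname(colSums(contribution))
  positions <- positions %||% as.numeric(colnames(R) %||% seq_along(r_tot))
  structure(list(
    prediction = tibble::tibble(position = positions, rate = r_tot,
                                mRNA = r_tot),
    contribution = contribution,
    window_start = attr(R, "window_start") %||% attr(T_frac, "window_start"),
    mode = "competition"
  ), class = "model_output")
}

#' @export
print.model_output <- function(x, ...) {
  cat("<model_output> mode=", x$mode, "; ", nrow(x$prediction),
      " positions; peak rate ", format(max(x$prediction$rate), digits = 4),
      "\n", sep = "")
  invisible(x)
}

# competition-weighted total rate without materialising the window
# matrices: N is piecewise constant in the window start (it changes only
# where a site midpoint enters or leaves the window), so rates and time
# fractions are accumulated over run-length segments
.rate_fast <- function(ea, sites, params, l) {
  g <- params$global
  alpha <- g$alpha
  E_A <- params$tf$E_A[match(sites$tf, params$tf$tf)]
  contrib <- ea$F * E_A
  mid <- floor((sites$start + sites$end) / 2)
  enter <- mid - alpha + 1L
  leave <- mid + 1L
  bp <- sort(unique(c(-alpha, enter, leave, l)))
  nseg <- length(bp) - 1L
  P <- ncol(contrib)
  delta <- matrix(0, nseg, P)
  ie <- match(enter, bp)
  il <- match(leave, bp)
  for (k in seq_len(nrow(sites))) {
    delta[ie[k], ] <- delta[ie[k], ] + contrib[k, ]
    if (il[k] <= nseg) delta[il[k], ] <- delta[il[k], ] - contrib[k, ]
  }
  Nseg <- apply(delta, 2, cumsum)
  len <- diff(bp)
  S <- g$beta * colSums(Nseg * len)
  Rseg <- g$Rmax / (1 + exp(g$theta - Nseg))
  Tseg <- sweep(g$beta * Nseg, 2, 1 + S, "/")
  unname(colSums(Rseg * Tseg * len))
}

#' Predict locus transcription from sequence, PWMs and profiles
#'
#' Full pipeline: PWM scan, optional accessibility masking, per-position
#' site weights, occupancy DP, coactivation and quenching, sliding-window
#' adaptor counts, and the competition-weighted rate. In
#' `mode = "no_competition"` a single window spanning the whole sequence
#' feeds the Arrhenius law directly (no time-fraction weighting): every
#' bound factor influences the promoter simultaneously.
#'
#' @param seq a [locus_sequence()] or character scalar.
#' @param pwms list of [pwm_record()] objects.
#' @param params a [param_set()].
#' @param profiles profile tibble with a concentration column per factor.
#' @param mask optional [accessibility_mask()]; when supplied, only sites
#'   within accessible chromatin are used.
#' @param mode `"competition"` or `"no_competition"`.
#' @param sites optional pre-computed site tibble (skips scanning).
#' @param details if `FALSE`, skip materialising the window-level `N`,
#'   rate and contribution matrices and return the per-position prediction
#'   only (identical values, computed over run-length segments; used in
#'   fitting loops).
#' @return A `"model_output"` (see [locus_rate()]) with extra fields
#'   `sites`, `occupancy`, `activation`, `N`.
#' @export
predict_locus <- function(seq, pwms, params, profiles, mask = NULL,
                          mode = c("competition", "no_competition"),
                          sites = NULL, details = TRUE) {
  mode <- match.arg(mode)
  seq <- .as_locus(seq)
  if (is.null(sites)) {
    sites <- scan_sites(pwms, seq, threshold = params$config$threshold)
    if (!is.null(mask)) {
      sites <- apply_mask(sites, mask, rule = params$config$mask_rule)
    }
  }
  positions <- profiles$position
  P <- length(positions)

  if (nrow(sites) == 0) {
    basal <- params$global$Rmax / (1 + exp(params$global$theta))
    rate <- if (mode == "competition") rep(0, P) else rep(basal, P)
    out <- structure(list(
      prediction = tibble::tibble(position = positions, rate = rate,
                                  mRNA = rate),
      contribution = matrix(rate, 1, P), window_start = 0L, mode = mode,
      sites = sites, occupancy = NULL, activation = NULL, N = NULL
    ), class = "model_output")
    return(out)
  }

  q <- site_weights(sites, params, profiles)
  occ <- occupancy_dp(sites, q, .coop_from_params(params))
  ea <- effective_activation(occ, sites, params)

  if (mode == "no_competition") {
    E_A <- params$tf$E_A[match(sites$tf, params$tf$tf)]
    N_tot <- colSums(ea$F * E_A)
    rate <- unname(window_rate(N_tot, params$global$theta, params$global$Rmax))
    out <- structure(list(
      prediction = tibble::tibble(position = positions, rate = rate,
                                  mRNA = rate),
      contribution = matrix(rate, 1, P, dimnames = list(NULL, positions)),
      window_start = 0L, mode = mode,
      sites = sites, occupancy = occ, activation = ea,
      N = matrix(N_tot, 1, P)
    ), class = "model_output")
    return(out)
  }

  if (!details) {
    rate <- .rate_fast(ea, sites, params, l = seq$length)
    return(structure(list(
      prediction = tibble::tibble(position = positions, rate = rate,
                                  mRNA = rate),
      contribution = NULL, window_start = NULL, mode = mode,
      sites = sites, occupancy = NULL, activation = NULL, N = NULL
    ), class = "model_output"))
  }

  N <- window_adaptors(ea, sites, params, l = seq$length)
  R <- window_rate(N, params$global$theta, params$global$Rmax)
  T_frac <- window_time(N, params$global$beta)
  attr(R, "window_start") <- attr(N, "window_start")
  out <- locus_rate(R, T_frac, positions)
  out$sites <- sites
  out$occupancy <- occ
  out$activation <- ea
  out$N <- N
  out
}
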