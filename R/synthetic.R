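#' Specification for a synthetic model system
#'
#' Describes a fully self-contained toy regulatory locus: a factor roster
#' with PWM lengths and information content, enhancers as planned clusters
#' of consensus sites, and smooth gradient/bump concentration profiles
#' emulating the maternal and gap-gene inputs of the fly blastoderm. All
#' generated objects are byte-identical under a fixed seed.
#'
#' @param seed integer RNG seed.
#' @param locus_length locus length in bp.
#' @param tf_roster tibble with columns `tf`, `role`, `coactivated_by`
#'   (list), `pwm_length`, `ic` (information content, bits per position).
#' @param enhancers list of enhancer plans: `list(position, sites, spacing)`
#'   with `sites` a character vector of factor names planted in order.
#' @param profile_shapes named list (one entry per factor) of shape
#'   descriptions: `list(shape = "uniform"|"anterior_gradient"|
#'   "posterior_gradient"|"bump"|"two_domain", ...)` with shape parameters
#'   `value`, `midpoint`, `width`, `center`, `amplitude`, `centers`,
#'   `widths`.
#' @param n_positions number of axis positions.
#' @param from,to axis range in percent embryo length.
#' @param gc background GC fraction of the random locus.
#' @return An object of class `"synth_spec"`.
#' @export
synth_spec <- function(seed = 1, locus_length = 6000,
                       tf_roster = default_tf_roster(),
                       enhancers = default_enhancers(),
                       profile_shapes = default_profile_shapes(),
                       n_positions = 58, from = 35.5, to = 92.5,
                       gc = 0.4) {
  miss <- setdiff(tf_roster$tf, names(profile_shapes))
  if (length(miss)) stop("no profile shape for: ", paste(miss, collapse = ", "))
  structure(list(seed = seed, locus_length = as.integer(locus_length),
                 tf_roster = tf_roster, enhancers = enhancers,
                 profile_shapes = profile_shapes,
                 n_positions = as.integer(n_positions),
                 from = from, to = to, gc = gc),
            class = "synth_spec")
}

#' Default six-factor roster of the synthetic benchmark
#'
#' Two activators (one graded and cooperative, one uniform), three pure
#' repressors and one coactivated repressor — enough to exercise every
#' regulatory mechanism of the model.
#'
#' @return Roster tibble for [synth_spec()].
#' @export
default_tf_roster <- function() {
  tibble::tibble(
    tf = c("actA", "actU", "repM", "repN", "repP", "hbC"),
    role = c("activator", "activator", "repressor", "repressor",
             "repressor", "repressor"),
    coactivated_by = list(character(), character(), character(), character(),
                          character(), "actA"),
    pwm_length = c(10L, 10L, 10L, 10L, 10L, 10L),
    ic = c(1.6, 1.6, 1.6, 1.6, 1.6, 1.6)
  )
}

#' Default enhancer plans of the synthetic benchmark
#'
#' Two enhancers 3 kb apart: "stripeA" mixes graded and uniform activator
#' sites with coactivated-repressor sites and middle/posterior repressor
#' flanks; "stripeB" pairs uniform-activator sites with anterior-repressor
#' sites, so the two elements drive separated expression domains.
#'
#' @return List of enhancer plans for [synth_spec()].
#' @export
default_enhancers <- function() {
  list(
    stripeA = list(position = 1200,
                   sites = c("actA", "hbC", "actA", "actU", "repM", "actU",
                             "repP", "repM"),
                   spacing = 30),
    stripeB = list(position = 4200,
                   sites = c("actU", "repN", "actU", "repN", "actU"),
                   spacing = 30)
  )
}

#' Default concentration-profile shapes of the synthetic benchmark
#'
#' Fluorescence-like amplitudes on a 0-255 scale: an anterior gradient and
#' a uniform activator, bump and gradient repressors, and a two-domain
#' profile for the coactivated repressor.
#'
#' @return Named list of shapes for [synth_spec()].
#' @export
default_profile_shapes <- function() {
  list(
    actA = list(shape = "anterior_gradient", midpoint = 55, width = 8,
                amplitude = 255),
    actU = list(shape = "uniform", value = 150),
    repM = list(shape = "bump", center = 62, width = 7, amplitude = 255),
    repN = list(shape = "anterior_gradient", midpoint = 60, width = 6,
                amplitude = 255),
    repP = list(shape = "posterior_gradient", midpoint = 78, width = 4,
                amplitude = 255),
    hbC = list(shape = "two_domain", centers = c(44, 80), widths = c(5, 5),
               amplitude = 200)
  )
}

# consensus probability achieving a given per-position information content
# (bits) for a (p, q, q, q) column
.ic_to_prob <- function(ic) {
  # cap just below 1 so log-odds stay finite at maximal information content
  if (ic >= 2) return(0.9999)
  h <- function(p) {
    q <- (1 - p) / 3
    2 + p * log2(p) + 3 * q * log2(q) - ic
  }
  stats::uniroot(h, c(0.2500001, 0.9999999), tol = 1e-12)$root
}

#' Generate toy PWMs for a synthetic roster
#'
#' Each factor gets a distinct random consensus with per-position columns
#' `(p, q, q, q)` at the probability matching the requested information
#' content, converted to natural-log odds against a uniform background.
#'
#' @param spec a [synth_spec()].
#' @return Named list of [pwm_record()] objects.
#' @export
make_toy_pwms <- function(spec) {
  roster <- spec$tf_roster
  if (anyDuplicated(roster$tf)) stop("roster name collision")
  .with_seed(.child_seed(spec$seed, 1), {
    seen <- character()
    out <- list()
    for (i in seq_len(nrow(roster))) {
      L <- roster$pwm_length[i]
      if (L < 4) stop("pwm_length must be at least 4")
      repeat {
        cons <- sample(4, L, replace = TRUE)
        key <- paste(cons, collapse = "")
        if (!key %in% seen) break
      }
      seen <- c(seen, key)
      p <- .ic_to_prob(roster$ic[i])
      mat <- matrix((1 - p) / 3, L, 4)
      mat[cbind(seq_len(L), cons)] <- p
      out[[roster$tf[i]]] <- pwm_record(roster$tf[i], log(mat / 0.25))
    }
    out
  })
}

#' Generate a synthetic locus with planted binding sites
#'
#' Background bases are i.i.d. at the stated GC fraction; each enhancer
#' plan's sites are planted as exact consensus sequences on the forward
#' strand at fixed spacing. The ground-truth site record is returned
#' alongside the sequence.
#'
#' @param spec a [synth_spec()].
#' @param pwms PWMs from [make_toy_pwms()].
#' @param allow_overlap permit overlapping planted sites.
#' @return List with `seq` (a [locus_sequence()]) and `truth` (tibble of
#'   planted sites: `enhancer`, `tf`, `start`, `end`, `strand`).
#' @export
make_locus <- function(spec, pwms, allow_overlap = FALSE) {
  .with_seed(.child_seed(spec$seed, 2), {
    probs <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
    bases <- sample(c("A", "C", "G", "T"), spec$locus_length, replace = TRUE,
                    prob = probs)
    truth <- list()
    for (en in names(spec$enhancers)) {
      plan <- spec$enhancers[[en]]
      pos <- plan$position
      for (tf in plan$sites) {
        cons <- strsplit(pwm_consensus(pwms[[tf]]), "")[[1]]
        if (pos + length(cons) > spec$locus_length) {
          stop("planted site extends past the locus end")
        }
        bases[(pos + 1):(pos + length(cons))] <- cons
        truth[[length(truth) + 1]] <- tibble::tibble(
          enhancer = en, tf = tf, start = pos, end = pos + length(cons),
          strand = "+")
        pos <- pos + plan$spacing
      }
    }
    truth <- dplyr::bind_rows(truth)
    if (!allow_overlap && nrow(truth) > 1) {
      tr <- dplyr::arrange(truth, .data$start)
      if (any(tr$start[-1] < tr$end[-nrow(tr)])) {
        stop("planted sites overlap (set allow_overlap = TRUE to permit)")
      }
    }
    list(seq = locus_sequence(paste(bases, collapse = ""), name = "synthetic"),
         truth = truth)
  })
}

.shape_profile <- function(x, sh) {
  switch(sh$shape,
    uniform = rep(sh$value, length(x)),
    anterior_gradient = sh$amplitude * stats::plogis((sh$midpoint - x) / sh$width),
    posterior_gradient = sh$amplitude * stats::plogis((x - sh$midpoint) / sh$width),
    bump = sh$amplitude * exp(-(x - sh$center)^2 / (2 * sh$width^2)),
    two_domain = sh$amplitude * pmin(1,
      exp(-(x - sh$centers[1])^2 / (2 * sh$widths[1]^2)) +
        exp(-(x - sh$centers[2])^2 / (2 * sh$widths[2]^2))),
    stop("unknown profile shape: ", sh$shape)
  )
}

#' Generate smooth synthetic concentration profiles
#'
#' @param spec a [synth_spec()].
#' @return Profile tibble (`position` plus one column per factor).
#' @export
make_profiles <- function(spec) {
  x <- seq(spec$from, spec$to, length.out = spec$n_positions)
  cols <- lapply(spec$tf_roster$tf,
                 function(tf) .shape_profile(x, spec$profile_shapes[[tf]]))
  names(cols) <- spec$tf_roster$tf
  tb <- tibble::tibble(position = x, !!!cols)
  validate_profiles(tb)
  tb
}

#' Hand-chosen parameters of the synthetic benchmark
#'
#' @param spec a [synth_spec()] (roster taken from it).
#' @return A [param_set()].
#' @export
benchmark_params <- function(spec = synth_spec()) {
  r <- spec$tf_roster
  tf <- tf_params(
    tf = r$tf, role = r$role, coactivated_by = r$coactivated_by,
    A = 0.5, lambda = 1.5,
    E_A = c(6, 5, 0, 0, 0, 4)[seq_len(nrow(r))],
    E_Q = c(0, 0, 0.9, 0.85, 0.85, 0.5)[seq_len(nrow(r))],
    E_C = c(0, 0, 0, 0, 0, 0.8)[seq_len(nrow(r))],
    cooperative = r$tf == "actA",
    omega = ifelse(r$tf == "actA", 5, 1)
  )
  param_set(tf, global_params(theta = 12, beta = 0.005, Rmax = 240,
                              alpha = 1000))
}

#' Build the standing two-enhancer synthetic benchmark
#'
#' Generates the full bundle — PWMs, locus with planted enhancers, ground
#' truth, profiles and hand-chosen parameters — used throughout the test
#' suite as an end-to-end fixture.
#'
#' @param seed integer seed.
#' @param ... further arguments to [synth_spec()].
#' @return List with `spec`, `pwms`, `seq`, `truth`, `profiles`, `params`.
#' @export
make_benchmark <- function(seed = 1, ...) {
  spec <- synth_spec(seed = seed, ...)
  pwms <- make_toy_pwms(spec)
  loc <- make_locus(spec, pwms)
  profiles <- make_profiles(spec)
  list(spec = spec, pwms = pwms, seq = loc$seq, truth = loc$truth,
       profiles = profiles, params = benchmark_params(spec))
}

#' Construct a fitting problem with a known global optimum
#'
#' Replaces the target data with the model's own output under a stated
#' parameter set, so that refitting has a known global minimum at zero SSE
#' and the generating parameters.
#'
#' @param spec a [synth_spec()].
#' @param params generating [param_set()] (defaults to
#'   [benchmark_params()]).
#' @return List with the input bundle (`pwms`, `seq`, `profiles`, `params`)
#'   and `target`, the per-position model output.
#' @export
make_known_optimum_problem <- function(spec = synth_spec(),
                                       params = benchmark_params(spec)) {
  validate_param_set(params)
  pwms <- make_toy_pwms(spec)
  loc <- make_locus(spec, pwms)
  profiles <- make_profiles(spec)
  out <- predict_locus(loc$seq, pwms, params, profiles)
  list(pwms = pwms, seq = loc$seq, truth = loc$truth, profiles = profiles,
       params = params, target = out$prediction$rate)
}
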