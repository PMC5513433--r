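#' Per-factor model parameters
#'
#' Builds the per-transcription-factor parameter table used throughout the
#' model. Each factor carries a concentration/affinity scale `A`, a score
#' softness `lambda`, and efficiency parameters matching its regulatory role:
#' activators recruit adaptors with efficiency `E_A`; repressors quench
#' nearby activators with efficiency `E_Q`; repressors listed with
#' coactivators additionally switch to activators with efficiency `E_C` (and
#' then also carry an `E_A` for their activating mode). A single factor may
#' bind cooperatively with itself (`cooperative = TRUE`), with pair weight
#' `omega`.
#'
#' @param tf character vector of factor names.
#' @param role `"activator"` or `"repressor"`, recycled.
#' @param coactivated_by list of character vectors naming the coactivator
#'   factors of each entry (empty for factors that are not coactivated).
#' @param A concentration/affinity scale, in `[1e-6, 4]`.
#' @param lambda score-to-affinity softness, in `[0.5, 5]`; larger values
#'   compress affinity differences between strong and weak sites.
#' @param E_A adaptor-recruitment efficiency, in `[0, 25]`.
#' @param E_Q quenching efficiency, in `[0, 1]`.
#' @param E_C coactivation efficiency, in `[0, 1]`.
#' @param cooperative logical; does this factor bind cooperatively with
#'   itself?
#' @param omega cooperativity weight for adjacent bound pairs, in
#'   `[1, 1000]`.
#' @return A tibble with one row per factor.
#' @export
tf_params <- function(tf, role, coactivated_by = NULL,
                      A = 1, lambda = 1, E_A = 0, E_Q = 0, E_C = 0,
                      cooperative = FALSE, omega = 1) {
  n <- length(tf)
  if (is.null(coactivated_by)) coactivated_by <- rep(list(character()), n)
  if (!is.list(coactivated_by)) coactivated_by <- list(coactivated_by)
  out <- tibble::tibble(
    tf = as.character(tf),
    role = rep_len(match.arg(role, c("activator", "repressor"), several.ok = TRUE),
                   n),
    coactivated_by = rep_len(coactivated_by, n),
    A = rep_len(A, n),
    lambda = rep_len(lambda, n),
    E_A = rep_len(E_A, n),
    E_Q = rep_len(E_Q, n),
    E_C = rep_len(E_C, n),
    cooperative = rep_len(cooperative, n),
    omega = rep_len(omega, n)
  )
  if (anyDuplicated(out$tf)) stop("duplicated factor names in tf_params")
  out
}

#' Global model parameters
#'
#' @param theta energy barrier to transcription initiation (adaptor units);
#'   the window rate is `Rmax / (1 + exp(theta - N))`. Range `[5, 25]`.
#' @param beta promoter-interaction weight per adaptor in the competition
#'   time fractions. Must be positive.
#' @param Rmax maximal transcription rate, in the units of the target data.
#' @param alpha window size in bp: the maximal DNA length that can
#'   simultaneously influence the promoter.
#' @return A list with class `"global_params"`.
#' @export
global_params <- function(theta = 15, beta = 0.01, Rmax = 255, alpha = 1000) {
  stopifnot(beta > 0, Rmax > 0, alpha >= 1)
  structure(list(theta = theta, beta = beta, Rmax = Rmax,
                 alpha = as.integer(alpha)),
            class = "global_params")
}

#' Model interaction-range configuration
#'
#' Fixed (non-fitted) ranges for the protein-protein interaction mechanisms
#' and the site-calling threshold.
#'
#' @param d_omega maximal edge-to-edge gap (bp) for a cooperative bound pair.
#' @param d_coact maximal centre-to-centre distance (bp) for coactivation.
#' @param d_quench maximal centre-to-centre distance (bp) for quenching.
#' @param threshold log-odds threshold for calling binding sites (sites must
#'   score strictly above it).
#' @param mask_rule how the accessibility mask filters sites:
#'   `"contain"` keeps sites whose full footprint lies inside an accessible
#'   interval; `"overlap"` keeps sites touching one.
#' @return A list with class `"model_config"`.
#' @export
model_config <- function(d_omega = 60, d_coact = 150, d_quench = 100,
                         threshold = 0, mask_rule = c("contain", "overlap")) {
  stopifnot(d_omega >= 0, d_coact >= 0, d_quench >= 0)
  structure(list(d_omega = d_omega, d_coact = d_coact, d_quench = d_quench,
                 threshold = threshold, mask_rule = match.arg(mask_rule)),
            class = "model_config")
}

#' Bundle per-factor, global and range parameters into a parameter set
#'
#' @param tf a [tf_params()] tibble.
#' @param global a [global_params()] list.
#' @param config a [model_config()] list.
#' @return An object of class `"param_set"`.
#' @export
param_set <- function(tf, global = global_params(), config = model_config()) {
  ps <- structure(list(tf = tf, global = global, config = config),
                  class = "param_set")
  validate_param_set(ps)
  ps
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set> ", nrow(x$tf), " factors; theta=", x$global$theta,
      ", beta=", format(x$global$beta), ", Rmax=", format(x$global$Rmax),
      ", alpha=", x$global$alpha, "\n", sep = "")
  print(x$tf, ...)
  invisible(x)
}

# search-space bounds; `scale` marks parameters proposed multiplicatively
.param_bound_table <- function() {
  tibble::tribble(
    ~kind,    ~lower, ~upper, ~scale,
    "A",      1e-6,   4,      "log",
    "lambda", 0.5,    5,      "linear",
    "E_A",    0,      25,     "linear",
    "E_Q",    0,      1,      "linear",
    "E_C",    0,      1,      "linear",
    "omega",  1,      1000,   "log",
    "theta",  5,      25,     "linear",
    "beta",   1e-6,   1e2,    "log",
    "Rmax",   1e-2,   1e4,    "log"
  )
}

.is_coactivated <- function(tf_tbl) {
  tf_tbl$role == "repressor" & lengths(tf_tbl$coactivated_by) > 0
}

#' Validate a parameter set against the search-space bounds
#'
#' @param ps a [param_set()].
#' @return `ps`, invisibly; errors on violation.
#' @export
validate_param_set <- function(ps) {
  b <- .param_bound_table()
  bd <- function(kind) b[b$kind == kind, ]
  tf <- ps$tf
  chk <- function(val, kind, who) {
    bb <- bd(kind)
    if (any(val < bb$lower - 1e-12 | val > bb$upper + 1e-12)) {
      stop(sprintf("%s out of bounds [%g, %g] for %s", kind, bb$lower,
                   bb$upper, paste(who[val < bb$lower | val > bb$upper],
                                   collapse = ", ")))
    }
  }
  chk(tf$A, "A", tf$tf)
  chk(tf$lambda, "lambda", tf$tf)
  chk(tf$E_A, "E_A", tf$tf)
  chk(tf$E_Q, "E_Q", tf$tf)
  chk(tf$E_C, "E_C", tf$tf)
  chk(tf$omega[tf$cooperative], "omega", tf$tf[tf$cooperative])
  chk(ps$global$theta, "theta", "theta")
  chk(ps$global$beta, "beta", "beta")
  chk(ps$global$Rmax, "Rmax", "Rmax")
  if (sum(tf$cooperative) > 1) {
    stop("at most one cooperative factor is supported")
  }
  unknown <- setdiff(unlist(tf$coactivated_by), tf$tf)
  if (length(unknown)) {
    stop("unknown coactivator factor(s): ", paste(unknown, collapse = ", "))
  }
  invisible(ps)
}

# names of all fittable scalar entries for a parameter set
.param_names <- function(ps) {
  tf <- ps$tf
  coact <- .is_coactivated(tf)
  nm <- character()
  for (i in seq_len(nrow(tf))) {
    nm <- c(nm, paste0("A.", tf$tf[i]), paste0("lambda.", tf$tf[i]))
    if (tf$role[i] == "activator" || coact[i]) nm <- c(nm, paste0("E_A.", tf$tf[i]))
    if (tf$role[i] == "repressor") nm <- c(nm, paste0("E_Q.", tf$tf[i]))
    if (coact[i]) nm <- c(nm, paste0("E_C.", tf$tf[i]))
    if (tf$cooperative[i]) nm <- c(nm, paste0("omega.", tf$tf[i]))
  }
  c(nm, "theta", "beta", "Rmax")
}

#' Flatten a parameter set to a named numeric vector
#'
#' The flat view exposes exactly the fittable scalars (per-factor `A`,
#' `lambda`, role-appropriate efficiencies, `omega` for the cooperative
#' factor, and global `theta`, `beta`, `Rmax`), named `kind.tf`. The
#' round trip through [unflatten_params()] is exact.
#'
#' @param ps a [param_set()].
#' @param free optional character vector restricting to a subset of names.
#' @return Named numeric vector.
#' @export
flatten_params <- function(ps, free = NULL) {
  nm <- .param_names(ps)
  val <- vapply(nm, function(x) .param_get(ps, x), numeric(1))
  if (!is.null(free)) {
    bad <- setdiff(free, nm)
    if (length(bad)) stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    val <- val[free]
  }
  val
}

.param_get <- function(ps, name) {
  if (name %in% c("theta", "beta", "Rmax")) return(ps$global[[name]])
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  kind <- parts[1]; tf <- paste(parts[-1], collapse = ".")
  ps$tf[[kind]][ps$tf$tf == tf]
}

.param_put <- function(ps, name, value) {
  if (name %in% c("theta", "beta", "Rmax")) {
    ps$global[[name]] <- value
  } else {
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    kind <- parts[1]; tf <- paste(parts[-1], collapse = ".")
    ps$tf[[kind]][ps$tf$tf == tf] <- value
  }
  ps
}

#' Write flat parameter values back into a parameter set
#'
#' @param ps a [param_set()].
#' @param x named numeric vector as produced by [flatten_params()] (possibly
#'   a subset).
#' @return The updated `param_set`.
#' @export
unflatten_params <- function(ps, x) {
  stopifnot(!is.null(names(x)))
  for (nm in names(x)) ps <- .param_put(ps, nm, unname(x[nm]))
  ps
}

#' Search-space bounds for the fittable parameters
#'
#' @param ps a [param_set()].
#' @param free optional character vector restricting to a subset.
#' @return A tibble with columns `name`, `kind`, `lower`, `upper`, `scale`.
#' @export
param_bounds <- function(ps, free = NULL) {
  nm <- .param_names(ps)
  if (!is.null(free)) nm <- nm[match(free, nm)]
  kind <- sub("\\..*$", "", nm)
  b <- .param_bound_table()
  i <- match(kind, b$kind)
  tibble::tibble(name = nm, kind = kind,
                 lower = b$lower[i], upper = b$upper[i], scale = b$scale[i])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy view of a parameter set
#'
#' @param x a [param_set()].
#' @param ... unused.
#' @return A tibble with one row per fittable scalar: `name`, `value`,
#'   `kind`, `lower`, `upper`, `scale`.
#' @export
tidy.param_set <- function(x, ...) {
  v <- flatten_params(x)
  dplyr::mutate(param_bounds(x), value = unname(v[.data$name]),
                .after = "kind")
}
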