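#' Cooperativity specification
#'
#' One factor (in the fly segmentation system, Bcd) may bind cooperatively
#' with itself: each pair of consecutively bound sites of that factor whose
#' edge-to-edge gap is at most `d_omega` multiplies the configuration weight
#' by `omega`.
#'
#' @param tf_name name of the cooperative factor, or `NULL` for none.
#' @param omega pair weight, `>= 1` (`1` disables cooperativity).
#' @param d_omega maximal edge-to-edge gap in bp.
#' @return An object of class `"coop_spec"`.
#' @export
coop_spec <- function(tf_name = NULL, omega = 1, d_omega = 60) {
  stopifnot(omega >= 1, d_omega >= 0)
  structure(list(tf_name = tf_name, omega = omega, d_omega = d_omega),
            class = "coop_spec")
}

# derive the cooperativity spec from a parameter set
.coop_from_params <- function(params) {
  tf <- params$tf
  i <- which(tf$cooperative)
  if (length(i) == 0) return(coop_spec())
  coop_spec(tf$tf[i], tf$omega[i], params$config$d_omega)
}

.occ_weights <- function(weights) {
  w <- as.matrix(weights)
  if (any(w < 0)) stop("negative site weights")
  w
}

.occ_table <- function(f, logZ, sites, positions) {
  dimnames(f) <- NULL
  structure(list(f = f, logZ = logZ, site_id = sites$site_id,
                 positions = positions),
            class = "occupancy_table")
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat("<occupancy_table> ", nrow(x$f), " sites x ", ncol(x$f),
      " positions\n", sep = "")
  invisible(x)
}

#' Fractional occupancy by exhaustive enumeration
#'
#' Reference implementation: enumerates all `2^n` binding configurations,
#' discards those with overlapping footprints, weights each by the product
#' of member site weights times `omega` per consecutively bound cooperative
#' pair within range, and normalises. Guarded to `n <= 20` sites; intended
#' as the oracle against which [occupancy_dp()] is verified.
#'
#' @param sites site tibble (`start`, `end`, `tf` columns used).
#' @param weights sites x positions weight matrix (or a vector for a single
#'   position).
#' @param coop a [coop_spec()].
#' @return An `occupancy_table`: list with `f` (sites x positions fractional
#'   occupancy) and `logZ` (per-position log partition function).
#' @export
occupancy_bruteforce <- function(sites, weights, coop = coop_spec()) {
  n <- nrow(sites)
  if (n > 20) stop("occupancy_bruteforce is guarded to n <= 20 sites")
  w <- .occ_weights(if (is.matrix(weights)) weights else matrix(weights, nrow = n))
  P <- ncol(w)
  if (n == 0) {
    return(.occ_table(matrix(0, 0, P), rep(0, P), sites, colnames(w)))
  }
  cfgs <- 0:(2^n - 1)
  bit <- 2^(seq_len(n) - 1)

  valid <- rep(TRUE, length(cfgs))
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      if (sites$start[j] < sites$end[i] && sites$start[i] < sites$end[j]) {
        m <- bit[i] + bit[j]
        valid[bitwAnd(cfgs, m) == m] <- FALSE
      }
    }
  }

  # count consecutively bound cooperative pairs within the gap limit
  ncoop <- integer(length(cfgs))
  is_coop <- !is.null(coop$tf_name) & sites$tf == coop$tf_name & coop$omega > 1
  ci <- which(is_coop)[order(sites$start[is_coop])]
  if (length(ci) >= 2) {
    for (a in seq_len(length(ci) - 1)) {
      for (b in seq(a + 1, length(ci))) {
        gap <- sites$start[ci[b]] - sites$end[ci[a]]
        if (gap > coop$d_omega) next
        req <- bit[ci[a]] + bit[ci[b]]
        between <- if (b > a + 1) sum(bit[ci[seq(a + 1, b - 1)]]) else 0
        hit <- bitwAnd(cfgs, req) == req & bitwAnd(cfgs, between) == 0
        ncoop[hit] <- ncoop[hit] + 1L
      }
    }
  }

  f <- matrix(0, n, P)
  logZ <- numeric(P)
  inset <- lapply(seq_len(n), function(i) bitwAnd(cfgs, bit[i]) > 0)
  for (x in seq_len(P)) {
    lw <- numeric(length(cfgs))
    for (i in seq_len(n)) {
      lw[inset[[i]]] <- lw[inset[[i]]] + log(w[i, x])
    }
    cw <- exp(lw) * coop$omega^ncoop
    cw[!valid] <- 0
    Z <- sum(cw)
    logZ[x] <- log(Z)
    for (i in seq_len(n)) f[i, x] <- sum(cw[inset[[i]]]) / Z
  }
  .occ_table(f, logZ, sites, colnames(w))
}

#' Fractional occupancy by linear-time dynamic programming
#'
#' Computes the same equilibrium occupancies as [occupancy_bruteforce()] —
#' steric exclusion of overlapping footprints plus nearest-neighbour
#' pairwise cooperativity — with cost linear in the number of sites (times
#' the local overlap/interaction window), so whole-locus calculations with
#' thousands of sites are feasible. All accumulation is performed in the log
#' domain. Every axis position (weight column) is an independent
#' calculation.
#'
#' @inheritParams occupancy_bruteforce
#' @return An `occupancy_table` (see [occupancy_bruteforce()]).
#' @export
occupancy_dp <- function(sites, weights, coop = coop_spec()) {
  n <- nrow(sites)
  w <- .occ_weights(if (is.matrix(weights)) weights else matrix(weights, nrow = n))
  P <- ncol(w)
  if (n == 0) {
    return(.occ_table(matrix(0, 0, P), rep(0, P), sites, colnames(w)))
  }
  is_coop <- !is.null(coop$tf_name) & sites$tf == coop$tf_name
  res <- .occupancy_dp_cpp(as.numeric(sites$start), as.numeric(sites$end),
                           as.logical(is_coop), log(w),
                           coop$omega, coop$d_omega)
  .occ_table(res$f, as.numeric(res$logZ), sites, colnames(w))
}

#' Tidy view of an occupancy table
#'
#' @param x an `occupancy_table`.
#' @param ... unused.
#' @return A tibble with columns `site_id`, `position`, `f`.
#' @export
tidy.occupancy_table <- function(x, ...) {
  pos <- x$positions %||% seq_len(ncol(x$f))
  tibble::tibble(
    site_id = rep(x$site_id, times = ncol(x$f)),
    position = as.numeric(rep(pos, each = nrow(x$f))),
    f = as.vector(x$f)
  )
}
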