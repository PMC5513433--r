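# prefix-sum machinery for products over centre-window ranges of sites:
# exact zeros are counted separately so log-prefix differences never see
# -Inf
.prefix_products <- function(M) {
  zero <- M <= 0
  M[zero] <- 1
  logM <- log(M)
  list(cumL = rbind(0, apply(logM, 2, cumsum)),
       cumZ = rbind(0, apply(zero + 0, 2, cumsum)),
       logM = logM, zero = zero)
}

# products over rows lo[k]..hi[k] (1-based, inclusive; lo > hi = empty
# product), optionally excluding row self[k]; returns length(lo) x P
.range_products <- function(pp, lo, hi, self = NULL) {
  empty <- lo > hi
  hi2 <- pmax(hi, lo - 1L)
  L <- pp$cumL[hi2 + 1L, , drop = FALSE] - pp$cumL[lo, , drop = FALSE]
  Z <- pp$cumZ[hi2 + 1L, , drop = FALSE] - pp$cumZ[lo, , drop = FALSE]
  if (!is.null(self)) {
    ex <- which(!is.na(self) & self >= lo & self <= hi)
    if (length(ex)) {
      L[ex, ] <- L[ex, ] - pp$logM[self[ex], , drop = FALSE]
      Z[ex, ] <- Z[ex, ] - pp$zero[self[ex], , drop = FALSE]
    }
  }
  out <- exp(L)
  out[Z > 0] <- 0
  out[empty, ] <- 1
  out
}

#' Coactivation: context-dependent repressor-to-activator switching
#'
#' Decomposes each site's occupancy `f` into an activating part `f_act` and
#' a repressing part `f_rep`. Pure activators activate with their full
#' occupancy (`f_act = f`). Pure repressors never activate (`f_act = 0`).
#' A coactivated repressor site `k` switches in proportion to the chance
#' that at least one coactivator site within `d_coact`
#' (centre-to-centre) is bound:
#' `f_act = f * E_C * (1 - prod_j (1 - f_j))`, with `f_rep = f - f_act`.
#'
#' @param occ an `occupancy_table` from [occupancy_dp()].
#' @param sites site tibble.
#' @param params a [param_set()].
#' @param config optional [model_config()] override (defaults to the one in
#'   `params`).
#' @return An object of class `"effective_activation"` with matrices
#'   `f_act`, `f_rep` (and `F` once [quench()] has run).
#' @export
coactivate <- function(occ, sites, params, config = NULL) {
  cfg <- config %||% params$config
  tf_tbl <- params$tf
  i <- match(sites$tf, tf_tbl$tf)
  role <- tf_tbl$role[i]
  coact_lists <- tf_tbl$coactivated_by[i]
  is_coactivated <- role == "repressor" & lengths(coact_lists) > 0
  E_C <- tf_tbl$E_C[i]

  f <- occ$f
  centre <- (sites$start + sites$end) / 2
  f_act <- matrix(0, nrow(f), ncol(f), dimnames = dimnames(f))
  f_act[role == "activator", ] <- f[role == "activator", ]

  # group coactivated sites by their coactivator name set, so the
  # "at least one bound" product runs over one centre-sorted prefix table
  if (any(is_coactivated)) {
    groups <- split(which(is_coactivated),
                    vapply(coact_lists[is_coactivated],
                           function(x) paste(sort(x), collapse = ","),
                           character(1)))
    for (g in groups) {
      set <- coact_lists[[g[1]]]
      js <- which(sites$tf %in% set)
      js <- js[order(centre[js])]
      if (length(js) == 0) next
      cj <- centre[js]
      pp <- .prefix_products(1 - f[js, , drop = FALSE])
      lo <- findInterval(centre[g] - cfg$d_coact, cj, left.open = TRUE) + 1L
      hi <- findInterval(centre[g] + cfg$d_coact, cj)
      p_any <- 1 - .range_products(pp, lo, hi)
      f_act[g, ] <- f[g, , drop = FALSE] * E_C[g] * p_any
    }
  }

  structure(list(f = f, f_act = f_act, f_rep = f - f_act, F = NULL,
                 role = role, is_coactivated = is_coactivated),
            class = "effective_activation")
}

#' Short-range quenching of activating occupancy
#'
#' Each site's activating occupancy is attenuated by every repressor-acting
#' site within `d_quench` (centre-to-centre):
#' `F_k = f_act_k * prod_r (1 - E_Q(r) * f_rep_r)`, where `f_rep_r` is the
#' full occupancy of a pure repressor and the non-switched part of a
#' coactivated repressor. Repressors do not quench other repressors, and a
#' coactivated site's own repressing part does not quench its activating
#' part. `F` is zero for sites acting purely as repressors.
#'
#' @param ea an `"effective_activation"` from [coactivate()].
#' @param sites site tibble.
#' @param params a [param_set()].
#' @param config optional [model_config()] override.
#' @return The `"effective_activation"` with `F` filled.
#' @export
quench <- function(ea, sites, params, config = NULL) {
  cfg <- config %||% params$config
  tf_tbl <- params$tf
  i <- match(sites$tf, tf_tbl$tf)
  E_Q <- tf_tbl$E_Q[i]
  role <- tf_tbl$role[i]
  centre <- (sites$start + sites$end) / 2

  FF <- ea$f_act
  reps <- which(role == "repressor")
  reps <- reps[order(centre[reps])]
  if (length(reps) > 0) {
    cr <- centre[reps]
    pp <- .prefix_products(1 - E_Q[reps] * ea$f_rep[reps, , drop = FALSE])
    acting <- which(role == "activator" | ea$is_coactivated)
    if (length(acting)) {
      lo <- findInterval(centre[acting] - cfg$d_quench, cr, left.open = TRUE) + 1L
      hi <- findInterval(centre[acting] + cfg$d_quench, cr)
      FF[acting, ] <- FF[acting, , drop = FALSE] *
        .range_products(pp, lo, hi, self = match(acting, reps))
    }
  }
  FF[role == "repressor" & !ea$is_coactivated, ] <- 0
  ea$F <- FF
  ea
}

#' Effective activation pipeline: coactivation then quenching
#'
#' @inheritParams coactivate
#' @return An `"effective_activation"` with `f_act`, `f_rep` and `F` filled.
#' @export
effective_activation <- function(occ, sites, params, config = NULL) {
  quench(coactivate(occ, sites, params, config), sites, params, config)
}

#' @export
print.effective_activation <- function(x, ...) {
  cat("<effective_activation> ", nrow(x$f_act), " sites x ", ncol(x$f_act),
      " positions; quenched: ", !is.null(x$F), "\n", sep = "")
  invisible(x)
}
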