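#' Call binding sites by PWM scanning
#'
#' Scans both strands of the locus with each PWM and returns every footprint
#' scoring strictly above the threshold. Reverse-strand hits are scored by
#' scanning the forward sequence with the reverse-complemented PWM, and all
#' coordinates are reported on the forward strand (0-based half-open).
#' Footprints spanning an `N` score `-Inf` and are never called.
#'
#' @param pwms a [pwm_record()] or list of them.
#' @param seq a [locus_sequence()] or character scalar.
#' @param threshold log-odds calling threshold (sites must exceed it
#'   strictly).
#' @return A tibble with columns `site_id`, `tf`, `start`, `end`, `strand`,
#'   `score`, `footprint`, `s_max`, sorted by `start` then strand.
#' @export
scan_sites <- function(pwms, seq, threshold = 0) {
  if (inherits(pwms, "pwm_record")) pwms <- list(pwms)
  seq <- .as_locus(seq)
  code <- match(strsplit(seq$bases, "")[[1]], c("A", "C", "G", "T"))
  hits <- purrr::map_dfr(pwms, function(p) {
    if (p$length > seq$length) {
      stop("PWM ", p$tf, " is longer than the sequence")
    }
    fwd <- .scan_one(p$mat, code)
    rev <- .scan_one(.pwm_revcomp(p), code)
    starts <- seq_len(seq$length - p$length + 1L) - 1L
    dplyr::bind_rows(
      tibble::tibble(tf = p$tf, start = starts, strand = "+", score = fwd),
      tibble::tibble(tf = p$tf, start = starts, strand = "-", score = rev)
    ) |>
      dplyr::filter(.data$score > threshold) |>
      dplyr::mutate(end = .data$start + p$length, footprint = p$length,
                    s_max = p$s_max)
  })
  hits <- dplyr::arrange(hits, .data$start, .data$strand, .data$tf)
  dplyr::mutate(hits, site_id = dplyr::row_number(), .before = 1) |>
    dplyr::select("site_id", "tf", "start", "end", "strand", "score",
                  "footprint", "s_max")
}

# sliding log-odds scores of one (already oriented) matrix over an
# integer-coded sequence; N (NA code) makes the spanning windows -Inf
.scan_one <- function(mat, code) {
  L <- nrow(mat)
  n <- length(code)
  nw <- n - L + 1L
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    v <- unname(mat[j, ])[code[j:(j + nw - 1L)]]
    v[is.na(v)] <- -Inf
    sc <- sc + v
  }
  sc
}

#' Filter sites by an accessibility mask
#'
#' With `rule = "contain"` (default) a site is kept only when its full
#' footprint lies within one accessible interval; `rule = "overlap"` keeps
#' sites touching any accessible base. With `enabled = FALSE` the site table
#' is returned unchanged.
#'
#' @param sites site tibble from [scan_sites()].
#' @param mask an [accessibility_mask()].
#' @param enabled logical switch.
#' @param rule `"contain"` or `"overlap"`.
#' @return Filtered site tibble.
#' @export
apply_mask <- function(sites, mask, enabled = TRUE,
                       rule = c("contain", "overlap")) {
  if (!enabled) return(sites)
  rule <- match.arg(rule)
  if (nrow(mask$intervals) == 0) return(sites[0, ])
  q <- IRanges::IRanges(start = sites$start + 1L, end = sites$end)
  s <- IRanges::IRanges(start = mask$intervals$start + 1L,
                        end = mask$intervals$end)
  keep <- if (rule == "contain") {
    IRanges::overlapsAny(q, s, type = "within")
  } else {
    IRanges::overlapsAny(q, s)
  }
  sites[keep, ]
}

#' Per-position statistical weights of called sites
#'
#' The weight of site `i` of factor `a` at axis position `x` is
#' `q = A_a * conc_a(x) * exp((s_i - s_max_a) / lambda_a)`: the
#' concentration-scaled relative affinity, with the score deficit from the
#' best attainable site compressed by `lambda_a`.
#'
#' @param sites site tibble from [scan_sites()] (carries `s_max`).
#' @param params a [param_set()] or [tf_params()] tibble.
#' @param profiles profile tibble with one column per factor.
#' @return Numeric matrix, sites x positions, with `site_id` rownames and
#'   position colnames.
#' @export
site_weights <- function(sites, params, profiles) {
  tf_tbl <- if (inherits(params, "param_set")) params$tf else params
  i <- match(sites$tf, tf_tbl$tf)
  if (anyNA(i)) {
    stop("no parameters for factor(s): ",
         paste(unique(sites$tf[is.na(i)]), collapse = ", "))
  }
  missing_col <- setdiff(unique(sites$tf), names(profiles))
  if (length(missing_col)) {
    stop("no concentration column for factor(s): ",
         paste(missing_col, collapse = ", "))
  }
  conc <- t(as.matrix(profiles[sites$tf]))     # sites x positions
  aff <- tf_tbl$A[i] * exp((sites$score - sites$s_max) / tf_tbl$lambda[i])
  q <- conc * aff
  dimnames(q) <- list(sites$site_id, profiles$position)
  q
}
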