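#' Position weight matrix record
#'
#' A PWM is stored as a log-odds matrix (natural log) with one row per
#' position and columns A, C, G, T, together with the maximum attainable
#' score `s_max` (sum of per-position column maxima) and the background base
#' composition the odds are taken against.
#'
#' @param tf factor name.
#' @param mat numeric matrix, `L x 4`, log-odds values; columns in A,C,G,T
#'   order (a 4-row matrix with positions in columns is transposed).
#' @param background background base probabilities (A,C,G,T), summing to 1.
#' @return An object of class `"pwm_record"`.
#' @export
pwm_record <- function(tf, mat, background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4 && nrow(mat) == 4) mat <- t(mat)
  if (ncol(mat) != 4) stop("PWM matrix must have 4 base columns")
  if (!all(is.finite(mat))) stop("PWM matrix entries must be finite")
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  colnames(mat) <- c("A", "C", "G", "T")
  structure(list(tf = tf, mat = mat, s_max = sum(apply(mat, 1, max)),
                 length = nrow(mat), background = background),
            class = "pwm_record")
}

#' Build a log-odds PWM from a count matrix
#'
#' Counts are converted to probabilities with a background-proportional
#' pseudocount, then to natural-log odds against the background.
#'
#' @param tf factor name.
#' @param counts non-negative count matrix, `L x 4` (or `4 x L`).
#' @param background background base probabilities.
#' @param pseudocount total pseudocount distributed proportionally to the
#'   background.
#' @return A [pwm_record()].
#' @export
pwm_from_counts <- function(tf, counts, background = rep(0.25, 4),
                            pseudocount = 1) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4 && nrow(counts) == 4) counts <- t(counts)
  if (ncol(counts) != 4) stop("count matrix must have 4 base columns")
  if (any(counts < 0)) stop("negative counts in PWM")
  p <- (counts + pseudocount * rep(background, each = nrow(counts))) /
    (rowSums(counts) + pseudocount)
  pwm_record(tf, log(p / rep(background, each = nrow(counts))), background)
}

#' @export
print.pwm_record <- function(x, ...) {
  cat("<pwm_record> ", x$tf, ": ", x$length, " bp, s_max = ",
      format(x$s_max, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param pwm a [pwm_record()].
#' @return Character scalar, the per-position argmax bases.
#' @export
pwm_consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$mat, 1, which.max)], collapse = "")
}

#' Score a single oligonucleotide with a PWM
#'
#' @param pwm a [pwm_record()].
#' @param kmer character scalar whose length equals the PWM length; any
#'   non-ACGT character scores `-Inf`.
#' @return Numeric log-odds score.
#' @export
pwm_score <- function(pwm, kmer) {
  b <- strsplit(toupper(kmer), "")[[1]]
  if (length(b) != pwm$length) stop("k-mer length does not match PWM length")
  i <- match(b, c("A", "C", "G", "T"))
  if (anyNA(i)) return(-Inf)
  sum(pwm$mat[cbind(seq_along(i), i)])
}

# reverse-complement a PWM (scan the forward strand with it to score the
# reverse strand)
.pwm_revcomp <- function(pwm) {
  m <- pwm$mat[rev(seq_len(pwm$length)), rev(seq_len(4)), drop = FALSE]
  colnames(m) <- c("A", "C", "G", "T")
  m
}
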