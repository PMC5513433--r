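#' Locus sequence container
#'
#' @param bases character scalar over A,C,G,T,N (lower case folded).
#' @param name sequence name.
#' @param genome_offset optional 1-based genomic start coordinate
#'   (informational only; all model coordinates are locus-local).
#' @return An object of class `"locus_seq"` with fields `name`, `bases`,
#'   `length`, `genome_offset`.
#' @export
locus_sequence <- function(bases, name = "locus", genome_offset = NULL) {
  bases <- toupper(as.character(bases))
  if (nchar(bases) == 0) stop("empty sequence")
  if (grepl("[^ACGTN]", bases)) {
    stop("sequence contains characters other than A,C,G,T,N")
  }
  structure(list(name = name, bases = bases, length = nchar(bases),
                 genome_offset = genome_offset),
            class = "locus_seq")
}

#' @export
print.locus_seq <- function(x, ...) {
  cat("<locus_seq> ", x$name, ": ", x$length, " bp\n", sep = "")
  invisible(x)
}

.as_locus <- function(x) {
  if (inherits(x, "locus_seq")) x else locus_sequence(x)
}

#' Read a locus from a FASTA file
#'
#' The first record is used; bases are uppercased and validated against the
#' alphabet A,C,G,T,N.
#'
#' @param path FASTA file path.
#' @param genome_offset optional 1-based genomic start of the sequence.
#' @return A [locus_sequence()].
#' @export
read_locus_fasta <- function(path, genome_offset = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("no FASTA records in ", path)
  locus_sequence(as.character(ss[[1]]), name = names(ss)[1],
                 genome_offset = genome_offset)
}

#' Write a locus to a FASTA file
#'
#' @param seq a [locus_sequence()] or character scalar.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(seq, path) {
  seq <- .as_locus(seq)
  ss <- Biostrings::DNAStringSet(seq$bases)
  names(ss) <- seq$name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---- PWM files ---------------------------------------------------------

#' Read a set of PWMs from a text file
#'
#' Two dialects are accepted, record by record. Each record starts with a
#' header line `>NAME` optionally carrying `type=counts|logodds` and
#' `background=pA,pC,pG,pT` tokens. The body is either one line per position
#' with four whitespace-separated values (A C G T order), or four
#' JASPAR-style base rows `A [ n1 n2 ... ]`. Count matrices are converted to
#' natural-log odds against the stated background with a pseudocount;
#' log-odds matrices are passed through.
#'
#' @param path PWM file path.
#' @param pseudocount pseudocount used for count matrices.
#' @return A named list of [pwm_record()] objects.
#' @export
read_pwm_set <- function(path, pseudocount = 1) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty PWM file: ", path)
  heads <- which(startsWith(lines, ">"))
  if (length(heads) == 0) stop("no '>' record headers in PWM file")
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (r in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[r]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    name <- toks[1]
    kv <- toks[-1]
    type <- sub("^type=", "", grep("^type=", kv, value = TRUE))
    bg <- sub("^background=", "", grep("^background=", kv, value = TRUE))
    background <- if (length(bg)) as.numeric(strsplit(bg, ",")[[1]]) else rep(0.25, 4)
    body <- lines[seq(heads[r] + 1L, bounds[r + 1L] - 1L)]
    if (length(body) == 0) stop("PWM record ", name, " has no matrix body")
    jaspar <- grepl("^[ACGT]\\s", body[1]) || grepl("^[ACGT]\\[", body[1])
    if (jaspar) {
      if (length(body) != 4) stop("JASPAR-style record ", name, " needs 4 base rows")
      base <- substr(body, 1, 1)
      rows <- lapply(body, function(l) {
        as.numeric(strsplit(trimws(gsub("[][]", " ", substr(l, 2, nchar(l)))),
                            "\\s+")[[1]])
      })
      if (length(unique(lengths(rows))) != 1) stop("ragged JASPAR rows in ", name)
      mat <- do.call(rbind, rows)[match(c("A", "C", "G", "T"), base), , drop = FALSE]
      mat <- t(mat)
      if (length(type) == 0) type <- "counts"
    } else {
      rows <- lapply(body, function(l) as.numeric(strsplit(l, "\\s+")[[1]]))
      if (any(lengths(rows) != 4)) stop("PWM row without 4 base values in ", name)
      mat <- do.call(rbind, rows)
      if (length(type) == 0) type <- "logodds"
    }
    if (anyNA(mat)) stop("non-numeric matrix cell in PWM record ", name)
    rec <- switch(match.arg(type, c("counts", "logodds")),
      counts = pwm_from_counts(name, mat, background, pseudocount),
      logodds = pwm_record(name, mat, background)
    )
    out[[name]] <- rec
  }
  out
}

#' Write a set of PWMs as log-odds matrices
#'
#' @param pwms named list of [pwm_record()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwm_set <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s type=logodds background=%s", p$tf,
                       paste(format(p$background, digits = 10), collapse = ",")),
               con)
    utils::write.table(format(p$mat, digits = 17), con, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# ---- profile tables ----------------------------------------------------

#' Read spatial concentration/expression profiles
#'
#' Tab-separated table with a `position` column (percent embryo length) and
#' one numeric column per factor or target. Positions must be strictly
#' increasing and evenly spaced.
#'
#' @param path TSV path.
#' @param resort if `TRUE`, rows are sorted by position; if `FALSE`
#'   out-of-order rows are an error.
#' @return A tibble with `position` first.
#' @export
read_profiles <- function(path, resort = FALSE) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"position" %in% names(tb)) stop("profiles need a 'position' column")
  tb <- dplyr::relocate(tb, "position")
  if (anyNA(tb)) stop("missing values in profile table")
  if (!all(vapply(tb, is.numeric, logical(1)))) {
    stop("non-numeric cells in profile table")
  }
  if (is.unsorted(tb$position, strictly = TRUE)) {
    if (!resort) stop("positions not strictly increasing (set resort = TRUE to sort)")
    tb <- dplyr::arrange(tb, .data$position)
  }
  validate_profiles(tb)
  tb
}

#' Validate a profile table
#'
#' @param profiles tibble with a `position` column and numeric factor columns.
#' @return `profiles`, invisibly.
#' @export
validate_profiles <- function(profiles) {
  p <- profiles$position
  if (length(p) > 2) {
    dp <- diff(p)
    if (max(abs(dp - dp[1])) > 1e-6 * max(abs(dp))) {
      stop("positions must be evenly spaced")
    }
  }
  if (any(vapply(profiles[-1], function(x) any(x < 0), logical(1)))) {
    stop("negative concentrations in profile table")
  }
  invisible(profiles)
}

#' Write a profile table as TSV
#'
#' @param profiles profile tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  readr::write_tsv(profiles, path)
  invisible(path)
}

# ---- accessibility masks ----------------------------------------------

#' Accessibility mask over locus-local coordinates
#'
#' Intervals are 0-based half-open, merged and clipped to `[0, l]`.
#'
#' @param start,end integer vectors of interval bounds.
#' @param l locus length in bp.
#' @return An object of class `"accessibility_mask"`.
#' @export
accessibility_mask <- function(start = integer(), end = integer(), l) {
  stopifnot(length(start) == length(end))
  keep <- end > 0 & start < l & end > start
  ir <- IRanges::reduce(IRanges::IRanges(start = pmax(start[keep], 0) + 1,
                                         end = pmin(end[keep], l)))
  structure(list(intervals = tibble::tibble(start = IRanges::start(ir) - 1L,
                                            end = IRanges::end(ir)),
                 l = as.integer(l)),
            class = "accessibility_mask")
}

#' @export
print.accessibility_mask <- function(x, ...) {
  cat("<accessibility_mask> ", nrow(x$intervals), " intervals covering ",
      sum(x$intervals$end - x$intervals$start), "/", x$l, " bp\n", sep = "")
  invisible(x)
}

#' Read accessible-chromatin intervals from BED files
#'
#' Genomic BED intervals (0-based half-open) are translated to locus-local
#' coordinates, intersected with the locus, and the union over all files is
#' merged. Intervals entirely outside the locus are dropped with a message.
#' An empty BED set yields an empty mask, under which every site is masked
#' out when masking is enabled.
#'
#' @param paths character vector of BED file paths.
#' @param locus_start 1-based genomic start coordinate of the locus.
#' @param l locus length in bp.
#' @return An [accessibility_mask()].
#' @export
read_accessibility <- function(paths, locus_start, l) {
  starts <- integer()
  ends <- integer()
  for (p in paths) {
    gr <- rtracklayer::import(p, format = "BED")
    if (length(gr) == 0) next
    s <- BiocGenerics::start(gr) - locus_start       # local 0-based start
    e <- BiocGenerics::end(gr) - locus_start + 1L    # local half-open end
    outside <- e <= 0 | s >= l
    if (any(outside)) {
      message(sum(outside), " interval(s) in ", p, " fall outside the locus")
    }
    starts <- c(starts, s[!outside])
    ends <- c(ends, e[!outside])
  }
  accessibility_mask(starts, ends, l)
}

# ---- site export -------------------------------------------------------

#' Export called binding sites as BED6
#'
#' Scores are min-max scaled to 0-1000 as BED requires; the raw log-odds
#' scores live in the site table itself.
#'
#' @param sites site tibble from [scan_sites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  rng <- range(sites$score)
  scl <- if (diff(rng) > 0) (sites$score - rng[1]) / diff(rng) else rep(1, nrow(sites))
  bed <- tibble::tibble(chrom = "locus", start = sites$start, end = sites$end,
                        name = sites$tf, score = round(1000 * scl),
                        strand = sites$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
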