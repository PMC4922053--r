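#' Pair-alignment tables
#'
#' Most functions in this package consume read-pair alignments as a plain
#' data.frame with one row per pair and columns `read_id`, `scaffold_a`,
#' `pos_a`, `end_a`, `strand_a`, `scaffold_b`, `pos_b`, `end_b`, `strand_b`,
#' `mapq_a`, `mapq_b`. Coordinates are 0-based half-open; strands are
#' `"+"`/`"-"`. SAM/BAM input (1-based) is converted at the boundary by
#' [read_pair_alignments()].
#'
#' @param read_id,scaffold_a,pos_a,end_a,strand_a,scaffold_b,pos_b,end_b,strand_b,mapq_a,mapq_b
#'   Vectors of equal length, one element per pair.
#' @return A validated pair-alignment data.frame.
#' @export
pair_alignments <- function(read_id, scaffold_a, pos_a, end_a, strand_a,
                            scaffold_b, pos_b, end_b, strand_b,
                            mapq_a = 60L, mapq_b = 60L) {
  df <- data.frame(read_id = as.character(read_id),
                   scaffold_a = as.character(scaffold_a),
                   pos_a = as.numeric(pos_a), end_a = as.numeric(end_a),
                   strand_a = as.character(strand_a),
                   scaffold_b = as.character(scaffold_b),
                   pos_b = as.numeric(pos_b), end_b = as.numeric(end_b),
                   strand_b = as.character(strand_b),
                   mapq_a = as.integer(mapq_a), mapq_b = as.integer(mapq_b),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$end_a > df$pos_a), all(df$end_b > df$pos_b),
            all(df$strand_a %in% c("+", "-")),
            all(df$strand_b %in% c("+", "-")))
  df
}

# orientation test: FR = leftmost mate forward, rightmost reverse (RF the
# converse); only meaningful for same-scaffold pairs
pair_orientation_ok <- function(df, expected = c("fr", "rf")) {
  expected <- match.arg(expected)
  a_first <- df$pos_a <= df$pos_b
  left_strand <- ifelse(a_first, df$strand_a, df$strand_b)
  right_strand <- ifelse(a_first, df$strand_b, df$strand_a)
  if (expected == "fr") left_strand == "+" & right_strand == "-"
  else left_strand == "-" & right_strand == "+"
}

pair_insert <- function(df) pmax(df$end_a, df$end_b) - pmin(df$pos_a, df$pos_b)

#' Estimate an insert-size distribution from pair alignments
#'
#' Uses same-scaffold pairs in the expected orientation with both mapping
#' qualities at or above `min_mapq`. The insert is the outer distance
#' `max(end) - min(pos)`. Mean and standard deviation are computed after
#' trimming the top and bottom 1 per cent of inserts; the consistency
#' bounds are `mean +/- 3 sd` (lower bound clamped at 0).
#'
#' @param pairs Pair-alignment data.frame (see [pair_alignments()]).
#' @param min_mapq Minimum mapping quality for both mates (default 0).
#' @param expected_orientation `"fr"` (paired-end) or `"rf"` (mate-pair).
#' @param min_pairs Minimum number of usable pairs (default 100).
#' @return An `insert_distribution`: list with `hist` (data.frame
#'   `insert`/`count`), `mu`, `sigma`, `lo`, `hi`, `expected_orientation`,
#'   `n_pairs`.
#' @export
estimate_insert_distribution <- function(pairs, min_mapq = 0L,
                                         expected_orientation = c("fr", "rf"),
                                         min_pairs = 100L) {
  expected_orientation <- match.arg(expected_orientation)
  ok <- pairs$scaffold_a == pairs$scaffold_b &
    pairs$mapq_a >= min_mapq & pairs$mapq_b >= min_mapq
  ok <- ok & pair_orientation_ok(pairs, expected_orientation)
  usable <- pairs[ok, , drop = FALSE]
  if (nrow(usable) < min_pairs)
    stop(sprintf("insufficient data: %d usable pairs (need >= %d)",
                 nrow(usable), min_pairs))
  ins <- pair_insert(usable)
  qs <- quantile(ins, c(0.01, 0.99), type = 1)
  trimmed <- ins[ins >= qs[1] & ins <= qs[2]]
  mu <- mean(trimmed)
  sigma <- if (length(trimmed) > 1L) sd(trimmed) else 0
  if (!is.finite(sigma)) sigma <- 0
  tab <- table(ins)
  hist <- data.frame(insert = as.numeric(names(tab)),
                     count = as.numeric(tab))
  structure(list(hist = hist, mu = mu, sigma = sigma,
                 lo = max(0, mu - 3 * sigma), hi = mu + 3 * sigma,
                 expected_orientation = expected_orientation,
                 n_pairs = length(ins)),
            class = "insert_distribution")
}

#' Construct an insert distribution from known parameters
#'
#' Useful when the distribution was estimated elsewhere (or is a simulation
#' truth) and only the consistency bounds are needed.
#'
#' @param mu,sigma Mean and standard deviation of the insert size (bp).
#' @param expected_orientation `"fr"` or `"rf"`.
#' @param hist Optional insert histogram data.frame.
#' @return An `insert_distribution`.
#' @export
insert_distribution <- function(mu, sigma, expected_orientation = "fr",
                                hist = NULL) {
  stopifnot(sigma >= 0)
  structure(list(hist = hist, mu = mu, sigma = sigma,
                 lo = max(0, mu - 3 * sigma), hi = mu + 3 * sigma,
                 expected_orientation = expected_orientation,
                 n_pairs = if (is.null(hist)) NA_integer_ else sum(hist$count)),
            class = "insert_distribution")
}

#' @export
print.insert_distribution <- function(x, ...) {
  cat(sprintf(
    "insert_distribution: mu=%.1f sd=%.1f bounds=[%.1f, %.1f] (%s, n=%s)\n",
    x$mu, x$sigma, x$lo, x$hi, x$expected_orientation, x$n_pairs))
  invisible(x)
}

#' Detect the main and minor modes of an insert-size distribution
#'
#' Smooths the insert histogram and reports local maxima. The main peak is
#' the one holding the most mass (ties broken toward the larger insert);
#' a minor peak is reported when another local maximum lies at least 25 per
#' cent of the main-peak location away from it, together with the fraction
#' of pairs closer to it than to the main peak. Short-insert library
#' contamination shows up as a minor peak well below the main one.
#'
#' @param dist An `insert_distribution` with a non-empty histogram.
#' @param bin Histogram bin width in bp (default: range/100, at least 1).
#' @param min_minor_fraction Minimum mass fraction for a minor mode to be
#'   reported (default 0.05); smaller local maxima are treated as
#'   histogram noise.
#' @return A `mode_pair`: list with `main_peak`, `minor_peak` (NA when
#'   unimodal) and `minor_mass_fraction`.
#' @export
detect_modes <- function(dist, bin = NULL, min_minor_fraction = 0.05) {
  h <- dist$hist
  if (is.null(h) || nrow(h) == 0L) stop("empty insert histogram")
  rng <- range(h$insert)
  if (is.null(bin)) bin <- max(1, floor((rng[2] - rng[1]) / 100))
  breaks <- seq(floor(rng[1] / bin) * bin, rng[2] + bin, by = bin)
  idx <- findInterval(h$insert, breaks)
  dens <- tapply(h$count, factor(idx, levels = seq_len(length(breaks))),
                 sum, default = 0)
  dens <- as.numeric(dens)
  centers <- breaks + bin / 2
  sm <- smooth_ma(dens, 5L)
  peaks <- local_maxima(sm)
  peaks <- peaks[dens[peaks] > 0 | sm[peaks] > 0]
  if (length(peaks) == 0L) peaks <- which.max(dens)
  # mass near each peak: pairs closer to this peak than to any other
  peak_loc <- centers[peaks]
  assign_peak <- function(x) peaks[max.col(-abs(outer(x, peak_loc, "-")),
                                           ties.method = "last")]
  pa <- assign_peak(h$insert)
  mass <- vapply(peaks, function(p) sum(h$count[pa == p]), numeric(1))
  ord <- order(mass, peak_loc, decreasing = TRUE)
  main_i <- ord[1]
  main <- peak_loc[main_i]
  minor <- NA_real_
  minor_frac <- 0
  for (i in ord[-1]) {
    frac <- mass[i] / sum(mass)
    if (abs(peak_loc[i] - main) >= 0.25 * main &&
        frac >= min_minor_fraction &&
        sm[peaks[i]] >= 0.05 * sm[peaks[main_i]]) {
      minor <- peak_loc[i]
      minor_frac <- frac
      break
    }
  }
  structure(list(main_peak = main, minor_peak = minor,
                 minor_mass_fraction = minor_frac),
            class = "mode_pair")
}

#' Filter read pairs overlapped by a connecting read
#'
#' Implements the short-insert contaminant filter: a pair is removed when
#' some third read's alignment interval overlaps both of its mate
#' intervals on the same scaffold by at least `min_overlap_bp`. Such a
#' connecting read can only exist when the two mates are close together,
#' i.e. when the pair belongs to a short-insert contaminant mode.
#'
#' @param pairs Pair-alignment data.frame.
#' @param connecting Data.frame of single-read alignments with columns
#'   `scaffold`, `pos`, `end` (0-based half-open).
#' @param min_overlap_bp Minimum overlap with each mate (default 10).
#' @return List with `kept` and `removed` pair data.frames; the two
#'   partition the input.
#' @export
filter_short_insert_pairs <- function(pairs, connecting, min_overlap_bp = 10L) {
  if (nrow(pairs) == 0L || is.null(connecting) || nrow(connecting) == 0L)
    return(list(kept = pairs, removed = pairs[0, , drop = FALSE]))
  removed <- logical(nrow(pairs))
  # same-scaffold mates only; a read cannot connect across scaffolds
  same <- pairs$scaffold_a == pairs$scaffold_b
  for (sc in unique(pairs$scaffold_a[same])) {
    pi <- which(same & pairs$scaffold_a == sc)
    ci <- which(connecting$scaffold == sc)
    if (!length(pi) || !length(ci)) next
    ra <- IRanges::IRanges(start = pairs$pos_a[pi] + 1L, end = pairs$end_a[pi])
    rb <- IRanges::IRanges(start = pairs$pos_b[pi] + 1L, end = pairs$end_b[pi])
    rc <- IRanges::IRanges(start = connecting$pos[ci] + 1L,
                           end = connecting$end[ci])
    ha <- IRanges::findOverlaps(ra, rc, minoverlap = min_overlap_bp)
    hb <- IRanges::findOverlaps(rb, rc, minoverlap = min_overlap_bp)
    ka <- split(S4Vectors::subjectHits(ha), S4Vectors::queryHits(ha))
    kb <- split(S4Vectors::subjectHits(hb), S4Vectors::queryHits(hb))
    common <- intersect(names(ka), names(kb))
    hit <- vapply(common, function(q) length(intersect(ka[[q]], kb[[q]])) > 0,
                  logical(1))
    removed[pi[as.integer(common[hit])]] <- TRUE
  }
  list(kept = pairs[!removed, , drop = FALSE],
       removed = pairs[removed, , drop = FALSE])
}

#' Deduplicate a length spectrum seen at high redundancy
#'
#' Fosmid-end mapping sees each clone length many times over. To recover
#' the underlying clone-length distribution, a length is kept (with weight
#' one) only when it was observed at least `min_count` times; summary
#' statistics are computed on the deduplicated set.
#'
#' @param lengths Numeric vector of observed lengths (bp, >= 0).
#' @param min_count Minimum number of observations for a length to be kept
#'   (default 100).
#' @return List with `hist` (data.frame `length`/`weight`), `mean`, `sd`,
#'   `n_unique`.
#' @export
dedup_length_spectrum <- function(lengths, min_count = 100L) {
  stopifnot(all(lengths >= 0))
  if (length(lengths) == 0L)
    return(list(hist = data.frame(length = numeric(0), weight = numeric(0)),
                mean = NA_real_, sd = NA_real_, n_unique = 0L))
  tab <- table(lengths)
  keep <- as.numeric(names(tab))[as.numeric(tab) >= min_count]
  list(hist = data.frame(length = keep, weight = rep(1, length(keep))),
       mean = if (length(keep)) mean(keep) else NA_real_,
       sd = if (length(keep) > 1L) sd(keep) else NA_real_,
       n_unique = length(keep))
}
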