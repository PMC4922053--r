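#' Merge configuration
#'
#' @param min_overlap Minimum overlap length in bp (default 2400, the
#'   stringent first-round value).
#' @param max_divergence Maximum edit distance over the overlap length
#'   (default 0.015).
#' @param tip_min_overlap Minimum overlap for absorbing dead-end tips
#'   (default 250).
#' @param rounds List of `c(min_overlap, max_divergence)` pairs; defaults
#'   to the two-round schedule 2400 bp / 1.5 pct then 4000 bp / 10 pct
#'   (the second, laxer round merges divergent allelic copies).
#' @param minimizer_k,minimizer_w K-mer size and window for minimizer
#'   candidate detection.
#' @return A `merge_config` list.
#' @export
merge_config <- function(min_overlap = 2400L, max_divergence = 0.015,
                         tip_min_overlap = 250L,
                         rounds = list(c(2400, 0.015), c(4000, 0.10)),
                         minimizer_k = 15L, minimizer_w = 10L) {
  stopifnot(min_overlap >= tip_min_overlap, tip_min_overlap >= 1,
            max_divergence >= 0, max_divergence <= 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_divergence = max_divergence,
                 tip_min_overlap = as.integer(tip_min_overlap),
                 rounds = rounds,
                 minimizer_k = as.integer(minimizer_k),
                 minimizer_w = as.integer(minimizer_w)),
            class = "merge_config")
}

#' Find pairwise overlaps between contigs
#'
#' Candidate contig pairs are detected by shared window minimizers of
#' canonical k-mers; each candidate is then verified by banded
#' edit-distance alignment of the implied overlap region. Only end-dovetail
#' and containment geometries are reported. Reverse-complement overlaps
#' carry `strand = "opposite"` with coordinates given on the original
#' (forward) sequences.
#'
#' @param contigs `DNAStringSet` (or FASTA path) with unique names.
#' @param cfg A `merge_config`; `min_overlap` and `max_divergence` are the
#'   acceptance thresholds.
#' @param min_shared Minimum clustered shared minimizers to attempt
#'   verification (default 3).
#' @return Data.frame of overlaps with columns `contig_a`, `contig_b`,
#'   `a_start`, `a_end`, `b_start`, `b_end` (0-based half-open), `strand`
#'   (`"same"`/`"opposite"`), `length`, `length_b`, `edit_distance`,
#'   `divergence`, `type` (`"dovetail"`, `"contains"` = B inside A,
#'   `"contained"` = A inside B), `diag` (offset of oriented B within A).
#' @export
find_overlaps <- function(contigs, cfg = merge_config(), min_shared = 3L) {
  ctg <- as_assembly(contigs)
  if (anyDuplicated(names(ctg)))
    stop("duplicate contig names in input")
  seqs <- as.character(ctg)
  lens <- nchar(seqs)
  names(lens) <- names(seqs)
  k <- cfg$minimizer_k; w <- cfg$minimizer_w
  mins <- lapply(seq_along(seqs), function(i) {
    m <- minimizers_cpp(seqs[[i]], k, w)
    if (nrow(m)) data.table::data.table(contig = i, pos = m$pos,
                                        hash = m$hash, strand = m$strand)
    else NULL
  })
  mt <- data.table::rbindlist(mins)
  if (is.null(mt) || nrow(mt) == 0L) return(empty_overlaps())
  # drop overly repetitive minimizers (repeat seeds explode the join)
  hash <- NULL; contig <- NULL; N <- NULL  # NSE placators
  mt <- mt[, if (.N <= 200L) .SD, by = hash]
  m2 <- mt
  cand <- merge(mt, m2, by = "hash", allow.cartesian = TRUE,
                suffixes = c("_a", "_b"))
  cand <- cand[cand$contig_a < cand$contig_b, ]
  if (nrow(cand) == 0L) return(empty_overlaps())
  cand$rel <- ifelse(cand$strand_a == cand$strand_b, 1L, -1L)
  cand$diag <- ifelse(cand$rel == 1L, cand$pos_a - cand$pos_b,
                      cand$pos_a + cand$pos_b)
  grp <- cand[, list(n = .N, diags = list(diag)),
              by = c("contig_a", "contig_b", "rel")]
  out <- list()
  for (r in seq_len(nrow(grp))) {
    ds <- sort(grp$diags[[r]])
    if (length(ds) < min_shared) next
    # densest +-100 bp diagonal cluster
    hi <- findInterval(ds + 100, ds)
    lo <- findInterval(ds - 100 - 1e-9, ds) + 1L
    best <- which.max(hi - lo)
    if (hi[best] - lo[best] + 1L < min_shared) next
    d_est <- stats::median(ds[lo[best]:hi[best]])
    ov <- verify_overlap(seqs, lens, grp$contig_a[r], grp$contig_b[r],
                         grp$rel[r], d_est, k, cfg)
    if (!is.null(ov)) out[[length(out) + 1L]] <- ov
  }
  if (!length(out)) return(empty_overlaps())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_overlaps <- function() {
  data.frame(contig_a = character(0), contig_b = character(0),
             a_start = numeric(0), a_end = numeric(0),
             b_start = numeric(0), b_end = numeric(0),
             strand = character(0), length = numeric(0),
             length_b = numeric(0), edit_distance = numeric(0),
             divergence = numeric(0), type = character(0),
             diag = numeric(0))
}

# verify one candidate: ia, ib contig indices, rel strand, diag estimate
# (minimizer-position based). Returns one overlap row or NULL.
verify_overlap <- function(seqs, lens, ia, ib, rel, d_est, k, cfg) {
  a <- seqs[[ia]]; la <- lens[[ia]]; lb <- lens[[ib]]
  bor <- if (rel == 1L) seqs[[ib]] else rc_chr(seqs[[ib]])
  # offset of oriented B within A coordinates
  d <- if (rel == 1L) round(d_est) else round(d_est + k - lb)
  ovs_a <- max(0, d); ove_a <- min(la, d + lb)
  L <- ove_a - ovs_a
  if (L < cfg$min_overlap) return(NULL)
  bs <- ovs_a - d; be <- ove_a - d
  sa <- substr(a, ovs_a + 1L, ove_a)
  sb <- substr(bor, bs + 1L, be)
  if (sa == sb) {
    ed <- 0L
  } else {
    band <- max(32L, as.integer(ceiling(cfg$max_divergence * L)) + 16L)
    ed <- banded_edit_cpp(sa, sb, band)
    if (ed < 0) ed <- banded_edit_cpp(sa, sb, band * 4L)
    if (ed < 0) return(NULL)
  }
  div <- ed / L
  if (div > cfg$max_divergence) return(NULL)
  type <- if (d >= 0 && d + lb <= la) "contains"
          else if (d <= 0 && d + lb >= la) "contained"
          else "dovetail"
  # map oriented-B coordinates back to the original strand
  if (rel == 1L) { b0 <- bs; b1 <- be } else { b0 <- lb - be; b1 <- lb - bs }
  nm <- names(lens)
  data.frame(contig_a = nm[ia], contig_b = nm[ib],
             a_start = ovs_a, a_end = ove_a, b_start = b0, b_end = b1,
             strand = if (rel == 1L) "same" else "opposite",
             length = L, length_b = be - bs,
             edit_distance = ed, divergence = div, type = type,
             diag = d, stringsAsFactors = FALSE)
}
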