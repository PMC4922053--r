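#' Build a k-mer spectrum from reads
#'
#' Counts canonical k-mers (the lexicographic minimum of each k-mer and its
#' reverse complement) across a read set and tabulates how many distinct
#' k-mer species occur at each multiplicity. The resulting spectrum is the
#' basis for genome-size and heterozygosity estimation: in a diploid sample
#' the homozygous peak sits at the sequencing k-mer depth and the
#' heterozygous peak at roughly half that depth.
#'
#' @param reads A `DNAStringSet`, character vector of sequences, or a path
#'   to a FASTA/FASTQ file (optionally gzipped).
#' @param k Odd k-mer length between 3 and 31. K-mers containing non-ACGT
#'   bases are skipped.
#' @return A `kmer_spectrum` object: list with `k`, `hist` (data.frame with
#'   columns `multiplicity`, `count`), `total_kmers` (number of counted
#'   k-mer instances) and `n_species`.
#' @examples
#' spec <- count_kmers(c("ACGTACGT"), k = 3)
#' spec$total_kmers  # 6
#' @export
count_kmers <- function(reads, k = 17L) {
  k <- as.integer(k)
  if (k < 3L || k > 31L || k %% 2L == 0L)
    stop("k must be odd and in [3, 31]")
  seqs <- read_seqs(reads)
  if (length(seqs) == 0L) stop("empty input: no sequences to count")
  res <- kmer_count_cpp(as.character(seqs), k)
  if (res$total == 0)
    stop("empty spectrum: no k-mer fits in any read (k too large?)")
  ord <- order(res$multiplicity)
  hist <- data.frame(multiplicity = res$multiplicity[ord],
                     count = res$count[ord])
  new_kmer_spectrum(k, hist)
}

new_kmer_spectrum <- function(k, hist) {
  stopifnot(all(hist$multiplicity >= 1), all(hist$count >= 0))
  total <- sum(hist$multiplicity * hist$count)
  structure(list(k = as.integer(k), hist = hist, total_kmers = total,
                 n_species = sum(hist$count)),
            class = "kmer_spectrum")
}

#' Construct a k-mer spectrum from a precomputed histogram
#'
#' @param multiplicity Integer vector of k-mer depths (>= 1).
#' @param count Number of distinct k-mer species at each depth.
#' @param k K-mer length the histogram was computed with.
#' @return A `kmer_spectrum`.
#' @export
kmer_spectrum <- function(multiplicity, count, k = 17L) {
  stopifnot(length(multiplicity) == length(count))
  ord <- order(multiplicity)
  new_kmer_spectrum(k, data.frame(multiplicity = as.numeric(multiplicity)[ord],
                                  count = as.numeric(count)[ord]))
}

#' Read a two-column multiplicity/count histogram file
#'
#' @param path Tab-separated file with columns multiplicity and count
#'   (no header).
#' @param k K-mer length to record on the spectrum.
#' @return A `kmer_spectrum`.
#' @export
read_kmer_histogram <- function(path, k = 17L) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    col.names = c("multiplicity", "count"))
  kmer_spectrum(tab$multiplicity, tab$count, k = k)
}

#' Write a spectrum histogram to a TSV file
#' @param spec A `kmer_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_histogram <- function(spec, path) {
  write.table(spec$hist, path, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("kmer_spectrum: k=%d, %.0f species, %.0f kmer instances\n",
              x$k, x$n_species, x$total_kmers))
  invisible(x)
}

# dense count vector over depths 1..max
dense_hist <- function(spec) {
  maxd <- max(spec$hist$multiplicity)
  dense <- numeric(maxd)
  dense[spec$hist$multiplicity] <- spec$hist$count
  dense
}

#' Detect error, heterozygous and homozygous peaks in a k-mer spectrum
#'
#' The histogram is smoothed with a centred moving average (window 3), the
#' error cutoff is placed at the first local minimum above depth 1 (falling
#' back to `min_depth` when the histogram is monotone there), the homozygous
#' peak is the global mode above the cutoff, and a heterozygous peak is
#' reported when a local maximum exists within `[0.35, 0.65]` times the
#' homozygous depth.
#'
#' @param spec A `kmer_spectrum`.
#' @param min_depth Fallback error cutoff when no local minimum exists
#'   (default 3).
#' @return A `peak_set`: list with `error_cutoff`, `hom_depth`, `het_depth`
#'   (NA when absent) and `peak_heights`.
#' @export
detect_peaks <- function(spec, min_depth = 3L) {
  stopifnot(inherits(spec, "kmer_spectrum"))
  dense <- dense_hist(spec)
  if (length(dense) == 0L || sum(dense) == 0) stop("empty spectrum")
  sm <- smooth_ma(dense, 3L)
  # error cutoff: first local minimum above depth 1
  cutoff <- NA_integer_
  if (length(sm) >= 3L) {
    for (d in 2:(length(sm) - 1L)) {
      if (sm[d] <= sm[d - 1L] && sm[d] <= sm[d + 1L]) { cutoff <- d; break }
    }
  }
  if (is.na(cutoff)) cutoff <- as.integer(min_depth)
  above <- seq_along(sm) > cutoff
  if (!any(above)) stop("no signal: spectrum has no mass above the error cutoff")
  lm_idx <- local_maxima(sm)
  lm_idx <- lm_idx[lm_idx > cutoff]
  # a flat (uniform) histogram has no interior maximum above the cutoff
  if (length(lm_idx) == 0L ||
      (length(unique(round(sm[above], 9))) == 1L && sum(above) > 2L))
    stop("no signal: no peak above the error cutoff")
  hom <- lm_idx[which.max(sm[lm_idx])]
  # in highly heterozygous samples the het peak can out-mass the hom peak:
  # when a substantial local maximum sits at ~2x the global mode, the mode
  # is the het peak and the doubled depth is the hom peak
  twice <- lm_idx[hom >= 0.35 * lm_idx & hom <= 0.65 * lm_idx &
                    sm[lm_idx] >= 0.25 * sm[hom]]
  if (length(twice)) hom <- twice[which.max(sm[twice])]
  # heterozygous peak: local maximum at roughly half the homozygous depth
  win <- lm_idx[lm_idx >= 0.35 * hom & lm_idx <= 0.65 * hom]
  het <- if (length(win)) win[which.max(sm[win])] else NA_integer_
  structure(list(error_cutoff = as.integer(cutoff),
                 hom_depth = as.integer(hom),
                 het_depth = as.integer(het),
                 peak_heights = c(hom = dense[hom],
                                  het = if (is.na(het)) NA_real_ else dense[het])),
            class = "peak_set")
}

#' Estimate genome size from a k-mer spectrum
#'
#' Genome size is the total number of counted k-mer instances divided by the
#' depth of the homozygous (main) peak, the classic total/peak estimator.
#'
#' @param spec A `kmer_spectrum`.
#' @param peaks A `peak_set` from [detect_peaks()], or a list with
#'   `hom_depth`.
#' @return A `genome_size_estimate`: list with `size_bp`, `method`,
#'   `het_ratio` (NA here).
#' @examples
#' spec <- kmer_spectrum(10, 100)
#' estimate_genome_size(spec, list(hom_depth = 10))$size_bp  # 100
#' @export
estimate_genome_size <- function(spec, peaks) {
  stopifnot(inherits(spec, "kmer_spectrum"))
  hom <- peaks$hom_depth
  if (is.null(hom) || is.na(hom) || hom <= 0)
    stop("homozygous peak depth must be positive")
  structure(list(size_bp = spec$total_kmers / hom,
                 method = "total/peak", het_ratio = NA_real_),
            class = "genome_size_estimate")
}

#' Approximate the heterozygous k-mer fraction and corrected genome size
#'
#' Fits a two-component Gaussian mixture to the smoothed spectrum above the
#' error cutoff, with component means fixed at the heterozygous and
#' homozygous peak depths and free masses and widths. The heterozygosity
#' proxy is the heterozygous component's share of the fitted non-error
#' species mass. The corrected genome size counts heterozygous-component
#' k-mer instances at half weight before dividing by the homozygous depth,
#' since each heterozygous site contributes two k-mer species from one
#' genomic locus.
#'
#' @param spec A `kmer_spectrum`.
#' @param peaks A `peak_set`; when `het_depth` is absent the function
#'   returns `het_ratio = 0` with a warning.
#' @return A `genome_size_estimate` with `method = "mixture"` and
#'   `het_ratio` populated.
#' @export
estimate_het_ratio <- function(spec, peaks) {
  stopifnot(inherits(spec, "kmer_spectrum"))
  hom <- peaks$hom_depth
  het <- peaks$het_depth
  if (is.null(het) || is.na(het)) {
    warning("no heterozygous peak: het_ratio set to 0")
    sz <- estimate_genome_size(spec, peaks)
    sz$method <- "mixture"
    sz$het_ratio <- 0
    return(sz)
  }
  dense <- dense_hist(spec)
  cutoff <- peaks$error_cutoff
  d <- seq_along(dense)
  use <- d > cutoff & dense > 0
  dd <- d[use]; cc <- dense[use]
  gauss <- function(x, mu, sg) exp(-0.5 * ((x - mu) / sg)^2)
  obj <- function(p) {
    a1 <- exp(p[1]); a2 <- exp(p[2]); s1 <- exp(p[3]); s2 <- exp(p[4])
    sum((cc - a1 * gauss(dd, het, s1) - a2 * gauss(dd, hom, s2))^2)
  }
  init <- c(log(max(dense[het], 1)), log(max(dense[hom], 1)),
            log(max(het / 4, 1)), log(max(hom / 4, 1)))
  fit <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  a1 <- exp(fit$par[1]); a2 <- exp(fit$par[2])
  s1 <- exp(fit$par[3]); s2 <- exp(fit$par[4])
  mass_het <- a1 * s1 * sqrt(2 * pi)
  mass_hom <- a2 * s2 * sqrt(2 * pi)
  het_ratio <- mass_het / (mass_het + mass_hom)
  het_ratio <- min(max(het_ratio, 0), 1)
  # per-depth responsibility of the het component, for the size correction
  r1 <- a1 * gauss(dd, het, s1)
  r2 <- a2 * gauss(dd, hom, s2)
  resp <- ifelse(r1 + r2 > 0, r1 / (r1 + r2), 0)
  inst <- dd * cc
  het_inst <- sum(inst * resp)
  nonerr_inst <- sum(inst)
  structure(list(size_bp = (nonerr_inst - 0.5 * het_inst) / hom,
                 method = "mixture", het_ratio = het_ratio),
            class = "genome_size_estimate")
}

#' Convert a C-value (pg of haploid DNA) to base pairs
#'
#' Uses the standard conversion 1 pg = 978 Mbp.
#'
#' @param cvalue C-value in picograms; must be positive.
#' @return Genome length in base pairs.
#' @examples
#' round(cvalue_to_bp(1.59) / 1e9, 2)  # 1.56 Gb
#' @export
cvalue_to_bp <- function(cvalue) {
  if (any(!is.finite(cvalue)) || any(cvalue <= 0))
    stop("C-value must be positive")
  cvalue * 978e6
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf("genome size estimate (%s): %.1f bp (%.2f Gb)", x$method,
              x$size_bp, x$size_bp / 1e9))
  if (!is.na(x$het_ratio)) cat(sprintf(", het ratio %.3f", x$het_ratio))
  cat("\n")
  invisible(x)
}

#' Profile a spectrum: peaks, genome size, heterozygosity in one report
#'
#' @param spec A `kmer_spectrum`.
#' @param min_depth Passed to [detect_peaks()].
#' @return List with `k`, `peaks`, `total_kmers`, `size_bp`, `het_ratio`.
#' @export
profile_spectrum <- function(spec, min_depth = 3L) {
  peaks <- detect_peaks(spec, min_depth = min_depth)
  size <- estimate_genome_size(spec, peaks)
  hetr <- if (!is.na(peaks$het_depth))
    estimate_het_ratio(spec, peaks)$het_ratio else 0
  list(k = spec$k, peaks = peaks, total_kmers = spec$total_kmers,
       size_bp = size$size_bp, het_ratio = hetr)
}

# read FASTA/FASTQ/character into DNAStringSet
read_seqs <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    first <- substr(readLines(if (grepl("\\.gz$", x)) gzfile(x) else x,
                              n = 1L), 1L, 1L)
    if (identical(first, "@"))
      return(Biostrings::readDNAStringSet(x, format = "fastq"))
    return(Biostrings::readDNAStringSet(x))
  }
  if (is.character(x)) {
    if (length(x) == 0L) stop("empty input: no sequences")
    return(Biostrings::DNAStringSet(x))
  }
  stop("unsupported read input")
}
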