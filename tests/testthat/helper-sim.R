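# shared test helpers: tiny generators and independent oracles

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

mutate_seq <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  idx <- which(stats::runif(length(ch)) < rate)
  ch[idx] <- vapply(ch[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  paste(ch, collapse = "")
}

n50 <- function(w) {
  w <- sort(w, decreasing = TRUE)
  w[which(cumsum(w) >= sum(w) / 2)[1]]
}

# brute-force canonical kmer spectrum via substring + Biostrings revcomp;
# independent of the package's rolling-hash counter
brute_spectrum <- function(reads, k) {
  kmers <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(character(0))
    substring(r, 1:(n - k + 1), k:n)
  }))
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  rcs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  canon <- ifelse(kmers <= rcs, kmers, rcs)
  counts <- table(canon)
  hist <- table(as.integer(counts))
  data.frame(multiplicity = as.integer(names(hist)),
             count = as.numeric(hist))
}

# ends-free full-DP overlap oracle built on Biostrings::pairwiseAlignment;
# returns sorted "a b" keys of accepted unordered pairs
overlap_oracle <- function(ctgs, min_overlap, max_div) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3,
                                                  baseOnly = TRUE)
  nm <- names(ctgs)
  out <- character(0)
  for (i in seq_len(length(ctgs) - 1L)) for (j in (i + 1L):length(ctgs)) {
    ok <- FALSE
    for (orient in 1:2) {
      B <- if (orient == 1) ctgs[[j]]
           else Biostrings::reverseComplement(ctgs[[j]])
      pa <- Biostrings::pairwiseAlignment(ctgs[[i]], B, type = "overlap",
                                          substitutionMatrix = mat,
                                          gapOpening = 5, gapExtension = 3)
      w <- nchar(as.character(Biostrings::pattern(pa)))
      ed <- Biostrings::nmismatch(pa) +
        Biostrings::nindel(pa)@insertion[, "WidthSum"] +
        Biostrings::nindel(pa)@deletion[, "WidthSum"]
      if (w >= min_overlap && ed / w <= max_div) ok <- TRUE
    }
    if (ok) out <- c(out, paste(nm[i], nm[j]))
  }
  sort(out)
}

# per-base depth oracle for clone pools (small genomes only)
pool_stats_oracle <- function(pool) {
  G <- pool$G
  depth <- integer(G); dA <- integer(G); dB <- integer(G)
  for (i in seq_len(nrow(pool$clones))) {
    cl <- pool$clones[i, ]
    idx <- (cl$start + 1L):cl$end
    depth[idx] <- depth[idx] + 1L
    if (cl$haplotype == "A") dA[idx] <- dA[idx] + 1L
    else dB[idx] <- dB[idx] + 1L
  }
  total <- sum(pool$clones$length)
  list(covered_fraction = sum(depth >= 1) / G,
       overlapped_base_fraction = sum(depth[depth >= 2]) / total,
       redundant_base_fraction = sum(pmax(depth - 1L, 0L)) / total,
       cross_hap_fraction = if (any(depth >= 2))
         sum(depth >= 2 & dA >= 1 & dB >= 1) / sum(depth >= 2) else 0)
}

# tiling contigs with guaranteed overlaps, for merge tests
tile_contigs <- function(genome, step, width, prefix = "c") {
  starts <- seq(0, nchar(genome) - width, by = step)
  seqs <- vapply(starts, function(s) substr(genome, s + 1, s + width), "")
  Biostrings::DNAStringSet(setNames(seqs, paste0(prefix, seq_along(starts))))
}

write_test_sam <- function(lines, ref = c(ref1 = 1000L)) {
  path <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref), ref))
  writeLines(c(hdr, lines), path)
  path
}
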