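# Synthetic-data generators: diploid genomes, fosmid clone pools, paired
# reads with bimodal insert contamination, and misjoin injection with
# truth breakpoints. All generators are deterministic under a fixed seed.

#' Simulate a diploid genome with known heterozygous sites
#'
#' Haplotype B is haplotype A with substitutions at Bernoulli(`het_rate`)
#' sites; repeats are emulated by copying a repeat unit over random
#' positions of haplotype A (before heterozygosity is applied) until
#' `repeat_fraction` of the length is repeat-derived. Substitution-only
#' heterozygosity keeps truth coordinates identical between haplotypes.
#'
#' @param length Genome length in bp (>= 1000).
#' @param het_rate Per-base heterozygosity probability in `[0, 0.2]`.
#' @param repeat_fraction Fraction of the genome covered by a duplicated
#'   repeat family (default 0).
#' @param seed Integer seed; the output is fully reproducible.
#' @return A `diploid_genome`: list with `hapA`, `hapB` (character),
#'   `truth` (data.frame `pos` 0-based, `allele_a`, `allele_b`),
#'   `repeats` (data.frame of inserted copy positions), `seed`.
#' @export
simulate_diploid <- function(length, het_rate = 0.01, repeat_fraction = 0,
                             seed = 1L) {
  if (length < 1000) stop("genome length must be >= 1 kb")
  if (het_rate < 0 || het_rate > 0.2) stop("het_rate must be in [0, 0.2]")
  if (repeat_fraction < 0 || repeat_fraction >= 1)
    stop("repeat_fraction must be in [0, 1)")
  set.seed(seed)
  hapA <- random_dna(length)
  repeats <- data.frame(start = numeric(0), end = numeric(0))
  if (repeat_fraction > 0) {
    unit_len <- min(2000L, max(200L, as.integer(length * 0.01)))
    unit <- random_dna(unit_len)
    n_copies <- max(2L, ceiling(repeat_fraction * length / unit_len))
    starts <- sort(sample.int(length - unit_len, n_copies))
    for (s in starts) {
      substr(hapA, s + 1L, s + unit_len) <- unit
    }
    repeats <- data.frame(start = starts, end = starts + unit_len)
  }
  n_het <- rbinom(1L, length, het_rate)
  truth <- data.frame(pos = integer(0), allele_a = character(0),
                      allele_b = character(0))
  hapB <- hapA
  if (n_het > 0) {
    pos <- sort(sample.int(length, n_het)) - 1L
    a <- substring(hapA, pos + 1L, pos + 1L)
    bases <- c("A", "C", "G", "T")
    b <- vapply(a, function(x) sample(setdiff(bases, x), 1L), character(1),
                USE.NAMES = FALSE)
    hb <- strsplit(hapB, "")[[1]]
    hb[pos + 1L] <- b
    hapB <- paste(hb, collapse = "")
    truth <- data.frame(pos = pos, allele_a = a, allele_b = b,
                        stringsAsFactors = FALSE)
  }
  structure(list(hapA = hapA, hapB = hapB, truth = truth,
                 repeats = repeats, seed = seed),
            class = "diploid_genome")
}

#' Simulate a fosmid clone pool
#'
#' Clone starts are uniform on the genome; clone lengths are
#' Normal(`insert_mean`, `insert_sd`) truncated at 1 kb. For a diploid
#' genome each clone carries one haplotype chosen uniformly. Defaults
#' mirror a 1,600-clone pool on a 1.38 Gb genome with a 36.7 kb +/- 4.97
#' kb clone-length distribution.
#'
#' @param G Genome length in bp.
#' @param n_clones Number of clones (default 1600).
#' @param insert_mean,insert_sd Clone-length distribution (bp; defaults
#'   36700 and 4970).
#' @param diploid Draw a haplotype per clone (default TRUE).
#' @param seed Integer seed.
#' @return A `clone_pool`: list with `G`, `clones` (data.frame `start`,
#'   `length`, `end`, `haplotype`), `n_clones`, `insert_mean`,
#'   `insert_sd`, `seed`.
#' @export
simulate_pool <- function(G, n_clones = 1600L, insert_mean = 36700,
                          insert_sd = 4970, diploid = TRUE, seed = 1L) {
  if (n_clones < 0) stop("n_clones must be >= 0")
  if (insert_mean >= G) stop("insert_mean must be smaller than the genome")
  set.seed(seed)
  if (n_clones == 0L) {
    clones <- data.frame(start = numeric(0), length = numeric(0),
                         end = numeric(0), haplotype = character(0))
  } else {
    len <- pmax(1000, round(rnorm(n_clones, insert_mean, insert_sd)))
    start <- floor(runif(n_clones, 0, G - len))
    hap <- if (diploid) sample(c("A", "B"), n_clones, replace = TRUE)
           else rep("A", n_clones)
    clones <- data.frame(start = start, length = len, end = start + len,
                         haplotype = hap, stringsAsFactors = FALSE)
  }
  structure(list(G = G, clones = clones, n_clones = n_clones,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 seed = seed),
            class = "clone_pool")
}

#' Overlap statistics of a clone pool
#'
#' Computed with an endpoint sweep (no per-base arrays), so pools on
#' gigabase genomes run in milliseconds. `covered_fraction` is the genome
#' fraction under at least one clone; `overlapped_base_fraction` is the
#' fraction of sequenced clone bases lying at positions covered by two or
#' more clones; `redundant_base_fraction` counts `(k-1)/k` of clone bases
#' at depth `k` (the bases that are pure re-sequencing);
#' `cross_hap_fraction` is, among genomic positions at depth >= 2, the
#' fraction covered by clones from both haplotypes.
#'
#' @param pool A `clone_pool`.
#' @return A `pool_stats` list with the four fractions plus
#'   `total_clone_bases`.
#' @export
pool_stats <- function(pool) {
  cl <- pool$clones
  if (nrow(cl) == 0L)
    return(structure(list(covered_fraction = 0, overlapped_base_fraction = 0,
                          redundant_base_fraction = 0, cross_hap_fraction = 0,
                          total_clone_bases = 0), class = "pool_stats"))
  ev_pos <- c(cl$start, cl$end)
  ev_all <- c(rep(1, nrow(cl)), rep(-1, nrow(cl)))
  ev_a <- ev_all * as.numeric(c(cl$haplotype, cl$haplotype) == "A")
  ev_b <- ev_all * as.numeric(c(cl$haplotype, cl$haplotype) == "B")
  ord <- order(ev_pos)
  pos <- ev_pos[ord]
  d_all <- cumsum(ev_all[ord])
  d_a <- cumsum(ev_a[ord])
  d_b <- cumsum(ev_b[ord])
  seg_len <- diff(pos)
  depth <- d_all[-length(d_all)]
  da <- d_a[-length(d_a)]
  db <- d_b[-length(d_b)]
  total <- sum(cl$length)
  covered <- sum(seg_len[depth >= 1]) / pool$G
  overlapped <- sum(seg_len[depth >= 2] * depth[depth >= 2]) / total
  redundant <- sum(seg_len[depth >= 1] * (depth[depth >= 1] - 1)) / total
  d2 <- depth >= 2
  cross <- if (any(d2)) sum(seg_len[d2 & da >= 1 & db >= 1]) /
    sum(seg_len[d2]) else 0
  structure(list(covered_fraction = covered,
                 overlapped_base_fraction = overlapped,
                 redundant_base_fraction = redundant,
                 cross_hap_fraction = cross,
                 total_clone_bases = total),
            class = "pool_stats")
}

#' Lander-Waterman covered fraction
#'
#' Expected genome fraction covered by `n` random clones of length `L` on
#' a genome of size `G`: `1 - exp(-nL/G)`.
#'
#' @param n Number of clones.
#' @param L Clone length (bp).
#' @param G Genome length (bp).
#' @return Covered fraction in `[0, 1]`.
#' @examples
#' lw_covered_fraction(1600, 36700, 1.38e9)  # ~0.0417
#' @export
lw_covered_fraction <- function(n, L, G) {
  stopifnot(G > 0)
  1 - exp(-n * L / G)
}

#' Lander-Waterman redundant base fraction
#'
#' Closed-form expectation of [pool_stats()]'s `redundant_base_fraction`
#' for Poisson clone coverage `c = nL/G`: `1 - (1 - exp(-c))/c`.
#'
#' @inheritParams lw_covered_fraction
#' @return Expected redundant fraction of sequenced clone bases.
#' @export
lw_redundant_fraction <- function(n, L, G) {
  c <- n * L / G
  if (c == 0) return(0)
  1 - (1 - exp(-c)) / c
}

#' Simulate paired reads with a configurable insert mixture
#'
#' Fragments are drawn from the genome (haplotype chosen per fragment for
#' a diploid input) with lengths from a main Normal component plus an
#' optional minor short-insert component, emulating bimodal
#' insert-contaminated libraries. Mates are emitted in FR orientation for
#' `type = "PE"` and RF for `type = "MP"`. Truth alignments (a
#' pair-alignment data.frame in genome coordinates) are returned
#' alongside the reads.
#'
#' @param genome A `diploid_genome`, `DNAStringSet`, or named character
#'   vector of scaffold sequences.
#' @param n_pairs Number of read pairs.
#' @param type `"PE"` (FR) or `"MP"` (RF).
#' @param insert_mean,insert_sd Main insert component (bp).
#' @param minor_insert_mean Optional short-insert contaminant mode (bp).
#' @param minor_fraction Fraction of pairs from the minor mode
#'   (default 0).
#' @param read_len Read length (default 150).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param seed Integer seed.
#' @return A `read_sim`: list with `r1`, `r2` (named character vectors of
#'   read sequences), `truth` (pair-alignment data.frame with extra
#'   columns `insert`, `minor`, `haplotype`), and the library parameters.
#' @export
simulate_reads <- function(genome, n_pairs, type = c("PE", "MP"),
                           insert_mean = 725, insert_sd = 60,
                           minor_insert_mean = NULL, minor_fraction = 0,
                           read_len = 150L, error_rate = 0, seed = 1L) {
  type <- match.arg(type)
  if (inherits(genome, "diploid_genome")) {
    scafs <- list(A = c(chr1 = genome$hapA), B = c(chr1 = genome$hapB))
    diploid <- TRUE
  } else {
    sq <- if (methods::is(genome, "DNAStringSet"))
      setNames(as.character(genome), names(genome)) else genome
    if (is.null(names(sq))) names(sq) <- paste0("seq", seq_along(sq))
    scafs <- list(A = sq)
    diploid <- FALSE
  }
  if (read_len >= insert_mean)
    stop("infeasible geometry: read_len must be below insert_mean")
  if (minor_fraction > 0 && is.null(minor_insert_mean))
    stop("minor_fraction > 0 requires minor_insert_mean")
  set.seed(seed)
  if (n_pairs == 0L) {
    truth <- pair_alignments(character(0), character(0), numeric(0),
                             numeric(0), character(0), character(0),
                             numeric(0), numeric(0), character(0),
                             integer(0), integer(0))
    truth$insert <- numeric(0); truth$minor <- logical(0)
    truth$haplotype <- character(0)
    return(structure(list(r1 = character(0), r2 = character(0),
                          truth = truth, type = type, seed = seed),
                     class = "read_sim"))
  }
  lens <- vapply(scafs$A, nchar, numeric(1))
  minor <- runif(n_pairs) < minor_fraction
  ins <- ifelse(minor,
                round(rnorm(n_pairs, minor_insert_mean %||% insert_mean,
                            (minor_insert_mean %||% insert_mean) * 0.1)),
                round(rnorm(n_pairs, insert_mean, insert_sd)))
  ins <- pmax(ins, read_len + 10L)
  sci <- sample.int(length(lens), n_pairs, replace = TRUE,
                    prob = lens / sum(lens))
  maxstart <- lens[sci] - ins
  ok <- maxstart >= 0
  ins[!ok] <- pmin(ins[!ok], lens[sci[!ok]])
  maxstart <- pmax(lens[sci] - ins, 0)
  start <- floor(runif(n_pairs, 0, maxstart + 1))
  hap <- if (diploid) sample(c("A", "B"), n_pairs, replace = TRUE)
         else rep("A", n_pairs)
  frag <- vapply(seq_len(n_pairs), function(i) {
    substr(scafs[[hap[i]]][[sci[i]]], start[i] + 1L, start[i] + ins[i])
  }, character(1))
  left <- substr(frag, 1L, read_len)
  right_fwd <- substr(frag, ins - read_len + 1L, ins)
  right <- rc_chr(right_fwd)
  if (type == "PE") { r1 <- left; r2 <- right } else {
    r1 <- rc_chr(left); r2 <- right_fwd
  }
  if (error_rate > 0) {
    mutate <- function(x) {
      vapply(x, function(s) {
        n <- nchar(s)
        nm <- rbinom(1L, n, error_rate)
        if (nm == 0L) return(s)
        ch <- strsplit(s, "")[[1]]
        at <- sample.int(n, nm)
        ch[at] <- vapply(ch[at], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    r1 <- mutate(r1); r2 <- mutate(r2)
  }
  ids <- sprintf("pair%06d", seq_len(n_pairs))
  names(r1) <- paste0(ids, "/1"); names(r2) <- paste0(ids, "/2")
  scn <- names(lens)[sci]
  s1 <- if (type == "PE") "+" else "-"
  s2 <- if (type == "PE") "-" else "+"
  truth <- pair_alignments(
    read_id = ids,
    scaffold_a = scn, pos_a = start, end_a = start + read_len, strand_a = s1,
    scaffold_b = scn, pos_b = start + ins - read_len, end_b = start + ins,
    strand_b = s2)
  truth$insert <- ins
  truth$minor <- minor
  truth$haplotype <- hap
  structure(list(r1 = r1, r2 = r2, truth = truth, type = type, seed = seed),
            class = "read_sim")
}

#' Inject misjoins into an assembly, recording truth breakpoints
#'
#' Performs `n_misjoins` random cut-and-swap events: two distinct
#' scaffolds are cut at interior positions and their tails exchanged.
#' The returned block map allows lifting coordinates from the original to
#' the misjoined assembly, and the truth table records every junction in
#' output coordinates.
#'
#' @param assembly `DNAStringSet`, FASTA path, or named character vector
#'   (needs at least two scaffolds).
#' @param n_misjoins Number of cut-and-swap events.
#' @param seed Integer seed.
#' @param margin Minimum distance of a cut from a scaffold end
#'   (default 5000).
#' @return List with `assembly` (misjoined `DNAStringSet`), `junctions`
#'   (data.frame `scaffold`, `pos` in output coordinates), and `blocks`
#'   (data.frame mapping output intervals back to source scaffold
#'   intervals, for coordinate liftover).
#' @export
inject_misjoins <- function(assembly, n_misjoins, seed = 1L,
                            margin = 5000L) {
  asm <- as_assembly(assembly)
  seqs <- as.character(asm)
  if (n_misjoins > 0 && length(seqs) < 2L)
    stop("need at least two scaffolds to swap tails")
  # block list per scaffold: source intervals in original coordinates
  blocks <- lapply(names(seqs), function(sc)
    data.frame(src = sc, src_start = 0, src_end = nchar(seqs[[sc]]),
               stringsAsFactors = FALSE))
  names(blocks) <- names(seqs)
  set.seed(seed)
  if (n_misjoins > 0 &&
      any(vapply(seqs, nchar, numeric(1)) < 2 * margin + 2))
    stop("n_misjoins too large for these scaffold lengths (margin)")
  for (ev in seq_len(n_misjoins)) {
    pick <- sample(names(seqs), 2L)
    s1 <- seqs[[pick[1]]]; s2 <- seqs[[pick[2]]]
    c1 <- sample(seq(margin, nchar(s1) - margin), 1L)
    c2 <- sample(seq(margin, nchar(s2) - margin), 1L)
    seqs[[pick[1]]] <- paste0(substr(s1, 1, c1), substr(s2, c2 + 1,
                                                        nchar(s2)))
    seqs[[pick[2]]] <- paste0(substr(s2, 1, c2), substr(s1, c1 + 1,
                                                        nchar(s1)))
    split_blocks <- function(bl, cut) {
      # split a scaffold's block list at output coordinate `cut`
      off <- 0; head_bl <- list(); tail_bl <- list()
      for (i in seq_len(nrow(bl))) {
        b <- bl[i, ]
        blen <- b$src_end - b$src_start
        if (off + blen <= cut) head_bl[[length(head_bl) + 1L]] <- b
        else if (off >= cut) tail_bl[[length(tail_bl) + 1L]] <- b
        else {
          at <- cut - off
          head_bl[[length(head_bl) + 1L]] <-
            data.frame(src = b$src, src_start = b$src_start,
                       src_end = b$src_start + at)
          tail_bl[[length(tail_bl) + 1L]] <-
            data.frame(src = b$src, src_start = b$src_start + at,
                       src_end = b$src_end)
        }
        off <- off + blen
      }
      list(head = do.call(rbind, head_bl), tail = do.call(rbind, tail_bl))
    }
    sp1 <- split_blocks(blocks[[pick[1]]], c1)
    sp2 <- split_blocks(blocks[[pick[2]]], c2)
    blocks[[pick[1]]] <- rbind(sp1$head, sp2$tail)
    blocks[[pick[2]]] <- rbind(sp2$head, sp1$tail)
  }
  # junctions = interior block boundaries in output coordinates
  junctions <- list()
  block_map <- list()
  for (sc in names(blocks)) {
    bl <- blocks[[sc]]
    blen <- bl$src_end - bl$src_start
    out_end <- cumsum(blen)
    out_start <- out_end - blen
    block_map[[sc]] <- data.frame(scaffold = sc, out_start = out_start,
                                  out_end = out_end, src = bl$src,
                                  src_start = bl$src_start,
                                  src_end = bl$src_end,
                                  stringsAsFactors = FALSE)
    if (nrow(bl) > 1L)
      junctions[[sc]] <- data.frame(scaffold = sc,
                                    pos = out_end[-length(out_end)])
  }
  out <- Biostrings::DNAStringSet(seqs)
  jdf <- if (length(junctions)) do.call(rbind, junctions)
         else data.frame(scaffold = character(0), pos = numeric(0))
  rownames(jdf) <- NULL
  bmap <- do.call(rbind, block_map)
  rownames(bmap) <- NULL
  list(assembly = out, junctions = jdf, blocks = bmap)
}

#' Lift pair alignments from source to misjoined coordinates
#'
#' Maps each mate of a truth pair table (coordinates on the original
#' assembly) through the block map of [inject_misjoins()]. Mates
#' straddling a block boundary are dropped (in real data they would align
#' partially); mates landing on different output scaffolds or at shuffled
#' distances become the discordant evidence the consistency check relies
#' on.
#'
#' @param pairs Pair-alignment data.frame in source coordinates.
#' @param blocks Block map from [inject_misjoins()].
#' @return Pair-alignment data.frame in misjoined-assembly coordinates.
#' @export
liftover_pairs <- function(pairs, blocks) {
  lift <- function(scaf, pos, end) {
    out_sc <- rep(NA_character_, length(pos))
    delta <- rep(NA_real_, length(pos))
    for (i in seq_len(nrow(blocks))) {
      sel <- scaf == blocks$src[i] & pos >= blocks$src_start[i] &
        end <= blocks$src_end[i]
      out_sc[sel] <- blocks$scaffold[i]
      delta[sel] <- blocks$out_start[i] - blocks$src_start[i]
    }
    list(sc = out_sc, pos = pos + delta, end = end + delta)
  }
  a <- lift(pairs$scaffold_a, pairs$pos_a, pairs$end_a)
  b <- lift(pairs$scaffold_b, pairs$pos_b, pairs$end_b)
  keep <- !is.na(a$sc) & !is.na(b$sc)
  out <- pairs[keep, , drop = FALSE]
  out$scaffold_a <- a$sc[keep]; out$pos_a <- a$pos[keep]
  out$end_a <- a$end[keep]
  out$scaffold_b <- b$sc[keep]; out$pos_b <- b$pos[keep]
  out$end_b <- b$end[keep]
  rownames(out) <- NULL
  out
}
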