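# SAM/BAM boundary. Plain SAM is converted to BAM with Rsamtools at the
# boundary; coordinates become 0-based half-open on the way in.

ensure_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
    return(paste0(dest, ".bam"))
  }
  path
}

flag_bit <- function(flag, bit) bitwAnd(flag, bit) != 0L

cigar_clip <- function(cigar) {
  # returns cbind(soft, hard) clipped base counts per cigar
  soft <- numeric(length(cigar)); hard <- numeric(length(cigar))
  ok <- !is.na(cigar)
  ops <- regmatches(cigar[ok], gregexpr("\\d+[MIDNSHP=X]", cigar[ok]))
  soft[ok] <- vapply(ops, function(o) {
    sum(as.numeric(sub("S$", "", o[grepl("S$", o)])))
  }, numeric(1))
  hard[ok] <- vapply(ops, function(o) {
    sum(as.numeric(sub("H$", "", o[grepl("H$", o)])))
  }, numeric(1))
  cbind(soft = soft, hard = hard)
}

# reference span of an alignment from its cigar (M/D/N/=/X)
cigar_ref_span <- function(cigar) {
  out <- numeric(length(cigar))
  ok <- !is.na(cigar)
  ops <- regmatches(cigar[ok], gregexpr("\\d+[MIDNSHP=X]", cigar[ok]))
  out[ok] <- vapply(ops, function(o) {
    sum(as.numeric(sub("[MDN=X]$", "", o[grepl("[MDN=X]$", o)])))
  }, numeric(1))
  out
}

#' Read primary alignment records from a SAM/BAM file
#'
#' @param path SAM or BAM file.
#' @param tags Optional character vector of tags to fetch (e.g.
#'   `c("AS", "XS")`).
#' @return Data.frame with one row per primary record: `qname`, `flag`,
#'   `rname`, `pos` (0-based), `end` (half-open, from the CIGAR), `strand`,
#'   `mapq`, `cigar`, `seq`, `qual`, `mate_unmapped`, `unmapped`, `first`,
#'   plus any requested tags.
#' @export
read_sam_records <- function(path, tags = character(0)) {
  bam <- ensure_bam(path)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  param <- Rsamtools::ScanBamParam(
    what = what, tag = tags,
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$flag)
  df <- data.frame(qname = res$qname, flag = res$flag,
                   rname = as.character(res$rname),
                   pos = ifelse(is.na(res$pos), NA_real_, res$pos - 1),
                   mapq = res$mapq, cigar = res$cigar,
                   seq = as.character(res$seq),
                   qual = as.character(res$qual),
                   stringsAsFactors = FALSE)
  df$end <- df$pos + cigar_ref_span(df$cigar)
  df$strand <- ifelse(flag_bit(df$flag, 0x10), "-", "+")
  df$unmapped <- flag_bit(df$flag, 0x4)
  df$mate_unmapped <- flag_bit(df$flag, 0x8)
  df$first <- flag_bit(df$flag, 0x40)
  if (length(tags)) for (tg in tags) df[[tg]] <- res$tag[[tg]] %||%
      rep(NA_integer_, n)
  df
}

#' Read paired-end alignments from SAM/BAM into a pair table
#'
#' Primary records are grouped by query name; pairs with both mates mapped
#' become rows of a pair-alignment data.frame (see [pair_alignments()]).
#'
#' @param path SAM or BAM file.
#' @return Pair-alignment data.frame (0-based half-open coordinates).
#' @export
read_pair_alignments <- function(path) {
  rec <- read_sam_records(path)
  rec <- rec[!rec$unmapped, , drop = FALSE]
  a <- rec[rec$first, , drop = FALSE]
  b <- rec[!rec$first, , drop = FALSE]
  common <- intersect(a$qname, b$qname)
  a <- a[match(common, a$qname), , drop = FALSE]
  b <- b[match(common, b$qname), , drop = FALSE]
  pair_alignments(read_id = common,
                  scaffold_a = a$rname, pos_a = a$pos, end_a = a$end,
                  strand_a = a$strand,
                  scaffold_b = b$rname, pos_b = b$pos, end_b = b$end,
                  strand_b = b$strand,
                  mapq_a = a$mapq, mapq_b = b$mapq)
}

#' Write sequences with qualities as FASTQ
#'
#' @param seqs Character vector or `DNAStringSet` of sequences (named).
#' @param quals Character vector of Phred strings, or `NULL` for uniform
#'   high quality.
#' @param path Output path (gzipped when ending in `.gz`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, quals = NULL, path) {
  sq <- as.character(seqs)
  nm <- names(seqs) %||% paste0("read", seq_along(sq))
  if (is.null(quals)) quals <- vapply(nchar(sq), function(n)
    strrep("I", n), character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", nm, "\n", sq, "\n+\n", quals), con)
  invisible(path)
}

#' Read a 12-column tabular homology report into hit intervals
#'
#' Standard tabular columns: query, subject, identity, alignment length,
#' mismatches, gap opens, qstart, qend, sstart, send, evalue, bitscore.
#' The query is taken to be the assembly scaffold; coordinates are
#' converted to 0-based half-open.
#'
#' @param path Tabular file.
#' @param db Label for the subject database class (`"phiX"`, `"vector"`,
#'   `"ecoli"`, `"plastid"`, `"mito"`, `"fungal"`, `"other"`), recycled.
#' @return Hit-interval data.frame with columns `scaffold`, `start`,
#'   `end`, `db`, `identity`, `bitscore`.
#' @export
read_blast_hits <- function(path, db = "other") {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopifnot(ncol(tab) >= 12L)
  hit_intervals(scaffold = tab[[1]],
                start = pmin(tab[[7]], tab[[8]]) - 1,
                end = pmax(tab[[7]], tab[[8]]),
                db = db, identity = tab[[3]], bitscore = tab[[12]])
}

#' Construct a hit-interval table
#'
#' @param scaffold Scaffold names.
#' @param start,end 0-based half-open interval on the scaffold.
#' @param db Subject database class label.
#' @param identity Percent identity in `[0, 100]`.
#' @param bitscore Bit score.
#' @return Validated hit-interval data.frame.
#' @export
hit_intervals <- function(scaffold, start, end, db = "other",
                          identity = 100, bitscore = 0) {
  df <- data.frame(scaffold = as.character(scaffold),
                   start = as.numeric(start), end = as.numeric(end),
                   db = as.character(db), identity = as.numeric(identity),
                   bitscore = as.numeric(bitscore),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$end > df$start), all(df$identity >= 0),
            all(df$identity <= 100))
  df
}
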