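test_that("masking replaces hit unions with Ns and keeps lengths", {
  set.seed(20)
  asm <- Biostrings::DNAStringSet(c(s1 = rand_seq(1000)))
  m <- mask_hits(asm, hit_intervals("s1", 100, 200, db = "ecoli"))
  expect_equal(unname(Biostrings::width(m)), 1000)
  expect_equal(unname(Biostrings::letterFrequency(m, "N")[, 1]), 100)
  expect_equal(substr(as.character(m[[1]]), 1, 100),
               substr(as.character(asm[[1]]), 1, 100))
  # overlapping hits form a single N run
  m2 <- mask_hits(asm, hit_intervals(c("s1", "s1"), c(100, 150),
                                     c(200, 300), db = "ecoli"))
  expect_equal(unname(Biostrings::letterFrequency(m2, "N")[, 1]), 200)
  # random intervals: masked bases equal the union measure (sweep oracle)
  for (seed in 1:3) {
    set.seed(seed)
    n <- 20
    st <- sample.int(900, n)
    en <- pmin(st + sample.int(80, n, replace = TRUE), 1000)
    hits <- hit_intervals("s1", st, en)
    mm <- mask_hits(asm, hits)
    cov <- logical(1000)
    for (i in seq_len(n)) cov[(st[i] + 1):en[i]] <- TRUE
    expect_equal(unname(Biostrings::letterFrequency(mm, "N")[, 1]),
                 sum(cov))
  }
  expect_error(mask_hits(asm, hit_intervals("s1", 990, 1100)),
               "coordinate")
})

test_that("scaffold drop/trim rules compose as specified", {
  set.seed(21)
  asm <- Biostrings::DNAStringSet(c(a = rand_seq(1000), b = rand_seq(1000),
                                    c = rand_seq(1000), d = rand_seq(1000)))
  hits <- rbind(hit_intervals("a", 0, 600, db = "ecoli"),
                hit_intervals("b", 10, 60, db = "mito"),
                hit_intervals("c", 0, 100, db = "vector"),
                hit_intervals("d", 400, 500, db = "phiX"))
  res <- drop_or_trim_scaffolds(asm, hits, depth = c(b = 6500))
  expect_setequal(res$removed$scaffold, c("a", "b"))
  expect_equal(res$removed$reason[res$removed$scaffold == "a"],
               "hit_fraction")
  expect_equal(res$removed$reason[res$removed$scaffold == "b"],
               "organelle_depth")
  # terminal hit trimmed away, interior hit masked
  expect_equal(res$trimmed$scaffold, "c")
  expect_equal(unname(Biostrings::width(res$assembly["c"])), 900)
  expect_equal(unname(Biostrings::letterFrequency(res$assembly["d"],
                                                  "N")[, 1]), 100)
  # mito hit without extreme depth does not delete
  res2 <- drop_or_trim_scaffolds(asm["b"], hits[hits$scaffold == "b", ],
                                 depth = c(b = 50))
  expect_equal(nrow(res2$removed), 0L)
})

test_that("explode/erode/filter arithmetic matches hand computation", {
  sc <- paste0(strrep("A", 300), strrep("N", 10), strrep("C", 100))
  out <- explode_erode_filter(Biostrings::DNAStringSet(c(x = sc)))
  expect_equal(unname(Biostrings::width(out)), 200)
  expect_equal(as.character(out[[1]]), strrep("A", 200))
  # 299 bp contig erodes to 199 < 200: dropped
  out2 <- explode_erode_filter(Biostrings::DNAStringSet(c(y = strrep("A", 299))))
  expect_equal(length(out2), 0L)
  # no Ns: single eroded contig
  set.seed(22)
  out3 <- explode_erode_filter(Biostrings::DNAStringSet(c(z = rand_seq(10000))))
  expect_equal(unname(Biostrings::width(out3)), 9900)
})

test_that("unmapped-pair extraction partitions primary records", {
  sam <- write_test_sam(c(
    "p1\t99\tref1\t101\t60\t10M\t=\t401\t310\tACGTACGTAA\tIIIIIIIIII",
    "p1\t147\tref1\t401\t60\t10M\t=\t101\t-310\tACGTACGTAA\tIIIIIIIIII",
    "p2\t77\t*\t0\t0\t*\t*\t0\t0\tAAAACCCCGG\tIIIIIIIIII",
    "p2\t141\t*\t0\t0\t*\t*\t0\t0\tGGGGTTTTAA\tIIIIIIIIII",
    "p3\t73\tref1\t51\t60\t10M\t*\t0\t0\tACGTACGTAA\tIIIIIIIIII",
    "p3\t133\t*\t0\t0\t*\t*\t0\t0\tTTTTAAAACC\tIIIIIIIIII"))
  res <- extract_unmapped_pairs(sam)
  expect_equal(res$pairs$r1$qname, "p2")
  expect_equal(res$pairs$r2$seq, "GGGGTTTTAA")
  expect_equal(res$singletons$qname, "p3")
  expect_equal(res$singletons$seq, "TTTTAAAACC")
})

test_that("recruitment enforces the clip-fraction and both-mates rules", {
  # 150 bp reads: 50 bp clip = 1/3 passes, 51 bp clip fails
  seq150 <- strrep("ACGTA", 30)
  q150 <- strrep("I", 150)
  sam <- write_test_sam(c(
    sprintf("p1\t99\tref1\t1\t60\t100M50S\t=\t301\t450\t%s\t%s", seq150, q150),
    sprintf("p1\t147\tref1\t301\t60\t150M\t=\t1\t-450\t%s\t%s", seq150, q150),
    sprintf("p2\t99\tref1\t1\t60\t99M51S\t=\t301\t450\t%s\t%s", seq150, q150),
    sprintf("p2\t147\tref1\t301\t60\t150M\t=\t1\t-450\t%s\t%s", seq150, q150)))
  res <- recruit_reads(sam)
  expect_equal(res$pairs$r1$qname, "p1")
  expect_equal(res$n_pairs_in, 2L)
  expect_equal(res$n_pairs_out, 1L)
  # hard clips count toward the clipped fraction
  rec <- data.frame(qname = c("h1", "h1"), flag = c(99L, 147L),
                    rname = "ref1", pos = c(0, 300), end = c(100, 450),
                    mapq = 60L, cigar = c("100M50H", "150M"),
                    seq = c(strrep("A", 100), seq150),
                    qual = c(strrep("I", 100), q150),
                    strand = c("+", "-"), unmapped = FALSE,
                    mate_unmapped = FALSE, first = c(TRUE, FALSE))
  res2 <- recruit_reads(rec)
  expect_equal(res2$n_pairs_out, 1L)  # 50/150 exactly at the bound
  rec$cigar[1] <- "99M51H"
  expect_equal(recruit_reads(rec)$n_pairs_out, 0L)
})

test_that("unique-mapping filter demands a clear best score", {
  sam <- write_test_sam(c(
    "u1\t0\tref1\t101\t60\t10M\t*\t0\t0\tACGTACGTAA\tIIIIIIIIII\tAS:i:100",
    "u2\t0\tref1\t201\t60\t10M\t*\t0\t0\tACGTACGTAA\tIIIIIIIIII\tAS:i:100\tXS:i:100",
    "u3\t0\tref1\t301\t60\t10M\t*\t0\t0\tACGTACGTAA\tIIIIIIIIII\tAS:i:100\tXS:i:90"))
  res <- unique_mapping_filter(sam)
  expect_setequal(res$kept$qname, c("u1", "u3"))
  expect_equal(res$dropped$qname, "u2")
  # no score tags: mapq fallback with a warning
  sam2 <- write_test_sam(c(
    "v1\t0\tref1\t101\t60\t10M\t*\t0\t0\tACGTACGTAA\tIIIIIIIIII",
    "v2\t0\tref1\t201\t5\t10M\t*\t0\t0\tACGTACGTAA\tIIIIIIIIII"))
  expect_warning(res2 <- unique_mapping_filter(sam2), "mapq")
  expect_equal(res2$kept$qname, "v1")
})

test_that("recruited output is invariant to record order", {
  seq150 <- strrep("ACGTA", 30)
  q150 <- strrep("I", 150)
  lines <- c(
    sprintf("a\t99\tref1\t1\t60\t150M\t=\t301\t450\t%s\t%s", seq150, q150),
    sprintf("a\t147\tref1\t301\t60\t150M\t=\t1\t-450\t%s\t%s", seq150, q150),
    sprintf("b\t99\tref1\t11\t60\t150M\t=\t311\t450\t%s\t%s", seq150, q150),
    sprintf("b\t147\tref1\t311\t60\t150M\t=\t11\t-450\t%s\t%s", seq150, q150))
  r1 <- recruit_reads(write_test_sam(lines))
  r2 <- recruit_reads(write_test_sam(lines[c(3, 1, 4, 2)]))
  expect_setequal(r1$pairs$r1$qname, r2$pairs$r1$qname)
})

test_that("length filter keeps the boundary and counts correctly", {
  set.seed(23)
  asm <- Biostrings::DNAStringSet(c(a = rand_seq(499), b = rand_seq(500),
                                    c = rand_seq(2000)))
  out <- filter_by_length(asm, 500)
  expect_setequal(names(out), c("b", "c"))
  expect_equal(length(filter_by_length(Biostrings::DNAStringSet(), 500)), 0L)
  # counting oracle on a random assembly
  set.seed(24)
  lens <- sample(100:1000, 50, replace = TRUE)
  rasm <- Biostrings::DNAStringSet(setNames(
    vapply(lens, function(n) strrep("A", n), ""), paste0("s", 1:50)))
  expect_equal(length(filter_by_length(rasm, 500)), sum(lens >= 500))
})
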