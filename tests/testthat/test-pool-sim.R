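test_that("diploid simulation is seeded, bounded and truthful", {
  g1 <- simulate_diploid(10000, het_rate = 0.01, seed = 3)
  g2 <- simulate_diploid(10000, het_rate = 0.01, seed = 3)
  expect_identical(g1$hapA, g2$hapA)
  expect_identical(g1$hapB, g2$hapB)
  expect_identical(g1$truth, g2$truth)
  # truth table is exact
  a <- strsplit(g1$hapA, "")[[1]]
  b <- strsplit(g1$hapB, "")[[1]]
  expect_equal(which(a != b) - 1, g1$truth$pos)
  # zero heterozygosity: identical haplotypes
  g0 <- simulate_diploid(5000, het_rate = 0, seed = 4)
  expect_identical(g0$hapA, g0$hapB)
  expect_equal(nrow(g0$truth), 0L)
  # het count within 3 sigma of Binomial(n, p)
  g3 <- simulate_diploid(1e5, het_rate = 0.01, seed = 5)
  expect_lt(abs(nrow(g3$truth) - 1000), 3 * sqrt(1e5 * 0.01 * 0.99))
  expect_error(simulate_diploid(500, 0.01), "1 kb")
  expect_error(simulate_diploid(10000, 0.5), "het_rate")
})

test_that("pool simulation respects its geometry and seed", {
  p0 <- simulate_pool(1e6, n_clones = 0)
  expect_equal(nrow(p0$clones), 0L)
  s0 <- pool_stats(p0)
  expect_equal(s0$covered_fraction, 0)
  expect_equal(s0$redundant_base_fraction, 0)
  p1 <- simulate_pool(1.38e9, n_clones = 1600, insert_mean = 36700,
                      insert_sd = 4970, seed = 7)
  expect_lt(abs(sum(p1$clones$length) - 1600 * 36700) / (1600 * 36700),
            0.01)
  expect_true(all(p1$clones$start >= 0))
  expect_true(all(p1$clones$end <= 1.38e9))
  expect_true(all(p1$clones$length >= 1000))
  p2 <- simulate_pool(1.38e9, n_clones = 1600, insert_mean = 36700,
                      insert_sd = 4970, seed = 7)
  expect_identical(p1$clones, p2$clones)
  expect_error(simulate_pool(1e4, insert_mean = 36700), "insert_mean")
})

test_that("pool statistics match hand computation and a per-base oracle", {
  pool <- structure(list(G = 1000, n_clones = 2,
                         clones = data.frame(start = c(0, 50),
                                             length = c(100, 100),
                                             end = c(100, 150),
                                             haplotype = c("A", "B"))),
                    class = "clone_pool")
  ps <- pool_stats(pool)
  expect_equal(ps$covered_fraction, 0.15)
  expect_equal(ps$overlapped_base_fraction, 0.5)
  expect_equal(ps$redundant_base_fraction, 0.25)
  expect_equal(ps$cross_hap_fraction, 1)
  # disjoint clones
  pool$clones$start <- c(0, 500); pool$clones$end <- c(100, 600)
  ps2 <- pool_stats(pool)
  expect_equal(ps2$overlapped_base_fraction, 0)
  expect_equal(ps2$redundant_base_fraction, 0)
  # per-base oracle on random pools
  for (seed in 1:3) {
    p <- simulate_pool(1e5, n_clones = 30, insert_mean = 5000,
                       insert_sd = 1000, seed = seed)
    got <- pool_stats(p)
    want <- pool_stats_oracle(p)
    for (f in names(want)) expect_equal(got[[f]], want[[f]], info = f)
  }
})

test_that("Lander-Waterman closed forms agree with simulation", {
  expect_equal(lw_covered_fraction(0, 36700, 1.38e9), 0)
  expect_equal(round(100 * lw_covered_fraction(1600, 36700, 1.38e9), 1),
               4.2)
  p <- simulate_pool(2e7, n_clones = 1600, insert_mean = 36700,
                     insert_sd = 4970, seed = 11)
  ps <- pool_stats(p)
  lw_cov <- lw_covered_fraction(1600, mean(p$clones$length), 2e7)
  lw_red <- lw_redundant_fraction(1600, mean(p$clones$length), 2e7)
  expect_lt(abs(ps$covered_fraction - lw_cov) / lw_cov, 0.05)
  expect_lt(abs(ps$redundant_base_fraction - lw_red) / lw_red, 0.05)
})

test_that("error-free reads are exact substrings of their haplotype", {
  g <- simulate_diploid(20000, het_rate = 0.01, seed = 12)
  rs <- simulate_reads(g, 200, insert_mean = 500, insert_sd = 40,
                       read_len = 100, seed = 13)
  hapof <- rs$truth$haplotype
  for (i in sample.int(200, 40)) {
    hap <- if (hapof[i] == "A") g$hapA else g$hapB
    expect_true(grepl(rs$r1[[i]], hap, fixed = TRUE))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rs$r2[[i]])))
    expect_true(grepl(rc, hap, fixed = TRUE))
  }
  # truth alignments point at the read origin
  i <- 1L
  hap <- if (hapof[i] == "A") g$hapA else g$hapB
  expect_equal(substr(hap, rs$truth$pos_a[i] + 1, rs$truth$end_a[i]),
               unname(rs$r1[[i]]))
  # zero reads requested
  rs0 <- simulate_reads(g, 0, insert_mean = 500, read_len = 100)
  expect_equal(length(rs0$r1), 0L)
  expect_equal(nrow(rs0$truth), 0L)
  expect_error(simulate_reads(g, 10, insert_mean = 80, read_len = 100),
               "geometry")
})

test_that("bimodal library simulation round-trips through mode detection", {
  g <- simulate_diploid(2e5, het_rate = 0, seed = 14)
  rs <- simulate_reads(g, 4000, insert_mean = 725, insert_sd = 60,
                       minor_insert_mean = 300, minor_fraction = 0.2,
                       read_len = 150, seed = 15)
  m <- detect_modes(estimate_insert_distribution(rs$truth))
  expect_lt(abs(m$main_peak - 725), 30)
  expect_lt(abs(m$minor_peak - 300), 30)
})

test_that("misjoin injection records exact truth junctions", {
  set.seed(16)
  asm <- Biostrings::DNAStringSet(c(s1 = rand_seq(30000),
                                    s2 = rand_seq(30000)))
  # n = 0: identity
  mj0 <- inject_misjoins(asm, 0)
  expect_identical(as.character(mj0$assembly), as.character(asm))
  expect_equal(nrow(mj0$junctions), 0L)
  # one swap: two 2-part chimeras, two junctions
  mj <- inject_misjoins(asm, 1, seed = 17, margin = 5000)
  expect_equal(nrow(mj$junctions), 2L)
  expect_equal(sum(Biostrings::width(mj$assembly)),
               sum(Biostrings::width(asm)))
  # block map lifts coordinates faithfully: sequence agrees at lifted spots
  pairs <- pair_alignments(paste0("p", 1:50), "s1",
                           seq(100, 25000, length.out = 50),
                           seq(100, 25000, length.out = 50) + 100, "+",
                           "s1", seq(200, 25100, length.out = 50),
                           seq(200, 25100, length.out = 50) + 100, "-")
  pairs$pos_a <- round(pairs$pos_a); pairs$end_a <- pairs$pos_a + 100
  pairs$pos_b <- round(pairs$pos_b); pairs$end_b <- pairs$pos_b + 100
  lifted <- liftover_pairs(pairs, mj$blocks)
  expect_gt(nrow(lifted), 40)
  for (i in sample.int(nrow(lifted), 5)) {
    orig <- substr(as.character(asm[["s1"]]),
                   pairs$pos_a[match(lifted$read_id[i], pairs$read_id)] + 1,
                   pairs$pos_a[match(lifted$read_id[i], pairs$read_id)] + 100)
    moved <- substr(as.character(mj$assembly[[lifted$scaffold_a[i]]]),
                    lifted$pos_a[i] + 1, lifted$pos_a[i] + 100)
    expect_equal(moved, orig)
  }
  expect_error(inject_misjoins(asm["s1"], 1), "two scaffolds")
})
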