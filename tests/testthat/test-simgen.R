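test_that("generators are pure functions of their seed", {
  cfg <- sim_config(n_transcripts = 10, N = 500, L = 30, seed = 60)
  a <- simulate_transcriptome(cfg)
  b <- simulate_transcriptome(cfg)
  expect_identical(a, b)
  ra <- simulate_reads(a$transcripts, a$tau, cfg)
  rb <- simulate_reads(b$transcripts, b$tau, cfg)
  expect_identical(ra$reads, rb$reads)
  expect_equal(sum(a$tau), 1)
})

test_that("simulated transcript lengths follow the negative binomial", {
  cfg <- sim_config(n_transcripts = 1e4, N = 1, L = 30, nb_mean = 500,
                    nb_size = 3, seed = 61)
  sim <- simulate_transcriptome(cfg)
  expect_lt(abs(mean(nchar(sim$transcripts)) - 500) / 500, 0.05)
})

test_that("simulated reads are faithful at eps = 0 and carry valid origins", {
  sim <- small_sim(seed = 62, eps = 0)
  rd <- sim$reads$reads
  seg <- substring(sim$transcripts[rd$transcript_id], rd$left, rd$right)
  seg[rd$strand == "-"] <- asmeval:::revcomp(seg[rd$strand == "-"])
  expect_identical(rd$seq, unname(seg))
  expect_true(all(rd$right - rd$left + 1 == sim$cfg$L))
  expect_true(all(rd$right <= nchar(sim$transcripts)[
    match(rd$transcript_id, names(sim$transcripts))]))
  ## origins round-trip through the read names
  dec <- decode_origin(rd$id, L = sim$cfg$L)
  expect_identical(dec$left, rd$left)
  expect_identical(dec$transcript_id, rd$transcript_id)
})

test_that("the observed mismatch rate matches epsilon", {
  eps <- 0.02
  sim <- small_sim(seed = 63, n_tx = 3, N = 4000, eps = eps)
  rd <- sim$reads$reads
  seg <- substring(sim$transcripts[rd$transcript_id], rd$left, rd$right)
  seg[rd$strand == "-"] <- asmeval:::revcomp(seg[rd$strand == "-"])
  mm <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
               rd$seq[1:1500], seg[1:1500])
  n_bases <- 1500 * sim$cfg$L
  se <- sqrt(eps * (1 - eps) / n_bases)
  expect_lt(abs(sum(mm) / n_bases - eps), 3 * se)
})

test_that("substitution perturbation changes the right number of bases", {
  set.seed(64)
  asm <- assembly(setNames(vapply(1:20, function(i) rseq(500), ""),
                           paste0("c", 1:20)))
  rate <- 0.01
  diffs <- vapply(1:30, function(s) {
    pert <- perturb_substitution(asm, rate, seed = 640 + s)
    sum(mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
               pert$contigs, asm$contigs))
  }, numeric(1))
  n <- asm$total_bases
  se <- sqrt(rate * (1 - rate) * n / 30)
  expect_lt(abs(mean(diffs) - rate * n), 3 * se)
  ## substituted bases always differ, lengths unchanged
  pert <- perturb_substitution(asm, 0.05, seed = 99)
  expect_identical(pert$lengths, asm$lengths)
  expect_gt(sum(mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
    pert$contigs, asm$contigs)), 0)
})

test_that("fusion joins contigs and collapses shared end sequence", {
  ## suffix TAG of the first contig equals the prefix of the second
  asm <- assembly(c(a = "GGCCATAG", b = "TAGTTCC"))
  fused <- perturb_fusion(asm, 1, seed = 65)
  expect_equal(fused$M, 1)
  expect_true(fused$contigs %in% c("GGCCATAGTTCC",     # a+b: overlap TAG
                                   "TAGTTCCGGCCATAG")) # b+a: no overlap
  set.seed(66)
  big <- assembly(setNames(vapply(1:12, function(i) rseq(100), ""),
                           paste0("c", 1:12)))
  f3 <- perturb_fusion(big, 3, seed = 66)
  expect_equal(f3$M, 9)
  expect_lte(f3$total_bases, big$total_bases)
  expect_error(perturb_fusion(big, 12, seed = 1), "n_events")
})

test_that("fission splits at read junctions and duplicates overlap", {
  tx <- c(t1 = paste(rep("ACGGTTACAT", 10), collapse = ""))  # 100 bp
  ## two reads overlapping by 10 bases: one junction
  rd <- read_set(substring(tx[[1]], c(1, 31), c(40, 70)),
                 origin = data.frame(transcript_id = "t1",
                                     left = c(1L, 31L), right = c(40L, 70L),
                                     strand = "+"))
  ta <- true_contigs(rd, tx, 0)
  expect_equal(nrow(ta$contigs), 1)
  split <- perturb_fission(ta, rate = 0.999999, seed = 67)
  expect_equal(split$M, 2)
  expect_equal(split$total_bases, ta$contigs$end - ta$contigs$start + 1 + 10)
  expect_equal(unname(split$contigs),
               c(substr(tx[[1]], 1, 40), substr(tx[[1]], 31, 70)))
  ## every fragment remains fully covered by its supporting reads
  sim <- small_sim(seed = 68, n_tx = 3, N = 300)
  ta2 <- true_contigs(sim$reads, sim$transcripts, 0)
  frag <- perturb_fission(ta2, 0.5, seed = 68)
  rd2 <- sim$reads$reads
  for (nm in names(frag$contigs)) {
    m <- regmatches(nm, regexec("^(.+):(\\d+)-(\\d+)", nm))[[1]]
    s <- as.integer(m[3]); e <- as.integer(m[4])
    keep <- rd2$transcript_id == m[2] & rd2$left <= e & rd2$right >= s
    cov <- unique(unlist(Map(seq, pmax(rd2$left[keep], s),
                             pmin(rd2$right[keep], e))))
    expect_true(all(s:e %in% cov))
  }
})

test_that("fission at vanishing rate is the identity", {
  sim <- small_sim(seed = 69, n_tx = 3, N = 300)
  ta <- true_contigs(sim$reads, sim$transcripts, 0)
  same <- perturb_fission(ta, rate = 1e-12, seed = 1)
  expect_equal(unname(same$contigs), ta$contigs$seq)
})

test_that("the two-isoform scenario generates the documented structure", {
  sc <- two_isoform_scenario(seed = 70)
  expect_equal(nchar(sc$transcripts), c(iso_short = 1000L, iso_long = 2000L))
  expect_equal(substr(sc$transcripts[["iso_long"]], 1, 1000),
               sc$transcripts[["iso_short"]])
  expect_equal(sc$reads$N, 5000L)
  expect_equal(sc$reads$L, 100L)
  ## ~90% of reads originate from the short isoform
  frac <- mean(sc$reads$reads$transcript_id == "iso_short")
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / 5000))
})
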