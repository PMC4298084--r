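prior_small <- prior_params(nb_size = 20, nb_prob = 20 / 170, max_len = 400)

test_that("the contig length prior is a normalised distribution", {
  for (lam in c(0.05, 0.5, 5)) {
    d <- contig_length_prior_dist(lam, prior_small, L = 50)
    expect_equal(sum(exp(d)), 1, tolerance = 1e-6)
  }
  expect_equal(contig_length_prior(20, 1, prior_small, L = 50), -Inf)
  expect_error(contig_length_prior(100, 0, prior_small, L = 50), "lambda")
})

test_that("at high coverage the length prior concentrates at full transcripts", {
  d <- contig_length_prior_dist(20, prior_small, L = 50)
  lens <- as.integer(names(d))
  ## nearly all mass within the bulk of the NB transcript-length range
  nb_lo <- qnbinom(0.01, size = 20, prob = 20 / 170)
  expect_gt(sum(exp(d)[lens >= nb_lo]), 0.97)
  ## and the distribution tracks the NB transcript-length pmf there
  mode_len <- lens[which.max(d)]
  nb_mode <- which.max(dnbinom(lens, size = 20, prob = 20 / 170)) + 49
  expect_lt(abs(mode_len - nb_mode), 5)
})

test_that("assembly prior is additive, empty for no contigs, and penalises duplication", {
  set.seed(30)
  asm <- assembly(c(a = rseq(120), b = rseq(200)))
  lam <- c(0.4, 0.8)
  p <- assembly_prior(asm, lam, prior_small, L = 50)
  parts <- contig_length_prior(asm$lengths, lam, prior_small, L = 50)
  expect_equal(p, sum(parts) + (120 + 200) * log(0.25), tolerance = 1e-9)
  expect_equal(assembly_prior(assembly(character(0)), numeric(0),
                              prior_small, L = 50), 0)
  dup <- assembly(c(a = asm$contigs[[1]], a2 = asm$contigs[[1]],
                    b = asm$contigs[[2]]))
  expect_lt(assembly_prior(dup, c(lam[1], lam[1], lam[2]), prior_small, 50),
            p)
})

test_that("coverage correction matches closed forms and Monte-Carlo placement", {
  params <- model_params(L = 50)
  set.seed(31)
  asm1 <- assembly(c(a = rseq(50)))            # single valid position
  for (lam in c(0.5, 3, 10)) {
    expect_equal(coverage_correction(asm1, lam, params),
                 log(1 - exp(-lam)), tolerance = 1e-12)
  }
  expect_equal(coverage_correction(assembly(c(a = rseq(80))), 0, params),
               -Inf)
  ## MC placement oracle on a moderate contig (fast version; the full
  ## acceptance run uses 1e5 replicates over a grid)
  asm2 <- assembly(c(a = rseq(250)))
  dp <- exp(coverage_correction(asm2, 0.6, params))
  mc <- asmeval:::cpp_mc_coverage(20000, 250, 50, 0.6, 0)
  expect_lt(abs(dp - mc), 0.015)
})

test_that("BIC penalty is (1/2)(M+1) ln N", {
  expect_equal(bic_penalty(1, 100), log(100))
  expect_equal(bic_penalty(0, 1), 0)
  ## linear in M at fixed N
  expect_equal(diff(vapply(1:5, bic_penalty, numeric(1), N = 50)),
               rep(0.5 * log(50), 4))
})

test_that("the score decomposes exactly into its reported components", {
  sim <- small_sim(seed = 32, n_tx = 5, N = 1500)
  ta <- true_contigs(sim$reads, sim$transcripts, 0)
  params <- model_params(L = sim$cfg$L, epsilon = sim$cfg$epsilon)
  sc <- score_assembly(sim$reads, ta, params, prior_small)
  expect_equal(sc$total,
               sc$loglik_uncorrected - sc$log_correction +
                 sc$log_contig_length_prior + sc$log_assembly_size_prior -
                 sc$bic_penalty,
               tolerance = 1e-9)
  expect_lte(sc$log_correction, 0)
  expect_equal(sc$normalized, sc$total - sc$total_null, tolerance = 1e-9)
  ## null assembly normalises to zero
  null_sc <- score_assembly(sim$reads, assembly(character(0)), params,
                            prior_small)
  expect_equal(null_sc$normalized, 0)
  expect_equal(null_sc$bic_penalty, 0.5 * log(sim$reads$N))
})

test_that("contig impact is positive for supported contigs, negative for junk", {
  sim <- small_sim(seed = 33, n_tx = 4, N = 2000)
  ta <- true_contigs(sim$reads, sim$transcripts, 0)
  asm <- asmeval:::as_assembly(ta)
  junk <- assembly(c(asm$contigs,
                     setNames(vapply(1:2, function(i) rseq(150), ""),
                              c("junk_1", "junk_2"))))
  params <- model_params(L = sim$cfg$L, epsilon = sim$cfg$epsilon)
  imp <- contig_impact_scores(sim$reads, junk, params, prior_small)
  expect_true(all(imp[startsWith(names(imp), "junk")] < 0))
  supported <- head(order(-vapply(ta$support, nrow, 1L)), 3)  # most reads
  expect_true(all(imp[supported] > 0))
})

test_that("impact equals leave-one-out re-scoring on disjoint-support contigs", {
  sim <- small_sim(seed = 34, n_tx = 2, N = 1200)
  ta <- true_contigs(sim$reads, sim$transcripts, 0)
  asm <- asmeval:::as_assembly(ta)
  expect_equal(asm$M, 2)  # the fixture yields one contig per transcript
  params <- model_params(L = sim$cfg$L, epsilon = sim$cfg$epsilon)
  sc <- score_assembly(sim$reads, asm, params, prior_small)
  imp <- contig_impact_scores(sim$reads, asm, params, prior_small,
                              score = sc)
  for (i in 1:2) {
    reduced <- assembly(asm$contigs[-i])
    sc_red <- score_assembly(sim$reads, reduced, params, prior_small)
    expect_equal(unname(imp[i]), sc$total - sc_red$total, tolerance = 1e-6)
  }
})

test_that("trimming drops exactly the negative-impact contigs, preserving order", {
  asm <- assembly(c(x = "ACGTACGTAA", y = "GGGTTTCCCA", z = "TTTTGGGGCC"))
  expect_equal(trim_assembly(asm, c(1, 2, 3))$contigs, asm$contigs)
  expect_equal(trim_assembly(asm, c(-1, -2, -3))$M, 0)
  kept <- trim_assembly(asm, c(5, -0.1, 0))
  expect_equal(names(kept$contigs), c("x", "z"))
})
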