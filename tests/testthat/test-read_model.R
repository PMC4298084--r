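params40 <- model_params(L = 40, epsilon = 0.01)

test_that("a read equal to a contig substring aligns exactly there", {
  set.seed(10)
  asm <- assembly(c(c1 = rseq(300)))
  rd <- read_set(substr(asm$contigs[[1]], 101, 140))
  aln <- align_reads(rd, asm, params40, include_noise = FALSE)
  fwd <- aln[aln$strand == "+", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$start, 100L)
  expect_equal(fwd$mm, 0L)
})

test_that("an unalignable read keeps only its noise pseudo-alignment", {
  set.seed(11)
  asm <- assembly(c(c1 = strrep("A", 200)))
  rd <- read_set(strrep("C", 40))
  aln <- align_reads(rd, asm, params40)
  expect_equal(aln$contig, 0L)
  expect_error(align_reads(read_set(strrep("C", 30)), asm, params40),
               "length")
})

test_that("alignment set equals the brute-force window scan on random instances", {
  set.seed(12)
  for (rep in 1:4) {
    M <- sample(2:5, 1)
    asm <- assembly(setNames(
      vapply(seq_len(M), function(i) rseq(sample(50:500, 1)), ""),
      paste0("c", seq_len(M))))
    L <- 30
    n <- 15
    src <- sample(M, n, TRUE)
    pos <- vapply(src, function(i)
      if (nchar(asm$contigs[i]) >= L)
        sample(nchar(asm$contigs[i]) - L + 1, 1) else 1L, 1L)
    seqs <- substring(asm$contigs[src], pos, pos + L - 1)
    seqs <- asmeval:::substitute_bases(seqs, rbinom(n, 3, 0.4), rep(L, n))
    seqs[1:4] <- vapply(1:4, function(i) rseq(L), "")
    params <- model_params(L = L, max_mismatches = 2,
                           strand_specific = rep %% 2 == 0)
    got <- align_reads(read_set(seqs), asm, params, include_noise = FALSE)
    want <- brute_align(read_set(seqs), asm, params)
    rownames(got) <- NULL
    expect_equal(got[, c("read", "contig", "start", "strand", "mm")], want)
  }
})

test_that("read-given-alignment log-likelihood matches the closed form", {
  set.seed(13)
  ## perfect strand-specific read on a contig of exactly L bases
  ps <- model_params(L = 8, epsilon = 0.01, strand_specific = TRUE)
  asm <- assembly(c(c1 = rseq(8)))
  expect_equal(read_given_alignment_loglik(NULL, 1, 0, 0, asm, ps),
               8 * log(0.99))
  ## uniform-background noise model, L = 4
  p4 <- model_params(L = 4)
  expect_equal(read_given_alignment_loglik("ACGT", 0, NA, NA, asm, p4),
               4 * log(0.25))
  ## mm=2, L=100, eps=0.01, l=199, non-strand-specific: direct product
  p100 <- model_params(L = 100, epsilon = 0.01)
  asm2 <- assembly(c(c1 = rseq(199)))
  direct <- log((1 / (199 - 100 + 1)) * 0.5 * 0.99^98 * (0.01 / 3)^2)
  expect_equal(read_given_alignment_loglik(NULL, 1, 10, 2, asm2, p100),
               direct)
  expect_error(read_given_alignment_loglik(NULL, 1, 150, 0, asm2, p100),
               "outside")
})

test_that("EM collapses to a single supported contig and is monotone", {
  set.seed(14)
  asm <- assembly(c(c1 = rseq(400)))
  pos <- sample(361, 300, TRUE)
  rd <- read_set(substring(asm$contigs[[1]], pos, pos + 39))
  fit <- em_fit(rd, asm, params40)
  expect_lt(fit$theta[1], 1e-4)            # noise fraction -> 0
  expect_gt(fit$theta[2], 1 - 1e-4)
  expect_false(is.unsorted(fit$trace))     # EM monotonicity
})

test_that("EM recovers a 90/10 split between non-homologous contigs", {
  sim <- small_sim(seed = 15, n_tx = 2, N = 5000)
  tau <- c(0.9, 0.1)
  reads <- simulate_reads(sim$transcripts, tau, sim$cfg)
  params <- model_params(L = sim$cfg$L, epsilon = sim$cfg$epsilon)
  fit <- em_fit(reads, assembly(sim$transcripts), params)
  eff <- nchar(sim$transcripts) - sim$cfg$L + 1
  want <- tau * eff / sum(tau * eff)       # read-generation fractions
  expect_lt(max(abs(fit$theta[-1] - want)), 0.02)
  expect_false(is.unsorted(fit$trace))
})

test_that("posterior probabilities are Bayes-consistent and sum to one", {
  set.seed(16)
  ## two identical contigs: posterior splits evenly
  s <- rseq(200)
  asm <- assembly(c(a = s, b = s))
  pos <- sample(161, 50, TRUE)
  rd <- read_set(substring(s, pos, pos + 39))
  fit <- em_fit(rd, asm, params40)
  post <- posterior_alignment_probs(rd, asm, fit, params40)
  sums <- rowsum(post$posterior, post$read)
  expect_true(all(abs(sums - 1) < 1e-9))
  fwd <- post[post$contig > 0 & post$strand == "+", ]
  expect_true(all(abs(fwd$posterior[fwd$contig == 1] -
                        fwd$posterior[fwd$contig == 2]) < 1e-9))

  ## hand-enumerated Bayes table on a 3-read toy instance
  asm1 <- assembly(c(c1 = rseq(50)))
  p10 <- model_params(L = 10, epsilon = 0.05, strand_specific = TRUE,
                      max_mismatches = 2)
  seqs <- c(substr(asm1$contigs[[1]], 1, 10),
            substr(asm1$contigs[[1]], 21, 30), rseq(10))
  rd3 <- read_set(seqs)
  fit3 <- em_fit(rd3, asm1, p10)
  post3 <- posterior_alignment_probs(rd3, asm1, fit3, p10)
  aln3 <- fit3$alignments
  for (r in 1:3) {
    rows <- which(post3$read == r)
    prior_w <- fit3$theta[aln3$contig[rows] + 1]
    lik <- exp(aln3$logp[rows])
    expect_equal(post3$posterior[rows], prior_w * lik / sum(prior_w * lik),
                 tolerance = 1e-9)
  }
})

test_that("theta-to-lambda conversion uses the l + L + 1 denominator", {
  asm <- assembly(c(c1 = strrep("A", 100)))
  lam <- convert_theta_to_lambda(c(0.9, 0.1), asm, N = 1000, L = 76)
  expect_equal(lam, 1000 * 0.1 / (100 + 76 + 1))  # = 100/177, not /25
  expect_equal(convert_theta_to_lambda(c(1, 0), asm, 1000, 76), 0)
})
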