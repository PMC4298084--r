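test_that("identical sequences give perfect contig and nucleotide scores", {
  set.seed(40)
  ref <- assembly(c(t1 = rseq(400)))
  asm <- assembly(c(c1 = ref$contigs[[1]]))
  al <- align_assembly_to_reference(asm, ref)
  expect_equal(nrow(al), 1)
  expect_equal(al$matches, 400L)
  cs <- contig_level_scores(al)
  expect_equal(c(cs$recall, cs$precision, cs$f1), c(1, 1, 1))
  ns <- nucleotide_level_scores(al)
  expect_equal(c(ns$recall, ns$precision, ns$f1), c(1, 1, 1))
})

test_that("a reverse-complement contig aligns on the minus strand", {
  set.seed(41)
  ref <- assembly(c(t1 = rseq(300)))
  asm <- assembly(c(c1 = asmeval:::revcomp(ref$contigs[[1]])))
  al <- align_assembly_to_reference(asm, ref)
  expect_true(any(al$strand == "-" & al$matches == 300))
  expect_equal(nucleotide_level_scores(al)$recall, 1)
})

test_that("a planted 98%-identity insert in random background is recovered", {
  set.seed(42)
  ref <- assembly(c(t1 = rseq(700)))
  insert <- substr(ref$contigs[[1]], 101, 600)          # 500 bp
  insert <- asmeval:::substitute_bases(insert, 10, 500)  # 98% identity
  asm <- assembly(c(c1 = paste0(rseq(150), insert, rseq(150))))
  al <- align_assembly_to_reference(asm, ref)
  best <- al[which.max(al$matches), ]
  expect_gte(best$matches, 485)
  expect_equal(best$ref_start, 100)
  expect_equal(best$ref_end, 600)
})

test_that("two 60% fragments: nucleotide recall full, contig recall zero", {
  set.seed(43)
  ref <- assembly(c(t1 = rseq(1000)))
  asm <- assembly(c(c1 = substr(ref$contigs[[1]], 1, 600),
                    c2 = substr(ref$contigs[[1]], 401, 1000)))
  al <- align_assembly_to_reference(asm, ref)
  expect_equal(contig_level_scores(al)$recall, 0)  # neither covers 99%
  ns <- nucleotide_level_scores(al)
  expect_equal(ns$recall, 1)                       # full credit jointly
  expect_equal(ns$precision, 1)                    # every contig base correct
})

test_that("maximum-cardinality matching resolves many-to-one matches", {
  set.seed(44)
  s <- rseq(500)
  ref <- assembly(c(t1 = s))
  asm <- assembly(c(a = s, b = s, c = s))
  al <- align_assembly_to_reference(asm, ref)
  cs <- contig_level_scores(al)
  expect_equal(cs$recall, 1)       # matching cardinality 1 / 1 reference
  expect_equal(cs$precision, 1 / 3)
  expect_equal(nrow(cs$matched_pairs), 1)
})

test_that("contig-level scores are invariant to order and renaming", {
  set.seed(45)
  ref <- assembly(c(t1 = rseq(300), t2 = rseq(250)))
  asm <- assembly(c(c1 = ref$contigs[[1]], c2 = rseq(200)))
  s1 <- contig_level_scores(align_assembly_to_reference(asm, ref))
  asm2 <- assembly(c(zz = asm$contigs[[2]], aa = asm$contigs[[1]]))
  s2 <- contig_level_scores(align_assembly_to_reference(asm2, ref))
  expect_equal(s1[c("recall", "precision", "f1")],
               s2[c("recall", "precision", "f1")])
})

test_that("greedy per-position selection equals exhaustive search on small instances", {
  ## exhaustive: the best achievable total of newly-correct reference
  ## positions over all selection orders of <= 4 alignments
  set.seed(46)
  for (rep in 1:3) {
    ref <- assembly(c(t1 = rseq(300)))
    windows <- replicate(4, sort(sample(300, 2)), simplify = FALSE)
    asm <- assembly(setNames(lapply(windows, function(wd) {
      s <- substr(ref$contigs[[1]], wd[1], wd[2])
      if (nchar(s) >= 60) s else paste0(s, rseq(60 - nchar(s)))
    }), paste0("c", 1:4)))
    al <- align_assembly_to_reference(asm, ref, min_matches = 20)
    got <- nucleotide_level_scores(al)$recall * 300
    mp <- attr(al, "ref_match_pos")
    spans <- Map(seq, al$ref_start + 1, al$ref_end)
    orders <- if (nrow(al)) all_perms(nrow(al)) else list()
    best <- 0
    for (ord in orders) {
      assigned <- rep(FALSE, 300)
      tot <- 0
      for (i in ord) {
        tot <- tot + sum(!assigned[mp[[i]] + 1])
        assigned[spans[[i]]] <- TRUE
      }
      best <- max(best, tot)
    }
    expect_equal(got, best)
  }
})

test_that("k-mer compression score closed forms hold", {
  set.seed(47)
  ref <- c(t1 = rseq(500))
  ## assembly identical to the reference: WKR = 1
  kc <- kc_score(assembly(ref), ref, tau = 1, N = 100, L = 100, k = 31)
  expect_equal(kc$wkr, 1)
  expect_equal(kc$icr, 500 / (100 * 100))
  expect_equal(kc$kc, kc$wkr - kc$icr)
  ## 1000 nt assembly, N=100, L=100: ICR = 0.1
  asm2 <- assembly(c(a = rseq(1000)))
  expect_equal(kc_score(asm2, ref, tau = 1, N = 100, L = 100, k = 31)$icr,
               0.1)
  expect_error(kc_score(asm2, ref, tau = 1, N = 100, L = 100, k = 501),
               "larger than every reference")
})

test_that("WKR weights k-mers by reference abundance", {
  set.seed(48)
  ## two references with disjoint k-mers (different alphabets of repeats)
  r1 <- paste(rep("ACGGT", 60), collapse = "")   # 300 bp
  r2 <- paste(rep("TTACC", 60), collapse = "")
  ref <- c(b1 = r1, b2 = r2)
  asm <- assembly(c(c1 = r1))
  kc <- kc_score(asm, ref, tau = c(0.9, 0.1), N = 10, L = 20, k = 20,
                 strand_specific = TRUE)
  expect_equal(kc$wkr, 0.9, tolerance = 1e-12)
  ## canonical counting folds a k-mer and its reverse complement
  asm_rc <- assembly(c(c1 = asmeval:::revcomp(r1)))
  kc2 <- kc_score(asm_rc, ref, tau = c(0.9, 0.1), N = 10, L = 20, k = 20,
                  strand_specific = FALSE)
  expect_equal(kc2$wkr, 0.9, tolerance = 1e-12)
})

test_that("N50 follows the cumulative-length definition", {
  mk <- function(lens) assembly(setNames(
    vapply(lens, function(n) strrep("A", n), ""),
    paste0("c", seq_along(lens))))
  expect_equal(n50(mk(10)), 10)
  expect_equal(n50(mk(c(1, 1, 1, 97))), 97)
  expect_equal(n50(mk(c(5, 4, 3, 2, 1))), 4)  # cum >= 7.5 first at 4
  expect_error(n50(assembly(character(0))), "empty")
})

test_that("PSL import reproduces internal-alignment scores on clean data", {
  set.seed(49)
  ref <- assembly(c(t1 = rseq(200)))
  asm <- assembly(c(c1 = ref$contigs[[1]]))
  psl_line <- paste(c(200, 0, 0, 0, 0, 0, 0, 0, "+", "c1", 200, 0, 200,
                      "t1", 200, 0, 200, 1, "200,", "0,", "0,"),
                    collapse = "\t")
  f <- withr::local_tempfile(fileext = ".psl")
  writeLines(psl_line, f)
  al <- psl_to_alignments(read_psl(f), asm, ref)
  expect_equal(al$matches, 200L)
  expect_equal(contig_level_scores(al)$f1, 1)
  expect_equal(nucleotide_level_scores(al)$recall, 1)
})
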