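## Benchmark experiments probing the score around a known ground truth:
## random perturbations of the true assembly (substitution / fission /
## indel / fusion) and guided perturbations (true assemblies built at
## increasing minimum overlap lengths).

#' Default study conditions for the perturbation experiments
#'
#' One simulated data set is shared by the random- and guided-perturbation
#' experiments: 250 transcripts with NB(size 2, mean 800) lengths,
#' Dirichlet(0.3) abundances, and 200,000 strand non-specific 76-base
#' single-end reads at 1% substitution error. These conditions give a
#' ground-truth assembly of several hundred contigs spanning deeply
#' covered and fragmented, sparsely covered transcripts.
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
perturbation_sim_config <- function(seed) {
  sim_config(n_transcripts = 250, N = 2e5, L = 76, epsilon = 0.01,
             nb_mean = 800, nb_size = 2, alpha = 0.3, seed = seed)
}

#' Random-perturbation experiment
#'
#' Scores randomly perturbed copies of a ground-truth assembly and
#' reports, per perturbation class (type x strength), the mean normalised
#' score change relative to the truth and the error rate (fraction of
#' perturbed assemblies scoring above the truth).
#'
#' @param reads the [read_set()] the truth was built from.
#' @param truth a `true_assembly` from [true_contigs()] (the fission
#'   perturbation needs its read layout).
#' @param params a [model_params()].
#' @param prior a [prior_params()].
#' @param types perturbation types to run (subset of
#'   `c("substitution", "fission", "indel")`).
#' @param strengths per-position (or per-junction) rates.
#' @param n_rep independent perturbed assemblies per class.
#' @param seed integer seed.
#' @return list with `truth_normalized` and `results`, a data frame with
#'   columns `type`, `strength`, `mean_delta` (mean normalised score minus
#'   truth), `error_rate`, and `n`.
#' @export
perturbation_experiment <- function(reads, truth, params, prior,
                                    types = c("substitution", "fission",
                                              "indel"),
                                    strengths = c(1e-4, 1e-3, 1e-2),
                                    n_rep = 50, seed = 1L) {
  asm <- as_assembly(truth)
  truth_sc <- score_assembly(reads, asm, params, prior)
  out <- NULL
  for (type in types) {
    for (s in strengths) {
      deltas <- vapply(seq_len(n_rep), function(r) {
        sub_seed <- (seed + 7919L * match(type, types) +
                       104729L * match(s, strengths) + r) %% 2147483647L
        p <- switch(type,
                    substitution = perturb_substitution(asm, s, sub_seed),
                    fission = perturb_fission(truth, s, sub_seed),
                    indel = perturb_indel(asm, s, sub_seed),
                    fusion = perturb_fusion(asm, max(1L, as.integer(s)),
                                            sub_seed))
        score_assembly(reads, p, params, prior)$normalized -
          truth_sc$normalized
      }, numeric(1))
      out <- rbind(out, data.frame(type = type, strength = s,
                                   mean_delta = mean(deltas),
                                   error_rate = mean(deltas > 0),
                                   n = n_rep, stringsAsFactors = FALSE))
    }
  }
  list(truth_normalized = truth_sc$normalized, results = out)
}

#' Guided-perturbation experiment
#'
#' Builds the true assembly of one read set at a series of minimum overlap
#' lengths and scores each, reporting the full score and the uncorrected
#' maximum-likelihood term. The score should be maximised at small `w`
#' (the true assembly at `w = 0` is the best achievable assembly), whereas
#' the bare likelihood keeps improving with `w`.
#'
#' @param reads a [read_set()] with origins.
#' @param transcripts the transcripts the origins refer to.
#' @param params a [model_params()].
#' @param prior a [prior_params()].
#' @param ws minimum overlap lengths to evaluate.
#' @return data frame with columns `w`, `M`, `total_bases`, `loglik_ml`
#'   and `total`.
#' @export
guided_experiment <- function(reads, transcripts, params, prior,
                              ws = c(0, 1, 2, 5, 10, 25, 75)) {
  out <- lapply(ws, function(w) {
    asm <- as_assembly(true_contigs(reads, transcripts, w = w))
    sc <- score_assembly(reads, asm, params, prior)
    data.frame(w = w, M = asm$M, total_bases = asm$total_bases,
               loglik_ml = sc$loglik_uncorrected, total = sc$total)
  })
  do.call(rbind, out)
}

#' Score-agreement experiment: reference-free score vs KC score
#'
#' Generates a spread of assemblies of one read set (the truth, a trimmed
#' variant, and perturbed variants across types and strengths), computes
#' the reference-free total score and the reference-based KC score of
#' each, and reports both with their Spearman rank correlation.
#'
#' @inheritParams perturbation_experiment
#' @param transcripts reference transcripts (for the KC side).
#' @param tau reference abundances for the KC score.
#' @param seed integer seed.
#' @return list with `table` (one row per assembly: `label`, `total`,
#'   `kc`) and `spearman`.
#' @export
score_agreement_experiment <- function(reads, truth, transcripts, tau,
                                       params, prior, seed = 1L) {
  asm <- as_assembly(truth)
  variants <- list(truth = asm)
  k <- 0L
  for (s in c(3e-4, 1e-3, 3e-3, 1e-2)) {
    k <- k + 1L
    variants[[paste0("sub_", s)]] <-
      perturb_substitution(asm, s, seed + k)
    variants[[paste0("indel_", s)]] <- perturb_indel(asm, s, seed + 100L + k)
  }
  variants[["fission_0.3"]] <- perturb_fission(truth, 0.3, seed + 200L)
  variants[["fused"]] <- perturb_fusion(asm, max(1L, asm$M %/% 4L),
                                        seed + 300L)
  sc <- score_assembly(reads, asm, params, prior)
  impacts <- contig_impact_scores(reads, asm, params, prior, score = sc)
  variants[["trimmed"]] <- trim_assembly(asm, impacts)
  tab <- do.call(rbind, lapply(names(variants), function(nm) {
    a <- variants[[nm]]
    total <- score_assembly(reads, a, params, prior)$total
    kc <- kc_score(a, transcripts, tau = tau, N = reads$N, L = reads$L,
                   k = reads$L)$kc
    data.frame(label = nm, total = total, kc = kc,
               stringsAsFactors = FALSE)
  }))
  list(table = tab,
       spearman = stats::cor(tab$total, tab$kc, method = "spearman"))
}
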