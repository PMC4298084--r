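## The reference-free assembly score: log joint probability of the assembly
## and the reads, decomposed as
##   total = [loglik - log P(C=1)] + [contig length prior + size prior]
##           - (1/2)(M+1) log N
## where C=1 is the event that the generated reads completely cover every
## contig with successive overlaps >= w. Natural logarithms throughout.

#' Log contig-length prior P(l | lambda)
#'
#' Probability that the bag-of-contigs process (negative-binomial parent
#' transcript length, Poisson(lambda) read starts per valid position,
#' contigs = maximal runs mergeable at minimum overlap `prior$w`) yields a
#' contig of length `ell`, normalised over the truncated support
#' `L..prior$max_len`.
#'
#' @param ell contig length(s) in bases (`ell < L` is impossible and gives
#'   `-Inf`).
#' @param lam expected read coverage (reads starting per valid position);
#'   must be positive. Recycled against `ell`.
#' @param prior a [prior_params()].
#' @param L read length.
#' @return log-probabilities, one per `ell`.
#' @export
contig_length_prior <- function(ell, lam, prior, L) {
  stopifnot(inherits(prior, "prior_params"))
  if (any(lam <= 0)) stop("contig_length_prior: lambda must be > 0")
  n <- max(length(ell), length(lam))
  ell <- rep_len(as.numeric(ell), n)
  lam <- rep_len(as.numeric(lam), n)
  ## the truncation bound is a computational device, not part of the
  ## model: when a contig exceeds it (e.g. fused contigs), enlarge the
  ## support so the tail keeps its small-but-finite probability
  max_len <- max(prior$max_len, if (length(ell)) max(ell) else 0)
  cpp_length_prior(ell, lam, as.integer(L), prior$w, prior$nb_size,
                   prior$nb_prob, as.integer(max_len))
}

#' Full contig-length prior distribution for one coverage value
#'
#' @inheritParams contig_length_prior
#' @return named numeric vector of log-probabilities over lengths
#'   `L..prior$max_len`.
#' @export
contig_length_prior_dist <- function(lam, prior, L) {
  stopifnot(inherits(prior, "prior_params"), lam > 0)
  d <- cpp_length_prior_dist(lam, as.integer(L), prior$w, prior$nb_size,
                             prior$nb_prob, prior$max_len)
  names(d) <- seq(from = L, length.out = length(d))
  d
}

#' Log assembly prior
#'
#' `sum_i log P(l_i | lambda_i) + (sum_i l_i) * log(1/4)`: per-contig
#' length-prior terms (contigs generated independently) times the uniform
#' sequence term penalising total assembly size. Contigs with zero
#' estimated coverage use the floor `lambda_min = 1/(l_i + L + 1)` (one
#' expected read) so the prior stays finite.
#'
#' @param assembly an [assembly()].
#' @param lam per-contig expected read coverage (length M).
#' @param prior a [prior_params()].
#' @param L read length.
#' @return log-probability; 0 for an empty assembly.
#' @export
assembly_prior <- function(assembly, lam, prior, L) {
  assembly <- as_assembly(assembly)
  if (assembly$M == 0) return(0)
  stopifnot(length(lam) == assembly$M)
  lam <- pmax(lam, 1 / (assembly$lengths + L + 1))
  sum(contig_length_prior(assembly$lengths, lam, prior, L)) +
    assembly$total_bases * log(0.25)
}

#' Log-probability that reads completely cover the assembly
#'
#' `log P(C = 1)`: for each contig independently, the probability that
#' Poisson(lambda_i) read starts per valid position produce a start at the
#' first position, a read ending at the last base, and successive starts
#' at most `L - w` apart (every position covered with overlaps >= `w`).
#' This is the likelihood correction term: the corrected log-likelihood is
#' the uncorrected one minus this quantity.
#'
#' @inheritParams assembly_prior
#' @param params a [model_params()] (its `L` is used).
#' @param w minimum overlap length (default 0).
#' @return log-probability (<= 0); `-Inf` if any contig has `lam = 0` and
#'   `l_i >= L` (an uncoverable contig).
#' @export
coverage_correction <- function(assembly, lam, params, w = 0L) {
  assembly <- as_assembly(assembly)
  if (assembly$M == 0) return(0)
  stopifnot(length(lam) == assembly$M)
  sum(cpp_coverage_logprob(as.numeric(assembly$lengths), as.numeric(lam),
                           params$L, as.integer(w)))
}

#' BIC penalty
#'
#' `(1/2) (M + 1) ln N`: one free parameter per contig's expected coverage
#' plus one for the noise component.
#'
#' @param M number of contigs.
#' @param N number of reads.
#' @return the penalty (subtracted from the score).
#' @export
bic_penalty <- function(M, N) {
  stopifnot(M >= 0, N >= 1)
  0.5 * (M + 1) * log(N)
}

#' Score an assembly against the reads used to build it
#'
#' Fits abundances by EM, converts them to expected read coverages, and
#' assembles the full score breakdown. The normalised score subtracts the
#' score of the null assembly with no contigs (all reads explained by the
#' noise model, no prior, BIC `(1/2) ln N`), which is useful when positive
#' values are needed.
#'
#' @param reads a [read_set()].
#' @param assembly an [assembly()] built from these reads.
#' @param params a [model_params()]; defaults to `model_params(reads$L)`.
#' @param prior a [prior_params()].
#' @param fit optional precomputed [em_fit()] result for this
#'   reads/assembly pair.
#' @return object of class `score_breakdown`: list with
#'   `loglik_uncorrected`, `log_correction`, `log_contig_length_prior`,
#'   `log_assembly_size_prior`, `bic_penalty`, `total`, `total_null`,
#'   `normalized`, plus `lam`, `lam_floored` and the `fit`.
#' @export
score_assembly <- function(reads, assembly, params = NULL,
                           prior = prior_params(), fit = NULL) {
  assembly <- as_assembly(assembly)
  if (is.null(params)) params <- model_params(L = reads$L)
  N <- reads$N; L <- params$L
  noise_ll <- sum(cpp_noise_loglik(reads$reads$seq, params$background))
  total_null <- noise_ll - bic_penalty(0, N)

  if (assembly$M == 0) {
    out <- list(loglik_uncorrected = noise_ll, log_correction = 0,
                log_contig_length_prior = 0, log_assembly_size_prior = 0,
                bic_penalty = bic_penalty(0, N), total = total_null,
                total_null = total_null, normalized = 0,
                lam = numeric(0), lam_floored = numeric(0), fit = NULL,
                M = 0L, N = N)
    class(out) <- "score_breakdown"
    return(out)
  }

  if (is.null(fit)) fit <- em_fit(reads, assembly, params)
  lam <- fit$lam
  lam_floored <- pmax(lam, 1 / (assembly$lengths + L + 1))
  ## contigs shorter than a read (possible in real assemblies, impossible
  ## under the bag process) are charged the boundary length L in the
  ## length-prior and correction terms; the size prior and the likelihood
  ## still see their true length
  ell_eff <- pmax(assembly$lengths, L)
  len_prior <- contig_length_prior(ell_eff, lam_floored, prior, L)
  size_prior <- assembly$total_bases * log(0.25)
  corr <- cpp_coverage_logprob(as.numeric(ell_eff), lam_floored,
                               L, prior$w)
  bic <- bic_penalty(assembly$M, N)
  total <- fit$loglik - sum(corr) + sum(len_prior) + size_prior - bic
  out <- list(loglik_uncorrected = fit$loglik, log_correction = sum(corr),
              log_contig_length_prior = sum(len_prior),
              log_assembly_size_prior = size_prior, bic_penalty = bic,
              total = total, total_null = total_null,
              normalized = total - total_null,
              lam = lam, lam_floored = lam_floored,
              per_contig_length_prior = len_prior, per_contig_corr = corr,
              fit = fit, M = assembly$M, N = N)
  class(out) <- "score_breakdown"
  out
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf(
    paste0("assembly score (M = %d contigs, N = %d reads)\n",
           "  log-likelihood (uncorrected): %14.3f\n",
           "  coverage correction:          %14.3f\n",
           "  contig length prior:          %14.3f\n",
           "  assembly size prior:          %14.3f\n",
           "  BIC penalty:                  %14.3f\n",
           "  total:                        %14.3f\n",
           "  normalized (vs null):         %14.3f\n"),
    x$M, x$N, x$loglik_uncorrected, x$log_correction,
    x$log_contig_length_prior, x$log_assembly_size_prior,
    x$bic_penalty, x$total, x$normalized))
  invisible(x)
}

#' Per-contig impact scores
#'
#' For each contig, the log ratio between the hypothesis that the contig is
#' a true contig and the hypothesis that the reads composing it come from
#' the background noise: the contig's additive contribution to the score
#' (its reads' corrected likelihood terms, its length- and size-prior
#' terms, its BIC share `(1/2) ln N`) minus the log-probability of those
#' same reads under the noise model (with the contig's mixture weight
#' folded into the noise fraction). Reads shared between contigs are
#' apportioned by their posterior weights. Where a contig shares no reads
#' with the rest of the assembly, its impact equals the difference between
#' the full score and the score of the assembly without it.
#'
#' @inheritParams score_assembly
#' @param score optional precomputed [score_assembly()] result.
#' @return named numeric vector of impact scores (one per contig).
#' @export
contig_impact_scores <- function(reads, assembly, params = NULL,
                                 prior = prior_params(), score = NULL) {
  assembly <- as_assembly(assembly)
  if (is.null(params)) params <- model_params(L = reads$L)
  if (is.null(score))
    score <- score_assembly(reads, assembly, params, prior)
  fit <- score$fit
  aln <- fit$alignments
  theta <- fit$theta
  noise_lp <- cpp_noise_loglik(reads$reads$seq, params$background)
  logdenom <- cpp_read_logdenom(aln$read, aln$contig, aln$logp, theta,
                                reads$N)
  real <- aln$contig > 0L
  contrib <- fit$gamma[real] *
    (logdenom[aln$read[real]] -
       (log(theta[1] + theta[aln$contig[real] + 1L]) +
          noise_lp[aln$read[real]]))
  by_contig <- rowsum(contrib, aln$contig[real])
  read_term <- numeric(assembly$M)
  read_term[as.integer(rownames(by_contig))] <- by_contig[, 1]
  ## genuine background reads are explained *better* once the contig's
  ## mixture weight is folded into the noise fraction; without this term
  ## the impact would overstate the contig's contribution by
  ## Gamma0 * log((theta0 + theta_i)/theta0), with Gamma0 the total
  ## posterior noise mass
  gamma0 <- sum(fit$gamma[!real])
  noise_shift <- if (theta[1] > 0 && gamma0 > 0)
    gamma0 * log(theta[1] / (theta[1] + theta[-1])) else numeric(assembly$M)
  impact <- read_term + noise_shift - score$per_contig_corr +
    score$per_contig_length_prior + assembly$lengths * log(0.25) -
    0.5 * log(reads$N)
  names(impact) <- names(assembly$contigs)
  impact
}

#' Remove contigs with negative impact scores
#'
#' @param assembly an [assembly()].
#' @param impacts impact scores from [contig_impact_scores()], aligned with
#'   the assembly's contigs.
#' @return the trimmed [assembly()] (contig order preserved).
#' @export
trim_assembly <- function(assembly, impacts) {
  assembly <- as_assembly(assembly)
  stopifnot(length(impacts) == assembly$M)
  assembly(assembly$contigs[impacts >= 0])
}
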