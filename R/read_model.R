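## Simplified RSEM-style generative model of single-end reads given an
## assembly treated as a transcript set: a read picks a mixture component
## (noise, or contig i with weight theta_i), a start position uniform over
## the contig's l_i - L + 1 valid positions, an orientation, and suffers
## independent per-base substitution errors at rate epsilon.

#' Align reads to an assembly
#'
#' Finds, for every read, all ungapped alignments with at most
#' `max_mismatches` mismatches against the assembly, on the forward strand
#' only when `params$strand_specific`, otherwise on both strands (the
#' reverse-complement of the read is matched). The search is exact: an
#' exact-seed index with `max_mismatches + 1` non-overlapping seeds
#' guarantees every qualifying window is inspected, so the result equals a
#' brute-force scan over all (contig, offset, strand) windows. Reads
#' containing `N` are skipped (they retain only the noise
#' pseudo-alignment); the skipped count is reported via an attribute.
#'
#' @param reads a [read_set()].
#' @param assembly an [assembly()].
#' @param params a [model_params()]; `params$L` must match the read length.
#' @param include_noise if `TRUE` (default) a noise pseudo-alignment row
#'   (`contig = 0`) is appended for every read.
#' @return data frame with columns `read` (index into `reads$reads`),
#'   `contig` (index into `assembly$contigs`, 0 for the noise component),
#'   `start` (0-based, NA for noise), `strand` (`"+"`/`"-"`, NA for noise)
#'   and `mm` (mismatch count), sorted by read then (contig, start,
#'   strand), with attribute `n_skipped`.
#' @export
align_reads <- function(reads, assembly, params, include_noise = TRUE) {
  stopifnot(inherits(reads, "read_set"), inherits(params, "model_params"))
  assembly <- as_assembly(assembly)
  if (reads$L != params$L)
    stop("align_reads: read length ", reads$L, " != params$L ", params$L)
  seed_len <- min(25L, params$L %/% (params$max_mismatches + 1L))
  res <- cpp_align_reads(unname(assembly$contigs), reads$reads$seq,
                         params$L, params$max_mismatches,
                         !params$strand_specific, seed_len)
  aln <- data.frame(read = res$read, contig = res$contig, start = res$start,
                    strand = c("+", "-")[res$strand + 1L], mm = res$mm,
                    stringsAsFactors = FALSE)
  if (include_noise && reads$N > 0) {
    noise <- data.frame(read = seq_len(reads$N), contig = 0L,
                        start = NA_integer_, strand = NA_character_,
                        mm = NA_integer_, stringsAsFactors = FALSE)
    aln <- rbind(aln, noise)
    aln <- aln[order(aln$read, aln$contig, aln$start, aln$strand), ,
               drop = FALSE]
    rownames(aln) <- NULL
  }
  attr(aln, "n_skipped") <- res$n_skipped
  aln
}

#' Log-probability of a read given one candidate alignment
#'
#' For an alignment to contig i (`contig >= 1`):
#' `log[ 1/(l_i - L + 1) * orientation * (1-eps)^(L-mm) * (eps/3)^mm ]`,
#' with orientation 1 for strand-specific data and 1/2 otherwise. For the
#' noise pseudo-alignment (`contig == 0`): the sum of log background
#' probabilities of the read's bases.
#'
#' @param read_seq read sequence (used only by the noise component).
#' @param contig contig index, 0 for noise.
#' @param start 0-based alignment start (checked against the contig).
#' @param mm mismatch count of the alignment.
#' @param assembly an [assembly()].
#' @param params a [model_params()].
#' @return log-probability (scalar).
#' @export
read_given_alignment_loglik <- function(read_seq, contig, start, mm,
                                        assembly, params) {
  L <- params$L
  if (contig == 0)
    return(cpp_noise_loglik(read_seq, params$background)[1])
  assembly <- as_assembly(assembly)
  len <- assembly$lengths[contig]
  if (is.na(start) || start < 0 || start + L > len)
    stop("read_given_alignment_loglik: alignment window outside contig")
  alignment_logprob(len, mm, params)
}

## vectorised core of the per-alignment log-probability (contig >= 1)
alignment_logprob <- function(contig_len, mm, params) {
  orient <- if (params$strand_specific) 0 else log(0.5)
  seqterm <- if (params$epsilon > 0)
    (params$L - mm) * log1p(-params$epsilon) + mm * log(params$epsilon / 3)
  else ifelse(mm == 0, 0, -Inf)
  -log(contig_len - params$L + 1) + orient + seqterm
}

## annotate an alignment table with per-row logp (noise rows included)
alignment_table_logp <- function(aln, reads, assembly, params) {
  logp <- numeric(nrow(aln))
  noise <- aln$contig == 0L
  if (any(noise)) {
    nl <- cpp_noise_loglik(reads$reads$seq, params$background)
    logp[noise] <- nl[aln$read[noise]]
  }
  if (any(!noise)) {
    len <- assembly$lengths[aln$contig[!noise]]
    logp[!noise] <- alignment_logprob(len, aln$mm[!noise], params)
  }
  aln$logp <- logp
  aln
}

#' Fit contig abundances by expectation-maximisation
#'
#' Maximum-likelihood estimation of the mixture weights
#' `theta_0..theta_M` (noise fraction plus one weight per contig) of the
#' read model, by EM over the candidate alignments of every read. The
#' dataset log-likelihood is non-decreasing across iterations; iteration
#' stops when its relative change drops below `tol`. The expected read
#' coverage `lambda_i = N * theta_i / (l_i + L + 1)` of each contig's
#' parent transcript is derived via [convert_theta_to_lambda()].
#'
#' @inheritParams align_reads
#' @param tol relative log-likelihood change convergence threshold.
#' @param max_iter maximum EM iterations.
#' @param alignments optional precomputed table from [align_reads()]
#'   (with noise rows); computed on the fly when `NULL`.
#' @return object of class `abundance_estimate`: list with `theta`
#'   (length M+1, `theta[1]` = noise fraction `theta_0`), `lam` (length M),
#'   `loglik`, `trace` (per-iteration log-likelihood), `iterations`,
#'   `gamma` (per-alignment posterior weights) and the alignment table.
#' @export
em_fit <- function(reads, assembly, params, tol = 1e-4, max_iter = 1000L,
                   alignments = NULL) {
  assembly <- as_assembly(assembly)
  if (is.null(alignments))
    alignments <- align_reads(reads, assembly, params)
  aln <- alignment_table_logp(alignments, reads, assembly, params)
  fit <- cpp_em(aln$read, aln$contig, aln$logp, reads$N, assembly$M,
                tol, max_iter)
  theta <- fit$theta
  lam <- convert_theta_to_lambda(theta, assembly, reads$N, params$L)
  structure(list(theta = theta, lam = lam, loglik = fit$loglik,
                 trace = fit$trace, iterations = fit$iterations,
                 gamma = fit$gamma, alignments = aln,
                 N = reads$N, L = params$L),
            class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf(
    "abundance_estimate: %d contigs, loglik %.3f after %d EM iterations, theta0 = %.4g\n",
    length(x$lam), x$loglik, x$iterations, x$theta[1]))
  invisible(x)
}

#' Convert mixture weights to expected read coverages
#'
#' `lambda_i = N * theta_i / (l_i + L + 1)` for contigs `i >= 1`. The
#' denominator is `l_i + L + 1` (not the contig-level `l_i - L + 1`):
#' under a minimum overlap length of 0, no reads can have started within
#' `L` bases on either side of the contig's read footprint, so the parent
#' transcript offered `l_i + L + 1` candidate start positions for the
#' contig's reads.
#'
#' @param theta numeric vector `theta_0..theta_M` summing to 1.
#' @param assembly an [assembly()] with M contigs.
#' @param N number of reads.
#' @param L read length.
#' @return numeric vector `lambda_1..lambda_M`.
#' @export
convert_theta_to_lambda <- function(theta, assembly, N, L) {
  assembly <- as_assembly(assembly)
  stopifnot(length(theta) == assembly$M + 1,
            abs(sum(theta) - 1) < 1e-6)
  if (assembly$M == 0) return(numeric(0))
  N * theta[-1] / (assembly$lengths + L + 1)
}

#' Posterior probabilities of each read's candidate alignments
#'
#' `P(alignment | read) proportional to theta_i * P(read | alignment)`,
#' including the null (noise) alignment; probabilities sum to 1 within
#' each read.
#'
#' @inheritParams align_reads
#' @param estimate an `abundance_estimate` from [em_fit()].
#' @return the estimate's alignment table with an added `posterior` column.
#' @export
posterior_alignment_probs <- function(reads, assembly, estimate, params) {
  aln <- estimate$alignments
  aln$posterior <- cpp_posteriors(aln$read, aln$contig, aln$logp,
                                  estimate$theta, reads$N)
  aln
}
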