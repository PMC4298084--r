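## Core containers. Coordinates are 0-based half-open internally; the only
## 1-based inclusive fields are read origins (left/right), mirroring the
## usual left(r)/right(r) convention for true read placements.

VALID_BASES <- c("A", "C", "G", "T")

#' Construct an assembly from contig sequences
#'
#' An assembly is an ordered collection of `M` contigs (or scaffolds). Contig
#' sequences may contain `N` only where they represent scaffold gap runs;
#' reads never do.
#'
#' @param seqs named character vector of contig sequences (alphabet ACGTN),
#'   or a list of such. Names are contig ids and must be unique, non-empty
#'   and free of whitespace.
#' @return An object of class `assembly` with elements `contigs` (named
#'   character vector), `M` (contig count), `lengths` (integer vector) and
#'   `total_bases` (sum of lengths).
#' @examples
#' a <- assembly(c(c1 = "ACGTACGT", c2 = "GGGTTT"))
#' a$M
#' a$total_bases
#' @export
assembly <- function(seqs) {
  seqs <- toupper(unlist(seqs))
  if (length(seqs) > 0) {
    ids <- names(seqs)
    if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids))
      stop("assembly: contigs must be named with non-empty ids")
    if (anyDuplicated(ids)) stop("assembly: duplicate contig ids")
    if (any(grepl("[[:space:]]", ids)))
      stop("assembly: contig ids must not contain whitespace")
    if (any(grepl("[^ACGTN]", seqs)))
      stop("assembly: sequences must be over {A,C,G,T,N}")
    if (any(!nzchar(seqs))) stop("assembly: empty contig sequence")
  }
  structure(
    list(contigs = seqs, M = length(seqs),
         lengths = if (length(seqs)) unname(nchar(seqs)) else integer(0),
         total_bases = sum(nchar(seqs))),
    class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("assembly: %d contigs, %d bases\n", x$M, x$total_bases))
  invisible(x)
}

is_assembly <- function(x) inherits(x, "assembly")

as_assembly <- function(x) {
  if (is_assembly(x)) return(x)
  if (inherits(x, "true_assembly")) {
    return(assembly(setNames(x$contigs$seq, x$contigs$id)))
  }
  assembly(x)
}

#' Construct a read set
#'
#' @param seqs character vector of read sequences, all the same length `L`
#'   for single-end data. Reads are uppercased and `U` is converted to `T`.
#' @param ids optional read ids; defaults to `read_1..read_N`. Origins
#'   encoded in ids (see [encode_origin()]) are decoded automatically.
#' @param origin optional data frame with columns `transcript_id`, `left`,
#'   `right` (1-based inclusive) and `strand`; row i is the true origin of
#'   read i, with `NA` transcript_id for unknown origins.
#' @param pair_id optional vector marking mate pairs: the two mates of a
#'   pair share a value; `NA` for unpaired reads.
#' @return Object of class `read_set`: list with `reads` (data frame of
#'   id/seq plus origin columns), `N` and `L`.
#' @export
read_set <- function(seqs, ids = NULL, origin = NULL, pair_id = NULL) {
  seqs <- chartr("u", "t", toupper(seqs))
  seqs <- chartr("U", "T", seqs)
  n <- length(seqs)
  if (n == 0) stop("read_set: no reads")
  L <- unique(nchar(seqs))
  if (length(L) != 1)
    stop("read_set: single-end reads must all have the same length")
  if (is.null(ids)) ids <- paste0("read_", seq_len(n))
  if (anyDuplicated(ids)) stop("read_set: duplicate read ids")
  if (is.null(origin)) {
    origin <- decode_origin(ids)
  } else {
    stopifnot(nrow(origin) == n)
  }
  ok <- !is.na(origin$transcript_id)
  if (any(ok)) {
    width <- origin$right[ok] - origin$left[ok] + 1L
    if (any(width != L))
      stop("read_set: origin right - left + 1 must equal read length")
    if (any(origin$left[ok] < 1L)) stop("read_set: origin left must be >= 1")
  }
  reads <- data.frame(id = as.character(ids), seq = seqs,
                      transcript_id = origin$transcript_id,
                      left = origin$left, right = origin$right,
                      strand = origin$strand,
                      stringsAsFactors = FALSE)
  if (!is.null(pair_id)) reads$pair_id <- pair_id
  structure(list(reads = reads, N = n, L = as.integer(L)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: N = %d reads of length L = %d (%d with origins)\n",
              x$N, x$L, sum(!is.na(x$reads$transcript_id))))
  invisible(x)
}

#' Read model parameters
#'
#' Parameters of the simplified single-end generative read model: reads are
#' drawn from a contig uniformly over its `l - L + 1` start positions (or
#' from a background noise component), with independent per-base
#' substitution errors at rate `epsilon` (the three alternative bases
#' equiprobable). Quality scores and indels are not modelled.
#'
#' @param L read length in bases.
#' @param epsilon per-base substitution error probability, in [0, 0.25).
#' @param strand_specific logical; if `FALSE` (default) reads come from
#'   either strand with probability 1/2 and the aligner searches both.
#' @param background length-4 probability vector over A,C,G,T used by the
#'   noise component. Default uniform.
#' @param max_mismatches maximum mismatches allowed in a candidate
#'   alignment (default 2).
#' @return list of class `model_params`.
#' @export
model_params <- function(L, epsilon = 0.01, strand_specific = FALSE,
                         background = rep(0.25, 4), max_mismatches = 2L) {
  stopifnot(L >= 1, epsilon >= 0, epsilon < 0.25, length(background) == 4,
            abs(sum(background) - 1) < 1e-8, max_mismatches >= 0)
  structure(list(L = as.integer(L), epsilon = epsilon,
                 strand_specific = isTRUE(strand_specific),
                 background = as.numeric(background),
                 max_mismatches = as.integer(max_mismatches)),
            class = "model_params")
}

#' Assembly prior parameters
#'
#' The assembly prior treats each contig as arising from a bag-of-contigs
#' process: a parent transcript length is drawn from a negative binomial,
#' Poisson(lambda) read starts land independently at each valid position,
#' and contigs are the maximal runs of starts whose successive reads
#' overlap by at least `w` bases (w = 0 by default: abutting reads merge).
#'
#' @param nb_size,nb_prob negative binomial transcript-length parameters
#'   (`size` and `prob` as in [stats::rnbinom]). Defaults give a mean of
#'   1500 bases with size 2, a vertebrate-transcriptome scale.
#' @param w minimum overlap length assumed by the model (default 0).
#' @param max_len truncation bound for the transcript-length
#'   marginalisation; defaults to the 0.9999 NB quantile.
#' @return list of class `prior_params`.
#' @seealso [estimate_prior_params()] to fit `nb_size`/`nb_prob` from a
#'   known transcript set by method of moments.
#' @export
prior_params <- function(nb_size = 2, nb_prob = 2 / 1502, w = 0L,
                         max_len = NULL) {
  stopifnot(nb_size > 0, nb_prob > 0, nb_prob < 1, w >= 0)
  if (is.null(max_len))
    max_len <- as.integer(qnbinom(0.9999, size = nb_size, prob = nb_prob))
  structure(list(nb_size = nb_size, nb_prob = nb_prob, w = as.integer(w),
                 max_len = as.integer(max_len)),
            class = "prior_params")
}

#' Estimate negative-binomial length-prior parameters from transcripts
#'
#' Method-of-moments fit of the negative binomial transcript-length
#' distribution used by the assembly prior.
#'
#' @param transcripts named character vector of transcript sequences, or an
#'   `assembly`.
#' @param w,max_len passed through to [prior_params()].
#' @return A `prior_params` object.
#' @export
estimate_prior_params <- function(transcripts, w = 0L, max_len = NULL) {
  lens <- if (is_assembly(transcripts)) transcripts$lengths
          else nchar(unlist(transcripts))
  stopifnot(length(lens) >= 2)
  m <- mean(lens); v <- var(lens)
  if (v <= m) v <- m * 1.5  # underdispersed sample: fall back to mild NB
  size <- m^2 / (v - m)
  prior_params(nb_size = size, nb_prob = size / (size + m), w = w,
               max_len = max_len)
}
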