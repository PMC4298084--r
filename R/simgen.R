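## Synthetic-data generators: transcriptomes with negative-binomial
## lengths and Dirichlet abundances, single-end reads with recorded true
## origins and uniform substitution errors, and the four random
## perturbations of an assembly (substitution, fusion, fission, indel)
## used to probe the score around a ground truth.

#' Simulation configuration
#'
#' Defaults emulate a strand non-specific single-end short-read data set:
#' 76-base reads, 1% substitution error, negative-binomial transcript
#' lengths and a broad (sparse Dirichlet) abundance distribution, so that
#' a simulated transcriptome mixes deeply covered transcripts with
#' fragmented, low-coverage ones.
#'
#' @param n_transcripts number of transcripts.
#' @param N number of reads.
#' @param L read length (default 76).
#' @param epsilon per-base substitution error rate (default 0.01).
#' @param nb_size,nb_mean negative-binomial transcript-length parameters
#'   (size and mean; default size 2, mean 1000).
#' @param alpha Dirichlet concentration for relative abundances
#'   (default 0.3: a broad, realistic spread of expression levels).
#' @param strand_specific simulate strand-specific reads (default FALSE).
#' @param seed mandatory integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts, N, L = 76L, epsilon = 0.01,
                       nb_size = 2, nb_mean = 1000, alpha = 0.3,
                       strand_specific = FALSE, seed) {
  stopifnot(n_transcripts >= 1, N >= 1, L >= 1, epsilon >= 0, epsilon < 1,
            nb_size > 0, nb_mean > 0, alpha > 0, !missing(seed))
  structure(list(n_transcripts = as.integer(n_transcripts), N = as.integer(N),
                 L = as.integer(L), epsilon = epsilon, nb_size = nb_size,
                 nb_prob = nb_size / (nb_size + nb_mean), nb_mean = nb_mean,
                 alpha = alpha, strand_specific = isTRUE(strand_specific),
                 seed = as.integer(seed)),
            class = "sim_config")
}

rand_seq <- function(total) {
  paste(sample(VALID_BASES, total, replace = TRUE), collapse = "")
}

#' Simulate a transcriptome and its relative abundances
#'
#' Transcript sequences are i.i.d. uniform over A,C,G,T with
#' `NB(nb_size, nb_prob)` lengths clamped below at `L`; relative
#' abundances `tau` are Dirichlet(`alpha`) distributed.
#'
#' @param config a [sim_config()].
#' @return list with `transcripts` (named character vector) and `tau`.
#' @export
simulate_transcriptome <- function(config) {
  set.seed(config$seed)
  lens <- pmax(config$L,
               rnbinom(config$n_transcripts, size = config$nb_size,
                       prob = config$nb_prob))
  big <- rand_seq(sum(lens))
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  tx <- substring(big, starts, ends)
  names(tx) <- paste0("tx_", seq_along(tx))
  tau <- stats::rgamma(config$n_transcripts, shape = config$alpha)
  tau <- tau / sum(tau)
  list(transcripts = tx, tau = tau)
}

## introduce k iid substitutions at distinct positions per sequence
## (counts in n_sub); returns the mutated sequences
substitute_bases <- function(seqs, n_sub, L = nchar(seqs)) {
  idx <- rep(seq_along(seqs), n_sub)
  if (!length(idx)) return(seqs)
  pos <- unlist(lapply(which(n_sub > 0),
                       function(i) sample.int(L[i], n_sub[i])))
  old <- substring(seqs[idx], pos, pos)
  alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                nrow = 3,
                dimnames = list(NULL, VALID_BASES))
  new <- alt[cbind(sample.int(3, length(pos), replace = TRUE),
                   match(old, VALID_BASES))]
  while (length(idx)) {
    take <- !duplicated(idx)
    i <- idx[take]
    substr(seqs[i], pos[take], pos[take]) <- new[take]
    idx <- idx[!take]; pos <- pos[!take]; new <- new[!take]
  }
  seqs
}

#' Simulate reads with recorded true origins
#'
#' Each read picks a transcript with probability proportional to
#' `tau * (length - L + 1)` (per-position start rates uniform within a
#' transcript), a start position uniform over the valid positions, a
#' strand (both equiprobable unless strand-specific), and suffers
#' independent substitution errors at rate `epsilon`. True origins are
#' recorded in the read names via [encode_origin()].
#'
#' @param transcripts named character vector; all at least `L` long.
#' @param tau relative transcript abundances (sums to 1).
#' @param config a [sim_config()] (its `N`, `L`, `epsilon`,
#'   `strand_specific` and `seed` are used).
#' @return a [read_set()] with origins.
#' @export
simulate_reads <- function(transcripts, tau, config) {
  L <- config$L
  lens <- nchar(transcripts)
  if (any(lens < L)) stop("simulate_reads: transcript shorter than L")
  set.seed(config$seed + 1L)
  w <- tau * (lens - L + 1)
  ti <- sample.int(length(transcripts), config$N, replace = TRUE,
                   prob = w / sum(w))
  left <- 1L + as.integer(floor(runif(config$N) * (lens[ti] - L + 1)))
  strand <- if (config$strand_specific) rep("+", config$N) else
    sample(c("+", "-"), config$N, replace = TRUE)
  seg <- substring(transcripts[ti], left, left + L - 1L)
  seqs <- ifelse(strand == "+", seg, revcomp(seg))
  n_err <- rbinom(config$N, L, config$epsilon)
  seqs <- substitute_bases(seqs, n_err, L = rep(L, config$N))
  ids <- encode_origin(seq_len(config$N), names(transcripts)[ti],
                       left, left + L - 1L, strand)
  origin <- data.frame(transcript_id = names(transcripts)[ti],
                       left = left, right = left + L - 1L,
                       strand = strand, stringsAsFactors = FALSE)
  read_set(seqs, ids = ids, origin = origin)
}

#' Randomly perturb an assembly
#'
#' `perturb_substitution` substitutes each base independently at the given
#' rate (the replacement always differs from the original).
#' `perturb_indel` introduces insertions and deletions at the given
#' per-position rate (each event an insertion or deletion with equal
#' probability), with lengths drawn from a geometric distribution on
#' 1,2,... with mean 3; a deletion never removes a whole contig.
#'
#' @param assembly an [assembly()].
#' @param rate per-position event rate in (0,1).
#' @param seed integer seed.
#' @return the perturbed [assembly()].
#' @export
perturb_substitution <- function(assembly, rate, seed) {
  assembly <- as_assembly(assembly)
  stopifnot(rate > 0, rate < 1)
  set.seed(seed)
  seqs <- assembly$contigs
  n_sub <- rbinom(assembly$M, assembly$lengths, rate)
  assembly(substitute_bases(seqs, n_sub))
}

#' @rdname perturb_substitution
#' @export
perturb_indel <- function(assembly, rate, seed) {
  assembly <- as_assembly(assembly)
  stopifnot(rate > 0, rate < 1)
  set.seed(seed)
  seqs <- assembly$contigs
  n_ev <- rbinom(assembly$M, assembly$lengths, rate)
  for (i in which(n_ev > 0)) {
    s <- seqs[[i]]
    pos <- sort(sample.int(nchar(s), n_ev[i]), decreasing = TRUE)
    for (p in pos) {  # right-to-left keeps earlier positions valid
      len <- 1L + rgeom(1, 1 / 3)
      if (runif(1) < 0.5) {      # insertion before position p
        s <- paste0(substr(s, 1, p - 1), rand_seq(len),
                    substr(s, p, nchar(s)))
      } else {                   # deletion starting at p, keep >= 1 base
        len <- min(len, nchar(s) - p + 1L)
        if (len >= nchar(s)) len <- nchar(s) - 1L
        if (len < 1L) next
        s <- paste0(substr(s, 1, p - 1), substr(s, p + len, nchar(s)))
      }
    }
    seqs[[i]] <- s
  }
  assembly(seqs)
}

longest_end_overlap <- function(a, b) {
  kmax <- min(nchar(a), nchar(b))
  for (k in seq(kmax, 1)) {
    if (substr(a, nchar(a) - k + 1, nchar(a)) == substr(b, 1, k)) return(k)
  }
  0L
}

#' Fuse randomly selected contig pairs
#'
#' Repeatedly joins two randomly selected contigs head-to-tail; when the
#' joined ends share a common sequence, the contigs are overlapped so the
#' shared sequence appears only once in the fused contig.
#'
#' @param assembly an [assembly()].
#' @param n_events number of fusion events (< M).
#' @param seed integer seed.
#' @return the perturbed [assembly()] with `M - n_events` contigs.
#' @export
perturb_fusion <- function(assembly, n_events, seed) {
  assembly <- as_assembly(assembly)
  if (n_events >= assembly$M)
    stop("perturb_fusion: n_events must be < M")
  set.seed(seed)
  seqs <- assembly$contigs
  for (e in seq_len(n_events)) {
    ij <- sample.int(length(seqs), 2)
    a <- seqs[[ij[1]]]; b <- seqs[[ij[2]]]
    k <- longest_end_overlap(a, b)
    fused <- paste0(a, substr(b, k + 1, nchar(b)))
    nm <- paste0(names(seqs)[ij[1]], "+", names(seqs)[ij[2]])
    seqs <- seqs[-ij]
    seqs[nm] <- fused
  }
  assembly(seqs)
}

#' Split true contigs at sampled read-merge junctions
#'
#' Every position at which two reads were merged during true-contig
#' construction is independently selected as a fission point at the given
#' rate. When the reads at a selected junction overlap, the overlapped
#' segment appears in both resulting fragments.
#'
#' @param ta a `true_assembly` from [true_contigs()] (the perturbation
#'   needs the supporting-read layout).
#' @param rate per-junction fission rate in (0,1).
#' @param seed integer seed.
#' @return an [assembly()] of the fissioned contigs.
#' @export
perturb_fission <- function(ta, rate, seed) {
  if (!inherits(ta, "true_assembly"))
    stop("perturb_fission: needs a true_assembly with its read layout")
  stopifnot(rate > 0, rate < 1)
  set.seed(seed)
  jn <- contig_junctions(ta)
  ct <- ta$contigs
  out <- character(0)
  for (i in seq_len(nrow(ct))) {
    j <- jn[[i]]
    cut <- which(runif(nrow(j)) < rate)
    if (!length(cut)) {
      out[ct$id[i]] <- ct$seq[i]
      next
    }
    bounds_start <- c(ct$start[i], j$next_start[cut])
    bounds_end <- c(j$frag_end[cut], ct$end[i])
    frag <- substring(ta$transcripts[[ct$transcript_id[i]]],
                      bounds_start, bounds_end)
    names(frag) <- sprintf("%s:%d-%d", ct$transcript_id[i],
                           bounds_start, bounds_end)
    ## duplicated overlap segments can create identical fragment ids
    names(frag) <- make.unique(names(frag), sep = "_")
    out[names(frag)] <- frag
  }
  assembly(out)
}

#' Six-read worked example of true-assembly construction
#'
#' One transcript with six reads placed at their true origins: reads 1-2
#' overlap, reads 2-3 are immediately adjacent but not overlapping, an
#' uncovered gap separates reads 3 and 4, and reads 4-6 overlap. At
#' minimum overlap length 0 the true assembly has two contigs; at 1 it has
#' three, because the abutting reads no longer merge.
#'
#' @return list with `transcripts` (one transcript) and `reads` (a
#'   [read_set()] of six 10-base reads with origins).
#' @export
overlap_demo_fixture <- function() {
  tx <- c(demo_tx = paste0("ACGTTGCAAGCTTACGGATCCATGAAGTCC",
                           "GTTACCAGTACGGTCATTGACGATCCGTAA",
                           "CCTTGAGCAT"))
  layout <- data.frame(left = c(1L, 8L, 18L, 40L, 45L, 52L),
                       right = c(10L, 17L, 27L, 49L, 54L, 61L))
  seqs <- substring(tx[[1]], layout$left, layout$right)
  origin <- data.frame(transcript_id = "demo_tx", left = layout$left,
                       right = layout$right, strand = "+",
                       stringsAsFactors = FALSE)
  reads <- read_set(seqs, ids = paste0("demo_read_", 1:6), origin = origin)
  list(transcripts = tx, reads = reads)
}

#' Two-isoform scenario probing abundance-aware scoring
#'
#' A gene with two isoforms: the short isoform (1,000 bases) is the first
#' half of the long one (2,000 bases). 5,000 single-end 100-base reads are
#' simulated with 0.01% sequencing error and a 90:10 split of reads
#' between the short and long isoform. An abundance-aware score should
#' rank the two-isoform assembly above both single-isoform assemblies.
#'
#' @param seed integer seed.
#' @return list with `transcripts`, `reads`, and `assemblies` (named list
#'   `both`, `long_only`, `short_only`).
#' @export
two_isoform_scenario <- function(seed) {
  set.seed(seed)
  long <- rand_seq(2000)
  tx <- c(iso_short = substr(long, 1, 1000), iso_long = long)
  L <- 100L
  ## 90:10 split of generated reads: invert the effective-length weighting
  theta <- c(0.9, 0.1)
  tau <- theta / (nchar(tx) - L + 1)
  tau <- tau / sum(tau)
  cfg <- sim_config(n_transcripts = 2, N = 5000L, L = L, epsilon = 1e-4,
                    alpha = 1, seed = seed)
  reads <- simulate_reads(tx, tau, cfg)
  list(transcripts = tx, reads = reads,
       assemblies = list(both = assembly(tx),
                         long_only = assembly(tx["iso_long"]),
                         short_only = assembly(tx["iso_short"])))
}
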