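## The true assembly of a read set at minimum overlap length w: the maximal
## transcript segments covered by reads whose successive true alignments
## overlap by at least w bases (w = 0: abutting reads also merge).

#' Construct the true contigs implied by known read origins
#'
#' Per transcript, reads are sorted by their left origin coordinate and
#' swept left to right; read `r` extends the open segment iff
#' `current_right - left(r) + 1 >= w`, where `current_right` is the
#' rightmost base covered so far. Each maximal segment is one true contig.
#'
#' @param reads a [read_set()] in which every read has an origin.
#' @param transcripts named character vector of transcript sequences.
#' @param w non-negative integer minimum overlap length.
#' @return object of class `true_assembly`: list with `contigs` (data frame
#'   `id`, `transcript_id`, `start`, `end` (1-based inclusive), `seq`),
#'   `support` (per-contig data frame of supporting reads, ordered by
#'   `left`: `read_id`, `left`, `right`), `w` and `transcripts`.
#' @export
true_contigs <- function(reads, transcripts, w = 0L) {
  stopifnot(inherits(reads, "read_set"), w >= 0)
  rd <- reads$reads
  if (anyNA(rd$transcript_id))
    stop("true_contigs: every read must have an origin")
  unknown <- setdiff(unique(rd$transcript_id), names(transcripts))
  if (length(unknown))
    stop("true_contigs: origin references unknown transcript(s): ",
         paste(head(unknown, 3), collapse = ", "))
  too_far <- rd$right > nchar(transcripts)[match(rd$transcript_id,
                                                 names(transcripts))]
  if (any(too_far))
    stop("true_contigs: read origin extends beyond its transcript")

  tx_order <- match(rd$transcript_id, names(transcripts))
  o <- order(tx_order, rd$left, rd$right)
  rd <- rd[o, , drop = FALSE]
  tid <- rd$transcript_id
  new_tx <- c(TRUE, tid[-1] != tid[-length(tid)])

  ## running rightmost covered base within each transcript
  run_right <- rd$right
  grp_tx <- cumsum(new_tx)
  cm <- stats::ave(rd$right, grp_tx, FUN = cummax)
  prev_right <- c(NA_integer_, cm[-length(cm)])
  breaks <- new_tx | (prev_right - rd$left + 1L < w)
  contig_of <- cumsum(breaks)

  start <- tapply(rd$left, contig_of, function(x) x[1])
  end <- tapply(cm, contig_of, function(x) x[length(x)])
  ctid <- tapply(tid, contig_of, function(x) x[1])
  start <- as.integer(start); end <- as.integer(end)
  ctid <- as.character(ctid)
  seqs <- substring(transcripts[ctid], start, end)
  ids <- sprintf("%s:%d-%d", ctid, start, end)
  support <- split(data.frame(read_id = rd$id, left = rd$left,
                              right = rd$right, stringsAsFactors = FALSE),
                   contig_of)
  names(support) <- ids
  structure(list(
    contigs = data.frame(id = ids, transcript_id = ctid, start = start,
                         end = end, seq = unname(seqs),
                         stringsAsFactors = FALSE),
    support = support, w = as.integer(w), transcripts = transcripts),
    class = "true_assembly")
}

#' @export
print.true_assembly <- function(x, ...) {
  cat(sprintf("true_assembly (w = %d): %d contigs on %d transcripts, %d bases\n",
              x$w, nrow(x$contigs), length(unique(x$contigs$transcript_id)),
              sum(nchar(x$contigs$seq))))
  invisible(x)
}

## the positions at which successive reads were merged within each contig,
## and the read overlap at each junction (used by the fission perturbation)
contig_junctions <- function(ta) {
  lapply(ta$support, function(s) {
    n <- nrow(s)
    if (n < 2) return(data.frame(after_read = integer(0),
                                 frag_end = integer(0),
                                 next_start = integer(0),
                                 overlap = integer(0)))
    cm <- cummax(s$right)
    data.frame(after_read = seq_len(n - 1),
               frag_end = cm[-n],
               next_start = s$left[-1],
               overlap = cm[-n] - s$left[-1] + 1L)
  })
}

#' Build true scaffolds from paired-end links
#'
#' Contigs linked by at least one read pair form the vertices of a graph;
#' each connected component becomes one scaffold, its contigs ordered by
#' transcript coordinate and joined by runs of `N` whose lengths equal the
#' uncovered gaps between them on the parent transcript.
#'
#' @param ta a `true_assembly` from [true_contigs()].
#' @param reads a [read_set()] whose `reads` carry `pair_id` (both mates of
#'   a pair share the value) and origins.
#' @return named character vector of scaffold sequences.
#' @export
true_scaffolds <- function(ta, reads) {
  rd <- reads$reads
  if (is.null(rd$pair_id)) stop("true_scaffolds: reads carry no pair_id")
  ct <- ta$contigs
  ## locate each read's contig (w = 0 contigs are disjoint per transcript)
  loc <- rep(NA_integer_, nrow(rd))
  for (t in unique(ct$transcript_id)) {
    ci <- which(ct$transcript_id == t)
    ri <- which(rd$transcript_id == t)
    if (!length(ri)) next
    ord <- order(ct$start[ci])
    ci <- ci[ord]
    j <- findInterval(rd$left[ri], ct$start[ci])
    ok <- j >= 1 & rd$right[ri] <= ct$end[ci][pmax(j, 1)]
    loc[ri[ok]] <- ci[j[ok]]
  }
  pairs <- split(seq_len(nrow(rd)), rd$pair_id)
  pairs <- pairs[lengths(pairs) == 2]
  edges <- integer(0)
  for (p in pairs) {
    a <- loc[p[1]]; b <- loc[p[2]]
    if (is.na(a) || is.na(b) || a == b) next
    if (ct$transcript_id[a] != ct$transcript_id[b])
      stop("true_scaffolds: mates with origins on different transcripts")
    edges <- c(edges, a, b)
  }
  g <- igraph::make_empty_graph(n = nrow(ct), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  out <- character(0)
  for (cmp in unique(comp)) {
    ci <- which(comp == cmp)
    ci <- ci[order(ct$start[ci])]
    if (length(ci) == 1) {
      out[ct$id[ci]] <- ct$seq[ci]
    } else {
      gaps <- ct$start[ci][-1] - ct$end[ci][-length(ci)] - 1L
      parts <- character(2 * length(ci) - 1)
      parts[seq(1, by = 2, length.out = length(ci))] <- ct$seq[ci]
      parts[seq(2, by = 2, length.out = length(ci) - 1)] <-
        strrep("N", pmax(gaps, 0L))
      out[paste(ct$id[ci], collapse = "|")] <- paste(parts, collapse = "")
    }
  }
  out
}

#' Estimate the true assembly from reads and reference transcripts
#'
#' Aligns reads against the reference transcripts, fits abundances by EM,
#' samples exactly one alignment per read from its posterior distribution
#' (the null/noise alignment discards the read), treats the sampled
#' alignments as true origins, and constructs the true contigs at minimum
#' overlap length `w`. With paired reads (`pair_id` present), contigs
#' spanned by a sampled pair are joined into scaffolds.
#'
#' @param reads a [read_set()].
#' @param reference_transcripts named character vector of transcript
#'   sequences.
#' @param params a [model_params()]; defaults to `model_params(reads$L)`.
#' @param seed integer seed making the posterior sampling reproducible.
#' @param w minimum overlap length for contig construction (default 0).
#' @return an [assembly()] of the estimated true contigs (or scaffolds).
#' @export
estimate_true_assembly <- function(reads, reference_transcripts,
                                   params = NULL, seed = 1L, w = 0L) {
  if (is.null(params)) params <- model_params(L = reads$L)
  ref <- assembly(reference_transcripts)
  fit <- em_fit(reads, ref, params)
  aln <- posterior_alignment_probs(reads, ref, fit, params)
  set.seed(seed %% .Machine$integer.max)

  ## inverse-CDF sample of one alignment per read, in the deterministic
  ## alignment order (noise first, then contig/start/strand)
  u <- runif(reads$N)[aln$read]
  csum <- cumsum(aln$posterior)
  last <- c(which(aln$read[-1] != aln$read[-nrow(aln)]), nrow(aln))
  offset <- c(0, csum[last[-length(last)]])
  within <- csum - offset[cumsum(c(TRUE, aln$read[-1] != aln$read[-nrow(aln)]))]
  hit <- within + 1e-12 >= u
  sel <- which(hit)[!duplicated(aln$read[hit])]

  keep <- aln$contig[sel] > 0
  sel <- sel[keep]
  if (!length(sel)) stop("estimate_true_assembly: all reads sampled to noise")
  origin <- data.frame(
    transcript_id = names(reference_transcripts)[aln$contig[sel]],
    left = aln$start[sel] + 1L,
    right = aln$start[sel] + params$L,
    strand = aln$strand[sel], stringsAsFactors = FALSE)
  rd <- reads$reads[aln$read[sel], , drop = FALSE]
  sampled <- read_set(rd$seq, ids = rd$id, origin = origin,
                      pair_id = rd$pair_id)
  ta <- true_contigs(sampled, reference_transcripts, w = w)
  if (!is.null(rd$pair_id)) {
    ## drop pairs whose mates were sampled onto different transcripts
    tx_of <- tapply(origin$transcript_id, rd$pair_id,
                    function(x) length(unique(x)))
    bad <- names(tx_of)[tx_of > 1]
    if (length(bad)) {
      ok <- !(rd$pair_id %in% bad)
      sampled <- read_set(rd$seq[ok], ids = rd$id[ok],
                          origin = origin[ok, , drop = FALSE],
                          pair_id = rd$pair_id[ok])
      ta <- true_contigs(sampled, reference_transcripts, w = w)
    }
    return(assembly(true_scaffolds(ta, sampled)))
  }
  as_assembly(ta)
}
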