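## Reference-based measures: contig- and nucleotide-level
## recall/precision/F1 under local alignments between assembly and
## reference, the k-mer compression score, and N50.

#' Compute local alignments between an assembly and a reference
#'
#' Seed-and-extend local alignment: exact k-mer seeds, greedy collinear
#' chaining within a diagonal band (small gaps stitched, indel bases
#' counted), and ungapped X-drop end extension. Both strands are searched.
#' Thresholds are permissive by design; the measures downstream apply
#' their own criteria.
#'
#' @param assembly an [assembly()] (query side).
#' @param reference named character vector of reference sequences, or an
#'   [assembly()] (target side).
#' @param seed_k exact seed length (default 12, small enough that any
#'   alignment of at least 50 bp at 95% identity or better contains a
#'   seed).
#' @param max_gap maximum per-side gap stitched within one alignment.
#' @param band maximum diagonal drift within one alignment.
#' @param xdrop X-drop threshold for end extension.
#' @param min_matches minimum matching bases for an alignment to be kept.
#' @return object of class `local_alignments`: data frame with columns
#'   `asm_id`, `ref_id`, `strand`, `asm_start`, `asm_end`, `ref_start`,
#'   `ref_end` (0-based half-open; query coords on the forward strand),
#'   `matches`, `mismatches`, `indel_bases`, plus attributes
#'   `ref_match_pos` / `asm_match_pos` (per-alignment 0-based positions of
#'   identical bases) and the two sequence sets.
#' @export
align_assembly_to_reference <- function(assembly, reference, seed_k = 12L,
                                        max_gap = 100L, band = 40L,
                                        xdrop = 20L, min_matches = 30L) {
  assembly <- as_assembly(assembly)
  reference <- as_assembly(reference)
  res <- cpp_local_align(unname(assembly$contigs), unname(reference$contigs),
                         as.integer(seed_k), as.integer(max_gap),
                         as.integer(band), as.integer(xdrop),
                         as.integer(min_matches), TRUE)
  df <- data.frame(
    asm_id = names(assembly$contigs)[res$q_id],
    ref_id = names(reference$contigs)[res$t_id],
    strand = res$strand,
    asm_start = res$q_start, asm_end = res$q_end,
    ref_start = res$t_start, ref_end = res$t_end,
    matches = res$matches, mismatches = res$mismatches,
    indel_bases = res$indel_bases, stringsAsFactors = FALSE)
  structure(df, ref_match_pos = res$t_match_pos,
            asm_match_pos = res$q_match_pos,
            assembly = assembly, reference = reference,
            class = c("local_alignments", "data.frame"))
}

#' Convert BLAT PSL records to local alignments
#'
#' Re-derives per-position identity by comparing the aligned blocks of the
#' actual sequences, so the PSL only provides the block coordinates.
#'
#' @param psl data frame from [read_psl()].
#' @param assembly,reference the sequence sets the PSL refers to (query =
#'   assembly, target = reference).
#' @return a `local_alignments` object (see
#'   [align_assembly_to_reference()]).
#' @export
psl_to_alignments <- function(psl, assembly, reference) {
  assembly <- as_assembly(assembly)
  reference <- as_assembly(reference)
  bad <- setdiff(psl$qName, names(assembly$contigs))
  if (length(bad)) stop("psl: unknown assembly id ", bad[1])
  bad <- setdiff(psl$tName, names(reference$contigs))
  if (length(bad)) stop("psl: unknown reference id ", bad[1])
  n <- nrow(psl)
  ref_pos <- vector("list", n); asm_pos <- vector("list", n)
  matches <- integer(n); mismatches <- integer(n)
  for (i in seq_len(n)) {
    q <- assembly$contigs[[psl$qName[i]]]
    t <- reference$contigs[[psl$tName[i]]]
    qlen <- nchar(q)
    minus <- psl$strand[i] == "-"
    if (minus) q <- revcomp(q)
    sizes <- as.integer(strsplit(sub(",$", "", psl$blockSizes[i]), ",")[[1]])
    qs <- as.integer(strsplit(sub(",$", "", psl$qStarts[i]), ",")[[1]])
    ts <- as.integer(strsplit(sub(",$", "", psl$tStarts[i]), ",")[[1]])
    rp <- integer(0); ap <- integer(0)
    for (b in seq_along(sizes)) {
      qb <- strsplit(substr(q, qs[b] + 1L, qs[b] + sizes[b]), "")[[1]]
      tb <- strsplit(substr(t, ts[b] + 1L, ts[b] + sizes[b]), "")[[1]]
      eq <- which(qb == tb & qb %in% VALID_BASES)
      rp <- c(rp, ts[b] + eq - 1L)
      qpos <- qs[b] + eq - 1L
      if (minus) qpos <- qlen - 1L - qpos
      ap <- c(ap, qpos)
    }
    ref_pos[[i]] <- rp; asm_pos[[i]] <- ap
    matches[i] <- length(rp)
    mismatches[i] <- sum(sizes) - length(rp)
  }
  df <- data.frame(
    asm_id = psl$qName, ref_id = psl$tName, strand = psl$strand,
    asm_start = psl$qStart, asm_end = psl$qEnd,
    ref_start = psl$tStart, ref_end = psl$tEnd,
    matches = matches, mismatches = mismatches,
    indel_bases = psl$qBaseInsert + psl$tBaseInsert,
    stringsAsFactors = FALSE)
  structure(df, ref_match_pos = ref_pos, asm_match_pos = asm_pos,
            assembly = assembly, reference = reference,
            class = c("local_alignments", "data.frame"))
}

non_n_length <- function(seqs) {
  nchar(seqs) - nchar(gsub("[^N]", "", seqs))
}

#' Contig-level recall, precision and F1
#'
#' An assembly sequence and a reference sequence are matched if their best
#' local alignment recovers at least 99% of the non-N length of *both*
#' sequences identically and contains indel bases totalling at most 1% of
#' the length of either sequence (whichever is most stringent). Recall and
#' precision come from the maximum-cardinality matching of the resulting
#' bipartite graph.
#'
#' @param alignments a `local_alignments` object.
#' @param min_identity,max_indel_frac the 99%/1% criteria.
#' @return list with `recall`, `precision`, `f1`, and `matched_pairs`
#'   (data frame of matched assembly/reference ids).
#' @export
contig_level_scores <- function(alignments, min_identity = 0.99,
                                max_indel_frac = 0.01) {
  assembly <- attr(alignments, "assembly")
  reference <- attr(alignments, "reference")
  asm_nn <- non_n_length(assembly$contigs)
  ref_nn <- non_n_length(reference$contigs)
  edges <- NULL
  if (nrow(alignments)) {
    key <- paste(alignments$asm_id, alignments$ref_id, sep = "\r")
    best <- tapply(alignments$matches, key, max)
    idx <- which(alignments$matches == best[key])
    al <- alignments[idx[!duplicated(key[idx])], , drop = FALSE]
    ai <- match(al$asm_id, names(assembly$contigs))
    ri <- match(al$ref_id, names(reference$contigs))
    if (anyNA(ai) || anyNA(ri))
      stop("contig_level_scores: alignment references unknown sequence id")
    ok <- al$matches >= min_identity * asm_nn[ai] &
      al$matches >= min_identity * ref_nn[ri] &
      al$indel_bases <= max_indel_frac *
        pmin(assembly$lengths[ai], reference$lengths[ri])
    edges <- al[ok, c("asm_id", "ref_id"), drop = FALSE]
  }
  n_match <- 0L
  matched <- data.frame(asm_id = character(0), ref_id = character(0))
  if (!is.null(edges) && nrow(edges)) {
    verts <- c(paste0("A\r", unique(edges$asm_id)),
               paste0("R\r", unique(edges$ref_id)))
    g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
    igraph::V(g)$name <- verts
    igraph::V(g)$type <- startsWith(verts, "R\r")
    g <- igraph::add_edges(g, rbind(match(paste0("A\r", edges$asm_id), verts),
                                    match(paste0("R\r", edges$ref_id), verts)))
    mm <- igraph::max_bipartite_match(g)
    n_match <- mm$matching_size
    ma <- mm$matching[startsWith(names(mm$matching), "A\r")]
    ma <- ma[!is.na(ma)]
    matched <- data.frame(asm_id = sub("^A\r", "", names(ma)),
                          ref_id = sub("^R\r", "", unname(ma)),
                          stringsAsFactors = FALSE)
  }
  recall <- if (reference$M) n_match / reference$M else 0
  precision <- if (assembly$M) n_match / assembly$M else 0
  list(recall = recall, precision = precision,
       f1 = f1_score(recall, precision), matched_pairs = matched)
}

f1_score <- function(recall, precision) {
  if (recall + precision == 0) return(0)
  2 * recall * precision / (recall + precision)
}

## greedy single-alignment-per-position selection; returns the number of
## correctly recovered target-side positions
greedy_recovered <- function(n_target_pos, target_of, span_start, span_end,
                             match_pos, aln_len, tie_ids) {
  offsets <- c(0, cumsum(n_target_pos))[seq_along(n_target_pos)]
  names(offsets) <- names(n_target_pos)
  assigned <- rep(FALSE, sum(n_target_pos))
  active <- rep(TRUE, length(target_of))
  total <- 0L
  ord_len <- order(-aln_len, tie_ids)
  while (any(active)) {
    gains <- vapply(which(active), function(i) {
      sum(!assigned[offsets[target_of[i]] + match_pos[[i]] + 1L])
    }, integer(1))
    if (!length(gains) || max(gains) == 0L) break
    cand <- which(active)[gains == max(gains)]
    pick <- cand[order(match(cand, ord_len))][1]
    idx <- offsets[target_of[pick]] +
      seq.int(span_start[pick] + 1L, span_end[pick])
    newly <- !assigned[offsets[target_of[pick]] + match_pos[[pick]] + 1L]
    total <- total + sum(newly)
    assigned[idx] <- TRUE
    active[pick] <- FALSE
  }
  total
}

#' Nucleotide-level recall, precision and F1
#'
#' Alignments are selected greedily in order of their marginal
#' contribution to the nucleotide recall (newly recovered identical
#' reference positions), each reference position being assigned to at most
#' one alignment; ties broken by longer alignment, then lexicographic ids.
#' Precision is computed symmetrically with the roles of assembly and
#' reference swapped.
#'
#' @param alignments a `local_alignments` object.
#' @return list with `recall`, `precision` and `f1`.
#' @export
nucleotide_level_scores <- function(alignments) {
  assembly <- attr(alignments, "assembly")
  reference <- attr(alignments, "reference")
  if (!nrow(alignments) || assembly$M == 0 || reference$M == 0) {
    return(list(recall = 0, precision = 0, f1 = 0))
  }
  aln_len <- alignments$matches + alignments$mismatches +
    alignments$indel_bases
  tie_ids <- paste(alignments$asm_id, alignments$ref_id, alignments$strand,
                   alignments$ref_start)
  rec_n <- greedy_recovered(
    setNames(reference$lengths, names(reference$contigs)),
    alignments$ref_id, alignments$ref_start, alignments$ref_end,
    attr(alignments, "ref_match_pos"), aln_len, tie_ids)
  prec_n <- greedy_recovered(
    setNames(assembly$lengths, names(assembly$contigs)),
    alignments$asm_id, alignments$asm_start, alignments$asm_end,
    attr(alignments, "asm_match_pos"), aln_len, tie_ids)
  recall <- rec_n / sum(reference$lengths)
  precision <- prec_n / sum(assembly$lengths)
  list(recall = recall, precision = precision,
       f1 = f1_score(recall, precision))
}

#' K-mer compression score
#'
#' `KC = WKR - ICR`. WKR (weighted k-mer recall) sums, over the distinct
#' k-mers present in the assembly, the reference k-mer frequency profile
#' `p(r) = sum_b n(r,b) tau(b) / sum_b n(b) tau(b)` weighted by the
#' relative abundances `tau`. ICR (inverse compression rate) is the total
#' number of assembly bases divided by the total read bases `N * L`.
#'
#' @param assembly an [assembly()].
#' @param reference named character vector (or [assembly()]) of reference
#'   sequences.
#' @param tau relative abundances of the reference sequences (summing
#'   to 1), `"uniform"`, or `NULL` to estimate from `reads` via [em_fit()].
#' @param N,L read count and read length (`N * L` = total read bases).
#' @param k k-mer size; defaults to the read length `L`.
#' @param reads optional [read_set()] used to estimate `tau` when
#'   `tau = NULL`.
#' @param strand_specific if `FALSE` (default) k-mers are counted
#'   strand-canonically (a k-mer and its reverse complement are one).
#' @param params optional [model_params()] for the tau estimation.
#' @return list with `kc`, `wkr` and `icr`.
#' @export
kc_score <- function(assembly, reference, tau = NULL, N, L, k = NULL,
                     reads = NULL, strand_specific = FALSE, params = NULL) {
  assembly <- as_assembly(assembly)
  reference <- as_assembly(reference)
  if (is.null(k)) k <- L
  if (k < 1) stop("kc_score: k must be >= 1")
  if (all(reference$lengths < k))
    stop("kc_score: k is larger than every reference sequence")
  if (is.null(tau)) {
    if (is.null(reads))
      stop("kc_score: provide tau or reads to estimate it from")
    if (is.null(params))
      params <- model_params(L = reads$L,
                             strand_specific = strand_specific)
    fit <- em_fit(reads, reference, params)
    eff <- pmax(reference$lengths - reads$L + 1, 1)
    tau <- fit$theta[-1] / eff
    if (sum(tau) <= 0) stop("kc_score: estimated abundances are all zero")
    tau <- tau / sum(tau)
  } else if (identical(tau, "uniform")) {
    tau <- rep(1 / reference$M, reference$M)
  }
  stopifnot(length(tau) == reference$M, abs(sum(tau) - 1) < 1e-6)
  res <- cpp_wkr(unname(reference$contigs), as.numeric(tau),
                 unname(assembly$contigs), as.integer(k), !strand_specific)
  icr <- assembly$total_bases / (N * L)
  list(kc = res$wkr - icr, wkr = res$wkr, icr = icr)
}

#' N50 of an assembly
#'
#' The length of the longest contig such that all contigs of at least that
#' length together comprise at least 50% of the bases of the assembly.
#'
#' @param assembly an [assembly()] (must be non-empty).
#' @return integer contig length.
#' @export
n50 <- function(assembly) {
  assembly <- as_assembly(assembly)
  if (assembly$M == 0) stop("n50: empty assembly")
  len <- sort(assembly$lengths, decreasing = TRUE)
  len[which(cumsum(len) >= sum(len) / 2)[1]]
}

#' Full reference-based evaluation report
#'
#' @inheritParams kc_score
#' @param alignments optional precomputed `local_alignments`; computed
#'   internally otherwise.
#' @return list with `contig` and `nucleotide` score lists, `kc` scores
#'   and `n50`.
#' @export
ref_eval_report <- function(assembly, reference, tau = "uniform", N, L,
                            k = NULL, reads = NULL, alignments = NULL,
                            strand_specific = FALSE) {
  assembly <- as_assembly(assembly)
  reference <- as_assembly(reference)
  if (is.null(alignments))
    alignments <- align_assembly_to_reference(assembly, reference)
  list(contig = contig_level_scores(alignments),
       nucleotide = nucleotide_level_scores(alignments),
       kc = kc_score(assembly, reference, tau = tau, N = N, L = L, k = k,
                     reads = reads, strand_specific = strand_specific),
       n50 = if (assembly$M) n50(assembly) else NA_integer_)
}
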