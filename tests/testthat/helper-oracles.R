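## Independent oracles and small fixtures used across the suite.

rseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")

## brute-force alignment oracle: scan every (contig, offset, strand) window
brute_align <- function(reads, asm, params) {
  out <- NULL
  strands <- if (params$strand_specific) "+" else c("+", "-")
  for (r in seq_len(reads$N)) {
    for (st in strands) {
      q <- if (st == "+") reads$reads$seq[r]
           else asmeval:::revcomp(reads$reads$seq[r])
      qc <- strsplit(q, "")[[1]]
      for (ci in seq_len(asm$M)) {
        s <- asm$contigs[[ci]]
        if (nchar(s) < params$L) next
        for (p in 0:(nchar(s) - params$L)) {
          mm <- sum(strsplit(substr(s, p + 1, p + params$L), "")[[1]] != qc)
          if (mm <= params$max_mismatches)
            out <- rbind(out, data.frame(read = r, contig = ci, start = p,
                                         strand = st, mm = mm,
                                         stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(out)) return(out)
  out <- out[order(out$read, out$contig, out$start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

## brute-force true-contig oracle: enumerate candidate segments and verify
## the defining conditions (ordered covering chain with overlaps >= w,
## endpoints on read boundaries, maximality) directly
brute_true_contigs <- function(reads, w) {
  rd <- reads$reads
  segments <- NULL
  for (t in unique(rd$transcript_id)) {
    sub <- rd[rd$transcript_id == t, , drop = FALSE]
    cand <- expand.grid(start = unique(sub$left), end = unique(sub$right))
    cand <- cand[cand$start <= cand$end, , drop = FALSE]
    ok <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      s <- cand$start[i]; e <- cand$end[i]
      ## greedy chain: start from a read with left == s, repeatedly take
      ## the furthest-reaching read that overlaps the chain by >= w
      inside <- sub[sub$left >= s & sub$right <= e, , drop = FALSE]
      if (!any(inside$left == s)) next
      reach <- max(inside$right[inside$left == s])
      repeat {
        if (reach >= e) break
        nxt <- inside[inside$left <= reach + 1 - w & inside$right > reach, ,
                      drop = FALSE]
        if (!nrow(nxt)) break
        reach <- max(nxt$right)
      }
      ok[i] <- (reach >= e) && any(inside$right == e)
    }
    cand <- cand[ok, , drop = FALSE]
    ## maximality: drop segments strictly contained in another valid one
    if (nrow(cand) > 1) {
      keep <- vapply(seq_len(nrow(cand)), function(i) {
        !any(cand$start <= cand$start[i] & cand$end >= cand$end[i] &
               (cand$start < cand$start[i] | cand$end > cand$end[i]))
      }, logical(1))
      cand <- cand[keep, , drop = FALSE]
    }
    if (nrow(cand))
      segments <- rbind(segments,
                        data.frame(transcript_id = t, start = cand$start,
                                   end = cand$end, stringsAsFactors = FALSE))
  }
  segments[order(segments$transcript_id, segments$start), , drop = FALSE]
}

## tiny simulated data set shared by several tests
small_sim <- function(seed = 5, n_tx = 8, N = 2000, L = 40, eps = 0.005) {
  cfg <- sim_config(n_transcripts = n_tx, N = N, L = L, epsilon = eps,
                    nb_mean = 400, nb_size = 4, alpha = 1, seed = seed)
  sim <- simulate_transcriptome(cfg)
  reads <- simulate_reads(sim$transcripts, sim$tau, cfg)
  list(cfg = cfg, transcripts = sim$transcripts, tau = sim$tau,
       reads = reads)
}

## all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_perms(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
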