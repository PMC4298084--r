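## Sequence and alignment I/O plus the read-name origin encoding shared by
## the simulator and the true-assembly builder.

#' Read a FASTA (or FASTQ) file into named sequences
#'
#' Sequences are uppercased and RNA `U` is converted to `T`. FASTQ quality
#' strings are parsed and discarded (the read model has no quality term).
#' Gzipped input is handled transparently.
#'
#' @param path path to a FASTA/FASTQ file (optionally .gz).
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("read_fasta: malformed ", format, " in ", path,
                             ": ", conditionMessage(e)))
  seqs <- chartr("Uu", "Tt", as.character(set))
  seqs <- toupper(seqs)
  ids <- sub("[[:space:]].*$", "", names(set))
  if (any(!nzchar(ids)))
    stop("read_fasta: record with empty id in ", path)
  if (anyDuplicated(ids))
    stop("read_fasta: duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  empties <- which(!nzchar(seqs))
  if (length(empties))
    stop("read_fasta: empty sequence for record '", ids[empties[1]], "'")
  names(seqs) <- ids
  seqs
}

#' Write named sequences to a FASTA file
#'
#' Round-trips with [read_fasta()]. Ids containing whitespace are rejected
#' because the part after the first space would be lost on re-reading.
#'
#' @param seqs named character vector of sequences (may be empty).
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- unlist(seqs)
  if (length(seqs)) {
    ids <- names(seqs)
    if (is.null(ids) || any(!nzchar(ids)))
      stop("write_fasta: sequences must have non-empty ids")
    if (any(grepl("[[:space:]]", ids)))
      stop("write_fasta: ids must not contain whitespace")
    if (anyDuplicated(ids)) stop("write_fasta: duplicate ids")
    set <- Biostrings::BStringSet(seqs)
    names(set) <- ids
    Biostrings::writeXStringSet(set, path, width = width)
  } else {
    file.create(path)
  }
  invisible(path)
}

#' Encode / decode true read origins in read names
#'
#' The simulator records each read's true origin in its name as
#' `{serial}_{transcript_id}_{left}_{right}_{strand}` with 1-based
#' inclusive `left`/`right`. [decode_origin()] is total: names not produced
#' by [encode_origin()] decode to an unknown (NA) origin rather than an
#' error.
#'
#' @param serial integer (or string) serial number distinguishing reads.
#' @param transcript_id origin transcript id.
#' @param left,right 1-based inclusive bounds of the read on the transcript.
#' @param strand `"+"` or `"-"`.
#' @return `encode_origin`: character vector of read names.
#' @export
encode_origin <- function(serial, transcript_id, left, right, strand) {
  stopifnot(all(left >= 1), all(right >= left), all(strand %in% c("+", "-")))
  sprintf("%s_%s_%d_%d_%s", as.character(serial), transcript_id,
          as.integer(left), as.integer(right), strand)
}

#' @rdname encode_origin
#' @param name character vector of read names.
#' @param L optional read length; when given, decoded origins with
#'   `right - left + 1 != L` raise a validation error.
#' @return `decode_origin`: data frame with columns `transcript_id`,
#'   `left`, `right`, `strand` (NA rows for non-conforming names).
#' @export
decode_origin <- function(name, L = NULL) {
  pat <- "^[^_]+_(.+)_([0-9]+)_([0-9]+)_([+-])$"
  hit <- grepl(pat, name)
  out <- data.frame(transcript_id = rep(NA_character_, length(name)),
                    left = NA_integer_, right = NA_integer_,
                    strand = NA_character_, stringsAsFactors = FALSE)
  if (any(hit)) {
    m <- regmatches(name[hit], regexec(pat, name[hit]))
    out$transcript_id[hit] <- vapply(m, `[`, "", 2L)
    out$left[hit] <- as.integer(vapply(m, `[`, "", 3L))
    out$right[hit] <- as.integer(vapply(m, `[`, "", 4L))
    out$strand[hit] <- vapply(m, `[`, "", 5L)
    bad <- hit & (out$left < 1L | out$right < out$left)
    if (any(bad)) stop("decode_origin: invalid coordinates in read name ",
                       name[which(bad)[1]])
    if (!is.null(L)) {
      badL <- hit & (out$right - out$left + 1L != as.integer(L))
      if (any(badL))
        stop("decode_origin: origin width differs from read length for ",
             name[which(badL)[1]])
    }
  }
  out
}

PSL_COLS <- c("matches", "misMatches", "repMatches", "nCount", "qNumInsert",
              "qBaseInsert", "tNumInsert", "tBaseInsert", "strand", "qName",
              "qSize", "qStart", "qEnd", "tName", "tSize", "tStart", "tEnd",
              "blockCount", "blockSizes", "qStarts", "tStarts")

#' Read a 21-column PSL local-alignment file
#'
#' The optional 5-line header is skipped. Coordinates are kept 0-based
#' half-open, as in the PSL convention.
#'
#' @param path path to a PSL file (optionally .gz).
#' @return data frame with the 21 standard PSL columns; `blockSizes`,
#'   `qStarts` and `tStarts` are kept as comma-separated strings.
#' @export
read_psl <- function(path) {
  if (!file.exists(path)) stop("read_psl: no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  ## header: "psLayout version 3", blank-ish lines, column names, dashes
  if (length(lines) && grepl("^psLayout", lines[1])) {
    dash <- grep("^-+$", lines)
    if (!length(dash)) stop("read_psl: malformed PSL header in ", path)
    lines <- lines[-seq_len(dash[1])]
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as.data.frame(setNames(rep(list(character(0)), 21), PSL_COLS))
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 21))
    stop("read_psl: line ", which(nf != 21)[1], " has ", nf[nf != 21][1],
         " columns, expected 21")
  out <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(out) <- PSL_COLS
  int_cols <- setdiff(PSL_COLS, c("strand", "qName", "tName", "blockSizes",
                                  "qStarts", "tStarts"))
  for (cc in int_cols) out[[cc]] <- as.integer(out[[cc]])
  bad <- with(out, qStart >= qEnd | qEnd > qSize | tStart >= tEnd |
                tEnd > tSize)
  if (any(bad)) stop("read_psl: inconsistent coordinates on line ",
                     which(bad)[1])
  nblock <- function(s) lengths(strsplit(sub(",$", "", s), ","))
  if (any(nblock(out$blockSizes) != out$blockCount) ||
      any(nblock(out$qStarts) != out$blockCount) ||
      any(nblock(out$tStarts) != out$blockCount))
    stop("read_psl: block lists do not match blockCount")
  out
}

## 1-based inclusive <-> 0-based half-open interval conversion. Kept as
## named helpers so the convention is applied in exactly one place.
to0h <- function(left, right) list(start = left - 1L, end = right)
to1i <- function(start, end) list(left = start + 1L, right = end)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
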