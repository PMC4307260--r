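#' Minimal exact-seed read mapper
#'
#' Maps reads to contigs by exact k-mer seeding and ungapped full-length
#' extension, counting mismatches. Non-overlapping seed windows along the
#' read are tried on both strands; among candidate placements the
#' smallest mismatch count wins, and a read whose best count is achieved
#' at more than one distinct location is kept at the first location
#' (contig id, then position) but flagged non-unique (MAPQ 0). Reads with
#' best mismatch count above `max_mismatches`, or with no exact seed
#' window, are dropped. The mapper is ungapped by design; gapped
#' alignments (indels) enter the pipeline through [read_sam()].
#'
#' @param reads data.frame with `read_id`, `seq` and optionally `qual`
#'   (e.g. a `read_set` from [generate_reads()]).
#' @param contigs named character vector of reference contigs.
#' @param seed_k seed length in bp (<= read length).
#' @param max_mismatches maximum mismatches for a reported placement.
#' @return data.frame of class `read_alignments`: `read_id`, `contig`,
#'   `start` (1-based on the contig), `strand`, `mismatches`, `unique`,
#'   `mapq`, `cigar`, `seq`, `qual` (reference orientation).
#' @export
map_reads <- function(reads, contigs, seed_k = 20, max_mismatches = 3) {
  if (length(contigs) == 0) stop_("contig set must not be empty")
  if (any(nchar(reads$seq) < seed_k))
    stop_("seed_k exceeds the length of some reads")
  index <- kmer_index(contigs, seed_k)
  clen <- nchar(contigs)
  cnames <- names(contigs)
  if (is.null(reads$qual)) reads$qual <- strrep("I", nchar(reads$seq))

  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    fwd <- reads$seq[i]
    rev <- revcomp(fwd)
    L <- nchar(fwd)
    cand <- rbind(candidate_sites(fwd, "+", index, seed_k, L),
                  candidate_sites(rev, "-", index, seed_k, L))
    if (is.null(cand) || nrow(cand) == 0) next
    cand <- unique(cand)
    cand <- cand[cand$start >= 1 & cand$start + L - 1 <= clen[cand$ci], ,
                 drop = FALSE]
    if (nrow(cand) == 0) next
    mm <- integer(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      refseq <- substr(contigs[[cand$ci[k]]], cand$start[k],
                       cand$start[k] + L - 1)
      q <- if (cand$strand[k] == "+") fwd else rev
      mm[k] <- count_mismatches(q, refseq)
    }
    best <- min(mm)
    if (best > max_mismatches) next
    hits <- cand[mm == best, , drop = FALSE]
    hits <- hits[order(hits$ci, hits$start, hits$strand), , drop = FALSE]
    uniq <- nrow(unique(hits[, c("ci", "start")])) == 1
    h <- hits[1, ]
    oriented_seq <- if (h$strand == "+") fwd else rev
    oriented_qual <- if (h$strand == "+") reads$qual[i] else
      collapse(rev(chars(reads$qual[i])))
    out[[i]] <- data.frame(
      read_id = reads$read_id[i], contig = cnames[h$ci], start = h$start,
      strand = h$strand, mismatches = best, unique = uniq,
      mapq = if (uniq) 60L else 0L, cigar = paste0(L, "M"),
      seq = oriented_seq, qual = oriented_qual, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(read_id = character(), contig = character(),
                      start = integer(), strand = character(),
                      mismatches = integer(), unique = logical(),
                      mapq = integer(), cigar = character(),
                      seq = character(), qual = character())
  rownames(res) <- NULL
  class(res) <- c("read_alignments", "data.frame")
  res
}

kmer_index <- function(contigs, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (ci in seq_along(contigs)) {
    s <- contigs[[ci]]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    for (p in seq_along(kmers)) {
      key <- kmers[p]
      env[[key]] <- rbind(get0(key, envir = env), c(ci, p))
    }
  }
  env
}

candidate_sites <- function(q, strand, index, k, L) {
  offs <- seq(1L, L - k + 1L, by = k)
  rows <- list()
  for (o in offs) {
    kmer <- substr(q, o, o + k - 1L)
    hit <- get0(kmer, envir = index)
    if (!is.null(hit))
      rows[[length(rows) + 1]] <- data.frame(
        ci = hit[, 1], start = hit[, 2] - o + 1L, strand = strand,
        stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

count_mismatches <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
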