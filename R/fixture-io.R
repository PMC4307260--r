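#' Read and write FASTA via Biostrings
#'
#' Thin wrappers keeping the package's working representation (named
#' character vectors) while delegating the format to \pkg{Biostrings}.
#' FASTA is wrapped at 60 columns.
#'
#' @param x named character vector of sequences.
#' @param path file path.
#' @param type `"AA"` or `"DNA"`.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(x, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(x) else
    Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path) else
    Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads a `read_set` from [generate_reads()] (columns `read_id`,
#'   `seq`, `qual`).
#' @param path file path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    lines <- rbind(paste0("@", reads$read_id), reads$seq,
                   rep("+", nrow(reads)), reads$qual)
    writeLines(as.vector(lines), con)
  }
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop_("malformed FASTQ: ", path)
  n <- length(lines) / 4
  idx <- seq_len(n) * 4 - 3
  data.frame(read_id = sub("^@", "", lines[idx]),
             seq = lines[idx + 1], qual = lines[idx + 3],
             stringsAsFactors = FALSE)
}

#' Write / read a complete synthetic fixture
#'
#' Writes the panel's protein and CDS FASTA per variety, the reads as
#' FASTQ, and the truth tables (orthology, expression, variants, member
#' metadata) as TSV. `read_fixture()` round-trips everything back.
#'
#' @param panel a `family_panel` from [generate_panel()].
#' @param reads optional `read_set` from [generate_reads()].
#' @param dir output directory (created if needed).
#' @return `write_fixture()` returns `dir` invisibly; `read_fixture()`
#'   returns a list with the panel components, reads and truth tables.
#' @export
write_fixture <- function(panel, reads = NULL, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop_("cannot create fixture directory: ", dir)
  p <- function(f) file.path(dir, f)
  tryCatch({
    write_fasta(panel$protein_A, p("proteins_A.fasta"), "AA")
    write_fasta(panel$protein_B, p("proteins_B.fasta"), "AA")
    write_fasta(panel$cds_A, p("cds_A.fasta"), "DNA")
    write_fasta(panel$cds_B, p("cds_B.fasta"), "DNA")
    wtsv <- function(d, f) write.table(d, p(f), sep = "\t", quote = FALSE,
                                       row.names = FALSE)
    wtsv(panel$orthology, "truth_orthology.tsv")
    wtsv(panel$meta, "members.tsv")
    if (!is.null(reads)) {
      write_fastq(reads, p("reads.fastq"))
      expr <- attr(reads, "truth_expression")
      wtsv(data.frame(gene = names(expr), reads = as.integer(expr)),
           "truth_expression.tsv")
      vs <- attr(reads, "truth_variants")
      if (!is.null(vs)) wtsv(vs, "truth_variants.tsv")
    }
  }, error = function(e) stop_("fixture write failed under ", dir, ": ",
                               conditionMessage(e)))
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  out <- list(
    protein_A = read_fasta(p("proteins_A.fasta"), "AA"),
    protein_B = read_fasta(p("proteins_B.fasta"), "AA"),
    cds_A = read_fasta(p("cds_A.fasta"), "DNA"),
    cds_B = read_fasta(p("cds_B.fasta"), "DNA"),
    orthology = read.delim(p("truth_orthology.tsv"),
                           colClasses = "character"),
    meta = read.delim(p("members.tsv")))
  if (file.exists(p("reads.fastq"))) {
    out$reads <- read_fastq(p("reads.fastq"))
    if (file.exists(p("truth_expression.tsv")))
      out$truth_expression <- read.delim(p("truth_expression.tsv"))
    if (file.exists(p("truth_variants.tsv")))
      out$truth_variants <- read.delim(p("truth_variants.tsv"))
  }
  out
}
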