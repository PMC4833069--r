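# Shared low-level helpers: DNA strings, 0-based half-open intervals,
# seeded stream derivation, small file formats.

BASES <- c("A", "C", "G", "T")

## required so that [.data.table dispatches correctly from package code
.datatable.aware <- TRUE

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings (ACGT alphabet).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    seqinr::c2s(rev(seqinr::s2c(chartr("ACGTacgt", "TGCAtgca", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Random DNA sequence
#'
#' @param n length in bp.
#' @param pi base frequencies over A,C,G,T.
#' @return a single DNA string of length `n`.
#' @export
random_dna <- function(n, pi = rep(0.25, 4)) {
  paste(sample(BASES, n, replace = TRUE, prob = pi), collapse = "")
}

## Intervals are data.frames with integer columns start, end and are
## 0-based half-open throughout the package.

intervals_df <- function(x) {
  if (is.null(x) || length(x) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  if (is.data.frame(x)) {
    stopifnot(all(c("start", "end") %in% names(x)))
    return(data.frame(start = as.integer(x$start), end = as.integer(x$end)))
  }
  do.call(rbind, lapply(x, function(iv)
    data.frame(start = as.integer(iv[1]), end = as.integer(iv[2]))))
}

#' Merge overlapping or adjacent half-open intervals
#'
#' @param iv data.frame (or list of length-2 vectors) with start/end columns,
#'   0-based half-open.
#' @return data.frame with disjoint sorted intervals.
#' @export
merge_intervals <- function(iv) {
  iv <- intervals_df(iv)
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  out_s <- iv$start[1]; out_e <- iv$end[1]
  res <- list()
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= out_e) {
      out_e <- max(out_e, iv$end[i])
    } else {
      res[[length(res) + 1L]] <- c(out_s, out_e)
      out_s <- iv$start[i]; out_e <- iv$end[i]
    }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e)
  intervals_df(res)
}

#' Test membership of positions in a set of half-open intervals
#'
#' @param pos integer vector of 0-based positions.
#' @param iv interval data.frame/list (0-based half-open).
#' @return logical vector, TRUE where `pos` falls inside any interval.
#' @export
in_intervals <- function(pos, iv) {
  iv <- intervals_df(iv)
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(iv)))
    out <- out | (pos >= iv$start[i] & pos < iv$end[i])
  out
}

interval_total_length <- function(iv) {
  iv <- merge_intervals(iv)
  sum(iv$end - iv$start)
}

## One master seed per run; each stage draws from its own derived stream so
## that adding draws to one stage does not perturb another.
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483629)
}

## ---- small plain-text formats -------------------------------------------

#' Write sequences to FASTA
#'
#' @param seqs named character vector of DNA strings.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  dna <- ape::as.DNAbin(lapply(seqs, function(s) seqinr::s2c(tolower(s))))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of uppercase DNA strings.
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  out <- vapply(as.character(dna), function(ch) toupper(paste(ch, collapse = "")),
                character(1))
  names(out) <- names(dna)
  out
}

#' Write intervals as BED (0-based half-open)
#'
#' @param iv interval data.frame; an optional `name` column is kept.
#' @param path output file.
#' @param chrom chromosome name used for every record.
#' @export
write_bed <- function(iv, path, chrom = "plastid") {
  iv <- as.data.frame(iv)
  df <- data.frame(chrom = chrom, start = as.integer(iv$start),
                   end = as.integer(iv$end))
  if (!is.null(iv$name)) df$name <- iv$name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into an interval data.frame
#'
#' @param path BED file (>= 3 columns, 0-based half-open).
#' @return data.frame with chrom, start, end (and name if present).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df
}

#' Write a pileup allele-count table as TSV
#'
#' Columns: sample, pos0, A, C, G, T, del, ins (SEQ:count pairs separated by
#' ';', empty if none), depth.
#'
#' @param tab allele-count table (data.frame/data.table).
#' @param path output file.
#' @export
write_pileup <- function(tab, path) {
  data.table::fwrite(as.data.frame(tab), path, sep = "\t")
  invisible(path)
}

#' Read a pileup allele-count TSV
#'
#' @param path TSV written by [write_pileup()].
#' @return data.table with the pileup columns.
#' @export
read_pileup <- function(path) {
  tab <- data.table::fread(path, sep = "\t",
                           colClasses = list(character = "ins"))
  tab$ins[is.na(tab$ins)] <- ""
  tab
}

#' Write a gene model table
#'
#' Columns: gene, strand (+/-), exon (1-based ordinal along the CDS),
#' start, end (0-based half-open genomic coordinates).
#'
#' @param genes gene model data.frame.
#' @param path output file.
#' @export
write_gene_model <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene model table
#'
#' @param path TSV written by [write_gene_model()].
#' @return data.frame with gene, strand, exon, start, end.
#' @export
read_gene_model <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
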