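# Masked multi-sample haploid variant matrix from allele-count pileups,
# nuclear-homology masking, variant classification against the gene model,
# and per-window densities.

#' Thresholds used across variant calling and masking
#'
#' `mapq_min` is carried as metadata only: reads are filtered upstream of
#' the allele-count tables this package consumes, and the mapping-quality
#' direction is ambiguous in common pipeline descriptions, so no read-level
#' action is taken here.
#'
#' @param genotype_support_min minimum fraction of covering reads that must
#'   support the majority allele for a haploid call (else MISSING).
#' @param homolog_evalue_max,homolog_len_min,homolog_identity_min thresholds
#'   for nuclear-homologous region masking.
#' @param mapq_min metadata only (see Details).
#' @param review_band support interval flagged for manual review.
#' @return list of class `threshold_config`.
#' @export
threshold_config <- function(genotype_support_min = 0.90,
                             homolog_evalue_max = 1e-4,
                             homolog_len_min = 101L,
                             homolog_identity_min = 0.90,
                             mapq_min = 29L,
                             review_band = c(0.90, 0.95)) {
  stopifnot(genotype_support_min > 0, genotype_support_min <= 1,
            homolog_identity_min > 0, homolog_identity_min <= 1)
  structure(list(genotype_support_min = genotype_support_min,
                 homolog_evalue_max = homolog_evalue_max,
                 homolog_len_min = as.integer(homolog_len_min),
                 homolog_identity_min = homolog_identity_min,
                 mapq_min = as.integer(mapq_min),
                 review_band = review_band),
            class = "threshold_config")
}

#' Find nuclear-homologous regions by ungapped seed-and-extend
#'
#' Local ungapped alignments between the plastid sequence and a decoy
#' nuclear sequence, seeded on exact 11-mers and extended with an X-drop
#' rule under a +1/-2 match/mismatch score. Significance uses a
#' Karlin-Altschul-style e-value E = K m n exp(-lambda S) with the
#' documented ungapped constants lambda = 1.33, K = 0.621. Hits longer
#' than `homolog_len_min - 1`, with identity >= `homolog_identity_min` and
#' e-value < `homolog_evalue_max` are kept; overlapping query intervals are
#' merged.
#'
#' @param query plastid sequence (string).
#' @param subject decoy nuclear sequence (string).
#' @param thresholds a [threshold_config()].
#' @param word_size exact seed length.
#' @param xdrop score drop-off terminating extension.
#' @param match,mismatch ungapped scores.
#' @param lambda,K Karlin-Altschul constants for the score system.
#' @return data.frame of merged query intervals (0-based half-open) with
#'   the underlying hits in attribute "hits".
#' @export
find_homologous_regions <- function(query, subject,
                                    thresholds = threshold_config(),
                                    word_size = 11L, xdrop = 20,
                                    match = 1, mismatch = -2,
                                    lambda = 1.33, K = 0.621) {
  qc <- seqinr::s2c(query); sc <- seqinr::s2c(subject)
  m <- length(qc); n <- length(sc)
  if (m < word_size || n < word_size) stop("sequences must be non-empty")
  qk <- substring(query, 1:(m - word_size + 1L), word_size:m)
  sk <- substring(subject, 1:(n - word_size + 1L), word_size:n)
  sk_map <- split(seq_along(sk), sk)
  qi_all <- which(qk %in% names(sk_map))
  if (!length(qi_all)) {
    out <- data.frame(start = integer(0), end = integer(0))
    attr(out, "hits") <- data.frame()
    return(out)
  }
  seeds <- do.call(rbind, lapply(qi_all, function(qi)
    cbind(q = qi, s = sk_map[[qk[qi]]])))
  seeds <- seeds[order(seeds[, "q"] - seeds[, "s"], seeds[, "q"]), ,
                 drop = FALSE]
  dg <- seeds[, "q"] - seeds[, "s"]
  first <- c(TRUE, !(dg[-1] == dg[-length(dg)] &
                     seeds[-1, "q"] == seeds[-nrow(seeds), "q"] + 1L))
  seeds <- seeds[first, , drop = FALSE]

  hits <- list()
  done <- list()  # per-diagonal rightmost extended query position
  for (i in seq_len(nrow(seeds))) {
    q0 <- seeds[i, "q"]; s0 <- seeds[i, "s"]
    key <- as.character(q0 - s0)
    if (!is.null(done[[key]]) && q0 <= done[[key]]) next
    sc0 <- word_size * match
    best <- sc0; qr <- q0 + word_size - 1L; sr <- s0 + word_size - 1L
    bqr <- qr; bsr <- sr
    cur <- sc0
    while (qr < m && sr < n) {
      qr <- qr + 1L; sr <- sr + 1L
      cur <- cur + if (qc[qr] == sc[sr]) match else mismatch
      if (cur > best) { best <- cur; bqr <- qr; bsr <- sr }
      if (best - cur > xdrop) break
    }
    ql <- q0; sl <- s0; bql <- q0; bsl <- s0
    cur <- best
    while (ql > 1L && sl > 1L) {
      ql <- ql - 1L; sl <- sl - 1L
      cur <- cur + if (qc[ql] == sc[sl]) match else mismatch
      if (cur > best) { best <- cur; bql <- ql; bsl <- sl }
      if (best - cur > xdrop) break
    }
    len <- bqr - bql + 1L
    nid <- sum(qc[bql:bqr] == sc[bsl:(bsl + len - 1L)])
    ev <- K * m * n * exp(-lambda * best)
    hits[[length(hits) + 1L]] <- data.frame(
      qstart = bql - 1L, qend = bqr, sstart = bsl - 1L, send = bsr,
      length = len, identity = nid / len, score = best, evalue = ev)
    done[[key]] <- bqr
  }
  hits <- do.call(rbind, hits)
  keep <- hits$length >= thresholds$homolog_len_min &
    hits$identity >= thresholds$homolog_identity_min &
    hits$evalue < thresholds$homolog_evalue_max
  out <- if (any(keep))
    merge_intervals(data.frame(start = hits$qstart[keep],
                               end = hits$qend[keep]))
  else data.frame(start = integer(0), end = integer(0))
  attr(out, "hits") <- hits
  out
}

#' Haploid genotype call for one sample at one position
#'
#' Returns the majority allele iff it is supported by at least
#' `genotype_support_min` of the covering reads, else MISSING (NA). Depth 0
#' is MISSING with a distinct no-coverage flag. Support in the review band
#' is flagged for manual inspection.
#'
#' @param counts named numeric vector of read counts; names are base
#'   alleles, "-" (deletion) and/or "+SEQ" (insertion).
#' @param thresholds a [threshold_config()].
#' @return list with allele (NA if missing), support, missing, no_coverage,
#'   review.
#' @export
call_genotype <- function(counts, thresholds = threshold_config()) {
  depth <- sum(counts)
  if (depth == 0)
    return(list(allele = NA_character_, support = NA_real_, missing = TRUE,
                no_coverage = TRUE, review = FALSE))
  counts <- sort(counts, decreasing = TRUE)
  top <- counts[1]
  sup <- top / depth
  if (sup >= thresholds$genotype_support_min) {
    list(allele = names(counts)[1], support = unname(sup), missing = FALSE,
         no_coverage = FALSE,
         review = sup < thresholds$review_band[2])
  } else {
    list(allele = NA_character_, support = unname(sup), missing = TRUE,
         no_coverage = FALSE, review = FALSE)
  }
}

parse_ins_count <- function(ins) {
  out <- numeric(length(ins))
  has <- !is.na(ins) & ins != ""
  out[has] <- as.numeric(sub("^.*:", "", ins[has]))
  out
}

parse_ins_seq <- function(ins) {
  out <- rep(NA_character_, length(ins))
  has <- !is.na(ins) & ins != ""
  out[has] <- sub(":[0-9]+$", "", ins[has])
  out
}

#' Build the masked multi-sample variant matrix
#'
#' A position enters the matrix iff at least one sample's haploid call
#' differs from the reference allele and the position is outside the mask.
#' Positions where every sample carries the same non-reference call are
#' reported separately as reference discrepancies (likely legacy errors in
#' the reference sequence) rather than as variation among samples.
#'
#' @param pileup allele-count table covering all samples (a `sample`
#'   column distinguishes them); all samples must share the same positions.
#' @param reference reference sequence string.
#' @param mask interval data.frame (0-based half-open) to exclude.
#' @param thresholds a [threshold_config()].
#' @return object of class `variant_matrix`: list with positions (0-based),
#'   ref, calls (positions x samples character matrix, NA = MISSING),
#'   type ("SNV"/"indel"), n_alleles, samples, review (logical matrix),
#'   ref_discrepancies, mask.
#' @export
build_variant_matrix <- function(pileup, reference, mask = NULL,
                                 thresholds = threshold_config()) {
  pk <- data.table::as.data.table(pileup)
  samples <- unique(pk$sample)
  pos_sets <- pk[, list(key = paste(sort(pos0), collapse = ",")), by = "sample"]
  if (length(unique(pos_sets$key)) != 1L)
    stop("samples cover inconsistent coordinate ranges")
  ref_chars <- seqinr::s2c(reference)

  calls <- NULL; review <- NULL; positions <- NULL
  for (s in samples) {
    tab <- pk[pk$sample == s]
    tab <- tab[order(tab$pos0)]
    if (is.null(positions)) positions <- tab$pos0
    cm <- as.matrix(tab[, c("A", "C", "G", "T", "del"), with = FALSE])
    colnames(cm) <- c(BASES, "-")
    depth <- rowSums(cm)
    top <- max.col(cm, ties.method = "first")
    topn <- cm[cbind(seq_len(nrow(cm)), top)]
    sup <- ifelse(depth > 0, topn / depth, NA_real_)
    call <- colnames(cm)[top]
    call[is.na(sup) | sup < thresholds$genotype_support_min] <- NA_character_
    ## insertion carriers: the inserted sequence needs >= the same support
    insn <- parse_ins_count(tab$ins)
    ins_frac <- ifelse(depth > 0, insn / depth, 0)
    has_ins <- ins_frac >= thresholds$genotype_support_min
    call[has_ins] <- paste0("+", parse_ins_seq(tab$ins)[has_ins])
    rev_flag <- !is.na(sup) & sup >= thresholds$genotype_support_min &
      sup < thresholds$review_band[2] & !is.na(call)
    calls <- cbind(calls, call)
    review <- cbind(review, rev_flag)
  }
  colnames(calls) <- samples; colnames(review) <- samples

  refa <- ref_chars[positions + 1L]
  differs <- calls != refa & !is.na(calls)
  any_diff <- rowSums(differs) > 0
  all_called <- rowSums(is.na(calls)) == 0
  n_distinct <- apply(calls, 1, function(x) length(unique(x[!is.na(x)])))
  is_discrepancy <- any_diff & all_called & n_distinct == 1L &
    rowSums(differs) == length(samples)
  masked <- if (is.null(mask)) rep(FALSE, length(positions)) else
    in_intervals(positions, mask)

  keep <- any_diff & !masked & !is_discrepancy
  kp <- which(keep)
  typ <- vapply(kp, function(i) {
    al <- unique(c(refa[i], calls[i, ][!is.na(calls[i, ])]))
    if (all(al %in% BASES)) "SNV" else "indel"
  }, character(1))
  n_all <- vapply(kp, function(i)
    length(unique(c(refa[i], calls[i, ][!is.na(calls[i, ])]))), integer(1))

  disc <- which(is_discrepancy & !masked)
  structure(list(
    positions = positions[kp], ref = refa[kp],
    calls = calls[kp, , drop = FALSE], type = typ, n_alleles = n_all,
    samples = samples, review = review[kp, , drop = FALSE],
    ref_discrepancies = data.frame(pos0 = positions[disc],
                                   ref = refa[disc],
                                   allele = calls[disc, 1]),
    mask = intervals_df(mask)),
    class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("variant_matrix: %d positions x %d samples (%d SNV, %d indel, %d triallelic+)\n",
              length(x$positions), length(x$samples),
              sum(x$type == "SNV"), sum(x$type == "indel"),
              sum(x$n_alleles >= 3)))
  invisible(x)
}

## group adjacent deletion rows with identical carrier sets into events
indel_events <- function(vm) {
  rows <- which(vm$type == "indel")
  ev <- list(); used <- logical(length(vm$positions))
  for (i in rows) {
    if (used[i]) next
    al <- vm$calls[i, ]
    if (any(!is.na(al) & startsWith(al, "+"))) {
      seq <- unname(sub("^\\+", "", al[!is.na(al) & startsWith(al, "+")][1]))
      ev[[length(ev) + 1L]] <- list(row = i, pos = vm$positions[i],
                                    kind = "ins", len = nchar(seq), seq = seq)
      used[i] <- TRUE
    } else {
      carriers <- !is.na(al) & al == "-"
      j <- i
      while (j < length(vm$positions) && vm$positions[j + 1L] == vm$positions[j] + 1L &&
             vm$type[j + 1L] == "indel" &&
             identical(!is.na(vm$calls[j + 1L, ]) & vm$calls[j + 1L, ] == "-",
                       carriers)) j <- j + 1L
      ev[[length(ev) + 1L]] <- list(row = i, pos = vm$positions[i],
                                    kind = "del", len = j - i + 1L, seq = NA)
      used[i:j] <- TRUE
    }
  }
  ev
}

#' Classify variants against the gene model
#'
#' Labels each variant intergenic / intron / exon. Exonic indels are
#' frameshift iff the net length change is not a multiple of 3; in-frame
#' insertions equal to the adjacent reference tract are labelled
#' duplications. Adjacent deletion rows with identical carriers are
#' treated as one event.
#'
#' @param vm a `variant_matrix`.
#' @param genes gene-model data.frame (gene, strand, exon, start, end).
#' @param reference reference string (needed for the duplication check).
#' @return data.frame: pos0, type, region, gene, effect, indel_len.
#' @export
classify_variants <- function(vm, genes, reference = NULL) {
  L <- if (is.null(reference)) max(vm$positions) + 1L else nchar(reference)
  if (any(vm$positions < 0 | vm$positions >= L))
    stop("variant outside reference bounds")
  spans <- do.call(rbind, lapply(split(genes, genes$gene), function(g)
    data.frame(gene = g$gene[1], strand = g$strand[1],
               start = min(g$start), end = max(g$end))))
  region <- rep("intergenic", length(vm$positions))
  gene <- rep(NA_character_, length(vm$positions))
  for (i in seq_len(nrow(spans))) {
    inside <- vm$positions >= spans$start[i] & vm$positions < spans$end[i]
    if (!any(inside)) next
    g <- genes[genes$gene == spans$gene[i], , drop = FALSE]
    in_exon <- in_intervals(vm$positions, g[, c("start", "end")])
    region[inside & in_exon] <- "exon"
    region[inside & !in_exon] <- "intron"
    gene[inside] <- spans$gene[i]
  }
  effect <- rep(NA_character_, length(vm$positions))
  ind_len <- rep(NA_integer_, length(vm$positions))
  effect[vm$type == "SNV" & region == "exon"] <- "substitution"
  for (e in indel_events(vm)) {
    i <- e$row
    net <- if (e$kind == "ins") e$len else -e$len
    ind_len[i] <- net
    if (region[i] != "exon") next
    if (abs(net) %% 3L != 0L) {
      effect[i] <- "frameshift"
    } else if (e$kind == "ins" && !is.null(reference)) {
      p <- e$pos
      prev <- substr(reference, p - e$len + 2L, p + 1L)
      nxt <- substr(reference, p + 2L, p + e$len + 1L)
      effect[i] <- if (identical(e$seq, prev) || identical(e$seq, nxt))
        "duplication" else "in-frame"
    } else effect[i] <- "in-frame"
  }
  data.frame(pos0 = vm$positions, type = vm$type, region = region,
             gene = gene, effect = effect, indel_len = ind_len,
             stringsAsFactors = FALSE)
}

#' Variant counts and per-kb densities over windows
#'
#' Density is count / (unmasked window length in kb): masked bases are
#' removed from the denominator.
#'
#' @param vm a `variant_matrix`.
#' @param windows interval data.frame (0-based half-open, non-overlapping);
#'   default: non-overlapping windows of `window_size` over `[0, L)`.
#' @param window_size default window width in bp.
#' @param L genome length (required when `windows` is NULL).
#' @param mask intervals excluded from the denominator (defaults to the
#'   matrix's own mask).
#' @return data.frame: start, end, n, unmasked_bp, density_per_kb.
#' @export
variant_density <- function(vm, windows = NULL, window_size = 100L, L = NULL,
                            mask = vm$mask) {
  if (is.null(windows)) {
    if (is.null(L)) stop("L required when windows is NULL")
    s <- seq(0L, L - 1L, by = window_size)
    windows <- data.frame(start = s, end = pmin(s + window_size, L))
  }
  windows <- intervals_df(windows)
  if (any(windows$end <= windows$start)) stop("zero-length window")
  n <- integer(nrow(windows)); ub <- integer(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows$start[i]:(windows$end[i] - 1L)
    n[i] <- sum(vm$positions >= windows$start[i] &
                vm$positions < windows$end[i])
    ub[i] <- sum(!in_intervals(w, mask))
  }
  data.frame(start = windows$start, end = windows$end, n = n,
             unmasked_bp = ub,
             density_per_kb = ifelse(ub > 0, n / (ub / 1000), NA_real_))
}

#' Variant accounting summary
#'
#' Totals the nonredundant variant set and the intergenic fraction of
#' indels, either from a [classify_variants()] annotation table or from
#' explicit counts.
#'
#' @param x annotation data.frame, or the SNV count.
#' @param n_indel,n_indel_intergenic explicit counts when `x` is numeric.
#' @return list: n_snv, n_indel, total, n_indel_intergenic,
#'   pct_indel_intergenic (rounded percent).
#' @export
variant_accounting <- function(x, n_indel = NULL, n_indel_intergenic = NULL) {
  if (is.data.frame(x)) {
    n_snv <- sum(x$type == "SNV")
    n_indel <- sum(x$type == "indel")
    n_int <- sum(x$type == "indel" & x$region == "intergenic")
  } else {
    n_snv <- x
    n_int <- n_indel_intergenic
  }
  list(n_snv = n_snv, n_indel = n_indel, total = n_snv + n_indel,
       n_indel_intergenic = n_int,
       pct_indel_intergenic = round(100 * n_int / n_indel))
}
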