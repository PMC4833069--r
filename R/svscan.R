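# Coverage-based large-deletion detection, breakpoint microhomology
# annotation, and mapping of deletion origins onto the phylogeny.

#' Detect large deletions from pileup coverage
#'
#' Scans each sample's base-supporting depth profile (A+C+G+T reads) for
#' maximal runs of at least `min_sv_len` positions whose depth falls below
#' `drop_ratio` times the flanking median. The residual reference fraction
#' is the interior median depth over the flanking median; calls with
#' residual >= 0.005 are flagged heteroplasmic. Breakpoints are
#' left-aligned to the leftmost equivalent representation when the
#' reference is supplied.
#'
#' @param pileup allele-count table (one or more samples) over a
#'   contiguous position range.
#' @param min_sv_len minimum deletion length (default 50 bp).
#' @param drop_ratio depth ratio defining a drop (default 0.2).
#' @param flank flanking window width used for the local median.
#' @param reference optional reference string for breakpoint
#'   left-alignment.
#' @return data.frame of class `sv_calls`: sample, start, end (0-based
#'   half-open), interior_depth, flank_depth, residual, heteroplasmic.
#' @export
detect_deletions <- function(pileup, min_sv_len = 50L, drop_ratio = 0.2,
                             flank = 500L, reference = NULL) {
  pk <- data.table::as.data.table(pileup)
  ref_chars <- if (is.null(reference)) NULL else seqinr::s2c(reference)
  out <- list()
  for (s in unique(pk$sample)) {
    tab <- pk[pk$sample == s][order(pos0)]
    if (any(diff(tab$pos0) != 1L))
      stop("coverage profile must be contiguous")
    if (nrow(tab) < 2L * min_sv_len)
      stop("profile shorter than twice min_sv_len")
    depth <- tab$A + tab$C + tab$G + tab$T
    pos <- tab$pos0
    gmed <- stats::median(depth)
    low <- depth < drop_ratio * gmed
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_sv_len)) {
      i0 <- starts[k]; i1 <- ends[k]
      li <- max(1L, i0 - flank):(i0 - 1L)
      ri <- (i1 + 1L):min(nrow(tab), i1 + flank)
      li <- li[li >= 1L]; ri <- ri[ri <= nrow(tab)]
      fmed <- stats::median(depth[c(li, ri)])
      imed <- stats::median(depth[i0:i1])
      if (!is.finite(fmed) || fmed <= 0 || imed >= drop_ratio * fmed) next
      st <- pos[i0]; en <- pos[i1] + 1L
      if (!is.null(ref_chars)) {
        while (st > 0L && st > pos[1] &&
               ref_chars[st] == ref_chars[en]) {
          st <- st - 1L; en <- en - 1L
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        sample = s, start = st, end = en,
        interior_depth = imed, flank_depth = fmed,
        residual = imed / fmed,
        heteroplasmic = (imed / fmed) >= 0.005,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(0), start = integer(0), end = integer(0),
               interior_depth = numeric(0), flank_depth = numeric(0),
               residual = numeric(0), heteroplasmic = logical(0))
  class(res) <- c("sv_calls", "data.frame")
  res
}

#' Annotate deletion breakpoint microhomology
#'
#' Finds the longest sequence that is shared context of the two
#' breakpoints of a deletion [start, end): the longest string that both
#' follows the left breakpoint and follows the right breakpoint (a
#' crossover between two homologous copies leaves one), or symmetrically
#' precedes both; the longer of the two is reported (searched up to
#' `max_probe` bp). Single-base microhomologies falling in homopolymer
#' runs are annotated with the unit and the run lengths at both
#' breakpoints.
#'
#' @param reference reference sequence string.
#' @param start,end deletion interval (0-based half-open).
#' @param max_probe maximum probe length each side (default 25 bp).
#' @return list: homology (string, "" if none), length, side
#'   ("right"/"left"/"none"), is_homopolymer, unit, left_run, right_run,
#'   left_track, right_track (0-based half-open coordinates of the two
#'   homologous copies).
#' @export
annotate_breakpoint_homology <- function(reference, start, end,
                                         max_probe = 25L) {
  ch <- seqinr::s2c(reference)
  L <- length(ch)
  if (start < 0 || end > L || start >= end)
    stop("call interval outside the reference")
  m_fwd <- 0L
  while (m_fwd < max_probe && start + m_fwd < end && end + m_fwd < L &&
         ch[start + m_fwd + 1L] == ch[end + m_fwd + 1L]) m_fwd <- m_fwd + 1L
  m_rev <- 0L
  while (m_rev < max_probe && start - m_rev > 0L && end - m_rev > start &&
         ch[start - m_rev] == ch[end - m_rev]) m_rev <- m_rev + 1L
  if (m_fwd == 0L && m_rev == 0L) {
    return(list(homology = "", length = 0L, side = "none",
                is_homopolymer = FALSE, unit = NA_character_,
                left_run = NA_integer_, right_run = NA_integer_,
                left_track = NULL, right_track = NULL))
  }
  if (m_fwd >= m_rev) {
    hom <- paste(ch[(start + 1L):(start + m_fwd)], collapse = "")
    ltr <- c(start, start + m_fwd); rtr <- c(end, end + m_fwd)
  } else {
    hom <- paste(ch[(start - m_rev + 1L):start], collapse = "")
    ltr <- c(start - m_rev, start); rtr <- c(end - m_rev, end)
  }
  u <- unique(seqinr::s2c(hom))
  is_hp <- length(u) == 1L
  lrun <- rrun <- NA_integer_
  if (is_hp) {
    run_len <- function(p0) {  # run of u around 0-based position p0
      i <- p0
      while (i > 0L && ch[i] == u) i <- i - 1L
      j <- p0 + 1L
      while (j <= L && ch[j] == u) j <- j + 1L
      j - i - 1L
    }
    lrun <- run_len(ltr[1])
    rrun <- run_len(rtr[1])
  }
  list(homology = hom, length = nchar(hom),
       side = if (m_fwd >= m_rev) "right" else "left",
       is_homopolymer = is_hp, unit = if (is_hp) u else NA_character_,
       left_run = lrun, right_run = rrun,
       left_track = ltr, right_track = rtr)
}

#' Assign deletion origins on the phylogeny
#'
#' Deletions with identical breakpoints shared by multiple leaves are one
#' event placed at the carriers' MRCA; overlapping but breakpoint-distinct
#' deletions remain independent events. The report flags groups of events
#' that overlap on the reference.
#'
#' @param calls `sv_calls` data.frame (sample, start, end).
#' @param tree `ape::phylo` containing every carrier as a tip.
#' @return data.frame: event, start, end, n_carriers, carriers, node,
#'   origin (tip label or "node<N>"), overlap_group (NA if disjoint from
#'   all other events).
#' @export
assign_origins <- function(calls, tree) {
  bad <- setdiff(unique(calls$sample), tree$tip.label)
  if (length(bad))
    stop("sample(s) not in tree: ", paste(bad, collapse = ", "))
  key <- paste(calls$start, calls$end, sep = "-")
  groups <- split(seq_len(nrow(calls)), key)
  rows <- lapply(groups, function(ix) {
    cs <- unique(calls$sample[ix])
    node <- if (length(cs) == 1L) match(cs, tree$tip.label) else
      ape::getMRCA(tree, cs)
    data.frame(start = calls$start[ix[1]], end = calls$end[ix[1]],
               n_carriers = length(cs),
               carriers = paste(sort(cs), collapse = ","),
               node = node,
               origin = if (node <= length(tree$tip.label))
                 tree$tip.label[node] else paste0("node", node),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  out$event <- seq_len(nrow(out))
  ## overlap groups: connected components of interval overlap
  og <- rep(NA_integer_, nrow(out))
  gid <- 0L
  for (i in seq_len(nrow(out))) {
    ov <- which(out$start < out$end[i] & out$end > out$start[i])
    if (length(ov) > 1L) {
      ex <- og[ov]; ex <- ex[!is.na(ex)]
      if (length(ex)) og[ov] <- ex[1] else {
        gid <- gid + 1L
        og[ov] <- gid
      }
    }
  }
  out$overlap_group <- og
  rownames(out) <- NULL
  out[, c("event", "start", "end", "n_carriers", "carriers", "node",
          "origin", "overlap_group")]
}
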