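# End-to-end orchestration: a single seeded config drives simulation (or
# file inputs), variant calling, heteroplasmy analysis, phylogeny, dating,
# selection scan and deletion calling, with a machine-readable summary.

ladder_newick <- function(parts, ages) {
  ## parts: list of list(str, age); joined as a ladder with the given
  ## ascending node ages; returns list(str, age)
  cur <- parts[[1]]
  for (i in seq_along(parts)[-1]) {
    a <- ages[i - 1L]
    cur <- list(str = sprintf("(%s:%.12g,%s:%.12g)", cur$str, a - cur$age,
                              parts[[i]]$str, a - parts[[i]]$age),
                age = a)
  }
  cur
}

clade_newick <- function(labels, crown_age) {
  parts <- lapply(labels, function(l) list(str = l, age = 0))
  if (length(parts) == 1L) return(parts[[1]])
  ages <- crown_age * seq_along(parts)[-1] / length(parts)
  ladder_newick(parts, ages[seq_len(length(parts) - 1L)])
}

#' Fixture configuration: small 8-taxon, 20-kb dataset
#'
#' @param seed master seed.
#' @return a [sim_config()].
#' @export
toy8_config <- function(seed = 42L) {
  nwk <- paste0("(((t1:2,t2:2):3,(t3:2.5,t4:2.5):2.5):5,",
                "((t5:3,t6:3):4,(t7:1.5,t8:1.5):5.5):3);")
  sim_config(
    genome_length = 20000L,
    ir_intervals = list(c(12000L, 14000L), c(16000L, 18000L)),
    homolog_tracts = list(c(1000L, 1200L)),
    tree = nwk,
    subst_rate = 4e-4,
    indel_rate = 8e-5,
    large_deletions = list(list(motif = "TCCT", start = 9324L, end = 9531L,
                                leaf = "t5")),
    hybrid_events = list(list(recipient = "t2", donor = "t7",
                              leakage = 0.05)),
    coverage = 2000, error_rate = 0.001, seed = seed)
}

#' Fixture configuration: full-scale 34-taxon, 160-kb dataset
#'
#' Eleven clades over 34 leaves on a 16-My-rooted ladder backbone; the
#' substitution and indel rates are calibrated so the expected variant
#' yield matches typical deep plastid resequencing panels (~1.5k SNVs,
#' ~300 indels); includes hybridization leakage and two TCCT-flanked
#' deletions (one 388 bp, one 207 bp).
#'
#' @param seed master seed.
#' @return a [sim_config()].
#' @export
citrus34_config <- function(seed = 7L) {
  sizes <- c(7, 3, 2, 5, 2, 2, 2, 4, 3, 2, 2)
  labels <- split(sprintf("s%02d", seq_len(sum(sizes))),
                  rep(seq_along(sizes), sizes))
  crowns <- c(2.5, 1.5, 1, 2, 0.8, 1.2, 0.9, 2.2, 1.4, 0.7, 1.1)
  clades <- Map(clade_newick, labels, crowns)
  backbone_ages <- seq(6, 16, length.out = length(clades) - 1L)
  nwk <- paste0(ladder_newick(clades, backbone_ages)$str, ";")
  tree <- ape::read.tree(text = nwk)
  L <- 160129L
  treelen <- sum(tree$edge.length)
  sim_config(
    genome_length = L,
    ir_intervals = list(c(85000L, 111000L), c(134129L, 160129L)),
    homolog_tracts = list(c(2000L, 2400L), c(50000L, 50250L)),
    tree = nwk,
    subst_rate = 1564 / (L * treelen),
    indel_rate = 323 / (L * treelen),
    large_deletions = list(
      list(motif = "TCCT", start = 13942L, end = 14330L, leaf = "s26"),
      list(motif = "TCCT", start = 9324L, end = 9531L, leaf = "s33")),
    hybrid_events = list(
      list(recipient = "s02", donor = "s27", leakage = 0.05),
      list(recipient = "s11", donor = "s18", leakage = 0.03)),
    coverage = 2000, error_rate = 0.001, seed = seed)
}

#' Pipeline configuration
#'
#' @param sim a [sim_config()] (simulated-input mode), or NULL.
#' @param paths named list of input files (pileup, reference, mask, genes,
#'   tree) for file mode.
#' @param stages character vector of stages to run, in order, from
#'   varcall, hetero, phylo, chrono, selpress, svscan.
#' @param clusters list of [cluster_spec()]s for sharing statistics.
#' @param known_hybrids sample names treated as hybrids (tested for
#'   paternity; excluded as candidates for each other).
#' @param outgroup tip used to root the tree for dating/origin mapping.
#' @param thresholds a [threshold_config()].
#' @param shp list(min_minor, min_depth).
#' @param sv list(min_sv_len, drop_ratio).
#' @param selection list(alpha, min_subs).
#' @param dating list(lambda = numeric or "cv", root_age, k_rate_classes).
#' @param n_boot bootstrap replicates for the NJ tree.
#' @param pileup_positions NULL (whole genome) or "variants".
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL,
                            stages = c("varcall", "hetero", "phylo",
                                       "chrono", "selpress", "svscan"),
                            clusters = list(), known_hybrids = character(0),
                            outgroup = NULL,
                            thresholds = threshold_config(),
                            shp = list(min_minor = 5L, min_depth = 1000L),
                            sv = list(min_sv_len = 50L, drop_ratio = 0.2),
                            selection = list(alpha = 0.05, min_subs = 5),
                            dating = list(lambda = 1, root_age = NULL,
                                          k_rate_classes = 3L),
                            n_boot = 100L, pileup_positions = NULL,
                            seed = 1L) {
  if (!length(stages)) stop("no stage selected")
  bad <- setdiff(stages, c("varcall", "hetero", "phylo", "chrono",
                           "selpress", "svscan"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(sim) && is.null(paths))
    stop("either a simulation config or input paths are required")
  if (!is.null(paths)) {
    need <- c("pileup", "reference")
    miss <- setdiff(need, names(paths))
    if (length(miss)) stop("missing input path(s): ",
                           paste(miss, collapse = ", "))
    for (p in unlist(paths)) if (!file.exists(p))
      stop("input path does not exist: ", p)
  }
  structure(list(sim = sim, paths = paths, stages = stages,
                 clusters = clusters, known_hybrids = known_hybrids,
                 outgroup = outgroup, thresholds = thresholds, shp = shp,
                 sv = sv, selection = selection, dating = dating,
                 n_boot = n_boot, pileup_positions = pileup_positions,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Runs the selected stages in dependency order and returns a result
#' bundle plus a per-stage count summary. Downstream stages depending on a
#' failed or skipped stage are skipped with a logged cause. Deterministic
#' given the config seed.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory for TSV/newick outputs.
#' @return list: results per stage, summary (named counts), log
#'   (character), config.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  res <- list()
  summary <- list()

  if (!is.null(cfg$sim)) {
    dat <- simulate_dataset(cfg$sim, pileups = TRUE,
                            positions = cfg$pileup_positions)
    reference <- dat$reference$sequence
    genes <- dat$reference$genes
    mask <- dat$reference$mask
    pileup <- dat$pileup
    genomes <- dat$genomes
    res$truth <- dat$truth
    say("simulate: %d leaves, %d true variants", length(genomes),
        nrow(dat$truth$variants))
  } else {
    pileup <- read_pileup(cfg$paths$pileup)
    reference <- read_fasta(cfg$paths$reference)[1]
    genes <- if (!is.null(cfg$paths$genes))
      read_gene_model(cfg$paths$genes) else NULL
    mask <- if (!is.null(cfg$paths$mask)) {
      b <- read_bed(cfg$paths$mask)
      data.frame(start = b$start, end = b$end)
    } else NULL
    genomes <- NULL
  }

  vm <- NULL
  if ("varcall" %in% cfg$stages) {
    vm <- build_variant_matrix(pileup, reference, mask, cfg$thresholds)
    res$variant_matrix <- vm
    if (!is.null(genes)) {
      res$annotation <- classify_variants(vm, genes, reference)
      acct <- variant_accounting(res$annotation)
      summary$n_snv <- acct$n_snv
      summary$n_indel <- acct$n_indel
      summary$n_variants <- acct$total
    } else {
      summary$n_snv <- sum(vm$type == "SNV")
      summary$n_variants <- length(vm$positions)
    }
    summary$n_triallelic <- sum(vm$n_alleles >= 3)
    say("varcall: %d variant positions (%d SNV)", length(vm$positions),
        summary$n_snv)
  }

  shp <- NULL
  if ("hetero" %in% cfg$stages) {
    if (is.null(vm)) {
      say("hetero: skipped (needs varcall)")
    } else {
      snv_pos <- vm$positions[vm$type == "SNV"]
      shp <- call_shp(pileup, snv_pos, cfg$shp$min_minor, cfg$shp$min_depth)
      res$shp <- shp
      summary$n_shp <- nrow(shp)
      calls <- vm$calls
      rownames(calls) <- vm$positions
      res$paternity <- lapply(cfg$known_hybrids, function(h)
        paternity_test(shp[shp$sample == h, , drop = FALSE], calls,
                       known_hybrids = cfg$known_hybrids, hybrid = h))
      names(res$paternity) <- cfg$known_hybrids
      res$sharing <- lapply(cfg$clusters, function(cl)
        sharing_stats(shp, cl))
      say("hetero: %d SHPs across %d samples", nrow(shp),
          length(unique(shp$sample)))
    }
  }

  tree <- NULL
  if ("phylo" %in% cfg$stages) {
    if (is.null(vm)) {
      say("phylo: skipped (needs varcall)")
    } else {
      aln <- concat_variable_sites(vm)
      res$alignment <- aln
      tree <- nj_bootstrap_tree(aln, cfg$n_boot,
                                seed = stage_seed(cfg$seed, 30L))
      if (!is.null(cfg$outgroup))
        tree <- ape::root(tree, cfg$outgroup, resolve.root = TRUE)
      res$tree <- tree
      fit_u <- fit_gtr(tree, aln, clock = FALSE)
      fit_c <- fit_gtr(tree, aln, clock = TRUE, gtr = fit_u$gtr)
      res$fit_unconstrained <- fit_u
      res$fit_clock <- fit_c
      res$clock_test <- clock_lrt(-fit_u$logLik, -fit_c$logLik,
                                  length(aln$samples))
      summary$n_sites <- length(aln$sites)
      summary$clock_chi2 <- res$clock_test$chi2
      say("phylo: %d variable sites; clock LRT chi2 = %.2f (p = %.3g)",
          length(aln$sites), res$clock_test$chi2, res$clock_test$p)
    }
  }

  if ("chrono" %in% cfg$stages) {
    if (is.null(tree) || is.null(cfg$dating$root_age)) {
      say("chrono: skipped (needs phylo stage and a root age)")
    } else {
      dtree <- res$fit_unconstrained$tree
      if (!ape::is.rooted(dtree) && !is.null(cfg$outgroup))
        dtree <- ape::root(dtree, cfg$outgroup, resolve.root = TRUE)
      counts <- branch_counts(dtree, length(res$alignment$sites))
      cons <- dating_constraints(cfg$dating$root_age)
      lam <- cfg$dating$lambda
      if (identical(lam, "cv")) {
        cv <- cross_validate_lambda(dtree, counts, cons)
        res$cv <- cv
        lam <- cv$lambda
      }
      res$dating <- fit_pl(dtree, counts, cons, lam)
      res$rate_classes <- classify_rates(res$dating,
                                         cfg$dating$k_rate_classes,
                                         seed = stage_seed(cfg$seed, 40L))
      summary$dating_lambda <- lam
      say("chrono: PL dating at lambda = %g", lam)
    }
  }

  if ("selpress" %in% cfg$stages) {
    if (is.null(genomes) || is.null(tree) || is.null(genes)) {
      say("selpress: skipped (needs simulated genomes, genes and a tree)")
    } else {
      rtree <- if (ape::is.rooted(tree)) tree else
        ape::root(tree, tree$tip.label[1], resolve.root = TRUE)
      spans <- split(genes, genes$gene)
      outside <- names(spans)[vapply(spans, function(g)
        !any(in_intervals(c(g$start, g$end - 1L), mask)), logical(1))]
      counts_list <- list()
      for (gid in outside) {
        aln_g <- tryCatch(
          withCallingHandlers(
            extract_codon_alignment(genomes, list(sequence = reference,
                                                  genes = genes, mask = mask),
                                    gid),
            warning = function(w) {
              say("selpress: %s", conditionMessage(w))
              invokeRestart("muffleWarning")
            }),
          error = function(e) NULL)
        if (is.null(aln_g) ||
            !all(rtree$tip.label %in% aln_g$samples)) next
        counts_list[[gid]] <- count_substitutions(rtree, aln_g)
      }
      if (length(counts_list)) {
        res$selection <- scan_selection(rtree, counts_list,
                                        alpha = cfg$selection$alpha,
                                        min_subs = cfg$selection$min_subs)
        summary$n_selection_tests <- nrow(res$selection)
        summary$n_positive <- sum(res$selection$verdict == "positive")
      }
      say("selpress: %d genes scanned", length(counts_list))
    }
  }

  if ("svscan" %in% cfg$stages) {
    if (!is.null(cfg$pileup_positions)) {
      say("svscan: skipped (needs whole-genome pileups)")
    } else {
      calls <- detect_deletions(pileup, cfg$sv$min_sv_len,
                                cfg$sv$drop_ratio, reference = reference)
      if (nrow(calls)) {
        calls$microhomology <- vapply(seq_len(nrow(calls)), function(i)
          annotate_breakpoint_homology(reference, calls$start[i],
                                       calls$end[i])$homology, character(1))
      }
      res$sv_calls <- calls
      if (nrow(calls) && !is.null(tree))
        res$sv_origins <- assign_origins(calls, tree)
      summary$n_deletions <- nrow(calls)
      say("svscan: %d deletion calls", nrow(calls))
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$shp))
      utils::write.table(res$shp, file.path(out_dir, "shp.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$annotation))
      utils::write.table(res$annotation,
                         file.path(out_dir, "variants.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$tree))
      ape::write.tree(res$tree, file.path(out_dir, "tree.nwk"))
    if (!is.null(res$sv_calls))
      utils::write.table(res$sv_calls, file.path(out_dir, "sv_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    for (h in names(res$paternity))
      utils::write.table(res$paternity[[h]],
                         file.path(out_dir, paste0("paternity_", h, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(results = res, summary = summary, log = log, config = cfg)
}

#' Write a named synthetic fixture to disk
#'
#' @param name fixture id: "toy8" or "citrus34".
#' @param dir output directory (created if needed).
#' @param pileups also write the (large) pileup table.
#' @param seed master seed override (default: the fixture's own).
#' @return invisible list of written paths.
#' @export
write_fixtures <- function(name, dir, pileups = TRUE, seed = NULL) {
  cfgs <- list(toy8 = toy8_config, citrus34 = citrus34_config)
  if (!name %in% names(cfgs))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(cfgs), collapse = ", "))
  cfg <- if (is.null(seed)) cfgs[[name]]() else cfgs[[name]](seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dat <- simulate_dataset(cfg, pileups = pileups)
  paths <- list()
  w <- function(key, path) { paths[[key]] <<- path; path }
  write_fasta(c(reference = dat$reference$sequence),
              w("reference", file.path(dir, "reference.fa")))
  write_fasta(dat$sequences, w("genomes", file.path(dir, "genomes.fa")))
  write_bed(dat$reference$mask, w("mask", file.path(dir, "mask.bed")))
  write_gene_model(dat$reference$genes,
                   w("genes", file.path(dir, "genes.tsv")))
  ape::write.tree(dat$tree, w("tree", file.path(dir, "tree.nwk")))
  utils::write.table(dat$truth$variants,
                     w("truth_variants", file.path(dir, "truth_variants.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dat$truth$shp,
                     w("truth_shp", file.path(dir, "truth_shp.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dat$truth$sv,
                     w("truth_sv", file.path(dir, "truth_sv.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (pileups && !is.null(dat$pileup))
    write_pileup(dat$pileup, w("pileup", file.path(dir, "pileup.tsv")))
  yaml::write_yaml(list(fixture = name, seed = cfg$seed,
                        genome_length = cfg$genome_length,
                        coverage = cfg$coverage,
                        error_rate = cfg$error_rate,
                        files = lapply(paths, basename)),
                   w("config", file.path(dir, "config.yaml")))
  invisible(paths)
}
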