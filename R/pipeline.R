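#' Validate a pipeline configuration
#'
#' Accepts a configuration list or a YAML file path. The configuration
#' names, per genotype, the input files (`gff`, `domains`, `parser`,
#' `coils`, `similarity`, `pseudoexons`, `repeats`, `translated_domains`,
#' optionally `proteome`), and may override threshold blocks
#' (`classify`, `collinear`, `pseudo`, `window_size`, `min_cluster_size`).
#' Missing threshold blocks are filled with the package defaults
#' (1 Mbp windows, minimum cluster size 3, and the gates described in
#' [classify_thresholds()], [collinear_params()] and [pseudo_filter()]).
#'
#' @param config A list or path to a YAML file.
#' @return The checked configuration (class `run_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$genotypes))
  required <- c("gff", "domains", "parser", "coils", "similarity",
                "pseudoexons", "repeats", "translated_domains")
  for (gname in names(config$genotypes)) {
    paths <- config$genotypes[[gname]]
    miss <- setdiff(required, names(paths))
    if (length(miss) > 0L) {
      stop("genotype ", gname, ": missing input field(s) ",
           paste(miss, collapse = ", "))
    }
    for (fld in required) {
      if (!file.exists(paths[[fld]])) {
        stop("genotype ", gname, ": file for '", fld, "' not found: ",
             paths[[fld]])
      }
    }
  }
  config$classify <- do.call(classify_thresholds,
                             as.list(config$classify %||% list()))
  config$collinear <- do.call(collinear_params,
                              as.list(config$collinear %||% list()))
  config$pseudo <- do.call(pseudo_filter, as.list(config$pseudo %||% list()))
  config$window_size <- config$window_size %||% 1e6
  config$min_cluster_size <- config$min_cluster_size %||% 3
  if (config$window_size <= 0) stop("window_size must be positive")
  if (config$min_cluster_size < 1) stop("min_cluster_size must be >= 1")
  class(config) <- c("run_config", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load one genotype's input files into memory
#'
#' Uses the package readers to turn a validated configuration entry into
#' the in-memory genotype structure [run_pipeline()] consumes (the same
#' shape [simulate_genotype()] produces).
#'
#' @param paths Named list of file paths (see [validate_config()]).
#' @param genotype Genotype label.
#' @param scaffold_lens Optional named scaffold lengths; defaults to the
#'   maximum annotated coordinate per chromosome.
#' @return Genotype list.
#' @export
load_genotype <- function(paths, genotype, scaffold_lens = NULL) {
  genes <- read_gff3(paths$gff, genotype = genotype)
  if (is.null(scaffold_lens)) {
    scaffold_lens <- tapply(genes$end, genes$chrom, max)
  }
  proteome <- NULL
  if (!is.null(paths$proteome) && file.exists(paths$proteome)) {
    proteome <- as.character(Biostrings::readAAStringSet(paths$proteome))
    names(proteome) <- sub("\\s.*$", "", names(proteome))
  }
  list(genotype = genotype, genes = genes, proteome = proteome,
       domain_hits = read_domain_hits(paths$domains),
       parser = read_motif_table(paths$parser),
       coils = read_motif_table(paths$coils),
       similarity = read_tabular_hits(paths$similarity, "similarity"),
       pseudoexons = read_tabular_hits(paths$pseudoexons, "pseudoexon",
                                       genotype = genotype),
       repeats = read_tabular_hits(paths$repeats, "repeat"),
       translated_domains = utils::read.delim(paths$translated_domains,
                                              stringsAsFactors = FALSE),
       scaffold_lens = scaffold_lens)
}

# Per-genotype stage computations; returns the stage outputs as a list.
run_genotype_stages <- function(g, config) {
  nlr_ids <- identify_nlrs(g$domain_hits, g$parser, config$classify)
  nlr_ids <- intersect(nlr_ids, g$genes$gene_id)
  records <- classify_architectures(
    nlr_ids, g$domain_hits, g$parser, g$coils,
    genes = g$genes, scaffold_lens = g$scaffold_lens,
    genotype = g$genotype, thresholds = config$classify)
  nlr_genes <- g$genes[g$genes$gene_id %in% nlr_ids, , drop = FALSE]
  ranks <- rank_genes(g$genes)
  blocks <- find_collinear_blocks(g$similarity, ranks, config$collinear)
  dups <- classify_duplicates(ranks, g$similarity, blocks,
                              evalue_cut = config$collinear$evalue_cut)
  clusters <- detect_clusters(nlr_genes, config$window_size,
                              config$min_cluster_size, g$genotype)
  q99 <- tryCatch(intron_q99(g$genes, config$pseudo$intron_quantile),
                  error = function(e) NA_real_)
  if (is.na(q99)) {
    pseudogenes <- empty_pseudogene_contigs()
  } else {
    surv <- filter_candidates(g$pseudoexons, g$genes, g$repeats,
                              config$pseudo)
    contigs <- link_pseudoexons(surv, q99)
    pseudogenes <- domain_confirm(contigs, g$translated_domains)
  }
  list(genotype = g$genotype, records = records, nlr_genes = nlr_genes,
       dups = dups, blocks = blocks, clusters = clusters,
       pseudogenes = pseudogenes, q99 = q99)
}

#' Run the full CNV pipeline
#'
#' Runs the stages classify, duplicates, clusters and pseudogenes per
#' genotype, then the cross-genotype statistics: CNV matrix, two-group
#' split on total NLR count, group summaries with Mann-Whitney tests,
#' complete-vs-partial contingency, pseudogene:parent ratios and the
#' negative-binomial count model. When `out_dir` is given each stage
#' writes its TSV before the next starts; a re-run with the same inputs
#' re-reads completed per-genotype stage files instead of recomputing them
#' unless `force = TRUE`.
#'
#' @param dataset A dataset from [simulate_dataset()], or a list with a
#'   `genotypes` list of genotype structures (see [load_genotype()]).
#' @param config A validated configuration; defaults are used when `NULL`.
#'   For file-based runs pass the config to [validate_config()] and load
#'   genotypes with [load_genotype()] first.
#' @param out_dir Output directory for stage TSVs and the report
#'   (`NULL` for in-memory only).
#' @param force Recompute even when stage outputs exist.
#' @return A `run_report` list: `cnv_matrix`, `groups`, `group_summary`,
#'   `mann_whitney`, `complete_partial`, `pseudo_ratios`,
#'   `cluster_summary`, `glm`, `stages` (per-genotype outputs),
#'   `provenance`.
#' @export
run_pipeline <- function(dataset, config = NULL, out_dir = NULL,
                         force = FALSE) {
  if (is.null(config)) {
    config <- list(classify = classify_thresholds(),
                   collinear = collinear_params(),
                   pseudo = pseudo_filter(),
                   window_size = 1e6, min_cluster_size = 3)
    class(config) <- c("run_config", "list")
  }
  stages <- list()
  skipped <- character(0)
  for (g in dataset$genotypes) {
    st <- NULL
    gdir <- if (!is.null(out_dir)) file.path(out_dir, g$genotype) else NULL
    if (!is.null(gdir) && !force && stage_files_complete(gdir)) {
      st <- read_genotype_stages(gdir, g$genotype)
      skipped <- c(skipped, g$genotype)
    }
    if (is.null(st)) {
      st <- run_genotype_stages(g, config)
      if (!is.null(gdir)) write_genotype_stages(st, gdir)
    }
    stages[[g$genotype]] <- st
  }
  records <- do.call(rbind, lapply(stages, `[[`, "records"))
  all_nlr_genes <- do.call(rbind, lapply(stages, `[[`, "nlr_genes"))
  pseudogenes <- do.call(rbind, lapply(stages, function(s) {
    s$pseudogenes[, setdiff(names(s$pseudogenes), "pseudoexons"),
                  drop = FALSE]
  }))
  clusters <- do.call(rbind, lapply(stages, function(s) {
    s$clusters[, setdiff(names(s$clusters), "members"), drop = FALSE]
  }))
  cnv <- build_cnv_matrix(records, all_nlr_genes, pseudogenes, clusters,
                          genotypes = names(stages))
  report <- list(cnv_matrix = cnv, stages = stages,
                 pseudo_ratios = pseudogene_parent_ratio(pseudogenes),
                 cluster_summary = cluster_summary(clusters),
                 provenance = list(
                   n_genotypes = length(stages),
                   skipped_stages = skipped,
                   window_size = config$window_size,
                   min_cluster_size = config$min_cluster_size))
  totals <- stats::setNames(cnv$total, cnv$genotype)
  if (length(totals) >= 2L && length(unique(totals)) > 1L) {
    groups <- assign_cnv_groups(totals)
    report$groups <- groups
    report$group_summary <- group_summary(totals, groups[cnv$genotype])
    hi <- totals[groups[names(totals)] == "HighCNV"]
    lo <- totals[groups[names(totals)] == "LowCNV"]
    report$mann_whitney <- mann_whitney(hi, lo)
    report$complete_partial <- complete_partial_table(records, groups)
    long <- do.call(rbind, lapply(c("NL", "CNL", "TNL", "RNL"), function(k) {
      data.frame(count = cnv[[k]], group = unname(groups[cnv$genotype]),
                 class = k, stringsAsFactors = FALSE)
    }))
    report$glm <- tryCatch(report_glms(long), error = function(e) {
      list(converged = FALSE, error = conditionMessage(e))
    })
  }
  class(report) <- c("run_report", "list")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

stage_files <- function(dir) {
  file.path(dir, c("nlr_records.tsv", "dup_calls.tsv", "clusters.tsv",
                   "pseudogenes.tsv", "nlr_genes.gff3", "stage_meta.tsv"))
}

stage_files_complete <- function(dir) all(file.exists(stage_files(dir)))

write_genotype_stages <- function(st, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- stage_files(dir)
  wt <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(st$records, f[1L])
  wt(st$dups, f[2L])
  cl <- st$clusters
  cl$members <- vapply(cl$members, paste, "", collapse = ",")
  wt(cl, f[3L])
  pg <- st$pseudogenes
  pg$pseudoexons <- vapply(pg$pseudoexons, function(m) {
    paste(sprintf("%d-%d", m[, "start"], m[, "end"]), collapse = ";")
  }, "")
  wt(pg, f[4L])
  write_gff3(st$nlr_genes, f[5L])
  wt(data.frame(genotype = st$genotype, q99 = st$q99), f[6L])
}

read_genotype_stages <- function(dir, genotype) {
  f <- stage_files(dir)
  rd <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)
  records <- rd(f[1L])
  class(records) <- c("nlr_records", "data.frame")
  cl <- rd(f[3L])
  cl$members <- strsplit(as.character(cl$members), ",", fixed = TRUE)
  pg <- rd(f[4L])
  pg$pseudoexons <- lapply(strsplit(as.character(pg$pseudoexons), ";",
                                    fixed = TRUE),
                           function(p) {
    m <- do.call(rbind, strsplit(p, "-", fixed = TRUE))
    exon_matrix(as.integer(m[, 1L]), as.integer(m[, 2L]))
  })
  meta <- rd(f[6L])
  list(genotype = genotype, records = records,
       nlr_genes = read_gff3(f[5L], genotype = genotype),
       dups = rd(f[2L]), blocks = NULL, clusters = cl,
       pseudogenes = pg, q99 = meta$q99[1L])
}

#' Write a pipeline report
#'
#' Writes the report as machine-readable JSON, the CNV matrix as TSV, and a
#' human-readable markdown summary with the group means, mean difference
#' and cluster table.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param dir Output directory.
#' @param formats Subset of `c("tsv", "json", "markdown")`.
#' @return Named vector of written paths, invisibly.
#' @export
write_report <- function(report, dir,
                         formats = c("tsv", "json", "markdown")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if ("tsv" %in% formats) {
    p <- file.path(dir, "cnv_matrix.tsv")
    utils::write.table(report$cnv_matrix, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["tsv"] <- p
  }
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    js <- list(cnv_matrix = report$cnv_matrix,
               pseudo_ratios = report$pseudo_ratios,
               cluster_summary = report$cluster_summary,
               provenance = report$provenance)
    if (!is.null(report$groups)) {
      js$groups <- as.list(unclass(report$groups))
      js$group_summary <- unclass(report$group_summary)
      js$mann_whitney <- report$mann_whitney
      js$complete_partial <- list(
        table = as.data.frame.matrix(report$complete_partial$table),
        proportions = report$complete_partial$proportions,
        p = report$complete_partial$p)
    }
    jsonlite::write_json(js, p, auto_unbox = TRUE, digits = 10,
                         dataframe = "columns")
    paths["json"] <- p
  }
  if ("markdown" %in% formats) {
    p <- file.path(dir, "report.md")
    lines <- c("# NLR CNV pipeline report", "",
               sprintf("Genotypes: %d", nrow(report$cnv_matrix)), "")
    if (!is.null(report$group_summary)) {
      gs <- report$group_summary
      lines <- c(lines,
        sprintf("High CNV: n = %d, mean total = %.2f (SEM %.2f)",
                gs$HighCNV$n, gs$HighCNV$mean, gs$HighCNV$sem),
        sprintf("Low CNV: n = %d, mean total = %.2f (SEM %.2f)",
                gs$LowCNV$n, gs$LowCNV$mean, gs$LowCNV$sem),
        sprintf("Group mean difference = %.2f (Mann-Whitney p = %.4g)",
                gs$mean_difference, report$mann_whitney$p), "")
    }
    lines <- c(lines, "| genotype | NL | CNL | TNL | RNL | total | pseudogenes |",
               "|---|---|---|---|---|---|---|")
    m <- report$cnv_matrix
    lines <- c(lines, sprintf("| %s | %d | %d | %d | %d | %d | %d |",
                              m$genotype, m$NL, m$CNL, m$TNL, m$RNL,
                              m$total, m$pseudogenes))
    writeLines(lines, p)
    paths["markdown"] <- p
  }
  invisible(paths)
}
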