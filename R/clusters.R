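#' Assign NLR genes to non-overlapping genomic windows
#'
#' Chromosomes are tiled with non-overlapping windows of `window_size` bp
#' starting at coordinate 1. A gene is counted in the unique window holding
#' more than 50% of its span; a gene split exactly 50/50 across a boundary
#' goes to the left window so that every gene is counted exactly once.
#'
#' @param genes A `gene_models` (or any) data frame with `gene_id`, `chrom`,
#'   `start`, `end`.
#' @param window_size Window size in bp (default 1e6).
#' @return Data frame `gene_id`, `chrom`, `window` (0-based window index).
#' @export
assign_windows <- function(genes, window_size = 1e6) {
  if (window_size <= 0) stop("window_size must be positive")
  n <- nrow(genes)
  win <- integer(n)
  for (i in seq_len(n)) {
    s <- genes$start[i]; e <- genes$end[i]
    w0 <- (s - 1) %/% window_size
    w1 <- (e - 1) %/% window_size
    if (w0 == w1) {
      win[i] <- w0
    } else {
      # overlap of the span with each candidate window; majority wins,
      # exact tie goes left (earlier window)
      ws <- w0:w1
      ov <- pmin(e, (ws + 1) * window_size) - pmax(s, ws * window_size + 1) + 1
      win[i] <- ws[which.max(ov)]  # which.max takes the first (left) maximum
    }
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             window = as.integer(win), stringsAsFactors = FALSE)
}

#' Merge adjacent occupied windows
#'
#' Iteratively merges adjacent windows that each hold at least one NLR until
#' no merge is possible. The fixpoint equals the maximal runs of consecutive
#' occupied window indices per chromosome, which is what this computes.
#'
#' @param assignments Window assignments from [assign_windows()].
#' @return Data frame of runs: `chrom`, `first_window`, `last_window`,
#'   `n_members`, list column `members` (gene ids).
#' @export
merge_windows <- function(assignments) {
  out <- list()
  for (ch in unique(assignments$chrom)) {
    a <- assignments[assignments$chrom == ch, , drop = FALSE]
    wins <- sort(unique(a$window))
    if (length(wins) == 0L) next
    run_id <- cumsum(c(1L, diff(wins) > 1L))
    for (r in unique(run_id)) {
      w <- wins[run_id == r]
      members <- a$gene_id[a$window %in% w]
      out[[length(out) + 1L]] <- list(
        chrom = ch, first_window = min(w), last_window = max(w),
        members = members)
    }
  }
  runs <- data.frame(
    chrom = vapply(out, `[[`, "", "chrom"),
    first_window = vapply(out, function(x) as.integer(x$first_window), integer(1)),
    last_window = vapply(out, function(x) as.integer(x$last_window), integer(1)),
    n_members = vapply(out, function(x) length(x$members), integer(1)),
    stringsAsFactors = FALSE)
  runs$members <- lapply(out, `[[`, "members")
  rownames(runs) <- NULL
  runs
}

#' Call NLR clusters from merged window runs
#'
#' A merged run of windows is an NLR cluster when it holds at least
#' `min_size` NLR genes.
#'
#' @param runs Merged runs from [merge_windows()].
#' @param min_size Minimum member count (default 3).
#' @param genotype Genotype label used in cluster ids.
#' @return Data frame `cluster_id`, `genotype`, `chrom`, `first_window`,
#'   `last_window`, `size`, list column `members`.
#' @export
call_clusters <- function(runs, min_size = 3, genotype = NA_character_) {
  keep <- runs$n_members >= min_size
  cl <- runs[keep, , drop = FALSE]
  out <- data.frame(
    cluster_id = sprintf("%s:%s:%d", genotype, cl$chrom, cl$first_window),
    genotype = rep_len(genotype, nrow(cl)), chrom = cl$chrom,
    first_window = cl$first_window, last_window = cl$last_window,
    size = cl$n_members, stringsAsFactors = FALSE)
  out$members <- cl$members
  rownames(out) <- NULL
  out
}

#' Detect NLR clusters for one genotype
#'
#' Convenience wrapper: window assignment, merging and cluster calling.
#' Unplaced scaffolds (`Chr0`) are excluded from clustering because merged
#' windows across unordered scaffolds are not meaningful.
#'
#' @param nlr_genes `gene_models` rows for the genotype's NLR genes.
#' @param window_size Window size in bp (default 1e6).
#' @param min_size Minimum cluster size (default 3).
#' @param genotype Genotype label (default taken from the genes).
#' @param exclude_chroms Chromosomes excluded from clustering
#'   (default `"Chr0"`).
#' @return Cluster data frame (see [call_clusters()]).
#' @export
detect_clusters <- function(nlr_genes, window_size = 1e6, min_size = 3,
                            genotype = NULL, exclude_chroms = "Chr0") {
  if (is.null(genotype)) {
    genotype <- if (nrow(nlr_genes) > 0L) nlr_genes$genotype[1L] else NA_character_
  }
  nlr_genes <- nlr_genes[!(nlr_genes$chrom %in% exclude_chroms), , drop = FALSE]
  if (nrow(nlr_genes) == 0L) {
    return(call_clusters(merge_windows(
      data.frame(gene_id = character(0), chrom = character(0),
                 window = integer(0), stringsAsFactors = FALSE)),
      min_size, genotype))
  }
  call_clusters(merge_windows(assign_windows(nlr_genes, window_size)),
                min_size, genotype)
}

#' Per-genotype cluster count and mean size
#'
#' @param clusters Cluster data frame(s), possibly row-bound across
#'   genotypes.
#' @return Data frame `genotype`, `n_clusters`, `mean_size` (`NA` when a
#'   genotype has no clusters).
#' @export
cluster_summary <- function(clusters) {
  if (nrow(clusters) == 0L) {
    return(data.frame(genotype = character(0), n_clusters = integer(0),
                      mean_size = numeric(0), stringsAsFactors = FALSE))
  }
  gts <- unique(clusters$genotype)
  data.frame(
    genotype = gts,
    n_clusters = vapply(gts, function(g) sum(clusters$genotype == g), integer(1)),
    mean_size = vapply(gts, function(g) {
      mean(clusters$size[clusters$genotype == g])
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write cluster spans as a BED track
#'
#' Window spans are converted to 0-based half-open BED intervals for genome
#' browsers.
#'
#' @param clusters Cluster data frame.
#' @param path Output path.
#' @param window_size Window size used during detection (default 1e6).
#' @return `path`, invisibly.
#' @export
clusters_to_bed <- function(clusters, path, window_size = 1e6) {
  bed <- data.frame(
    chrom = clusters$chrom,
    start = format(clusters$first_window * window_size, scientific = FALSE,
                   trim = TRUE),
    end = format((clusters$last_window + 1) * window_size,
                 scientific = FALSE, trim = TRUE),
    name = clusters$cluster_id,
    score = clusters$size,
    strand = ".",
    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
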