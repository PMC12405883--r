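# Fixtures and independent brute-force oracles used across the suite.

make_genes <- function(starts, ends, chrom = "Chr1", genotype = "g1",
                       prefix = "g", exons = NULL) {
  n <- length(starts)
  ids <- paste0(prefix, seq_len(n))
  out <- data.frame(gene_id = ids, genotype = genotype,
                    chrom = rep_len(chrom, n),
                    start = as.integer(starts), end = as.integer(ends),
                    strand = "+", aed = NA_real_, stringsAsFactors = FALSE)
  out$exons <- if (is.null(exons)) {
    lapply(seq_len(n), function(i) {
      cbind(start = as.integer(starts[i]), end = as.integer(ends[i]))
    })
  } else exons
  class(out) <- c("gene_models", "data.frame")
  out
}

sim_hit <- function(q, s, pident = 90, evalue = 1e-50) {
  n <- length(q)
  data.frame(query_id = q, subject_id = s,
             pct_identity = rep_len(pident, n), align_len = rep_len(100L, n),
             evalue = rep_len(evalue, n), q_start = rep_len(1L, n),
             q_end = rep_len(100L, n), s_start = rep_len(1L, n),
             s_end = rep_len(100L, n), stringsAsFactors = FALSE)
}

make_pseudo_hits <- function(parent, chrom, g_start, g_end,
                             pct_identity = 60, aa_len = 50,
                             evalue = 1e-30, genotype = "g1") {
  n <- length(g_start)
  data.frame(
    hit_id = sprintf("%s:%s:%d-%d", rep_len(parent, n), rep_len(chrom, n),
                     as.integer(g_start), as.integer(g_end)),
    parent_protein = rep_len(parent, n), genotype = genotype,
    chrom = rep_len(chrom, n),
    g_start = as.integer(g_start), g_end = as.integer(g_end),
    frame = 1L, pct_identity = rep_len(pct_identity, n),
    aa_len = as.integer(rep_len(aa_len, n)),
    evalue = rep_len(evalue, n), stringsAsFactors = FALSE)
}

# Direct rule-by-rule duplication classifier (no shared code with the
# package implementation): per-gene loops over all hits.
oracle_dup_classify <- function(ranks, hits, anchor_ids = character(0),
                                max_proximal = 20, evalue_cut = 1e-10) {
  hits <- hits[hits$evalue <= evalue_cut &
                 hits$query_id != hits$subject_id, , drop = FALSE]
  vapply(seq_len(nrow(ranks)), function(i) {
    gid <- ranks$gene_id[i]
    if (gid %in% anchor_ids) return("wgd_segmental")
    partners <- unique(c(hits$subject_id[hits$query_id == gid],
                         hits$query_id[hits$subject_id == gid]))
    partners <- partners[partners %in% ranks$gene_id]
    if (length(partners) == 0L) return("singleton")
    pr <- ranks[match(partners, ranks$gene_id), ]
    same <- pr$chrom == ranks$chrom[i]
    d <- abs(pr$rank - ranks$rank[i])
    if (any(same & d == 1)) return("tandem")
    if (any(same & d >= 2 & d <= max_proximal)) return("proximal")
    "dispersed"
  }, "")
}

# Fixpoint of literal pairwise merging of adjacent occupied windows,
# applied in a caller-chosen order until no merge applies.
oracle_merge_windows <- function(assignments, order_fun = identity) {
  runs <- lapply(split(assignments$gene_id,
                       paste(assignments$chrom, assignments$window,
                             sep = "\r")),
                 identity)
  meta <- unique(assignments[, c("chrom", "window")])
  key <- paste(meta$chrom, meta$window, sep = "\r")
  runs <- lapply(seq_len(nrow(meta)), function(i) {
    list(chrom = meta$chrom[i], lo = meta$window[i], hi = meta$window[i],
         members = runs[[key[i]]])
  })
  repeat {
    n <- length(runs)
    pairs <- list()
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && runs[[i]]$chrom == runs[[j]]$chrom &&
            runs[[j]]$lo == runs[[i]]$hi + 1L) {
          pairs[[length(pairs) + 1L]] <- c(i, j)
        }
      }
    }
    if (length(pairs) == 0L) break
    pick <- order_fun(seq_along(pairs))[1L]
    ij <- pairs[[pick]]
    runs[[ij[1L]]]$hi <- runs[[ij[2L]]]$hi
    runs[[ij[1L]]]$members <- c(runs[[ij[1L]]]$members,
                                runs[[ij[2L]]]$members)
    runs <- runs[-ij[2L]]
  }
  runs
}

run_signature <- function(chrom, lo, hi, members) {
  if (!is.list(members)) members <- list(members)
  mapply(function(ch, l, h, m) {
    paste(ch, l, h, paste(sort(m), collapse = "+"), sep = "|")
  }, chrom, lo, hi, members, USE.NAMES = FALSE)
}

# Exhaustive validation of pseudoexon chaining: over all 2^(n-1) contiguous
# partitions of the sorted fragments, exactly one satisfies "every
# within-segment consecutive pair linkable, every boundary pair not".
oracle_link_partitions <- function(exons, q99) {
  o <- order(exons$genotype, exons$chrom, exons$g_start, exons$g_end)
  exons <- exons[o, , drop = FALSE]
  n <- nrow(exons)
  linkable <- function(i, j) {
    gap <- exons$g_start[j] - exons$g_end[i] - 1
    exons$genotype[i] == exons$genotype[j] &&
      exons$chrom[i] == exons$chrom[j] &&
      exons$parent_protein[i] == exons$parent_protein[j] &&
      gap >= 0 && gap <= q99
  }
  if (n == 1L) return(list(list(1L)))
  valid <- list()
  for (mask in 0:(2^(n - 1L) - 1L)) {
    breaks <- which(bitwAnd(mask, 2^(0:(n - 2L))) > 0L)
    seg <- cumsum(c(1L, as.integer(seq_len(n - 1L) %in% breaks)))
    ok <- TRUE
    for (i in seq_len(n - 1L)) {
      li <- linkable(i, i + 1L)
      if (seg[i] == seg[i + 1L] && !li) ok <- FALSE
      if (seg[i] != seg[i + 1L] && li) ok <- FALSE
    }
    if (ok) valid[[length(valid) + 1L]] <- split(seq_len(n), seg)
  }
  valid
}
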