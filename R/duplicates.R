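#' Rank genes along chromosomes
#'
#' Orders a genotype's genes by (chromosome, start, end, gene_id) and assigns
#' a 0-based rank within each chromosome. Rank distance is the unit in which
#' tandem (distance 1) and proximal (distance <= 20) duplicates are defined.
#'
#' @param genes A `gene_models` data frame (one genotype).
#' @return Data frame `gene_id`, `chrom`, `rank`, `start`, `end`.
#' @export
rank_genes <- function(genes) {
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1L])
  }
  o <- order(genes$chrom, genes$start, genes$end, genes$gene_id)
  out <- data.frame(gene_id = genes$gene_id[o], chrom = genes$chrom[o],
                    start = genes$start[o], end = genes$end[o],
                    stringsAsFactors = FALSE)
  out$rank <- stats::ave(seq_len(nrow(out)), out$chrom,
                         FUN = seq_along) - 1L
  rownames(out) <- NULL
  out[, c("gene_id", "chrom", "rank", "start", "end")]
}

#' Collinear chaining parameters
#'
#' Scoring and geometry of MCScanX-style block chaining: each anchor adds
#' `match_score`, each skipped gene rank between consecutive anchors costs
#' `gap_penalty`, consecutive anchors may be at most `max_gaps` ranks apart
#' on either genome, and only chains of at least `match_size` anchors are
#' reported. Hits are pre-filtered at `evalue_cut`.
#'
#' @param match_score Per-anchor score (default 50).
#' @param gap_penalty Per-skipped-rank penalty (default -1).
#' @param match_size Minimum anchors per block (default 5).
#' @param max_gaps Maximum rank gap between consecutive anchors (default 20).
#' @param evalue_cut Similarity-hit e-value cutoff (default 1e-10).
#' @return A `collinear_params` list.
#' @export
collinear_params <- function(match_score = 50, gap_penalty = -1,
                             match_size = 5, max_gaps = 20,
                             evalue_cut = 1e-10) {
  stopifnot(match_size >= 2, max_gaps >= 1)
  structure(list(match_score = match_score, gap_penalty = gap_penalty,
                 match_size = match_size, max_gaps = max_gaps,
                 evalue_cut = evalue_cut),
            class = "collinear_params")
}

#' Find collinear blocks by dynamic-programming chaining
#'
#' Maps similarity hits to rank points per (ordered) chromosome pair and
#' chains them: a point extends a chain when its rank strictly increases on
#' chromosome A and strictly increases (same orientation) or strictly
#' decreases (inverted) on chromosome B, with both rank gaps at most
#' `max_gaps`. Chain score is
#' `match_score * n_anchors + gap_penalty * sum(skipped ranks)`.
#' Chains are extracted greedily by descending score; a hit consumed by one
#' block is not reused. Within-chromosome blocks are allowed but their two
#' rank intervals must not overlap.
#'
#' @param hits Similarity-hit data frame (see [read_tabular_hits()]).
#' @param ranks Ranked-gene table from [rank_genes()].
#' @param params A [collinear_params()] object.
#' @return Data frame of blocks: `block_id`, `chrom_a`, `chrom_b`,
#'   `orientation` (`same`/`inverted`), `n_anchors`, `score`, and a list
#'   column `anchors` (two-column character matrices `gene_a`, `gene_b`).
#' @export
find_collinear_blocks <- function(hits, ranks, params = collinear_params()) {
  hits <- hits[!is.na(hits$evalue) & hits$evalue <= params$evalue_cut &
                 hits$query_id != hits$subject_id, , drop = FALSE]
  qi <- match(hits$query_id, ranks$gene_id)
  si <- match(hits$subject_id, ranks$gene_id)
  unknown <- is.na(qi) | is.na(si)
  if (any(unknown)) {
    warning(sum(unknown), " hit(s) referencing unknown genes skipped")
    hits <- hits[!unknown, , drop = FALSE]
    qi <- qi[!unknown]; si <- si[!unknown]
  }
  if (nrow(hits) == 0L) return(empty_blocks())
  pts <- data.frame(
    chrom_a = ranks$chrom[qi], ra = ranks$rank[qi], ga = ranks$gene_id[qi],
    chrom_b = ranks$chrom[si], rb = ranks$rank[si], gb = ranks$gene_id[si],
    stringsAsFactors = FALSE)
  # canonical orientation of each pair so mirrored hits coincide
  swap <- pts$chrom_a > pts$chrom_b |
    (pts$chrom_a == pts$chrom_b & pts$ra > pts$rb)
  pts[swap, c("chrom_a", "ra", "ga", "chrom_b", "rb", "gb")] <-
    pts[swap, c("chrom_b", "rb", "gb", "chrom_a", "ra", "ga")]
  pts <- pts[!duplicated(pts[, c("chrom_a", "chrom_b", "ra", "rb")]), ,
             drop = FALSE]
  blocks <- list()
  for (key in unique(paste(pts$chrom_a, pts$chrom_b, sep = "\r"))) {
    pp <- pts[paste(pts$chrom_a, pts$chrom_b, sep = "\r") == key, ,
              drop = FALSE]
    blocks <- c(blocks, chain_chrom_pair(pp, params))
  }
  if (length(blocks) == 0L) return(empty_blocks())
  scores <- vapply(blocks, `[[`, numeric(1), "score")
  blocks <- blocks[order(-scores,
                         vapply(blocks, function(b) b$anchors[1L, 1L], ""))]
  out <- data.frame(
    block_id = sprintf("block%03d", seq_along(blocks)),
    chrom_a = vapply(blocks, `[[`, "", "chrom_a"),
    chrom_b = vapply(blocks, `[[`, "", "chrom_b"),
    orientation = vapply(blocks, `[[`, "", "orientation"),
    n_anchors = vapply(blocks, function(b) nrow(b$anchors), integer(1)),
    score = vapply(blocks, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  out$anchors <- lapply(blocks, `[[`, "anchors")
  rownames(out) <- NULL
  out
}

empty_blocks <- function() {
  out <- data.frame(block_id = character(0), chrom_a = character(0),
                    chrom_b = character(0), orientation = character(0),
                    n_anchors = integer(0), score = numeric(0),
                    stringsAsFactors = FALSE)
  out$anchors <- list()
  out
}

# Greedy best-chain extraction for one chromosome pair.
chain_chrom_pair <- function(pp, params) {
  within <- pp$chrom_a[1L] == pp$chrom_b[1L]
  found <- list()
  repeat {
    if (nrow(pp) < params$match_size) break
    best <- NULL
    for (orient in c(1L, -1L)) {
      ch <- chain_dp(pp, orient, params)
      if (!is.null(ch) && (is.null(best) || ch$score > best$score)) best <- ch
    }
    if (is.null(best)) break
    idx <- best$idx
    if (within) {
      ia <- range(pp$ra[idx]); ib <- range(pp$rb[idx])
      if (ia[2L] >= ib[1L] && ib[2L] >= ia[1L]) {
        # self-comparison chain whose two rank intervals overlap (e.g. the
        # trivial near-diagonal chain): not a duplicated segment; drop its
        # points and continue
        pp <- pp[-idx, , drop = FALSE]
        next
      }
    }
    found[[length(found) + 1L]] <- list(
      chrom_a = pp$chrom_a[1L], chrom_b = pp$chrom_b[1L],
      orientation = if (best$orient == 1L) "same" else "inverted",
      score = best$score,
      anchors = cbind(gene_a = pp$ga[idx], gene_b = pp$gb[idx]))
    pp <- pp[-idx, , drop = FALSE]
  }
  found
}

# DP over points sorted by (ra, rb): best-scoring chain with >= match_size
# anchors for one orientation, or NULL.
chain_dp <- function(pp, orient, params) {
  o <- order(pp$ra, pp$rb * orient)
  ra <- pp$ra[o]; rb <- pp$rb[o]
  n <- length(ra)
  score <- rep(params$match_score, n)
  len <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      da <- ra[j] - ra[i]
      db <- (rb[j] - rb[i]) * orient
      if (da > 0L && da <= params$max_gaps &&
          db > 0L && db <= params$max_gaps) {
        gap <- (da - 1L) + (db - 1L)
        cand <- score[i] + params$match_score + params$gap_penalty * gap
        if (cand > score[j] ||
            (cand == score[j] && !is.na(prev[j]) && i < prev[j])) {
          score[j] <- cand
          len[j] <- len[i] + 1L
          prev[j] <- i
        }
      }
    }
  }
  ok <- which(len >= params$match_size)
  if (length(ok) == 0L) return(NULL)
  end <- ok[order(-score[ok], ra[ok])][1L]
  idx <- end
  while (!is.na(prev[idx[1L]])) idx <- c(prev[idx[1L]], idx)
  list(idx = o[idx], score = score[end], orient = orient)
}

#' Classify gene duplication types
#'
#' Every gene receives exactly one duplication class, by precedence
#' `wgd_segmental > tandem > proximal > dispersed > singleton`:
#' a collinear-block anchor is a WGD/segmental duplicate; otherwise a gene
#' with a same-chromosome similarity partner exactly 1 rank away is tandem;
#' at rank distance 2..`max_proximal` it is proximal; any remaining partner
#' anywhere makes it dispersed; a gene with no non-self partner is a
#' singleton.
#'
#' @param ranks Ranked-gene table from [rank_genes()].
#' @param hits Similarity-hit data frame (filtered internally at
#'   `evalue_cut`).
#' @param blocks Collinear blocks from [find_collinear_blocks()] (may have
#'   zero rows).
#' @param max_proximal Maximum rank distance for a proximal call
#'   (default 20).
#' @param evalue_cut Hit e-value cutoff (default 1e-10).
#' @return Data frame `gene_id`, `dup_type`.
#' @export
classify_duplicates <- function(ranks, hits, blocks = empty_blocks(),
                                max_proximal = 20, evalue_cut = 1e-10) {
  hits <- hits[!is.na(hits$evalue) & hits$evalue <= evalue_cut &
                 hits$query_id != hits$subject_id, , drop = FALSE]
  qi <- match(hits$query_id, ranks$gene_id)
  si <- match(hits$subject_id, ranks$gene_id)
  unknown <- is.na(qi) | is.na(si)
  if (any(unknown)) {
    warning(sum(unknown), " hit(s) referencing unknown genes skipped")
    qi <- qi[!unknown]; si <- si[!unknown]
  }
  # undirected partner pairs, both directions
  gi <- c(qi, si)
  pi <- c(si, qi)
  same <- ranks$chrom[gi] == ranks$chrom[pi]
  dist <- abs(ranks$rank[gi] - ranks$rank[pi])
  has_any <- has_adj <- has_prox <- logical(nrow(ranks))
  has_any[unique(gi)] <- TRUE
  has_adj[unique(gi[same & dist == 1L])] <- TRUE
  has_prox[unique(gi[same & dist >= 2L & dist <= max_proximal])] <- TRUE
  anchor_ids <- unique(unlist(lapply(blocks$anchors, as.character)))
  is_anchor <- ranks$gene_id %in% anchor_ids
  dup_type <- ifelse(is_anchor, "wgd_segmental",
              ifelse(has_adj, "tandem",
              ifelse(has_prox, "proximal",
              ifelse(has_any, "dispersed", "singleton"))))
  data.frame(gene_id = ranks$gene_id, dup_type = dup_type,
             stringsAsFactors = FALSE)
}
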