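#' Pseudoexon filter settings
#'
#' Candidate tBLASTn hits enter at e-value <= 1e-20 (upstream); surviving
#' pseudoexons must be non-genic, longer than 30 aa (strict), above 40%
#' identity (strict), and must not match a repeat library at
#' e-value < 1e-5 (strict). Pseudoexons are linked into pseudogene contigs
#' when their gap is inside the 99th percentile of the genotype's intron
#' length distribution.
#'
#' @param cand_evalue Candidate-hit gate (default 1e-20).
#' @param min_aa_len Minimum hit length in aa, exclusive (default 30).
#' @param min_identity Minimum percent identity, exclusive (default 40).
#' @param repeat_evalue Repeat-match exclusion gate, strict (default 1e-5).
#' @param intron_quantile Intron-length quantile bounding linkable gaps
#'   (default 0.99).
#' @return A `pseudo_filter` list.
#' @export
pseudo_filter <- function(cand_evalue = 1e-20, min_aa_len = 30,
                          min_identity = 40, repeat_evalue = 1e-5,
                          intron_quantile = 0.99) {
  stopifnot(cand_evalue > 0, min_aa_len > 0, min_identity > 0,
            repeat_evalue > 0, intron_quantile > 0, intron_quantile < 1)
  structure(list(cand_evalue = cand_evalue, min_aa_len = min_aa_len,
                 min_identity = min_identity, repeat_evalue = repeat_evalue,
                 intron_quantile = intron_quantile),
            class = "pseudo_filter")
}

#' The common NLR Pfam domains
#'
#' Domains whose presence in a six-frame translation confirms a putative
#' pseudogene as NLR-derived: the LRR set (PF00560, PF07725, PF12799,
#' PF13855), NB-ARC (PF00931), TIR (PF01582, PF13676), RPW8 (PF05659) and
#' CC (PF18052).
#'
#' @return Character vector of Pfam accessions.
#' @export
common_nlr_domains <- function() {
  c("PF00560", "PF07725", "PF12799", "PF13855", "PF00931",
    "PF01582", "PF13676", "PF05659", "PF18052")
}

#' Filter candidate pseudoexon hits
#'
#' Keeps hits that (a) do not overlap any annotated gene span by even 1 bp,
#' (b) are longer than `min_aa_len` amino acids, (c) exceed `min_identity`
#' percent identity, and (d) have no repeat-library match below
#' `repeat_evalue`. Candidate e-value gating (<= `cand_evalue`) is applied
#' first in case upstream search was run looser.
#'
#' @param hits Pseudoexon-hit data frame (see [read_tabular_hits()]).
#' @param genes Annotated `gene_models` for the same genotype.
#' @param repeats Data frame `hit_id`, `evalue` of repeat-library matches.
#' @param filter A [pseudo_filter()] object.
#' @return The surviving hits, with attribute `removed`: a named integer
#'   vector of removal counts per criterion (`evalue`, `genic`, `short`,
#'   `low_identity`, `repeat`) summing to `nrow(hits) - nrow(result)`.
#' @export
filter_candidates <- function(hits, genes, repeats = NULL,
                              filter = pseudo_filter()) {
  keep <- rep(TRUE, nrow(hits))
  removed <- c(evalue = 0L, genic = 0L, short = 0L, low_identity = 0L,
               "repeat" = 0L)
  drop_for <- function(keep, bad, reason, removed) {
    newly <- keep & bad
    removed[reason] <- removed[reason] + sum(newly)
    list(keep = keep & !bad, removed = removed)
  }
  st <- drop_for(keep, !(hits$evalue <= filter$cand_evalue), "evalue", removed)
  if (nrow(genes) > 0L && nrow(hits) > 0L) {
    hr <- GenomicRanges::GRanges(hits$chrom,
                                 IRanges::IRanges(hits$g_start, hits$g_end))
    gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
    genic <- IRanges::overlapsAny(hr, gr)
  } else {
    genic <- rep(FALSE, nrow(hits))
  }
  st <- drop_for(st$keep, genic, "genic", st$removed)
  st <- drop_for(st$keep, hits$aa_len <= filter$min_aa_len, "short", st$removed)
  st <- drop_for(st$keep, hits$pct_identity <= filter$min_identity,
                 "low_identity", st$removed)
  if (!is.null(repeats) && nrow(repeats) > 0L) {
    rep_bad <- hits$hit_id %in%
      repeats$hit_id[repeats$evalue < filter$repeat_evalue]
  } else {
    rep_bad <- rep(FALSE, nrow(hits))
  }
  st <- drop_for(st$keep, rep_bad, "repeat", st$removed)
  out <- hits[st$keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- st$removed
  out
}

#' Empirical intron-length quantile of an annotation
#'
#' Pools intron lengths from all annotated genes of a genotype (see
#' [intron_lengths()]) and returns the `q`-th empirical quantile with
#' linear interpolation between order statistics.
#'
#' @param genes A `gene_models` data frame.
#' @param q Quantile in (0, 1) (default 0.99).
#' @return Quantile in bp.
#' @export
intron_q99 <- function(genes, q = 0.99) {
  il <- intron_lengths(genes)
  if (length(il) == 0L) {
    stop("annotation contains no introns; supply a configured fallback ",
         "gap limit instead of the intron-length quantile")
  }
  unname(stats::quantile(il, q, type = 7))
}

#' Link pseudoexons into pseudogene contigs
#'
#' Pseudoexons are sorted by (chromosome, genomic start) and consecutive
#' hits are chained when they share the same best-hit parent NLR, lie on the
#' same chromosome, and the gap between them
#' (`next_start - prev_end - 1`) is at most `q99` bp (the intron-length
#' quantile). Maximal chains become pseudogene contigs; a single surviving
#' pseudoexon forms a one-exon contig when `min_exons = 1`. Overlapping
#' same-parent hits are merged into one pseudoexon spanning their union
#' (reported via a message).
#'
#' Where one genomic interval has hits to several parents, the best hit
#' (lowest e-value, ties by higher identity then parent id) decides the
#' parent attribution before chaining.
#'
#' @param exons Filtered pseudoexon hits (see [filter_candidates()]).
#' @param q99 Maximum linkable gap in bp (from [intron_q99()]).
#' @param min_exons Minimum pseudoexons per reported contig (default 1).
#' @return Data frame `contig_id`, `genotype`, `chrom`, `start`, `end`,
#'   `parent_protein`, `n_exons`, list column `pseudoexons` (two-column
#'   `start`/`end` matrices).
#' @export
link_pseudoexons <- function(exons, q99, min_exons = 1) {
  if (nrow(exons) == 0L) return(empty_pseudogene_contigs())
  # best-hit parent per genomic interval
  key <- sprintf("%s:%s:%d-%d", exons$genotype, exons$chrom,
                 exons$g_start, exons$g_end)
  o <- order(key, exons$evalue, -exons$pct_identity, exons$parent_protein)
  exons <- exons[o, , drop = FALSE]
  exons <- exons[!duplicated(key[o]), , drop = FALSE]
  o <- order(exons$genotype, exons$chrom, exons$g_start, exons$g_end)
  exons <- exons[o, , drop = FALSE]
  n <- nrow(exons)
  # merge overlapping same-parent hits into single pseudoexons
  merged <- 0L
  keep <- rep(TRUE, n)
  for (i in seq_len(n)[-1L]) {
    j <- max(which(keep[seq_len(i - 1L)]))
    same <- exons$genotype[i] == exons$genotype[j] &&
      exons$chrom[i] == exons$chrom[j] &&
      exons$parent_protein[i] == exons$parent_protein[j]
    if (same && exons$g_start[i] <= exons$g_end[j] + 0L) {
      exons$g_end[j] <- max(exons$g_end[j], exons$g_end[i])
      keep[i] <- FALSE
      merged <- merged + 1L
    }
  }
  if (merged > 0L) {
    message("merged ", merged, " overlapping same-parent pseudoexon(s)")
  }
  exons <- exons[keep, , drop = FALSE]
  n <- nrow(exons)
  gap <- exons$g_start[-1L] - exons$g_end[-n] - 1L
  linkable <- exons$genotype[-1L] == exons$genotype[-n] &
    exons$chrom[-1L] == exons$chrom[-n] &
    exons$parent_protein[-1L] == exons$parent_protein[-n] &
    gap >= 0L & gap <= q99
  contig <- cumsum(c(1L, !linkable))
  parts <- split(seq_len(n), contig)
  parts <- parts[vapply(parts, length, integer(1)) >= min_exons]
  if (length(parts) == 0L) return(empty_pseudogene_contigs())
  out <- data.frame(
    genotype = vapply(parts, function(ix) exons$genotype[ix[1L]], ""),
    chrom = vapply(parts, function(ix) exons$chrom[ix[1L]], ""),
    start = vapply(parts, function(ix) min(exons$g_start[ix]), integer(1)),
    end = vapply(parts, function(ix) max(exons$g_end[ix]), integer(1)),
    parent_protein = vapply(parts, function(ix) exons$parent_protein[ix[1L]], ""),
    n_exons = vapply(parts, length, integer(1)),
    stringsAsFactors = FALSE)
  out$contig_id <- sprintf("%s:%s:%d", out$genotype, out$chrom, out$start)
  out$pseudoexons <- lapply(parts, function(ix) {
    cbind(start = exons$g_start[ix], end = exons$g_end[ix])
  })
  rownames(out) <- NULL
  out[, c("contig_id", "genotype", "chrom", "start", "end",
          "parent_protein", "n_exons", "pseudoexons")]
}

empty_pseudogene_contigs <- function() {
  out <- data.frame(contig_id = character(0), genotype = character(0),
                    chrom = character(0), start = integer(0),
                    end = integer(0), parent_protein = character(0),
                    n_exons = integer(0), stringsAsFactors = FALSE)
  out$pseudoexons <- list()
  out
}

#' Confirm pseudogene contigs by NLR domain content
#'
#' Putative pseudogenes whose six-frame translation contains none of the
#' common NLR domains (see [common_nlr_domains()]) are removed; they are
#' likely derived from integrated non-NLR domains. A contig absent from the
#' translated-domain table counts as having no domains.
#'
#' @param contigs Pseudogene contigs from [link_pseudoexons()].
#' @param translated_hits Data frame `contig_id`, `accession` of Pfam hits
#'   on six-frame translations.
#' @param common Character vector of confirming accessions.
#' @return The confirmed contigs, with columns `domains_found`
#'   (comma-separated) and `passed_domain_filter` added.
#' @export
domain_confirm <- function(contigs, translated_hits,
                           common = common_nlr_domains()) {
  found <- lapply(contigs$contig_id, function(id) {
    sort(unique(translated_hits$accession[translated_hits$contig_id == id]))
  })
  passed <- vapply(found, function(f) any(f %in% common), logical(1))
  out <- contigs[passed, , drop = FALSE]
  out$domains_found <- vapply(found[passed], paste, "", collapse = ",")
  out$passed_domain_filter <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Pseudogene-to-parent ratio per genotype
#'
#' Number of pseudogene contigs divided by the number of distinct parent
#' NLRs they derive from, per genotype; a skewed ratio indicates repeated
#' duplication of already-pseudogenized copies.
#'
#' @param contigs Confirmed pseudogene contigs.
#' @return Data frame `genotype`, `n_pseudo`, `n_parents`, `ratio`
#'   (rounded to 1 decimal; `NA` when there are no parents).
#' @export
pseudogene_parent_ratio <- function(contigs) {
  gts <- unique(contigs$genotype)
  out <- data.frame(
    genotype = gts,
    n_pseudo = vapply(gts, function(g) sum(contigs$genotype == g), integer(1)),
    n_parents = vapply(gts, function(g) {
      length(unique(contigs$parent_protein[contigs$genotype == g]))
    }, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out$ratio <- ifelse(out$n_parents > 0,
                      round(out$n_pseudo / out$n_parents, 1), NA_real_)
  out
}

#' Write pseudogene contigs as GFF3
#'
#' Emits `pseudogene` and `pseudogenic_exon` features with a `Parent_NLR`
#' attribute naming the parent protein.
#'
#' @param contigs Pseudogene contigs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pseudogene_gff3 <- function(contigs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(contigs))) {
    p <- contigs[i, ]
    writeLines(sprintf(
      "%s\tnlrcnv\tpseudogene\t%d\t%d\t.\t.\t.\tID=%s;Parent_NLR=%s",
      p$chrom, p$start, p$end, p$contig_id, p$parent_protein), con)
    ex <- contigs$pseudoexons[[i]]
    writeLines(sprintf(
      "%s\tnlrcnv\tpseudogenic_exon\t%d\t%d\t.\t.\t.\tID=%s.pe%d;Parent=%s",
      p$chrom, ex[, "start"], ex[, "end"], p$contig_id,
      seq_len(nrow(ex)), p$contig_id), con)
  }
  invisible(path)
}
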