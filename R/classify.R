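#' Pfam accessions used for NLR classification
#'
#' The diagnostic domain set: NB-ARC (PF00931), TIR (PF01582, PF13676),
#' RPW8 (PF05659), the Rx N-terminal coiled-coil (PF18052) and the LRR
#' family accessions (PF00560, PF07725, PF12799, PF13855).
#'
#' @return Named list of character vectors: `nbarc`, `tir`, `rpw8`, `cc_rx`,
#'   `lrr`.
#' @export
nlr_pfam_accessions <- function() {
  list(
    nbarc = "PF00931",
    tir = c("PF01582", "PF13676"),
    rpw8 = "PF05659",
    cc_rx = "PF18052",
    lrr = c("PF00560", "PF07725", "PF12799", "PF13855")
  )
}

#' Classification thresholds
#'
#' E-value gates and the clustering identity used during NLR identification:
#' seed-domain selection keeps NB-ARC Pfam hits at e-value <= 1e-60 and
#' TIR/RPW8 hits at <= 1e-40; a protein is called an NLR when a
#' domain-specific HMM hit reaches e-value <= 1e-4; redundant domain
#' sequences are collapsed at >= 98% identity before HMM construction.
#'
#' @param seed_evalue_nbarc,seed_evalue_tir_rpw8 Seed-domain e-value gates.
#' @param hmm_call_evalue NLR call gate for custom-HMM hits.
#' @param rep_identity Representative clustering identity in (0, 1].
#' @return A `classify_thresholds` list.
#' @export
classify_thresholds <- function(seed_evalue_nbarc = 1e-60,
                                seed_evalue_tir_rpw8 = 1e-40,
                                hmm_call_evalue = 1e-4,
                                rep_identity = 0.98) {
  stopifnot(seed_evalue_nbarc > 0, seed_evalue_nbarc <= 1,
            seed_evalue_tir_rpw8 > 0, seed_evalue_tir_rpw8 <= 1,
            hmm_call_evalue > 0, hmm_call_evalue <= 1,
            rep_identity > 0, rep_identity <= 1)
  structure(list(seed_evalue_nbarc = seed_evalue_nbarc,
                 seed_evalue_tir_rpw8 = seed_evalue_tir_rpw8,
                 hmm_call_evalue = hmm_call_evalue,
                 rep_identity = rep_identity),
            class = "classify_thresholds")
}

#' Select seed domain hits for HMM construction
#'
#' Keeps Pfam hits to the three diagnostic domains at seed-quality e-values:
#' NB-ARC at e <= 1e-60, TIR and RPW8 at e <= 1e-40 (both gates inclusive).
#' Hits to other accessions are ignored (counted in a message).
#'
#' @param hits Domain-hit data frame (see [read_domain_hits()]).
#' @param thresholds A [classify_thresholds()] object.
#' @return The selected hits with an added `family` column
#'   (`nbarc`/`tir`/`rpw8`).
#' @export
select_seed_domains <- function(hits, thresholds = classify_thresholds()) {
  acc <- nlr_pfam_accessions()
  pfam <- hits[hits$source == "pfam_hmm", , drop = FALSE]
  fam <- rep(NA_character_, nrow(pfam))
  fam[pfam$accession %in% acc$nbarc] <- "nbarc"
  fam[pfam$accession %in% acc$tir] <- "tir"
  fam[pfam$accession %in% acc$rpw8] <- "rpw8"
  n_other <- sum(is.na(fam))
  if (n_other > 0L) {
    message(n_other, " hit(s) to non-seed accessions ignored")
  }
  gate <- ifelse(fam == "nbarc", thresholds$seed_evalue_nbarc,
                 thresholds$seed_evalue_tir_rpw8)
  keep <- !is.na(fam) & !is.na(pfam$evalue) & pfam$evalue <= gate
  out <- pfam[keep, , drop = FALSE]
  out$family <- fam[keep]
  rownames(out) <- NULL
  out
}

#' Extract domain subsequences from proteins
#'
#' Cuts the `[aa_start, aa_end]` substring (1-based inclusive) of each seed
#' hit out of its protein. Hits whose coordinates exceed the protein length,
#' or whose protein is absent from the proteome, are skipped with a warning.
#'
#' @param seeds Seed-hit data frame (see [select_seed_domains()]).
#' @param proteins A named [Biostrings::AAStringSet] or named character
#'   vector of protein sequences.
#' @return A named character vector of domain sequences; names are
#'   `protein_id:accession:aa_start-aa_end`.
#' @export
extract_domain_seqs <- function(seeds, proteins) {
  if (methods::is(proteins, "XStringSet")) {
    proteins <- as.character(proteins)
  }
  lens <- nchar(proteins)[seeds$protein_id]
  ok <- !is.na(lens) & seeds$aa_start >= 1L & seeds$aa_end <= lens &
    seeds$aa_start <= seeds$aa_end
  if (any(!ok)) {
    warning(sum(!ok), " seed hit(s) skipped: coordinates outside protein ",
            "or unknown protein")
  }
  s <- seeds[ok, , drop = FALSE]
  out <- substr(proteins[s$protein_id], s$aa_start, s$aa_end)
  names(out) <- sprintf("%s:%s:%d-%d", s$protein_id, s$accession,
                        s$aa_start, s$aa_end)
  out
}

#' Global-alignment identity between two amino-acid sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and a linear
#' gap penalty of -1 per gapped column (scoring used only to pick the
#' alignment); identity is then the number of identical columns divided by
#' the total number of alignment columns, gap columns included.
#'
#' @param a,b Non-empty amino-acid strings.
#' @return Identity in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  chars <- unique(strsplit(paste0(a, b), "", fixed = TRUE)[[1L]])
  m <- matrix(0, length(chars), length(chars),
              dimnames = list(chars, chars))
  diag(m) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    substitutionMatrix = m, gapOpening = 0, gapExtension = 1,
    type = "global")
  Biostrings::nmatch(aln) /
    nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' Greedy centroid clustering of domain sequences
#'
#' Collapses near-identical domain sequences before HMM construction.
#' Sequences are processed in decreasing length order (ties broken
#' lexicographically by name); each joins the first existing centroid whose
#' global-alignment identity (see [pairwise_identity()]) reaches
#' `rep_identity`, otherwise it founds a new cluster. Cluster
#' representatives are the centroids, returned in founding order.
#'
#' @param seqs Named character vector (or `AAStringSet`) of sequences.
#' @param thresholds A [classify_thresholds()] object (uses `rep_identity`).
#' @return Named character vector of representatives, with a `clusters`
#'   attribute mapping every input name to its representative.
#' @export
cluster_representatives <- function(seqs, thresholds = classify_thresholds()) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  centroids <- integer(0)  # indices into seqs
  assign <- character(length(seqs))
  for (i in seq_along(seqs)) {
    joined <- FALSE
    for (ci in centroids) {
      if (pairwise_identity(seqs[[i]], seqs[[ci]]) >=
          thresholds$rep_identity) {
        assign[i] <- names(seqs)[ci]
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      centroids <- c(centroids, i)
      assign[i] <- names(seqs)[i]
    }
  }
  reps <- seqs[centroids]
  attr(reps, "clusters") <- stats::setNames(assign, names(seqs))
  reps
}

#' Identify NLR proteins from HMM and motif evidence
#'
#' A protein is called an NLR when it has at least one custom-HMM hit to
#' NB-ARC, TIR or RPW8 at e-value <= 1e-4, or when the NLR-motif caller
#' reports a CC motif for it. A COILS coiled-coil prediction alone is not an
#' identification criterion (it only feeds architecture assignment).
#'
#' @param domain_hits Domain-hit data frame ([read_domain_hits()]).
#' @param parser_cc Character vector of protein ids with parser CC motifs,
#'   or a motif table from [read_motif_table()].
#' @param thresholds A [classify_thresholds()] object.
#' @return Sorted character vector of NLR protein ids.
#' @export
identify_nlrs <- function(domain_hits, parser_cc = character(0),
                          thresholds = classify_thresholds()) {
  if (is.data.frame(parser_cc)) {
    parser_cc <- parser_cc$protein_id[parser_cc$has_cc]
  }
  acc <- nlr_pfam_accessions()
  diagnostic <- c(acc$nbarc, acc$tir, acc$rpw8)
  hmm <- domain_hits$source == "custom_hmm" &
    domain_hits$accession %in% diagnostic &
    !is.na(domain_hits$evalue) &
    domain_hits$evalue <= thresholds$hmm_call_evalue
  sort(unique(c(domain_hits$protein_id[hmm], parser_cc)))
}

#' Assign NLR architecture classes
#'
#' Classifies identified NLRs into the four canonical architecture classes
#' by first-matching rule: a TIR domain gives TNL; an RPW8 domain gives RNL;
#' an Rx N-terminal domain (PF18052), or a parser CC motif together with a
#' COILS coiled-coil, gives CNL; everything else is NL. Proteins carrying
#' both TIR and RPW8 are classified TNL and reported in the
#' `conflicts` attribute. An NLR is `complete` when it has a canonical
#' N-terminal domain (TIR, RPW8 or CC), an NB-ARC and an LRR.
#'
#' Domain presence is taken from Pfam or custom-HMM hits at e-value <= 1e-4.
#'
#' @param protein_ids NLR protein ids (from [identify_nlrs()]).
#' @param domain_hits Domain-hit data frame.
#' @param parser_cc,coils_cc Character vectors of protein ids with parser CC
#'   motifs / COILS coiled-coils (or motif tables).
#' @param genes Optional `gene_models` data frame whose `gene_id` matches
#'   protein ids; used with `scaffold_lens` to compute `nbarc_rel_pos`.
#' @param scaffold_lens Optional named numeric vector of scaffold lengths
#'   (bp) indexed by chromosome name.
#' @param genotype Genotype label for the output records.
#' @param thresholds A [classify_thresholds()] object.
#' @return An `nlr_records` data frame: `gene_id`, `genotype`, `nlr_class`,
#'   the `has_*` domain flags, `complete`, `nbarc_rel_pos`.
#' @export
classify_architectures <- function(protein_ids, domain_hits,
                                   parser_cc = character(0),
                                   coils_cc = character(0),
                                   genes = NULL, scaffold_lens = NULL,
                                   genotype = NA_character_,
                                   thresholds = classify_thresholds()) {
  if (is.data.frame(parser_cc)) parser_cc <- parser_cc$protein_id[parser_cc$has_cc]
  if (is.data.frame(coils_cc)) coils_cc <- coils_cc$protein_id[coils_cc$has_cc]
  acc <- nlr_pfam_accessions()
  sig <- domain_hits[domain_hits$source %in% c("pfam_hmm", "custom_hmm") &
                       !is.na(domain_hits$evalue) &
                       domain_hits$evalue <= thresholds$hmm_call_evalue, ,
                     drop = FALSE]
  has_acc <- function(ids, accs) {
    ids %in% unique(sig$protein_id[sig$accession %in% accs])
  }
  has_tir <- has_acc(protein_ids, acc$tir)
  has_rpw8 <- has_acc(protein_ids, acc$rpw8)
  has_nbarc <- has_acc(protein_ids, acc$nbarc)
  has_lrr <- has_acc(protein_ids, acc$lrr)
  has_rx <- has_acc(protein_ids, acc$cc_rx)
  p_cc <- protein_ids %in% parser_cc
  c_cc <- protein_ids %in% coils_cc
  has_cc <- has_rx | (p_cc & c_cc)
  nlr_class <- ifelse(has_tir, "TNL",
               ifelse(has_rpw8, "RNL",
               ifelse(has_cc, "CNL", "NL")))
  complete <- has_nbarc & has_lrr & (has_tir | has_rpw8 | has_cc)
  rel_pos <- rep(NA_real_, length(protein_ids))
  if (!is.null(genes) && !is.null(scaffold_lens)) {
    gi <- match(protein_ids, genes$gene_id)
    ok <- !is.na(gi)
    rel_pos[ok] <- nbarc_relative_position(
      genes$start[gi[ok]], genes$end[gi[ok]],
      scaffold_lens[genes$chrom[gi[ok]]])
    rel_pos[!has_nbarc] <- NA_real_
  }
  out <- data.frame(
    gene_id = protein_ids, genotype = genotype, nlr_class = nlr_class,
    has_nbarc = has_nbarc, has_lrr = has_lrr, has_tir = has_tir,
    has_rpw8 = has_rpw8, has_cc = has_cc,
    complete = complete, nbarc_rel_pos = rel_pos,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  conflicts <- protein_ids[has_tir & has_rpw8]
  if (length(conflicts) > 0L) {
    message(length(conflicts),
            " protein(s) with both TIR and RPW8 classified TNL")
  }
  attr(out, "conflicts") <- conflicts
  class(out) <- c("nlr_records", "data.frame")
  out
}

#' Relative scaffold position of a gene
#'
#' Distance of the gene's genomic midpoint to the nearer scaffold end,
#' normalised by scaffold length: `min(d5, scaffold_len - d5) / scaffold_len`
#' where `d5` is the midpoint. Ranges over \[0, 0.5\]; fragmented assemblies
#' that truncate genes push this value toward 0.
#'
#' @param start,end Gene coordinates (bp, 1-based inclusive); vectorised.
#' @param scaffold_len Scaffold length(s) in bp.
#' @return Numeric vector in \[0, 0.5\].
#' @export
nbarc_relative_position <- function(start, end, scaffold_len) {
  if (any(is.na(scaffold_len)) || any(scaffold_len < end)) {
    stop("scaffold_len must be known and >= gene end")
  }
  mid <- (start + end) / 2
  pmin(mid, scaffold_len - mid) / scaffold_len
}
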