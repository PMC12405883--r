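#' Read a 12-column BLAST-like tabular hit file
#'
#' Reads tab-separated alignment tables in the standard outfmt-6 column order
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`) and types them for the pipeline:
#'
#' * `kind = "similarity"`: all-vs-all protein hits. Self-hits
#'   (`qseqid == sseqid`) are dropped and the number dropped is reported via
#'   a message.
#' * `kind = "pseudoexon"`: tBLASTn-style hits of an NLR protein against a
#'   genome. Subject coordinates are genomic; when `sstart > send` the hit is
#'   on the reverse strand, coordinates are swapped so `g_start <= g_end` and
#'   the reading frame is negative.
#' * `kind = "repeat"`: hits of pseudoexon intervals against a repeat
#'   library; reduced to (`hit_id`, `evalue`).
#'
#' @param path Path to the TSV file.
#' @param kind One of `"similarity"`, `"pseudoexon"`, `"repeat"`.
#' @param genotype Genotype label attached to pseudoexon hits.
#' @return A typed data frame (see Details).
#' @export
read_tabular_hits <- function(path, kind = c("similarity", "pseudoexon", "repeat"),
                              genotype = NA_character_) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(switch(kind,
      similarity = empty_similarity_hits(),
      pseudoexon = empty_pseudoexon_hits(),
      "repeat" = data.frame(hit_id = character(0), evalue = numeric(0),
                            stringsAsFactors = FALSE)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad) > 0L) {
    stop("expected 12 tab-separated columns, got ", lengths(fields)[bad[1L]],
         " at data line ", bad[1L], " of ", path)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  tab <- data.frame(
    qseqid = m[, 1L], sseqid = m[, 2L],
    pident = as.numeric(m[, 3L]), length = as.integer(m[, 4L]),
    mismatch = as.integer(m[, 5L]), gapopen = as.integer(m[, 6L]),
    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
    sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE)
  switch(kind,
    similarity = {
      self <- tab$qseqid == tab$sseqid
      if (any(self)) {
        message("dropped ", sum(self), " self-hit(s)")
        tab <- tab[!self, , drop = FALSE]
      }
      out <- data.frame(
        query_id = tab$qseqid, subject_id = tab$sseqid,
        pct_identity = tab$pident, align_len = tab$length,
        evalue = tab$evalue,
        q_start = tab$qstart, q_end = tab$qend,
        s_start = tab$sstart, s_end = tab$send,
        stringsAsFactors = FALSE)
      rownames(out) <- NULL
      out
    },
    pseudoexon = {
      rev <- tab$sstart > tab$send
      g_start <- ifelse(rev, tab$send, tab$sstart)
      g_end <- ifelse(rev, tab$sstart, tab$send)
      frame <- as.integer(((g_start - 1L) %% 3L) + 1L) * ifelse(rev, -1L, 1L)
      out <- data.frame(
        hit_id = sprintf("%s:%s:%d-%d", tab$qseqid, tab$sseqid, g_start, g_end),
        parent_protein = tab$qseqid, genotype = genotype,
        chrom = tab$sseqid,
        g_start = as.integer(g_start), g_end = as.integer(g_end),
        frame = frame,
        pct_identity = tab$pident,
        aa_len = as.integer(tab$qend - tab$qstart + 1L),
        evalue = tab$evalue,
        stringsAsFactors = FALSE)
      rownames(out) <- NULL
      out
    },
    "repeat" = data.frame(hit_id = tab$qseqid, evalue = tab$evalue,
                          stringsAsFactors = FALSE))
}

empty_similarity_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), align_len = integer(0),
             evalue = numeric(0), q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             stringsAsFactors = FALSE)
}

empty_pseudoexon_hits <- function() {
  data.frame(hit_id = character(0), parent_protein = character(0),
             genotype = character(0), chrom = character(0),
             g_start = integer(0), g_end = integer(0), frame = integer(0),
             pct_identity = numeric(0), aa_len = integer(0),
             evalue = numeric(0), stringsAsFactors = FALSE)
}

#' Read Interproscan-style protein domain hits
#'
#' Expects the Interproscan TSV layout: protein accession, MD5, sequence
#' length, analysis, signature accession, signature description, start, stop,
#' e-value (further columns ignored). Rows from the `Coils` analysis carry no
#' e-value and are returned with `evalue = NA`.
#'
#' @param path Path to the TSV file.
#' @return A data frame of domain hits with columns `protein_id`, `source`
#'   (`pfam_hmm`, `custom_hmm` or `coils`), `accession`, `evalue`,
#'   `aa_start`, `aa_end`.
#' @export
read_domain_hits <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(empty_domain_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad) > 0L) {
    stop("expected >= 9 tab-separated columns at data line ", bad[1L],
         " of ", path)
  }
  get <- function(k) vapply(fields, `[[`, "", k)
  analysis <- get(4L)
  source <- ifelse(tolower(analysis) == "pfam", "pfam_hmm",
            ifelse(tolower(analysis) == "coils", "coils", "custom_hmm"))
  out <- data.frame(
    protein_id = get(1L),
    source = source,
    accession = get(5L),
    evalue = suppressWarnings(as.numeric(get(9L))),
    aa_start = as.integer(get(7L)),
    aa_end = as.integer(get(8L)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_domain_hits <- function() {
  data.frame(protein_id = character(0), source = character(0),
             accession = character(0), evalue = numeric(0),
             aa_start = integer(0), aa_end = integer(0),
             stringsAsFactors = FALSE)
}

#' Read an NLR-motif caller table
#'
#' Two-or-more-column TSV with a header, first column the protein id, and a
#' column named `has_cc` (`TRUE`/`FALSE` or `1`/`0`) flagging a detected
#' coiled-coil motif. Used both for NLR-parser-style CC motif calls and for
#' COILS coiled-coil predictions.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `protein_id`, `has_cc` (logical).
#' @export
read_motif_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    return(data.frame(protein_id = character(0), has_cc = logical(0),
                      stringsAsFactors = FALSE))
  }
  if (!"has_cc" %in% names(tab)) {
    stop("motif table must contain a 'has_cc' column: ", path)
  }
  data.frame(protein_id = as.character(tab[[1L]]),
             has_cc = as.logical(tab$has_cc),
             stringsAsFactors = FALSE)
}
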