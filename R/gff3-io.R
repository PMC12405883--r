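#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `mRNA` and `exon` features into a flat gene-model table.
#' Each gene is represented by a single transcript: the mRNA with the largest
#' summed exon length (ties broken by mRNA ID). MAKER-style annotation edit
#' distance is picked up from the `_AED` attribute when present.
#'
#' All coordinates are 1-based and inclusive, as in GFF3; that convention is
#' kept throughout the package.
#'
#' @param path Path to a GFF3 file.
#' @param genotype Genotype label attached to every gene
#'   (default: file name without extension).
#' @return A `gene_models` data frame with columns `gene_id`, `genotype`,
#'   `chrom`, `start`, `end`, `strand`, `aed` and a list column `exons`
#'   (two-column `start`/`end` matrices, sorted, possibly zero-row).
#' @export
read_gff3 <- function(path, genotype = NULL) {
  if (is.null(genotype)) {
    genotype <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  body <- grep("^[^#]", lines)
  if (length(body) == 0L) {
    return(empty_gene_models())
  }
  # record-level coordinate validation with line numbers, before parsing
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 9L)) {
    stop("malformed GFF3: fewer than 9 columns at line ",
         body[which(nfield < 9L)[1L]])
  }
  starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  bad <- which(is.na(starts) | is.na(ends) | ends < starts)
  if (length(bad) > 0L) {
    stop("malformed GFF3 coordinates (end < start or non-numeric) at line ",
         body[bad[1L]])
  }
  gff <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent", "_AED")))
  genes <- gff[gff$type == "gene", , drop = FALSE]
  mrnas <- gff[gff$type == "mRNA", , drop = FALSE]
  exons <- gff[gff$type == "exon", , drop = FALSE]
  if (nrow(genes) == 0L) {
    return(empty_gene_models())
  }
  first_parent <- function(p) {
    vapply(p, function(x) if (length(x)) x[[1L]] else NA_character_, "")
  }
  mrna_gene <- first_parent(mrnas$Parent)
  exon_mrna <- first_parent(exons$Parent)
  exon_len <- exons$end - exons$start + 1L
  mrna_exlen <- vapply(mrnas$ID, function(id) {
    sum(exon_len[exon_mrna == id])
  }, numeric(1))

  exon_list <- vector("list", nrow(genes))
  aed <- rep(NA_real_, nrow(genes))
  no_exon <- character(0)
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    mi <- which(mrna_gene == gid)
    if (length(mi) > 0L) {
      # representative mRNA: longest summed exon length, then ID
      mi <- mi[order(-mrna_exlen[mi], mrnas$ID[mi])][1L]
      aed_i <- suppressWarnings(as.numeric(mrnas$X_AED[mi]))
      if (length(aed_i) == 1L && !is.na(aed_i)) aed[i] <- aed_i
      ei <- which(exon_mrna == mrnas$ID[mi])
    } else {
      ei <- which(exon_mrna == gid)  # exons parented directly on the gene
    }
    if (length(ei) == 0L) {
      no_exon <- c(no_exon, gid)
      exon_list[[i]] <- exon_matrix(integer(0), integer(0))
    } else {
      o <- order(exons$start[ei])
      exon_list[[i]] <- exon_matrix(exons$start[ei][o], exons$end[ei][o])
    }
    if (is.na(aed[i]) && !is.null(genes$X_AED)) {
      aed_g <- suppressWarnings(as.numeric(genes$X_AED[i]))
      if (length(aed_g) == 1L && !is.na(aed_g)) aed[i] <- aed_g
    }
  }
  if (length(no_exon) > 0L) {
    warning("gene(s) without exon features kept with empty exon list: ",
            paste(utils::head(no_exon, 5L), collapse = ", "),
            if (length(no_exon) > 5L) ", ..." else "")
  }
  out <- data.frame(
    gene_id = genes$ID,
    genotype = genotype,
    chrom = as.character(genes$seqid),
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = as.character(genes$strand),
    aed = aed,
    stringsAsFactors = FALSE
  )
  out$exons <- exon_list
  if (anyDuplicated(out$gene_id)) {
    stop("duplicate gene_id within genotype: ",
         out$gene_id[duplicated(out$gene_id)][1L])
  }
  class(out) <- c("gene_models", "data.frame")
  out
}

exon_matrix <- function(start, end) {
  cbind(start = as.integer(start), end = as.integer(end))
}

empty_gene_models <- function() {
  out <- data.frame(
    gene_id = character(0), genotype = character(0), chrom = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    aed = numeric(0), stringsAsFactors = FALSE)
  out$exons <- list()
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Write gene models to a GFF3 file
#'
#' Emits one `gene`, one `mRNA` and the exon features per gene, with
#' `ID`/`Parent` attributes and `_AED` on the mRNA when available.
#' `read_gff3(write_gff3(x))` reproduces `x` field by field.
#'
#' @param genes A `gene_models` data frame (see [read_gff3()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    mid <- paste0(g$gene_id, ".t1")
    aed_attr <- if (!is.na(g$aed)) sprintf(";_AED=%s", format(g$aed)) else ""
    writeLines(c(
      sprintf("%s\tnlrcnv\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, g$start, g$end, g$strand, g$gene_id),
      sprintf("%s\tnlrcnv\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s%s",
              g$chrom, g$start, g$end, g$strand, mid, g$gene_id, aed_attr)),
      con)
    ex <- genes$exons[[i]]
    if (nrow(ex) > 0L) {
      writeLines(sprintf(
        "%s\tnlrcnv\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        g$chrom, ex[, "start"], ex[, "end"], g$strand, mid,
        seq_len(nrow(ex)), mid), con)
    }
  }
  invisible(path)
}

#' Intron lengths of annotated gene models
#'
#' Introns are the gaps between consecutive exons of a gene's representative
#' transcript: `next_start - prev_end - 1` bp. Genes with fewer than two
#' exons contribute nothing.
#'
#' @param genes A `gene_models` data frame.
#' @return Integer vector of intron lengths pooled over all genes.
#' @export
intron_lengths <- function(genes) {
  out <- lapply(genes$exons, function(ex) {
    if (nrow(ex) < 2L) return(integer(0))
    ex[-1L, "start"] - ex[-nrow(ex), "end"] - 1L
  })
  as.integer(unlist(out))
}
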