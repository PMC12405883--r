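#' Simulation configuration for synthetic genotypes
#'
#' Defines the study conditions the generator emulates: multiple genotypes
#' of one species whose NLR complements diverge through local gene birth.
#' Genotypes follow a `high` or `low` duplication regime; high-regime
#' genotypes put most duplication probability on tandem and proximal events
#' and run more events per founder, producing the several-fold NLR
#' copy-number gap and the clustered chromosomal distribution the pipeline
#' is designed to measure. NLR founders are concentrated on four designated
#' chromosomes, mirroring the uneven chromosomal NLR density of real plant
#' genomes.
#'
#' @param seed Master seed; per-genotype streams are derived from it.
#' @param n_genotypes Number of genotypes.
#' @param regimes Character vector (`"high"`/`"low"`) per genotype.
#' @param n_chroms Number of ordered chromosomes (plus an unplaced `Chr0`).
#' @param chrom_len Chromosome length in bp (desk scale default 5 Mbp).
#' @param n_background_genes Non-NLR genes per genotype.
#' @param n_nlr_founders NLR founder loci per genotype.
#' @param nlr_chroms Chromosomes carrying most founders.
#' @param nlr_chrom_weight Probability mass of founders on `nlr_chroms`.
#' @param events_per_founder Named vector: duplication events per founder
#'   in each regime.
#' @param p_event Named list of per-regime event-type probabilities
#'   (`tandem`, `proximal`, `dispersed`, `segmental`).
#' @param p_pseudogenize Probability a non-segmental duplicate decays into
#'   a pseudogene instead of a gene.
#' @param identity_decay Percent identity lost per duplication event.
#' @param mean_intron_len,intron_sdlog Log-normal intron length model (bp).
#' @param class_probs Founder architecture class probabilities.
#' @param p_decoy Fraction of background genes given near-threshold decoy
#'   domain hits.
#' @param protein_len NLR protein length (aa).
#' @param pseudo_category Probabilities over planted pseudogene categories:
#'   `ok` (recoverable) and the single-criterion violations
#'   `bad_identity`, `bad_len`, `repeat`, `bad_gap`, `genic`, `no_domain`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_genotypes = 11,
                       regimes = c(rep("high", 7), rep("low", 4)),
                       n_chroms = 10,
                       chrom_len = 5e6,
                       n_background_genes = 300,
                       n_nlr_founders = 25,
                       nlr_chroms = c("Chr5", "Chr6", "Chr7", "Chr10"),
                       nlr_chrom_weight = 0.75,
                       events_per_founder = c(high = 5, low = 1),
                       p_event = list(
                         high = c(tandem = 0.5, proximal = 0.3,
                                  dispersed = 0.1, segmental = 0.1),
                         low = c(tandem = 0.05, proximal = 0.05,
                                 dispersed = 0.8, segmental = 0.1)),
                       p_pseudogenize = 0.1,
                       identity_decay = 1.5,
                       mean_intron_len = 300,
                       intron_sdlog = 0.5,
                       class_probs = c(NL = 0.5, CNL = 0.35,
                                       TNL = 0.12, RNL = 0.03),
                       p_decoy = 0.05,
                       protein_len = 300,
                       pseudo_category = c(ok = 0.8, bad_identity = 0.04,
                                           bad_len = 0.04, "repeat" = 0.04,
                                           bad_gap = 0.04, genic = 0.02,
                                           no_domain = 0.02)) {
  stopifnot(length(regimes) == n_genotypes,
            all(regimes %in% c("high", "low")),
            all(unlist(p_event) >= 0), p_pseudogenize >= 0,
            p_pseudogenize <= 1, identity_decay >= 0)
  structure(as.list(environment()), class = "sim_config")
}

aa_letters <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

random_protein <- function(len) {
  paste(sample(aa_letters(), len, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, pct) {
  n <- nchar(seq)
  k <- max(1L, round(pct / 100 * n))
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  chars[pos] <- vapply(chars[pos], function(ch) {
    sample(setdiff(aa_letters(), ch), 1L)
  }, "")
  paste(chars, collapse = "")
}

log_uniform_evalue <- function(n, lo_exp, hi_exp) {
  10^-stats::runif(n, lo_exp, hi_exp)
}

#' Simulate one synthetic genotype
#'
#' Places background genes and NLR founders, applies the regime's
#' duplication events (tandem: copy inserted adjacent to its source;
#' proximal: 2-20 gene ranks away; dispersed: random position on another
#' chromosome; segmental: a run of 5 consecutive genes copied in order onto
#' another chromosome), decays sequence identity per duplication event, and
#' with probability `p_pseudogenize` emits a duplicate as degraded
#' pseudoexon fragments instead of an annotated gene. Returns all evidence
#' tables in the exact shapes the readers produce, plus a planted truth
#' table for every stage. Deterministic for a fixed seed.
#'
#' @param cfg A [sim_config()] object.
#' @param index Genotype index in `1..n_genotypes`.
#' @param seed Stream seed for this genotype (derived from `cfg$seed` by
#'   [simulate_dataset()]).
#' @return A list: `genotype`, `regime`, `genes` (`gene_models`),
#'   `proteome` (named character), `domain_hits`, `parser`, `coils`,
#'   `similarity`, `pseudoexons`, `repeats`, `translated_domains`,
#'   `scaffold_lens`, `truth` (list `genes`, `pseudogenes`).
#' @export
simulate_genotype <- function(cfg, index, seed = cfg$seed + index) {
  set.seed(seed %% .Machine$integer.max)
  regime <- cfg$regimes[index]
  genotype <- sprintf("G%02d_%s", index, regime)
  chroms <- c(paste0("Chr", seq_len(cfg$n_chroms)), "Chr0")

  # --- gene registry and per-chromosome gene order -------------------------
  registry <- new.env(parent = emptyenv())
  order_by_chrom <- stats::setNames(
    replicate(length(chroms), character(0), simplify = FALSE), chroms)
  add_gene <- function(uid, info) assign(uid, info, envir = registry)
  insert_at <- function(chrom, uid, pos) {
    v <- order_by_chrom[[chrom]]
    order_by_chrom[[chrom]] <<- append(v, uid, after = pos)
  }

  # background genes: bulk on the ordered chromosomes, a sliver on Chr0
  n_bg <- cfg$n_background_genes
  bg_chroms <- sample(c(paste0("Chr", seq_len(cfg$n_chroms)), "Chr0"),
                      n_bg, replace = TRUE,
                      prob = c(rep(0.97 / cfg$n_chroms, cfg$n_chroms), 0.03))
  for (i in seq_len(n_bg)) {
    uid <- sprintf("%s.bg%04d", genotype, i)
    add_gene(uid, list(type = "bg", family = NA, class = NA,
                       generation = 0L, parent = NA))
    ch <- bg_chroms[i]
    insert_at(ch, uid, sample.int(length(order_by_chrom[[ch]]) + 1L, 1L) - 1L)
  }

  # NLR founders, biased to the designated chromosomes
  other <- setdiff(paste0("Chr", seq_len(cfg$n_chroms)), cfg$nlr_chroms)
  chrom_prob <- stats::setNames(
    c(rep(cfg$nlr_chrom_weight / length(cfg$nlr_chroms),
          length(cfg$nlr_chroms)),
      rep((1 - cfg$nlr_chrom_weight) / length(other), length(other))),
    c(cfg$nlr_chroms, other))
  classes <- sample(names(cfg$class_probs), cfg$n_nlr_founders,
                    replace = TRUE, prob = cfg$class_probs)
  seqs <- list()
  copy_counter <- new.env(parent = emptyenv())
  for (f in seq_len(cfg$n_nlr_founders)) {
    uid <- sprintf("%s.nlr%03d.c0", genotype, f)
    fam <- sprintf("fam%03d", f)
    add_gene(uid, list(type = "nlr", family = fam, class = classes[f],
                       generation = 0L, parent = NA))
    seqs[[uid]] <- random_protein(cfg$protein_len)
    ch <- sample(names(chrom_prob), 1L, prob = chrom_prob)
    insert_at(ch, uid, sample.int(length(order_by_chrom[[ch]]) + 1L, 1L) - 1L)
    assign(fam, 1L, envir = copy_counter)
  }

  chrom_of <- function(uid) {
    for (ch in chroms) if (uid %in% order_by_chrom[[ch]]) return(ch)
    NA_character_
  }

  # --- duplication events --------------------------------------------------
  n_events <- cfg$events_per_founder[[regime]]
  p_ev <- cfg$p_event[[regime]]
  pseudo_plans <- list()
  sim_hits <- list()
  for (f in seq_len(cfg$n_nlr_founders)) {
    fam <- sprintf("fam%03d", f)
    members <- function() {
      all <- ls(registry)
      all[vapply(all, function(u) identical(get(u, registry)$family, fam),
                 logical(1))]
    }
    for (ev in seq_len(n_events)) {
      fam_members <- members()
      src <- sample(fam_members, 1L)
      src_info <- get(src, registry)
      type <- sample(names(p_ev), 1L, prob = p_ev)
      src_ch <- chrom_of(src)
      k <- get(fam, copy_counter)
      assign(fam, k + 1L, envir = copy_counter)
      new_uid <- sprintf("%s.nlr%03d.c%d", genotype, f, k)
      gen <- src_info$generation + 1L
      if (type == "segmental") {
        seg_ok <- length(order_by_chrom[[src_ch]]) >= 5L
        if (!seg_ok) type <- "dispersed"
      }
      pseudo <- type != "segmental" &&
        stats::runif(1L) < cfg$p_pseudogenize
      if (pseudo) {
        pseudo_plans[[length(pseudo_plans) + 1L]] <- list(
          parent = src, chrom = src_ch, family = fam,
          class = src_info$class)
        next
      }
      if (type == "segmental") {
        v <- order_by_chrom[[src_ch]]
        si <- match(src, v)
        lo <- max(1L, min(si, length(v) - 4L))
        seg <- v[lo:(lo + 4L)]
        tgt <- sample(setdiff(paste0("Chr", seq_len(cfg$n_chroms)), src_ch), 1L)
        at <- sample.int(length(order_by_chrom[[tgt]]) + 1L, 1L) - 1L
        for (j in seq_along(seg)) {
          su <- seg[j]
          info <- get(su, registry)
          if (info$type == "nlr") {
            sf <- sub("^fam", "", info$family)
            kk <- get(info$family, copy_counter)
            assign(info$family, kk + 1L, envir = copy_counter)
            cu <- sprintf("%s.nlr%s.c%d", genotype, sf, kk)
            add_gene(cu, list(type = "nlr", family = info$family,
                              class = info$class,
                              generation = info$generation + 1L,
                              parent = su))
            seqs[[cu]] <- mutate_protein(seqs[[su]], cfg$identity_decay)
          } else {
            cu <- sprintf("%s.sg%03d_%d", su, f, k)
            add_gene(cu, list(type = "bg", family = NA, class = NA,
                              generation = 0L, parent = su))
            sim_hits[[length(sim_hits) + 1L]] <-
              c(cu, su, 99 - stats::runif(1L))
          }
          insert_at(tgt, cu, at + j - 1L)
        }
        next
      }
      add_gene(new_uid, list(type = "nlr", family = fam,
                             class = src_info$class, generation = gen,
                             parent = src))
      seqs[[new_uid]] <- mutate_protein(seqs[[src]], cfg$identity_decay)
      v <- order_by_chrom[[src_ch]]
      si <- match(src, v)
      if (type == "tandem") {
        insert_at(src_ch, new_uid, si)
      } else if (type == "proximal") {
        d <- sample(2:20, 1L)
        insert_at(src_ch, new_uid, min(si + d - 1L, length(v)))
      } else {  # dispersed
        tgt <- sample(setdiff(paste0("Chr", seq_len(cfg$n_chroms)), src_ch), 1L)
        insert_at(tgt, new_uid,
                  sample.int(length(order_by_chrom[[tgt]]) + 1L, 1L) - 1L)
      }
    }
  }

  # --- coordinates and exon structure --------------------------------------
  gene_rows <- list()
  for (ch in chroms) {
    v <- order_by_chrom[[ch]]
    n <- length(v)
    if (n == 0L) next
    exsets <- vector("list", n)
    spans <- numeric(n)
    for (i in seq_len(n)) {
      ne <- sample(1:4, 1L)
      elens <- sample(200:1500, ne, replace = TRUE)
      ilens <- if (ne > 1L) {
        pmax(20L, round(stats::rlnorm(ne - 1L, log(cfg$mean_intron_len),
                                      cfg$intron_sdlog)))
      } else integer(0)
      st <- cumsum(c(1L, utils::head(elens, -1L) + ilens))
      exsets[[i]] <- exon_matrix(st, st + elens - 1L)
      spans[i] <- st[ne] + elens[ne] - 1L
    }
    free <- cfg$chrom_len - sum(spans)
    if (free <= n) stop("chromosome ", ch, " is full; increase chrom_len")
    g <- stats::rexp(n + 1L)
    g <- floor(g / sum(g) * free)
    pos <- 1 + cumsum(g[seq_len(n)]) +
      c(0, cumsum(spans)[seq_len(n - 1L)])
    for (i in seq_len(n)) {
      off <- as.integer(pos[i]) - 1L
      ex <- exsets[[i]]
      ex[, "start"] <- ex[, "start"] + off
      ex[, "end"] <- ex[, "end"] + off
      gene_rows[[length(gene_rows) + 1L]] <- list(
        gene_id = v[i], chrom = ch, start = as.integer(pos[i]),
        end = as.integer(pos[i] + spans[i] - 1L), exons = ex)
    }
  }
  genes <- data.frame(
    gene_id = vapply(gene_rows, `[[`, "", "gene_id"),
    genotype = genotype,
    chrom = vapply(gene_rows, `[[`, "", "chrom"),
    start = vapply(gene_rows, `[[`, integer(1), "start"),
    end = vapply(gene_rows, `[[`, integer(1), "end"),
    strand = sample(c("+", "-"), length(gene_rows), replace = TRUE),
    aed = round(stats::runif(length(gene_rows), 0.05, 0.35), 2),
    stringsAsFactors = FALSE)
  genes$exons <- lapply(gene_rows, `[[`, "exons")
  class(genes) <- c("gene_models", "data.frame")

  truth_genes <- do.call(rbind, lapply(genes$gene_id, function(u) {
    info <- get(u, registry)
    data.frame(gene_id = u, genotype = genotype,
               is_nlr = info$type == "nlr",
               nlr_class = ifelse(is.na(info$class), NA_character_,
                                  info$class),
               family = ifelse(is.na(info$family), NA_character_,
                               info$family),
               generation = info$generation,
               parent = ifelse(is.na(info$parent), NA_character_,
                               info$parent),
               stringsAsFactors = FALSE)
  }))

  nlr_ids <- truth_genes$gene_id[truth_genes$is_nlr]
  ev <- emit_domain_evidence(truth_genes, genotype, cfg)
  sim <- emit_similarity_hits(truth_genes, sim_hits, cfg)
  pseudo <- emit_pseudoexon_evidence(pseudo_plans, genes, genotype, cfg)

  proteome <- unlist(seqs[nlr_ids])
  list(genotype = genotype, regime = regime, genes = genes,
       proteome = proteome,
       domain_hits = ev$domain_hits, parser = ev$parser, coils = ev$coils,
       similarity = sim,
       pseudoexons = pseudo$pseudoexons, repeats = pseudo$repeats,
       translated_domains = pseudo$translated_domains,
       scaffold_lens = stats::setNames(rep(cfg$chrom_len, length(chroms)),
                                       chroms),
       truth = list(genes = truth_genes, pseudogenes = pseudo$truth))
}

# Domain, motif and coiled-coil evidence from planted truth.
emit_domain_evidence <- function(truth_genes, genotype, cfg) {
  nlr <- truth_genes[truth_genes$is_nlr, , drop = FALSE]
  rows <- list()
  add <- function(pid, source, acc, evalue, s, e) {
    rows[[length(rows) + 1L]] <<- data.frame(
      protein_id = pid, source = source, accession = acc, evalue = evalue,
      aa_start = s, aa_end = e, stringsAsFactors = FALSE)
  }
  parser_cc <- character(0)
  coils_cc <- character(0)
  for (i in seq_len(nrow(nlr))) {
    pid <- nlr$gene_id[i]
    cls <- nlr$nlr_class[i]
    # Pfam NB-ARC seed evidence spanning the seed gate
    add(pid, "pfam_hmm", "PF00931", log_uniform_evalue(1L, 50, 120),
        100L, 200L)
    # custom-HMM calls at NLR-call quality
    add(pid, "custom_hmm", "PF00931", log_uniform_evalue(1L, 6, 30),
        100L, 200L)
    if (cls == "TNL") {
      add(pid, "pfam_hmm", "PF01582", log_uniform_evalue(1L, 30, 80),
          10L, 80L)
      add(pid, "custom_hmm", "PF01582", log_uniform_evalue(1L, 6, 30),
          10L, 80L)
    }
    if (cls == "RNL") {
      add(pid, "pfam_hmm", "PF05659", log_uniform_evalue(1L, 30, 80),
          10L, 80L)
      add(pid, "custom_hmm", "PF05659", log_uniform_evalue(1L, 6, 30),
          10L, 80L)
    }
    if (cls %in% c("NL", "CNL", "TNL") || stats::runif(1L) < 0.8) {
      add(pid, "pfam_hmm", "PF00560", log_uniform_evalue(1L, 8, 30),
          210L, 290L)
    }
    if (cls == "CNL") {
      if (i %% 2L == 0L) {
        add(pid, "pfam_hmm", "PF18052", log_uniform_evalue(1L, 10, 40),
            10L, 80L)
      } else {
        parser_cc <- c(parser_cc, pid)
        coils_cc <- c(coils_cc, pid)
      }
    }
  }
  # decoys: background proteins with hits just above the call gate
  bg <- truth_genes$gene_id[!truth_genes$is_nlr]
  n_decoy <- round(cfg$p_decoy * length(bg))
  if (n_decoy > 0L) {
    for (pid in sample(bg, n_decoy)) {
      add(pid, "custom_hmm", "PF00931", log_uniform_evalue(1L, 1, 3.9),
          100L, 200L)
    }
  }
  domain_hits <- if (length(rows)) do.call(rbind, rows) else
    empty_domain_hits()
  all_ids <- truth_genes$gene_id
  list(domain_hits = domain_hits,
       parser = data.frame(protein_id = all_ids,
                           has_cc = all_ids %in% parser_cc,
                           stringsAsFactors = FALSE),
       coils = data.frame(protein_id = all_ids,
                          has_cc = all_ids %in% coils_cc,
                          stringsAsFactors = FALSE))
}

# All-vs-all similarity hits: within-family NLR pairs with identity decayed
# by duplication distance, plus segmental background-copy hits.
emit_similarity_hits <- function(truth_genes, extra_hits, cfg) {
  rows <- list()
  nlr <- truth_genes[truth_genes$is_nlr, , drop = FALSE]
  for (fam in unique(nlr$family)) {
    ids <- nlr$gene_id[nlr$family == fam]
    gen <- nlr$generation[nlr$family == fam]
    if (length(ids) < 2L) next
    for (i in seq_len(length(ids) - 1L)) {
      for (j in (i + 1L):length(ids)) {
        pid <- max(30, 100 - cfg$identity_decay * (gen[i] + gen[j]))
        rows[[length(rows) + 1L]] <- c(ids[i], ids[j], pid)
      }
    }
  }
  rows <- c(rows, extra_hits)
  if (length(rows) == 0L) return(empty_similarity_hits())
  m <- do.call(rbind, rows)
  data.frame(query_id = m[, 1L], subject_id = m[, 2L],
             pct_identity = round(as.numeric(m[, 3L]), 1),
             align_len = cfg$protein_len,
             evalue = 1e-80,
             q_start = 1L, q_end = cfg$protein_len,
             s_start = 1L, s_end = cfg$protein_len,
             stringsAsFactors = FALSE)
}

# Pseudoexon, repeat and translated-domain evidence for decayed copies.
emit_pseudoexon_evidence <- function(pseudo_plans, genes, genotype, cfg) {
  empty <- list(pseudoexons = empty_pseudoexon_hits(),
                repeats = data.frame(hit_id = character(0),
                                     evalue = numeric(0),
                                     stringsAsFactors = FALSE),
                translated_domains = data.frame(contig_id = character(0),
                                                accession = character(0),
                                                stringsAsFactors = FALSE),
                truth = data.frame(pseudo_id = character(0),
                                   parent = character(0),
                                   chrom = character(0),
                                   category = character(0),
                                   expected = character(0),
                                   n_frags = integer(0),
                                   stringsAsFactors = FALSE))
  if (length(pseudo_plans) == 0L) return(empty)
  q99 <- tryCatch(intron_q99(genes), error = function(e) cfg$mean_intron_len * 3)
  # centre each planted pseudogene in its own intergenic gap so that planted
  # fragment chains cannot merge across pseudogenes
  gaps <- list()
  for (ch in unique(genes$chrom)) {
    gg <- genes[genes$chrom == ch, , drop = FALSE]
    gg <- gg[order(gg$start), , drop = FALSE]
    if (nrow(gg) < 2L) next
    gs <- gg$end[-nrow(gg)] + 1L
    ge <- gg$start[-1L] - 1L
    ok <- ge - gs + 1L > 20000L
    for (k in which(ok)) {
      gaps[[length(gaps) + 1L]] <- list(chrom = ch, start = gs[k],
                                        end = ge[k])
    }
  }
  if (length(gaps) < length(pseudo_plans)) {
    warning("not enough wide intergenic gaps; dropping ",
            length(pseudo_plans) - length(gaps), " planted pseudogene(s)")
    pseudo_plans <- pseudo_plans[seq_len(length(gaps))]
    if (length(pseudo_plans) == 0L) return(empty)
  }
  gap_pick <- sample.int(length(gaps), length(pseudo_plans))
  pe_rows <- list(); rep_rows <- list(); td_rows <- list(); tr_rows <- list()
  cats <- sample(names(cfg$pseudo_category), length(pseudo_plans),
                 replace = TRUE, prob = cfg$pseudo_category)
  for (k in seq_along(pseudo_plans)) {
    plan <- pseudo_plans[[k]]
    gap <- gaps[[gap_pick[k]]]
    cat <- cats[k]
    n_frag <- sample(1:4, 1L)
    if (cat == "bad_gap" && n_frag < 2L) n_frag <- 2L
    aa_len <- sample(35:120, n_frag, replace = TRUE)
    ident <- round(stats::runif(n_frag, 45, 90), 1)
    if (cat == "bad_len") aa_len <- sample(5:30, n_frag, replace = TRUE)
    if (cat == "bad_identity") ident <- round(stats::runif(n_frag, 10, 40), 1)
    frag_len <- aa_len * 3L
    frag_gap <- if (n_frag > 1L) {
      if (cat == "bad_gap") {
        rep(as.integer(ceiling(q99 * 1.5)) + 10L, n_frag - 1L)
      } else {
        sample.int(max(1L, floor(0.8 * q99)), n_frag - 1L, replace = TRUE)
      }
    } else integer(0)
    total <- sum(frag_len) + sum(frag_gap)
    g0 <- gap$start + (gap$end - gap$start + 1L - total) %/% 2L
    starts <- g0 + cumsum(c(0L, utils::head(frag_len, -1L) + frag_gap))
    ends <- starts + frag_len - 1L
    if (cat == "genic") {
      # first fragment dropped into an annotated gene on the same chromosome
      host <- genes[genes$chrom == gap$chrom, , drop = FALSE][1L, ]
      starts[1L] <- host$start + 5L
      ends[1L] <- starts[1L] + frag_len[1L] - 1L
    }
    hid <- sprintf("%s:%s:%d-%d", plan$parent, gap$chrom, starts, ends)
    pe_rows[[k]] <- data.frame(
      hit_id = hid, parent_protein = plan$parent, genotype = genotype,
      chrom = gap$chrom, g_start = as.integer(starts),
      g_end = as.integer(ends),
      frame = as.integer((((starts - 1L) %% 3L) + 1L) *
                           sample(c(-1L, 1L), n_frag, replace = TRUE)),
      pct_identity = ident, aa_len = aa_len,
      evalue = log_uniform_evalue(n_frag, 21, 40),
      stringsAsFactors = FALSE)
    if (cat == "repeat") {
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        hit_id = hid, evalue = log_uniform_evalue(n_frag, 6, 12),
        stringsAsFactors = FALSE)
    }
    # expected contigs under the linking rule, for the translated-domain table
    chain <- cumsum(c(1L, as.integer(frag_gap > q99)))
    dom_acc <- if (cat == "no_domain") "PF00069" else
      switch(plan$class, TNL = "PF01582", RNL = "PF05659", "PF00931")
    contig_ids <- character(0)
    for (cc in unique(chain)) {
      cid <- sprintf("%s:%s:%d", genotype, gap$chrom,
                     min(starts[chain == cc]))
      contig_ids <- c(contig_ids, cid)
      td_rows[[length(td_rows) + 1L]] <- data.frame(
        contig_id = cid, accession = dom_acc, stringsAsFactors = FALSE)
    }
    expected <- switch(cat, ok = "one_contig", bad_gap = "split", "absent")
    tr_rows[[k]] <- data.frame(
      pseudo_id = sprintf("%s.pseudo%03d", genotype, k),
      parent = plan$parent, chrom = gap$chrom, category = cat,
      expected = expected, n_frags = n_frag,
      contig_ids = paste(contig_ids, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  list(pseudoexons = do.call(rbind, pe_rows),
       repeats = if (length(rep_rows)) do.call(rbind, rep_rows) else
         empty$repeats,
       translated_domains = do.call(rbind, td_rows),
       truth = do.call(rbind, tr_rows))
}

#' Simulate a multi-genotype dataset
#'
#' Draws an independent seed stream per genotype from the master seed and
#' simulates each genotype. Fixed seeds give identical output.
#'
#' @param cfg A [sim_config()] object.
#' @return List with `cfg` and `genotypes` (list of [simulate_genotype()]
#'   results, named by genotype label).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed %% .Machine$integer.max)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_genotypes)
  genotypes <- lapply(seq_len(cfg$n_genotypes), function(i) {
    simulate_genotype(cfg, i, seed = sub_seeds[i])
  })
  names(genotypes) <- vapply(genotypes, `[[`, "", "genotype")
  list(cfg = cfg, genotypes = genotypes)
}

#' Simulate a genome with planted NLR window clusters
#'
#' Places `length(sizes)` clusters of NLR genes on one chromosome, each
#' confined to a single window and separated from the next cluster by at
#' least `spacing` empty windows, so the planted cluster count and
#' membership are recovered exactly by window-merge detection.
#'
#' @param sizes Integer vector of cluster sizes (each >= 1).
#' @param window_size Window size in bp (default 1e6).
#' @param spacing Empty windows between planted clusters (default 2).
#' @param genotype Genotype label.
#' @param chrom Chromosome name.
#' @return List `genes` (`gene_models`) and `truth` (data frame `gene_id`,
#'   `cluster`).
#' @export
simulate_clustered_nlrs <- function(sizes, window_size = 1e6, spacing = 2,
                                    genotype = "sim", chrom = "Chr1") {
  rows <- list()
  truth <- list()
  win <- 0L
  for (k in seq_along(sizes)) {
    base <- win * window_size
    pos <- sort(sample.int(window_size - 5000L, sizes[k]))
    for (j in seq_len(sizes[k])) {
      gid <- sprintf("%s.cl%d.g%d", genotype, k, j)
      s <- as.integer(base + pos[j])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, genotype = genotype, chrom = chrom, start = s,
        end = s + 2000L, strand = "+", aed = NA_real_,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = gid, cluster = k, stringsAsFactors = FALSE)
    }
    win <- win + 1L + spacing
  }
  genes <- do.call(rbind, rows)
  genes$exons <- lapply(seq_len(nrow(genes)), function(i) {
    exon_matrix(genes$start[i], genes$end[i])
  })
  class(genes) <- c("gene_models", "data.frame")
  list(genes = genes, truth = do.call(rbind, truth))
}

#' Write a simulated genotype to disk in the pipeline's file dialects
#'
#' Emits `genes.gff3`, `proteome.faa`, `domains.tsv` (Interproscan-style),
#' `parser.tsv`, `coils.tsv`, `similarity.tsv`, `pseudoexons.tsv` and
#' `repeats.tsv` (12-column tabular), `translated_domains.tsv`, and
#' `truth/` tables, so every reader can be exercised round-trip.
#'
#' @param g A genotype list from [simulate_genotype()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_genotype_dataset <- function(g, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  paths <- c(
    gff = file.path(dir, "genes.gff3"),
    proteome = file.path(dir, "proteome.faa"),
    domains = file.path(dir, "domains.tsv"),
    parser = file.path(dir, "parser.tsv"),
    coils = file.path(dir, "coils.tsv"),
    similarity = file.path(dir, "similarity.tsv"),
    pseudoexons = file.path(dir, "pseudoexons.tsv"),
    repeats = file.path(dir, "repeats.tsv"),
    translated_domains = file.path(dir, "translated_domains.tsv"))
  write_gff3(g$genes, paths["gff"])
  Biostrings::writeXStringSet(Biostrings::AAStringSet(g$proteome),
                              paths["proteome"])
  dh <- g$domain_hits
  analysis <- ifelse(dh$source == "pfam_hmm", "Pfam",
              ifelse(dh$source == "coils", "Coils", "CustomHMM"))
  utils::write.table(
    data.frame(dh$protein_id, "-", 0L, analysis, dh$accession, "-",
               dh$aa_start, dh$aa_end, dh$evalue),
    paths["domains"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  utils::write.table(g$parser, paths["parser"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(g$coils, paths["coils"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- g$similarity
  utils::write.table(
    data.frame(s$query_id, s$subject_id, s$pct_identity, s$align_len, 0L,
               0L, s$q_start, s$q_end, s$s_start, s$s_end, s$evalue, 100),
    paths["similarity"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  p <- g$pseudoexons
  ptab <- if (nrow(p) > 0L) {
    rev <- p$frame < 0L
    data.frame(p$parent_protein, p$chrom, p$pct_identity, p$aa_len, 0L, 0L,
               1L, p$aa_len, ifelse(rev, p$g_end, p$g_start),
               ifelse(rev, p$g_start, p$g_end), p$evalue, 50)
  } else p[0, 0]
  utils::write.table(ptab, paths["pseudoexons"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  r <- g$repeats
  rtab <- if (nrow(r) > 0L) {
    data.frame(r$hit_id, "rep", 80, 50, 0L, 0L, 1L, 50L, 1L, 150L,
               r$evalue, 60)
  } else r[0, 0]
  utils::write.table(rtab, paths["repeats"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(g$translated_domains, paths["translated_domains"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(g$truth$genes, file.path(dir, "truth", "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(g$truth$pseudogenes,
                     file.path(dir, "truth", "pseudogenes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
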