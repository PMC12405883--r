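test_that("gene ranking sorts by chromosome then coordinates", {
  genes <- make_genes(c(100L, 50L, 200L, 10L), c(150L, 80L, 260L, 40L),
                      chrom = c("Chr1", "Chr1", "Chr1", "Chr2"))
  r <- rank_genes(genes)
  expect_equal(r$gene_id, c("g2", "g1", "g3", "g4"))
  expect_equal(r$rank, c(0L, 1L, 2L, 0L))
  dup <- genes; dup$gene_id[2] <- "g1"
  expect_error(rank_genes(dup), "duplicate")
})

test_that("a planted collinear segment is chained in both orientations", {
  genes <- make_genes(seq(1000, by = 10000, length.out = 16),
                      seq(1000, by = 10000, length.out = 16) + 500,
                      chrom = rep(c("Chr1", "Chr2"), each = 8))
  genes$gene_id <- c(paste0("a", 1:8), paste0("b", 1:8))
  ranks <- rank_genes(genes)
  fwd <- sim_hit(paste0("a", 1:6), paste0("b", 1:6))
  b <- find_collinear_blocks(fwd, ranks)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_anchors, 6L)
  expect_equal(b$orientation, "same")
  expect_equal(b$score, 6 * 50)  # gap-free chain
  expect_equal(unname(b$anchors[[1]][, "gene_b"]), paste0("b", 1:6))

  rev <- sim_hit(paste0("a", 1:6), paste0("b", 6:1))
  binv <- find_collinear_blocks(rev, ranks)
  expect_equal(binv$orientation, "inverted")
  expect_equal(binv$n_anchors, 6L)

  # four collinear pairs are below match_size and give no block
  expect_equal(nrow(find_collinear_blocks(fwd[1:4, ], ranks)), 0L)
})

test_that("duplicate classes respect the stated rank-distance boundaries", {
  genes <- make_genes((1:30) * 1000L, (1:30) * 1000L + 100L)
  ranks <- rank_genes(genes)
  cls <- function(h, blocks = NULL) {
    d <- if (is.null(blocks)) classify_duplicates(ranks, h)
         else classify_duplicates(ranks, h, blocks)
    stats::setNames(d$dup_type, d$gene_id)
  }
  expect_equal(unname(cls(sim_hit("g1", "g2"))[c("g1", "g2")]),
               c("tandem", "tandem"))
  expect_equal(unname(cls(sim_hit("g1", "g11"))[c("g1", "g11")]),
               c("proximal", "proximal"))
  expect_equal(unname(cls(sim_hit("g1", "g21"))[c("g1", "g21")]),
               c("proximal", "proximal"))  # exactly 20 ranks away
  expect_equal(unname(cls(sim_hit("g1", "g22"))[c("g1", "g22")]),
               c("dispersed", "dispersed"))  # 21 ranks: beyond the bound
  expect_equal(unname(cls(sim_hit("g1", "g2"))["g5"]), "singleton")
  # anchors take precedence over tandem
  blocks <- data.frame(block_id = "b1", chrom_a = "Chr1", chrom_b = "Chr1",
                       orientation = "same", n_anchors = 5L, score = 250,
                       stringsAsFactors = FALSE)
  blocks$anchors <- list(cbind(gene_a = "g1", gene_b = "g2"))
  expect_equal(unname(cls(sim_hit("g1", "g2"), blocks)[c("g1", "g2")]),
               c("wgd_segmental", "wgd_segmental"))
})

test_that("classification partitions the gene set and matches the oracle", {
  set.seed(202)
  for (rep in 1:60) {
    n <- sample(10:120, 1)
    nchrom <- sample(1:3, 1)
    genes <- make_genes(sort(sample.int(1e6, n)),
                        sort(sample.int(1e6, n)) + 100L,
                        chrom = sample(paste0("Chr", 1:nchrom), n, TRUE))
    ranks <- rank_genes(genes)
    nh <- sample(0:40, 1)
    hits <- if (nh > 0) {
      sim_hit(sample(genes$gene_id, nh, TRUE),
              sample(genes$gene_id, nh, TRUE))
    } else sim_hit(character(0), character(0))
    anchors <- sample(genes$gene_id, sample(0:5, 1))
    blocks <- data.frame(block_id = "b", chrom_a = "Chr1",
                         chrom_b = "Chr1", orientation = "same",
                         n_anchors = length(anchors), score = 1,
                         stringsAsFactors = FALSE)[rep(1, length(anchors) > 0), ]
    blocks$anchors <- if (length(anchors) > 0) {
      list(cbind(gene_a = anchors, gene_b = anchors))
    } else list()
    got <- classify_duplicates(ranks, hits, blocks)
    expect_equal(sum(table(got$dup_type)), n)
    expect_equal(got$dup_type,
                 oracle_dup_classify(ranks, hits, anchors))
  }
})

test_that("adding a hit never demotes a gene to lower precedence", {
  set.seed(7)
  prec <- c(singleton = 0, dispersed = 1, proximal = 2, tandem = 3,
            wgd_segmental = 4)
  genes <- make_genes((1:40) * 500L, (1:40) * 500L + 100L)
  ranks <- rank_genes(genes)
  hits <- sim_hit(sample(genes$gene_id, 10), sample(genes$gene_id, 10))
  base <- classify_duplicates(ranks, hits)
  for (i in 1:20) {
    extra <- rbind(hits, sim_hit(sample(genes$gene_id, 1),
                                 sample(genes$gene_id, 1)))
    more <- classify_duplicates(ranks, extra)
    expect_true(all(prec[more$dup_type] >= prec[base$dup_type]))
  }
})

test_that("planted tandem arrays are fully recovered from simulation", {
  cfg <- sim_config(seed = 5, n_genotypes = 1, regimes = "high",
                    n_background_genes = 100, n_nlr_founders = 10,
                    events_per_founder = c(high = 2, low = 1),
                    p_event = list(
                      high = c(tandem = 1, proximal = 0, dispersed = 0,
                               segmental = 0),
                      low = c(tandem = 1, proximal = 0, dispersed = 0,
                              segmental = 0)),
                    p_pseudogenize = 0)
  g <- simulate_genotype(cfg, 1)
  ranks <- rank_genes(g$genes)
  blocks <- find_collinear_blocks(g$similarity, ranks)
  calls <- classify_duplicates(ranks, g$similarity, blocks)
  nlr <- g$truth$genes$gene_id[g$truth$genes$is_nlr]
  got <- calls$dup_type[match(nlr, calls$gene_id)]
  expect_true(all(got == "tandem"))
})
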