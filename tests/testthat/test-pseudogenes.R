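test_that("candidate filters enforce the stated strict boundaries", {
  genes <- make_genes(10000L, 12000L)
  f <- pseudo_filter()
  mk <- function(...) make_pseudo_hits("nlrA", "Chr1", ...)
  # length: 30 aa removed, 31 kept
  h <- mk(g_start = c(1e5, 2e5), g_end = c(1e5, 2e5) + 90, aa_len = c(30, 31))
  kept <- filter_candidates(h, genes, filter = f)
  expect_equal(kept$aa_len, 31L)
  expect_equal(attr(kept, "removed")[["short"]], 1L)
  # identity: 40.0 removed, 40.1 kept
  h <- mk(g_start = c(1e5, 2e5), g_end = c(1e5, 2e5) + 90,
          pct_identity = c(40.0, 40.1))
  expect_equal(filter_candidates(h, genes, filter = f)$pct_identity, 40.1)
  # genic overlap by a single bp removes the hit
  h <- mk(g_start = c(9850L, 3e5), g_end = c(10000L, 3e5 + 90))
  kept <- filter_candidates(h, genes, filter = f)
  expect_equal(kept$g_start, 3e5)
  expect_equal(attr(kept, "removed")[["genic"]], 1L)
  # repeat gate is strict: e = 1e-5 kept, e = 1e-6 removed
  h <- mk(g_start = c(1e5, 2e5), g_end = c(1e5, 2e5) + 90)
  reps <- data.frame(hit_id = h$hit_id, evalue = c(1e-6, 1e-5),
                     stringsAsFactors = FALSE)
  kept <- filter_candidates(h, genes, repeats = reps, filter = f)
  expect_equal(kept$hit_id, h$hit_id[2])
  # removal reasons account for every dropped hit
  expect_equal(sum(attr(kept, "removed")), nrow(h) - nrow(kept))
})

test_that("relaxing length or identity never removes survivors", {
  set.seed(12)
  genes <- make_genes(50000L, 60000L)
  h <- make_pseudo_hits("p", "Chr1", g_start = (1:40) * 3000L,
                        g_end = (1:40) * 3000L + 200L,
                        pct_identity = runif(40, 20, 90),
                        aa_len = sample(10:120, 40, TRUE))
  n_strict <- nrow(filter_candidates(h, genes, filter = pseudo_filter()))
  n_loose_len <- nrow(filter_candidates(h, genes,
                                        filter = pseudo_filter(min_aa_len = 15)))
  n_loose_id <- nrow(filter_candidates(h, genes,
                                       filter = pseudo_filter(min_identity = 25)))
  expect_gte(n_loose_len, n_strict)
  expect_gte(n_loose_id, n_strict)
})

test_that("intron quantile uses linear interpolation over pooled introns", {
  g3 <- make_genes(rep(1L, 3), rep(400L, 3),
                   exons = lapply(1:3, function(i) {
                     cbind(start = c(1L, 202L), end = c(100L, 400L))
                   }))
  expect_equal(intron_q99(g3), 101)
  # exons (100..200),(301..400): one intron of 301-200-1 = 100 bp
  g1 <- make_genes(100L, 400L,
                   exons = list(cbind(start = c(100L, 301L),
                                      end = c(200L, 400L))))
  expect_equal(intron_lengths(g1), 100L)
  # introns 1..1000: interpolated 99th percentile
  gmany <- make_genes(rep(1L, 1000), rep(5000L, 1000),
                      exons = lapply(1:1000, function(i) {
                        cbind(start = c(1L, 100L + i + 1L),
                              end = c(100L, 5000L))
                      }))
  expect_equal(intron_q99(gmany), 990.01)
  expect_error(intron_q99(make_genes(1L, 50L)), "fallback")
})

test_that("pseudoexon linking follows the parent and gap criteria", {
  mk <- function(parent, starts, lens = 100L) {
    make_pseudo_hits(parent, "Chr1", g_start = starts,
                     g_end = starts + lens - 1L)
  }
  # same parent, gap 500 <= q99 1000: one 2-exon contig
  two <- mk("pA", c(1000L, 1600L))
  expect_equal(link_pseudoexons(two, 1000)$n_exons, 2L)
  # gap 1500 > q99: two contigs
  split2 <- mk("pA", c(1000L, 2600L))
  expect_equal(nrow(link_pseudoexons(split2, 1000)), 2L)
  # different parents, gap 10: two contigs
  diffp <- rbind(mk("pA", 1000L), mk("pB", 1110L))
  expect_equal(nrow(link_pseudoexons(diffp, 1000)), 2L)
  # chain A-B-C with gaps 400 and 900 under q99 = 1000: one 3-exon contig
  abc <- mk("pA", c(1000L, 1500L, 2500L))
  got <- link_pseudoexons(abc, 1000)
  expect_equal(got$n_exons, 3L)
  expect_equal(got$start, 1000L)
  expect_equal(got$end, 2599L)
  # boundary: gap exactly q99 links (inclusive rule)
  atq <- mk("pA", c(1000L, 1100L + 1000L))
  expect_equal(link_pseudoexons(atq, 1000)$n_exons, 2L)
})

test_that("linking equals the exhaustive contiguous-partition oracle", {
  set.seed(77)
  for (i in 1:150) {
    n <- sample(2:10, 1)
    starts <- sort(sample.int(50000L, n)) * 2L
    h <- make_pseudo_hits(sample(c("pA", "pB"), n, TRUE), "Chr1",
                          g_start = starts,
                          g_end = starts + sample(50:400, n, TRUE))
    # drop overlapping hits so the oracle's partition logic applies cleanly
    keep <- c(TRUE, h$g_start[-1] > cummax(h$g_end)[-n])
    h <- h[keep, , drop = FALSE]
    if (nrow(h) < 2) next
    q99 <- sample(500:5000, 1)
    got <- link_pseudoexons(h, q99)
    valid <- oracle_link_partitions(h, q99)
    expect_length(valid, 1L)
    segs <- valid[[1]]
    expect_equal(nrow(got), length(segs))
    expect_equal(sort(got$n_exons), sort(unname(lengths(segs))))
    # permutation invariance of the input order
    perm <- h[sample(nrow(h)), , drop = FALSE]
    got2 <- link_pseudoexons(perm, q99)
    expect_equal(got[order(got$start), ]$contig_id,
                 got2[order(got2$start), ]$contig_id)
  }
})

test_that("domain confirmation keeps only contigs with common NLR domains", {
  contigs <- link_pseudoexons(rbind(
    make_pseudo_hits("pA", "Chr1", 1000L, 1300L),
    make_pseudo_hits("pB", "Chr1", 9000L, 9300L),
    make_pseudo_hits("pC", "Chr1", 20000L, 20300L)), 500)
  td <- data.frame(contig_id = contigs$contig_id[1:2],
                   accession = c("PF00931", "PF00069"),
                   stringsAsFactors = FALSE)
  ok <- domain_confirm(contigs, td)
  expect_equal(ok$parent_protein, "pA")
  # CC (PF18052) counts as a common domain
  td2 <- data.frame(contig_id = contigs$contig_id[3],
                    accession = "PF18052", stringsAsFactors = FALSE)
  expect_equal(domain_confirm(contigs, td2)$parent_protein, "pC")
})

test_that("pseudogene:parent ratios divide contig count by distinct parents", {
  contigs <- data.frame(
    contig_id = paste0("c", 1:241),
    genotype = c(rep("skewed", 198), rep("even", 43)),
    parent_protein = c(paste0("p", rep(1:43, length.out = 198)),
                       paste0("q", 1:43)),
    stringsAsFactors = FALSE)
  r <- pseudogene_parent_ratio(contigs)
  expect_equal(r$ratio[r$genotype == "skewed"], 4.6)
  expect_equal(r$ratio[r$genotype == "even"], 1.0)
  expect_equal(nrow(pseudogene_parent_ratio(contigs[0, ])), 0L)
})
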