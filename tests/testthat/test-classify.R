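dh <- function(pid, acc, evalue, source = "pfam_hmm", s = 1L, e = 50L) {
  data.frame(protein_id = pid, source = source, accession = acc,
             evalue = evalue, aa_start = s, aa_end = e,
             stringsAsFactors = FALSE)
}

test_that("seed-domain gates are inclusive at the stated e-values", {
  hits <- rbind(
    dh("p1", "PF00931", 1e-70),   # NB-ARC, well past gate
    dh("p2", "PF00931", 1e-60),   # NB-ARC, at gate (kept: <=)
    dh("p3", "PF00931", 1e-50),   # NB-ARC, too weak
    dh("p4", "PF05659", 1e-40),   # RPW8, at gate
    dh("p5", "PF01582", 1e-39),   # TIR, too weak
    dh("p6", "PF99999", 1e-99))   # unrelated accession
  expect_message(sel <- select_seed_domains(hits), "1 hit")
  expect_setequal(sel$protein_id, c("p1", "p2", "p4"))
  expect_equal(sel$family[sel$protein_id == "p4"], "rpw8")
})

test_that("domain subsequences extract 1-based inclusive ranges", {
  seeds <- rbind(dh("pA", "PF00931", 1e-70, s = 3L, e = 5L),
                 dh("pA", "PF00931", 1e-70, s = 1L, e = 8L),
                 dh("pA", "PF00931", 1e-70, s = 4L, e = 10L))
  prot <- c(pA = "MAAKVLLD")
  expect_warning(seqs <- extract_domain_seqs(seeds, prot), "skipped")
  expect_equal(unname(seqs), c("AKV", "MAAKVLLD"))
  expect_equal(names(seqs)[1], "pA:PF00931:3-5")
})

test_that("pairwise identity matches enumeration on small cases", {
  expect_equal(pairwise_identity(strrep("K", 50), strrep("K", 50)), 1.0)
  # best global alignment of AAAA/AATA has 3 matches over 4 columns
  expect_equal(pairwise_identity("AAAA", "AATA"), 0.75)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  expect_error(pairwise_identity("", "AAA"), "empty")
})

test_that("greedy centroid clustering collapses near-identical domains", {
  expect_length(
    cluster_representatives(stats::setNames(rep(strrep("ARND", 25), 5),
                                            paste0("s", 1:5))), 1L)
  two <- c(a = strrep("ARNDCEQGHI", 5),
           b = paste0(strrep("ARNDCEQGHI", 4), "WWWWWWWWWW"))
  expect_length(cluster_representatives(two), 2L)  # 80% identity

  # 9 sequences within >=98% of the longest plus one distant outlier;
  # expected cluster count from the all-pairs identity matrix at 0.98
  set.seed(42)
  base <- paste(sample(c("A", "R", "N", "D", "C"), 100, TRUE),
                collapse = "")
  near <- vapply(1:9, function(i) {
    ch <- strsplit(base, "")[[1]]
    ch[i] <- "W"  # single substitution: 99% identity
    paste(ch, collapse = "")
  }, "")
  far <- paste(sample(c("G", "H", "I", "L", "K"), 100, TRUE), collapse = "")
  seqs <- stats::setNames(c(base, near, far), paste0("q", 1:11))
  reps <- cluster_representatives(seqs)
  expect_length(reps, 2L)
  cl <- attr(reps, "clusters")
  expect_equal(sum(cl == "q1"), 10L)

  # at identity 1.0 all distinct sequences stay separate
  reps1 <- cluster_representatives(seqs,
                                   classify_thresholds(rep_identity = 1))
  expect_length(reps1, 11L)
})

test_that("NLR identification unions HMM calls and parser CC motifs", {
  hits <- rbind(dh("p1", "PF00931", 1e-5, source = "custom_hmm"),
                dh("p2", "PF00931", 1e-3, source = "custom_hmm"),
                dh("p3", "PF00931", 1e-4, source = "custom_hmm"),
                dh("p5", "PF00931", 1e-50))  # pfam evidence only, no call
  ids <- identify_nlrs(hits, parser_cc = "p4")
  expect_setequal(ids, c("p1", "p3", "p4"))
})

test_that("architecture rules follow TNL > RNL > CNL > NL precedence", {
  hits <- rbind(
    dh("tnl", "PF01582", 1e-20), dh("tnl", "PF00931", 1e-30),
    dh("tnl", "PF00560", 1e-10),
    dh("rnl", "PF05659", 1e-20), dh("rnl", "PF00931", 1e-30),
    dh("cnl", "PF00931", 1e-30), dh("cnl", "PF00560", 1e-10),
    dh("nl", "PF00931", 1e-30),
    dh("both", "PF01582", 1e-20), dh("both", "PF05659", 1e-20),
    dh("both", "PF00931", 1e-30))
  expect_message(
    rec <- classify_architectures(c("tnl", "rnl", "cnl", "nl", "both"),
                                  hits, parser_cc = "cnl",
                                  coils_cc = "cnl"),
    "TIR and RPW8")
  got <- stats::setNames(rec$nlr_class, rec$gene_id)
  expect_equal(unname(got[c("tnl", "rnl", "cnl", "nl", "both")]),
               c("TNL", "RNL", "CNL", "NL", "TNL"))
  expect_true(rec$complete[rec$gene_id == "tnl"])
  expect_false(rec$complete[rec$gene_id == "rnl"])  # no LRR
  expect_false(rec$complete[rec$gene_id == "nl"])   # no N-terminal domain
  # parser CC alone (without COILS) does not make a CNL
  rec2 <- classify_architectures("cnl", hits, parser_cc = "cnl",
                                 coils_cc = character(0))
  expect_equal(rec2$nlr_class, "NL")
})

test_that("relative scaffold position folds the midpoint to [0, 0.5]", {
  expect_equal(nbarc_relative_position(999L, 1001L, 2000L), 0.5)
  expect_equal(nbarc_relative_position(99000L, 101000L, 1e6), 0.1)
  expect_equal(nbarc_relative_position(899000L, 901000L, 1e6), 0.1)
  expect_error(nbarc_relative_position(100L, 900L, 500L), "scaffold_len")
})

test_that("class assignment is total and counts are conserved", {
  cfg <- sim_config(seed = 11, n_genotypes = 1, regimes = "high",
                    n_background_genes = 120, n_nlr_founders = 12)
  g <- simulate_genotype(cfg, 1)
  ids <- identify_nlrs(g$domain_hits, g$parser)
  ids <- intersect(ids, g$genes$gene_id)
  rec <- classify_architectures(ids, g$domain_hits, g$parser, g$coils)
  expect_equal(nrow(rec), length(ids))
  expect_true(all(rec$nlr_class %in% c("TNL", "RNL", "CNL", "NL")))
  expect_equal(sum(table(rec$nlr_class)), nrow(rec))
  # planted classes recovered for every conflict-free protein
  truth <- g$truth$genes
  expect_equal(rec$nlr_class,
               truth$nlr_class[match(rec$gene_id, truth$gene_id)])
})
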