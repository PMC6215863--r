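test_that("generators are byte-deterministic under a fixed seed", {
  g1 <- gen_genome(gc_model(0.4), 5000L, seed = 9)
  g2 <- gen_genome(gc_model(0.4), 5000L, seed = 9)
  expect_identical(g1$sequence, g2$sequence)
  i1 <- gen_operon_insert(gc_model(0.6), seed = 9)
  i2 <- gen_operon_insert(gc_model(0.6), seed = 9)
  expect_identical(i1, i2)
  s1 <- sim_gene_families(seq_len = 100L, seed = 9)
  s2 <- sim_gene_families(seq_len = 100L, seed = 9)
  expect_identical(s1$alignments, s2$alignments)
})

test_that("order-0 genomes hit their target GC within 1%", {
  g <- gen_genome(gc_model(0.6), 100000L, seed = 10)
  gc <- sum(strsplit(g$sequence, "")[[1]] %in% c("G", "C")) / g$length
  expect_equal(gc, 0.6, tolerance = 0.017)  # +-1% absolute
})

test_that("higher-order chains reproduce conditional frequencies", {
  # order-1 model with strong CG avoidance
  probs <- matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                              c("A", "C", "G", "T")))
  probs["C", ] <- c(0.4, 0.25, 0.05, 0.3)  # rare CpG
  m <- markov_model(1L, probs, "cpg_poor")
  g <- gen_genome(m, 100000L, seed = 11)
  s <- strsplit(g$sequence, "")[[1]]
  after_c <- s[which(s[-length(s)] == "C") + 1L]
  emp <- table(factor(after_c, levels = c("A", "C", "G", "T"))) /
    length(after_c)
  expect_lt(max(abs(as.numeric(emp) - probs["C", ])), 0.02)
})

test_that("operon inserts are CAB-ordered with in-frame genes", {
  ins <- gen_operon_insert(gc_model(0.6), seed = 12)
  expect_equal(ins$order_tag, "CAB")
  expect_equal(ins$genes$label, c("xmoC", "xmoA", "xmoB"))
  expect_true(all((ins$genes$end - ins$genes$start) %% 3 == 0))
  expect_gte(nchar(ins$sequence), 1500L)
  abc <- gen_operon_insert(gc_model(0.6), seed = 12, order = "ABC")
  expect_equal(abc$order_tag, "ABC")
  expect_equal(abc$genes$label, c("xmoA", "xmoB", "xmoC"))
})

test_that("insert spanning lengths average near 2730 nt", {
  lens <- vapply(1:200, function(i)
    nchar(gen_operon_insert(gc_model(0.6), seed = 1000L + i)$sequence), 0)
  expect_equal(mean(lens), 2730, tolerance = 0.02)
})

test_that("implant conserves every base and records exact truth", {
  host <- gen_genome(gc_model(0.4), 80000L, seed = 13, id = "h")
  ins <- lapply(14:15, function(s) gen_operon_insert(gc_model(0.6), seed = s))
  imp <- implant(host, ins, seed = 16)
  expect_equal(imp$genome$length,
               host$length + sum(nchar(vapply(ins, `[[`, "", "sequence"))))
  # truth intervals slice out exactly the implanted sequences
  for (i in 1:2) {
    got <- extract_region(imp$genome, imp$truth$start[i], imp$truth$end[i])
    expect_identical(got, ins[[i]]$sequence)
  }
  # removing the inserts restores the host
  s <- imp$genome$sequence
  for (i in 2:1)
    s <- paste0(substr(s, 1, imp$truth$start[i]),
                substr(s, imp$truth$end[i] + 1, nchar(s)))
  expect_identical(s, host$sequence)
  # spacing respected
  expect_gte(imp$truth$start[2] - imp$truth$end[1], 0L)
})

test_that("implanted regions out-diverge matched native regions", {
  hits <- vapply(1:15, function(s) {
    sc <- simulate_scenario("lgt", seed = 300L + s, host_length = 80000L)
    gp <- kmer_profile(sc$genome$sequence, source_kind = "genome")
    kl_of <- function(ids) vapply(ids, function(id) {
      l <- Filter(function(x) x$operon_id == id, sc$loci)[[1]]
      kl_divergence(kmer_profile(operon_sequence(sc$genome, l, "spanning")),
                    gp)$kl_nats
    }, 0)
    min(kl_of(c("implant_1", "implant_2"))) >
      max(kl_of(c("native_1", "native_2")))
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("codon-usage draws match the table and separate under KL", {
  usage <- gc_codon_usage(0.6)
  expect_equal(sum(usage), 1, tolerance = 1e-12)
  expect_false(any(c("TAA", "TAG", "TGA") %in% names(usage)))
  cds <- gen_codon_cds(usage, 10000L, seed = 17)
  expect_equal(nchar(cds), 3 * 10000 + 3)
  prof <- codon_profile(cds)
  emp <- prof$frequencies[match(names(usage), prof$categories)]
  expect_lt(max(abs(emp - usage * 10000 / 10001)), 0.01)
  # concentrated usage gives a homopolymer of codons
  atg <- gen_codon_cds(c(ATG = 1), 5L, seed = 18)
  expect_equal(atg, paste0(strrep("ATG", 5), "TAA"))
  # different usage tables -> strictly positive codon KL
  a <- codon_profile(gen_codon_cds(gc_codon_usage(0.4), 3000L, seed = 19))
  b <- codon_profile(gen_codon_cds(gc_codon_usage(0.6), 3000L, seed = 20))
  expect_gt(kl_divergence(a, b)$kl_nats, 0)
  bad <- c(usage * 0.9, TAA = 0.1)
  expect_error(gen_codon_cds(bad / sum(bad), 10L), "stop")
})

test_that("gene families without perturbations give congruent trees", {
  sim <- sim_gene_families(seq_len = 500L, seed = 21)
  expect_false(any(sim$truth$topology_swap))
  trees <- lapply(sim$alignments,
                  function(a) suppressMessages(nj_tree(poisson_distance(a))))
  it <- incongruence_table(trees)
  expect_true(all(it$rf == 0))
})

test_that("swap and rate perturbations are recorded and applied", {
  sim <- sim_gene_families(
    swap = list("2" = list(clade = default_focal_clade(), attach = "t1")),
    rate = list("3" = list(clade = default_focal_clade(), m = 2.5)),
    seq_len = 50L, seed = 22)
  expect_equal(sim$truth$topology_swap, c(FALSE, TRUE, FALSE))
  expect_equal(sim$truth$rate_multiplier, c(1, 1, 2.5))
  # true tree 2 disagrees with the base tree; true tree 3 has scaled depth
  expect_gt(rf_distance(sim$trees_used[[2]], sim$trees_used[[1]])$rf, 0)
  d1 <- ape::cophenetic.phylo(sim$trees_used[[1]])["op3a", "op3b"]
  d3 <- ape::cophenetic.phylo(sim$trees_used[[3]])["op3a", "op3b"]
  expect_equal(d3 / d1, 2.5, tolerance = 1e-9)
  expect_error(sim_gene_families(
    swap = list("1" = list(clade = default_focal_clade(), attach = "op3a")),
    seq_len = 10L, seed = 1), "inside")
})

test_that("scenario files are written and reproducible", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  simulate_scenario("lgt", seed = 23, host_length = 100000L, out = out1)
  simulate_scenario("lgt", seed = 23, host_length = 100000L, out = out2)
  expect_true(all(file.exists(file.path(out1, c("genome.fasta", "loci.tsv",
                                                "truth.json")))))
  expect_identical(readLines(file.path(out1, "genome.fasta")),
                   readLines(file.path(out2, "genome.fasta")))
  expect_identical(readLines(file.path(out1, "truth.json")),
                   readLines(file.path(out2, "truth.json")))
  out3 <- withr::local_tempdir()
  simulate_scenario("incongruence", seed = 24, out = out3)
  expect_true(file.exists(file.path(out3, "gene2.afa")))
})
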