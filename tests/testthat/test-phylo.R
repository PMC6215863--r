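random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

test_that("Poisson distance follows -ln(1 - p) with pairwise gap deletion", {
  a <- aa_alignment(c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAC"))
  expect_equal(poisson_distance(a)["s1", "s2"], -log(1 - 0.1))
  # 10 columns, 2 gap columns, 3 differences among the 8 compared
  b <- aa_alignment(c(x = "AC-DEFGH-K", y = "ACWDQFGAWK"))
  # compared columns: 1,2,4,5,6,7,8,10 -> diffs at 5,8 ... count by hand:
  # A=A, C=C, D=D, E!=Q, F=F, G=G, H!=A, K=K -> 2/8
  expect_equal(poisson_distance(b)["x", "y"], -log(1 - 2 / 8))
  ident <- aa_alignment(c(p = "MKV", q = "MKV"))
  expect_equal(poisson_distance(ident)["p", "q"], 0)
})

test_that("saturated and non-overlapping pairs are named errors", {
  sat <- aa_alignment(c(u = "AAAAAAAAAAAAAAAAAAAA",
                        v = "CCCCCCCCCCCCCCCCCCCC"))
  expect_error(poisson_distance(sat), "saturated pair u / v")
  nov <- aa_alignment(c(m = "AA--", n = "--CC"))
  expect_error(poisson_distance(nov), "no overlapping sites")
})

test_that("distance is permutation-equivariant and dominates p", {
  set.seed(41)
  base <- strsplit(random_aa(60), "")[[1]]
  rows <- setNames(vapply(1:5, function(i) {
    mutated <- base
    pos <- sample(60, sample(5:20, 1))
    mutated[pos] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                           length(pos), replace = TRUE)
    paste(mutated, collapse = "")
  }, ""), paste0("s", 1:5))
  d1 <- poisson_distance(aa_alignment(rows))
  perm <- sample(names(rows))
  d2 <- poisson_distance(aa_alignment(rows[perm]))
  expect_equal(d2[names(rows), names(rows)], d1)
  p <- 1 - exp(-d1)
  expect_true(all(d1 >= p - 1e-12))
})

test_that("NJ solves the three-taxon star exactly", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  pl <- ape::cophenetic.phylo(tr)
  expect_equal(pl[rownames(d), colnames(d)], d, tolerance = 1e-9)
})

test_that("NJ recovers additive matrices exactly (path lengths to 1e-9)", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    tr0 <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(tr0)
    tr <- suppressMessages(nj_tree(d))
    expect_equal(rf_distance(tr, tr0)$rf, 0)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
  }
})

test_that("NJ places a 4-taxon split by the quartet criterion", {
  # d(AB), d(CD) small; cross distances large -> AB|CD, checked against
  # brute force over the three possible quartets via the four-point rule
  d <- matrix(c(0, 1, 6, 6.2,
                1, 0, 6.1, 6.3,
                6, 6.1, 0, 1.2,
                6.2, 6.3, 1.2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  sums <- c(ab_cd = d["a", "b"] + d["c", "d"],
            ac_bd = d["a", "c"] + d["b", "d"],
            ad_bc = d["a", "d"] + d["b", "c"])
  expect_equal(names(which.min(sums)), "ab_cd")  # oracle agrees
  tr <- nj_tree(d)
  split <- xenocomp:::tree_splits(tr)
  expect_equal(split, "c,d")
})

test_that("NJ agrees with an independent implementation on noisy data", {
  set.seed(43)
  sim <- sim_gene_families(seq_len = 300L, seed = 99)
  dm <- poisson_distance(sim$alignments$gene1)
  ours <- suppressMessages(nj_tree(dm))
  ref <- ape::nj(as.dist(dm))
  expect_equal(rf_distance(ours, ref)$rf, 0)
})

test_that("concatenation keeps shared taxa and drops short rows", {
  parts <- list(
    aa_alignment(c(a = "AAAA", b = "CCCC", c = "DDDD")),
    aa_alignment(c(a = "EEEE", b = "FFFF", c = "----", d = "GGGG")),
    aa_alignment(c(a = "HHHH", b = "IIII", c = "KKKK")))
  cat0 <- concat_alignment(parts, min_len = 0)
  expect_equal(sort(names(cat0)), c("a", "b", "c"))  # d not shared
  expect_equal(nchar(cat0[["a"]]), 12L)
  expect_message(concat_alignment(parts, min_len = 10), "dropping c")
  expect_false("c" %in% names(
    suppressMessages(concat_alignment(parts, min_len = 10))))
  expect_error(concat_alignment(list(
    aa_alignment(c(x = "AA")), aa_alignment(c(y = "AA")))), "shared")
})

test_that("RF distance counts discordant splits and normalizes", {
  t1 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  t2 <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1);")
  expect_equal(rf_distance(t1, t1)$rf, 0)
  r <- rf_distance(t1, t2)
  expect_equal(r$rf, 2L)
  expect_equal(r$rf_normalized, 1)
  expect_length(r$discordant_splits, 2L)
  expect_error(rf_distance(ape::read.tree(text = "((a,b),c);"),
                           ape::read.tree(text = "((a,c),b);")), "4")
})

test_that("RF behaves as a metric on random trees and matches phangorn", {
  skip_if_not_installed("phangorn")
  set.seed(44)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    tips <- paste0("t", 1:n)
    t1 <- ape::rtree(n, tip.label = tips)
    t2 <- ape::rtree(n, tip.label = sample(tips))
    t3 <- ape::rtree(n, tip.label = sample(tips))
    r12 <- rf_distance(t1, t2)$rf
    r21 <- rf_distance(t2, t1)$rf
    expect_equal(r12, r21)
    expect_equal(rf_distance(t1, t1)$rf, 0)
    expect_lte(r12, rf_distance(t1, t3)$rf + rf_distance(t3, t2)$rf)
    expect_equal(r12,
                 as.integer(phangorn::RF.dist(ape::unroot(t1),
                                              ape::unroot(t2))))
  }
})

test_that("root-to-tip ratio is 1 on a clock-like tree and tracks scaling", {
  tr <- default_gene_tree()
  expect_equal(rate_ratio(tr, default_focal_clade(), "og")$rate_ratio, 1,
               tolerance = 1e-9)
  # scaling the focal clade (stem + internals) by 3 on the rooted base
  # tree: focal depth 0.02 + 3*0.35, background depth 0.37 (hand-derived)
  scaled <- xenocomp:::scale_clade(tr, default_focal_clade(), 3)
  expect_equal(rate_ratio(scaled, default_focal_clade(), "og")$rate_ratio,
               (0.02 + 3 * 0.35) / 0.37, tolerance = 1e-9)
  expect_error(rate_ratio(tr, tr$tip.label, "og"), "focal|background")
})

test_that("the three-gene pipeline flags exactly the swapped gene", {
  sim <- simulate_scenario("incongruence", seed = 7)
  trees <- lapply(sim$alignments,
                  function(a) suppressMessages(nj_tree(poisson_distance(a))))
  it <- incongruence_table(trees)
  rf13 <- it$rf[it$gene1 == "gene1" & it$gene2 == "gene3"]
  expect_equal(rf13, 0L)
  expect_gt(it$rf[it$gene1 == "gene1" & it$gene2 == "gene2"], 0L)
  expect_gt(it$rf[it$gene1 == "gene2" & it$gene2 == "gene3"], 0L)
})
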