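test_that("IUPAC matching follows the code expansions", {
  expect_true(iupac_match("R", "G"))
  expect_false(iupac_match("R", "C"))
  expect_true(iupac_match("N", "T"))
  expect_false(iupac_match("Y", "A"))
  expect_error(iupac_match("Z", "A"), "invalid")
})

test_that("primer_spec reports degeneracy and validates length", {
  p <- primer_spec("A189f-style", "GGNGACTGGGACTTCTGG", "forward")
  expect_equal(p$degeneracy, 4L)
  expect_error(primer_spec("short", "ACGTACGT", "forward"), "shorter")
  expect_error(primer_spec("bad", "ACGTACGTZZ", "forward"), "invalid IUPAC")
})

test_that("best_hit finds exact and near matches with position", {
  set.seed(51)
  flank <- random_dna(40)
  core <- "GGAGACTGGGACTTCTGG"  # concrete instance of GGN...
  target <- paste0(flank, core, random_dna(30))
  p <- primer_spec("p1", "GGNGACTGGGACTTCTGG", "forward")
  h <- best_hit(p, target)
  expect_equal(h$best_mismatches, 0L)
  expect_equal(h$best_position, 40L)
  # one substitution outside the N position
  mutated <- core
  substr(mutated, 6, 6) <- "T"  # C -> T at a fixed position
  h1 <- best_hit(p, paste0(flank, mutated, random_dna(30)))
  expect_equal(h1$best_mismatches, 1L)
  # fully degenerate primer matches anywhere with 0 mismatches
  hn <- best_hit(primer_spec("allN", "NNNNNNNNNN", "forward"),
                 random_dna(60))
  expect_equal(hn$best_mismatches, 0L)
  expect_error(best_hit(p, "ACGT"), "shorter")
})

test_that("a reverse-role primer is matched via its reverse complement", {
  set.seed(52)
  site <- "ACCGTAGGTTAGGCAT"
  target <- paste0(random_dna(25), site, random_dna(25))
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(site, "")[[1]]),
                                     collapse = ""))
  r <- primer_spec("rev1", rc, "reverse")
  h <- best_hit(r, target)
  expect_equal(h$best_mismatches, 0L)
  expect_equal(h$best_position, 25L)
  expect_equal(h$strand, "+")
})

test_that("best_hit equals the degenerate-expansion brute force", {
  set.seed(53)
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "N")
  for (i in 1:40) {
    repeat {
      primer <- paste(sample(codes, 12, replace = TRUE,
                             prob = c(rep(0.2, 4), rep(0.04, 7))),
                      collapse = "")
      sizes <- c(A = 1, C = 1, G = 1, T = 1, R = 2, Y = 2, S = 2, W = 2,
                 K = 2, M = 2, N = 4)
      if (prod(sizes[strsplit(primer, "")[[1]]]) <= 1024) break
    }
    target <- random_dna(sample(30:80, 1))
    ours <- best_hit(primer_spec("p", primer, "forward"), target)
    expect_equal(ours$best_mismatches, brute_best_mismatches(primer, target))
  }
})

test_that("coverage is monotone in max_mm and strand-symmetric", {
  set.seed(54)
  fwd <- primer_spec("f", "GGNGACTGGGACTTCTGG", "forward")
  rev_site <- "TTCAAGGCCTACGATCCG"
  rev <- primer_spec("r", chartr("ACGT", "TGCA",
                                 paste(rev(strsplit(rev_site, "")[[1]]),
                                       collapse = "")), "reverse")
  mk_target <- function(mm_in_fwd) {
    core <- "GGAGACTGGGACTTCTGG"
    # positions 7, 8, 9 are T, G, G in both core and primer: each A
    # substitution is a genuine mismatch
    if (mm_in_fwd > 0)
      for (k in c(7L, 8L, 9L)[seq_len(mm_in_fwd)]) substr(core, k, k) <- "A"
    paste0(random_dna(20), core, random_dna(150), rev_site, random_dna(20))
  }
  targets <- c(t1 = mk_target(0), t2 = mk_target(0), t3 = mk_target(2),
               t4 = mk_target(3))
  groups <- c("grpA", "grpA", "grpB", "grpB")
  pairs <- list(list(fwd = fwd, rev = rev))
  fr <- function(mm) coverage_table(pairs, targets, groups, max_mm = mm)
  cov0 <- fr(0); cov2 <- fr(2); cov3 <- fr(3)
  expect_equal(cov0$fraction[cov0$group == "grpA"], 1.0)
  expect_equal(cov0$fraction[cov0$group == "grpB"], 0.0)
  expect_equal(cov2$fraction[cov2$group == "grpB"], 0.5)
  expect_true(all(cov3$fraction >= cov2$fraction))
  expect_true(all(cov2$fraction >= cov0$fraction))
  # verbatim sites give the expected amplicon length
  expect_equal(cov0$median_amplicon[cov0$group == "grpA"],
               18 + 150 + 18)
  # reverse-complementing every target leaves coverage unchanged
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  cov_rc <- coverage_table(pairs, vapply(targets, rc, ""), groups,
                           max_mm = 2)
  expect_equal(cov_rc$fraction, cov2$fraction)
})

test_that("a pair losing its reverse site in half a group scores 0.5", {
  set.seed(55)
  fwd_site <- "ACGGATTCAGGCATCAGG"
  rev_site <- "TGCCATTGGACCGATACG"
  fwd <- primer_spec("f", fwd_site, "forward")
  rev <- primer_spec("r", chartr("ACGT", "TGCA",
                                 paste(rev(strsplit(rev_site, "")[[1]]),
                                       collapse = "")), "reverse")
  with_site <- paste0(random_dna(10), fwd_site, random_dna(100), rev_site,
                      random_dna(10))
  without <- paste0(random_dna(10), fwd_site, random_dna(100),
                    random_dna(10))
  tab <- coverage_table(list(list(fwd = fwd, rev = rev)),
                        c(a = with_site, b = without),
                        c("g", "g"), max_mm = 0)
  expect_equal(tab$fraction, 0.5)
})
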