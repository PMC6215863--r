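# Shared fixtures, generated in code.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Brute-force KL over raw count vectors, written independently of the
# package internals: explicit two-pass summation.
brute_kl <- function(region_counts, genome_counts, pseudocount) {
  p <- region_counts + pseudocount
  q <- genome_counts + pseudocount
  p_tot <- 0; q_tot <- 0
  for (i in seq_along(p)) p_tot <- p_tot + p[[i]]
  for (i in seq_along(q)) q_tot <- q_tot + q[[i]]
  acc <- 0
  for (i in seq_along(p)) {
    pi <- p[[i]] / p_tot
    qi <- q[[i]] / q_tot
    if (pi > 0) acc <- acc + pi * log(pi / qi)
  }
  acc
}

# Brute-force best mismatch count: expand the degenerate primer into all
# concrete strings and compare every one at every placement on both
# strands.
brute_best_mismatches <- function(iupac_seq, target) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  chars <- strsplit(toupper(iupac_seq), "")[[1]]
  expansions <- Reduce(function(acc, ch) {
    unlist(lapply(acc, function(a) paste0(a, sets[[ch]])))
  }, chars, accumulate = FALSE, init = "")
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  best <- nchar(iupac_seq)
  for (tg in c(target, rc(target))) {
    tc <- strsplit(tg, "")[[1]]
    L <- length(chars)
    for (off in 0:(length(tc) - L)) {
      window <- tc[(off + 1):(off + L)]
      for (ex in expansions) {
        mm <- sum(strsplit(ex, "")[[1]] != window)
        if (mm < best) best <- mm
      }
    }
  }
  best
}

# A tiny GenBank flat file written on the fly.
write_mini_genbank <- function(path, seq = "ATGGCCTTTAA",
                               locations = c("2..7", "complement(4..9)")) {
  lines <- c(
    sprintf("LOCUS       testrec %d bp    DNA     linear", nchar(seq)),
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq)))
  for (loc in locations) {
    lines <- c(lines,
               sprintf("     CDS             %s", loc),
               "                     /product=\"hypothetical\"")
  }
  lines <- c(lines, "ORIGIN",
             sprintf("        1 %s", tolower(seq)), "//")
  writeLines(lines, path)
  path
}
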