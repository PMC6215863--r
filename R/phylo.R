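#' Amino-acid alignments
#'
#' An `aa_alignment` is a named character vector of equal-length aligned
#' amino-acid sequences (gaps `-` or `.`). Aligning itself is out of scope:
#' alignments are inputs, read from aligned FASTA.
#'
#' @param rows Named character vector of aligned rows.
#' @return An `aa_alignment`.
#' @export
aa_alignment <- function(rows) {
  stopifnot(is.character(rows), length(rows) >= 1L,
            !is.null(names(rows)), all(nzchar(names(rows))))
  if (anyDuplicated(names(rows)))
    stop("duplicate sequence names in alignment")
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows differ in length")
  structure(toupper(rows), class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<aa_alignment> %d sequences x %d columns\n",
              length(x), nchar(x[[1]])))
  invisible(x)
}

#' Read an aligned amino-acid FASTA file
#'
#' @param path Path to aligned FASTA.
#' @return An [aa_alignment()].
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, "", 1L)
  aa_alignment(setNames(as.character(set), ids))
}

#' Write an alignment as FASTA
#' @param aln An [aa_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  writeLines(paste0(">", names(aln), "\n", unclass(aln)), path)
  invisible(path)
}

#' Poisson-corrected amino-acid distance matrix
#'
#' For each pair, `p` is the proportion of differing sites over columns
#' where both sequences are non-gap (pairwise gap deletion), and the
#' distance is the Poisson correction `d = -ln(1 - p)`. Pairs with no
#' overlap, or saturated pairs with `p >= saturation`, are errors naming the
#' pair: deeply saturated sequences should be excluded, not silently
#' clamped.
#'
#' @param aln An [aa_alignment()] with at least 2 sequences.
#' @param saturation Proportion at or above which a pair is declared
#'   saturated (default 0.95).
#' @return A symmetric numeric matrix with zero diagonal.
#' @examples
#' a <- aa_alignment(c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAC"))
#' poisson_distance(a)["s1", "s2"]  # -log(0.9)
#' @export
poisson_distance <- function(aln, saturation = 0.95) {
  stopifnot(inherits(aln, "aa_alignment"), length(aln) >= 2L)
  n <- length(aln)
  chars <- do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
  gap <- chars == "-" | chars == "."
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok))
        stop("no overlapping sites for pair ", names(aln)[i], " / ",
             names(aln)[j])
      p <- sum(chars[i, ok] != chars[j, ok]) / sum(ok)
      if (p >= saturation)
        stop("saturated pair ", names(aln)[i], " / ", names(aln)[j],
             " (p = ", signif(p, 3), "); exclude one of the sequences")
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on the Q-criterion. Ties in Q are broken
#' deterministically by the lowest `(i, j)` index pair in the current
#' matrix; negative branch lengths are clamped to zero and the clamped
#' deficit reported via `message()`. The result is an unrooted `phylo`
#' (ape) tree.
#'
#' @param dm Symmetric distance matrix with row/column names, >= 3 taxa.
#' @return An object of class `phylo`.
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(dm)
  stopifnot(!is.null(labels))
  # Each active node carries a growing newick fragment.
  frag <- labels
  D <- dm
  clamped <- 0
  bl <- function(x) {
    if (x < 0) { clamped <<- clamped - x; 0 } else x
  }
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    # Q matrix; pick the minimal entry, lowest (i, j) on ties.
    best <- c(NA, NA); bestq <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- bl(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    vj <- bl(D[i, j] - D[i, j] / 2 - (r[i] - r[j]) / (2 * (m - 2)))
    newfrag <- sprintf("(%s:%.17g,%s:%.17g)", frag[i], vi, frag[j], vj)
    others <- setdiff(seq_len(m), c(i, j))
    newd <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D <- rbind(cbind(D[others, others, drop = FALSE], newd),
               c(newd, 0))
    frag <- c(frag[others], newfrag)
  }
  # Final three nodes joined at the central unrooted node.
  v1 <- bl((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  v2 <- bl((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  v3 <- bl((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  if (clamped > 0)
    message(sprintf("nj_tree: clamped %.4g of negative branch length to 0",
                    clamped))
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 frag[1], v1, frag[2], v2, frag[3], v3)
  ape::read.tree(text = nwk)
}

#' Concatenate per-gene alignments
#'
#' Rows are joined in the given order (by convention C, A, B for xmoCAB)
#' over the taxa shared by all parts. Taxa whose concatenated row has fewer
#' than `min_len` non-gap residues are dropped, one `message()` per drop —
#' mirroring a minimum-information filter for concatenated-operon trees.
#'
#' @param parts List of [aa_alignment()] objects.
#' @param min_len Minimum non-gap residues to keep a taxon (default 910).
#' @return An [aa_alignment()].
#' @export
concat_alignment <- function(parts, min_len = 910L) {
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, TRUE, "aa_alignment")))
  shared <- Reduce(intersect, lapply(parts, names))
  if (length(shared) == 0L) stop("no taxa shared by all alignment parts")
  rows <- vapply(shared, function(nm) {
    paste(vapply(parts, function(p) unclass(p)[[nm]], ""), collapse = "")
  }, "")
  nongap <- nchar(gsub("[-.]", "", rows))
  drop <- nongap < min_len
  for (nm in names(rows)[drop])
    message("concat_alignment: dropping ", nm, " (", nongap[nm],
            " non-gap residues < ", min_len, ")")
  if (all(drop)) stop("all taxa fall below min_len = ", min_len)
  aa_alignment(rows[!drop])
}

# Canonical representation of each non-trivial split of an unrooted tree:
# the side of the bipartition not containing the alphabetically first leaf,
# serialized as a sorted, comma-joined string.
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  pp <- ape::prop.part(tree)
  splits <- character()
  for (i in seq_along(pp)) {
    tips <- tree$tip.label[pp[[i]]]
    if (length(tips) <= 1L || length(tips) >= n - 1L) next
    side <- if (anchor %in% tips) setdiff(tree$tip.label, tips) else tips
    if (length(side) <= 1L || length(side) >= n - 1L) next
    splits <- c(splits, paste(sort(side), collapse = ","))
  }
  unique(splits)
}

#' Robinson-Foulds incongruence between two gene trees
#'
#' Both trees are pruned to their shared leaf set; the RF distance is the
#' size of the symmetric difference of their non-trivial splits, normalized
#' by the maximum `2 * (n - 3)` for `n` shared leaves. Splits present in
#' exactly one tree are listed, so a topology conflict can be traced to the
#' clade that moved.
#'
#' @param t1,t2 `phylo` trees.
#' @return An `incongruence_report`: list with `n_shared`, `rf`,
#'   `rf_normalized`, `discordant_splits`.
#' @export
rf_distance <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L)
    stop("need >= 4 shared leaves for a non-trivial comparison")
  t1 <- ape::keep.tip(t1, shared)
  t2 <- ape::keep.tip(t2, shared)
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  disc <- c(setdiff(s1, s2), setdiff(s2, s1))
  n <- length(shared)
  structure(list(n_shared = n, rf = length(disc),
                 rf_normalized = if (n > 3L) length(disc) / (2 * (n - 3L)) else 0,
                 discordant_splits = disc),
            class = "incongruence_report")
}

#' @export
print.incongruence_report <- function(x, ...) {
  cat(sprintf("<incongruence_report> %d shared leaves: RF = %d (normalized %.3f)\n",
              x$n_shared, x$rf, x$rf_normalized))
  if (length(x$discordant_splits))
    cat("  discordant splits:\n",
        paste0("   {", x$discordant_splits, "}\n"), sep = "")
  invisible(x)
}

#' Pairwise incongruence table for a set of gene trees
#'
#' @param trees Named list of `phylo` trees.
#' @return Data frame: `gene1`, `gene2`, `n_shared`, `rf`, `rf_normalized`.
#' @export
incongruence_table <- function(trees) {
  stopifnot(length(trees) >= 2L, !is.null(names(trees)))
  nm <- names(trees)
  rows <- list()
  for (i in seq_len(length(trees) - 1L)) {
    for (j in (i + 1L):length(trees)) {
      r <- rf_distance(trees[[i]], trees[[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        gene1 = nm[i], gene2 = nm[j], n_shared = r$n_shared, rf = r$rf,
        rf_normalized = r$rf_normalized, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Root-to-tip rate ratio for a focal clade
#'
#' A light-weight clock-violation contrast: the tree is rooted on the named
#' outgroup, and the ratio of the mean root-to-tip path length over the
#' focal leaves to the mean over the background leaves (everything that is
#' neither focal nor outgroup) is reported. On a clock-like (ultrametric)
#' tree the ratio is 1; a lineage whose branches evolved `m` times faster
#' over essentially its whole root-to-tip path shows a ratio near `m`.
#'
#' @param tree A `phylo` tree containing `focal` and `outgroup` leaves.
#' @param focal Character vector of focal-clade leaf names.
#' @param outgroup Character vector of outgroup leaf names.
#' @return A `rate_report`: list with `rate_ratio`, `focal_mean`,
#'   `background_mean`, `focal`, `outgroup`.
#' @export
rate_ratio <- function(tree, focal, outgroup) {
  stopifnot(all(focal %in% tree$tip.label),
            all(outgroup %in% tree$tip.label))
  background <- setdiff(tree$tip.label, c(focal, outgroup))
  if (length(background) == 0L) stop("no background leaves left")
  if (setequal(focal, tree$tip.label)) stop("focal set is the whole tree")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  depth <- ape::node.depth.edgelength(rooted)
  names(depth)[seq_along(rooted$tip.label)] <- rooted$tip.label
  fm <- mean(depth[focal])
  bm <- mean(depth[background])
  if (bm <= 0) stop("zero background root-to-tip mean")
  structure(list(rate_ratio = fm / bm, focal_mean = fm,
                 background_mean = bm, focal = focal, outgroup = outgroup),
            class = "rate_report")
}

#' @export
print.rate_report <- function(x, ...) {
  cat(sprintf(
    "<rate_report> focal/background root-to-tip ratio = %.3f (%.4f / %.4f)\n",
    x$rate_ratio, x$focal_mean, x$background_mean))
  invisible(x)
}
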