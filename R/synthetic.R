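#' Markov sequence model
#'
#' An order-`k` Markov chain over `{A,C,G,T}` used as a compositional
#' signature for synthetic host genomes and donor inserts. `probs` is a
#' matrix with one row per conditioning `k`-mer (lexicographic; a single
#' row for order 0) and columns `A`, `C`, `G`, `T`, each row summing to 1.
#'
#' @param order Integer >= 0.
#' @param probs Row-stochastic matrix of conditional base probabilities.
#' @param label Model label recorded in ground truth.
#' @return A `markov_model`.
#' @seealso [gc_model()] for the common order-0 GC-content parameterization.
#' @export
markov_model <- function(order, probs, label = "model") {
  probs <- as.matrix(probs)
  stopifnot(order >= 0, ncol(probs) == 4L, nrow(probs) == 4^order)
  if (any(abs(rowSums(probs) - 1) > 1e-12))
    stop("each conditional distribution must sum to 1")
  colnames(probs) <- c("A", "C", "G", "T")
  rownames(probs) <- if (order == 0) "" else
    mkAllStrings(c("A", "C", "G", "T"), order)
  structure(list(order = as.integer(order), probs = probs, label = label),
            class = "markov_model")
}

mkAllStrings <- function(alpha, k) {
  out <- ""
  for (i in seq_len(k)) out <- as.vector(outer(out, alpha, paste0))
  sort(out)
}

#' Order-0 model from a GC content
#'
#' Bases are i.i.d. with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1-gc)/2`.
#'
#' @param gc GC fraction in (0, 1).
#' @param label Model label.
#' @return A `markov_model` of order 0.
#' @export
gc_model <- function(gc, label = sprintf("gc%.0f", 100 * gc)) {
  stopifnot(gc > 0, gc < 1)
  markov_model(0L, matrix(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2),
                          nrow = 1), label = label)
}

#' Sample a genome from a Markov model
#'
#' Deterministic given `seed`. The first `order` bases are drawn from the
#' marginal base composition of the model.
#'
#' @param model A [markov_model()].
#' @param length Sequence length, greater than the model order.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param id Genome id for the returned record.
#' @return A [genome_record()].
#' @export
gen_genome <- function(model, length, seed = NULL, id = model$label) {
  stopifnot(inherits(model, "markov_model"), length > model$order)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    if (model$order == 0L) {
      s <- sample(bases, length, replace = TRUE, prob = model$probs[1, ])
    } else {
      marginal <- colMeans(model$probs)
      s <- character(length)
      s[seq_len(model$order)] <- sample(bases, model$order, replace = TRUE,
                                        prob = marginal)
      for (i in (model$order + 1L):length) {
        ctx <- paste(s[(i - model$order):(i - 1L)], collapse = "")
        s[i] <- sample(bases, 1L, prob = model$probs[ctx, ])
      }
    }
    genome_record(id, paste(s, collapse = ""))
  })
}

#' Codon usage table from an order-0 base model
#'
#' Codon probabilities proportional to the product of base probabilities,
#' with the three stop codons removed and the rest renormalized — a simple
#' way to give donor and host coding sequences distinct codon biases that
#' track their GC contents.
#'
#' @param gc GC fraction.
#' @return Named numeric vector over the 61 sense codons, summing to 1.
#' @export
gc_codon_usage <- function(gc) {
  base_p <- setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2),
                     c("A", "C", "G", "T"))
  codons <- mkAllStrings(c("A", "C", "G", "T"), 3)
  p <- vapply(codons, function(cd) {
    prod(base_p[strsplit(cd, "")[[1]]])
  }, 0)
  p <- p[!names(p) %in% c("TAA", "TAG", "TGA")]
  p / sum(p)
}

#' Generate a coding sequence with a given codon usage
#'
#' Codons are drawn i.i.d. from `usage` and a single terminal stop (`TAA`)
#' is appended, so the result has length `3 * n_codons + 3`. `usage` must
#' put no mass on stop codons (internal stops are not modelled).
#'
#' @param usage Named probability vector over sense codons.
#' @param n_codons Number of sense codons to draw.
#' @param seed Integer seed or `NULL`.
#' @return A DNA string.
#' @export
gen_codon_cds <- function(usage, n_codons, seed = NULL) {
  stopifnot(n_codons >= 1L, abs(sum(usage) - 1) < 1e-9)
  if (any(names(usage) %in% c("TAA", "TAG", "TGA") & usage > 0))
    stop("usage puts mass on stop codons; supply sense-codon usage only")
  with_seed(seed, {
    paste(c(sample(names(usage), n_codons, replace = TRUE, prob = usage),
            "TAA"), collapse = "")
  })
}

#' Generate an operon-sized donor insert
#'
#' Emits one synthetic three-gene operon: a spanning sequence whose length
#' is drawn from `Normal(length_mean, length_sd)` truncated at >= 1500 nt,
#' containing three same-strand genes labelled `xmoC`, `xmoA`, `xmoB` (CAB
#' order by default, ABC for the pxm-like arrangement) with CDS lengths that
#' are multiples of 3, separated by short intergenic spacers drawn from the
#' donor model. Gene bodies are drawn from `usage` when given (codon-biased
#' coding sequence) and from the donor model otherwise.
#'
#' @param donor A [markov_model()] for the donor compositional signature.
#' @param length_mean,length_sd Spanning-length distribution in nt
#'   (defaults 2730 and 300, the typical xmoCAB operon scale).
#' @param seed Integer seed or `NULL`.
#' @param order `"CAB"` or `"ABC"` gene arrangement.
#' @param usage Optional sense-codon usage for the gene bodies.
#' @return List with `sequence`, `genes` (data frame of relative 0-based
#'   half-open coordinates with labels), `order_tag`, `donor_label`.
#' @export
gen_operon_insert <- function(donor, length_mean = 2730, length_sd = 300,
                              seed = NULL, order = c("CAB", "ABC"),
                              usage = NULL) {
  order <- match.arg(order)
  stopifnot(inherits(donor, "markov_model"), length_mean > 3 * 300,
            length_sd >= 0)
  with_seed(seed, {
    span <- max(1500L, as.integer(round(rnorm(1, length_mean, length_sd))))
    gap <- 15L
    coding <- span - 2L * gap
    # Gene-length proportions echo typical xmoC/xmoA/xmoB sizes.
    frac <- c(0.28, 0.27, 0.45)
    lens <- 3L * as.integer(round(coding * frac / 3))
    lens[3] <- coding - lens[1] - lens[2]
    lens[3] <- lens[3] - (lens[3] %% 3L)
    labels <- if (order == "CAB") c("xmoC", "xmoA", "xmoB") else
      c("xmoA", "xmoB", "xmoC")
    draw_gene <- function(len) {
      if (!is.null(usage)) {
        s <- gen_codon_cds(usage, len %/% 3L - 1L)
        substr(s, 1L, len)
      } else {
        gen_genome(donor, len)$sequence
      }
    }
    pieces <- character(5)
    starts <- integer(3); ends <- integer(3)
    pos <- 0L
    for (g in 1:3) {
      pieces[2 * g - 1] <- draw_gene(lens[g])
      starts[g] <- pos
      ends[g] <- pos + lens[g]
      pos <- pos + lens[g]
      if (g < 3) {
        pieces[2 * g] <- gen_genome(donor, gap)$sequence
        pos <- pos + gap
      }
    }
    seqn <- paste(pieces[nzchar(pieces)], collapse = "")
    list(sequence = seqn,
         genes = data.frame(label = labels, start = starts, end = ends,
                            strand = "+", stringsAsFactors = FALSE),
         order_tag = order, donor_label = donor$label)
  })
}

#' Implant donor inserts into a host genome
#'
#' Inserts are placed at uniform-random positions at least `min_gap` apart
#' (and from the genome ends), host bases are conserved unedited, existing
#' host features are coordinate-shifted, and the ground truth (final insert
#' intervals, donor labels, seed) is recorded.
#'
#' @param host A [genome_record()].
#' @param inserts List of [gen_operon_insert()] results (or plain DNA
#'   strings).
#' @param seed Integer seed or `NULL`.
#' @param min_gap Minimum distance between insertion points in bp.
#' @return List with `genome` (new [genome_record()] carrying the operon
#'   CDS features), `loci` (list of [operon_locus()] for the implanted
#'   operons), and `truth` (data frame `start`, `end`, `operon_id`,
#'   `donor`, plus the seed as an attribute).
#' @export
implant <- function(host, inserts, seed = NULL, min_gap = 5000L) {
  stopifnot(inherits(host, "genome_record"), length(inserts) >= 1L)
  ins_seq <- lapply(inserts, function(x) if (is.character(x)) x else x$sequence)
  total_len <- sum(nchar(unlist(ins_seq)))
  if (total_len >= host$length / 10)
    stop("total insert length must stay below a tenth of the host")
  with_seed(seed, {
    k <- length(inserts)
    pts <- NULL
    for (try in 1:1000) {
      cand <- sort(sample(seq(min_gap, host$length - min_gap), k))
      if (k == 1L || all(diff(cand) >= min_gap)) { pts <- cand; break }
    }
    if (is.null(pts)) stop("cannot satisfy insert spacing of ", min_gap, " bp")

    pieces <- character(2 * k + 1)
    prev <- 0L
    shift <- 0L
    truth <- list(); loci <- list(); feats <- list()
    for (i in seq_len(k)) {
      pieces[2 * i - 1] <- substr(host$sequence, prev + 1L, pts[i])
      pieces[2 * i] <- ins_seq[[i]]
      ins_start <- pts[i] + shift
      ins_end <- ins_start + nchar(ins_seq[[i]])
      operon_id <- sprintf("implant_%d", i)
      truth[[i]] <- data.frame(start = ins_start, end = ins_end,
                               operon_id = operon_id,
                               donor = if (is.character(inserts[[i]]))
                                 "raw" else inserts[[i]]$donor_label,
                               stringsAsFactors = FALSE)
      if (!is.character(inserts[[i]])) {
        g <- inserts[[i]]$genes
        g$start <- g$start + ins_start
        g$end <- g$end + ins_start
        loci[[length(loci) + 1L]] <- operon_locus(host$id, operon_id, g)
        feats[[length(feats) + 1L]] <- data.frame(
          gene_id = paste0(operon_id, "_", g$label), start = g$start,
          end = g$end, strand = g$strand, phase = 0L,
          stringsAsFactors = FALSE)
      }
      shift <- shift + nchar(ins_seq[[i]])
      prev <- pts[i]
    }
    pieces[2 * k + 1] <- substr(host$sequence, prev + 1L, host$length)
    features <- host$features
    if (nrow(features)) {
      # Shift host features lying at/after each original insertion point.
      features$shift <- vapply(features$start, function(s)
        sum(nchar(unlist(ins_seq))[pts <= s]), 0)
      features$start <- features$start + features$shift
      features$end <- features$end + features$shift
      features$shift <- NULL
    }
    if (length(feats)) features <- rbind(features, do.call(rbind, feats))
    genome <- genome_record(host$id, paste(pieces, collapse = ""),
                            topology = host$topology, features = features)
    truth <- do.call(rbind, truth)
    attr(truth, "seed") <- seed
    list(genome = genome, loci = loci, truth = truth)
  })
}

#' Default 12-taxon base tree for gene-family simulation
#'
#' A rooted, clock-like (ultrametric ingroup) binary tree: one outgroup
#' (`og`), a 3-leaf focal clade (`op3a`, `op3b`, `op3c`) emulating a third
#' operon copy, and 8 background taxa. All internal ingroup branches are
#' at least 0.05 expected substitutions/site, so neighbor joining on
#' 500-site alignments recovers the topology reliably.
#'
#' @return A `phylo` tree.
#' @export
default_gene_tree <- function() {
  ape::read.tree(text = paste0(
    "(og:0.40,(((op3a:0.1,op3b:0.1):0.1,op3c:0.2):0.15,",
    "(((t1:0.1,t2:0.1):0.1,(t3:0.1,t4:0.1):0.1):0.1,",
    "((t5:0.1,t6:0.1):0.1,(t7:0.1,t8:0.1):0.1):0.1):0.05):0.02);"))
}

#' Leaves of the default focal clade
#' @return Character vector `c("op3a", "op3b", "op3c")`.
#' @export
default_focal_clade <- function() c("op3a", "op3b", "op3c")

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Evolve one ungapped amino-acid alignment along a rooted tree under the
# Poisson model: per site, substitution events arrive at rate = branch
# length; each event jumps to one of the 19 other residues uniformly.
# The jump chain is implemented as addition mod 20 of uniform{1..19}
# increments, which is exactly uniform over the other 19 states.
evolve_alignment <- function(tree, seq_len) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample.int(20L, seq_len, replace = TRUE)
  tree <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    b <- tree$edge.length[e]
    s <- seqs[[parent]]
    nev <- rpois(seq_len, b)
    hit <- which(nev > 0L)
    if (length(hit)) {
      jumps <- sample.int(19L, sum(nev[hit]), replace = TRUE)
      shift <- rowsum(jumps, rep(hit, nev[hit]))[, 1]
      s[hit] <- (s[hit] - 1L + shift) %% 20L + 1L
    }
    seqs[[child]] <- s
  }
  rows <- vapply(seq_len(ntip), function(i)
    paste(AA_LETTERS[seqs[[i]]], collapse = ""), "")
  aa_alignment(setNames(rows, tree$tip.label))
}

# Regraft the named clade: prune it and re-attach its stem halfway along
# the edge above `attach_leaf`.
regraft_clade <- function(tree, clade, attach_leaf) {
  if (attach_leaf %in% clade)
    stop("regraft target lies inside the clade being moved")
  mrca <- ape::getMRCA(tree, clade)
  sub <- ape::extract.clade(tree, mrca)
  stem_edge <- which(tree$edge[, 2] == mrca)
  sub$root.edge <- tree$edge.length[stem_edge]
  rest <- ape::drop.tip(tree, clade)
  tip <- which(rest$tip.label == attach_leaf)
  edge <- which(rest$edge[, 2] == tip)
  ape::bind.tree(rest, sub, where = tip,
                 position = rest$edge.length[edge] / 2)
}

# Multiply branch lengths of the subtree rooted at the clade MRCA,
# including its stem branch.
scale_clade <- function(tree, clade, multiplier) {
  if (multiplier <= 0) stop("rate multiplier must be positive")
  mrca <- ape::getMRCA(tree, clade)
  inside <- c(mrca, phangorn_descendants(tree, mrca))
  sel <- tree$edge[, 2] %in% inside
  tree$edge.length[sel] <- tree$edge.length[sel] * multiplier
  tree
}

# All descendant node ids of `node` (tips and internals), without
# depending on phangorn.
phangorn_descendants <- function(tree, node) {
  out <- integer(0)
  stack <- tree$edge[tree$edge[, 1] == node, 2]
  while (length(stack)) {
    out <- c(out, stack)
    stack <- tree$edge[tree$edge[, 1] %in% stack, 2]
  }
  out
}

#' Simulate gene families on a known tree
#'
#' Evolves `n_genes` ungapped amino-acid alignments along `base_tree` under
#' the Poisson substitution model. A gene listed in `swap` evolves instead
#' on a tree where the named clade is pruned and regrafted above
#' `attach`; a gene listed in `rate` has branch lengths within the named
#' clade (stem included) multiplied by `m`. Both perturbations are the
#' synthetic analogs of a laterally transferred operon gene and an
#' accelerated operon copy.
#'
#' @param base_tree Rooted binary `phylo` with branch lengths (default
#'   [default_gene_tree()]).
#' @param n_genes Number of gene families (default 3).
#' @param swap Named list, e.g. `list("2" = list(clade = ..., attach =
#'   "t1"))`, keyed by gene index.
#' @param rate Named list, e.g. `list("3" = list(clade = ..., m = 3.46))`,
#'   keyed by gene index.
#' @param seq_len Alignment length in sites (default 500).
#' @param seed Integer seed or `NULL`.
#' @return List with `alignments` (list of [aa_alignment()]), `trees_used`
#'   (the per-gene true trees), and `truth` (swap flags and multipliers).
#' @export
sim_gene_families <- function(base_tree = default_gene_tree(),
                              n_genes = 3L, swap = list(), rate = list(),
                              seq_len = 500L, seed = NULL) {
  stopifnot(ape::is.rooted(base_tree), ape::is.binary(base_tree),
            !is.null(base_tree$edge.length))
  with_seed(seed, {
    alignments <- list(); trees_used <- list()
    topology_swap <- logical(n_genes)
    rate_multiplier <- rep(1, n_genes)
    for (g in seq_len(n_genes)) {
      tr <- base_tree
      key <- as.character(g)
      if (!is.null(swap[[key]])) {
        tr <- regraft_clade(tr, swap[[key]]$clade, swap[[key]]$attach)
        topology_swap[g] <- TRUE
      }
      if (!is.null(rate[[key]])) {
        tr <- scale_clade(tr, rate[[key]]$clade, rate[[key]]$m)
        rate_multiplier[g] <- rate[[key]]$m
      }
      trees_used[[g]] <- tr
      alignments[[g]] <- evolve_alignment(tr, seq_len)
    }
    names(alignments) <- names(trees_used) <- paste0("gene", seq_len(n_genes))
    list(alignments = alignments, trees_used = trees_used,
         truth = list(topology_swap = topology_swap,
                      rate_multiplier = rate_multiplier, seed = seed,
                      seq_len = seq_len))
  })
}

#' Generate a complete named scenario with ground truth
#'
#' Three study conditions, each emitting every input its pipeline stage
#' needs plus a truth record:
#' \describe{
#'   \item{`lgt`}{200-kb host genome (GC 40\%) with two implanted donor
#'     operons (GC 60\%, codon-biased CDS) and two matched native operon
#'     loci carved from host sequence.}
#'   \item{`incongruence`}{Three simulated gene families; gene 2 evolves
#'     with the focal clade regrafted (the swapped-topology pattern).}
#'   \item{`rates`}{Three gene families; gene 3 has the focal clade's
#'     branch lengths multiplied by 3.46 (an accelerated third operon
#'     copy).}
#' }
#'
#' @param scenario One of `"lgt"`, `"incongruence"`, `"rates"`.
#' @param seed Integer seed.
#' @param host_gc,donor_gc GC contents for the `lgt` scenario.
#' @param host_length Host genome length in bp for `lgt`.
#' @param out Optional directory: when given, the scenario's files (FASTA,
#'   loci TSV, aligned FASTA, truth JSON) are written there.
#' @return Scenario-specific list including a `truth` element.
#' @export
simulate_scenario <- function(scenario = c("lgt", "incongruence", "rates"),
                              seed = 42L, host_gc = 0.4, donor_gc = 0.6,
                              host_length = 200000L, out = NULL) {
  scenario <- match.arg(scenario)
  res <- switch(scenario,
    lgt = {
      host <- gen_genome(gc_model(host_gc, "host"), host_length,
                         seed = child_seed(seed, 1), id = "synthetic_host")
      usage <- gc_codon_usage(donor_gc)
      ins <- lapply(1:2, function(i)
        gen_operon_insert(gc_model(donor_gc, "donor"),
                          seed = child_seed(seed, 1 + i), usage = usage))
      imp <- implant(host, ins, seed = child_seed(seed, 4))
      # Two matched native loci: operon-shaped slices of host background,
      # placed away from the implants.
      nat <- native_loci(imp$genome, imp$truth, n = 2,
                         seed = child_seed(seed, 5))
      # Background coding genes so the genome codon profile is dominated
      # by host usage, as in a real genome.
      genome <- background_cds(nat$genome, imp$truth,
                               seed = child_seed(seed, 6))
      list(genome = genome, loci = c(imp$loci, nat$loci),
           truth = imp$truth)
    },
    incongruence = sim_gene_families(
      swap = list("2" = list(clade = default_focal_clade(), attach = "t1")),
      seed = child_seed(seed, 11)),
    rates = sim_gene_families(
      rate = list("3" = list(clade = default_focal_clade(), m = 3.46)),
      seed = child_seed(seed, 12)))
  if (!is.null(out)) write_scenario(res, scenario, out)
  res
}

# Carve native operon-shaped loci out of host background, >= 5 kb away
# from any true insert, and register their CDS on the genome record.
native_loci <- function(genome, truth, n = 2, seed = NULL,
                        span = 2730L) {
  with_seed(seed, {
    taken <- truth[, c("start", "end")]
    loci <- list(); feats <- list()
    tries <- 0L
    while (length(loci) < n && tries < 1000L) {
      tries <- tries + 1L
      s <- sample(seq(1000L, genome$length - span - 1000L), 1L)
      ok <- all(pmin(taken$end + 5000L, genome$length) <= s |
                  taken$start - 5000L >= s + span)
      if (!ok) next
      lens <- c(756L, 738L, span - 30L - 756L - 738L)
      lens[3] <- lens[3] - lens[3] %% 3L
      starts <- s + c(0L, lens[1] + 15L, lens[1] + lens[2] + 30L)
      id <- sprintf("native_%d", length(loci) + 1L)
      g <- data.frame(label = c("xmoC", "xmoA", "xmoB"),
                      start = starts, end = starts + lens, strand = "+",
                      stringsAsFactors = FALSE)
      loci[[length(loci) + 1L]] <- operon_locus(genome$id, id, g)
      feats[[length(feats) + 1L]] <- data.frame(
        gene_id = paste0(id, "_", g$label), start = g$start, end = g$end,
        strand = "+", phase = 0L, stringsAsFactors = FALSE)
      taken <- rbind(taken, data.frame(start = s, end = s + span))
    }
    if (length(loci) < n) stop("could not place native loci")
    genome$features <- rbind(genome$features, do.call(rbind, feats))
    list(genome = genome, loci = loci)
  })
}

# Annotate n background CDS on host sequence (in-frame slices of the host
# background, away from the implanted inserts) so genome-wide codon usage
# reflects the host signature.
background_cds <- function(genome, truth, n = 150L, len = 900L,
                           seed = NULL) {
  with_seed(seed, {
    feats <- list()
    tries <- 0L
    while (length(feats) < n && tries < 20L * n) {
      tries <- tries + 1L
      s <- sample(seq(100L, genome$length - len - 100L), 1L)
      if (any(truth$start < s + len & s < truth$end)) next
      feats[[length(feats) + 1L]] <- data.frame(
        gene_id = sprintf("bg_%04d", length(feats) + 1L), start = s,
        end = s + len, strand = if (stats::runif(1) < 0.5) "+" else "-",
        phase = 0L, stringsAsFactors = FALSE)
    }
    genome$features <- rbind(genome$features, do.call(rbind, feats))
    genome
  })
}

write_scenario <- function(res, scenario, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (scenario == "lgt") {
    write_fasta(res$genome, file.path(out, "genome.fasta"))
    write_loci_tsv(res$loci, file.path(out, "loci.tsv"))
    jsonlite::write_json(res$truth, file.path(out, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  } else {
    for (nm in names(res$alignments))
      write_alignment(res$alignments[[nm]],
                      file.path(out, paste0(nm, ".afa")))
    for (nm in names(res$trees_used))
      ape::write.tree(res$trees_used[[nm]],
                      file.path(out, paste0(nm, "_true.nwk")))
    jsonlite::write_json(res$truth, file.path(out, "truth.json"),
                         auto_unbox = TRUE)
  }
  invisible(out)
}
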