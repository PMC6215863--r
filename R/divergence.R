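#' Kullback-Leibler divergence of a region's composition from its genome
#'
#' The core statistic: with `p` the smoothed frequency vector of the region
#' and `q` that of the genome over the same alphabet,
#' `D_KL(region || genome) = sum_i p_i * ln(p_i / q_i)` in nats. Both
#' profiles get a Laplace pseudocount added to every category's count before
#' renormalization, so the divergence is always finite even when a genome
#' category is absent from a short operon. A bounded normalized score
#' `score01 = 1 - exp(-KL)` in `[0, 1)` is attached: 0 means identical
#' composition, values near 1 mean strongly foreign composition.
#'
#' @param region,genome `composition_profile` objects over the same
#'   alphabet.
#' @param pseudocount Positive count added to every category (default 1).
#' @param method Tag recorded on the result (`"tetra"`, `"codon"`,
#'   `"window"`, or any label).
#' @return A `divergence_result` with fields `region_id`, `genome_id`,
#'   `method`, `kl_nats` and `score01`.
#' @examples
#' p <- kmer_profile("ACGTACGTAA", k = 2)
#' kl_divergence(p, p)$kl_nats  # 0
#' @export
kl_divergence <- function(region, genome, pseudocount = 1, method = NULL) {
  stopifnot(inherits(region, "composition_profile"),
            inherits(genome, "composition_profile"))
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (region$alphabet_kind != genome$alphabet_kind ||
      !identical(region$categories, genome$categories))
    stop("alphabet mismatch between region and genome profiles")
  kl <- kl_from_counts(region$counts, genome$counts, pseudocount)
  structure(list(region_id = region$source_id, genome_id = genome$source_id,
                 method = method %||%
                   switch(region$alphabet_kind, kmer4 = "tetra",
                          codon = "codon", region$alphabet_kind),
                 kl_nats = kl, score01 = 1 - exp(-kl)),
            class = "divergence_result")
}

# Smoothed KL in nats from raw count vectors. Zero-probability region terms
# cannot arise after smoothing, but the p>0 guard keeps the formula honest.
kl_from_counts <- function(region_counts, genome_counts, pseudocount) {
  p <- region_counts + pseudocount
  q <- genome_counts + pseudocount
  p <- p / sum(p)
  q <- q / sum(q)
  keep <- p > 0
  sum(p[keep] * log(p[keep] / q[keep]))
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("<divergence_result> %s vs %s [%s]: KL = %.4f nats, score01 = %.4f\n",
              x$region_id, x$genome_id, x$method, x$kl_nats, x$score01))
  invisible(x)
}

#' Operon-versus-genome divergence table
#'
#' For each operon locus computes the KL divergence of the operon's
#' composition against the whole genome's (the genome profile includes the
#' operon; no leave-one-out). The `tetra` method profiles the spanning
#' operon sequence with reverse-complement extension; the `codon` method
#' profiles the operon's concatenated coding sequences against the codon
#' usage of all annotated CDS in the genome.
#'
#' @param genomes Named list of [genome_record()] objects.
#' @param loci List of [operon_locus()] objects.
#' @param methods Character subset of `c("tetra", "codon")`.
#' @param pseudocount Laplace smoothing count (see [kl_divergence()]).
#' @return Data frame with columns `genome_id`, `operon_id`, `method`,
#'   `kl_nats`, `score01`, ordered by those keys.
#' @export
operon_kl_table <- function(genomes, loci, methods = c("tetra", "codon"),
                            pseudocount = 1) {
  stopifnot(all(methods %in% c("tetra", "codon")))
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  if (is.null(names(genomes)) || !all(nzchar(names(genomes))))
    names(genomes) <- vapply(genomes, `[[`, "", "id")
  rows <- list()
  genome_prof <- list()  # cache per (genome, method)
  for (locus in loci) {
    g <- genomes[[locus$genome_id]]
    if (is.null(g)) stop("locus '", locus$operon_id,
                         "' references unknown genome '", locus$genome_id, "'")
    for (m in methods) {
      key <- paste(locus$genome_id, m)
      if (is.null(genome_prof[[key]])) {
        genome_prof[[key]] <- if (m == "tetra") {
          kmer_profile(g$sequence, k = 4L, source_id = g$id,
                       source_kind = "genome")
        } else {
          if (nrow(g$features) == 0L)
            stop("codon method needs CDS features on genome '", g$id, "'")
          cds <- vapply(seq_len(nrow(g$features)), function(i) {
            f <- g$features[i, ]
            extract_region(g, f$start, f$end, f$strand)
          }, "")
          codon_profile(cds, source_id = g$id, source_kind = "genome")
        }
      }
      region_prof <- if (m == "tetra") {
        kmer_profile(operon_sequence(g, locus, "spanning"), k = 4L,
                     source_id = locus$operon_id)
      } else {
        codon_profile(operon_sequence(g, locus, "concatenated_cds"),
                      source_id = locus$operon_id)
      }
      d <- kl_divergence(region_prof, genome_prof[[key]],
                         pseudocount = pseudocount, method = m)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = locus$genome_id, operon_id = locus$operon_id,
        method = m, kl_nats = d$kl_nats, score01 = d$score01,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genome_id = character(), operon_id = character(),
               method = character(), kl_nats = numeric(),
               score01 = numeric(), stringsAsFactors = FALSE)
  out[order(out$genome_id, out$operon_id, out$method), , drop = FALSE]
}

#' Sliding-window compositional scan
#'
#' Slides a window (default 2500 bp, the classical alien-region window)
#' along the genome and, for each word size `k` in `k_range`, computes the
#' smoothed KL divergence of the window's k-mer profile against the whole
#' genome's. Per-window scores are combined over orders with geometrically
#' decaying weights `w_k` proportional to `4^-(k-2)` (normalized to sum 1):
#' higher orders carry more categories than a 2.5-kb window can estimate and
#' are down-weighted accordingly. A final partial window is kept when it is
#' at least half the window length.
#'
#' @param genome A [genome_record()].
#' @param window Window length in bp.
#' @param step Step between window starts (default `window / 5`).
#' @param k_range Integer vector of word sizes (default `2:8`).
#' @param pseudocount Laplace smoothing count.
#' @return An `alien_scan` object: data frame `windows` with columns
#'   `start`, `end`, `combined_kl` and one `kl_k<k>` column per order, plus
#'   scan metadata.
#' @export
window_scan <- function(genome, window = 2500L, step = NULL,
                        k_range = 2:8, pseudocount = 1) {
  stopifnot(inherits(genome, "genome_record"))
  step <- as.integer(step %||% max(1L, window %/% 5L))
  if (window > genome$length) stop("window longer than genome")
  if (step < 1L) stop("step must be >= 1")
  L <- genome$length
  starts <- seq(0L, max(0L, L - window), by = step)
  # Append a trailing partial window if >= window/2 of genome remains.
  last_end <- starts[length(starts)] + window
  if (last_end < L && (L - last_end) >= window / 2)
    starts <- c(starts, last_end)
  ends <- pmin(starts + window, L)

  gseq <- Biostrings::DNAString(genome$sequence)
  views <- Biostrings::Views(gseq, start = starts + 1L, end = ends)
  w <- 4^-(k_range - 2)
  w <- w / sum(w)
  per_k <- matrix(0, nrow = length(starts), ncol = length(k_range),
                  dimnames = list(NULL, paste0("kl_k", k_range)))
  for (j in seq_along(k_range)) {
    k <- k_range[j]
    gcounts <- Biostrings::oligonucleotideFrequency(gseq, width = k)
    q <- (gcounts + pseudocount) / sum(gcounts + pseudocount)
    wcounts <- Biostrings::oligonucleotideFrequency(views, width = k)
    P <- wcounts + pseudocount
    P <- P / rowSums(P)
    per_k[, j] <- rowSums(P * log(P)) - as.vector(P %*% log(q))
  }
  windows <- data.frame(start = starts, end = ends,
                        combined_kl = as.vector(per_k %*% w))
  windows <- cbind(windows, as.data.frame(per_k))
  structure(list(genome_id = genome$id, window = window, step = step,
                 k_range = k_range, weights = w, windows = windows),
            class = "alien_scan")
}

#' @export
print.alien_scan <- function(x, ...) {
  cat(sprintf(
    "<alien_scan> %s: %d windows of %d bp (step %d), k = %s\n",
    x$genome_id, nrow(x$windows), x$window, x$step,
    paste(range(x$k_range), collapse = "-")))
  cat(sprintf("  combined KL: median %.4f, max %.4f\n",
              stats::median(x$windows$combined_kl),
              max(x$windows$combined_kl)))
  invisible(x)
}

#' Plot a window scan
#'
#' Combined KL along the genome, with called regions shaded if supplied.
#'
#' @param x An `alien_scan`.
#' @param calls Optional data frame from [call_alien_regions()].
#' @param ... Passed to [plot()].
#' @export
plot.alien_scan <- function(x, calls = NULL, ...) {
  mid <- (x$windows$start + x$windows$end) / 2
  plot(mid, x$windows$combined_kl, type = "l",
       xlab = "genome position (bp)", ylab = "combined KL (nats)",
       main = paste("Compositional scan of", x$genome_id), ...)
  if (!is.null(calls) && nrow(calls)) {
    for (i in seq_len(nrow(calls)))
      graphics::rect(calls$start[i], 0, calls$end[i],
                     max(x$windows$combined_kl), border = NA,
                     col = grDevices::adjustcolor("red", 0.2))
    graphics::abline(h = calls$threshold[1], lty = 2, col = "red")
  }
  invisible(x)
}

#' Call compositionally alien regions from a window scan
#'
#' Splits the combined window scores into two groups by 1-D 2-means; the
#' threshold is the smallest score in the upper group, accepted only if the
#' upper group's mean exceeds the overall mean by more than two overall
#' standard deviations (an effect-size guard that suppresses calls on
#' homogeneous genomes). Contiguous or overlapping supra-threshold windows
#' are merged, and each merged call is annotated with the operon loci it
#' overlaps.
#'
#' @param scan An `alien_scan` from [window_scan()].
#' @param operons Optional list of [operon_locus()] objects for overlap
#'   annotation.
#' @return Data frame with columns `start`, `end`, `peak_score`,
#'   `threshold`, `overlapping_operons` (comma-separated ids); zero rows if
#'   nothing exceeds the guard.
#' @export
call_alien_regions <- function(scan, operons = list()) {
  stopifnot(inherits(scan, "alien_scan"))
  win <- scan$windows
  if (nrow(win) < 10L)
    stop("fewer than 10 windows; score the operon directly with ",
         "operon_kl_table()")
  s <- win$combined_kl
  empty <- data.frame(start = integer(), end = integer(),
                      peak_score = numeric(), threshold = numeric(),
                      overlapping_operons = character(),
                      stringsAsFactors = FALSE)
  if (max(s) - min(s) < .Machine$double.eps^0.5) return(empty)
  km <- kmeans(s, centers = matrix(c(min(s), max(s)), ncol = 1))
  upper <- which.max(km$centers)
  if (mean(s[km$cluster == upper]) <= mean(s) + 2 * sd(s)) return(empty)
  threshold <- min(s[km$cluster == upper])
  hot <- which(s >= threshold)
  # Merge overlapping/adjacent supra-threshold windows into calls.
  calls <- list()
  cur_s <- win$start[hot[1]]
  cur_e <- win$end[hot[1]]
  cur_p <- s[hot[1]]
  for (i in hot[-1]) {
    if (win$start[i] <= cur_e) {
      cur_e <- max(cur_e, win$end[i])
      cur_p <- max(cur_p, s[i])
    } else {
      calls[[length(calls) + 1L]] <- c(cur_s, cur_e, cur_p)
      cur_s <- win$start[i]; cur_e <- win$end[i]; cur_p <- s[i]
    }
  }
  calls[[length(calls) + 1L]] <- c(cur_s, cur_e, cur_p)
  out <- do.call(rbind, lapply(calls, function(v) {
    data.frame(start = as.integer(v[1]), end = as.integer(v[2]),
               peak_score = v[3], threshold = threshold,
               stringsAsFactors = FALSE)
  }))
  out$overlapping_operons <- vapply(seq_len(nrow(out)), function(i) {
    ids <- vapply(operons, function(l) {
      os <- min(l$genes$start); oe <- max(l$genes$end)
      if (min(out$end[i], oe) - max(out$start[i], os) > 0) l$operon_id else NA_character_
    }, "")
    paste(ids[!is.na(ids)], collapse = ",")
  }, "")
  out
}

#' Write alien-region calls as BED
#'
#' 0-based half-open intervals; the BED score column is `peak_score` mapped
#' through the bounded `1 - exp(-KL)` transform and scaled to 0-1000.
#'
#' @param calls Data frame from [call_alien_regions()].
#' @param genome_id Chromosome/genome name for column 1.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, genome_id, path) {
  bed <- data.frame(chrom = rep(genome_id, length.out = nrow(calls)),
                    start = calls$start, end = calls$end,
                    name = sprintf("alien_%d", seq_len(max(0L, nrow(calls)))),
                    score = round(1000 * (1 - exp(-calls$peak_score))))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
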