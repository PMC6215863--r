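#' Build a composition profile from raw counts
#'
#' A `composition_profile` is a normalized frequency vector over a fixed,
#' ordered alphabet: all `4^k` k-mers in lexicographic order, the 64
#' codons, or any user-defined category set. It carries raw counts
#' alongside frequencies; smoothing happens only in the divergence stage.
#' [kmer_profile()] and [codon_profile()] build profiles from sequence;
#' this constructor builds one from counts directly (e.g. for simulation
#' studies of the divergence statistic itself).
#'
#' @param counts Named non-negative numeric vector; names are the
#'   categories, in the order given.
#' @param alphabet_kind Label of the alphabet (e.g. `"kmer4"`, `"codon"`).
#' @param source_id,source_kind Provenance tags (`source_kind` is
#'   `"region"` or `"genome"`).
#' @return A `composition_profile`.
#' @export
composition_profile <- function(counts, alphabet_kind = "custom",
                                source_id = "profile",
                                source_kind = c("region", "genome")) {
  source_kind <- match.arg(source_kind)
  stopifnot(is.numeric(counts), !is.null(names(counts)),
            all(nzchar(names(counts))), all(counts >= 0))
  if (anyDuplicated(names(counts))) stop("duplicate category names")
  new_profile(alphabet_kind, counts, source_id, source_kind)
}

new_profile <- function(alphabet_kind, counts, source_id, source_kind) {
  total <- sum(counts)
  freqs <- if (total > 0) as.numeric(counts) / total
    else as.numeric(counts) * 0
  structure(list(alphabet_kind = alphabet_kind,
                 categories = names(counts),
                 counts = as.numeric(counts), frequencies = freqs,
                 total = total, source_id = source_id,
                 source_kind = source_kind),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile> %s of %s (%s): %d categories, %s counts\n",
              x$alphabet_kind, x$source_id, x$source_kind,
              length(x$categories), format(x$total, big.mark = ",")))
  invisible(x)
}

#' k-mer composition profile
#'
#' Counts every window of `k` consecutive unambiguous bases; windows
#' containing `N` or any other ambiguity code are skipped entirely. With
#' `revcomp_extend` (the default, matching tetranucleotide-signature
#' practice) the reverse complement is counted as a second independent
#' sequence — no junction windows are created — which makes the profile
#' exactly strand-symmetric.
#'
#' @param seq DNA string, or a character vector of sequences counted as one
#'   collection (no windows across sequence boundaries).
#' @param k Word length, 2 to 8. The default `k = 4` gives the 256
#'   tetranucleotide categories.
#' @param revcomp_extend Logical; also count the reverse complement.
#' @param source_id,source_kind Provenance tags carried on the profile.
#' @return A `composition_profile` with `4^k` categories in lexicographic
#'   order.
#' @examples
#' p <- kmer_profile("AAAA")
#' p$counts[p$categories %in% c("AAAA", "TTTT")]  # 1 1
#' @export
kmer_profile <- function(seq, k = 4L, revcomp_extend = TRUE,
                         source_id = "seq", source_kind = "region") {
  stopifnot(k >= 2L, k <= 8L, is.character(seq), length(seq) >= 1L)
  seq <- vapply(seq, normalize_dna, "", USE.NAMES = FALSE)
  x <- Biostrings::DNAStringSet(seq)
  counts <- colSums(Biostrings::oligonucleotideFrequency(x, width = k))
  if (revcomp_extend) {
    counts <- counts + colSums(Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(x), width = k))
  }
  if (sum(counts) == 0)
    stop("sequence too short/ambiguous for k = ", k)
  new_profile(paste0("kmer", k), counts, source_id, source_kind)
}

#' Codon usage profile
#'
#' Reads codons in frame from each coding sequence independently — never
#' across CDS boundaries. A trailing partial codon is dropped with a
#' warning. Frequencies are `count / total codons` over the 64 codons.
#'
#' @param cds_list Character vector or list of CDS DNA strings (frame 0;
#'   apply any phase offset before calling).
#' @param source_id,source_kind Provenance tags.
#' @return A `composition_profile` with 64 categories.
#' @examples
#' codon_profile("ATGAAATAA")$frequencies[c("ATG", "AAA", "TAA")]
#' @export
codon_profile <- function(cds_list, source_id = "cds",
                          source_kind = "region") {
  cds_list <- unlist(cds_list, use.names = FALSE)
  if (length(cds_list) == 0L) stop("empty CDS list")
  cds_list <- vapply(cds_list, normalize_dna, "", USE.NAMES = FALSE)
  if (any(nchar(cds_list) < 3L)) stop("CDS shorter than one codon")
  if (any(nchar(cds_list) %% 3L != 0L))
    warning("trailing partial codon(s) dropped from ",
            sum(nchar(cds_list) %% 3L != 0L), " CDS")
  x <- Biostrings::DNAStringSet(cds_list)
  counts <- colSums(Biostrings::oligonucleotideFrequency(x, width = 3L,
                                                         step = 3L))
  if (sum(counts) == 0) stop("no unambiguous codons in input")
  new_profile("codon", counts, source_id, source_kind)
}

#' Write a composition profile as TSV
#'
#' Columns: `category`, `count`, `frequency`.
#'
#' @param profile A `composition_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "composition_profile"))
  write.table(data.frame(category = profile$categories,
                         count = profile$counts,
                         frequency = profile$frequencies),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
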