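#' Genome records
#'
#' A `genome_record` holds one DNA sequence (uppercase `A`/`C`/`G`/`T`/`N`),
#' its declared topology, and any CDS features attached to it. It is the
#' container every downstream stage (composition profiling, window scanning,
#' operon extraction) consumes.
#'
#' @param id Single character identifier.
#' @param sequence DNA string; lowercase and `U` are normalized away.
#' @param topology `"linear"` (default) or `"circular"`. Circular topology is
#'   only honored when declared; coordinates may then wrap.
#' @param features A data frame of CDS features as produced by
#'   [cds_feature()]-style rows, or `NULL`.
#' @return An object of class `genome_record` with elements `id`, `sequence`,
#'   `topology`, `features` and `length`.
#' @examples
#' g <- genome_record("g1", "acgu")
#' g$sequence  # "ACGT"
#' @export
genome_record <- function(id, sequence, topology = c("linear", "circular"),
                          features = NULL) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_dna(sequence, what = id)
  if (nchar(sequence) < 1L) stop("genome '", id, "' has an empty sequence")
  if (is.null(features)) features <- empty_features()
  validate_features(features, nchar(sequence), id)
  structure(list(id = id, sequence = sequence, topology = topology,
                 features = features, length = nchar(sequence)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s nt (%s), %d CDS feature(s)\n",
              x$id, format(x$length, big.mark = ","), x$topology,
              nrow(x$features)))
  invisible(x)
}

# Uppercase, U->T; reject anything outside the IUPAC DNA alphabet, reporting
# the first offending position.
normalize_dna <- function(sequence, what = "sequence") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- chartr("U", "T", toupper(sequence))
  bad <- regexpr("[^ACGTNRYSWKMBDHV]", s)
  if (bad > 0L) {
    stop("non-IUPAC character '", substr(s, bad, bad), "' at position ", bad,
         " in ", what)
  }
  s
}

empty_features <- function() {
  data.frame(gene_id = character(), start = integer(), end = integer(),
             strand = character(), phase = integer(),
             stringsAsFactors = FALSE)
}

#' Build a CDS feature row
#'
#' Coordinates are 0-based half-open on the forward strand; `phase` is the
#' number of bases to skip before the first complete codon. A CDS whose
#' length (after phase) is not a multiple of 3 is allowed (truncated gene)
#' and flagged as truncated by downstream consumers.
#'
#' @param gene_id Character label.
#' @param start,end Integers, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @param phase 0, 1 or 2.
#' @return One-row data frame.
#' @export
cds_feature <- function(gene_id, start, end, strand = "+", phase = 0L) {
  stopifnot(end > start, start >= 0, strand %in% c("+", "-"),
            phase %in% 0:2)
  data.frame(gene_id = as.character(gene_id), start = as.integer(start),
             end = as.integer(end), strand = strand,
             phase = as.integer(phase), stringsAsFactors = FALSE)
}

validate_features <- function(features, genome_length, id) {
  if (nrow(features) == 0L) return(invisible(TRUE))
  stopifnot(all(c("gene_id", "start", "end", "strand") %in% names(features)))
  if (any(features$end <= features$start))
    stop("feature with end <= start in genome '", id, "'")
  if (any(features$start < 0L) || any(features$end > genome_length))
    stop("feature outside [0, ", genome_length, ") in genome '", id, "'")
  invisible(TRUE)
}

#' Read a multi-record FASTA file
#'
#' Sequences are uppercased with `U` converted to `T`; record ids are the
#' first whitespace-delimited token of each header. Duplicate ids, empty
#' records and non-IUPAC characters are rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named list of [genome_record()] objects, in file order.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  widths <- Biostrings::width(set)
  if (any(widths == 0L))
    stop("record(s) with no sequence: ",
         paste(ids[widths == 0L], collapse = ", "))
  recs <- lapply(seq_along(set), function(i) {
    genome_record(ids[i], as.character(set[[i]]))
  })
  names(recs) <- ids
  recs
}

#' Write genome records to FASTA
#'
#' @param records A `genome_record` or list of them.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "genome_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    s <- r$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read CDS features from a GenBank flat file
#'
#' Consumes only `CDS` feature lines and the `ORIGIN` sequence block.
#' 1-based inclusive GenBank coordinates become 0-based half-open;
#' `complement(...)` maps to strand `-`; `join(...)` spans are returned as
#' one feature row per span, sharing a `gene_id` so downstream extraction
#' concatenates them in order.
#'
#' @param path Path to a GenBank flat file with an ORIGIN sequence.
#' @return A [genome_record()] with `features` populated.
#' @export
read_genbank_cds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1])),
                                    "[ \t]+")[[1]][1] else basename(path)
  origin <- grep("^ORIGIN", lines)
  if (!length(origin)) stop("no ORIGIN sequence block in ", path)
  seq_lines <- lines[(origin[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  # Collect CDS location strings (which may continue over several lines).
  feat <- character()
  in_cds <- FALSE
  buf <- ""
  for (ln in lines[seq_len(origin[1] - 1L)]) {
    if (grepl("^ {5}CDS {2,}", ln)) {
      if (in_cds) feat <- c(feat, buf)
      in_cds <- TRUE
      buf <- trimws(sub("^ {5}CDS +", "", ln))
    } else if (in_cds) {
      if (grepl("^ {21}[^/]", ln) && !grepl("=", ln)) {
        buf <- paste0(buf, trimws(ln))
      } else {
        feat <- c(feat, buf)
        in_cds <- FALSE
      }
    }
  }
  if (in_cds) feat <- c(feat, buf)

  rows <- list()
  for (i in seq_along(feat)) {
    loc <- parse_genbank_location(feat[i])
    for (j in seq_len(nrow(loc$spans))) {
      rows[[length(rows) + 1L]] <- cds_feature(
        gene_id = sprintf("cds_%03d", i),
        start = loc$spans$start[j], end = loc$spans$end[j],
        strand = loc$strand)
    }
  }
  features <- if (length(rows)) do.call(rbind, rows) else empty_features()
  if (nrow(features) && any(features$end > nchar(sequence)))
    stop("CDS location beyond sequence bounds in ", path)
  genome_record(id, sequence, features = features)
}

# "complement(join(1..3,7..9))" etc. -> 0-based half-open spans + strand.
parse_genbank_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[ <>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)\\.\\.([0-9]+)$", parts))
  if (any(vapply(m, length, 1L) != 3L))
    stop("unparseable GenBank location: ", loc)
  start <- as.integer(vapply(m, `[`, "", 2L)) - 1L
  end <- as.integer(vapply(m, `[`, "", 3L))
  if (any(end <= start)) stop("invalid span in GenBank location: ", loc)
  list(spans = data.frame(start = start, end = end), strand = strand)
}

#' Extract a genomic interval as sequence
#'
#' Coordinates are 0-based half-open. On strand `-` the reverse complement is
#' returned. For a circular genome the interval may run past the end and wrap
#' around the origin.
#'
#' @param genome A [genome_record()].
#' @param start,end Interval bounds, `end > start`; for circular genomes
#'   `end` may exceed the genome length by at most one full wrap.
#' @param strand `"+"` or `"-"`.
#' @return A DNA string of length `end - start`.
#' @export
extract_region <- function(genome, start, end, strand = "+") {
  stopifnot(inherits(genome, "genome_record"), end > start, start >= 0,
            strand %in% c("+", "-"))
  L <- genome$length
  if (end > L) {
    if (genome$topology != "circular")
      stop("interval [", start, ", ", end, ") outside linear genome '",
           genome$id, "' of length ", L)
    if (end - start > L) stop("interval longer than circular genome")
    s <- paste0(substr(genome$sequence, start + 1L, L),
                substr(genome$sequence, 1L, end - L))
  } else {
    s <- substr(genome$sequence, start + 1L, end)
  }
  if (strand == "-") revcomp(s) else s
}

#' Define an operon locus
#'
#' An ordered set of gene features (labels `xmoC`, `xmoA`, `xmoB`) on one
#' genome. The `order_tag` records whether the labels run CAB (the common
#' arrangement), ABC (the pxm arrangement) or otherwise along the coding
#' strand, and is checked against the supplied coordinates.
#'
#' @param genome_id,operon_id Identifiers.
#' @param genes Data frame with columns `label`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @return An `operon_locus` object.
#' @export
operon_locus <- function(genome_id, operon_id, genes) {
  stopifnot(all(c("label", "start", "end", "strand") %in% names(genes)))
  genes <- genes[order(genes$start), , drop = FALSE]
  if (nrow(genes) >= 2L &&
      any(genes$start[-1L] < genes$end[-nrow(genes)]))
    stop("overlapping gene intervals in operon '", operon_id, "'")
  order_tag <- infer_order_tag(genes)
  structure(list(genome_id = genome_id, operon_id = operon_id,
                 genes = genes, order_tag = order_tag),
            class = "operon_locus")
}

infer_order_tag <- function(genes) {
  lab <- sub("^xmo", "", genes$label)
  if (!all(lab %in% c("A", "B", "C")) || length(lab) != 3L) return("other")
  # Read along the coding strand: a minus-strand operon runs right-to-left.
  if (all(genes$strand == "-")) lab <- rev(lab)
  ord <- paste(lab, collapse = "")
  if (ord == "CAB") "CAB" else if (ord == "ABC") "ABC" else "other"
}

#' Extract an operon's sequence from its genome
#'
#' `spanning` returns the single interval `min(start)..max(end)` on the
#' genome (used for tetranucleotide analysis, mirroring the whole locus
#' being profiled as one sequence); `concatenated_cds` joins the
#' strand-resolved coding sequences in operon order (used for codon
#' analysis).
#'
#' @param genome A [genome_record()].
#' @param locus An [operon_locus()].
#' @param mode `"spanning"` or `"concatenated_cds"`.
#' @return A DNA string.
#' @export
operon_sequence <- function(genome, locus,
                            mode = c("spanning", "concatenated_cds")) {
  mode <- match.arg(mode)
  stopifnot(inherits(locus, "operon_locus"))
  g <- locus$genes
  if (any(g$end > genome$length))
    stop("operon '", locus$operon_id, "' not resolvable in genome '",
         genome$id, "'")
  if (mode == "spanning") {
    strands <- unique(g$strand)
    if (length(strands) > 1L && locus$order_tag == "other")
      stop("ambiguous operon '", locus$operon_id,
           "': genes on both strands with order_tag 'other'")
    strand <- if (length(strands) == 1L) strands else "+"
    extract_region(genome, min(g$start), max(g$end), strand)
  } else {
    paste(vapply(seq_len(nrow(g)), function(i) {
      extract_region(genome, g$start[i], g$end[i], g$strand[i])
    }, ""), collapse = "")
  }
}

#' Read operon loci from a TSV file
#'
#' Expected columns: `genome_id`, `operon_id`, `gene_label`, `start`, `end`,
#' `strand`. Coordinates in the file are 1-based inclusive and are converted
#' to the package's 0-based half-open convention.
#'
#' @param path Path to the TSV.
#' @return List of [operon_locus()] objects.
#' @export
read_loci_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "operon_id", "gene_label", "start", "end", "strand")
  if (!all(need %in% names(tab)))
    stop("loci TSV must have columns: ", paste(need, collapse = ", "))
  keys <- unique(tab[, c("genome_id", "operon_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- tab$genome_id == keys$genome_id[i] &
      tab$operon_id == keys$operon_id[i]
    g <- tab[sel, , drop = FALSE]
    operon_locus(keys$genome_id[i], keys$operon_id[i],
                 data.frame(label = g$gene_label, start = g$start - 1L,
                            end = g$end, strand = g$strand,
                            stringsAsFactors = FALSE))
  })
}

#' Write operon loci to TSV (1-based inclusive coordinates)
#'
#' @param loci List of [operon_locus()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_tsv <- function(loci, path) {
  rows <- do.call(rbind, lapply(loci, function(l) {
    data.frame(genome_id = l$genome_id, operon_id = l$operon_id,
               gene_label = l$genes$label, start = l$genes$start + 1L,
               end = l$genes$end, strand = l$genes$strand,
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
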