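IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Does an IUPAC code match a concrete base?
#'
#' @param code Single IUPAC DNA character.
#' @param base One of `A`, `C`, `G`, `T`.
#' @return Logical.
#' @examples
#' iupac_match("R", "G")  # TRUE
#' iupac_match("Y", "A")  # FALSE
#' @export
iupac_match <- function(code, base) {
  code <- toupper(code); base <- toupper(base)
  set <- IUPAC_SETS[[code]]
  if (is.null(set)) stop("invalid IUPAC code: ", code)
  stopifnot(base %in% c("A", "C", "G", "T"))
  base %in% set
}

#' Define a degenerate primer
#'
#' @param name Primer name (e.g. `"A189f"`).
#' @param iupac_seq Sequence over IUPAC DNA codes, length >= 10.
#' @param role `"forward"` or `"reverse"`. A reverse primer anneals to the
#'   sense strand via its reverse complement.
#' @return A `primer_spec` with the degeneracy (product of per-position
#'   code sizes) attached.
#' @export
primer_spec <- function(name, iupac_seq, role = c("forward", "reverse")) {
  role <- match.arg(role)
  iupac_seq <- toupper(iupac_seq)
  chars <- strsplit(iupac_seq, "", fixed = TRUE)[[1]]
  if (length(chars) < 10L) stop("primer '", name, "' shorter than 10 nt")
  sizes <- vapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (is.null(s)) stop("invalid IUPAC code '", ch, "' in primer ", name)
    length(s)
  }, 0L)
  structure(list(name = name, iupac_seq = iupac_seq, role = role,
                 degeneracy = prod(sizes)),
            class = "primer_spec")
}

#' @export
print.primer_spec <- function(x, ...) {
  cat(sprintf("<primer_spec> %s (%s): %s, degeneracy %d\n",
              x$name, x$role, x$iupac_seq, x$degeneracy))
  invisible(x)
}

# Reverse complement of an IUPAC string (complement maps the ambiguity
# codes onto each other).
revcomp_iupac <- function(seq) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(toupper(seq), "")[[1]]), collapse = ""))
}

# Mismatch counts of an IUPAC pattern at every placement on a concrete
# target string. Returns integer vector of length m - L + 1.
placement_mismatches <- function(pattern, target) {
  pc <- strsplit(toupper(pattern), "")[[1]]
  tc <- strsplit(toupper(target), "")[[1]]
  L <- length(pc); m <- length(tc)
  if (m < L) stop("target shorter than primer")
  n_place <- m - L + 1L
  mm <- integer(n_place)
  for (k in seq_len(L)) {
    ok <- tc[k:(k + n_place - 1L)] %in% IUPAC_SETS[[pc[k]]]
    mm <- mm + !ok
  }
  mm
}

#' Best (minimum-mismatch) placement of a primer on a target
#'
#' Scans every ungapped placement on the sense strand and on the reverse
#' complement of the target; mismatches at a placement are positions where
#' the target base is outside the primer code's IUPAC expansion. The
#' minimum is reported with a leftmost tie-break. For a reverse-role
#' primer the reverse complement of the primer is scanned against the
#' sense strand (and the primer itself against the antisense), so
#' `best_position` is always a sense-strand offset.
#'
#' @param primer A [primer_spec()].
#' @param target DNA string (concrete bases).
#' @param target_id Identifier recorded on the report.
#' @return A `mismatch_report`: list with `primer`, `target_id`,
#'   `best_mismatches`, `best_position` (0-based sense-strand offset),
#'   `strand`.
#' @export
best_hit <- function(primer, target, target_id = "target") {
  stopifnot(inherits(primer, "primer_spec"))
  target <- normalize_dna(target, what = target_id)
  pat <- if (primer$role == "forward") primer$iupac_seq else
    revcomp_iupac(primer$iupac_seq)
  mm_fwd <- placement_mismatches(pat, target)
  mm_rev <- placement_mismatches(revcomp_iupac(pat), target)
  best_f <- min(mm_fwd); best_r <- min(mm_rev)
  if (best_f <= best_r) {
    pos <- which.min(mm_fwd) - 1L
    strand <- "+"
    best <- best_f
  } else {
    pos <- which.min(mm_rev) - 1L
    strand <- "-"
    best <- best_r
  }
  structure(list(primer = primer$name, target_id = target_id,
                 best_mismatches = as.integer(best),
                 best_position = as.integer(pos), strand = strand),
            class = "mismatch_report")
}

#' @export
print.mismatch_report <- function(x, ...) {
  cat(sprintf("<mismatch_report> %s on %s: %d mismatch(es) at %d (%s)\n",
              x$primer, x$target_id, x$best_mismatches, x$best_position,
              x$strand))
  invisible(x)
}

# Amplifiable configuration of a primer pair on one sense-strand target:
# forward site (<= max_mm) upstream of a reverse-complement site of the
# reverse primer (<= max_mm). Returns amplicon length or NA.
pair_amplicon <- function(fwd, rev, target, max_mm) {
  f_len <- nchar(fwd$iupac_seq)
  r_len <- nchar(rev$iupac_seq)
  scan_orientation <- function(sense) {
    mm_f <- placement_mismatches(fwd$iupac_seq, sense)
    mm_r <- placement_mismatches(revcomp_iupac(rev$iupac_seq), sense)
    f_pos <- which(mm_f <= max_mm)
    r_pos <- which(mm_r <= max_mm)
    best <- NA_integer_
    for (fp in f_pos) {
      down <- r_pos[r_pos >= fp + f_len]
      if (length(down)) {
        amp <- min(down) + r_len - fp
        if (is.na(best) || amp < best) best <- amp
      }
    }
    best
  }
  a1 <- scan_orientation(target)
  a2 <- scan_orientation(revcomp(target))
  if (is.na(a1)) a2 else if (is.na(a2)) a1 else min(a1, a2)
}

#' Primer-pair coverage over grouped targets
#'
#' For each primer pair and target group, the fraction of targets where
#' both primers find a site with at most `max_mm` mismatches in an
#' amplifiable arrangement (forward site upstream of the reverse primer's
#' reverse-complement site, on either strand of the target). The median
#' amplicon length over amplified targets is reported.
#'
#' @param primer_pairs List of `list(fwd = primer_spec, rev = primer_spec)`.
#' @param targets Named character vector of target DNA sequences.
#' @param groups Character vector of group labels, parallel to `targets`.
#' @param max_mm Maximum mismatches tolerated per primer.
#' @return Data frame: `fwd`, `rev`, `group`, `n`, `n_amplified`,
#'   `fraction`, `median_amplicon`.
#' @export
coverage_table <- function(primer_pairs, targets, groups, max_mm = 1L) {
  stopifnot(length(targets) == length(groups), length(targets) >= 1L)
  if (is.null(names(targets)))
    names(targets) <- sprintf("target_%d", seq_along(targets))
  rows <- list()
  for (pair in primer_pairs) {
    stopifnot(inherits(pair$fwd, "primer_spec"),
              inherits(pair$rev, "primer_spec"))
    amps <- vapply(targets, function(tg)
      pair_amplicon(pair$fwd, pair$rev, normalize_dna(tg), max_mm),
      NA_integer_)
    for (g in unique(groups)) {
      sel <- groups == g
      hit <- !is.na(amps[sel])
      rows[[length(rows) + 1L]] <- data.frame(
        fwd = pair$fwd$name, rev = pair$rev$name, group = g,
        n = sum(sel), n_amplified = sum(hit),
        fraction = mean(hit),
        median_amplicon = if (any(hit))
          stats::median(amps[sel][hit]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
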