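#' Build a run configuration
#'
#' Validates stage toggles and numeric parameters for [run_full()].
#' At least one stage must be enabled.
#'
#' @param genomes,loci,alignments,primers,groups Input paths (FASTA, loci
#'   TSV, aligned FASTA vector, primer TSV, group TSV) as each enabled
#'   stage requires; or pre-loaded objects of the matching classes.
#' @param stages Character subset of
#'   `c("tetra", "codon", "scan", "trees", "rates", "primers")`.
#' @param window,step,k_min,k_max,pseudocount,min_len,max_mm Numeric
#'   parameters, documented on the stage functions they feed.
#' @param focal,outgroup Leaf-name vectors for the `rates` stage.
#' @param seed Integer seed echoed into the bundle.
#' @param out Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(genomes = NULL, loci = NULL, alignments = NULL,
                       primers = NULL, groups = NULL,
                       stages = c("tetra", "codon"),
                       window = 2500L, step = 500L, k_min = 2L, k_max = 8L,
                       pseudocount = 1, min_len = 910L, max_mm = 1L,
                       focal = NULL, outgroup = NULL, seed = 42L,
                       out = "xenocomp_out") {
  all_stages <- c("tetra", "codon", "scan", "trees", "rates", "primers")
  stages <- unique(stages)
  if (length(stages) == 0L || !all(stages %in% all_stages))
    stop("stages must be a non-empty subset of: ",
         paste(all_stages, collapse = ", "))
  stopifnot(window >= 100L, step >= 1L, k_min >= 2L, k_max <= 8L,
            k_min <= k_max, pseudocount > 0, min_len >= 0L, max_mm >= 0L)
  structure(list(genomes = genomes, loci = loci, alignments = alignments,
                 primers = primers, groups = groups, stages = stages,
                 window = as.integer(window), step = as.integer(step),
                 k_range = seq(as.integer(k_min), as.integer(k_max)),
                 pseudocount = pseudocount, min_len = as.integer(min_len),
                 max_mm = as.integer(max_mm), focal = focal,
                 outgroup = outgroup, seed = as.integer(seed), out = out),
            class = "run_config")
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the enabled stages and writes a deterministic report
#' bundle into `config$out`: `kl_table.tsv`, `alien_calls.bed`, per-gene
#' newick trees, `incongruence.tsv`, `rates.tsv`, `primer_coverage.tsv`,
#' a `run.log` narrating inputs and row counts, a `config.json` echo, and
#' a `MANIFEST` marking each stage `ok` or `failed`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the in-memory stage results; an error is
#'   raised (after the MANIFEST is written) if any stage failed.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(config$out, "run.log"), "w")
  on.exit(close(log_con))
  cfg_echo <- config[!vapply(config, is.null, TRUE)]
  cfg_echo <- cfg_echo[!names(cfg_echo) %in%
                         c("genomes", "loci", "alignments", "primers",
                           "groups")]
  jsonlite::write_json(cfg_echo, file.path(config$out, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  genomes <- load_genomes(config$genomes)
  loci <- load_loci(config$loci)
  results <- list()
  status <- c()
  run_stage <- function(name, fun) {
    out <- tryCatch(fun(), error = function(e) {
      log_line(log_con, "[", name, "] FAILED: ", conditionMessage(e))
      e
    })
    status[[name]] <<- if (inherits(out, "error")) "failed" else "ok"
    if (!inherits(out, "error")) results[[name]] <<- out
  }

  if (any(c("tetra", "codon") %in% config$stages)) {
    run_stage("kl", function() {
      methods <- intersect(config$stages, c("tetra", "codon"))
      log_line(log_con, "[kl] ", length(loci), " loci, methods: ",
               paste(methods, collapse = ","), ", pseudocount ",
               config$pseudocount)
      tab <- operon_kl_table(genomes, loci, methods = methods,
                             pseudocount = config$pseudocount)
      write.table(tab, file.path(config$out, "kl_table.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      log_line(log_con, "[kl] wrote ", nrow(tab), " rows")
      tab
    })
  }
  if ("scan" %in% config$stages) {
    run_stage("scan", function() {
      calls_all <- list()
      for (g in genomes) {
        log_line(log_con, "[scan] ", g$id, ": window ", config$window,
                 ", step ", config$step, ", k ",
                 paste(range(config$k_range), collapse = "-"))
        sc <- window_scan(g, window = config$window, step = config$step,
                          k_range = config$k_range,
                          pseudocount = config$pseudocount)
        ops <- Filter(function(l) l$genome_id == g$id, loci)
        calls <- call_alien_regions(sc, ops)
        calls$genome_id <- rep(g$id, length.out = nrow(calls))
        calls_all[[g$id]] <- calls
      }
      calls <- do.call(rbind, calls_all)
      bed <- file.path(config$out, "alien_calls.bed")
      if (nrow(calls)) {
        write_calls_bed(calls, calls$genome_id, bed)
      } else file.create(bed)
      log_line(log_con, "[scan] ", nrow(calls), " alien call(s)")
      calls
    })
  }
  trees <- NULL
  if (any(c("trees", "rates") %in% config$stages)) {
    run_stage("trees", function() {
      alns <- load_alignments(config$alignments)
      log_line(log_con, "[trees] ", length(alns), " alignment(s)")
      trees <<- lapply(alns, function(a) nj_tree(poisson_distance(a)))
      for (nm in names(trees))
        ape::write.tree(trees[[nm]],
                        file.path(config$out, paste0(nm, ".nwk")))
      inc <- incongruence_table(trees)
      write.table(inc, file.path(config$out, "incongruence.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      log_line(log_con, "[trees] incongruence rows: ", nrow(inc))
      list(trees = trees, incongruence = inc)
    })
  }
  if ("rates" %in% config$stages) {
    run_stage("rates", function() {
      if (is.null(trees)) stop("rates stage needs the trees stage")
      if (is.null(config$focal) || is.null(config$outgroup))
        stop("rates stage needs focal and outgroup leaf sets")
      rows <- do.call(rbind, lapply(names(trees), function(nm) {
        r <- rate_ratio(trees[[nm]], config$focal, config$outgroup)
        data.frame(gene = nm, rate_ratio = r$rate_ratio,
                   focal_mean = r$focal_mean,
                   background_mean = r$background_mean,
                   stringsAsFactors = FALSE)
      }))
      write.table(rows, file.path(config$out, "rates.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      log_line(log_con, "[rates] ", nrow(rows), " gene(s)")
      rows
    })
  }
  if ("primers" %in% config$stages) {
    run_stage("primers", function() {
      pr <- load_primers(config$primers)
      tg <- load_targets(config$groups)
      log_line(log_con, "[primers] ", length(pr), " pair(s), ",
               length(tg$targets), " target(s), max_mm ", config$max_mm)
      tab <- coverage_table(pr, tg$targets, tg$groups,
                            max_mm = config$max_mm)
      write.table(tab, file.path(config$out, "primer_coverage.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    })
  }

  writeLines(paste(names(status), unlist(status), sep = "\t"),
             file.path(config$out, "MANIFEST"))
  if (any(unlist(status) == "failed"))
    stop("stage(s) failed: ",
         paste(names(status)[unlist(status) == "failed"], collapse = ", "),
         " (partial outputs retained in ", config$out, ")")
  invisible(results)
}

load_genomes <- function(x) {
  if (is.null(x)) return(list())
  if (is.character(x)) return(read_fasta(x))
  if (inherits(x, "genome_record")) return(setNames(list(x), x$id))
  x
}
load_loci <- function(x) {
  if (is.null(x)) return(list())
  if (is.character(x)) return(read_loci_tsv(x))
  x
}
load_alignments <- function(x) {
  if (is.null(x)) stop("trees stage needs alignments")
  if (is.character(x)) {
    alns <- lapply(x, read_alignment)
    names(alns) <- sub("\\.[^.]*$", "", basename(x))
    return(alns)
  }
  x
}
load_primers <- function(x) {
  if (is.null(x)) stop("primers stage needs a primer table")
  if (is.character(x)) {
    tab <- read.delim(x, stringsAsFactors = FALSE)
    stopifnot(all(c("name", "sequence", "role") %in% names(tab)))
    fwd <- tab[tab$role == "forward", ]
    rev <- tab[tab$role == "reverse", ]
    return(unlist(lapply(seq_len(nrow(fwd)), function(i)
      lapply(seq_len(nrow(rev)), function(j)
        list(fwd = primer_spec(fwd$name[i], fwd$sequence[i], "forward"),
             rev = primer_spec(rev$name[j], rev$sequence[j], "reverse")))),
      recursive = FALSE))
  }
  x
}
load_targets <- function(x) {
  if (is.null(x)) stop("primers stage needs targets with group labels")
  if (is.character(x) && length(x) == 2L) {
    recs <- read_fasta(x[1])
    tab <- read.delim(x[2], stringsAsFactors = FALSE)
    stopifnot(all(c("target_id", "group") %in% names(tab)))
    targets <- vapply(recs, `[[`, "", "sequence")
    return(list(targets = targets,
                groups = tab$group[match(names(targets), tab$target_id)]))
  }
  x
}

#' Group-level summary of an operon KL table
#'
#' The high-versus-low contrast across taxonomic/functional groups: per
#' group and method, the count, mean, minimum and maximum KL, sorted by
#' mean divergence descending.
#'
#' @param kl_table Data frame from [operon_kl_table()].
#' @param group_labels Named character vector mapping `operon_id` to a
#'   group label; every operon in the table must be labelled.
#' @return Data frame: `group`, `method`, `n`, `mean_kl`, `min_kl`,
#'   `max_kl`, `mean_score01`.
#' @export
summarize_groups <- function(kl_table, group_labels) {
  if (nrow(kl_table) == 0L)
    return(data.frame(group = character(), method = character(),
                      n = integer(), mean_kl = numeric(),
                      min_kl = numeric(), max_kl = numeric(),
                      mean_score01 = numeric(), stringsAsFactors = FALSE))
  miss <- setdiff(unique(kl_table$operon_id), names(group_labels))
  if (length(miss))
    stop("unlabelled operon(s): ", paste(miss, collapse = ", "))
  kl_table$group <- group_labels[kl_table$operon_id]
  out <- do.call(rbind, lapply(
    split(kl_table, list(kl_table$group, kl_table$method), drop = TRUE),
    function(d) data.frame(group = d$group[1], method = d$method[1],
                           n = nrow(d), mean_kl = mean(d$kl_nats),
                           min_kl = min(d$kl_nats), max_kl = max(d$kl_nats),
                           mean_score01 = mean(d$score01),
                           stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$method, -out$mean_kl), , drop = FALSE]
}
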