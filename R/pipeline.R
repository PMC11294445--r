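# End-to-end orchestration: simulate/ingest -> read filter -> genome stats
# -> orthogroups -> secretome classification -> entropy -> synteny, driven
# by a single validated configuration, with a JSON run report.

#' Default pipeline configuration
#'
#' Every parameter equals the default documented in its module; unknown
#' keys in a user configuration are rejected rather than ignored.
#'
#' @return A nested list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "wolbpan_run",
    stages = list(simulate = TRUE, filter = TRUE, genome_stats = TRUE,
                  orthogroups = TRUE, classify = TRUE, entropy = TRUE,
                  synteny = TRUE),
    simulate = list(n_strains = 8L, n_clades = 2L, n_core = 240L,
                    n_accessory = 60L, gain_rate = 0.5, loss_rate = 0.3,
                    accessory_root_prob = 0.5, body_length = 120L,
                    max_variable = 12L, n_reads = 400L, inversions = 1L,
                    intergenic_mean = 300L, skew_amplitude = 0.6,
                    origin_position = 0.25, gene_length = 600L,
                    gc_mean = 0.35),
    filter = list(threshold = 0.04),
    genome_stats = list(window = 10000L, step = 1000L, deviation = TRUE),
    orthogroups = list(min_score = 0.2, k = 4L),
    classify = list(sp_threshold = 1.6, tm_threshold = 1.6),
    entropy = list(variable_threshold = 0, min_coverage = 2L),
    synteny = list(k = 15L, max_gap = 5000L, min_anchors = 3L))
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_condition(sprintf("unknown configuration key: %s%s", path,
                           unknown[1]), "wolbpan_parameter")
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

#' Run the comparative-genomics pipeline end to end
#'
#' Executes the enabled stages in dependency order on a simulated strain
#' set, writing every stage's outputs under `out_dir` plus a JSON run
#' report. Identical configuration and seed produce byte-identical TSV/
#' FASTA outputs (the report's wall-times differ between runs and live only
#' in the report).
#'
#' @param config nested list overriding [pipeline_defaults()], or a path to
#'   a YAML file with the same structure.
#' @param out_dir output directory (overrides the config value when given).
#' @param seed integer seed (overrides the config value when given).
#' @return The run report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_defaults(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("wolbpan")),
                 seed = cfg$seed, parameters = cfg, stages = list())
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr
    list(value = v, seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }
  log_stage <- function(name, msg)
    message(sprintf("[%s] %s", name, msg))

  sim <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    st <- t_stage({
      sim <- do.call(simulate_strain_set, c(cfg$simulate, list(seed = cfg$seed)))
      write_strain_set(sim, file.path(cfg$out_dir, "inputs"))
      sim
    })
    sim <- st$value
    log_stage("simulate", sprintf("%d strains, %d families",
                                  length(sim$proteomes), nrow(sim$families)))
    report$stages$simulate <- list(seconds = st$seconds,
                                   n_strains = length(sim$proteomes),
                                   n_families = nrow(sim$families))
  }
  need_sim <- function(stage) {
    if (is.null(sim))
      stop_condition(sprintf(
        "stage '%s' requires the simulate stage (no inputs available)",
        stage), "wolbpan_dependency")
  }
  strains <- if (!is.null(sim)) names(sim$proteomes) else character(0)

  if (isTRUE(cfg$stages$filter)) {
    need_sim("filter")
    st <- t_stage({
      recs <- read_alignment_records(file.path(cfg$out_dir, "inputs", "reads.sam"),
                                     dialect = "sam")
      res <- filter_by_divergence(recs, threshold = cfg$filter$threshold)
      write_tsv(filter_report_df(res$report),
                file.path(cfg$out_dir, "filter_report.tsv"))
      write_tsv(data.frame(read_id = vapply(res$retained, function(r) r$read_id,
                                            character(1)),
                           stringsAsFactors = FALSE),
                file.path(cfg$out_dir, "retained_reads.tsv"))
      res$report
    })
    log_stage("filter", sprintf("%d/%d reads retained",
                                st$value$n_retained, st$value$n_input))
    report$stages$filter <- list(seconds = st$seconds,
                                 n_input = st$value$n_input,
                                 n_retained = st$value$n_retained)
  }

  if (isTRUE(cfg$stages$genome_stats)) {
    need_sim("genome_stats")
    st <- t_stage({
      summaries <- lapply(strains, function(s) genome_summary(sim$genomes[[s]]))
      write_tsv(data.frame(
        strain = strains,
        length_bp = vapply(summaries, function(x) x$length_bp, numeric(1)),
        gc_percent = vapply(summaries, function(x) x$gc_percent, numeric(1)),
        stringsAsFactors = FALSE),
        file.path(cfg$out_dir, "genome_summary.tsv"))
      for (s in strains) {
        track <- windowed_profile(sim$genomes[[s]], metric = "gc_skew",
                                  window = cfg$genome_stats$window,
                                  step = cfg$genome_stats$step,
                                  deviation = cfg$genome_stats$deviation)
        write_track(track, file.path(cfg$out_dir,
                                     sprintf("gc_skew_%s.tsv", s)))
      }
      length(strains)
    })
    log_stage("genome_stats", sprintf("%d genomes profiled", st$value))
    report$stages$genome_stats <- list(seconds = st$seconds,
                                       n_genomes = st$value)
  }

  ogs <- NULL; og_aln <- NULL
  if (isTRUE(cfg$stages$orthogroups)) {
    need_sim("orthogroups")
    st <- t_stage({
      ogs <- infer_orthogroups(sim$proteomes,
                               min_score = cfg$orthogroups$min_score,
                               k = cfg$orthogroups$k)
      write_orthogroup_table(ogs, file.path(cfg$out_dir, "orthogroups.tsv"))
      pav <- build_pav(ogs, strains)
      write_tsv(data.frame(orthogroup = rownames(pav),
                           as.data.frame(unclass(pav), check.names = FALSE),
                           check.names = FALSE, stringsAsFactors = FALSE),
                file.path(cfg$out_dir, "pav.tsv"))
      scos <- extract_scos(ogs, strains)
      write_tsv(data.frame(orthogroup = scos, stringsAsFactors = FALSE),
                file.path(cfg$out_dir, "scos.tsv"))
      gene_seqs <- unlist(lapply(strains, function(s)
        stats::setNames(sim$proteomes[[s]]$seq, sim$proteomes[[s]]$id)))
      og_aln <- lapply(ogs, function(o) {
        genes <- unlist(o$members, use.names = FALSE)
        align_orthogroup(gene_seqs[genes])
      })
      names(og_aln) <- vapply(ogs, function(o) o$og_id, character(1))
      if (length(scos)) {
        sm <- export_supermatrix(og_aln[scos], ogs, strains)
        write_fasta(sm$alignment, file.path(cfg$out_dir, "sco_supermatrix.fasta"))
        write_tsv(sm$partitions, file.path(cfg$out_dir, "sco_partitions.tsv"))
      }
      list(ogs = ogs, og_aln = og_aln, n_sco = length(scos))
    })
    ogs <- st$value$ogs; og_aln <- st$value$og_aln
    log_stage("orthogroups", sprintf("%d orthogroups, %d SCOs",
                                     length(ogs), st$value$n_sco))
    report$stages$orthogroups <- list(seconds = st$seconds,
                                      n_orthogroups = length(ogs),
                                      n_sco = st$value$n_sco)
  }

  og_classes <- NULL
  if (isTRUE(cfg$stages$classify)) {
    need_sim("classify")
    if (is.null(ogs))
      stop_condition("stage 'classify' requires the orthogroups stage",
                     "wolbpan_dependency")
    st <- t_stage({
      per_protein <- do.call(rbind, lapply(strains, function(s) {
        df <- classify_proteins(sim$proteomes[[s]],
                                sp_threshold = cfg$classify$sp_threshold,
                                tm_threshold = cfg$classify$tm_threshold)
        df$strain <- s
        df
      }))
      write_tsv(per_protein[, c("strain", "gene", "has_signal_peptide",
                                "n_tm_segments", "class", "evidence_source")],
                file.path(cfg$out_dir, "protein_classes.tsv"))
      cls_by_gene <- stats::setNames(per_protein$class, per_protein$gene)
      og_classes <- vapply(ogs, function(o) {
        genes <- unlist(o$members, use.names = FALSE)
        classify_orthogroup(cls_by_gene[genes])$class
      }, character(1))
      names(og_classes) <- vapply(ogs, function(o) o$og_id, character(1))
      write_tsv(data.frame(orthogroup = names(og_classes),
                           class = unname(og_classes),
                           stringsAsFactors = FALSE),
                file.path(cfg$out_dir, "orthogroup_classes.tsv"))
      og_classes
    })
    og_classes <- st$value
    log_stage("classify", sprintf("%d orthogroups classified",
                                  length(og_classes)))
    report$stages$classify <- list(
      seconds = st$seconds,
      n_membrane = sum(og_classes == "membrane-bound"),
      n_secreted = sum(og_classes == "secreted"))
  }

  if (isTRUE(cfg$stages$entropy)) {
    if (is.null(og_aln) || is.null(og_classes))
      stop_condition("stage 'entropy' requires the orthogroups and classify stages",
                     "wolbpan_dependency")
    st <- t_stage({
      multi <- og_aln[vapply(og_aln, length, integer(1)) >= 2L]
      profiles <- lapply(names(multi), function(id)
        entropy_profile(multi[[id]],
                        variable_threshold = cfg$entropy$variable_threshold,
                        min_coverage = cfg$entropy$min_coverage, og_id = id))
      names(profiles) <- names(multi)
      write_tsv(data.frame(
        orthogroup = names(profiles),
        class = unname(og_classes[names(profiles)]),
        alignment_length = vapply(profiles, function(p) p$length, numeric(1)),
        n_variable = vapply(profiles, function(p) p$n_variable, numeric(1)),
        fraction_variable = vapply(profiles, function(p) p$fraction_variable,
                                   numeric(1)),
        stringsAsFactors = FALSE),
        file.path(cfg$out_dir, "variability_per_orthogroup.tsv"))
      vs <- summarize_variability(profiles, og_classes)
      write_tsv(vs$per_class, file.path(cfg$out_dir, "variability_summary.tsv"))
      write_tsv(vs$histogram, file.path(cfg$out_dir, "variability_histogram.tsv"))
      vs
    })
    log_stage("entropy", sprintf("medians (all/secreted/membrane): %s",
      paste(st$value$per_class$median_n_variable[c(1, 3, 2)], collapse = "/")))
    report$stages$entropy <- list(
      seconds = st$seconds,
      n_zero_variable = st$value$n_zero_variable_orthogroups,
      medians = stats::setNames(as.list(st$value$per_class$median_n_variable),
                                st$value$per_class$class))
  }

  if (isTRUE(cfg$stages$synteny)) {
    need_sim("synteny")
    if (length(strains) < 2L)
      stop_condition("synteny stage needs at least two strains",
                     "wolbpan_parameter")
    st <- t_stage({
      a <- sim$genomes[[strains[1]]]; b <- sim$genomes[[strains[2]]]
      anchors <- kmer_anchors(a, b, k = cfg$synteny$k)
      write_anchors_paf(anchors, file.path(cfg$out_dir, "synteny_anchors.paf"),
                        name_a = strains[1], name_b = strains[2])
      blocks <- chain_anchors(anchors, max_gap = cfg$synteny$max_gap,
                              min_anchors = cfg$synteny$min_anchors,
                              circular = TRUE)
      write_tsv(as.data.frame(blocks),
                file.path(cfg$out_dir, "synteny_blocks.tsv"))
      bps <- breakpoint_report(blocks)
      write_tsv(bps, file.path(cfg$out_dir, "synteny_breakpoints.tsv"))
      list(n_blocks = nrow(blocks), n_breakpoints = nrow(bps),
           n_strand_change = sum(bps$strand_change))
    })
    log_stage("synteny", sprintf("%d blocks, %d breakpoints",
                                 st$value$n_blocks, st$value$n_breakpoints))
    report$stages$synteny <- c(list(seconds = st$seconds), st$value)
  }

  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(cfg$out_dir, "report.json"))
  invisible(report)
}

#' Optional online replication against deposited assemblies
#'
#' Fetches assemblies by accession from NCBI efetch, runs
#' [genome_summary()] on each, and compares length/GC against expected
#' values when provided. This is an explicitly network-dependent
#' convenience: any fetch failure yields a report marked `"skipped"` with a
#' warning, never an error, and the function is excluded from the default
#' analysis path.
#'
#' @param accessions character vector of nucleotide accessions (e.g.
#'   `"CP157591.1"`); empty vector is a no-op.
#' @param workdir directory for downloaded FASTA files.
#' @param expected optional data.frame (accession, length_bp, gc_percent).
#' @param timeout download timeout in seconds (default 60).
#' @return A list with `status` (`"ok"`, `"skipped"` or `"empty"`) and
#'   `summaries` (data.frame accession, length_bp, gc_percent, plus
#'   matches_expected when `expected` is given).
#' @export
replicate_online <- function(accessions, workdir = tempdir(),
                             expected = NULL, timeout = 60) {
  if (!length(accessions))
    return(list(status = "empty",
                summaries = data.frame(accession = character(0),
                                       length_bp = numeric(0),
                                       gc_percent = numeric(0))))
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
  rows <- list()
  for (acc in accessions) {
    dest <- file.path(workdir, paste0(acc, ".fasta"))
    ok <- tryCatch({
      if (!file.exists(dest)) {
        old <- getOption("timeout"); options(timeout = timeout)
        on.exit(options(timeout = old), add = TRUE)
        url <- sprintf("%s?db=nuccore&id=%s&rettype=fasta&retmode=text",
                       base, acc)
        utils::download.file(url, dest, quiet = TRUE, mode = "wb")
      }
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(dest) || file.size(dest) < 100) {
      warning(sprintf("could not fetch %s; online replication skipped", acc))
      return(list(status = "skipped",
                  summaries = data.frame(accession = character(0),
                                         length_bp = numeric(0),
                                         gc_percent = numeric(0))))
    }
    row <- tryCatch({
      fa <- read_fasta(dest, alphabet = "nucleotide")
      gs <- genome_summary(genome_record(acc, fa$seq[1], circular = TRUE))
      data.frame(accession = acc, length_bp = gs$length_bp,
                 gc_percent = gs$gc_percent, stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (is.null(row)) {
      warning(sprintf("fetched file for %s is not parseable; skipped", acc))
      return(list(status = "skipped",
                  summaries = data.frame(accession = character(0),
                                         length_bp = numeric(0),
                                         gc_percent = numeric(0))))
    }
    rows[[acc]] <- row
  }
  summaries <- do.call(rbind, rows)
  rownames(summaries) <- NULL
  if (!is.null(expected)) {
    m <- match(summaries$accession, expected$accession)
    summaries$matches_expected <- !is.na(m) &
      summaries$length_bp == expected$length_bp[m] &
      summaries$gc_percent == expected$gc_percent[m]
  }
  list(status = "ok", summaries = summaries)
}
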