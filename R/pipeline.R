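## End-to-end orchestration: validated configuration, staged execution
## with per-stage audit logging, deterministic outputs and a manifest
## of checksums.

#' Default pipeline configuration
#'
#' Every stage threshold appears once, under a single name, with its
#' standard default: length filter 18-30 nt, at least 10 mature and 1
#' star read, duplex space <= 35 and bulge <= 5, homology flank 90 nt
#' with word size 7, seed length 7, energy cutoff -20 kcal/mol,
#' significance p < 0.05, cluster gap 10,000 nt, arm-dominance ratio 2.
#'
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(min_len = 18L, max_len = 30L,
       min_mature = 10L, min_star = 1L,
       max_space = 35L, max_bulge = 5L,
       flank = 90L, word = 7L, seed_len = 7L,
       dG_cutoff = -20, p_cutoff = 0.05,
       max_gap = 10000L, dominance_ratio = 2,
       adapter = NULL, rng_seed = 1L,
       genome = NULL, reads = NULL, references = NULL,
       simulate = TRUE, sim = NULL)
}

config_bounds <- list(
  min_len = c(1, 50), max_len = c(1, 100), min_mature = c(1, Inf),
  min_star = c(0, Inf), max_space = c(0, 500), max_bulge = c(0, 50),
  flank = c(0, 1000), word = c(4, 15), seed_len = c(7, 8),
  dG_cutoff = c(-100, 0), p_cutoff = c(0, 1), max_gap = c(1, 1e7),
  dominance_ratio = c(1, 100), rng_seed = c(-2^31, 2^31))

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path, YAML text, or a named list. All problems
#' are collected (not fail-on-first): unknown keys are rejected,
#' non-numeric values for numeric keys are typed errors, out-of-bounds
#' values are errors, and values beyond the standard working limits
#' (e.g. `max_bulge > 5`) draw a note. Missing keys take defaults.
#'
#' @param raw path, YAML string or named list.
#' @return list with `config` (completed configuration or NULL when
#'   invalid), `errors` (character), `notes` (character).
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw)) {
    raw <- if (length(raw) == 1 && file.exists(raw)) yaml::read_yaml(raw)
    else yaml::yaml.load(paste(raw, collapse = "\n"))
    if (is.null(raw)) raw <- list()
  }
  defaults <- pipeline_defaults()
  errors <- character(0); notes <- character(0)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    errors <- c(errors, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  cfg <- modifyList(defaults, raw[intersect(names(raw), names(defaults))])
  for (key in names(config_bounds)) {
    v <- cfg[[key]]
    if (is.null(v)) next
    if (!is.numeric(v)) {
      errors <- c(errors, paste0("key '", key, "' must be numeric, got ",
                                 class(v)[1]))
      next
    }
    b <- config_bounds[[key]]
    if (v < b[1] || v > b[2])
      errors <- c(errors, paste0("key '", key, "' = ", v,
                                 " outside bounds [", b[1], ", ", b[2], "]"))
  }
  if (is.numeric(cfg$min_len) && is.numeric(cfg$max_len) &&
      cfg$min_len > cfg$max_len)
    errors <- c(errors, "min_len exceeds max_len")
  if (is.numeric(cfg$max_bulge) && cfg$max_bulge > 5)
    notes <- c(notes, "max_bulge > 5 exceeds the standard duplex limit")
  if (is.numeric(cfg$max_space) && cfg$max_space > 35)
    notes <- c(notes, "max_space > 35 exceeds the standard duplex limit")
  if (!length(raw)) notes <- c(notes, "empty configuration; using defaults")
  list(config = if (length(errors)) NULL else cfg,
       errors = errors, notes = notes)
}

#' Run the pipeline end to end
#'
#' From a validated configuration: simulate (or load) the genome and
#' read libraries, preprocess, discover loci, profile arm usage and
#' isomiR fidelity, detect clusters, and test differential expression.
#' Every stage writes its tables under a numbered subdirectory of
#' `out_dir`; a manifest of MD5 checksums makes reruns comparable
#' (identical configuration and seed give identical checksums).
#'
#' @param config configuration list (validated with
#'   [validate_config()]) or anything `validate_config` accepts.
#' @param out_dir output directory.
#' @return list with `manifest` (data.frame file, md5), `loci`,
#'   `de`, `clusters`, `log` (per-stage counts), invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  v <- validate_config(config)
  if (is.null(v$config))
    stop("invalid configuration:\n  ", paste(v$errors, collapse = "\n  "))
  cfg <- v$config
  for (n in v$notes) message("note: ", n)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()

  ## stage 1: inputs
  if (isTRUE(cfg$simulate) || is.null(cfg$genome)) {
    sim_args <- if (is.list(cfg$sim)) cfg$sim else list()
    sim_args$rng_seed <- cfg$rng_seed
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_genome(scfg)
    reads_obj <- simulate_reads(sim)
    sim_dir <- file.path(out_dir, "01_simulate")
    write_simulation(sim, reads_obj, sim_dir)
    genome <- c(chr1 = sim$genome)
    reads_by_lib <- lapply(reads_obj$libraries, `[[`, "sequence")
    conditions <- stats::setNames(scfg$libraries$condition, scfg$libraries$name)
  } else {
    if (!file.exists(cfg$genome)) stop("genome file not found: ", cfg$genome)
    genome <- NULL  # loaded by genome_index below
    lib_files <- cfg$reads
    missing <- lib_files[!file.exists(lib_files)]
    if (length(missing)) stop("read file(s) not found: ",
                              paste(missing, collapse = ", "))
    reads_by_lib <- lapply(lib_files, read_reads)
    if (is.null(names(reads_by_lib)))
      names(reads_by_lib) <- tools::file_path_sans_ext(basename(lib_files))
    conditions <- NULL
    sim <- NULL
  }

  ## stage 2: preprocess
  pp <- preprocess_reads(reads_by_lib, adapter = cfg$adapter,
                         min_len = cfg$min_len, max_len = cfg$max_len,
                         references = cfg$references)
  pre_dir <- file.path(out_dir, "02_preprocess")
  dir.create(pre_dir, showWarnings = FALSE)
  write_tsv(pp$tags, file.path(pre_dir, "tags.tsv"))
  write_tsv(pp$stats, file.path(pre_dir, "stats.tsv"))
  log$preprocess <- c(tags = nrow(pp$tags), clean = nrow(pp$clean))

  ## stage 3: discovery
  idx <- if (is.null(genome)) genome_index(cfg$genome, k = cfg$word)
  else genome_index(genome, k = cfg$word)
  called <- call_loci(pp$clean, idx,
                      params = list(min_mature_reads = cfg$min_mature,
                                    min_star_reads = cfg$min_star,
                                    max_space = cfg$max_space,
                                    max_bulge = cfg$max_bulge))
  disc_dir <- file.path(out_dir, "03_discover")
  dir.create(disc_dir, showWarnings = FALSE)
  write_tsv(called$loci, file.path(disc_dir, "loci.tsv"))
  acc <- accepted_loci(called)
  if (nrow(acc)) {
    gr <- intervals_to_granges(data.frame(
      seqname = acc$seqname, start = acc$start, end = acc$end,
      strand = acc$strand, ID = acc$id, type = "pre_miRNA",
      stringsAsFactors = FALSE))
    rtracklayer::export(gr, file.path(disc_dir, "loci.gff3"), format = "gff3")
    Biostrings::writeXStringSet(
      Biostrings::RNAStringSet(stats::setNames(acc$mature_seq, acc$id)),
      file.path(disc_dir, "mature.fa"))
  }
  counts <- called$mature_counts
  write_tsv(data.frame(id = rownames(counts), counts, check.names = FALSE),
            file.path(disc_dir, "mature_counts.tsv"))
  log$discover <- c(candidates = nrow(called$loci), accepted = nrow(acc))

  ## stage 4: profiles
  prof_dir <- file.path(out_dir, "04_profiles")
  dir.create(prof_dir, showWarnings = FALSE)
  if (nrow(acc)) {
    usage <- do.call(rbind, lapply(seq_len(nrow(acc)), function(i) {
      u <- arm_usage(acc[i, , drop = FALSE], ratio = cfg$dominance_ratio)
      data.frame(id = u$id, reads_5p = u$reads_5p, reads_3p = u$reads_3p,
                 fraction_5p = u$fraction_5p, dominant = u$dominant,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(usage, file.path(prof_dir, "arm_usage.tsv"))
  }
  spectrum <- length_spectrum(called)
  write_tsv(data.frame(length = names(spectrum$lengths),
                       fraction = as.numeric(spectrum$lengths)),
            file.path(prof_dir, "length_spectrum.tsv"))
  write_tsv(data.frame(nt = names(first_nt_bias(called)),
                       fraction = as.numeric(first_nt_bias(called))),
            file.path(prof_dir, "first_nt.tsv"))

  ## stage 5: clusters
  clus <- find_clusters(acc, max_gap = cfg$max_gap)
  write_tsv(clus, file.path(out_dir, "05_clusters.tsv"))

  ## stage 6: differential expression
  de <- NULL
  if (!is.null(conditions) && nrow(counts) &&
      all(c("male", "female") %in% conditions[colnames(counts)])) {
    acc_counts <- counts[rownames(counts) %in% acc$id, , drop = FALSE]
    if (nrow(acc_counts)) {
      de <- de_test(acc_counts, conditions[colnames(acc_counts)],
                    p_cutoff = cfg$p_cutoff)
      write_tsv(de, file.path(out_dir, "06_diffexp.tsv"))
      log$diffexp <- c(tested = nrow(de), biased = sum(de$biased != "none"))
    }
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.tsv"))
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(manifest = manifest, loci = called, de = de,
                 clusters = clus, log = log))
}
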