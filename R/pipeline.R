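#' Presence/absence matrix from breadth
#'
#' A vOTU is present in a sample when its mapped breadth reaches the
#' detection threshold (default 0.70, the common read-mapping detection
#' convention).
#'
#' @param breadth_mat vOTU x sample breadth matrix (see
#'   [abundance_table()]).
#' @param threshold breadth required for presence.
#' @return logical matrix of the same shape.
#' @export
presence_matrix <- function(breadth_mat, threshold = 0.70) {
  breadth_mat >= threshold
}

default_thresholds <- function() {
  list(min_identity = 0.95, min_read_frac = 0.90,
       txn_min_identity = 0.90, txn_min_read_frac = 0.90,
       txn_min_breadth = 0.50,
       min_ani = 95, min_af = 80,
       hvr_frac = 0.20, hvr_min_len = 500L, hvr_min_median = 5,
       min_cov = 10L, min_count = 4L, min_freq = 0.01,
       presence_breadth = 0.70)
}

## hash of the analytic config: the output location does not change results,
## so it is excluded — reruns into different directories stay byte-identical
config_hash <- function(config) {
  config$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

write_stage_table <- function(df, path, config_hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# viropop ", as.character(utils::packageVersion("viropop"))),
    paste0("# config_hash: ", config_hash),
    paste0("# seed: ", seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON; see [run_pipeline()] for the recognized fields. Values
#' omitted from `thresholds` take the package defaults.
#'
#' @param path config file path.
#' @return config list.
#' @export
read_config <- function(path) {
  config <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path, simplifyVector = FALSE)
            else yaml::read_yaml(path)
  config
}

#' Run the full synthetic-community analysis pipeline
#'
#' Orchestrates simulate -> (classify) -> vOTU clustering -> coverage ->
#' HVR detection -> microdiversity -> ecology/activity as a seeded,
#' deterministic run. Every emitted table carries a header block with the
#' package version, a hash of the effective config, and the seed, so a
#' rerun with the same config is byte-identical.
#'
#' @param config a config list (or a path read via [read_config()]) with
#'   fields: `seed`, `out_dir`, `stages` (subset of `simulate`, `classify`,
#'   `votu`, `coverage`, `hvr`, `microdiv`, `ecology`, in any order —
#'   dependencies are checked), `samples` (list of
#'   `sample_id`, `group`, and a `sim` block of [community_spec()] /
#'   [strain_spec()] fields: `n_genomes`, `genome_len`, `gene_density`,
#'   `depth_mean`, `read_len`, `error_rate`, `n_strains`, `target_pi`,
#'   `frac_nonsyn`), optional `active` (ids simulated as transcriptionally
#'   active, per sample), optional `scores_tsv` (detector scores to gate
#'   contigs through [classify_viral()]), and optional `thresholds`.
#' @return list with per-sample results (`community`, `abundance`,
#'   `hvrs`, `microdiv`), shared results (`votus`, `ecology`), the
#'   effective `config`, and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$seed)) stop("config error: seed is required")
  if (is.null(config$samples) || !length(config$samples))
    stop("config error: at least one sample is required")
  th <- utils::modifyList(default_thresholds(),
                          if (is.null(config$thresholds)) list()
                          else config$thresholds)
  config$thresholds <- th
  stages <- config$stages
  if (is.null(stages))
    stages <- c("simulate", "votu", "coverage", "hvr", "microdiv", "ecology")
  deps <- list(votu = "simulate", coverage = c("simulate", "votu"),
               hvr = "coverage", microdiv = "coverage",
               ecology = "coverage")
  for (s in intersect(names(deps), stages)) {
    missing <- setdiff(deps[[s]], stages)
    if (length(missing))
      stop("stage '", s, "' requires stage(s): ",
           paste(missing, collapse = ", "))
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  hash <- config_hash(config)
  seed <- as.integer(config$seed)
  emit <- function(df, name) {
    if (!is.null(out_dir))
      write_stage_table(df, file.path(out_dir, name), hash, seed)
  }
  message("viropop: running stages [", paste(stages, collapse = ", "),
          "] with seed ", seed)

  ## --- simulate -------------------------------------------------------
  communities <- list()
  for (i in seq_along(config$samples)) {
    sm <- config$samples[[i]]
    sim <- sm$sim
    spec <- community_spec(
      n_genomes = sim$n_genomes %||% 3L,
      genome_len_range = rep(sim$genome_len %||% 30000L, 2L),
      gene_density = sim$gene_density %||% 1,
      read_len = sim$read_len %||% 100L,
      error_rate = sim$error_rate %||% 0.001,
      depth_mean = sim$depth_mean %||% 30,
      seed = seed + 101L * i,
      id_prefix = paste0(sm$sample_id, "_g"))
    sspec <- strain_spec(n_strains = sim$n_strains %||% 2L,
                         target_pi = sim$target_pi %||% 0.005,
                         frac_nonsyn = sim$frac_nonsyn %||% 0.5)
    active <- unlist(sm$active) %||% character(0)
    communities[[sm$sample_id]] <- simulate_community(
      spec, sspec, active_ids = active,
      transcript_depth = sim$transcript_depth %||% 20)
  }

  ## --- classify (optional, gated on a detector score table) -----------
  viral_ids <- NULL
  if (!is.null(config$scores_tsv)) {
    cls <- classify_viral(read_detector_scores(config$scores_tsv))
    viral_ids <- cls$contig_id[cls$viral]
    emit(cls, "viral_classification.tsv")
  }

  ## --- vOTU clustering over all samples' contigs ----------------------
  all_contigs <- do.call(c, unname(lapply(communities, `[[`, "contigs")))
  if (!is.null(viral_ids))
    all_contigs <- all_contigs[names(all_contigs) %in% viral_ids]
  votus <- NULL
  refs <- all_contigs
  if ("votu" %in% stages) {
    votus <- cluster_votus(all_contigs, min_ani = th$min_ani,
                           min_af = th$min_af)
    refs <- all_contigs[votus$clusters$representative_id]
    emit(votus$clusters, "votus.tsv")
  }

  ## --- coverage -------------------------------------------------------
  results <- list()
  profiles_by_sample <- list()
  library_bases <- numeric(0)
  if ("coverage" %in% stages) {
    for (sid in names(communities)) {
      cm <- communities[[sid]]
      kept <- filter_alignments(cm$aln, th$min_identity, th$min_read_frac)
      profs <- depth_profiles(kept, refs)
      profiles_by_sample[[sid]] <- profs
      library_bases[[sid]] <- cm$library_bases
      results[[sid]] <- list(kept = kept, profiles = profs)
    }
    ab <- abundance_table(profiles_by_sample, library_bases)
    emit(data.frame(votu = rownames(ab$abundance), ab$abundance,
                    check.names = FALSE), "abundance.tsv")
  }

  ## --- HVR ------------------------------------------------------------
  if ("hvr" %in% stages) {
    for (sid in names(communities)) {
      hv <- do.call(rbind, lapply(names(refs), function(id)
        detect_hvrs(results[[sid]]$profiles[[id]], id,
                    frac = th$hvr_frac, min_len = th$hvr_min_len,
                    min_median = th$hvr_min_median)))
      results[[sid]]$hvrs <- hv
      emit(hv, paste0("hvrs_", sid, ".tsv"))
    }
  }

  ## --- microdiversity -------------------------------------------------
  if ("microdiv" %in% stages) {
    all_genes <- do.call(rbind, unname(lapply(communities, `[[`, "genes")))
    for (sid in names(communities)) {
      cm <- communities[[sid]]
      per_contig <- list(); per_gene <- list()
      for (id in names(refs)) {
        sub <- results[[sid]]$kept
        sub <- sub[sub$contig_id == id, , drop = FALSE]
        counts <- allele_counts(sub, refs[[id]])
        snps <- call_snps(counts, refs[[id]], min_cov = th$min_cov,
                          min_count = th$min_count, min_freq = th$min_freq)
        cd <- contig_microdiversity(counts, snps, min_cov = th$min_cov)
        per_contig[[id]] <- cbind(data.frame(contig_id = id), cd)
        gg <- all_genes[all_genes$contig_id == id, , drop = FALSE]
        if (nrow(gg))
          per_gene[[id]] <- gene_microdiversity(gg, snps, counts, refs[[id]],
                                                min_cov = th$min_cov)
      }
      results[[sid]]$microdiv <- list(
        contigs = do.call(rbind, per_contig),
        genes = do.call(rbind, per_gene))
      emit(results[[sid]]$microdiv$contigs,
           paste0("microdiv_contigs_", sid, ".tsv"))
      emit(results[[sid]]$microdiv$genes,
           paste0("microdiv_genes_", sid, ".tsv"))
    }
  }

  ## --- ecology / activity ---------------------------------------------
  ecology <- NULL
  if ("ecology" %in% stages) {
    ab <- abundance_table(profiles_by_sample, library_bases)
    div <- data.frame(
      sample = colnames(ab$abundance),
      richness = colSums(ab$breadth >= th$presence_breadth),
      shannon = apply(ab$abundance, 2, function(x)
        if (sum(x) > 0) shannon(x) else NA_real_))
    rownames(div) <- NULL
    venn <- if (ncol(ab$abundance) >= 2)
      shared_unique(presence_matrix(ab$breadth, th$presence_breadth),
                    ab$relative,
                    samples = utils::head(colnames(ab$abundance), 3))
    else NULL
    activity <- list()
    for (sid in names(communities)) {
      txn <- communities[[sid]]$transcriptome
      if (!is.null(txn))
        activity[[sid]] <- call_active(
          txn$aln, refs, min_identity = th$txn_min_identity,
          min_read_frac = th$txn_min_read_frac,
          min_breadth = th$txn_min_breadth,
          genes = do.call(rbind, unname(lapply(communities, `[[`, "genes"))))
    }
    ecology <- list(diversity = div, venn = venn, activity = activity,
                    abundance = ab)
    emit(div, "diversity.tsv")
    if (!is.null(venn)) emit(venn, "venn.tsv")
  }

  invisible(list(samples = results, communities = communities,
                 votus = votus, refs = refs, ecology = ecology,
                 config = config, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a pipeline run per sample group
#'
#' One row per group: richness, Shannon, median genome-level pi, median SNP
#' density, percent of genes with SNPs, percent of genes under positive
#' selection (pN/pS > 1), HVR count, and active vOTU count.
#'
#' @param run result of [run_pipeline()].
#' @return data.frame, one row per group.
#' @export
summarize_run <- function(run) {
  groups <- vapply(run$config$samples, function(s)
    s$group %||% s$sample_id, character(1))
  sids <- vapply(run$config$samples, `[[`, character(1), "sample_id")
  rows <- lapply(unique(groups), function(g) {
    ids <- sids[groups == g]
    div <- run$ecology$diversity
    md_c <- do.call(rbind, lapply(ids, function(s)
      run$samples[[s]]$microdiv$contigs))
    md_g <- do.call(rbind, lapply(ids, function(s)
      run$samples[[s]]$microdiv$genes))
    hv <- do.call(rbind, lapply(ids, function(s) run$samples[[s]]$hvrs))
    n_active <- sum(vapply(ids, function(s) {
      a <- run$ecology$activity[[s]]
      if (is.null(a)) 0L else length(a$active)
    }, integer(1)))
    defined <- !is.na(md_g$pnps) | md_g$class == "no-variation"
    data.frame(
      group = g,
      richness = if (is.null(div)) NA else
        mean(div$richness[div$sample %in% ids]),
      shannon = if (is.null(div)) NA else
        mean(div$shannon[div$sample %in% ids]),
      median_pi = stats::median(md_c$pi, na.rm = TRUE),
      median_snp_density = stats::median(md_c$snp_density, na.rm = TRUE),
      pct_genes_with_snps = 100 * genes_with_snp_fraction(md_g),
      pct_genes_positive = 100 * mean(md_g$class[defined] == "positive"),
      n_hvrs = if (is.null(hv)) 0L else nrow(hv),
      n_active_votus = n_active,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
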