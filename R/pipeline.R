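# End-to-end orchestration over a simulated (or user-supplied) experiment:
# simulate -> srna catalog -> hairpin validation -> degradome targets ->
# differential expression -> integration -> coexpression network, with
# every stage table written as headered TSV plus JSON manifests.

#' Pipeline configuration
#'
#' @param outdir output directory.
#' @param seed integer seed used by every stochastic stage (recorded in
#'   the run manifest and logs).
#' @param thresholds see [de_thresholds()].
#' @param control control sample id.
#' @param simulate named list of overrides for [simulate_experiment()].
#' @param stages character vector of stages to run after simulation; any
#'   of "srna", "hairpin", "degradome", "de", "integrate", "network".
#' @param fold_engine folding engine for the hairpin stage.
#' @return a config list for [run_pipeline()].
#' @export
pipeline_config <- function(outdir = tempfile("mirdegnet_run_"),
                            seed = 1,
                            thresholds = de_thresholds(),
                            control = "S1",
                            simulate = list(),
                            stages = c("srna", "hairpin", "degradome",
                                       "de", "integrate", "network"),
                            fold_engine = NULL) {
  known <- c("srna", "hairpin", "degradome", "de", "integrate", "network")
  if (length(setdiff(stages, known)) > 0) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  list(outdir = outdir, seed = as.integer(seed), thresholds = thresholds,
       control = control, simulate = simulate, stages = stages,
       fold_engine = fold_engine)
}

#' Run the full pipeline on a simulated experiment
#'
#' Stages run in order; a failing stage aborts with its name, keeping the
#' outputs already written. Reruns with an identical config reproduce the
#' stage tables byte for byte (the run manifest carries the only
#' timestamp).
#'
#' @param config see [pipeline_config()].
#' @return (invisibly) a list with the experiment and every stage result.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$outdir, ...)
  th <- config$thresholds
  message("[simulate] seed=", config$seed)
  experiment <- do.call(simulate_experiment,
                        c(config$simulate, list(seed = config$seed)))
  validate_manifest(experiment)
  write_experiment(experiment, config$outdir)
  res <- list(experiment = experiment)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if ("srna" %in% config$stages) {
    message("[srna] seed=", config$seed)
    res$catalog <- stage("srna", {
      catalog <- build_catalog(experiment$srna,
                               reference = experiment$mirnas)
      write_tsv(catalog, p("catalog.tsv"))
      catalog
    })
  }
  if ("hairpin" %in% config$stages) {
    message("[hairpin] seed=", config$seed)
    res$precursors <- stage("hairpin", {
      engine <- config$fold_engine %||% fold_engine_default()
      seed_tags <- data.frame(tag = experiment$mirnas$seq,
                              stringsAsFactors = FALSE)
      pre <- find_hairpins(seed_tags, experiment$hairpin_hosts,
                           catalog = res$catalog, engine = engine)
      write_tsv(pre, p("precursors.tsv"))
      write_fasta(
        vapply(seq_len(nrow(pre)), function(i) {
          substr(experiment$hairpin_hosts$seq[
            match(pre$source_id[i], experiment$hairpin_hosts$id)],
            pre$precursor_start[i], pre$precursor_end[i])
        }, character(1)),
        pre$id, p("precursors.fa"))
      pre
    })
  }
  if ("degradome" %in% config$stages) {
    message("[degradome] seed=", config$seed)
    res$targets <- stage("degradome", {
      hits <- call_targets(experiment$mirnas, experiment$transcripts,
                           experiment$degradome,
                           max_score = th$score_cutoff)
      out <- data.frame(`Small RNA` = hits$mirna_id,
                        Target = hits$transcript_id,
                        `Alignment Score` = hits$score,
                        `Cleavage Site` = hits$cleavage_site,
                        Category = hits$category,
                        check.names = FALSE)
      write_tsv(out, p("targets.tsv"))
      hits
    })
  }
  if ("de" %in% config$stages) {
    message("[de] seed=", config$seed)
    res$de_genes <- stage("de", {
      lens <- stats::setNames(experiment$transcripts$length,
                              experiment$transcripts$id)
      deg <- call_deg(experiment$gene_counts, lens,
                      control = config$control, thresholds = th)
      write_tsv(deg, p("de_genes.tsv"))
      deg
    })
    res$de_mirnas <- stage("de", {
      dem <- call_de_mirna(experiment$mirna_counts,
                           control = config$control, thresholds = th)
      write_tsv(dem$mirnas, p("de_mirnas.tsv"))
      write_tsv(dem$updown, p("updown_by_timepoint.tsv"))
      dem
    })
    stage("de", {
      z <- zscore(experiment$gene_counts)
      write_tsv(cbind(data.frame(feature = rownames(z)),
                      as.data.frame(z)), p("zscores.tsv"))
    })
  }
  if ("integrate" %in% config$stages) {
    message("[integrate] seed=", config$seed)
    res$pairs <- stage("integrate", {
      pr <- pair_de(res$de_mirnas$mirnas, res$targets, res$de_genes)
      pr <- correlate_pairs(pr, experiment$mirna_counts,
                            experiment$gene_counts,
                            negative_threshold = th$corr_negative)
      write_tsv(pr, p("pairs.tsv"))
      pr
    })
    res$enrichment <- stage("integrate", {
      de_targets <- unique(res$pairs$transcript_id)
      enr <- if (length(de_targets) > 0) {
        term_enrichment(de_targets, gene2term = experiment$gene2term)
      } else {
        data.frame(term = character(0), overlap = integer(0), p = numeric(0))
      }
      write_tsv(enr, p("enrichment.tsv"))
      enr
    })
    stage("integrate", {
      dir.create(p("tplots"), showWarnings = FALSE)
      profs <- map_degradome(experiment$degradome, experiment$transcripts)
      for (i in seq_len(nrow(res$pairs))) {
        tp <- tplot_data(profs[[res$pairs$transcript_id[i]]],
                         res$pairs$cleavage_site[i])
        write_tsv(tp, p("tplots", sprintf("%s_%s.tsv",
                                          res$pairs$mirna_id[i],
                                          res$pairs$transcript_id[i])))
      }
    })
  }
  if ("network" %in% config$stages) {
    message("[network] seed=", config$seed)
    res$network <- stage("network", {
      net <- build_network(experiment$coexpr$counts,
                           power = th$network_power)
      write_tsv(data.frame(gene = names(net$labels),
                           module = unname(net$labels),
                           connectivity = unname(
                             net$connectivity[names(net$labels)])),
                p("modules.tsv"))
      if (nrow(net$eigengenes) > 0) {
        write_tsv(cbind(data.frame(module = rownames(net$eigengenes)),
                        as.data.frame(net$eigengenes)),
                  p("eigengenes.tsv"))
      }
      hubs <- experiment$truth$planted_hubs
      sub <- hub_subnetwork(net$adjacency, hubs)
      write_tsv(sub$edges, p("edges.tsv"))
      c(net, list(hub_edges = sub))
    })
  }
  manifest <- list(
    package = "mirdegnet",
    version = as.character(utils::packageVersion("mirdegnet")),
    seed = config$seed,
    control = config$control,
    thresholds = th,
    stages = config$stages,
    simulate = config$simulate,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, p("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}
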