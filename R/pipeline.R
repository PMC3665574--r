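#' Pipeline configuration
#'
#' Builds and validates the flat configuration driving [run_pipeline()].
#' Defaults follow the conventional study thresholds: DE alpha 0.05 with
#' 1.5 / 0.67 fold-change gates, enrichment alpha 0.05, STRING score
#' cutoff 400, 1000 background replicates, 90% identity for coevolution
#' redundancy removal and a 0.95 flagging quantile.
#'
#' @param network path to a STRING-style protein-links TSV.
#' @param expression,design expression matrix and design TSV paths
#'   (alternatively supply `de_up`/`de_down` files of precomputed DE gene
#'   lists, one id per line).
#' @param mutations mutated-gene list TSV path.
#' @param annotations annotation map path.
#' @param output_dir output directory.
#' @param ... overrides of the defaults listed by
#'   `pipeline_config_defaults()`: `alpha`, `fc_up`, `fc_down`, `adjust`,
#'   `knn_k`, `lowess_span`, `score_threshold`, `weight_scheme`,
#'   `n_replicates`, `core_mode`, `core_k`, `core_threshold`,
#'   `core_terms`, `annotation_format`, `universe`, `de_up`, `de_down`,
#'   `msa`, `msa_reference`, `identity_threshold`, `flag_quantile`,
#'   `max_gap_fraction`, `min_term_size`, `rng_seed`, `log2_scale`.
#' @return object of class `pipeline_config` (a named list with a
#'   `config_hash` attribute).
#' @export
pipeline_config <- function(network, mutations, annotations, output_dir,
                            expression = NULL, design = NULL, ...) {
  cfg <- pipeline_config_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop_mssnet("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$network <- network
  cfg$mutations <- mutations
  cfg$annotations <- annotations
  cfg$output_dir <- output_dir
  cfg$expression <- expression
  cfg$design <- design
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @export
pipeline_config_defaults <- function() {
  list(network = NULL, mutations = NULL, annotations = NULL,
       output_dir = NULL, expression = NULL, design = NULL,
       de_up = NULL, de_down = NULL,
       alpha = 0.05, fc_up = 1.5, fc_down = 0.67, adjust = "holm",
       knn_k = 10, lowess_span = 0.4, log2_scale = NA,
       score_threshold = 400, weight_scheme = "unit",
       n_replicates = 1000,
       core_mode = "top_k", core_k = 4, core_threshold = 0.5,
       core_terms = NULL, annotation_format = "tsv2col", universe = NULL,
       min_term_size = 2,
       msa = NULL, msa_reference = NULL, identity_threshold = 0.90,
       flag_quantile = 0.95, max_gap_fraction = 0.5,
       rng_seed = 17)
}

validate_config <- function(cfg) {
  for (key in c("network", "mutations", "annotations", "output_dir")) {
    if (is.null(cfg[[key]]))
      stop_mssnet("config is missing required key '%s'", key)
  }
  has_expr <- !is.null(cfg$expression) && !is.null(cfg$design)
  has_lists <- !is.null(cfg$de_up) && !is.null(cfg$de_down)
  if (!has_expr && !has_lists)
    stop_mssnet(
      "config needs either expression + design or de_up + de_down gene lists")
  for (key in c("network", "mutations", "annotations", "expression",
                "design", "de_up", "de_down", "msa")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p))
      stop_mssnet("config path '%s' (%s) does not exist", p, key)
  }
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$fc_up > 1,
            cfg$fc_down < 1, cfg$fc_down > 0, cfg$n_replicates >= 2)
  # hash of the canonicalized config identifies the analysis in output
  # headers; the output location is not part of the analysis identity
  canon <- cfg[setdiff(sort(names(cfg)), "output_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(canon), tmp)
  attr(cfg, "config_hash") <- substr(unname(tools::md5sum(tmp)), 1, 10)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with keys as in [pipeline_config()].
#' @param overrides named list applied on top of the file (CLI flags).
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config_defaults()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown) > 0)
    stop_mssnet("unknown config key(s) in %s: %s", path,
                paste(unknown, collapse = ", "))
  cfg[names(raw)] <- raw
  cfg[names(overrides)] <- overrides
  validate_config(cfg)
}

#' Run the full driver-prioritization workflow
#'
#' Executes the staged workflow: (A) load the network, mutations and
#' annotations; (B) call DE genes from the expression contrast (or load
#' precomputed lists); (C) build and score one MSSN per seed and
#' direction; (D) per-MSSN overrepresentation, cross-MSSN core-pathway
#' profile and the tiered driver ranking; optionally (E) the coevolution
#' consensus for mutations covered by a supplied MSA.  Stage outputs are
#' written before the next stage runs; identical config + seed reruns are
#' byte-identical.  A stage failure leaves a `FAILED` marker file naming
#' the stage.
#'
#' @param config a [pipeline_config], or a YAML path.
#' @param quiet suppress progress messages.
#' @param dry_run validate all inputs, print the execution plan and return
#'   `NULL` without computing.
#' @return list with `de`, `stats` (per seed x direction data.frame),
#'   `mssns`, `enrichment`, `core`, `core_terms`, `ranking` and (when an
#'   MSA is configured) `coevolution`.
#' @export
run_pipeline <- function(config, quiet = FALSE, dry_run = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  hash <- attr(config, "config_hash")
  seed <- config$rng_seed
  if (dry_run) {
    plan <- c("load_inputs",
              if (!is.null(config$expression)) "dge" else "dge (precomputed)",
              "mssn", "enrichment", "ranking",
              if (!is.null(config$msa)) "coevolution")
    message(sprintf("dry run (config %s, seed %s): %s", hash, seed,
                    paste(plan, collapse = " -> ")))
    return(invisible(NULL))
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(config$output_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- "load_inputs"
  res <- tryCatch({
    say("[%s] reading inputs", stage)
    net <- read_string_links(config$network,
                             score_threshold = config$score_threshold,
                             weight_scheme = config$weight_scheme)
    muts <- read_gene_list(config$mutations)
    ann <- read_annotation_map(config$annotations,
                               format = config$annotation_format,
                               universe = config$universe)

    stage <- "dge"
    if (!is.null(config$expression)) {
      say("[%s] differential expression", stage)
      em <- read_expression_matrix(config$expression, config$design,
                                   log2_scale = config$log2_scale)
      if (anyNA(em$values)) em <- knn_impute(em, k = config$knn_k)
      tt <- two_class_ttest(em)
      de <- call_de_genes(tt, alpha = config$alpha,
                          up_threshold = config$fc_up,
                          down_threshold = config$fc_down,
                          adjust = config$adjust)
      write_tsv_provenance(de$table,
                           file.path(config$output_dir, "de_genes.tsv"),
                           hash, seed)
    } else {
      say("[%s] loading precomputed DE lists", stage)
      de <- list(up = trimws(readLines(config$de_up)),
                 down = trimws(readLines(config$de_down)))
    }

    stage <- "mssn"
    say("[%s] mutation-seeded subnetworks (%d seeds)", stage,
        length(unique(muts$gene)))
    nodes <- network_nodes(net)
    seeds <- unique(muts$gene)
    in_net <- seeds %in% nodes
    if (any(!in_net))
      warn_mssnet("%d seed gene(s) absent from the network: %s",
                  sum(!in_net), paste(seeds[!in_net], collapse = ", "))
    dist_matrix <- NULL
    if (length(nodes) <= 2000)
      dist_matrix <- igraph::distances(net$graph,
                                       weights = igraph::E(net$graph)$weight,
                                       algorithm = "dijkstra")
    mssns <- list(); stat_rows <- list()
    mssn_dir <- file.path(config$output_dir, "mssn")
    dir.create(mssn_dir, showWarnings = FALSE)
    for (sd in seeds[in_net]) {
      for (dir in c("up", "down")) {
        de_set <- de[[dir]]
        if (length(intersect(setdiff(de_set, sd), nodes)) == 0) next
        ms <- mssn_statistics(net, sd, de_set, dir,
                              n_replicates = config$n_replicates,
                              rng_seed = seed, dist_matrix = dist_matrix)
        key <- paste(sd, dir, sep = ":")
        mssns[[key]] <- ms$mssn
        st <- ms$stats
        stat_rows[[key]] <- data.frame(
          seed = sd, direction = dir,
          n_targets = length(ms$mssn$targets),
          n_reachable = length(ms$mssn$distances),
          mean_mssn = if (inherits(st, "path_statistics")) st$mean_mssn else NA,
          mean_bg = if (inherits(st, "path_statistics")) st$mean_bg else NA,
          t = if (inherits(st, "path_statistics")) st$t else NA,
          z = if (inherits(st, "path_statistics")) st$z else NA,
          empirical_p = if (inherits(st, "path_statistics"))
            st$empirical_p else NA,
          stringsAsFactors = FALSE)
        write_mssn_files(ms$mssn, mssn_dir, hash, seed)
      }
    }
    if (length(stat_rows) == 0)
      stop_mssnet("no seed produced a scorable subnetwork")
    stats <- do.call(rbind, c(stat_rows, list(make.row.names = FALSE)))
    write_tsv_provenance(stats, file.path(config$output_dir,
                                          "mssn_stats.tsv"), hash, seed)

    stage <- "enrichment"
    say("[%s] overrepresentation analysis (%d subnetworks)", stage,
        length(mssns))
    enr_dir <- file.path(config$output_dir, "enrich")
    dir.create(enr_dir, showWarnings = FALSE)
    enrichment <- lapply(mssns, function(m)
      enrich_subnetwork(m, ann, alpha = config$alpha,
                        min_term_size = config$min_term_size))
    for (key in names(enrichment))
      write_tsv_provenance(enrichment[[key]],
                           file.path(enr_dir, paste0(gsub(":", "_", key),
                                                     ".tsv")), hash, seed)
    core <- core_pathways(enrichment, alpha = config$alpha)
    write_tsv_provenance(core$profile,
                         file.path(config$output_dir, "core_pathways.tsv"),
                         hash, seed)
    core_terms <- designate_core(core, mode = config$core_mode,
                                 k = config$core_k,
                                 threshold = config$core_threshold,
                                 terms = config$core_terms, ann = ann)

    stage <- "ranking"
    say("[%s] ranking %d seeds against %d core term(s)", stage,
        length(seeds), length(core_terms))
    enrich_by_seed <- split_enrichment_by_seed(enrichment)
    ranking <- rank_drivers(stats, enrich_by_seed, core_terms,
                            mutations = muts, alpha = config$alpha)
    write_tsv_provenance(as.data.frame(ranking),
                         file.path(config$output_dir, "drivers.tsv"),
                         hash, seed)

    coevo <- NULL
    if (!is.null(config$msa)) {
      stage <- "coevolution"
      say("[%s] residue coevolution", stage)
      m <- read_msa(config$msa, reference = config$msa_reference)
      coevo <- list()
      for (r in which(!is.na(muts$substitution))) {
        token <- muts$substitution[r]
        cv <- tryCatch(
          coevolve(m, token,
                   identity_threshold = config$identity_threshold,
                   flag_quantile = config$flag_quantile,
                   max_gap_fraction = config$max_gap_fraction),
          error = function(e) e)
        if (inherits(cv, "error")) {
          say("  %s %s: skipped (%s)", muts$gene[r], token,
              conditionMessage(cv))
          next
        }
        coevo[[paste(muts$gene[r], token, sep = ":")]] <- cv
        write_tsv_provenance(
          cv$consensus$couplings,
          file.path(config$output_dir,
                    sprintf("coevolution_%s_%s.tsv", muts$gene[r], token)),
          hash, seed)
      }
    }
    list(de = de, stats = stats, mssns = mssns, enrichment = enrichment,
         core = core, core_terms = core_terms, ranking = ranking,
         coevolution = coevo)
  }, error = function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               failed_marker)
    stop_mssnet("pipeline failed at stage '%s': %s", stage,
                conditionMessage(e))
  })
  writeLines(yaml::as.yaml(unclass(config)),
             file.path(config$output_dir, "run_config.yaml"))
  res
}

split_enrichment_by_seed <- function(enrichment) {
  keys <- strsplit(names(enrichment), ":", fixed = TRUE)
  out <- list()
  for (k in seq_along(keys)) {
    sd <- keys[[k]][1]; dir <- keys[[k]][2]
    if (is.null(out[[sd]])) out[[sd]] <- list()
    out[[sd]][[dir]] <- enrichment[[k]]
  }
  out
}

write_mssn_files <- function(m, dir, hash, seed) {
  base <- sprintf("%s_%s", m$seed, m$direction)
  edges <- as.data.frame(m$edges, stringsAsFactors = FALSE)
  write_tsv_provenance(edges, file.path(dir, paste0(base, "_edges.tsv")),
                       hash, seed)
  # SIF for network-viewer import: node <tab> interaction <tab> node
  sif <- sprintf("%s\tpp\t%s", m$edges[, 1], m$edges[, 2])
  writeLines(sif, file.path(dir, paste0(base, ".sif")))
  invisible(base)
}
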