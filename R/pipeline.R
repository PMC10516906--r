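#' Derive a per-stage RNG seed from the global run seed
#'
#' One global seed expands deterministically into distinct per-stage seeds
#' via a small stage-name hash, so stages are reproducible in isolation.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

.cfg <- function(x, name, default = NULL) {
  if (!is.null(x[[name]])) x[[name]] else default
}

.enabled <- function(config, stage) isTRUE(.cfg(config[[stage]], "enabled", FALSE))

#' Run the full analysis pipeline from one configuration
#'
#' Stages (each toggled by \code{<stage>$enabled}): \code{simulate} a
#' synthetic community (or read \code{inputs$table} / \code{inputs$tree} /
#' \code{inputs$metadata}), \code{rarefy}, \code{ordinate} (Bray-Curtis +
#' NMDS + PERMANOVA), \code{assembly} (betaNTI), \code{network} (RMT
#' threshold + co-occurrence graph), and \code{stats} (Mantel regression of
#' community dissimilarity against the assembly-process matrix).  All
#' intermediates are written under \code{output_dir}; a manifest records
#' parameters, per-stage seeds and md5 checksums of every output, so
#' identical config + seed reproduces identical checksums.  Configuration
#' is validated before any stage runs, and a stage failure aborts with the
#' stage name.
#'
#' @param config a named list, or path to a YAML file with the same
#'   structure; must contain \code{output_dir} and \code{seed}.
#' @return the manifest, invisibly (also written as manifest.json).
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- .cfg(config, "output_dir")
  if (is.null(out_dir)) stop("config needs output_dir", call. = FALSE)
  seed <- .cfg(config, "seed", 1)

  # fail fast: every enabled stage must have its inputs resolvable
  have_table <- .enabled(config, "simulate") ||
    !is.null(.cfg(config$inputs, "table"))
  have_tree <- .enabled(config, "simulate") ||
    !is.null(.cfg(config$inputs, "tree"))
  have_groups <- .enabled(config, "simulate") ||
    !is.null(.cfg(config$inputs, "metadata"))
  for (stage in c("rarefy", "ordinate", "assembly", "network", "stats"))
    if (.enabled(config, stage) && !have_table)
      stop("stage '", stage, "' enabled but no count table is configured",
           call. = FALSE)
  if (.enabled(config, "assembly") && !have_tree)
    stop("stage 'assembly' enabled but no tree is configured", call. = FALSE)
  if (.enabled(config, "ordinate") && !have_groups)
    stop("stage 'ordinate' enabled but no sample metadata is configured",
         call. = FALSE)
  if (.enabled(config, "stats") &&
      !(.enabled(config, "ordinate") && .enabled(config, "assembly")))
    stop("stage 'stats' needs the ordinate and assembly stages enabled",
         call. = FALSE)
  for (p in unlist(config$inputs))
    if (!file.exists(p)) stop("configured input does not exist: ", p, call. = FALSE)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, stages = list(), outputs = list())
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  tree <- NULL; groups <- NULL
  if (.enabled(config, "simulate")) {
    sc <- config$simulate$scenario
    s_seed <- stage_seed(seed, "simulate")
    scenario <- assembly_scenario(
      regime = .cfg(sc, "regime", "neutral"),
      n_taxa = .cfg(sc, "n_taxa", 60),
      n_samples = .cfg(sc, "n_samples", 10),
      depth = .cfg(sc, "depth", 2000),
      selection_strength = .cfg(sc, "selection_strength", 0.5),
      n_blocks = .cfg(sc, "n_blocks", 2),
      seed = s_seed)
    run_stage("simulate", {
      tree <- simulate_tree(scenario$n_taxa, seed = s_seed)
      table <- simulate_communities(tree, scenario)
      blocks <- if (scenario$regime == "variable_selection")
        sort(rep(seq_len(scenario$n_blocks), length.out = scenario$n_samples))
      else rep(1:2, length.out = scenario$n_samples)
      groups <- stats::setNames(paste0("g", blocks), colnames(table))
      write_count_table(table, file.path(out_dir, "table.tsv"))
      ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
      utils::write.table(
        data.frame(sample_id = colnames(table), group = groups),
        file.path(out_dir, "metadata.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      jsonlite::write_json(
        list(regime = scenario$regime, seed = s_seed,
             optima = attr(table, "optima")),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
      manifest$stages$simulate <- list(seed = s_seed, regime = scenario$regime,
                                        n_taxa = scenario$n_taxa,
                                        n_samples = scenario$n_samples)
      table
    }) -> table
  } else {
    table <- if (have_table) read_count_table(config$inputs$table) else NULL
    if (have_tree && !is.null(.cfg(config$inputs, "tree")))
      tree <- read_tree(config$inputs$tree)
    if (!is.null(.cfg(config$inputs, "metadata"))) {
      md <- read_sample_metadata(config$inputs$metadata)
      if (!is.null(table)) groups <- sample_groups(md, colnames(table))
    }
  }

  if (.enabled(config, "rarefy")) {
    s_seed <- stage_seed(seed, "rarefy")
    depth <- .cfg(config$rarefy, "depth", min(colSums(table)))
    table <- run_stage("rarefy", rarefy(table, depth, seed = s_seed))
    if (!is.null(groups)) groups <- groups[colnames(table)]
    write_count_table(table, file.path(out_dir, "table_rarefied.tsv"))
    manifest$stages$rarefy <- list(seed = s_seed, depth = depth,
                                   n_samples_kept = ncol(table))
  }

  bc <- NULL
  if (.enabled(config, "ordinate")) {
    s_seed <- stage_seed(seed, "ordinate")
    run_stage("ordinate", {
      bc <- bray_curtis(table)
      ord <- nmds(bc, k = .cfg(config$ordinate, "k", 2), seed = s_seed)
      pmv <- permanova(bc, groups,
                       n_perm = .cfg(config$ordinate, "n_perm", 999),
                       seed = s_seed)
      write_distance_matrix(bc, file.path(out_dir, "bray_curtis.tsv"))
      utils::write.table(
        data.frame(sample_id = rownames(ord$points), ord$points,
                   group = groups[rownames(ord$points)]),
        file.path(out_dir, "nmds_coordinates.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(stress = ord$stress, permanova_f = pmv$f, permanova_r2 = pmv$r2,
             permanova_p = pmv$p, n_perm = pmv$n_perm),
        file.path(out_dir, "ordination.json"), auto_unbox = TRUE, digits = NA)
      manifest$stages$ordinate <- list(seed = s_seed, stress = ord$stress,
                                       permanova_p = pmv$p)
    })
  }

  bnti_m <- NULL
  if (.enabled(config, "assembly")) {
    s_seed <- stage_seed(seed, "assembly")
    run_stage("assembly", {
      res <- beta_nti(table, tree,
                      n_rand = .cfg(config$assembly, "n_rand", 1000),
                      weighted = .cfg(config$assembly, "weighted", TRUE),
                      seed = s_seed)
      utils::write.table(res, file.path(out_dir, "assembly_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      bnti_m <- assembly_distance_matrix(res)
      write_distance_matrix(bnti_m, file.path(out_dir, "bnti_matrix.tsv"))
      manifest$stages$assembly <- list(
        seed = s_seed, n_rand = res$n_randomizations[1],
        weighted = .cfg(config$assembly, "weighted", TRUE),
        class_counts = as.list(table(res$assembly_class)))
    })
  }

  if (.enabled(config, "network")) {
    run_stage("network", {
      r <- correlation_matrix(
        table, prevalence = .cfg(config$network, "prevalence", 0.5),
        pseudo_zero_factor = .cfg(config$network, "pseudo_zero", 0.01))
      s_star <- .cfg(config$network, "threshold")
      scan <- NULL
      if (is.null(s_star)) {
        th <- rmt_threshold(r)
        s_star <- th$s_star
        scan <- th$scan
        utils::write.table(scan, file.path(out_dir, "threshold_scan.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      net <- build_network(r, s_star,
                           positive_only = .cfg(config$network, "positive_only",
                                                FALSE))
      write_graphml(net, file.path(out_dir, "network.graphml"))
      utils::write.table(net$edges, file.path(out_dir, "network_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(taxon = net$nodes, degree = as.integer(net$degree)),
        file.path(out_dir, "network_nodes.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      manifest$stages$network <- list(s_star = s_star,
                                      n_nodes = length(net$nodes),
                                      n_edges = nrow(net$edges))
    })
  }

  if (.enabled(config, "stats")) {
    s_seed <- stage_seed(seed, "stats")
    run_stage("stats", {
      mt <- mantel(bc, bnti_m, n_perm = .cfg(config$stats, "n_perm", 999),
                   seed = s_seed)
      jsonlite::write_json(
        list(mantel_r = mt$r, mantel_p = mt$p, n_perm = mt$n_perm,
             kind = mt$kind),
        file.path(out_dir, "mantel.json"), auto_unbox = TRUE, digits = NA)
      manifest$stages$stats <- list(seed = s_seed, mantel_r = mt$r,
                                    mantel_p = mt$p)
    })
  }

  skipped <- setdiff(c("simulate", "rarefy", "ordinate", "assembly",
                       "network", "stats"), names(manifest$stages))
  manifest$skipped_stages <- skipped
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$outputs <- as.list(tools::md5sum(files))
  names(manifest$outputs) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
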