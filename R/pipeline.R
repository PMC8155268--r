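#' Export a network to Cytoscape-importable edge and node tables
#'
#' Edges are the unordered gene pairs whose weight in the chosen matrix (TOM
#' by default, adjacency as fallback or on request) reaches `threshold`; each
#' pair appears once (source before target in gene order). Nodes carry the
#' module label and any extra attributes. Grey-module genes are excluded by
#' default.
#'
#' @param net `gene_network` from [build_network()], or a bare weight matrix.
#' @param partition Optional named gene -> module vector for node labels and
#'   grey exclusion.
#' @param threshold Minimum edge weight in `[0, 1]`.
#' @param matrix_choice `"tom"` (default; falls back to adjacency when the
#'   network has no TOM) or `"adjacency"`.
#' @param node_attrs Optional data.frame with a `gene` column of extra node
#'   attributes.
#' @param exclude_grey Drop grey-module genes before exporting (default TRUE;
#'   ignored when no partition is given).
#' @param edge_file,node_file Optional paths; when given, tab-separated tables
#'   are written.
#' @return List with data.frames `edges` (source, target, weight) and `nodes`
#'   (gene, module, ...), invisibly when files are written.
#' @export
export_cytoscape <- function(net, partition = NULL, threshold = 0.05,
                             matrix_choice = c("tom", "adjacency"),
                             node_attrs = NULL, exclude_grey = TRUE,
                             edge_file = NULL, node_file = NULL) {
  matrix_choice <- match.arg(matrix_choice)
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  w <- if (is.matrix(net)) net
       else if (matrix_choice == "tom" && !is.null(net$tom)) net$tom
       else net$adjacency
  genes <- rownames(w)
  if (!is.null(partition) && exclude_grey) {
    keep <- genes[genes %in% names(partition)[partition != "grey"]]
    w <- w[keep, keep, drop = FALSE]
    genes <- keep
  }
  ut <- upper.tri(w)
  hit <- which(ut & w >= threshold, arr.ind = TRUE)
  edges <- data.frame(source = genes[hit[, 1L]], target = genes[hit[, 2L]],
                      weight = w[hit], stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(gene = genes, stringsAsFactors = FALSE)
  if (!is.null(partition)) nodes$module <- unname(unclass(partition)[genes])
  if (!is.null(node_attrs)) {
    nodes <- merge(nodes, node_attrs, by = "gene", all.x = TRUE, sort = TRUE)
  }
  nodes <- nodes[order(nodes$gene), , drop = FALSE]
  rownames(nodes) <- NULL
  out <- list(edges = edges, nodes = nodes)
  if (!is.null(edge_file)) write_tsv(edges, edge_file)
  if (!is.null(node_file)) write_tsv(nodes, node_file)
  if (is.null(edge_file) && is.null(node_file)) out else invisible(out)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full co-expression comparison pipeline from a config
#'
#' Per dataset: read (or simulate), optional probe collapse and log2
#' transform, quality screen, MAD filter, soft-threshold scan, network with
#' TOM, module detection with eigengene merging, optional enrichment, and a
#' Cytoscape export. Across datasets: Venn decomposition of analyzed gene
#' sets, pairwise module cross-tabulation and connectivity rank divergence,
#' plus optional neighbour lookup and druggability rank join. Every table is
#' written under `out_dir` and listed in `manifest.tsv`; `log.txt` records
#' parameters and package version. Outputs are a pure function of (inputs,
#' config, seed): a rerun reproduces them byte for byte.
#'
#' @param config Path to a YAML file or an equivalent nested list. Top level:
#'   `seed`, `datasets` (named; each with either `path`/`delimiter`/
#'   `genes_in_rows` or `simulate` holding [synthetic_spec()] fields, plus
#'   optional `log2`, `log2_offset`, `probe_map`, `max_missing_frac`,
#'   `min_variance`, `mad_top`, `powers`, `r2_target`, `power`, `signed`,
#'   `min_module_size`, `cut_height_quantile`, `merge_cut_height`,
#'   `gene_sets`, `export_threshold`, `export_matrix`), and optional
#'   `compare` (`neighbors`: dataset/gene/top_n; `druggability`:
#'   scores/top_n; `rank_within`).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the per-dataset results (`datasets`),
#'   cross-dataset results (`compare`) and the manifest data.frame.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$datasets) || length(cfg$datasets) < 1L ||
      is.null(names(cfg$datasets))) {
    stop("config key 'datasets' must name at least one dataset")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  manifest <- data.frame(stage = character(0), dataset = character(0),
                         file = character(0), stringsAsFactors = FALSE)
  log_lines <- c(sprintf("coexdiff pipeline, package version %s",
                         as.character(utils::packageVersion("coexdiff"))),
                 sprintf("seed: %d", seed),
                 sprintf("datasets: %s", paste(names(cfg$datasets), collapse = ", ")))
  note <- function(stage, dataset, file) {
    manifest[nrow(manifest) + 1L, ] <<- list(stage, dataset, file)
  }
  emit <- function(df, stage, dataset, file) {
    write_tsv(df, file.path(out_dir, file)); note(stage, dataset, file)
  }

  results <- list()
  for (nm in names(cfg$datasets)) {
    dc <- cfg$datasets[[nm]]
    step <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("pipeline stage '%s' failed for dataset '%s': %s",
                     what, nm, conditionMessage(e)), call. = FALSE)
      })
    }
    m <- if (!is.null(dc$simulate)) {
      sim_args <- dc$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- seed
      if (!is.null(sim_args$module_sizes)) sim_args$module_sizes <- unlist(sim_args$module_sizes)
      if (!is.null(sim_args$loading_range)) sim_args$loading_range <- unlist(sim_args$loading_range)
      sim <- simulate_expression(do.call(synthetic_spec, sim_args))
      results[[nm]]$truth <- sim$truth
      sim$expression
    } else if (!is.null(dc$path)) {
      step("read", read_expression(dc$path,
                                   delimiter = if (is.null(dc$delimiter)) "\t" else dc$delimiter,
                                   genes_in_rows = !isFALSE(dc$genes_in_rows)))
    } else {
      stop(sprintf("dataset '%s' needs either 'path' or 'simulate' in the config", nm))
    }
    if (!is.null(dc$probe_map)) {
      pm <- utils::read.table(dc$probe_map, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
      m <- step("collapse_probes", collapse_probes(m, pm))
    }
    if (isTRUE(dc$log2)) {
      m <- step("log2_transform",
                log2_transform(m, offset = if (is.null(dc$log2_offset)) 0 else dc$log2_offset))
    }
    qf <- step("quality_filter",
               quality_filter(m,
                              max_missing_frac = if (is.null(dc$max_missing_frac)) 0.5 else dc$max_missing_frac,
                              min_variance = if (is.null(dc$min_variance)) 0 else dc$min_variance))
    m <- qf$matrix
    outliers <- step("detect_sample_outliers", detect_sample_outliers(m))
    if (length(outliers) > 0L) m <- m[, !(colnames(m) %in% outliers), drop = FALSE]
    qc_tab <- rbind(
      data.frame(item = qf$report$removed_genes$gene,
                 kind = rep("gene", nrow(qf$report$removed_genes)),
                 reason = qf$report$removed_genes$reason, stringsAsFactors = FALSE),
      data.frame(item = outliers, kind = rep("sample", length(outliers)),
                 reason = rep("outlier", length(outliers)), stringsAsFactors = FALSE))
    emit(qc_tab, "qc", nm, sprintf("%s_qc_report.tsv", nm))
    if (!is.null(dc$mad_top)) m <- mad_filter(m, dc$mad_top)

    powers <- if (is.null(dc$powers)) 1:20 else unlist(dc$powers)
    scan <- step("soft_threshold_scan",
                 soft_threshold_scan(m, powers = powers,
                                     r2_target = if (is.null(dc$r2_target)) 0.85 else dc$r2_target,
                                     signed = isTRUE(dc$signed)))
    emit(scan$table, "power_scan", nm, sprintf("%s_power_scan.tsv", nm))
    power <- as.integer(if (!is.null(dc$power)) dc$power else scan$chosen_power)
    if (is.na(power)) stop(sprintf("pipeline stage 'power selection' failed for dataset '%s': no power reached the scale-free target; set 'power' in the config", nm))
    net <- step("network", build_network(m, power = power, signed = isTRUE(dc$signed)))

    part <- step("detect_modules",
                 detect_modules(net$tom,
                                min_module_size = if (is.null(dc$min_module_size)) 100L else dc$min_module_size,
                                cut_height_quantile = if (is.null(dc$cut_height_quantile)) 0.85 else dc$cut_height_quantile))
    if (any(part != "grey")) {
      part <- step("merge_modules",
                   merge_similar_modules(m, part,
                                         merge_cut_height = if (is.null(dc$merge_cut_height)) 0.15 else dc$merge_cut_height))
      eig <- module_eigengenes(m, part)
      emit(data.frame(module = rownames(eig$eigengenes), eig$eigengenes,
                      check.names = FALSE), "eigengenes", nm,
           sprintf("%s_eigengenes.tsv", nm))
    }
    emit(data.frame(gene = names(part), module = unname(unclass(part)),
                    stringsAsFactors = FALSE),
         "modules", nm, sprintf("%s_modules.tsv", nm))
    prof <- connectivity_profile(net$adjacency)
    emit(as.data.frame(prof), "connectivity", nm, sprintf("%s_connectivity.tsv", nm))

    if (!is.null(dc$gene_sets) && any(part != "grey")) {
      sets <- step("read_gene_sets", read_gene_sets(dc$gene_sets))
      enr <- step("enrichment", enrich_partition(part, sets))
      emit(enr, "enrichment", nm, sprintf("%s_enrichment.tsv", nm))
      results[[nm]]$enrichment <- enr
    }
    if (any(part != "grey")) {
      exp_files <- export_cytoscape(
        net, part,
        threshold = if (is.null(dc$export_threshold)) 0.05 else dc$export_threshold,
        matrix_choice = if (is.null(dc$export_matrix)) "tom" else dc$export_matrix,
        edge_file = file.path(out_dir, sprintf("%s_edges.tsv", nm)),
        node_file = file.path(out_dir, sprintf("%s_nodes.tsv", nm)))
      note("export", nm, sprintf("%s_edges.tsv", nm))
      note("export", nm, sprintf("%s_nodes.tsv", nm))
    }
    results[[nm]]$matrix <- m
    results[[nm]]$scan <- scan
    results[[nm]]$network <- net
    results[[nm]]$partition <- part
    results[[nm]]$profile <- prof
    log_lines <- c(log_lines,
                   sprintf("dataset %s: %d genes x %d samples, power %d, %d module(s)",
                           nm, nrow(m), ncol(m), power,
                           length(setdiff(unique(unclass(part)), "grey"))))
  }

  compare <- list()
  if (length(results) >= 2L) {
    gene_lists <- lapply(results, function(r) rownames(r$matrix))
    venn <- venn_decompose(gene_lists[seq_len(min(3L, length(gene_lists)))])
    emit(data.frame(region = names(venn$regions), count = unname(venn$regions),
                    stringsAsFactors = FALSE), "venn", "all", "venn.tsv")
    compare$venn <- venn
    nms <- names(results)
    rank_within <- if (is.null(cfg$compare$rank_within)) "common" else cfg$compare$rank_within
    for (i in seq_len(length(nms) - 1L)) for (j in seq((i + 1L), length(nms))) {
      pa <- nms[i]; pb <- nms[j]; tag <- paste0(pa, "_vs_", pb)
      ct <- module_crosstab(results[[pa]]$partition, results[[pb]]$partition)
      emit(ct, "crosstab", tag, sprintf("crosstab_%s.tsv", tag))
      dv <- connectivity_rank_divergence(results[[pa]]$profile, results[[pb]]$profile,
                                         rank_within = rank_within)
      emit(dv$table, "rank_divergence", tag, sprintf("rank_divergence_%s.tsv", tag))
      emit(dv$histogram, "rank_divergence_hist", tag,
           sprintf("rank_divergence_hist_%s.tsv", tag))
      compare$crosstab[[tag]] <- ct
      compare$divergence[[tag]] <- dv
      log_lines <- c(log_lines, sprintf("%s: mean |rank diff| %.2f over %d common genes",
                                        tag, dv$mean_abs_rank_diff, nrow(dv$table)))
    }
  }
  nb <- cfg$compare$neighbors
  if (!is.null(nb)) {
    if (is.null(nb$dataset) || is.null(nb$gene)) stop("config key 'compare.neighbors' needs 'dataset' and 'gene'")
    nbt <- gene_neighbors(results[[nb$dataset]]$matrix, nb$gene,
                          top_n = if (is.null(nb$top_n)) 50L else nb$top_n)
    emit(nbt, "neighbors", nb$dataset, sprintf("neighbors_%s_%s.tsv", nb$dataset, nb$gene))
    compare$neighbors <- nbt
  }
  dg <- cfg$compare$druggability
  if (!is.null(dg)) {
    if (is.null(dg$scores)) stop("config key 'compare.druggability' needs 'scores'")
    scores <- read_score_table(dg$scores)
    dj <- druggability_rank_join(scores, lapply(results, `[[`, "profile"),
                                 top_n = if (is.null(dg$top_n)) 30L else dg$top_n)
    for (nm in names(dj$top_sets)) {
      emit(dj$top_sets[[nm]], "druggability", nm, sprintf("druggability_top_%s.tsv", nm))
    }
    emit(data.frame(dataset = rownames(dj$overlap), dj$overlap, check.names = FALSE),
         "druggability_overlap", "all", "druggability_overlap.tsv")
    compare$druggability <- dj
  }

  emit(manifest, "manifest", "all", "manifest.tsv")
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(datasets = results, compare = compare, manifest = manifest))
}
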