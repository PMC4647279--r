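# End-to-end orchestration: sign -> classify -> build -> reduce ->
# weight -> enumerate -> score -> report, with reproducible outputs.

#' Pipeline configuration
#'
#' Defaults follow the method's stated parameters: signature heights 1
#' and 2, cophenetic cut 90 for the height-2 refinement, PageRank
#' damping 0.85, loop-free paths of length 1 to 4, conserved modules at
#' PCI >= 2.
#'
#' @param heights RMS heights to compute (subset of `c(1, 2)`; height 1
#'   is required).
#' @param h2_threshold cophenetic distance threshold for height-2
#'   sub-classification.
#' @param h2_linkage Ward linkage variant for `hclust`.
#' @param damping,pagerank_tol PageRank parameters.
#' @param min_len,max_len path length range in edges.
#' @param min_pci PCI threshold defining a conserved module.
#' @param support PCI support rule (see [compute_pci()]).
#' @param summary_length window length of the pathway-type summary.
#' @param seed seed for any sampling utilities.
#' @return An `rms_config` list.
#' @export
rms_config <- function(heights = c(1L, 2L), h2_threshold = 90,
                       h2_linkage = "ward.D", damping = 0.85,
                       pagerank_tol = 1e-9, min_len = 1L, max_len = 4L,
                       min_pci = 2L, support = "pathway",
                       summary_length = 2L, seed = 1L) {
  stopifnot(1L %in% heights, min_len >= 1L, max_len >= min_len)
  structure(list(heights = as.integer(heights), h2_threshold = h2_threshold,
                 h2_linkage = h2_linkage, damping = damping,
                 pagerank_tol = pagerank_tol, min_len = as.integer(min_len),
                 max_len = as.integer(max_len), min_pci = as.integer(min_pci),
                 support = support, summary_length = as.integer(summary_length),
                 seed = as.integer(seed)),
            class = "rms_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Fields not present fall back to the defaults of [rms_config()].
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return An `rms_config`.
#' @export
read_rms_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed to read YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(rms_config, vals[intersect(names(vals), names(formals(rms_config)))])
}

#' Run the full RMS-network pipeline
#'
#' Classifies the reactions, builds the main-compound reaction network,
#' reduces it at each requested height, computes node weights, scores
#' all loop-free paths, extracts conserved modules, summarises pathway
#' conservation by type, and (when EC numbers are present) compares the
#' classification with the EC hierarchy.
#'
#' @param reactions reaction tibble (see [read_reactions()]).
#' @param pathways pathway link tibble (see [read_pathways()]).
#' @param molecules named list of `rms_molecule` objects.
#' @param proteins optional protein tibble (see [read_proteins()]).
#' @param config an [rms_config()].
#' @param out_dir optional output directory: classification, edge
#'   lists, weights, path tables, module report and provenance log are
#'   written as TSV/JSON.
#' @return An object of class `rms_run`: list with `classification`,
#'   `reaction_network`, and per height `rms_network`, `weights`,
#'   `paths`, `modules`, `summary`; plus `ec_comparison` and
#'   `provenance`.
#' @export
run_rms_pipeline <- function(reactions, pathways, molecules, proteins = NULL,
                             config = rms_config(), out_dir = NULL) {
  stopifnot(inherits(config, "rms_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  molecules <- stage("standardize", standardize_all(molecules))
  cls <- stage("classify", rms_classify(
    reactions, molecules, heights = config$heights,
    h2_threshold = config$h2_threshold, h2_linkage = config$h2_linkage))
  net <- stage("network", build_reaction_network(reactions, pathways))
  per_height <- list()
  for (h in config$heights) {
    hres <- list()
    hres$rms_network <- stage("reduce", reduce_to_rms_network(net, cls, h))
    hres$weights <- stage("weights", compute_node_weights(
      hres$rms_network, cls, proteins,
      damping = config$damping, tol = config$pagerank_tol))
    hres$paths <- stage("paths", score_all_paths(
      hres$rms_network, pathways, cls, hres$weights,
      min_len = config$min_len, max_len = config$max_len,
      support = config$support))
    hres$modules <- stage("modules", find_conserved_modules(
      hres$rms_network, pathways, cls, hres$weights,
      min_pci = config$min_pci, min_len = config$min_len,
      max_len = config$max_len, support = config$support))
    hres$summary <- stage("summary", pathway_conservation_summary(
      pathways, hres$modules, cls, height = h,
      length = config$summary_length, min_pci = config$min_pci))
    hres$node_reduction_rate <- node_reduction_rate(net, hres$rms_network)
    per_height[[paste0("h", h)]] <- hres
  }
  ec_cmp <- if (any(!is.na(reactions$ec)))
    stage("eval", compare_with_ec(cls, reactions, height = 1L)) else NULL
  prov <- list(
    package_version = as.character(utils::packageVersion("rmsnet")),
    parameters = unclass(config),
    n_reactions = nrow(reactions),
    n_molecules = length(molecules),
    n_pathway_links = nrow(pathways),
    n_proteins = if (is.null(proteins)) 0L else nrow(proteins),
    input_hashes = list(
      reactions = input_digest(reactions$reaction_id),
      pathways = input_digest(pathways),
      molecules = input_digest(names(molecules))))
  run <- structure(list(classification = cls, reaction_network = net,
                        heights = per_height, ec_comparison = ec_cmp,
                        provenance = prov, config = config),
                   class = "rms_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

input_digest <- function(x) {
  old <- options(width = 80)
  on.exit(options(old), add = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(utils::capture.output(print(as.data.frame(x))), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.rms_run <- function(x, ...) {
  cat("<rms_run>\n")
  print(x$classification)
  print(x$reaction_network)
  for (h in names(x$heights)) {
    hr <- x$heights[[h]]
    cat(sprintf("  %s: %d RMS nodes (reduction rate %.2f), %d paths, %d conserved modules\n",
                h, nrow(hr$rms_network$nodes), hr$node_reduction_rate,
                nrow(hr$paths), nrow(hr$modules)))
  }
  if (!is.null(x$ec_comparison)) print(x$ec_comparison)
  invisible(x)
}

#' @method glance rms_run
#' @export
glance.rms_run <- function(x, ...) {
  h1 <- x$heights$h1
  tibble::tibble(
    n_reactions = x$provenance$n_reactions,
    n_h1_classes = nrow(h1$rms_network$nodes),
    node_reduction_rate_h1 = h1$node_reduction_rate,
    n_paths_h1 = nrow(h1$paths),
    n_modules_h1 = nrow(h1$modules),
    rand_index = if (is.null(x$ec_comparison)) NA_real_
                 else x$ec_comparison$rand_index)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(sprintf("# rmsnet %s", run$provenance$package_version),
           sprintf("# %s", jsonlite::toJSON(run$provenance$parameters,
                                            auto_unbox = TRUE)))
  write_with_preamble <- function(df, file) {
    p <- file.path(out_dir, file)
    writeLines(hdr, p)
    suppressWarnings(utils::write.table(
      df, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "",
      append = TRUE))
    p
  }
  write_with_preamble(run$classification$assignments, "classification.tsv")
  write_with_preamble(run$reaction_network$edges[c("from", "to", "n_supports")],
                      "reaction_network.tsv")
  for (h in names(run$heights)) {
    hr <- run$heights[[h]]
    write_with_preamble(hr$rms_network$edges, sprintf("rms_network_%s.tsv", h))
    write_with_preamble(hr$weights, sprintf("weights_%s.tsv", h))
    write_paths(hr$paths, file.path(out_dir, sprintf("paths_%s.tsv", h)))
    write_paths(hr$modules, file.path(out_dir, sprintf("modules_%s.tsv", h)))
    write_with_preamble(hr$summary, sprintf("pathway_summary_%s.tsv", h))
    mod_json <- lapply(seq_len(nrow(hr$modules)), function(i) list(
      path = hr$modules$path_id[i], length = hr$modules$length[i],
      pci = hr$modules$pci[i],
      supports = hr$modules$supports[[i]]))
    jsonlite::write_json(mod_json, file.path(out_dir,
                                             sprintf("modules_%s.json", h)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(run$ec_comparison))
    write_ec_report(run$ec_comparison, file.path(out_dir, "ec_comparison.json"))
  jsonlite::write_json(run$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
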