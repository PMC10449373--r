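#' Build a pipeline configuration
#'
#' Collects every tunable of the per-lake analysis chain (ingest or
#' simulate, rarefy, filter, core partition, turnover/decay statistics,
#' association testing, networks, keystones) with the standard defaults:
#' delay limit 1, alpha 0.01 on both p and q, 1% / 10-read / 3-sample
#' node filter, WI^3 keystones.
#'
#' @param inputs named list lake -> list(table =, metadata =) of TSV
#'   paths, or `NULL` to simulate.
#' @param synthetic list of arguments for [generate_study()] (used when
#'   `inputs` is `NULL`).
#' @param outdir output directory.
#' @param depth_policy `"min"` (rarefy to the global minimum row sum) or
#'   `"fixed"`.
#' @param depth fixed rarefaction depth (required for `"fixed"`).
#' @param abun_threshold,read_threshold,sample_min node filter settings.
#' @param D delay limit.
#' @param alpha edge significance level (p and q).
#' @param n_perm permutations per pair.
#' @param q_method FDR method passed to [stats::p.adjust()].
#' @param fill_method missing-value fill, currently `"linear"`.
#' @param wi_steps WI steps.
#' @param seasons named list season -> time indices, or `NULL` for the
#'   default partition.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = NULL, synthetic = list(),
                            outdir = tempfile("lsanet_run_"),
                            depth_policy = c("min", "fixed"), depth = NULL,
                            abun_threshold = 0.01, read_threshold = 10,
                            sample_min = 3, D = 1, alpha = 0.01,
                            n_perm = 1000, q_method = "BH",
                            fill_method = "linear", wi_steps = 3,
                            seasons = NULL, seed = 1L) {
  depth_policy <- match.arg(depth_policy)
  structure(list(inputs = inputs, synthetic = synthetic, outdir = outdir,
                 depth_policy = depth_policy, depth = depth,
                 abun_threshold = abun_threshold,
                 read_threshold = read_threshold, sample_min = sample_min,
                 D = D, alpha = alpha, n_perm = n_perm,
                 q_method = q_method, fill_method = fill_method,
                 wi_steps = wi_steps, seasons = seasons,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path configuration file (`.yml`/`.yaml` or `.json`).
#' @param ... overrides applied after reading (e.g. `seed`, `outdir`).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  over <- list(...)
  cfg[names(over)] <- over
  do.call(pipeline_config, cfg)
}

#' Validate a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @return character vector of violations (empty when valid), each naming
#'   the offending field.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(config$alpha > 0 && config$alpha < 1, "alpha: must be in (0, 1)")
  chk(config$n_perm >= 1, "n_perm: must be >= 1")
  chk(config$D >= 0, "D: must be >= 0")
  chk(config$wi_steps >= 1, "wi_steps: must be >= 1")
  chk(config$abun_threshold > 0, "abun_threshold: must be positive")
  chk(config$read_threshold > 0, "read_threshold: must be positive")
  chk(config$sample_min > 0, "sample_min: must be positive")
  if (identical(config$depth_policy, "fixed"))
    chk(is.numeric(config[["depth"]]) && config[["depth"]] > 0,
        "depth: required and positive under the fixed depth policy")
  if (!is.null(config$synthetic$edge_delays))
    chk(max(abs(config$synthetic$edge_delays)) <= config$D,
        "synthetic$edge_delays: planted delays exceed the delay limit D")
  if (!is.null(config$seasons)) {
    idx <- unlist(config$seasons, use.names = FALSE)
    chk(!anyDuplicated(idx), "seasons: partitions overlap")
    chk(identical(sort(as.integer(idx)), seq_along(idx)),
        "seasons: must cover 1..T disjointly")
  }
  chk(is.null(config$inputs) || length(config$synthetic) == 0 ||
        length(config$inputs) > 0,
      "inputs: provide input paths or a synthetic spec")
  v
}

#' Run the full multi-lake analysis pipeline
#'
#' Ingests (or simulates) per-lake tables, rarefies all samples to a
#' common depth, applies the network node filter, partitions the core
#' microbiome across lakes, computes turnover and time-distance-decay
#' tables, a two-way PERMANOVA (lake x season) on the pooled Bray-Curtis
#' matrix, per-lake association tables, synchronous and time-shifted
#' networks (GraphML), network property summaries and keystone reports,
#' and writes a JSON manifest of all parameters. A failure in one lake
#' is recorded in the manifest and does not stop the other lakes.
#' Rerunning with the same configuration and seed reproduces all outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `outdir`, per-lake results, the core
#'   partition, the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  viol <- validate_config(config)
  if (length(viol))
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(config$inputs)) {
    say("simulating study (seed ", config$seed, ")")
    study <- do.call(generate_study,
                     c(config$synthetic, list(seed = config$seed)))
    tables <- study$tables
    metadata <- study$metadata
    truth <- study$truth
  } else {
    tables <- list(); metadata <- NULL; truth <- NULL
    ingest_status <- list()
    for (lake in names(config$inputs)) {
      ingest_status[[lake]] <- tryCatch({
        io <- read_otutab(config$inputs[[lake]]$table,
                          config$inputs[[lake]]$metadata)
        tables[[lake]] <- io$table
        metadata <- rbind(metadata, io$metadata)
        "ok"
      }, error = function(e) paste("failed:", conditionMessage(e)))
    }
    if (!length(tables)) stop("no lake could be ingested")
  }
  lakes <- names(tables)

  depth <- if (config$depth_policy == "fixed") config[["depth"]] else
    min(unlist(lapply(tables, rowSums)))
  say("rarefying to depth ", depth)
  rarefied <- lapply(seq_along(tables), function(i)
    rarefy_counts(tables[[i]], depth = depth,
                  seed = config$seed + 11L + i))
  names(rarefied) <- lakes

  core <- if (length(lakes) >= 2) partition_core(rarefied) else
    structure(list(lakes_considered = lakes,
                   core = colnames(rarefied[[1]]),
                   noncore = stats::setNames(list(character(0)), lakes),
                   label = "core1"), class = "core_partition")
  core_partition_table(core, file.path(config$outdir, "core_partition.tsv"))
  contrib <- do.call(rbind, lapply(lakes, function(l) {
    cc <- core_contribution(rarefied[[l]], core$core)
    data.frame(sample_id = names(cc$per_sample), lake = l,
               core_share = unname(cc$per_sample), stringsAsFactors = FALSE)
  }))
  utils::write.table(contrib, file.path(config$outdir, "core_contribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(metadata, file.path(config$outdir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # pooled two-way PERMANOVA (lake x season) when the design allows it
  permanova_out <- NULL
  pooled <- tryCatch({
    shared <- Reduce(intersect, lapply(rarefied, colnames))
    pooled_m <- do.call(rbind, lapply(rarefied, function(tb)
      unclass(tb)[, shared, drop = FALSE]))
    md <- metadata[match(rownames(pooled_m), metadata$sample_id), ]
    d <- vegan::vegdist(pooled_m, method = "bray")
    fac <- data.frame(lake = md$lake, season = md$season)
    if (length(lakes) >= 2)
      permanova_out <- permanova(d, fac, n_perm = 999,
                                 seed = config$seed + 7L)
    else
      permanova_out <- permanova(d, fac["season"], n_perm = 999,
                                 seed = config$seed + 7L)
    utils::write.table(permanova_out,
                       file.path(config$outdir, "permanova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) {
    say("pooled PERMANOVA skipped: ", conditionMessage(e)); FALSE
  })

  lake_results <- list()
  status <- if (is.null(config$inputs)) list() else
    ingest_status[vapply(ingest_status, function(s) s != "ok", TRUE)]
  for (li in seq_along(lakes)) {
    lake <- lakes[li]
    status[[lake]] <- tryCatch({
      say("lake ", lake)
      ldir <- file.path(config$outdir, lake)
      dir.create(ldir, showWarnings = FALSE)
      tab <- rarefied[[lake]]
      md_l <- metadata[metadata$lake == lake, , drop = FALSE]
      write_otutab(tab, file.path(ldir, "rarefied.tsv"))

      turn <- turnover_series(tab, md_l)
      utils::write.table(turn, file.path(ldir, "turnover.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      decay <- distance_decay(tab, md_l)
      utils::write.table(decay, file.path(ldir, "distance_decay.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)

      filt <- filter_for_network(tab, config$abun_threshold,
                                 config$read_threshold, config$sample_min)
      write_otutab(filt, file.path(ldir, "filtered.tsv"))
      ts <- timeseries_set(filt, md_l)
      assoc <- pairwise_associations(ts, D = config$D,
                                     alpha = config$alpha,
                                     n_perm = config$n_perm,
                                     seed = config$seed + 100L * li)
      utils::write.table(assoc, file.path(ldir, "associations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)

      nets <- list()
      props <- list()
      for (which in c("synchronous", "time_shifted")) {
        net <- suppressWarnings(build_network(assoc, which))
        nets[[which]] <- net
        props[[which]] <- network_properties(net)
        export_network(net,
                       file.path(ldir, paste0("network_", which, ".graphml")),
                       file.path(ldir, paste0("edges_", which, ".tsv")))
      }
      prop_df <- do.call(rbind, lapply(names(props), function(w)
        data.frame(network = w, nodes = props[[w]]$nodes,
                   edges = props[[w]]$edges, density = props[[w]]$density,
                   mean_degree = props[[w]]$mean_degree,
                   n_positive = props[[w]]$n_positive,
                   n_negative = props[[w]]$n_negative)))
      utils::write.table(prop_df, file.path(ldir, "network_properties.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)

      ks <- keystone_report(nets, tab, md_l, core$core,
                            steps = config$wi_steps)
      utils::write.table(ks, file.path(ldir, "keystones.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      lake_results[[lake]] <- list(turnover = turn, associations = assoc,
                                   networks = nets, properties = props,
                                   keystones = ks)
      "ok"
    }, error = function(e) paste("failed:", conditionMessage(e)))
  }

  manifest <- list(
    package = "lsanet",
    version = as.character(utils::packageVersion("lsanet")),
    seed = config$seed,
    depth = depth,
    parameters = config[setdiff(names(config), c("inputs", "synthetic"))],
    lakes = status,
    pooled_permanova = pooled
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(outdir = config$outdir, lakes = lake_results,
                 core = core, permanova = permanova_out,
                 truth = if (is.null(config$inputs)) truth else NULL,
                 manifest = manifest))
}
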