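# Configuration-driven end-to-end pipeline with display thresholding,
# force-directed layout export, and a small command-line front end.

#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis.  Input is either a
#' pair of files (`input`, optionally `input_followup`) or a
#' [generator_config()] for synthetic data.  Each stage derives its own
#' seed from `seed` via [derive_seed()], so stages are independently
#' reproducible.
#'
#' @param input,input_followup paths to panel files (see
#'   [load_paired_panel()]); `NULL` to generate data instead.
#' @param generator a [generator_config()] used when no input file is given.
#' @param exclude items dropped before analysis (default the `bnss4`
#'   control item when present).
#' @param estimator an [estimator_settings()].
#' @param edge_boot_B,casedrop_B,casedrop_proportions bootstrap settings.
#' @param nct_B,alpha,edge_tests network-comparison settings.
#' @param community_runs,community stochastic community-detection settings
#'   (`community` is a list of [spinglass_partition()] arguments).
#' @param display_threshold minimum `|e_ij|` kept in the exported display
#'   network (analysis networks are never thresholded).
#' @param layout_iterations force-directed layout iterations.
#' @param outdir output directory.
#' @param seed master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, input_followup = NULL,
                            generator = generator_config(),
                            exclude = "bnss4",
                            estimator = estimator_settings(),
                            edge_boot_B = 1000L, casedrop_B = 250L,
                            casedrop_proportions = seq(0.1, 0.9, by = 0.1),
                            nct_B = 1000L, alpha = 0.05,
                            edge_tests = "when_significant",
                            community_runs = 10000L, community = list(),
                            display_threshold = 0.05,
                            layout_iterations = 500L,
                            outdir = "pairnet_output", seed = 1L) {
  structure(list(input = input, input_followup = input_followup,
                 generator = generator, exclude = exclude,
                 estimator = estimator,
                 edge_boot_B = as.integer(edge_boot_B),
                 casedrop_B = as.integer(casedrop_B),
                 casedrop_proportions = casedrop_proportions,
                 nct_B = as.integer(nct_B), alpha = alpha,
                 edge_tests = edge_tests,
                 community_runs = as.integer(community_runs),
                 community = community,
                 display_threshold = display_threshold,
                 layout_iterations = as.integer(layout_iterations),
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Threshold a network for display
#'
#' Returns a copy with `|e_ij| < min_abs` set to zero.  Display only:
#' analysis statistics are always computed on the unthresholded network.
#'
#' @param net a [pc_network].
#' @param min_abs minimum retained absolute weight (default 0.05,
#'   boundary inclusive).
#' @return A [pc_network].
#' @export
threshold_for_display <- function(net, min_abs = 0.05) {
  stopifnot(min_abs >= 0)
  W <- .network_weights(.as_network(net))
  W[abs(W) < min_abs] <- 0
  pc_network(W)
}

#' Force-directed (Fruchterman-Reingold) node layout
#'
#' Weighted force-directed layout with `|e_ij|` as attraction weights, so
#' strongly associated nodes end up close together.  Deterministic for a
#' fixed seed; coordinates are rescaled to `[-1, 1]^2`.
#'
#' @param net a [pc_network].
#' @param seed RNG seed.
#' @param iterations number of layout iterations.
#' @return A data frame with columns `item`, `x`, `y`.
#' @export
fr_layout <- function(net, seed = 1L, iterations = 500L) {
  net <- .as_network(net)
  p <- ncol(net)
  if (p == 1L)
    return(data.frame(item = colnames(net), x = 0, y = 0,
                      stringsAsFactors = FALSE))
  g <- .network_igraph(net)
  w <- igraph::E(g)$weight
  .set_seed_if(seed)
  xy <- igraph::layout_with_fr(g, niter = as.integer(iterations),
                               weights = if (length(w)) w else NULL)
  rescale <- function(v) {
    v <- v - mean(range(v))
    m <- max(abs(v))
    if (m > 0) v / m else v
  }
  data.frame(item = colnames(net), x = rescale(xy[, 1L]),
             y = rescale(xy[, 2L]), stringsAsFactors = FALSE)
}

.matrix_rows <- function(M) unname(apply(M, 1L, as.numeric, simplify = FALSE))

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Load or generate the paired panel, drop excluded items, estimate both
#' wave networks (nonparanormal transform, correlation, EBIC-glasso),
#' compute centralities, run the edge and case-dropping bootstraps, the
#' dependent-samples network-comparison test, and the community tallies for
#' both waves; write all results plus a run manifest under
#' `config$outdir`.  With a single-wave input the comparison and second
#' tally are skipped and the manifest records the skip.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  t0 <- Sys.time()
  manifest <- list(package_version = as.character(utils::packageVersion("pairnet")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed, stages = list())
  results <- list()
  stage <- function(name, expr) {
    ts <- Sys.time()
    value <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      .write_json(manifest, file.path(outdir, "manifest.json"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = as.numeric(Sys.time() - ts, units = "secs"))
    value
  }

  # ---- data -----------------------------------------------------------
  data_stage <- stage("data", {
    if (is.null(config$input)) {
      gen <- config$generator
      gen$seed <- gen$seed %||% derive_seed(config$seed, "generate")
      made <- make_paired_panel(gen)
      write_panel_csv(made$panel, file.path(outdir, "panels.csv"))
      write_truth(made$truth, file.path(outdir, "truth.json"),
                  file.path(outdir, "truth_edges.tsv"))
      list(pair = made$panel, truth = made$truth)
    } else {
      loaded <- tryCatch(
        load_paired_panel(config$input, config$input_followup),
        error = function(e) e)
      if (inherits(loaded, "error")) # e.g. no follow-up rows in the file
        loaded <- load_panel(config$input, "baseline")
      list(pair = loaded, truth = NULL)
    }
  })
  pair <- data_stage$pair
  truth <- data_stage$truth
  single_wave <- inherits(pair, "item_panel")
  drop <- intersect(config$exclude,
                    if (single_wave) pair$item_labels
                    else pair$baseline$item_labels)
  if (length(drop) > 0) pair <- exclude_items(pair, drop)
  manifest$stages$data$excluded_items <- drop
  manifest$stages$data$single_wave <- single_wave
  waves <- if (single_wave) list(baseline = pair)
           else list(baseline = pair$baseline, followup = pair$followup)

  # ---- estimation + centrality + display ------------------------------
  nets <- list()
  for (wv in names(waves)) {
    panel <- waves[[wv]]
    path <- stage(paste0("estimate_", wv), {
      Z <- nonparanormal_transform(panel)
      S <- panel_correlation(Z)
      estimate_network(S, n = nrow(panel$scores),
                       settings = config$estimator)
    })
    nets[[wv]] <- path$network
    write_network_files(path$network,
                        csv_path = file.path(outdir, paste0("network_", wv, ".csv")),
                        tsv_path = file.path(outdir, paste0("network_", wv, ".tsv")),
                        graphml_path = file.path(outdir, paste0("network_", wv, ".graphml")))
    write.csv(data.frame(lambda = path$lambdas, nedge = path$nedge,
                         ebic = path$ebic, loglik = path$loglik,
                         selected = seq_along(path$lambdas) == path$selected_index),
              file.path(outdir, paste0("path_", wv, ".csv")),
              row.names = FALSE, quote = FALSE)
    ct <- stage(paste0("centrality_", wv),
                suppressMessages(centrality_table(nets[[wv]])))
    results[[paste0("centrality_", wv)]] <- ct
    write.csv(ct, file.path(outdir, paste0("centrality_", wv, ".csv")),
              row.names = FALSE, quote = FALSE)
    disp <- threshold_for_display(nets[[wv]], config$display_threshold)
    lay <- fr_layout(disp, seed = derive_seed(config$seed,
                                              paste0("layout_", wv)),
                     iterations = config$layout_iterations)
    write.csv(lay, file.path(outdir, paste0("layout_", wv, ".csv")),
              row.names = FALSE, quote = FALSE)
    write_network_files(disp,
                        csv_path = file.path(outdir,
                                             paste0("display_network_", wv, ".csv")))
  }
  results$networks <- nets
  results$truth <- truth

  # ---- stability ------------------------------------------------------
  eb <- stage("edge_bootstrap", edge_bootstrap(
    waves$baseline, config$estimator, B = config$edge_boot_B,
    seed = derive_seed(config$seed, "edge_bootstrap")))
  results$edge_bootstrap <- eb
  write.csv(eb$edges, file.path(outdir, "edge_stability_baseline.csv"),
            row.names = FALSE, quote = FALSE)
  cd <- stage("case_drop", suppressWarnings(case_drop_bootstrap(
    waves$baseline, config$estimator,
    proportions = config$casedrop_proportions, B = config$casedrop_B,
    seed = derive_seed(config$seed, "case_drop"))))
  results$case_drop <- cd
  write.csv(cd$summary, file.path(outdir, "casedrop_baseline.csv"),
            row.names = FALSE, quote = FALSE)
  .write_json(as.list(cd$cs), file.path(outdir, "cs_coefficients.json"))

  # ---- comparison -----------------------------------------------------
  if (!single_wave) {
    nct <- stage("comparison", nct_dependent(
      pair, config$estimator, B = config$nct_B,
      seed = derive_seed(config$seed, "nct"),
      edge_tests = config$edge_tests, alpha = config$alpha))
    results$nct <- nct
    .write_json(list(M = nct$M, S = nct$S, g1 = nct$g1, g2 = nct$g2,
                     p_M = nct$p_M, p_S = nct$p_S, B = nct$B,
                     n_effective = nct$n_effective,
                     edges_reported = nct$edges_reported,
                     edge_p_holm = as.list(nct$edge_p_holm)),
                file.path(outdir, "nct.json"))
    if (!is.null(nct$edge_table))
      write.csv(nct$edge_table, file.path(outdir, "nct_edges.csv"),
                row.names = FALSE, quote = FALSE)
  } else {
    manifest$stages$comparison <- list(status = "skipped",
                                       reason = "single wave input")
  }

  # ---- communities ----------------------------------------------------
  for (wv in names(waves)) {
    if (global_strength(nets[[wv]]) == 0) {
      manifest$stages[[paste0("communities_", wv)]] <-
        list(status = "skipped", reason = "empty estimated network")
      next
    }
    tal <- stage(paste0("communities_", wv), do.call(community_tally, c(
      list(net = nets[[wv]], n_runs = config$community_runs,
           seed = derive_seed(config$seed, paste0("communities_", wv))),
      config$community)))
    results[[paste0("communities_", wv)]] <- tal
    .write_json(list(n_runs = tal$n_runs,
                     item_labels = tal$item_labels,
                     partitions = lapply(tal$partitions, as.integer),
                     frequencies = tal$frequencies,
                     energies = tal$energies),
                file.path(outdir, paste0("communities_", wv, ".json")))
    write.csv(data.frame(frequency = tal$frequencies,
                         n_communities = vapply(tal$partitions, max, 1L),
                         assignment = vapply(tal$partitions, paste,
                                             character(1), collapse = "-")),
              file.path(outdir, paste0("communities_", wv, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  if (single_wave)
    manifest$stages$communities_followup <-
      list(status = "skipped", reason = "single wave input")

  manifest$total_seconds <- as.numeric(Sys.time() - t0, units = "secs")
  .write_json(manifest, file.path(outdir, "manifest.json"))
  results$manifest <- manifest
  invisible(results)
}

# ---------------------------------------------------------------------------
# command-line front end

.cli_options <- function(args) {
  opts <- list()
  positional <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (grepl("=", key, fixed = TRUE)) {
        kv <- strsplit(key, "=", fixed = TRUE)[[1L]]
        opts[[kv[1L]]] <- paste(kv[-1L], collapse = "=")
      } else {
        opts[[key]] <- if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
          i <- i + 1L; args[[i]]
        } else TRUE
      }
    } else positional <- c(positional, a)
    i <- i + 1L
  }
  list(opts = opts, positional = positional)
}

.config_from_cli <- function(opts) {
  cfg <- if (!is.null(opts$config)) {
    raw <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
    gen <- do.call(generator_config, raw$generator %||% list())
    est <- do.call(estimator_settings, raw$estimator %||% list())
    base <- raw[setdiff(names(raw), c("generator", "estimator"))]
    do.call(pipeline_config,
            c(base, list(generator = gen, estimator = est)))
  } else pipeline_config()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$outdir)) cfg$outdir <- opts$outdir
  if (!is.null(opts$input)) cfg$input <- opts$input
  if (!is.null(opts[["input-followup"]]))
    cfg$input_followup <- opts[["input-followup"]]
  cfg
}

#' Command-line entry point
#'
#' Subcommands: `generate`, `estimate`, `centrality`, `stability`,
#' `compare`, `communities`, `run-all`.  Common flags: `--config FILE`
#' (JSON mirror of [pipeline_config()]), `--seed N`, `--outdir DIR`,
#' `--input FILE`, `--input-followup FILE`, `--threads N` (accepted for
#' interface compatibility; results never depend on it).
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return Invisibly, the result of the subcommand.
#' @export
pairnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- .cli_options(args)
  cmd <- if (length(parsed$positional) > 0) parsed$positional[[1L]] else "help"
  cfg <- .config_from_cli(parsed$opts)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  load_pair <- function() {
    if (is.null(cfg$input)) {
      gen <- cfg$generator
      gen$seed <- gen$seed %||% derive_seed(cfg$seed, "generate")
      make_paired_panel(gen)$panel
    } else load_paired_panel(cfg$input, cfg$input_followup)
  }
  prep <- function(pair) {
    drop <- intersect(cfg$exclude, pair$baseline$item_labels)
    if (length(drop)) exclude_items(pair, drop) else pair
  }

  res <- switch(
    cmd,
    "generate" = {
      gen <- cfg$generator
      gen$seed <- gen$seed %||% derive_seed(cfg$seed, "generate")
      made <- make_paired_panel(gen)
      write_panel_csv(made$panel, file.path(cfg$outdir, "panels.csv"))
      write_truth(made$truth, file.path(cfg$outdir, "truth.json"),
                  file.path(cfg$outdir, "truth_edges.tsv"))
      message("wrote ", file.path(cfg$outdir, "panels.csv"))
      made
    },
    "estimate" = {
      pair <- prep(load_pair())
      net <- fit_panel_network(pair$baseline, cfg$estimator)
      write_network_files(net,
                          csv_path = file.path(cfg$outdir, "network_baseline.csv"),
                          tsv_path = file.path(cfg$outdir, "network_baseline.tsv"),
                          graphml_path = file.path(cfg$outdir, "network_baseline.graphml"))
      net
    },
    "centrality" = {
      pair <- prep(load_pair())
      ct <- centrality_table(fit_panel_network(pair$baseline, cfg$estimator))
      write.csv(ct, file.path(cfg$outdir, "centrality_baseline.csv"),
                row.names = FALSE, quote = FALSE)
      ct
    },
    "stability" = {
      pair <- prep(load_pair())
      eb <- edge_bootstrap(pair$baseline, cfg$estimator, B = cfg$edge_boot_B,
                           seed = derive_seed(cfg$seed, "edge_bootstrap"))
      write.csv(eb$edges, file.path(cfg$outdir, "edge_stability_baseline.csv"),
                row.names = FALSE, quote = FALSE)
      eb
    },
    "compare" = {
      pair <- prep(load_pair())
      nct <- nct_dependent(pair, cfg$estimator, B = cfg$nct_B,
                           seed = derive_seed(cfg$seed, "nct"),
                           edge_tests = cfg$edge_tests, alpha = cfg$alpha)
      .write_json(list(M = nct$M, S = nct$S, p_M = nct$p_M, p_S = nct$p_S),
                  file.path(cfg$outdir, "nct.json"))
      nct
    },
    "communities" = {
      pair <- prep(load_pair())
      net <- fit_panel_network(pair$baseline, cfg$estimator)
      tal <- do.call(community_tally, c(
        list(net = net, n_runs = cfg$community_runs,
             seed = derive_seed(cfg$seed, "communities_baseline")),
        cfg$community))
      .write_json(list(n_runs = tal$n_runs,
                       partitions = lapply(tal$partitions, as.integer),
                       frequencies = tal$frequencies),
                  file.path(cfg$outdir, "communities_baseline.json"))
      tal
    },
    "run-all" = run_pipeline(cfg),
    {
      cat("usage: pairnet <generate|estimate|centrality|stability|compare|",
          "communities|run-all> [--config FILE] [--seed N] [--outdir DIR]\n",
          sep = "")
      invisible(NULL)
    })
  invisible(res)
}
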