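#' Write a cohort to disk
#'
#' One tab-delimited time-series file per subject (header = region names),
#' a BIDS-style events table, behavior and structural tables, and a YAML
#' manifest mapping subject ids to files and groups.
#'
#' @param cohort a `cohort`
#' @param dir output directory (created if needed)
#' @return the manifest path, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- list()
  for (sid in names(cohort$timeseries)) {
    f <- file.path(dir, paste0(sid, ".tsv"))
    write_timeseries(cohort$timeseries[[sid]], f)
    subjects[[sid]] <- list(file = basename(f),
                            group = cohort$timeseries[[sid]]$group_label)
  }
  write_events(cohort$design, file.path(dir, "events.tsv"))
  write.table(cohort$behavior, file.path(dir, "behavior.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$structure)) {
    write.table(cohort$structure, file.path(dir, "structure.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(TR = cohort$design$TR,
                   regions = cohort$region_names,
                   events = "events.tsv", behavior = "behavior.tsv",
                   structure = if (is.null(cohort$structure)) NULL
                               else "structure.tsv",
                   subjects = subjects)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a cohort from a manifest
#'
#' @param manifest_path path to a `manifest.yaml` written by
#'   [write_cohort()] (or hand-authored with the same schema)
#' @return a `cohort` (without ground truth)
#' @export
read_cohort <- function(manifest_path) {
  man <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  TR <- man$TR
  regions <- unlist(man$regions)
  ts_list <- list()
  for (sid in names(man$subjects)) {
    entry <- man$subjects[[sid]]
    ts <- read_timeseries(file.path(base, entry$file), TR = TR,
                          subject_id = sid, group_label = entry$group)
    if (!identical(ts$region_names, regions)) {
      if (setequal(ts$region_names, regions)) {
        ts$values <- ts$values[, regions, drop = FALSE]
        ts$region_names <- regions
      } else {
        stopf("subject %s has regions not in the manifest", sid)
      }
    }
    ts_list[[sid]] <- ts
  }
  design <- read_events(file.path(base, man$events), TR = TR)
  behavior <- if (!is.null(man$behavior)) {
    read.delim(file.path(base, man$behavior))
  }
  structure_tab <- if (!is.null(man$structure)) {
    read.delim(file.path(base, man$structure))
  }
  structure(list(timeseries = ts_list, design = design,
                 behavior = behavior, structure = structure_tab,
                 ground_truth = NULL, region_names = regions,
                 groups = unique(vapply(ts_list, function(t) t$group_label,
                                        ""))),
            class = "cohort")
}

#' Serialize a causal graph
#'
#' Edge-list TSV (`source`, `target`, `strength`, `p`, `q`, `significant`)
#' and a JSON document carrying the full matrices.
#'
#' @param graph a `causal_graph`
#' @param path_tsv,path_json output paths (either may be NULL)
#' @return invisibly, the edge-list data.frame
#' @export
write_causal_graph <- function(graph, path_tsv = NULL, path_json = NULL) {
  stopifnot(inherits(graph, "causal_graph"))
  rn <- graph$region_names
  M <- length(rn)
  rows <- list()
  for (m in seq_len(M)) {
    for (n in seq_len(M)) {
      if (m == n) next
      rows[[length(rows) + 1]] <- data.frame(
        source = rn[n], target = rn[m],
        strength = graph$edge_strength[m, n],
        p = graph$edge_p[m, n], q = graph$edge_q[m, n],
        significant = graph$significant[m, n])
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(path_tsv)) {
    write.table(df, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(region_names = rn, edge_strength = graph$edge_strength,
           edge_p = graph$edge_p, edge_q = graph$edge_q,
           significant = graph$significant, alpha = graph$alpha),
      path_json, digits = NA, matrix = "rowmajor")
  }
  invisible(df)
}

#' Validate a pipeline run configuration
#'
#' Checks the manifest / subject / file consistency of a run configuration
#' before any computation: referenced files exist, all subjects share the
#' manifest's region set and TR, and every subject has a behavior row (and
#' structure rows when a structural table is configured). All violations
#' are collected and reported together.
#'
#' @param cfg a run-configuration list (see [run_pipeline()]) or the path
#'   to a YAML file holding one
#' @return character vector of violations (empty when valid), invisibly;
#'   also printed when violations exist
#' @export
validate_run_config <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  viol <- character(0)
  if (is.null(cfg$simulate) && is.null(cfg$manifest)) {
    viol <- c(viol, "config needs either a `simulate` block or a `manifest` path")
  }
  if (!is.null(cfg$manifest)) {
    if (!file.exists(cfg$manifest)) {
      viol <- c(viol, sprintf("manifest not found: %s", cfg$manifest))
    } else {
      man <- yaml::read_yaml(cfg$manifest)
      base <- dirname(cfg$manifest)
      regions <- unlist(man$regions)
      for (sid in names(man$subjects)) {
        f <- file.path(base, man$subjects[[sid]]$file)
        if (!file.exists(f)) {
          viol <- c(viol, sprintf("subject %s: file missing (%s)", sid, f))
          next
        }
        hdr <- names(read.delim(f, nrows = 1, check.names = FALSE))
        if (!setequal(hdr, regions)) {
          viol <- c(viol, sprintf("subject %s: region set differs from manifest", sid))
        } else if (!identical(hdr, regions)) {
          message(sprintf("note: subject %s columns reordered to manifest order", sid))
        }
      }
      if (!is.null(man$behavior)) {
        bf <- file.path(base, man$behavior)
        if (!file.exists(bf)) {
          viol <- c(viol, sprintf("behavior table missing: %s", bf))
        } else {
          bh <- read.delim(bf)
          missing <- setdiff(names(man$subjects), bh$subject_id)
          for (sid in missing) {
            viol <- c(viol, sprintf("subject %s: no behavior row", sid))
          }
        }
      }
      if (!is.null(man$events) &&
          !file.exists(file.path(base, man$events))) {
        viol <- c(viol, sprintf("events table missing: %s", man$events))
      }
    }
  }
  if (length(viol) > 0) {
    message("configuration problems:\n", paste(" -", viol, collapse = "\n"))
  }
  invisible(viol)
}

#' Demo run configuration
#'
#' A small synthetic two-group run (8 subjects per group, ~200 scans)
#' exercising every stage of the pipeline in a few minutes on one CPU.
#'
#' @param out_dir output directory
#' @param seed master seed
#' @return a run-configuration list for [run_pipeline()]
#' @export
demo_run_config <- function(out_dir = tempfile("causalconn_demo"),
                            seed = 1) {
  list(out_dir = out_dir, seed = seed,
       simulate = list(n_subjects = 8, n_trials = 24, TR = 2,
                       hub_strength = 0.5, hub_delta = 0.3,
                       obs_noise_var = 1),
       mds = list(n_lags = 12, n_surrogates = 199, alpha = 0.05,
                  max_iter = 60, surrogate_max_iter = 10),
       granger = list(order = 1, n_surrogates = 499, alpha = 0.05),
       latency = list(threshold_frac = 0.10),
       fc = list(alpha = 0.05),
       behavior = list(folds = 5))
}

#' Run the full analysis pipeline
#'
#' Executes, from one configuration: cohort simulation (or loading),
#' preprocessing, state-space (MDS) and Granger causal estimation with
#' surrogate nulls and group comparison, latency analysis, graph metrics
#' with hub tests, functional-connectivity and structural comparisons, and
#' sparse behavior regression per group. Every stage writes its outputs
#' under `cfg$out_dir`; per-stage seeds are derived deterministically from
#' the master seed so identical configurations reproduce identical
#' numbers.
#'
#' @param cfg run-configuration list (see [demo_run_config()]) or YAML path
#' @return a run report (list of per-stage outputs and output paths)
#' @export
run_pipeline <- function(cfg = demo_run_config()) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  viol <- validate_run_config(cfg)
  if (length(viol) > 0) stopf("invalid configuration (%d problem(s))",
                              length(viol))
  out_dir <- cfg$out_dir %||% tempfile("causalconn_run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed %||% 1
  report <- list(seed = seed, out_dir = out_dir, config = cfg)

  # --- cohort ---
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    spec <- default_cohort_spec(
      n_subjects = sim$n_subjects %||% 8,
      n_trials = sim$n_trials %||% 24, TR = sim$TR %||% 2,
      hub_strength = sim$hub_strength %||% 0.5,
      hub_delta = sim$hub_delta %||% 0.3,
      obs_noise_var = sim$obs_noise_var %||% 1,
      embedding_lags = cfg$mds$n_lags %||% 12,
      seed = derive_seed(seed, 1))
    cohort <- generate_cohort(spec)
    write_cohort(cohort, file.path(out_dir, "cohort"))
  } else {
    cohort <- read_cohort(cfg$manifest)
  }
  groups <- cohort$groups
  by_group <- lapply(groups, function(g) {
    Filter(function(ts) ts$group_label == g, cohort$timeseries)
  })
  names(by_group) <- groups
  basis <- build_hrf_basis(cohort$design$TR, cfg$mds$n_lags %||% 12)

  # --- MDS ---
  mcfg <- mds_config(max_iter = cfg$mds$max_iter %||% 60)
  scfg <- mds_config(max_iter = cfg$mds$surrogate_max_iter %||% 10,
                     tol = 1e-4)
  mds <- list()
  for (g in groups) {
    fit <- fit_mds(by_group[[g]], cohort$design, basis, mcfg)
    null <- surrogate_null_mds(by_group[[g]], cohort$design, basis,
                               n_surrogates = cfg$mds$n_surrogates %||% 199,
                               seed = derive_seed(seed, 2, match(g, groups)),
                               config = scfg)
    graph <- significant_edges(fit, null, alpha = cfg$mds$alpha %||% 0.05)
    write_causal_graph(graph,
                       file.path(out_dir, sprintf("mds_graph_%s.tsv", g)),
                       file.path(out_dir, sprintf("mds_graph_%s.json", g)))
    mds[[g]] <- list(fit = fit, null = null, graph = graph)
  }
  mds$comparison <- compare_groups_mds(mds[[groups[1]]]$fit,
                                       mds[[groups[2]]]$fit,
                                       mds[[groups[1]]]$null,
                                       mds[[groups[2]]]$null,
                                       alpha = cfg$mds$alpha %||% 0.05)
  report$mds <- mds

  # --- Granger ---
  ord <- cfg$granger$order %||% 1
  gr <- list()
  for (g in groups) {
    null <- surrogate_null_granger(
      by_group[[g]], order = ord,
      n_surrogates = cfg$granger$n_surrogates %||% 499,
      seed = derive_seed(seed, 3, match(g, groups)))
    graph <- group_causal_graph(by_group[[g]], order = ord, null = null,
                                alpha = cfg$granger$alpha %||% 0.05)
    write_causal_graph(graph,
                       file.path(out_dir, sprintf("granger_graph_%s.tsv", g)),
                       file.path(out_dir, sprintf("granger_graph_%s.json", g)))
    gr[[g]] <- list(null = null, graph = graph)
  }
  gr$comparison <- compare_groups_doi(by_group[[groups[1]]],
                                      by_group[[groups[2]]], order = ord,
                                      nullA = gr[[groups[1]]]$null,
                                      nullB = gr[[groups[2]]]$null,
                                      alpha = cfg$granger$alpha %||% 0.05)
  report$granger <- gr

  # --- latency ---
  lat_basis <- build_hrf_basis(cohort$design$TR,
                               cfg$latency$n_lags %||%
                                 ceiling(24 / cohort$design$TR))
  lat_profiles <- list()
  for (g in groups) {
    fr <- fit_event_response(by_group[[g]], cohort$design, lat_basis)
    lat_profiles[[g]] <- onset_latency(
      fr, threshold_frac = cfg$latency$threshold_frac %||% 0.10)
  }
  lat_cmp <- compare_latencies(lat_profiles)
  lat_tab <- do.call(rbind, lapply(groups, function(g) {
    data.frame(region = names(lat_profiles[[g]]$onsets), group = g,
               mean_onset_s = unname(lat_profiles[[g]]$onsets))
  }))
  write.table(lat_tab, file.path(out_dir, "latency.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report$latency <- list(profiles = lat_profiles, comparisons = lat_cmp)

  # --- graph metrics ---
  gm <- list()
  for (g in groups) {
    graph <- gr[[g]]$graph
    psm <- per_subject_graph_metrics(
      lapply(graph$per_subject_doi, t), graph$significant)
    gm[[g]] <- list(
      degrees = degree_metrics(graph),
      path_length = node_path_length(graph),
      hub_net_outflow = hub_test(psm$net_outflow),
      hub_path_length = hub_test(psm$path_length))
  }
  metrics_tab <- do.call(rbind, lapply(groups, function(g) {
    cbind(group = g, gm[[g]]$degrees,
          path_length = unname(gm[[g]]$path_length))
  }))
  write.table(metrics_tab, file.path(out_dir, "graph_metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report$graph_metrics <- gm

  # --- functional connectivity ---
  fc_by_group <- lapply(groups, function(g) {
    lapply(by_group[[g]], function(ts) {
      functional_connectivity(preprocess_timeseries(ts))
    })
  })
  names(fc_by_group) <- groups
  fc_cmp <- compare_fc_groups(fc_by_group[[groups[1]]],
                              fc_by_group[[groups[2]]],
                              alpha = cfg$fc$alpha %||% 0.05)
  write.table(fc_cmp, file.path(out_dir, "fc_comparison.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report$fc <- list(matrices = fc_by_group, comparison = fc_cmp)

  # --- structure-function ---
  if (!is.null(cohort$structure)) {
    sf <- list()
    for (g in groups) {
      sids <- names(by_group[[g]])
      fcv <- setNames(vapply(fc_by_group[[g]],
                             function(m) m["rAI", "rPPC"], 0), sids)
      sc_g <- cohort$structure[cohort$structure$group == g, ]
      sf[[g]] <- tryCatch(
        structure_function_correlation(fcv, sc_g, "rAI->rPPC"),
        error = function(e) list(r = NA_real_, p = NA_real_,
                                 note = conditionMessage(e)))
    }
    sf$structural_tests <- compare_structural(
      cohort$structure[cohort$structure$group == groups[1], ],
      cohort$structure[cohort$structure$group == groups[2], ],
      "rAI->rPPC")
    report$structure <- sf
  }

  # --- behavior prediction ---
  if (!is.null(cohort$behavior)) {
    bh <- list()
    for (g in groups) {
      sids <- names(by_group[[g]])
      doi_list <- gr[[g]]$graph$per_subject_doi
      regions <- cohort$region_names
      pairs <- utils::combn(regions, 2)
      X <- sapply(seq_len(ncol(pairs)), function(k) {
        vapply(doi_list, function(d) d[pairs[1, k], pairs[2, k]], 0)
      })
      colnames(X) <- apply(pairs, 2, function(p) edge_key(p[1], p[2]))
      rownames(X) <- sids
      beh <- cohort$behavior[match(sids, cohort$behavior$subject_id), ]
      bh[[g]] <- list(
        rt = sparse_regression(X, beh$reaction_time,
                               folds = cfg$behavior$folds %||% 5,
                               seed = derive_seed(seed, 4, match(g, groups))),
        accuracy = sparse_regression(X, beh$accuracy,
                                     folds = cfg$behavior$folds %||% 5,
                                     seed = derive_seed(seed, 5,
                                                        match(g, groups))))
    }
    bh$rt_comparison <- compare_model_fit(bh[[groups[1]]]$rt,
                                          bh[[groups[2]]]$rt, groups)
    report$behavior <- bh
  }

  saveRDS_free_report(report, file.path(out_dir, "report.json"))
  report
}

# JSON summary of the run (numbers only; full objects stay in memory)
saveRDS_free_report <- function(report, path) {
  summ <- list(
    seed = report$seed,
    mds_significant = lapply(report$mds[names(report$mds) != "comparison"],
                             function(x) sum(x$graph$significant)),
    granger_significant = lapply(
      report$granger[names(report$granger) != "comparison"],
      function(x) sum(x$graph$significant)),
    latency_onsets = lapply(report$latency$profiles, function(p)
      as.list(p$onsets)),
    behavior_r2 = if (!is.null(report$behavior)) {
      lapply(report$behavior[!grepl("comparison",
                                    names(report$behavior))],
             function(x) list(rt = x$rt$r_squared,
                              accuracy = x$accuracy$r_squared))
    })
  jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
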