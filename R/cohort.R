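#' Edge label helpers
#'
#' Directed edges are labelled `"source->target"` throughout.
#'
#' @param source,target region names
#' @param key edge label
#' @return `edge_key` a character label; `parse_edge_key` a length-2
#'   character vector `(source, target)`
#' @export
edge_key <- function(source, target) paste0(source, "->", target)

#' @rdname edge_key
#' @export
parse_edge_key <- function(key) {
  parts <- strsplit(key, "->", fixed = TRUE)[[1]]
  if (length(parts) != 2) stopf("malformed edge key '%s'", key)
  parts
}

#' Specification of a synthetic two-group cohort
#'
#' Encodes everything needed to generate a multi-subject, two-group dataset
#' from the bilinear state-space generative model: a shared parameter
#' template, per-group edge perturbations (e.g. a weakened hub-to-parietal
#' connection in one group), behavior coupled linearly to designated edge
#' strengths, and structural-connectivity tables whose fiber density tracks
#' an edge's functional strength in the group(s) flagged as coupled.
#'
#' @param base_params an `mds_params` template shared by both groups
#' @param groups named list (two entries, distinct labels); each element a
#'   list with `n_subjects` (>= 3), optional `edge_perturbations` (list of
#'   `list(source, target, delta)` applied to the template's first
#'   modulatory matrix), optional `structure_coupled` flag, optional
#'   `rt_noise_sd`, `acc_noise_sd`, `rt_intercept`, `acc_intercept`,
#'   `fiber_mean`, `fa_mean`
#' @param design an `event_design` shared by all subjects
#' @param subject_sd sd of the subject-level Gaussian perturbation applied
#'   to each nonzero off-diagonal template edge
#' @param behavior list with `rt_coefficients` and `acc_coefficients`
#'   (named vectors keyed by edge label, ms resp. proportion per unit
#'   strength)
#' @param structure list with `edge` (edge label), `coupling_slope`
#'   (fibers per unit strength), `fiber_sd`, `fa_sd`, `fa_slope`
#' @param hrf_basis an `hrf_basis` used for BOLD generation
#' @param seed master seed
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(base_params, groups, design, subject_sd = 0.1,
                        behavior = NULL, structure = NULL,
                        hrf_basis = NULL, seed = 1) {
  stopifnot(inherits(base_params, "mds_params"),
            inherits(design, "event_design"))
  if (length(groups) != 2 || is.null(names(groups)) ||
      anyDuplicated(names(groups))) {
    stopf("`groups` must be a named list of two distinct groups")
  }
  for (g in names(groups)) {
    n <- groups[[g]]$n_subjects
    if (is.null(n) || n < 3) {
      stopf("group '%s' needs n_subjects >= 3 (group tests are undefined below that)", g)
    }
    for (pert in groups[[g]]$edge_perturbations) {
      if (!all(c(pert[[1]], pert[[2]]) %in% base_params$region_names)) {
        stopf("perturbed edge %s->%s refers to unknown regions",
              pert[[1]], pert[[2]])
      }
    }
  }
  if (is.null(hrf_basis)) {
    hrf_basis <- build_hrf_basis(design$TR, base_params$embedding_lags)
  }
  if (is.null(behavior)) behavior <- list(rt_coefficients = NULL,
                                          acc_coefficients = NULL)
  if (!is.null(structure)) {
    se <- parse_edge_key(structure$edge)
    if (!all(se %in% base_params$region_names)) {
      stopf("structure edge '%s' refers to unknown regions", structure$edge)
    }
  }
  structure(list(base_params = base_params, groups = groups,
                 design = design, subject_sd = subject_sd,
                 behavior = behavior, structure = structure,
                 hrf_basis = hrf_basis, seed = seed),
            class = "cohort_spec")
}

#' Default study-like cohort specification
#'
#' The shipped study conditions: five regions (rAI, rVLPFC, ACC, rDLPFC,
#' rPPC) with the right anterior insula acting as the causal outflow hub
#' (directed edges rAI -> rVLPFC, ACC, rDLPFC, rPPC of strength 0.5, modest
#' self-decay 0.35 on every region), a jittered 52-trial event-related
#' design (5 s stimuli, 1 s fixed gap, 0-3.5 s uniform jitter, TR 2 s), an
#' "adult" and a "child" group in which the child group's rAI -> rPPC edge
#' is weakened by `hub_delta`, reaction time and accuracy coupled to the
#' rAI out-edge strengths (with lower behavior noise in adults), and a
#' structural table whose rAI-rPPC fiber density tracks that edge's
#' strength in adults only.
#'
#' @param n_subjects per-group subject count (named vector or scalar)
#' @param n_trials,TR design parameters
#' @param hub_strength strength of each rAI out-edge
#' @param hub_delta weakening of rAI -> rPPC in the child group (subtracted)
#' @param subject_sd between-subject sd of nonzero edge strengths
#' @param obs_noise_var observation noise variance (SNR control)
#' @param state_noise_var variance of the latent state noise
#' @param input_mode `"all"` drives every region with the stimulus;
#'   `"hub_only"` drives only the hub so downstream regions respond one
#'   sample later through the coupling (lead-lag design for latency tests)
#' @param embedding_lags HRF embedding length L (default covers 32 s)
#' @param coupling_zero set TRUE for a zero-coupling (null) cohort
#' @param seed master seed
#' @return a `cohort_spec`
#' @export
default_cohort_spec <- function(n_subjects = c(adult = 22, child = 23),
                                n_trials = 52, TR = 2, hub_strength = 0.5,
                                hub_delta = 0.3, subject_sd = 0.1,
                                obs_noise_var = 1, state_noise_var = 1,
                                input_mode = c("all", "hub_only"),
                                embedding_lags = ceiling(32 / TR),
                                coupling_zero = FALSE, seed = 1) {
  input_mode <- match.arg(input_mode)
  regions <- c("rAI", "rVLPFC", "ACC", "rDLPFC", "rPPC")
  if (length(n_subjects) == 1) {
    n_subjects <- c(adult = unname(n_subjects), child = unname(n_subjects))
  }
  M <- length(regions)
  C <- matrix(0, M, M, dimnames = list(regions, regions))
  diag(C) <- 0.35
  if (!coupling_zero) {
    C[c("rVLPFC", "ACC", "rDLPFC", "rPPC"), "rAI"] <- hub_strength
  }
  d <- if (input_mode == "all") rep(1, M) else c(1, rep(0, M - 1))
  params <- mds_parameters(C, input_strengths = d,
                           state_noise_cov = state_noise_var,
                           obs_noise_var = obs_noise_var,
                           embedding_lags = embedding_lags,
                           region_names = regions)
  design <- generate_event_design(n_trials, 5, iti_fixed = 1,
                                  jitter_bounds = c(0, 3.5), TR = TR,
                                  seed = derive_seed(seed, 101))
  groups <- list(
    adult = list(n_subjects = unname(n_subjects["adult"]),
                 edge_perturbations = NULL, structure_coupled = TRUE,
                 rt_noise_sd = 100, acc_noise_sd = 0.03,
                 rt_intercept = 1400, acc_intercept = 0.95,
                 fiber_mean = 35, fa_mean = 0.55),
    child = list(n_subjects = unname(n_subjects["child"]),
                 edge_perturbations = if (coupling_zero) NULL else
                   list(list("rAI", "rPPC", -hub_delta)),
                 structure_coupled = FALSE,
                 rt_noise_sd = 150, acc_noise_sd = 0.05,
                 rt_intercept = 2200, acc_intercept = 0.85,
                 fiber_mean = 25, fa_mean = 0.45))
  behavior <- list(
    rt_coefficients = c("rAI->rPPC" = -800, "rAI->ACC" = -500,
                        "rAI->rDLPFC" = -500),
    acc_coefficients = c("rAI->ACC" = 0.25, "rAI->rPPC" = 0.2))
  structure <- list(edge = "rAI->rPPC", coupling_slope = 50,
                    fiber_sd = 5, fa_sd = 0.05, fa_slope = 0)
  cohort_spec(params, groups, design, subject_sd = subject_sd,
              behavior = behavior, structure = structure, seed = seed)
}

# subject-level parameter draw: template + Gaussian jitter on nonzero
# off-diagonal edges, resampled until the process stays stable
subject_params <- function(spec, group, subj_seed) {
  base <- spec$base_params
  C <- base$modulatory_matrices[[1]]
  for (pert in spec$groups[[group]]$edge_perturbations) {
    C[pert[[2]], pert[[1]]] <- C[pert[[2]], pert[[1]]] + pert[[3]]
  }
  with_seed(subj_seed, {
    free <- which(C != 0 & row(C) != col(C))
    for (try in 1:50) {
      Cs <- C
      if (spec$subject_sd > 0 && length(free) > 0) {
        Cs[free] <- Cs[free] + rnorm(length(free), 0, spec$subject_sd)
      }
      if (spectral_radius(Cs) < 0.97) break
    }
    base$modulatory_matrices[[1]] <- Cs
    base
  })
}

#' Generate a synthetic two-group cohort
#'
#' Draws, for every subject, perturbed model parameters, a latent series and
#' BOLD observations under the shared event design; behavior as a linear
#' function of the subject's designated edge strengths plus noise; and a
#' structural-connectivity table in which fiber density tracks the
#' designated edge's strength only in groups flagged `structure_coupled`.
#' Ground-truth per-subject edge strengths are returned for recovery tests.
#'
#' @param spec a `cohort_spec`
#' @return a `cohort`: list with `timeseries` (list of `roi_timeseries`),
#'   `design`, `behavior` (data.frame), `structure` (data.frame),
#'   `ground_truth` (list: `edge_strengths` data.frame subjects x edges,
#'   `subject_params`), `region_names`, `groups`
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  regions <- spec$base_params$region_names
  M <- length(regions)
  # label matrix aligned with C: entry (m, n) is the edge n -> m
  edges <- outer(regions, regions, function(tgt, src) edge_key(src, tgt))
  ts_list <- list()
  gt_params <- list()
  gi <- 0
  for (g in names(spec$groups)) {
    gi <- gi + 1
    n <- spec$groups[[g]]$n_subjects
    for (i in seq_len(n)) {
      sid <- sprintf("%s_%02d", g, i)
      pseed <- derive_seed(spec$seed, gi, i, 1)
      par_i <- subject_params(spec, g, pseed)
      lat <- simulate_latent(par_i, spec$design,
                             seed = derive_seed(spec$seed, gi, i, 2))
      bold <- simulate_bold(lat, par_i, spec$hrf_basis,
                            seed = derive_seed(spec$seed, gi, i, 3),
                            subject_id = sid, group_label = g)
      ts_list[[sid]] <- bold
      gt_params[[sid]] <- par_i
    }
  }
  # per-subject off-diagonal strengths, keyed source->target
  off <- which(row(edges) != col(edges))
  gt <- do.call(rbind, lapply(names(gt_params), function(sid) {
    Cs <- gt_params[[sid]]$modulatory_matrices[[1]]
    vals <- sapply(seq_along(off), function(k) Cs[off[k]])
    df <- as.data.frame(as.list(setNames(vals, edges[off])), optional = TRUE,
                        check.names = FALSE)
    cbind(data.frame(subject_id = sid,
                     group = ts_list[[sid]]$group_label,
                     stringsAsFactors = FALSE), df)
  }))
  rownames(gt) <- gt$subject_id

  behavior <- generate_behavior(spec, gt)
  structure_tab <- generate_structure(spec, gt)
  structure(list(timeseries = ts_list, design = spec$design,
                 behavior = behavior, structure = structure_tab,
                 ground_truth = list(edge_strengths = gt,
                                     subject_params = gt_params),
                 region_names = regions, groups = names(spec$groups),
                 spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(sapply(x$timeseries, function(t) t$group_label))
  cat(sprintf("<cohort> %d subjects (%s), %d regions, %d samples\n",
              length(x$timeseries),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              length(x$region_names), nrow(x$timeseries[[1]]$values)))
  invisible(x)
}

generate_behavior <- function(spec, gt) {
  bh <- spec$behavior
  out <- data.frame(subject_id = gt$subject_id, group = gt$group,
                    stringsAsFactors = FALSE)
  n <- nrow(gt)
  # couple behavior to within-group centered strengths so the group-level
  # intercepts keep their meaning (mean RT / accuracy of the group) and the
  # accuracy scale does not saturate
  center_by_group <- function(x) {
    stats::ave(x, gt$group, FUN = function(v) v - mean(v))
  }
  rt_sig <- rep(0, n)
  acc_sig <- rep(0, n)
  for (e in names(bh$rt_coefficients)) {
    rt_sig <- rt_sig + bh$rt_coefficients[[e]] * center_by_group(gt[[e]])
  }
  for (e in names(bh$acc_coefficients)) {
    acc_sig <- acc_sig + bh$acc_coefficients[[e]] * center_by_group(gt[[e]])
  }
  rt <- acc <- rep(0, n)
  for (g in unique(gt$group)) {
    idx <- which(gt$group == g)
    gs <- spec$groups[[g]]
    noise <- with_seed(derive_seed(spec$seed, 7, match(g, names(spec$groups))), {
      list(rt = rnorm(length(idx), 0, gs$rt_noise_sd %||% 100),
           acc = rnorm(length(idx), 0, gs$acc_noise_sd %||% 0.04))
    })
    rt[idx] <- (gs$rt_intercept %||% 1800) + rt_sig[idx] + noise$rt
    acc[idx] <- (gs$acc_intercept %||% 0.9) + acc_sig[idx] + noise$acc
  }
  out$reaction_time <- pmax(rt, 150)
  out$accuracy <- pmin(pmax(acc, 0), 1)
  out
}

generate_structure <- function(spec, gt) {
  st <- spec$structure
  if (is.null(st)) return(NULL)
  regions <- spec$base_params$region_names
  pairs <- t(utils::combn(regions, 2))
  out <- list()
  for (g in unique(gt$group)) {
    idx <- which(gt$group == g)
    gs <- spec$groups[[g]]
    coupled <- isTRUE(gs$structure_coupled)
    vals <- with_seed(derive_seed(spec$seed, 8, match(g, names(spec$groups))), {
      lapply(seq_len(nrow(pairs)), function(k) {
        a <- pairs[k, 1]; b <- pairs[k, 2]
        und_key <- paste(a, b, sep = "-")
        fib <- rnorm(length(idx), gs$fiber_mean %||% 30, st$fiber_sd)
        fa <- rnorm(length(idx), gs$fa_mean %||% 0.5, st$fa_sd)
        se <- parse_edge_key(st$edge)
        if (coupled && setequal(c(a, b), se)) {
          s <- gt[[st$edge]][idx]
          fib <- fib + st$coupling_slope * (s - mean(s))
          fa <- fa + st$fa_slope * (s - mean(s))
        }
        data.frame(subject_id = gt$subject_id[idx], group = g,
                   region_a = a, region_b = b,
                   fiber_density = pmax(fib, 0),
                   mean_FA = pmin(pmax(fa, 0), 1),
                   stringsAsFactors = FALSE)
      })
    })
    out[[g]] <- do.call(rbind, vals)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
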