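#' @name pipeline
#' @title End-to-end pipeline stages
#' @description
#' `run_simulate()`, `run_reactivity()` and `run_transcriptome()` orchestrate
#' the package's stages over files on disk, driven by a validated
#' configuration (YAML file or named list). Every run writes a resolved copy
#' of its configuration (`config_resolved.yaml`) next to its outputs and is
#' deterministic given the seed, so reruns overwrite identical files.
#' Unknown configuration keys are rejected by name. A thin command-line
#' wrapper over these functions ships in `inst/cli/nociceptR.R`.
NULL

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file or a list",
                             call. = FALSE)
  config
}

check_keys <- function(cfg, allowed, where) {
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown %s config key(s): %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  invisible(cfg)
}

default_if_null <- function(x, default) if (is.null(x)) default else x

# derived stream seed, kept inside 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 10000 + k) %% .Machine$integer.max)
}

write_resolved_config <- function(cfg, outdir) {
  cfg$package_version <- as.character(utils::packageVersion("nociceptR"))
  yaml::write_yaml(cfg, file.path(outdir, "config_resolved.yaml"))
}

#' @rdname pipeline
#' @param config YAML file path or named list. For `run_simulate()` the
#'   recognised keys are `seed`, `stimulus_times`, `protocol`
#'   (`rebaseline_length`), `wells` (a list of condition blocks with keys
#'   `condition`, `n_replicates`, `wells_per_replicate`, `is_control`, plus
#'   any [sim_well_config()] override), `counts` (the [sim_counts_config()]
#'   fields plus `n_sets`, `set_size`, `groups`) and `write_tiff`.
#' @param outdir Output directory (created if needed).
#' @param seed Optional integer overriding the config seed.
#' @return `run_simulate()`: the output directory, invisibly.
#' @export
run_simulate <- function(config, outdir, seed = NULL) {
  cfg <- read_config(config)
  check_keys(cfg, c("seed", "stimulus_times", "protocol", "wells", "counts",
                    "write_tiff"), "simulate")
  if (!is.null(seed)) cfg$seed <- seed
  cfg$seed <- default_if_null(cfg$seed, 1L)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  st <- unlist(default_if_null(cfg$stimulus_times, list(A = 10)))
  rebase <- default_if_null(cfg$protocol$rebaseline_length, 5)
  protocol <- stimulation_protocol(st, duration = 45,
                                   rebaseline_length = rebase)
  write_protocol_yaml(protocol, file.path(outdir, "protocol.yaml"))

  well_cfg_keys <- setdiff(names(formals(sim_well_config)), "seed")
  blocks <- default_if_null(cfg$wells, list(list(condition = "control",
                                                 n_replicates = 3)))
  wells_meta <- list()
  widx <- 0L
  for (b in blocks) {
    check_keys(b, c("condition", "n_replicates", "wells_per_replicate",
                    "is_control", well_cfg_keys), "well block")
    if (is.null(b$condition)) stop("well block without 'condition' key",
                                   call. = FALSE)
    n_rep <- default_if_null(b$n_replicates, 3L)
    n_tech <- default_if_null(b$wells_per_replicate, 1L)
    overrides <- b[intersect(names(b), well_cfg_keys)]
    overrides$stimulus_times <- st
    if (!is.null(overrides$class_probabilities)) {
      overrides$class_probabilities <- unlist(overrides$class_probabilities)
    }
    for (r in seq_len(n_rep)) {
      for (tw in seq_len(n_tech)) {
        widx <- widx + 1L
        wid <- sprintf("well_%03d", widx)
        wcfg <- do.call(sim_well_config,
                        c(overrides, list(seed = child_seed(cfg$seed, widx))))
        sim <- simulate_well(wcfg)
        write_trace_csv(sim$traces, file.path(outdir,
                                              paste0("traces_", wid, ".csv")))
        utils::write.csv(sim$truth,
                         file.path(outdir, paste0("truth_", wid, ".csv")),
                         row.names = FALSE)
        if (isTRUE(cfg$write_tiff)) {
          stack <- render_image_stack(sim$traces, sim$truth)
          write_image_stack(stack, file.path(outdir,
                                             paste0("stack_", wid, ".tif")))
        }
        wells_meta[[widx]] <- data.frame(
          well_id = wid, plate = "plate_1", condition = b$condition,
          replicate = r, is_control = isTRUE(b$is_control))
      }
    }
  }
  utils::write.csv(do.call(rbind, wells_meta),
                   file.path(outdir, "wells.csv"), row.names = FALSE)

  if (!is.null(cfg$counts)) {
    cc <- cfg$counts
    check_keys(cc, c(setdiff(names(formals(sim_counts_config)),
                             c("geneset_definitions", "seed")),
                     "n_sets", "set_size", "groups"), "counts")
    n_sets <- default_if_null(cc$n_sets, 8L)
    set_size <- default_if_null(cc$set_size, 25L)
    groups <- default_if_null(cc$groups,
                              c("Synapse signaling", "Neurotransmitter",
                                "Receptors Channels Transporters",
                                "Morphogenesis"))
    sim_args <- cc[setdiff(names(cc), c("n_sets", "set_size", "groups"))]
    if (!is.null(sim_args$effect_log2fc_range)) {
      sim_args$effect_log2fc_range <- unlist(sim_args$effect_log2fc_range)
    }
    ccfg <- do.call(sim_counts_config,
                    c(sim_args, list(seed = child_seed(cfg$seed, 9999L))))
    sim <- simulate_counts(ccfg)
    # gene sets enriched in planted DEGs to varying degrees
    set.seed(child_seed(cfg$seed, 9998L))
    deg_pool <- sim$truth$gene
    other_pool <- setdiff(rownames(sim$counts), deg_pool)
    sets <- list()
    for (i in seq_len(n_sets)) {
      frac_deg <- if (length(deg_pool)) (i - 1) / max(1, n_sets - 1) else 0
      n_deg <- min(round(frac_deg * set_size), length(deg_pool))
      sets[[sprintf("set_%02d", i)]] <-
        c(sample(deg_pool, n_deg), sample(other_pool, set_size - n_deg))
    }
    write_gmt(sets, file.path(outdir, "sets.gmt"))
    utils::write.csv(data.frame(set = names(sets),
                                group = rep(groups,
                                            length.out = length(sets))),
                     file.path(outdir, "groups.csv"), row.names = FALSE)
    utils::write.csv(data.frame(gene = rownames(sim$counts), sim$counts,
                                check.names = FALSE),
                     file.path(outdir, "counts.csv"), row.names = FALSE)
    utils::write.csv(sim$sample_info, file.path(outdir, "samples.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$truth, file.path(outdir, "counts_truth.csv"),
                     row.names = FALSE)
  }
  write_resolved_config(cfg, outdir)
  invisible(outdir)
}

#' @rdname pipeline
#' @param indir Directory holding the stage inputs (for `run_reactivity()`:
#'   `wells.csv`, `protocol.yaml` and one `traces_<well_id>.csv` per well,
#'   as written by `run_simulate()`).
#' @return `run_reactivity()`: the output directory, invisibly; writes
#'   `delta_f.csv`, `thresholds.csv`, `well_summary.csv`,
#'   `condition_summary.csv` and, when applicable, `comparisons.csv` and
#'   `overlap.csv`.
#' @export
run_reactivity <- function(config, indir, outdir = indir) {
  cfg <- read_config(config)
  check_keys(cfg, c("control_stimulus", "cap", "reference_condition",
                    "design", "posthoc", "baseline_stat", "response_stat"),
             "reactivity")
  control_stimulus <- default_if_null(cfg$control_stimulus, "HBSS")
  cap <- default_if_null(cfg$cap, 18)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wells_path <- file.path(indir, "wells.csv")
  if (!file.exists(wells_path)) {
    stop("no wells.csv in ", indir, call. = FALSE)
  }
  wells <- utils::read.csv(wells_path)
  protocol <- read_protocol_yaml(file.path(indir, "protocol.yaml"))
  dfs <- list()
  for (w in wells$well_id) {
    tp <- file.path(indir, paste0("traces_", w, ".csv"))
    if (!file.exists(tp)) stop("missing trace file for well ", w,
                               call. = FALSE)
    traces <- read_trace_csv(tp)
    d <- compute_delta_f(traces, protocol,
                         baseline_stat = default_if_null(cfg$baseline_stat,
                                                         "mean"),
                         response_stat = default_if_null(cfg$response_stat,
                                                         "max"))
    d$well_id <- w
    dfs[[w]] <- d
  }
  delta_f <- do.call(rbind, dfs)
  rownames(delta_f) <- NULL
  utils::write.csv(delta_f, file.path(outdir, "delta_f.csv"),
                   row.names = FALSE)
  thr <- well_thresholds(delta_f, wells, control_stimulus = control_stimulus,
                         cap = cap)
  utils::write.csv(do.call(rbind, lapply(thr, function(t)
    data.frame(well_id = t$well_id, threshold = t$value,
               control_mean = t$control_mean, control_sd = t$control_sd,
               capped = t$capped, mode = t$mode))),
    file.path(outdir, "thresholds.csv"), row.names = FALSE)

  summaries <- list()
  calls_by_well <- list()
  for (w in names(thr)) {
    calls <- classify(delta_f[delta_f$well_id == w, ], thr[[w]])
    calls_by_well[[w]] <- calls
    summaries[[w]] <- fraction_reactive(calls, well_id = w)
  }
  well_summary <- do.call(rbind, summaries)
  rownames(well_summary) <- NULL
  well_summary <- merge(well_summary, wells, by = "well_id")
  utils::write.csv(well_summary, file.path(outdir, "well_summary.csv"),
                   row.names = FALSE)
  cond_summary <- summarize_replicates(well_summary, by = "stimulus")
  utils::write.csv(cond_summary, file.path(outdir, "condition_summary.csv"),
                   row.names = FALSE)

  if (!is.null(cfg$reference_condition) &&
      length(unique(wells$condition)) >= 2L) {
    comps <- list()
    for (s in unique(well_summary$stimulus)) {
      sub <- well_summary[well_summary$stimulus == s, ]
      rep_level <- summarize_technical(sub)
      cmp <- compare_conditions(rep_level, cfg$reference_condition,
                                design = default_if_null(cfg$design,
                                                         "unpaired"),
                                posthoc = default_if_null(cfg$posthoc,
                                                          "dunnett"))
      cmp$stimulus <- s
      comps[[s]] <- cmp
    }
    utils::write.csv(do.call(rbind, comps),
                     file.path(outdir, "comparisons.csv"), row.names = FALSE)
  }

  responder_stims <- intersect(c("A", "B"), unique(delta_f$stimulus))
  if (length(responder_stims) == 2L) {
    ov <- lapply(names(calls_by_well), function(w) {
      calls <- calls_by_well[[w]]
      o <- double_stim_overlap(calls[calls$stimulus == "A", ],
                               calls[calls$stimulus == "B", ])
      data.frame(well_id = w, n_cells = o$n_cells,
                 fraction_both = o$fraction_both,
                 fraction_A_only = o$fraction_A_only,
                 fraction_B_only = o$fraction_B_only,
                 fraction_neither = o$fraction_neither)
    })
    utils::write.csv(do.call(rbind, ov), file.path(outdir, "overlap.csv"),
                     row.names = FALSE)
  }
  write_resolved_config(cfg, outdir)
  invisible(outdir)
}

# collapse technical replicates to biological-replicate means
summarize_technical <- function(well_summary) {
  agg <- stats::aggregate(fraction_reactive ~ condition + replicate,
                          data = well_summary, FUN = mean)
  agg
}

#' @rdname pipeline
#' @return `run_transcriptome()`: the output directory, invisibly; writes
#'   `expression_stats.csv`, `ogo.csv`, `activation_scores.csv` and
#'   `group_trajectories.csv`.
#' @export
run_transcriptome <- function(config, indir, outdir = indir) {
  cfg <- read_config(config)
  check_keys(cfg, c("baseline", "alpha", "fc_threshold", "fc_type",
                    "ogo_time_point", "reference_time_point", "top_n"),
             "transcriptome")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  counts_df <- utils::read.csv(file.path(indir, "counts.csv"),
                               check.names = FALSE)
  counts <- as.matrix(counts_df[, -1L, drop = FALSE])
  rownames(counts) <- counts_df[[1L]]
  sample_info <- utils::read.csv(file.path(indir, "samples.csv"))
  if (!all(colnames(counts) %in% sample_info$sample)) {
    stop("sample metadata does not cover all count columns", call. = FALSE)
  }
  tab <- table(sample_info$time_point)
  if (any(tab < 2L)) {
    stop("time point(s) with < 2 replicates: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  }
  gene_sets <- read_gmt(file.path(indir, "sets.gmt"))
  groups_df <- utils::read.csv(file.path(indir, "groups.csv"))
  groups <- stats::setNames(groups_df$group, groups_df$set)

  stats_long <- differential_expression(
    counts, sample_info, baseline = cfg$baseline,
    alpha = default_if_null(cfg$alpha, 0.05),
    fc_threshold = default_if_null(cfg$fc_threshold, 2))
  utils::write.csv(stats_long, file.path(outdir, "expression_stats.csv"),
                   row.names = FALSE)

  tps <- sort(unique(stats_long$time_point))
  ogo_tp <- default_if_null(cfg$ogo_time_point, max(tps))
  degs <- stats_long$gene[stats_long$time_point == ogo_tp &
                          stats_long$is_deg]
  ogo <- find_ogo(degs, gene_sets, universe = rownames(counts),
                  top_n = default_if_null(cfg$top_n, 50))
  utils::write.csv(ogo, file.path(outdir, "ogo.csv"), row.names = FALSE)

  score_sets <- gene_sets[ogo$set[ogo$over_represented]]
  if (length(score_sets) == 0L) score_sets <- gene_sets
  scores <- score_matrix(score_sets, stats_long,
                         fc_type = default_if_null(cfg$fc_type, "abs_log2"))
  utils::write.csv(data.frame(set = rownames(scores), scores,
                              check.names = FALSE),
                   file.path(outdir, "activation_scores.csv"),
                   row.names = FALSE)

  ref_tp <- default_if_null(cfg$reference_time_point, tps[1L])
  traj <- group_trajectories(scores, groups, reference_tp = ref_tp)
  utils::write.csv(traj, file.path(outdir, "group_trajectories.csv"),
                   row.names = FALSE)
  write_resolved_config(cfg, outdir)
  invisible(outdir)
}
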