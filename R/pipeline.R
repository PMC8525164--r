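## Config-driven end-to-end run: (simulated or loaded) inputs -> breadth
## profile -> signal table -> host-sharing regression -> strict-clock
## chronogram -> DEC* ancestral reconstruction, with every artifact
## serialized into an output directory and a MANIFEST marking completeness.
## All randomness flows from one master seed through fixed per-stage child
## seeds so stages are individually re-runnable yet reproducible.

#' Default pipeline configuration
#'
#' `preset = "dacini"` emulates the dimensions of a tephritid fruit-fly
#' host-use study: 37 flies, 286 host genera in 87 families, 8 monophages
#' and 11 extreme polyphages (>= 20 families), attack probability decaying
#' with host distance (beta0 = 1.7962, beta1 = -1.6633 on the
#' log10(Myr + 1) scale). `preset = "mini"` is a small smoke-test system.
#'
#' @param preset `"dacini"` or `"mini"`.
#' @param seed master seed.
#' @return a config list accepted by [run_pipeline()].
#' @export
pipeline_preset <- function(preset = c("dacini", "mini"), seed = 1) {
  preset <- match.arg(preset)
  sim <- switch(preset,
    dacini = list(n_flies = 37, n_genera = 286, n_families = 87,
                  beta0 = 1.7962, beta1 = -1.6633, host_root_age = 150,
                  breadth_profile = list(n_monophages = 8, n_extreme = 11,
                                         extreme_min_families = 20)),
    mini = list(n_flies = 12, n_genera = 40, n_families = 10,
                beta0 = 1.8, beta1 = -1.7, host_root_age = 150,
                breadth_profile = NULL))
  list(seed = seed,
       simulate = sim,
       stages = c("simulate", "breadth", "signal", "sharing",
                  "chronogram", "dec"),
       signal = list(thresholds = c(2, 3, 4),
                     n_perm = if (preset == "dacini") 10000 else 500),
       sharing = list(n_runs = if (preset == "dacini") 1000 else 100,
                      min_hosts = 3),
       chronogram = list(root_age = 1),
       dec = list(k_families = if (preset == "dacini") 9 else 3,
                  max_families = 20, exclude = character(),
                  max_range_size = NULL, root_prior = "uniform"))
}

.pl_log <- function(state, ...) {
  line <- paste0(...)
  cat(line, "\n", sep = "", file = state$logfile, append = TRUE)
  .msg(line)
}

.pl_manifest <- function(state) {
  df <- state$manifest
  df <- rbind(df, data.frame(
    stage = "run",
    status = if (all(df$status == "complete")) "complete" else "partial"))
  write.table(df, file.path(state$dir, "MANIFEST"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order, writing machine-readable
#' artifacts (TSV/JSON/Newick) into `output_dir` plus `run.log`,
#' `config.yaml` (the configuration as run) and a `MANIFEST` listing each
#' stage's status. A failing stage halts with a stage-named error; the
#' MANIFEST then records which stages completed.
#'
#' @param config a config list (see [pipeline_preset()]) or the path of a
#'   YAML file with the same structure. Either `simulate` parameters or
#'   `inputs` paths (`fly_tree`, `host_tree`, `associations`) must be
#'   provided for the stages that need them.
#' @param output_dir output directory (created if absent); defaults to
#'   `config$output_dir`.
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir <- output_dir %||% config$output_dir
  if (is.null(dir)) stop("no output directory given")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  stages <- config$stages %||%
    c("simulate", "breadth", "signal", "sharing", "chronogram", "dec")

  # pre-flight validation before any compute
  need_assoc <- any(c("breadth", "signal", "sharing", "dec") %in% stages)
  need_fly <- any(c("signal", "chronogram", "dec") %in% stages)
  need_host <- any(c("sharing") %in% stages)
  if (!"simulate" %in% stages) {
    inp <- config$inputs
    if (need_assoc && is.null(inp$associations))
      stop("pre-flight: stage needs 'inputs$associations' but none given")
    if (need_fly && is.null(inp$fly_tree))
      stop("pre-flight: stage needs 'inputs$fly_tree' but none given")
    if (need_host && is.null(inp$host_tree))
      stop("pre-flight: stage needs 'inputs$host_tree' but none given")
    for (p in unlist(inp)) if (!file.exists(p))
      stop("pre-flight: input file not found: ", p)
  }

  state <- new.env()
  state$dir <- dir
  state$logfile <- file.path(dir, "run.log")
  cat("", file = state$logfile)
  state$manifest <- data.frame(stage = character(), status = character())
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  res <- list()

  mark <- function(stage) {
    state$manifest <- rbind(state$manifest,
                            data.frame(stage = stage, status = "complete"))
    .pl_manifest(state)
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      sim <- config$simulate %||% list()
      sys <- do.call(simulate_association_system,
                     c(sim, list(seed = .child_seed(seed, 1))))
      res$system <<- sys
      write_newick(sys$fly_tree, file.path(dir, "fly_tree.nwk"))
      write_newick(sys$host_tree, file.path(dir, "host_tree.nwk"))
      write_association_table(sys$table, file.path(dir, "associations.tsv"))
      jsonlite::write_json(unclass(sys$truth),
                           file.path(dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      .pl_log(state, "simulate: ", nrow(sys$table), " records, ",
              sys$truth$n_flies, " flies, child seed ", .child_seed(seed, 1))
    })
    mark("simulate")
    table <- res$system$table
    fly_tree <- res$system$fly_tree
    host_tree <- res$system$host_tree
  } else {
    inp <- config$inputs
    table <- if (need_assoc) load_association_table(inp$associations)
    fly_tree <- if (need_fly)
      parse_newick(paste(readLines(inp$fly_tree), collapse = ""))
    host_tree <- if (need_host)
      parse_newick(paste(readLines(inp$host_tree), collapse = ""))
  }

  if ("breadth" %in% stages) {
    run_stage("breadth", function() {
      prof <- host_breadth(table)
      res$breadth <<- prof
      write.table(prof, file.path(dir, "breadth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      .pl_log(state, "breadth: ", nrow(prof), " flies; ",
              sum(prof$n_host_families == 1), " monophagous")
    })
    mark("breadth")
  }

  if ("signal" %in% stages) {
    run_stage("signal", function() {
      sg <- config$signal %||% list()
      tab <- signal_table(fly_tree, table,
                          thresholds = sg$thresholds %||% c(2, 3, 4),
                          n_perm = sg$n_perm %||% 10000,
                          seed = .child_seed(seed, 2))
      res$signal <<- tab
      write.table(tab, file.path(dir, "signal.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      .pl_log(state, "signal: ", nrow(tab), " characters, child seed ",
              .child_seed(seed, 2))
    })
    mark("signal")
  }

  if ("sharing" %in% stages) {
    run_stage("sharing", function() {
      sh <- config$sharing %||% list()
      mat <- interaction_matrix(table)
      D <- patristic_distances(host_tree)
      fit <- resample_regression(mat, D,
                                 n_runs = sh$n_runs %||% 1000,
                                 min_hosts = sh$min_hosts %||% 3,
                                 seed = .child_seed(seed, 3))
      res$sharing <<- fit
      write.table(fit$runs, file.path(dir, "sharing_runs.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(beta0 = fit$beta0, beta1 = fit$beta1,
             ci_beta0 = fit$ci_beta0, ci_beta1 = fit$ci_beta1,
             n_runs = fit$n_runs, n_flagged = fit$n_flagged,
             n_flies = fit$n_flies, seed = fit$seed,
             ci_method = fit$ci_method),
        file.path(dir, "sharing_summary.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      grid <- seq(0, max(D), length.out = 200)
      write.table(
        data.frame(distance_myr = grid,
                   probability = sharing_probability(fit, grid)),
        file.path(dir, "sharing_curve.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      .pl_log(state, sprintf(
        "sharing: logit(S) = %.4f %+.4f x over %d runs (child seed %d)",
        fit$beta0, fit$beta1, fit$n_runs, .child_seed(seed, 3)))
    })
    mark("sharing")
  }

  if ("chronogram" %in% stages) {
    run_stage("chronogram", function() {
      ch <- config$chronogram %||% list()
      chrono <- strict_clock_chronogram(fly_tree,
                                        root_age = ch$root_age %||% 1)
      res$chronogram <<- chrono
      write_newick(chrono, file.path(dir, "chronogram.nwk"))
      .pl_log(state, sprintf(
        "chronogram: rate %.6g, residual %.3g",
        attr(chrono, "rate"), attr(chrono, "objective")))
    })
    mark("chronogram")
  }

  if ("dec" %in% stages) {
    run_stage("dec", function() {
      dc <- config$dec %||% list()
      flt <- filter_for_dec(table,
                            max_families = dc$max_families %||% 20,
                            exclude = dc$exclude %||% character())
      fams <- main_host_families(flt$table, k = dc$k_families %||% 9)
      states_all <- tip_range_states_permissive(flt$table, fams)
      usable <- names(states_all)[lengths(states_all) > 0]
      dropped <- setdiff(flt$retained, usable)
      if (length(dropped))
        .pl_log(state, "dec: dropped ", length(dropped),
                " fly/flies with no main-family host: ",
                paste(dropped, collapse = ", "))
      if (length(usable) < 3) stop("fewer than 3 flies usable for DEC")
      chrono <- res$chronogram %||%
        strict_clock_chronogram(fly_tree,
                                root_age =
                                  (config$chronogram %||% list())$root_age
                                  %||% 1)
      keep <- intersect(chrono$tip.label, usable)
      sub <- ape::keep.tip(chrono, keep)
      sub <- resolve_polytomies(sub)
      tips <- states_all[sub$tip.label]
      space <- build_state_space(fams,
                                 max_size = dc$max_range_size %||%
                                   length(fams))
      fit <- fit_dec(sub, tips, space,
                     root_prior = dc$root_prior %||% "uniform")
      anc <- ancestral_states(sub, tips, fit$params, space,
                              root_prior = dc$root_prior %||% "uniform")
      res$dec <<- list(fit = fit, ancestral = anc, tree = sub,
                       families = fams)
      jsonlite::write_json(
        list(d = fit$params$d, e = fit$params$e, logL = fit$logL,
             bound_hit = fit$bound_hit, families = fams,
             n_states = space$n_states, n_tips = length(keep)),
        file.path(dir, "dec_params.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      top5 <- t(apply(anc$probs, 1, function(p) {
        o <- order(-p)[1:min(5, length(p))]
        paste0(space$labels[o], ":", signif(p[o], 6), collapse = ";")
      }))
      write.table(
        data.frame(node = rownames(anc$probs),
                   postorder_index = seq_len(nrow(anc$probs)),
                   map_state = anc$map_label,
                   top_states = as.vector(top5)),
        file.path(dir, "dec_nodes.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      ann <- sub
      ann$node.label <- gsub("[ ,():;]", "_", anc$map_label)
      write_newick(ann, file.path(dir, "dec_annotated.nwk"))
      .pl_log(state, sprintf(
        "dec: %d tips, %d states, d = %.4g, e = %.4g, logL = %.4f, root = %s",
        length(keep), space$n_states, fit$params$d, fit$params$e,
        fit$logL, anc$map_label[1]))
    })
    mark("dec")
  }

  invisible(res)
}

#' Tip range states, permissive variant
#'
#' Like [tip_range_states()] but returns an empty vector (instead of
#' erroring) for flies using none of the listed families, so callers can
#' drop them explicitly.
#'
#' @inheritParams tip_range_states
#' @return named list mapping fly name to a (possibly empty) family vector.
#' @export
tip_range_states_permissive <- function(table, families) {
  v <- table[table$status == "valid", , drop = FALSE]
  flies <- sort(unique(v$fly_species))
  states <- lapply(flies, function(f)
    intersect(families, unique(v$host_family[v$fly_species == f])))
  names(states) <- flies
  states
}
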