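#' Parse a region definition from configuration
#'
#' Region configurations are plain lists (typically deserialized from a
#' JSON config): `kind = "ball"` with `center` and `radius`;
#' `kind = "halfspace"` with `weights`, `offset`, `positive_label`,
#' `negative_label` and a `side`; `kind = "union"` with a `members` list.
#'
#' @param cfg A list as described above.
#' @return A `region`.
#' @export
parse_region_config <- function(cfg) {
  if (inherits(cfg, "region")) return(cfg)
  kind <- cfg$kind
  if (is.null(kind)) stop("region config lacks 'kind'", call. = FALSE)
  switch(kind,
    ball = region_ball(as.numeric(cfg$center), as.numeric(cfg$radius)),
    halfspace = {
      ld <- structure(list(weights = as.numeric(cfg$weights),
                           offset = as.numeric(cfg$offset),
                           positive_label = cfg$positive_label %||%
                             "positive",
                           negative_label = cfg$negative_label %||%
                             "negative"),
                      class = "linear_discriminant")
      region_halfspace(ld, side = cfg$side %||% "positive")
    },
    union = region_union(lapply(cfg$members, parse_region_config)),
    stop("unknown region kind '", kind, "'", call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_from <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else if (is.list(config)) config else
    stop("config must be a list or a JSON file path", call. = FALSE)
}

build_clustering_config <- function(cfg, seed = NULL) {
  cfg <- cfg %||% list()
  clustering_config(
    dc_mode = cfg$dc_mode %||% "fraction",
    dc_value = cfg$dc_value %||% 0.02,
    kernel = cfg$kernel %||% "hard",
    selection = cfg$selection %||% "gamma_gap",
    k = cfg$k,
    threshold_multiplier = cfg$threshold_multiplier %||% 2,
    assign = cfg$assign %||% "nearest",
    seed = seed)
}

run_simulate_stage <- function(cfg, seed) {
  kind <- cfg$kind %||% "bimodal"
  if (!is.null(cfg$seed)) seed <- cfg$seed
  switch(kind,
    bimodal = {
      args <- cfg[setdiff(names(cfg), c("kind", "seed"))]
      args$seed <- seed
      sim <- simulate_bimodal_response(
        do.call(bimodal_response_spec, args))
      list(cohort = sim$cohort,
           truth = data.frame(patient_id = unique(sim$cohort$patient_id),
                              responder = sim$responder))
    },
    mixture = {
      args <- cfg[setdiff(names(cfg), c("kind", "seed"))]
      args$seed <- seed
      sim <- simulate_mixture(do.call(mixture_spec, args))
      list(cohort = sim$cohort,
           truth = data.frame(patient_id = sim$cohort$patient_id,
                              label = sim$labels))
    },
    two_timepoint = {
      mix <- do.call(mixture_spec,
                     cfg$t1_mixture[setdiff(names(cfg$t1_mixture),
                                            "seed")])
      spec <- two_timepoint_spec(
        mix, transition = do.call(rbind, cfg$transition),
        t2_centroids = if (!is.null(cfg$t2_centroids))
          do.call(rbind, cfg$t2_centroids),
        t2_within_sd = cfg$t2_within_sd %||% 1, seed = seed)
      sim <- simulate_two_timepoint(spec)
      list(cohort = sim$cohort,
           truth = data.frame(
             patient_id = unique(sim$cohort$patient_id),
             label_t1 = sim$labels_t1, label_t2 = sim$labels_t2))
    },
    stop("unknown simulate kind '", kind, "'", call. = FALSE))
}

#' Run the multi-stage stratification pipeline
#'
#' Executes, in order and as configured: simulate (or load) a cohort;
#' density-peak clustering per timepoint; soft/hard stratification
#' against the discovered prototypes; transition-model estimation between
#' two timepoints; and outcome-region evaluation.  Every run writes its
#' artifacts plus a machine-readable JSON manifest (resolved
#' configuration, seed, stage log, output checksums) to `out_dir`; a
#' rerun of the same config is bit-identical.
#'
#' @param config A list or path to a JSON configuration with optional
#'   elements `seed`, `out_dir`, `simulate` (or `cohort` with `path`,
#'   `scale_path`, `layout`), `cluster`, `stratify`, `trajectory`,
#'   `evaluate`.
#' @param out_dir Output directory (overrides `config$out_dir`; default
#'   a fresh temporary directory).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- config_from(config)
  out_dir <- out_dir %||% config$out_dir %||%
    tempfile("stratsig_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  manifest <- list(package = "stratsig",
                   version = as.character(utils::packageVersion(
                     "stratsig")),
                   seed = seed, config = config, stages = list(),
                   outputs = character(0))
  results <- list()
  log <- character(0)
  emit <- function(name, df) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    manifest$outputs <<- c(manifest$outputs, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## --- cohort acquisition -------------------------------------------
  co <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", run_simulate_stage(config$simulate, seed))
    co <- sim$cohort
    write_cohort(co, file.path(out_dir, "cohort.csv"))
    manifest$outputs <- c(manifest$outputs,
                          file.path(out_dir, "cohort.csv"))
    emit("truth.csv", sim$truth)
    results$simulate <- sim
    log <- c(log, sprintf("simulate: %d signatures", n_signatures(co)))
    manifest$stages$simulate <- list(kind = config$simulate$kind %||%
                                       "bimodal")
  } else if (!is.null(config$cohort)) {
    co <- stage("load", {
      sc <- read_scale(config$cohort$scale_path)
      load_cohort(config$cohort$path, sc,
                  layout = config$cohort$layout %||% "wide")
    })
    results$cohort <- co
    log <- c(log, sprintf("load: %d signatures", n_signatures(co)))
  }

  ## --- clustering per timepoint -------------------------------------
  if (!is.null(config$cluster)) {
    if (is.null(co)) stop("cluster stage needs a cohort", call. = FALSE)
    ccfg <- build_clustering_config(config$cluster, seed)
    tps <- config$cluster$timepoints %||% unique(co$timepoint)
    results$cluster <- list()
    for (tp in tps) {
      dp <- stage("cluster", dp_cluster(co, ccfg, timepoint = tp))
      results$cluster[[tp]] <- dp
      sub <- cohort_at(co, tp)
      emit(paste0("clusters_", tp, ".csv"),
           data.frame(patient_id = sub$patient_id, timepoint = tp,
                      rho = dp$rho, delta = dp$delta, gamma = dp$gamma,
                      label = dp$labels,
                      prototype = seq_along(dp$labels) %in%
                        dp$prototypes))
      emit(paste0("prototypes_", tp, ".csv"),
           data.frame(label = seq_along(dp$prototypes), dp$centroids,
                      check.names = FALSE))
      log <- c(log, sprintf(
        "cluster[%s]: d_c = %.6g, %d prototype(s), selection = %s",
        tp, dp$dc, length(dp$prototypes), ccfg$selection))
    }
    manifest$stages$cluster <- list(
      timepoints = tps, selection = ccfg$selection, kernel = ccfg$kernel,
      dc = vapply(results$cluster, `[[`, numeric(1), "dc"))
  }

  ## --- stratification ------------------------------------------------
  if (!is.null(config$stratify)) {
    if (is.null(results$cluster))
      stop("stratify stage needs clustering results", call. = FALSE)
    temp <- config$stratify$temperature %||% 1
    mode <- config$stratify$mode %||% "soft"
    results$stratify <- list()
    for (tp in names(results$cluster)) {
      dp <- results$cluster[[tp]]
      ps <- prototypes_from_dp(dp)
      sub <- cohort_at(co, tp)
      m <- if (mode == "soft")
        soft_assign(sub$values, ps, temperature = temp)
      else
        membership(diag(length(ps$labels))[
          match(hard_assign(sub$values, ps), ps$labels), ,
          drop = FALSE], ps$labels)
      if (!is.null(config$stratify$priors))
        m <- apply_prior(m, as.numeric(config$stratify$priors))
      results$stratify[[tp]] <- m
      emit(paste0("memberships_", tp, ".csv"),
           data.frame(patient_id = sub$patient_id, unclass(m),
                      check.names = FALSE))
    }
    log <- c(log, sprintf("stratify: %s mode, temperature = %g",
                          mode, temp))
    manifest$stages$stratify <- list(mode = mode, temperature = temp)
  }

  ## --- trajectory -----------------------------------------------------
  if (!is.null(config$trajectory)) {
    t1 <- config$trajectory$t1 %||% "t1"
    t2 <- config$trajectory$t2 %||% "t2"
    if (is.null(results$stratify) ||
        is.null(results$stratify[[t1]]) ||
        is.null(results$stratify[[t2]]))
      stop("trajectory stage needs memberships at '", t1, "' and '",
           t2, "'", call. = FALSE)
    ids1 <- cohort_at(co, t1)$patient_id
    ids2 <- cohort_at(co, t2)$patient_id
    common <- intersect(ids1, ids2)
    dropped <- length(union(ids1, ids2)) - length(common)
    if (dropped > 0)
      log <- c(log, sprintf(
        "trajectory: dropped %d patient(s) absent at one timepoint",
        dropped))
    m1 <- results$stratify[[t1]][match(common, ids1), , drop = FALSE]
    m2 <- results$stratify[[t2]][match(common, ids2), , drop = FALSE]
    alpha <- config$trajectory$alpha %||% 0.5
    model <- stage("trajectory", estimate_transition(
      membership(m1), membership(m2),
      mode = config$trajectory$mode %||% "hard",
      smoothing_alpha = alpha))
    results$trajectory <- model
    write_transition_model(model, file.path(out_dir, "model.json"))
    manifest$outputs <- c(manifest$outputs,
                          file.path(out_dir, "model.json"))
    emit("trajectory_edges.csv",
         trajectory_graph(model,
                          config$trajectory$min_weight %||% 0))
    log <- c(log, sprintf("trajectory: %s counts, alpha = %g, %dx%d CPT",
                          model$mode, alpha, length(model$t1_labels),
                          length(model$t2_labels)))
    manifest$stages$trajectory <- list(mode = model$mode, alpha = alpha)
  }

  ## --- outcome evaluation --------------------------------------------
  if (!is.null(config$evaluate)) {
    if (is.null(co)) stop("evaluate stage needs a cohort", call. = FALSE)
    region <- parse_region_config(config$evaluate$region)
    tp <- config$evaluate$timepoint %||% "t2"
    ev <- stage("evaluate", evaluate_response(co, region,
                                              timepoint = tp))
    results$evaluate <- ev
    emit("response.csv",
         data.frame(patient_id = names(ev$responded),
                    responded = as.logical(ev$responded)))
    log <- c(log, sprintf("evaluate: response rate %.4f at %s",
                          ev$response_rate, tp))
    manifest$stages$evaluate <- list(timepoint = tp,
                                     response_rate = ev$response_rate)
  }

  manifest$log <- log
  manifest$checksums <- as.list(tools::md5sum(manifest$outputs))
  jsonlite::write_json(manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  results$manifest <- manifest
  results$out_dir <- out_dir
  invisible(results)
}
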