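# End-to-end pipeline driver: simulate -> preprocess -> baseline strata ->
# change points -> GKF matrices -> CCA (whole cohort and per cluster) ->
# connectivity graphs -> event-locked differences -> individual effects.

#' Pipeline configuration
#'
#' Single configuration object for [run_pipeline()]. Every random stage
#' derives its own sub-seed from `seed` (counter-based), so stages can be
#' re-run individually and the whole pipeline is deterministic.
#'
#' @param sim named list of [sim_config()] arguments for the synthetic
#'   cohort (the stated world; empty list = defaults)
#' @param sigma Gaussian kernel SD for GKF series, seconds
#' @param tau consensus threshold for the ensemble detector
#' @param delta minimum change-point spacing, seconds
#' @param tolerance ensemble vote window half-width, seconds
#' @param display_threshold loading display threshold for graphs
#' @param alpha significance level
#' @param windows event-response window lengths, seconds
#' @param n_surrogates surrogates for variate retention
#' @param n_perm permutations for p-values
#' @param penalty_mults,resolutions_hz detector grid parameters
#' @param seed master seed
#' @param out_dir output directory, or `NULL` to skip writing
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(sim = list(), sigma = 2, tau = 0.5, delta = 5,
                            tolerance = 1, display_threshold = 0.3,
                            alpha = 0.05, windows = c(8, 10, 12),
                            n_surrogates = 50, n_perm = 99,
                            penalty_mults = c(0.5, 1, 2, 3),
                            resolutions_hz = c(5, 1), seed = 1L,
                            out_dir = NULL) {
  structure(list(sim = sim, sigma = sigma, tau = tau, delta = delta,
                 tolerance = tolerance,
                 display_threshold = display_threshold, alpha = alpha,
                 windows = windows, n_surrogates = n_surrogates,
                 n_perm = n_perm, penalty_mults = penalty_mults,
                 resolutions_hz = resolutions_hz, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# stable small checksum of a serializable object (manifest traceability)
param_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, force = TRUE)
  v <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

perf_key <- function(piece, version) sprintf("p%d_v%d", piece, version)

# musical event onsets for one performance: detected acoustic categories
# (channel x direction) plus annotation categories
musical_events_table <- function(cps_by_channel, ann) {
  ev <- list()
  for (ch in names(cps_by_channel)) {
    cp <- cps_by_channel[[ch]]
    if (nrow(cp)) for (i in seq_len(nrow(cp)))
      ev[[length(ev) + 1]] <- data.frame(onset_s = cp$onset_s[i],
                                         category = cp$category[i])
  }
  if (nrow(ann$events)) for (i in seq_len(nrow(ann$events)))
    ev[[length(ev) + 1]] <- data.frame(onset_s = ann$events$onset_s[i],
                                       category = ann$events$category[i])
  if (!length(ev))
    return(data.frame(onset_s = numeric(0), category = character(0)))
  out <- do.call(rbind, ev)
  out[order(out$onset_s), ]
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a freshly generated synthetic cohort and
#' returns a result bundle; with `out_dir` set, all tabular outputs are
#' written as CSV, structured outputs as JSON, graphs as SVG, plus a
#' manifest of parameters, seeds and a parameter hash. Per-cluster CCA is
#' run on each autonomic cluster's listeners only, with physiological
#' averaging within the cluster.
#'
#' @param config a [pipeline_config()]
#' @param grid optional detector grid override (list of
#'   [detector_config()])
#' @return result bundle (see details); fields: `cohort`, `baseline`,
#'   `musical_cps`, `events_by_perf`, `cca` (per stratum: inputs, result,
#'   selection, perm_p, graph), `event_tables`, `individual`, `manifest`
#' @export
run_pipeline <- function(config, grid = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(grid))
    grid <- detector_grid(config$penalty_mults, config$resolutions_hz)
  sim_args <- config$sim
  if (is.null(sim_args$seed)) sim_args$seed <- derive_seed(config$seed, "sim")
  scfg <- do.call(sim_config, sim_args)

  cohort <- generate_cohort(scfg)
  channels <- preprocess_cohort(cohort)

  # --- baseline stratification ---
  summaries <- lapply(cohort$listeners, function(l) hrv_summary(l$baseline_rr))
  indices <- pns_sns_indices(summaries)
  clus <- cluster_autonomic(indices, seed = derive_seed(config$seed, "kmeans"))
  baseline <- list(summaries = summaries, indices = indices, clusters = clus)

  # --- musical change points and events per performance ---
  musical_cps <- list(); events_by_perf <- list()
  for (r in seq_len(nrow(cohort$performances))) {
    p <- cohort$performances$piece[r]; v <- cohort$performances$version[r]
    ms <- cohort$music[[p]][[v]]
    cps <- lapply(ms$channels, function(s)
      ensemble_detect(s, grid, consensus = config$tau,
                      min_spacing = config$delta,
                      tolerance = config$tolerance))
    key <- perf_key(p, v)
    musical_cps[[key]] <- cps
    events_by_perf[[key]] <- musical_events_table(cps, cohort$annotations[[p]])
  }

  # --- physiological change points and per-listener GKF series ---
  dur <- scfg$piece_duration_s
  phys_gkf <- list()   # listener -> session -> channel -> gkf_series
  for (li in seq_along(cohort$listeners)) {
    phys_gkf[[li]] <- lapply(seq_along(channels[[li]]), function(si) {
      chs <- channels[[li]][[si]]
      out <- list()
      for (ch in physio_channels()) {
        cp <- ensemble_detect(chs[[ch]], grid, consensus = config$tau,
                              min_spacing = config$delta,
                              tolerance = config$tolerance)
        out[[ch]] <- gkf(cp$onset_s, sigma = config$sigma, start = 0,
                         end = dur, rate = 5, channel = ch)
      }
      out
    })
  }

  # --- musical GKF and row onsets per performance ---
  x_gkf_by_perf <- list(); row_onsets_by_perf <- list()
  for (key in names(musical_cps)) {
    cps <- musical_cps[[key]]
    p <- as.integer(sub("p(\\d+)_v.*", "\\1", key))
    ann <- cohort$annotations[[p]]
    xg <- list()
    for (ch in acoustic_channels())
      xg[[ch]] <- gkf(cps[[ch]]$onset_s, sigma = config$sigma, start = 0,
                      end = dur, rate = 5, channel = ch)
    for (cat in annotation_categories())
      xg[[cat]] <- gkf(ann$events$onset_s[ann$events$category == cat],
                       sigma = config$sigma, start = 0, end = dur, rate = 5,
                       channel = cat)
    x_gkf_by_perf[[key]] <- xg
    row_onsets_by_perf[[key]] <-
      c(unlist(lapply(cps, function(cp) cp$onset_s)), ann$events$onset_s)
  }

  # listener index by performance key
  heard <- lapply(seq_along(cohort$listeners), function(li) {
    pl <- cohort$listeners[[li]]$playlist
    vapply(seq_len(nrow(pl)), function(j) perf_key(pl$piece[j], pl$version[j]),
           character(1))
  })

  assemble_stratum <- function(listener_ids) {
    pieces <- list()
    for (key in names(x_gkf_by_perf)) {
      contrib <- list()
      for (li in listener_ids) {
        si <- which(heard[[li]] == key)
        for (s in si) contrib[[length(contrib) + 1]] <- phys_gkf[[li]][[s]]
      }
      if (!length(contrib)) next
      yg <- stats::setNames(lapply(physio_channels(), function(ch)
        average_listeners(lapply(contrib, `[[`, ch))), physio_channels())
      pieces[[key]] <- list(
        piece = as.integer(sub("p(\\d+)_v.*", "\\1", key)),
        version = as.integer(sub(".*_v(\\d+)", "\\1", key)),
        onsets = row_onsets_by_perf[[key]],
        x_gkf = x_gkf_by_perf[[key]], y_gkf = yg)
    }
    assemble_cca_inputs(pieces, delta = config$delta)
  }

  strata <- c(list(all = seq_along(cohort$listeners)),
              stats::setNames(lapply(1:3, function(k)
                which(clus$cluster == k)), paste0("cluster", 1:3)))
  cca_out <- list()
  for (nm in names(strata)) {
    ids <- strata[[nm]]
    if (length(ids) < 1) { cca_out[[nm]] <- NULL; next }
    inputs <- assemble_stratum(ids)
    sel <- suppressWarnings(
      surrogate_selection(inputs$X, inputs$Y,
                          n_surrogates = config$n_surrogates,
                          seed = derive_seed(config$seed, "surr", nm),
                          alpha = config$alpha))
    pp <- suppressWarnings(
      permutation_pvalues(inputs$X, inputs$Y, n_perm = config$n_perm,
                          seed = derive_seed(config$seed, "perm", nm)))
    retained <- sel$retained
    if (!any(retained)) retained[1] <- TRUE   # always display variate 1
    gr <- suppressWarnings(build_graph(sel$result, retained,
                                       config$display_threshold))
    cca_out[[nm]] <- list(inputs = inputs, result = sel$result,
                          selection = sel, perm_p = pp, graph = gr)
  }

  # --- event-locked differences ---
  events_fn <- function(li, si, category) {
    ev <- events_by_perf[[heard[[li]][si]]]
    ev$onset_s[ev$category == category]
  }
  event_tables <- run_event_response(channels, events_fn,
                                     windows = config$windows,
                                     alpha = config$alpha,
                                     seed = derive_seed(config$seed, "boot"))

  # --- individual effects ---
  listener_inputs <- list()
  for (li in seq_along(cohort$listeners)) {
    pieces <- list()
    for (s in seq_along(heard[[li]])) {
      key <- heard[[li]][s]
      pieces[[paste0(key, "_s", s)]] <- list(
        piece = as.integer(sub("p(\\d+)_v.*", "\\1", key)),
        version = as.integer(sub(".*_v(\\d+)", "\\1", key)),
        onsets = row_onsets_by_perf[[key]],
        x_gkf = x_gkf_by_perf[[key]],
        y_gkf = phys_gkf[[li]][[s]])
    }
    listener_inputs[[as.character(li)]] <-
      assemble_cca_inputs(pieces, delta = config$delta)
  }
  simrec <- similarity_records(listener_inputs, cca_out$all$result)
  individual <- NULL
  if (!is.null(simrec$records) && nrow(simrec$records) >= 8) {
    recs <- simrec$records
    li <- as.integer(recs$listener)
    recs$pns <- indices$pns[li]; recs$sns <- indices$sns[li]
    recs$sys <- vapply(li, function(i)
      mean(cohort$listeners[[i]]$sessions[[1]]$sys), numeric(1))
    recs$dia <- vapply(li, function(i)
      mean(cohort$listeners[[i]]$sessions[[1]]$dia), numeric(1))
    dg <- lapply(li, function(i) cohort$listeners[[i]]$demographics)
    recs$age <- vapply(dg, `[[`, numeric(1), "age")
    recs$gender <- factor(vapply(dg, `[[`, character(1), "gender"))
    recs$musician <- vapply(dg, `[[`, logical(1), "musician")
    recs$classical_pref <- vapply(dg, `[[`, logical(1), "classical_pref")
    individual <- list(records = recs, skipped = simrec$skipped,
                       gam = tryCatch(suppressWarnings(fit_gam(recs)),
                                      error = function(e) NULL))
  }

  manifest <- list(parameters = unclass(config), seed = config$seed,
                   stage_seeds = list(
                     sim = sim_args$seed,
                     kmeans = derive_seed(config$seed, "kmeans"),
                     surrogates = derive_seed(config$seed, "surr", "all"),
                     permutations = derive_seed(config$seed, "perm", "all"),
                     bootstrap = derive_seed(config$seed, "boot")),
                   n_listeners = length(cohort$listeners),
                   cluster_sizes = as.integer(table(factor(clus$cluster, 1:3))))
  manifest$param_hash <- param_hash(manifest$parameters)

  bundle <- list(cohort = cohort, baseline = baseline,
                 musical_cps = musical_cps, events_by_perf = events_by_perf,
                 cca = cca_out, event_tables = event_tables,
                 individual = individual, manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_outputs(bundle, config)
  bundle
}

# write the bundle's tabular/structured outputs
write_pipeline_outputs <- function(bundle, config) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prof <- cbind(listener = seq_len(nrow(bundle$baseline$indices)),
                bundle$baseline$indices,
                cluster = bundle$baseline$clusters$cluster)
  write_csv_plain(prof, file.path(dir, "autonomic_profiles.csv"))
  cps <- do.call(rbind, lapply(names(bundle$musical_cps), function(key)
    do.call(rbind, lapply(bundle$musical_cps[[key]], function(cp)
      if (nrow(cp)) cbind(performance = key, as.data.frame(cp)) else NULL))))
  if (!is.null(cps)) write_csv_plain(cps, file.path(dir, "musical_changepoints.csv"))
  for (nm in names(bundle$cca)) {
    cc <- bundle$cca[[nm]]
    if (is.null(cc)) next
    jsonlite::write_json(
      list(cor = cc$result$cor, relcov_pct = cc$result$relcov,
           wilks_p = cc$result$wilks_p, perm_p = cc$perm_p,
           retained = cc$selection$retained,
           surrogate_threshold = cc$selection$threshold,
           loadings_x = as.data.frame(cc$result$loadings_x),
           loadings_y = as.data.frame(cc$result$loadings_y)),
      file.path(dir, sprintf("cca_%s.json", nm)),
      auto_unbox = TRUE, digits = NA, null = "null")
    render_graph(cc$graph, file.path(dir, sprintf("graph_%s.svg", nm)))
    write_graph_json(cc$graph, file.path(dir, sprintf("graph_%s.json", nm)))
  }
  for (wn in names(bundle$event_tables))
    write_csv_plain(bundle$event_tables[[wn]],
                    file.path(dir, sprintf("event_diffs_%s.csv", wn)))
  if (!is.null(bundle$individual)) {
    write_csv_plain(bundle$individual$records,
                    file.path(dir, "similarity_records.csv"))
    if (!is.null(bundle$individual$gam))
      jsonlite::write_json(bundle$individual$gam$terms,
                           file.path(dir, "gam_report.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
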