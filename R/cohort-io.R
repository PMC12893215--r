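# Plain-text serialization of a synthetic cohort: per-piece feature and
# annotation tables (CSV), per-listener signal tables (CSV), manifest and
# truth ledger (JSON).

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
}

#' Write a cohort to a directory
#'
#' Layout: `features_p<piece>_v<version>.csv` (time_s + channel columns),
#' `annotations_p<piece>.csv` (onset_s, category),
#' `listener<i>_baseline_rr.csv`, per-session
#' `listener<i>_session<j>_{rr,resp,bp}.csv`, `manifest.json` (config,
#' playlists, demographics), `truth.json` (planted change points,
#' annotations, couplings, archetypes).
#'
#' @param cohort a `cohort`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in seq_along(cohort$music))
    for (v in seq_along(cohort$music[[p]])) {
      ms <- cohort$music[[p]][[v]]
      df <- data.frame(time_s = series_time(ms$channels[[1]]))
      for (ch in names(ms$channels)) df[[ch]] <- ms$channels[[ch]]$values
      write_csv_plain(df, file.path(dir, sprintf("features_p%d_v%d.csv", p, v)))
    }
  for (p in seq_along(cohort$annotations))
    write_csv_plain(cohort$annotations[[p]]$events,
                    file.path(dir, sprintf("annotations_p%d.csv", p)))
  for (l in cohort$listeners) {
    i <- l$listener_id
    write_csv_plain(data.frame(rr_s = l$baseline_rr),
                    file.path(dir, sprintf("listener%d_baseline_rr.csv", i)))
    for (j in seq_along(l$sessions)) {
      s <- l$sessions[[j]]
      write_csv_plain(data.frame(beat_time_s = s$beat_times, rr_s = s$rr),
                      file.path(dir, sprintf("listener%d_session%d_rr.csv", i, j)))
      write_csv_plain(data.frame(time_s = series_time(s$resp),
                                 value = s$resp$values),
                      file.path(dir, sprintf("listener%d_session%d_resp.csv", i, j)))
      write_csv_plain(data.frame(beat_time_s = s$beat_times, sys_mmhg = s$sys,
                                 dia_mmhg = s$dia),
                      file.path(dir, sprintf("listener%d_session%d_bp.csv", i, j)))
    }
  }
  manifest <- list(
    config = unclass(cohort$config),
    performances = cohort$performances,
    listeners = lapply(cohort$listeners, function(l)
      list(listener_id = l$listener_id, playlist = l$playlist,
           demographics = l$demographics)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort directory back into memory
#'
#' Inverse of [write_cohort()] up to numeric round-trip of the CSV/JSON
#' serialization; truth respiratory intervals are not round-tripped (they
#' live only in the in-memory truth ledger).
#'
#' @param dir directory written by [write_cohort()]
#' @return a `cohort`-like list
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  cfg <- manifest$config
  music <- list(); anns <- list()
  for (p in seq_len(cfg$n_pieces)) {
    music[[p]] <- list()
    for (v in seq_len(cfg$n_versions)) {
      f <- file.path(dir, sprintf("features_p%d_v%d.csv", p, v))
      if (!file.exists(f)) next
      df <- utils::read.csv(f)
      rate <- 1 / (df$time_s[2] - df$time_s[1])
      chans <- lapply(setdiff(names(df), "time_s"), function(ch)
        uniform_series(df[[ch]], rate = rate, start = df$time_s[1],
                       channel = ch))
      names(chans) <- setdiff(names(df), "time_s")
      music[[p]][[v]] <- structure(
        list(piece_id = p, version = v, channels = chans,
             truth_changepoints = NULL), class = "music_feature_set")
    }
    adf <- utils::read.csv(file.path(dir, sprintf("annotations_p%d.csv", p)),
                           colClasses = c("numeric", "character"))
    anns[[p]] <- structure(list(piece_id = p, events = adf),
                           class = "annotation_set")
  }
  listeners <- lapply(manifest$listeners, function(ml) {
    i <- ml$listener_id
    ml$playlist <- do.call(rbind, lapply(ml$playlist, as.data.frame))
    base <- utils::read.csv(file.path(dir,
                                      sprintf("listener%d_baseline_rr.csv", i)))
    sessions <- lapply(seq_len(nrow(ml$playlist)), function(j) {
      rr <- utils::read.csv(file.path(dir,
             sprintf("listener%d_session%d_rr.csv", i, j)))
      rs <- utils::read.csv(file.path(dir,
             sprintf("listener%d_session%d_resp.csv", i, j)))
      bp <- utils::read.csv(file.path(dir,
             sprintf("listener%d_session%d_bp.csv", i, j)))
      rate <- 1 / (rs$time_s[2] - rs$time_s[1])
      list(piece_id = ml$playlist$piece[j], version = ml$playlist$version[j],
           rr = rr$rr_s, beat_times = rr$beat_time_s,
           resp = uniform_series(rs$value, rate = rate, start = rs$time_s[1],
                                 channel = "resp_wave", units = "au"),
           sys = bp$sys_mmhg, dia = bp$dia_mmhg)
    })
    structure(list(listener_id = i, archetype = NA_character_,
                   baseline_rr = base$rr_s, demographics = ml$demographics,
                   playlist = ml$playlist, sessions = sessions),
              class = "listener_record")
  })
  structure(list(config = cfg, music = music, annotations = anns,
                 listeners = listeners, performances = manifest$performances,
                 truth = truth), class = "cohort")
}
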