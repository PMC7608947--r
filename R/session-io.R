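# Session store: one directory per session with CSV manifests and one file
# per channel, written/read with data.table for speed at 25 kHz scale.
#
# Layout:
#   <path>/manifest.csv            trace metadata
#   <path>/traces/<id>.csv         position [, curvature]
#   <path>/spikes.csv              spike-train metadata
#   <path>/spikes/<unit>.csv       t_s
#   <path>/truth/collisions.csv    ground-truth collision times (optional)
#   <path>/truth/manifest.csv      generator parameters per trace (optional)

#' Write a session to disk
#'
#' Stores a [whisker_session()] as a deterministic directory layout of CSV
#' files (15 significant digits, lossless for the declared um/s precision).
#'
#' @param session A `whisker_session`.
#' @param path Directory to create (must not exist unless `overwrite`).
#' @param overwrite Replace an existing session directory.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, overwrite = FALSE) {
  if (!inherits(session, "whisker_session"))
    wp_abort("write_session expects a whisker_session")
  if (dir.exists(path)) {
    if (!overwrite)
      wp_abort(sprintf("path '%s' already exists (use overwrite = TRUE)", path))
    unlink(path, recursive = TRUE)
  }
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(path))
    wp_abort(sprintf("cannot create session directory '%s'", path))
  dir.create(file.path(path, "traces"))
  dir.create(file.path(path, "spikes"))

  man <- data.table::rbindlist(lapply(session$traces, function(tr) {
    data.table::data.table(
      id = tr$id, whisker = tr$whisker$name, side = tr$whisker$side,
      row = tr$whisker$row, arc = tr$whisker$arc,
      condition = if (is.null(tr$condition)) NA_character_ else tr$condition$grade,
      diameter_um = if (is.null(tr$condition)) NA_real_ else tr$condition$diameter_um,
      sample_rate = tr$sample_rate, n_samples = length(tr$position),
      revolution_period = tr$revolution_period,
      has_curvature = !is.null(tr$curvature),
      file = file.path("traces", paste0(tr$id, ".csv")))
  }))
  if (nrow(man) == 0L)
    man <- data.table::data.table(
      id = character(), whisker = character(), side = character(),
      row = character(), arc = integer(), condition = character(),
      diameter_um = numeric(), sample_rate = numeric(), n_samples = integer(),
      revolution_period = numeric(), has_curvature = logical(), file = character())
  data.table::fwrite(man, file.path(path, "manifest.csv"))

  for (tr in session$traces) {
    dt <- data.table::data.table(position = tr$position)
    if (!is.null(tr$curvature)) dt$curvature <- tr$curvature
    data.table::fwrite(dt, file.path(path, "traces", paste0(tr$id, ".csv")))
  }

  train_keys <- names(session$trains) %||% as.character(seq_along(session$trains))
  sman <- data.table::rbindlist(lapply(seq_along(session$trains), function(i) {
    st <- session$trains[[i]]
    data.table::data.table(
      unit_id = st$unit_id, whisker = st$whisker$name, side = st$whisker$side,
      adaptation_class = st$adaptation_class,
      t_max = st$t_max %||% NA_real_,
      trace_id = attr(st, "trace_id") %||% NA_character_,
      n_spikes = length(st$times),
      file = file.path("spikes", paste0(train_keys[i], ".csv")))
  }))
  if (nrow(sman) == 0L)
    sman <- data.table::data.table(
      unit_id = character(), whisker = character(), side = character(),
      adaptation_class = character(), t_max = numeric(), trace_id = character(),
      n_spikes = integer(), file = character())
  data.table::fwrite(sman, file.path(path, "spikes.csv"))
  for (i in seq_along(session$trains))
    data.table::fwrite(data.table::data.table(t_s = session$trains[[i]]$times),
                       file.path(path, "spikes", paste0(train_keys[i], ".csv")))

  coll <- data.table::rbindlist(lapply(session$traces, function(tr) {
    tc <- attr(tr, "collision_times")
    if (is.null(tc)) NULL
    else data.table::data.table(trace_id = tr$id, t_s = tc)
  }))
  has_truth <- !is.null(session$truth) || nrow(coll) > 0L
  if (has_truth) {
    dir.create(file.path(path, "truth"))
    if (nrow(coll) > 0L)
      data.table::fwrite(coll, file.path(path, "truth", "collisions.csv"))
    if (!is.null(session$truth$manifest))
      data.table::fwrite(data.table::as.data.table(session$truth$manifest),
                         file.path(path, "truth", "manifest.csv"))
  }
  invisible(path)
}

#' Read a session from disk
#'
#' Reads a directory written by [write_session()], validating every trace and
#' spike train against the type invariants; malformed records raise a
#' validation error naming the offending file.
#'
#' @param path Session directory.
#' @return A [whisker_session()].
#' @export
read_session <- function(path) {
  if (!dir.exists(path))
    wp_abort(sprintf("session directory '%s' does not exist", path))
  man_file <- file.path(path, "manifest.csv")
  if (!file.exists(man_file))
    wp_abort(sprintf("'%s' is not a session directory (no manifest.csv)", path))
  man <- data.table::fread(man_file)

  coll_file <- file.path(path, "truth", "collisions.csv")
  coll <- if (file.exists(coll_file)) data.table::fread(coll_file) else NULL

  traces <- lapply(seq_len(nrow(man)), function(i) {
    rec <- man[i]
    f <- file.path(path, rec$file)
    if (!file.exists(f))
      wp_abort(sprintf("trace '%s': missing channel file '%s'", rec$id, rec$file))
    dat <- data.table::fread(f)
    if (!"position" %in% names(dat))
      wp_abort(sprintf("trace '%s': file '%s' has no position channel",
                       rec$id, rec$file))
    curv <- if (isTRUE(rec$has_curvature)) {
      if (!"curvature" %in% names(dat))
        wp_abort(sprintf("trace '%s': curvature channel missing from '%s'",
                         rec$id, rec$file))
      dat$curvature
    } else NULL
    cond <- if (is.na(rec$condition)) NULL
            else list(grade = rec$condition, diameter_um = rec$diameter_um)
    tr <- kinematic_trace(dat$position, rec$sample_rate,
                          whisker_id(rec$whisker, rec$side),
                          condition = cond, curvature = curv,
                          revolution_period = rec$revolution_period,
                          id = rec$id)
    if (!is.null(coll)) {
      tc <- coll[coll$trace_id == rec$id, ]$t_s
      if (length(tc)) attr(tr, "collision_times") <- tc
    }
    tr
  })

  sman_file <- file.path(path, "spikes.csv")
  sman <- if (file.exists(sman_file)) data.table::fread(sman_file) else NULL
  trains <- if (is.null(sman) || nrow(sman) == 0L) list() else
    lapply(seq_len(nrow(sman)), function(i) {
      rec <- sman[i]
      f <- file.path(path, rec$file)
      if (!file.exists(f))
        wp_abort(sprintf("unit '%s': missing spike file '%s'", rec$unit_id, rec$file))
      dat <- data.table::fread(f)
      st <- spike_train(if (nrow(dat)) dat$t_s else numeric(0), rec$unit_id,
                        whisker_id(rec$whisker, rec$side),
                        adaptation_class = rec$adaptation_class,
                        t_max = if (is.na(rec$t_max)) NULL else rec$t_max)
      if (!is.na(rec$trace_id)) attr(st, "trace_id") <- rec$trace_id
      st
    })

  truth <- NULL
  tman_file <- file.path(path, "truth", "manifest.csv")
  if (file.exists(tman_file) || !is.null(coll))
    truth <- list(
      manifest = if (file.exists(tman_file))
        as.data.frame(data.table::fread(tman_file)) else NULL,
      collisions = if (!is.null(coll)) as.data.frame(coll) else NULL)

  whisker_session(traces, trains, truth = truth)
}
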