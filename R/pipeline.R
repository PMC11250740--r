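#' Simulate a whole study: groups of sessions written to disk
#'
#' Batches [simulate_session()] over groups, writing one directory per
#' session plus a study-level `manifest.csv` and `truth.json` linking every
#' session to its generating parameters. Default group size is 8 sessions
#' per group, the per-group animal count of the study design the pipeline
#' targets.
#'
#' @param out_dir Study directory (created).
#' @param groups Named list of [sim_config()] objects, one per group label
#'   (e.g. `list(model = cfgA, control = cfgB)`).
#' @param n_per_group Sessions per group (default 8).
#' @param seed Study-level seed; per-session seeds are derived from it, so a
#'   fixed seed reproduces the whole directory tree.
#' @return The manifest tibble (`session_id`, `group`, `path`), invisibly
#'   written to `manifest.csv`.
#' @export
simulate_study <- function(out_dir, groups, n_per_group = 8, seed = 1) {
  stopifnot(is.list(groups), length(names(groups)) == length(groups))
  for (g in groups) stopifnot(inherits(g, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  idx <- 0L
  for (gname in names(groups)) {
    for (i in seq_len(n_per_group)) {
      idx <- idx + 1L
      cfg <- groups[[gname]]
      cfg$seed <- child_seed(seed, idx)
      sid <- sprintf("%s_%02d", gname, i)
      sdir <- file.path(out_dir, sid)
      write_session(simulate_session(cfg), sdir)
      rows[[idx]] <- tibble(session_id = sid, group = gname, path = sdir)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, n_per_group = n_per_group, groups = names(groups)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

#' Default analysis parameters
#'
#' Every threshold of the pipeline in one place: unit-classification cuts
#' (0.5 ms width, 0.5 Hz rate), PSTH binning (0.1 s bins over a -2..2 s
#' window), per-bin alpha, multitaper settings (10-s segments, nw 3, 5
#' tapers, 1-46 Hz), FDR level q, the MVAR order search, and the band for
#' directional summaries (20-46 Hz, beta + gamma).
#'
#' @return Named list of parameters; pass (possibly modified) to
#'   [run_pipeline()].
#' @export
pipeline_params <- function() {
  list(
    width_threshold_ms = 0.5,
    min_rate = 0.5,
    bin_width = 0.1,
    window = c(-2, 2),
    alpha = 0.05,
    q = 0.05,
    seg_len = 10,
    nw = 3,
    k = 5,
    fmin = 1,
    fmax = 46,
    lfp_rate = 1250,
    max_order = 12,
    criterion = "bic",
    gpdc_band = c(20, 46)
  )
}

#' Run the full analysis over a study directory
#'
#' Reads every session of a manifest, classifies units, labels evoked
#' responses and modulation, computes per-channel multitaper PSDs with band
#' summaries and per-session segment-averaged gPDC, then compares the first
#' two groups: point-by-point FDR-corrected relative-PSD tests per region,
#' point-by-point gPDC tests per direction, and response-class proportion
#' tables. All inputs are validated before any output is written, so a
#' malformed manifest produces a single error and no partial results.
#'
#' @param manifest A manifest tibble (`session_id`, `group`, `path`) or the
#'   path to a `manifest.csv` (a study directory containing one also works).
#' @param out_dir Optional output directory; when given, all result tables
#'   are written as tab-separated text plus a JSON run log.
#' @param params Parameter list from [pipeline_params()].
#' @return A list of tibbles: `units`, `psd`, `bands`, `gpdc_bands`,
#'   `psd_tests`, `gpdc_tests`, `proportions`, `proportion_tests`, and
#'   `log` (parameters and per-stage counts).
#' @export
run_pipeline <- function(manifest, out_dir = NULL, params = pipeline_params()) {
  if (is.character(manifest)) {
    mpath <- if (dir.exists(manifest)) file.path(manifest, "manifest.csv") else manifest
    if (!file.exists(mpath)) abort(sprintf("Manifest not found: %s", mpath))
    manifest <- as_tibble(utils::read.csv(mpath, stringsAsFactors = FALSE))
  }
  need <- c("session_id", "group", "path")
  if (!all(need %in% names(manifest))) {
    abort("Manifest needs columns session_id, group, path.")
  }
  # validate everything up front: no partial outputs on malformed input
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    if (!dir.exists(p)) {
      abort(sprintf("Session %s: directory missing: %s", manifest$session_id[i], p))
    }
    if (!file.exists(file.path(p, "events.txt"))) {
      abort(sprintf("Session %s: missing events.txt in %s", manifest$session_id[i], p))
    }
    lfp_bins <- list.files(p, pattern = "^lfp_.*\\.bin$")
    for (f in lfp_bins) {
      if (!file.exists(file.path(p, sub("\\.bin$", ".json", f)))) {
        abort(sprintf("Session %s: missing sidecar for %s", manifest$session_id[i], f))
      }
    }
  }

  units_rows <- list()
  psd_rows <- list()
  band_rows <- list()
  gpdc_band_rows <- list()
  psd_by <- list()   # region -> group -> list of psd_result
  gpdc_by <- list()  # group -> list of gpdc_spectrum
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$session_id[i]
    grp <- manifest$group[i]
    ses <- read_session(manifest$path[i])
    dur <- ses$truth$session_duration %||%
      (max(unlist(ses$units$spike_times), ses$events) + 1)

    cls <- classify_units(ses$units, session_duration = dur,
                          width_threshold_ms = params$width_threshold_ms,
                          min_rate = params$min_rate)
    resp <- purrr::map_dfr(seq_len(nrow(cls)), function(j) {
      tt <- build_trial_tensor(cls$spike_times[[j]], ses$events,
                               bin_width = params$bin_width,
                               window = params$window)
      lab <- classify_response(tt, alpha = params$alpha)
      mi <- modulation_from_tensor(tt)
      tibble(response_label = lab$label,
             first_significant_bin = lab$first_significant_bin,
             f_before = mi$f_before, f_after = mi$f_after,
             modulation_index = mi$index)
    })
    units_rows[[i]] <- dplyr::bind_cols(
      tibble(session_id = sid, group = grp),
      cls[, c("unit_id", "region", "label", "peak_to_valley_ms", "mean_rate_hz")],
      resp
    )

    for (nm in names(ses$lfps)) {
      l <- ses$lfps[[nm]]
      if (l$sampling_rate > params$lfp_rate) {
        l <- preprocess_lfp(l, target_rate = params$lfp_rate)
      }
      psd <- lfp_psd(l, seg_len = params$seg_len, nw = params$nw,
                     k = params$k, fmin = params$fmin, fmax = params$fmax)
      psd_rows[[length(psd_rows) + 1]] <- dplyr::mutate(
        psd$spectrum, session_id = sid, group = grp, region = nm,
        .before = 1
      )
      band_rows[[length(band_rows) + 1]] <- dplyr::mutate(
        band_power(psd), session_id = sid, group = grp, region = nm,
        .before = 1
      )
      psd_by[[nm]][[grp]] <- c(psd_by[[nm]][[grp]] %||% list(), list(psd))
    }

    if (length(ses$lfps) >= 2) {
      gp <- segment_gpdc(ses$lfps, seg_len = params$seg_len,
                         max_order = params$max_order,
                         criterion = params$criterion,
                         freqs = seq(params$fmin, params$fmax, by = 0.1))
      gpdc_by[[grp]] <- c(gpdc_by[[grp]] %||% list(), list(gp))
      gpdc_band_rows[[length(gpdc_band_rows) + 1]] <- dplyr::mutate(
        directional_band_gpdc(gp, params$gpdc_band),
        session_id = sid, group = grp, .before = 1
      )
    }
  }

  units_tbl <- dplyr::bind_rows(units_rows)
  groups <- unique(manifest$group)

  psd_tests <- list()
  gpdc_tests <- list()
  prop_tests <- list()
  if (length(groups) >= 2) {
    ga <- groups[1]
    gb <- groups[2]
    for (nm in names(psd_by)) {
      if (length(psd_by[[nm]][[ga]] %||% list()) >= 2 &&
          length(psd_by[[nm]][[gb]] %||% list()) >= 2) {
        psd_tests[[nm]] <- pointwise_group_test(
          psd_by[[nm]][[ga]], psd_by[[nm]][[gb]], q = params$q
        )
      }
    }
    if (length(gpdc_by[[ga]] %||% list()) >= 2 &&
        length(gpdc_by[[gb]] %||% list()) >= 2) {
      nms <- gpdc_by[[ga]][[1]]$channel_names
      for (tg in nms) for (sr in nms) {
        if (tg != sr) {
          gpdc_tests[[paste0(tg, "<-", sr)]] <- pointwise_gpdc_test(
            gpdc_by[[ga]], gpdc_by[[gb]], target = tg, source = sr,
            q = params$q
          )
        }
      }
    }
  }

  proportions <- units_tbl |>
    dplyr::filter(.data$label != "excluded_low_rate") |>
    dplyr::count(.data$group, .data$region, .data$response_label) |>
    tidyr::complete(
      group = groups, region = unique(units_tbl$region),
      response_label = c("excitatory", "inhibitory", "neutral"),
      fill = list(n = 0L)
    )
  if (length(groups) >= 2) {
    for (rg in unique(proportions$region)) {
      tab <- proportions |>
        dplyr::filter(.data$region == rg, .data$group %in% groups[1:2]) |>
        tidyr::pivot_wider(names_from = "response_label", values_from = "n")
      m <- as.matrix(tab[, c("excitatory", "inhibitory", "neutral")])
      if (all(rowSums(m) > 0)) {
        prop_tests[[rg]] <- dplyr::mutate(
          proportion_test(m, force = "chisq"), region = rg, .before = 1
        )
      }
    }
  }

  log <- list(
    params = params,
    n_sessions = nrow(manifest),
    groups = as.list(table(manifest$group)),
    n_units = nrow(units_tbl),
    n_units_retained = sum(units_tbl$label != "excluded_low_rate"),
    n_psd = length(psd_rows),
    n_gpdc = sum(lengths(gpdc_by))
  )

  result <- list(
    units = units_tbl,
    psd = dplyr::bind_rows(psd_rows),
    bands = dplyr::bind_rows(band_rows),
    gpdc_bands = dplyr::bind_rows(gpdc_band_rows),
    psd_tests = psd_tests,
    gpdc_tests = gpdc_tests,
    proportions = proportions,
    proportion_tests = dplyr::bind_rows(prop_tests),
    log = log
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    wt(result$units, "units.tsv")
    wt(result$psd, "psd.tsv")
    wt(result$bands, "bands.tsv")
    if (nrow(result$gpdc_bands)) wt(result$gpdc_bands, "gpdc_bands.tsv")
    wt(result$proportions, "response_proportions.tsv")
    if (nrow(result$proportion_tests)) {
      wt(result$proportion_tests, "proportion_tests.tsv")
    }
    for (nm in names(psd_tests)) {
      wt(psd_tests[[nm]]$table, sprintf("psd_test_%s.tsv", nm))
    }
    for (nm in names(gpdc_tests)) {
      safe <- gsub("<-", "_from_", nm, fixed = TRUE)
      wt(gpdc_tests[[nm]]$table, sprintf("gpdc_test_%s.tsv", safe))
    }
    jsonlite::write_json(
      c(log, list(
        significant_psd_intervals = lapply(psd_tests, function(t) t$intervals),
        significant_gpdc_intervals = lapply(gpdc_tests, function(t) t$intervals)
      )),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows"
    )
  }
  result
}
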