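#' Triphasic classification at the motoneuron level
#'
#' Applies the same betweenness rule as [classify_triphasic()] to the
#' FlxAlpha/ExtAlpha membrane potentials (threshold -60 mV) instead of
#' the muscle potentials.  Because the muscle is driven by its
#' motoneuron through a -60 mV-thresholded synapse, every EMG-level
#' triphasic movement is also MN-level triphasic, but subthreshold MN
#' patterns can be triphasic without producing one in the EMGs.
#'
#' @param trace a [run_trial()] trace.
#' @return A `triphasic_label` (see [classify_triphasic()]).
#' @export
mn_level_triphasic <- function(trace) {
  sel <- trace$time >= 2
  classify_triphasic(
    detect_peaks(trace$FlxAlpha[sel], trace$time[sel], baseline = -60),
    detect_peaks(trace$ExtAlpha[sel], trace$time[sel], baseline = -60)
  )
}

# Rest level of each recorded channel, used as peak baseline.
channel_baseline <- function(channel) {
  if (channel %in% AFFERENT_NAMES) -65 else -60
}

#' Per-movement peak amplitudes of the mechanism channels
#'
#' Extracts, for one trace, the suprabaseline peak amplitudes (mV above
#' each channel's rest level) of the neurons implicated in the second
#' agonist burst: the first and second FlxAlpha and FlxPN peaks, the
#' late Flx1a peak (the last Flx1a peak in the movement window), and the
#' largest Ext1a, Ext1b, ExtPN and ExtAlpha peaks.  Missing peaks are
#' `NA`.
#'
#' @param trace a [run_trial()] trace.
#' @return A one-row tibble.
#' @export
movement_peak_amplitudes <- function(trace) {
  sel <- trace$time >= 2
  pk <- function(channel) {
    base <- channel_baseline(channel)
    detect_peaks(trace[[channel]][sel], trace$time[sel],
                 baseline = base)$peaks$value - base
  }
  nth <- function(x, i) if (length(x) >= i) x[i] else NA_real_
  last_or_na <- function(x) if (length(x)) x[length(x)] else NA_real_
  tibble::tibble(
    flxalpha_peak1 = nth(pk("FlxAlpha"), 1),
    flxalpha_peak2 = nth(pk("FlxAlpha"), 2),
    flxpn_peak1 = nth(pk("FlxPN"), 1),
    flxpn_peak2 = nth(pk("FlxPN"), 2),
    flx1a_late_peak = last_or_na(pk("Flx1a")),
    ext1a_peak = suppressWarnings(max(pk("Ext1a"), -Inf)) |>
      (\(x) if (is.finite(x)) x else NA_real_)(),
    ext1b_peak = suppressWarnings(max(pk("Ext1b"), -Inf)) |>
      (\(x) if (is.finite(x)) x else NA_real_)(),
    extpn_peak = suppressWarnings(max(pk("ExtPN"), -Inf)) |>
      (\(x) if (is.finite(x)) x else NA_real_)(),
    extalpha_peak = suppressWarnings(max(pk("ExtAlpha"), -Inf)) |>
      (\(x) if (is.finite(x)) x else NA_real_)()
  )
}

#' Pearson correlations between peak-amplitude pairs
#'
#' For each requested pair of columns, computes the Pearson correlation
#' over complete cases with its Fisher-z 95% confidence interval and
#' p-value (via [stats::cor.test()]).  Pairs with fewer than 3 complete
#' observations are reported as not computed (`NA` statistics).
#'
#' @param peaks a tibble of per-movement peak amplitudes (e.g. rows of
#'   [movement_peak_amplitudes()]).
#' @param pairs list of `c(x, y)` column-name pairs.
#' @return A `correlation_report` tibble: `x`, `y`, `n`, `r`,
#'   `conf_low`, `conf_high`, `p_value`.
#' @export
peak_correlations <- function(peaks, pairs) {
  rows <- lapply(pairs, function(pr) {
    x <- peaks[[pr[1]]]; y <- peaks[[pr[2]]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3) {
      return(tibble::tibble(x = pr[1], y = pr[2], n = n, r = NA_real_,
                            conf_low = NA_real_, conf_high = NA_real_,
                            p_value = NA_real_))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    ci <- if (!is.null(ct$conf.int)) ct$conf.int else c(NA_real_, NA_real_)
    tibble::tibble(x = pr[1], y = pr[2], n = n, r = unname(ct$estimate),
                   conf_low = ci[1], conf_high = ci[2],
                   p_value = ct$p.value)
  })
  structure(dplyr::bind_rows(rows),
            class = c("correlation_report", "tbl_df", "tbl", "data.frame"))
}

# Second-FlxAlpha-peak amplitude (mV above rest) of a trace, NA if absent.
flx_second_peak <- function(trace) {
  sel <- trace$time >= 2
  p <- detect_peaks(trace$FlxAlpha[sel], trace$time[sel],
                    baseline = -60)$peaks
  if (nrow(p) >= 2) p$value[2] + 60 else NA_real_
}

#' Replay a movement under a battery of lesions
#'
#' Re-simulates one archived command vector under each lesion (clamped
#' nodes and/or suppressed synapses) and classifies the outcome against
#' the unlesioned baseline replay:
#'
#' * `"no-movement"` — total angular excursion below 1 degree;
#' * `"overshoot"` — angle exceeds the baseline fitted amplitude by more
#'   than 10 degrees;
#' * `"2nd-peak-abolished"` — the baseline trace has a second FlxAlpha
#'   peak and the lesioned trace does not;
#' * `"unchanged"` — angle trajectory within 1 degree of baseline
#'   throughout; otherwise `"altered"`.
#'
#' An empty lesion reproduces the baseline trace exactly (determinism).
#'
#' @param vector the command vector to replay.
#' @param topology,plant,sim,ranges,go_include_alpha as in [run_trial()].
#' @param lesions named list of [lesion_spec()] objects.
#' @return A `lesion_report` tibble, one row per lesion: `lesion`,
#'   `outcome`, `max_excursion` (deg), `max_angle_dev` (deg, vs
#'   baseline), `flx2nd_base`, `flx2nd_lesion` (mV above rest), plus a
#'   `trace` list-column with the lesioned traces.
#' @export
lesion_screen <- function(vector, topology, lesions,
                          plant = default_plant(), sim = sim_config(),
                          ranges = command_ranges(),
                          go_include_alpha = FALSE) {
  base_trace <- run_trial(vector, topology, plant, sim, ranges = ranges,
                          go_include_alpha = go_include_alpha)
  base_fit <- fit_minjerk(base_trace)
  base_2nd <- flx_second_peak(base_trace)
  theta0 <- base_trace$angle[1]
  rows <- lapply(names(lesions), function(nm) {
    tr <- run_trial(vector, topology, plant, sim, lesion = lesions[[nm]],
                    ranges = ranges, go_include_alpha = go_include_alpha)
    n <- min(nrow(tr), nrow(base_trace))
    excursion <- max(abs(tr$angle - theta0))
    dev <- max(abs(tr$angle[seq_len(n)] - base_trace$angle[seq_len(n)]))
    les_2nd <- flx_second_peak(tr)
    outcome <- if (excursion < 1) {
      "no-movement"
    } else if (dev < 1) {
      "unchanged"
    } else if (!is.na(base_fit$amplitude) &&
               max(tr$angle) > theta0 + base_fit$amplitude + 10) {
      "overshoot"
    } else if (!is.na(base_2nd) && is.na(les_2nd)) {
      "2nd-peak-abolished"
    } else {
      "altered"
    }
    tibble::tibble(lesion = nm, outcome = outcome,
                   max_excursion = excursion, max_angle_dev = dev,
                   flx2nd_base = base_2nd, flx2nd_lesion = les_2nd,
                   trace = list(tr))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "baseline") <- base_trace
  class(out) <- c("lesion_report", class(out))
  out
}
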