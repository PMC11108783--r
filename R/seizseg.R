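#' Spike-cluster seizure segmentation parameters
#'
#' Two rules govern segmentation: spikes whose interspike interval stays
#' below `max_isi` (default 1 s) form the core of a seizure, and a seizure
#' is not considered ended until the spiking rate falls below one spike
#' per `end_gap` (default 2 s). The two rules can disagree for trailing
#' intervals in `[max_isi, end_gap)`: a cluster forms at `max_isi` but
#' extends through trailing gaps shorter than `end_gap` before it
#' terminates. Gap comparisons use `>=` for termination and `<` for
#' inclusion throughout.
#'
#' @param max_isi maximum interspike interval inside a cluster core, s.
#' @param min_spikes minimum spikes in a cluster core for it to count as a
#'   seizure (>= 2; singletons and pairs are interictal events).
#' @param end_gap gap that terminates a seizure, s (>= `max_isi`).
#' @param intercluster_interval minimum separation for two clusters to be
#'   distinct, s (defaults to `end_gap`).
#' @return list of class `"cluster_params"`.
#' @export
cluster_params <- function(max_isi = 1, min_spikes = 3, end_gap = 2,
                           intercluster_interval = end_gap) {
  if (max_isi <= 0) stop("max_isi must be > 0")
  if (end_gap < max_isi) stop("end_gap must be >= max_isi")
  if (min_spikes < 2) stop("min_spikes must be >= 2")
  structure(list(max_isi = max_isi, min_spikes = min_spikes,
                 end_gap = end_gap,
                 intercluster_interval = intercluster_interval),
            class = "cluster_params")
}

#' Segment spike times into seizures
#'
#' Greedy single pass: spikes separated by gaps below `end_gap` belong to
#' the same candidate group (the rate never fell below one spike per
#' `end_gap` inside a group); a group is a seizure when it contains a run
#' of at least `min_spikes` consecutive spikes with interspike intervals
#' below `max_isi`. The seizure's onset is the first spike of its first
#' such dense run; its end is the group's last spike — trailing spikes
#' whose gaps stay below `end_gap` extend the seizure even when those
#' gaps reach or exceed `max_isi`.
#'
#' @param spike_times sorted, unique spike times, s.
#' @param params a [cluster_params()].
#' @return data.frame `(onset, end, n_spikes)` sorted by onset, with a
#'   `spike_times` list-column of each seizure's spikes.
#' @export
#' @examples
#' cluster_spikes(c(0, 0.5, 1.2, 1.8, 10, 10.4, 10.9), cluster_params())
cluster_spikes <- function(spike_times, params = cluster_params()) {
  if (length(spike_times) == 0)
    return(empty_seizure_frame())
  if (is.unsorted(spike_times, strictly = TRUE))
    stop("spike times must be sorted and unique")
  gaps <- diff(spike_times)
  # groups: break where gap >= end_gap (rate fell below 1 spike / end_gap)
  grp <- cumsum(c(1, as.integer(gaps >= params$end_gap)))
  out <- lapply(split(seq_along(spike_times), grp), function(idx) {
    ts <- spike_times[idx]
    core_start <- first_dense_run(ts, params$max_isi, params$min_spikes)
    if (is.na(core_start)) return(NULL)
    ts <- ts[core_start:length(ts)]
    data.frame(onset = ts[1], end = ts[length(ts)], n_spikes = length(ts),
               spike_times = I(list(ts)))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) return(empty_seizure_frame())
  rownames(out) <- NULL
  out[order(out$onset), , drop = FALSE]
}

empty_seizure_frame <- function() {
  data.frame(onset = numeric(0), end = numeric(0), n_spikes = integer(0),
             spike_times = I(list()))
}

# index of the first spike starting a run of >= min_spikes spikes with all
# ISIs < max_isi, or NA
first_dense_run <- function(ts, max_isi, min_spikes) {
  if (length(ts) < min_spikes) return(NA_integer_)
  dense <- diff(ts) < max_isi
  need <- min_spikes - 1L                       # consecutive dense gaps
  run <- 0L
  for (i in seq_along(dense)) {
    run <- if (dense[i]) run + 1L else 0L
    if (run >= need) return(i - need + 1L)
  }
  NA_integer_
}

#' Seizure end under the rate-termination rule
#'
#' Returns the time of the last spike that is followed by a gap of at
#' least `end_gap` (or the final spike): the seizure extends through any
#' trailing spikes whose gaps stay below `end_gap`, then terminates.
#'
#' @param spike_times spikes of one cluster plus any trailing spikes, s,
#'   sorted.
#' @param params a [cluster_params()].
#' @return end time, s.
#' @export
seizure_end <- function(spike_times, params = cluster_params()) {
  if (length(spike_times) == 0) stop("empty cluster")
  gaps <- diff(spike_times)
  brk <- which(gaps >= params$end_gap)
  if (length(brk) == 0) return(spike_times[length(spike_times)])
  spike_times[brk[1]]
}

#' Duration of a seizure measured from the detection trigger
#'
#' The analysis duration of a closed-loop-detected seizure runs from the
#' trigger time to the seizure's end, so `end - trigger_time`.
#'
#' @param seizure one row of the [cluster_spikes()] output (or any list
#'   with `onset` and `end`).
#' @param trigger_time s; must lie inside `[onset, end]`.
#' @return the seizure row with `trigger_time` and `duration_from_trigger`
#'   attached.
#' @export
duration_from_trigger <- function(seizure, trigger_time) {
  if (trigger_time < seizure$onset || trigger_time > seizure$end)
    stop("trigger_time outside the seizure interval")
  seizure$trigger_time <- trigger_time
  seizure$duration_from_trigger <- seizure$end - trigger_time
  seizure
}
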