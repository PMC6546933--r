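#' Acquisition protocol for vessel-encoded multi-delay ASL
#'
#' Bundles the timing parameters of a vessel-encoded pseudo-continuous ASL
#' (VEPCASL) acquisition: labeling duration, the schedule of nominal
#' post-labeling delays (PLDs), repetition time, the 2D multi-slice readout
#' timing and the encoding-cycle structure. These fix the time axis of the
#' kinetic model and the ordering of the acquired volumes.
#'
#' @param label_duration_s Labeling pulse-train duration tau, seconds.
#' @param nominal_plds_s Strictly increasing vector of nominal PLDs, seconds.
#' @param tr_s Repetition time, seconds.
#' @param n_slices Number of 2D slices acquired in ascending order.
#' @param readout_duration_ms Total time to read all slices, milliseconds.
#' @param n_repeats Repetitions of the full encoding cycle per PLD.
#' @param encoding_cycle_names Ordered labels of the encoding cycles.
#' @return An object of class `asl_protocol`.
#' @seealso [default_protocol()] for the study protocol,
#'   [effective_plds()], [slice_pld()].
#' @export
asl_protocol <- function(label_duration_s,
                         nominal_plds_s,
                         tr_s,
                         n_slices,
                         readout_duration_ms,
                         n_repeats = 2L,
                         encoding_cycle_names = default_cycle_names()) {
  stopifnot(
    is.numeric(label_duration_s), length(label_duration_s) == 1L,
    label_duration_s > 0,
    is.numeric(nominal_plds_s), length(nominal_plds_s) >= 1L,
    all(nominal_plds_s > 0),
    is.numeric(tr_s), tr_s > 0,
    n_slices >= 1L,
    readout_duration_ms > 0,
    n_repeats >= 1L
  )
  if (is.unsorted(nominal_plds_s, strictly = TRUE)) {
    stop("nominal PLDs must be strictly increasing", call. = FALSE)
  }
  structure(
    list(
      label_duration_s = as.numeric(label_duration_s),
      nominal_plds_s = as.numeric(nominal_plds_s),
      tr_s = as.numeric(tr_s),
      n_slices = as.integer(n_slices),
      readout_duration_ms = as.numeric(readout_duration_ms),
      n_repeats = as.integer(n_repeats),
      encoding_cycle_names = as.character(encoding_cycle_names)
    ),
    class = "asl_protocol"
  )
}

default_cycle_names <- function() {
  c("control", "label",
    "LR_1", "LR_2",
    "AP_1", "AP_2",
    "DIAG_1", "DIAG_2")
}

#' Default study acquisition protocol
#'
#' The protocol used throughout this package's phantom experiments: a 1.4 s
#' labeling train, six nominal PLDs from 0.25 to 1.5 s in 0.25 s steps,
#' TR 4.1 s, a 24-slice ascending 2D readout taking 1085 ms in total, and
#' eight encoding cycles (non-selective label and control, two left-right,
#' two anterior-posterior, two diagonal) repeated twice per PLD, giving
#' 8 x 2 x 6 = 96 volumes.
#'
#' @return An `asl_protocol` object.
#' @export
default_protocol <- function() {
  asl_protocol(
    label_duration_s = 1.4,
    nominal_plds_s = c(0.25, 0.5, 0.75, 1.0, 1.25, 1.5),
    tr_s = 4.1,
    n_slices = 24L,
    readout_duration_ms = 1085,
    n_repeats = 2L
  )
}

#' @export
print.asl_protocol <- function(x, ...) {
  cat("VEPCASL acquisition protocol\n")
  cat(sprintf("  labeling duration: %.2f s\n", x$label_duration_s))
  cat(sprintf("  nominal PLDs (s):  %s\n",
              paste(format(x$nominal_plds_s), collapse = ", ")))
  cat(sprintf("  TR: %.2f s; %d slices, readout %.0f ms\n",
              x$tr_s, x$n_slices, x$readout_duration_ms))
  cat(sprintf("  %d encoding cycles x %d repeats x %d PLDs = %d volumes\n",
              length(x$encoding_cycle_names), x$n_repeats,
              length(x$nominal_plds_s), n_volumes(x)))
  invisible(x)
}

#' Total number of volumes in the acquisition schedule
#'
#' @param protocol An `asl_protocol`.
#' @return Integer count: encodings x repeats x PLDs.
#' @export
n_volumes <- function(protocol) {
  stopifnot(inherits(protocol, "asl_protocol"))
  length(protocol$encoding_cycle_names) * protocol$n_repeats *
    length(protocol$nominal_plds_s)
}

#' Average effective post-labeling delays
#'
#' With an ascending 2D multi-slice readout, later slices are read later
#' after labeling, so the brain-average effective PLD is the nominal PLD
#' plus half the total readout duration.
#'
#' @param protocol An `asl_protocol`.
#' @param round_to Rounding step in seconds for reporting (default 0.01 s);
#'   use `NULL` for the unrounded values used internally.
#' @return Numeric vector, one effective PLD per nominal PLD, seconds.
#' @export
effective_plds <- function(protocol, round_to = 0.01) {
  stopifnot(inherits(protocol, "asl_protocol"))
  eff <- protocol$nominal_plds_s + protocol$readout_duration_ms / 1000 / 2
  if (is.null(round_to)) eff else round(eff / round_to) * round_to
}

#' Per-slice post-labeling delay
#'
#' Slice `slice_index` (0-based, ascending order) is read
#' `slice_index * readout_duration / n_slices` after the first slice.
#'
#' @param protocol An `asl_protocol`.
#' @param pld_index 1-based index into the nominal PLD schedule.
#' @param slice_index 0-based slice index, `0 <= slice_index < n_slices`.
#' @return PLD for that slice, seconds.
#' @export
slice_pld <- function(protocol, pld_index, slice_index) {
  stopifnot(inherits(protocol, "asl_protocol"))
  if (any(pld_index < 1L) || any(pld_index > length(protocol$nominal_plds_s))) {
    stop("pld_index out of range", call. = FALSE)
  }
  if (any(slice_index < 0L) || any(slice_index >= protocol$n_slices)) {
    stop("slice_index out of range (0-based)", call. = FALSE)
  }
  protocol$nominal_plds_s[pld_index] +
    slice_index * (protocol$readout_duration_ms / 1000) / protocol$n_slices
}

#' Volume acquisition schedule
#'
#' The ordering of the acquired 4D series: for each PLD, each repetition of
#' the full encoding cycle is played out in cycle order. Decoding consumes
#' this table (normally carried in the series sidecar), so a permuted series
#' with a matching schedule decodes identically.
#'
#' @param protocol An `asl_protocol`.
#' @return A data.frame with columns `volume`, `pld_index`, `repeat_index`,
#'   `cycle_index`, `cycle_name`.
#' @export
protocol_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "asl_protocol"))
  n_enc <- length(protocol$encoding_cycle_names)
  grid <- expand.grid(
    cycle_index = seq_len(n_enc),
    repeat_index = seq_len(protocol$n_repeats),
    pld_index = seq_along(protocol$nominal_plds_s)
  )
  data.frame(
    volume = seq_len(nrow(grid)),
    pld_index = grid$pld_index,
    repeat_index = grid$repeat_index,
    cycle_index = grid$cycle_index,
    cycle_name = protocol$encoding_cycle_names[grid$cycle_index],
    stringsAsFactors = FALSE
  )
}

#' Read or write a protocol as a YAML config block
#'
#' @param protocol An `asl_protocol`.
#' @param path File path.
#' @return `read_protocol` returns an `asl_protocol`; `write_protocol`
#'   returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "asl_protocol"))
  yaml::write_yaml(unclass(protocol), path, precision = 15L)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(asl_protocol, x)
}
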