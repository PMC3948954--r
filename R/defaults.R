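#' Pipeline defaults
#'
#' Every numeric default of the analysis pipeline, defined in one place:
#' the acquisition geometry (TR 2 s, 478 s scan, 10 discarded volumes, 229
#' analysis frames), the 0.01-0.08 Hz band, the fifth-order model, 10,000
#' surrogates, the within- and between-group alpha of 0.01, the 12 mm ROI
#' sphere radius and the 50 mm head radius used to convert rotational motion
#' to millimetres.
#'
#' @return Named list of defaults.
#' @export
#' @examples
#' cpgc_defaults()$order
cpgc_defaults <- function() {
  list(
    tr            = 2,      # repetition time, seconds
    scan_seconds  = 478,    # total functional scan duration
    n_discard     = 10,     # equilibration volumes dropped
    n_frames      = 229,    # analysis frames after discarding
    band          = c(0.01, 0.08),  # Hz
    order         = 5,      # mMVAR model order when selection is disabled
    n_surrogates  = 10000,
    alpha_within  = 0.01,
    alpha_between = 0.01,
    roi_radius    = 12,     # mm
    head_radius   = 50,     # mm, rotation-to-displacement conversion
    global_signal = FALSE   # global-signal regression off by default
  )
}

#' Number of analysis frames implied by an acquisition
#'
#' Frames acquired at one volume per TR over `scan_seconds`, minus the
#' equilibration volumes discarded at the start of the run.
#'
#' @param scan_seconds Scan duration in seconds.
#' @param tr Repetition time in seconds.
#' @param n_discard Number of initial volumes discarded.
#' @return Integer frame count.
#' @export
#' @examples
#' analysis_frames(478, 2, 10)  # 229
analysis_frames <- function(scan_seconds = cpgc_defaults()$scan_seconds,
                            tr = cpgc_defaults()$tr,
                            n_discard = cpgc_defaults()$n_discard) {
  stopifnot(scan_seconds > 0, tr > 0, n_discard >= 0)
  n <- floor(scan_seconds / tr) - n_discard
  if (n <= 0) stop("no frames left after discarding ", n_discard, " volumes")
  as.integer(n)
}
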