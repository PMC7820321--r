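#' Configuration objects for the detection pipeline
#'
#' Each stage of the pipeline is parameterised by a small validated list.
#' `uc_config()` bundles them, together with the evaluation tolerance, into
#' the single object consumed by [detect_contractions()] and the command-line
#' interface.
#'
#' @param lpf_cutoff_hz Low-pass cut-off frequency in Hz. Uterine electrical
#'   activity of interest lies below 3 Hz; everything above (maternal ECG,
#'   power-line interference) is rejected.
#' @param lpf_order Butterworth filter order (applied forward-backward, so the
#'   effective roll-off is twice this order).
#' @param median_kernel_s Length of the running-median kernel in seconds,
#'   used to suppress short spikes (ECG residue, motion) after low-pass
#'   filtering. Rounded to the nearest odd sample count >= 3.
#' @return A validated config list of the corresponding class.
#' @export
preprocess_config <- function(lpf_cutoff_hz = 3, lpf_order = 4,
                              median_kernel_s = 0.2) {
  stopifnot(is.numeric(lpf_cutoff_hz), length(lpf_cutoff_hz) == 1,
            lpf_cutoff_hz > 0)
  stopifnot(is.numeric(lpf_order), length(lpf_order) == 1, lpf_order >= 1,
            lpf_order == round(lpf_order))
  stopifnot(is.numeric(median_kernel_s), length(median_kernel_s) == 1,
            median_kernel_s > 0)
  structure(
    list(lpf_cutoff_hz = lpf_cutoff_hz, lpf_order = as.integer(lpf_order),
         median_kernel_s = median_kernel_s),
    class = "preprocess_config"
  )
}

#' @rdname preprocess_config
#' @param alpha Offset coefficient for the amplitude elevation: the signal is
#'   shifted upward by `alpha` times its mean amplitude so that low-amplitude
#'   (non-contraction) oscillations no longer cross zero. Valid range
#'   \[0, 5\]; default 1.5, the midpoint of the useful range \[1, 2\].
#' @param gamma Exponent applied to the normalised zero-crossing rate
#'   (must be > 1): larger values sharpen the contrast between contraction
#'   and non-contraction segments. Default 3.5, midpoint of \[3, 4\].
#' @param window_s Sliding-window length in seconds for the zero-crossing
#'   rate; 40 s covers a typical contraction burst (30-60 s).
#' @param mean_mode How the mean amplitude E used for elevation is computed:
#'   `"abs"` (mean of absolute sample values, the default) or `"signed"`
#'   (plain arithmetic mean, which is ~0 after zero-phase low-pass filtering
#'   and makes elevation a no-op; retained for comparison).
#' @export
zcr_config <- function(alpha = 1.5, gamma = 3.5, window_s = 40,
                       mean_mode = c("abs", "signed")) {
  mean_mode <- match.arg(mean_mode)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha <= 5)
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma > 1)
  stopifnot(is.numeric(window_s), length(window_s) == 1, window_s > 0)
  structure(
    list(alpha = alpha, gamma = gamma, window_s = window_s,
         mean_mode = mean_mode),
    class = "zcr_config"
  )
}

#' @rdname preprocess_config
#' @param rms_window_s RMS envelope window in seconds (default 10 s, i.e.
#'   N = 2500 points at 250 Hz).
#' @param thd_s Duration threshold in seconds: a supra-threshold envelope run
#'   must last strictly longer than this to count as a contraction.
#' @param tha_mode Amplitude threshold mode: `"mean"` uses the mean of the
#'   envelope; `"explicit"` uses `tha_value`.
#' @param tha_value Explicit amplitude threshold (required iff
#'   `tha_mode = "explicit"`).
#' @param toco_smooth_s Moving-average window in seconds applied to the raw
#'   TOCO trace before thresholding.
#' @param merge_gap_s Supra-threshold runs separated by a dip shorter than
#'   this many seconds are merged before the duration test (default 0: no
#'   merging).
#' @export
detection_config <- function(rms_window_s = 10, thd_s = 30,
                             tha_mode = c("mean", "explicit"),
                             tha_value = NULL, toco_smooth_s = 40,
                             merge_gap_s = 0) {
  tha_mode <- match.arg(tha_mode)
  stopifnot(is.numeric(rms_window_s), length(rms_window_s) == 1,
            rms_window_s > 0)
  stopifnot(is.numeric(thd_s), length(thd_s) == 1, thd_s > 0)
  stopifnot(is.numeric(toco_smooth_s), length(toco_smooth_s) == 1,
            toco_smooth_s > 0)
  stopifnot(is.numeric(merge_gap_s), length(merge_gap_s) == 1,
            merge_gap_s >= 0)
  if (tha_mode == "explicit") {
    if (is.null(tha_value) || !is.numeric(tha_value) || length(tha_value) != 1)
      stop("`tha_value` must be a single number when tha_mode = \"explicit\"",
           call. = FALSE)
  } else if (!is.null(tha_value)) {
    stop("`tha_value` is only used when tha_mode = \"explicit\"",
         call. = FALSE)
  }
  structure(
    list(rms_window_s = rms_window_s, thd_s = thd_s, tha_mode = tha_mode,
         tha_value = tha_value, toco_smooth_s = toco_smooth_s,
         merge_gap_s = merge_gap_s),
    class = "detection_config"
  )
}

#' @rdname preprocess_config
#' @param preprocess,zcr,detection Stage configs (see the constructors above).
#' @param match_tol_s Matching tolerance in seconds between a detected peak
#'   and a maternal-perception label (default 20 s).
#' @export
uc_config <- function(preprocess = preprocess_config(), zcr = zcr_config(),
                      detection = detection_config(), match_tol_s = 20) {
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(zcr, "zcr_config"),
            inherits(detection, "detection_config"))
  stopifnot(is.numeric(match_tol_s), length(match_tol_s) == 1, match_tol_s > 0)
  structure(
    list(preprocess = preprocess, zcr = zcr, detection = detection,
         match_tol_s = match_tol_s),
    class = "uc_config"
  )
}

#' Resolve a run configuration from a YAML file or nested list
#'
#' Reads a nested configuration (sections `preprocess`, `zcr`, `detection`,
#' `sim`, `evaluation`) and merges it over the documented defaults. Unknown
#' sections or keys are rejected so that typos do not silently fall back to
#' defaults.
#'
#' @param x Path to a YAML file, a nested list, or `NULL` (all defaults).
#' @return A list with elements `config` (a [uc_config()]) and `sim`
#'   (a [sim_config()]).
#' @export
resolve_run_config <- function(x = NULL) {
  raw <- if (is.null(x)) {
    list()
  } else if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    yaml::read_yaml(x)
  } else if (is.list(x)) {
    x
  } else {
    stop("config must be a file path, a list, or NULL", call. = FALSE)
  }
  if (is.null(raw)) raw <- list()

  known <- c("preprocess", "zcr", "detection", "sim", "evaluation")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)

  take <- function(section, constructor) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(constructor)))
    if (length(bad) > 0)
      stop("unknown key(s) in config section '", section, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    do.call(constructor, args)
  }

  eval_args <- raw[["evaluation"]]
  if (is.null(eval_args)) eval_args <- list()
  bad <- setdiff(names(eval_args), "match_tol_s")
  if (length(bad) > 0)
    stop("unknown key(s) in config section 'evaluation': ",
         paste(bad, collapse = ", "), call. = FALSE)
  tol <- eval_args$match_tol_s %||% 20

  list(
    config = uc_config(
      preprocess = take("preprocess", preprocess_config),
      zcr = take("zcr", zcr_config),
      detection = take("detection", detection_config),
      match_tol_s = tol
    ),
    sim = take("sim", sim_config)
  )
}
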