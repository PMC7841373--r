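#' Detector thresholds and tuning parameters
#'
#' Bundles every constant the macro and micro detectors use: the published
#' detection thresholds (names starting with `TH_`), the common low-pass
#' filter settings, and the search-window / gating parameters of this
#' implementation. All values can be overridden by name; the defaults are
#' the working set of the method.
#'
#' Units: thresholds on acceleration are in g, on angular velocity in deg/s,
#' on instantaneous energy in (deg/s)^2 (quoted as deg/s^2 by the rules);
#' windows and times are in seconds.
#'
#' @param ... named overrides of individual fields, e.g.
#'   `threshold_set(TH_BW = 1.8)`.
#' @return an object of class `threshold_set` (a named list).
#' @export
#' @examples
#' th <- threshold_set()
#' th$TH_BW
threshold_set <- function(...) {
  th <- list(
    # --- macro: bout detection ---
    fraction_B = 0.3,       # sharp-change fraction of the derivative extremum
    sc_fc = 0.15,           # Hz, low-pass inside sharp-change detection
    sc_min_slope = 0.1,     # g/s, absolute floor for posture-change slopes
    TH_BW = 1.6,            # g, wrist |Acc| envelope level during swimming
    min_bout_time = 5,      # s, discard shorter activity intervals (wrist)
    bout_merge_gap = 10,    # s, merge wrist activity intervals closer than this
    rw_bout_refine = 1.3,   # g, |Acc| crossing marking upper-limb cycling onset
    # --- macro: lap / approximate-turn detection ---
    min_lap_time = 10,      # s, minimal separation between accepted turns
    turn_peak_frac = 0.6,   # accept turn peaks >= this fraction of the bout max
    TH_LW = 200,            # deg/s, wrist |Gyr| drop marking the turn
    rw_turn_min_gap = 1,    # s, minimal duration of the wrist low-|Gyr| interval
    ls_ref_window = 2,      # s, shank reference window for the runtime TH_LS
    # --- macro: technique identification ---
    technique_window = 6,   # s, window covering >= 2 arm cycles / >= 5 kicks
    technique_pos = 0.55,   # window center as a fraction of the lap span
    stroke_band = c(0.3, 1.5),  # Hz, plausible arm-cycle frequencies
    stroke_freq_nom = 0.6,  # Hz, nominal arm-cycle frequency
    TH_StyleHE = 0.2,       # g, head spectral magnitude separating butterfly
    TH_StyleSA = 0.16,      # g, sacrum spectral magnitude separating butterfly
    TH_StyleWmean = 1.7,    # g, wrist mean |Acc| above -> butterfly
    TH_StyleWvar = 0.01,    # g^2, wrist |Acc| variance below -> front crawl
    rs_kick_freq_split = 1.8,   # Hz, shank kick frequency separating FC from Bf
    # --- micro: common ---
    filter_fc = 10,         # Hz, common noise-removal low-pass
    filter_order = 2,
    event_guard = 0.1,      # s, exclusion zone right after the previous event
    push_window_pre = 1,    # s, Push_B search starts this early before anchor
    push_window_post = 2,   # s, ... and ends this late after it
    glide_window = 3,       # s, Glid_B searched within this after Push_B
    stpr_window = 8,        # s, StPr_B searched within this after Glid_B
    swim_window = 10,       # s, Swim_B searched within this after StPr_B
    turn_window_pre = 3,    # s, Turn_B search starts this early before anchor
    turn_window_post = 1,   # s, ... and ends this late after it
    # --- micro: per-event gates of this implementation ---
    th_glide_sahe = -0.15,  # g, Acc_y trough depth marking glide (SA/HE)
    th_glide_rw = 0.2,      # g, wrist Acc_y peak marking glide
    th_glide_rs = 50,       # deg/s, shank |Gyr| peak marking glide
    TH_SPSA = 1.0,          # g, sacrum kick-burst extremum magnitude
    TH_SPSAvar = 0.06,      # g, sacrum rolling-sd gate at the kick burst
    TH_SPHE = -0.5,         # g, head Acc_y trough threshold
    TH_SPHEprom = 0.1,      # g, head trough prominence
    TH_SPRW = -0.9,         # g, wrist (|Acc| - 1 g) trough threshold
    TH_SPRS = 1.3,          # g, shank |Acc_x| kick threshold
    th_stpr_rs_bas = 0.3,   # g, shank Acc_y peak threshold (backstroke)
    TH_SSA_FCBaS = 200,     # deg/s, sacrum |Gyr_y| rolling onset
    TH_SSA_BrS = 550,       # (deg/s)^2, sacrum Gyr_z IMF2 energy onset (Br)
    TH_SSA_BF = 0.1,        # g, sacrum Acc_y IMF2 onset (Bf)
    TH_SHE_FC = 5000,       # (deg/s)^2, head Gyr_y energy onset (FC)
    TH_SHE_BFBrS = 12000,   # (deg/s)^2, head Gyr_z energy onset (Bf/Br)
    TH_SHE_BaS = 1000,      # (deg/s)^2, head Gyr_z energy drop (BaS)
    th_swim_wrist_acc = 0.4,   # g, wrist first-cycle peak gate
    th_swim_wrist_gyr = 100,   # deg/s, wrist first-cycle peak gate (Br)
    TH_T_RS = 1.7,          # g, shank IMF2 cycle-peak gate for Swim_B
    th_turn_prom = 0.5,     # g, prominence of the sacrum pre-turn trough
    turn_rel_frac = 0.5,    # accept pre-turn peaks >= this fraction of window max
    rw_turn_fc = 3,         # Hz, extra smoothing of wrist Acc_y (tumble turn)
    # --- validation ---
    tolerance_match = 0.3   # s, event matching tolerance for scores
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(th))
    if (length(bad)) {
      stop("threshold_set: unknown field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    th[names(ov)] <- ov
  }
  num <- unlist(th)
  if (!all(is.finite(num))) {
    stop("threshold_set: all fields must be finite", call. = FALSE)
  }
  structure(th, class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set> with", length(unclass(x)), "fields\n")
  invisible(x)
}

# numeric scalar fields eligible for the +/-10% sensitivity sweep
sweepable_thresholds <- function(th) {
  nm <- names(th)[vapply(th, function(v) is.numeric(v) && length(v) == 1L,
                         logical(1))]
  setdiff(nm, c("filter_order"))
}
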