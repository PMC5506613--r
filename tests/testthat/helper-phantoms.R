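# Shared fixtures built in code.

# uniform-amplitude phantom over the standard lung ellipses
uniform_phantom_spec <- function(amp = 1, rr = 20, duration = 45,
                                 frac = 0.5, delay_map = NULL, eeli = 0,
                                 noise_sd = 0, cardiac_amplitude = 0,
                                 fs = 20, seed = 1L) {
  a <- matrix(0, 32, 32)
  a[lung_ellipses()] <- amp
  phantom_spec(lung_amplitude_map = a, delay_map = delay_map,
               respiratory_rate = rr, inspiration_fraction = frac,
               eeli_trajectory = eeli, cardiac_amplitude = cardiac_amplitude,
               noise_sd = noise_sd, sampling_rate = fs, duration = duration,
               seed = seed)
}

# hand-built breath segmentation (1-based frame indices)
make_seg <- function(starts, peaks, ends, sampling_rate = 20,
                     selected = TRUE) {
  structure(list(
    breaths = data.frame(start = starts, peak = peaks, end = ends,
                         selected = rep_len(selected, length(starts))),
    sampling_rate = sampling_rate),
    class = "breath_seg")
}

# curve object from raw values
make_curve <- function(values, sampling_rate = 20) {
  structure(list(values = values, sampling_rate = sampling_rate,
                 mask_id = "test"),
            class = "eit_curve")
}

# tidal image object from a DI matrix
make_tidal <- function(di) {
  structure(list(di = di, breath_ids = 1L), class = "tidal_image")
}

# mask object from a logical matrix
make_mask <- function(member, threshold_fraction = 0.2) {
  structure(list(member = member, threshold_fraction = threshold_fraction,
                 source_sessions = 1L),
            class = "lung_mask")
}

# independently coded brute-force GI: literal transcription of the printed
# equation, deliberately loop-based and separate from gi_index()
brute_force_gi <- function(di_values) {
  med <- median(di_values)
  num <- 0
  for (v in di_values) num <- num + abs(v - med)
  num / sum(di_values)
}

# independently coded AUC by exhaustive pair counting (ties count 1/2)
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
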