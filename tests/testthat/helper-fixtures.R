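# Small, fast fixtures shared across test files. Everything is generated in
# code; seeds are fixed so expectations are stable.

# a tiny signal-level cohort: 2+2 subjects, 2 channels-coupled config kept at
# full 10 channels but short nights so preprocessing runs in well under a second
tiny_signal_config <- function(...) {
  cohort_config(n_ptsd = 2, n_control = 2, duration = 60, artifact_rate = 0,
                seed = 42, ...)
}

# a feature-table config at study scale (78 subjects, 2 nights)
table_config <- function(...) {
  cohort_config(seed = 42, ...)
}

# a deterministic sinusoidal recording
sine_recording <- function(freqs, fs = 250, duration = 20, amp = 10) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  samples <- do.call(rbind, lapply(freqs, function(f) amp * sin(2 * pi * f * t)))
  recording(samples, fs, paste0("C", seq_along(freqs)))
}

# build an epoch grid directly from given per-epoch rejection-band powers so
# the rejection rules can be tested against hand-computable inputs
grid_from_powers <- function(emg = NULL, move = NULL) {
  n <- max(length(emg), length(move))
  if (is.null(emg)) emg <- rep(1, n)
  if (is.null(move)) move <- rep(1, n)
  structure(
    list(subject_id = "S001", night = 1L, fs = 250, channel_labels = "C3",
         epoch_length = 5, n_epochs = n, freq = numeric(0),
         spectra = NULL, psd = NULL,
         emg_power = matrix(emg, 1, dimnames = list("C3", NULL)),
         move_power = matrix(move, 1, dimnames = list("C3", NULL)),
         keep_mask = matrix(TRUE, 1, n, dimnames = list("C3", NULL)),
         rejection_reason = matrix("none", 1, n, dimnames = list("C3", NULL))),
    class = "wn_epochgrid"
  )
}

# brute-force AUC by explicit pair counting (oracle for rank_auc)
pair_count_auc <- function(values, labels) {
  pos <- values[labels]
  neg <- values[!labels]
  wins <- 0
  for (a in pos) for (b in neg) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(pos) * length(neg))
}

# brute-force distance correlation with explicit loops (oracle)
loop_dcor <- function(x, y) {
  n <- length(x)
  a <- matrix(0, n, n); b <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    a[i, j] <- abs(x[i] - x[j]); b[i, j] <- abs(y[i] - y[j])
  }
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  dcov2 <- mean(A * B); dvx <- mean(A^2); dvy <- mean(B^2)
  if (dvx == 0 || dvy == 0) return(0)
  sqrt(max(dcov2, 0)) / (dvx * dvy)^0.25
}

# brute-force WPLI from first principles: re-derives the Hann-tapered
# cross-spectra with explicit loops over epochs and bins (oracle for wpli())
loop_wpli <- function(x, y, fs, low, high, epoch_s = 5) {
  spe <- epoch_s * fs
  n_ep <- floor(length(x) / spe)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(spe) - 1) / (spe - 1))
  num <- 0; den <- 0
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1) * spe + 1):(e * spe)
    Fx <- fft(x[idx] * w); Fy <- fft(y[idx] * w)
    freq <- (seq_len(spe) - 1) * fs / spe
    for (k in which(freq >= low & freq < high & freq <= fs / 2 & freq > 0)) {
      im <- Im(Fx[k] * Conj(Fy[k]))
      num <- num + im; den <- den + abs(im)
    }
  }
  if (den == 0) return(NA_real_)
  abs(num) / den
}
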