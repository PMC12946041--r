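# Small fixtures built in code, shared across test files.

# three collinear sensors 30 mm apart
toy_montage <- function() {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("label\tx\ty\tz", "A\t0\t0\t0", "B\t30\t0\t0", "C\t60\t0\t0"),
             path)
  load_montage(path)
}

# n x n planar grid, `spacing` mm apart (diagonals farther than sides)
grid_montage <- function(n, spacing = 30) {
  g <- expand.grid(ix = seq_len(n), iy = seq_len(n))
  new_montage_tsv(paste0("g", seq_len(n * n)),
                  cbind(g$ix * spacing, g$iy * spacing, 0))
}

new_montage_tsv <- function(labels, xyz) {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path), add = TRUE)
  writeLines(c("label\tx\ty\tz",
               paste(labels, xyz[, 1], xyz[, 2], xyz[, 3], sep = "\t")),
             path)
  load_montage(path)
}

# eeg_epochs with prescribed data array and trivial metadata
toy_epochs <- function(data, fs_hz = 256, t0_ms = -500,
                       condition = NULL, correct = NULL, participant = NULL) {
  n_e <- dim(data)[3]
  eeg_epochs(
    data,
    times_ms = t0_ms + (0:(dim(data)[2] - 1)) * 1000 / fs_hz,
    fs_hz = fs_hz,
    channels = paste0("ch", seq_len(dim(data)[1])),
    epoch_table = tibble::tibble(
      participant = participant %||% rep(1L, n_e),
      trial = seq_len(n_e),
      condition = condition %||% rep(c("symmetric", "asymmetric"),
                                     length.out = n_e),
      correct = correct %||% rep(TRUE, n_e))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# subject_erps built directly from a channels x samples x participants x 2
# array (conditions symmetric, asymmetric)
toy_erps <- function(arr, times_ms = NULL, channels = NULL) {
  structure(
    list(data = arr,
         channels = channels %||% paste0("ch", seq_len(dim(arr)[1])),
         times_ms = times_ms %||% seq_len(dim(arr)[2]),
         fs_hz = 256,
         participants = seq_len(dim(arr)[3]),
         conditions = c("symmetric", "asymmetric"),
         n_trials = tibble::tibble(), excluded = integer(0)),
    class = "subject_erps")
}

# tmap with a prescribed t matrix (df chosen so qt(0.975, df) ~ 2.2)
toy_tmap <- function(tmat, df = 10, times_ms = NULL, channels = NULL) {
  structure(list(t = tmat, df = df,
                 times_ms = times_ms %||% seq_len(ncol(tmat)),
                 channels = channels %||% paste0("ch", seq_len(nrow(tmat)))),
            class = "tmap")
}

# per-subject null difference maps for permutation calibration
null_diffs <- function(n_ch, n_s, n_subj, seed) {
  withr::with_seed(seed, {
    d <- array(rnorm(n_ch * n_s * n_subj), c(n_ch, n_s, n_subj),
               dimnames = list(paste0("g", seq_len(n_ch)), NULL, NULL))
    attr(d, "times_ms") <- seq_len(n_s)
    d
  })
}
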