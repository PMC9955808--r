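# Shared fixtures: everything is generated in code; expensive cohorts are
# cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

noise_free <- list(noise_sd = list(angle = 0, force = 0, semg = 0))

# one noise-free session per grade (plus processed segments and ground truth)
nf_session <- function(mas, seed = 3) {
  cached(paste0("nf-", mas, "-", seed), {
    ses <- generate_session(mas, seed = seed, overrides = noise_free)
    proc <- process_recording(ses$recording)
    segs <- suppressWarnings(segment_session(proc))
    list(rec = ses$recording, gt = ses$ground_truth$stretches,
         proc = proc, segs = segs)
  })
}

# small noisy cohort with extracted features
noisy_feature_table <- function(n_per_class = 4, seed = 11) {
  cached(paste0("feat-", n_per_class, "-", seed), {
    coh <- generate_cohort(n_per_class, seed = seed)
    list(cohort = coh,
         features = suppressWarnings(cohort_features(coh$recordings)))
  })
}

# labelled feature table with arbitrary values, for dataset-module tests
make_feature_df <- function(labels, speeds = rep("fast", length(labels)),
                            seed = 1) {
  set.seed(seed)
  n <- length(labels)
  feats <- as.data.frame(matrix(rnorm(n * 17), nrow = n,
                                dimnames = list(NULL, feature_names())))
  cbind(data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                   trial_id = sprintf("t%03d", seq_len(n)),
                   stretch_index = seq_len(n), speed = speeds,
                   mas_label = labels, stringsAsFactors = FALSE),
        feats)
}

# a tiny but valid two-second recording with analytically known channels
tiny_recording <- function(mas_label = "1") {
  n_lo <- 2000L
  t_lo <- (seq_len(n_lo) - 1) / 1000
  t_hi <- (seq_len(2L * n_lo) - 1) / 2000
  stretch_recording(
    subject_id = "subj-a", trial_id = "trial-1",
    time_lo = t_lo,
    angle_x = 30 + 20 * sin(2 * pi * 0.5 * t_lo),
    angle_y = 10 + 5 * cos(2 * pi * 0.5 * t_lo),
    force = 4 + 0.5 * sin(2 * pi * 1.3 * t_lo),
    time_hi = t_hi,
    semg = 0.05 * sin(2 * pi * 80 * t_hi),
    mas_label = mas_label)
}

# a stretch segment with a planted catch: constant-velocity rise with a
# smooth sigmoid velocity drop whose acceleration minimum sits exactly at
# the drop centre; returns the segment plus its planted quantities
planted_segment <- function(rom = 100, dip_frac = 0.4, n = 2000, fs = 1000,
                            dip_depth = 0.7, dip_w = 0.02) {
  t <- seq_len(n) / fs
  t_c <- dip_frac * n / fs
  v <- rep(rom / (n / fs), n) * (1 - dip_depth * pnorm((t - t_c) / dip_w))
  ang <- cumsum(v) / fs
  ang <- ang * rom / ang[n]
  ci_planted <- round(t_c * fs)
  list(angle = ang, fs = fs, planted_idx = ci_planted,
       planted_catch_angle = ang[ci_planted], rom = rom)
}

# identity scaler over the canonical features
identity_scaler <- function() {
  structure(list(feature = feature_names(),
                 mean = stats::setNames(rep(0, 17), feature_names()),
                 sd = stats::setNames(rep(1, 17), feature_names()),
                 constant = stats::setNames(rep(FALSE, 17), feature_names())),
            class = "scaler_params")
}

# a cascade whose sub-models are deterministic stubs, for rule tracing
stub_cascade <- function(svm_label = "2", rf_probs = c(0.2, 0.5, 0.3),
                         rom_threshold = 10) {
  lv <- c("0", "1", "1+", "2", "3")
  svm <- manual_classifier(lv, label_fun = function(x) {
    rep(svm_label, nrow(as.data.frame(x)))
  })
  rf <- manual_classifier(lv, prob_fun = function(x) {
    k <- nrow(as.data.frame(x))
    probs <- c(rf_probs[1], 0, rf_probs[2], rf_probs[3], 0)
    matrix(rep(probs, each = k), nrow = k, dimnames = list(NULL, lv))
  })
  structure(list(rom_threshold = rom_threshold, svm = svm, rf = rf,
                 scaler = identity_scaler(),
                 svm_accept_set = c("1", "3"),
                 rf_allowed_set = c("0", "1+", "2"),
                 feature_cols = feature_names(), seed = 0L,
                 schema_version = "spastimas-cascade-1"),
            class = "cascade_model")
}

# one row of plausible raw-scale features
one_feature_row <- function(rom = 90) {
  row <- as.data.frame(as.list(stats::setNames(runif(17), feature_names())))
  row$rom <- rom
  row
}

# clean/noisy 6-rise ramp staircase with known corner positions
ramp_staircase <- function(noise_sd = 0, seed = 1, fs = 1000) {
  blocks <- list(rep(0, fs))
  starts <- ends <- integer(0)
  for (i in 1:6) {
    starts <- c(starts, sum(lengths(blocks)))
    blocks <- c(blocks, list(seq(0, 100, length.out = fs)))
    ends <- c(ends, sum(lengths(blocks)))
    blocks <- c(blocks, list(rep(100, fs)), list(seq(100, 0, length.out = 500)),
                list(rep(0, fs)))
  }
  ang <- 10 + unlist(blocks)
  if (noise_sd > 0) {
    set.seed(seed)
    ang <- ang + rnorm(length(ang), 0, noise_sd)
  }
  list(angle = ang, starts = starts, ends = ends, fs = fs)
}
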