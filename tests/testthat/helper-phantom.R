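# Shared phantom fixtures, generated once per test run.
.fixture_env <- new.env(parent = emptyenv())

phantom_subject_fixture <- function(seed = 5L) {
  key <- paste0("subj_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_subject(phantom_spec(seed = seed))
  }
  .fixture_env[[key]]
}

subject_contours_fixture <- function(seed = 5L) {
  key <- paste0("ct_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- subject_contours(phantom_subject_fixture(seed)$dec)
  }
  .fixture_env[[key]]
}

dice_coef <- function(a, b) {
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# slices with substantial brain tissue, used for contour scoring
central_slices <- function(nslices, k = 20) {
  mid <- (nslices + 1) / 2
  seq(round(mid - k / 2 + 0.5), length.out = k)
}

# two well-separated Gaussian feature clouds with known classes
# (SOZ-like: fast, sparse, bullseye; RSN-like: slow, template-bound)
sim_clouds <- function(seed, n = 20, sd = 0.05) {
  set.seed(seed)
  soz <- data.frame(
    bullseye_score = rnorm(n, 0.9, sd),
    gray_matter_fraction = rnorm(n, 0.9, sd),
    rsn_template_overlap = rnorm(n, 0.05, sd),
    dominant_freq_hz = rnorm(n, 0.1, sd),
    gini_activelet = rnorm(n, 0.85, sd),
    gini_sine_mp = rnorm(n, 0.8, sd))
  rsn <- data.frame(
    bullseye_score = rnorm(n, 0.1, sd),
    gray_matter_fraction = rnorm(n, 0.9, sd),
    rsn_template_overlap = rnorm(n, 0.8, sd),
    dominant_freq_hz = rnorm(n, 0.03, sd),
    gini_activelet = rnorm(n, 0.4, sd),
    gini_sine_mp = rnorm(n, 0.3, sd))
  list(features = rbind(soz, rsn),
       truth = rep(c("soz", "rsn"), each = n))
}
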