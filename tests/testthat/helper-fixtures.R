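# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a short clean session plus its preprocessing, reused across files
clean_session <- function() fixture("clean_session", function() {
  simulate_session(gait_profile(), duration = 120, label = "NF", seed = 101)
})

clean_pp <- function() fixture("clean_pp", function() {
  preprocess_session(clean_session()$recordings)
})

# fully deterministic session: no noise, no asymmetry, no rate jitter
ideal_session <- function() fixture("ideal_session", function() {
  simulate_session(
    gait_profile(asymmetry = 0, hf_noise_power = 0, section_variability = 0,
                 sample_rate_jitter = 0, cadence_sd = 0, amp_jitter = 0),
    duration = 120, label = "NF", seed = 7)
})

ideal_pp <- function() fixture("ideal_pp", function() {
  preprocess_session(ideal_session()$recordings)
})

# small labelled feature matrix with k planted informative features
toy_feature_matrix <- function(n_per_class = 10, n_noise = 20, sep = 3,
                               seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- factor(rep(c("NF", "PF"), each = n_per_class),
                   levels = c("NF", "PF"))
  x <- matrix(rnorm(n * (n_noise + 1)), n)
  x[labels == "PF", 1] <- x[labels == "PF", 1] + sep
  colnames(x) <- c("signal", paste0("noise", seq_len(n_noise)))
  rownames(x) <- sprintf("P%02d", seq_len(n))
  structure(list(x = x, labels = labels, participants = rownames(x)),
            class = "feature_matrix")
}
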