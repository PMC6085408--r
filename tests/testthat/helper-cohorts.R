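# Shared synthetic fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

planted_feature_name <- "Cclcr h\u03b3"

# 12 vs 12 animals, 2 sessions, one planted coherence effect (+0.3 on
# Cclcr high-gamma for group R), 30 s at 500 Hz.
planted_cohort_features <- function(seed = 11) {
  memo(paste0("planted", seed), {
    cs <- cohort_spec(
      n_per_group = 12, groups = c("R", "NR"),
      planted = list(kind = "coherence", channels = c("cl", "cr"),
                     band = "h\u03b3", delta = 0.3, group = "R"),
      sessions = 2, base = mixing_spec(fs = 500, duration = 30),
      seed = seed)
    extract_feature_table(simulate_cohort(cs))
  })
}

# Same geometry, no planted effect.
null_cohort_features <- function(seed = 21) {
  memo(paste0("null", seed), {
    cs <- cohort_spec(n_per_group = 6, groups = c("A", "B"), sessions = 2,
                      base = mixing_spec(fs = 500, duration = 30),
                      seed = seed)
    extract_feature_table(simulate_cohort(cs))
  })
}

# animal -> binary label table from the cohort's group column
group_label_table <- function(features, one = "R") {
  anim <- unique(features$animal)
  data.frame(animal = anim,
             label = as.integer(features$group[match(anim,
                                                     features$animal)] == one))
}

# Mann-Whitney U by direct pairwise comparison (independent oracle).
brute_force_u <- function(x1, x2) {
  sum(outer(x1, x2, ">")) + 0.5 * sum(outer(x1, x2, "=="))
}

# Outcome-label tables reproducing printed response profiles.
profile_labels <- function(core_only, shell_only, both, neither) {
  n <- core_only + shell_only + both + neither
  core <- c(rep("responder", core_only), rep("non-responder", shell_only),
            rep("responder", both), rep("non-responder", neither))
  shell <- c(rep("non-responder", core_only), rep("responder", shell_only),
             rep("responder", both), rep("non-responder", neither))
  structure(data.frame(animal = sprintf("rat%02d", seq_len(n)),
                       core_status = core, shell_status = shell,
                       stringsAsFactors = FALSE),
            targets = c("core", "shell"))
}
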