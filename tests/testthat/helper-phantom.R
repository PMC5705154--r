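# Shared phantom fixtures, generated in code and cached per test run so the
# expensive full tracks are computed once.

.phantom_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .phantom_cache)) {
    assign(name, build(), envir = .phantom_cache)
  }
  get(name, envir = .phantom_cache)
}

truth_point <- function(truth, p) {
  df <- truth$trajectories[truth$trajectories$point == p, ]
  df[, c("frame", "x", "y")]
}

# default 90-frame phantom with occlusion, head motion and noise, tracked
# from the true first-frame positions
default_tracked <- function() {
  cached("default_tracked", function() {
    sim <- simulate_vfss(phantom_spec())
    seeds <- sim$truth$trajectories[sim$truth$trajectories$frame == 0,
                                    c("point", "x", "y")]
    run <- track_sequence(sim$frames, seeds)
    list(sim = sim, run = run)
  })
}

# 60-frame phantom without occlusion (clean motion), tracked
clean_tracked <- function() {
  cached("clean_tracked", function() {
    spec <- phantom_spec(n_frames = 60, occlusion_len = 0, seed = 3L)
    sim <- simulate_vfss(spec)
    seeds <- sim$truth$trajectories[sim$truth$trajectories$frame == 0,
                                    c("point", "x", "y")]
    run <- track_sequence(sim$frames, seeds)
    list(sim = sim, run = run)
  })
}

tracking_errors <- function(run, truth) {
  tr <- tidy(run)
  truth_df <- truth$trajectories
  m <- merge(as.data.frame(tr), as.data.frame(truth_df),
             by = c("point", "frame"), suffixes = c("", "_t"))
  m$err <- sqrt((m$x - m$x_t)^2 + (m$y - m$y_t)^2)
  m[order(m$point, m$frame), ]
}
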