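# Shared fixtures. All synthetic, generated at test time; the study-sized
# grids keep the full 512 x 512 x 160 mm field of view of the default
# phantom so compartment and ROI placements (specified in mm) are unchanged,
# only sampled more coarsely.

# study-sized grid: full protocol grid runs in ~40 s
small_spec <- function() {
  phantom_spec(shape = c(64L, 64L, 16L), spacing = c(8, 8, 10),
               ct_supersample = 2L)
}

# minimal grid for structural / determinism tests
tiny_spec <- function() {
  phantom_spec(shape = c(32L, 32L, 8L), spacing = c(16, 16, 20),
               ct_supersample = 1L)
}

# memoised small-grid studies so several test files can share one bundle
.fixture_env <- new.env(parent = emptyenv())

small_study <- function(seed = 1L) {
  key <- paste0("study_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_study(small_spec(), seed = seed)
  .fixture_env[[key]]
}

# a deterministic SUV volume with heterogeneous values
toy_suv_volume <- function(dims = c(10L, 10L, 3L), seed = 99L) {
  set.seed(seed)
  image_volume(array(stats::runif(prod(dims), 0.5, 4), dims), c(4, 4, 4),
               "SUV", "toy")
}

# closed-form paired t test (textbook formula), the oracle for the t-test
# wrappers
paired_t_oracle <- function(x, y) {
  d <- x - y
  n <- length(d)
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  list(t = t_stat, p = p)
}
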