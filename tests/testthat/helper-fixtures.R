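# Shared fixtures, built in code. Heavier objects are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

small_map <- function(n = 24, seed = 101) build_retinotopic_map(n, 4, seed)

small_schedule <- function(n_runs = 4, seed = 202) make_block_schedule(n_runs, seed)

# A 4-vertex map with exactly one vertex per quadrant, at known coordinates.
quadrant_map <- function() {
  m <- data.frame(vertex_id = 1:4,
                  hemisphere = c("R", "L", "R", "L"),
                  vf_x = c(-1, 1, -1, 1),
                  vf_y = c(1, 1, -1, -1))
  m$eccentricity <- sqrt(m$vf_x^2 + m$vf_y^2)
  m$quadrant <- vf_quadrant(m$vf_x, m$vf_y)
  class(m) <- c("retinotopic_map", "data.frame")
  m
}

null_cohort <- function(n_subjects = 6, n_vertices = 24, seed = 11) {
  simulate_cohort(n_subjects, small_map(n_vertices), small_schedule(),
                  effect_spec("null"), seed = seed)
}

planted_cohort <- function(n_subjects = 8, n_vertices = 40, seed = 12) {
  simulate_cohort(n_subjects, build_retinotopic_map(n_vertices, 4, seed = 7),
                  small_schedule(), effect_spec("level_topology"), seed = seed)
}

# Reduced Gabor bank on a 64 px field of view (levels 1-4).
reduced_bank <- function() cached("reduced_bank", function()
  build_gabor_bank(c(64, 64), levels = c(1, 2, 4, 8),
                   positions_per_level = c(2, 8, 16, 64)))

# Resolution at which the Navon grid fits a 64 px screen (24 x 60 raster).
DPP64 <- 2 / 24

navon_set <- function(dpp = DPP64) cached(paste0("navon", dpp), function()
  list(EG = render_navon("E", "Global", dpp),
       EL = render_navon("E", "Local", dpp),
       UG = render_navon("U", "Global", dpp),
       UL = render_navon("U", "Local", dpp)))

# Separable two-class feature set: one informative edge on top of noise.
separable_features <- function(n_subj = 10, n_edges = 30, gap = 4, seed = 5) {
  with_seed <- function(s, e) { set.seed(s); e }
  set.seed(seed)
  x <- matrix(abs(rnorm(2 * n_subj * n_edges, sd = 0.2)), 2 * n_subj)
  y <- rep(c("A", "B"), n_subj)
  x[y == "B", 3] <- x[y == "B", 3] + gap
  list(x = x, y = y, subject = rep(seq_len(n_subj), each = 2))
}

# Balanced control-experiment design table.
control_design <- function(n_part = 6, trials_per_cell = 3) {
  des <- expand.grid(participant = seq_len(n_part),
                     rep = seq_len(trials_per_cell),
                     level = c("Global", "Local"), letter = c("E", "U"),
                     stringsAsFactors = FALSE)
  des$trial_order <- stats::ave(seq_len(nrow(des)), des$participant,
                                FUN = seq_along)
  des
}
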