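# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small three-group cohort with planted effects, plus its edge features.
small_cohort <- function() {
  cached("small_cohort", function() {
    spec <- cohort_spec(n_hc = 8, n_pd_nonmci = 10, n_pd_mci = 8,
                        n_nodes = 20, n_frames = 120, n_noise_voxels = 40,
                        seed = 7)
    cohort <- generate_cohort(spec)
    features <- edge_table(lapply(cohort$subjects, function(s)
      build_connectome(s$roi_series, compute_acompcor(s$noise_pool),
                       s$motion_params)))
    list(spec = spec, cohort = cohort, features = features,
         groups = cohort$truth$group)
  })
}

# Cohort with no planted effects (exchangeable groups).
null_cohort <- function() {
  cached("null_cohort", function() {
    edges <- data.frame(i = 1, j = 2, delta = 0)
    spec <- cohort_spec(n_hc = 6, n_pd_nonmci = 12, n_pd_mci = 10,
                        n_nodes = 16, n_frames = 100, n_noise_voxels = 30,
                        signal_edges = edges, seed = 19)
    cohort <- generate_cohort(spec)
    features <- edge_table(lapply(cohort$subjects, function(s)
      build_connectome(s$roi_series, compute_acompcor(s$noise_pool),
                       s$motion_params)))
    list(spec = spec, cohort = cohort, features = features,
         groups = cohort$truth$group)
  })
}

# Deterministic toy feature matrix with one perfectly separating column.
toy_signal_features <- function(n_per_class = 8, n_noise = 60, seed = 5) {
  set.seed(seed)
  y <- factor(rep(c("PD-nonMCI", "PD-MCI"), each = n_per_class))
  signal <- ifelse(y == "PD-MCI", 1, -1) + rnorm(2 * n_per_class, 0, 0.1)
  x <- cbind(signal, matrix(rnorm(2 * n_per_class * n_noise), 2 * n_per_class))
  colnames(x) <- paste0("e", seq_len(ncol(x)))
  list(x = x, y = y)
}
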