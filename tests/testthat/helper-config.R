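# Shared small fixtures: a compact model configuration and dataset builders
# used across the unit tests. Sizes are chosen so every block is exercised
# with non-trivial shapes while keeping graphs small.

tiny_config <- function(...) {
  args <- list(d_model = 8L, patch_long_len = 16L, patch_long_stride = 16L,
               patch_short_len = 4L, patch_short_stride = 2L,
               mamba_hidden = 16L, mamba_state = 4L, mamba_conv_kernel = 2L,
               lwt_heads = 2L, lwt_head_dim = 4L, lwt_ff_dim = 16L,
               lwt_window = 5L, lwt_layers = 1L, router_dim = 8L,
               n_units = 2L, gate_hidden = 32L, lr = 5e-3, batch_size = 16L,
               max_epochs = 5L, patience = 3L, seed = 42L)
  do.call(run_config, utils::modifyList(args, list(...)))
}

tiny_dataset <- function(n = 12L, T = 32L, D = 3L, seed = 1L,
                         informative = "audio", trend = 1.5, fluct = 0,
                         noise = 0.3, pos = 0.5) {
  generate_dataset(generator_config(
    n_samples = n, T_a = T, D_a = D, T_v = T, D_v = D,
    trend_strength = trend, fluctuation_strength = fluct,
    informative_modality = informative, noise_sd = noise,
    positive_fraction = pos, seed = seed))
}

tiny_model <- function(cfg = tiny_config(), T = 32L) build_model(cfg, T, T)

random_sample <- function(T = 32L, D = 3L, label = 1L, seed = 1L,
                          id = "s0001") {
  set.seed(seed)
  multimodal_sample(id, matrix(rnorm(T * D), T), matrix(rnorm(T * D), T),
                    label)
}

# force the path gate toward a fixed path by biasing its output layer
force_gate_to_path <- function(model, k, strength = 50) {
  b <- model$params$dynmm$gate2$b
  b$val[] <- 0
  b$val[1, k] <- strength
  invisible(model)
}
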