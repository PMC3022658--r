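# shared fixtures, all generated in code

tiny_montage <- function(n = 16) spherical_montage(n)

# epochs x channels x samples array of bounded noise with optional
# injected artifact excursions; ground truth recorded in attributes
make_epoch_fixture <- function(n_epochs = 12, n_channels = 8, n_samples = 64,
                               artifact_epochs = integer(0),
                               artifact_uv = 150, seed = 404) {
  withr::with_seed(seed, {
    a <- array(rnorm(n_epochs * n_channels * n_samples, 0, 10),
               dim = c(n_epochs, n_channels, n_samples))
    a <- pmin(pmax(a, -50), 50)
    for (e in artifact_epochs) {
      a[e, sample(n_channels, 1), sample(n_samples, 1)] <- artifact_uv
    }
    attr(a, "artifact_epochs") <- artifact_epochs
    a
  })
}

# noiseless two-template alternating map sequence
make_two_template_data <- function(n_channels = 16, block = 8, n_blocks = 4,
                                   seed = 11) {
  tpl <- generate_template_maps(tiny_montage(n_channels), k = 2, seed = seed)
  lab <- rep(rep(1:2, each = block), n_blocks)
  x <- tpl[, lab] * rep(seq(1, 3, length.out = length(lab)),
                        each = n_channels)
  list(x = x, labels = lab, templates = tpl)
}

# small head model + grid + lead field for source tests (coarse but real)
make_forward_fixture <- function(n_channels = 48, spacing_mm = 22,
                                 n_terms = 50) {
  head <- head_model(spherical_montage(n_channels, coverage = 1))
  grid <- source_grid(head, spacing_mm)
  list(head = head, grid = grid,
       lf = generate_forward(head, grid, n_terms = n_terms))
}
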