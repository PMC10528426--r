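# Shared desk-scale fixtures. Unit tests mostly use 1/10-scale images
# (390 x 307, macula radius 25) for speed; end-to-end checks use the
# 1/5-scale mode.

tiny_config <- function(...) synth_config(scale = 1 / 10, ...)

desk_config <- function(...) synth_config(scale = 1 / 5, ...)

# Single-direction (horizontal) GLRLM features, for hand-worked run examples.
rlm_features_for_test <- function(lv, n_bins) {
  m <- glrlm_matrix(lv, n_bins, directions = list(c(1L, 0L)))[[1]]
  stats::setNames(retinomics:::rlm_skeleton(m, sum(!is.na(lv))),
                  retinomics:::glrlm_names)
}

# A deterministic separable two-class feature table for classifier tests.
toy_classification_data <- function(n_per_class = 30, shift = 3, sd = 1,
                                    p = 4, seed = 42) {
  set.seed(seed)
  X <- rbind(
    matrix(stats::rnorm(n_per_class * p, 0, sd), n_per_class),
    matrix(stats::rnorm(n_per_class * p, shift, sd), n_per_class))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep(c("Negative", "AMD"), each = n_per_class))
}
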