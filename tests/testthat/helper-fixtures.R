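# Shared expensive fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# A small default-recipe synthetic corpus and a level-1 bundle trained on it.
test_corpus <- function() memo("corpus", {
  set.seed(20260924)
  make_labeled_corpus(hairpin_recipe(), n_pos = 40L, level = 1L)
})

# The documented synthetic study conditions: 200 positives, level 1.
test_corpus200 <- function() memo("corpus200", {
  set.seed(909090)
  make_labeled_corpus(hairpin_recipe(), n_pos = 200L, level = 1L)
})

test_bundle <- function() memo("bundle", {
  ds <- test_corpus()
  feats <- attr(ds, "features")
  set.seed(101)
  rf <- fit_range_filter(feats$positives)
  params <- intersect(svm_eligible_params(), names(ds$data))
  train_svm(ds, params, range_filter = rf,
            grid = list(cost = 2^seq(-1, 7, 2), gamma = 2^seq(-9, -1, 2)),
            cv_folds = 3L, group = "synthetic")
})

# Synthetic numeric feature frames with a planted signal in 3 features; all
# other features are noise. Used by the selection tests (no folding needed).
planted_feature_data <- function(n, n_feat = 40L, signal = c("f01", "f02", "f03")) {
  X <- as.data.frame(matrix(stats::rnorm(n * 2 * n_feat), n * 2, n_feat))
  names(X) <- sprintf("f%02d", seq_len(n_feat))
  y <- rep(c(1, 0), each = n)
  shift <- 1.6
  for (s in signal) X[[s]] <- X[[s]] + shift * y
  pos <- X[y == 1, , drop = FALSE]
  neg <- X[y == 0, , drop = FALSE]
  list(pos = pos, neg = neg)
}
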