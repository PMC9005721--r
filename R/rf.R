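# Thin wrappers around randomForest so every stage fits classifiers with the
# same defaults: 500 trees, sqrt(p) variables per split, no depth cap, and
# terminal nodes of >= 25 observations. The forests are used as probability
# machines (class-vote proportions are read as occurrence probabilities), and
# larger leaves give markedly lower-variance, better-calibrated vote
# proportions than fully grown trees.

default_rf_params <- function(p, rf_params = list()) {
  out <- list(ntree = 500, mtry = max(1L, floor(sqrt(p))), nodesize = 25)
  out[names(rf_params)] <- rf_params
  out
}

rf_fit <- function(features, labels, rf_params = list(), seed = 1, ...) {
  if (length(unique(labels)) < 2L)
    stop("labels contain a single class; cannot fit a classifier")
  pars <- default_rf_params(ncol(features), rf_params)
  set.seed(seed)
  do.call(randomForest::randomForest,
          c(list(x = features, y = factor(labels, levels = c(0, 1))),
            pars, list(...)))
}

# Predicted probability of the presence class.
rf_prob <- function(model, newdata) {
  unname(stats::predict(model, newdata, type = "prob")[, "1"])
}
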