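# Shared fixtures and independent oracles, built in code at test time.

# Pairwise Mann-Whitney AUC oracle: P(score_mal > score_ben) + 0.5 P(tie).
auc_mann_whitney <- function(score, truth) {
  sm <- score[truth == "malignant"]
  sb <- score[truth == "benign"]
  if (length(sm) == 0 || length(sb) == 0) return(NA_real_)
  cmp <- outer(sm, sb, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Independent closed-form parameter count: walks every unit of a layer graph
# and sums kernel/BN/linear elements from first principles, without calling
# the builder's per-node accounting.
oracle_param_count <- function(graph) {
  total <- 0
  for (node in graph$nodes) {
    total <- total + switch(
      node$op,
      conv = node$kernel[1] * node$kernel[2] * node$in_ch * node$out_ch +
        (if (isTRUE(node$bias)) node$out_ch else 0),
      bn = 2 * node$ch,
      linear = node$in_ch * node$out_ch +
        (if (isTRUE(node$bias)) node$out_ch else 0),
      0)
  }
  total
}

# Small synthetic manifest with given class sizes (no pixel data needed).
tiny_manifest <- function(n_benign, n_malignant, seed = 1,
                          n_partial = NULL) {
  if (is.null(n_partial)) n_partial <- n_malignant
  build_manifest(synth_config(
    n_no_cancer = n_benign, n_partial = n_partial,
    n_full = n_malignant - n_partial,
    image_height = 32, image_width = 32,
    n_patients = c(no_cancer = max(1, n_benign %/% 2),
                   partial_cancer = max(1, n_partial %/% 2),
                   full_cancer = max(1, (n_malignant - n_partial))),
    seed = seed))
}

# Random prediction set with score ties, for AUC property tests.
random_prediction_set <- function(n, tie_digits = 2) {
  truth <- sample(c("benign", "malignant"), n, replace = TRUE)
  while (length(unique(truth)) < 2) {
    truth <- sample(c("benign", "malignant"), n, replace = TRUE)
  }
  shift <- runif(1, -0.2, 0.4)
  score <- ifelse(truth == "malignant",
                  pmin(pmax(runif(n, 0.2 + shift, 1), 0), 1),
                  pmin(pmax(runif(n, 0, 0.8), 0), 1))
  data.frame(truth = truth,
             pred = ifelse(score >= 0.5, "malignant", "benign"),
             score = round(score, tie_digits))
}
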