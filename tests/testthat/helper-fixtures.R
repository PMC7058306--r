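# Shared fixtures, built in code at test time.

# Flat gray test image of arbitrary size with a deterministic gradient so
# geometric transforms are distinguishable.
gradient_image <- function(H, W) {
  img <- array(0, dim = c(H, W, 3L))
  img[, , 1L] <- matrix(seq(0, 255, length.out = H), H, W)
  img[, , 2L] <- matrix(seq(0, 255, length.out = W), H, W, byrow = TRUE)
  img[, , 3L] <- (img[, , 1L] + img[, , 2L]) / 2
  round(img)
}

constant_image <- function(H, W, value = c(120, 80, 200)) {
  array(rep(value, each = H * W), dim = c(H, W, 3L))
}

# Deterministic prediction records with a given AUC structure.
random_records <- function(n, seed, ties = FALSE) {
  set.seed(seed)
  s <- runif(n)
  if (ties) s <- round(s, 1)
  data.frame(score = s,
             true_label = sample(c("benign", "malignant"), n, replace = TRUE,
                                 prob = c(0.5, 0.5)),
             stringsAsFactors = FALSE)
}

# Brute-force Mann-Whitney AUC oracle: fraction of positive/negative pairs
# ordered correctly, ties counted one half.
mann_whitney_auc <- function(records) {
  pos <- records$score[records$true_label == "malignant"]
  neg <- records$score[records$true_label == "benign"]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Brute-force 1-D Wasserstein-1 oracle on equal-size samples.
wasserstein_1d <- function(a, b) mean(abs(sort(a) - sort(b)))

# Small rendered image sets, cached across tests within a run.
.fixture_env <- new.env(parent = emptyenv())
rendered_set <- function(class = "benign", n = 20L, size = 32L,
                         seed0 = 100L) {
  key <- paste(class, n, size, seed0, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    params <- if (class == "benign") benign_render_params() else
      malignant_render_params()
    .fixture_env[[key]] <- lapply(seq_len(n), function(i)
      render_patch(params, size, seed = seed0 + i)$image)
  }
  .fixture_env[[key]]
}

# Manifest of n patch rows without image files (descriptor-level tests).
fake_manifest <- function(n_benign, n_malignant = 0L, n_excluded = 0L) {
  n <- n_benign + n_malignant + n_excluded
  data.frame(
    path = sprintf("patch_%04d.png", seq_len(n)),
    case_id = sprintf("case_%02d", (seq_len(n) - 1L) %/% 5L + 1L),
    label = rep(c("benign", "malignant", "excluded"),
                times = c(n_benign, n_malignant, n_excluded)),
    split = "none", stringsAsFactors = FALSE)
}
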