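# Shared fixtures and independent oracles used across test files.

the_library <- spectral_library()

# Small synthetic image stack: value = wavelength index everywhere except a
# brighter square, useful for ROI arithmetic.
make_test_image <- function(nwl = 3, h = 4, w = 5, rois = list()) {
  stack <- array(0, c(nwl, h, w))
  for (i in seq_len(nwl)) stack[i, , ] <- i
  multispectral_image(stack, wavelength_grid(700, 700 + 10 * (nwl - 1), 10),
                      rois = rois)
}

# Independent brute-force AUROC: explicit loop over all (pos, neg) pairs.
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (x in pos) for (y in neg) {
    total <- total + (x > y) + 0.5 * (x == y)
  }
  total / (length(pos) * length(neg))
}

# Independent exhaustive Youden search: evaluate J at every threshold in a
# fine sweep over observed values and midpoints, tracking max J only.
youden_bruteforce_j <- function(scores, labels) {
  s <- sort(unique(scores))
  cands <- c(-Inf, s, (s[-length(s)] + s[-1]) / 2, Inf)
  best <- -Inf
  for (ct in cands) {
    pred <- scores >= ct
    se <- sum(pred & labels) / sum(labels)
    sp <- sum(!pred & !labels) / sum(!labels)
    best <- max(best, se + sp - 1)
  }
  best
}

# Normal-equations least-squares oracle (independent of qr-based unmix()).
normal_equations_fit <- function(X, y) {
  as.vector(solve(t(X) %*% X, t(X) %*% y))
}

# Noiseless bi-exponential clearance evaluated directly from the closed form.
biexp <- function(t, k_in, k_out, amplitude = 1, baseline = 0) {
  baseline + amplitude * (exp(-k_out * t) - exp(-k_in * t))
}
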