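# Shared fixture builders: everything is generated in code at test time.

# a filled disc mask in a square frame
disc_fixture <- function(radius, pad = 4) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  (rr - ctr)^2 + (cc - ctr)^2 <= radius^2
}

# one circular nucleus truth with k chromocenters, centred in the image
single_nucleus_truth <- function(radius = 25, k = 0, shape = c(96, 96),
                                 nucleus_intensity = 90, cc_intensity = 180,
                                 background_level = 10, noise_sd = 2,
                                 seed = 1) {
  set.seed(seed)
  cc <- empty_chromocenters()
  if (k > 0) {
    ang <- 2 * pi * (seq_len(k) - 1) / k
    rad <- 0.55 * radius
    cc <- data.frame(row = shape[1] / 2 + rad * cos(ang),
                     col = shape[2] / 2 + rad * sin(ang),
                     radius = 2.5, intensity = cc_intensity)
  }
  nucleus_truth(center = shape / 2, axes = c(radius, radius),
                nucleus_intensity = nucleus_intensity, chromocenters = cc,
                background_level = background_level, noise_sd = noise_sd)
}

# small 5-chromosome study-scale population helpers
study_map <- function() make_genetic_map(5, 100, 5)

null_phenotype <- function(n) stats::rnorm(n)
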