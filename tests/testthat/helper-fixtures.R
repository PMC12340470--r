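# Shared fixtures, built in code. The toy shape model is reused across
# test files; building it once keeps the suite fast.
toy_ssm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_toy_ssm(seed = 7, n_train = 50)
    cache
  }
})

# pure-R brute-force point-to-triangle distance, the oracle for the
# compiled closest-point kernel (region-by-region clamping of the
# quadratic, written independently of the C++ path)
brute_closest_distance <- function(p, mesh) {
  V <- mesh$vertices; F <- mesh$faces
  best <- Inf
  for (f in seq_len(nrow(F))) {
    a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; c <- V[F[f, 3], ]
    E0 <- b - a; E1 <- c - a; D <- a - p
    aa <- sum(E0 * E0); bb <- sum(E0 * E1); cc <- sum(E1 * E1)
    dd <- sum(E0 * D); ee <- sum(E1 * D)
    det <- aa * cc - bb * bb
    s <- bb * ee - cc * dd; t <- bb * dd - aa * ee
    if (s + t <= det && s >= 0 && t >= 0) {
      s <- s / det; t <- t / det
    } else {
      # clamp to the triangle boundary: check the three edges
      cand <- list()
      clamp01 <- function(x) min(1, max(0, x))
      s1 <- clamp01(-dd / aa); cand[[1]] <- c(s1, 0)
      t2 <- clamp01(-ee / cc); cand[[2]] <- c(0, t2)
      u <- clamp01((cc + ee - bb - dd) / (aa - 2 * bb + cc))
      cand[[3]] <- c(u, 1 - u)
      dbest <- Inf
      for (st in cand) {
        q <- a + st[1] * E0 + st[2] * E1
        dq <- sum((q - p)^2)
        if (dq < dbest) { dbest <- dq; s <- st[1]; t <- st[2] }
      }
    }
    q <- a + s * E0 + t * E1
    best <- min(best, sqrt(sum((q - p)^2)))
  }
  best
}

# annotation sampled (without noise) from a mesh surface
surface_annotation <- function(mesh, n = 100, seed = 1,
                               patient = "P", expert = "E",
                               method = "manual", session = 0) {
  set.seed(seed)
  pts <- sample_surface_points(mesh, n)
  point_annotation(patient, expert, method, session, pts,
                   mesh_landmarks(mesh))
}

# small cohort configuration used by the pipeline tests
tiny_cohort_config <- function(seed = 5)
  cohort_config(n_patients = 4, n_experts = 3, seed = seed,
                shared_subset_size = 3, bis_subset_size = 2,
                manual_points_range = c(60, 120),
                semi_auto_points_range = c(15, 25))

tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(tiny_cohort_config(), ssm = toy_ssm())
    cache
  }
})
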